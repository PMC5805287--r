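# End-to-end two-phase pipeline: holdout split, Phase I cross-validated
# evolution, Phase II pruning, test-set reporting.

#' Run the full two-phase classifier pipeline
#'
#' Splits the data 90/10 into training and test partitions (stratified and
#' patient-grouped), runs Phase I cross-validated evolution on the training
#' partition to build one classifier pool per fold, then prunes each fold's
#' pool with the Phase II genetic algorithm.  Pruning fitness uses the
#' fold's standardised view of the full training partition as `U`; the test
#' partition `V` is scored once per fold by the final ensemble.  Reported
#' measures follow the control-as-positive convention; for patient-grouped
#' data, record-level predictions are aggregated to individuals by strict
#' majority before scoring.
#'
#' @param data A [wnn_dataset()].
#' @param test_fraction Held-out test fraction (default 0.10).
#' @param n_folds,n_runs,mu,lambda,generations,n_wavelons,n_inputs,wavelet_set,mutation_rate,mutation_magnitude,standardize
#'   Phase I settings, passed to [run_phase1()].
#' @param prune_mu,prune_lambda,prune_generations,prune_mutation_rate
#'   Phase II settings, passed to [prune_ensemble()].
#' @param aggregate Aggregate record-level test predictions per patient
#'   before scoring (automatic only when patient ids exist).
#' @param seed Master seed controlling the split, both phases and all runs.
#' @return An object of class `wnn_two_phase`: a list with `phase1`
#'   (the [run_phase1()] result), `ensembles` (per-fold
#'   [prune_ensemble()] results), `te_acc`, `ete_acc` (mean over folds of
#'   the ensemble test accuracy), `individual_test_acc` (mean over all pool
#'   members of their accuracy on the test partition), `mean_ensemble_size`
#'   and the per-fold test metrics.
#' @export
run_two_phase <- function(data, test_fraction = 0.10,
                          n_folds = 10L, n_runs = 50L,
                          mu = 1L, lambda = 25L, generations = 2000L,
                          n_wavelons = 4L, n_inputs = NULL,
                          wavelet_set = "mexican_hat",
                          mutation_rate = 0.01, mutation_magnitude = 0.1,
                          standardize = TRUE,
                          prune_mu = 3L, prune_lambda = 25L,
                          prune_generations = 1000L,
                          prune_mutation_rate = 0.01,
                          aggregate = !is.null(data$patient_ids),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  split <- holdout_split(data, test_fraction = test_fraction)
  phase1_seed <- sample.int(2147483646L, 1)
  prune_seeds <- sample.int(2147483646L, n_folds)

  phase1 <- run_phase1(split$train, n_folds = n_folds, n_runs = n_runs,
                       mu = mu, lambda = lambda, generations = generations,
                       n_wavelons = n_wavelons, n_inputs = n_inputs,
                       wavelet_set = wavelet_set,
                       mutation_rate = mutation_rate,
                       mutation_magnitude = mutation_magnitude,
                       standardize = standardize, seed = phase1_seed)

  score <- function(pred, truth, ids) {
    if (aggregate && !is.null(ids)) {
      pred <- aggregate_patients(pred, ids)
      truth <- aggregate_patients(truth, ids)
    }
    cc <- confusion_counts(truth, pred)
    list(ete_acc = accuracy(cc), sensitivity = sensitivity(cc),
         specificity = specificity(cc), mcc = mcc(cc), confusion = cc)
  }

  ensembles <- vector("list", n_folds)
  fold_metrics <- vector("list", n_folds)
  indiv_acc <- numeric(0)
  for (f in seq_len(n_folds)) {
    fold <- phase1$folds[[f]]
    u <- split$train
    v <- split$test
    if (!is.null(fold$scaler)) {
      u <- apply_scaler(fold$scaler, u)
      v <- apply_scaler(fold$scaler, v)
    }
    ens <- prune_ensemble(fold$pool, u, mu = prune_mu, lambda = prune_lambda,
                          generations = prune_generations,
                          mutation_rate = prune_mutation_rate,
                          seed = prune_seeds[f])
    pred_v <- ensemble_predict(fold$pool, ens$mask, v)
    ens$test <- score(pred_v, v$labels, v$patient_ids)
    ensembles[[f]] <- ens
    fold_metrics[[f]] <- ens$test
    votes_v <- pool_votes(fold$pool, v)
    indiv_acc <- c(indiv_acc, colMeans(votes_v == v$labels))
  }

  structure(
    list(phase1 = phase1, ensembles = ensembles,
         split = split,
         te_acc = phase1$te_acc,
         ete_acc = mean(vapply(fold_metrics, `[[`, numeric(1), "ete_acc")),
         individual_test_acc = mean(indiv_acc),
         mean_ensemble_size = ensemble_size_summary(
           lapply(ensembles, `[[`, "mask")),
         fold_metrics = fold_metrics),
    class = "wnn_two_phase"
  )
}

#' @export
print.wnn_two_phase <- function(x, ...) {
  cat("Two-phase EWNN ensemble\n")
  cat("  Phase I  mean validation accuracy (Te_acc): ",
      sprintf("%.1f%%", 100 * x$te_acc), "\n")
  cat("  Phase II mean ensemble test accuracy (ETe_acc): ",
      sprintf("%.1f%%", 100 * x$ete_acc), "\n")
  cat("  mean individual test accuracy: ",
      sprintf("%.1f%%", 100 * x$individual_test_acc), "\n")
  cat("  mean ensemble size: ", sprintf("%.2f", x$mean_ensemble_size),
      "of", x$ensembles[[1]]$pool_size, "\n")
  invisible(x)
}
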