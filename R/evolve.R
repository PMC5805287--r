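# Phase I: (mu+lambda) evolution strategy over wavelet-network genomes, and
# the cross-validation harness that produces a classifier pool.

#' Evaluate a genome on a dataset
#'
#' Computes the two fitness criteria of the evolution strategy: the
#' classification accuracy (fraction of records whose thresholded output
#' matches the label) and the mean squared error of the raw output against
#' the 0/1 targets.
#'
#' @param genome A [wnn_genome][init_genome].
#' @param data A [wnn_dataset()] with matching feature count.
#' @return A list with components `accuracy` and `mse`.
#' @export
evaluate_genome <- function(genome, data) {
  out <- predict(genome, data)
  pred <- as.integer(out >= 0.5)
  list(accuracy = mean(pred == data$labels),
       mse = mean((out - data$labels)^2))
}

#' Rank a population by accuracy, then mean squared error
#'
#' Two-dimensional sorting promotes networks that do well on both criteria:
#' the primary key is accuracy (descending), ties are broken by MSE
#' (ascending), and remaining ties keep their original order (stable), so
#' the first element is the individual promoted as parent.
#'
#' @param evals A list of evaluation records (each with `accuracy` and
#'   `mse`), as returned by [evaluate_genome()].
#' @return An integer permutation ordering the population best-first.
#' @export
sort_population <- function(evals) {
  acc <- vapply(evals, `[[`, numeric(1), "accuracy")
  mse <- vapply(evals, `[[`, numeric(1), "mse")
  if (any(!is.finite(acc)) || any(!is.finite(mse))) {
    stop("non-finite evaluation record", call. = FALSE)
  }
  order(-acc, mse)
}

#' Evolve a wavelet neural network with a (mu+lambda) evolution strategy
#'
#' All network parameters evolve concurrently; there is no gradient step and
#' no recombination.  Each generation, every individual is evaluated on the
#' training data, parents and offspring are ranked together by accuracy then
#' MSE ([sort_population()]), the best `mu` survive (elitism), and `lambda`
#' offspring are produced by mutating parents drawn uniformly.  The loop
#' runs for a fixed `generations` budget.
#'
#' @param data Training [wnn_dataset()].
#' @param mu,lambda Parent and offspring counts, e.g. `(1+25)` or `(3+20)`.
#' @param generations Number of generations (default 2000).
#' @param n_wavelons,n_inputs,wavelet_set Genome structure, passed to
#'   [init_genome()].
#' @param mutation_rate,mutation_magnitude Passed to [mutate_genome()].
#' @param seed Optional seed; the same seed reproduces the run exactly.
#' @return An object of class `wnn_evolution`: a list with `best` (the final
#'   parent genome), `best_eval` (its accuracy and MSE) and `trajectory` (a
#'   data frame with the best accuracy and MSE per generation).
#' @examples
#' \donttest{
#' sp <- two_spiral()
#' run <- evolve_wnn(sp, generations = 50, n_wavelons = 2,
#'                   wavelet_set = "morlet", seed = 1)
#' run$best_eval$accuracy
#' }
#' @export
evolve_wnn <- function(data, mu = 1L, lambda = 25L, generations = 2000L,
                       n_wavelons = 4L, n_inputs = NULL,
                       wavelet_set = "mexican_hat",
                       mutation_rate = 0.01, mutation_magnitude = 0.1,
                       seed = NULL) {
  stopifnot(inherits(data, "wnn_dataset"), mu >= 1L, lambda >= 1L,
            generations >= 1L, length(data$labels) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  n_features <- ncol(data$features)
  if (is.null(n_inputs)) n_inputs <- n_features

  parents <- replicate(
    mu,
    init_genome(n_features, n_wavelons = n_wavelons, n_inputs = n_inputs,
                wavelet_set = wavelet_set),
    simplify = FALSE
  )
  p_eval <- lapply(parents, evaluate_genome, data = data)
  ord <- sort_population(p_eval)
  parents <- parents[ord]
  p_eval <- p_eval[ord]

  traj_acc <- numeric(generations)
  traj_mse <- numeric(generations)
  for (gen in seq_len(generations)) {
    idx <- if (mu == 1L) rep(1L, lambda) else sample.int(mu, lambda, replace = TRUE)
    offspring <- lapply(idx, function(i) {
      mutate_genome(parents[[i]], mutation_rate, mutation_magnitude)
    })
    o_eval <- lapply(offspring, evaluate_genome, data = data)
    all_g <- c(parents, offspring)
    all_e <- c(p_eval, o_eval)
    keep <- sort_population(all_e)[seq_len(mu)]
    parents <- all_g[keep]
    p_eval <- all_e[keep]
    traj_acc[gen] <- p_eval[[1L]]$accuracy
    traj_mse[gen] <- p_eval[[1L]]$mse
  }
  structure(
    list(best = parents[[1L]], best_eval = p_eval[[1L]],
         trajectory = data.frame(generation = seq_len(generations),
                                 accuracy = traj_acc, mse = traj_mse)),
    class = "wnn_evolution"
  )
}

#' @export
print.wnn_evolution <- function(x, ...) {
  cat("WNN evolution:", nrow(x$trajectory), "generations; best accuracy",
      sprintf("%.4f", x$best_eval$accuracy), "mse",
      sprintf("%.4f", x$best_eval$mse), "\n")
  invisible(x)
}

#' Phase I: build classifier pools by cross-validated evolution
#'
#' Runs stratified (patient-grouped, when identifiers exist) k-fold
#' cross-validation over the training partition.  Within each fold,
#' `n_runs` independent evolution-strategy runs are executed on the
#' fold-train split; the best genome of each run joins that fold's
#' classifier pool (pool size = `n_runs`) and is scored once on the
#' fold-validation split.  The grand mean of those validation accuracies is
#' the reported individual-classifier test accuracy `Te_acc`.  Features are
#' z-scored per fold (fitted on the fold-train split only) unless
#' `standardize = FALSE`.
#'
#' Reproducibility: per-run seeds are drawn up-front from the master seed
#' (`set.seed(seed)` followed by one `sample.int()` of `n_folds * n_runs`
#' seeds, laid out fold-by-fold), so any single run can be replayed in
#' isolation from its seed in the manifest.
#'
#' @param data Training [wnn_dataset()].
#' @param n_folds Number of cross-validation folds (default 10).
#' @param n_runs Independent evolutionary runs per fold (default 50).
#' @param standardize Fit a per-fold feature scaler on the fold-train split.
#' @param seed Master seed.
#' @inheritParams evolve_wnn
#' @return An object of class `wnn_phase1`: a list with `folds` (per fold:
#'   `pool`, `scaler`, `fold` record index) , `manifest` (fold, run, seed,
#'   training and validation scores per pool member), `te_acc` (grand mean
#'   validation accuracy) and `fold_te_acc`.
#' @export
run_phase1 <- function(data, n_folds = 10L, n_runs = 50L,
                       mu = 1L, lambda = 25L, generations = 2000L,
                       n_wavelons = 4L, n_inputs = NULL,
                       wavelet_set = "mexican_hat",
                       mutation_rate = 0.01, mutation_magnitude = 0.1,
                       standardize = TRUE, seed = NULL) {
  stopifnot(inherits(data, "wnn_dataset"), n_folds >= 2L, n_runs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  fold_id <- make_folds(data, n_folds)
  run_seeds <- matrix(sample.int(2147483646L, n_folds * n_runs),
                      nrow = n_folds, ncol = n_runs)

  folds <- vector("list", n_folds)
  manifest <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    in_val <- fold_id == f
    if (!is.null(data$patient_ids)) {
      leaked <- intersect(unique(data$patient_ids[in_val]),
                          unique(data$patient_ids[!in_val]))
      if (length(leaked)) {
        stop("internal error: patient(s) ", paste(leaked, collapse = ", "),
             " span fold ", f, call. = FALSE)
      }
    }
    tr <- dataset_subset(data, !in_val)
    va <- dataset_subset(data, in_val)
    scaler <- NULL
    if (standardize) {
      scaler <- fit_scaler(tr)
      tr <- apply_scaler(scaler, tr)
      va <- apply_scaler(scaler, va)
    }
    pool <- vector("list", n_runs)
    rows <- vector("list", n_runs)
    for (r in seq_len(n_runs)) {
      run <- evolve_wnn(tr, mu = mu, lambda = lambda,
                        generations = generations, n_wavelons = n_wavelons,
                        n_inputs = n_inputs, wavelet_set = wavelet_set,
                        mutation_rate = mutation_rate,
                        mutation_magnitude = mutation_magnitude,
                        seed = run_seeds[f, r])
      pool[[r]] <- run$best
      val <- evaluate_genome(run$best, va)
      rows[[r]] <- data.frame(fold = f, run = r, seed = run_seeds[f, r],
                              train_accuracy = run$best_eval$accuracy,
                              train_mse = run$best_eval$mse,
                              val_accuracy = val$accuracy)
    }
    folds[[f]] <- list(pool = pool, scaler = scaler, val_index = which(in_val))
    manifest[[f]] <- do.call(rbind, rows)
  }
  manifest <- do.call(rbind, manifest)
  fold_te_acc <- tapply(manifest$val_accuracy, manifest$fold, mean)
  structure(
    list(folds = folds, manifest = manifest,
         te_acc = mean(manifest$val_accuracy),
         fold_te_acc = as.numeric(fold_te_acc)),
    class = "wnn_phase1"
  )
}

#' @export
print.wnn_phase1 <- function(x, ...) {
  cat("Phase I pools:", length(x$folds), "folds x",
      length(x$folds[[1]]$pool), "runs; mean Te_acc",
      sprintf("%.4f", x$te_acc), "\n")
  invisible(x)
}
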