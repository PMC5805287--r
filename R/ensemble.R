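# Phase II: majority-vote ensembles and GA-based pruning of a classifier
# pool.

# 0/1 vote matrix (records x classifiers) of a pool on a dataset.
pool_votes <- function(pool, data) {
  v <- vapply(pool, function(g) predict(g, data, type = "class"),
              integer(length(data$labels)))
  if (!is.matrix(v)) v <- matrix(v, nrow = 1L)
  v
}

# Strict-majority vote over the columns of a 0/1 vote matrix: class 1 wins
# only when it gets strictly more than half of the k votes; an even split
# returns 0.
majority_vote <- function(votes) {
  votes <- as.matrix(votes)
  as.integer(rowSums(votes) > ncol(votes) / 2)
}

#' Majority vote of a pruned ensemble on one record
#'
#' The active classifiers (mask bits set to 1) each cast a 0/1 vote; the
#' ensemble returns 1 only when the number of votes for class 1 strictly
#' exceeds half of the active-classifier count `k`.  With even `k`, a split
#' vote therefore returns 0 (control).
#'
#' @param pool A list of [wnn_genome][init_genome] classifiers.
#' @param mask 0/1 integer vector of length `length(pool)`; at least one bit
#'   must be set.
#' @param x Numeric feature vector.
#' @return Integer label, 0 or 1.
#' @export
ensemble_vote <- function(pool, mask, x) {
  stopifnot(length(mask) == length(pool))
  if (active_count(mask) == 0L) stop("empty ensemble", call. = FALSE)
  votes <- vapply(pool[mask == 1L], classify, integer(1), x = x)
  as.integer(sum(votes) > length(votes) / 2)
}

#' Batch majority-vote prediction of a pruned ensemble
#'
#' @inheritParams ensemble_vote
#' @param data A [wnn_dataset()].
#' @return Integer vector of 0/1 labels, one per record.
#' @export
ensemble_predict <- function(pool, mask, data) {
  stopifnot(length(mask) == length(pool))
  if (active_count(mask) == 0L) stop("empty ensemble", call. = FALSE)
  majority_vote(pool_votes(pool[mask == 1L], data))
}

#' Number of active classifiers in a mask
#'
#' @param mask 0/1 integer vector.
#' @return Count of set bits.
#' @export
active_count <- function(mask) {
  sum(mask == 1L)
}

# Fast fitness used inside the GA: votes and individual training accuracies
# are precomputed once per pruning run.
prune_fitness_votes <- function(mask, votes, labels, indiv_acc) {
  act <- which(mask == 1L)
  if (length(act) == 0L) return(0)
  ens <- as.integer(rowSums(votes[, act, drop = FALSE]) > length(act) / 2)
  0.5 * (mean(indiv_acc[act]) + mean(ens == labels))
}

#' Pruning fitness of an ensemble mask
#'
#' The fitness of a candidate ensemble is the average of two training-set
#' accuracies: the mean individual accuracy `Tr_acc` of the active
#' classifiers, and the accuracy `Ens(U)` of their strict-majority vote:
#' `FE = 0.5 * (Tr_acc + Ens(U))`.  An empty mask scores 0, which keeps the
#' genetic algorithm total and drives it away from degenerate ensembles.
#'
#' @inheritParams ensemble_vote
#' @param data Training [wnn_dataset()] `U`.
#' @return Fitness in `[0, 1]`.
#' @export
prune_fitness <- function(mask, pool, data) {
  stopifnot(length(mask) == length(pool))
  if (active_count(mask) == 0L) return(0)
  votes <- pool_votes(pool, data)
  indiv_acc <- colMeans(votes == data$labels)
  prune_fitness_votes(mask, votes, data$labels, indiv_acc)
}

#' Phase II: prune a classifier pool into a voting ensemble
#'
#' A (3+25) elitist genetic algorithm searches over bit masks selecting
#' pool members.  Parents start as i.i.d. Bernoulli(0.5) bit strings;
#' offspring are produced by independent per-bit inversion at
#' `mutation_rate`; parents and offspring are ranked together by the
#' pruning fitness ([prune_fitness()]) computed on the training set `U`
#' only, with ties broken in favour of fewer active classifiers (smaller
#' ensembles), and the best `mu` survive.  The held-out set `V` is touched
#' exactly once, after the final generation, to report the best ensemble's
#' test accuracy `ETe_acc`, sensitivity, specificity and MCC.
#'
#' @param pool A list of [wnn_genome][init_genome] classifiers.
#' @param train_data Training [wnn_dataset()] `U` driving the fitness.
#' @param test_data Optional held-out [wnn_dataset()] `V`; scored once at
#'   the end.
#' @param mu,lambda Parent and offspring counts (default 3 and 25).
#' @param generations GA budget (default 1000).
#' @param mutation_rate Per-bit inversion probability (default 1\%).
#' @param seed Optional seed; the same seed reproduces the mask exactly.
#' @return An object of class `wnn_ensemble`: a list with `mask` (best bit
#'   string), `fitness`, `n_active`, `trajectory` (best fitness per
#'   generation) and, when `test_data` is given, `test` (a list with
#'   `ete_acc`, `sensitivity`, `specificity`, `mcc` and the
#'   [confusion_counts()]).
#' @export
prune_ensemble <- function(pool, train_data, test_data = NULL,
                           mu = 3L, lambda = 25L, generations = 1000L,
                           mutation_rate = 0.01, seed = NULL) {
  stopifnot(length(pool) >= 1L, inherits(train_data, "wnn_dataset"),
            mu >= 1L, lambda >= 1L, generations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  k <- length(pool)
  votes_u <- pool_votes(pool, train_data)
  labels_u <- train_data$labels
  indiv_acc <- colMeans(votes_u == labels_u)

  parents <- matrix(rbinom(mu * k, 1L, 0.5), nrow = mu, ncol = k)
  p_fit <- apply(parents, 1, prune_fitness_votes,
                 votes = votes_u, labels = labels_u, indiv_acc = indiv_acc)
  ord <- order(-p_fit, rowSums(parents))
  parents <- parents[ord, , drop = FALSE]
  p_fit <- p_fit[ord]

  traj <- numeric(generations)
  for (gen in seq_len(generations)) {
    idx <- sample.int(mu, lambda, replace = TRUE)
    flip <- matrix(runif(lambda * k) < mutation_rate, lambda, k)
    offspring <- abs(parents[idx, , drop = FALSE] - flip)
    o_fit <- apply(offspring, 1, prune_fitness_votes,
                   votes = votes_u, labels = labels_u, indiv_acc = indiv_acc)
    all_m <- rbind(parents, offspring)
    all_f <- c(p_fit, o_fit)
    keep <- order(-all_f, rowSums(all_m))[seq_len(mu)]
    parents <- all_m[keep, , drop = FALSE]
    p_fit <- all_f[keep]
    traj[gen] <- p_fit[1L]
  }

  mask <- as.integer(parents[1L, ])
  res <- list(mask = mask, fitness = p_fit[1L], n_active = active_count(mask),
              pool_size = k, trajectory = traj)
  if (!is.null(test_data)) {
    pred_v <- ensemble_predict(pool, mask, test_data)
    cc <- confusion_counts(test_data$labels, pred_v)
    res$test <- list(ete_acc = accuracy(cc),
                     sensitivity = sensitivity(cc),
                     specificity = specificity(cc),
                     mcc = mcc(cc),
                     confusion = cc)
  }
  structure(res, class = "wnn_ensemble")
}

#' @export
print.wnn_ensemble <- function(x, ...) {
  cat("Pruned ensemble:", x$n_active, "of", x$pool_size,
      "classifiers active; fitness", sprintf("%.4f", x$fitness), "\n")
  if (!is.null(x$test)) {
    cat("  test:", metrics_row(ete_acc = x$test$ete_acc,
                               sens = x$test$sensitivity,
                               spec = x$test$specificity,
                               mcc = x$test$mcc), "\n")
  }
  invisible(x)
}
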