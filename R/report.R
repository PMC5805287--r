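# Post-hoc analyses of pools and ensembles: feature connectivity, wavelon
# dimensionality and ensemble size.

mask_pool <- function(pool, mask) {
  if (is.null(mask)) return(pool)
  stopifnot(length(mask) == length(pool))
  pool[mask == 1L]
}

#' Average feature connectivity of a pool
#'
#' A feature counts as connected to a wavelon only when the wavelon is
#' active (`ot = 1`) AND an input slot with its switch on (`c = 1`) points
#' at that feature; silent wavelons contribute nothing.  Returns, for each
#' feature, the mean number of such connections per network, averaged over
#' the pool (or over the active classifiers when a mask is given).
#'
#' @param pool A list of [wnn_genome][init_genome] classifiers.
#' @param mask Optional 0/1 ensemble mask restricting the pool to its active
#'   members.
#' @return Named numeric vector, one mean connection count per feature.
#' @export
feature_connectivity <- function(pool, mask = NULL) {
  pool <- mask_pool(pool, mask)
  stopifnot(length(pool) >= 1L)
  n_features <- pool[[1L]]$n_features
  counts <- vapply(pool, function(g) {
    act <- which(g$ot == 1L)
    connected <- g$feat[, act, drop = FALSE][g$switch[, act, drop = FALSE] == 1L]
    tabulate(connected, nbins = n_features)
  }, numeric(n_features))
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  out <- rowMeans(counts)
  names(out) <- paste0("f", seq_len(n_features))
  out
}

#' Wavelon dimensionality histogram of a pool
#'
#' The dimensionality of a wavelon is its number of connected inputs
#' (switches on).  Counts active wavelons by dimensionality, summed over
#' all networks of the pool (or of the masked sub-pool).
#'
#' @inheritParams feature_connectivity
#' @return Named integer vector of counts for dimensionalities
#'   `0, 1, ..., n_inputs`; sums to the total number of active wavelons.
#' @export
wavelon_dimensionality <- function(pool, mask = NULL) {
  pool <- mask_pool(pool, mask)
  stopifnot(length(pool) >= 1L)
  n_inputs <- pool[[1L]]$n_inputs
  hist <- integer(n_inputs + 1L)
  for (g in pool) {
    for (m in which(g$ot == 1L)) {
      d <- sum(g$switch[, m] == 1L)
      hist[d + 1L] <- hist[d + 1L] + 1L
    }
  }
  names(hist) <- 0:n_inputs
  hist
}

#' Mean ensemble size across pruning runs
#'
#' @param masks A list of 0/1 ensemble masks (e.g. one per fold or per
#'   independent pruning run).
#' @return Mean number of active classifiers.
#' @export
ensemble_size_summary <- function(masks) {
  stopifnot(length(masks) >= 1L)
  mean(vapply(masks, active_count, numeric(1)))
}
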