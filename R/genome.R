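# Genome encoding, initialisation, mutation and (de)serialisation.

GENOME_SCHEMA <- "wnn_genome"
POOL_SCHEMA <- "wnn_pool"
SCHEMA_VERSION <- 1L

new_wnn_genome <- function(n_features, n_wavelons, n_inputs, wavelet_set,
                           feat, switch, w, alpha, beta, rotation,
                           psi, wt, ot, a, theta) {
  structure(
    list(
      n_features = as.integer(n_features),
      n_wavelons = as.integer(n_wavelons),
      n_inputs = as.integer(n_inputs),
      wavelet_set = wavelet_set,
      feat = feat, switch = switch, w = w, alpha = alpha, beta = beta,
      rotation = rotation, psi = psi, wt = wt, ot = ot, a = a, theta = theta
    ),
    class = "wnn_genome"
  )
}

#' Initialise a random wavelet-network genome
#'
#' A genome fully parameterises one wavelet neural network.  Each of the
#' `n_wavelons` hidden units carries `n_inputs` input slots; slot `n` of
#' wavelon `m` has a feature index `feat` in `[1, n_features]`, a
#' connection switch `c` in `{0, 1}`, an input weight `w` in `[-1, 1]`, a
#' dilation `alpha` in `[0, 1]`, an unbounded translation `beta`, and a
#' rotation `R` in `[-1, 1]`.  Each wavelon additionally carries its wavelet
#' identity `psi` (an index into `wavelet_set`), its output weight `wt` in
#' `[-1, 1]` and an activity flag `ot` in `{0, 1}`.  The network-level genes
#' are the shortcut weights `a` (one per feature, in `[-1, 1]`) and the bias
#' `theta` in `[-1, 1]`.
#'
#' All bounded genes are drawn uniformly over their ranges.  The translation
#' is unbounded, so it is drawn from a standard normal proposal: with
#' standardised inputs that is the region where translations are useful, and
#' mutation can move it anywhere from there.
#'
#' @param n_features Number of input features of the task.
#' @param n_wavelons Number of hidden wavelons (fixed for the genome's life).
#' @param n_inputs Number of input slots per wavelon; defaults to
#'   `n_features`.  Fewer slots than features forces sparser wavelons.
#' @param wavelet_set Character vector of allowed activation identities,
#'   a subset of `c("morlet", "mexican_hat", "gauss1", "haar")`.
#' @param seed Optional integer seed for reproducible initialisation.
#' @return An object of class `wnn_genome`.
#' @examples
#' g <- init_genome(n_features = 6, n_wavelons = 4,
#'                  wavelet_set = c("morlet", "mexican_hat"), seed = 1)
#' network_output(g, rnorm(6))
#' @export
init_genome <- function(n_features, n_wavelons = 4L, n_inputs = n_features,
                        wavelet_set = "mexican_hat", seed = NULL) {
  if (length(wavelet_set) == 0L) {
    stop("wavelet_set must name at least one wavelet function", call. = FALSE)
  }
  bad <- setdiff(wavelet_set, names(wavelet_codes))
  if (length(bad)) {
    stop("unknown wavelet function(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(n_features >= 1L, n_wavelons >= 1L, n_inputs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  I <- as.integer(n_inputs)
  M <- as.integer(n_wavelons)
  Fn <- as.integer(n_features)
  new_wnn_genome(
    n_features = Fn, n_wavelons = M, n_inputs = I, wavelet_set = wavelet_set,
    feat = matrix(sample.int(Fn, I * M, replace = TRUE), I, M),
    switch = matrix(sample(0:1, I * M, replace = TRUE), I, M),
    w = matrix(runif(I * M, -1, 1), I, M),
    alpha = matrix(runif(I * M, 0, 1), I, M),
    beta = matrix(rnorm(I * M), I, M),
    rotation = matrix(runif(I * M, -1, 1), I, M),
    psi = sample.int(length(wavelet_set), M, replace = TRUE),
    wt = runif(M, -1, 1),
    ot = sample(0:1, M, replace = TRUE),
    a = runif(Fn, -1, 1),
    theta = runif(1, -1, 1)
  )
}

#' @export
print.wnn_genome <- function(x, ...) {
  cat("Wavelet neural network genome\n")
  cat("  features:", x$n_features, " wavelons:", x$n_wavelons,
      "(", sum(x$ot == 1L), "active )  slots/wavelon:", x$n_inputs, "\n")
  cat("  wavelet set:", paste(x$wavelet_set, collapse = ", "), "\n")
  invisible(x)
}

# Perturb continuous genes selected at `rate`: g <- g + U(-mag, mag) * g,
# clamped to [lo, hi] (pass lo = NULL for unclamped genes).  A gene exactly 0
# would be stuck under multiplicative perturbation, so it gets an additive
# U(-0.01, 0.01) kick instead.
mutate_continuous <- function(x, rate, magnitude, lo = NULL, hi = NULL) {
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    xi <- x[hit]
    delta <- runif(length(hit), -magnitude, magnitude) * xi
    zero <- xi == 0
    if (any(zero)) delta[zero] <- runif(sum(zero), -0.01, 0.01)
    xi <- xi + delta
    if (!is.null(lo)) xi <- pmin(pmax(xi, lo), hi)
    x[hit] <- xi
  }
  x
}

mutate_binary <- function(x, rate) {
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) x[hit] <- 1L - x[hit]
  x
}

# Resample a categorical gene uniformly among the *other* members of a
# k-member list.  With a single member there is nothing to change to.
mutate_categorical <- function(x, rate, k) {
  if (k < 2L) return(x)
  hit <- which(runif(length(x)) < rate)
  if (length(hit)) {
    r <- sample.int(k - 1L, length(hit), replace = TRUE)
    x[hit] <- r + (r >= x[hit])
  }
  x
}

#' Mutate a genome
#'
#' Every gene is independently selected for mutation with probability
#' `rate`.  Selected genes mutate by type: continuous genes (input weights,
#' dilations, translations, rotations, wavelon weights, shortcut weights,
#' bias) are perturbed by adding a uniform fraction of up to `magnitude` of
#' their current value, then clamped back to their range (the translation is
#' unbounded and never clamped; a gene exactly at 0 receives a small additive
#' kick so it can escape zero); binary genes (switches, activity flags) are
#' inverted; categorical genes (feature indices, wavelet identities) are
#' resampled uniformly among the other members of their list.  The parent is
#' not modified.
#'
#' @param genome A [wnn_genome][init_genome].
#' @param rate Per-gene mutation probability (the evolution strategy uses 1\%).
#' @param magnitude Relative perturbation bound for continuous genes.
#' @return A new mutated `wnn_genome`.
#' @export
mutate_genome <- function(genome, rate = 0.01, magnitude = 0.1) {
  stopifnot(inherits(genome, "wnn_genome"), rate >= 0, rate <= 1)
  g <- genome
  g$w <- mutate_continuous(g$w, rate, magnitude, -1, 1)
  g$alpha <- mutate_continuous(g$alpha, rate, magnitude, 0, 1)
  g$beta <- mutate_continuous(g$beta, rate, magnitude)
  g$rotation <- mutate_continuous(g$rotation, rate, magnitude, -1, 1)
  g$wt <- mutate_continuous(g$wt, rate, magnitude, -1, 1)
  g$a <- mutate_continuous(g$a, rate, magnitude, -1, 1)
  g$theta <- mutate_continuous(g$theta, rate, magnitude, -1, 1)
  g$switch <- mutate_binary(g$switch, rate)
  g$ot <- mutate_binary(g$ot, rate)
  g$feat <- mutate_categorical(g$feat, rate, g$n_features)
  g$psi <- mutate_categorical(g$psi, rate, length(g$wavelet_set))
  g
}

# ---- validation ------------------------------------------------------------

check_range <- function(x, lo, hi, field) {
  if (any(!is.finite(x)) || any(x < lo) || any(x > hi)) {
    stop("genome field '", field, "' out of range [", lo, ", ", hi, "]",
         call. = FALSE)
  }
}

validate_genome <- function(g) {
  if (!all(c("n_features", "n_wavelons", "n_inputs", "wavelet_set", "feat",
             "switch", "w", "alpha", "beta", "rotation", "psi", "wt", "ot",
             "a", "theta") %in% names(g))) {
    stop("genome is missing required fields", call. = FALSE)
  }
  I <- g$n_inputs; M <- g$n_wavelons; Fn <- g$n_features
  for (field in c("feat", "switch", "w", "alpha", "beta", "rotation")) {
    if (!is.matrix(g[[field]]) || nrow(g[[field]]) != I || ncol(g[[field]]) != M) {
      stop("genome field '", field, "' must be a ", I, "x", M, " matrix",
           call. = FALSE)
    }
  }
  if (length(g$psi) != M || length(g$wt) != M || length(g$ot) != M) {
    stop("genome per-wavelon fields must have length ", M, call. = FALSE)
  }
  if (length(g$a) != Fn) {
    stop("genome field 'a' must have length ", Fn, call. = FALSE)
  }
  check_range(g$feat, 1L, Fn, "feat")
  if (!all(g$switch %in% c(0L, 1L))) {
    stop("genome field 'switch' must be 0 or 1", call. = FALSE)
  }
  if (!all(g$ot %in% c(0L, 1L))) {
    stop("genome field 'ot' must be 0 or 1", call. = FALSE)
  }
  check_range(g$w, -1, 1, "w")
  check_range(g$alpha, 0, 1, "alpha")
  if (any(!is.finite(g$beta))) stop("genome field 'beta' must be finite", call. = FALSE)
  check_range(g$rotation, -1, 1, "rotation")
  check_range(g$psi, 1L, length(g$wavelet_set), "psi")
  check_range(g$wt, -1, 1, "wt")
  check_range(g$a, -1, 1, "a")
  check_range(g$theta, -1, 1, "theta")
  invisible(g)
}

# ---- serialisation ---------------------------------------------------------

# Continuous genes are stored as decimal strings with 17 significant digits,
# which round-trips IEEE doubles exactly.
fmt_full <- function(x) {
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  out
}

genome_to_list <- function(g) {
  list(
    schema = GENOME_SCHEMA, version = SCHEMA_VERSION,
    n_features = g$n_features, n_wavelons = g$n_wavelons,
    n_inputs = g$n_inputs, wavelet_set = as.list(g$wavelet_set),
    feat = g$feat, switch = g$switch, w = fmt_full(g$w),
    alpha = fmt_full(g$alpha), beta = fmt_full(g$beta),
    rotation = fmt_full(g$rotation),
    psi = g$psi, wt = fmt_full(g$wt), ot = g$ot, a = fmt_full(g$a),
    theta = fmt_full(g$theta)
  )
}

as_gene_matrix <- function(x, I, M, field, integer = FALSE) {
  x <- if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
  if (length(x) != I * M) {
    stop("genome field '", field, "' has wrong size", call. = FALSE)
  }
  x <- matrix(if (integer) as.integer(x) else as.numeric(x), I, M)
  if (any(is.na(x))) stop("genome field '", field, "' is malformed", call. = FALSE)
  x
}

genome_from_list <- function(lst) {
  for (field in c("schema", "n_features", "n_wavelons", "n_inputs",
                  "wavelet_set", "theta")) {
    if (is.null(lst[[field]])) {
      stop("genome text is missing field '", field, "'", call. = FALSE)
    }
  }
  if (!identical(as.character(lst$schema), GENOME_SCHEMA)) {
    stop("unexpected schema '", lst$schema, "' (field 'schema')", call. = FALSE)
  }
  I <- as.integer(lst$n_inputs); M <- as.integer(lst$n_wavelons)
  g <- new_wnn_genome(
    n_features = lst$n_features, n_wavelons = M, n_inputs = I,
    wavelet_set = as.character(unlist(lst$wavelet_set)),
    feat = as_gene_matrix(lst$feat, I, M, "feat", integer = TRUE),
    switch = as_gene_matrix(lst$switch, I, M, "switch", integer = TRUE),
    w = as_gene_matrix(lst$w, I, M, "w"),
    alpha = as_gene_matrix(lst$alpha, I, M, "alpha"),
    beta = as_gene_matrix(lst$beta, I, M, "beta"),
    rotation = as_gene_matrix(lst$rotation, I, M, "rotation"),
    psi = as.integer(unlist(lst$psi)),
    wt = as.numeric(unlist(lst$wt)),
    ot = as.integer(unlist(lst$ot)),
    a = as.numeric(unlist(lst$a)),
    theta = as.numeric(lst$theta)
  )
  validate_genome(g)
}

#' Read and write genomes and classifier pools
#'
#' Genomes are stored as structured JSON text with an explicit schema tag and
#' full numeric precision, so a write/read round trip reproduces every gene
#' exactly.  A pool file holds an array of genomes together with a manifest
#' (fold, run, seed and training/validation scores per member).
#'
#' @param genome A [wnn_genome][init_genome].
#' @param path File path.
#' @return `read_genome()` returns a validated `wnn_genome`; `read_pool()`
#'   returns a `wnn_pool` (list with `genomes` and `manifest`).
#' @name genome_io
NULL

#' @rdname genome_io
#' @export
write_genome <- function(genome, path) {
  validate_genome(genome)
  jsonlite::write_json(genome_to_list(genome), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname genome_io
#' @export
read_genome <- function(path) {
  genome_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' @rdname genome_io
#' @param pool A list of `wnn_genome` objects (e.g. one fold's pool from
#'   [run_phase1()]).
#' @param manifest Optional data frame of per-member metadata.
#' @export
write_pool <- function(pool, path, manifest = NULL) {
  lapply(pool, validate_genome)
  obj <- list(
    schema = POOL_SCHEMA, version = SCHEMA_VERSION,
    genomes = lapply(pool, genome_to_list)
  )
  if (!is.null(manifest)) obj$manifest <- manifest
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname genome_io
#' @export
read_pool <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(as.character(lst$schema), POOL_SCHEMA)) {
    stop("unexpected schema '", lst$schema, "' (field 'schema')", call. = FALSE)
  }
  genomes <- lapply(lst$genomes, genome_from_list)
  manifest <- if (!is.null(lst$manifest)) {
    as.data.frame(lapply(lst$manifest, unlist), stringsAsFactors = FALSE)
  }
  structure(list(genomes = genomes, manifest = manifest), class = "wnn_pool")
}
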