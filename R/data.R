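# Datasets: container, benchmark and synthetic generators, I/O, splitting.

#' Binary-classification dataset container
#'
#' @param features Numeric matrix (records x features); must be finite.
#' @param labels Integer vector of class labels, 0 = control, 1 = diseased.
#' @param patient_ids Optional vector of per-record individual identifiers.
#'   When present, splitting and cross-validation keep all records of an
#'   individual on the same side of every split.
#' @param feature_names Optional feature names; defaults to the column names
#'   of `features` or `f1, f2, ...`.
#' @return An object of class `wnn_dataset`.
#' @export
wnn_dataset <- function(features, labels, patient_ids = NULL,
                        feature_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  labels <- as.integer(labels)
  if (nrow(features) != length(labels)) {
    stop("features has ", nrow(features), " rows but labels has length ",
         length(labels), call. = FALSE)
  }
  if (any(!is.finite(features))) {
    stop("features must be finite", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0 (control) or 1 (diseased)", call. = FALSE)
  }
  if (!is.null(patient_ids) && length(patient_ids) != length(labels)) {
    stop("patient_ids must have one entry per record", call. = FALSE)
  }
  if (is.null(feature_names)) {
    feature_names <- colnames(features)
    if (is.null(feature_names)) {
      feature_names <- paste0("f", seq_len(ncol(features)))
    }
  }
  colnames(features) <- feature_names
  structure(
    list(features = features, labels = labels,
         patient_ids = if (!is.null(patient_ids)) as.character(patient_ids),
         feature_names = feature_names),
    class = "wnn_dataset"
  )
}

#' @export
print.wnn_dataset <- function(x, ...) {
  cat("wnn_dataset:", nrow(x$features), "records,", ncol(x$features),
      "features (control:", sum(x$labels == 0L),
      " diseased:", sum(x$labels == 1L), ")\n")
  if (!is.null(x$patient_ids)) {
    cat("  individuals:", length(unique(x$patient_ids)), "\n")
  }
  invisible(x)
}

#' Subset a dataset by record index
#'
#' @param data A [wnn_dataset()].
#' @param idx Integer or logical record index.
#' @return A `wnn_dataset` with the selected records.
#' @export
dataset_subset <- function(data, idx) {
  wnn_dataset(data$features[idx, , drop = FALSE], data$labels[idx],
              patient_ids = if (!is.null(data$patient_ids)) data$patient_ids[idx],
              feature_names = data$feature_names)
}

#' Two-spiral benchmark task
#'
#' Generates the classic two interleaved planar spirals, one class each,
#' with the standard parameterisation: for `i = 0, ..., P-1`, angle
#' `phi = i * pi / 16` and radius `r = 6.5 * (104 - i) / 104`; the class-0
#' point is `(r sin phi, r cos phi)` and the class-1 point is its negation.
#' With `noise_sd = 0` the dataset is deterministic and the two classes are
#' exact mirror images through the origin.
#'
#' @param points_per_spiral Points on each spiral (default 97, giving the
#'   194-point benchmark).
#' @param noise_sd Standard deviation of optional Gaussian jitter.
#' @param seed Optional seed (only used when `noise_sd > 0`).
#' @return A [wnn_dataset()] with 2 features and `2 * points_per_spiral`
#'   records.
#' @examples
#' sp <- two_spiral()
#' plot(sp$features, col = sp$labels + 1, pch = 19, asp = 1)
#' @export
two_spiral <- function(points_per_spiral = 97L, noise_sd = 0, seed = NULL) {
  stopifnot(points_per_spiral >= 1L)
  i <- seq_len(points_per_spiral) - 1
  phi <- i * pi / 16
  r <- 6.5 * (104 - i) / 104
  half <- cbind(r * sin(phi), r * cos(phi))
  features <- rbind(half, -half)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    features <- features + rnorm(length(features), sd = noise_sd)
  }
  wnn_dataset(features,
              labels = rep(c(0L, 1L), each = points_per_spiral),
              feature_names = c("x", "y"))
}

#' Synthetic patient-structured clinical dataset
#'
#' Emulates speech-recording style clinical data in which each individual
#' contributes several records and the class label attaches to the
#' individual, not the record.  Each patient receives a class label, then a
#' latent per-patient feature mean drawn from a class-shifted Gaussian; the
#' patient's records are that latent mean plus independent record noise.
#' Variances are chosen so every feature has unit marginal variance: the
#' between-patient share is `within_patient_corr`, which is then the
#' intraclass correlation of records from one patient, and `effect_size` is
#' the class separation in marginal standard-deviation units on every
#' feature.
#'
#' @param n_patients Number of individuals.
#' @param records_per_patient Records contributed by each individual.
#' @param n_features Number of features.
#' @param class_balance Fraction of individuals labelled diseased.
#' @param effect_size Class mean shift, in units of the marginal SD.
#' @param within_patient_corr Intraclass correlation of records within an
#'   individual, in `[0, 1)`.
#' @param seed Optional seed.
#' @return A [wnn_dataset()] with patient identifiers.
#' @examples
#' d <- synth_clinical(n_patients = 40, records_per_patient = 26,
#'                     n_features = 26, effect_size = 1, seed = 1)
#' @export
synth_clinical <- function(n_patients, records_per_patient, n_features,
                           class_balance = 0.5, effect_size = 1,
                           within_patient_corr = 0.5, seed = NULL) {
  stopifnot(n_patients >= 1L, records_per_patient >= 1L, n_features >= 1L,
            class_balance >= 0, class_balance <= 1,
            within_patient_corr >= 0, within_patient_corr < 1)
  if (!is.null(seed)) set.seed(seed)
  n_dis <- round(n_patients * class_balance)
  pat_label <- rep(c(1L, 0L), c(n_dis, n_patients - n_dis))
  sd_between <- sqrt(within_patient_corr)
  sd_within <- sqrt(1 - within_patient_corr)
  n_rec <- n_patients * records_per_patient
  latent <- matrix(rnorm(n_patients * n_features, sd = sd_between),
                   n_patients, n_features) + effect_size * pat_label
  rec_pat <- rep(seq_len(n_patients), each = records_per_patient)
  features <- latent[rec_pat, , drop = FALSE] +
    matrix(rnorm(n_rec * n_features, sd = sd_within), n_rec, n_features)
  wnn_dataset(features,
              labels = pat_label[rec_pat],
              patient_ids = sprintf("P%03d", rec_pat))
}

# Group records for splitting: one group per patient when ids exist,
# otherwise each record is its own group.  Returns a list with the group key
# per record, the unique groups and each group's class.
split_groups <- function(data) {
  if (is.null(data$patient_ids)) {
    key <- as.character(seq_along(data$labels))
    groups <- key
    group_label <- data$labels
  } else {
    key <- data$patient_ids
    groups <- unique(key)
    group_label <- vapply(groups, function(g) {
      labs <- unique(data$labels[key == g])
      if (length(labs) != 1L) {
        stop("patient ", g, " has records with conflicting labels",
             call. = FALSE)
      }
      labs
    }, integer(1))
  }
  list(key = key, groups = groups, group_label = group_label)
}

#' Stratified (patient-grouped) holdout split
#'
#' Splits a dataset into training and test partitions, stratified by class.
#' When patient identifiers are present, whole individuals are assigned to
#' one side, so no individual ever spans the split.
#'
#' @param data A [wnn_dataset()].
#' @param test_fraction Target fraction of groups per class in the test set.
#' @param seed Optional seed for a reproducible split.
#' @return A list with components `train` and `test`.
#' @export
holdout_split <- function(data, test_fraction = 0.10, seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  grp <- split_groups(data)
  test_groups <- character(0)
  for (cls in c(0L, 1L)) {
    g_cls <- grp$groups[grp$group_label == cls]
    if (length(g_cls) == 0L) next
    n_test <- max(1L, round(length(g_cls) * test_fraction))
    if (n_test >= length(g_cls)) {
      stop("not enough groups in class ", cls, " for a ",
           test_fraction, " holdout", call. = FALSE)
    }
    test_groups <- c(test_groups, sample(g_cls, n_test))
  }
  in_test <- grp$key %in% test_groups
  list(train = dataset_subset(data, !in_test),
       test = dataset_subset(data, in_test))
}

# Stratified (grouped) fold assignment: within each class, groups are
# shuffled and dealt round-robin to folds.  Returns an integer fold id per
# record.
make_folds <- function(data, n_folds) {
  stopifnot(n_folds >= 2L)
  grp <- split_groups(data)
  if (length(grp$groups) < n_folds) {
    stop("fewer groups than folds", call. = FALSE)
  }
  fold_of_group <- integer(length(grp$groups))
  names(fold_of_group) <- grp$groups
  for (cls in c(0L, 1L)) {
    g_cls <- grp$groups[grp$group_label == cls]
    if (length(g_cls) == 0L) next
    g_cls <- sample(g_cls)
    fold_of_group[g_cls] <- rep_len(seq_len(n_folds), length(g_cls))
  }
  unname(fold_of_group[grp$key])
}

#' Feature standardisation
#'
#' `fit_scaler()` learns per-feature means and standard deviations from a
#' training partition; `apply_scaler()` z-scores any dataset with them.
#' Evolution initialises translations around 0, so centred unit-variance
#' inputs are the intended operating regime; [run_phase1()] applies this per
#' fold by default.  Constant features get unit scale so they pass through
#' centred.
#'
#' @param data A [wnn_dataset()].
#' @return `fit_scaler()` returns a `wnn_scaler`; `apply_scaler()` returns a
#'   standardised `wnn_dataset`.
#' @name scaling
NULL

#' @rdname scaling
#' @export
fit_scaler <- function(data) {
  mu <- colMeans(data$features)
  sigma <- apply(data$features, 2, sd)
  sigma[!is.finite(sigma) | sigma == 0] <- 1
  structure(list(mean = mu, sd = sigma), class = "wnn_scaler")
}

#' @rdname scaling
#' @param scaler A `wnn_scaler` from `fit_scaler()`.
#' @export
apply_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "wnn_scaler"))
  feats <- sweep(sweep(data$features, 2, scaler$mean), 2, scaler$sd, "/")
  wnn_dataset(feats, data$labels, patient_ids = data$patient_ids,
              feature_names = data$feature_names)
}

#' Read and write delimited datasets
#'
#' Datasets travel as comma-separated text with a header row: numeric
#' feature columns, a 0/1 label column and an optional individual-identifier
#' column (UCI-style clinical files map directly).  Values are written with
#' 17 significant digits so a write/read round trip preserves them exactly.
#'
#' @param path File path.
#' @param label_column Name of the label column.
#' @param patient_column Optional name of the individual-identifier column.
#' @param feature_columns Optional explicit feature column names; defaults
#'   to every remaining column.
#' @return `read_dataset()` returns a [wnn_dataset()].
#' @name dataset_io
NULL

#' @rdname dataset_io
#' @export
read_dataset <- function(path, label_column = "label", patient_column = NULL,
                         feature_columns = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!label_column %in% names(df)) {
    stop("label column '", label_column, "' not found in ", path,
         call. = FALSE)
  }
  if (!is.null(patient_column) && !patient_column %in% names(df)) {
    stop("patient column '", patient_column, "' not found in ", path,
         call. = FALSE)
  }
  labels <- df[[label_column]]
  bad <- which(!(labels %in% c(0, 1)))
  if (length(bad)) {
    stop("unknown label value '", labels[bad[1]], "' at row ", bad[1],
         " (labels must be 0 or 1)", call. = FALSE)
  }
  if (is.null(feature_columns)) {
    feature_columns <- setdiff(names(df), c(label_column, patient_column))
  }
  for (fc in feature_columns) {
    if (!fc %in% names(df)) {
      stop("feature column '", fc, "' not found in ", path, call. = FALSE)
    }
    if (!is.numeric(df[[fc]])) {
      first_bad <- which(is.na(suppressWarnings(as.numeric(df[[fc]]))))[1]
      stop("non-numeric feature cell in column '", fc, "' at row ",
           ifelse(is.na(first_bad), 1L, first_bad), call. = FALSE)
    }
  }
  wnn_dataset(as.matrix(df[feature_columns]), as.integer(labels),
              patient_ids = if (!is.null(patient_column)) df[[patient_column]],
              feature_names = feature_columns)
}

#' @rdname dataset_io
#' @param data A [wnn_dataset()].
#' @export
write_dataset <- function(data, path) {
  df <- as.data.frame(
    apply(data$features, 2, function(x) sprintf("%.17g", x)),
    stringsAsFactors = FALSE
  )
  names(df) <- data$feature_names
  df$label <- data$labels
  if (!is.null(data$patient_ids)) df$patient_id <- data$patient_ids
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
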