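#' Lesion-level feature tables
#'
#' A lesion table is the package's universal exchange object: one row per
#' lesion, with a unique `lesion_id`, the owning `patient_id`, the `center`
#' and `scanner` labels under which the image was acquired, and `d`
#' continuous radiomic features in columns `f1..fd` (default d = 45).
#'
#' Invariants enforced on construction: no missing values, unique lesion
#' ids, and every patient maps to exactly one center.
#'
#' @param df data.frame with columns `lesion_id`, `patient_id`, `center`,
#'   `scanner`, and `f1..fd`.
#' @return An object of class `lesion_table` (a validated data.frame).
#' @export
lesion_table <- function(df) {
  req <- c("lesion_id", "patient_id", "center", "scanner")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0) {
    stopf("lesion table format error: missing column(s) %s",
          paste(missing_cols, collapse = ", "))
  }
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) == 0) {
    stopf("lesion table format error: no feature columns f1..fd found")
  }
  # order feature columns numerically (f2 before f10)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  df <- df[, c(req, fcols), drop = FALSE]
  df$lesion_id <- as.character(df$lesion_id)
  df$patient_id <- as.character(df$patient_id)
  df$center <- as.character(df$center)
  df$scanner <- as.character(df$scanner)
  for (fc in fcols) {
    if (!is.numeric(df[[fc]])) {
      stopf("lesion table parse error: feature column %s is not numeric", fc)
    }
  }
  if (anyNA(df)) stopf("lesion table consistency error: missing values present")
  if (anyDuplicated(df$lesion_id)) {
    stopf("lesion table consistency error: duplicated lesion_id")
  }
  pc <- unique(df[, c("patient_id", "center")])
  if (anyDuplicated(pc$patient_id)) {
    bad <- pc$patient_id[duplicated(pc$patient_id)][1]
    stopf("lesion table consistency error: patient %s appears with more than one center", bad)
  }
  rownames(df) <- NULL
  structure(df, class = c("lesion_table", "data.frame"))
}

#' @export
print.lesion_table <- function(x, ...) {
  cat(sprintf("<lesion_table> %d lesions, %d patients, %d centers, %d scanners, d = %d\n",
              nrow(x), length(unique(x$patient_id)), length(unique(x$center)),
              length(unique(x$scanner)), n_features(x)))
  invisible(x)
}

#' Number of radiomic features in a lesion table
#' @param table a `lesion_table`
#' @return integer d
#' @export
n_features <- function(table) {
  sum(grepl("^f[0-9]+$", names(table)))
}

#' Extract the n x d feature matrix of a lesion table
#' @param table a `lesion_table`
#' @return numeric matrix with lesion ids as rownames
#' @export
feature_matrix <- function(table) {
  fcols <- grep("^f[0-9]+$", names(table), value = TRUE)
  m <- as.matrix(as.data.frame(table)[, fcols, drop = FALSE])
  rownames(m) <- table$lesion_id
  m
}

#' Replace the feature matrix of a lesion table, keeping the id columns
#' @param table a `lesion_table`
#' @param m numeric matrix, nrow(m) == nrow(table)
#' @return a `lesion_table` with features from `m` (renamed f1..fk)
#' @export
set_features <- function(table, m) {
  stopifnot(nrow(m) == nrow(table))
  out <- as.data.frame(table)[, c("lesion_id", "patient_id", "center", "scanner")]
  m <- as.matrix(m)
  colnames(m) <- paste0("f", seq_len(ncol(m)))
  lesion_table(cbind(out, as.data.frame(m)))
}

#' Read a lesion table from CSV
#'
#' Expects a header `lesion_id,patient_id,center,scanner,f1,...,fd`
#' (comma-separated, UTF-8, '.' decimal). Validates all invariants.
#'
#' @param path CSV file path
#' @return a `lesion_table`
#' @export
read_lesion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lesion_table(df)
}

#' Write a lesion table to CSV
#'
#' Values are printed with 15 significant digits so that a write/read
#' round trip is lossless at 12 significant digits.
#'
#' @param table a `lesion_table`
#' @param path output path
#' @export
write_lesion_table <- function(table, path) {
  df <- as.data.frame(table)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  for (fc in fcols) df[[fc]] <- format(df[[fc]], digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Survival tables
#'
#' One row per patient: `patient_id`, follow-up `time` (> 0) and `event`
#' indicator (1 = event observed, 0 = right-censored).
#'
#' @param df data.frame with columns patient_id, time, event
#' @return object of class `survival_table`
#' @export
survival_table <- function(df) {
  req <- c("patient_id", "time", "event")
  if (!all(req %in% names(df))) {
    stopf("survival table format error: need columns %s", paste(req, collapse = ", "))
  }
  df <- df[, req, drop = FALSE]
  df$patient_id <- as.character(df$patient_id)
  if (anyNA(df)) stopf("survival table consistency error: missing values")
  if (anyDuplicated(df$patient_id)) stopf("survival table consistency error: duplicated patient_id")
  if (!all(df$time > 0)) stopf("survival table consistency error: times must be > 0")
  if (!all(df$event %in% c(0, 1))) stopf("survival table consistency error: event must be 0/1")
  rownames(df) <- NULL
  structure(df, class = c("survival_table", "data.frame"))
}

#' @rdname survival_table
#' @param path CSV file path
#' @export
read_survival_table <- function(path) {
  survival_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname survival_table
#' @param table a `survival_table`
#' @export
write_survival_table <- function(table, path) {
  df <- as.data.frame(table)
  df$time <- format(df$time, digits = 15, trim = TRUE, scientific = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Z-score standardization of lesion features
#'
#' Fits per-feature mean and standard deviation (when `params` is NULL) or
#' applies previously fitted parameters — the fit-on-train / apply-on-test
#' pattern. Constant features get their sd floored at 1e-8 with a warning
#' so degenerate inputs still run.
#'
#' @param table a `lesion_table`
#' @param params optional parameters from a previous call
#' @return list with elements `table` (standardized) and `params`
#'   (class `standardization_params`: `mean`, `sd` per feature)
#' @export
standardize <- function(table, params = NULL) {
  m <- feature_matrix(table)
  if (is.null(params)) {
    mu <- colMeans(m)
    sd_ <- apply(m, 2, stats::sd)
    if (any(sd_ < 1e-8)) {
      warnf("standardize: %d constant feature(s); sd floored at 1e-8",
            sum(sd_ < 1e-8))
      sd_ <- pmax(sd_, 1e-8)
    }
    params <- structure(list(mean = mu, sd = sd_), class = "standardization_params")
  } else {
    stopifnot(inherits(params, "standardization_params"))
    if (length(params$mean) != ncol(m)) {
      stopf("standardize: params fitted for d = %d, table has d = %d",
            length(params$mean), ncol(m))
    }
  }
  z <- sweep(sweep(m, 2, params$mean, "-"), 2, params$sd, "/")
  list(table = set_features(table, z), params = params)
}

#' Invert a standardization
#' @param table standardized `lesion_table`
#' @param params `standardization_params` used to standardize
#' @return `lesion_table` on the original scale
#' @export
unstandardize <- function(table, params) {
  stopifnot(inherits(params, "standardization_params"))
  z <- feature_matrix(table)
  set_features(table, sweep(sweep(z, 2, params$sd, "*"), 2, params$mean, "+"))
}

#' PCA reduction of a feature matrix
#'
#' Centers the matrix and keeps the leading principal components; the
#' default of 16 components is the dimensionality used for non-embedding
#' modalities before survival modeling, chosen to be comparable to the
#' autoencoder embedding width.
#'
#' @param m numeric n x d matrix
#' @param n_components number of components to keep (default 16)
#' @return list with `scores` (n x n_components), `explained` (variance
#'   fractions per kept component) and `cumulative` (cumulative fractions)
#' @export
pca_reduce <- function(m, n_components = 16) {
  m <- as.matrix(m)
  if (!is_count(n_components) || n_components < 1) {
    stopf("pca_reduce: n_components must be a positive integer")
  }
  if (n_components > min(nrow(m), ncol(m))) {
    stopf("pca_reduce: n_components (%d) exceeds min(n, d) = %d",
          n_components, min(nrow(m), ncol(m)))
  }
  if (nrow(m) <= n_components) {
    stopf("pca_reduce: need n > n_components")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  frac <- p$sdev^2 / sum(p$sdev^2)
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- rownames(m)
  list(scores = scores,
       explained = frac[seq_len(n_components)],
       cumulative = cumsum(frac)[seq_len(n_components)])
}

#' Patient-level train/test split
#'
#' Splits at the patient level so that all lesions of one patient land on
#' the same side — lesion-level splits would leak patient identity across
#' the partition.
#'
#' @param table a `lesion_table`
#' @param survival optional `survival_table` to split alongside
#' @param fraction train fraction in (0,1), applied to patients
#' @param seed integer seed; the same seed reproduces the same split
#' @return list with `train` and `test`, each a list of `table`,
#'   `survival` (NULL if not given) and `patients`
#' @export
split_by_patient <- function(table, survival = NULL, fraction = 0.7, seed = 1) {
  if (!(fraction > 0 && fraction < 1)) stopf("split_by_patient: fraction must be in (0,1)")
  patients <- sort(unique(table$patient_id))
  if (length(patients) < 2) stopf("split_by_patient: need at least 2 patients")
  n_train <- max(1L, min(length(patients) - 1L, round(fraction * length(patients))))
  train_pat <- with_seed(seed, sample(patients, n_train))
  take <- function(tab, pats) {
    out <- as.data.frame(tab)[tab$patient_id %in% pats, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  side <- function(pats) {
    list(table = lesion_table(take(table, pats)),
         survival = if (is.null(survival)) NULL else survival_table(take(survival, pats)),
         patients = sort(pats))
  }
  list(train = side(train_pat), test = side(setdiff(patients, train_pat)))
}
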