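#' Bootstrap confounder-predictability test
#'
#' Measures how predictable a batch label (center or scanner) is from a
#' feature set: per trial, a bootstrap sample (drawn with replacement)
#' trains an L2-penalized (multinomial) logistic regression and accuracy
#' is scored on the out-of-bag lesions. High accuracy means a strong
#' confounder signal; successful harmonization drives it toward the
#' majority-class prevalence.
#'
#' @param features numeric n x m matrix
#' @param labels categorical vector of length n (>= 2 classes, each with
#'   >= 5 samples)
#' @param n_trials number of bootstrap trials (default 100)
#' @param seed RNG seed; the same seed reproduces the same resamples, so
#'   distributions from different feature sets are paired
#' @param name label carried into reports
#' @return object of class `accuracy_distribution`: `accuracies` (length
#'   `n_trials`), `mean`, `sd`, `prevalence` (majority class), `name`
#' @export
confounder_accuracy <- function(features, labels, n_trials = 100, seed = 1,
                                name = "features") {
  x <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("confounder_accuracy: need >= 2 classes")
  if (any(table(y) < 5)) stopf("confounder_accuracy: every class needs >= 5 samples")
  n <- nrow(x)
  fam <- if (nlevels(y) == 2) "binomial" else "multinomial"
  acc <- with_seed(seed, vapply(seq_len(n_trials), function(tr) {
    for (attempt in seq_len(10)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (length(oob) > 0 && nlevels(droplevels(y[idx])) == nlevels(y)) break
      if (attempt == 10) stopf("confounder_accuracy: a class kept missing from the bootstrap draw")
    }
    fit <- glmnet::glmnet(x[idx, , drop = FALSE], y[idx], family = fam,
                          alpha = 0, lambda = 1 / length(idx),
                          standardize = TRUE)
    pred <- predict(fit, x[oob, , drop = FALSE], type = "class")
    mean(pred == as.character(y[oob]))
  }, 0))
  structure(list(name = name, accuracies = acc, mean = mean(acc), sd = stats::sd(acc),
                 prevalence = max(table(y)) / n, n_trials = n_trials),
            class = "accuracy_distribution")
}

#' @export
print.accuracy_distribution <- function(x, ...) {
  cat(sprintf("<accuracy_distribution> %s: %.4f +/- %.4f (%d trials, prevalence %.3f)\n",
              x$name, x$mean, x$sd, x$n_trials, x$prevalence))
  invisible(x)
}

# paired t-test that tolerates identical vectors: with all-zero
# differences the p-value is 1 by convention
paired_t_p <- function(a, b, alternative) {
  d <- a - b
  if (length(d) < 2) {
    warnf("paired test: fewer than 2 paired values; returning NA")
    return(NA_real_)
  }
  if (stats::sd(d) < .Machine$double.eps) {
    m <- mean(d)
    if (abs(m) < .Machine$double.eps) return(1)
    return(switch(alternative,
                  two.sided = 0,
                  greater = if (m > 0) 0 else 1,
                  less = if (m < 0) 0 else 1))
  }
  stats::t.test(a, b, paired = TRUE, alternative = alternative)$p.value
}

#' Paired t-test between two bootstrap accuracy distributions
#'
#' Trials must be paired by seed (the same resamples on both feature
#' sets).
#'
#' @param a,b `accuracy_distribution`s of equal length
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#' @return p-value
#' @export
paired_accuracy_test <- function(a, b, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(a$accuracies) != length(b$accuracies)) {
    stopf("paired_accuracy_test: distributions have different lengths")
  }
  paired_t_p(a$accuracies, b$accuracies, alternative)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Patient-level representations of lesion clouds
#'
#' Summarizes each patient's lesions into one vector:
#' * `centroid` — coordinate-wise mean of the lesion vectors;
#' * `cloud` — 4 topology indexes: mean and (population) sd of the
#'   pairwise inter-lesion Euclidean distances, and mean and sd of the
#'   lesion-to-centroid distances;
#' * `combined` — concatenation of the two.
#'
#' Single-lesion patients get zeros in the 4 cloud indexes with a
#' degeneracy flag.
#'
#' @param x a `lesion_table` or a numeric matrix (lesions x dims)
#' @param kind `"centroid"`, `"cloud"` or `"combined"`
#' @param patient_ids patient label per row, required when `x` is a matrix
#' @return object of class `patient_representation`: a data.frame with
#'   `patient_id`, representation columns, and attributes `kind` and
#'   `degenerate`
#' @export
build_representation <- function(x, kind = c("centroid", "cloud", "combined"),
                                 patient_ids = NULL) {
  kind <- match.arg(kind)
  if (inherits(x, "lesion_table")) {
    m <- feature_matrix(x)
    patient_ids <- x$patient_id
  } else {
    m <- as.matrix(x)
    if (is.null(patient_ids)) stopf("build_representation: patient_ids required for a matrix")
  }
  pats <- unique(patient_ids)
  rows <- lapply(pats, function(p) {
    mi <- m[patient_ids == p, , drop = FALSE]
    if (nrow(mi) == 0) stopf("build_representation: patient %s has no lesions", p)
    centroid <- colMeans(mi)
    degenerate <- nrow(mi) < 2
    if (kind == "centroid") {
      return(list(vec = centroid, degenerate = FALSE))
    }
    if (degenerate) {
      cloud <- c(0, 0, 0, 0)
    } else {
      pw <- as.numeric(stats::dist(mi))
      dc <- sqrt(rowSums(sweep(mi, 2, centroid, "-")^2))
      cloud <- c(mean(pw), pop_sd(pw), mean(dc), pop_sd(dc))
    }
    vec <- if (kind == "cloud") cloud else c(centroid, cloud)
    list(vec = vec, degenerate = degenerate)
  })
  mat <- do.call(rbind, lapply(rows, `[[`, "vec"))
  cn <- switch(kind,
               centroid = paste0("c", seq_len(ncol(mat))),
               cloud = c("pairwise_mean", "pairwise_sd", "centroid_mean", "centroid_sd"),
               combined = c(paste0("c", seq_len(ncol(mat) - 4)),
                            "pairwise_mean", "pairwise_sd", "centroid_mean", "centroid_sd"))
  colnames(mat) <- cn
  df <- cbind(data.frame(patient_id = pats, stringsAsFactors = FALSE),
              as.data.frame(mat))
  structure(df, kind = kind,
            degenerate = pats[vapply(rows, `[[`, TRUE, "degenerate")],
            class = c("patient_representation", "data.frame"))
}

#' Repeated-split Cox concordance evaluation
#'
#' Over `n_splits` patient-level train/test splits, fits a
#' ridge-penalized Cox proportional-hazards model on the training
#' patients' representation vectors and records Harrell's concordance
#' index (ties credited 0.5) on train and test. A small ridge (1e-4)
#' stabilizes fits against separation on small splits; on failure the
#' penalty is escalated tenfold up to 3 times before the split is marked
#' failed. Splits depend only on the seed and the patient set, so
#' reports from different modalities under one seed are paired.
#'
#' @param representations a `patient_representation`
#' @param survival a `survival_table` covering the same patients
#' @param n_splits number of random splits (default 20)
#' @param split_fraction train fraction at patient level
#' @param seed RNG seed
#' @param ridge initial ridge penalty of the Cox fit
#' @return object of class `concordance_report`: per-split `train` and
#'   `test` concordances, means, sds, `failed` count
#' @export
prognostic_eval <- function(representations, survival, n_splits = 20,
                            split_fraction = 0.7, seed = 1, ridge = 1e-4) {
  df <- merge(as.data.frame(representations), as.data.frame(survival),
              by = "patient_id")
  if (nrow(df) < 4) stopf("prognostic_eval: too few patients with survival records")
  feat_cols <- setdiff(names(df), c("patient_id", "time", "event"))
  x <- as.matrix(df[, feat_cols, drop = FALSE])
  if (!all(is.finite(x))) stopf("prognostic_eval: non-finite representation values")
  keep <- apply(x, 2, function(col) stats::sd(col) > 1e-12)
  x <- x[, keep, drop = FALSE]
  y <- survival::Surv(df$time, df$event)
  patients <- df$patient_id
  n_pat <- length(patients)
  n_train <- max(2L, round(split_fraction * n_pat))

  train_c <- test_c <- rep(NA_real_, n_splits)
  failed <- 0L
  for (s in seq_len(n_splits)) {
    tr <- with_seed(derive_seed(seed, s), sample.int(n_pat, n_train))
    te <- setdiff(seq_len(n_pat), tr)
    lam <- ridge
    done <- FALSE
    for (attempt in 0:3) {
      res <- tryCatch({
        if (ncol(x) == 1) {
          df1 <- data.frame(risk = x[tr, 1])
          cfit <- survival::coxph(y[tr] ~ risk, data = df1)
          risk_tr <- as.numeric(x[tr, 1] * stats::coef(cfit))
          risk_te <- as.numeric(x[te, 1] * stats::coef(cfit))
        } else {
          fit <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "cox",
                                alpha = 0, lambda = lam, standardize = TRUE)
          risk_tr <- as.numeric(predict(fit, x[tr, , drop = FALSE]))
          risk_te <- as.numeric(predict(fit, x[te, , drop = FALSE]))
        }
        cc <- function(yy, risk) {
          survival::concordance(yy ~ risk, reverse = TRUE)$concordance
        }
        list(tr = cc(y[tr], risk_tr), te = cc(y[te], risk_te))
      }, error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(res) && is.finite(res$tr) && is.finite(res$te)) {
        train_c[s] <- res$tr; test_c[s] <- res$te
        done <- TRUE
        break
      }
      lam <- lam * 10
    }
    if (!done) failed <- failed + 1L
  }
  structure(list(train = train_c, test = test_c,
                 train_mean = mean(train_c, na.rm = TRUE),
                 train_sd = stats::sd(train_c[!is.na(train_c)]),
                 test_mean = mean(test_c, na.rm = TRUE),
                 test_sd = stats::sd(test_c[!is.na(test_c)]),
                 n_splits = n_splits, failed = failed,
                 seed = seed, split_fraction = split_fraction),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> train %.3f +/- %.3f, test %.3f +/- %.3f (%d splits, %d failed)\n",
              x$train_mean, x$train_sd, x$test_mean, x$test_sd, x$n_splits, x$failed))
  invisible(x)
}

#' One-sided paired t-test between concordance reports
#'
#' Reports must come from the same seed (same splits); tests whether
#' `a`'s per-split concordances exceed `b`'s.
#'
#' @param a,b `concordance_report`s paired by seed
#' @param alternative test direction (default `"greater"`: a > b)
#' @param on `"test"` (default) or `"train"` concordances
#' @return p-value
#' @export
paired_concordance_test <- function(a, b, alternative = c("greater", "less", "two.sided"),
                                    on = c("test", "train")) {
  alternative <- match.arg(alternative)
  on <- match.arg(on)
  if (a$n_splits != b$n_splits || a$seed != b$seed ||
      a$split_fraction != b$split_fraction) {
    stopf("paired_concordance_test: reports are not paired (seed/splits differ)")
  }
  va <- a[[on]]; vb <- b[[on]]
  ok <- !is.na(va) & !is.na(vb)
  paired_t_p(va[ok], vb[ok], alternative)
}

#' Deconfusion report across modalities (Experiment 1 layout)
#'
#' Runs [confounder_accuracy()] for every modality and factor, compares
#' each modality against the baseline with a two-sided paired t-test,
#' and flags a modality when p < `alpha` with a mean below the
#' baseline's — the successful-deconfusion marking.
#'
#' @param modalities named list of n x m feature matrices, row-aligned on
#'   the same lesions (the first entry is the baseline unless `baseline`
#'   names another)
#' @param labels named list of label vectors (e.g. `center`, `scanner`)
#' @param n_trials,seed passed to [confounder_accuracy()]
#' @param baseline name of the reference modality
#' @param alpha significance level of the flag (default 0.001)
#' @return list with `table` (data.frame) and `distributions` (nested
#'   list modality -> factor)
#' @export
deconfusion_report <- function(modalities, labels, n_trials = 100, seed = 1,
                               baseline = names(modalities)[1], alpha = 0.001) {
  check_alignment(modalities)
  dists <- lapply(names(modalities), function(mod) {
    lapply(names(labels), function(fac) {
      confounder_accuracy(modalities[[mod]], labels[[fac]],
                          n_trials = n_trials, seed = seed,
                          name = paste(mod, fac, sep = "/"))
    }) |> stats::setNames(names(labels))
  }) |> stats::setNames(names(modalities))
  rows <- list()
  for (mod in names(modalities)) {
    for (fac in names(labels)) {
      d <- dists[[mod]][[fac]]
      b <- dists[[baseline]][[fac]]
      p <- if (mod == baseline) NA_real_ else paired_accuracy_test(d, b, "two.sided")
      rows[[length(rows) + 1]] <- data.frame(
        modality = mod, factor = fac, mean = d$mean, sd = d$sd,
        prevalence = d$prevalence, p_vs_baseline = p,
        deconfounded = !is.na(p) && p < alpha && d$mean < b$mean,
        stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), distributions = dists)
}

check_alignment <- function(modalities) {
  ids <- lapply(modalities, rownames)
  ref <- ids[[1]]
  for (i in seq_along(ids)) {
    if (!is.null(ref) && !is.null(ids[[i]]) && !identical(ids[[i]], ref)) {
      stopf("modalities are not row-aligned on lesion ids ('%s' differs)",
            names(modalities)[i])
    }
    if (nrow(modalities[[i]]) != nrow(modalities[[1]])) {
      stopf("modalities have different row counts")
    }
  }
  invisible(TRUE)
}

#' Prognostic comparison across modalities (Experiment 3 layout)
#'
#' For every modality and representation kind, builds the patient
#' representation, evaluates repeated-split Cox concordance, and tests
#' (one-sided, paired) whether the reference modality outperforms each
#' other modality on the same splits.
#'
#' @param modalities named list of lesion-level matrices, row-aligned;
#'   entries named in `reduce` are first reduced to
#'   `n_components` principal components (the non-embedding modalities)
#' @param patient_ids patient label per row
#' @param survival a `survival_table`
#' @param kinds representation kinds to evaluate
#' @param reference modality whose superiority is tested (default the
#'   last entry)
#' @param reduce names of modalities to PCA-reduce before representation
#' @param n_components PCA dimensionality (default 16)
#' @param n_splits,split_fraction,seed passed to [prognostic_eval()]
#' @param alpha significance level for flagging
#' @return list with `table` (data.frame of concordances and p-values)
#'   and `reports` (nested list modality -> kind)
#' @export
prognostic_report <- function(modalities, patient_ids, survival,
                              kinds = c("centroid", "cloud", "combined"),
                              reference = names(modalities)[length(modalities)],
                              reduce = character(), n_components = 16,
                              n_splits = 20, split_fraction = 0.7, seed = 1,
                              alpha = 0.05) {
  check_alignment(modalities)
  feats <- modalities
  for (mod in intersect(reduce, names(feats))) {
    feats[[mod]] <- pca_reduce(feats[[mod]], n_components)$scores
  }
  reports <- lapply(names(feats), function(mod) {
    lapply(kinds, function(kind) {
      rep_ <- build_representation(feats[[mod]], kind, patient_ids = patient_ids)
      prognostic_eval(rep_, survival, n_splits = n_splits,
                      split_fraction = split_fraction, seed = seed)
    }) |> stats::setNames(kinds)
  }) |> stats::setNames(names(feats))
  rows <- list()
  for (mod in names(feats)) {
    for (kind in kinds) {
      r <- reports[[mod]][[kind]]
      if (mod == reference) {
        p_tr <- p_te <- NA_real_
      } else {
        p_tr <- paired_concordance_test(reports[[reference]][[kind]], r, "greater", "train")
        p_te <- paired_concordance_test(reports[[reference]][[kind]], r, "greater", "test")
      }
      rows[[length(rows) + 1]] <- data.frame(
        modality = mod, representation = kind,
        train_mean = r$train_mean, train_sd = r$train_sd,
        test_mean = r$test_mean, test_sd = r$test_sd,
        p_train_ref_greater = p_tr, p_test_ref_greater = p_te,
        ref_better_test = !is.na(p_te) && p_te < alpha,
        failed_splits = r$failed, stringsAsFactors = FALSE)
    }
  }
  list(table = do.call(rbind, rows), reports = reports)
}

#' Write experiment report tables to CSV + JSON
#' @param report list with elements `table1` and/or `table2` (data.frames)
#' @param dir output directory
#' @export
write_report_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$table1)) {
    utils::write.csv(report$table1, file.path(dir, "table1.csv"), row.names = FALSE)
  }
  if (!is.null(report$table2)) {
    utils::write.csv(report$table2, file.path(dir, "table2.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report[intersect(names(report), c("table1", "table2"))],
                       file.path(dir, "report.json"), digits = NA, dataframe = "rows")
  invisible(dir)
}
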