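#' Patient point clouds
#'
#' A patient's lesions form a point cloud: each lesion is a point in
#' feature space (45-dim raw features) or embedding space (16-dim). The
#' cloud's shape encodes intra-tumor heterogeneity, and the drift
#' statistics below quantify how much a transformation (harmonization,
#' embedding) reorders each lesion's neighbors.
#'
#' @param points numeric K x dim matrix, one row per lesion
#' @param patient_id patient label
#' @param lesion_ids unique lesion ids (default: rownames of `points`)
#' @return object of class `point_cloud`
#' @export
point_cloud <- function(points, patient_id = "patient", lesion_ids = rownames(points)) {
  points <- as.matrix(points)
  if (is.null(lesion_ids)) lesion_ids <- paste0("L", seq_len(nrow(points)))
  lesion_ids <- as.character(lesion_ids)
  if (nrow(points) < 2) stopf("point_cloud: need K >= 2 lesions")
  if (anyDuplicated(lesion_ids)) stopf("point_cloud: duplicated lesion ids")
  rownames(points) <- lesion_ids
  structure(list(patient_id = patient_id, lesion_ids = lesion_ids,
                 points = points), class = "point_cloud")
}

#' Split a lesion table (or an aligned matrix) into per-patient clouds
#'
#' @param x a `lesion_table`, or a numeric matrix with lesion ids as
#'   rownames
#' @param patient_ids required when `x` is a matrix: patient label per row
#' @return named list of `point_cloud` objects (patients with a single
#'   lesion are dropped, since a cloud needs at least two points)
#' @export
clouds_from_table <- function(x, patient_ids = NULL) {
  if (inherits(x, "lesion_table")) {
    m <- feature_matrix(x)
    patient_ids <- x$patient_id
  } else {
    m <- as.matrix(x)
    if (is.null(patient_ids)) stopf("clouds_from_table: patient_ids required for a matrix")
  }
  out <- list()
  for (p in unique(patient_ids)) {
    rows <- which(patient_ids == p)
    if (length(rows) < 2) next
    out[[p]] <- point_cloud(m[rows, , drop = FALSE], patient_id = p)
  }
  out
}

#' Rank a lesion's neighbors within its cloud
#'
#' Euclidean distances from the anchor to every other lesion, divided by
#' their maximum, give scores M in (0, 1] (the farthest neighbor scores
#' 1); ascending ranks 1..K-1 follow, with distance ties broken by
#' lesion-id order so the ranking is deterministic.
#'
#' @param cloud a `point_cloud`
#' @param anchor lesion id of the anchor point
#' @return object of class `neighbor_ranking`: `anchor`, `ranked_ids`
#'   (ascending distance), `rank` and `score` (named by lesion id)
#' @export
neighbor_ranking <- function(cloud, anchor) {
  stopifnot(inherits(cloud, "point_cloud"))
  ai <- match(anchor, cloud$lesion_ids)
  if (is.na(ai)) stopf("neighbor_ranking: anchor '%s' not in cloud", anchor)
  others <- cloud$lesion_ids[-ai]
  diff <- sweep(cloud$points[-ai, , drop = FALSE], 2, cloud$points[ai, ], "-")
  d <- sqrt(rowSums(diff^2))
  m <- d / max(d)
  ord <- order(d, others, method = "radix")
  r <- integer(length(d))
  r[ord] <- seq_along(d)
  names(r) <- names(m) <- others
  structure(list(anchor = anchor, ranked_ids = others[ord], rank = r, score = m),
            class = "neighbor_ranking")
}

capped_ranks <- function(ids, universe, k) {
  r <- match(universe, ids)
  r[is.na(r) | r > k] <- k + 1
  names(r) <- universe
  r
}

#' Spearman footrule distance between two ranked lists
#'
#' Sum over the union of both lists of the absolute rank differences,
#' with ranks capped at k+1 for elements outside the top k of a list.
#'
#' @param list_a,list_b character vectors of ids, best first
#' @param k truncation depth (>= 1)
#' @return non-negative integer
#' @export
footrule <- function(list_a, list_b, k = max(length(list_a), length(list_b))) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stopf("footrule: duplicate ids within a list")
  }
  if (k < 1) stopf("footrule: k must be >= 1")
  universe <- union(list_a, list_b)
  sum(abs(capped_ranks(list_b, universe, k) - capped_ranks(list_a, universe, k)))
}

#' Point Semantic Drift of one anchor
#'
#' The footrule weighted by score changes:
#' \eqn{PSD = \sum_t |M_{transf}(t) - M_{orig}(t)| \cdot
#' |r_{transf}(t) - r_{orig}(t)|}, ranks capped at k+1 as in
#' [footrule()]. Swaps between close-by and far-distant neighbors weigh
#' more than shuffles among near-equidistant ones.
#'
#' @param orig,transf `neighbor_ranking`s of the same anchor in the
#'   original and transformed space
#' @param k truncation depth (default: full lists)
#' @return non-negative real
#' @export
point_semantic_drift <- function(orig, transf, k = length(orig$ranked_ids)) {
  stopifnot(inherits(orig, "neighbor_ranking"), inherits(transf, "neighbor_ranking"))
  if (!identical(orig$anchor, transf$anchor)) {
    stopf("point_semantic_drift: rankings have different anchors")
  }
  if (!setequal(names(orig$rank), names(transf$rank))) {
    stopf("point_semantic_drift: rankings cover different lesion sets")
  }
  universe <- union(orig$ranked_ids, transf$ranked_ids)
  r_o <- capped_ranks(orig$ranked_ids, universe, k)
  r_t <- capped_ranks(transf$ranked_ids, universe, k)
  sum(abs(transf$score[universe] - orig$score[universe]) * abs(r_t - r_o))
}

# fast path used by pcsd/null draws: distance matrices once per cloud,
# rank/score arithmetic per anchor without building ranking objects
pcsd_fast <- function(p_orig, p_transf, ids, k = NULL) {
  K <- nrow(p_orig)
  if (K < 3) return(structure(0, degenerate = TRUE))
  d_o <- as.matrix(stats::dist(p_orig))
  d_t <- as.matrix(stats::dist(p_transf))
  kk <- if (is.null(k)) K - 1 else k
  psd <- numeric(K)
  for (i in seq_len(K)) {
    do_i <- d_o[i, -i]; dt_i <- d_t[i, -i]
    oid <- ids[-i]
    m_o <- do_i / max(do_i)
    m_t <- dt_i / max(dt_i)
    r_o <- integer(K - 1); r_o[order(do_i, oid, method = "radix")] <- seq_len(K - 1)
    r_t <- integer(K - 1); r_t[order(dt_i, oid, method = "radix")] <- seq_len(K - 1)
    r_o <- pmin(r_o, kk + 1)
    r_t <- pmin(r_t, kk + 1)
    psd[i] <- sum(abs(m_t - m_o) * abs(r_t - r_o))
  }
  structure(mean(psd), degenerate = FALSE, psd = psd)
}

#' Point Cloud Semantic Drift of a patient
#'
#' Average [point_semantic_drift()] over every lesion of the cloud used
#' as anchor. Zero when the transformation preserves all neighbor
#' rankings and normalized distances; invariant to rigid motions and
#' uniform scaling of the cloud (max-normalization cancels scale).
#'
#' Clouds with fewer than 3 lesions are flagged degenerate (the
#' statistic is identically 0 for K = 2 under max-normalization) and are
#' excluded from population summaries by default.
#'
#' @param orig,transf paired `point_cloud`s with identical lesion-id sets
#' @param k truncation depth; default K-1 (no truncation)
#' @return non-negative real, with attributes `degenerate` and `psd`
#'   (per-anchor values)
#' @export
pcsd <- function(orig, transf, k = NULL) {
  stopifnot(inherits(orig, "point_cloud"), inherits(transf, "point_cloud"))
  if (!setequal(orig$lesion_ids, transf$lesion_ids)) {
    stopf("pcsd: clouds have different lesion-id sets")
  }
  p_t <- transf$points[orig$lesion_ids, , drop = FALSE]
  pcsd_fast(orig$points, p_t, orig$lesion_ids, k)
}

#' Population mean PCSD over paired cloud lists
#' @param orig_clouds,transf_clouds named lists of paired `point_cloud`s
#' @param k truncation depth
#' @return list with `per_patient`, `excluded` (degenerate patients) and
#'   `mean`
#' @export
population_pcsd <- function(orig_clouds, transf_clouds, k = NULL) {
  stopifnot(setequal(names(orig_clouds), names(transf_clouds)))
  vals <- vapply(names(orig_clouds), function(p) {
    as.numeric(pcsd(orig_clouds[[p]], transf_clouds[[p]], k))
  }, 0)
  deg <- vapply(names(orig_clouds), function(p) {
    nrow(orig_clouds[[p]]$points) < 3
  }, TRUE)
  list(per_patient = vals[!deg], excluded = names(orig_clouds)[deg],
       mean = mean(vals[!deg]))
}

#' Gaussian-noise null distribution of the population PCSD
#'
#' Each iteration perturbs, in every cloud, a random subset of
#' ceiling(`subset_fraction` * K) lesions with i.i.d. Gaussian noise
#' (mean 0, variance `noise_variance`; set `noise_is_sd = TRUE` to read
#' the value as a standard deviation) and records the population mean
#' PCSD between the original and perturbed clouds. The draws bound the
#' drift an arbitrary structure-blind transformation would cause; clouds
#' should be on a standardized scale for the noise variance to be
#' meaningful.
#'
#' @param orig_clouds named list of `point_cloud`s
#' @param n_iter number of draws (default 100)
#' @param noise_variance Gaussian noise variance (default 3)
#' @param subset_fraction fraction of lesions perturbed per cloud
#' @param seed RNG seed
#' @param k truncation depth for PCSD
#' @param noise_is_sd interpret `noise_variance` as an sd instead
#' @return numeric vector of `n_iter` mean-PCSD draws
#' @export
null_pcsd <- function(orig_clouds, n_iter = 100, noise_variance = 3,
                      subset_fraction = 0.5, seed = 1, k = NULL,
                      noise_is_sd = FALSE) {
  if (n_iter < 1) stopf("null_pcsd: n_iter must be >= 1")
  sd_ <- if (noise_is_sd) noise_variance else sqrt(noise_variance)
  keep <- Filter(function(cl) nrow(cl$points) >= 3, orig_clouds)
  if (length(keep) == 0) stopf("null_pcsd: no cloud with K >= 3")
  with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      vals <- vapply(keep, function(cl) {
        K <- nrow(cl$points)
        n_pert <- max(1L, ceiling(subset_fraction * K))
        rows <- sample.int(K, n_pert)
        pert <- cl$points
        pert[rows, ] <- pert[rows, ] +
          matrix(stats::rnorm(n_pert * ncol(pert), sd = sd_), n_pert)
        as.numeric(pcsd_fast(cl$points, pert, cl$lesion_ids, k))
      }, 0)
      mean(vals)
    }, 0)
  })
}

#' Left-tail empirical p-value of an observed mean PCSD
#'
#' Fraction of null draws strictly below the observed value: a small p
#' says the observed drift sits in the left tail of what a random,
#' structure-blind transformation would cause, i.e. the transformation
#' preserved the cloud shapes.
#'
#' @param observed_mean observed population mean PCSD
#' @param null_draws vector of null draws from [null_pcsd()]
#' @return p in \[0, 1\]
#' @export
pcsd_empirical_p <- function(observed_mean, null_draws) {
  if (length(null_draws) == 0) stopf("pcsd_empirical_p: empty null draws")
  mean(null_draws < observed_mean)
}

#' Cloud shape-invariance test of a transformation
#'
#' Computes per-patient PCSD between original and transformed clouds,
#' the population mean, a Gaussian-noise null distribution, and the
#' left-tail empirical p-value. By convention the null perturbs the
#' original clouds; set `perturb = "transformed"` to perturb the
#' transformed clouds instead.
#'
#' @param orig_clouds,transf_clouds named lists of paired `point_cloud`s
#' @param n_iter,noise_variance,subset_fraction,seed,k,noise_is_sd see
#'   [null_pcsd()]
#' @param perturb which space the null perturbation targets
#' @return object of class `drift_result`: `per_patient`, `excluded`,
#'   `observed_mean`, `null_draws`, `p_value`
#' @export
drift_test <- function(orig_clouds, transf_clouds, n_iter = 100,
                       noise_variance = 3, subset_fraction = 0.5,
                       seed = 1, k = NULL, noise_is_sd = FALSE,
                       perturb = c("original", "transformed")) {
  perturb <- match.arg(perturb)
  obs <- population_pcsd(orig_clouds, transf_clouds, k)
  base <- if (perturb == "original") orig_clouds else transf_clouds
  draws <- null_pcsd(base, n_iter = n_iter, noise_variance = noise_variance,
                     subset_fraction = subset_fraction, seed = seed, k = k,
                     noise_is_sd = noise_is_sd)
  structure(list(per_patient = obs$per_patient, excluded = obs$excluded,
                 observed_mean = obs$mean, null_draws = draws,
                 p_value = pcsd_empirical_p(obs$mean, draws)),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf("<drift_result> %d patients (%d excluded), mean PCSD %.4f, empirical p = %.2f\n",
              length(x$per_patient), length(x$excluded), x$observed_mean, x$p_value))
  invisible(x)
}

#' Write a drift report to JSON
#' @param result a `drift_result`
#' @param path output path
#' @export
write_drift_report <- function(result, path) {
  jsonlite::write_json(list(
    per_patient = as.list(result$per_patient),
    excluded = result$excluded,
    observed_mean = result$observed_mean,
    null_draws = result$null_draws,
    p_value = result$p_value), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
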