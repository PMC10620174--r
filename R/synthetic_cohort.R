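#' Simulation configuration for the synthetic multi-center cohort
#'
#' The generator emulates the statistical structure the harmonization
#' methods assume: lesions nested in patients nested in centers, scanners
#' nested in centers, collinear feature blocks driven by a low-dimensional
#' latent signal, additive + multiplicative batch effects in the
#' location/scale form (with optional interaction and nonlinear warp
#' terms), patient-level cloud heterogeneity, and heterogeneity-linked
#' right-censored survival.
#'
#' Defaults mirror a two-center Hodgkin-lymphoma cohort: 128 + 78 patients,
#' a mean of 10.5 FDG-avid lesions per patient (at least 3), 45 radiomic
#' features in 6 collinear families, 2 scanners in center 1 and 3 in
#' center 2 (5 scanner classes in total), and roughly 80% censoring.
#'
#' @param n_patients_per_center integer vector, patients per center
#' @param lesion_mean Poisson mean of the per-patient lesion count
#' @param min_lesions lower truncation of the lesion count (3 keeps the
#'   cloud-drift statistic non-degenerate; set 1 to exercise degenerate
#'   handling)
#' @param latent_dim dimension q of the latent clean signal
#' @param feature_dim number d of radiomic features
#' @param scanners_per_center integer vector, scanners hosted by each center
#' @param center_effect_sd sd of the per-feature additive center effects
#' @param scanner_effect_sd sd of the per-feature additive scanner effects
#' @param delta_center per-center multiplicative effect on the residual term
#' @param delta_scanner per-scanner multiplicative effect on the residual
#'   term
#' @param delta_feature_sdlog log-sd of the per-feature spread of the
#'   multiplicative effects around each batch's scalar: the scale effect
#'   of a scanner differs by feature family (as the location/scale model
#'   indexes it per batch and feature), warping clouds anisotropically
#'   rather than uniformly rescaling them; 0 gives scalar effects
#' @param interaction_strength scale of the center-by-scanner additive shift
#' @param nonlinear_strength scale of the center-signed tanh warp of the
#'   clean signal
#' @param heterogeneity_meanlog,heterogeneity_sdlog log-normal law of the
#'   per-patient lesion dispersion sd
#' @param noise_sd sd of the lesion-level feature noise
#' @param survival list: `scale`, `shape` (Weibull baseline), `beta_h`
#'   (log-hazard per unit heterogeneity), `beta_m` (log-hazard per unit
#'   centroid score), `censoring` (target censored fraction)
#' @param loading_seed seed fixing the loading matrix and batch parameters
#' @param seed seed for patient/lesion sampling
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_patients_per_center = c(128, 78),
                       lesion_mean = 10.5,
                       min_lesions = 3,
                       latent_dim = 5,
                       feature_dim = 45,
                       scanners_per_center = c(2, 3),
                       center_effect_sd = 1.0,
                       scanner_effect_sd = 1.0,
                       delta_center = c(0.8, 1.3),
                       delta_scanner = c(0.7, 1.4, 0.9, 1.2, 1.0),
                       delta_feature_sdlog = 0.4,
                       interaction_strength = 0.3,
                       nonlinear_strength = 0.3,
                       heterogeneity_meanlog = log(0.5),
                       heterogeneity_sdlog = 0.6,
                       noise_sd = 1.0,
                       survival = list(scale = 24, shape = 1.5,
                                       beta_h = 2, beta_m = 0.5,
                                       censoring = 0.8),
                       loading_seed = 20,
                       seed = 1) {
  if (length(n_patients_per_center) != length(scanners_per_center)) {
    stopf("sim_config: scanner map inconsistent with centers (%d centers, %d scanner groups)",
          length(n_patients_per_center), length(scanners_per_center))
  }
  if (length(delta_center) != length(n_patients_per_center)) {
    stopf("sim_config: delta_center must have one entry per center")
  }
  if (length(delta_scanner) != sum(scanners_per_center)) {
    stopf("sim_config: delta_scanner must have one entry per scanner (total %d)",
          sum(scanners_per_center))
  }
  if (any(delta_center <= 0) || any(delta_scanner <= 0)) {
    stopf("sim_config: multiplicative effects must be positive")
  }
  if (noise_sd <= 0) stopf("sim_config: noise_sd must be > 0")
  if (!is.null(survival) && survival$scale <= 0) {
    stopf("sim_config: survival baseline scale must be > 0")
  }
  cfg <- list(n_patients_per_center = as.integer(n_patients_per_center),
              lesion_mean = lesion_mean, min_lesions = as.integer(min_lesions),
              latent_dim = as.integer(latent_dim),
              feature_dim = as.integer(feature_dim),
              scanners_per_center = as.integer(scanners_per_center),
              center_effect_sd = center_effect_sd,
              scanner_effect_sd = scanner_effect_sd,
              delta_center = delta_center, delta_scanner = delta_scanner,
              delta_feature_sdlog = delta_feature_sdlog,
              interaction_strength = interaction_strength,
              nonlinear_strength = nonlinear_strength,
              heterogeneity_meanlog = heterogeneity_meanlog,
              heterogeneity_sdlog = heterogeneity_sdlog,
              noise_sd = noise_sd, survival = survival,
              loading_seed = as.integer(loading_seed), seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

#' Null-effect variant of a simulation configuration
#'
#' Sets every batch-effect magnitude to its neutral value (additive 0,
#' multiplicative 1, no interaction or warp) so the confounded table
#' equals the clean table exactly.
#'
#' @param config a `sim_config`
#' @return a `sim_config` with no batch effects
#' @export
null_effect_config <- function(config) {
  config$center_effect_sd <- 0
  config$scanner_effect_sd <- 0
  config$delta_center[] <- 1
  config$delta_scanner[] <- 1
  config$delta_feature_sdlog <- 0
  config$interaction_strength <- 0
  config$nonlinear_strength <- 0
  config
}

# fixed structural parameters drawn once from loading_seed: the latent ->
# feature loading (6 column-blocks sharing latent factors, emulating the 6
# radiomic feature families), the batch-effect vectors, and warp masks
sim_structure <- function(config) {
  q <- config$latent_dim
  d <- config$feature_dim
  n_centers <- length(config$n_patients_per_center)
  n_scanners <- sum(config$scanners_per_center)
  with_seed(config$loading_seed, {
    blocks <- sort(rep_len(seq_len(6), d))
    W <- matrix(stats::rnorm(q * d), q, d)
    for (b in seq_len(6)) {
      active <- c((b - 1) %% q + 1, b %% q + 1)
      w <- rep(0.15, q)
      w[active] <- 1
      W[, blocks == b] <- W[, blocks == b] * w
    }
    # unit-scale patterns scaled afterwards: the same loading_seed yields
    # proportional effects across strength settings
    gamma_center <- matrix(stats::rnorm(n_centers * d), n_centers, d) * config$center_effect_sd
    gamma_scanner <- matrix(stats::rnorm(n_scanners * d), n_scanners, d) * config$scanner_effect_sd
    interaction_shift <- matrix(stats::rnorm(n_scanners * d), n_scanners, d) *
      config$interaction_strength
    warp_mask <- matrix(sample(c(-1, 1), n_centers * d, replace = TRUE), n_centers, d)
    fsd <- config$delta_feature_sdlog
    delta_center_f <- exp(sweep(matrix(stats::rnorm(n_centers * d, sd = fsd),
                                       n_centers, d),
                                1, log(config$delta_center), "+"))
    delta_scanner_f <- exp(sweep(matrix(stats::rnorm(n_scanners * d, sd = fsd),
                                        n_scanners, d),
                                 1, log(config$delta_scanner), "+"))
    list(W = W, blocks = blocks, gamma_center = gamma_center,
         gamma_scanner = gamma_scanner, interaction_shift = interaction_shift,
         warp_mask = warp_mask, delta_center_f = delta_center_f,
         delta_scanner_f = delta_scanner_f)
  })
}

#' Generate a synthetic multi-center cohort
#'
#' Produces a clean lesion table (latent signal + lesion noise), its
#' confounded counterpart with center/scanner batch effects injected in
#' the location/scale generative form
#' \eqn{Y = signal + \gamma_c + \gamma_s + interaction + warp +
#' \delta_c\delta_s\,\sigma\epsilon}, a survival table whose hazard is
#' linked to the patient's true heterogeneity and centroid score, and the
#' ground truth needed for parameter-recovery tests.
#'
#' @param config a `sim_config`
#' @return list with `clean` and `confounded` (`lesion_table`s sharing ids),
#'   `survival` (`survival_table` or NULL), and `ground_truth` (latents,
#'   per-patient heterogeneity, batch parameters, hazard linear predictor)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  st <- sim_structure(config)
  q <- config$latent_dim
  d <- config$feature_dim
  n_centers <- length(config$n_patients_per_center)
  scanner_of_center <- rep(seq_len(n_centers), config$scanners_per_center)

  cohort <- with_seed(config$seed, {
    pats <- list()
    pid <- 0L
    for (ce in seq_len(n_centers)) {
      local_scanners <- which(scanner_of_center == ce)
      for (i in seq_len(config$n_patients_per_center[ce])) {
        pid <- pid + 1L
        k <- max(config$min_lesions, stats::rpois(1, config$lesion_mean))
        pats[[pid]] <- list(
          patient_id = sprintf("P%03d", pid), center = ce,
          scanner = local_scanners[sample.int(length(local_scanners), 1)],
          n_lesions = k,
          u = stats::rnorm(q),
          h = stats::rlnorm(1, config$heterogeneity_meanlog, config$heterogeneity_sdlog))
      }
    }
    n_total <- sum(vapply(pats, `[[`, 0L, "n_lesions"))
    Z <- matrix(0, n_total, q)
    E <- matrix(stats::rnorm(n_total * d), n_total, d)
    patient_id <- character(n_total); center <- integer(n_total)
    scanner <- integer(n_total); het <- numeric(n_total)
    row <- 0L
    for (p in pats) {
      idx <- row + seq_len(p$n_lesions)
      Z[idx, ] <- matrix(p$u, p$n_lesions, q, byrow = TRUE) +
        p$h * matrix(stats::rnorm(p$n_lesions * q), p$n_lesions, q)
      patient_id[idx] <- p$patient_id
      center[idx] <- p$center
      scanner[idx] <- p$scanner
      het[idx] <- p$h
      row <- row + p$n_lesions
    }
    list(pats = pats, Z = Z, E = E, patient_id = patient_id,
         center = center, scanner = scanner)
  })

  Z <- cohort$Z
  signal <- Z %*% st$W
  noise <- config$noise_sd * cohort$E
  clean_m <- signal + noise

  ce <- cohort$center
  sc <- cohort$scanner
  # delta multiplies the full residual around the grand mean (biological
  # deviation + lesion noise): with an intercept-only design that whole
  # term is the epsilon of the location/scale model, so a scanner's scale
  # effect rescales the patient clouds themselves, not just the noise floor
  mult <- st$delta_center_f[ce, , drop = FALSE] * st$delta_scanner_f[sc, , drop = FALSE]
  conf_m <- st$gamma_center[ce, , drop = FALSE] +
    st$gamma_scanner[sc, , drop = FALSE] +
    st$interaction_shift[sc, , drop = FALSE] +
    config$nonlinear_strength * st$warp_mask[ce, , drop = FALSE] * tanh(signal) +
    mult * (signal + noise)

  ids <- sprintf("L%05d", seq_len(nrow(clean_m)))
  base <- data.frame(lesion_id = ids, patient_id = cohort$patient_id,
                     center = paste0("C", ce), scanner = paste0("S", sc),
                     stringsAsFactors = FALSE)
  mk <- function(m) {
    colnames(m) <- paste0("f", seq_len(ncol(m)))
    lesion_table(cbind(base, as.data.frame(m)))
  }

  pats <- cohort$pats
  patient_ids <- vapply(pats, `[[`, "", "patient_id")
  h_p <- vapply(pats, `[[`, 0, "h")
  u_p <- t(vapply(pats, `[[`, numeric(q), "u"))
  centroid_score <- u_p[, 1]
  surv_cfg <- config$survival
  eta <- if (is.null(surv_cfg)) NULL else
    surv_cfg$beta_h * h_p + surv_cfg$beta_m * centroid_score

  gt <- structure(list(
    latents = Z, loading = st$W, blocks = st$blocks,
    patient_ids = patient_ids, heterogeneity = h_p,
    latent_means = u_p, centroid_score = centroid_score,
    gamma_center = st$gamma_center, gamma_scanner = st$gamma_scanner,
    delta_center = st$delta_center_f, delta_scanner = st$delta_scanner_f,
    interaction_shift = st$interaction_shift, warp_mask = st$warp_mask,
    linear_predictor = eta), class = "ground_truth")

  survival <- if (is.null(surv_cfg)) NULL else generate_survival(gt, config)
  list(clean = mk(clean_m), confounded = mk(conf_m),
       survival = survival, ground_truth = gt)
}

#' Generate heterogeneity-linked survival outcomes
#'
#' Weibull proportional-hazards event times with linear predictor
#' \eqn{\eta_p = \beta_h h_p + \beta_m m_p} (heterogeneity and centroid
#' score); uniform censoring times are calibrated so the expected censored
#' fraction matches the configured target.
#'
#' @param ground_truth a `ground_truth` object from [generate_cohort()]
#' @param config the `sim_config` used for generation
#' @return a `survival_table`
#' @export
generate_survival <- function(ground_truth, config) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  s <- config$survival
  if (s$scale <= 0) stopf("generate_survival: baseline scale must be > 0")
  eta <- s$beta_h * ground_truth$heterogeneity +
    s$beta_m * ground_truth$centroid_score
  eta <- eta - mean(eta)
  with_seed(derive_seed(config$seed, 7L), {
    u <- stats::runif(length(eta))
    t_event <- s$scale * (-log(u) / exp(eta))^(1 / s$shape)
    if (is.null(s$censoring) || s$censoring <= 0) {
      time <- t_event; event <- rep(1, length(eta))
    } else {
      # with C ~ U(0, tau): P(censored_i) = min(t_i, tau)/tau; solve for tau
      target <- s$censoring
      f <- function(log_tau) mean(pmin(t_event / exp(log_tau), 1)) - target
      lo <- log(min(t_event)) - 5; hi <- log(max(t_event)) + 5
      tau <- exp(stats::uniroot(f, c(lo, hi))$root)
      cens <- stats::runif(length(eta), 0, tau)
      time <- pmin(t_event, cens)
      event <- as.numeric(t_event <= cens)
    }
    survival_table(data.frame(patient_id = ground_truth$patient_ids,
                              time = pmax(time, 1e-8), event = event,
                              stringsAsFactors = FALSE))
  })
}

#' Write a generated cohort to a directory
#'
#' Emits `lesions_clean.csv`, `lesions_confounded.csv`, `survival.csv`
#' and `ground_truth.json` (batch parameters, per-patient heterogeneity,
#' hazard linear predictors).
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lesion_table(cohort$clean, file.path(dir, "lesions_clean.csv"))
  write_lesion_table(cohort$confounded, file.path(dir, "lesions_confounded.csv"))
  if (!is.null(cohort$survival)) {
    write_survival_table(cohort$survival, file.path(dir, "survival.csv"))
  }
  gt <- cohort$ground_truth
  jsonlite::write_json(list(
    patient_ids = gt$patient_ids,
    heterogeneity = gt$heterogeneity,
    centroid_score = gt$centroid_score,
    linear_predictor = gt$linear_predictor,
    gamma_center = gt$gamma_center,
    gamma_scanner = gt$gamma_scanner,
    delta_center = gt$delta_center,
    delta_scanner = gt$delta_scanner
  ), file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = FALSE)
  invisible(dir)
}
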