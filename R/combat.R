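#' Location/scale ComBat batch correction
#'
#' Fits the location/scale model
#' \eqn{Y_{ijf} = a_f + X\beta_f + \gamma_{if} + \delta_{if}\epsilon_{ijf}}
#' for one batch factor: per-feature grand intercept and covariate
#' coefficients by (optionally ridge-penalized) least squares, per-batch
#' additive effects \eqn{\gamma_{if}} and multiplicative effects
#' \eqn{\delta_{if}} on standardized residuals. In `eb-parametric` mode
#' the batch effects are shrunk toward batch-level priors (normal for
#' gamma, inverse-gamma for delta-squared, hyperparameters by method of
#' moments) via the standard iterative conditional posterior means;
#' `ls-only` keeps the raw per-batch moments.
#'
#' A positive `ridge` gives the ridge-regularized variant (ReComBat):
#' the L2 penalty acts on the covariate coefficients, guarding against
#' singular designs.
#'
#' @param table a `lesion_table`
#' @param batch_factor `"center"` or `"scanner"`
#' @param design optional numeric covariate matrix (no intercept column;
#'   one row per lesion). Default NULL: intercept-only.
#' @param mode `"eb-parametric"` (default) or `"ls-only"`
#' @param ridge L2 penalty on covariate coefficients (>= 0; 0 = plain
#'   ComBat)
#' @param tol,max_iter convergence control of the EB iteration
#' @return object of class `combat_model`
#' @export
combat_fit <- function(table, batch_factor = c("center", "scanner"),
                       design = NULL, mode = c("eb-parametric", "ls-only"),
                       ridge = 0, tol = 1e-6, max_iter = 500) {
  batch_factor <- match.arg(batch_factor)
  mode <- match.arg(mode)
  y <- feature_matrix(table)
  batch <- factor(table[[batch_factor]])
  n <- nrow(y); d <- ncol(y)
  counts <- table(batch)
  if (any(counts < 2)) {
    stopf("combat_fit error: batch '%s' has %d sample(s); every batch needs >= 2",
          names(counts)[which.min(counts)], min(counts))
  }
  if (!is.null(design)) {
    design <- as.matrix(design)
    stopifnot(nrow(design) == n)
  }

  # batch-indicator + covariate regression; grand mean is the
  # batch-size-weighted combination of batch intercepts
  B <- if (nlevels(batch) == 1) matrix(1, n, 1) else stats::model.matrix(~ batch - 1)
  X <- if (is.null(design)) B else cbind(B, design)
  n_b <- nlevels(batch)
  if (ridge > 0) {
    pen <- diag(c(rep(0, n_b), rep(ridge, ncol(X) - n_b)), ncol(X))
    beta <- solve(crossprod(X) + pen, crossprod(X, y))
  } else {
    xtx <- crossprod(X)
    if (rcond(xtx) < .Machine$double.eps * 100) {
      stopf("combat_fit error: singular design; refit with ridge > 0 (ReComBat)")
    }
    beta <- solve(xtx, crossprod(X, y))
  }
  batch_int <- beta[seq_len(n_b), , drop = FALSE]
  beta_cov <- if (ncol(X) > n_b) beta[-seq_len(n_b), , drop = FALSE] else NULL
  w <- as.numeric(counts) / n
  grand <- drop(w %*% batch_int)                      # a_f
  fitted_cov <- if (is.null(beta_cov)) 0 else design %*% beta_cov

  resid <- y - matrix(grand, n, d, byrow = TRUE) - fitted_cov
  # pooled per-feature variance of the full-model residual
  s2 <- colMeans((y - X %*% beta)^2)
  s <- sqrt(pmax(s2, 1e-16))
  z <- sweep(resid, 2, s, "/")

  idx <- split(seq_len(n), batch)
  gamma_hat <- t(vapply(idx, function(i) colMeans(z[i, , drop = FALSE]), numeric(d)))
  # ls-only uses the population variance so the correction is an exact
  # location/scale identity (single batch corrects to itself); EB mode uses
  # the n-1 convention of the reference parametric implementation
  delta2_hat <- t(vapply(idx, function(i) {
    zi <- z[i, , drop = FALSE]
    v <- apply(zi, 2, stats::var)
    if (mode == "ls-only") v * (nrow(zi) - 1) / nrow(zi) else v
  }, numeric(d)))
  delta2_hat <- pmax(delta2_hat, 1e-12)

  if (mode == "eb-parametric") {
    eb <- lapply(seq_len(n_b), function(b) {
      eb_shrink(gamma_hat[b, ], delta2_hat[b, ], length(idx[[b]]),
                z[idx[[b]], , drop = FALSE], tol, max_iter)
    })
    gamma_star <- t(vapply(eb, `[[`, numeric(d), "gamma"))
    delta2_star <- t(vapply(eb, `[[`, numeric(d), "delta2"))
    hyper <- lapply(eb, `[[`, "hyper")
  } else {
    gamma_star <- gamma_hat
    delta2_star <- delta2_hat
    hyper <- NULL
  }
  rownames(gamma_star) <- rownames(delta2_star) <- levels(batch)

  structure(list(batch_factor = batch_factor, batches = levels(batch),
                 mode = mode, ridge = ridge,
                 grand_mean = grand, beta_cov = beta_cov,
                 pooled_sd = s,
                 gamma_hat = gamma_hat, delta2_hat = delta2_hat,
                 gamma_star = gamma_star, delta2_star = delta2_star,
                 eb_hyper = hyper, has_design = !is.null(design)),
            class = "combat_model")
}

# parametric EB shrinkage for one batch: normal prior on gamma,
# inverse-gamma prior on delta^2, moments-matched hyperparameters,
# iterated conditional posterior means (standard parametric ComBat)
eb_shrink <- function(g_hat, d2_hat, n_b, z_b, tol, max_iter) {
  g_bar <- mean(g_hat)
  t2 <- stats::var(g_hat)
  # inverse-gamma moments for delta^2 across features
  v <- mean(d2_hat)
  s2 <- stats::var(d2_hat)
  a_prior <- (2 * s2 + v^2) / s2
  b_prior <- (v * s2 + v^3) / s2
  g_new <- g_old <- g_hat
  d2_new <- d2_old <- d2_hat
  change <- 1
  it <- 0
  while (change > tol && it < max_iter) {
    g_new <- (n_b * t2 * g_hat + d2_old * g_bar) / (n_b * t2 + d2_old)
    sum2 <- colSums((sweep(z_b, 2, g_new, "-"))^2)
    d2_new <- (0.5 * sum2 + b_prior) / (n_b / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                  abs(d2_new - d2_old) / pmax(abs(d2_old), 1e-12))
    g_old <- g_new
    d2_old <- d2_new
    it <- it + 1
  }
  list(gamma = g_new, delta2 = d2_new,
       hyper = list(gamma_bar = g_bar, tau2 = t2,
                    a_prior = a_prior, b_prior = b_prior, iterations = it))
}

#' Batch-effect estimates on the original feature scale
#'
#' @param model a `combat_model`
#' @return list with `gamma` (additive, batches x features) and `delta`
#'   (multiplicative), both rescaled by the pooled per-feature sd so they
#'   are comparable with the generative parameters
#' @export
combat_estimates <- function(model) {
  list(gamma = sweep(model$gamma_star, 2, model$pooled_sd, "*"),
       delta = sweep(sqrt(model$delta2_star), 2, model$pooled_sd, "*"))
}

#' Apply a fitted ComBat correction
#'
#' Corrects each feature as
#' \eqn{Y^* = (Y - \hat a - X\hat\beta - \hat\gamma^*) / \hat\delta^* +
#' \hat a + X\hat\beta}, using the (EB-shrunk) batch estimates stored in
#' the model. The id, center and scanner columns are never altered.
#'
#' @param model a `combat_model`
#' @param table a `lesion_table` whose batch labels are a subset of the
#'   model's batches
#' @param design covariate matrix matching the one used at fit time
#' @return corrected `lesion_table`
#' @export
combat_apply <- function(model, table, design = NULL) {
  stopifnot(inherits(model, "combat_model"))
  y <- feature_matrix(table)
  batch <- as.character(table[[model$batch_factor]])
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen) > 0) {
    stopf("combat_apply error: unseen batch label(s): %s",
          paste(unseen, collapse = ", "))
  }
  if (model$has_design && is.null(design)) {
    stopf("combat_apply error: model was fitted with covariates; supply design")
  }
  n <- nrow(y); d <- ncol(y)
  fitted_cov <- if (is.null(model$beta_cov)) 0 else as.matrix(design) %*% model$beta_cov
  mu <- matrix(model$grand_mean, n, d, byrow = TRUE) + fitted_cov
  bi <- match(batch, model$batches)
  z <- sweep(y - mu, 2, model$pooled_sd, "/")
  z_corr <- (z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta2_star[bi, , drop = FALSE])
  y_corr <- sweep(z_corr, 2, model$pooled_sd, "*") + mu
  set_features(table, y_corr)
}

#' Sequential two-factor harmonization cascade
#'
#' Applies ComBat (or ReComBat) once per factor, in the given order, each
#' step consuming the previous step's corrected table — e.g.
#' `c("center", "scanner")` for the center-then-scanner cascade.
#'
#' @param table a `lesion_table`
#' @param factors ordered character vector of batch factors
#' @param method `"combat"` or `"recombat"` (recycled per step)
#' @param ridge ridge strength per step (default 0 for combat, 1e-3 for
#'   recombat)
#' @param mode EB mode passed to [combat_fit()]
#' @return list with `table` (corrected) and `models` (one per step)
#' @export
sequential_harmonize <- function(table, factors = c("center", "scanner"),
                                 method = "combat", ridge = NULL,
                                 mode = "eb-parametric") {
  if (length(factors) < 1) stopf("sequential_harmonize: empty factor list")
  if (anyDuplicated(factors)) stopf("sequential_harmonize: factors must be distinct")
  method <- rep_len(method, length(factors))
  if (is.null(ridge)) ridge <- ifelse(method == "recombat", 1e-3, 0)
  ridge <- rep_len(ridge, length(factors))
  models <- vector("list", length(factors))
  out <- table
  for (i in seq_along(factors)) {
    step <- tryCatch({
      m <- combat_fit(out, batch_factor = factors[i], mode = mode, ridge = ridge[i])
      list(model = m, table = combat_apply(m, out))
    }, error = function(e) {
      stopf("sequential_harmonize: step %d (%s) failed: %s",
            i, factors[i], conditionMessage(e))
    })
    models[[i]] <- step$model
    out <- step$table
  }
  names(models) <- factors
  list(table = out, models = models)
}

#' Order selection for sequential multi-factor correction
#'
#' A simplified order selector in the spirit of nested-ComBat pipelines:
#' every permutation of the factors is harmonized sequentially, residual
#' batch association is counted per (feature, factor) pair with a
#' Kruskal-Wallis test at level `alpha`, and the order leaving the fewest
#' significant associations wins. Ties go to the first permutation in
#' lexicographic enumeration.
#'
#' @param table a `lesion_table`
#' @param factors character vector of >= 2 batch factors
#' @param alpha significance level of the residual association test
#' @param method,mode passed to [sequential_harmonize()]
#' @return list with `best_order`, `table` (corrected with the best
#'   order), and `report` (data.frame of association counts per order)
#' @export
opnested_select_order <- function(table, factors = c("center", "scanner"),
                                  alpha = 0.05, method = "combat",
                                  mode = "eb-parametric") {
  if (length(factors) < 2) stopf("opnested_select_order: need >= 2 factors")
  perms <- permutations_of(sort(factors))
  counts <- integer(length(perms))
  corrected <- vector("list", length(perms))
  for (i in seq_along(perms)) {
    res <- sequential_harmonize(table, perms[[i]], method = method, mode = mode)
    corrected[[i]] <- res$table
    m <- feature_matrix(res$table)
    cnt <- 0L
    for (fac in factors) {
      g <- factor(res$table[[fac]])
      if (nlevels(g) < 2) next
      for (j in seq_len(ncol(m))) {
        p <- stats::kruskal.test(m[, j], g)$p.value
        if (is.finite(p) && p < alpha) cnt <- cnt + 1L
      }
    }
    counts[i] <- cnt
  }
  best <- which.min(counts)  # which.min returns the first minimum: lexicographic tie-break
  report <- data.frame(order = vapply(perms, paste, "", collapse = ","),
                       significant_pairs = counts, stringsAsFactors = FALSE)
  list(best_order = perms[[best]], table = corrected[[best]], report = report)
}

# all permutations in lexicographic order of the (sorted) input
permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Export a ComBat model's parameters as JSON
#' @param model a `combat_model`
#' @param path output path
#' @export
write_combat_model <- function(model, path) {
  jsonlite::write_json(list(
    batch_factor = model$batch_factor, batches = model$batches,
    mode = model$mode, ridge = model$ridge,
    grand_mean = model$grand_mean, pooled_sd = model$pooled_sd,
    gamma_hat = model$gamma_hat, delta2_hat = model$delta2_hat,
    gamma_star = model$gamma_star, delta2_star = model$delta2_star),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
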