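test_that("single-batch ls-only correction is the identity", {
  tab <- random_lesion_table(n = 30, d = 6, seed = 2)
  df <- as.data.frame(tab); df$center <- "only"; tab <- lesion_table(df)
  model <- combat_fit(tab, "center", mode = "ls-only")
  out <- combat_apply(model, tab)
  expect_lt(max(abs(feature_matrix(out) - feature_matrix(tab))), 1e-8)
})

test_that("batch parameters are recovered from the generative model", {
  tab <- ls_model_table(seed = 3)
  model <- combat_fit(tab, "center", mode = "eb-parametric")
  est <- combat_estimates(model)
  # estimates are relative to the weighted grand mean (here 0 since the
  # batch sizes are equal and gamma is symmetric)
  expect_lt(mean(abs(est$gamma[1, ] - (-1))), 0.1)
  expect_lt(mean(abs(est$gamma[2, ] - 1)), 0.1)
  expect_lt(mean(abs(est$delta[1, ] / 0.5 - 1)), 0.1)
  expect_lt(mean(abs(est$delta[2, ] / 2 - 1)), 0.1)
})

test_that("correction matches first and second moments across batches", {
  tab <- ls_model_table(seed = 4)
  # exact location/scale removal (no shrinkage bias) in ls-only mode
  out_ls <- feature_matrix(combat_apply(combat_fit(tab, "center", mode = "ls-only"), tab))
  b <- tab$center
  mu_diff <- abs(colMeans(out_ls[b == "B1", ]) - colMeans(out_ls[b == "B2", ]))
  expect_lt(max(mu_diff / apply(out_ls, 2, sd)), 0.05)
  # EB shrinkage trades a little moment bias for stability: variances must
  # still match within 10%
  out_eb <- feature_matrix(combat_apply(combat_fit(tab, "center"), tab))
  v1 <- apply(out_eb[b == "B1", ], 2, var); v2 <- apply(out_eb[b == "B2", ], 2, var)
  expect_true(all(v1 / v2 > 0.9 & v1 / v2 < 1.1))
})

test_that("EB shrinks batch effects relative to raw moments", {
  shrunk <- raw <- numeric(100)
  for (i in 1:100) {
    tab <- ls_model_table(n_per_batch = 10, d = 45, gamma = c(-0.5, 0.5),
                          delta = c(0.8, 1.25), seed = 100 + i)
    eb <- combat_fit(tab, "center", mode = "eb-parametric")
    ls <- combat_fit(tab, "center", mode = "ls-only")
    shrunk[i] <- var(eb$gamma_star[1, ])
    raw[i] <- var(ls$gamma_hat[1, ])
  }
  expect_gt(mean(shrunk < raw), 0.95)
})

test_that("null batch parameters give the identity transform", {
  tab <- random_lesion_table(n = 20, d = 5, seed = 6)
  model <- combat_fit(tab, "center", mode = "ls-only")
  model$gamma_star[] <- 0
  model$delta2_star[] <- 1
  model$grand_mean[] <- 0
  out <- combat_apply(model, tab)
  expect_lt(max(abs(feature_matrix(out) - feature_matrix(tab))), 1e-10)
})

test_that("correction is idempotent: re-fit on corrected data finds no effects", {
  tab <- ls_model_table(n_per_batch = 200, d = 10, seed = 7)
  out <- combat_apply(combat_fit(tab, "center"), tab)
  refit <- combat_fit(out, "center")
  est <- combat_estimates(refit)
  expect_lt(max(abs(est$gamma)), 1e-2)
  out2 <- combat_apply(refit, out)
  expect_lt(max(abs(feature_matrix(out2) - feature_matrix(out))), 0.05)
})

test_that("a batch with one sample is rejected", {
  with_seed_test(8, m <- matrix(rnorm(10 * 4), 10, 4))
  colnames(m) <- paste0("f", 1:4)
  df <- cbind(data.frame(lesion_id = paste0("L", 1:10),
                         patient_id = paste0("P", 1:10),
                         center = c("A", rep("B", 9)), scanner = "S1",
                         stringsAsFactors = FALSE), as.data.frame(m))
  expect_error(combat_fit(lesion_table(df), "center"), "needs >= 2")
})

test_that("unseen batch labels are an apply error", {
  tab <- ls_model_table(n_per_batch = 20, d = 4, seed = 9)
  model <- combat_fit(tab, "center")
  df <- as.data.frame(tab); df$center <- "NEW"
  expect_error(combat_apply(model, lesion_table(df)), "unseen batch")
})

test_that("ls-only correction on balanced batches equalizes means exactly", {
  tab <- ls_model_table(n_per_batch = 100, d = 8, seed = 10)
  out <- combat_apply(combat_fit(tab, "center", mode = "ls-only"), tab)
  m <- feature_matrix(out)
  mu1 <- colMeans(m[tab$center == "B1", ])
  mu2 <- colMeans(m[tab$center == "B2", ])
  expect_lt(max(abs(mu1 - mu2)), 1e-8)
})

test_that("ridge-regularized estimates converge to plain ComBat as ridge -> 0", {
  tab <- ls_model_table(n_per_batch = 150, d = 10, seed = 11)
  design <- with_seed_test(12, matrix(rnorm(nrow(tab) * 2), ncol = 2))
  plain <- combat_fit(tab, "center", design = design, ridge = 0)
  reg <- combat_fit(tab, "center", design = design, ridge = 1e-10)
  expect_lt(max(abs(plain$beta_cov - reg$beta_cov)), 1e-6)
  expect_lt(max(abs(plain$gamma_star - reg$gamma_star)), 1e-6)
})

test_that("correction never alters the id and label columns", {
  tab <- fx_small()$confounded
  out <- sequential_harmonize(tab, c("center", "scanner"))$table
  expect_identical(out$lesion_id, tab$lesion_id)
  expect_identical(out$patient_id, tab$patient_id)
  expect_identical(out$center, tab$center)
  expect_identical(out$scanner, tab$scanner)
})

test_that("a one-factor plan equals plain fit + apply", {
  tab <- ls_model_table(n_per_batch = 50, d = 6, seed = 13)
  seq1 <- sequential_harmonize(tab, "center")$table
  direct <- combat_apply(combat_fit(tab, "center"), tab)
  expect_equal(feature_matrix(seq1), feature_matrix(direct), tolerance = 1e-12)
})

test_that("both cascade orders deconfound an additive-only cohort", {
  cfg <- sim_config(n_patients_per_center = c(90, 60), seed = 14,
                    delta_center = c(1, 1), delta_scanner = rep(1, 5),
                    delta_feature_sdlog = 0, interaction_strength = 0,
                    nonlinear_strength = 0)
  co <- generate_cohort(cfg)
  std <- standardize(co$confounded)$table
  for (ord in list(c("center", "scanner"), c("scanner", "center"))) {
    out <- sequential_harmonize(std, ord)$table
    acc <- confounder_accuracy(feature_matrix(out), out$center,
                               n_trials = 20, seed = 1)
    expect_lt(abs(acc$mean - acc$prevalence), 0.08)
  }
})

test_that("cascade order matters once interactions are present", {
  std <- fx_std()$table
  cs <- sequential_harmonize(std, c("center", "scanner"))$table
  sc <- sequential_harmonize(std, c("scanner", "center"))$table
  expect_gt(max(abs(feature_matrix(cs) - feature_matrix(sc))), 0.01)
})

test_that("order selection breaks ties deterministically and bounds its counts", {
  tab <- ls_model_table(n_per_batch = 60, d = 6, seed = 15)
  # center and scanner coincide here, so both orders are equivalent
  sel <- opnested_select_order(tab, c("center", "scanner"))
  expect_identical(sel$best_order, c("center", "scanner"))
  expect_true(all(sel$report$significant_pairs >= 0))
  expect_true(all(sel$report$significant_pairs <= 6 * 2))
  sel2 <- opnested_select_order(tab, c("center", "scanner"))
  expect_identical(sel$report, sel2$report)
})

test_that("order selection prefers the order that removes nested effects better", {
  hits <- 0
  for (r in 1:10) {
    cfg <- sim_config(n_patients_per_center = c(30, 20), feature_dim = 15,
                      seed = 400 + r,
                      center_effect_sd = 0.2, scanner_effect_sd = 1.5,
                      delta_center = c(1, 1),
                      delta_scanner = c(0.5, 2, 0.8, 1.6, 1),
                      delta_feature_sdlog = 0.3,
                      interaction_strength = 0.4, nonlinear_strength = 0)
    co <- generate_cohort(cfg)
    std <- standardize(co$confounded)$table
    sel <- opnested_select_order(std, c("center", "scanner"))
    counts <- sel$report$significant_pairs
    if (identical(sel$best_order, c("scanner", "center")) ||
        counts[1] == counts[2]) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a brute-force per-feature loop reproduces the vectorized correction", {
  for (s in 1:5) {
    tab <- ls_model_table(n_per_batch = 40, d = 5, gamma = c(-0.7, 0.4),
                          delta = c(0.7, 1.5), seed = 500 + s)
    model <- combat_fit(tab, "center", mode = "eb-parametric")
    fast <- feature_matrix(combat_apply(model, tab))

    y <- feature_matrix(tab)
    slow <- y * NA
    batches <- model$batches
    for (f in seq_len(ncol(y))) {
      for (i in seq_len(nrow(y))) {
        b <- match(tab$center[i], batches)
        z <- (y[i, f] - model$grand_mean[f]) / model$pooled_sd[f]
        z_star <- (z - model$gamma_star[b, f]) / sqrt(model$delta2_star[b, f])
        slow[i, f] <- z_star * model$pooled_sd[f] + model$grand_mean[f]
      }
    }
    expect_lt(max(abs(fast - slow)), 1e-10)
  }
})

test_that("the correction agrees with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  tab <- ls_model_table(n_per_batch = 80, d = 12, seed = 16)
  model <- combat_fit(tab, "center", mode = "eb-parametric")
  ours <- feature_matrix(combat_apply(model, tab))
  ref <- t(suppressMessages(
    sva::ComBat(dat = t(feature_matrix(tab)), batch = factor(tab$center))))
  expect_lt(max(abs(ours - ref)), 1e-3)
})
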