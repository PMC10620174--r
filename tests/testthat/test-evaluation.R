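test_that("bootstrap accuracy is at chance for independent features", {
  with_seed_test(1, {
    x <- matrix(rnorm(400 * 10), 400, 10)
    y <- rep(c("A", "B"), each = 200)
  })
  acc <- confounder_accuracy(x, y, n_trials = 50, seed = 2)
  expect_lt(abs(acc$mean - 0.5), 0.05)
  expect_length(acc$accuracies, 50)
  expect_true(all(acc$accuracies >= 0 & acc$accuracies <= 1))
})

test_that("a leaked label gives near-perfect accuracy", {
  with_seed_test(3, {
    x <- matrix(rnorm(200 * 5), 200, 5)
    y <- rep(c("A", "B"), each = 100)
  })
  x_leak <- cbind(x, leak = as.numeric(y == "A"))
  acc <- confounder_accuracy(x_leak, y, n_trials = 20, seed = 4)
  expect_gte(acc$mean, 0.99)
})

test_that("accuracy trials are paired by seed across feature sets", {
  with_seed_test(5, x <- matrix(rnorm(150 * 4), 150, 4))
  y <- rep(c("A", "B", "C"), each = 50)
  a1 <- confounder_accuracy(x, y, n_trials = 10, seed = 6)
  a2 <- confounder_accuracy(x, y, n_trials = 10, seed = 6)
  expect_identical(a1$accuracies, a2$accuracies)
})

test_that("paired accuracy test follows t-test conventions", {
  mk <- function(v) structure(list(accuracies = v, mean = mean(v)),
                              class = "accuracy_distribution")
  a <- mk(rep(0.8, 20))
  expect_equal(paired_accuracy_test(a, a), 1.0)
  with_seed_test(7, {
    base <- runif(30, 0.7, 0.75)
    jit <- rnorm(30, sd = 1e-3)
  })
  b <- mk(base); c <- mk(base - 0.2 + jit)
  expect_lt(paired_accuracy_test(b, c), 1e-6)
  p_two <- paired_accuracy_test(b, c, "two.sided")
  p_one <- paired_accuracy_test(b, c, "greater")
  expect_equal(p_two, 2 * min(p_one, 1 - p_one), tolerance = 1e-12)
  expect_error(paired_accuracy_test(b, mk(base[1:10])), "different lengths")
})

test_that("patient representations match hand computations", {
  m <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("l1", "l2"), NULL))
  cen <- build_representation(m, "centroid", patient_ids = c("P1", "P1"))
  expect_equal(unname(as.matrix(cen[, -1])), matrix(c(1, 1), 1))

  m1 <- matrix(c(0, 1, 2), ncol = 1, dimnames = list(paste0("l", 1:3), NULL))
  cl <- build_representation(m1, "cloud", patient_ids = rep("P1", 3))
  expect_equal(cl$pairwise_mean, 4 / 3, tolerance = 1e-12)
  expect_equal(cl$pairwise_sd, sqrt(2 / 9), tolerance = 1e-12)
  expect_equal(cl$centroid_mean, 2 / 3, tolerance = 1e-12)
  expect_equal(cl$centroid_sd, sqrt(2 / 9), tolerance = 1e-12)

  comb <- build_representation(m1, "combined", patient_ids = rep("P1", 3))
  expect_equal(ncol(comb), 1 + 1 + 4)
})

test_that("single-lesion patients get zeroed cloud indexes with a flag", {
  m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("l", 1:3), NULL))
  r <- build_representation(m, "cloud", patient_ids = c("P1", "P1", "P2"))
  expect_equal(unname(unlist(r[r$patient_id == "P2", -1])), rep(0, 4))
  expect_identical(attr(r, "degenerate"), "P2")
})

test_that("representations are invariant to lesion order within a patient", {
  co <- fx_small()
  m <- feature_matrix(co$confounded)
  pid <- co$confounded$patient_id
  perm <- with_seed_test(8, sample(nrow(m)))
  for (kind in c("centroid", "cloud", "combined")) {
    a <- build_representation(m, kind, patient_ids = pid)
    b <- build_representation(m[perm, ], kind, patient_ids = pid[perm])
    b <- b[match(a$patient_id, b$patient_id), ]
    rownames(b) <- NULL
    expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-12)
  }
})

test_that("concordance is near 0.5 when survival is independent of features", {
  with_seed_test(9, {
    reps <- data.frame(patient_id = paste0("P", 1:150),
                       r1 = rnorm(150), r2 = rnorm(150))
    surv <- survival_table(data.frame(patient_id = paste0("P", 1:150),
                                      time = rexp(150, 0.1),
                                      event = rbinom(150, 1, 0.7)))
  })
  reps <- structure(reps, class = c("patient_representation", "data.frame"))
  pe <- prognostic_eval(reps, surv, n_splits = 20, seed = 10)
  expect_lt(abs(pe$test_mean - 0.5), 0.07)
})

test_that("a representation that generates the hazard ranks almost perfectly", {
  with_seed_test(11, {
    eta <- rnorm(120, sd = 5)
    t_event <- (-log(runif(120)) / exp(eta))^(1 / 1.5)
  })
  reps <- structure(data.frame(patient_id = paste0("P", 1:120), risk = eta),
                    class = c("patient_representation", "data.frame"))
  surv <- survival_table(data.frame(patient_id = paste0("P", 1:120),
                                    time = t_event, event = 1))
  pe <- prognostic_eval(reps, surv, n_splits = 10, seed = 12)
  expect_gte(pe$train_mean, 0.9)
})

test_that("paired concordance test is directional and guards pairing", {
  mk <- function(v, seed = 1) structure(
    list(train = v, test = v, n_splits = length(v), seed = seed,
         split_fraction = 0.7), class = "concordance_report")
  a <- mk(rep(0.7, 20))
  expect_equal(paired_concordance_test(a, a), 1.0)
  with_seed_test(13, jit <- rnorm(20, sd = 1e-3))
  b <- mk(rep(0.7, 20) + 0.05 + jit)
  expect_lt(paired_concordance_test(b, a), 1e-6)
  p_fwd <- paired_concordance_test(b, mk(rep(0.7, 20) + jit))
  p_rev <- paired_concordance_test(mk(rep(0.7, 20) + jit), b)
  expect_equal(p_fwd + p_rev, 1, tolerance = 0.02)
  expect_error(paired_concordance_test(a, mk(rep(0.7, 20), seed = 2)),
               "not paired")
})

test_that("deconfusion report flags only truly deconfounded modalities", {
  co <- fx_small()
  std <- standardize(co$confounded)$table
  x <- feature_matrix(std)
  rep_twice <- list(raw = x, same = x)
  rep1 <- deconfusion_report(rep_twice, labels = list(center = std$center),
                             n_trials = 10, seed = 1)
  expect_false(any(rep1$table$deconfounded, na.rm = TRUE))
  expect_true(all(rep1$table$p_vs_baseline >= 0.05, na.rm = TRUE))

  misaligned <- list(raw = x, other = x[rev(seq_len(nrow(x))), ])
  expect_error(deconfusion_report(misaligned, labels = list(center = std$center),
                                  n_trials = 2, seed = 1), "row-aligned")
})

test_that("report tables round trip through CSV and JSON", {
  dir <- withr::local_tempdir()
  t1 <- data.frame(modality = c("raw", "emb"), factor = "center",
                   mean = c(0.9, 0.6), sd = c(0.01, 0.02))
  write_report_tables(list(table1 = t1), dir)
  back <- utils::read.csv(file.path(dir, "table1.csv"))
  expect_equal(back$mean, t1$mean, tolerance = 1e-12)
  expect_true(file.exists(file.path(dir, "report.json")))
})
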