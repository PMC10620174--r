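test_that("neighbor ranking normalizes distances and breaks ties by id", {
  pts <- matrix(c(0, 1, 2, 4), ncol = 1,
                dimnames = list(c("a", "b", "c", "d"), NULL))
  cl <- point_cloud(pts)
  nr <- neighbor_ranking(cl, "a")
  expect_identical(nr$ranked_ids, c("b", "c", "d"))
  expect_equal(unname(nr$rank[c("b", "c", "d")]), c(1, 2, 3))
  expect_equal(unname(nr$score[c("b", "c", "d")]), c(0.25, 0.5, 1.0))

  tie <- point_cloud(matrix(c(0, 1, -1), ncol = 1,
                            dimnames = list(c("m", "zz", "aa"), NULL)))
  nt <- neighbor_ranking(tie, "m")
  expect_identical(nt$ranked_ids, c("aa", "zz"))

  two <- point_cloud(matrix(c(0, 3), ncol = 1,
                            dimnames = list(c("x", "y"), NULL)))
  n2 <- neighbor_ranking(two, "x")
  expect_equal(unname(n2$rank[["y"]]), 1)
  expect_equal(unname(n2$score[["y"]]), 1.0)
  expect_error(neighbor_ranking(two, "nope"), "not in cloud")
})

test_that("the footrule matches hand-computed and capped examples", {
  expect_equal(footrule(c("A", "B", "C"), c("A", "B", "C"), 3), 0)
  expect_equal(footrule(c("A", "B", "C"), c("C", "B", "A"), 3), 4)
  expect_equal(footrule(c("A", "B"), c("B", "A"), 1), 2)
  expect_error(footrule(c("A", "A"), c("A", "B")), "duplicate")
})

test_that("point semantic drift weighs rank changes by score changes", {
  mk <- function(ids_ranked, scores, anchor = "x") {
    r <- seq_along(ids_ranked); names(r) <- ids_ranked
    structure(list(anchor = anchor, ranked_ids = ids_ranked,
                   rank = r, score = scores), class = "neighbor_ranking")
  }
  orig <- mk(c("a", "b", "c"), c(a = 0.2, b = 0.5, c = 1.0))
  transf <- mk(c("b", "a", "c"), c(a = 0.6, b = 0.3, c = 1.0))
  expect_equal(point_semantic_drift(orig, transf, k = 3), 0.6)
  expect_equal(point_semantic_drift(orig, orig, k = 3), 0)
  bad <- mk(c("a", "b", "c"), c(a = 0.2, b = 0.5, c = 1.0), anchor = "other")
  expect_error(point_semantic_drift(orig, bad), "different anchors")
})

test_that("pcsd is zero under identity, rigid motion and scaling", {
  pair <- random_cloud_pair(K = 6, dim = 3, seed = 5)
  cl <- pair$orig
  expect_equal(as.numeric(pcsd(cl, cl)), 0)
  expect_equal(as.numeric(pcsd(cl, point_cloud(cl$points * 10))), 0)

  with_seed_test(6, {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    shift <- rnorm(3)
  })
  moved <- sweep(cl$points %*% q, 2, shift, "+")
  expect_lt(as.numeric(pcsd(cl, point_cloud(moved))), 1e-9)
})

test_that("pcsd on a hand-built 3-point swap equals the anchor-wise mean", {
  orig <- point_cloud(matrix(c(0, 1.1, 2), ncol = 1,
                             dimnames = list(c("a", "b", "c"), NULL)))
  transf <- point_cloud(matrix(c(0, 2.2, 1), ncol = 1,
                               dimnames = list(c("a", "b", "c"), NULL)))
  manual <- mean(vapply(c("a", "b", "c"), function(anchor) {
    point_semantic_drift(neighbor_ranking(orig, anchor),
                         neighbor_ranking(transf, anchor), k = 2)
  }, 0))
  expect_equal(as.numeric(pcsd(orig, transf)), manual, tolerance = 1e-12)
})

test_that("clouds with mismatched lesions or K < 3 are handled", {
  pair <- random_cloud_pair(K = 4, dim = 2, seed = 7)
  other <- point_cloud(pair$transf$points[1:3, ])
  expect_error(pcsd(pair$orig, other), "different lesion-id sets")
  two <- point_cloud(pair$orig$points[1:2, ])
  v <- pcsd(two, point_cloud(pair$transf$points[1:2, ]))
  expect_true(attr(v, "degenerate"))
  expect_equal(as.numeric(v), 0)
})

test_that("vectorized statistics agree with the brute-force oracle", {
  for (i in 1:60) {
    K <- 3 + (i %% 6)
    dim <- c(2, 16, 45)[1 + (i %% 3)]
    pair <- random_cloud_pair(K, dim, seed = 1000 + i)
    fast <- as.numeric(pcsd(pair$orig, pair$transf))
    slow <- oracle_pcsd(pair$orig$points, pair$transf$points[pair$ids, , drop = FALSE],
                        pair$ids)
    expect_lt(abs(fast - slow), 1e-12)
    # truncated variant
    kk <- max(1, K - 2)
    fast_k <- as.numeric(pcsd(pair$orig, pair$transf, k = kk))
    slow_k <- oracle_pcsd(pair$orig$points, pair$transf$points[pair$ids, , drop = FALSE],
                          pair$ids, k = kk)
    expect_lt(abs(fast_k - slow_k), 1e-12)
  }
})

test_that("null draws behave: zero noise, determinism, positivity", {
  clouds <- lapply(1:8, function(i) random_cloud_pair(5, 4, seed = 30 + i)$orig)
  names(clouds) <- paste0("P", 1:8)
  expect_true(all(null_pcsd(clouds, n_iter = 5, noise_variance = 0, seed = 1) == 0))
  d1 <- null_pcsd(clouds, n_iter = 10, seed = 9)
  d2 <- null_pcsd(clouds, n_iter = 10, seed = 9)
  expect_identical(d1, d2)
  d3 <- null_pcsd(clouds, n_iter = 100, noise_variance = 3, seed = 2)
  expect_true(all(d3 > 0))
  expect_error(null_pcsd(clouds, n_iter = 0), "n_iter")
})

test_that("empirical p is the left-tail fraction of null draws", {
  expect_equal(pcsd_empirical_p(0, c(0.5, 1, 2)), 0)
  expect_equal(pcsd_empirical_p(10, c(0.5, 1, 2)), 1)
  draws <- c(rep(0.1, 7), rep(5, 93))
  expect_equal(pcsd_empirical_p(0.2, draws), 0.07)
  expect_error(pcsd_empirical_p(1, numeric(0)), "empty")
})

test_that("mean pcsd grows with the perturbation variance", {
  clouds <- lapply(1:50, function(i) random_cloud_pair(6, 8, seed = 600 + i)$orig)
  names(clouds) <- paste0("P", 1:50)
  means <- vapply(c(0, 0.5, 1, 2, 4), function(v) {
    mean(null_pcsd(clouds, n_iter = 8, noise_variance = v, seed = 77))
  }, 0)
  expect_true(all(diff(means) >= 0))
})

test_that("drift test composes the statistic, the null and the p-value", {
  co <- fx_small()
  std <- standardize(co$confounded)$table
  orig <- clouds_from_table(std)
  shrunk <- clouds_from_table(feature_matrix(std)[, 1:20] * 0.5,
                              patient_ids = std$patient_id)
  res <- drift_test(orig, shrunk[names(orig)], n_iter = 30, seed = 3)
  expect_s3_class(res, "drift_result")
  expect_equal(res$p_value, mean(res$null_draws < res$observed_mean))
  expect_true(all(res$per_patient >= 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_drift_report(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$p_value, res$p_value)
  expect_equal(back$observed_mean, res$observed_mean)
})
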