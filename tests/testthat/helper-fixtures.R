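# Shared fixtures, memoized so expensive objects (the default synthetic
# cohort and the trained dual AD-AE) are built once per test run.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, build) {
  if (!exists(name, envir = .fx)) assign(name, build(), envir = .fx)
  get(name, envir = .fx)
}

fx_cohort <- function() fx_get("cohort", function() {
  generate_cohort(sim_config(seed = 1))
})

fx_std <- function() fx_get("std", function() standardize(fx_cohort()$confounded))

fx_adae <- function() fx_get("adae", function() {
  train_adae(init_adae(adae_spec(), seed = 11), fx_std()$table,
             adae_config(max_epochs = 500, seed = 21))
})

fx_embeddings <- function() fx_get("emb", function() {
  adae_encode(fx_adae(), fx_std()$table)
})

fx_combat <- function(order = c("center", "scanner")) {
  key <- paste0("combat_", paste(order, collapse = "_"))
  fx_get(key, function() sequential_harmonize(fx_std()$table, order)$table)
}

# small cohort for cheap structural tests
fx_small <- function() fx_get("small", function() {
  generate_cohort(sim_config(n_patients_per_center = c(14, 10), seed = 3))
})

# plain autoencoder (lambda = 0) trained on the standardized cohort
fx_plain_ae <- function() fx_get("plain_ae", function() {
  train_adae(init_adae(adae_spec(), seed = 11), fx_std()$table,
             adae_config(lambda_center = 0, lambda_scanner = 0,
                         max_epochs = 300, seed = 21))
})

random_lesion_table <- function(n = 10, d = 45, n_patients = 3, seed = 1) {
  with_seed_test(seed, {
    pid <- sample(paste0("P", seq_len(n_patients)), n, replace = TRUE)
    centers <- ifelse(as.integer(sub("P", "", pid)) %% 2 == 0, "A", "B")
    m <- matrix(rnorm(n * d), n, d)
    colnames(m) <- paste0("f", seq_len(d))
    lesion_table(cbind(
      data.frame(lesion_id = paste0("L", seq_len(n)), patient_id = pid,
                 center = centers, scanner = paste0("s_", centers),
                 stringsAsFactors = FALSE),
      as.data.frame(m)))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# ---- brute-force rank-statistic oracles -----------------------------------
# Deliberately naive: explicit double loops, no caching, no shared code with
# the package implementation.

oracle_ranking <- function(points, ids, anchor_idx) {
  K <- nrow(points)
  d <- numeric(0); oid <- character(0)
  for (j in seq_len(K)) {
    if (j == anchor_idx) next
    s <- 0
    for (c in seq_len(ncol(points))) s <- s + (points[j, c] - points[anchor_idx, c])^2
    d <- c(d, sqrt(s)); oid <- c(oid, ids[j])
  }
  m <- d / max(d)
  ord <- order(d, oid, method = "radix")
  list(ids_ranked = oid[ord], score = stats::setNames(m, oid))
}

oracle_footrule <- function(list_a, list_b, k) {
  universe <- union(list_a, list_b)
  total <- 0
  for (t in universe) {
    ra <- match(t, list_a); if (is.na(ra) || ra > k) ra <- k + 1
    rb <- match(t, list_b); if (is.na(rb) || rb > k) rb <- k + 1
    total <- total + abs(rb - ra)
  }
  total
}

oracle_psd <- function(rank_o, rank_t, k) {
  universe <- union(rank_o$ids_ranked, rank_t$ids_ranked)
  total <- 0
  for (t in universe) {
    ro <- match(t, rank_o$ids_ranked); if (is.na(ro) || ro > k) ro <- k + 1
    rt <- match(t, rank_t$ids_ranked); if (is.na(rt) || rt > k) rt <- k + 1
    total <- total + abs(rank_t$score[[t]] - rank_o$score[[t]]) * abs(rt - ro)
  }
  total
}

oracle_pcsd <- function(p_orig, p_transf, ids, k = NULL) {
  K <- nrow(p_orig)
  if (is.null(k)) k <- K - 1
  vals <- numeric(K)
  for (i in seq_len(K)) {
    vals[i] <- oracle_psd(oracle_ranking(p_orig, ids, i),
                          oracle_ranking(p_transf, ids, i), k)
  }
  mean(vals)
}

random_cloud_pair <- function(K, dim, seed) {
  with_seed_test(seed, {
    ids <- paste0("L", sample(100:999, K))
    a <- matrix(rnorm(K * dim), K, dim, dimnames = list(ids, NULL))
    b <- a + matrix(rnorm(K * dim, sd = 0.8), K, dim)
    rownames(b) <- ids
    list(orig = point_cloud(a), transf = point_cloud(b), ids = ids)
  })
}

# lesion table drawn exactly from the location/scale generative model:
# y_ijf = a_f + gamma_if + delta_if * eps_ijf
ls_model_table <- function(n_per_batch = 500, d = 45, gamma = c(-1, 1),
                           delta = c(0.5, 2), a = 0, seed = 1) {
  with_seed_test(seed, {
    rows <- lapply(seq_along(gamma), function(b) {
      eps <- matrix(rnorm(n_per_batch * d), n_per_batch, d)
      m <- a + gamma[b] + delta[b] * eps
      colnames(m) <- paste0("f", seq_len(d))
      cbind(data.frame(
        lesion_id = paste0("L", b, "_", seq_len(n_per_batch)),
        patient_id = paste0("P", b, "_", seq_len(n_per_batch)),
        center = paste0("B", b), scanner = paste0("S", b),
        stringsAsFactors = FALSE), as.data.frame(m))
    })
    lesion_table(do.call(rbind, rows))
  })
}

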