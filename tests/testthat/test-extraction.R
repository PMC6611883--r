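test_that("bootstrap resampling preserves per-sample totals", {
  co <- recovery_cohort(n_samples = 5, total = 800, seed = 3)
  C <- co$sim$catalog
  C[, 3] <- 0L
  B <- bootstrap_catalog(C, seed = 42)
  expect_equal(colSums(B), colSums(C))
  expect_true(all(B[, 3] == 0))
  expect_true(all(B >= 0))
})

test_that("bootstrap means match multinomial expectations", {
  co <- recovery_cohort(n_samples = 2, total = 2000, seed = 6)
  C <- co$sim$catalog
  acc <- matrix(0, 96, 2)
  n_boot <- 1000
  for (b in seq_len(n_boot)) acc <- acc + bootstrap_catalog(C, seed = b)
  m <- acc / n_boot
  tot <- colSums(C)
  p <- sweep(C, 2, tot, "/")
  se <- sqrt(sweep(p * (1 - p), 2, tot, "*") / n_boot)
  dev <- abs(m - C)
  expect_true(all(dev <= 3 * se + 1e-9))
})

test_that("NMF recovers a pure single-signature sample at K = 1", {
  s <- sigcraft:::random_sparse_signatures(1, seed = 9)[, 1]
  C <- matrix(round(1000 * s), 96, 1,
              dimnames = list(sbs96_channels(), "s1"))
  fit <- nmf_decompose(C, 1, seed = 4, max_iter = 2000, tol = 1e-9)
  expect_gt(cosine_similarity(fit$signatures[, 1], s), 0.999)
})

test_that("the NMF objective is non-increasing and runs are deterministic", {
  co <- recovery_cohort(n_samples = 8, total = 1000, seed = 12)
  C <- co$sim$catalog
  f1 <- nmf_decompose(C, 2, seed = 5, max_iter = 100, tol = 0)
  f2 <- nmf_decompose(C, 2, seed = 5, max_iter = 400, tol = 0)
  expect_lte(f2$objective, f1$objective + 1e-8)
  f3 <- nmf_decompose(C, 2, seed = 5, max_iter = 400, tol = 0)
  expect_identical(f2$signatures, f3$signatures)
  expect_identical(f2$exposures, f3$exposures)
  expect_error(nmf_decompose(C, 0), "K must")
  expect_error(nmf_decompose(C, 9), "K must")
})

test_that("bootstrap extraction recovers well-separated signatures", {
  co <- recovery_cohort(n_samples = 30, total = 3000, K = 3, seed = 7)
  res <- extract_signatures(co$sim$catalog, 3, n_bootstraps = 8,
                            n_restarts = 2, seed = 2,
                            max_iter = 1500, tol = 1e-6)
  M <- sigcraft:::cosine_matrix(res$signatures, co$S)
  expect_true(all(apply(M, 2, max) > 0.9))
  expect_true(all(res$stability > 0.8))
  # exposures track the generating weights
  rel <- relative_exposures(res$exposures)
  match_idx <- apply(M, 2, which.max)
  r <- sapply(1:3, function(k) cor(rel[match_idx[k], ], co$W[k, ]))
  expect_true(all(r > 0.9))
})

test_that("a single-process cohort is maximally stable at K = 1", {
  s <- sigcraft:::random_sparse_signatures(1, seed = 14)
  sim <- generate_catalog(s, matrix(1, 1, 12), totals = rep(2000, 12), seed = 15)
  res <- extract_signatures(sim$catalog, 1, n_bootstraps = 6, n_restarts = 2,
                            seed = 3, max_iter = 1000, tol = 1e-6)
  expect_identical(res$stability, 1.0)
  rk <- select_rank(sim$catalog, 1:3, n_bootstraps = 6, n_restarts = 2,
                    seed = 3, max_iter = 1000, tol = 1e-6)
  expect_equal(rk$recommended_K, 1L)
})

test_that("rank selection finds the generating rank", {
  co <- recovery_cohort(n_samples = 30, total = 3000, K = 3, seed = 7)
  rk <- select_rank(co$sim$catalog, 1:4, n_bootstraps = 6, n_restarts = 2,
                    seed = 2, max_iter = 1200, tol = 1e-6)
  expect_equal(rk$recommended_K, 3L)
  expect_equal(nrow(rk$metrics), 4)
})

test_that("replicating a sample's counts leaves relative exposures unchanged", {
  co <- recovery_cohort(n_samples = 10, total = 2000, seed = 20)
  C <- co$sim$catalog
  C2 <- cbind(C, scaled = 3L * C[, 4])
  res <- extract_signatures(C2, 3, n_bootstraps = 5, n_restarts = 2,
                            seed = 6, max_iter = 1200, tol = 1e-6)
  rel <- relative_exposures(res$exposures)
  expect_lt(max(abs(rel[, "scaled"] - rel[, 4])), 0.02)
})

test_that("reconstructed column sums match the catalog after exposure fitting", {
  co <- recovery_cohort(n_samples = 12, total = 2000, seed = 22)
  res <- extract_signatures(co$sim$catalog, 3, n_bootstraps = 5,
                            n_restarts = 2, seed = 4, max_iter = 1500, tol = 1e-7)
  recon <- res$signatures %*% res$exposures
  expect_true(all(abs(colSums(recon) - colSums(co$sim$catalog)) /
                    colSums(co$sim$catalog) < 0.01))
})

test_that("near-collinear signatures drop stability below the K = 1 value", {
  F2 <- make_flat_signature_set(2, target_cosine = 0.96, seed = 8)
  set.seed(9)
  W <- sapply(1:15, function(j) { w <- runif(2, 0.3, 0.7); w / sum(w) })
  sim <- generate_catalog(F2, W, totals = rep(2000, 15), seed = 10)
  r1 <- extract_signatures(sim$catalog, 1, n_bootstraps = 5, n_restarts = 2,
                           seed = 3, max_iter = 800, tol = 1e-6)
  r2 <- extract_signatures(sim$catalog, 2, n_bootstraps = 5, n_restarts = 2,
                           seed = 3, max_iter = 800, tol = 1e-6)
  expect_lt(mean(r2$stability), mean(r1$stability))
})
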