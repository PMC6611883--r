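test_that("reconstruction error vanishes on an exact reconstruction", {
  S <- sigcraft:::random_sparse_signatures(2, seed = 3)
  E <- matrix(c(500, 300), 2, 1)
  C <- S %*% E
  colnames(C) <- "s1"
  expect_lt(reconstruction_error(C, S, E, "cosine"), 1e-9)
  expect_lt(reconstruction_error(C, S, E, "rmse"), 1e-9)
  expect_lt(reconstruction_error(C, S, E, "kld"), 1e-6)
  expect_error(reconstruction_error(C, S, E, "nope"))
})

test_that("RMSE matches the hand-computed two-channel example", {
  obs <- matrix(c(2, rep(0, 95)), 96, 1)
  S <- matrix(c(1, 1, rep(0, 94)) / 2, 96, 1)
  E <- matrix(2, 1, 1)   # reconstruction (1,1,0,...,0)
  expect_equal(unname(reconstruction_error(obs, S, E, "rmse")),
               sqrt(2 / 96), tolerance = 1e-12)
})

test_that("perturbing a perfect reconstruction raises every metric", {
  S <- sigcraft:::random_sparse_signatures(2, seed = 4)
  E <- matrix(c(800, 400), 2, 1)
  C <- S %*% E; colnames(C) <- "s1"
  E_bad <- E * c(1.5, 0.4)
  for (m in c("cosine", "kld", "rmse"))
    expect_gt(reconstruction_error(C, S, E_bad, m),
              reconstruction_error(C, S, E, m))
})

test_that("an actively contributing candidate is judged necessary", {
  S2 <- sigcraft:::random_sparse_signatures(2, seed = 21)
  cand <- sigcraft:::random_sparse_signatures(3, seed = 22)[, 3]
  W <- matrix(0, 3, 16)
  W[, 1:8] <- c(0.4, 0.35, 0.25)   # candidate at 25% in half the cohort
  W[, 9:16] <- c(0.6, 0.4, 0)
  sim <- generate_catalog(cbind(S2, cand), W, totals = rep(4000, 16), seed = 23)
  rep <- signature_necessity_test(sim$catalog, S2, cand,
                                  candidate_name = "CAND")
  expect_true(rep$qualitative)
  expect_true(all(rep$significant))
})

test_that("a collinear absent candidate is significant but not qualitative", {
  F3 <- make_flat_signature_set(3, target_cosine = 0.88, seed = 31)
  base <- cbind(F3[, 1:2], sigcraft:::random_sparse_signatures(1, seed = 32))
  colnames(base) <- c("Flat1", "Flat2", "Sparse1")
  set.seed(33)
  W <- sapply(1:16, function(j) {
    w <- c(runif(2, 0.25, 0.45), runif(1, 0.2, 0.4)); w / sum(w)
  })
  sim <- generate_catalog(base, W, totals = rep(4000, 16), seed = 34)
  rep <- signature_necessity_test(sim$catalog, base, F3[, 3],
                                  candidate_name = "Flat3")
  expect_false(rep$qualitative)
  expect_true(any(rep$significant))
  excluded <- sum(rep$exposures_with["Flat3", ])
  to_flats <- sum(rep$reassignment[c("Flat1", "Flat2")])
  expect_gt(to_flats / excluded, 0.7)

  # substituting a truly active signature with the inactive candidate hurts
  rep_sub <- signature_necessity_test(sim$catalog, base, F3[, 3],
                                      mode = "substitute",
                                      substitute_target = "Sparse1",
                                      candidate_name = "Flat3")
  expect_true(rep_sub$qualitative)
})

test_that("excluding a zero-exposure signature changes no error metric", {
  S <- sigcraft:::random_sparse_signatures(3, seed = 41)
  sim <- generate_catalog(S[, 1:2], matrix(c(0.5, 0.5), 2, 10),
                          totals = rep(3000, 10), seed = 42)
  rep <- signature_necessity_test(sim$catalog, S[, 1:2], S[, 3],
                                  candidate_name = "unused")
  used <- sum(rep$exposures_with["unused", ])
  if (used == 0) {
    expect_true(all(abs(rep$errors_with - rep$errors_without) < 1e-9))
    expect_true(all(!rep$significant | rep$p_values >= 0.05))
  } else {
    # noise may give it a tiny exposure; the change must stay non-qualitative
    expect_false(rep$qualitative)
  }
})

test_that("exposure clustering separates groups with disjoint processes", {
  S <- sigcraft:::random_sparse_signatures(4, seed = 51)
  W <- cbind(matrix(rep(c(0.8, 0.2, 0, 0), 8), 4),
             matrix(rep(c(0, 0, 0.3, 0.7), 8), 4))
  set.seed(52); W <- W + matrix(runif(4 * 16, 0, 0.05), 4)
  W <- sweep(W, 2, colSums(W), "/")
  sim <- generate_catalog(S, W, totals = rep(3000, 16), seed = 53)
  E <- fit_exposures(sim$catalog, S)
  cl <- exposure_clustering(relative_exposures(E))
  expect_equal(cl$n_clusters, 2L)
  truth <- rep(1:2, each = 8)
  expect_equal(length(unique(cl$labels[truth == 1])), 1)
  expect_equal(length(unique(cl$labels[truth == 2])), 1)
  expect_false(cl$labels[1] == cl$labels[16])

  # permutation invariance as a partition
  perm <- sample(16)
  cl2 <- exposure_clustering(relative_exposures(E)[, perm])
  agree <- outer(cl$labels[perm], cl$labels[perm], "==") ==
    outer(cl2$labels, cl2$labels, "==")
  expect_true(all(agree))
})

test_that("identical exposure vectors collapse to one cluster", {
  E <- matrix(rep(c(0.5, 0.5), 6), 2, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  cl <- exposure_clustering(E)
  expect_equal(cl$n_clusters, 1L)
})

test_that("a single whole-cohort group reduces to plain extraction", {
  co <- recovery_cohort(n_samples = 10, total = 1500, seed = 61)
  grp <- setNames(rep("all", 10), colnames(co$sim$catalog))
  sp <- split_extraction(co$sim$catalog, grp, K = 2, seed = 5,
                         n_bootstraps = 4, n_restarts = 2,
                         max_iter = 800, tol = 1e-6)
  direct <- extract_signatures(co$sim$catalog, 2,
                               seed = sigcraft:::derive_seed(5, "group", 1),
                               n_bootstraps = 4, n_restarts = 2,
                               max_iter = 800, tol = 1e-6)
  expect_equal(sp$results$all$signatures, direct$signatures)
  expect_null(sp$cross_match)
})

test_that("identical groups extract matching signature sets", {
  co <- recovery_cohort(n_samples = 20, total = 2500, K = 2, seed = 62)
  grp <- setNames(rep(c("g1", "g2"), each = 10), colnames(co$sim$catalog))
  sp <- split_extraction(co$sim$catalog, grp, K = 2, seed = 6,
                         n_bootstraps = 5, n_restarts = 2,
                         max_iter = 1200, tol = 1e-6)
  M <- sigcraft:::cosine_matrix(sp$results$g1$signatures,
                                sp$results$g2$signatures)
  expect_true(all(apply(M, 1, max) > 0.95))
  expect_true(all(sp$cross_match$cosine <= 1))
})
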