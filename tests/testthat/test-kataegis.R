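mk_mut <- function(pos, chrom = "1", sid = "s1") {
  data.frame(sample_id = sid, chrom = chrom, pos = as.integer(pos),
             ref = "C", alt = "T", context = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("intermutation distances follow the sorted per-chromosome order", {
  m <- mk_mut(c(1200, 100, 200))
  expect_equal(intermutation_distances(m)[["1"]], c(100, 1000))
  expect_length(intermutation_distances(mk_mut(500)), 0)
  m2 <- rbind(mk_mut(c(300, 100), chrom = "2"), mk_mut(c(50, 60)))
  d <- intermutation_distances(m2)
  expect_equal(d[["1"]], 10)
  expect_equal(d[["2"]], 200)
})

test_that("the run definition detects and sizes a simple cluster", {
  m <- mk_mut(seq(1000, by = 100, length.out = 6))
  cl <- detect_clusters(m)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_mutations, 6L)
  expect_equal(cl$imd_stat, 100)
  expect_equal(cl$start, 1000L)
  expect_equal(cl$end, 1500L)
  # below the minimum run length nothing is reported
  expect_equal(nrow(detect_clusters(mk_mut(seq(1000, by = 100,
                                               length.out = 5)))), 0)
})

test_that("the degenerate limit returns one run per chromosome", {
  m <- rbind(mk_mut(c(1e4, 5e5, 9e6)), mk_mut(c(100, 5e6), chrom = "2"))
  cl <- detect_clusters(m, min_mutations = 2, max_imd = Inf)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$chrom, c("1", "2"))
  expect_equal(sum(cl$n_mutations), 5)
})

test_that("mean and median definitions differ only when they straddle the ceiling", {
  # run of 6 whose distances are 1001,1001,1001,1001,1: mean 801 passes
  # <=1000, median 1001 fails the strict <1000 rule
  pos <- cumsum(c(5000, 1001, 1001, 1001, 1001, 1))
  m <- mk_mut(pos)
  by_mean <- detect_clusters(m, statistic = "mean", strict = FALSE)
  by_median <- detect_clusters(m, statistic = "median", strict = TRUE)
  expect_equal(nrow(by_mean), 1)
  expect_equal(nrow(by_median), 0)
  # and the mirror case: median tiny, mean blown out by two large gaps
  pos2 <- cumsum(c(5000, 1, 1, 5000, 5000, 1))
  by_mean2 <- detect_clusters(mk_mut(pos2), statistic = "mean")
  by_median2 <- detect_clusters(mk_mut(pos2), statistic = "median",
                                strict = TRUE)
  expect_equal(nrow(by_mean2), 0)
  expect_equal(nrow(by_median2), 1)
})

test_that("detection matches the brute-force oracle on random replicates", {
  for (rep_i in 1:60) {
    set.seed(1000 + rep_i)
    n <- rpois(1, 10)
    if (n < 2) next
    pos <- sort(sample(1:1e7, n))
    m <- mk_mut(pos)
    got <- detect_clusters(m)
    want <- oracle_kataegis(pos)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$n_mutations, want$n_mutations)
      expect_equal(got$imd_stat, want$imd_stat)
    }
    # reported clusters are disjoint
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] > got$end[-nrow(got)]))
  }
})

test_that("planted clusters are recovered with exact membership", {
  sim <- generate_positioned_cohort(
    n_samples = 2, signatures = sigcraft:::random_sparse_signatures(2, seed = 3),
    background_rate = 1e-6, kataegis_clusters = 3, kataegis_size = 8,
    kataegis_spacing = 400, kataegis_signature = apobec_like_profile(),
    seed = 31)
  for (sid in unique(sim$mutations$sample_id)) {
    m <- sim$mutations[sim$mutations$sample_id == sid, ]
    m <- m[order(sigcraft:::norm_chrom(m$chrom), m$pos), ]
    cl <- detect_clusters(m)
    expect_equal(nrow(cl), 3)
    detected <- sort(m$pos[unlist(cl$members)] +
                       1e9 * match(sigcraft:::norm_chrom(m$chrom[unlist(cl$members)]),
                                   c("1", "2")))
    truth <- m[!is.na(m$cluster_id), ]
    planted <- sort(truth$pos + 1e9 * match(sigcraft:::norm_chrom(truth$chrom),
                                            c("1", "2")))
    expect_equal(detected, planted)
  }
})

test_that("localized fit sees the cluster process the genome-wide fit dilutes", {
  sim <- simulate_preset("kataegis", seed = 5)
  sigs <- cbind(sim$signatures, APOBEC = apobec_like_profile())
  loc <- localized_analysis(sim$mutations, sigs, source = "clusters",
                            reference_genome = sim$genome)
  expect_true(all(loc$relative["APOBEC", ] > 0.8))
  # localized catalog conserves exactly the in-cluster mutations
  n_in_clusters <- sapply(colnames(loc$catalog), function(sid) {
    m <- sim$mutations[sim$mutations$sample_id == sid, ]
    cl <- detect_clusters(m[order(sigcraft:::norm_chrom(m$chrom), m$pos), ])
    length(unique(unlist(cl$members)))
  })
  expect_equal(unname(colSums(loc$catalog)), unname(n_in_clusters))
  # genome-wide forward fit attributes almost nothing to the cluster process
  C <- build_catalog(sim$mutations, sample_ids = colnames(sim$truth_catalog))
  Eg <- fit_forward_selection(C, sigs)
  expect_true(all(relative_exposures(Eg)["APOBEC", ] < 0.1))
})

test_that("a region set covering no mutations yields an all-zero catalog", {
  m <- mk_mut(c(1000, 2000, 3000))
  m$context <- "ACA"
  empty_r <- regions("9", 1, 100)
  loc <- localized_analysis(m, sigcraft:::random_sparse_signatures(2, seed = 4),
                            source = empty_r)
  expect_true(all(loc$catalog == 0))
  expect_identical(loc$flagged, "s1")
})

test_that("rainfall export reports per-chromosome distances and classes", {
  m <- rbind(mk_mut(c(100, 300, 1300)), mk_mut(500, chrom = "2"))
  m$context <- "ACG"
  rf <- rainfall_data(m)
  expect_equal(rf$imd, c(NA, 200, 1000, NA))
  expect_true(all(rf$channel == "A[C>T]G"))
  expect_true(all(rf$substitution == "C>T"))
})
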