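# Independent oracles and small fixture builders shared across test files.

# Random SNV records with self-consistent contexts (middle base = ref).
random_snv_records <- function(n, seed, sample_ids = "s1", chroms = "1") {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ctx <- paste0(sample(bases, n, replace = TRUE), ref,
                sample(bases, n, replace = TRUE))
  data.frame(sample_id = sample(sample_ids, n, replace = TRUE),
             chrom = sample(chroms, n, replace = TRUE),
             pos = sample(1000:2e6, n), ref = ref, alt = unname(alt),
             context = ctx, stringsAsFactors = FALSE)
}

revcomp_records <- function(records) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc3 <- function(s) vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(comp[ch])), collapse = ""), character(1))
  records$ref <- unname(comp[records$ref])
  records$alt <- unname(comp[records$alt])
  records$context <- rc3(records$context)
  records
}

# Brute-force kataegis oracle: enumerate every window of >= min_mut
# consecutive same-chromosome mutations whose IMD statistic passes, union
# overlapping windows, report the connected components.
oracle_kataegis <- function(positions, chrom = NULL, min_mut = 6,
                            max_imd = 1000, statistic = "mean",
                            strict = FALSE) {
  if (is.null(chrom)) chrom <- rep("1", length(positions))
  ord <- order(chrom, positions)
  chrom <- chrom[ord]; positions <- positions[ord]
  out <- list()
  for (ch in unique(chrom)) {
    p <- positions[chrom == ch]
    n <- length(p)
    wins <- list()   # every qualifying window, exhaustively enumerated
    if (n >= min_mut) {
      for (i in 1:(n - min_mut + 1)) for (j in (i + min_mut - 1):n) {
        d <- diff(p[i:j])
        stat <- if (statistic == "mean") mean(d) else median(d)
        pass <- if (strict) stat < max_imd else stat <= max_imd
        if (pass) wins[[length(wins) + 1]] <- c(i, j)
      }
    }
    # repeatedly merge any two windows sharing a mutation index
    changed <- TRUE
    while (changed && length(wins) > 1) {
      changed <- FALSE
      for (a in 1:(length(wins) - 1)) {
        for (b in (a + 1):length(wins)) {
          ia <- wins[[a]]; ib <- wins[[b]]
          if (max(ia[1], ib[1]) <= min(ia[2], ib[2])) {
            wins[[a]] <- c(min(ia[1], ib[1]), max(ia[2], ib[2]))
            wins[[b]] <- NULL
            changed <- TRUE
            break
          }
        }
        if (changed) break
      }
    }
    wins <- wins[order(vapply(wins, `[`, numeric(1), 1))]
    for (w in wins) {
      d <- diff(p[w[1]:w[2]])
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = p[w[1]], end = p[w[2]],
        n_mutations = w[2] - w[1] + 1,
        imd_stat = if (statistic == "mean") mean(d) else median(d))
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(chrom = character(0), start = numeric(0),
                  end = numeric(0), n_mutations = integer(0),
                  imd_stat = numeric(0))
}

# Brute-force pair-assignment oracle: best cosine over all reference pairs
# on a weight grid of step 0.01.
oracle_best_pair_cosine <- function(x, reference, step = 0.01) {
  best <- 0
  w <- seq(0, 1, by = step)
  for (a in 1:(ncol(reference) - 1)) for (b in (a + 1):ncol(reference)) {
    for (wi in w) {
      v <- wi * reference[, a] + (1 - wi) * reference[, b]
      cs <- sum(v * x) / sqrt(sum(v^2) * sum(x^2))
      if (cs > best) best <- cs
    }
  }
  best
}

# Three well-separated generating signatures plus a mixed cohort, reused by
# extraction tests.
recovery_cohort <- function(n_samples = 30, total = 3000, K = 3, seed = 7) {
  S <- sigcraft:::random_sparse_signatures(K, seed = seed)
  set.seed(seed + 1)
  W <- sapply(seq_len(n_samples), function(j) {
    w <- stats::rgamma(K, 2); w / sum(w)
  })
  sim <- generate_catalog(S, W, totals = rep(total, n_samples),
                          seed = seed + 2)
  list(S = S, W = W, sim = sim)
}

expect_matrix_equal <- function(a, b, tol = 1e-9) {
  expect_equal(dim(a), dim(b))
  expect_lt(max(abs(a - b)), tol)
}
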