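# Synthetic-cohort simulator with full ground-truth bookkeeping: catalogs
# drawn from known signature mixtures, positioned mutation cohorts on a toy
# genome (FASTA + per-sample VCF) with Poisson background and planted
# kataegis clusters, group-structured cohorts for bleeding experiments, and
# constructed flat-signature sets for ambiguity studies.

#' Simulate a catalog from known signature mixtures
#'
#' Each sample's column is one multinomial draw of the sample's total
#' mutation count from the mixture distribution S w (signatures times the
#' sample's weights).
#'
#' @param signatures 96 x K signature matrix (columns sum 1).
#' @param weights K x n matrix of per-sample mixture weights (columns sum
#'   to 1, non-negative).
#' @param totals Length-n vector of per-sample mutation counts.
#' @param seed Integer seed.
#' @param sample_ids Optional sample names.
#' @return List with `catalog` (96 x n integer matrix) and `truth`
#'   (list: `signatures`, `weights`, `totals`, `expected_exposures`,
#'   `seed`).
#' @export
generate_catalog <- function(signatures, weights, totals, seed = 1L,
                             sample_ids = NULL) {
  S <- as.matrix(signatures); W <- as.matrix(weights)
  stopifnot(nrow(W) == ncol(S), length(totals) == ncol(W))
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(abs(colSums(W) - 1) > 1e-8)) stop("per-sample weights must sum to 1")
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(ncol(W)))
  set.seed(seed)
  C <- matrix(0L, 96, ncol(W), dimnames = list(sbs96_channels(), sample_ids))
  P <- S %*% W
  for (j in seq_len(ncol(W)))
    if (totals[j] > 0)
      C[, j] <- as.integer(stats::rmultinom(1, totals[j], P[, j]))
  truth <- list(signatures = S, weights = W, totals = totals,
                expected_exposures = sweep(W, 2, totals, "*"),
                seed = seed)
  list(catalog = C, truth = truth)
}

#' Construct flat signatures with target pairwise cosine similarity
#'
#' Builds K normalized non-negative profiles around a common near-uniform
#' base so that measured pairwise cosines land within +/- 0.03 of the
#' target — the ambiguity regime in which flat signatures substitute for
#' one another during fitting.
#'
#' @param K Number of signatures.
#' @param target_cosine Desired pairwise cosine (scalar), ignored for
#'   `K = 1`.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget (default 1000).
#' @return 96 x K matrix, columns `Flat1..FlatK` summing to 1.
#' @export
make_flat_signature_set <- function(K, target_cosine = 0.9, seed = 1L,
                                    max_attempts = 1000L) {
  set.seed(seed)
  base <- stats::runif(96, 0.8, 1.2); base <- base / sum(base)
  if (K == 1) {
    S <- matrix(base, 96, 1)
    dimnames(S) <- list(sbs96_channels(), "Flat1")
    return(S)
  }
  for (attempt in seq_len(max_attempts)) {
    # bisect the perturbation scale shared by all members
    lo <- 0; hi <- 8
    for (it in 1:60) {
      a <- (lo + hi) / 2
      set.seed(derive_seed(seed, "flatdir", attempt))
      D <- matrix(stats::rexp(96 * K), 96, K)
      S <- sapply(seq_len(K), function(k) {
        v <- base + a * base * (D[, k] - 1)
        v[v < 1e-9] <- 1e-9
        v / sum(v)
      })
      cs <- cosine_matrix(S, S); cs <- cs[upper.tri(cs)]
      if (mean(cs) > target_cosine) lo <- a else hi <- a
    }
    cs <- cosine_matrix(S, S); cs <- cs[upper.tri(cs)]
    if (all(abs(cs - target_cosine) <= 0.03)) {
      dimnames(S) <- list(sbs96_channels(), paste0("Flat", seq_len(K)))
      return(S)
    }
  }
  stop("could not construct flat signatures at the requested cosine target")
}

# Peaked, well-separated signatures for recovery experiments.
random_sparse_signatures <- function(K, seed, concentration = 0.15,
                                     max_pairwise_cosine = 0.6,
                                     max_attempts = 200L) {
  for (attempt in seq_len(max_attempts)) {
    set.seed(derive_seed(seed, "sparsesig", attempt))
    S <- sapply(seq_len(K), function(k) {
      g <- stats::rgamma(96, shape = concentration)
      g[g < 1e-12] <- 1e-12
      g / sum(g)
    })
    if (K == 1) break
    cs <- cosine_matrix(S, S)
    if (max(cs[upper.tri(cs)]) < max_pairwise_cosine) break
    if (attempt == max_attempts)
      stop("could not generate well-separated signatures")
  }
  dimnames(S) <- list(sbs96_channels(), paste0("True", seq_len(K)))
  S
}

# Channel -> (ref, alt, context) in a randomly chosen strand representation.
channel_to_mutation <- function(channel_idx, strand_flip) {
  labs <- sbs96_channels()
  lab <- labs[channel_idx + 1L]
  ref <- substr(lab, 3, 3); alt <- substr(lab, 5, 5)
  ctx <- paste0(substr(lab, 1, 1), ref, substr(lab, 7, 7))
  if (strand_flip) {
    ctx <- revcomp(ctx)
    new_ref <- substr(ctx, 2, 2)
    alt <- unname(revcomp_base(alt))
    ref <- new_ref
  }
  list(ref = ref, alt = alt, context = ctx)
}

write_simple_vcf <- function(records, path, contigs = NULL) {
  con <- file(path, "w")
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs))
    for (nm in names(contigs))
      writeLines(sprintf("##contig=<ID=%s,length=%d>", nm, contigs[[nm]]), con)
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(records)) {
    records <- records[order(norm_chrom(records$chrom), records$pos), ]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       records$chrom, records$pos, records$ref, records$alt), con)
  }
  close(con)
  invisible(path)
}

#' Simulate a positioned mutation cohort on a toy genome
#'
#' Builds a random toy genome, plants per-sample background mutations at
#' Poisson-distributed density with channels drawn from the sample group's
#' signature mixture, then plants kataegis runs with channels from a
#' cluster signature and tight inter-mutation spacing. Reference bases
#' around every planted site are edited so the mutation's trinucleotide
#' context matches its drawn channel exactly (half the sites are planted in
#' the purine strand representation). Writes FASTA and per-sample VCF when
#' `out_dir` is given.
#'
#' @param n_samples Samples in the cohort.
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (default two chromosomes of 5 Mb).
#' @param background_rate Background mutations per bp (default 1e-6, i.e.
#'   1/Mb).
#' @param group_weights K x G matrix of signature mixture weights per
#'   group (columns sum 1); single-group cohorts may pass a vector.
#' @param group_of Length-`n_samples` integer/character vector assigning
#'   samples to columns of `group_weights` (default all group 1).
#' @param signatures 96 x K signature matrix generating the background.
#' @param kataegis_clusters Clusters planted per sample (default 0).
#' @param kataegis_size Mutations per planted cluster (default 8).
#' @param kataegis_spacing Maximum inter-mutation gap inside a cluster in
#'   bp (default 500; gaps are drawn uniformly from 3..spacing so planted
#'   contexts never overlap).
#' @param kataegis_signature Optional 96-vector profile for cluster
#'   mutations (defaults to the group mixture).
#' @param seed Master seed.
#' @param out_dir Optional directory for FASTA + VCF fixtures.
#' @return List with `genome` (DNAStringSet), `mutations` (records with
#'   truth columns `channel`, `source`, `cluster_id`), `truth_catalog`,
#'   `group_of`, `files` (paths, when written), `seed`.
#' @export
generate_positioned_cohort <- function(n_samples = 4L,
                                       chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                                       background_rate = 1e-6,
                                       signatures,
                                       group_weights = NULL,
                                       group_of = NULL,
                                       kataegis_clusters = 0L,
                                       kataegis_size = 8L,
                                       kataegis_spacing = 500L,
                                       kataegis_signature = NULL,
                                       seed = 1L,
                                       out_dir = NULL) {
  S <- as.matrix(signatures)
  K <- ncol(S)
  if (is.null(group_weights)) group_weights <- matrix(rep(1 / K, K), K, 1)
  group_weights <- as.matrix(group_weights)
  if (is.null(group_of)) group_of <- rep(1L, n_samples)
  stopifnot(length(group_of) == n_samples)
  chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                   norm_chrom(names(chrom_lengths)))

  set.seed(derive_seed(seed, "genome"))
  genome_chars <- lapply(chrom_lengths, function(L)
    sample(BASES, L, replace = TRUE))

  sample_ids <- sprintf("sample%02d", seq_len(n_samples))
  labs <- sbs96_channels()
  all_rows <- list()
  taken <- lapply(chrom_lengths, function(L) integer(0))  # occupied sites

  place_mutations <- function(sid, chrom, positions, channel_idx, source, cluster_id) {
    n <- length(positions)
    if (n == 0) return(NULL)
    flips <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ref <- alt <- ctx <- character(n)
    for (i in seq_len(n)) {
      m <- channel_to_mutation(channel_idx[i], flips[i])
      ref[i] <- m$ref; alt[i] <- m$alt; ctx[i] <- m$context
      p <- positions[i]
      genome_chars[[chrom]][(p - 1):(p + 1)] <<- strsplit(m$context, "")[[1]]
    }
    data.frame(sample_id = sid, chrom = chrom, pos = positions, ref = ref,
               alt = alt, context = ctx, channel = labs[channel_idx + 1L],
               source = source, cluster_id = cluster_id,
               stringsAsFactors = FALSE)
  }

  free_positions <- function(chrom, n, lo = 2L, hi = chrom_lengths[[chrom]] - 1L) {
    got <- integer(0)
    while (length(got) < n) {
      cand <- sample(lo:hi, n - length(got), replace = TRUE)
      for (p in cand) {
        # keep sites >= 3 bp apart so planted contexts never collide
        occ <- c(taken[[chrom]], got)
        if (length(occ) == 0 || all(abs(occ - p) >= 3L)) got <- c(got, p)
        if (length(got) == n) break
      }
    }
    taken[[chrom]] <<- c(taken[[chrom]], got)
    got
  }

  for (si in seq_len(n_samples)) {
    set.seed(derive_seed(seed, "sample", si))
    g <- match(group_of[si], unique(group_of))
    mix <- as.numeric(S %*% group_weights[, g])
    mix <- mix / sum(mix)
    for (chrom in names(chrom_lengths)) {
      n_bg <- stats::rpois(1, background_rate * chrom_lengths[[chrom]])
      if (n_bg > 0) {
        pos <- free_positions(chrom, n_bg)
        chans <- sample(0:95, n_bg, replace = TRUE, prob = mix)
        all_rows[[length(all_rows) + 1L]] <-
          place_mutations(sample_ids[si], chrom, pos, chans, "background", NA_character_)
      }
    }
    if (kataegis_clusters > 0) {
      kmix <- if (is.null(kataegis_signature)) mix
              else { v <- as.numeric(kataegis_signature); v / sum(v) }
      for (cl in seq_len(kataegis_clusters)) {
        chrom <- names(chrom_lengths)[1 + (cl - 1) %% length(chrom_lengths)]
        span <- kataegis_size * kataegis_spacing
        repeat {
          anchor <- sample(seq(2L, chrom_lengths[[chrom]] - span - 2L), 1)
          gaps <- sample(3:kataegis_spacing, kataegis_size - 1L, replace = TRUE)
          pos <- anchor + c(0L, cumsum(gaps))
          occ <- taken[[chrom]]
          if (length(occ) == 0 || all(vapply(pos, function(p)
            all(abs(occ - p) >= 3L), logical(1)))) break
        }
        taken[[chrom]] <- c(taken[[chrom]], pos)
        chans <- sample(0:95, kataegis_size, replace = TRUE, prob = kmix)
        all_rows[[length(all_rows) + 1L]] <-
          place_mutations(sample_ids[si], chrom, pos, chans, "kataegis",
                          sprintf("%s_k%02d", sample_ids[si], cl))
      }
    }
  }

  mutations <- if (length(all_rows)) do.call(rbind, all_rows)
               else cbind(empty_records(), channel = character(0),
                          source = character(0), cluster_id = character(0))
  rownames(mutations) <- NULL

  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, character(1),
                                            collapse = ""))
  names(genome) <- names(chrom_lengths)

  truth_catalog <- matrix(0L, 96, n_samples,
                          dimnames = list(labs, sample_ids))
  if (nrow(mutations)) {
    tb <- table(factor(mutations$channel, levels = labs),
                factor(mutations$sample_id, levels = sample_ids))
    truth_catalog[] <- as.integer(tb)
  }

  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(out_dir, "genome.fa")
    Biostrings::writeXStringSet(genome, fasta)
    vcfs <- character(n_samples); names(vcfs) <- sample_ids
    for (sid in sample_ids) {
      vcfs[sid] <- file.path(out_dir, paste0(sid, ".vcf"))
      write_simple_vcf(mutations[mutations$sample_id == sid, , drop = FALSE],
                       vcfs[sid], contigs = as.list(chrom_lengths))
    }
    truth_tsv <- file.path(out_dir, "truth_catalog.tsv")
    write_tsv_matrix(truth_catalog, truth_tsv)
    files <- list(fasta = fasta, vcfs = vcfs, truth_catalog = truth_tsv)
  }

  list(genome = genome, mutations = mutations, truth_catalog = truth_catalog,
       group_of = stats::setNames(group_of, sample_ids),
       signatures = S, seed = seed, files = files)
}

#' Preset simulation scenarios
#'
#' Canned cohorts used throughout the test surface and the worked
#' examples: `"mixtures"` (catalog cohort from well-separated signatures),
#' `"kataegis"` (positioned cohort with planted clusters on an APOBEC-like
#' profile), `"bleeding"` (two groups, one carrying an extra signature),
#' and `"flat-ambiguity"` (two near-collinear flat signatures).
#'
#' @param preset One of `"mixtures"`, `"kataegis"`, `"bleeding"`,
#'   `"flat-ambiguity"`.
#' @param seed Master seed.
#' @param out_dir Optional output directory; positioned fixtures and truth
#'   tables are written there.
#' @return The scenario's simulation bundle (see Details of each
#'   generator).
#' @export
simulate_preset <- function(preset = c("mixtures", "kataegis", "bleeding",
                                       "flat-ambiguity"),
                            seed = 1L, out_dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "mixtures") {
    S <- random_sparse_signatures(4, seed = derive_seed(seed, "sig"))
    n <- 50
    set.seed(derive_seed(seed, "wts"))
    W <- sapply(seq_len(n), function(j) { w <- stats::rgamma(4, 2); w / sum(w) })
    sim <- generate_catalog(S, W, totals = rep(5000, n),
                            seed = derive_seed(seed, "draw"))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_matrix(sim$catalog, file.path(out_dir, "catalog.tsv"))
      write_tsv_matrix(S, file.path(out_dir, "true_signatures.tsv"))
    }
    return(sim)
  }
  if (preset == "kataegis") {
    S <- random_sparse_signatures(2, seed = derive_seed(seed, "sig"))
    apobec <- apobec_like_profile()
    # background burden well above the planted-cluster load, so localized
    # activity is a small share of the genome-wide catalog as in real tumors
    return(generate_positioned_cohort(
      n_samples = 4L, signatures = S, background_rate = 5e-5,
      kataegis_clusters = 3L, kataegis_size = 8L, kataegis_spacing = 400L,
      kataegis_signature = apobec, seed = seed, out_dir = out_dir))
  }
  if (preset == "bleeding") {
    # one sharp signature shared by all samples plus a pair of moderately
    # collinear flat signatures, one of which is active only in group A —
    # the similarity-driven configuration in which pooled extraction
    # bleeds the group-restricted process into the other group
    flats <- make_flat_signature_set(2, target_cosine = 0.75,
                                     seed = derive_seed(seed, "flat"))
    S <- cbind(random_sparse_signatures(1, seed = derive_seed(seed, "sig")),
               flats)
    colnames(S) <- c("True1", "True2", "True3")
    nA <- 12L; nB <- 12L
    set.seed(derive_seed(seed, "wts"))
    WA <- sapply(seq_len(nA), function(j) {
      w <- c(stats::rgamma(1, 8), stats::rgamma(1, 8), stats::rgamma(1, 10))
      w / sum(w)
    })
    WB <- sapply(seq_len(nB), function(j) {
      w <- c(stats::rgamma(1, 8), stats::rgamma(1, 8), 0); w / sum(w)
    })
    sim <- generate_catalog(S, cbind(WA, WB), totals = rep(4000, nA + nB),
                            seed = derive_seed(seed, "draw"))
    sim$group_of <- stats::setNames(rep(c("A", "B"), c(nA, nB)),
                                    colnames(sim$catalog))
    sim$bleeding_signature <- "True3"
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_tsv_matrix(sim$catalog, file.path(out_dir, "catalog.tsv"))
      write_tsv_matrix(S, file.path(out_dir, "true_signatures.tsv"))
      utils::write.table(
        data.frame(sample = names(sim$group_of), group = sim$group_of),
        file.path(out_dir, "groups.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    return(sim)
  }
  # flat-ambiguity
  S <- make_flat_signature_set(2, target_cosine = 0.9,
                               seed = derive_seed(seed, "flat"))
  n <- 30
  set.seed(derive_seed(seed, "wts"))
  W <- sapply(seq_len(n), function(j) { w <- stats::runif(2, 0.2, 0.8); w / sum(w) })
  sim <- generate_catalog(S, W, totals = rep(4000, n),
                          seed = derive_seed(seed, "draw"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_matrix(sim$catalog, file.path(out_dir, "catalog.tsv"))
    write_tsv_matrix(S, file.path(out_dir, "true_signatures.tsv"))
  }
  sim
}

#' APOBEC-like localized profile (synthetic)
#'
#' A synthetic stand-in for an APOBEC-style profile: mass concentrated on
#' T\[C>T\]N and T\[C>G\]N channels (TpC deamination), used as the default
#' kataegis cluster signature in simulations.
#'
#' @return Named 96-vector summing to 1.
#' @export
apobec_like_profile <- function() {
  labs <- sbs96_channels()
  v <- stats::setNames(rep(1e-4, 96), labs)
  tc <- grepl("^T\\[C>[TG]\\]", labs)
  v[tc] <- 1
  v / sum(v)
}

#' c-AID-like localized profile (synthetic)
#'
#' A synthetic stand-in for a canonical-AID somatic-hypermutation profile:
#' mass concentrated on C>T/C>G at WRC-like contexts (A/T 5' flank) and a
#' T>C component, for immunoglobulin-locus simulations. Not a measured
#' profile; supply a real one as TSV for actual analyses.
#'
#' @return Named 96-vector summing to 1.
#' @export
caid_like_profile_synthetic <- function() {
  labs <- sbs96_channels()
  v <- stats::setNames(rep(5e-4, 96), labs)
  v[grepl("^[AT]\\[C>[TG]\\]", labs)] <- 1
  v[grepl("^[AT]\\[T>C\\]", labs)] <- 0.35
  v / sum(v)
}
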