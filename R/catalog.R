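# Assembly of the SBS96 catalog matrix C (channels x samples) from
# mutation records, with optional restriction to genomic regions.

#' Annotate mutation records with trinucleotide contexts
#'
#' Fills the `context` column from the reference genome where it is unset.
#'
#' @param mutations Mutation-record `data.frame` (see [read_snvs()]).
#' @param reference Genome accessor ([load_genome()] output or FASTA path).
#' @return The records with `context` filled; mutations whose position has
#'   no flanking base are dropped and counted in attribute `n_skipped`.
#' @export
annotate_contexts <- function(mutations, reference) {
  g <- load_genome(reference)
  need <- is.na(mutations$context)
  n_skipped <- 0L
  if (any(need)) {
    chrom <- norm_chrom(mutations$chrom[need])
    len <- Biostrings::width(g)[match(chrom, names(g))]
    ok <- !is.na(len) & mutations$pos[need] - 1 >= 1 & mutations$pos[need] + 1 <= len
    idx <- which(need)
    if (any(ok))
      mutations$context[idx[ok]] <-
        fetch_context(g, chrom[ok], mutations$pos[idx[ok]])
    drop <- idx[!ok]
    n_skipped <- length(drop)
    if (n_skipped) {
      dropped_by_sample <- table(mutations$sample_id[drop])
      mutations <- mutations[-drop, , drop = FALSE]
    }
  }
  rownames(mutations) <- NULL
  attr(mutations, "n_skipped") <- n_skipped
  if (n_skipped) attr(mutations, "skipped_by_sample") <- dropped_by_sample
  mutations
}

#' Build the SBS96 mutation catalog
#'
#' Classifies every SNV into its channel and counts per sample, producing
#' the catalog matrix C. Mutations whose context contains N, sits on a
#' chromosome edge, or disagrees with the recorded ref base are excluded
#' and reported per sample in the `exclusions` attribute.
#'
#' @param mutations Mutation records for one or more samples.
#' @param reference Optional genome accessor, required when any `context`
#'   is unset.
#' @param sample_ids Optional vector fixing the set and order of catalog
#'   columns (samples without mutations get zero columns).
#' @return Integer 96 x n_samples matrix, rownames the canonical channel
#'   labels, colnames the sample ids; attribute `exclusions` is a named
#'   per-sample count of skipped mutations.
#' @export
build_catalog <- function(mutations, reference = NULL, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- unique(mutations$sample_id)
  excl <- stats::setNames(integer(length(sample_ids)), sample_ids)
  if (nrow(mutations) > 0 && any(is.na(mutations$context))) {
    if (is.null(reference))
      stop("mutations lack contexts and no reference genome was given")
    mutations <- annotate_contexts(mutations, reference)
    edge <- attr(mutations, "skipped_by_sample")
    if (!is.null(edge)) {
      common <- intersect(names(edge), names(excl))
      excl[common] <- excl[common] + as.integer(edge[common])
    }
  }
  C <- matrix(0L, 96, length(sample_ids),
              dimnames = list(sbs96_channels(), sample_ids))
  if (nrow(mutations)) {
    usable <- !is.na(mutations$context) &
      !grepl("[^ACGT]", mutations$context) &
      substr(mutations$context, 2, 2) == mutations$ref
    skipped <- mutations[!usable, , drop = FALSE]
    if (nrow(skipped)) {
      tb <- table(skipped$sample_id)
      excl[names(tb)] <- excl[names(tb)] + as.integer(tb)
    }
    mutations <- mutations[usable, , drop = FALSE]
    if (nrow(mutations)) {
      idx <- classify_snv(mutations$ref, mutations$alt, mutations$context) + 1L
      j <- match(mutations$sample_id, sample_ids)
      if (anyNA(j)) stop("mutation with sample_id not in sample_ids")
      for (k in seq_along(idx)) C[idx[k], j[k]] <- C[idx[k], j[k]] + 1L
    }
  }
  attr(C, "exclusions") <- excl
  C
}

#' Restrict mutations to (or away from) a region set
#'
#' Keeps mutations whose position falls inside some interval of the region
#' set (1-based inclusive on both ends); with `invert = TRUE` keeps the
#' complement. Input order is preserved.
#'
#' @param mutations Mutation records.
#' @param region_set Region `data.frame` from [regions()] or
#'   [read_bed_regions()].
#' @param invert Keep mutations *outside* all intervals instead.
#' @return The matching subset of `mutations`.
#' @export
restrict_to_regions <- function(mutations, region_set, invert = FALSE) {
  if (nrow(mutations) == 0) return(mutations)
  gr_m <- GenomicRanges::GRanges(norm_chrom(mutations$chrom),
                                 IRanges::IRanges(mutations$pos, mutations$pos))
  gr_r <- GenomicRanges::GRanges(norm_chrom(region_set$chrom),
                                 IRanges::IRanges(region_set$start, region_set$end))
  # suppress the benign seqlevel-union notice when the two sets of
  # chromosome names differ
  hit <- suppressWarnings(IRanges::overlapsAny(gr_m, gr_r))
  out <- mutations[if (invert) !hit else hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
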