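# Input/output for the formats the toolkit touches: VCF 4.x somatic SNV
# calls, FASTA reference genomes, BED3 region lists, and the tab-delimited
# matrix dialect shared by signature, catalog and exposure tables.

#' Read biallelic somatic SNVs from a VCF
#'
#' Keeps records with single-base REF and ALT passing FILTER (`PASS` or
#' `.`; set `pass_only = FALSE` to keep everything). Multiallelic lines are
#' split on ALT and the SNV alleles kept individually. Indels, MNVs and
#' symbolic alleles are skipped and the skip count attached as an attribute.
#'
#' @param vcf_source Path to a VCF file (plain or bgzipped).
#' @param sample_id Sample label stored on every returned record.
#' @param pass_only Keep only FILTER `PASS`/`.` records (default `TRUE`).
#' @return A `data.frame` of mutation records with columns `sample_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `context` (`NA` until
#'   annotated), plus attribute `n_skipped` (non-SNV or filtered records).
#' @export
read_snvs <- function(vcf_source, sample_id, pass_only = TRUE) {
  v <- tryCatch(
    vcfR::read.vcfR(vcf_source, verbose = FALSE),
    error = function(e) stop("malformed VCF '", vcf_source, "': ",
                             conditionMessage(e), call. = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(fx) || nrow(fx) == 0) {
    out <- empty_records(sample_id)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  filt <- fx$FILTER
  filt[is.na(filt)] <- "."
  keep_filter <- if (pass_only) filt %in% c("PASS", ".") else rep(TRUE, nrow(fx))

  rows <- list(); n_skipped <- sum(!keep_filter)
  fx <- fx[keep_filter, , drop = FALSE]
  for (i in seq_len(nrow(fx))) {
    ref <- toupper(fx$REF[i])
    alts <- toupper(strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]])
    if (nchar(ref) != 1 || !ref %in% BASES) { n_skipped <- n_skipped + length(alts); next }
    for (alt in alts) {
      if (nchar(alt) == 1 && alt %in% BASES && alt != ref) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = fx$CHROM[i],
          pos = as.integer(fx$POS[i]), ref = ref, alt = alt,
          context = NA_character_, stringsAsFactors = FALSE)
      } else n_skipped <- n_skipped + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_records(sample_id)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_records <- function(sample_id = character(0)) {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             context = character(0), stringsAsFactors = FALSE)
}

#' Multi-caller consensus of SNV call sets
#'
#' Presence-based consensus over several callers for one sample: a variant,
#' keyed by (chrom, pos, ref, alt), is kept when at least `min_callers` call
#' sets contain it. This is the "2 of 4 callers" rule used for
#' low-mappability regions such as IGH.
#'
#' @param callsets List of mutation-record data.frames, one per caller.
#' @param min_callers Minimum number of supporting callers (>= 1).
#' @return Deduplicated records sorted by (chrom, pos).
#' @export
consensus_calls <- function(callsets, min_callers = 2L) {
  if (min_callers < 1) stop("min_callers must be >= 1")
  if (min_callers > length(callsets))
    stop("min_callers exceeds the number of call sets")
  keyed <- lapply(callsets, function(cs)
    unique(paste(norm_chrom(cs$chrom), cs$pos, cs$ref, cs$alt, sep = ":")))
  tab <- table(unlist(keyed))
  keep_keys <- names(tab)[tab >= min_callers]
  all_rec <- do.call(rbind, callsets)
  key <- paste(norm_chrom(all_rec$chrom), all_rec$pos, all_rec$ref, all_rec$alt, sep = ":")
  out <- all_rec[key %in% keep_keys & !duplicated(key), , drop = FALSE]
  out <- out[order(norm_chrom(out$chrom), out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load a reference genome as a DNAStringSet
#'
#' Accepts a FASTA path or an existing `Biostrings::DNAStringSet`; sequence
#' names are normalized by dropping any "chr" prefix and anything after the
#' first whitespace, so VCF/BED/FASTA naming dialects match.
#'
#' @param reference FASTA path or DNAStringSet.
#' @return DNAStringSet with normalized names.
#' @export
load_genome <- function(reference) {
  g <- if (inherits(reference, "DNAStringSet")) reference
       else Biostrings::readDNAStringSet(reference)
  names(g) <- norm_chrom(sub("\\s.*$", "", names(g)))
  g
}

#' Fetch the trinucleotide context around a position
#'
#' @param reference Genome accessor (`load_genome()` output or FASTA path).
#' @param chrom Chromosome name (with or without "chr").
#' @param pos 1-based position; must have a base on each side.
#' @return Uppercase 3-base string covering `pos - 1 .. pos + 1`. Vectorized
#'   over `chrom`/`pos`. Contexts containing N are returned as-is so the
#'   caller can flag and skip the mutation.
#' @export
fetch_context <- function(reference, chrom, pos) {
  g <- load_genome(reference)
  chrom <- norm_chrom(chrom)
  miss <- setdiff(unique(chrom), names(g))
  if (length(miss)) stop("chromosome(s) absent from reference: ",
                         paste(miss, collapse = ", "))
  len <- Biostrings::width(g)[match(chrom, names(g))]
  if (any(pos - 1 < 1) || any(pos + 1 > len))
    stop("position too close to a chromosome edge for a trinucleotide context")
  ctx <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    v <- Biostrings::extractAt(g[[ch]], IRanges::IRanges(pos[i] - 1, pos[i] + 1))
    ctx[i] <- toupper(as.character(v))
  }
  ctx
}

#' Read a signature (or catalog/exposure) TSV
#'
#' Expects the shared matrix dialect: a header row, first column
#' `MutationType` holding the 96 channel labels (any row order), remaining
#' columns one per signature or sample. Rows are coerced to canonical
#' channel order; signature columns are renormalized to sum to 1.
#'
#' @param tsv_source Path to a tab-delimited file.
#' @param renormalize Renormalize columns to sum 1 (default `TRUE`; set
#'   `FALSE` for count matrices such as catalogs).
#' @return Numeric 96 x K matrix, rownames the canonical channels.
#' @export
read_signature_table <- function(tsv_source, renormalize = TRUE) {
  df <- utils::read.table(tsv_source, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  labs <- sbs96_channels()
  if (nrow(df) != 96)
    stop("expected 96 data rows, found ", nrow(df))
  rn <- as.character(df[[1]])
  bad <- setdiff(rn, labs)
  if (length(bad)) stop("unknown channel label(s): ", paste(utils::head(bad, 3), collapse = ", "))
  if (anyDuplicated(rn)) stop("duplicated channel label(s)")
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  if (any(M < 0)) {
    bad_row <- rn[which(rowSums(M < 0) > 0)[1]]
    stop("negative entry in row ", bad_row)
  }
  M <- M[match(labs, rn), , drop = FALSE]
  rownames(M) <- labs
  if (renormalize) M <- norm_cols(M)
  M
}

#' Write a matrix in the shared TSV dialect
#'
#' @param matrix Numeric matrix with rownames (channels or signature names)
#'   and colnames (signatures or samples).
#' @param path Output path.
#' @param row_label Header of the first column (default `"MutationType"`).
#' @export
write_matrix <- function(matrix, path, row_label = "MutationType") {
  write_tsv_matrix(as.matrix(matrix), path, row_label = row_label)
}

#' Read a BED3 file as a 1-based inclusive region set
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive, so
#' a BED line `chr1 99 200` becomes the interval (1, 100, 200). Per-chromosome
#' intervals are sorted and overlapping ones merged.
#'
#' @param bed_source Path to a BED file (first three columns used).
#' @param label Optional label for the region set (e.g. `"IGH/IGK/IGL"`).
#' @return A `data.frame` with columns `chrom`, `start`, `end` (1-based,
#'   inclusive) and attribute `label`.
#' @export
read_bed_regions <- function(bed_source, label = basename(bed_source)) {
  df <- utils::read.table(bed_source, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric", rep("NULL", 20))[1:3],
                          fill = TRUE, comment.char = "#")
  regions(chrom = df[[1]], start = df[[2]] + 1, end = df[[3]], label = label)
}

#' Build a region set from vectors
#'
#' @param chrom,start,end Equal-length vectors; `start`/`end` are 1-based
#'   inclusive internal coordinates.
#' @param label Region-set label.
#' @return Normalized (sorted, merged) region `data.frame`.
#' @export
regions <- function(chrom, start, end, label = "regions") {
  stopifnot(all(start <= end))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    norm_chrom(chrom), IRanges::IRanges(start, end)))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- label
  out
}
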