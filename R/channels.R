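# The SBS96 channel system: 6 pyrimidine substitution classes x 16
# trinucleotide contexts, in the canonical (COSMIC) order used by every
# matrix in the package.

SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical SBS96 channel labels
#'
#' Labels of the 96 single-base-substitution channels in canonical order:
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the
#' 16 flanking-base combinations with the 5' base varying slowest, both
#' flanks ordered A, C, G, T. Channel `i` (0-based) is `16*s + 4*f + t`.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...
#' @export
#' @examples
#' sbs96_channels()[35]  # "A[C>T]G"
sbs96_channels <- function() {
  labs <- character(96)
  k <- 1
  for (s in SUB_CLASSES) for (f in BASES) for (t in BASES) {
    labs[k] <- paste0(f, "[", s, "]", t)
    k <- k + 1
  }
  labs
}

revcomp_base <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

revcomp <- function(s) {
  vapply(strsplit(s, ""), function(ch)
    paste(rev(unname(revcomp_base(ch))), collapse = ""), character(1))
}

#' Classify an SNV into its SBS96 channel
#'
#' Maps a single-base substitution with its trinucleotide context to one of
#' the 96 canonical channels. Purine-reference mutations (ref A or G) are
#' reverse-complemented to their pyrimidine representation first, so the two
#' strand representations of a mutation always land in the same channel.
#'
#' @param ref,alt Single reference/alternate bases in A, C, G, T (`ref != alt`).
#' @param context 3-base string whose middle base equals `ref`; no N bases.
#' @return 0-based channel index in `0:95`. Vectorized over all arguments.
#' @export
#' @examples
#' classify_snv("C", "T", "ACG")  # 34, i.e. A[C>T]G
#' classify_snv("G", "A", "CGT")  # 34 as well (opposite strand)
classify_snv <- function(ref, alt, context) {
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  context <- toupper(as.character(context))
  n <- max(length(ref), length(alt), length(context))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n); context <- rep_len(context, n)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop("ref and alt must be single bases in A/C/G/T")
  if (any(ref == alt)) stop("ref and alt must differ")
  if (any(nchar(context) != 3)) stop("context must be 3 bases")
  if (any(substr(context, 2, 2) != ref))
    stop("context middle base must equal ref")
  if (any(grepl("[^ACGT]", context))) stop("context must contain only A/C/G/T")

  pur <- ref %in% c("A", "G")
  ref[pur] <- revcomp_base(ref[pur])
  alt[pur] <- revcomp_base(alt[pur])
  context[pur] <- revcomp(context[pur])

  s <- match(paste0(ref, ">", alt), SUB_CLASSES) - 1L
  f <- match(substr(context, 1, 1), BASES) - 1L
  t <- match(substr(context, 3, 3), BASES) - 1L
  as.integer(16L * s + 4L * f + t)
}

#' Channel label for an SNV
#'
#' @inheritParams classify_snv
#' @return Canonical label such as `"A[C>T]G"`.
#' @export
channel_label <- function(ref, alt, context) {
  sbs96_channels()[classify_snv(ref, alt, context) + 1L]
}
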