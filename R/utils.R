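# Deterministic sub-seed derivation: one master seed, named/indexed substreams.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 131 + as.numeric(index) * 7919) %% 2147483647)
}

# Strip an optional "chr" prefix so VCF/BED/FASTA dialects interoperate.
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Cosine similarity between two non-negative profiles
#'
#' Standard inner-product cosine, the field's similarity measure for
#' 96-channel mutational profiles.
#'
#' @param a,b Numeric vectors of equal length, non-negative, not all zero.
#' @return A number in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("vectors must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  min(1, max(0, sum(a * b) / (na * nb)))
}

# Column-wise cosine similarity matrix: t(A) %*% B on L2-normalized columns.
cosine_matrix <- function(A, B) {
  An <- sweep(A, 2, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  M <- crossprod(An, Bn)
  M[M > 1] <- 1; M[M < 0] <- 0
  M
}

# Non-negative least squares of y on the columns of X (pracma's Lawson-Hanson).
nnls_fit <- function(X, y) {
  fit <- pracma::lsqnonneg(as.matrix(X), as.numeric(y))
  fit$x
}

# Normalize columns to sum 1; all-zero columns stay zero.
norm_cols <- function(M) {
  s <- colSums(M)
  nz <- s > 0
  M[, nz] <- sweep(M[, nz, drop = FALSE], 2, s[nz], "/")
  M
}

#' Convert absolute exposures to per-sample relative contributions
#'
#' @param exposures K x n_samples non-negative matrix of absolute exposures.
#' @return Matrix of the same shape whose columns sum to 1 for samples with
#'   at least one attributed mutation (all-zero columns are left at zero).
#' @export
relative_exposures <- function(exposures) {
  norm_cols(as.matrix(exposures))
}

# Fixed-format TSV writer so identical matrices serialize byte-identically.
write_tsv_matrix <- function(M, path, row_label = "MutationType") {
  df <- data.frame(rownames(M), format(M, trim = TRUE, digits = 15, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(row_label, colnames(M))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
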