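# Exposure estimation for a fixed signature set: plain per-sample
# non-negative least squares, sparse forward selection with a
# relative-contribution pruning rule, and the shortlist refit that closes
# the extract-assign-refit workflow.

#' Fit per-sample exposures by non-negative least squares
#'
#' For each catalog column c solves min ||c - S e||_2 over e >= 0, then
#' rescales the solution so the attributed mutations sum to the sample's
#' mutation count.
#'
#' @param catalog 96 x n catalog matrix.
#' @param signatures 96 x K signature matrix in canonical channel order.
#' @param rescale_to_counts Rescale each sample's exposures to its total
#'   mutation count (default `TRUE`).
#' @return K x n exposure matrix (absolute, in mutations).
#' @export
fit_exposures <- function(catalog, signatures, rescale_to_counts = TRUE) {
  C <- as.matrix(catalog); S <- as.matrix(signatures)
  E <- matrix(0, ncol(S), ncol(C),
              dimnames = list(colnames(S), colnames(C)))
  for (j in seq_len(ncol(C))) {
    if (sum(C[, j]) == 0) next
    e <- nnls_fit(S, C[, j])
    if (rescale_to_counts && sum(e) > 0) e <- e * sum(C[, j]) / sum(e)
    E[, j] <- e
  }
  E
}

#' Fit exposures by KL-divergence multiplicative updates
#'
#' Estimates E for fixed signatures S by the same generalized-KL
#' multiplicative updates used during extraction, i.e. the unpenalized
#' fit an NMF framework itself reports. Unlike [fit_exposures()] this fit
#' has no sparsity: every signature typically receives a small positive
#' exposure in every sample, which is exactly the behaviour that produces
#' inter-sample bleeding and overfitting artifacts.
#'
#' @param catalog 96 x n catalog matrix.
#' @param signatures 96 x K signature matrix (columns sum 1).
#' @param max_iter,tol Update budget and relative objective tolerance.
#' @return K x n exposure matrix (absolute, in mutations).
#' @export
fit_exposures_kl <- function(catalog, signatures, max_iter = 2000L, tol = 1e-8) {
  C <- as.matrix(catalog); S <- as.matrix(signatures)
  K <- ncol(S); n <- ncol(C)
  eps <- 1e-12
  H <- matrix(1, K, n) * rep(colSums(C) / K, each = K)
  H[H == 0] <- eps
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- pmax(S %*% H, eps)
    H <- H * (t(S) %*% (C / WH)) / matrix(colSums(S), K, n)
    if (it %% 10L == 0L || it == max_iter) {
      obj <- gkl_div(C, S %*% H)
      if (is.finite(obj_prev) && abs(obj_prev - obj) <= tol * max(obj_prev, 1)) break
      obj_prev <- obj
    }
  }
  dimnames(H) <- list(colnames(S), colnames(C))
  H
}

# Cosine error (1 - similarity) of one sample against its reconstruction;
# used as the forward-selection improvement metric.
sample_cosine_error <- function(obs, S, e) {
  recon <- S %*% e
  if (sum(recon) == 0 || sum(obs) == 0) return(1)
  1 - cosine_similarity(obs, recon)
}

#' Sparse exposure fitting by forward selection with pruning
#'
#' Per sample: starts from an empty signature set and greedily adds the
#' signature whose inclusion (with full NNLS refit of the candidate set)
#' most decreases the cosine reconstruction error, stopping when the best
#' improvement falls below `stop_tol`. Selected signatures whose relative
#' contribution is below `prune_threshold` are then zeroed and the
#' survivors refit once. This mirrors the minimal-signature fitting style
#' with the "<6% of the sample's mutations" removal rule.
#'
#' @param catalog 96 x n catalog matrix.
#' @param signatures 96 x K candidate signature matrix.
#' @param prune_threshold Relative-contribution floor below which a
#'   selected signature is removed (default 0.06).
#' @param stop_tol Minimum cosine-error improvement to keep adding
#'   signatures (default 0.001).
#' @param min_mutations Samples below this burden are fitted but flagged
#'   in the `low_confidence` attribute (default 50).
#' @return K x n exposure matrix (absolute); every nonzero relative
#'   contribution is `>= prune_threshold`.
#' @export
fit_forward_selection <- function(catalog, signatures, prune_threshold = 0.06,
                                  stop_tol = 0.001, min_mutations = 50L) {
  stopifnot(prune_threshold >= 0, prune_threshold < 1)
  C <- as.matrix(catalog); S <- as.matrix(signatures)
  K <- ncol(S)
  E <- matrix(0, K, ncol(C), dimnames = list(colnames(S), colnames(C)))
  for (j in seq_len(ncol(C))) {
    obs <- C[, j]
    if (sum(obs) == 0) next
    selected <- integer(0)
    err <- 1  # cosine error of the empty model
    repeat {
      best_k <- NA_integer_; best_err <- err; best_e <- NULL
      for (k in setdiff(seq_len(K), selected)) {
        cand <- c(selected, k)
        e <- nnls_fit(S[, cand, drop = FALSE], obs)
        e_err <- sample_cosine_error(obs, S[, cand, drop = FALSE], e)
        if (e_err < best_err - 1e-15) { best_err <- e_err; best_k <- k; best_e <- e }
      }
      if (is.na(best_k) || (err - best_err) < stop_tol) break
      selected <- c(selected, best_k)
      err <- best_err
    }
    if (length(selected)) {
      e <- nnls_fit(S[, selected, drop = FALSE], obs)
      rel <- if (sum(e) > 0) e / sum(e) else e
      keep <- selected[rel >= prune_threshold]
      if (length(keep) == 0) keep <- selected[which.max(rel)]
      e <- nnls_fit(S[, keep, drop = FALSE], obs)
      if (sum(e) > 0) e <- e * sum(obs) / sum(e)
      E[keep, j] <- e
    }
  }
  low <- colSums(C) < min_mutations & colSums(C) > 0
  attr(E, "low_confidence") <- colnames(C)[low]
  E
}

#' Refit exposures against the shortlist identified by extraction
#'
#' Builds the shortlist signature set from an assignment report — the
#' deduplicated union of chosen reference labels (pair labels contribute
#' both members) plus any extracted signature flagged potentially novel,
#' included as-is — and delegates to the chosen fitter. Signatures outside
#' the shortlist get exactly zero exposure.
#'
#' @param catalog 96 x n catalog matrix.
#' @param assignment Report from [assign_to_reference()].
#' @param reference Reference signature matrix the report refers to.
#' @param mode `"forward"` (default) or `"plain"`.
#' @param extracted The extracted signature matrix; required when the
#'   report flags potentially novel signatures.
#' @param ... Passed to the fitter.
#' @return Exposure matrix over the shortlist signatures.
#' @export
refit_with_shortlist <- function(catalog, assignment, reference,
                                 mode = c("forward", "plain"),
                                 extracted = NULL, ...) {
  mode <- match.arg(mode)
  labels <- unique(unlist(strsplit(assignment$chosen_label[!assignment$potentially_novel],
                                   "+", fixed = TRUE)))
  labels <- intersect(colnames(reference), labels)
  shortlist <- reference[, labels, drop = FALSE]
  novel <- assignment$extracted[assignment$potentially_novel]
  if (length(novel)) {
    if (is.null(extracted))
      stop("assignment flags potentially novel signatures; supply `extracted`")
    shortlist <- cbind(shortlist, extracted[, novel, drop = FALSE])
  }
  if (ncol(shortlist) == 0) stop("empty shortlist")
  if (mode == "plain") fit_exposures(catalog, shortlist, ...)
  else fit_forward_selection(catalog, shortlist, ...)
}
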