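# De novo signature extraction: bootstrapped non-negative matrix
# factorization (generalized Kullback-Leibler objective, multiplicative
# updates) with consensus clustering of bootstrap signatures and
# silhouette-based stability, in the style of the consensus-NMF
# extraction frameworks standard in the field.

#' Bootstrap-resample a mutation catalog
#'
#' Each sample column is replaced by an independent multinomial draw of the
#' same total, with channel probabilities proportional to the observed
#' counts. Zero columns stay zero.
#'
#' @param catalog 96 x n integer catalog matrix.
#' @param seed Integer seed for the draw.
#' @return Resampled catalog of identical shape and column sums.
#' @export
bootstrap_catalog <- function(catalog, seed) {
  set.seed(seed)
  out <- catalog
  for (j in seq_len(ncol(catalog))) {
    tot <- sum(catalog[, j])
    if (tot > 0)
      out[, j] <- as.integer(stats::rmultinom(1, tot, catalog[, j] / tot))
  }
  out
}

# Generalized KL divergence D(V || WH), the NMF objective.
gkl_div <- function(V, WH) {
  eps <- 1e-12
  sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
}

#' Single NMF decomposition of a catalog
#'
#' Factorizes C ~ S E by multiplicative updates minimizing the generalized
#' Kullback-Leibler divergence (Frobenius updates behind
#' `objective = "frobenius"`), from a seeded random non-negative start.
#' Signature columns are renormalized to sum 1 with the scale absorbed
#' into the exposures, so exposures are in mutation counts.
#'
#' @param catalog 96 x n catalog matrix.
#' @param K Number of signatures, `1 <= K <= min(96, n_samples)`.
#' @param seed Integer seed for the random initialization.
#' @param max_iter Iteration cap (default 10000).
#' @param tol Relative objective-change stopping tolerance (default 1e-9).
#' @param objective `"kl"` (default) or `"frobenius"`.
#' @return List with `signatures` (96 x K, columns sum 1), `exposures`
#'   (K x n), `objective` (final divergence), `iterations`.
#' @export
nmf_decompose <- function(catalog, K, seed = 1L, max_iter = 10000L,
                          tol = 1e-9, objective = c("kl", "frobenius")) {
  objective <- match.arg(objective)
  V <- as.matrix(catalog); storage.mode(V) <- "double"
  n <- ncol(V)
  if (K < 1 || K > n || K > nrow(V))
    stop("K must satisfy 1 <= K <= min(n_samples, n_channels)")
  set.seed(seed)
  W <- matrix(stats::runif(nrow(V) * K, 0.1, 1), nrow(V), K)
  H <- matrix(stats::runif(K * n, 0.1, 1), K, n)
  # scale start to the data's magnitude
  H <- H * (sum(V) / sum(W %*% H))
  eps <- 1e-12
  obj_prev <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    if (objective == "kl") {
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H), nrow(V), K, byrow = TRUE)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / matrix(colSums(W), K, n)
    } else {
      W <- W * (V %*% t(H)) / pmax(W %*% (H %*% t(H)), eps)
      H <- H * (t(W) %*% V) / pmax((t(W) %*% W) %*% H, eps)
    }
    if (it %% 10L == 0L || it == max_iter) {
      obj <- if (objective == "kl") gkl_div(V, W %*% H)
             else 0.5 * sum((V - W %*% H)^2)
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= tol * max(abs(obj_prev), 1)) { obj_prev <- obj; break }
      obj_prev <- obj
    }
  }
  scale <- colSums(W)
  W <- sweep(W, 2, scale, "/")
  H <- sweep(H, 1, scale, "*")
  sig_names <- paste0("S", seq_len(K))
  dimnames(W) <- list(rownames(V), sig_names)
  dimnames(H) <- list(sig_names, colnames(V))
  list(signatures = W, exposures = H, objective = obj_prev, iterations = it)
}

# Deterministic spherical K-partition of pooled bootstrap signatures on
# cosine distance. Centroids are seeded from one reference decomposition
# and refined by assign/recenter passes.
cluster_pooled_signatures <- function(pooled, K, init, max_pass = 100L) {
  cent <- sweep(init, 2, sqrt(colSums(init^2)), "/")
  assign_prev <- rep(0L, ncol(pooled))
  for (pass in seq_len(max_pass)) {
    sim <- cosine_matrix(pooled, cent)
    assign <- max.col(sim, ties.method = "first")
    if (length(unique(assign)) < K) return(NULL)      # degenerate partition
    if (all(assign == assign_prev)) break
    assign_prev <- assign
    for (k in seq_len(K)) {
      m <- rowMeans(pooled[, assign == k, drop = FALSE])
      cent[, k] <- m / sqrt(sum(m^2))
    }
  }
  list(assign = assign, centroids = cent)
}

#' Extract signatures with bootstrap stability
#'
#' Runs NMF on `n_bootstraps` resampled catalogs (`n_restarts` random
#' starts each, best objective kept), pools the resulting K * n_bootstraps
#' signature vectors, partitions them into K clusters by cosine distance,
#' and reports the normalized cluster centroids as consensus signatures.
#' Per-signature stability is the mean silhouette width of its cluster
#' (defined as 1 for K = 1, where no between-cluster term exists).
#' Exposures of the consensus signatures on the original catalog are, by
#' default, the framework's own unpenalized KL fit ([fit_exposures_kl()]),
#' which is what an NMF pipeline reports and what exhibits inter-sample
#' bleeding on heterogeneous cohorts; `exposure_fit = "nnls"` switches to
#' the sparser least-squares fit.
#'
#' @param catalog 96 x n catalog matrix.
#' @param K Number of signatures.
#' @param n_bootstraps Bootstrap resamples (default 100).
#' @param n_restarts Random NMF starts per bootstrap (default 10).
#' @param seed Master seed; all sub-seeds derive from it.
#' @param max_iter,tol,objective Passed to [nmf_decompose()].
#' @param exposure_fit `"kl"` (default) or `"nnls"`.
#' @return An `extraction_result` list: `signatures`, `exposures`, `rank`,
#'   `stability` (per-signature mean silhouette), `reconstruction_error`
#'   (mean per-sample cosine error), `degenerate` flag.
#' @export
extract_signatures <- function(catalog, K, n_bootstraps = 100L,
                               n_restarts = 10L, seed = 1L,
                               max_iter = 10000L, tol = 1e-9,
                               objective = "kl",
                               exposure_fit = c("kl", "nnls")) {
  exposure_fit <- match.arg(exposure_fit)
  stopifnot(n_bootstraps >= 1)
  pooled <- matrix(NA_real_, 96, K * n_bootstraps)
  best_overall <- NULL
  for (b in seq_len(n_bootstraps)) {
    bc <- bootstrap_catalog(catalog, derive_seed(seed, "bootstrap", b))
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- nmf_decompose(bc, K, seed = derive_seed(seed, "nmf", b * 1000L + r),
                           max_iter = max_iter, tol = tol, objective = objective)
      if (is.null(best) || fit$objective < best$objective) best <- fit
    }
    pooled[, (b - 1L) * K + seq_len(K)] <- best$signatures
    if (is.null(best_overall) || best$objective < best_overall$objective)
      best_overall <- best
  }
  rownames(pooled) <- rownames(catalog)

  degenerate <- FALSE
  cl <- cluster_pooled_signatures(pooled, K, best_overall$signatures)
  if (is.null(cl)) {
    # retry from a different bootstrap's solution, then give up and report
    for (b in seq_len(min(5L, n_bootstraps))) {
      cl <- cluster_pooled_signatures(pooled, K,
        pooled[, (b - 1L) * K + seq_len(K), drop = FALSE])
      if (!is.null(cl)) break
    }
    if (is.null(cl)) {
      degenerate <- TRUE
      cl <- list(assign = rep(seq_len(K), n_bootstraps),
                 centroids = best_overall$signatures)
    }
  }

  consensus <- norm_cols(cl$centroids)
  colnames(consensus) <- paste0("S", seq_len(K))
  rownames(consensus) <- rownames(catalog)

  stability <- if (K == 1L) 1.0 else {
    d <- 1 - cosine_matrix(pooled, pooled)
    sil <- cluster::silhouette(cl$assign, dmatrix = d)
    as.numeric(tapply(sil[, "sil_width"], cl$assign, mean))
  }
  if (degenerate) stability <- rep(NA_real_, K)

  exposures <- if (exposure_fit == "kl")
    fit_exposures_kl(catalog, consensus, max_iter = max_iter,
                     tol = max(tol, 1e-10))
  else fit_exposures(catalog, consensus)
  err <- mean(reconstruction_error(catalog, consensus, exposures, metric = "cosine"))
  structure(list(signatures = consensus, exposures = exposures, rank = K,
                 stability = stability, reconstruction_error = err,
                 degenerate = degenerate),
            class = "extraction_result")
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("De novo extraction: K =", x$rank,
      "| mean stability =", round(mean(x$stability), 3),
      "| mean cosine error =", signif(x$reconstruction_error, 3), "\n")
  invisible(x)
}

#' Select the number of signatures by bootstrap stability
#'
#' Runs [extract_signatures()] for each candidate rank and recommends the
#' largest K whose mean stability meets `stability_threshold`; the full
#' per-rank table is returned so the user can override.
#'
#' @param catalog 96 x n catalog matrix.
#' @param K_range Integer vector of candidate ranks.
#' @param stability_threshold Minimum acceptable mean silhouette
#'   (default 0.8).
#' @param ... Passed to [extract_signatures()].
#' @return List with `recommended_K`, `metrics` (data.frame of K, mean
#'   stability, mean reconstruction error), and `results` (per-K
#'   extraction results).
#' @export
select_rank <- function(catalog, K_range, stability_threshold = 0.8, ...) {
  stopifnot(length(K_range) >= 1)
  K_range <- sort(unique(as.integer(K_range)))
  results <- list()
  metrics <- data.frame(K = K_range, mean_stability = NA_real_,
                        mean_error = NA_real_)
  for (i in seq_along(K_range)) {
    res <- extract_signatures(catalog, K_range[i], ...)
    results[[as.character(K_range[i])]] <- res
    metrics$mean_stability[i] <- mean(res$stability)
    metrics$mean_error[i] <- res$reconstruction_error
  }
  ok <- which(!is.na(metrics$mean_stability) &
                metrics$mean_stability >= stability_threshold)
  recommended <- if (length(ok)) K_range[max(ok)] else K_range[1]
  list(recommended_K = recommended, metrics = metrics, results = results)
}
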