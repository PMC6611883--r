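# Diagnostics for signature analyses: reconstruction-error metrics, the
# necessity/substitution test used to decide whether a candidate signature
# (e.g. a flat HRD-like profile) is actually required to explain a cohort,
# exposure-based cohort clustering, and per-group split extraction for
# inter-sample bleeding checks.

#' Per-sample reconstruction error
#'
#' Error between each observed catalog column and its reconstruction S e
#' under one of three metrics: cosine error (1 - cosine similarity), RMSE
#' over the 96 channels of the raw count vectors, or generalized KL
#' divergence between the two normalized profiles (with a pseudocount on
#' both, since zero channels are common at low burden).
#'
#' @param catalog 96 x n catalog matrix.
#' @param signatures 96 x K signature matrix.
#' @param exposures K x n exposure matrix.
#' @param metric `"cosine"`, `"kld"` or `"rmse"`.
#' @param pseudocount Added to both normalized profiles for KLD
#'   (default 1e-9).
#' @return Named numeric vector, one error per sample.
#' @export
reconstruction_error <- function(catalog, signatures, exposures,
                                 metric = c("cosine", "kld", "rmse"),
                                 pseudocount = 1e-9) {
  metric <- match.arg(metric)
  C <- as.matrix(catalog)
  R <- as.matrix(signatures) %*% as.matrix(exposures)
  out <- numeric(ncol(C))
  for (j in seq_len(ncol(C))) {
    obs <- C[, j]; rec <- R[, j]
    out[j] <- switch(metric,
      cosine = if (sum(obs) == 0 && sum(rec) == 0) 0
               else if (sum(obs) == 0 || sum(rec) == 0) 1
               else 1 - cosine_similarity(obs, rec),
      rmse = sqrt(mean((obs - rec)^2)),
      kld = {
        p <- obs / max(sum(obs), 1) + pseudocount
        q <- rec / max(sum(rec), .Machine$double.xmin) + pseudocount
        p <- p / sum(p); q <- q / sum(q)
        sum(p * log(p / q))
      })
  }
  stats::setNames(out, colnames(C))
}

#' Test whether a candidate signature is necessary
#'
#' Fits the cohort twice — with the candidate present and with it absent
#' (`mode = "exclude"`), or with a named base signature replaced by the
#' candidate (`mode = "substitute"`) — and compares per-sample
#' reconstruction errors under all three metrics. A paired two-sided
#' Wilcoxon signed-rank test is reported per metric, along with a
#' reassignment table showing where the candidate's attributed mutations
#' go when it is removed. The "qualitative" verdict operationalizes a
#' visually obvious error increase as a median relative increase above
#' `qualitative_threshold` (a choice of this package; the raw
#' distributions are returned so users can judge directly).
#'
#' @param catalog 96 x n catalog matrix.
#' @param base_signatures Signature matrix *without* the candidate.
#' @param candidate 96-vector (or 96 x 1 matrix) profile of the candidate.
#' @param mode `"exclude"` (with-vs-without candidate) or `"substitute"`.
#' @param substitute_target Name of the base signature the candidate
#'   replaces in substitute mode.
#' @param candidate_name Label for the candidate (default "candidate").
#' @param qualitative_threshold Median relative error increase declaring a
#'   qualitative change (default 0.2).
#' @param alpha Significance level for the paired tests (default 0.05).
#' @param fitter Exposure fitter, [fit_exposures()] by default.
#' @return A `necessity_report` list: `errors_with`, `errors_without`
#'   (3 x n matrices), `p_values`, `significant`, `relative_increase`
#'   (per metric median), `qualitative`, `reassignment` (per retained
#'   signature, change in attributed mutations when the candidate is
#'   dropped), `exposures_with`, `exposures_without`.
#' @export
signature_necessity_test <- function(catalog, base_signatures, candidate,
                                     mode = c("exclude", "substitute"),
                                     substitute_target = NULL,
                                     candidate_name = "candidate",
                                     qualitative_threshold = 0.2,
                                     alpha = 0.05,
                                     fitter = fit_exposures) {
  mode <- match.arg(mode)
  S0 <- as.matrix(base_signatures)
  cand <- as.numeric(candidate)
  if (length(cand) != 96) stop("candidate must be a 96-channel profile")
  cand <- cand / sum(cand)
  if (candidate_name %in% colnames(S0))
    stop("candidate must not already be in the base set")

  if (mode == "exclude") {
    S_with <- cbind(S0, cand)
    colnames(S_with) <- c(colnames(S0), candidate_name)
    S_without <- S0
  } else {
    if (is.null(substitute_target) || !substitute_target %in% colnames(S0))
      stop("substitute_target must name a base signature")
    S_with <- S0
    S_without <- S0
    S_without[, substitute_target] <- cand
    colnames(S_without)[colnames(S0) == substitute_target] <- candidate_name
  }

  E_with <- fitter(catalog, S_with)
  E_without <- fitter(catalog, S_without)

  metrics <- c("cosine", "kld", "rmse")
  err_with <- sapply(metrics, function(m)
    reconstruction_error(catalog, S_with, E_with, metric = m))
  err_without <- sapply(metrics, function(m)
    reconstruction_error(catalog, S_without, E_without, metric = m))
  err_with <- t(err_with); err_without <- t(err_without)

  p_values <- vapply(metrics, function(m) {
    d <- err_without[m, ] - err_with[m, ]
    if (all(abs(d) < 1e-15)) return(1)
    suppressWarnings(stats::wilcox.test(err_without[m, ], err_with[m, ],
                                        paired = TRUE)$p.value)
  }, numeric(1))

  rel_inc <- vapply(metrics, function(m) {
    base <- err_with[m, ]
    d <- (err_without[m, ] - base) / pmax(base, 1e-12)
    stats::median(d)
  }, numeric(1))

  reassignment <- NULL
  if (mode == "exclude") {
    shared <- colnames(S0)
    reassignment <- rowSums(E_without[shared, , drop = FALSE]) -
      rowSums(E_with[shared, , drop = FALSE])
  }

  structure(list(
    mode = mode, candidate = candidate_name,
    errors_with = err_with, errors_without = err_without,
    p_values = p_values, significant = p_values < alpha,
    relative_increase = rel_inc,
    qualitative = stats::median(rel_inc["cosine"]) > qualitative_threshold,
    qualitative_threshold = qualitative_threshold,
    reassignment = reassignment,
    exposures_with = E_with, exposures_without = E_without),
    class = "necessity_report")
}

#' @export
print.necessity_report <- function(x, ...) {
  cat("Necessity test (", x$mode, ") for '", x$candidate, "'\n", sep = "")
  cat("  median relative error increase:",
      paste(names(x$relative_increase),
            signif(x$relative_increase, 3), collapse = ", "), "\n")
  cat("  qualitative verdict (threshold ", x$qualitative_threshold, "): ",
      x$qualitative, "\n", sep = "")
  invisible(x)
}

#' Cluster samples by relative signature exposure
#'
#' Hierarchical clustering (average linkage on cosine distance) of the
#' per-sample relative-exposure vectors, with the cut chosen by the
#' largest mean silhouette over 2..min(8, n-1) clusters. Degenerate
#' inputs (all samples effectively identical) fall back to one cluster.
#'
#' @param relative_exposures K x n matrix of relative exposures (columns
#'   sum to 1).
#' @param max_clusters Upper bound on the number of clusters tried
#'   (default 8).
#' @return List with `labels` (named integer vector), `n_clusters`,
#'   `silhouette` (mean width at the chosen cut), `hclust` (the tree).
#' @export
exposure_clustering <- function(relative_exposures, max_clusters = 8L) {
  X <- as.matrix(relative_exposures)
  n <- ncol(X)
  if (n < 2) stop("need at least 2 samples")
  d <- 1 - cosine_matrix(X, X)
  if (max(d) < 1e-10) {
    labels <- stats::setNames(rep(1L, n), colnames(X))
    return(list(labels = labels, n_clusters = 1L, silhouette = NA_real_,
                hclust = NULL))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ks <- 2:min(max_clusters, n - 1)
  best_k <- NA_integer_; best_sil <- -Inf
  for (k in ks) {
    lab <- stats::cutree(hc, k = k)
    sil <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
    if (sil > best_sil + 1e-12) { best_sil <- sil; best_k <- k }
  }
  labels <- stats::cutree(hc, k = best_k)
  # relabel clusters by first appearance so labels are sample-order-free
  # only up to the deterministic tree; renumber by cluster size then name
  names(labels) <- colnames(X)
  list(labels = labels, n_clusters = best_k, silhouette = best_sil,
       hclust = hc)
}

#' Independent per-group signature extraction
#'
#' Runs [extract_signatures()] separately on each sample group — the
#' bleeding cure of analysing heterogeneous subgroups in independent runs
#' — and cross-matches the per-group signatures by cosine similarity.
#'
#' @param catalog 96 x n catalog matrix.
#' @param grouping Named vector mapping sample id to group label.
#' @param K Signatures per group (single value or named per-group vector).
#' @param seed Master seed; each group gets a derived sub-seed.
#' @param ... Passed to [extract_signatures()].
#' @return List with `results` (per-group extraction results; singleton
#'   groups are skipped with a warning) and `cross_match` (data.frame of
#'   best cosine matches between groups' signatures).
#' @export
split_extraction <- function(catalog, grouping, K, seed = 1L, ...) {
  grouping <- grouping[colnames(catalog)]
  groups <- unique(grouping)
  results <- list()
  for (g in groups) {
    ids <- colnames(catalog)[grouping == g]
    if (length(ids) < 2) {
      warning("group '", g, "' has fewer than 2 samples; skipped")
      next
    }
    Kg <- if (length(K) > 1) K[[g]] else K
    results[[g]] <- extract_signatures(catalog[, ids, drop = FALSE], Kg,
                                       seed = derive_seed(seed, "group", match(g, groups)),
                                       ...)
  }
  cross <- NULL
  gn <- names(results)
  if (length(gn) >= 2) {
    rows <- list()
    for (a in seq_along(gn)) for (b in seq_along(gn)) {
      if (a >= b) next
      M <- cosine_matrix(results[[gn[a]]]$signatures,
                         results[[gn[b]]]$signatures)
      for (i in seq_len(nrow(M))) {
        j <- which.max(M[i, ])
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = gn[a], signature_a = rownames(M)[i] %||% paste0("S", i),
          group_b = gn[b], signature_b = colnames(M)[j] %||% paste0("S", j),
          cosine = M[i, j], stringsAsFactors = FALSE)
      }
    }
    cross <- do.call(rbind, rows)
  }
  list(results = results, cross_match = cross)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
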