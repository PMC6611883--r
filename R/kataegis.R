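# Localized hypermutation: intermutation distances, run-based kataegis
# detection (both published definitions expressible via parameters), and
# signature analysis restricted to clusters or user-supplied loci such as
# the immunoglobulin IGH/IGK/IGL regions.

#' Intermutation distances for one sample
#'
#' Sorts mutations by (chrom, pos) and returns the successive position
#' differences within each chromosome. Chromosomes with fewer than two
#' mutations contribute nothing.
#'
#' @param mutations Mutation records for a single sample.
#' @return List keyed by chromosome, each an integer vector of distances
#'   (length = mutations on that chromosome minus one).
#' @export
intermutation_distances <- function(mutations) {
  if (nrow(mutations) == 0) return(list())
  mutations <- mutations[order(norm_chrom(mutations$chrom), mutations$pos), ]
  out <- list()
  for (ch in unique(norm_chrom(mutations$chrom))) {
    p <- mutations$pos[norm_chrom(mutations$chrom) == ch]
    if (length(p) >= 2) out[[ch]] <- diff(p)
  }
  out
}

# stat over a run's internal distances
run_stat <- function(d, statistic) if (statistic == "mean") mean(d) else stats::median(d)

#' Detect kataegis clusters from intermutation distances
#'
#' Scans each chromosome's sorted mutations for maximal runs of at least
#' `min_mutations` consecutive mutations whose intermutation-distance
#' statistic is within the ceiling; overlapping qualifying runs are merged
#' into one maximal cluster. Two in-use definitions are both expressible:
#' the default (>= 6 consecutive mutations, *mean* IMD <= 1 kb,
#' `strict = FALSE`) and the alternative (> 5 mutations, *median*
#' IMD < 1 kb, `statistic = "median", strict = TRUE`).
#'
#' @param mutations Mutation records for one sample (any order).
#' @param min_mutations Minimum run length (default 6; must be >= 2).
#' @param max_imd IMD ceiling in bp (default 1000).
#' @param statistic `"mean"` (default) or `"median"`.
#' @param strict Use a strict `<` comparison against `max_imd` instead of
#'   `<=` (default `FALSE`).
#' @return `data.frame` with one row per cluster: `sample_id`, `chrom`,
#'   `start`, `end`, `n_mutations`, `imd_stat`, and `members` (list column
#'   of row indices into the sample's sorted mutation table).
#' @export
detect_clusters <- function(mutations, min_mutations = 6L, max_imd = 1000,
                            statistic = c("mean", "median"), strict = FALSE) {
  statistic <- match.arg(statistic)
  if (min_mutations < 2) stop("min_mutations must be >= 2")
  ok <- function(x) if (strict) x < max_imd else x <= max_imd
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_mutations = integer(0), imd_stat = numeric(0))
  if (nrow(mutations) == 0) return(empty)
  sample_id <- mutations$sample_id[1]
  mutations <- mutations[order(norm_chrom(mutations$chrom), mutations$pos), ]
  rows <- list(); members <- list()
  offset <- 0L
  for (ch in unique(norm_chrom(mutations$chrom))) {
    p <- mutations$pos[norm_chrom(mutations$chrom) == ch]
    n <- length(p)
    if (n >= min_mutations) {
      d <- diff(p)
      csum <- c(0, cumsum(d))
      # for each start, the furthest end of any qualifying window: the union
      # of all qualifying windows starting at i is the index range [i, jmax]
      spans <- list()
      for (i in seq_len(n - min_mutations + 1L)) {
        jmax <- NA_integer_
        for (j in seq(i + min_mutations - 1L, n)) {
          stat <- if (statistic == "mean") (csum[j] - csum[i]) / (j - i)
                  else stats::median(d[i:(j - 1L)])
          if (ok(stat)) jmax <- j
        }
        if (!is.na(jmax)) spans[[length(spans) + 1L]] <- c(i, jmax)
      }
      # merge index ranges that share at least one mutation; merely adjacent
      # runs stay separate clusters (the gap between them violates the rule)
      k <- 0L
      while (k < length(spans)) {
        k <- k + 1L
        cur <- spans[[k]]
        while (k < length(spans) && spans[[k + 1L]][1] <= cur[2]) {
          cur[2] <- max(cur[2], spans[[k + 1L]][2])
          spans[[k + 1L]] <- NULL
        }
        spans[[k]] <- cur
      }
      for (sp in spans) {
        i <- sp[1]; j <- sp[2]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, chrom = ch, start = p[i], end = p[j],
          n_mutations = j - i + 1L,
          imd_stat = run_stat(d[i:(j - 1L)], statistic),
          stringsAsFactors = FALSE)
        members[[length(members) + 1L]] <- offset + (i:j)
      }
    }
    n_ch <- n
    offset <- offset + n_ch
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  out$members <- if (length(members)) members else list()
  out
}

#' Signature analysis of localized mutations
#'
#' Restricts a cohort's mutations to detected kataegis clusters (per
#' sample) or to a fixed region set (e.g. IGH/IGK/IGL), builds the
#' localized per-sample catalog, and fits exposures against an extended
#' reference that may include user-supplied localized profiles such as a
#' c-AID 96-class profile.
#'
#' @param mutations Mutation records for one or more samples (contexts
#'   annotated, or supply `reference_genome`).
#' @param signatures Extended 96 x K reference signature matrix.
#' @param source `"clusters"` or a region `data.frame` from [regions()].
#' @param reference_genome Optional genome accessor for context
#'   annotation.
#' @param fitter `"forward"` (default) or `"plain"`.
#' @param sample_ids Optional fixed sample set for the catalog columns.
#' @param ... Extra arguments for [detect_clusters()] (when
#'   `source = "clusters"`) are given via `cluster_args`; this `...` is
#'   passed to the fitter.
#' @param cluster_args List of arguments for [detect_clusters()].
#' @return List with `catalog` (localized counts), `exposures` (absolute),
#'   `relative` (per-sample relative contributions), and `flagged`
#'   (samples with no localized mutations).
#' @export
localized_analysis <- function(mutations, signatures, source = "clusters",
                               reference_genome = NULL,
                               fitter = c("forward", "plain"),
                               sample_ids = NULL, cluster_args = list(), ...) {
  fitter <- match.arg(fitter)
  if (is.null(sample_ids)) sample_ids <- unique(mutations$sample_id)
  if (identical(source, "clusters")) {
    parts <- lapply(sample_ids, function(sid) {
      m <- mutations[mutations$sample_id == sid, , drop = FALSE]
      m <- m[order(norm_chrom(m$chrom), m$pos), , drop = FALSE]
      cl <- do.call(detect_clusters, c(list(m), cluster_args))
      idx <- unique(unlist(cl$members))
      m[idx, , drop = FALSE]
    })
    loc <- do.call(rbind, parts)
  } else {
    loc <- restrict_to_regions(mutations, source)
  }
  catalog <- build_catalog(loc, reference = reference_genome,
                           sample_ids = sample_ids)
  E <- if (fitter == "forward") fit_forward_selection(catalog, signatures, ...)
       else fit_exposures(catalog, signatures, ...)
  flagged <- colnames(catalog)[colSums(catalog) == 0]
  list(catalog = catalog, exposures = E, relative = relative_exposures(E),
       flagged = flagged)
}

#' Rainfall-plot export
#'
#' Per-mutation table of genomic position, distance to the previous
#' mutation on the same chromosome, and SBS96 channel class — the data
#' behind a rainfall plot.
#'
#' @param mutations Context-annotated mutation records for one sample.
#' @return `data.frame` with `chrom`, `pos`, `imd` (NA for each
#'   chromosome's first mutation), `channel`, `substitution` (six-class).
#' @export
rainfall_data <- function(mutations) {
  mutations <- mutations[order(norm_chrom(mutations$chrom), mutations$pos), ]
  labs <- sbs96_channels()
  idx <- classify_snv(mutations$ref, mutations$alt, mutations$context)
  imd <- rep(NA_real_, nrow(mutations))
  ch <- norm_chrom(mutations$chrom)
  for (c0 in unique(ch)) {
    i <- which(ch == c0)
    if (length(i) >= 2) imd[i[-1]] <- diff(mutations$pos[i])
  }
  data.frame(chrom = ch, pos = mutations$pos, imd = imd,
             channel = labs[idx + 1L],
             substitution = SUB_CLASSES[idx %/% 16L + 1L],
             stringsAsFactors = FALSE)
}
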