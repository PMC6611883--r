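# End-to-end orchestration of the recommended workflow: consensus and
# catalog construction, de novo extraction with rank selection, assignment
# to a reference, shortlist refit by forward selection, diagnostics
# (exposure clustering, optional necessity test, split-extraction bleeding
# check), and optional localized analysis — with a JSON run manifest.

#' Run the full signature-analysis workflow
#'
#' Executes, in order: (1) catalog construction from VCFs (multi-caller
#' consensus when several VCFs are given per sample) or directly from a
#' supplied catalog; (2) de novo extraction with stability-based rank
#' selection; (3) assignment of extracted signatures to the reference
#' catalog; (4) refit of exposures against the shortlist by forward
#' selection; (5) diagnostics — exposure clustering, an optional necessity
#' test for a named candidate reference signature, and a split-extraction
#' bleeding check when a sample grouping is given; (6) localized analysis
#' when regions or kataegis detection are enabled. All numeric outputs are
#' written as TSV under `out_dir` together with a JSON manifest recording
#' the seed, settings and input checksums.
#'
#' @param catalog 96 x n catalog matrix (alternative to `vcfs`).
#' @param vcfs Named list (by sample) of VCF paths, or of *vectors* of
#'   VCF paths (one per caller, combined by [consensus_calls()]).
#' @param reference_genome FASTA path or DNAStringSet (needed with
#'   `vcfs`).
#' @param reference_signatures 96 x R reference signature matrix.
#' @param K_range Candidate ranks for [select_rank()] (default 1:6).
#' @param n_bootstraps,n_restarts,max_iter,tol Extraction settings.
#' @param min_callers Consensus threshold when multiple VCFs per sample
#'   (default 2).
#' @param prune_threshold Forward-selection pruning rule (default 0.06).
#' @param grouping Optional named sample-to-group vector enabling the
#'   split-extraction bleeding check.
#' @param necessity_candidate Optional reference signature name to put
#'   through [signature_necessity_test()].
#' @param regions Optional region set for localized analysis.
#' @param detect_kataegis Run kataegis detection + localized fit on the
#'   mutation records (requires `vcfs`).
#' @param localized_signatures Extended reference for the localized fit
#'   (defaults to `reference_signatures`).
#' @param seed Master seed for every random stage.
#' @param out_dir Output directory (created; default a tempdir).
#' @return List with `catalog`, `rank_selection`, `extraction`,
#'   `assignment`, `exposures` (shortlist refit), `clustering`,
#'   `necessity`, `bleeding`, `localized`, `manifest`.
#' @export
run_workflow <- function(catalog = NULL, vcfs = NULL, reference_genome = NULL,
                         reference_signatures,
                         K_range = 1:6, n_bootstraps = 30L, n_restarts = 3L,
                         max_iter = 3000L, tol = 1e-7,
                         min_callers = 2L, prune_threshold = 0.06,
                         grouping = NULL, necessity_candidate = NULL,
                         regions = NULL, detect_kataegis = FALSE,
                         localized_signatures = NULL,
                         seed = 1L, out_dir = tempfile("sigcraft_run")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "input"
  result <- list()
  input_checksums <- NULL
  mutations <- NULL
  tryCatch({
    if (is.null(catalog)) {
      stage <- "catalog"
      if (is.null(vcfs) || is.null(reference_genome))
        stop("supply either a catalog or vcfs + reference_genome")
      per_sample <- lapply(names(vcfs), function(sid) {
        paths <- vcfs[[sid]]
        sets <- lapply(paths, read_snvs, sample_id = sid)
        if (length(sets) > 1) consensus_calls(sets, min_callers = min_callers)
        else sets[[1]]
      })
      mutations <- do.call(rbind, per_sample)
      mutations <- annotate_contexts(mutations, reference_genome)
      catalog <- build_catalog(mutations, reference = reference_genome,
                               sample_ids = names(vcfs))
      vcf_paths <- unlist(vcfs)
      input_checksums <- as.list(tools::md5sum(vcf_paths))
    }
    write_matrix(catalog, file.path(out_dir, "catalog.tsv"))
    result$catalog <- catalog

    stage <- "extraction"
    rk <- select_rank(catalog, K_range, n_bootstraps = n_bootstraps,
                      n_restarts = n_restarts, seed = derive_seed(seed, "extract"),
                      max_iter = max_iter, tol = tol)
    extraction <- rk$results[[as.character(rk$recommended_K)]]
    result$rank_selection <- rk$metrics
    result$extraction <- extraction
    write_matrix(extraction$signatures, file.path(out_dir, "signatures_denovo.tsv"))
    write_matrix(extraction$exposures, file.path(out_dir, "exposures_denovo.tsv"),
                 row_label = "Signature")
    utils::write.table(rk$metrics, file.path(out_dir, "rank_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "assignment"
    assignment <- assign_to_reference(extraction$signatures, reference_signatures)
    result$assignment <- assignment
    utils::write.table(assignment, file.path(out_dir, "assignment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "refit"
    exposures <- refit_with_shortlist(catalog, assignment, reference_signatures,
                                      mode = "forward",
                                      extracted = extraction$signatures,
                                      prune_threshold = prune_threshold)
    result$exposures <- exposures
    write_matrix(exposures, file.path(out_dir, "exposures_refit.tsv"),
                 row_label = "Signature")

    stage <- "diagnostics"
    if (ncol(catalog) >= 2)
      result$clustering <- exposure_clustering(relative_exposures(exposures))
    if (!is.null(necessity_candidate)) {
      shortlist <- colnames(exposures)
      base <- setdiff(shortlist, necessity_candidate)
      base <- intersect(colnames(reference_signatures), base)
      result$necessity <- signature_necessity_test(
        catalog, reference_signatures[, base, drop = FALSE],
        reference_signatures[, necessity_candidate],
        candidate_name = necessity_candidate)
    }
    if (!is.null(grouping))
      result$bleeding <- split_extraction(
        catalog, grouping, K = max(1L, extraction$rank - 1L),
        seed = derive_seed(seed, "split"),
        n_bootstraps = n_bootstraps, n_restarts = n_restarts,
        max_iter = max_iter, tol = tol)

    stage <- "localized"
    if ((!is.null(regions) || detect_kataegis) && !is.null(mutations)) {
      loc_sigs <- localized_signatures %||% reference_signatures
      src <- if (!is.null(regions)) regions else "clusters"
      result$localized <- localized_analysis(mutations, loc_sigs, source = src,
                                             reference_genome = reference_genome)
      write_matrix(result$localized$exposures,
                   file.path(out_dir, "exposures_localized.tsv"),
                   row_label = "Signature")
    }

    stage <- "manifest"
    manifest <- list(
      package = "sigcraft",
      version = as.character(utils::packageVersion("sigcraft")),
      seed = seed,
      settings = list(K_range = K_range, n_bootstraps = n_bootstraps,
                      n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                      min_callers = min_callers,
                      prune_threshold = prune_threshold,
                      recommended_K = rk$recommended_K),
      input_checksums = input_checksums,
      samples = colnames(catalog))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    result$manifest <- manifest
    result$out_dir <- out_dir
    result
  }, error = function(e) {
    stop("workflow failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
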