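#' Pipeline configuration with study defaults
#'
#' Returns the full parameter set of the two pipelines, with defaults equal
#' to the study settings: consensus support 3 (of 4), 1,000 bp active-gene
#' window, 1,638 bp stitching, 2,500 bp TSS exclusion, motif q < 1e-5,
#' |log2FC| > 0.6 with adjusted p < 1e-10, 10 kb windows in 10 bp bins,
#' k = 3 chromatin states, 10 kb / 400 kb distance bins, 200 bp read
#' extension, 50 kb proximal assignment window.
#'
#' @param ... Named overrides of any default.
#' @return A named list of parameters (class `crc_config`).
#' @export
crc_config <- function(...) {
  defaults <- list(
    min_support = 3L,
    active_window = 1000L,
    stitch = 1638L,
    tss_exclusion = 2500L,
    q_threshold = 1e-5,
    lfc_cutoff = 0.6,
    padj_cutoff = 1e-10,
    window = 10000L,
    bin_width = 10L,
    k = 3L,
    promoter_max = 10000L,
    enhancer_max = 400000L,
    proximal_window = 50000L,
    extension = 200L,
    pseudocount = 0.1,
    granularity = 1e-3,
    score_mode = "total",
    scale_states = TRUE,
    fdr_scope = "per-tf",
    exclude_self = FALSE
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(overrides)] <- overrides
  structure(defaults, class = "crc_config")
}

# Pools per-line fragment tracks: fragments concatenated, totals summed.
pool_tracks <- function(tracks, label = "pooled") {
  frags <- dplyr::bind_rows(lapply(tracks, `[[`, "fragments"))
  fragment_track(frags, sum(vapply(tracks, `[[`, numeric(1),
                                   "total_mapped")), label)
}

stage_msg <- function(...) message("[crcmapr] ", sprintf(...))

#' Run the core regulatory circuitry pipeline
#'
#' Executes active-gene calling, enhancer stitching, signal ranking and the
#' super-enhancer cutoff, SE-to-gene assignment, nucleosome-free-region
#' definition, motif scanning and graph construction, and ranks candidate
#' TFs by total degree. Stage-boundary record counts are logged. Outputs
#' are deterministic given identical inputs and parameters.
#'
#' @param bundle A loaded input bundle (see [read_bundle()]); needs
#'   `genome`, `tss`, `motifs` and the `H3K27ac` / `ATAC` peaksets and
#'   `H3K27ac` fragment tracks.
#' @param params A [crc_config()].
#' @param outdir Optional output directory; when given, node/edge tables,
#'   BED files and a run manifest are written.
#' @return A `crc_network` object.
#' @export
run_crc <- function(bundle, params = crc_config(), outdir = NULL) {
  for (need in c("genome", "tss", "motifs")) {
    if (is.null(bundle[[need]])) stop("bundle lacks '", need, "'",
                                      call. = FALSE)
  }
  actives <- active_genes(bundle$tss, bundle$peaks$H3K27ac,
                          window = params$active_window)
  stage_msg("active genes: %d", length(actives))
  regions <- stitch_enhancers(bundle$peaks$H3K27ac, bundle$tss,
                              stitch = params$stitch,
                              tss_exclusion = params$tss_exclusion)
  stage_msg("stitched regions: %d", nrow(regions))
  pooled <- pool_tracks(bundle$fragments$H3K27ac, "H3K27ac_pooled")
  scored <- score_and_rank(regions, pooled, extension = params$extension,
                           score_mode = params$score_mode)
  se_tbl <- super_cutoff(scored)
  supers <- se_tbl[se_tbl$is_super, ]
  supers$se_id <- supers$region_id
  stage_msg("super-enhancers: %d of %d (cutoff %.3f)", nrow(supers),
            nrow(se_tbl), attr(se_tbl, "cutoff_signal"))
  assignments <- assign_to_genes(supers, bundle$tss,
                                 proximal_window = params$proximal_window)
  nfrs <- nucleosome_free_regions(bundle$peaks$ATAC, supers, actives,
                                  assignments)
  stage_msg("nucleosome-free regions: %d", nrow(nfrs))
  hits <- scan_nfrs(nfrs, bundle$genome, bundle$motifs,
                    q_threshold = params$q_threshold,
                    fdr_scope = params$fdr_scope,
                    granularity = params$granularity)
  stage_msg("q-passing motif hits: %d", nrow(hits))
  candidates <- candidate_tfs(actives, assignments, bundle$motifs,
                              bundle$tss)
  stage_msg("candidate TFs: %d", length(candidates))
  edges <- build_graph(candidates, hits, nfrs, assignments, bundle$tss)
  if (params$exclude_self) {
    edges <- edges[edges$source != edges$target, ]
  }
  nodes <- rank_tfs(total_degrees(edges, candidates))
  stage_msg("edges: %d; top TF: %s", nrow(edges),
            if (nrow(nodes) > 0) nodes$tf[1] else "<none>")
  result <- crc_network(nodes, edges, candidates, hits, se_tbl, nfrs,
                        assignments, actives)
  if (!is.null(outdir)) write_crc_outputs(result, params, outdir)
  result
}

write_crc_outputs <- function(result, params, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$nodes, file.path(outdir, "tf_nodes.tsv"))
  readr::write_tsv(result$edges[, c("source", "target", "n_evidence")],
                   file.path(outdir, "tf_edges.tsv"))
  se <- tibble::as_tibble(result$superenhancers)
  se$signal <- round(se$signal, 6)
  se$density <- round(se$density, 6)
  readr::write_tsv(se, file.path(outdir, "stitched_regions.tsv"))
  write_bed(se[se$is_super, c("chrom", "start", "end", "region_id")] |>
              dplyr::rename(name = "region_id"),
            file.path(outdir, "superenhancers.bed"))
  write_bed(result$nfrs |> dplyr::rename(name = "nfr_id"),
            file.path(outdir, "nfrs.bed"))
  readr::write_tsv(result$hits[, c("tf", "chrom", "start", "end", "strand",
                                   "score", "p", "q", "nfr_id")] |>
                     dplyr::mutate(score = round(.data$score, 4)),
                   file.path(outdir, "motif_hits.tsv"))
  writeLines(result$active_genes, file.path(outdir, "active_genes.txt"))
  yaml::write_yaml(unclass(params), file.path(outdir, "run_manifest.yaml"))
  invisible(result)
}

#' Run the binding-site characterization pipeline
#'
#' Builds the cross-cell-line TF consensus peakset, summit-centered signal
#' matrices for all marks, clusters the three histone marks into chromatin
#' states, filters the differential-expression table, categorizes regulated
#' genes by distance to the nearest consensus TF peak, and compares
#' category effect sizes with Welch's t-test.
#'
#' @param bundle A loaded input bundle with `TF` peaksets, per-mark
#'   fragment tracks, the TSS table and a DE table.
#' @param params A [crc_config()].
#' @param outdir Optional output directory.
#' @return A list of class `target_report` with `consensus`, `matrices`,
#'   `states`, `de`, `categories`, `welch`.
#' @export
run_targets <- function(bundle, params = crc_config(), outdir = NULL) {
  consensus <- consensus_peaks(bundle$peaks$TF,
                               min_support = params$min_support)
  stage_msg("consensus TF peaks: %d", nrow(consensus))
  mats <- state_matrix(consensus, bundle$fragments,
                       window = params$window,
                       bin_width = params$bin_width,
                       extension = params$extension)
  states <- cluster_states(mats, k = params$k,
                           scale = params$scale_states)
  stage_msg("chromatin states: %s",
            paste(table(states$assignments$cluster), collapse = "/"))
  de <- filter_de(bundle$de, lfc_cutoff = params$lfc_cutoff,
                  padj_cutoff = params$padj_cutoff)
  if (nrow(de) == 0) {
    warning("no genes pass the DE filter; category report is empty")
    categories <- tibble::tibble(gene_id = character(),
                                 distance = numeric(),
                                 category = factor(character(),
                                                   levels = c("Promoter",
                                                              "Enhancer",
                                                              "Distal",
                                                              "Unassigned")))
    welch <- tibble::tibble(category_a = character(),
                            category_b = character())
  } else {
    categories <- categorize_by_peak_distance(
      bundle$tss[bundle$tss$gene_id %in% de$gene_id, ], consensus,
      promoter_max = params$promoter_max,
      enhancer_max = params$enhancer_max)
    welch <- welch_by_category(de, categories)
  }
  stage_msg("regulated genes: %d (%s)", nrow(de),
            paste(table(categories$category), collapse = "/"))
  result <- structure(list(consensus = consensus, matrices = mats,
                           states = states, de = de,
                           categories = categories, welch = welch),
                      class = "target_report")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(consensus[, c("peak_id", "chrom", "start", "end",
                                   "summit", "support")],
                     file.path(outdir, "consensus_peaks.tsv"))
    readr::write_tsv(states$assignments,
                     file.path(outdir, "chromatin_states.tsv"))
    readr::write_tsv(dplyr::mutate(categories,
                                   distance = ifelse(
                                     is.infinite(.data$distance), -1,
                                     .data$distance)),
                     file.path(outdir, "gene_categories.tsv"))
    readr::write_tsv(welch, file.path(outdir, "welch_report.tsv"))
    yaml::write_yaml(unclass(params), file.path(outdir,
                                                "run_manifest.yaml"))
  }
  result
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf(paste0("<target_report: %d consensus peaks, %d states, ",
                     "%d regulated genes>\n"),
              nrow(x$consensus), x$states$k, nrow(x$de)))
  invisible(x)
}
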