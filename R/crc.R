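#' Candidate transcription factors for circuitry mapping
#'
#' A candidate TF is a gene that is (i) active, (ii) assigned a
#' super-enhancer (overlapping, proximal or closest) and (iii) present in
#' the motif database. Motif names are matched to annotation gene symbols
#' exactly but case-insensitively; unmatched motifs are reported via a
#' message, not dropped silently.
#'
#' @param active_gene_ids Character vector of active genes.
#' @param assignments SE-to-gene assignments (from [assign_to_genes()]).
#' @param motifs Named list of `motif_model`s.
#' @param tss TSS annotation tibble (maps `gene_id` to `gene_symbol`).
#' @return Alphabetically sorted character vector of candidate TF gene
#'   symbols.
#' @export
candidate_tfs <- function(active_gene_ids, assignments, motifs, tss) {
  motif_names <- vapply(motifs, `[[`, "", "tf_name")
  symbol_map <- unique(tss[, c("gene_id", "gene_symbol")])
  matched <- symbol_map[toupper(symbol_map$gene_symbol) %in%
                          toupper(motif_names), ]
  unmatched <- motif_names[!toupper(motif_names) %in%
                             toupper(symbol_map$gene_symbol)]
  if (length(unmatched) > 0) {
    message("motifs without a matching annotation symbol: ",
            paste(unmatched, collapse = ", "))
  }
  ok <- matched$gene_id %in% active_gene_ids &
    matched$gene_id %in% assignments$gene_id
  sort(unique(matched$gene_symbol[ok]))
}

#' Build the TF-TF regulatory graph
#'
#' An edge A -> B exists when at least one q-passing motif hit of A lies in
#' a nucleosome-free region contained in a super-enhancer assigned to B,
#' with both A and B candidate TFs. One edge per ordered pair; evidence is
#' aggregated and counted.
#'
#' @param candidates Candidate TF symbols (from [candidate_tfs()]).
#' @param hits Motif hits tibble (from [scan_nfrs()]), with `tf`, `nfr_id`.
#' @param nfrs NFR tibble with `nfr_id`, `se_id` (from
#'   [nucleosome_free_regions()]).
#' @param assignments SE-to-gene assignments.
#' @param tss TSS annotation tibble.
#' @return A tibble with `source`, `target`, `n_evidence` and an `evidence`
#'   list-column of the supporting hits.
#' @export
build_graph <- function(candidates, hits, nfrs, assignments, tss) {
  empty <- tibble::tibble(source = character(), target = character(),
                          n_evidence = integer(), evidence = list())
  if (nrow(hits) == 0) return(empty)
  unknown <- setdiff(unique(hits$nfr_id), nfrs$nfr_id)
  if (length(unknown) > 0) {
    stop("motif hit in NFR not mapped to any super-enhancer: ",
         paste(head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  symbol_map <- unique(tss[, c("gene_id", "gene_symbol")])
  cand_hits <- hits[toupper(hits$tf) %in% toupper(candidates), ]
  if (nrow(cand_hits) == 0) return(empty)
  cand_hits <- cand_hits[, setdiff(names(cand_hits), "se_id")]
  edges <- cand_hits |>
    dplyr::left_join(nfrs[, c("nfr_id", "se_id")], by = "nfr_id")
  edges <- edges[, c("tf", "nfr_id", "se_id", "chrom", "start", "end",
                     "strand", "score", "p", "q")] |>
    dplyr::inner_join(assignments[, c("se_id", "gene_id")], by = "se_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(symbol_map, by = "gene_id") |>
    dplyr::filter(toupper(.data$gene_symbol) %in% toupper(candidates))
  if (nrow(edges) == 0) return(empty)
  edges |>
    dplyr::rename(source = "tf", target = "gene_symbol") |>
    dplyr::group_by(.data$source, .data$target) |>
    dplyr::summarise(
      n_evidence = dplyr::n(),
      evidence = list(dplyr::pick(dplyr::everything())),
      .groups = "drop") |>
    dplyr::arrange(.data$source, .data$target)
}

#' Total degree of each candidate TF
#'
#' For each TF, `in_set` is the unique set of TFs with an edge into it and
#' `out_set` the unique set it has edges to; `total_degree` is the sum of
#' the two set sizes. A self-loop contributes the TF once to each set.
#'
#' @param edges Edge tibble with `source`, `target`.
#' @param candidates Candidate TF symbols (isolated candidates get degree
#'   0).
#' @return A tibble with `tf`, `in_degree`, `out_degree`, `total_degree`.
#' @export
total_degrees <- function(edges, candidates) {
  pairs <- unique(edges[, c("source", "target")])
  cands <- sort(unique(candidates))
  tibble::tibble(
    tf = cands,
    in_degree = vapply(cands, function(t) {
      length(unique(pairs$source[pairs$target == t]))
    }, integer(1), USE.NAMES = FALSE),
    out_degree = vapply(cands, function(t) {
      length(unique(pairs$target[pairs$source == t]))
    }, integer(1), USE.NAMES = FALSE)
  ) |>
    dplyr::mutate(total_degree = .data$in_degree + .data$out_degree)
}

#' Rank TFs by total degree
#'
#' Descending total degree; ties broken by descending out-degree, then
#' alphabetically.
#'
#' @param nodes Node tibble (from [total_degrees()]).
#' @return `nodes` with a `rank` column, sorted by rank.
#' @export
rank_tfs <- function(nodes) {
  nodes <- nodes[order(-nodes$total_degree, -nodes$out_degree, nodes$tf), ]
  nodes$rank <- seq_len(nrow(nodes))
  tibble::as_tibble(nodes)
}

# Bundles the pipeline products into a single result object.
crc_network <- function(nodes, edges, candidates, hits, superenhancers,
                        nfrs, assignments, active) {
  structure(list(nodes = nodes, edges = edges, candidates = candidates,
                 hits = hits, superenhancers = superenhancers, nfrs = nfrs,
                 assignments = assignments, active_genes = active),
            class = "crc_network")
}

#' @export
print.crc_network <- function(x, ...) {
  cat(sprintf(paste0("<crc_network: %d candidate TFs, %d edges, ",
                     "%d super-enhancers, %d NFRs>\n"),
              length(x$candidates), nrow(x$edges),
              sum(x$superenhancers$is_super %||% TRUE), nrow(x$nfrs)))
  if (nrow(x$nodes) > 0) {
    cat(sprintf("  top TF by total degree: %s (%d)\n", x$nodes$tf[1],
                x$nodes$total_degree[1]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
tidy.crc_network <- function(x, ...) x$nodes

#' @export
glance.crc_network <- function(x, ...) {
  tibble::tibble(n_candidates = length(x$candidates),
                 n_edges = nrow(x$edges),
                 n_super_enhancers = nrow(x$superenhancers),
                 n_nfrs = nrow(x$nfrs),
                 top_tf = if (nrow(x$nodes) > 0) x$nodes$tf[1] else
                   NA_character_)
}
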