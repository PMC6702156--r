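#' Identify active genes from promoter H3K27ac
#'
#' A gene is active when any of its TSS records lies within `window` bases
#' (gap distance) of at least one H3K27ac peak from any supplied cell line
#' (default 1,000 bp, one line sufficing).
#'
#' @param tss TSS annotation tibble (`gene_id`, `chrom`, `tss`, ...).
#' @param h3k27ac_peaksets Named list of per-line peaks tibbles.
#' @param window Maximum TSS-to-peak distance in bases.
#' @return Sorted character vector of active `gene_id`s.
#' @export
active_genes <- function(tss, h3k27ac_peaksets, window = 1000) {
  pooled <- dplyr::bind_rows(h3k27ac_peaksets)
  if (nrow(pooled) == 0 || nrow(tss) == 0) return(character(0))
  d <- min_distance_to_targets(tss$chrom, tss$tss, pooled)
  sort(unique(tss$gene_id[d <= window]))
}

#' Stitch enhancer peaks into candidate regions
#'
#' Pools H3K27ac peaks from all cell lines, removes peaks lying entirely
#' within `tss_exclusion` bases of any TSS (promoter-proximal signal), and
#' merges the survivors with a gap of `stitch` bases (defaults 2,500 bp and
#' 1,638 bp).
#'
#' @param h3k27ac_peaksets Named list of per-line peaks tibbles.
#' @param tss TSS annotation tibble.
#' @param stitch Stitching distance in bases.
#' @param tss_exclusion Half-width of the TSS exclusion zone in bases.
#' @return A tibble of stitched regions with `region_id`, `chrom`, `start`,
#'   `end`, `n_constituents`.
#' @export
stitch_enhancers <- function(h3k27ac_peaksets, tss, stitch = 1638,
                             tss_exclusion = 2500) {
  pooled <- dplyr::bind_rows(h3k27ac_peaksets)
  empty <- tibble::tibble(region_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_constituents = integer())
  if (nrow(pooled) == 0) return(empty)
  check_intervals(pooled, "peak")
  # whole peaks fully inside the +/- exclusion zone of any TSS are removed
  excluded <- vapply(seq_len(nrow(pooled)), function(i) {
    sel <- tss$chrom == pooled$chrom[i]
    any(tss$tss[sel] - tss_exclusion <= pooled$start[i] &
          pooled$end[i] <= tss$tss[sel] + tss_exclusion + 1)
  }, logical(1))
  survivors <- pooled[!excluded, ]
  if (nrow(survivors) == 0) return(empty)
  regions <- merge_intervals(survivors, gap = stitch)
  counts <- vapply(seq_len(nrow(regions)), function(i) {
    sum(survivors$chrom == regions$chrom[i] &
          survivors$start < regions$end[i] &
          survivors$end > regions$start[i])
  }, integer(1))
  regions$n_constituents <- counts
  regions$region_id <- sprintf("region_%05d", seq_len(nrow(regions)))
  regions[, c("region_id", "chrom", "start", "end", "n_constituents")]
}

#' Score and rank stitched regions by total signal
#'
#' Region signal is the rpm/bp read density of the (optionally
#' control-subtracted, floored at zero) treatment track multiplied by the
#' region length, i.e. total stitched signal, the quantity ROSE ranks on.
#' Rank 1 is the largest signal; ties are broken by longer region, then by
#' coordinate order.
#'
#' @param regions Stitched regions tibble (from [stitch_enhancers()]).
#' @param track Treatment `fragment_track` (typically pooled H3K27ac).
#' @param control Optional control/input `fragment_track` to subtract.
#' @param extension Read extension in bases.
#' @param score_mode `"total"` (density x length, the ROSE convention) or
#'   `"mean"` (density alone).
#' @return `regions` with added `density`, `signal`, `rank`, sorted by rank.
#' @export
score_and_rank <- function(regions, track, control = NULL, extension = 200,
                           score_mode = c("total", "mean")) {
  score_mode <- match.arg(score_mode)
  if (nrow(regions) == 0) stop("no regions to score", call. = FALSE)
  dens <- region_densities(track, regions, extension)
  if (!is.null(control)) {
    dens <- pmax(dens - region_densities(control, regions, extension), 0)
  }
  regions$density <- dens
  len <- regions$end - regions$start
  regions$signal <- if (score_mode == "total") dens * len else dens
  ord <- order(-regions$signal, -len, regions$chrom, regions$start)
  regions$rank <- NA_integer_
  regions$rank[ord] <- seq_len(nrow(regions))
  dplyr::arrange(regions, .data$rank)
}

#' Super-enhancer cutoff on the scaled rank-signal curve
#'
#' Regions are ordered by ascending signal, rank and signal are each scaled
#' to `[0, 1]`, and the cutoff is placed at the first point whose outgoing
#' discrete slope exceeds 1 (the tangent-slope-1 rule on the hockey-stick
#' curve). That point and every higher-signal region are flagged
#' `is_super`. If all signals are equal (or no slope exceeds 1) no region
#' is flagged and a warning is raised.
#'
#' @param regions Scored regions (from [score_and_rank()]).
#' @return `regions` with an `is_super` column, attribute `cutoff_signal`
#'   (the signal at the cutoff point, `NA` when no cutoff exists), ordered
#'   by rank, with class `se_table`.
#' @export
super_cutoff <- function(regions) {
  n <- nrow(regions)
  regions$is_super <- FALSE
  cutoff <- NA_real_
  if (n < 2 || length(unique(regions$signal)) < 2) {
    warning("all region signals equal (or fewer than 2 regions); ",
            "no super-enhancers called")
  } else {
    asc <- regions[order(regions$rank, decreasing = TRUE), ]
    y <- (asc$signal - min(asc$signal)) /
      (max(asc$signal) - min(asc$signal))
    slopes <- diff(y) * (n - 1)  # x spacing is 1/(n-1) after scaling
    i_star <- which(slopes > 1)[1]
    if (is.na(i_star)) {
      warning("scaled rank-signal curve never exceeds slope 1; ",
              "no super-enhancers called")
    } else {
      cutoff <- asc$signal[i_star]
      super_ranks <- asc$rank[i_star:n]
      regions$is_super <- regions$rank %in% super_ranks
    }
  }
  regions <- dplyr::arrange(regions, .data$rank)
  attr(regions, "cutoff_signal") <- cutoff
  class(regions) <- c("se_table", class(regions))
  regions
}

#' @export
glance.se_table <- function(x, ...) {
  tibble::tibble(n_regions = nrow(x), n_super = sum(x$is_super),
                 cutoff_signal = attr(x, "cutoff_signal"))
}

#' Assign super-enhancers to genes
#'
#' Each region is assigned the genes whose TSS overlaps it
#' (`overlapping`), the genes with a TSS within `proximal_window` bases
#' (`proximal`), and the single nearest-TSS gene (`closest`, ties by
#' smaller TSS start then input order); duplicates collapse to the
#' strongest relation. Every region on a gene-bearing chromosome receives
#' at least one gene.
#'
#' @param superenhancers Regions tibble with `region_id` (or `se_id`),
#'   `chrom`, `start`, `end`.
#' @param tss TSS annotation tibble.
#' @param proximal_window Proximal assignment window in bases (default
#'   50,000).
#' @return A tibble with `se_id`, `gene_id`, `relation`
#'   (overlapping/proximal/closest) and `distance`.
#' @export
assign_to_genes <- function(superenhancers, tss, proximal_window = 50000) {
  id_col <- if ("se_id" %in% names(superenhancers)) "se_id" else "region_id"
  relation_levels <- c("overlapping", "proximal", "closest")
  out <- lapply(seq_len(nrow(superenhancers)), function(i) {
    se <- superenhancers[i, ]
    sel <- which(tss$chrom == se$chrom)
    if (length(sel) == 0) return(NULL)
    d <- interval_gap(se$start, se$end, tss$tss[sel], tss$tss[sel] + 1)
    rel <- rep(NA_character_, length(sel))
    rel[d <= proximal_window] <- "proximal"
    rel[d == 0] <- "overlapping"
    closest <- order(d, tss$tss[sel], sel)[1]
    if (is.na(rel[closest])) rel[closest] <- "closest"
    keep <- which(!is.na(rel))
    tibble::tibble(se_id = se[[id_col]], gene_id = tss$gene_id[sel][keep],
                   relation = rel[keep], distance = d[keep])
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(se_id = character(), gene_id = character(),
                          relation = character(), distance = numeric()))
  }
  # one row per (se, gene): strongest relation, smallest distance
  res |>
    dplyr::mutate(rel_rank = match(.data$relation, relation_levels)) |>
    dplyr::group_by(.data$se_id, .data$gene_id) |>
    dplyr::summarise(
      relation = relation_levels[min(.data$rel_rank)],
      distance = min(.data$distance), .groups = "drop") |>
    dplyr::arrange(.data$se_id, .data$relation, .data$gene_id)
}

#' Nucleosome-free regions within active super-enhancers
#'
#' Pools ATAC peaks across cell lines, merges overlapping peaks, and keeps
#' merged regions fully contained within a super-enhancer assigned to at
#' least one active gene (containment, not mere overlap).
#'
#' @param atac_peaksets Named list of per-line ATAC peaks tibbles.
#' @param superenhancers Super-enhancer regions tibble (with `region_id` or
#'   `se_id`).
#' @param active_gene_ids Character vector of active genes.
#' @param assignments SE-to-gene assignments (from [assign_to_genes()]).
#' @return A tibble with `nfr_id`, `chrom`, `start`, `end`, `se_id`.
#' @export
nucleosome_free_regions <- function(atac_peaksets, superenhancers,
                                    active_gene_ids, assignments) {
  id_col <- if ("se_id" %in% names(superenhancers)) "se_id" else "region_id"
  merged <- merge_intervals(dplyr::bind_rows(atac_peaksets), gap = 0)
  empty <- tibble::tibble(nfr_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          se_id = character())
  if (nrow(merged) == 0 || nrow(superenhancers) == 0) return(empty)
  active_se <- unique(assignments$se_id[assignments$gene_id %in%
                                          active_gene_ids])
  ses <- superenhancers[superenhancers[[id_col]] %in% active_se, ]
  if (nrow(ses) == 0) return(empty)
  hit <- lapply(seq_len(nrow(merged)), function(i) {
    sel <- which(ses$chrom == merged$chrom[i] &
                   ses$start <= merged$start[i] &
                   merged$end[i] <= ses$end)
    if (length(sel) == 0) return(NULL)
    tibble::tibble(chrom = merged$chrom[i], start = merged$start[i],
                   end = merged$end[i], se_id = ses[[id_col]][sel[1]])
  })
  res <- dplyr::bind_rows(hit)
  if (nrow(res) == 0) return(empty)
  res <- dplyr::arrange(res, .data$chrom, .data$start)
  res$nfr_id <- sprintf("nfr_%05d", seq_len(nrow(res)))
  res[, c("nfr_id", "chrom", "start", "end", "se_id")]
}
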