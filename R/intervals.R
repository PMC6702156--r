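#' Interval algebra on 0-based half-open genomic intervals
#'
#' All coordinates in this package follow the BED convention: 0-based starts,
#' exclusive ends, so an interval `[start, end)` covers `end - start` bases.
#' Strand is carried where present but ignored by interval arithmetic; only
#' motif scanning is strand-aware.
#'
#' @name interval-conventions
NULL

# Validates chrom/start/end columns; errors name the offending row so that
# malformed records in large peak files are traceable.
check_intervals <- function(x, what = "interval") {
  needed <- c("chrom", "start", "end")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop(what, " table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) | is.na(x$start) |
                 is.na(x$end) | x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    b <- bad[1]
    stop(sprintf("malformed %s in row %d: %s:%s-%s", what, b,
                 x$chrom[b], format(x$start[b]), format(x$end[b])),
         call. = FALSE)
  }
  invisible(x)
}

#' Merge genomic intervals lying within a gap of one another
#'
#' Sorts intervals and unions any two whose intervening gap is at most `gap`
#' bases. With `gap = 0` this merges overlapping and book-ended intervals
#' (half-open adjacency means zero intervening bases), exactly preserving the
#' covered base set. With `gap` equal to a stitching distance (e.g. the
#' 1,638 bp used for enhancer stitching) it reproduces ROSE-style stitching.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open). Extra columns are dropped.
#' @param gap Non-negative integer; two intervals separated by at most this
#'   many bases are merged.
#' @return A tibble with columns `chrom`, `start`, `end`, sorted by
#'   coordinate, in which consecutive intervals on a chromosome are separated
#'   by more than `gap` bases.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(0, 50), end = c(100, 150))
#' merge_intervals(x, gap = 0)
#' @export
merge_intervals <- function(x, gap = 0) {
  stopifnot(is.numeric(gap), length(gap) == 1, gap >= 0)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  check_intervals(x)
  x |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      run_end = cummax(as.numeric(.data$end)),
      new_run = .data$start > dplyr::lag(.data$run_end, default = -Inf) + gap,
      run_id = cumsum(.data$new_run)
    ) |>
    dplyr::group_by(.data$chrom, .data$run_id) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select("chrom", "start", "end")
}

# Gap distance between half-open intervals [qs,qe) and vectors of targets:
# 0 when overlapping, otherwise the number of bases strictly between them.
interval_gap <- function(qs, qe, ts, te) {
  pmax(ts - qe, qs - te, 0)
}

#' Distance from a query interval to its nearest target
#'
#' Distance is 0 for any overlap, otherwise the number of bases separating
#' the closest ends; targets on other chromosomes are infinitely far. Ties
#' are broken by smaller target start, then by input order.
#'
#' @param query A one-row data frame with `chrom`, `start`, `end`.
#' @param targets A data frame of intervals (any chromosomes).
#' @return A one-row tibble with `distance` (`Inf` when no target shares the
#'   chromosome) and `target` (row index into `targets`, `NA` when none).
#' @examples
#' q <- tibble::tibble(chrom = "chr1", start = 100, end = 200)
#' t <- tibble::tibble(chrom = "chr1", start = c(300, 1000), end = c(400, 1100))
#' nearest_distance(q, t)
#' @export
nearest_distance <- function(query, targets) {
  stopifnot(nrow(query) == 1)
  check_intervals(query, "query")
  if (nrow(targets) > 0) check_intervals(targets, "target")
  same <- which(targets$chrom == query$chrom)
  if (length(same) == 0) {
    return(tibble::tibble(distance = Inf, target = NA_integer_))
  }
  d <- interval_gap(query$start, query$end, targets$start[same],
                    targets$end[same])
  ord <- order(d, targets$start[same], same)
  best <- ord[1]
  tibble::tibble(distance = d[best], target = same[best])
}

# Vectorized helper: minimum gap distance from each point (1 bp interval at
# `pos` on `chrom`) to any target interval. Returns Inf off-chromosome.
min_distance_to_targets <- function(chrom, pos, targets) {
  vapply(seq_along(pos), function(i) {
    same <- targets$chrom == chrom[i]
    if (!any(same)) return(Inf)
    min(interval_gap(pos[i], pos[i] + 1, targets$start[same],
                     targets$end[same]))
  }, numeric(1))
}
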