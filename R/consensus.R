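#' Cross-cell-line consensus peaks
#'
#' Pools peaks from several cell lines, groups them transitively by overlap
#' (at least 1 bp), and keeps groups supported by at least `min_support`
#' distinct lines (default 3, the 3-of-4 rule). The consensus interval is
#' the union span of the members; the representative summit is the summit
#' of the highest-signal member (ties broken by leftmost summit).
#'
#' @param peaksets A named list of peaks tibbles, one per cell line.
#' @param min_support Minimum number of distinct supporting lines.
#' @return A tibble with `peak_id`, `chrom`, `start`, `end`, `name`,
#'   `summit`, `support` and a `members` list-column of the contributing
#'   peaks.
#' @export
consensus_peaks <- function(peaksets, min_support = 3) {
  if (min_support > length(peaksets)) {
    stop("min_support (", min_support, ") exceeds the number of peaksets (",
         length(peaksets), ")", call. = FALSE)
  }
  if (is.null(names(peaksets))) {
    names(peaksets) <- sprintf("line%d", seq_along(peaksets))
  }
  pooled <- dplyr::bind_rows(peaksets, .id = "line")
  if (nrow(pooled) == 0) {
    return(tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          name = character(), summit = integer(),
                          support = integer(), members = list()))
  }
  check_intervals(pooled, "peak")
  pooled <- pooled |>
    dplyr::arrange(.data$chrom, .data$start, .data$end) |>
    dplyr::group_by(.data$chrom) |>
    # transitive overlap groups: a new group starts where a peak begins at or
    # after the running maximum end (no shared base)
    dplyr::mutate(
      run_end = cummax(as.numeric(.data$end)),
      new_run = .data$start >= dplyr::lag(.data$run_end, default = -Inf),
      run_id = cumsum(.data$new_run)
    ) |>
    dplyr::ungroup()
  groups <- pooled |>
    dplyr::group_by(.data$chrom, .data$run_id) |>
    dplyr::group_split()
  out <- lapply(groups, function(g) {
    support <- dplyr::n_distinct(g$line)
    best <- order(-g$signal, g$summit)[1]
    tibble::tibble(chrom = g$chrom[1], start = min(g$start),
                   end = max(g$end), summit = g$summit[best],
                   support = support,
                   members = list(g[, setdiff(names(g),
                                              c("run_end", "new_run",
                                                "run_id"))]))
  })
  res <- dplyr::bind_rows(out) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(.data$chrom, .data$start)
  res$peak_id <- sprintf("cons_%05d", seq_len(nrow(res)))
  res$name <- res$peak_id
  res[, c("peak_id", "chrom", "start", "end", "name", "summit", "support",
          "members")]
}

STATE_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3")

#' Summit-centered signal matrices per chromatin mark
#'
#' For each mark, computes the summit-centered binned matrix per cell line
#' and averages them bin-wise, giving one row-aligned matrix per mark
#' (rows in consensus-peak order). The three clustering marks (H3K27ac,
#' H3K4me1, H3K4me3) are required; extra marks (ATAC, TF ChIP) are carried
#' for display.
#'
#' @param consensus Consensus peaks tibble (from [consensus_peaks()]).
#' @param tracks A named list `mark -> (named list line -> fragment_track)`.
#' @param window,bin_width,extension Passed to [summit_matrix()].
#' @return A named list of matrices, one per mark, rows aligned across
#'   marks.
#' @export
state_matrix <- function(consensus, tracks, window = 10000, bin_width = 10,
                         extension = 200) {
  missing <- setdiff(STATE_MARKS, names(tracks))
  if (length(missing) > 0) {
    stop("missing clustering mark track(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  peaks <- tibble::tibble(chrom = consensus$chrom, summit = consensus$summit,
                          name = consensus$peak_id)
  lapply(tracks, function(lines) {
    mats <- lapply(lines, function(tr) {
      summit_matrix(peaks, tr, window = window, bin_width = bin_width,
                    extension = extension)
    })
    out <- Reduce(`+`, mats) / length(mats)
    attr(out, "window") <- window
    attr(out, "bin_width") <- bin_width
    out
  })
}

#' Cluster binding sites into chromatin states
#'
#' Concatenates the summit-centered bin vectors of the three histone marks
#' (optionally z-scaled per mark so no mark dominates the Euclidean
#' distance), clusters rows by agglomerative hierarchical clustering with
#' Ward's D2 linkage, and cuts the tree into `k` clusters. Cluster labels
#' are renumbered 1..k by decreasing mean raw H3K27ac signal, making labels
#' deterministic across runs.
#'
#' @param mats A named list of row-aligned matrices including `H3K27ac`,
#'   `H3K4me1`, `H3K4me3` (as from [state_matrix()]).
#' @param k Number of chromatin states (default 3).
#' @param scale Z-scale each mark's block before clustering (default TRUE).
#' @return An object of class `state_clustering` with `assignments` (tibble
#'   `peak_id`, `cluster`), the `hclust` tree, `k` and per-cluster mark
#'   means.
#' @export
cluster_states <- function(mats, k = 3, scale = TRUE) {
  missing <- setdiff(STATE_MARKS, names(mats))
  if (length(missing) > 0) {
    stop("missing clustering mark(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ids <- rownames(mats[[STATE_MARKS[1]]])
  n <- length(ids)
  if (n < k) stop("fewer rows (", n, ") than clusters (", k, ")",
                  call. = FALSE)
  for (m in STATE_MARKS) {
    if (!identical(rownames(mats[[m]]), ids)) {
      stop("mark matrices are not row-aligned", call. = FALSE)
    }
  }
  feats <- do.call(cbind, lapply(STATE_MARKS, function(m) {
    x <- mats[[m]]
    if (scale) {
      s <- sd(x)
      x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
    }
    x
  }))
  if (k == 1) {
    raw <- setNames(rep(1L, n), ids)
    h <- NULL
  } else {
    h <- hclust(dist(feats), method = "ward.D2")
    raw <- cutree(h, k = k)
  }
  k27_mean <- tapply(rowMeans(mats$H3K27ac), raw, mean)
  relabel <- setNames(seq_len(k), names(sort(k27_mean, decreasing = TRUE)))
  cluster <- as.integer(relabel[as.character(raw)])
  means <- dplyr::bind_rows(lapply(STATE_MARKS, function(m) {
    by_cluster <- tapply(rowMeans(mats[[m]]), cluster,
                         mean)[as.character(seq_len(k))]
    tibble::tibble(mark = m, cluster = seq_len(k),
                   mean_signal = as.numeric(by_cluster))
  }))
  structure(list(assignments = tibble::tibble(peak_id = ids,
                                              cluster = cluster),
                 hclust = h, k = k, scaled = scale, means = means),
            class = "state_clustering")
}

#' @export
print.state_clustering <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat(sprintf("<state_clustering: %d sites in %d states (%s)>\n",
              nrow(x$assignments), x$k,
              paste(sprintf("%s: %d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.state_clustering <- function(x, ...) x$assignments

#' @export
glance.state_clustering <- function(x, ...) {
  tibble::tibble(n_sites = nrow(x$assignments), k = x$k, scaled = x$scaled)
}
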