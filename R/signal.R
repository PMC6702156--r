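#' Construct a fragment track
#'
#' A fragment track holds aligned sequencing fragments (or 5'-positioned
#' reads to be extended) together with the library's total mapped read
#' count, which is the denominator of rpm/bp normalization.
#'
#' @param fragments A data frame with `chrom`, `start`, `end` and optionally
#'   `strand` (`+`, `-` or `.`; missing means unstranded).
#' @param total_mapped Positive count of mapped reads in the library; must be
#'   at least the number of fragments supplied.
#' @param label Track / cell-line name.
#' @return An object of class `fragment_track`.
#' @export
fragment_track <- function(fragments, total_mapped, label = "track") {
  if (nrow(fragments) > 0) check_intervals(fragments, "fragment")
  stopifnot(length(total_mapped) == 1, total_mapped >= 1)
  if (total_mapped < nrow(fragments)) {
    stop("total_mapped (", total_mapped, ") is smaller than the number of ",
         "fragments (", nrow(fragments), ")", call. = FALSE)
  }
  if (!"strand" %in% names(fragments)) fragments$strand <- "."
  structure(list(fragments = tibble::as_tibble(fragments),
                 total_mapped = as.numeric(total_mapped), label = label),
            class = "fragment_track")
}

#' @export
print.fragment_track <- function(x, ...) {
  cat(sprintf("<fragment_track '%s': %d fragments, %s total mapped reads>\n",
              x$label, nrow(x$fragments), format(x$total_mapped)))
  invisible(x)
}

#' Read a fragment track from BED with a total-mapped sidecar
#'
#' Fragments are one BED line per read. The total mapped read count is taken
#' from `total_mapped` if given, otherwise from the sidecar file
#' `<path>.total` (a single integer).
#'
#' @param path BED file of fragments (3 or 6 columns).
#' @param total_mapped Optional total mapped read count.
#' @param label Track label (defaults to the file name).
#' @return A `fragment_track`.
#' @export
read_fragment_track <- function(path, total_mapped = NULL,
                                label = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    frags <- tibble::tibble(
      chrom = vapply(fields, `[`, "", 1),
      start = as.integer(vapply(fields, `[`, "", 2)),
      end = as.integer(vapply(fields, `[`, "", 3)),
      strand = vapply(fields, function(f) if (length(f) >= 6) f[6] else ".",
                      "")
    )
  } else {
    frags <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), strand = character())
  }
  if (is.null(total_mapped)) {
    sidecar <- paste0(path, ".total")
    if (!file.exists(sidecar)) {
      stop("no total_mapped given and sidecar not found: ", sidecar,
           call. = FALSE)
    }
    total_mapped <- as.numeric(readLines(sidecar)[1])
  }
  fragment_track(frags, total_mapped, label)
}

#' @rdname read_fragment_track
#' @param track A `fragment_track` to write; the total mapped count goes to
#'   the `<path>.total` sidecar.
#' @export
write_fragment_track <- function(track, path) {
  f <- track$fragments
  writeLines(sprintf("%s\t%d\t%d\tf%d\t0\t%s", f$chrom, as.integer(f$start),
                     as.integer(f$end), seq_len(nrow(f)), f$strand),
             path)
  writeLines(format(track$total_mapped, scientific = FALSE),
             paste0(path, ".total"))
  invisible(track)
}

# Extends fragments 3'-ward from their 5' start to length
# max(native, extension); unstranded fragments extend rightward. Starts are
# clipped at 0.
extend_fragments <- function(fragments, extension) {
  if (extension <= 0 || nrow(fragments) == 0) return(fragments)
  len <- fragments$end - fragments$start
  ext <- pmax(len, extension)
  minus <- !is.na(fragments$strand) & fragments$strand == "-"
  start <- ifelse(minus, fragments$end - ext, fragments$start)
  end <- ifelse(minus, fragments$end, fragments$start + ext)
  fragments$start <- pmax(start, 0)
  fragments$end <- end
  fragments
}

#' Normalized read density (rpm/bp) over a region
#'
#' Fragments are extended to `extension` bases (reproducing the 200 bp read
#' extension used for enhancer signal), per-base coverage is summed over the
#' region, divided by the region length and normalized to reads per million
#' mapped reads, giving rpm/bp.
#'
#' @param track A `fragment_track`.
#' @param region A one-row data frame with `chrom`, `start`, `end`.
#' @param extension Read extension length in bases (default 200).
#' @return A single non-negative density in rpm/bp.
#' @export
region_density <- function(track, region, extension = 200) {
  stopifnot(inherits(track, "fragment_track"), nrow(region) == 1)
  check_intervals(region, "region")
  if (track$total_mapped <= 0) stop("total_mapped must be positive",
                                    call. = FALSE)
  region_densities(track, region, extension)
}

# Vectorized density over many regions; exact integer coverage sums before
# normalization.
region_densities <- function(track, regions, extension = 200) {
  f <- extend_fragments(track$fragments, extension)
  per_million <- track$total_mapped / 1e6
  vapply(seq_len(nrow(regions)), function(i) {
    sel <- f$chrom == regions$chrom[i]
    if (!any(sel)) return(0)
    ov <- pmin(f$end[sel], regions$end[i]) -
      pmax(f$start[sel], regions$start[i])
    covsum <- sum(ov[ov > 0])
    covsum / (regions$end[i] - regions$start[i]) / per_million
  }, numeric(1))
}

# Per-chromosome coverage Rle of the extended fragments.
coverage_by_chrom <- function(track, extension = 200) {
  f <- extend_fragments(track$fragments, extension)
  split(f, f$chrom) |>
    lapply(function(d) IRanges::coverage(IRanges::IRanges(d$start + 1L,
                                                          d$end)))
}

#' Summit-centered binned signal matrix
#'
#' For each peak, normalized read densities are collected over a window
#' centered on the peak summit, in fixed-width bins (defaults: 10,000 bases
#' in bins of 10, i.e. 1,000 columns). Bins running off a chromosome end are
#' zero-filled.
#'
#' @param peaks A peaks tibble (needs `chrom`, `summit`, `name`).
#' @param track A `fragment_track`.
#' @param window Total window span in bases; must be divisible by
#'   `bin_width`.
#' @param bin_width Bases per column.
#' @param extension Read extension (default 200).
#' @return A numeric matrix, one row per peak (rownames from `name`), one
#'   column per bin, holding rpm/bp densities. Attributes `window` and
#'   `bin_width` record the geometry.
#' @export
summit_matrix <- function(peaks, track, window = 10000, bin_width = 10,
                          extension = 200) {
  stopifnot(inherits(track, "fragment_track"))
  if (window %% bin_width != 0) {
    stop("window (", window, ") must be divisible by bin_width (", bin_width,
         ")", call. = FALSE)
  }
  n_bins <- window %/% bin_width
  half <- window %/% 2
  cov <- coverage_by_chrom(track, extension)
  per_million <- track$total_mapped / 1e6
  out <- matrix(0, nrow = nrow(peaks), ncol = n_bins)
  rownames(out) <- if ("name" %in% names(peaks)) peaks$name else
    sprintf("peak_%d", seq_len(nrow(peaks)))
  for (i in seq_len(nrow(peaks))) {
    rle <- cov[[peaks$chrom[i]]]
    lo <- peaks$summit[i] - half + 1L  # 1-based inclusive
    hi <- peaks$summit[i] + half
    v <- numeric(window)
    if (!is.null(rle)) {
      clo <- max(lo, 1L)
      chi <- min(hi, length(rle))
      if (chi >= clo) {
        v[(clo - lo + 1L):(chi - lo + 1L)] <-
          as.numeric(IRanges::Views(rle, clo, chi)[[1]])
      }
    }
    out[i, ] <- colSums(matrix(v, nrow = bin_width)) / bin_width / per_million
  }
  attr(out, "window") <- window
  attr(out, "bin_width") <- bin_width
  out
}
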