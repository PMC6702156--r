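# Shared synthetic bundle, generated once per test session and reused.
.bundle_cache <- new.env()

shared_bundle <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.bundle_cache[[key]])) {
    dir <- file.path(tempdir(), sprintf("crcmapr_bundle_%d", seed))
    if (!dir.exists(dir) || length(list.files(dir)) == 0) {
      gen <- generate_bundle(make_fixture("small", seed = seed), dir)
    }
    .bundle_cache[[key]] <- list(dir = dir, bundle = read_bundle(dir))
  }
  .bundle_cache[[key]]
}

tiny_track <- function(starts, ends, total_mapped, chrom = "chr1",
                       strand = "+") {
  fragment_track(tibble::tibble(chrom = chrom, start = starts, end = ends,
                                strand = strand),
                 total_mapped)
}

iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

peak_tbl <- function(chrom, start, end, signal = 1,
                     summit = NULL, name = NULL) {
  n <- length(start)
  tibble::tibble(chrom = chrom, start = start, end = end,
                 name = name %||% sprintf("p%d", seq_len(n)),
                 strand = ".", signal = signal,
                 summit = summit %||% ((start + end) %/% 2L),
                 source = "test")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
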