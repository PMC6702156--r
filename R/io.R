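#' Read a peak file (narrowPeak or BED6)
#'
#' narrowPeak is the 10-column ENCODE format; column 10 is the summit offset
#' from `start` (`-1` meaning unknown, mapped to the interval midpoint).
#' BED6 peaks get `summit` at the midpoint and `signal` from the score
#' column.
#'
#' @param path File path.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @param source Track/cell-line label stored in the `source` column
#'   (defaults to the file name).
#' @return A peaks tibble with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, `signal`, `summit` (absolute 0-based position), `source`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6"),
                       source = basename(path)) {
  format <- match.arg(format)
  ncol_needed <- if (format == "narrowPeak") 10L else 6L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), name = character(),
                          strand = character(), signal = numeric(),
                          summit = integer(), source = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < ncol_needed)) {
    stop(sprintf("cannot parse %s line %d: expected %d columns, found %d",
                 path, which(nf < ncol_needed)[1], ncol_needed,
                 nf[which(nf < ncol_needed)[1]]), call. = FALSE)
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(ncol_needed)))
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop(sprintf("cannot parse %s line %d: non-integer coordinates",
                 path, bad[1]), call. = FALSE)
  }
  x <- tibble::tibble(
    chrom = m[, 1], start = start, end = end, name = m[, 4],
    strand = m[, 6],
    signal = if (format == "narrowPeak") as.numeric(m[, 7]) else
      as.numeric(m[, 5]),
    source = source
  )
  if (format == "narrowPeak") {
    off <- suppressWarnings(as.integer(m[, 10]))
    x$summit <- ifelse(off < 0, (x$start + x$end) %/% 2L, x$start + off)
  } else {
    x$summit <- (x$start + x$end) %/% 2L
  }
  check_intervals(x, sprintf("peak (%s)", path))
  bad <- which(x$summit < x$start | x$summit >= x$end | x$signal < 0)
  if (length(bad) > 0) {
    stop(sprintf("invalid peak in %s line %d: summit outside interval or negative signal",
                 path, bad[1]), call. = FALSE)
  }
  x[, c("chrom", "start", "end", "name", "strand", "signal", "summit",
        "source")]
}

#' Write intervals or peaks as BED6 / narrowPeak
#'
#' `write_bed()` emits BED6 (missing `name`/`signal`/`strand` columns are
#' filled with defaults). `write_narrowpeak()` emits the 10-column format and
#' round-trips `read_peaks()` output exactly.
#'
#' @param x A data frame with at least `chrom`, `start`, `end`.
#' @param path Output file path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  name <- if ("name" %in% names(x)) x$name else
    sprintf("region_%d", seq_len(nrow(x)))
  score <- if ("signal" %in% names(x)) x$signal else 0
  strand <- if ("strand" %in% names(x)) x$strand else "."
  writeLines(sprintf("%s\t%d\t%d\t%s\t%s\t%s", x$chrom, as.integer(x$start),
                     as.integer(x$end), name, format_num(score), strand),
             path)
  invisible(x)
}

#' @rdname write_bed
#' @export
write_narrowpeak <- function(x, path) {
  check_intervals(x, "peak")
  stopifnot(all(c("name", "strand", "signal", "summit") %in% names(x)))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s\t-1\t-1\t%d",
                     x$chrom, as.integer(x$start), as.integer(x$end),
                     x$name, x$strand, format_num(x$signal),
                     as.integer(x$summit - x$start)),
             path)
  invisible(x)
}

# Fixed-notation number formatting so written files are locale- and
# precision-stable (needed for byte-identical reruns).
format_num <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  has_dec <- grepl(".", out, fixed = TRUE)
  out[has_dec] <- sub("\\.?0+$", "", out[has_dec])
  out
}

#' Read / write the TSS annotation table
#'
#' A headered TSV with columns `gene_id`, `gene_symbol`, `chrom`,
#' `tss_position` (0-based), `strand`, `is_tf`. One gene may have several
#' transcript records; gene-level rules take any TSS.
#'
#' @param path File path.
#' @return A tibble with columns `gene_id`, `gene_symbol`, `chrom`, `tss`,
#'   `strand`, `is_tf`.
#' @export
read_tss_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), gene_symbol = readr::col_character(),
    chrom = readr::col_character(), tss_position = readr::col_integer(),
    strand = readr::col_character(), is_tf = readr::col_logical()
  ))
  tibble::tibble(gene_id = x$gene_id, gene_symbol = x$gene_symbol,
                 chrom = x$chrom, tss = x$tss_position, strand = x$strand,
                 is_tf = x$is_tf)
}

#' @rdname read_tss_table
#' @param x A TSS tibble as returned by `read_tss_table()`.
#' @export
write_tss_table <- function(x, path) {
  out <- tibble::tibble(gene_id = x$gene_id, gene_symbol = x$gene_symbol,
                        chrom = x$chrom, tss_position = as.integer(x$tss),
                        strand = x$strand, is_tf = x$is_tf)
  readr::write_tsv(out, path)
  invisible(x)
}

#' Read / write a differential-expression results table
#'
#' A headered TSV with columns `gene_id`, `log2fc`, `padj` and an optional
#' `tag` column carrying a functional annotation label.
#'
#' @param path File path.
#' @return A tibble with `gene_id`, `log2fc`, `padj` and (if present) `tag`.
#' @export
read_de_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), log2fc = readr::col_double(),
    padj = readr::col_double(), .default = readr::col_character()
  ))
  x
}

#' @rdname read_de_table
#' @param x A DE tibble.
#' @export
write_de_table <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(x)
}

#' Read a genome FASTA
#'
#' @param path FASTA file path.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# Extracts the 0-based half-open span [start, end) of `chrom`; errors name
# the offending region so NFRs outside the assembly are caught early.
get_sequence <- function(genome, chrom, start, end, what = "region") {
  if (!chrom %in% names(genome)) {
    stop(sprintf("%s %s:%d-%d: chromosome not in genome", what, chrom,
                 start, end), call. = FALSE)
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len) {
    stop(sprintf("%s %s:%d-%d outside chromosome bounds (length %d)",
                 what, chrom, start, end, len), call. = FALSE)
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}
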