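DNA_BASES <- c("A", "C", "G", "T")

#' Construct a transcription-factor motif model
#'
#' Wraps a 4 x L position count matrix (rows A, C, G, T) together with the
#' background base frequencies and the log-odds position weight matrix
#' derived from them.
#'
#' @param tf_name Transcription factor name (matched case-insensitively to
#'   annotation gene symbols).
#' @param counts Numeric 4 x L matrix of non-negative base counts; every
#'   column must have a positive sum.
#' @param background Length-4 vector of base frequencies (A, C, G, T)
#'   summing to 1, all entries positive.
#' @param pseudocount Pseudocount added (scaled by background) before taking
#'   log-odds; default 0.1.
#' @return An object of class `motif_model` with elements `tf_name`,
#'   `counts`, `background`, `pseudocount` and `pwm` (log2-odds).
#' @export
motif_model <- function(tf_name, counts, background = rep(0.25, 4),
                        pseudocount = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-6, pseudocount > 0)
  rownames(counts) <- DNA_BASES
  structure(list(tf_name = tf_name, counts = counts,
                 background = setNames(as.numeric(background), DNA_BASES),
                 pseudocount = pseudocount,
                 pwm = pfm_to_pwm(counts, background, pseudocount)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model '%s': length %d, max score %.2f bits>\n",
              x$tf_name, ncol(x$pwm), sum(apply(x$pwm, 2, max))))
  invisible(x)
}

#' Convert a position count matrix to a log-odds position weight matrix
#'
#' `pwm[b, i] = log2(((counts[b, i] + pseudocount * background[b]) /
#' (colsum_i + pseudocount)) / background[b])`.
#'
#' @inheritParams motif_model
#' @return A 4 x L numeric matrix of log2-odds scores.
#' @export
pfm_to_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(pseudocount > 0, all(background > 0))
  csum <- colSums(counts)
  if (any(csum <= 0)) {
    stop("motif count matrix has a zero column sum (column ",
         which(csum <= 0)[1], ")", call. = FALSE)
  }
  freq <- sweep(counts + pseudocount * background,
                2, csum + pseudocount, "/")
  log2(freq / background)
}

#' Exact null distribution of PWM scores
#'
#' Computes the distribution of the total log-odds score of a random
#' background-distributed sequence by column-wise convolution over a rounded
#' score grid (granularity in bits), and returns the exact upper-tail
#' p-value function `P(Score >= s)`. For motif lengths up to ~8 this is
#' verifiable against full enumeration of all 4^L sequences.
#'
#' @param motif A `motif_model`.
#' @param granularity Score grid resolution in bits (default 1e-3). Rounding
#'   introduces at most `L * granularity / 2` bits of score slack.
#' @return An object of class `score_distribution` with elements `grid`
#'   (integer 4 x L matrix of rounded column scores), `support` (integer
#'   grid scores), `prob`, `tail`, `granularity` and `background`.
#' @export
exact_score_pvalue <- function(motif, granularity = 1e-3) {
  stopifnot(inherits(motif, "motif_model"), granularity > 0)
  grid <- round(motif$pwm / granularity)
  storage.mode(grid) <- "integer"
  bg <- motif$background
  L <- ncol(grid)
  # probability vector over grid scores; `offset` = score of index 1
  prob <- 1
  offset <- 0L
  for (j in seq_len(L)) {
    col <- grid[, j]
    newmin <- offset + min(col)
    newmax <- offset + length(prob) - 1L + max(col)
    newp <- numeric(newmax - newmin + 1L)
    for (b in 1:4) {
      at <- (offset + col[b] - newmin + 1L):(offset + col[b] - newmin +
                                               length(prob))
      newp[at] <- newp[at] + bg[b] * prob
    }
    prob <- newp
    offset <- newmin
  }
  support <- offset + seq_along(prob) - 1L
  tail_p <- rev(cumsum(rev(prob)))
  tail_p <- pmin(pmax(tail_p, 0), 1)
  structure(list(grid = grid, support = support, prob = prob,
                 tail = tail_p, granularity = granularity,
                 background = bg),
            class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("<score_distribution: %d grid points, p(max) = %.3g>\n",
              length(x$support), x$tail[length(x$tail)]))
  invisible(x)
}

# p-value of integer grid scores: P(Score >= s), clamped to p = 1 below the
# support minimum and to the smallest positive tail above the maximum.
pvalue_grid <- function(dist, grid_score) {
  n <- length(dist$tail)
  idx <- pmin(pmax(grid_score - dist$support[1] + 1L, 1L), n)
  as.numeric(dist$tail[idx])
}

#' @rdname exact_score_pvalue
#' @param dist A `score_distribution`.
#' @param score Real-valued log2-odds score(s); rounded to the grid before
#'   lookup.
#' @return `score_pvalue()`: exact tail probabilities in (0, 1].
#' @export
score_pvalue <- function(dist, score) {
  stopifnot(inherits(dist, "score_distribution"))
  pvalue_grid(dist, as.integer(round(score / dist$granularity)))
}

# Reverse-complement of a PWM-like 4 x L matrix (rows A,C,G,T): complement
# rows (reverse row order) and reverse column order.
revcomp_matrix <- function(m) {
  m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
}

#' Reverse-complement a DNA string
#' @param seq A DNA character string.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

encode_dna <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], DNA_BASES)
}

# Sum windowed column scores of `mat` (4 x L) over a coded sequence.
# Windows containing N (NA codes) score NA.
window_scores <- function(code, mat) {
  mat <- unname(mat)
  L <- ncol(mat)
  n_win <- length(code) - L + 1L
  if (n_win < 1) return(numeric(0))
  total <- numeric(n_win)
  idx <- seq_len(n_win)
  for (j in seq_len(L)) {
    total <- total + mat[, j][code[idx + j - 1L]]
  }
  total
}

#' Scan a sequence with a motif on both strands
#'
#' Scores every window of the sequence with the motif's log-odds matrix on
#' the forward strand and (via the reverse-complemented matrix) on the
#' reverse strand; positions are reported on the forward coordinate system.
#' Windows containing N are skipped. A hit is emitted where the exact tail
#' p-value of the score is at most `p_threshold`.
#'
#' @param seq DNA string over A, C, G, T, N.
#' @param motif A `motif_model`.
#' @param p_threshold Upper bound on the exact p-value (default 1 returns
#'   every scoreable window, which is what FDR control over all scanned
#'   windows requires).
#' @param dist Optional precomputed `exact_score_pvalue(motif)`.
#' @param granularity Grid resolution passed on when `dist` is not supplied.
#' @return A tibble with `start`, `end` (0-based half-open, relative to
#'   `seq`), `strand`, `score` (log2-odds, bits) and `p`.
#' @export
scan_sequence <- function(seq, motif, p_threshold = 1, dist = NULL,
                          granularity = 1e-3) {
  stopifnot(inherits(motif, "motif_model"))
  if (is.null(dist)) dist <- exact_score_pvalue(motif, granularity)
  L <- ncol(motif$pwm)
  code <- encode_dna(seq)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          strand = character(), score = numeric(),
                          p = numeric())
  if (length(code) < L) return(empty)
  out <- list()
  mats <- list(`+` = list(grid = dist$grid, pwm = motif$pwm),
               `-` = list(grid = revcomp_matrix(dist$grid),
                          pwm = revcomp_matrix(motif$pwm)))
  for (strand in names(mats)) {
    gs <- window_scores(code, mats[[strand]]$grid)
    keep <- which(!is.na(gs))
    if (length(keep) == 0) next
    p <- pvalue_grid(dist, gs[keep])
    pass <- p <= p_threshold
    if (!any(pass)) next
    real <- window_scores(code, mats[[strand]]$pwm)
    out[[strand]] <- tibble::tibble(
      start = keep[pass] - 1L, end = keep[pass] - 1L + L,
      strand = strand, score = real[keep][pass], p = p[pass]
    )
  }
  if (length(out) == 0) return(empty)
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$strand)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjusted p-values, order preserved on return.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Read and write JASPAR-format position frequency matrices
#'
#' The text format is `>ID NAME` followed by four rows `A [ ... ]`,
#' `C [ ... ]`, `G [ ... ]`, `T [ ... ]` (brackets optional).
#'
#' @param path File path.
#' @param background,pseudocount Passed to [motif_model()].
#' @return A named list of `motif_model`s (names are TF names).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no JASPAR records in ", path, call. = FALSE)
  motifs <- lapply(starts, function(s) {
    header <- sub("^>", "", lines[s])
    parts <- strsplit(header, "\\s+")[[1]]
    name <- if (length(parts) >= 2) parts[2] else parts[1]
    rows <- lapply(lines[(s + 1):(s + 4)], function(r) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?\\s*|\\s*\\]\\s*$", "", r)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop("ragged JASPAR record '", name, "' in ", path, call. = FALSE)
    }
    motif_model(name, do.call(rbind, rows), background, pseudocount)
  })
  names(motifs) <- vapply(motifs, `[[`, "", "tf_name")
  motifs
}

#' @rdname read_jaspar
#' @param motifs A list of `motif_model`s.
#' @export
write_jaspar <- function(motifs, path) {
  out <- unlist(lapply(seq_along(motifs), function(i) {
    m <- motifs[[i]]
    c(sprintf(">M%04d %s", i, m$tf_name),
      vapply(1:4, function(b) {
        sprintf("%s  [ %s ]", DNA_BASES[b],
                paste(format_num(m$counts[b, ]), collapse = " "))
      }, ""))
  }))
  writeLines(out, path)
  invisible(motifs)
}

#' Scan nucleosome-free regions with a motif database
#'
#' Extracts each NFR's sequence, estimates the background base composition
#' from the pooled NFR sequences (overridable), scans every NFR with every
#' motif on both strands, and applies Benjamini-Hochberg control over all
#' scanned windows (per TF by default, matching scanner convention; or one
#' global family). Only hits with q-value at most `q_threshold` are
#' returned.
#'
#' @param nfrs A tibble of NFRs with `nfr_id`, `chrom`, `start`, `end` (and
#'   optionally `se_id`, carried through).
#' @param genome A [Biostrings::DNAStringSet].
#' @param motifs A named list of `motif_model`s.
#' @param q_threshold FDR threshold (default 1e-5).
#' @param fdr_scope `"per-tf"` (one family per motif) or `"global"`.
#' @param background Optional length-4 base frequency override.
#' @param granularity Score grid resolution in bits.
#' @return A tibble with `tf`, `nfr_id`, `chrom`, `start`, `end` (absolute
#'   genomic coordinates), `strand`, `score`, `p`, `q` and any carried NFR
#'   columns.
#' @export
scan_nfrs <- function(nfrs, genome, motifs, q_threshold = 1e-5,
                      fdr_scope = c("per-tf", "global"), background = NULL,
                      granularity = 1e-3) {
  fdr_scope <- match.arg(fdr_scope)
  empty <- tibble::tibble(tf = character(), nfr_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          score = numeric(), p = numeric(), q = numeric())
  if (nrow(nfrs) == 0 || length(motifs) == 0) return(empty)
  seqs <- vapply(seq_len(nrow(nfrs)), function(i) {
    get_sequence(genome, nfrs$chrom[i], nfrs$start[i], nfrs$end[i], "NFR")
  }, character(1))
  if (is.null(background)) {
    counts <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(seqs), DNA_BASES))
    background <- (counts + 1) / (sum(counts) + 4)
  }
  all_hits <- lapply(names(motifs), function(tf) {
    m <- motifs[[tf]]
    m_bg <- motif_model(m$tf_name, m$counts, background, m$pseudocount)
    dist <- exact_score_pvalue(m_bg, granularity)
    per_nfr <- lapply(seq_len(nrow(nfrs)), function(i) {
      h <- scan_sequence(seqs[i], m_bg, p_threshold = 1, dist = dist)
      if (nrow(h) == 0) return(NULL)
      h$nfr_id <- nfrs$nfr_id[i]
      h$chrom <- nfrs$chrom[i]
      h$start <- h$start + nfrs$start[i]
      h$end <- h$end + nfrs$start[i]
      h
    })
    h <- dplyr::bind_rows(per_nfr)
    if (nrow(h) == 0) return(NULL)
    h$tf <- tf
    h
  })
  hits <- dplyr::bind_rows(all_hits)
  if (nrow(hits) == 0) return(empty)
  if (fdr_scope == "per-tf") {
    hits <- hits |>
      dplyr::group_by(.data$tf) |>
      dplyr::mutate(q = bh_qvalues(.data$p)) |>
      dplyr::ungroup()
  } else {
    hits$q <- bh_qvalues(hits$p)
  }
  hits <- hits[hits$q <= q_threshold, ]
  extra <- setdiff(names(nfrs), c("nfr_id", "chrom", "start", "end"))
  if (length(extra) > 0) {
    hits <- dplyr::left_join(hits, nfrs[, c("nfr_id", extra)], by = "nfr_id")
  }
  dplyr::arrange(
    hits[, c("tf", "nfr_id", "chrom", "start", "end", "strand", "score",
             "p", "q", extra)],
    .data$tf, .data$chrom, .data$start)
}
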