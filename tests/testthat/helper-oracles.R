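# Brute-force reference implementations, independent of the package's
# vectorized code paths.

# per-base union with gap bridging
oracle_merge <- function(x, gap) {
  out <- list()
  for (ch in sort(unique(x$chrom))) {
    d <- x[x$chrom == ch, ]
    covered <- rep(FALSE, max(d$end))
    for (i in seq_len(nrow(d))) covered[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    segs <- data.frame(s = starts[r$values], e = ends[r$values])
    cs <- segs$s[1]
    ce <- segs$e[1]
    for (i in seq_len(nrow(segs))[-1]) {
      if (segs$s[i] - ce - 1 <= gap) {
        ce <- segs$e[i]
      } else {
        out[[length(out) + 1]] <- tibble::tibble(chrom = ch, start = cs - 1,
                                                 end = ce)
        cs <- segs$s[i]
        ce <- segs$e[i]
      }
    }
    out[[length(out) + 1]] <- tibble::tibble(chrom = ch, start = cs - 1,
                                             end = ce)
  }
  dplyr::bind_rows(out)
}

# exhaustive O(n) scan with the documented tie-breaks
oracle_nearest <- function(query, targets) {
  best_d <- Inf
  best_i <- NA_integer_
  for (i in seq_len(nrow(targets))) {
    if (targets$chrom[i] != query$chrom) next
    d <- max(targets$start[i] - query$end, query$start - targets$end[i], 0)
    if (is.na(best_i) || d < best_d ||
        (d == best_d && targets$start[i] < targets$start[best_i])) {
      best_d <- d
      best_i <- i
    }
  }
  list(distance = best_d, target = best_i)
}

# per-base coverage accumulation
oracle_density <- function(track, region, extension = 200) {
  f <- track$fragments
  len <- f$end - f$start
  ext <- pmax(len, extension)
  st <- ifelse(!is.na(f$strand) & f$strand == "-", f$end - ext, f$start)
  en <- ifelse(!is.na(f$strand) & f$strand == "-", f$end, f$start + ext)
  st <- pmax(st, 0)
  bases <- seq(region$start, region$end - 1)
  cov <- rep(0, length(bases))
  for (i in seq_along(st)) {
    if (f$chrom[i] != region$chrom) next
    cov <- cov + as.numeric(st[i] <= bases & bases < en[i])
  }
  sum(cov) / length(bases) / (track$total_mapped / 1e6)
}

# naive per-offset, per-column PWM scoring of the forward strand
oracle_scan_scores <- function(seq, mat) {
  bases <- strsplit(seq, "")[[1]]
  L <- ncol(mat)
  n <- length(bases) - L + 1
  if (n < 1) return(numeric(0))
  vapply(seq_len(n), function(i) {
    s <- 0
    for (j in seq_len(L)) {
      b <- match(bases[i + j - 1], c("A", "C", "G", "T"))
      if (is.na(b)) return(NA_real_)
      s <- s + mat[b, j]
    }
    s
  }, numeric(1))
}

# full 4^L enumeration of the rounded-score null distribution
oracle_enum_distribution <- function(motif, granularity = 1e-3) {
  grid <- round(motif$pwm / granularity)
  L <- ncol(grid)
  bg <- motif$background
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- integer(nrow(seqs))
  pr <- rep(1, nrow(seqs))
  for (j in seq_len(L)) {
    sc <- sc + grid[cbind(seqs[, j], j)]
    pr <- pr * bg[seqs[, j]]
  }
  list(score = sc, prob = pr)
}

oracle_enum_tail <- function(enum, s) sum(enum$prob[enum$score >= s])

# exhaustive scan over candidate cutoff ranks; returns flags aligned to the
# signals sorted ascending
oracle_cutoff_flags <- function(sorted_signals) {
  n <- length(sorted_signals)
  y <- (sorted_signals - min(sorted_signals)) /
    (max(sorted_signals) - min(sorted_signals))
  istar <- NA
  for (i in seq_len(n - 1)) {
    if ((y[i + 1] - y[i]) * (n - 1) > 1) {
      istar <- i
      break
    }
  }
  if (is.na(istar)) return(rep(FALSE, n))
  c(rep(FALSE, istar - 1), rep(TRUE, n - istar + 1))
}

# degree arithmetic from an adjacency matrix (adj[i, j]: edge i -> j)
oracle_degrees <- function(adj) {
  data.frame(in_degree = colSums(adj), out_degree = rowSums(adj),
             total_degree = colSums(adj) + rowSums(adj))
}

adj_to_edges <- function(adj, names) {
  idx <- which(adj, arr.ind = TRUE)
  tibble::tibble(source = names[idx[, 1]], target = names[idx[, 2]])
}

# plain Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  (comb2(n) + 2 * sum(comb2(tab)) - sum(comb2(rowSums(tab))) -
      sum(comb2(colSums(tab)))) / comb2(n)
}

random_intervals <- function(n, max_coord = 5000, chroms = c("chr1", "chr2"),
                             max_len = 400) {
  start <- sample.int(max_coord, n, replace = TRUE) - 1L
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start,
                 end = start + sample.int(max_len, n, replace = TRUE))
}

random_motif <- function(L, bg = rep(0.25, 4)) {
  motif_model("RND", matrix(rpois(4 * L, 4) + 1, 4, L), bg)
}

random_dna <- function(len, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else
    c("A", "C", "G", "T")
  paste(sample(alphabet, len, replace = TRUE,
               prob = if (with_n) c(rep(0.24, 4), 0.04) else rep(0.25, 4)),
        collapse = "")
}
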