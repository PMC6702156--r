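#' Synthetic study configuration
#'
#' Parameters of the seeded generator that emulates the structure of the
#' real inputs: a genome, a TSS annotation, per-cell-line peak calls and
#' fragment tracks for H3K27ac/H3K4me1/H3K4me3/ATAC/TF ChIP, JASPAR motif
#' matrices, a differential-expression table, and a planted TF regulatory
#' network whose motifs are written into nucleosome-free regions of planted
#' super-enhancers. Enhancer signal follows a hockey-stick law (many weak
#' stitched regions, a high-signal upper tail) and TF binding sites fall
#' into three chromatin-state archetypes (enhancer-like, promoter-like,
#' low-signal).
#'
#' @param seed Integer seed; a fixed seed yields byte-identical output
#'   directories.
#' @param chrom_length Chromosome length in bases (one chromosome).
#' @param n_genes,n_tfs,n_promoter_genes Gene counts; TFs carry motifs and
#'   planted super-enhancers, promoter-category genes sit inside the TF
#'   binding-site block.
#' @param n_state_sites Number of TF binding sites drawn from the three
#'   chromatin-state archetypes.
#' @param n_body Number of low-signal stitched enhancer regions forming the
#'   hockey-stick body.
#' @param n_cell_lines Number of cell lines (default 4).
#' @param motif_length Motif width in bases; with near-deterministic
#'   columns this gives information content well above 12 bits.
#' @param gc Genome GC content.
#' @param lambda_se,lambda_body,lambda_promoter Poisson means of H3K27ac
#'   fragment counts per SE constituent peak, body peak and promoter peak,
#'   per cell line; region signal scales linearly with these.
#' @param frag_len Written read length (extended to 200 bp by the
#'   pipeline).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, chrom_length = 2e6, n_genes = 40,
                         n_tfs = 8, n_promoter_genes = 8,
                         n_state_sites = 150, n_body = NULL,
                         n_cell_lines = 4, motif_length = 18, gc = 0.5,
                         lambda_se = 150, lambda_body = 25,
                         lambda_promoter = 30, frag_len = 50) {
  cfg <- list(seed = as.integer(seed), chrom = "chr1",
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_promoter_genes = as.integer(n_promoter_genes),
              n_state_sites = as.integer(n_state_sites),
              n_body = if (is.null(n_body)) NULL else as.integer(n_body),
              n_cell_lines = as.integer(n_cell_lines),
              motif_length = as.integer(motif_length),
              gc = gc, lambda_se = lambda_se, lambda_body = lambda_body,
              lambda_promoter = lambda_promoter, frag_len = frag_len,
              tf_start = 100000L, tf_spacing = 150000L,
              site_spacing = 800L, site_width = 400L,
              se_constituents = list(c(8000L, 9500L), c(10600L, 12100L),
                                     c(13200L, 14700L)),
              nfr_width = 400L, nfr_first = 8600L, nfr_step = 650L,
              plant_slots = 5L, plant_first = 30L, plant_step = 70L)
  class(cfg) <- "synth_config"
  cfg
}

#' Preset synthetic fixtures
#'
#' `"small"` (1 chromosome x 2 Mb, 40 genes, 8 TFs) runs the full pipeline
#' in seconds; `"medium"` (10 Mb, 300 genes, 25 candidate TFs, the scale of
#' a real circuitry run) in minutes.
#'
#' @param name `"small"` or `"medium"`.
#' @param seed Integer seed.
#' @return A `synth_config`.
#' @export
make_fixture <- function(name = c("small", "medium"), seed = 1L) {
  name <- match.arg(name)
  if (name == "small") {
    synth_config(seed = seed, chrom_length = 2e6, n_genes = 40, n_tfs = 8,
                 n_promoter_genes = 8, n_state_sites = 150)
  } else {
    synth_config(seed = seed, chrom_length = 1e7, n_genes = 300,
                 n_tfs = 25, n_promoter_genes = 20, n_state_sites = 150,
                 n_body = 60)
  }
}

# Deterministic sub-seed per (seed, label) so adding a track never perturbs
# the random stream of another file.
stream_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1000003
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483629)
}

# Planted TF network: a master regulator that regulates every TF (itself
# included), every TF regulating the master back, plus a chain among the
# remaining TFs. The master's total degree strictly dominates.
planted_network <- function(tf_symbols) {
  master <- tf_symbols[1]
  edges <- dplyr::bind_rows(
    tibble::tibble(source = master, target = tf_symbols),
    tibble::tibble(source = setdiff(tf_symbols, master), target = master),
    if (length(tf_symbols) > 2) {
      tibble::tibble(source = tf_symbols[2:(length(tf_symbols) - 1)],
                     target = tf_symbols[3:length(tf_symbols)])
    }
  )
  dplyr::distinct(dplyr::arrange(edges, .data$source, .data$target))
}

# Deterministic layout of genes, super-enhancers, NFRs, motif plants, body
# enhancers and chromatin-state sites; errors before any file is written if
# the requested counts cannot fit on the chromosome.
synth_geometry <- function(cfg) {
  n_nt <- cfg$n_genes - cfg$n_tfs - cfg$n_promoter_genes
  if (n_nt < 6) stop("too few non-TF genes for the layout", call. = FALSE)
  site_block <- cfg$n_state_sites * cfg$site_spacing
  site_start <- cfg$chrom_length - site_block
  tf_tss <- cfg$tf_start + (seq_len(cfg$n_tfs) - 1L) * cfg$tf_spacing
  nt_start <- tf_tss[cfg$n_tfs] + 100000L
  nt_space <- site_start - 50000L - nt_start
  nt_spacing <- as.integer(nt_space %/% n_nt)
  if (nt_spacing < 19000 || site_start < nt_start + 100000) {
    stop("impossible geometry: chromosome too short for the requested ",
         "gene and site counts", call. = FALSE)
  }
  nt_tss <- nt_start + (seq_len(n_nt) - 1L) * nt_spacing
  n_prom <- cfg$n_promoter_genes
  step_sites <- max(1L, as.integer(cfg$n_state_sites %/% (n_prom + 1)))
  prom_tss <- site_start + (seq_len(n_prom) * step_sites - 1L) *
    cfg$site_spacing + 2000L
  if (any(prom_tss >= cfg$chrom_length - 2000)) {
    stop("impossible geometry: promoter-category genes overflow the ",
         "chromosome", call. = FALSE)
  }

  tf_symbols <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  genes <- dplyr::bind_rows(
    tibble::tibble(symbol = tf_symbols, tss = tf_tss, role = "tf",
                   j = seq_len(cfg$n_tfs)),
    tibble::tibble(symbol = sprintf("GENE%03d", seq_len(n_nt)),
                   tss = nt_tss, role = "nt", j = seq_len(n_nt)),
    tibble::tibble(symbol = sprintf("PGENE%02d", seq_len(n_prom)),
                   tss = prom_tss, role = "prom", j = seq_len(n_prom))
  )
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes$chrom <- cfg$chrom
  genes$is_tf <- genes$role == "tf"
  genes$strand <- rep(c("+", "-"), length.out = nrow(genes))
  # every TF and both SE-bearing non-TF genes are active; other non-TF
  # genes are active unless j is a multiple of 5; promoter-block genes are
  # inactive (no promoter H3K27ac)
  se_nt_j <- c(n_nt - 1L, n_nt)
  genes$active <- genes$role == "tf" |
    (genes$role == "nt" & (genes$j %% 5 != 0 | genes$j %in% se_nt_j))
  # promoter peak present in all lines, except the first non-TF gene which
  # is supported by a single line (any-line sufficiency)
  genes$promoter_lines <- ifelse(!genes$active, 0L,
                                 ifelse(genes$role == "nt" & genes$j == 1L,
                                        1L, cfg$n_cell_lines))

  network <- planted_network(tf_symbols)
  se_genes <- c(tf_symbols, sprintf("GENE%03d", se_nt_j))
  in_deg <- vapply(se_genes, function(g) sum(network$target == g),
                   integer(1))
  ses <- lapply(seq_along(se_genes), function(i) {
    g <- genes[genes$symbol == se_genes[i], ]
    base <- g$tss
    n_plants <- in_deg[i]
    n_nfrs <- max(2L, ceiling(n_plants / cfg$plant_slots))
    if (cfg$nfr_first + (n_nfrs - 1L) * cfg$nfr_step + cfg$nfr_width >
        cfg$se_constituents[[3]][2]) {
      stop("impossible geometry: NFRs overflow the super-enhancer span",
           call. = FALSE)
    }
    consts <- lapply(cfg$se_constituents, function(cc) base + cc)
    nfrs <- tibble::tibble(
      start = base + cfg$nfr_first + (seq_len(n_nfrs) - 1L) * cfg$nfr_step,
      end = base + cfg$nfr_first + (seq_len(n_nfrs) - 1L) * cfg$nfr_step +
        cfg$nfr_width)
    list(symbol = se_genes[i], gene_id = g$gene_id,
         start = base + cfg$se_constituents[[1]][1],
         end = base + cfg$se_constituents[[3]][2],
         constituents = consts, nfrs = nfrs)
  })
  names(ses) <- se_genes

  # motif plants: the s-th regulator of B (alphabetical) gets slot s
  plants <- dplyr::bind_rows(lapply(tf_symbols, function(b) {
    sources <- sort(network$source[network$target == b])
    if (length(sources) == 0) return(NULL)
    s <- seq_along(sources)
    nfr_idx <- (s - 1L) %/% cfg$plant_slots + 1L
    slot <- (s - 1L) %% cfg$plant_slots
    tibble::tibble(
      source = sources, target = b,
      pos = ses[[b]]$nfrs$start[nfr_idx] + cfg$plant_first +
        slot * cfg$plant_step,
      strand = ifelse(s %% 3 == 0, "-", "+"))
  }))

  n_body <- cfg$n_body %||% min(n_nt - 2L, 30L)
  n_body <- min(n_body, n_nt - 2L)
  body_owner <- genes[genes$role == "nt" & genes$j <= n_body, ]
  body <- tibble::tibble(gene_id = body_owner$gene_id,
                         start = body_owner$tss + 9000L,
                         end = body_owner$tss + 10500L)

  sites <- tibble::tibble(
    site_id = sprintf("site_%03d", seq_len(cfg$n_state_sites)),
    start = site_start + (seq_len(cfg$n_state_sites) - 1L) *
      cfg$site_spacing,
    state = (seq_len(cfg$n_state_sites) - 1L) %% 3L + 1L)
  sites$end <- sites$start + cfg$site_width
  sites$center <- sites$start + cfg$site_width %/% 2L
  sites$support <- ifelse(seq_len(cfg$n_state_sites) %% 7 == 3, 3L,
                          cfg$n_cell_lines)
  decoys <- tibble::tibble(start = site_start - c(4000L, 8000L))
  decoys$end <- decoys$start + cfg$site_width
  decoys$center <- decoys$start + cfg$site_width %/% 2L

  list(genes = genes, network = network, ses = ses, plants = plants,
       body = body, sites = sites, decoys = decoys, site_start = site_start,
       tf_symbols = tf_symbols, master = tf_symbols[1], n_nt = n_nt,
       se_nt_j = se_nt_j)
}

# Random motif consensus k-mers with pairwise Hamming distance >= 6 so that
# no motif can fire on another's plant.
draw_consensus <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    ok <- all(vapply(out, function(o) {
      sum(strsplit(cand, "")[[1]] != strsplit(o, "")[[1]]) >= 6
    }, logical(1)))
    if (ok) out <- c(out, cand)
  }
  out
}

consensus_to_counts <- function(consensus, total = 1000) {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, nrow = 4, ncol = length(bases),
                   dimnames = list(DNA_BASES, NULL))
  for (i in seq_along(bases)) counts[bases[i], i] <- total - 3
  counts
}

# Poisson fragment draws centered in elements (uniform) or on points
# (normal). Returns a fragments tibble of `frag_len` reads whose 200 bp
# extension is centered on the drawn midpoint.
draw_fragments <- function(starts, ends, lambda, frag_len, spread = NULL) {
  n <- rpois(length(starts), lambda)
  if (sum(n) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  s <- rep(starts, n)
  e <- rep(ends, n)
  if (is.null(spread)) {
    mid <- s + floor(runif(length(s)) * (e - s))
  } else {
    mid <- round(rnorm(length(s), (s + e) / 2, spread))
  }
  strand <- sample(c("+", "-"), length(mid), replace = TRUE)
  start <- ifelse(strand == "+", mid - 100L, mid + 100L - frag_len)
  tibble::tibble(start = pmax(as.integer(start), 0L),
                 strand = strand) |>
    dplyr::mutate(end = .data$start + frag_len)
}

# Per-line peak jitter helper.
jitter_peaks <- function(start, end, amount) {
  j1 <- sample(seq(-amount, amount), length(start), replace = TRUE)
  j2 <- sample(seq(-amount, amount), length(start), replace = TRUE)
  tibble::tibble(start = as.integer(start + j1),
                 end = as.integer(end + j2))
}

make_peaks <- function(chrom, start, end, signal, prefix,
                       summit = NULL) {
  n <- length(start)
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    name = sprintf("%s_%04d", prefix, seq_len(n)), strand = ".",
    signal = round(signal, 3),
    summit = as.integer(if (is.null(summit)) (start + end) %/% 2 else
      summit))
}

#' Generate a complete synthetic input bundle
#'
#' Writes, under `outdir`: `genome.fa`, `tss.tsv`, `motifs.jaspar`,
#' per-line narrowPeak files and fragment BEDs (with `.total` sidecars) for
#' H3K27ac, H3K4me1, H3K4me3, ATAC and TF ChIP, `de_table.tsv`,
#' `ground_truth.json` and a `bundle.yaml` manifest. For every planted edge
#' A -> B, at least one instance of A's consensus motif is written into an
#' NFR of B's super-enhancer. Same seed, same bytes.
#'
#' @param cfg A `synth_config`.
#' @param outdir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with `dir`, the `truth` list and the geometry.
#' @export
generate_bundle <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synth_config"))
  geo <- synth_geometry(cfg)  # validates before any file is written
  if (dir.exists(outdir) && length(list.files(outdir)) > 0) {
    stop("output directory exists and is not empty: ", outdir,
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("peaks", "fragments")) {
    dir.create(file.path(outdir, d), showWarnings = FALSE)
  }
  lines_v <- sprintf("cl%d", seq_len(cfg$n_cell_lines))
  chrom <- cfg$chrom

  # --- motifs -------------------------------------------------------------
  consensus <- withr::with_seed(stream_seed(cfg$seed, "motifs"), {
    draw_consensus(cfg$n_tfs, cfg$motif_length)
  })
  names(consensus) <- geo$tf_symbols
  motifs <- lapply(geo$tf_symbols, function(tf) {
    motif_model(tf, consensus_to_counts(consensus[[tf]]))
  })
  names(motifs) <- geo$tf_symbols
  write_jaspar(motifs, file.path(outdir, "motifs.jaspar"))

  # --- genome with planted motif instances --------------------------------
  genome_str <- withr::with_seed(stream_seed(cfg$seed, "genome"), {
    probs <- c((1 - cfg$gc) / 2, cfg$gc / 2, cfg$gc / 2, (1 - cfg$gc) / 2)
    paste(sample(DNA_BASES, cfg$chrom_length, replace = TRUE, prob = probs),
          collapse = "")
  })
  for (i in seq_len(nrow(geo$plants))) {
    p <- geo$plants[i, ]
    inst <- consensus[[p$source]]
    if (p$strand == "-") inst <- revcomp(inst)
    substr(genome_str, p$pos + 1L, p$pos + cfg$motif_length) <- inst
  }
  genome <- Biostrings::DNAStringSet(setNames(genome_str, chrom))
  Biostrings::writeXStringSet(genome, file.path(outdir, "genome.fa"),
                              width = 80)

  # --- annotation ---------------------------------------------------------
  tss <- tibble::tibble(gene_id = geo$genes$gene_id,
                        gene_symbol = geo$genes$symbol,
                        chrom = chrom, tss = geo$genes$tss,
                        strand = geo$genes$strand,
                        is_tf = geo$genes$is_tf)
  write_tss_table(tss, file.path(outdir, "tss.tsv"))

  # --- per-line peak calls ------------------------------------------------
  se_consts <- dplyr::bind_rows(lapply(geo$ses, function(se) {
    dplyr::bind_rows(lapply(se$constituents,
                            function(cc) tibble::tibble(start = cc[1],
                                                        end = cc[2])))
  }))
  all_nfrs <- dplyr::bind_rows(lapply(geo$ses, function(se) se$nfrs))
  straddlers <- tibble::tibble(
    start = vapply(geo$ses, function(se) se$start - 150L, integer(1)),
    end = vapply(geo$ses, function(se) se$start + 150L, integer(1)))
  for (li in seq_along(lines_v)) {
    line <- lines_v[li]
    # H3K27ac: promoters of active genes (line-dependent), SE constituents,
    # hockey-stick body peaks
    withr::with_seed(stream_seed(cfg$seed, paste0("peaks_H3K27ac_", line)), {
      prom <- geo$genes[geo$genes$promoter_lines >= li, ]
      pk_prom <- make_peaks(chrom, prom$tss - 500L, prom$tss + 500L,
                            8 + runif(nrow(prom), 0, 2), "prom")
      jc <- jitter_peaks(se_consts$start, se_consts$end, 25L)
      pk_se <- make_peaks(chrom, jc$start, jc$end,
                          20 + runif(nrow(jc), 0, 5), "se")
      jb <- jitter_peaks(geo$body$start, geo$body$end, 25L)
      pk_body <- make_peaks(chrom, jb$start, jb$end,
                            5 + runif(nrow(jb), 0, 2), "body")
      k27 <- dplyr::bind_rows(pk_prom, pk_se, pk_body)
      f <- file.path(outdir, "peaks",
                     sprintf("H3K27ac_%s.narrowPeak", line))
      write_narrowpeak(dplyr::arrange(k27, .data$start), f)
    })
    # ATAC: NFRs, promoter-open chromatin, SE-boundary straddlers, open
    # chromatin at enhancer/promoter-like state sites
    withr::with_seed(stream_seed(cfg$seed, paste0("peaks_ATAC_", line)), {
      jn <- jitter_peaks(all_nfrs$start, all_nfrs$end, 8L)
      pk_nfr <- make_peaks(chrom, jn$start, jn$end,
                           10 + runif(nrow(jn), 0, 3), "nfr")
      active <- geo$genes[geo$genes$active, ]
      pk_patac <- make_peaks(chrom, active$tss - 300L, active$tss + 300L,
                             8 + runif(nrow(active), 0, 2), "patac")
      pk_str <- make_peaks(chrom, straddlers$start, straddlers$end,
                           6 + runif(nrow(straddlers), 0, 2), "strad")
      open_sites <- geo$sites[geo$sites$state %in% c(1L, 2L), ]
      pk_satac <- make_peaks(chrom, open_sites$center - 150L,
                             open_sites$center + 150L,
                             8 + runif(nrow(open_sites), 0, 2), "satac")
      atac <- dplyr::bind_rows(pk_nfr, pk_patac, pk_str, pk_satac)
      f <- file.path(outdir, "peaks", sprintf("ATAC_%s.narrowPeak", line))
      write_narrowpeak(dplyr::arrange(atac, .data$start), f)
    })
    # TF ChIP: state sites (per support pattern) plus two low-support
    # decoys present in only two lines
    withr::with_seed(stream_seed(cfg$seed, paste0("peaks_TF_", line)), {
      sites <- geo$sites[geo$sites$support >= li, ]
      js <- jitter_peaks(sites$start, sites$end, 20L)
      pk_site <- make_peaks(chrom, js$start, js$end,
                            10 + runif(nrow(js), 0, 5), "tf",
                            summit = sites$center +
                              sample(-20:20, nrow(sites), replace = TRUE))
      if (li <= 2) {
        pk_site <- dplyr::bind_rows(
          pk_site,
          make_peaks(chrom, geo$decoys$start, geo$decoys$end,
                     5 + runif(nrow(geo$decoys), 0, 2), "decoy"))
      }
      f <- file.path(outdir, "peaks", sprintf("TF_%s.narrowPeak", line))
      write_narrowpeak(dplyr::arrange(pk_site, .data$start), f)
    })
    # histone mark peaks at the matching state archetypes
    for (spec in list(list(mark = "H3K4me1", states = 1L),
                      list(mark = "H3K4me3", states = 2L))) {
      withr::with_seed(stream_seed(cfg$seed,
                                   paste0("peaks_", spec$mark, "_", line)), {
        sites <- geo$sites[geo$sites$state %in% spec$states, ]
        js <- jitter_peaks(sites$start - 100L, sites$end + 100L, 20L)
        pk <- make_peaks(chrom, js$start, js$end,
                         8 + runif(nrow(js), 0, 3), tolower(spec$mark))
        f <- file.path(outdir, "peaks",
                       sprintf("%s_%s.narrowPeak", spec$mark, line))
        write_narrowpeak(dplyr::arrange(pk, .data$start), f)
      })
    }
  }

  # --- fragment tracks ----------------------------------------------------
  state_lambda <- list(
    H3K27ac = c(60, 60, 3), H3K4me1 = c(60, 3, 3), H3K4me3 = c(3, 60, 3),
    ATAC = c(40, 40, 5), TF = c(50, 50, 25))
  for (li in seq_along(lines_v)) {
    line <- lines_v[li]
    for (mark in names(state_lambda)) {
      withr::with_seed(stream_seed(cfg$seed,
                                   paste0("frags_", mark, "_", line)), {
        parts <- list(
          draw_fragments(geo$sites$start, geo$sites$end,
                         state_lambda[[mark]][geo$sites$state],
                         cfg$frag_len, spread = 120))
        if (mark == "H3K27ac") {
          prom <- geo$genes[geo$genes$promoter_lines >= li, ]
          parts <- c(parts, list(
            draw_fragments(prom$tss - 500L, prom$tss + 500L,
                           cfg$lambda_promoter, cfg$frag_len),
            draw_fragments(se_consts$start, se_consts$end, cfg$lambda_se,
                           cfg$frag_len),
            draw_fragments(geo$body$start, geo$body$end, cfg$lambda_body,
                           cfg$frag_len)))
        }
        if (mark == "ATAC") {
          active <- geo$genes[geo$genes$active, ]
          parts <- c(parts, list(
            draw_fragments(all_nfrs$start, all_nfrs$end, 40, cfg$frag_len),
            draw_fragments(active$tss - 300L, active$tss + 300L, 30,
                           cfg$frag_len)))
        }
        if (mark == "TF") {
          parts <- c(parts, list(
            draw_fragments(geo$decoys$start, geo$decoys$end,
                           if (li <= 2) 20 else 2, cfg$frag_len)))
        }
        frags <- dplyr::bind_rows(parts)
        frags$chrom <- chrom
        frags <- dplyr::arrange(frags[, c("chrom", "start", "end",
                                          "strand")],
                                .data$start, .data$end, .data$strand)
        tr <- fragment_track(frags, max(nrow(frags), 1),
                             sprintf("%s_%s", mark, line))
        f <- file.path(outdir, "fragments", sprintf("%s_%s.bed", mark,
                                                    line))
        write_fragment_track(tr, f)
      })
    }
  }

  # --- differential expression -------------------------------------------
  gene_site_dist <- vapply(geo$genes$tss, function(t) {
    min(interval_gap(t, t + 1, geo$sites$start, geo$sites$end))
  }, numeric(1))
  category <- ifelse(gene_site_dist < 10000, "Promoter",
                     ifelse(gene_site_dist <= 400000, "Enhancer",
                            "Distal"))
  enh_idx <- which(geo$genes$role == "nt" & category == "Enhancer")
  enh_targets <- utils::tail(enh_idx, 10)
  dist_targets <- which(geo$genes$role == "nt")[1:6]
  prom_targets <- which(geo$genes$role == "prom")
  group <- rep("null", nrow(geo$genes))
  group[enh_targets] <- "enhancer_target"
  group[dist_targets] <- "distal_target"
  group[prom_targets] <- "promoter_target"
  de <- withr::with_seed(stream_seed(cfg$seed, "de_table"), {
    mu <- c(promoter_target = -1.0, enhancer_target = -2.0,
            distal_target = -1.5)
    lfc <- rnorm(nrow(geo$genes), 0, 0.15)
    planted <- group != "null"
    lfc[planted] <- rnorm(sum(planted), mu[group[planted]], 0.3)
    padj <- runif(nrow(geo$genes), 0.05, 1)
    padj[planted] <- 1e-15
    tibble::tibble(gene_id = geo$genes$gene_id,
                   log2fc = round(lfc, 4), padj = padj,
                   tag = dplyr::case_when(
                     group == "promoter_target" ~ "cell_cycle",
                     group %in% c("enhancer_target",
                                  "distal_target") ~ "metabolism",
                     TRUE ~ "none"))
  })
  write_de_table(de, file.path(outdir, "de_table.tsv"))

  # --- ground truth -------------------------------------------------------
  truth_degrees <- rank_tfs(total_degrees(geo$network, geo$tf_symbols))
  truth <- list(
    master = geo$master,
    tf_symbols = geo$tf_symbols,
    edges = geo$network,
    degrees = truth_degrees,
    superenhancers = tibble::tibble(
      gene_symbol = vapply(geo$ses, `[[`, "", "symbol"),
      chrom = chrom,
      start = vapply(geo$ses, `[[`, integer(1), "start"),
      end = vapply(geo$ses, `[[`, integer(1), "end")),
    nfrs = dplyr::bind_rows(lapply(geo$ses, function(se) {
      dplyr::mutate(se$nfrs, gene_symbol = se$symbol, chrom = chrom)
    })),
    plants = geo$plants,
    state_sites = geo$sites[, c("site_id", "start", "end", "center",
                                "state", "support")],
    de = tibble::tibble(gene_id = geo$genes$gene_id,
                        gene_symbol = geo$genes$symbol,
                        group = group, category = category,
                        distance = gene_site_dist,
                        log2fc = de$log2fc, padj = de$padj,
                        regulated = abs(de$log2fc) > 0.6 &
                          de$padj < 1e-10),
    active_gene_ids = sort(geo$genes$gene_id[geo$genes$active]),
    n_cell_lines = cfg$n_cell_lines,
    seed = cfg$seed)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- manifest -----------------------------------------------------------
  marks <- c("H3K27ac", "H3K4me1", "H3K4me3", "ATAC", "TF")
  by_line <- function(tpl) {
    lapply(setNames(marks, marks), function(mk) {
      out <- lapply(lines_v, function(line) sprintf(tpl, mk, line))
      names(out) <- lines_v
      out
    })
  }
  manifest <- list(
    chrom = chrom, chrom_length = cfg$chrom_length,
    lines = as.list(lines_v),
    genome = "genome.fa", tss = "tss.tsv", motifs = "motifs.jaspar",
    de_table = "de_table.tsv", ground_truth = "ground_truth.json",
    peaks = by_line("peaks/%s_%s.narrowPeak"),
    fragments = by_line("fragments/%s_%s.bed"))
  yaml::write_yaml(manifest, file.path(outdir, "bundle.yaml"))
  invisible(list(dir = outdir, truth = truth, geometry = geo,
                 manifest = manifest))
}

#' Load a synthetic (or equivalently structured) input bundle
#'
#' Reads the `bundle.yaml` manifest and loads every input into memory:
#' genome, TSS table, motifs, DE table, per-mark/per-line peaksets and
#' fragment tracks, and the ground truth when present.
#'
#' @param dir Bundle directory containing `bundle.yaml`.
#' @return A named list of loaded inputs.
#' @export
read_bundle <- function(dir) {
  mf <- yaml::read_yaml(file.path(dir, "bundle.yaml"))
  ab <- function(p) file.path(dir, p)
  peaks <- lapply(mf$peaks, function(x) {
    lapply(x, function(p) read_peaks(ab(p), "narrowPeak"))
  })
  fragments <- lapply(mf$fragments, function(x) {
    out <- lapply(names(x), function(line) {
      read_fragment_track(ab(x[[line]]), label = line)
    })
    names(out) <- names(x)
    out
  })
  truth <- NULL
  if (!is.null(mf$ground_truth) && file.exists(ab(mf$ground_truth))) {
    truth <- jsonlite::fromJSON(ab(mf$ground_truth))
    for (nm in c("edges", "degrees", "superenhancers", "nfrs", "plants",
                 "state_sites", "de")) {
      if (!is.null(truth[[nm]])) truth[[nm]] <- tibble::as_tibble(truth[[nm]])
    }
  }
  list(chrom = mf$chrom, chrom_length = mf$chrom_length,
       lines = unlist(mf$lines),
       genome = read_genome(ab(mf$genome)),
       tss = read_tss_table(ab(mf$tss)),
       motifs = read_jaspar(ab(mf$motifs)),
       de = read_de_table(ab(mf$de_table)),
       peaks = peaks, fragments = fragments, truth = truth)
}

#' Synthetic summit profiles from the three chromatin-state archetypes
#'
#' Draws summit-centered signal matrices for the three marks directly from
#' the archetype mean profiles (enhancer-like: H3K27ac + H3K4me1;
#' promoter-like: H3K27ac + H3K4me3; low signal) with additive noise, for
#' clustering tests that do not need files on disk.
#'
#' @param n Number of sites (balanced across the three states).
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_bins Number of bins per mark.
#' @return A list with `mats` (named list of matrices) and `states` (true
#'   archetype per row).
#' @export
synth_state_profiles <- function(n = 150, seed = 1L, noise_sd = 0.5,
                                 n_bins = 1000) {
  states <- rep(1:3, length.out = n)
  bump <- exp(-((seq_len(n_bins) - n_bins / 2) / (n_bins / 25))^2)
  amp <- list(H3K27ac = c(3, 3, 0.2), H3K4me1 = c(3, 0.2, 0.2),
              H3K4me3 = c(0.2, 3, 0.2))
  withr::with_seed(seed, {
    mats <- lapply(amp, function(a) {
      m <- outer(a[states], bump) +
        matrix(rnorm(n * n_bins, 0, noise_sd), n, n_bins)
      m <- pmax(m, 0)
      rownames(m) <- sprintf("site_%03d", seq_len(n))
      m
    })
    list(mats = mats, states = states)
  })
}
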