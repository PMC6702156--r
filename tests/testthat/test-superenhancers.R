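tss_one <- function(pos, gene = "g1", chrom = "chr1") {
  tibble::tibble(gene_id = gene, gene_symbol = toupper(gene), chrom = chrom,
                 tss = as.integer(pos), strand = "+", is_tf = FALSE)
}

test_that("active_genes applies the 1 kb any-line, any-TSS rule", {
  tss <- tss_one(10000)
  # peak edge 999 bp away in one line only -> active
  sets <- list(l1 = peak_tbl("chr1", 11000L, 11500L),
               l2 = peak_tbl("chr1", 900000L, 900500L))
  expect_equal(active_genes(tss, sets, window = 1000), "g1")
  # 1001 bp away from every peak -> inactive
  sets2 <- list(l1 = peak_tbl("chr1", 11002L, 11500L))
  expect_equal(active_genes(tss, sets2, window = 1000), character(0))
  # gene with two TSS records, one qualifying -> active
  tss2 <- dplyr::bind_rows(tss_one(10000), tss_one(500000))
  expect_equal(active_genes(tss2, sets, window = 1000), "g1")
})

test_that("stitch_enhancers removes TSS-proximal peaks and stitches at 1638", {
  tss <- tss_one(10500)
  # one peak overlapping the TSS -> removed, zero regions
  expect_equal(nrow(stitch_enhancers(list(peak_tbl("chr1", 10000L, 11000L)),
                                     tss)), 0)
  far_tss <- tss_one(900000)
  two <- list(peak_tbl("chr1", c(10000L, 12000L), c(11000L, 12500L)))
  got <- stitch_enhancers(two, far_tss)
  expect_equal(c(got$start, got$end), c(10000L, 12500L))
  # gap 2000 > 1638 -> two regions
  two2 <- list(peak_tbl("chr1", c(10000L, 13000L), c(11000L, 13500L)))
  expect_equal(nrow(stitch_enhancers(two2, far_tss)), 2)
})

test_that("raising stitch distance never increases region count", {
  set.seed(31)
  tss <- tss_one(1)
  for (case in 1:20) {
    peaks <- list(random_intervals(20, max_coord = 30000,
                                   chroms = "chr1") |>
                    dplyr::mutate(name = "p", strand = ".", signal = 1,
                                  summit = (start + end) %/% 2L,
                                  source = "x"))
    prev <- Inf
    for (st in c(0, 500, 2000, 10000)) {
      r <- stitch_enhancers(peaks, tss, stitch = st)
      expect_lte(nrow(r), prev)
      prev <- nrow(r)
    }
  }
})

test_that("score_and_rank equals length x density and breaks ties as documented", {
  regions <- tibble::tibble(region_id = c("r1", "r2", "r3"),
                            chrom = "chr1",
                            start = c(0L, 5000L, 20000L),
                            end = c(2000L, 6000L, 22000L))
  set.seed(2)
  s <- sample(0:21000, 400)
  tr <- tiny_track(as.integer(s), as.integer(s) + 50L, total_mapped = 1e6)
  scored <- score_and_rank(regions, tr)
  for (i in seq_len(nrow(scored))) {
    d <- region_density(tr, scored[i, c("chrom", "start", "end")])
    expect_equal(scored$density[i], d)
    expect_equal(scored$signal[i],
                 d * (scored$end[i] - scored$start[i]))
  }
  expect_equal(scored$rank, seq_len(3))
  # control exceeding treatment floors the signal at zero
  ctrl <- tiny_track(as.integer(rep(s, 3)), as.integer(rep(s, 3)) + 50L,
                     total_mapped = 1e6)
  floored <- score_and_rank(regions, tr, control = ctrl)
  expect_true(all(floored$signal == 0))
  # identical regions/tracks: ties resolved by coordinate order
  same <- tibble::tibble(region_id = c("a", "b"), chrom = "chr1",
                         start = c(5000L, 0L), end = c(6000L, 1000L))
  tied <- score_and_rank(same, tiny_track(100000L, 100050L, 1e6))
  expect_equal(tied$region_id, c("b", "a"))
})

test_that("super_cutoff flags the outlier tail of the scaled curve", {
  mk <- function(sig) {
    n <- length(sig)
    regions <- tibble::tibble(region_id = sprintf("r%d", seq_len(n)),
                              chrom = "chr1", start = seq_len(n) * 1000L,
                              end = seq_len(n) * 1000L + 500L,
                              density = sig / 500, signal = sig)
    regions$rank <- NA_integer_
    regions$rank[order(-sig)] <- seq_len(n)
    super_cutoff(regions)
  }
  se <- mk(c(rep(1, 8), 10, 100))
  expect_equal(sort(se$signal[se$is_super]), c(10, 100))
  expect_equal(attr(se, "cutoff_signal"), 10)
  # all-equal signals -> warning, no super-enhancers
  expect_warning(se0 <- mk(rep(3, 5)), "no super-enhancers")
  expect_false(any(se0$is_super))
})

test_that("super-enhancer sets are a prefix of the signal ranking", {
  set.seed(55)
  for (case in 1:30) {
    n <- sample(20:60, 1)
    sig <- c(rlnorm(n - 3, 1, 0.4), rlnorm(3, 5, 0.3))
    regions <- tibble::tibble(region_id = sprintf("r%03d", seq_len(n)),
                              chrom = "chr1",
                              start = seq_len(n) * 1000L,
                              end = seq_len(n) * 1000L + 500L,
                              density = sig / 500, signal = sig)
    regions$rank <- NA_integer_
    regions$rank[order(-regions$signal)] <- seq_len(n)
    se <- super_cutoff(regions)
    if (any(se$is_super)) {
      expect_gte(min(se$signal[se$is_super]),
                 max(se$signal[!se$is_super]))
    }
  }
})

test_that("assign_to_genes uses overlap, proximity and closest fallback", {
  se <- tibble::tibble(se_id = "se1", chrom = "chr1", start = 100000L,
                       end = 110000L)
  # TSS inside the region -> overlapping
  a <- assign_to_genes(se, tss_one(105000))
  expect_equal(a$relation, "overlapping")
  # no TSS within the window -> only the closest gene
  b <- assign_to_genes(se, dplyr::bind_rows(tss_one(400000, "far1"),
                                            tss_one(700000, "far2")))
  expect_equal(nrow(b), 1)
  expect_equal(b$gene_id, "far1")
  expect_equal(b$relation, "closest")
  # 30 kb is proximal and also closest; 60 kb is neither -> one assignment
  c_ <- assign_to_genes(se, dplyr::bind_rows(tss_one(140000, "g30"),
                                             tss_one(170000, "g60")))
  expect_equal(nrow(c_), 1)
  expect_equal(c_$gene_id, "g30")
  expect_equal(c_$relation, "proximal")
})

test_that("NFRs require full containment in an active gene's super-enhancer", {
  se <- tibble::tibble(se_id = "se1", chrom = "chr1", start = 10000L,
                       end = 20000L, is_super = TRUE)
  assignments <- tibble::tibble(se_id = "se1", gene_id = "g1",
                                relation = "proximal", distance = 100)
  # straddling peak excluded; inside peaks merged to one NFR
  atac <- list(l1 = peak_tbl("chr1", c(9800L, 12000L), c(10200L, 12400L)),
               l2 = peak_tbl("chr1", 12300L, 12700L))
  nfr <- nucleosome_free_regions(atac, se, "g1", assignments)
  expect_equal(nrow(nfr), 1)
  expect_equal(c(nfr$start, nfr$end), c(12000L, 12700L))
  expect_equal(nfr$se_id, "se1")
  # inactive gene -> no NFRs
  expect_equal(nrow(nucleosome_free_regions(atac, se, "other",
                                            assignments)), 0)
})

test_that("planted super-enhancers are recovered at high base-level Jaccard", {
  sb <- shared_bundle(1)
  res <- suppressMessages(run_crc(sb$bundle))
  truth <- sb$bundle$truth$superenhancers
  got <- res$superenhancers[res$superenhancers$is_super, ]
  cover <- function(d) unlist(lapply(seq_len(nrow(d)), function(i) {
    seq(d$start[i], d$end[i] - 1)
  }))
  a <- cover(got)
  b <- cover(truth)
  jac <- length(intersect(a, b)) / length(union(a, b))
  expect_gte(jac, 0.95)
})
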