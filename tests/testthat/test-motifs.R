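test_that("pfm_to_pwm follows the pseudocount log-odds construction", {
  # uniform counts against uniform background -> zero log-odds
  expect_equal(pfm_to_pwm(matrix(5, 4, 3)), matrix(0, 4, 3),
               ignore_attr = TRUE)
  # hand arithmetic: log2((10.025/10.1)/0.25)
  got <- pfm_to_pwm(matrix(c(10, 0, 0, 0), 4, 1))
  expect_equal(got[1, 1], log2((10 + 0.1 * 0.25) / 10.1 / 0.25))
  expect_equal(got[1, 1], 1.9892, tolerance = 1e-4)
  # scaling counts x10 converges toward pseudocount-free log-odds
  counts <- matrix(c(6, 2, 1, 1), 4, 1)
  free <- log2((counts / sum(counts)) / 0.25)
  err1 <- abs(pfm_to_pwm(counts)[, 1] - free)
  err10 <- abs(pfm_to_pwm(counts * 10)[, 1] - free)
  expect_true(all(err10 < err1))
  expect_error(pfm_to_pwm(matrix(0, 4, 2)), "zero column")
})

test_that("exact score p-values match enumeration at L = 1 and 2", {
  m1 <- motif_model("X", matrix(c(10, 0, 0, 0), 4, 1))
  d1 <- exact_score_pvalue(m1)
  expect_equal(score_pvalue(d1, max(m1$pwm)), 0.25)
  expect_equal(score_pvalue(d1, min(m1$pwm) - 5), 1)  # below the support
  set.seed(14)
  m2 <- random_motif(2)
  d2 <- exact_score_pvalue(m2)
  enum <- oracle_enum_distribution(m2)
  for (s in unique(enum$score)) {
    expect_equal(crcmapr:::pvalue_grid(d2, s), oracle_enum_tail(enum, s),
                 tolerance = 1e-12)
  }
})

test_that("tail probabilities are monotone non-increasing in score", {
  set.seed(25)
  for (case in 1:10) {
    d <- exact_score_pvalue(random_motif(sample(3:8, 1),
                                         bg = c(0.3, 0.2, 0.2, 0.3)))
    expect_true(all(diff(d$tail) <= 1e-15))
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("scan_sequence finds planted consensus on both strands", {
  m <- motif_model("X", crcmapr:::consensus_to_counts("ACGTACGTAA"))
  d <- exact_score_pvalue(m)
  left <- "GGGGGGGGGG"
  right <- "CCCCCCCCCC"
  hits <- scan_sequence(paste0(left, "ACGTACGTAA", right), m,
                        p_threshold = 1e-4, dist = d)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 20L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, sum(apply(m$pwm, 2, max)), tolerance = 1e-9)
  # reverse complement of the consensus -> one reverse-strand hit there
  rc <- scan_sequence(paste0(left, revcomp("ACGTACGTAA"), right), m,
                      p_threshold = 1e-4, dist = d)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 10L)
  # all-N sequence and too-short sequence are empty
  expect_equal(nrow(scan_sequence(strrep("N", 50), m, 1)), 0)
  expect_equal(nrow(scan_sequence("ACGT", m, 1)), 0)
})

test_that("scanner scores match the naive summation oracle", {
  set.seed(77)
  for (case in 1:200) {
    m <- random_motif(sample(3:9, 1))
    seq <- random_dna(sample(30:120, 1), with_n = (case %% 5 == 0))
    hits <- scan_sequence(seq, m, p_threshold = 1)
    fwd_ref <- oracle_scan_scores(seq, m$pwm)
    rev_ref <- oracle_scan_scores(seq, crcmapr:::revcomp_matrix(m$pwm))
    fwd <- hits[hits$strand == "+", ]
    rev <- hits[hits$strand == "-", ]
    expect_equal(fwd$start, which(!is.na(fwd_ref)) - 1L)
    expect_equal(fwd$score, fwd_ref[!is.na(fwd_ref)], tolerance = 1e-9)
    expect_equal(rev$score, rev_ref[!is.na(rev_ref)], tolerance = 1e-9)
  }
})

test_that("BH q-values implement the step-up rule", {
  expect_equal(bh_qvalues(0.04), 0.04)
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))
  # order preserved
  p <- c(0.5, 0.001, 0.2)
  expect_equal(order(bh_qvalues(p)), order(p))
  expect_error(bh_qvalues(c(0.1, 0)), NULL)
})

test_that("scan_nfrs retains exactly the planted high-information hit", {
  consensus <- "ACGTTGCAACGTACGTAG"
  m <- list(TFX = motif_model("TFX",
                              crcmapr:::consensus_to_counts(consensus)))
  set.seed(6)
  bgseq <- random_dna(4000)
  planted <- paste0(substr(bgseq, 1, 1000), consensus,
                    substr(bgseq, 1019, 4000))
  genome <- Biostrings::DNAStringSet(c(chr1 = planted))
  nfrs <- tibble::tibble(nfr_id = c("n1", "n2"), chrom = "chr1",
                         start = c(900L, 3000L), end = c(1400L, 3400L),
                         se_id = c("se1", "se2"))
  hits <- scan_nfrs(nfrs, genome, m, q_threshold = 1e-5)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$tf, "TFX")
  expect_equal(hits$nfr_id, "n1")
  expect_equal(hits$start, 1000L)
  expect_equal(hits$se_id, "se1")
  # raising the threshold never removes a hit
  more <- scan_nfrs(nfrs, genome, m, q_threshold = 1e-2)
  expect_true(all(hits$start %in% more$start))
  expect_equal(nrow(scan_nfrs(nfrs[0, ], genome, m)), 0)
  expect_error(scan_nfrs(tibble::tibble(nfr_id = "bad", chrom = "chr1",
                                        start = 3900L, end = 4300L),
                         genome, m), "bad|bounds")
})
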