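test_that("consensus peaks apply the 3-of-4 support rule", {
  one <- peak_tbl("chr1", 100L, 200L, signal = 5)
  sets <- list(a = one, b = one, c = one, d = one)
  cp <- consensus_peaks(sets, min_support = 3)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$support, 4L)
  # present in only 2 of 4 lines -> excluded
  sets2 <- list(a = one, b = one, c = one[0, ], d = one[0, ])
  expect_equal(nrow(consensus_peaks(sets2, min_support = 3)), 0)
  expect_error(consensus_peaks(list(a = one), min_support = 3),
               "min_support")
})

test_that("chained overlaps group transitively into one consensus peak", {
  sets <- list(A = peak_tbl("chr1", 0L, 100L, signal = 1),
               B = peak_tbl("chr1", 80L, 180L, signal = 9),
               C = peak_tbl("chr1", 160L, 260L, signal = 2),
               D = peak_tbl("chr1", 5000L, 5100L, signal = 1))
  cp <- consensus_peaks(sets, min_support = 3)
  expect_equal(nrow(cp), 1)
  expect_equal(c(cp$start, cp$end), c(0L, 260L))
  expect_equal(cp$support, 3L)
  # representative summit comes from the strongest member (B)
  expect_equal(cp$summit, (80L + 180L) %/% 2L)
})

test_that("book-ended peaks (no shared base) do not group", {
  sets <- list(a = peak_tbl("chr1", 0L, 100L),
               b = peak_tbl("chr1", 100L, 200L),
               c = peak_tbl("chr1", c(0L, 100L), c(100L, 200L)))
  cp <- consensus_peaks(sets, min_support = 2)
  expect_equal(nrow(cp), 2)
})

test_that("consensus is monotone in min_support", {
  set.seed(17)
  sets <- lapply(1:4, function(i) {
    s <- sample.int(4000, 25) - 1L
    peak_tbl("chr1", s, s + sample.int(200, 25) + 20L,
             signal = runif(25, 1, 10))
  })
  names(sets) <- paste0("l", 1:4)
  for (ms in 1:3) {
    hi <- consensus_peaks(sets, min_support = ms + 1)
    lo <- consensus_peaks(sets, min_support = ms)
    key <- function(x) paste(x$chrom, x$start, x$end)
    expect_true(all(key(hi) %in% key(lo)))
    # support equals count of distinct contributing lines
    all_cp <- consensus_peaks(sets, min_support = 1)
    for (i in seq_len(nrow(all_cp))) {
      expect_equal(all_cp$support[i],
                   dplyr::n_distinct(all_cp$members[[i]]$line))
    }
  }
})

test_that("state_matrix keeps rows aligned across marks and averages lines", {
  cp <- tibble::tibble(peak_id = c("a", "b"), chrom = "chr1",
                       start = c(900L, 4900L), end = c(1100L, 5100L),
                       summit = c(1000L, 5000L))
  mk_track <- function(mult) {
    s <- rep(c(950L, 4950L), each = 10 * mult)
    tiny_track(s, s + 50L, total_mapped = 1e6)
  }
  tracks <- list(H3K27ac = list(l1 = mk_track(1), l2 = mk_track(3)),
                 H3K4me1 = list(l1 = mk_track(1)),
                 H3K4me3 = list(l1 = mk_track(1)))
  mats <- state_matrix(cp, tracks, window = 1000, bin_width = 10)
  expect_equal(rownames(mats$H3K27ac), c("a", "b"))
  expect_equal(rownames(mats$H3K4me1), rownames(mats$H3K27ac))
  # per-line average: (1x + 3x)/2 = 2x the single-line matrix
  expect_equal(mats$H3K27ac, 2 * mats$H3K4me1,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(state_matrix(cp, tracks[c("H3K27ac", "H3K4me1")]),
               "H3K4me3")
})

test_that("cluster_states recovers well-separated archetypes exactly", {
  prof <- synth_state_profiles(n = 150, seed = 4, noise_sd = 0.3)
  cs <- cluster_states(prof$mats, k = 3)
  expect_equal(rand_index(cs$assignments$cluster, prof$states), 1)
  # k = 1 labels everything 1
  cs1 <- cluster_states(prof$mats, k = 1)
  expect_true(all(cs1$assignments$cluster == 1L))
  expect_error(cluster_states(lapply(prof$mats, function(m) m[1:2, ]),
                              k = 3), "fewer rows")
})

test_that("cluster_states is invariant to row permutation", {
  prof <- synth_state_profiles(n = 60, seed = 9, noise_sd = 0.4)
  cs <- cluster_states(prof$mats, k = 3)
  set.seed(1)
  perm <- sample(60)
  cs_p <- cluster_states(lapply(prof$mats, function(m) m[perm, ]), k = 3)
  back <- cs_p$assignments$cluster[order(perm)]
  expect_equal(rand_index(back, cs$assignments$cluster), 1)
})

test_that("ward-D2 merge heights match hand-computed costs for 3 points", {
  # singleton merges at euclidean distance; then sqrt(2 * ESS increase)
  mats <- list(H3K27ac = matrix(c(0, 1, 10), 3, 1,
                                dimnames = list(c("a", "b", "c"), NULL)),
               H3K4me1 = matrix(0, 3, 1,
                                dimnames = list(c("a", "b", "c"), NULL)),
               H3K4me3 = matrix(0, 3, 1,
                                dimnames = list(c("a", "b", "c"), NULL)))
  cs <- cluster_states(mats, k = 2, scale = FALSE)
  expect_equal(sort(unname(cs$assignments$cluster[1:2])),
               sort(unname(cs$assignments$cluster[2:1])))
  expect_equal(cs$assignments$cluster[1], cs$assignments$cluster[2])
  expect_false(cs$assignments$cluster[3] == cs$assignments$cluster[1])
  h <- cs$hclust
  expect_equal(h$height[1], 1)                        # d({0},{1})
  expect_equal(h$height[2], sqrt(2 * (2 * 1 / 3) * 9.5^2))  # vs centroid 0.5
})

test_that("state labels are ordered by decreasing mean H3K27ac", {
  prof <- synth_state_profiles(n = 90, seed = 12, noise_sd = 0.3)
  cs <- cluster_states(prof$mats, k = 3)
  m <- tapply(rowMeans(prof$mats$H3K27ac), cs$assignments$cluster, mean)
  expect_true(all(diff(m[as.character(1:3)]) < 0))
})
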