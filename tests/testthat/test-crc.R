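mini_tss <- function(symbols) {
  tibble::tibble(gene_id = paste0("g_", symbols), gene_symbol = symbols,
                 chrom = "chr1", tss = seq_along(symbols) * 100000L,
                 strand = "+", is_tf = TRUE)
}

mini_motifs <- function(symbols) {
  out <- lapply(symbols, function(s) {
    motif_model(s, matrix(c(9, 1, 1, 1), 4, 4))
  })
  names(out) <- symbols
  out
}

test_that("candidate TFs require activity, an SE assignment and a motif", {
  tss <- mini_tss(c("TFA", "TFB", "TFC", "GENE1"))
  assignments <- tibble::tibble(
    se_id = c("se1", "se2", "se3"),
    gene_id = c("g_TFA", "g_TFB", "g_GENE1"),
    relation = "proximal", distance = 0)
  motifs <- mini_motifs(c("TFA", "TFC", "ORPHAN"))
  active <- c("g_TFA", "g_TFC", "g_GENE1")
  expect_message(
    cands <- candidate_tfs(active, assignments, motifs, tss), "ORPHAN")
  # TFA: all three conditions; TFB inactive+no motif; TFC no SE;
  # GENE1 has SE but no motif
  expect_equal(cands, "TFA")
})

test_that("build_graph creates edges from hits in target SEs, with fan-out", {
  tss <- mini_tss(c("TFA", "TFB", "TFC"))
  nfrs <- tibble::tibble(nfr_id = c("n1", "n2"), chrom = "chr1",
                         start = c(0L, 1000L), end = c(400L, 1400L),
                         se_id = c("seB", "seShared"))
  assignments <- tibble::tibble(
    se_id = c("seB", "seShared", "seShared"),
    gene_id = c("g_TFB", "g_TFB", "g_TFC"),
    relation = "proximal", distance = 0)
  hit <- function(tf, nfr) {
    tibble::tibble(tf = tf, nfr_id = nfr, chrom = "chr1", start = 10L,
                   end = 14L, strand = "+", score = 5, p = 1e-9, q = 1e-7)
  }
  cands <- c("TFA", "TFB", "TFC")
  expect_equal(nrow(build_graph(cands, hit("TFA", "n1")[0, ], nfrs,
                                assignments, tss)), 0)
  # one SE assigned to both B and C, hit by A -> A->B and A->C
  g <- build_graph(cands, hit("TFA", "n2"), nfrs, assignments, tss)
  expect_equal(g$source, c("TFA", "TFA"))
  expect_equal(sort(g$target), c("TFB", "TFC"))
  # reciprocal regulation
  g2 <- build_graph(c("TFA", "TFB"),
                    dplyr::bind_rows(hit("TFA", "n1"), hit("TFB", "n1")),
                    nfrs,
                    tibble::tibble(se_id = "seB",
                                   gene_id = c("g_TFA", "g_TFB"),
                                   relation = "proximal", distance = 0) |>
                      dplyr::slice(rep(1:2, 1)),
                    tss)
  expect_setequal(paste(g2$source, g2$target),
                  c("TFA TFA", "TFA TFB", "TFB TFA", "TFB TFB"))
  # a hit in an unmapped NFR violates the construction contract
  expect_error(build_graph(cands, hit("TFA", "nope"), nfrs, assignments,
                           tss), "not mapped")
})

test_that("evidence multiplicity does not change degrees", {
  edges1 <- tibble::tibble(source = "A", target = "B")
  edges2 <- tibble::tibble(source = c("A", "A"), target = c("B", "B"))
  expect_equal(total_degrees(edges1, c("A", "B")),
               total_degrees(edges2, c("A", "B")))
})

test_that("total degree counts unique partners, self-loops once per set", {
  cands <- c("A", "B", "C")
  edges <- tibble::tibble(source = c("A", "A", "B"),
                          target = c("B", "C", "A"))
  deg <- total_degrees(edges, cands)
  expect_equal(deg$total_degree[deg$tf == "A"], 3L)  # |{B}| + |{B,C}|
  expect_equal(deg$total_degree[deg$tf == "B"], 2L)
  expect_equal(deg$total_degree[deg$tf == "C"], 1L)
  # pure self-loop
  self <- total_degrees(tibble::tibble(source = "A", target = "A"), "A")
  expect_equal(self$total_degree, 2L)
  # isolated candidate
  iso <- total_degrees(edges[0, ], "Z")
  expect_equal(iso$total_degree, 0L)
})

test_that("degree sums equal the number of distinct ordered edges", {
  set.seed(41)
  for (case in 1:50) {
    n <- sample(2:6, 1)
    cands <- LETTERS[1:n]
    adj <- matrix(runif(n * n) < 0.4, n, n)
    edges <- adj_to_edges(adj, cands)
    deg <- total_degrees(edges, cands)
    expect_equal(sum(deg$in_degree), nrow(edges))
    expect_equal(sum(deg$out_degree), nrow(edges))
  }
})

test_that("rank_tfs orders by degree, out-degree, then name", {
  nodes <- tibble::tibble(tf = c("Z", "A", "M", "B"),
                          in_degree = c(3L, 1L, 2L, 2L),
                          out_degree = c(3L, 1L, 2L, 2L),
                          total_degree = c(6L, 2L, 4L, 4L))
  r <- rank_tfs(nodes)
  expect_equal(r$tf, c("Z", "B", "M", "A"))
  expect_equal(r$rank, 1:4)
  # out-degree tie-break
  nodes2 <- tibble::tibble(tf = c("A", "B"), in_degree = c(3L, 1L),
                           out_degree = c(1L, 3L),
                           total_degree = c(4L, 4L))
  expect_equal(rank_tfs(nodes2)$tf, c("B", "A"))
})
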