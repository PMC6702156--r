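#' Filter a differential-expression table
#'
#' Keeps genes with `|log2fc| > lfc_cutoff` (strict) and
#' `padj < padj_cutoff` (strict), splitting them by sign. The defaults
#' (0.6, i.e. 1.5-fold, and 1e-10) reproduce the knockdown analysis
#' thresholds; note some write-ups quote the adjusted-p inequality with the
#' opposite sign, which would select the null genes and is treated here as
#' an erratum. Records with non-finite values are skipped with a warning.
#'
#' @param records DE tibble with `gene_id`, `log2fc`, `padj`.
#' @param lfc_cutoff Absolute log2 fold-change cutoff (strict).
#' @param padj_cutoff Adjusted p-value cutoff (strict).
#' @return `records` filtered, with a `direction` column (`"up"` for
#'   positive `log2fc`, `"down"` for negative).
#' @export
filter_de <- function(records, lfc_cutoff = 0.6, padj_cutoff = 1e-10) {
  ok <- is.finite(records$log2fc) & is.finite(records$padj)
  if (any(!ok)) {
    warning(sum(!ok), " DE record(s) with non-finite values skipped")
    records <- records[ok, ]
  }
  kept <- records[abs(records$log2fc) > lfc_cutoff &
                    records$padj < padj_cutoff, ]
  kept$direction <- ifelse(kept$log2fc > 0, "up", "down")
  tibble::as_tibble(kept)
}

#' Categorize genes by distance to the nearest TF binding site
#'
#' The distance is the minimum over a gene's TSS records of the gap
#' distance to any consensus TF peak. Categories: Promoter (< 10 kb),
#' Enhancer (10 kb to 400 kb inclusive on both ends, so the partition is
#' total), Distal (> 400 kb), Unassigned (no peak on the chromosome).
#'
#' @param tss TSS annotation tibble (only the genes of interest).
#' @param peaks Consensus TF peaks tibble (`chrom`, `start`, `end`).
#' @param promoter_max Exclusive upper bound of the Promoter bin (bases).
#' @param enhancer_max Inclusive upper bound of the Enhancer bin (bases).
#' @return A tibble with `gene_id`, `distance`, `category`.
#' @export
categorize_by_peak_distance <- function(tss, peaks, promoter_max = 10000,
                                        enhancer_max = 400000) {
  genes <- unique(tss$gene_id)
  d <- vapply(genes, function(g) {
    rows <- which(tss$gene_id == g)
    min(min_distance_to_targets(tss$chrom[rows], tss$tss[rows], peaks))
  }, numeric(1))
  category <- dplyr::case_when(
    is.infinite(d) ~ "Unassigned",
    d < promoter_max ~ "Promoter",
    d <= enhancer_max ~ "Enhancer",
    TRUE ~ "Distal"
  )
  tibble::tibble(gene_id = genes, distance = unname(d),
                 category = factor(category,
                                   levels = c("Promoter", "Enhancer",
                                              "Distal", "Unassigned")))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, as used to compare effect sizes between gene
#' categories.
#'
#' @param group_a,group_b Numeric vectors, each of length at least 2 and
#'   not both constant.
#' @return A one-row tibble with `t`, `p`, `df`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("both groups need at least 2 observations", call. = FALSE)
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      stop("degenerate groups: both constant and equal", call. = FALSE)
    }
    stop("degenerate groups: zero variance in both", call. = FALSE)
  }
  fit <- t.test(group_a, group_b, var.equal = FALSE)
  tibble::tibble(t = unname(fit$statistic), p = fit$p.value,
                 df = unname(fit$parameter),
                 mean_a = mean(group_a), mean_b = mean(group_b),
                 n_a = length(group_a), n_b = length(group_b))
}

#' Pairwise Welch comparisons of log2 fold-changes across categories
#'
#' @param de Filtered DE tibble (with `gene_id`, `log2fc`).
#' @param categories Category tibble (from
#'   [categorize_by_peak_distance()]).
#' @return A tibble of category pairs with the Welch statistics; pairs with
#'   a group smaller than 2 are omitted.
#' @export
welch_by_category <- function(de, categories) {
  x <- dplyr::inner_join(de, categories, by = "gene_id")
  cats <- intersect(c("Promoter", "Enhancer", "Distal"),
                    as.character(unique(x$category)))
  if (length(cats) < 2) {
    return(tibble::tibble(category_a = character(),
                          category_b = character()))
  }
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    a <- x$log2fc[x$category == pr[1]]
    b <- x$log2fc[x$category == pr[2]]
    if (length(a) < 2 || length(b) < 2) return(NULL)
    dplyr::bind_cols(tibble::tibble(category_a = pr[1], category_b = pr[2]),
                     welch_t(a, b))
  })
  dplyr::bind_rows(out)
}
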