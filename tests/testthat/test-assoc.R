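test_that("gene-DMR linking respects the 2-kb flank in half-open coords", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "sA1", start = 3000L,
                          end = 4000L, strand = "+",
                          homolog_id = NA_character_)
  dmr_in <- fake_calls(-0.6, TRUE, start = 1000) # (1000,1100)
  links <- genes_near_dmrs(dmr_in, genes)
  expect_equal(nrow(links), 1) # flank region starts exactly at 1000
  expect_equal(links$relation, "flank5")
  expect_gt(links$distance, 0)

  dmr_out <- fake_calls(-0.6, TRUE, start = 900) # (900,1000), ends before
  expect_equal(nrow(genes_near_dmrs(dmr_out, genes)), 0)

  dmr_body <- fake_calls(-0.6, TRUE, start = 3200)
  body <- genes_near_dmrs(dmr_body, genes)
  expect_equal(body$relation, "body")
  expect_equal(body$distance, 0L)

  # flank = 0 reduces to body-only overlap
  expect_equal(nrow(genes_near_dmrs(dmr_in, genes, flank = 0)), 0)
  expect_equal(nrow(genes_near_dmrs(dmr_body, genes, flank = 0)), 1)
  expect_error(genes_near_dmrs(dmr_in, genes, flank = -1), "non-negative")

  # strand-aware relation: same upstream DMR is 3' for a minus-strand gene
  genes_minus <- dplyr::mutate(genes, strand = "-")
  expect_equal(genes_near_dmrs(dmr_in, genes_minus)$relation, "flank3")
})

test_that("gene methylation pools cytosines like window pooling", {
  mat <- dplyr::bind_rows(
    cyt("Chr1", c(10, 60), "+", "CG", c(5, 5), c(5, 5)),
    cyt("Chr1", c(10, 60), "+", "CG", c(2, 0), c(8, 10))
  ) |>
    dplyr::mutate(line = rep(c("a", "b"), each = 2),
                  n_total = n_meth + n_unmeth)
  genes <- tibble::tibble(gene_id = "g1", chrom = "Chr1", start = 0L,
                          end = 100L, strand = "+",
                          homolog_id = NA_character_)
  gm <- gene_methylation(mat, genes)
  expect_equal(gm$m[gm$line == "a"], 0.5)
  expect_equal(gm$m[gm$line == "b"], 0.1)
  # gene equal to one tile reproduces the window pooling exactly
  w <- make_windows(mat, window_size = 100)
  expect_equal(sort(gm$m), sort(w$meth / w$total))

  none <- gene_methylation(mat, dplyr::mutate(genes, start = 5000L,
                                              end = 6000L))
  expect_equal(nrow(none), 0) # flagged missing by absence
})

test_that("expression ratios use replicate means and a pseudocount", {
  expr <- tibble::tibble(
    gene_id = rep("g1", 4), line = rep(c("asu", "aar"), each = 2),
    replicate = rep(1:2, 2), tpm = c(14, 16, 2, 4)
  )
  r <- expression_ratio(expr, "asu", "aar")
  expect_equal(r$log2_ratio, log2((15 + 1) / (3 + 1))) # exactly 2
  expect_equal(r$log2_ratio, 2)

  same <- dplyr::mutate(expr, tpm = 8)
  expect_equal(expression_ratio(same, "asu", "aar")$log2_ratio, 0)

  zero <- dplyr::mutate(expr, tpm = 0)
  expect_equal(expression_ratio(zero, "asu", "aar")$log2_ratio, 0)

  expect_error(expression_ratio(expr, "asu", "aar", gene_id = "gX"),
               "absent")
})

test_that("Mann-Whitney comparison matches enumeration for small groups", {
  res <- compare_groups(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1) # 2 of the 20 assignments are as extreme
  expect_equal(res$p, enum_mannwhitney_p(c(1, 2, 3), c(4, 5, 6)))

  # label swap reflects U and keeps p
  swap <- compare_groups(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swap$statistic, 9) # n1*n2 - 0
  expect_equal(swap$p, res$p)

  ident <- compare_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(ident$p, 0.9)
  expect_error(compare_groups(numeric(0), 1), "non-empty")
})

test_that("methylation-expression correlation handles signs and degeneracy", {
  m <- c(0.9, 0.8, 0.7, 0.6, 0.2)
  e <- c(1, 2, 3, 4, 8)
  r <- methylation_expression_correlation(m, e)
  expect_lt(r$r, 0)
  expect_false(r$degenerate)

  exact <- methylation_expression_correlation(m, 3 - 2 * m)
  expect_equal(exact$r, -1)

  flat <- methylation_expression_correlation(rep(0.5, 5), e)
  expect_true(flat$degenerate)
  expect_true(is.na(flat$r))

  expect_error(methylation_expression_correlation(c(0.1, 0.2), c(1, 2)),
               "at least 3")

  spear <- methylation_expression_correlation(m, e, method = "spearman")
  expect_equal(spear$r, -1) # opposite monotone ranks

  # permuted pairings are uncorrelated on average
  set.seed(17)
  rs <- replicate(300, {
    methylation_expression_correlation(m, sample(e))$r
  })
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.05)
})

test_that("homolog convergence counts candidates and decreased pairs", {
  pairs <- tibble::tibble(
    m_parent_a = c(0.8, 0.4, 0.9), m_parent_t = c(0.2, 0.1, 0.1),
    m_asu_a = c(0.25, 0.2, 0.8), m_asu_t = c(0.15, 0.1, 0.1),
    lr_parent = c(2, 2, 2), lr_asu = c(0.5, 0.5, 2.5)
  )
  # pair 1: candidate (parent diff 0.6, Asu diff 0.1) and decreased;
  # pair 2: parent diff 0.3 is no candidate; pair 3: Asu still differs
  res <- homolog_convergence(pairs)
  expect_equal(res$n_candidates, 1L)
  expect_equal(res$n_decreased, 1L)
  expect_equal(res$percent, 100)

  none <- dplyr::mutate(pairs, m_parent_a = 0.2)
  expect_warning(r0 <- homolog_convergence(none), "No candidate")
  expect_true(is.na(r0$percent))

  # the reported convention: decreased / candidates as a one-decimal percent
  expect_equal(percentage(569, 764), 74.5)
})

test_that("upregulation breakdown classifies homolog pairs", {
  base_reps <- c(8, 8.1, 7.9)
  mk_expr <- function(asu_a, asu_t) {
    tibble::tibble(
      gene_id = rep(c("g1_A", "g1_T"), each = 9),
      line = rep(rep(c("asu", "aar", "ath"), each = 3), 2),
      replicate = rep(1:3, 6),
      tpm = c(asu_a, base_reps, base_reps, asu_t, base_reps, base_reps)
    )
  }
  pairs <- tibble::tibble(gene_a = "g1_A", gene_t = "g1_T")

  up_a <- mk_expr(c(40, 41, 39), base_reps)
  res <- upregulation_breakdown(pairs, up_a)
  expect_equal(res$genes$class, "A_only")
  expect_equal(res$summary$percent_upregulated, 100)

  flat <- mk_expr(base_reps, base_reps)
  res0 <- upregulation_breakdown(pairs, flat)
  expect_equal(res0$genes$class, "none")
  expect_equal(res0$summary$n_upregulated, 0L)
  # classes partition the classified pairs
  s <- res0$summary
  expect_equal(s$n_A_only + s$n_T_only + s$n_both + s$n_none,
               s$n_pairs - s$n_skipped)

  missing <- upregulation_breakdown(
    tibble::tibble(gene_a = "gX_A", gene_t = "gX_T"), flat
  )
  expect_equal(missing$summary$n_skipped, 1L)
  expect_true(is.na(missing$summary$percent_upregulated))
})
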