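test_that("windows tile the genome and pool counts per context", {
  mat <- cyt("Chr1", c(10, 50, 150), "+", "CG", c(5, 3, 0),
             c(5, 7, 10)) |>
    dplyr::mutate(line = "x", n_total = n_meth + n_unmeth)
  w <- make_windows(mat, window_size = 100)
  expect_equal(nrow(w), 2)
  expect_equal(w$start, c(0L, 100L))
  expect_equal(w$n_sites, c(2L, 1L))
  expect_equal(w$meth, c(8L, 0L))
  expect_equal(w$total, c(20L, 10L))
})

test_that("overlapping windows replicate sites into every covering tile", {
  mat <- cyt("Chr1", 61, "+", "CG", 1, 1) |>
    dplyr::mutate(line = "x", n_total = 2L)
  w <- make_windows(mat, window_size = 100, step = 50)
  expect_equal(sort(w$start), c(0L, 50L)) # site at 0-based 60
  expect_error(make_windows(mat, window_size = 0), "positive")
  expect_error(make_windows(mat, step = -1), "positive")
  empty <- make_windows(mat[0, ], 100)
  expect_equal(nrow(empty), 0)
})

test_that("weighted methylation is the pooled count ratio", {
  # hand summation: (5 + 3 + 0) / (10 + 10 + 10)
  expect_equal(weighted_methylation(5 + 3 + 0, 30), 8 / 30)
  expect_equal(weighted_methylation(10, 10), 1)
  expect_equal(weighted_methylation(0, 10), 0)
  expect_true(is.na(weighted_methylation(0, 0)))
  expect_error(weighted_methylation(5, 3), "exceed")
  expect_error(weighted_methylation(-1, 3), "non-negative")
})

test_that("Fisher p-values match hand-enumerated worked cases", {
  # [[1,0],[0,1]]: both point probabilities are 1/2
  expect_equal(fisher_exact_2x2(1, 0, 0, 1), 1)
  # [[2,0],[0,2]]: P(a=0)=P(a=2)=1/6, P(a=1)=4/6
  expect_equal(fisher_exact_2x2(2, 0, 0, 2), 1 / 3)
  expect_equal(fisher_exact_2x2(10, 10, 10, 10), 1)
  # zero-margin convention
  expect_equal(fisher_exact_2x2(0, 0, 5, 5), 1)
  expect_equal(fisher_exact_2x2(c(1, 2), c(0, 0), c(0, 0), c(1, 2)),
               c(1, 1 / 3))
  expect_error(fisher_exact_2x2(-1, 0, 0, 1), "non-negative")
  expect_error(fisher_exact_2x2(0.5, 0, 0, 1), "integer")
})

test_that("Fisher agrees with enumeration and stats::fisher.test on random tables", {
  set.seed(5)
  for (i in 1:200) {
    tab <- as.integer(rmultinom(1, sample(4:40, 1), rep(0.25, 4)))
    p_vec <- fisher_exact_2x2(tab[1], tab[2], tab[3], tab[4])
    expect_equal(p_vec, enum_fisher_p(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    p_ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
    expect_equal(p_vec, p_ref, tolerance = 1e-7)
  }
})

test_that("BH adjustment reproduces the step-up worked example", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH output dominates p and is monotone in p", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(2:200, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("DMR calls combine FDR and context effect-size cutoffs", {
  w <- dplyr::bind_rows(
    win("Chr1", 0, "CG", "foc", 5, 90, 100),
    win("Chr1", 0, "CG", "ref", 5, 20, 100),
    win("Chr1", 100, "CG", "foc", 5, 60, 100),
    win("Chr1", 100, "CG", "ref", 5, 20, 100),
    win("Chr1", 200, "CG", "foc", 3, 90, 100), # below CG site minimum
    win("Chr1", 200, "CG", "ref", 3, 10, 100)
  )
  calls <- call_dmrs(w, "foc", "ref", "CG")
  expect_s3_class(calls, "dmr_calls")
  expect_equal(nrow(calls), 2) # 3-site window never tested
  first <- calls[calls$start == 0, ]
  expect_true(first$is_dmr)
  expect_equal(first$direction, "hyper")
  expect_equal(first$delta, 0.7)
  # delta 0.4 fails the 0.5 CG cutoff no matter the p-value
  second <- calls[calls$start == 100, ]
  expect_false(second$is_dmr)
  expect_lt(second$p, 0.05)

  # swapping focal and reference flips direction, keeps p
  swapped <- call_dmrs(w, "ref", "foc", "CG")
  expect_equal(swapped$p, calls$p)
  expect_equal(swapped$delta, -calls$delta)
  expect_equal(swapped$direction[swapped$start == 0], "hypo")

  expect_error(call_dmrs(w, "foc", "ref", "CpX"), "context")
  expect_error(call_dmrs(w, "foc", "nope", "CG"), "not present")
  expect_error(call_dmrs(w, "foc", "ref", "CG", fdr = 0), "fdr")
})

test_that("hyper and hypo DMR sets are disjoint and m stays in [0,1]", {
  cfg <- tiny_cohort_config()
  co <- simulate_cohort(cfg, seed = 3)
  h <- harmonize_cohort(co)
  w <- make_windows(h$matrix)
  calls <- call_dmrs(w, "asu_A", "aar", "CG")
  expect_true(all(calls$m_focal >= 0 & calls$m_focal <= 1))
  expect_true(all(calls$m_ref >= 0 & calls$m_ref <= 1))
  hyper <- calls[calls$is_dmr & calls$direction == "hyper", ]
  hypo <- calls[calls$is_dmr & calls$direction == "hypo", ]
  expect_length(intersect(
    paste(hyper$chrom, hyper$start), paste(hypo$chrom, hypo$start)
  ), 0)
  # site-count minimums are respected in the output
  expect_true(all(calls$n_sites >= 4))
  chh <- call_dmrs(dplyr::mutate(w, context = "CHH"), "asu_A", "aar", "CHH")
  expect_true(all(chh$n_sites >= 16) || nrow(chh) == 0)
})

test_that("tidy and glance summarise DMR calls", {
  w <- dplyr::bind_rows(
    win("Chr1", 0, "CG", "foc", 5, 90, 100),
    win("Chr1", 0, "CG", "ref", 5, 20, 100)
  )
  calls <- call_dmrs(w, "foc", "ref", "CG")
  td <- tidy(calls)
  expect_named(td, c("chrom", "start", "end", "context", "n_sites",
                     "m_focal", "m_ref", "delta", "p", "q", "direction",
                     "is_dmr"))
  gl <- glance(calls)
  expect_equal(gl$n_tested, 1L)
  expect_equal(gl$n_hyper, 1L)
  expect_equal(gl$focal, "foc")
})
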