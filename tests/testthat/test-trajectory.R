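make_avt <- function(parents, f1, a733, a738, asu) {
  # each argument: list(delta =, dmr =) vectors over a shared window set
  lst <- list(parents = parents, f1 = f1, a733 = a733, a738 = a738,
              asu = asu)
  lapply(lst, function(x) fake_calls(x$delta, x$dmr))
}

test_that("convergent windows need sustained A>T hyper collapsing in Asu", {
  avt <- make_avt(
    parents = list(delta = c(0.6, 0.6, 0.3), dmr = c(TRUE, TRUE, FALSE)),
    f1 = list(delta = c(0.6, 0.6, 0.6), dmr = c(TRUE, TRUE, TRUE)),
    a733 = list(delta = c(0.55, 0.55, 0.6), dmr = c(TRUE, TRUE, TRUE)),
    a738 = list(delta = c(0.6, 0.6, 0.6), dmr = c(TRUE, TRUE, TRUE)),
    asu = list(delta = c(0.1, 0.6, 0.1), dmr = c(FALSE, TRUE, FALSE))
  )
  res <- classify_convergent(avt)
  # window 1: the A-T difference collapses in the natural line
  expect_equal(res$convergent, c(TRUE, FALSE, FALSE))
  # window 2: still hyper in Asu
  expect_equal(res$hyper_class[2], "persistent_hyper")
  # window 3: parents' delta 0.3 is below the CG cutoff, so never convergent
  expect_true(is.na(res$hyper_class[3]))
})

test_that("parent-hyper windows partition into exactly one class", {
  set.seed(31)
  for (i in 1:10) {
    n <- 50
    mk <- function() list(delta = runif(n, -0.8, 0.8),
                          dmr = runif(n) < 0.5)
    avt <- make_avt(mk(), mk(), mk(), mk(), mk())
    res <- classify_convergent(avt)
    parent_hyper <- !is.na(res$hyper_class)
    expect_true(all(res$hyper_class[parent_hyper] %in%
                      c("convergent", "persistent_hyper", "other")))
    # flags are consistent with the label
    expect_equal(res$convergent, !is.na(res$hyper_class) &
                   res$hyper_class == "convergent")
  }
})

test_that("the change threshold acts monotonically on each criterion", {
  set.seed(32)
  n <- 200
  mk <- function() list(delta = runif(n, -0.8, 0.8), dmr = runif(n) < 0.6)
  avt <- make_avt(mk(), mk(), mk(), mk(), mk())
  # the hyper requirement tightens with the cutoff: among windows whose
  # natural-line similarity is unaffected (|delta_asu| far below any
  # cutoff), raising the threshold never adds convergent windows
  stable <- abs(avt$asu$delta) < 0.05
  counts <- vapply(
    c(0.3, 0.5, 0.7),
    function(ct) sum(classify_convergent(avt, ct)$convergent[stable]),
    numeric(1)
  )
  expect_true(all(diff(counts) <= 0))
  # a cutoff beyond every observed delta admits nothing
  expect_equal(sum(classify_convergent(avt, 0.9)$convergent), 0)
})

test_that("conserved flags follow Asu hypo-DMRs shared with earlier lines", {
  vsp <- list(
    f1 = fake_calls(c(-0.6, 0, -0.6), c(TRUE, FALSE, TRUE)),
    a733 = fake_calls(c(0, 0, -0.6), c(FALSE, FALSE, TRUE)),
    a738 = fake_calls(c(0, 0, -0.6), c(FALSE, FALSE, TRUE)),
    asu = fake_calls(c(-0.6, -0.6, -0.6), c(TRUE, TRUE, TRUE))
  )
  res <- classify_conserved(vsp)
  expect_equal(res$conserved_f1, c(TRUE, FALSE, TRUE))
  expect_equal(res$conserved_all, c(FALSE, FALSE, TRUE))
  expect_equal(res$conserved_any, c(TRUE, FALSE, TRUE))
  fr <- conserved_fractions(res)
  expect_equal(fr$total, rep(3L, 4))
  expect_equal(fr$overlap[fr$line == "f1"], 2L)
  expect_equal(fr$percent[fr$line == "f1"], percentage(2, 3))
})

test_that("classification requires matching window universes", {
  vsp <- list(
    f1 = fake_calls(c(-0.6, 0), c(TRUE, FALSE)),
    a733 = fake_calls(c(0, 0), c(FALSE, FALSE)),
    a738 = fake_calls(c(0, 0), c(FALSE, FALSE)),
    asu = fake_calls(-0.6, TRUE) # one window only
  )
  expect_error(classify_conserved(vsp), "universes differ")
  expect_error(classify_conserved(vsp[-1]), "Missing DMR calls")
})

test_that("trajectory labels combine both criteria with 'both' precedence", {
  avt <- make_avt(
    parents = list(delta = c(0.6, 0.6), dmr = c(TRUE, TRUE)),
    f1 = list(delta = c(0.6, 0.6), dmr = c(TRUE, TRUE)),
    a733 = list(delta = c(0.6, 0.6), dmr = c(TRUE, TRUE)),
    a738 = list(delta = c(0.6, 0.6), dmr = c(TRUE, TRUE)),
    asu = list(delta = c(0.1, 0.1), dmr = c(FALSE, FALSE))
  )
  vsp <- list(
    f1 = fake_calls(c(-0.6, 0), c(TRUE, FALSE)),
    a733 = fake_calls(c(0, 0), c(FALSE, FALSE)),
    a738 = fake_calls(c(0, 0), c(FALSE, FALSE)),
    asu = fake_calls(c(-0.6, -0.1), c(TRUE, FALSE))
  )
  res <- classify_trajectory(avt, vsp)
  expect_equal(res$class, c("both", "convergent"))
})

test_that("inheritance fraction is plain set arithmetic on windows", {
  child <- fake_calls(c(-0.6, -0.6), c(TRUE, TRUE), start = c(0, 100))
  anc <- fake_calls(c(-0.6, -0.6), c(TRUE, TRUE), start = c(100, 200))
  res <- inheritance_fraction(child, anc)
  expect_equal(res$overlap, 1L)
  expect_equal(res$total, 2L)
  expect_equal(res$fraction, 0.5)

  expect_equal(inheritance_fraction(child, child)$fraction, 1)
  disjoint <- fake_calls(-0.6, TRUE, start = 900)
  expect_equal(inheritance_fraction(child, disjoint)$fraction, 0)
  none <- fake_calls(0, FALSE, start = 0)
  expect_warning(res0 <- inheritance_fraction(none, anc), "undefined")
  expect_true(is.na(res0$fraction))
})

test_that("overlap enrichment builds the right 2x2 and Fisher p", {
  # the [[2,0],[0,2]]-margin table: p = 1/3 by enumeration
  res <- overlap_enrichment(c("w1", "w2"), c("w3", "w4"), 4)
  expect_equal(res$overlap, 0L)
  expect_equal(res$p, 1 / 3)
  expect_equal(res$odds_ratio, 0)

  expect_error(overlap_enrichment(c("a", "b"), c("c", "d"), 3), "universe")

  # independent random splits have odds ratio around 1
  set.seed(41)
  ors <- replicate(40, {
    u <- paste0("w", 1:100)
    a <- sample(u, 50)
    b <- sample(u, 50)
    overlap_enrichment(a, b, 100)$odds_ratio
  })
  expect_equal(median(ors), 1, tolerance = 0.35)
  expect_gt(mean(ors > 0.4 & ors < 2.5), 0.9)
})
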