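test_that("cohort generation is deterministic given (config, seed)", {
  cfg <- tiny_cohort_config()
  a <- simulate_cohort(cfg, seed = 5)
  b <- simulate_cohort(cfg, seed = 5)
  expect_equal(a$reports, b$reports)
  expect_equal(a$truth, b$truth)
  expect_equal(a$genes, b$genes)
  c <- simulate_cohort(cfg, seed = 6)
  expect_false(identical(a$reports$aar[[1]], c$reports$aar[[1]]))

  # byte-identical files on disk
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(a, d1)
  write_cohort(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("expression generation is deterministic and coupled to truth", {
  cfg <- tiny_cohort_config()
  co <- simulate_cohort(cfg, seed = 9)
  e1 <- simulate_expression(co)
  e2 <- simulate_expression(co)
  expect_equal(e1, e2)
  expect_true(all(e1$tpm >= 0))
  # parents only express their own subgenome's genes
  expect_true(all(grepl("_A$", e1$gene_id[e1$line == "aar"])))
  expect_true(all(grepl("_T$", e1$gene_id[e1$line == "ath"])))
})

test_that("planting more windows than the genome holds is an error", {
  expect_error(
    cohort_config(genome_length = 10000L, spacing = 10L,
                  n_planted = c(convergent = 50L, conserved = 0L,
                                persistent_hyper = 0L, asu_hyper = 0L)),
    "capacity"
  )
  expect_error(cohort_config(mu_low = 0.8, mu_high = 0.2), "mu_low")
  expect_error(cohort_config(not_a_field = 1), "Unknown")
})

test_that("planted windows are non-overlapping, on tiles, class-consistent", {
  cfg <- tiny_cohort_config()
  co <- simulate_cohort(cfg, seed = 13)
  planted <- co$truth[co$truth$class != "null", ]
  expect_equal(nrow(planted), sum(cfg$n_planted))
  expect_true(all(planted$start %% cfg$window_size == 0))
  expect_true(all(planted$end - planted$start == cfg$window_size))
  expect_equal(anyDuplicated(planted$start), 0)
  # class-consistent truth means: convergent windows separate A from T in
  # parents and neo-allotetraploids but not in the natural line
  conv <- planted[planted$class == "convergent", ]
  expect_true(all(conv$mu_aar - conv$mu_ath >= 0.5))
  expect_true(all(conv$mu_f1_A - conv$mu_f1_T >= 0.5))
  expect_true(all(abs(conv$mu_asu_A - conv$mu_asu_T) < 0.5))
  cons <- planted[planted$class == "conserved", ]
  expect_true(all(cons$mu_aar - cons$mu_asu_A >= 0.5))
  expect_true(all(cons$mu_aar - cons$mu_f1_A >= 0.5))
  expect_true(all(co$truth[, grep("^mu_", names(co$truth))] >= 0 &
                    co$truth[, grep("^mu_", names(co$truth))] <= 1))
})

test_that("without site noise the per-site probabilities equal the truth means", {
  cfg <- tiny_cohort_config(site_noise_sd = 0)
  co <- simulate_cohort(cfg, seed = 4)
  sites_cg <- co$sites[co$sites$context == "CG", ]
  for (s in c("aar", "asu_A", "f1_T")) {
    mu_col <- co$truth[[paste0("mu_", s)]]
    expect_equal(sites_cg[[s]], mu_col[sites_cg$tile + 1L])
  }
})

test_that("doubling depth shrinks window-level sampling error by ~sqrt(2)", {
  sd_at_depth <- function(depth, seeds = 1:6) {
    cfg <- cohort_config(
      lines = c("aar", "asu"), contexts = "CG", genome_length = 30000L,
      n_planted = c(convergent = 0L, conserved = 0L,
                    persistent_hyper = 0L, asu_hyper = 0L),
      n_null_genes = 0L, mean_depth = depth, site_noise_sd = 0
    )
    resid <- unlist(lapply(seeds, function(s) {
      co <- simulate_cohort(cfg, seed = s)
      rep1 <- co$reports$aar[[1]]
      w <- make_windows(
        dplyr::mutate(rep1, line = "aar", n_total = n_meth + n_unmeth)
      )
      w <- w[w$context == "CG", ]
      mu <- co$truth$mu_aar[w$start %/% 100 + 1]
      w$meth / w$total - mu
    }))
    sqrt(mean(resid^2))
  }
  ratio <- sd_at_depth(10) / sd_at_depth(20)
  expect_gt(ratio, sqrt(2) * 0.85)
  expect_lt(ratio, sqrt(2) * 1.15)
})

test_that("expression effects follow the planted methylation direction", {
  cfg <- tiny_cohort_config(expr_noise_sd = 0.05)
  co <- simulate_cohort(cfg, seed = 21)
  expr <- simulate_expression(co)
  ratios <- expression_ratio(expr, "asu", "aar")
  genes_a <- co$genes[grepl("_A$", co$genes$gene_id), ]
  by_class <- merge(ratios, genes_a[, c("gene_id", "window_class")])
  # hypomethylated-in-Asu genes (conserved trajectory) are upregulated ~ +1
  hypo <- by_class$log2_ratio[by_class$window_class == "conserved"]
  expect_equal(mean(hypo), 1, tolerance = 0.15)
  # methylation gain pushes expression down
  hyper <- by_class$log2_ratio[by_class$window_class == "asu_hyper"]
  expect_lt(mean(hyper), -0.5)
  # null genes are symmetric around 0 within 3 SE
  null <- by_class$log2_ratio[by_class$window_class == "null"]
  se <- sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null)), 3 * se + 0.05)
})
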