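#' Empirical false-discovery proportion under the synthetic null
#'
#' Repeatedly simulates a cohort with zero planted effects, runs the DMR
#' caller on one comparison and records the false-discovery proportion
#' `V / max(R, 1)` per replicate (with no planted effect every discovery
#' is false). Benjamini-Hochberg at level `fdr` controls the expectation
#' of this quantity, so its Monte-Carlo mean should not exceed `fdr` by
#' more than sampling error.
#'
#' @param n_seeds Number of independent cohorts.
#' @param config Cohort configuration; the default simulates only the two
#'   compared lines, CG context, 5,000 windows at depth 20 with no
#'   planted windows.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @param focal,reference Samples compared (defaults `asu_A` vs `aar`).
#' @param context Context tested.
#' @param fdr FDR level.
#' @return A tibble with one row per cohort: `seed`, `n_tested`,
#'   `n_discoveries`, `fdp`.
#' @export
estimate_null_fdp <- function(n_seeds = 200,
                              config = null_cohort_config(),
                              seed = 1L, focal = "asu_A",
                              reference = "aar", context = "CG",
                              fdr = 0.05) {
  purrr::map(seq_len(n_seeds), function(i) {
    cohort <- simulate_cohort(config, seed = seed + i)
    calls <- pair_dmr_calls(cohort, focal, reference, context, fdr)
    R <- sum(calls$is_dmr)
    tibble(seed = seed + i, n_tested = nrow(calls), n_discoveries = R,
           fdp = R / max(R, 1))
  }) %>% bind_rows()
}

#' Null cohort configuration (no planted effects)
#'
#' Two lines (the A parent and the natural allotetraploid), CG context
#' only, 5,000 windows, depth 20, no planted windows — the configuration
#' of the null false-discovery experiment.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @export
null_cohort_config <- function(...) {
  cohort_config(
    lines = c("aar", "asu"),
    contexts = "CG",
    genome_length = 500000L,
    n_planted = c(convergent = 0L, conserved = 0L, persistent_hyper = 0L,
                  asu_hyper = 0L),
    n_null_genes = 0L,
    ...
  )
}

# merge, filter and harmonize just the two samples of a pairwise
# comparison, then call DMRs
pair_dmr_calls <- function(cohort, focal, reference, context, fdr = 0.05) {
  config <- cohort$config
  samples <- cohort_samples(config)
  pick <- function(sample_name) {
    row <- samples[samples$sample == sample_name, , drop = FALSE]
    if (nrow(row) == 0) {
      abort(sprintf("Sample '%s' is not part of this cohort.", sample_name))
    }
    merged <- merge_replicates(cohort$reports[[row$line]])
    rec <- filter_coverage(filter(merged, .data$chrom == row$chrom))
    if (row$subgenome == "T") rec <- map_to_homolog_frame(rec, cohort$blocks)
    rec
  }
  recs <- list(pick(focal), pick(reference))
  names(recs) <- c(focal, reference)
  mat <- harmonize(recs)
  windows <- make_windows(mat, window_size = config$window_size)
  call_dmrs(windows, focal, reference, context, fdr = fdr)
}

#' Recovery of planted trajectory classes
#'
#' Simulates full six-line cohorts with planted convergent and conserved
#' CG windows, runs the complete harmonize / DMR / classification
#' pipeline, and scores the classifier against the planted truth:
#' per-class recall (planted windows recovered) and precision (flagged
#' windows that were planted).
#'
#' @param n_seeds Number of cohorts.
#' @param config Cohort configuration; the default plants 200 convergent
#'   and 200 conserved windows with effect 0.6 at depth 20.
#' @param seed Base seed; cohort `i` uses `seed + i`.
#' @return A tibble with one row per cohort: recall and precision for the
#'   convergent and conserved classes.
#' @export
evaluate_trajectory_recovery <- function(n_seeds = 20,
                                         config = recovery_cohort_config(),
                                         seed = 1L) {
  purrr::map(seq_len(n_seeds), function(i) {
    cohort <- simulate_cohort(config, seed = seed + i)
    harm <- harmonize_cohort(cohort)
    windows <- make_windows(harm$matrix,
                            window_size = config$window_size)
    ctx <- config$planted_context
    avt <- purrr::map(avt_comparisons(),
                      ~ call_dmrs(windows, .x[1], .x[2], ctx))
    vsp <- purrr::map(vsp_comparisons("A"),
                      ~ call_dmrs(windows, .x[1], .x[2], ctx))
    traj <- classify_trajectory(avt, vsp)
    truth <- cohort$truth
    scored <- traj %>%
      mutate(window_id = paste0(.data$chrom, ":", .data$start, "-",
                                .data$end)) %>%
      left_join(select(truth, "window_id", truth_class = "class"),
                by = "window_id")
    score <- function(pred, truth_flag) {
      tp <- sum(pred & truth_flag)
      tibble(
        recall = tp / max(sum(truth_flag), 1),
        precision = if (sum(pred) > 0) tp / sum(pred) else NA_real_
      )
    }
    conv <- score(scored$convergent, scored$truth_class == "convergent")
    cons <- score(scored$conserved_any & scored$hypo_asu,
                  scored$truth_class == "conserved")
    tibble(
      seed = seed + i,
      recall_convergent = conv$recall,
      precision_convergent = conv$precision,
      recall_conserved = cons$recall,
      precision_conserved = cons$precision
    )
  }) %>% bind_rows()
}

#' Planted-recovery cohort configuration
#'
#' Full six-line cohort, CG context only, 200 convergent and 200
#' conserved planted windows (effect |delta mu| = 0.6), depth 20, two
#' replicates.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @export
recovery_cohort_config <- function(...) {
  cohort_config(
    contexts = "CG",
    genome_length = 250000L,
    spacing = 5L,
    n_planted = c(convergent = 200L, conserved = 200L,
                  persistent_hyper = 0L, asu_hyper = 0L),
    n_null_genes = 0L,
    ...
  )
}

#' Direction of the methylation-expression association
#'
#' Simulates a cohort with planted hypo- and hyper-methylation windows in
#' the natural allotetraploid and coupled expression, calls DMRs for the
#' A subgenome vs its parent, links genes within 2 kb, and compares the
#' log2 expression ratios (natural allotetraploid / parent) of hypo- vs
#' hyper-DMR-linked genes with a Mann-Whitney test.
#'
#' @param config Cohort configuration; the default plants 200 hypo
#'   (conserved trajectory) and 200 hyper windows with expression effect
#'   1 on linked genes.
#' @param seed Master seed.
#' @param flank Gene linking distance (default 2000).
#' @return A one-row tibble: group sizes, group means, U statistic, p.
#' @export
evaluate_association_direction <- function(config = association_cohort_config(),
                                           seed = 1L, flank = 2000) {
  cohort <- simulate_cohort(config, seed = seed)
  expression <- simulate_expression(cohort)
  calls <- pair_dmr_calls(cohort, "asu_A", "aar",
                          config$planted_context)
  genes_a <- filter(cohort$genes, grepl("_A$", .data$gene_id))
  links <- genes_near_dmrs(calls, genes_a, flank = flank)
  ratios <- expression_ratio(expression, "asu", "aar",
                             gene_id = unique(genes_a$gene_id))
  linked <- links %>%
    distinct(.data$gene_id, .data$direction) %>%
    inner_join(ratios, by = "gene_id")
  hypo <- filter(linked, .data$direction == "hypo")$log2_ratio
  hyper <- filter(linked, .data$direction == "hyper")$log2_ratio
  test <- compare_groups(hypo, hyper)
  mutate(test,
         mean_log2_hypo = mean(hypo),
         mean_log2_hyper = mean(hyper))
}

#' Association cohort configuration
#'
#' Two lines (A parent and natural allotetraploid), CG context, 200
#' planted hypo (conserved) and 200 hyper windows, one linked gene per
#' planted window, expression effect 1.
#'
#' @param ... Overrides passed to [cohort_config()].
#' @export
association_cohort_config <- function(...) {
  cohort_config(
    lines = c("aar", "asu"),
    contexts = "CG",
    genome_length = 1100000L,
    n_planted = c(convergent = 0L, conserved = 200L,
                  persistent_hyper = 0L, asu_hyper = 200L),
    n_null_genes = 50L,
    ...
  )
}
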