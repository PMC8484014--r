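#' Harmonize a cohort into one analysis-ready site matrix
#'
#' Runs the site-level stages for every sample of a cohort: replicate
#' merging, the minimum-read filter, projection of the T-subgenome
#' samples into the A-subgenome frame through the homology map, the joint
#' shared-site intersection across all samples, and the conserved-region
#' filter. Counts at every stage are logged.
#'
#' @param cohort A `methyl_cohort` from [simulate_cohort()], or a list
#'   with the same `reports`/`blocks`/`config` fields built from files.
#' @param min_reads Minimum merged reads per cytosine per sample
#'   (default 3).
#' @param min_block_len,min_block_score Conserved-region thresholds
#'   (defaults 1000 and 1000).
#' @return A list with `matrix` (the harmonized site matrix, all samples
#'   in A-frame coordinates) and `log` (a tibble of per-stage site
#'   counts).
#' @export
harmonize_cohort <- function(cohort, min_reads = 3, min_block_len = 1000,
                             min_block_score = 1000) {
  config <- cohort$config
  samples <- cohort_samples(config)
  log <- list()
  per_sample <- list()
  for (ln in names(cohort$reports)) {
    merged <- merge_replicates(cohort$reports[[ln]])
    covered <- filter_coverage(merged, min_reads = min_reads)
    log[[length(log) + 1]] <- tibble(
      line = ln, stage = "merged", n_sites = nrow(merged)
    )
    log[[length(log) + 1]] <- tibble(
      line = ln, stage = sprintf("coverage>=%d", min_reads),
      n_sites = nrow(covered)
    )
    smp <- samples[samples$line == ln, , drop = FALSE]
    for (j in seq_len(nrow(smp))) {
      rec <- filter(covered, .data$chrom == smp$chrom[j])
      if (smp$subgenome[j] == "T") {
        rec <- map_to_homolog_frame(rec, cohort$blocks)
      }
      per_sample[[smp$sample[j]]] <- rec
    }
  }
  mat <- harmonize(per_sample)
  log[[length(log) + 1]] <- tibble(
    line = "all", stage = "shared_sites",
    n_sites = nrow(distinct(mat, .data$chrom, .data$pos, .data$strand))
  )
  mat <- filter_conserved_regions(mat, cohort$blocks,
                                  min_len = min_block_len,
                                  min_score = min_block_score)
  log[[length(log) + 1]] <- tibble(
    line = "all", stage = "conserved_regions",
    n_sites = nrow(distinct(mat, .data$chrom, .data$pos, .data$strand))
  )
  list(matrix = mat, log = bind_rows(log))
}

# the standard comparisons of the six-line design, in the A frame
avt_comparisons <- function() {
  list(parents = c("aar", "ath"), f1 = c("f1_A", "f1_T"),
       a733 = c("a733_A", "a733_T"), a738 = c("a738_A", "a738_T"),
       asu = c("asu_A", "asu_T"))
}

vsp_comparisons <- function(side = c("A", "T")) {
  side <- match.arg(side)
  if (side == "A") {
    list(f1 = c("f1_A", "aar"), a733 = c("a733_A", "aar"),
         a738 = c("a738_A", "aar"), asu = c("asu_A", "aar"))
  } else {
    list(f1 = c("f1_T", "ath"), a733 = c("a733_T", "ath"),
         a738 = c("a738_T", "ath"), asu = c("asu_T", "ath"))
  }
}

#' Run the full methylome-trajectory analysis on a synthetic cohort
#'
#' End-to-end orchestration: simulate (or accept) a cohort, harmonize
#' sites, call context-specific DMRs for the subgenome-vs-subgenome
#' (A-vs-T) and subgenome-vs-parent comparisons, classify trajectories,
#' link DMRs to genes and expression, and assemble a summary report. All
#' stages are deterministic given `(config, seed)`.
#'
#' @param config A [cohort_config()] describing the six-line cohort; all
#'   six lines are required.
#' @param seed Master seed.
#' @param contexts Contexts to analyse (default: the planted context).
#' @param fdr FDR threshold for DMR calls.
#' @param flank Gene-DMR linking distance in bp (default 2000).
#' @param out_dir Optional directory; when given, DMR BEDs, the
#'   trajectory table, the stage log, the resolved configuration and the
#'   summary are written there.
#' @param cohort Optionally a pre-built `methyl_cohort` (then `config`
#'   and `seed` are taken from it).
#' @return An object of class `allomethyl_run`: a list with `cohort`,
#'   `expression`, `matrix`, `log`, `dmr` (named calls per comparison and
#'   context), `trajectory`, `conserved_fractions`, `association` and
#'   `summary`.
#' @export
run_cohort_analysis <- function(config = cohort_config(), seed = 1L,
                                contexts = NULL, fdr = 0.05, flank = 2000,
                                out_dir = NULL, cohort = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config, seed)
  } else {
    config <- cohort$config
    seed <- cohort$seed
  }
  if (!all(c("ath", "aar", "f1", "a733", "a738", "asu") %in% config$lines)) {
    abort("The full analysis needs all six lines; see `cohort_config()`.")
  }
  if (is.null(contexts)) contexts <- config$planted_context
  expression <- simulate_expression(cohort)
  harm <- harmonize_cohort(cohort)
  windows <- make_windows(harm$matrix, window_size = config$window_size)

  dmr <- list()
  trajectory <- list()
  cons_frac <- list()
  for (ctx in contexts) {
    avt <- purrr::map(avt_comparisons(), function(cmp) {
      call_dmrs(windows, cmp[1], cmp[2], ctx, fdr = fdr)
    })
    vsp <- purrr::map(vsp_comparisons("A"), function(cmp) {
      call_dmrs(windows, cmp[1], cmp[2], ctx, fdr = fdr)
    })
    dmr[[ctx]] <- list(avt = avt, vsp_a = vsp)
    trajectory[[ctx]] <- classify_trajectory(avt, vsp)
    cons_frac[[ctx]] <- classify_conserved(vsp) %>% conserved_fractions()
  }

  assoc <- association_summary(cohort, expression, dmr, contexts[1],
                               flank = flank)

  summary <- build_summary(dmr, trajectory, cons_frac, assoc)
  run <- structure(
    list(cohort = cohort, expression = expression, matrix = harm$matrix,
         log = harm$log, dmr = dmr, trajectory = trajectory,
         conserved_fractions = cons_frac, association = assoc,
         summary = summary, config = config, seed = seed),
    class = "allomethyl_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# DMR-gene-expression association for the natural allotetraploid
# (A subgenome vs its parent), in one context
association_summary <- function(cohort, expression, dmr, ctx,
                                flank = 2000) {
  calls <- dmr[[ctx]]$vsp_a$asu
  genes_a <- filter(cohort$genes, grepl("_A$", .data$gene_id))
  links <- genes_near_dmrs(calls, genes_a, flank = flank)
  ratios <- expression_ratio(expression, "asu", "aar",
                             gene_id = unique(genes_a$gene_id))
  linked <- links %>%
    distinct(.data$gene_id, .data$direction) %>%
    inner_join(ratios, by = "gene_id")
  hypo <- filter(linked, .data$direction == "hypo")$log2_ratio
  hyper <- filter(linked, .data$direction == "hyper")$log2_ratio
  test <- if (length(hypo) > 0 && length(hyper) > 0) {
    compare_groups(hypo, hyper)
  } else {
    tibble(n1 = length(hypo), n2 = length(hyper),
           statistic = NA_real_, p = NA_real_)
  }
  list(
    links = links,
    ratio_test = mutate(test,
                        mean_log2_hypo = mean(hypo),
                        mean_log2_hyper = mean(hyper))
  )
}

build_summary <- function(dmr, trajectory, cons_frac, assoc) {
  dmr_counts <- purrr::imap(dmr, function(by_ctx, ctx) {
    avt <- bind_rows(purrr::imap(
      by_ctx$avt,
      ~ mutate(glance(.x), comparison = "A_vs_T", generation = .y)
    ))
    vsp <- bind_rows(purrr::imap(
      by_ctx$vsp_a,
      ~ mutate(glance(.x), comparison = "A_vs_parent", generation = .y)
    ))
    bind_rows(avt, vsp)
  }) %>% bind_rows()
  traj_counts <- purrr::imap(trajectory, function(tr, ctx) {
    tr %>% count(.data$class) %>% mutate(context = ctx)
  }) %>% bind_rows()
  conv_pct <- purrr::imap(trajectory, function(tr, ctx) {
    parent_hyper <- filter(tr, !is.na(.data$hyper_class))
    tibble(
      context = ctx,
      n_parent_hyper = nrow(parent_hyper),
      n_convergent = sum(parent_hyper$hyper_class == "convergent"),
      percent_convergent = if (nrow(parent_hyper) > 0) {
        percentage(sum(parent_hyper$hyper_class == "convergent"),
                   nrow(parent_hyper))
      } else {
        NA_real_
      }
    )
  }) %>% bind_rows()
  list(
    dmr_counts = dmr_counts,
    trajectory_counts = traj_counts,
    convergent_fraction = conv_pct,
    conserved_fractions = bind_rows(purrr::imap(
      cons_frac, ~ mutate(.x, context = .y)
    )),
    association = assoc$ratio_test
  )
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (ctx in names(run$dmr)) {
    for (grp in names(run$dmr[[ctx]])) {
      for (nm in names(run$dmr[[ctx]][[grp]])) {
        write_dmr_bed(
          run$dmr[[ctx]][[grp]][[nm]],
          file.path(out_dir, sprintf("dmr_%s_%s_%s.bed", ctx, grp, nm))
        )
      }
    }
    readr::write_tsv(run$trajectory[[ctx]],
                     file.path(out_dir, sprintf("trajectory_%s.tsv", ctx)),
                     progress = FALSE)
  }
  readr::write_tsv(run$log, file.path(out_dir, "stage_log.tsv"),
                   progress = FALSE)
  resolved <- run$config
  class(resolved) <- NULL
  jsonlite::write_json(
    list(config = resolved, seed = run$seed),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(run$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.allomethyl_run <- function(x, ...) {
  cat("# Methylome trajectory analysis\n")
  print(x$summary$dmr_counts)
  cat("\n# Trajectory classes\n")
  print(x$summary$trajectory_counts)
  invisible(x)
}

#' @rdname run_cohort_analysis
#' @param x An `allomethyl_run`.
#' @param ... Unused.
#' @method tidy allomethyl_run
#' @export
tidy.allomethyl_run <- function(x, ...) {
  x$summary$dmr_counts
}

#' @rdname run_cohort_analysis
#' @method glance allomethyl_run
#' @export
glance.allomethyl_run <- function(x, ...) {
  conv <- x$summary$convergent_fraction[1, ]
  tibble(
    n_lines = length(x$config$lines),
    n_shared_sites = x$log$n_sites[x$log$stage == "shared_sites"][1],
    n_tested_windows = nrow(x$trajectory[[1]]),
    n_dmr_total = sum(x$summary$dmr_counts$n_dmr),
    percent_convergent = conv$percent_convergent,
    association_p = x$summary$association$p[1],
    seed = x$seed
  )
}
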