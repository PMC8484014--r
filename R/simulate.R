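#' Configuration for a synthetic allopolyploid methylome cohort
#'
#' Builds the configuration of the six-line synthetic cohort (the two
#' parents `ath` and `aar`, the `f1` hybrid, the resynthesized
#' allotetraploids `a733` and `a738`, and the natural allotetraploid
#' `asu`) on a pair of homologous subgenome chromosomes. Planted 100-bp
#' windows follow one of four trajectory classes:
#'
#' * `convergent` — A hypermethylated relative to T in parents, F1 and
#'   both resynthesized lines; collapsed to the T level in the natural
#'   line.
#' * `conserved` — hypomethylated (vs the A parent) in F1, both
#'   resynthesized lines and the natural line.
#' * `persistent_hyper` — A hypermethylated through the natural line.
#' * `asu_hyper` — methylation gained in the natural line only.
#'
#' All remaining windows are `null` (a shared beta-distributed baseline).
#'
#' @param ... Overrides for the defaults listed below.
#' @return A named list of class `cohort_config`.
#'
#' @section Defaults:
#' `genome_length` 750000 bp per subgenome; `window_size` 100;
#' `contexts` CG/CHG/CHH with per-window cytosine counts 6/6/20 and
#' baseline Beta shapes (0.6, 1.9), (0.4, 3.6), (0.3, 9.7); planted
#' classes (CG context) 60 convergent, 60 conserved, 30 persistent_hyper,
#' 60 asu_hyper, spaced 26 windows apart; `mu_low` 0.15 / `mu_high` 0.75
#' (planted effect 0.6); site noise sd 0.05; negative-binomial depth
#' (mean 20, dispersion 5) with 2 replicates; 500-bp genes with 3
#' expression replicates, log2 expression effect 1 and replicate noise sd
#' 0.25.
#' @export
cohort_config <- function(...) {
  config <- list(
    lines = c("ath", "aar", "f1", "a733", "a738", "asu"),
    chrom_a = "sA1",
    chrom_t = "sT1",
    genome_length = 750000L,
    window_size = 100L,
    contexts = c("CG", "CHG", "CHH"),
    density = c(CG = 6L, CHG = 6L, CHH = 20L),
    beta_shape = list(CG = c(0.6, 1.9), CHG = c(0.4, 3.6),
                      CHH = c(0.3, 9.7)),
    n_planted = c(convergent = 60L, conserved = 60L,
                  persistent_hyper = 30L, asu_hyper = 60L),
    planted_context = "CG",
    mu_low = 0.15,
    mu_high = 0.75,
    site_noise_sd = 0.05,
    mean_depth = 20,
    dispersion = 5,
    replicates = 2L,
    spacing = 26L,
    gene_length = 500L,
    n_null_genes = 60L,
    expr_replicates = 3L,
    expr_effect = 1,
    expr_noise_sd = 0.25,
    expr_base_mean = 5,
    expr_base_sd = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(config))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown cohort_config field(s): %s.",
                  paste(unknown, collapse = ", ")))
  }
  config[names(overrides)] <- overrides
  validate_cohort_config(config)
  structure(config, class = "cohort_config")
}

validate_cohort_config <- function(config) {
  check_context(config$contexts)
  check_context(config$planted_context)
  if (!config$planted_context %in% config$contexts) {
    abort("`planted_context` must be one of `contexts`.")
  }
  if (config$mean_depth <= 0) abort("`mean_depth` must be > 0.")
  if (config$replicates < 1) abort("`replicates` must be >= 1.")
  bad_class <- setdiff(names(config$n_planted),
                       c("convergent", "conserved", "persistent_hyper",
                         "asu_hyper"))
  if (length(bad_class) > 0) {
    abort(sprintf("Unknown planted class(es): %s.",
                  paste(bad_class, collapse = ", ")))
  }
  if (config$mu_low < 0 || config$mu_high > 1 ||
      config$mu_low >= config$mu_high) {
    abort("Need 0 <= mu_low < mu_high <= 1.")
  }
  total_dens <- sum(vapply(config$contexts,
                           function(ctx) config$density[[ctx]], integer(1)))
  if (total_dens > config$window_size) {
    abort("Per-window cytosine counts exceed the window size.")
  }
  n_tiles <- config$genome_length %/% config$window_size
  capacity <- length(seq.int(1L, n_tiles, by = config$spacing))
  if (sum(config$n_planted) > capacity) {
    abort(sprintf(
      "Planted windows (%d) exceed genome capacity (%d slots at spacing %d).",
      sum(config$n_planted), capacity, config$spacing
    ))
  }
  invisible(config)
}

# sample names and the chromosome each lives on, for the configured lines
cohort_samples <- function(config) {
  per_line <- list(
    ath = c(ath = "T"), aar = c(aar = "A"),
    f1 = c(f1_A = "A", f1_T = "T"),
    a733 = c(a733_A = "A", a733_T = "T"),
    a738 = c(a738_A = "A", a738_T = "T"),
    asu = c(asu_A = "A", asu_T = "T")
  )
  sub <- unlist(unname(per_line[config$lines]))
  tibble(
    sample = names(sub),
    subgenome = unname(sub),
    chrom = ifelse(sub == "A", config$chrom_a, config$chrom_t),
    line = rep(config$lines, times = lengths(per_line[config$lines]))
  )
}

# planted per-sample methylation means; samples not simulated still get a
# truth column so the table describes the full design
planted_mu <- function(class, config) {
  H <- config$mu_high
  L <- config$mu_low
  a_side <- switch(
    class,
    convergent = c(aar = H, f1_A = H, a733_A = H, a738_A = H, asu_A = L),
    conserved = c(aar = H, f1_A = L, a733_A = L, a738_A = L, asu_A = L),
    persistent_hyper = c(aar = H, f1_A = H, a733_A = H, a738_A = H,
                         asu_A = H),
    asu_hyper = c(aar = L, f1_A = L, a733_A = L, a738_A = L, asu_A = H),
    abort(sprintf("Class '%s' cannot be planted.", class))
  )
  t_side <- c(ath = L, f1_T = L, a733_T = L, a738_T = L, asu_T = L)
  c(a_side, t_side)
}

.ALL_SAMPLES <- c("ath", "aar", "f1_A", "f1_T", "a733_A", "a733_T",
                  "a738_A", "a738_T", "asu_A", "asu_T")

#' Simulate a synthetic allopolyploid methylome cohort
#'
#' Generates per-cytosine bisulfite reports for every configured line and
#' replicate, the gene models, the A-T homology map and the truth table
#' of planted trajectory windows. Homologous cytosines sit at identical
#' positions on the two subgenome chromosomes (they are "conserved
#' cytosines" by construction) and carry one shared site-level propensity,
#' so differences between samples at null windows are pure sampling noise.
#'
#' Per cytosine and sample, the methylation probability is the window mean
#' of that sample's trajectory plus a site effect drawn once per
#' homologous site (`Normal(0, site_noise_sd)`, clipped to `[0, 1]`,
#' shared across samples and replicates). Read depth per site, sample and
#' replicate is negative binomial (`mean_depth`, `dispersion`); methylated
#' counts are binomial.
#'
#' @param config A [cohort_config()].
#' @param seed Master seed; named child streams (placement, baseline,
#'   counts, expression) are derived from it, so equal `(config, seed)`
#'   give identical cohorts.
#' @return A list of class `methyl_cohort`: `reports` (nested list,
#'   `reports[[line]][[replicate]]` is a cytosine tibble), `genes`,
#'   `blocks`, `truth`, `sites` (per-site truth probabilities per sample),
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1L) {
  validate_cohort_config(config)
  ws <- config$window_size
  n_tiles <- config$genome_length %/% ws
  samples <- cohort_samples(config)

  # --- placement stream: planted tiles, site positions, strands, genes
  set.seed(child_seed(seed, "placement"))
  slots <- seq.int(0L, n_tiles - 1L, by = config$spacing)
  n_plant <- sum(config$n_planted)
  planted_tiles <- sort(slots[sample.int(length(slots), n_plant)])
  classes <- sample(rep(names(config$n_planted), times = config$n_planted))
  free_slots <- setdiff(slots, planted_tiles)
  null_gene_tiles <- sort(free_slots[sample.int(
    length(free_slots), min(config$n_null_genes, length(free_slots))
  )])
  # one cytosine has one context: draw all per-tile offsets jointly
  # without replacement, then split them among the contexts
  dens_vec <- vapply(config$contexts, function(ctx) config$density[[ctx]],
                     integer(1))
  total_dens <- sum(dens_vec)
  offs <- vapply(seq_len(n_tiles),
                 function(i) sample.int(ws, total_dens) - 1L,
                 integer(total_dens))
  site_layout <- tibble(
    context = rep(rep(config$contexts, times = dens_vec), n_tiles),
    tile = rep(seq_len(n_tiles) - 1L, each = total_dens),
    pos = as.integer(as.vector(offs)) +
      rep((seq_len(n_tiles) - 1L) * ws, each = total_dens) + 1L,
    strand = sample(c("+", "-"), n_tiles * total_dens, replace = TRUE)
  )

  # --- baseline stream: per-window baseline and per-site propensity noise
  set.seed(child_seed(seed, "baseline"))
  mu <- purrr::map(config$contexts, function(ctx) {
    sh <- config$beta_shape[[ctx]]
    base <- rbeta(n_tiles, sh[1], sh[2])
    m <- matrix(base, nrow = n_tiles, ncol = length(.ALL_SAMPLES),
                dimnames = list(NULL, .ALL_SAMPLES))
    m
  })
  names(mu) <- config$contexts
  for (i in seq_along(planted_tiles)) {
    prof <- planted_mu(classes[i], config)
    mu[[config$planted_context]][planted_tiles[i] + 1L, names(prof)] <- prof
  }
  site_layout$eps <- rnorm(nrow(site_layout), 0, config$site_noise_sd)

  # per-site truth probability per sample (shared by both subgenome
  # chromosomes at homologous positions)
  prob <- matrix(NA_real_, nrow = nrow(site_layout),
                 ncol = length(.ALL_SAMPLES),
                 dimnames = list(NULL, .ALL_SAMPLES))
  for (s in .ALL_SAMPLES) {
    mu_site <- numeric(nrow(site_layout))
    for (ctx in config$contexts) {
      rows <- site_layout$context == ctx
      mu_site[rows] <- mu[[ctx]][site_layout$tile[rows] + 1L, s]
    }
    prob[, s] <- pmin(1, pmax(0, mu_site + site_layout$eps))
  }

  # --- truth table for the planted context
  truth <- tibble(
    chrom = config$chrom_a,
    start = (seq_len(n_tiles) - 1L) * ws,
    end = (seq_len(n_tiles) - 1L) * ws + ws,
    context = config$planted_context,
    class = "null"
  )
  truth$class[planted_tiles + 1L] <- classes
  truth$window_id <- paste0(truth$chrom, ":", truth$start, "-", truth$end)
  mu_ctx <- mu[[config$planted_context]]
  for (s in .ALL_SAMPLES) truth[[paste0("mu_", s)]] <- mu_ctx[, s]
  truth <- select(truth, "window_id", "chrom", "start", "end", "context",
                  "class", dplyr::starts_with("mu_"))

  # --- counts stream: depths and methylated reads per sample x replicate
  set.seed(child_seed(seed, "counts"))
  n_sites <- nrow(site_layout)
  reports <- purrr::map(config$lines, function(ln) {
    smp <- samples[samples$line == ln, , drop = FALSE]
    purrr::map(seq_len(config$replicates), function(rep_i) {
      purrr::map(seq_len(nrow(smp)), function(j) {
        depth <- rnbinom(n_sites, mu = config$mean_depth,
                         size = config$dispersion)
        n_meth <- rbinom(n_sites, depth, prob[, smp$sample[j]])
        tibble(
          chrom = smp$chrom[j],
          pos = site_layout$pos,
          strand = site_layout$strand,
          context = site_layout$context,
          n_meth = n_meth,
          n_unmeth = depth - n_meth
        )
      }) %>%
        bind_rows() %>%
        arrange(.data$chrom, .data$pos, .data$strand)
    })
  })
  names(reports) <- config$lines

  # --- genes and homology map
  gene_tiles <- c(planted_tiles, null_gene_tiles)
  gene_class <- c(classes, rep("null", length(null_gene_tiles)))
  ord <- order(gene_tiles)
  gene_tiles <- gene_tiles[ord]
  gene_class <- gene_class[ord]
  ids <- sprintf("g%04d", seq_along(gene_tiles))
  genes <- bind_rows(
    tibble(
      gene_id = paste0(ids, "_A"), chrom = config$chrom_a,
      start = gene_tiles * ws,
      end = gene_tiles * ws + config$gene_length,
      strand = "+", homolog_id = paste0(ids, "_T"),
      window_class = gene_class
    ),
    tibble(
      gene_id = paste0(ids, "_T"), chrom = config$chrom_t,
      start = gene_tiles * ws,
      end = gene_tiles * ws + config$gene_length,
      strand = "+", homolog_id = paste0(ids, "_A"),
      window_class = gene_class
    )
  )
  blocks <- tibble(
    chrom_a = config$chrom_a, start_a = 0L,
    end_a = as.integer(config$genome_length),
    chrom_b = config$chrom_t, start_b = 0L,
    end_b = as.integer(config$genome_length),
    score = 10000, strand_rel = "+"
  )

  sites <- bind_cols(
    site_layout[, c("context", "tile", "pos", "strand")],
    as_tibble(prob)
  )
  structure(
    list(reports = reports, genes = genes, blocks = blocks, truth = truth,
         sites = sites, config = config, seed = seed),
    class = "methyl_cohort"
  )
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat(sprintf(
    "# Synthetic methylome cohort: %d lines x %d replicates, %d kb/subgenome, %d planted windows (seed %d)\n",
    length(x$config$lines), x$config$replicates,
    x$config$genome_length %/% 1000, sum(x$truth$class != "null"), x$seed
  ))
  invisible(x)
}

#' Simulate expression coupled to planted methylation trajectories
#'
#' Generates a gene x line x replicate TPM table for the cohort's genes.
#' Each gene has a log2 baseline shared across lines; in lines where the
#' gene's subgenome is hypomethylated relative to the parent at the
#' planted window, the log2 expression is raised in proportion to the
#' methylation loss (negative methylation-expression coupling), and
#' lowered where methylation was gained. Replicate noise is log-normal.
#' Parents only express the genes of their own subgenome.
#'
#' @param cohort A `methyl_cohort` from [simulate_cohort()].
#' @param seed Seed for the expression stream; defaults to the cohort's
#'   master seed (child stream "expression").
#' @return An expression tibble `gene_id`, `line`, `replicate`, `tpm`.
#' @export
simulate_expression <- function(cohort, seed = cohort$seed) {
  config <- cohort$config
  genes <- cohort$genes
  set.seed(child_seed(seed, "expression"))
  base <- setNames(rnorm(nrow(genes), config$expr_base_mean,
                         config$expr_base_sd), genes$gene_id)

  # methylation change of the gene's subgenome relative to its parent,
  # scaled to the planted effect size
  delta_scale <- config$mu_high - config$mu_low
  truth <- cohort$truth
  tile_of <- (genes$start %/% config$window_size) + 1L
  effect_for <- function(line) {
    vapply(seq_len(nrow(genes)), function(i) {
      cls <- genes$window_class[i]
      if (cls == "null") return(0)
      is_a <- grepl("_A$", genes$gene_id[i])
      parent_col <- if (is_a) "mu_aar" else "mu_ath"
      line_col <- if (line %in% c("ath", "aar")) {
        parent_col
      } else {
        paste0("mu_", line, if (is_a) "_A" else "_T")
      }
      mu_parent <- truth[[parent_col]][tile_of[i]]
      mu_line <- truth[[line_col]][tile_of[i]]
      config$expr_effect * (mu_parent - mu_line) / delta_scale
    }, numeric(1))
  }

  rows <- purrr::map(config$lines, function(ln) {
    sub_ok <- if (ln == "ath") {
      grepl("_T$", genes$gene_id)
    } else if (ln == "aar") {
      grepl("_A$", genes$gene_id)
    } else {
      rep(TRUE, nrow(genes))
    }
    eff <- effect_for(ln)
    purrr::map(seq_len(config$expr_replicates), function(rep_i) {
      lg <- base[genes$gene_id[sub_ok]] + eff[sub_ok] +
        rnorm(sum(sub_ok), 0, config$expr_noise_sd)
      tibble(gene_id = genes$gene_id[sub_ok], line = ln,
             replicate = as.integer(rep_i), tpm = 2^lg)
    }) %>% bind_rows()
  }) %>% bind_rows()
  arrange(rows, .data$gene_id, .data$line, .data$replicate)
}

#' Write a synthetic cohort to disk
#'
#' Emits exactly the formats the readers consume: one Bismark-style
#' cytosine report per line and replicate (`<line>_rep<k>.cov.tsv`),
#' `genes.bed`, `homology.tsv`, `truth.tsv` and, when supplied,
#' `expression.tsv`.
#'
#' @param cohort A `methyl_cohort`.
#' @param dir Output directory (created if needed).
#' @param expression Optional expression tibble from
#'   [simulate_expression()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, expression = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (ln in names(cohort$reports)) {
    for (k in seq_along(cohort$reports[[ln]])) {
      write_cytosine_report(
        cohort$reports[[ln]][[k]],
        file.path(dir, sprintf("%s_rep%d.cov.tsv", ln, k))
      )
    }
  }
  write_genes_bed(cohort$genes, file.path(dir, "genes.bed"))
  write_homology_map(cohort$blocks, file.path(dir, "homology.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  if (!is.null(expression)) {
    readr::write_tsv(expression, file.path(dir, "expression.tsv"),
                     progress = FALSE)
  }
  invisible(dir)
}
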