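#' Link genes to DMRs within a flanking distance
#'
#' A gene is linked to a DMR when the DMR interval intersects the gene
#' body extended by `flank` bp on both sides (default 2 kb), all in
#' 0-based half-open coordinates. Each (gene, DMR) pair yields one link
#' with the relation (`body`, `flank5`, `flank3`, strand-aware) and the
#' distance from the nearest gene edge (0 for body overlaps).
#'
#' @param dmrs A `dmr_calls` tibble (its `is_dmr` rows are used) or any
#'   tibble with `chrom`, `start`, `end`.
#' @param genes Gene tibble from [read_genes()].
#' @param flank Flanking distance in bp (default 2000, must be >= 0).
#' @return A tibble with `gene_id`, `chrom`, `start`, `end` (the DMR),
#'   `direction` (if present), `relation` and `distance`.
#' @export
genes_near_dmrs <- function(dmrs, genes, flank = 2000) {
  if (flank < 0) abort("`flank` must be non-negative.")
  dmrs <- as_tibble(dmrs)
  if ("is_dmr" %in% names(dmrs)) dmrs <- filter(dmrs, .data$is_dmr)
  out_cols <- c("gene_id", "chrom", "start", "end",
                intersect("direction", names(dmrs)),
                "relation", "distance")
  if (nrow(dmrs) == 0 || nrow(genes) == 0) {
    empty <- tibble(
      gene_id = character(), chrom = character(), start = integer(),
      end = integer(), direction = character(), relation = character(),
      distance = integer()
    )
    return(empty[, out_cols])
  }
  links <- purrr::map(unique(genes$chrom), function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    d <- dmrs[dmrs$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = d$start + 1L, end = d$end),
      IRanges::IRanges(start = g$start + 1L - flank, end = g$end + flank)
    )
    if (length(hits) == 0) return(NULL)
    di <- S4Vectors::queryHits(hits)
    gi <- S4Vectors::subjectHits(hits)
    res <- d[di, , drop = FALSE]
    res$gene_id <- g$gene_id[gi]
    gs <- g$start[gi]
    ge <- g$end[gi]
    gstrand <- g$strand[gi]
    body <- res$start < ge & res$end > gs
    left <- res$end <= gs # DMR entirely before the gene start
    dist <- ifelse(body, 0L, ifelse(left, gs - res$end + 1L,
                                    res$start - ge + 1L))
    res$relation <- ifelse(
      body, "body",
      ifelse(xor(left, gstrand == "-"), "flank5", "flank3")
    )
    res$distance <- as.integer(dist)
    res
  }) %>% bind_rows()
  if (nrow(links) == 0) {
    return(genes_near_dmrs(dmrs[0, , drop = FALSE], genes, flank))
  }
  links %>%
    arrange(.data$gene_id, .data$chrom, .data$start) %>%
    select(all_of(out_cols))
}

#' Gene-level weighted methylation
#'
#' Pools a harmonized site matrix over each gene's cytosines of one
#' context and returns the weighted methylation level per gene per sample.
#' `region = "body"` uses the gene interval; `"flank5"`/`"flank3"` use the
#' strand-aware flanking window of `flank` bp.
#'
#' @param matrix Site matrix from [harmonize()].
#' @param genes Gene tibble from [read_genes()].
#' @param context Methylation context (default `"CG"`).
#' @param region `"body"`, `"flank5"` or `"flank3"`.
#' @param flank Flank width in bp used for the flank regions.
#' @return A tibble `gene_id`, `line`, `n_sites`, `meth`, `total`, `m`;
#'   genes with no covered cytosine in a sample are absent (flagged by the
#'   caller via join).
#' @export
gene_methylation <- function(matrix, genes, context = "CG",
                             region = c("body", "flank5", "flank3"),
                             flank = 2000) {
  region <- match.arg(region)
  check_context(context)
  m <- filter(matrix, .data$context == .env$context)
  iv <- switch(
    region,
    body = tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                  start = genes$start, end = genes$end),
    flank5 = tibble(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = ifelse(genes$strand == "-", genes$end, genes$start - flank),
      end = ifelse(genes$strand == "-", genes$end + flank, genes$start)
    ),
    flank3 = tibble(
      gene_id = genes$gene_id, chrom = genes$chrom,
      start = ifelse(genes$strand == "-", genes$start - flank, genes$end),
      end = ifelse(genes$strand == "-", genes$start, genes$end + flank)
    )
  )
  iv$start <- pmax(0L, as.integer(iv$start))
  pieces <- purrr::map(unique(iv$chrom), function(ch) {
    g <- iv[iv$chrom == ch, , drop = FALSE]
    s <- m[m$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0 || nrow(g) == 0) return(NULL)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = s$pos, width = 1L),
      IRanges::IRanges(start = g$start + 1L, end = g$end)
    )
    if (length(hits) == 0) return(NULL)
    s[S4Vectors::queryHits(hits), , drop = FALSE] %>%
      mutate(gene_id = g$gene_id[S4Vectors::subjectHits(hits)])
  }) %>% bind_rows()
  if (nrow(pieces) == 0) {
    return(tibble(gene_id = character(), line = character(),
                  n_sites = integer(), meth = integer(), total = integer(),
                  m = double()))
  }
  pieces %>%
    group_by(.data$gene_id, .data$line) %>%
    summarise(
      n_sites = dplyr::n(),
      meth = sum(.data$n_meth), total = sum(.data$n_total),
      .groups = "drop"
    ) %>%
    mutate(m = weighted_methylation(.data$meth, .data$total))
}

#' Log2 expression ratio between two lines
#'
#' `log2((mean TPM in line_num + pc) / (mean TPM in line_den + pc))` per
#' gene, replicate means taken first. The pseudocount guards zero
#' expression (two silent genes get ratio 0).
#'
#' @param expr Expression tibble (`gene_id`, `line`, `replicate`, `tpm`).
#' @param line_num,line_den Line names for numerator and denominator.
#' @param gene_id Optional gene subset; an unknown gene is an error.
#' @param pseudocount Added to both means before the ratio (default 1).
#' @return A tibble `gene_id`, `mean_num`, `mean_den`, `log2_ratio`.
#' @export
expression_ratio <- function(expr, line_num, line_den, gene_id = NULL,
                             pseudocount = 1) {
  if (!is.null(gene_id)) {
    missing <- setdiff(gene_id, expr$gene_id)
    if (length(missing) > 0) {
      abort(sprintf("Gene(s) absent from the expression table: %s.",
                    paste(head(missing, 3), collapse = ", ")))
    }
    expr <- filter(expr, .data$gene_id %in% .env$gene_id)
  }
  means <- expr %>%
    filter(.data$line %in% c(line_num, line_den)) %>%
    group_by(.data$gene_id, .data$line) %>%
    summarise(mean_tpm = mean(.data$tpm), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "line", values_from = "mean_tpm")
  for (l in c(line_num, line_den)) {
    if (!l %in% names(means)) {
      abort(sprintf("No expression values for line '%s'.", l))
    }
  }
  tibble(
    gene_id = means$gene_id,
    mean_num = means[[line_num]],
    mean_den = means[[line_den]],
    log2_ratio = log2((means[[line_num]] + pseudocount) /
                        (means[[line_den]] + pseudocount))
  )
}

#' Mann-Whitney comparison of two ratio groups
#'
#' Two-sided Mann-Whitney U test (exact for small samples without ties,
#' normal approximation with tie correction otherwise, as implemented by
#' [stats::wilcox.test()]).
#'
#' @param ratios_group1,ratios_group2 Numeric vectors (each non-empty).
#' @return A one-row tibble `n1`, `n2`, `statistic` (U for group 1), `p`.
#' @export
compare_groups <- function(ratios_group1, ratios_group2) {
  if (length(ratios_group1) == 0 || length(ratios_group2) == 0) {
    abort("Both groups must be non-empty.")
  }
  wt <- suppressWarnings(
    wilcox.test(ratios_group1, ratios_group2, alternative = "two.sided")
  )
  tibble(
    n1 = length(ratios_group1), n2 = length(ratios_group2),
    statistic = unname(wt$statistic), p = wt$p.value
  )
}

#' Per-gene methylation-expression correlation
#'
#' Correlates one gene's methylation level with its expression across
#' lines (e.g. the five allotetraploid-relevant lines). Requires at least
#' 3 paired values; returns `NA` (flagged) when either vector has zero
#' variance.
#'
#' @param methylation,expression Paired numeric vectors across lines.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble `n`, `r`, `degenerate`.
#' @export
methylation_expression_correlation <- function(methylation, expression,
                                               method = c("pearson",
                                                          "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(methylation, expression)
  x <- methylation[ok]
  y <- expression[ok]
  if (length(x) < 3) {
    abort("Need at least 3 paired (methylation, expression) values.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble(n = length(x), r = NA_real_, degenerate = TRUE))
  }
  tibble(n = length(x), r = cor(x, y, method = method), degenerate = FALSE)
}

#' Homolog-pair methylation and expression convergence
#'
#' Among homolog pairs that were differentially methylated between the two
#' parents (|m_Aar - m_Ath| at or above `meth_threshold`) but have similar
#' methylation between the two subgenomes of the natural allotetraploid
#' (|m_sA - m_sT| below it), counts how many show a decreased absolute
#' log2 expression ratio in the allotetraploid relative to the parents.
#'
#' @param pairs Tibble with one row per homolog pair and columns
#'   `m_parent_a`, `m_parent_t` (gene-level CG methylation in the two
#'   parents), `m_asu_a`, `m_asu_t` (in the two subgenomes of the natural
#'   allotetraploid), `lr_parent` (log2 A/T expression ratio in parents)
#'   and `lr_asu` (in the allotetraploid).
#' @param meth_threshold Methylation-difference threshold; default 0.5,
#'   the CG change cutoff.
#' @return A one-row tibble `n_pairs`, `n_candidates`, `n_decreased`,
#'   `percent` (`NA`, flagged by warning, when there is no candidate).
#' @export
homolog_convergence <- function(pairs, meth_threshold = 0.5) {
  cand <- abs(pairs$m_parent_a - pairs$m_parent_t) >= meth_threshold &
    abs(pairs$m_asu_a - pairs$m_asu_t) < meth_threshold
  cand[is.na(cand)] <- FALSE
  dec <- cand & abs(pairs$lr_asu) < abs(pairs$lr_parent)
  n_cand <- sum(cand)
  if (n_cand == 0) {
    warn("No candidate homolog pairs; convergence fraction is undefined.")
    return(tibble(n_pairs = nrow(pairs), n_candidates = 0L,
                  n_decreased = 0L, percent = NA_real_))
  }
  tibble(
    n_pairs = nrow(pairs), n_candidates = n_cand, n_decreased = sum(dec),
    percent = percentage(sum(dec), n_cand)
  )
}

#' Homolog upregulation breakdown in the natural allotetraploid
#'
#' For each homolog pair, tests whether the A homolog is upregulated in
#' the natural allotetraploid relative to its parent (positive mean log2
#' ratio with a two-sided two-sample test over replicates at `alpha`),
#' likewise for the T homolog, and classifies the pair as `A_only`,
#' `T_only`, `both` or `none`. Pairs with missing expression are skipped
#' and counted.
#'
#' @param pairs Tibble with columns `gene_a`, `gene_t` (homolog gene ids).
#' @param expr Expression tibble covering the allotetraploid and parents.
#' @param line_asu,line_parent_a,line_parent_t Line names (defaults
#'   `"asu"`, `"aar"`, `"ath"`).
#' @param alpha Per-gene significance level (default 0.05).
#' @param test Two-sample test function taking two numeric vectors and
#'   returning an object with `$p.value`; default [stats::t.test()].
#' @param pseudocount Added to TPM before the log ratio.
#' @return A list with `genes` (per-pair tibble: ratios, p-values,
#'   `class`) and `summary` (one-row tibble of class counts, `n_skipped`
#'   and `percent_upregulated` = upregulated pairs / classified pairs).
#' @export
upregulation_breakdown <- function(pairs, expr, line_asu = "asu",
                                   line_parent_a = "aar",
                                   line_parent_t = "ath",
                                   alpha = 0.05, test = stats::t.test,
                                   pseudocount = 1) {
  get_tpm <- function(gene, line) {
    expr$tpm[expr$gene_id == gene & expr$line == line]
  }
  one <- function(gene, line_num, line_den) {
    x <- get_tpm(gene, line_num)
    y <- get_tpm(gene, line_den)
    if (length(x) == 0 || length(y) == 0) return(NULL)
    lr <- log2((mean(x) + pseudocount) / (mean(y) + pseudocount))
    pv <- if (length(x) > 1 && length(y) > 1 &&
              (stats::sd(c(x, y)) > 0)) {
      tryCatch(test(x, y)$p.value, error = function(e) 1)
    } else {
      1
    }
    c(lr = lr, p = pv)
  }
  rows <- purrr::map(seq_len(nrow(pairs)), function(i) {
    ra <- one(pairs$gene_a[i], line_asu, line_parent_a)
    rt <- one(pairs$gene_t[i], line_asu, line_parent_t)
    if (is.null(ra) || is.null(rt)) {
      return(tibble(gene_a = pairs$gene_a[i], gene_t = pairs$gene_t[i],
                    lr_a = NA_real_, p_a = NA_real_, lr_t = NA_real_,
                    p_t = NA_real_, class = NA_character_))
    }
    up_a <- ra[["lr"]] > 0 && ra[["p"]] < alpha
    up_t <- rt[["lr"]] > 0 && rt[["p"]] < alpha
    tibble(
      gene_a = pairs$gene_a[i], gene_t = pairs$gene_t[i],
      lr_a = ra[["lr"]], p_a = ra[["p"]],
      lr_t = rt[["lr"]], p_t = rt[["p"]],
      class = case_when(
        up_a && up_t ~ "both", up_a ~ "A_only", up_t ~ "T_only",
        TRUE ~ "none"
      )
    )
  }) %>% bind_rows()
  classified <- filter(rows, !is.na(.data$class))
  n_up <- sum(classified$class != "none")
  summary <- tibble(
    n_pairs = nrow(pairs),
    n_skipped = sum(is.na(rows$class)),
    n_A_only = sum(classified$class == "A_only"),
    n_T_only = sum(classified$class == "T_only"),
    n_both = sum(classified$class == "both"),
    n_none = sum(classified$class == "none"),
    n_upregulated = n_up,
    percent_upregulated = if (nrow(classified) > 0) {
      percentage(n_up, nrow(classified))
    } else {
      NA_real_
    }
  )
  list(genes = rows, summary = summary)
}
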