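#' Pool a site matrix into fixed genomic windows
#'
#' Tiles the genome into `window_size`-bp windows advanced by `step` bp
#' (default: non-overlapping 100-bp tiles) and pools read counts over the
#' cytosines of each context falling in each window. With `step <
#' window_size` a cytosine contributes to every window covering it.
#'
#' @param matrix A harmonized site matrix from [harmonize()].
#' @param window_size Window width in bp (default 100).
#' @param step Distance between window starts in bp (default `window_size`).
#' @return A tibble with one row per `(chrom, start, context, line)` having
#'   at least one cytosine: columns `chrom`, `start`, `end` (0-based
#'   half-open), `context`, `line`, `n_sites`, `meth`, `total`.
#' @export
make_windows <- function(matrix, window_size = 100, step = window_size) {
  if (window_size <= 0 || step <= 0) {
    abort("`window_size` and `step` must be positive.")
  }
  if (nrow(matrix) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      context = character(), line = character(), n_sites = integer(),
      meth = integer(), total = integer()
    ))
  }
  g <- matrix$pos - 1L # 0-based genomic coordinate
  k_hi <- g %/% step
  k_lo <- pmax(0L, (g - window_size) %/% step + 1L)
  reps <- k_hi - k_lo + 1L
  idx <- rep(seq_len(nrow(matrix)), reps)
  tile <- sequence(reps, from = k_lo)
  expanded <- matrix[idx, , drop = FALSE]
  expanded$start <- as.integer(tile * step)
  key <- paste(expanded$chrom, expanded$start, expanded$context,
               expanded$line, sep = "\r")
  sums <- rowsum(cbind(1L, expanded$n_meth, expanded$n_total), group = key,
                 reorder = FALSE)
  firsts <- expanded[!duplicated(key), , drop = FALSE]
  tibble(
    chrom = firsts$chrom,
    start = firsts$start,
    end = firsts$start + as.integer(window_size),
    context = firsts$context,
    line = firsts$line,
    n_sites = as.integer(sums[, 1]),
    meth = as.integer(sums[, 2]),
    total = as.integer(sums[, 3])
  ) %>%
    arrange(.data$chrom, .data$start, .data$context, .data$line)
}

#' Weighted methylation level
#'
#' The pooled methylated read count divided by the pooled total read count
#' over a region — robust to per-site coverage differences. Undefined (NA)
#' when the pooled total is zero.
#'
#' @param pooled_meth,pooled_total Non-negative counts, `pooled_meth <=
#'   pooled_total`; vectorized.
#' @return Methylation level(s) in `[0, 1]`, `NA` where `pooled_total == 0`.
#' @export
weighted_methylation <- function(pooled_meth, pooled_total) {
  if (any(pooled_meth < 0) || any(pooled_total < 0)) {
    abort("Counts must be non-negative.")
  }
  if (any(pooled_meth > pooled_total)) {
    abort("`pooled_meth` cannot exceed `pooled_total`.")
  }
  ifelse(pooled_total == 0, NA_real_, pooled_meth / pooled_total)
}

#' Two-sided Fisher's exact test for 2x2 count tables (vectorized)
#'
#' Computes the exact two-sided p-value for tables
#' `rbind(c(a, b), c(c, d))` (rows = samples, columns = methylated /
#' unmethylated counts) as the sum of hypergeometric point probabilities no
#' larger than that of the observed table (with the customary 1 + 1e-7
#' relative tolerance), margins fixed. All four arguments are recycled
#' vectors, so one call scores an entire window set.
#'
#' Degenerate tables with a zero margin carry no information and return
#' p = 1 by convention.
#'
#' @param a,b,c,d Non-negative integer counts.
#' @return A numeric vector of two-sided p-values.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  n_tab <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n_tab)
  b <- rep_len(as.numeric(b), n_tab)
  c <- rep_len(as.numeric(c), n_tab)
  d <- rep_len(as.numeric(d), n_tab)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0) ||
      any(c(a, b, c, d) != floor(c(a, b, c, d)))) {
    abort("Table entries must be non-negative integers.")
  }
  m <- a + c # methylated margin
  n <- b + d # unmethylated margin
  k <- a + b # first-sample margin
  p <- rep(1, n_tab)
  active <- which(m > 0 & n > 0 & k > 0 & (c + d) > 0)
  if (length(active) == 0) return(p)
  lo <- pmax(0, k - n)
  hi <- pmin(k, m)
  # chunk the concatenated supports to bound memory
  sizes <- hi[active] - lo[active] + 1
  chunks <- split(active, ceiling(cumsum(sizes) / 5e6))
  d_obs <- dhyper(a, m, n, k)
  for (ch in chunks) {
    sz <- hi[ch] - lo[ch] + 1
    idx <- rep(ch, sz)
    x <- sequence(sz, from = lo[ch])
    dp <- dhyper(x, m[idx], n[idx], k[idx])
    keep <- dp <= d_obs[idx] * (1 + 1e-7)
    sums <- rowsum(dp * keep, group = idx, reorder = TRUE)
    p[ch] <- pmin(1, as.numeric(sums))
  }
  p
}

#' Benjamini-Hochberg adjusted values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]), input order preserved.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return The adjusted q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call differentially methylated regions between two samples
#'
#' For each window of one context shared by the focal and reference
#' samples, pools counts into a 2x2 table, tests it with two-sided
#' Fisher's exact test, adjusts p-values by Benjamini-Hochberg within this
#' comparison and context, and flags windows with `q < fdr` and a weighted
#' methylation difference of at least the context cutoff (0.5 CG, 0.3 CHG,
#' 0.1 CHH) as DMRs. Windows below the context site minimum (4 CG/CHG, 16
#' CHH cytosines) or with zero pooled coverage in either sample are not
#' tested.
#'
#' @param windows Window tibble from [make_windows()].
#' @param focal,reference Sample (line) names; `delta = m_focal - m_ref`,
#'   so `direction = "hyper"` means the focal sample is more methylated.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param fdr FDR threshold (default 0.05).
#' @param min_delta Minimum |delta| for a DMR; default the context cutoff.
#' @param min_sites Minimum cytosines per window; default the context rule.
#' @return A tibble of all tested windows with columns `chrom`, `start`,
#'   `end`, `context`, `n_sites`, pooled counts for both samples,
#'   `m_focal`, `m_ref`, `delta`, `p`, `q`, `direction` and `is_dmr`;
#'   attributes record the comparison. Class `"dmr_calls"`.
#' @export
call_dmrs <- function(windows, focal, reference, context,
                      fdr = 0.05, min_delta = NULL, min_sites = NULL) {
  check_context(context)
  stopifnot(length(context) == 1)
  if (fdr <= 0 || fdr >= 1) abort("`fdr` must lie in (0, 1).")
  if (is.null(min_delta)) min_delta <- context_min_delta(context)
  if (is.null(min_sites)) min_sites <- context_min_sites(context)
  for (s in c(focal, reference)) {
    if (!s %in% windows$line) {
      abort(sprintf("Sample '%s' is not present in `windows`.", s))
    }
  }
  w <- filter(windows, .data$context == .env$context)
  f <- filter(w, .data$line == .env$focal)
  r <- filter(w, .data$line == .env$reference)
  tab <- inner_join(
    select(f, "chrom", "start", "end", "context", "n_sites",
           meth_focal = "meth", total_focal = "total"),
    select(r, "chrom", "start", "end", "context", "n_sites",
           meth_ref = "meth", total_ref = "total"),
    by = c("chrom", "start", "end", "context", "n_sites")
  ) %>%
    filter(.data$n_sites >= .env$min_sites,
           .data$total_focal > 0, .data$total_ref > 0)
  tab <- tab %>%
    mutate(
      m_focal = weighted_methylation(.data$meth_focal, .data$total_focal),
      m_ref = weighted_methylation(.data$meth_ref, .data$total_ref),
      delta = .data$m_focal - .data$m_ref,
      p = fisher_exact_2x2(
        .data$meth_focal, .data$total_focal - .data$meth_focal,
        .data$meth_ref, .data$total_ref - .data$meth_ref
      ),
      q = bh_fdr(.data$p),
      is_dmr = .data$q < .env$fdr & abs(.data$delta) >= .env$min_delta,
      direction = case_when(
        .data$delta > 0 ~ "hyper",
        .data$delta < 0 ~ "hypo",
        TRUE ~ NA_character_
      )
    ) %>%
    arrange(.data$chrom, .data$start)
  structure(
    tab,
    focal = focal, reference = reference, context = context,
    fdr = fdr, min_delta = min_delta, min_sites = min_sites,
    class = c("dmr_calls", class(tab))
  )
}

#' @export
print.dmr_calls <- function(x, ...) {
  cat(sprintf(
    "# DMR calls: %s vs %s, %s context (%d tested windows, %d DMRs: %d hyper / %d hypo)\n",
    attr(x, "focal"), attr(x, "reference"), attr(x, "context"),
    nrow(x), sum(x$is_dmr),
    sum(x$is_dmr & x$direction == "hyper"),
    sum(x$is_dmr & x$direction == "hypo")
  ))
  NextMethod()
}

#' @rdname call_dmrs
#' @param x A `dmr_calls` object.
#' @param ... Unused.
#' @method tidy dmr_calls
#' @export
tidy.dmr_calls <- function(x, ...) {
  as_tibble(x)[, c("chrom", "start", "end", "context", "n_sites",
                   "m_focal", "m_ref", "delta", "p", "q",
                   "direction", "is_dmr")]
}

#' @rdname call_dmrs
#' @method glance dmr_calls
#' @export
glance.dmr_calls <- function(x, ...) {
  tibble(
    focal = attr(x, "focal"),
    reference = attr(x, "reference"),
    context = attr(x, "context"),
    n_tested = nrow(x),
    n_dmr = sum(x$is_dmr),
    n_hyper = sum(x$is_dmr & x$direction == "hyper"),
    n_hypo = sum(x$is_dmr & x$direction == "hypo"),
    fdr = attr(x, "fdr"),
    min_delta = attr(x, "min_delta")
  )
}
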