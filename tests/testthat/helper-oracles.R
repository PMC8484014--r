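# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# test: sums the point probabilities of every table with the observed
# margins whose probability does not exceed the observed one. Kept
# deliberately independent of fisher_exact_2x2().
enum_fisher_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  if (m == 0 || n == 0 || k == 0 || (c + d) == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments
# (no ties assumed); independent of stats::wilcox.test.
enum_mannwhitney_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  u_stat <- function(idx) {
    xs <- pooled[idx]
    ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(seq_len(n1))
  all_u <- apply(utils::combn(length(pooled), n1), 2, u_stat)
  center <- length(x) * length(y) / 2
  mean(abs(all_u - center) >= abs(u_obs - center) - 1e-12)
}

# small cytosine tibble constructor for unit tests
cyt <- function(chrom, pos, strand, context, n_meth, n_unmeth) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), strand = strand,
                 context = context, n_meth = as.integer(n_meth),
                 n_unmeth = as.integer(n_unmeth))
}

# window-table constructor matching make_windows() output
win <- function(chrom, start, context, line, n_sites, meth, total,
                window_size = 100) {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(start + window_size), context = context,
                 line = line, n_sites = as.integer(n_sites),
                 meth = as.integer(meth), total = as.integer(total))
}

# fake dmr_calls-shaped table for classifier tests: one row per window
fake_calls <- function(delta, is_dmr, start = seq_along(delta) * 100 - 100,
                       context = "CG") {
  tibble::tibble(
    chrom = "sA1", start = as.integer(start),
    end = as.integer(start + 100L), context = context,
    delta = delta, is_dmr = is_dmr,
    direction = dplyr::case_when(delta > 0 ~ "hyper", delta < 0 ~ "hypo",
                                 TRUE ~ NA_character_)
  )
}

# small fast cohort for smoke tests
tiny_cohort_config <- function(...) {
  cohort_config(
    genome_length = 60000L,
    contexts = "CG",
    spacing = 5L,
    n_planted = c(convergent = 6L, conserved = 6L, persistent_hyper = 3L,
                  asu_hyper = 6L),
    n_null_genes = 5L,
    ...
  )
}
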