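#' Jukes-Cantor distance from an observed mismatch proportion
#'
#' Corrects the raw proportion of mismatched sites `d` between the 5' and
#' 3' LTRs of a retrotransposon for multiple substitutions:
#' `K = -(3/4) * log(1 - (4/3) * d)`. Defined for `0 <= d < 0.75`;
#' divergence at or beyond 3/4 is saturated and an error.
#'
#' @param d Observed mismatch proportion(s) in `[0, 0.75)`.
#' @return The corrected distance(s) `K >= d`.
#' @export
jc_distance <- function(d) {
  if (any(is.na(d)) || any(d < 0) || any(d >= 0.75)) {
    abort("`d` must lie in [0, 0.75); the Jukes-Cantor correction saturates at 3/4.")
  }
  -0.75 * log(1 - (4 / 3) * d)
}

#' LTR insertion time from a Jukes-Cantor distance
#'
#' `t = K / (2 r)` with `r` the substitution rate per site per generation
#' (default 7e-9, one generation taken as one year), so `t` is in years.
#'
#' @param K Jukes-Cantor distance(s), `K >= 0`.
#' @param r Substitution rate per site per generation (> 0).
#' @return Insertion time(s) in years.
#' @export
insertion_time <- function(K, r = 7e-9) {
  if (any(K < 0)) abort("`K` must be non-negative.")
  if (r <= 0) abort("`r` must be positive.")
  K / (2 * r)
}

#' Mismatch proportion between two aligned LTR sequences
#'
#' Site-wise mismatch proportion of two equal-length aligned sequences,
#' ignoring columns where either sequence has a gap (`-`) or `N`.
#'
#' @param seq_5p,seq_3p Aligned sequences as single strings.
#' @return The proportion of mismatched comparable sites.
#' @export
ltr_divergence <- function(seq_5p, seq_3p) {
  a <- toupper(strsplit(seq_5p, "")[[1]])
  b <- toupper(strsplit(seq_3p, "")[[1]])
  if (length(a) != length(b)) {
    abort("Aligned LTR sequences must have equal length.")
  }
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  if (!any(ok)) abort("No comparable (gap-free) columns.")
  mean(a[ok] != b[ok])
}

#' Date LTR retrotransposon insertions
#'
#' Applies the Jukes-Cantor correction and the molecular clock
#' `t = K / 2r` to a table of per-element LTR divergences.
#'
#' @param ltrs Tibble with columns `element_id` and `d` (observed LTR
#'   mismatch proportion), or a path to a TSV with those columns.
#' @param r Substitution rate per site per generation (default 7e-9).
#' @return A tibble `element_id`, `d`, `K`, `t_years`.
#' @export
ltr_age <- function(ltrs, r = 7e-9) {
  if (is.character(ltrs)) {
    ltrs <- readr::read_tsv(
      ltrs,
      col_types = readr::cols(element_id = readr::col_character(),
                              d = readr::col_double()),
      progress = FALSE
    )
  }
  K <- jc_distance(ltrs$d)
  tibble(
    element_id = ltrs$element_id, d = ltrs$d, K = K,
    t_years = insertion_time(K, r)
  )
}
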