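window_key <- function(x) {
  if (nrow(x) == 0) return(character(0))
  paste0(x$chrom, ":", x$start, "-", x$end)
}

# Align a named list of dmr_calls tables on one shared window universe and
# return a wide tibble with per-line delta / q / is_dmr / direction columns.
align_calls <- function(calls, required) {
  missing <- setdiff(required, names(calls))
  if (length(missing) > 0) {
    abort(sprintf("Missing DMR calls for line(s): %s.",
                  paste(missing, collapse = ", ")))
  }
  keys <- purrr::map(calls[required], window_key)
  ref <- keys[[1]]
  for (i in seq_along(keys)[-1]) {
    if (length(keys[[i]]) != length(ref) || !setequal(keys[[i]], ref)) {
      abort(sprintf(
        "Window universes differ between '%s' (%d windows) and '%s' (%d windows).",
        required[1], length(ref), required[i], length(keys[[i]])
      ))
    }
  }
  wide <- as_tibble(calls[[required[1]]])[, c("chrom", "start", "end", "context")]
  for (nm in required) {
    tab <- as_tibble(calls[[nm]]) %>% arrange(.data$chrom, .data$start)
    wide <- wide %>% arrange(.data$chrom, .data$start)
    stopifnot(identical(window_key(wide), window_key(tab)))
    wide[[paste0("delta_", nm)]] <- tab$delta
    wide[[paste0("dmr_", nm)]] <- tab$is_dmr
    wide[[paste0("dir_", nm)]] <- tab$direction
  }
  wide
}

#' Flag convergent methylation windows across generations
#'
#' A window is convergent when the A subgenome is hypermethylated relative
#' to the T subgenome (a hyper A-vs-T DMR) in the parents, the F1 and both
#' resynthesized allotetraploids, but the difference has collapsed in the
#' natural allotetraploid ("decreased to a similar level": not a DMR there
#' and |delta| below the context cutoff). Windows that stay hypermethylated
#' through the natural line are flagged `persistent_hyper`; every
#' parent-hyper window receives exactly one of
#' `{convergent, persistent_hyper, other}`.
#'
#' @param avt_calls Named list of [call_dmrs()] results for the A-vs-T
#'   comparison in `parents`, `f1`, `a733`, `a738` and `asu`, all on the
#'   same window universe (delta oriented A minus T).
#' @param delta_cutoff Similarity threshold for the natural line; default
#'   the context DMR cutoff.
#' @return A tibble with the window keys, per-line `delta_*`/`dmr_*`
#'   columns, logicals `convergent` and `persistent_hyper`, and
#'   `hyper_class` (`NA` for windows not parent-hyper).
#' @export
classify_convergent <- function(avt_calls, delta_cutoff = NULL) {
  lines <- c("parents", "f1", "a733", "a738", "asu")
  wide <- align_calls(avt_calls, lines)
  if (is.null(delta_cutoff)) {
    delta_cutoff <- context_min_delta(wide$context[1])
  }
  # the change threshold plays both roles: a hyper window must differ by at
  # least `delta_cutoff`, and the natural line must sit within it
  hyper <- function(nm) {
    wide[[paste0("dmr_", nm)]] &
      !is.na(wide[[paste0("dir_", nm)]]) &
      wide[[paste0("dir_", nm)]] == "hyper" &
      wide[[paste0("delta_", nm)]] >= delta_cutoff
  }
  neo_hyper <- hyper("parents") & hyper("f1") & hyper("a738") & hyper("a733")
  asu_similar <- !wide$dmr_asu & abs(wide$delta_asu) < delta_cutoff
  wide %>%
    mutate(
      convergent = neo_hyper & asu_similar,
      persistent_hyper = neo_hyper & hyper("asu"),
      hyper_class = dplyr::if_else(
        hyper("parents"),
        case_when(
          neo_hyper & asu_similar ~ "convergent",
          neo_hyper & hyper("asu") ~ "persistent_hyper",
          TRUE ~ "other"
        ),
        NA_character_
      )
    )
}

#' Flag conserved hypomethylation windows
#'
#' A conserved window is a hypo-DMR (allotetraploid subgenome vs its
#' parent) in the natural allotetraploid that is already present in the F1
#' and/or the resynthesized lines. Flags are reported per line and as the
#' all-three intersection.
#'
#' @param vsp_calls Named list of [call_dmrs()] results for the
#'   subgenome-vs-parent comparison in `f1`, `a733`, `a738` and `asu`, on
#'   one window universe.
#' @return A tibble with window keys, per-line `delta_*`/`dmr_*` columns,
#'   logicals `hypo_asu`, `conserved_f1`, `conserved_a733`,
#'   `conserved_a738`, `conserved_all` and `conserved_any`.
#' @seealso [conserved_fractions()] for the per-line overlap fractions.
#' @export
classify_conserved <- function(vsp_calls) {
  lines <- c("f1", "a733", "a738", "asu")
  wide <- align_calls(vsp_calls, lines)
  hypo <- function(nm) {
    wide[[paste0("dmr_", nm)]] &
      !is.na(wide[[paste0("dir_", nm)]]) &
      wide[[paste0("dir_", nm)]] == "hypo"
  }
  wide %>%
    mutate(
      hypo_asu = hypo("asu"),
      conserved_f1 = .data$hypo_asu & hypo("f1"),
      conserved_a733 = .data$hypo_asu & hypo("a733"),
      conserved_a738 = .data$hypo_asu & hypo("a738"),
      conserved_all = .data$conserved_f1 & .data$conserved_a733 &
        .data$conserved_a738,
      conserved_any = .data$conserved_f1 | .data$conserved_a733 |
        .data$conserved_a738
    )
}

#' Per-line conserved-DMR fractions
#'
#' Summarises a [classify_conserved()] table as `(overlap, total,
#' percent)` per line and for all three lines jointly, where `total` is
#' the number of hypo-DMRs in the natural allotetraploid.
#'
#' @param conserved A tibble from [classify_conserved()].
#' @return A tibble with columns `line`, `overlap`, `total`, `percent`.
#' @export
conserved_fractions <- function(conserved) {
  total <- sum(conserved$hypo_asu)
  frac <- function(flag) {
    ov <- sum(conserved[[flag]])
    tibble(overlap = ov, total = total,
           percent = if (total > 0) percentage(ov, total) else NA_real_)
  }
  bind_rows(
    mutate(frac("conserved_f1"), line = "f1"),
    mutate(frac("conserved_a733"), line = "a733"),
    mutate(frac("conserved_a738"), line = "a738"),
    mutate(frac("conserved_all"), line = "all_three")
  ) %>%
    select("line", "overlap", "total", "percent")
}

#' Classify full methylation trajectories
#'
#' Combines the convergence ([classify_convergent()]) and conservation
#' ([classify_conserved()]) criteria into a single label per window:
#' `both` when a window satisfies both, then `convergent`, `conserved`,
#' `persistent_hyper`, else `other`.
#'
#' @inheritParams classify_convergent
#' @inheritParams classify_conserved
#' @return A tibble with window keys, the component flags and a `class`
#'   column.
#' @export
classify_trajectory <- function(avt_calls, vsp_calls, delta_cutoff = NULL) {
  conv <- classify_convergent(avt_calls, delta_cutoff)
  cons <- classify_conserved(vsp_calls)
  key_c <- window_key(conv)
  key_s <- window_key(cons)
  if (!identical(sort(key_c), sort(key_s))) {
    abort("A-vs-T and vs-parent calls are on different window universes.")
  }
  joined <- inner_join(
    select(conv, "chrom", "start", "end", "context",
           "convergent", "persistent_hyper", "hyper_class"),
    select(cons, "chrom", "start", "end",
           "hypo_asu", "conserved_f1", "conserved_a733", "conserved_a738",
           "conserved_all", "conserved_any"),
    by = c("chrom", "start", "end")
  )
  joined %>%
    mutate(class = case_when(
      .data$convergent & .data$conserved_any ~ "both",
      .data$convergent ~ "convergent",
      .data$conserved_any ~ "conserved",
      .data$persistent_hyper ~ "persistent_hyper",
      TRUE ~ "other"
    ))
}

#' Fraction of DMRs inherited from an earlier generation
#'
#' The share of one line's DMRs already present (same window, same
#' direction) in an earlier line, e.g. hypo-DMRs of the natural
#' allotetraploid that already existed in the F1.
#'
#' @param child_dmrs,ancestor_dmrs `dmr_calls` tibbles (their `is_dmr`
#'   rows are used) or tibbles of DMR windows with `chrom`, `start`,
#'   `end`.
#' @param direction Optional `"hyper"`/`"hypo"` filter applied to both.
#' @return A one-row tibble `overlap`, `total`, `fraction` (`NA` fraction
#'   when the child set is empty).
#' @export
inheritance_fraction <- function(child_dmrs, ancestor_dmrs,
                                 direction = NULL) {
  pick <- function(x) {
    x <- as_tibble(x)
    if ("is_dmr" %in% names(x)) x <- filter(x, .data$is_dmr)
    if (!is.null(direction) && "direction" %in% names(x)) {
      x <- filter(x, .data$direction == .env$direction)
    }
    unique(window_key(x))
  }
  child <- pick(child_dmrs)
  anc <- pick(ancestor_dmrs)
  ov <- length(intersect(child, anc))
  if (length(child) == 0) {
    warn("Child DMR set is empty; inheritance fraction is undefined.")
    return(tibble(overlap = 0L, total = 0L, fraction = NA_real_))
  }
  tibble(overlap = ov, total = length(child),
         fraction = ov / length(child))
}

#' Enrichment of the overlap between two window (or gene) sets
#'
#' Builds the 2x2 table of membership in two sets over a common universe
#' and reports the overlap, its expectation under independence, the sample
#' odds ratio and the two-sided Fisher p-value.
#'
#' @param set_a,set_b Character vectors of member identifiers.
#' @param universe_size Size of the common universe (must be at least the
#'   size of the union).
#' @return A one-row tibble `overlap`, `expected`, `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  ab <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - ab
  b_only <- length(set_b) - ab
  rest <- universe_size - ab - a_only - b_only
  if (rest < 0) {
    abort("`universe_size` is smaller than the union of the two sets.")
  }
  odds <- if (a_only == 0 || b_only == 0) {
    if (ab == 0) NaN else Inf
  } else {
    (ab * rest) / (a_only * b_only)
  }
  tibble(
    overlap = ab,
    expected = length(set_a) * length(set_b) / universe_size,
    odds_ratio = odds,
    p = fisher_exact_2x2(ab, a_only, b_only, rest)
  )
}
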