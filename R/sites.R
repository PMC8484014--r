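#' Merge replicate cytosine reports
#'
#' Pools methylated/unmethylated read counts over replicates of the same
#' line. A site present in any replicate is present in the merge; counts at
#' shared sites are summed. Merging is commutative and associative.
#'
#' @param ... Two or more cytosine tibbles (see [read_cytosine_report()]),
#'   or a single list of them.
#' @return A merged cytosine tibble, sorted by `(chrom, pos, strand)`.
#' @export
merge_replicates <- function(...) {
  reps <- list(...)
  if (length(reps) == 1 && is.list(reps[[1]]) && !is.data.frame(reps[[1]])) {
    reps <- reps[[1]]
  }
  if (length(reps) == 0) abort("No replicates supplied.")
  all <- bind_rows(reps)
  key <- paste(all$chrom, all$pos, all$strand)
  first_kc <- !duplicated(paste(key, all$context))
  dup_key <- key[first_kc][duplicated(key[first_kc])]
  if (length(dup_key) > 0) {
    abort(sprintf("Conflicting context across replicates at site '%s'.",
                  dup_key[1]))
  }
  sums <- rowsum(cbind(all$n_meth, all$n_unmeth), group = key,
                 reorder = FALSE)
  firsts <- all[!duplicated(key), , drop = FALSE]
  stopifnot(identical(rownames(sums), paste(firsts$chrom, firsts$pos,
                                            firsts$strand)))
  tibble(
    chrom = firsts$chrom, pos = firsts$pos, strand = firsts$strand,
    context = firsts$context,
    n_meth = as.integer(sums[, 1]), n_unmeth = as.integer(sums[, 2])
  ) %>%
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Keep cytosines with sufficient read depth
#'
#' Retains sites whose total (methylated + unmethylated) read count is at
#' least `min_reads`, the "conserved cytosines with three or more reads"
#' rule applied per line after replicate merging.
#'
#' @param records A cytosine tibble.
#' @param min_reads Minimum total reads per site (default 3).
#' @return The filtered tibble.
#' @export
filter_coverage <- function(records, min_reads = 3) {
  if (min_reads < 1) abort("`min_reads` must be >= 1.")
  filter(records, .data$n_meth + .data$n_unmeth >= min_reads)
}

#' Harmonize cytosines across lines into a site matrix
#'
#' Restricts every line to the cytosines shared by all lines (the joint
#' intersection over site keys `(chrom, pos, strand, context)`), the
#' "shared methylation sites" filter that makes lines comparable. Counts
#' are preserved per line.
#'
#' @param records_by_line Named list of cytosine tibbles, one per
#'   line/sample, each already replicate-merged and coverage-filtered.
#' @return A long site-matrix tibble with columns `chrom`, `pos`, `strand`,
#'   `context`, `line`, `n_meth`, `n_total`; every site appears once per
#'   line.
#' @export
harmonize <- function(records_by_line) {
  if (length(records_by_line) < 2) {
    abort("`harmonize()` needs at least two lines.")
  }
  if (is.null(names(records_by_line)) || any(names(records_by_line) == "")) {
    abort("`records_by_line` must be a fully named list.")
  }
  keys <- purrr::map(records_by_line, function(r) {
    paste(r$chrom, r$pos, r$strand, r$context)
  })
  shared <- Reduce(intersect, keys)
  if (length(shared) == 0) {
    sizes <- paste(sprintf("%s=%d", names(keys), lengths(keys)),
                   collapse = ", ")
    abort(sprintf(
      "No cytosines are shared by all lines (per-line site counts: %s).",
      sizes
    ))
  }
  mat <- purrr::imap(records_by_line, function(r, nm) {
    r %>%
      filter(paste(.data$chrom, .data$pos, .data$strand, .data$context) %in%
               .env$shared) %>%
      mutate(line = nm, n_total = .data$n_meth + .data$n_unmeth)
  }) %>%
    bind_rows() %>%
    arrange(.data$chrom, .data$pos, .data$strand, .data$line) %>%
    select("chrom", "pos", "strand", "context", "line", "n_meth", "n_total")
  mat
}

#' Restrict a site matrix to conserved homology blocks
#'
#' Keeps cytosines that fall inside a homology block at least `min_len`
#' bp long with alignment score at least `min_score` (default: blocks of
#' 1 kb or longer, scores below 1,000 removed). A site matches a block on
#' either side of the alignment.
#'
#' @param matrix A site matrix from [harmonize()] (or any cytosine tibble
#'   with `chrom` and `pos`).
#' @param blocks Homology blocks from [read_homology_map()].
#' @param min_len Minimum block length in bp.
#' @param min_score Minimum alignment score.
#' @return The filtered tibble; a warning is raised when nothing survives.
#' @export
filter_conserved_regions <- function(matrix, blocks, min_len = 1000,
                                     min_score = 1000) {
  keep <- filter(blocks,
                 .data$end_a - .data$start_a >= min_len,
                 .data$score >= min_score)
  iv <- bind_rows(
    tibble(chrom = keep$chrom_a, start = keep$start_a, end = keep$end_a),
    tibble(chrom = keep$chrom_b, start = keep$start_b, end = keep$end_b)
  )
  out <- matrix[sites_in_intervals(matrix$chrom, matrix$pos, iv), , drop = FALSE]
  if (nrow(out) == 0) {
    warn("No cytosines remain after the conserved-region filter.")
  }
  out
}

# TRUE for each 1-based site position covered by any 0-based half-open
# interval in `iv` on the same chromosome.
sites_in_intervals <- function(chrom, pos, iv) {
  keep <- logical(length(pos))
  if (nrow(iv) == 0 || length(pos) == 0) return(keep)
  for (ch in unique(iv$chrom)) {
    on_ch <- which(chrom == ch)
    if (length(on_ch) == 0) next
    ivc <- iv[iv$chrom == ch, , drop = FALSE]
    hits <- IRanges::overlapsAny(
      IRanges::IRanges(start = pos[on_ch], width = 1L),
      IRanges::IRanges(start = ivc$start + 1L, end = ivc$end)
    )
    keep[on_ch] <- hits
  }
  keep
}

#' Project cytosines through a homology map into the partner frame
#'
#' Translates records that live on the `b` side of a homology map into the
#' coordinates of the `a` side, so homologous cytosines of two subgenomes
#' (or two assemblies) can be compared at one position. Gapless blocks make
#' the translation a pure offset; records outside every block are dropped.
#'
#' @param records Cytosine tibble with coordinates on `chrom_b`.
#' @param blocks Homology blocks from [read_homology_map()].
#' @return The records re-addressed to `chrom_a` coordinates, with strand
#'   flipped for inverted blocks.
#' @export
map_to_homolog_frame <- function(records, blocks) {
  if (nrow(records) == 0) return(records)
  pieces <- purrr::map(seq_len(nrow(blocks)), function(i) {
    b <- blocks[i, ]
    hit <- records$chrom == b$chrom_b &
      records$pos > b$start_b & records$pos <= b$end_b
    if (!any(hit)) return(NULL)
    r <- records[hit, , drop = FALSE]
    if (identical(b$strand_rel, "-")) {
      r$pos <- b$start_a + (b$end_b - r$pos) + 1L
      r$strand <- ifelse(r$strand == "+", "-", "+")
    } else {
      r$pos <- b$start_a + (r$pos - b$start_b)
    }
    r$chrom <- b$chrom_a
    r
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    warn("No records fall inside any homology block.")
    return(records[0, , drop = FALSE])
  }
  arrange(out, .data$chrom, .data$pos, .data$strand)
}
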