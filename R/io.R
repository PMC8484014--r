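#' Read a per-cytosine methylation report
#'
#' Reads a Bismark-style cytosine report: a headerless tab-separated file with
#' columns chromosome, 1-based position, strand, methylated read count,
#' unmethylated read count, context (and optionally the trinucleotide, which
#' is ignored). Gzipped files are read transparently. Rows with zero total
#' coverage are retained; coverage filtering happens downstream
#' ([filter_coverage()]).
#'
#' @param path Path to the report (optionally `.gz`).
#' @param context_filter Optional character vector of contexts to keep
#'   (subset of `"CG"`, `"CHG"`, `"CHH"`); default keeps all.
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `n_meth`, `n_unmeth`, one row per cytosine in file order.
#' @seealso [write_cytosine_report()], [merge_replicates()]
#' @export
read_cytosine_report <- function(path, context_filter = NULL) {
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      chrom = character(), pos = integer(), strand = character(),
      context = character(), n_meth = integer(), n_unmeth = integer()
    ))
  }
  if (ncol(raw) < 6) {
    abort(sprintf("Cytosine report '%s' has %d columns; expected at least 6.",
                  path, ncol(raw)))
  }
  rec <- tibble(
    chrom = raw[[1]],
    pos = suppressWarnings(as.integer(raw[[2]])),
    strand = raw[[3]],
    n_meth = suppressWarnings(as.integer(raw[[4]])),
    n_unmeth = suppressWarnings(as.integer(raw[[5]])),
    context = normalize_context(raw[[6]], path)
  )
  bad <- which(
    is.na(rec$pos) | rec$pos < 1L |
      is.na(rec$n_meth) | rec$n_meth < 0L |
      is.na(rec$n_unmeth) | rec$n_unmeth < 0L |
      !rec$strand %in% c("+", "-")
  )
  if (length(bad) > 0) {
    abort(sprintf("Malformed cytosine report row at line %d of '%s'.",
                  bad[1], path))
  }
  rec <- select(rec, "chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  if (!is.null(context_filter)) {
    check_context(context_filter)
    rec <- filter(rec, .data$context %in% context_filter)
  }
  rec
}

normalize_context <- function(x, path = "<input>") {
  up <- toupper(x)
  up[up == "CPG"] <- "CG"
  bad <- which(!up %in% .CONTEXTS)
  if (length(bad) > 0) {
    abort(sprintf("Unknown context token '%s' at line %d of '%s'.",
                  x[bad[1]], bad[1], path))
  }
  up
}

#' Write a per-cytosine methylation report
#'
#' Inverse of [read_cytosine_report()]: emits the headerless six-column
#' Bismark-style TSV.
#'
#' @param records Tibble as returned by [read_cytosine_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path) {
  out <- select(records, "chrom", "pos", "strand", "n_meth", "n_unmeth",
                "context")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read gene models from BED or GFF3
#'
#' Both formats are normalized to the package-internal convention of 0-based
#' half-open intervals: BED coordinates are used as is, GFF3 `start`/`end`
#' (1-based inclusive) become `(start - 1, end)`. An optional homolog
#' identifier pairs each gene with its partner on the other subgenome
#' (BED column 7, or a `homolog_id=` GFF3 attribute).
#'
#' @param path Path to a `.bed` or `.gff`/`.gff3` file.
#' @param format `"bed"`, `"gff3"`, or `"auto"` (from the extension).
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `homolog_id` (`NA` when unpaired).
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)) {
      "gff3"
    } else {
      "bed"
    }
  }
  genes <- if (format == "bed") read_genes_bed(path) else read_genes_gff3(path)
  if (any(genes$start >= genes$end)) {
    i <- which(genes$start >= genes$end)[1]
    abort(sprintf("Gene '%s' has an empty interval after normalization (start %d >= end %d).",
                  genes$gene_id[i], genes$start[i], genes$end[i]))
  }
  check_homolog_symmetry(genes)
  genes
}

read_genes_bed <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) return(empty_genes())
  if (ncol(raw) < 6) {
    abort(sprintf("BED gene file '%s' needs at least 6 columns.", path))
  }
  tibble(
    gene_id = raw[[4]],
    chrom = raw[[1]],
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]]),
    strand = raw[[6]],
    homolog_id = if (ncol(raw) >= 7) {
      dplyr::na_if(raw[[7]], ".")
    } else {
      NA_character_
    }
  )
}

read_genes_gff3 <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) return(empty_genes())
  raw <- raw[raw[[3]] == "gene", , drop = FALSE]
  attr_field <- function(attrs, key) {
    m <- stringr::str_match(attrs, paste0("(?:^|;)\\s*", key, "=([^;]+)"))
    m[, 2]
  }
  tibble(
    gene_id = attr_field(raw[[9]], "ID"),
    chrom = raw[[1]],
    start = as.integer(raw[[4]]) - 1L,
    end = as.integer(raw[[5]]),
    strand = raw[[7]],
    homolog_id = attr_field(raw[[9]], "homolog_id")
  )
}

empty_genes <- function() {
  tibble(
    gene_id = character(), chrom = character(), start = integer(),
    end = integer(), strand = character(), homolog_id = character()
  )
}

check_homolog_symmetry <- function(genes) {
  paired <- filter(genes, !is.na(.data$homolog_id))
  if (nrow(paired) == 0) return(invisible(genes))
  partner <- setNames(paired$homolog_id, paired$gene_id)
  back <- partner[paired$homolog_id]
  bad <- which(is.na(back) | back != paired$gene_id)
  if (length(bad) > 0) {
    abort(sprintf("Homolog pairing is not symmetric for gene '%s'.",
                  paired$gene_id[bad[1]]))
  }
  invisible(genes)
}

#' Write gene models as BED6(+1)
#'
#' @param genes Tibble as returned by [read_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genes_bed <- function(genes, path) {
  out <- tibble(
    chrom = genes$chrom, start = genes$start, end = genes$end,
    name = genes$gene_id, score = ".", strand = genes$strand,
    homolog_id = dplyr::coalesce(genes$homolog_id, ".")
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a homology-block map
#'
#' Reads the tabular output of a whole-genome aligner as gapless paired
#' blocks: eight tab-separated columns `chrom_a start_a end_a chrom_b
#' start_b end_b score strand_rel` (0-based half-open on both sides).
#' Blocks are returned sorted by `(chrom_a, start_a)`.
#'
#' @param path Path to the TSV (no header).
#' @return A tibble of homology blocks.
#' @export
read_homology_map <- function(path) {
  raw <- readr::read_tsv(
    path, col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0) {
    return(tibble(
      chrom_a = character(), start_a = integer(), end_a = integer(),
      chrom_b = character(), start_b = integer(), end_b = integer(),
      score = double(), strand_rel = character()
    ))
  }
  if (ncol(raw) < 8) {
    abort(sprintf("Homology map '%s' needs 8 columns.", path))
  }
  blocks <- tibble(
    chrom_a = raw[[1]], start_a = as.integer(raw[[2]]),
    end_a = as.integer(raw[[3]]),
    chrom_b = raw[[4]], start_b = as.integer(raw[[5]]),
    end_b = as.integer(raw[[6]]),
    score = as.numeric(raw[[7]]), strand_rel = raw[[8]]
  )
  validate_homology_blocks(blocks)
  arrange(blocks, .data$chrom_a, .data$start_a)
}

validate_homology_blocks <- function(blocks) {
  len_a <- blocks$end_a - blocks$start_a
  len_b <- blocks$end_b - blocks$start_b
  bad <- which(len_a != len_b)
  if (length(bad) > 0) {
    abort(sprintf(
      "Homology block %d is not gapless: lengths %d (a) vs %d (b).",
      bad[1], len_a[bad[1]], len_b[bad[1]]
    ))
  }
  if (any(blocks$score < 0)) abort("Homology block scores must be >= 0.")
  invisible(blocks)
}

#' Write a homology-block map
#'
#' @param blocks Tibble as returned by [read_homology_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_homology_map <- function(blocks, path) {
  out <- select(blocks, "chrom_a", "start_a", "end_a", "chrom_b", "start_b",
                "end_b", "score", "strand_rel")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read an expression table
#'
#' @param path TSV with header columns `gene_id`, `line`, `replicate`, `tpm`.
#' @return A tibble with those columns; TPM must be non-negative.
#' @export
read_expression <- function(path) {
  expr <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(), line = readr::col_character(),
      replicate = readr::col_integer(), tpm = readr::col_double()
    ),
    progress = FALSE
  )
  if (any(expr$tpm < 0)) abort("TPM values must be non-negative.")
  expr
}

#' Write DMR calls as an annotated BED
#'
#' Writes the significant windows of a [call_dmrs()] result as a BED file
#' with extra columns `context`, `m_focal`, `m_ref`, `delta`, `p`, `q` and
#' `direction`, deterministically ordered by `(chrom, start, context)`.
#' A commented header line names the columns, so an empty DMR set yields a
#' header-only file.
#'
#' @param dmrs A tibble of DMR calls (only rows with `is_dmr = TRUE` are
#'   written when the column is present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if ("is_dmr" %in% names(dmrs)) dmrs <- filter(dmrs, .data$is_dmr)
  dmrs <- dmrs %>%
    mutate(context = factor(.data$context, levels = .CONTEXTS)) %>%
    arrange(.data$chrom, .data$start, .data$context) %>%
    mutate(context = as.character(.data$context))
  cols <- c("chrom", "start", "end", "context", "m_focal", "m_ref",
            "delta", "p", "q", "direction")
  header <- paste0("#", paste(cols, collapse = "\t"))
  body <- if (nrow(dmrs) > 0) {
    do.call(paste, c(lapply(cols, function(cl) {
      x <- dmrs[[cl]]
      if (is.double(x)) formatC(x, digits = 15, format = "g") else x
    }), sep = "\t"))
  } else {
    character()
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an annotated DMR BED written by [write_dmr_bed()]
#'
#' @param path Path to the file.
#' @return A tibble of DMRs (all rows flagged `is_dmr = TRUE`).
#' @export
read_dmr_bed <- function(path) {
  header <- readLines(path, n = 1L)
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  raw <- readr::read_tsv(
    path, col_names = cols, comment = "#",
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), context = readr::col_character(),
      direction = readr::col_character(), .default = readr::col_double()
    ),
    progress = FALSE
  )
  mutate(raw, is_dmr = TRUE)
}
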