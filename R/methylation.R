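# germline methylation calls from bisulfite count tables

#' Pool bisulfite counts over samples of one tissue
#'
#' Sums methylated and total read counts over all samples of a tissue and
#' over both strands of each CpG dinucleotide (methylation is treated as
#' strand symmetric), then computes the methylation ratio. Rows at positions
#' that do not host a reference CpG are skipped and counted in attribute
#' `"skipped"` when a genome is supplied.
#'
#' @param samples List of per-sample tibbles `chrom`, `pos` (0-based),
#'   `strand`, `methylated_reads`, `total_reads`. `-`-strand rows are
#'   assigned to the CpG whose C sits at `pos - 1`.
#' @param tissue Tissue label stored on the output.
#' @param genome Optional genome used to verify that positions host CpGs.
#' @return Tibble `chrom`, `pos` (C of the CpG, forward strand),
#'   `methylated_reads`, `total_reads`, `ratio` (NA when depth is 0),
#'   `tissue`, `n_samples`.
#' @export
pool_methylation <- function(samples, tissue, genome = NULL) {
  if (!is.list(samples) || length(samples) < 1) {
    abort("need at least one sample per tissue")
  }
  d <- bind_rows(samples)
  if (any(d$methylated_reads < 0 | d$total_reads < 0)) {
    abort("read counts must be non-negative")
  }
  if (any(d$methylated_reads > d$total_reads)) {
    abort("methylated_reads cannot exceed total_reads")
  }
  # collapse strands: the '-' strand row of a CpG sits one base after its C
  d$cpg_pos <- ifelse(d$strand == "-", d$pos - 1L, d$pos)
  skipped <- 0L
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    ok <- rep(FALSE, nrow(d))
    for (ch in unique(d$chrom)) {
      idx <- which(d$chrom == ch)
      if (!ch %in% names(genome)) next
      codes <- encode_bases(genome[[ch]])
      L <- length(codes)
      p <- d$cpg_pos[idx] + 1L
      valid <- p >= 1L & p < L
      is_cpg <- valid
      is_cpg[valid] <- !is.na(codes[p[valid]]) & codes[p[valid]] == 1L &
        !is.na(codes[p[valid] + 1L]) & codes[p[valid] + 1L] == 2L
      ok[idx] <- is_cpg
    }
    skipped <- sum(!ok)
    d <- d[ok, , drop = FALSE]
  }
  out <- d |>
    group_by(.data$chrom, pos = .data$cpg_pos) |>
    summarise(methylated_reads = sum(.data$methylated_reads),
              total_reads = sum(.data$total_reads), .groups = "drop") |>
    mutate(ratio = ifelse(.data$total_reads > 0,
                          .data$methylated_reads / .data$total_reads,
                          NA_real_),
           tissue = tissue, n_samples = length(samples)) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  out
}

#' Call germline-methylated CpG dinucleotides
#'
#' A CpG is called methylated iff its methylation ratio is at least
#' `ratio_min` in both tissues and its pooled depth in each tissue reaches
#' that tissue's threshold. With `depth_rule = "max"` (default) the
#' threshold is `max(fixed floor, 10 * n_samples)`; `"floor"` uses the
#' fixed floors alone (the two readings coincide at the default sample
#' counts of 2 testis-like and 3 ovary-like samples). Sites with undefined
#' ratio (zero depth) in either tissue are never called.
#'
#' @param testis_pooled,ovary_pooled Pooled tables from
#'   [pool_methylation()].
#' @param ratio_min Minimum methylation ratio in both tissues (default 0.7).
#' @param testis_depth_floor,ovary_depth_floor Fixed depth floors
#'   (defaults 20 and 30 reads).
#' @param depth_rule `"max"` or `"floor"` (see above).
#' @return Tibble `chrom`, `pos`, per-tissue ratio and depth columns, and
#'   logical `methylated`; one row per CpG present in both tables.
#' @export
call_germline_methylated <- function(testis_pooled, ovary_pooled,
                                     ratio_min = 0.7,
                                     testis_depth_floor = 20,
                                     ovary_depth_floor = 30,
                                     depth_rule = c("max", "floor")) {
  depth_rule <- match.arg(depth_rule)
  t_min <- if (depth_rule == "max") {
    max(testis_depth_floor, 10 * testis_pooled$n_samples[[1]])
  } else testis_depth_floor
  o_min <- if (depth_rule == "max") {
    max(ovary_depth_floor, 10 * ovary_pooled$n_samples[[1]])
  } else ovary_depth_floor
  t <- select(testis_pooled, "chrom", "pos",
              testis_ratio = "ratio", testis_depth = "total_reads")
  o <- select(ovary_pooled, "chrom", "pos",
              ovary_ratio = "ratio", ovary_depth = "total_reads")
  dplyr::full_join(t, o, by = c("chrom", "pos")) |>
    mutate(methylated =
             !is.na(.data$testis_ratio) & !is.na(.data$ovary_ratio) &
             .data$testis_ratio >= ratio_min & .data$ovary_ratio >= ratio_min &
             tidyr::replace_na(.data$testis_depth, 0) >= t_min &
             tidyr::replace_na(.data$ovary_depth, 0) >= o_min) |>
    arrange(.data$chrom, .data$pos)
}

#' CpG>TpG mutation opportunities of a methylated-CpG set
#'
#' Each methylated CpG dinucleotide offers two CpG>TpG opportunities: the C
#' on each strand.
#'
#' @param cpg_set Either a tibble with a logical `methylated` column (from
#'   [call_germline_methylated()]) or a plain count of methylated CpG
#'   dinucleotides.
#' @return Number of CpG>TpG mutation opportunities
#'   (`2 * n_methylated_dinucleotides`).
#' @export
cpg_mutation_opportunities <- function(cpg_set) {
  n <- if (is.numeric(cpg_set) && length(cpg_set) == 1) {
    cpg_set
  } else if (is.data.frame(cpg_set) && "methylated" %in% names(cpg_set)) {
    sum(cpg_set$methylated)
  } else {
    abort("cpg_set must be a methylation call table or a count")
  }
  if (n < 0) abort("count must be non-negative")
  2 * n
}

#' Write/read bedMethyl-like count tables
#'
#' Plain TSV with columns `chrom`, `pos` (0-based), `strand`,
#' `methylated_reads`, `total_reads`. `col_map` renames other dialects'
#' columns onto these on read.
#'
#' @param x Count tibble.
#' @param path File path.
#' @param col_map Named character vector mapping standard names to the
#'   file's names, e.g. `c(pos = "start")`.
#' @return `path` (write) or the count tibble (read).
#' @export
write_bedmethyl <- function(x, path) {
  readr::write_tsv(x[, c("chrom", "pos", "strand", "methylated_reads",
                         "total_reads")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_bedmethyl
#' @export
read_bedmethyl <- function(path, col_map = NULL) {
  std <- c("chrom", "pos", "strand", "methylated_reads", "total_reads")
  d <- readr::read_tsv(path, col_names = std, show_col_types = FALSE,
                       col_types = "cicii")
  if (!is.null(col_map)) {
    for (nm in names(col_map)) names(d)[names(d) == col_map[[nm]]] <- nm
  }
  d
}
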