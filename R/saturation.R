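# mutation-class saturation, spectra, and de novo recurrence

#' Count per-class mutation opportunities at reliable bases
#'
#' Each reliable A or T base is one opportunity for each of T>A, T>C and
#' T>G; each reliable C or G base one for each of C>A, C>G, and for
#' CpG>TpG or C>T(non-CpG) depending on whether it lies in a reference CpG
#' dinucleotide. Autosomes and chromosome X are tallied separately.
#'
#' @param genome Genome.
#' @param mask A `genome_mask`.
#' @param chrx_names Chromosome names treated as chrX (default
#'   `c("chrX", "X")`).
#' @return Tibble `scope` (`"autosomes"`/`"chrX"`), `class`,
#'   `opportunities`, complete over the seven classes per scope present.
#' @export
count_opportunities <- function(genome, mask, chrx_names = c("chrX", "X")) {
  genome <- as_genome(genome)
  acc <- list()
  for (ch in names(genome)) {
    codes <- encode_bases(genome[[ch]])
    rel <- mask_logical(mask, ch)
    scope <- if (ch %in% chrx_names) "chrX" else "autosomes"
    at <- rel & !is.na(codes) & (codes == 0L | codes == 3L)
    cg <- rel & !is.na(codes) & (codes == 1L | codes == 2L)
    cpg <- cpg_member_flags(codes)
    n_at <- sum(at)
    n_cg <- sum(cg)
    n_cpg <- sum(cg & cpg)
    cls <- mutation_classes()
    add <- setNames(c(n_at, n_at, n_at, n_cg, n_cg, n_cpg, n_cg - n_cpg), cls)
    acc[[scope]] <- (acc[[scope]] %||% setNames(numeric(7), cls)) + add
  }
  purrr::imap(acc, function(v, scope) {
    tibble(scope = scope, class = names(v), opportunities = unname(v))
  }) |> bind_rows()
}

normal_ci <- function(ratio, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(ratio * (1 - ratio) / n)
  list(low = pmax(ratio - half, 0), high = pmin(ratio + half, 1))
}

#' Per-class saturation ratios with confidence intervals
#'
#' Saturation of a class is the number of observed distinct (site, alt)
#' variants of that class divided by its opportunity count. The 95% CI uses
#' the normal approximation to the binomial, treating each site as an
#' independent observation, clipped to `[0, 1]`.
#'
#' @param variants SNV tibble with a `class` column (see
#'   [classify_variants()]); pre-filter to qualifying variants at reliable
#'   bases.
#' @param opportunities Opportunity tibble from [count_opportunities()].
#' @param chrx_names Chromosome names treated as chrX.
#' @return Tibble `scope`, `class`, `opportunities`, `observed`, `ratio`,
#'   `ci_low`, `ci_high` (class `saturation_report`). Classes with zero
#'   opportunities report `NA` ratios.
#' @export
saturation <- function(variants, opportunities, chrx_names = c("chrX", "X")) {
  if (!"class" %in% names(variants)) {
    abort("variants need a class column; see classify_variants()")
  }
  obs <- variants |>
    filter(!is.na(.data$class)) |>
    distinct(.data$chrom, .data$pos, .data$alt, .data$class) |>
    mutate(scope = ifelse(.data$chrom %in% chrx_names, "chrX", "autosomes")) |>
    count(.data$scope, .data$class, name = "observed")
  out <- opportunities |>
    left_join(obs, by = c("scope", "class")) |>
    mutate(observed = tidyr::replace_na(.data$observed, 0L),
           ratio = ifelse(.data$opportunities > 0,
                          .data$observed / .data$opportunities, NA_real_))
  ci <- normal_ci(out$ratio, out$opportunities)
  out$ci_low <- ci$low
  out$ci_high <- ci$high
  class(out) <- c("saturation_report", class(out))
  out
}

#' Mutation-class spectrum and Ts/Tv ratio
#'
#' Fraction of distinct (site, alt) SNVs in each of the seven classes, and
#' the transition:transversion ratio
#' `(T>C + CpG>TpG + C>T(non-CpG)) / (T>A + T>G + C>A + C>G)`.
#'
#' @param variants Classified SNV tibble.
#' @param subset `"all"`, `"singletons"` (`carrier_count == 1`) or
#'   `"non-singletons"`.
#' @return Tibble `class`, `n`, `fraction` with attributes `"ts_tv"`
#'   (NA when there are no transversions) and `"subset"`.
#' @export
class_spectrum <- function(variants, subset = c("all", "singletons",
                                                "non-singletons")) {
  subset <- match.arg(subset)
  if (!"class" %in% names(variants)) {
    abort("variants need a class column; see classify_variants()")
  }
  v <- filter(variants, !is.na(.data$class))
  if (subset != "all") {
    if (!"carrier_count" %in% names(v)) {
      abort("carrier_count needed for singleton subsets")
    }
    v <- if (subset == "singletons") filter(v, .data$carrier_count == 1L)
         else filter(v, .data$carrier_count != 1L)
  }
  v <- distinct(v, .data$chrom, .data$pos, .data$alt, .data$class)
  if (nrow(v) == 0) abort("no variants in the requested subset")
  counts <- v |> count(.data$class, name = "n")
  out <- tibble(class = mutation_classes()) |>
    left_join(counts, by = "class") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           fraction = .data$n / sum(.data$n))
  ts <- sum(out$n[out$class %in% c("T>C", "CpG>TpG", "C>T(non-CpG)")])
  tv <- sum(out$n[out$class %in% c("T>A", "T>G", "C>A", "C>G")])
  attr(out, "ts_tv") <- if (tv > 0) ts / tv else NA_real_
  attr(out, "subset") <- subset
  out
}

#' Ts/Tv ratio of a spectrum
#' @param spectrum Output of [class_spectrum()].
#' @return The transition:transversion ratio (NA if no transversions).
#' @export
ts_tv <- function(spectrum) attr(spectrum, "ts_tv")

#' Saturation at methylated CpG sites, stratified by label
#'
#' Each methylated CpG dinucleotide contributes two opportunities to the
#' label assigned at its C position; sites with several label rows take the
#' alphabetically last label; unlabelled sites are `"intergenic"`. Observed
#' counts are distinct CpG>TpG variant positions falling on either base of
#' a methylated CpG.
#'
#' @param cpg_set Methylation call table (see
#'   [call_germline_methylated()]); only `methylated` rows are used.
#' @param variants Classified SNV tibble.
#' @param labels Optional tibble `chrom`, `pos`, `label` mapping C positions
#'   to consequence or annotation labels (duplicates allowed).
#' @return `saturation_report` tibble: `label`, `opportunities`,
#'   `observed`, `ratio`, `ci_low`, `ci_high`.
#' @export
cpg_saturation_by_class <- function(cpg_set, variants, labels = NULL) {
  if (!"class" %in% names(variants)) {
    abort("variants need a class column; see classify_variants()")
  }
  mcpg <- filter(cpg_set, .data$methylated)
  lab <- if (is.null(labels)) {
    mutate(mcpg[, c("chrom", "pos")], label = "intergenic")
  } else {
    assigned <- labels |>
      arrange(.data$chrom, .data$pos, .data$label) |>
      group_by(.data$chrom, .data$pos) |>
      summarise(label = dplyr::last(.data$label), .groups = "drop")
    mcpg[, c("chrom", "pos")] |>
      left_join(assigned, by = c("chrom", "pos")) |>
      mutate(label = tidyr::replace_na(.data$label, "intergenic"))
  }
  # CpG>TpG variants mapped back to the C position of their dinucleotide
  v <- variants |>
    filter(.data$class == "CpG>TpG") |>
    mutate(cpg_pos = ifelse(.data$ref == "G", .data$pos - 1L, .data$pos)) |>
    distinct(.data$chrom, .data$pos, cpg_pos = .data$cpg_pos)
  obs <- v |>
    inner_join(lab, by = c("chrom", "cpg_pos" = "pos")) |>
    count(.data$label, name = "observed")
  out <- lab |>
    count(.data$label, name = "n_cpg") |>
    left_join(obs, by = "label") |>
    mutate(observed = tidyr::replace_na(.data$observed, 0L),
           opportunities = 2 * .data$n_cpg,
           ratio = .data$observed / .data$opportunities) |>
    select("label", "opportunities", "observed", "ratio")
  ci <- normal_ci(out$ratio, out$opportunities)
  out$ci_low <- ci$low
  out$ci_high <- ci$high
  class(out) <- c("saturation_report", class(out))
  out
}

#' De novo recurrence overlap with a population call set
#'
#' A de novo record overlaps if the same (chrom, pos, ref, alt) is present
#' in the population set; such variants must derive from at least two
#' independent mutational events. Duplicate de novo entries are deduplicated
#' with a warning.
#'
#' @param denovo Tibble `chrom`, `pos`, `ref`, `alt` (optionally `class`).
#' @param population SNV tibble on the same reference coordinates.
#' @return List of class `recurrence_overlap`: `n_denovo`, `n_overlap`,
#'   `percent` (1 decimal, round-half-up), `percent_raw`, and `by_class`
#'   (per-class overlap fractions and enrichment relative to the overall
#'   fraction; `NULL` without a `class` column).
#' @export
recurrence_overlap <- function(denovo, population) {
  key_cols <- c("chrom", "pos", "ref", "alt")
  dn <- distinct(denovo, dplyr::pick(dplyr::all_of(key_cols)), .keep_all = TRUE)
  if (nrow(dn) < nrow(denovo)) {
    warn(sprintf("deduplicated %d duplicate de novo entries",
                 nrow(denovo) - nrow(dn)))
  }
  popk <- distinct(population[, key_cols])
  hit <- dn |>
    dplyr::semi_join(popk, by = key_cols)
  n <- nrow(dn)
  k <- nrow(hit)
  pct_raw <- if (n > 0) 100 * k / n else NA_real_
  by_class <- NULL
  if ("class" %in% names(dn) && n > 0) {
    overall <- k / n
    by_class <- dn |>
      mutate(overlap = paste(.data$chrom, .data$pos, .data$ref, .data$alt) %in%
               paste(hit$chrom, hit$pos, hit$ref, hit$alt)) |>
      filter(!is.na(.data$class)) |>
      group_by(.data$class) |>
      summarise(n = n(), n_overlap = sum(.data$overlap),
                fraction = .data$n_overlap / .data$n, .groups = "drop") |>
      mutate(enrichment = .data$fraction / overall)
  }
  structure(
    list(n_denovo = n, n_overlap = k,
         percent = round_half_up(pct_raw, 1), percent_raw = pct_raw,
         by_class = by_class),
    class = "recurrence_overlap"
  )
}

#' @export
print.recurrence_overlap <- function(x, ...) {
  cat(sprintf("<recurrence_overlap> %d of %d de novo mutations (%.1f%%) found in the population set\n",
              x$n_overlap, x$n_denovo, x$percent))
  if (!is.null(x$by_class)) print(x$by_class)
  invisible(x)
}
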