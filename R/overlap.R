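# crossing two variant datasets against annotation regions; union-relative
# presence/absence percentages

# left-align and trim a single ref/alt pair; returns c(pos, ref, alt)
normalize_one <- function(pos, ref, alt) {
  # trim shared suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix, advancing pos
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Normalize variant allele representations
#'
#' Trims shared suffix then shared prefix bases from ref/alt (keeping at
#' least one base each) and advances the position accordingly, so that
#' differently decomposed representations of the same allele match on
#' (chrom, pos, ref, alt).
#'
#' @param variants Tibble `chrom`, `pos`, `ref`, `alt`.
#' @return Normalized tibble with attribute `"n_normalized"` (number of
#'   rows changed).
#' @export
normalize_variant_alleles <- function(variants) {
  needs <- which(nchar(variants$ref) > 1 & nchar(variants$alt) > 1)
  changed <- 0L
  for (i in needs) {
    nz <- normalize_one(variants$pos[[i]], variants$ref[[i]],
                        variants$alt[[i]])
    if (nz$pos != variants$pos[[i]] || nz$ref != variants$ref[[i]] ||
        nz$alt != variants$alt[[i]]) {
      variants$pos[[i]] <- nz$pos
      variants$ref[[i]] <- nz$ref
      variants$alt[[i]] <- nz$alt
      changed <- changed + 1L
    }
  }
  attr(variants, "n_normalized") <- changed
  variants
}

#' Partition two variant sets into intersection and unique sides
#'
#' Both sets are normalized (see [normalize_variant_alleles()]) and matched
#' on (chrom, pos, ref, alt).
#'
#' @param set_a,set_b Variant tibbles (`chrom`, `pos`, `ref`, `alt`).
#' @return List of class `variant_partition`: `intersection`, `unique_a`,
#'   `unique_b` (deduplicated tibbles).
#' @export
match_variants <- function(set_a, set_b) {
  key <- c("chrom", "pos", "ref", "alt")
  a <- distinct(normalize_variant_alleles(as_tibble(set_a))[, key])
  b <- distinct(normalize_variant_alleles(as_tibble(set_b))[, key])
  structure(
    list(
      intersection = dplyr::semi_join(a, b, by = key),
      unique_a = dplyr::anti_join(a, b, by = key),
      unique_b = dplyr::anti_join(b, a, by = key)
    ),
    class = "variant_partition"
  )
}

#' Union-relative presence/absence percentages from overlap counts
#'
#' Given per-annotation counts of set A variants, set B variants and their
#' intersection, computes percentages relative to the union
#' (`n_a + n_unique_b`): `present_b_pct = 100 * n_b / union`,
#' `missing_b_pct = 100 * (union - n_b) / union`,
#' `present_a_pct = 100 * n_a / union`,
#' `missing_a_pct = 100 * n_unique_b / union`. `*_pct` columns are rounded
#' half-up to 2 decimals; `*_raw` columns keep full precision.
#'
#' @param n_a,n_b,n_intersection Count vectors.
#' @return Tibble of counts and percentages.
#' @export
overlap_percentages <- function(n_a, n_b, n_intersection) {
  if (any(n_intersection > pmin(n_a, n_b))) {
    abort("n_intersection cannot exceed min(n_a, n_b)")
  }
  n_unique_b <- n_b - n_intersection
  union <- n_a + n_unique_b
  raw <- tibble(
    n_a = n_a, n_b = n_b, n_intersection = n_intersection,
    n_unique_b = n_unique_b, n_union = union,
    present_b_raw = 100 * n_b / union,
    missing_b_raw = 100 * (union - n_b) / union,
    present_a_raw = 100 * n_a / union,
    missing_a_raw = 100 * n_unique_b / union
  )
  raw |>
    mutate(
      present_b_pct = round_half_up(.data$present_b_raw, 2),
      missing_b_pct = round_half_up(.data$missing_b_raw, 2),
      present_a_pct = round_half_up(.data$present_a_raw, 2),
      missing_a_pct = round_half_up(.data$missing_a_raw, 2)
    )
}

# assign each variant exactly one annotation by precedence order; anything
# unassigned is "intergenic"
assign_annotation <- function(variants, annotations, precedence) {
  label <- rep("intergenic", nrow(variants))
  pts <- tibble(chrom = variants$chrom, start = variants$pos,
                end = variants$pos + 1L)
  for (nm in rev(intersect(precedence, names(annotations)))) {
    hit <- intervals_overlap_any(pts, annotations[[nm]])
    label[hit] <- nm
  }
  label
}

#' Per-annotation overlap table of two variant datasets
#'
#' Assigns every variant in the union exactly one annotation by the fixed
#' precedence order, then reports per-annotation counts and union-relative
#' presence/absence percentages (see [overlap_percentages()]).
#'
#' @param partition A `variant_partition` from [match_variants()].
#' @param annotations Named list of interval tibbles, highest precedence
#'   first (e.g. coding, splice, utr5, utr3, proximal); unmatched variants
#'   are `"intergenic"`.
#' @param precedence Annotation precedence order (default
#'   `names(annotations)`).
#' @return Tibble with one row per annotation (plus `intergenic`).
#' @export
overlap_table <- function(partition, annotations,
                          precedence = names(annotations)) {
  stopifnot(inherits(partition, "variant_partition"))
  u <- bind_rows(
    mutate(partition$intersection, in_a = TRUE, in_b = TRUE),
    mutate(partition$unique_a, in_a = TRUE, in_b = FALSE),
    mutate(partition$unique_b, in_a = FALSE, in_b = TRUE)
  )
  u$annotation <- assign_annotation(u, annotations, precedence)
  counts <- u |>
    group_by(.data$annotation) |>
    summarise(n_a = sum(.data$in_a), n_b = sum(.data$in_b),
              n_intersection = sum(.data$in_a & .data$in_b),
              .groups = "drop")
  order_levels <- c(precedence, "intergenic")
  counts <- counts |>
    mutate(annotation = factor(.data$annotation, levels = order_levels)) |>
    arrange(.data$annotation) |>
    mutate(annotation = as.character(.data$annotation))
  dplyr::bind_cols(
    counts["annotation"],
    overlap_percentages(counts$n_a, counts$n_b, counts$n_intersection)
  )
}
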