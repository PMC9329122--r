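# strand-collapsed mutation classes and heptamer-context mutation rates.
# Heptamers are encoded as base-4 integers (A=0, C=1, G=2, T=3), 0..4^7-1;
# the canonical heptamer of a site is the one whose central base is A or C
# (reverse complement otherwise), so tallies are strand-symmetric.

N_HEPTAMER <- 4L^7L

#' The seven strand-collapsed mutation classes
#'
#' `T>A`, `T>C`, `T>G`, `C>A`, `C>G`, `CpG>TpG` and `C>T(non-CpG)`.
#' A/G-reference substitutions map onto these via reverse complement; C>T is
#' split by whether the site lies in a CpG dinucleotide.
#'
#' @return Character vector of the seven class labels.
#' @export
mutation_classes <- function() {
  c("T>A", "T>C", "T>G", "C>A", "C>G", "CpG>TpG", "C>T(non-CpG)")
}

# full-length canonical heptamer code vector for one chromosome; NA at the
# three edge positions on each side and wherever the 7-mer contains a non-
# ACGT base
canonical_heptamer_codes <- function(codes) {
  L <- length(codes)
  out <- rep(NA_real_, L)
  if (L < 7L) return(out)
  centers <- 4L:(L - 3L)
  fwd <- 0
  for (k in -3:3) fwd <- fwd * 4 + codes[centers + k]
  rc <- 0
  for (k in 3:-3) rc <- rc * 4 + (3L - codes[centers + k])
  central <- codes[centers]
  out[centers] <- ifelse(!is.na(central) & central <= 1L, fwd, rc)
  out
}

heptamer_code_to_string <- function(code) {
  vapply(code, function(c1) {
    if (is.na(c1)) return(NA_character_)
    d <- integer(7)
    for (i in 7:1) {
      d[i] <- c1 %% 4
      c1 <- c1 %/% 4
    }
    paste(.code_base[d + 1L], collapse = "")
  }, character(1))
}

heptamer_string_to_code <- function(s) {
  vapply(s, function(x) {
    b <- encode_bases(x)
    if (length(b) != 7L || anyNA(b)) return(NA_real_)
    sum(b * 4^(6:0))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Canonical heptamer of a 7-mer
#'
#' Returns the input if its central base is A or C, otherwise its reverse
#' complement, so that each site and its complement share one canonical
#' context. `N`s away from the centre are propagated; an `N` (or any
#' non-ACGT base) at the central position is an error.
#'
#' @param seq7 Character vector of 7-base strings.
#' @return Character vector of canonical 7-mers.
#' @export
canonical_heptamer <- function(seq7) {
  if (any(nchar(seq7) != 7L)) abort("heptamers must be exactly 7 bases")
  central <- toupper(substr(seq7, 4L, 4L))
  if (any(!central %in% .code_base)) {
    abort("central base must be A, C, G or T")
  }
  up <- toupper(seq7)
  ifelse(central %in% c("A", "C"), up, revcomp(up))
}

#' Classify a single-nucleotide variant into a mutation class
#'
#' Strand-collapsed: A- and G-reference substitutions are mapped through the
#' reverse complement onto T- and C-reference classes. C>T at a CpG
#' dinucleotide (central C followed by G, or central G preceded by C on the
#' given strand) is `CpG>TpG`; other C>T is `C>T(non-CpG)`.
#'
#' @param context7 Character vector of 7-mers centred on the variant site.
#' @param ref_base,alt_base Reference and alternate alleles (single bases).
#' @return Character vector of class labels (see [mutation_classes()]).
#' @export
classify_snv <- function(context7, ref_base, alt_base) {
  if (any(nchar(context7) != 7L)) abort("context7 must be 7 bases")
  context7 <- toupper(context7)
  ref_base <- toupper(ref_base)
  alt_base <- toupper(alt_base)
  central <- substr(context7, 4L, 4L)
  if (any(central != ref_base)) {
    abort("central base of context7 must equal ref_base")
  }
  if (any(!ref_base %in% .code_base)) abort("N at central base")
  if (any(!alt_base %in% .code_base)) abort("alt_base must be A, C, G or T")
  if (any(ref_base == alt_base)) abort("ref_base and alt_base must differ")
  rc <- encode_bases(paste(ref_base, collapse = ""))
  ac <- encode_bases(paste(alt_base, collapse = ""))
  nxt <- encode_bases(paste(substr(context7, 5L, 5L), collapse = ""))
  prv <- encode_bases(paste(substr(context7, 3L, 3L), collapse = ""))
  classify_codes(rc, ac, prv, nxt)
}

# vectorized class computation on integer codes; prv/nxt may be NA (edge)
classify_codes <- function(ref, alt, prv, nxt) {
  purine <- ref == 0L | ref == 2L # A or G: collapse to complement strand
  cpg <- (ref == 1L & !is.na(nxt) & nxt == 2L) |
    (ref == 2L & !is.na(prv) & prv == 1L)
  ref2 <- ifelse(purine, 3L - ref, ref)
  alt2 <- ifelse(purine, 3L - alt, alt)
  out <- rep(NA_character_, length(ref))
  t_ref <- !is.na(ref2) & ref2 == 3L
  out[t_ref & alt2 == 0L] <- "T>A"
  out[t_ref & alt2 == 1L] <- "T>C"
  out[t_ref & alt2 == 2L] <- "T>G"
  c_ref <- !is.na(ref2) & ref2 == 1L
  out[c_ref & alt2 == 0L] <- "C>A"
  out[c_ref & alt2 == 2L] <- "C>G"
  out[c_ref & alt2 == 3L & cpg] <- "CpG>TpG"
  out[c_ref & alt2 == 3L & !cpg] <- "C>T(non-CpG)"
  out
}

#' Add a mutation-class column to a variant tibble
#'
#' Looks up each variant's 7-mer context in the genome and classifies it with
#' [classify_snv()] semantics. Variants that are not simple SNVs, disagree
#' with the reference base, or sit within 3 bp of a chromosome end or next
#' to an ambiguous context centre get `NA`.
#'
#' @param variants Tibble with `chrom`, `pos` (0-based), `ref`, `alt`.
#' @param genome Genome.
#' @return `variants` with a `class` column added.
#' @export
classify_variants <- function(variants, genome) {
  genome <- as_genome(genome)
  variants$class <- NA_character_
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    if (!ch %in% names(genome)) next
    codes <- encode_bases(genome[[ch]])
    L <- length(codes)
    p <- variants$pos[idx] + 1L # 1-based
    valid <- p >= 1L & p <= L &
      nchar(variants$ref[idx]) == 1L & nchar(variants$alt[idx]) == 1L &
      variants$ref[idx] %in% .code_base & variants$alt[idx] %in% .code_base
    rg <- rep(NA_integer_, length(idx))
    rg[valid] <- codes[p[valid]]
    ref_c <- encode_bases(paste(substr(variants$ref[idx], 1, 1), collapse = ""))
    valid <- valid & !is.na(rg) & rg == ref_c
    alt_c <- encode_bases(paste(substr(variants$alt[idx], 1, 1), collapse = ""))
    prv <- ifelse(p >= 2L, codes[pmax(p - 1L, 1L)], NA_integer_)
    nxt <- ifelse(p <= L - 1L, codes[pmin(p + 1L, L)], NA_integer_)
    cls <- classify_codes(ref_c, alt_c, prv, nxt)
    cls[!valid] <- NA_character_
    variants$class[idx] <- cls
  }
  variants
}

# shared qualification rule for rate fitting: a center position qualifies if
# its full 7-mer lies within the chromosome, is N-free, and the center is a
# reliable base. Returns list(canon, qualify, part) per chromosome.
heptamer_site_info <- function(genome, mask, partition_track = NULL) {
  genome <- as_genome(genome)
  purrr::imap(as.list(genome), function(seq, ch) {
    codes <- encode_bases(seq)
    canon <- canonical_heptamer_codes(codes)
    rel <- mask_logical(mask, ch)
    qualify <- !is.na(canon) & rel
    part <- if (is.null(partition_track)) {
      rep(1L, length(codes))
    } else {
      ifelse(intervals_to_logical(partition_track, ch, length(codes)), 2L, 1L)
    }
    list(canon = canon, qualify = qualify, part = part)
  })
}

partition_labels <- function(partition_track) {
  if (is.null(partition_track)) "all"
  else c("outside_CG_enriched", "inside_CG_enriched")
}

#' Tally heptamer occurrences (H)
#'
#' Counts, for every canonical heptamer, the positions whose full 7-mer lies
#' within the chromosome, is N-free, and whose central base is reliable.
#' Each qualifying position is counted exactly once (the non-overlapping
#' tiling of the genome partitions all positions). Counts are split by
#' whether the central base falls inside the C>G-enriched partition when a
#' `partition_track` is given.
#'
#' @param genome Genome.
#' @param mask A `genome_mask`.
#' @param partition_track Optional tibble `chrom`, `start`, `end` of
#'   C>G-enriched regions; `NULL` gives a single partition `"all"`.
#' @return Tibble `partition`, `heptamer`, `H` (rows with `H > 0`).
#' @export
tally_heptamers <- function(genome, mask, partition_track = NULL) {
  info <- heptamer_site_info(genome, mask, partition_track)
  labels <- partition_labels(partition_track)
  counts <- matrix(0, nrow = N_HEPTAMER, ncol = length(labels))
  for (chi in info) {
    for (p in seq_along(labels)) {
      sel <- chi$qualify & chi$part == p
      if (any(sel)) {
        counts[, p] <- counts[, p] +
          tabulate(chi$canon[sel] + 1L, nbins = N_HEPTAMER)
      }
    }
  }
  tidy_heptamer_counts(counts, labels, value = "H")
}

tidy_heptamer_counts <- function(counts, labels, value) {
  out <- purrr::map(seq_along(labels), function(p) {
    nz <- which(counts[, p] > 0)
    if (length(nz) == 0) return(NULL)
    tibble(partition = labels[[p]],
           heptamer = heptamer_code_to_string(nz - 1),
           !!value := counts[nz, p])
  }) |> bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(partition = character(), heptamer = character(),
                  !!value := numeric())
  }
  arrange(out, .data$partition, .data$heptamer)
}

# filter to qualifying SNVs: single-base ref/alt over ACGT, aa_score above
# threshold (strict, per the high-quality definition), carrier >= 1
filter_qualifying_snvs <- function(variants, aa_min = 0.5) {
  keep <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L &
    variants$ref %in% .code_base & variants$alt %in% .code_base &
    variants$ref != variants$alt
  if ("aa_score" %in% names(variants) && !is.null(aa_min)) {
    keep <- keep & variants$aa_score > aa_min
  }
  if ("carrier_count" %in% names(variants)) {
    keep <- keep & variants$carrier_count >= 1L
  }
  variants[keep, , drop = FALSE]
}

#' Tally heptamer variant sites (S) and compute rates
#'
#' Counts, per canonical heptamer and partition, the positions with at least
#' one qualifying SNV at the central base (sites, not alleles), and computes
#' the context mutation rate `rate = S / H`. Heptamers with `H = 0` are
#' excluded (rate undefined). Variant sites that fail the qualification rule
#' (masked out, N context, chromosome edge) are skipped and counted in
#' attribute `"skipped"`.
#'
#' @param variants SNV tibble (`chrom`, `pos`, `ref`, `alt`, optionally
#'   `aa_score`, `carrier_count`).
#' @param genome Genome.
#' @param mask A `genome_mask`.
#' @param partition_track Optional C>G-enriched region track (as in
#'   [tally_heptamers()]).
#' @param h_table Optional precomputed [tally_heptamers()] output (must use
#'   the same mask and partition); computed when `NULL`.
#' @param aa_min Quality threshold; only variants with `aa_score > aa_min`
#'   enter the tallies (default 0.5).
#' @return Tibble `partition`, `heptamer`, `H`, `S`, `rate`, of class
#'   `heptamer_rates`, with attribute `"skipped"`.
#' @export
tally_heptamer_variants <- function(variants, genome, mask,
                                    partition_track = NULL, h_table = NULL,
                                    aa_min = 0.5) {
  if (is.null(h_table)) {
    h_table <- tally_heptamers(genome, mask, partition_track)
  }
  v <- filter_qualifying_snvs(variants, aa_min)
  sites <- distinct(v, .data$chrom, .data$pos)
  info <- heptamer_site_info(genome, mask, partition_track)
  labels <- partition_labels(partition_track)
  counts <- matrix(0, nrow = N_HEPTAMER, ncol = length(labels))
  skipped <- 0L
  for (ch in unique(sites$chrom)) {
    chi <- info[[ch]]
    if (is.null(chi)) {
      skipped <- skipped + sum(sites$chrom == ch)
      next
    }
    p1 <- sites$pos[sites$chrom == ch] + 1L
    inb <- p1 >= 1L & p1 <= length(chi$canon)
    ok <- inb
    ok[inb] <- chi$qualify[p1[inb]]
    skipped <- skipped + sum(!ok)
    p1 <- p1[ok]
    for (p in seq_along(labels)) {
      sel <- chi$part[p1] == p
      if (any(sel)) {
        counts[, p] <- counts[, p] +
          tabulate(chi$canon[p1[sel]] + 1L, nbins = N_HEPTAMER)
      }
    }
  }
  s_table <- tidy_heptamer_counts(counts, labels, value = "S")
  out <- h_table |>
    left_join(s_table, by = c("partition", "heptamer")) |>
    mutate(S = tidyr::replace_na(.data$S, 0),
           rate = .data$S / .data$H)
  attr(out, "skipped") <- skipped
  class(out) <- c("heptamer_rates", class(out))
  out
}

# rate lookup matrix [heptamer code + 1, partition index]; partition columns
# with H = 0 for a heptamer fall back to the pooled rate across partitions;
# heptamers unseen everywhere contribute 0
rate_lookup_matrix <- function(rates, labels) {
  mat <- matrix(NA_real_, nrow = N_HEPTAMER, ncol = length(labels))
  codes <- heptamer_string_to_code(rates$heptamer)
  for (p in seq_along(labels)) {
    sel <- rates$partition == labels[[p]]
    mat[codes[sel] + 1L, p] <- rates$rate[sel]
  }
  pooled_tbl <- rates |>
    group_by(.data$heptamer) |>
    summarise(rate = sum(.data$S) / sum(.data$H), .groups = "drop")
  pooled <- rep(NA_real_, N_HEPTAMER)
  pooled[heptamer_string_to_code(pooled_tbl$heptamer) + 1L] <- pooled_tbl$rate
  for (p in seq_along(labels)) {
    miss <- is.na(mat[, p])
    mat[miss, p] <- pooled[miss]
  }
  mat[is.na(mat)] <- 0
  mat
}

#' Expected variant count per window from heptamer rates
#'
#' For each window, sums the context mutation rate over all qualifying
#' central positions in the window (same qualification rule as
#' [tally_heptamers()]): `E = sum(rate(canonical heptamer, partition))`.
#' Heptamers without a rate in a position's partition fall back to the
#' pooled rate; heptamers absent from the table contribute 0.
#'
#' @param windows Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param genome Genome.
#' @param rates A `heptamer_rates` table (from [tally_heptamer_variants()]).
#' @param mask A `genome_mask`.
#' @param partition_track Partition track matching the one used to fit
#'   `rates`.
#' @return `windows` with an `E` column added.
#' @export
expected_window_variants <- function(windows, genome, rates, mask,
                                     partition_track = NULL) {
  labels <- partition_labels(partition_track)
  if (!setequal(unique(rates$partition), intersect(labels, unique(rates$partition)))) {
    abort("rates partitions do not match partition_track")
  }
  mat <- rate_lookup_matrix(rates, labels)
  info <- heptamer_site_info(genome, mask, partition_track)
  windows$E <- 0
  for (ch in unique(windows$chrom)) {
    chi <- info[[ch]]
    wi <- which(windows$chrom == ch)
    if (is.null(chi)) next
    r <- numeric(length(chi$canon))
    q <- chi$qualify
    r[q] <- mat[chi$canon[q] + 1L, 1L]
    if (length(labels) > 1L) {
      q2 <- q & chi$part == 2L
      r[q2] <- mat[chi$canon[q2] + 1L, 2L]
    }
    cs <- c(0, cumsum(r))
    s <- pmax(windows$start[wi], 0L)
    e <- pmin(windows$end[wi], length(r))
    windows$E[wi] <- ifelse(e > s, cs[e + 1L] - cs[s + 1L], 0)
  }
  windows
}

#' Non-overlapping rate-fitting tiling of a genome
#'
#' The genome partition into consecutive `size`-bp chunks per chromosome,
#' including the trailing partial chunk, so every position belongs to
#' exactly one tile.
#'
#' @param genome Genome or named chromosome lengths.
#' @param size Tile size in bp (default 500).
#' @return Tibble `chrom`, `start`, `end`.
#' @export
tiling_windows <- function(genome, size = 500L) {
  lens <- if (is.numeric(genome)) setNames(as.integer(genome), names(genome))
          else genome_lengths(genome)
  purrr::imap(as.list(lens), function(L, ch) {
    starts <- seq(0L, L - 1L, by = size)
    tibble(chrom = ch, start = starts, end = pmin(starts + size, L))
  }) |> bind_rows()
}

#' Write/read a heptamer rate table as TSV
#' @param rates A `heptamer_rates` tibble.
#' @param path File path.
#' @return `path` (write) or the rates tibble (read).
#' @export
write_rates_tsv <- function(rates, path) {
  readr::write_tsv(as_tibble(rates), path)
  invisible(path)
}

#' @rdname write_rates_tsv
#' @export
read_rates_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           partition = readr::col_character(),
                           heptamer = readr::col_character(),
                           H = readr::col_double(),
                           S = readr::col_double(),
                           rate = readr::col_double()))
  class(out) <- c("heptamer_rates", class(out))
  out
}
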