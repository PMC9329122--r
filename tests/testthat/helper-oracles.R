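# brute-force per-base oracles, deliberately independent of the package's
# vectorized kernels: string scans and boolean position arrays only

orc_revcomp1 <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

orc_canonical <- function(s7) {
  if (substr(s7, 4, 4) %in% c("A", "C")) s7 else orc_revcomp1(s7)
}

# logical reliability array for one chromosome from a genome_mask
orc_mask_vec <- function(mask, chrom, L) {
  v <- logical(L)
  iv <- mask$intervals[mask$intervals$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    if (iv$end[i] > iv$start[i]) v[(iv$start[i] + 1):iv$end[i]] <- TRUE
  }
  v
}

# per-position H tally: named counts of canonical heptamers
orc_tally_h <- function(genome, mask) {
  counts <- list()
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    if (L < 7) next
    rel <- orc_mask_vec(mask, ch, L)
    for (i in 4:(L - 3)) {
      if (!rel[i]) next
      h7 <- substr(s, i - 3, i + 3)
      if (grepl("[^ACGT]", h7)) next
      k <- orc_canonical(h7)
      counts[[k]] <- (counts[[k]] %||% 0) + 1
    }
  }
  counts
}

# per-position S tally over distinct variant sites
orc_tally_s <- function(variants, genome, mask, aa_min = 0.5) {
  keep <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1 &
    variants$ref %in% c("A", "C", "G", "T") &
    variants$alt %in% c("A", "C", "G", "T")
  if ("aa_score" %in% names(variants)) keep <- keep & variants$aa_score > aa_min
  v <- unique(variants[keep, c("chrom", "pos")])
  counts <- list()
  for (r in seq_len(nrow(v))) {
    ch <- v$chrom[r]
    s <- genome[[ch]]
    L <- nchar(s)
    i <- v$pos[r] + 1
    if (i < 4 || i > L - 3) next
    if (!orc_mask_vec(mask, ch, L)[i]) next
    h7 <- substr(s, i - 3, i + 3)
    if (grepl("[^ACGT]", h7)) next
    k <- orc_canonical(h7)
    counts[[k]] <- (counts[[k]] %||% 0) + 1
  }
  counts
}

# per-base opportunity counts for one genome (single scope)
orc_opportunities <- function(genome, mask) {
  cls <- c("T>A", "T>C", "T>G", "C>A", "C>G", "CpG>TpG", "C>T(non-CpG)")
  out <- stats::setNames(numeric(7), cls)
  for (ch in names(genome)) {
    s <- genome[[ch]]
    L <- nchar(s)
    rel <- orc_mask_vec(mask, ch, L)
    for (i in seq_len(L)) {
      if (!rel[i]) next
      b <- substr(s, i, i)
      if (b %in% c("A", "T")) {
        out[c("T>A", "T>C", "T>G")] <- out[c("T>A", "T>C", "T>G")] + 1
      } else if (b %in% c("C", "G")) {
        out[c("C>A", "C>G")] <- out[c("C>A", "C>G")] + 1
        cpg <- (b == "C" && i < L && substr(s, i + 1, i + 1) == "G") ||
          (b == "G" && i > 1 && substr(s, i - 1, i - 1) == "C")
        if (cpg) out["CpG>TpG"] <- out["CpG>TpG"] + 1
        else out["C>T(non-CpG)"] <- out["C>T(non-CpG)"] + 1
      }
    }
  }
  out
}

# observed and expected counts for one window via per-position lookup
orc_window_oe <- function(chrom, start, end, variants, genome, mask, rates,
                          aa_min = 0.5) {
  s <- genome[[chrom]]
  L <- nchar(s)
  rel <- orc_mask_vec(mask, chrom, L)
  rate_of <- stats::setNames(rates$rate, rates$heptamer)
  E <- 0
  for (i in (start + 1):end) {
    if (i < 4 || i > L - 3 || !rel[i]) next
    h7 <- substr(s, i - 3, i + 3)
    if (grepl("[^ACGT]", h7)) next
    E <- E + (rate_of[[orc_canonical(h7)]] %||% 0)
  }
  keep <- variants$chrom == chrom & variants$pos >= start &
    variants$pos < end & nchar(variants$ref) == 1 &
    nchar(variants$alt) == 1
  if ("aa_score" %in% names(variants)) keep <- keep & variants$aa_score > aa_min
  keep <- keep & rel[variants$pos + 1]
  list(O = sum(keep), E = E)
}

# boolean-array interval intersection
orc_intersect_bp <- function(mask, intervals, chrom_lengths) {
  total <- 0
  for (ch in unique(intervals$chrom)) {
    L <- chrom_lengths[[ch]]
    a <- orc_mask_vec(mask, ch, L)
    b <- logical(L)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    for (i in seq_len(nrow(iv))) {
      if (iv$end[i] > iv$start[i]) {
        b[(iv$start[i] + 1):min(L, iv$end[i])] <- TRUE
      }
    }
    total <- total + sum(a & b)
  }
  total
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small literal genome + full mask fixture
mk_genome <- function(...) {
  g <- c(...)
  stopifnot(!is.null(names(g)))
  toupper(g)
}

rates_tbl_to_named <- function(rates) {
  stats::setNames(as.numeric(rates$H), rates$heptamer)
}
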