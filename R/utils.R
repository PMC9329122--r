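# shared helpers: rounding, interval arithmetic, seeding

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves going up (0.005 -> 0.01),
#' matching how percentages are conventionally printed in tables, unlike
#' [base::round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # the sqrt(eps) guard keeps floating-point representations of exact halves
  # (e.g. 2.675 stored as 2.67499...) rounding up
  sign(x) * trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# derive a deterministic sub-seed for an internal RNG stream; kept < 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 7919) %% 2147483629)
}

check_intervals <- function(x, what = "intervals") {
  if (is.null(x)) return(invisible(NULL))
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    abort(paste0(what, " must have columns chrom, start, end"))
  }
  if (any(x$start < 0) || any(x$end < x$start)) {
    abort(paste0(what, " must satisfy 0 <= start <= end"))
  }
  invisible(x)
}

check_intervals_in_bounds <- function(x, chrom_lengths, what = "intervals") {
  check_intervals(x, what)
  if (is.null(x) || nrow(x) == 0) return(invisible(x))
  bad_chrom <- setdiff(unique(x$chrom), names(chrom_lengths))
  if (length(bad_chrom)) {
    abort(paste0(what, ": unknown chromosome(s): ", paste(bad_chrom, collapse = ", ")))
  }
  if (any(x$end > unname(chrom_lengths[x$chrom]))) {
    abort(paste0(what, " extend beyond chromosome bounds"))
  }
  invisible(x)
}

# 0-based half-open tibble -> IRanges (1-based closed)
as_iranges0 <- function(x) {
  IRanges::IRanges(start = x$start + 1L, end = x$end)
}

iranges_to_tbl <- function(ir, chrom) {
  tibble(
    chrom = chrom,
    start = BiocGenerics::start(ir) - 1L,
    end = BiocGenerics::end(ir)
  )
}

# sort + merge touching/overlapping intervals within each chromosome
reduce_intervals <- function(x) {
  if (is.null(x) || nrow(x) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  x |>
    dplyr::group_split(.data$chrom) |>
    purrr::map(function(d) {
      ir <- IRanges::reduce(as_iranges0(d))
      iranges_to_tbl(ir, d$chrom[[1]])
    }) |>
    bind_rows() |>
    arrange(.data$chrom, .data$start)
}

# logical per-row flag: does each query interval overlap >= 1 bp of track?
# `track` may be intervals (start/end) or points (pos); points use [start,end).
intervals_overlap_any <- function(query, track) {
  if (is.null(track) || nrow(track) == 0) return(rep(FALSE, nrow(query)))
  if (!"start" %in% names(track) && "pos" %in% names(track)) {
    track <- tibble(chrom = track$chrom, start = track$pos, end = track$pos + 1L)
  }
  out <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    tr <- track[track$chrom == ch, , drop = FALSE]
    if (nrow(tr) == 0) next
    hits <- IRanges::overlapsAny(as_iranges0(query[qi, ]), as_iranges0(tr))
    out[qi] <- hits
  }
  out
}

# per-position logical membership vector of length len for one chromosome
intervals_to_logical <- function(intervals, chrom, len) {
  v <- logical(len)
  if (is.null(intervals)) return(v)
  d <- intervals[intervals$chrom == chrom, , drop = FALSE]
  if (nrow(d) == 0) return(v)
  for (i in seq_len(nrow(d))) {
    s <- max(0L, d$start[[i]])
    e <- min(len, d$end[[i]])
    if (e > s) v[(s + 1L):e] <- TRUE
  }
  v
}

`%||%` <- rlang::`%||%`
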