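# per-base reliability mask from coverage statistics

new_genome_mask <- function(chrom_lengths, intervals) {
  intervals <- as_tibble(intervals)
  check_intervals_in_bounds(intervals, chrom_lengths, "mask intervals")
  intervals <- arrange(intervals, .data$chrom, .data$start)
  # disjointness within chromosomes
  ok <- intervals |>
    group_by(.data$chrom) |>
    summarise(ok = all(.data$start >= dplyr::lag(.data$end, default = -1L)),
              .groups = "drop")
  if (!all(ok$ok)) abort("mask intervals must be disjoint and sorted")
  structure(
    list(chrom_lengths = chrom_lengths,
         intervals = select(intervals, "chrom", "start", "end")),
    class = "genome_mask"
  )
}

#' @export
print.genome_mask <- function(x, ...) {
  cat("<genome_mask>", length(x$chrom_lengths), "chromosome(s),",
      format(reliable_bp(x), big.mark = ","), "of",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","),
      "bp reliable\n")
  invisible(x)
}

#' Total reliable base pairs in a mask
#' @param mask A `genome_mask`.
#' @return Number of reliable bases.
#' @export
reliable_bp <- function(mask) {
  stopifnot(inherits(mask, "genome_mask"))
  sum(as.numeric(mask$intervals$end - mask$intervals$start))
}

#' Summarize per-individual depth tracks into per-base coverage statistics
#'
#' Computes, at every base, the mean and standard deviation of depth across
#' individuals. The s.d. uses the population divisor `n` by default (the
#' individuals are treated as the full summary set); set
#' `divisor = "n-1"` for the sample form.
#'
#' @param tracks List (length >= 2) of per-individual tibbles
#'   `chrom`, `pos` (0-based), `depth`, all on the same positions.
#' @param divisor `"n"` (population s.d., default) or `"n-1"`.
#' @return Tibble `chrom`, `pos`, `mean_depth`, `sd_depth`.
#' @export
summarize_coverage <- function(tracks, divisor = c("n", "n-1")) {
  divisor <- match.arg(divisor)
  if (!is.list(tracks) || length(tracks) < 2) {
    abort("need at least 2 depth tracks")
  }
  key0 <- paste(tracks[[1]]$chrom, tracks[[1]]$pos)
  for (t in tracks[-1]) {
    if (!identical(paste(t$chrom, t$pos), key0)) {
      abort("depth tracks disagree on chromosomes/positions")
    }
  }
  depth <- vapply(tracks, function(t) as.numeric(t$depth),
                  numeric(nrow(tracks[[1]])))
  if (nrow(tracks[[1]]) == 1L) depth <- matrix(depth, nrow = 1L)
  n <- length(tracks)
  m <- rowMeans(depth)
  ss <- rowMeans(depth^2) - m^2
  ss[ss < 0] <- 0
  s <- if (divisor == "n") sqrt(ss) else sqrt(ss * n / (n - 1))
  tibble(chrom = tracks[[1]]$chrom, pos = tracks[[1]]$pos,
         mean_depth = m, sd_depth = s)
}

#' Build the reliable-base mask from coverage statistics
#'
#' A base is reliable iff `mean_depth >= mean_min` and `sd_depth <= sd_max`
#' (both boundaries inclusive). Positions absent from `stats` count as depth
#' 0 and are therefore unreliable. Adjacent reliable bases are merged into
#' 0-based half-open intervals.
#'
#' @param stats Tibble `chrom`, `pos`, `mean_depth`, `sd_depth` (e.g. from
#'   [summarize_coverage()] or [generate_coverage_stats()]).
#' @param mean_min Minimum mean depth (default 20 reads).
#' @param sd_max Maximum s.d. of depth (default 12 reads).
#' @param chrom_lengths Optional named chromosome lengths; defaults to
#'   `max(pos) + 1` per chromosome in `stats`.
#' @return A `genome_mask`.
#' @export
build_reliable_mask <- function(stats, mean_min = 20, sd_max = 12,
                                chrom_lengths = NULL) {
  if (mean_min < 0 || sd_max < 0) abort("thresholds must be non-negative")
  if (is.null(chrom_lengths)) {
    chrom_lengths <- stats |>
      group_by(.data$chrom) |>
      summarise(len = max(.data$pos) + 1L, .groups = "drop")
    chrom_lengths <- setNames(chrom_lengths$len, chrom_lengths$chrom)
  }
  ok <- stats[stats$mean_depth >= mean_min & stats$sd_depth <= sd_max, ,
              drop = FALSE]
  intervals <- ok |>
    dplyr::group_split(.data$chrom) |>
    purrr::map(function(d) {
      p <- sort(unique(d$pos))
      if (length(p) == 0) return(NULL)
      run <- cumsum(c(1L, as.integer(diff(p) != 1L)))
      tibble(chrom = d$chrom[[1]],
             start = as.integer(tapply(p, run, min)),
             end = as.integer(tapply(p, run, max)) + 1L)
    }) |>
    bind_rows()
  if (nrow(intervals) == 0) {
    intervals <- tibble(chrom = character(), start = integer(), end = integer())
  }
  new_genome_mask(chrom_lengths, intervals)
}

#' Build a mask directly from intervals
#'
#' Used to rebuild a mask from its own BED dump (round trips are lossless)
#' or to construct fully-known masks in analyses and tests.
#'
#' @param intervals Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param chrom_lengths Named chromosome lengths.
#' @return A `genome_mask`.
#' @export
mask_from_intervals <- function(intervals, chrom_lengths) {
  new_genome_mask(chrom_lengths, reduce_intervals(intervals))
}

#' Fully-reliable mask over a genome
#' @param genome Genome or named chromosome lengths.
#' @return A `genome_mask` marking every base reliable.
#' @export
full_genome_mask <- function(genome) {
  lens <- if (is.numeric(genome)) {
    setNames(as.integer(genome), names(genome))
  } else {
    genome_lengths(genome)
  }
  mask_from_intervals(
    tibble(chrom = names(lens), start = 0L, end = unname(lens)), lens)
}

#' Intersect a mask with intervals
#'
#' @param mask A `genome_mask`.
#' @param intervals Tibble `chrom`, `start`, `end` (0-based half-open),
#'   within chromosome bounds.
#' @return List with `intervals` (tibble of the exact intersection) and
#'   `bp` (total intersected base pairs).
#' @export
mask_intersect <- function(mask, intervals) {
  stopifnot(inherits(mask, "genome_mask"))
  check_intervals(intervals)
  bad <- setdiff(unique(intervals$chrom), names(mask$chrom_lengths))
  if (length(bad)) {
    abort(paste0("unknown chromosome(s): ", paste(bad, collapse = ", ")))
  }
  out <- purrr::map(unique(intervals$chrom), function(ch) {
    mi <- mask$intervals[mask$intervals$chrom == ch, , drop = FALSE]
    qi <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(mi) == 0 || nrow(qi) == 0) return(NULL)
    ir <- IRanges::intersect(IRanges::reduce(as_iranges0(mi)),
                             IRanges::reduce(as_iranges0(qi)))
    if (length(ir) == 0) return(NULL)
    iranges_to_tbl(ir, ch)
  }) |> bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer())
  }
  list(intervals = arrange(out, .data$chrom, .data$start),
       bp = sum(as.numeric(out$end - out$start)))
}

# per-position logical reliability vector for one chromosome
mask_logical <- function(mask, chrom) {
  stopifnot(inherits(mask, "genome_mask"))
  L <- mask$chrom_lengths[[chrom]]
  if (is.null(L)) abort(paste0("unknown chromosome: ", chrom))
  intervals_to_logical(mask$intervals, chrom, L)
}

#' Write a mask as BED3
#' @param mask A `genome_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_bed <- function(mask, path) {
  stopifnot(inherits(mask, "genome_mask"))
  write_bed(mask$intervals, path)
}

#' Read a mask from BED3
#' @param path BED file path.
#' @param chrom_lengths Named chromosome lengths for the mask.
#' @return A `genome_mask`.
#' @export
read_mask_bed <- function(path, chrom_lengths) {
  mask_from_intervals(read_bed(path), chrom_lengths)
}
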