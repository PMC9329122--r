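# windowed depletion scoring and the DR percentile

#' Enumerate candidate scoring windows
#'
#' Windows of `size` bp every `step` bp, anchored at coordinate 0 of each
#' chromosome and fully contained in it; a window is retained iff at least
#' `min_reliable` of its bases are reliable.
#'
#' @param mask A `genome_mask`.
#' @param size Window size in bp (default 500).
#' @param step Step between window starts in bp (default 50).
#' @param min_reliable Minimum reliable bases per retained window
#'   (default 450).
#' @return Tibble `chrom`, `start`, `end`, `reliable_bp`.
#' @export
enumerate_windows <- function(mask, size = 500L, step = 50L,
                              min_reliable = 450L) {
  stopifnot(inherits(mask, "genome_mask"))
  if (step > size) abort("step must not exceed window size")
  out <- purrr::imap(as.list(mask$chrom_lengths), function(L, ch) {
    if (L < size) return(NULL)
    starts <- seq(0L, L - size, by = step)
    m <- mask_logical(mask, ch)
    cs <- c(0, cumsum(m))
    rel <- cs[starts + size + 1L] - cs[starts + 1L]
    keep <- rel >= min_reliable
    if (!any(keep)) return(NULL)
    tibble(chrom = ch, start = starts[keep], end = starts[keep] + size,
           reliable_bp = as.integer(rel[keep]))
  }) |> bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start = integer(), end = integer(),
                  reliable_bp = integer())
  }
  out
}

#' Score windows: observed, expected and depletion score
#'
#' `O` is the number of qualifying variant records (alt alleles by default)
#' at reliable bases within the window; `E` comes from
#' [expected_window_variants()]; the depletion score is `(O - E) / sqrt(E)`.
#' Windows whose variants have mean quality below `aa_min_mean` are failed
#' with reason `"low_mean_aa"` (zero-variant windows pass: no evidence
#' against them); windows with `E = 0` are unscorable
#' (`"zero_expected"`).
#'
#' @param windows Window tibble from [enumerate_windows()].
#' @param variants SNV tibble.
#' @param genome Genome.
#' @param rates A `heptamer_rates` table.
#' @param mask A `genome_mask`.
#' @param partition_track Partition track matching `rates`.
#' @param aa_min_mean Minimum mean variant quality per window (default
#'   0.85).
#' @param aa_min Per-variant quality threshold (default 0.5).
#' @param count `"alleles"` counts each variant record; `"sites"` counts
#'   distinct positions.
#' @return `windows` with `O`, `E`, `score`, `mean_aa`, `pass`, `reason`.
#' @export
score_windows <- function(windows, variants, genome, rates, mask,
                          partition_track = NULL, aa_min_mean = 0.85,
                          aa_min = 0.5, count = c("alleles", "sites")) {
  count <- match.arg(count)
  v <- filter_qualifying_snvs(variants, aa_min)
  if (!"aa_score" %in% names(v)) v$aa_score <- 1
  windows <- expected_window_variants(windows, genome, rates, mask,
                                      partition_track)
  windows$O <- 0
  windows$sum_aa <- 0
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    L <- mask$chrom_lengths[[ch]]
    if (is.null(L)) next
    rel <- mask_logical(mask, ch)
    vc <- v[v$chrom == ch & v$pos >= 0 & v$pos < L, , drop = FALSE]
    vc <- vc[rel[vc$pos + 1L], , drop = FALSE]
    if (count == "sites") {
      vc <- vc |>
        group_by(.data$pos) |>
        summarise(aa_score = mean(.data$aa_score), .groups = "drop")
    }
    cnt <- numeric(L)
    saa <- numeric(L)
    if (nrow(vc) > 0) {
      cnt <- tabulate(vc$pos + 1L, nbins = L)
      agg <- rowsum(vc$aa_score, vc$pos)
      saa[as.integer(rownames(agg)) + 1L] <- agg[, 1L]
    }
    cso <- c(0, cumsum(cnt))
    csa <- c(0, cumsum(saa))
    s <- windows$start[wi]; e <- windows$end[wi]
    windows$O[wi] <- cso[e + 1L] - cso[s + 1L]
    windows$sum_aa[wi] <- csa[e + 1L] - csa[s + 1L]
  }
  windows |>
    mutate(
      mean_aa = ifelse(.data$O > 0, .data$sum_aa / .data$O, NA_real_),
      score = ifelse(.data$E > 0, (.data$O - .data$E) / sqrt(.data$E), NA_real_),
      reason = dplyr::case_when(
        .data$E <= 0 ~ "zero_expected",
        .data$O > 0 & .data$mean_aa < aa_min_mean ~ "low_mean_aa",
        TRUE ~ "ok"
      ),
      pass = .data$reason == "ok"
    ) |>
    select(-"sum_aa")
}

#' Assign Depletion Rank percentiles
#'
#' Sorts the passing windows by depletion score and assigns the window with
#' the i-th lowest score `DR = 100 * (i - 0.5) / n`. Exactly tied scores
#' receive the mean of their positional DRs, keeping the assignment
#' deterministic and permutation-invariant. DR lies strictly inside
#' (0, 100); low DR means stronger depletion (stronger constraint).
#'
#' @param windows Scored window tibble (needs a `score` column; rows with a
#'   `pass` column are filtered to `pass == TRUE`).
#' @param cohort Optional cohort label stored in the track's provenance.
#' @return A `dr_track`: the passing windows sorted by position with a `dr`
#'   column.
#' @export
assign_dr <- function(windows, cohort = NULL) {
  if (!"score" %in% names(windows)) abort("windows must carry a score column")
  w <- if ("pass" %in% names(windows)) windows[windows$pass, , drop = FALSE] else windows
  w <- w[is.finite(w$score), , drop = FALSE]
  n <- nrow(w)
  if (n < 1) abort("no scored windows to rank")
  r <- rank(w$score, ties.method = "average")
  w$dr <- 100 * (r - 0.5) / n
  w <- arrange(w, .data$chrom, .data$start)
  structure(w, class = c("dr_track", class(tibble())),
            provenance = list(n = n, cohort = cohort))
}

#' @export
print.dr_track <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<dr_track>", prov$n, "windows",
      if (!is.null(prov$cohort)) paste0("(cohort ", prov$cohort, ")") else "",
      "\n")
  NextMethod()
}

#' @rdname assign_dr
#' @param x A `dr_track`.
#' @param ... Unused.
#' @export
tidy.dr_track <- function(x, ...) {
  out <- as_tibble(x)
  attr(out, "provenance") <- NULL
  out
}

#' @rdname assign_dr
#' @export
glance.dr_track <- function(x, ...) {
  tibble(
    n_windows = nrow(x),
    mean_dr = mean(x$dr),
    mean_score = mean(x$score),
    sd_score = sd(x$score),
    min_dr = min(x$dr),
    max_dr = max(x$dr)
  )
}

#' Cohort-restricted Depletion Rank
#'
#' Refits heptamer rates and rescores windows using only variants present in
#' the given cohort (variants must carry a `cohorts` list-column of labels).
#'
#' @param variants SNV tibble with a `cohorts` list-column.
#' @param cohort Cohort label (e.g. `"XAF"`).
#' @param genome Genome.
#' @param mask A `genome_mask`.
#' @param windows Optional precomputed windows (default
#'   [enumerate_windows()] on `mask`).
#' @param partition_track Optional C>G-enriched region track.
#' @param ... Passed to [score_windows()].
#' @return A `dr_track` labelled with the cohort.
#' @export
cohort_dr <- function(variants, cohort, genome, mask, windows = NULL,
                      partition_track = NULL, ...) {
  if (!"cohorts" %in% names(variants)) {
    abort("variants must carry a cohorts list-column")
  }
  keep <- purrr::map_lgl(variants$cohorts, ~ cohort %in% .x)
  if (!any(keep)) abort(paste0("unknown or empty cohort: ", cohort))
  v <- variants[keep, , drop = FALSE]
  windows <- windows %||% enumerate_windows(mask)
  rates <- tally_heptamer_variants(v, genome, mask, partition_track)
  scored <- score_windows(windows, v, genome, rates, mask, partition_track, ...)
  assign_dr(scored, cohort = cohort)
}

#' Write a DR track as bedGraph or full TSV
#'
#' The bedGraph carries `chrom`, `start`, `end`, `dr`; the TSV additionally
#' carries `O`, `E`, `score`, `reliable_bp` and `mean_aa`. Floats are
#' written with `%.6g` for reproducibility.
#'
#' @param track A `dr_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dr_bedgraph <- function(track, path) {
  lines <- sprintf("%s\t%d\t%d\t%.6g", track$chrom, track$start, track$end,
                   track$dr)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dr_bedgraph
#' @export
write_dr_tsv <- function(track, path) {
  d <- tidy(track) |>
    mutate(across(dplyr::where(is.double), ~ as.numeric(sprintf("%.6g", .x))))
  readr::write_tsv(d, path)
  invisible(path)
}

#' Read a DR track written by [write_dr_tsv()]
#' @param path TSV path.
#' @return A `dr_track`.
#' @export
read_dr_tsv <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  structure(d, class = c("dr_track", class(tibble())),
            provenance = list(n = nrow(d), cohort = NULL))
}
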