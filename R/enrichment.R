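# downstream DR statistics: FRV, tail enrichment, odds ratios, gene-level
# regressions, distance profiles

#' Fraction of rare variants by DR bin
#'
#' Each variant is assigned the mean DR of the scored windows containing it
#' and binned; the FRV of a bin is the fraction of its variants carried by
#' at most `carrier_max` individuals.
#'
#' @param variants SNV tibble with `carrier_count`.
#' @param dr_track A `dr_track`.
#' @param carrier_max Rare-variant carrier threshold (default 4).
#' @param bins DR bin boundaries (default deciles `seq(0, 100, 10)`).
#' @param exclude Optional interval track; variants inside it are dropped
#'   (e.g. coding exons for the non-coding restriction).
#' @return Tibble `bin_low`, `bin_high`, `n`, `frv` (NA for empty bins).
#' @export
frv_by_dr <- function(variants, dr_track, carrier_max = 4,
                      bins = seq(0, 100, by = 10), exclude = NULL) {
  if (!"carrier_count" %in% names(variants)) {
    abort("variants must carry carrier_count")
  }
  v <- variants
  if (!is.null(exclude)) {
    inside <- intervals_overlap_any(
      tibble(chrom = v$chrom, start = v$pos, end = v$pos + 1L), exclude)
    v <- v[!inside, , drop = FALSE]
  }
  w <- tidy(dr_track)
  v$dr <- NA_real_
  for (ch in unique(v$chrom)) {
    vi <- which(v$chrom == ch)
    wc <- w[w$chrom == ch, , drop = FALSE]
    if (nrow(wc) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = v$pos[vi] + 1L, width = 1L),
      as_iranges0(wc))
    mean_dr <- tapply(wc$dr[S4Vectors::subjectHits(hits)],
                      S4Vectors::queryHits(hits), mean)
    v$dr[vi[as.integer(names(mean_dr))]] <- unname(mean_dr)
  }
  v <- v[!is.na(v$dr), , drop = FALSE]
  v$bin <- cut(v$dr, breaks = bins, include.lowest = TRUE)
  out <- tibble(bin_low = head(bins, -1), bin_high = bins[-1],
                bin = levels(cut(numeric(), breaks = bins, include.lowest = TRUE)))
  stats <- v |>
    group_by(bin = as.character(.data$bin)) |>
    summarise(n = n(), frv = mean(.data$carrier_count <= carrier_max),
              .groups = "drop")
  out |>
    left_join(stats, by = "bin") |>
    mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    select("bin_low", "bin_high", "n", "frv")
}

#' Fold enrichment of a feature track in a DR tail
#'
#' Fold = (feature density among tail windows) / (feature density among all
#' retained windows), where a window carries the feature if it overlaps a
#' feature interval by at least 1 bp (or contains a feature point). Windows
#' overlapping the exclusion track are removed first. The CI and P value
#' come from a bootstrap over windows; with the default 2,500 replicates the
#' smallest attainable two-sided P is 0.0004.
#'
#' @param dr_track A `dr_track`.
#' @param features Interval tibble (`chrom`, `start`, `end`) or point tibble
#'   (`chrom`, `pos`).
#' @param q Tail size in DR percentage points, in (0, 50].
#' @param tail `"low"` (most depleted) or `"high"`.
#' @param exclude Optional interval track of windows to remove (e.g. coding
#'   exons).
#' @param n_boot Bootstrap replicates (default 2500).
#' @param level CI level (default 0.95).
#' @param seed Optional seed for the bootstrap.
#' @return One-row tibble of class `enrichment_result`: `kind`, `estimate`,
#'   `ci_low`, `ci_high`, `p_value`, `q`, `tail`, `n_windows`, `n_tail`.
#' @export
tail_enrichment <- function(dr_track, features, q = 1,
                            tail = c("low", "high"), exclude = NULL,
                            n_boot = 2500, level = 0.95, seed = NULL) {
  tail <- match.arg(tail)
  if (q <= 0 || q > 50) abort("q must lie in (0, 50]")
  w <- tidy(dr_track)
  if (!is.null(exclude)) {
    w <- w[!intervals_overlap_any(w, exclude), , drop = FALSE]
  }
  if (nrow(w) == 0) abort("no windows retained after exclusion")
  feat <- intervals_overlap_any(w, features)
  in_tail <- if (tail == "low") w$dr <= q else w$dr >= 100 - q
  if (!any(in_tail)) abort("empty DR tail after exclusion")
  fold_of <- function(f, t) (sum(f & t) / sum(t)) / (sum(f) / length(f))
  est <- fold_of(feat, in_tail)
  boot <- function() {
    n <- length(feat)
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    fm <- matrix(feat[idx], nrow = n_boot)
    tm <- matrix(in_tail[idx], nrow = n_boot)
    n_tail_b <- rowSums(tm)
    n_feat_b <- rowSums(fm)
    fold_b <- (rowSums(fm & tm) / n_tail_b) / (n_feat_b / n)
    fold_b[is.finite(fold_b)]
  }
  fold_b <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  ci <- quantile(fold_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                 na.rm = TRUE, names = FALSE)
  p <- max(2 * min(mean(fold_b <= 1), mean(fold_b >= 1)), 1 / n_boot)
  p <- min(p, 1)
  out <- tibble(kind = "fold", estimate = est,
                ci_low = ci[[1]], ci_high = ci[[2]], p_value = p,
                q = q, tail = tail,
                n_windows = length(feat), n_tail = sum(in_tail))
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Odds ratio of a 2x2 table with Wald confidence interval
#'
#' `OR = a*d / (b*c)` with the Wald CI
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is 0,
#' the Haldane-Anscombe correction adds 0.5 to every cell; when both cells
#' of a row or column are 0 the OR is undefined and reported missing.
#'
#' @param a,b,c,d Non-negative cell counts (a = exposed cases, b = exposed
#'   controls, c = unexposed cases, d = unexposed controls).
#' @param level CI level (default 0.95).
#' @return One-row tibble: `estimate`, `ci_low`, `ci_high`, `p_value`,
#'   `corrected`.
#' @export
odds_ratio_2x2 <- function(a, b, c, d, level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("cell counts must be non-negative")
  degenerate <- (a == 0 && b == 0) || (c == 0 && d == 0) ||
    (a == 0 && c == 0) || (b == 0 && d == 0)
  if (degenerate) {
    return(tibble(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  p_value = NA_real_, corrected = NA))
  }
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  est <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    estimate = est,
    ci_low = exp(log(est) - z * se),
    ci_high = exp(log(est) + z * se),
    p_value = 2 * pnorm(-abs(log(est) / se)),
    corrected = corrected
  )
}

#' cCRE enrichment odds ratios in low-DR tails
#'
#' For each feature track and tail percentile, forms the 2x2 table of
#' retained windows (in tail x overlapping the track) and computes the odds
#' ratio via [odds_ratio_2x2()]. Windows overlapping the exclusion track
#' (e.g. coding exons) are removed first.
#'
#' @param dr_track A `dr_track`.
#' @param tracks Named list of interval tibbles.
#' @param percentiles DR tail percentiles (default `c(1, 5)`).
#' @param exclude Optional exclusion track.
#' @return Tibble `track`, `percentile`, `a`..`d`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `corrected`.
#' @export
ccre_enrichment <- function(dr_track, tracks, percentiles = c(1, 5),
                            exclude = NULL) {
  w <- tidy(dr_track)
  if (!is.null(exclude)) {
    w <- w[!intervals_overlap_any(w, exclude), , drop = FALSE]
  }
  purrr::map(names(tracks), function(nm) {
    feat <- intervals_overlap_any(w, tracks[[nm]])
    purrr::map(percentiles, function(q) {
      in_tail <- w$dr <= q
      a <- sum(in_tail & feat); b <- sum(in_tail & !feat)
      c_ <- sum(!in_tail & feat); d <- sum(!in_tail & !feat)
      dplyr::bind_cols(tibble(track = nm, percentile = q,
                              a = a, b = b, c = c_, d = d),
                       odds_ratio_2x2(a, b, c_, d))
    }) |> bind_rows()
  }) |> bind_rows()
}

#' Residualize one score on another
#'
#' Ordinary least squares residuals of `y` regressed on `x`; the residuals
#' have mean 0 and are uncorrelated with `x`.
#'
#' @param y,x Numeric vectors.
#' @return Residual vector.
#' @export
residualize <- function(y, x) {
  unname(resid(lm(y ~ x)))
}

#' Aggregate DR over a gene's exonic windows
#'
#' @param dr_track A `dr_track`.
#' @param exons Tibble `chrom`, `start`, `end`, `gene`.
#' @param stat `"mean"` (default) or `"median"`.
#' @return Tibble `gene`, `n_windows`, `dr_aggregate`.
#' @export
aggregate_gene_dr <- function(dr_track, exons, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- if (stat == "mean") mean else stats::median
  w <- tidy(dr_track)
  purrr::map(unique(exons$chrom), function(ch) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    ec <- exons[exons$chrom == ch, , drop = FALSE]
    if (nrow(wc) == 0 || nrow(ec) == 0) return(NULL)
    hits <- IRanges::findOverlaps(as_iranges0(wc), as_iranges0(ec))
    if (length(hits) == 0) return(NULL)
    tibble(gene = ec$gene[S4Vectors::subjectHits(hits)],
           dr = wc$dr[S4Vectors::queryHits(hits)])
  }) |>
    bind_rows() |>
    distinct() |>
    group_by(.data$gene) |>
    summarise(n_windows = n(), dr_aggregate = f(.data$dr), .groups = "drop")
}

#' Regressions of gene-level DR on external constraint scores
#'
#' Ordinary least squares of the DR aggregate on LOEUF, on GERP, and on
#' LOEUF|GERP (the residuals of LOEUF regressed on GERP, a human-specific
#' constraint proxy). `r_squared` is the squared sample correlation; the P
#' value is the standard two-sided slope test.
#'
#' @param gene_table Tibble with `dr_aggregate`, `loeuf`, `gerp`.
#' @return Tibble `model`, `n`, `slope`, `r_squared`, `p_value`.
#' @export
gene_dr_regressions <- function(gene_table) {
  need <- c("dr_aggregate", "loeuf", "gerp")
  if (!all(need %in% names(gene_table))) {
    abort("gene_table needs dr_aggregate, loeuf and gerp columns")
  }
  d <- gene_table[complete.cases(gene_table[, need]), , drop = FALSE]
  if (nrow(d) < 3) abort("need at least 3 genes with complete scores")
  if (sd(d$loeuf) == 0 || sd(d$gerp) == 0) {
    abort("zero-variance predictor")
  }
  d$loeuf_given_gerp <- residualize(d$loeuf, d$gerp)
  fit_one <- function(nm, x) {
    fit <- lm(d$dr_aggregate ~ x)
    s <- summary(fit)
    tibble(model = nm, n = nrow(d),
           slope = unname(coef(fit)[2]),
           r_squared = s$r.squared,
           p_value = s$coefficients[2, 4])
  }
  bind_rows(
    fit_one("dr~loeuf", d$loeuf),
    fit_one("dr~gerp", d$gerp),
    fit_one("dr~loeuf|gerp", d$loeuf_given_gerp)
  )
}

#' Mean DR by distance from the nearest exon
#'
#' Non-exonic windows are assigned the distance (bp gap) to the nearest
#' exon and that exon's gene; optionally stratified by LOEUF decile of the
#' gene. Means and normal-approximation 95% CIs treat genes as independent
#' units (per-gene means are averaged within each bin).
#'
#' @param dr_track A `dr_track`.
#' @param exons Tibble `chrom`, `start`, `end`, `gene` (nonempty).
#' @param gene_scores Optional tibble `gene`, `loeuf` for decile
#'   stratification.
#' @param breaks Distance bin boundaries in bp.
#' @param n_deciles Number of LOEUF quantile groups (default 10).
#' @return Tibble `distance_bin` (, `loeuf_decile`), `n_genes`,
#'   `n_windows`, `mean_dr`, `ci_low`, `ci_high`.
#' @export
dr_vs_distance <- function(dr_track, exons, gene_scores = NULL,
                           breaks = c(0, 500, 1000, 2000, 5000, 10000, Inf),
                           n_deciles = 10) {
  if (nrow(exons) == 0) abort("exon track must be nonempty")
  w <- tidy(dr_track)
  rows <- purrr::map(unique(w$chrom), function(ch) {
    wc <- w[w$chrom == ch, , drop = FALSE]
    ec <- exons[exons$chrom == ch, , drop = FALSE]
    if (nrow(wc) == 0 || nrow(ec) == 0) return(NULL)
    wir <- as_iranges0(wc)
    eir <- as_iranges0(ec)
    exonic <- IRanges::overlapsAny(wir, eir)
    wc <- wc[!exonic, , drop = FALSE]
    if (nrow(wc) == 0) return(NULL)
    wir <- wir[!exonic]
    near <- IRanges::nearest(wir, eir)
    dist <- IRanges::distance(wir, eir[near])
    tibble(gene = ec$gene[near], distance = as.numeric(dist), dr = wc$dr)
  }) |> bind_rows()
  if (nrow(rows) == 0) {
    return(tibble(distance_bin = character(), n_genes = integer(),
                  n_windows = integer(), mean_dr = numeric(),
                  ci_low = numeric(), ci_high = numeric()))
  }
  rows$distance_bin <- cut(rows$distance, breaks = breaks,
                           include.lowest = TRUE)
  grouping <- "distance_bin"
  if (!is.null(gene_scores)) {
    gs <- gene_scores |>
      mutate(loeuf_decile = dplyr::ntile(.data$loeuf, n_deciles))
    rows <- left_join(rows, gs[, c("gene", "loeuf_decile")], by = "gene")
    grouping <- c(grouping, "loeuf_decile")
  }
  rows |>
    group_by(dplyr::pick(dplyr::all_of(c(grouping, "gene")))) |>
    summarise(gene_mean = mean(.data$dr), nw = n(), .groups = "drop") |>
    group_by(dplyr::pick(dplyr::all_of(grouping))) |>
    summarise(
      n_genes = n(), n_windows = sum(.data$nw),
      mean_dr = mean(.data$gene_mean),
      ci_low = .data$mean_dr -
        1.96 * sd(.data$gene_mean) / sqrt(.data$n_genes),
      ci_high = .data$mean_dr +
        1.96 * sd(.data$gene_mean) / sqrt(.data$n_genes),
      .groups = "drop"
    ) |>
    mutate(distance_bin = as.character(.data$distance_bin))
}
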