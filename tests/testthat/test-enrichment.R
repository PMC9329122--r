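# FRV, tail enrichment, odds ratios, gene regressions, distance profiles

mk_track <- function(n, scores = NULL, chrom = "chr1", step = 500L) {
  w <- tibble::tibble(chrom = chrom,
                      start = seq(0L, by = step, length.out = n),
                      end = start + step,
                      score = scores %||% seq_len(n))
  assign_dr(w)
}

test_that("odds_ratio_2x2 matches hand computation and handles zeros", {
  r <- odds_ratio_2x2(10, 90, 5, 95)
  expect_equal(r$estimate, 10 * 95 / (90 * 5))
  expect_false(r$corrected)
  expect_true(r$ci_low < r$estimate && r$estimate < r$ci_high)
  expect_equal(odds_ratio_2x2(7, 7, 7, 7)$estimate, 1)
  # Haldane-Anscombe correction from (0.5, 10.5, 5.5, 95.5)
  rc <- odds_ratio_2x2(0, 10, 5, 95)
  expect_true(rc$corrected)
  expect_equal(rc$estimate, 0.5 * 95.5 / (10.5 * 5.5))
  # two zeros in a margin -> undefined
  expect_true(is.na(odds_ratio_2x2(0, 0, 5, 95)$estimate))
  expect_true(is.na(odds_ratio_2x2(0, 10, 0, 95)$estimate))
  expect_error(odds_ratio_2x2(-1, 1, 1, 1), "non-negative")
})

test_that("odds_ratio_2x2 equals the probability-ratio oracle on small tables", {
  # OR = [a/(a+b)] / [b/(a+b)] over [c/(c+d)] / [d/(c+d)] = (a/b)/(c/d)
  withr::with_seed(10, {
    cells <- expand.grid(a = c(1, 3, 9, 20), b = c(1, 4, 20),
                         c = c(1, 5, 20), d = c(2, 7, 20))
  })
  for (i in seq_len(nrow(cells))) {
    with(cells[i, ], {
      got <- odds_ratio_2x2(a, b, c, d)$estimate
      want <- (a / b) / (c / d)
      expect_equal(got, want)
    })
  }
})

test_that("tail enrichment fold matches the density arithmetic", {
  tr <- mk_track(100)
  w <- tidy(tr)
  low10 <- w[w$dr <= 10, ]
  # all features inside a 10% tail -> fold = 10
  r <- tail_enrichment(tr, low10[, c("chrom", "start", "end")], q = 10,
                       n_boot = 200, seed = 1)
  expect_equal(r$estimate, 10)
  # features only outside the tail -> fold 0
  out_t <- w[w$dr > 10, c("chrom", "start", "end")]
  r0 <- tail_enrichment(tr, out_t, q = 10, n_boot = 200, seed = 1)
  expect_equal(r0$estimate, 0)
  # uniform features -> fold ~ 1, CI covers 1
  withr::with_seed(2, feat <- w[runif(nrow(w)) < 0.5, c("chrom", "start", "end")])
  r1 <- tail_enrichment(tr, feat, q = 30, n_boot = 500, seed = 3)
  expect_true(r1$ci_low <= 1 && 1 <= r1$ci_high)
  expect_error(tail_enrichment(tr, feat, q = 0), "q must")
  # point features: a hit at a window start counts, end does not
  pts <- tibble::tibble(chrom = "chr1", pos = c(0L, 500L))
  rp <- tail_enrichment(tr, pts, q = 50, n_boot = 100, seed = 1)
  expect_gt(rp$estimate, 0)
})

test_that("high tail and exclusion tracks behave", {
  tr <- mk_track(100)
  w <- tidy(tr)
  high <- w[w$dr >= 90, c("chrom", "start", "end")]
  r <- tail_enrichment(tr, high, q = 10, tail = "high", n_boot = 100, seed = 1)
  expect_equal(r$estimate, 10)
  # excluding all windows errors
  expect_error(tail_enrichment(tr, high, exclude = w[, c("chrom", "start", "end")]),
               "no windows retained")
})

test_that("ccre enrichment nests across percentiles for an extreme-low track", {
  n <- 400
  withr::with_seed(20, tr <- mk_track(n, scores = rnorm(n)))
  w <- tidy(tr)
  # a track concentrated at the extreme low tail
  feat <- w[w$dr <= 2, c("chrom", "start", "end")]
  res <- ccre_enrichment(tr, list(extreme = feat), percentiles = c(1, 5))
  expect_equal(nrow(res), 2)
  or1 <- res$estimate[res$percentile == 1]
  or5 <- res$estimate[res$percentile == 5]
  expect_gte(or1, or5)
  # independent random track -> OR near 1
  withr::with_seed(21, rnd <- w[runif(n) < 0.3, c("chrom", "start", "end")])
  null_or <- ccre_enrichment(tr, list(rand = rnd), percentiles = 20)
  expect_lt(abs(log(null_or$estimate)), log(2.5))
})

test_that("frv_by_dr computes per-bin rare fractions", {
  tr <- mk_track(20, step = 500L)
  # non-overlapping windows: variant DR = its window's DR
  v <- tibble::tibble(chrom = "chr1",
                      pos = as.integer(seq(250, by = 500, length.out = 20)),
                      ref = "A", alt = "C",
                      carrier_count = rep(c(1L, 10L, 2L, 99L), 5))
  f <- frv_by_dr(v, tr, bins = c(0, 50, 100))
  expect_equal(nrow(f), 2)
  expect_equal(sum(f$n), 20)
  expect_equal(f$frv, c(0.5, 0.5)) # half of carriers <= 4 in every bin
  # all singletons -> FRV 1
  f1 <- frv_by_dr(dplyr::mutate(v, carrier_count = 1L), tr, bins = c(0, 100))
  expect_equal(f1$frv, 1)
  # empty bin -> NA
  f2 <- frv_by_dr(v[1:2, ], tr, bins = c(0, 5, 100))
  expect_true(any(is.na(f2$frv)) || all(f2$n > 0))
  # exclusion removes variants
  excl <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L)
  fx <- frv_by_dr(v, tr, bins = c(0, 100), exclude = excl)
  expect_equal(sum(fx$n), 0)
})

test_that("frv recovers a planted rare fraction within 3 s.e.", {
  n <- 2000
  withr::with_seed(30, {
    tr <- mk_track(n, scores = rnorm(n))
    rare_frac <- 0.7
    v <- tibble::tibble(
      chrom = "chr1",
      pos = as.integer(seq(250, by = 500, length.out = n)),
      ref = "A", alt = "C",
      carrier_count = ifelse(runif(n) < rare_frac, 1L, 50L)
    )
  })
  f <- frv_by_dr(v, tr, bins = c(0, 25, 50, 75, 100))
  se <- sqrt(0.7 * 0.3 / (n / 4))
  expect_true(all(abs(f$frv - rare_frac) < 3 * se))
})

test_that("gene regressions return exact r-squared in constructed cases", {
  d <- tibble::tibble(gene = paste0("g", 1:10),
                      dr_aggregate = 2 * (1:10),
                      loeuf = 1:10,
                      gerp = c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  res <- suppressWarnings(gene_dr_regressions(d)) # exact fit is intentional
  expect_equal(res$r_squared[res$model == "dr~loeuf"], 1)
  expect_equal(res$slope[res$model == "dr~loeuf"], 2)
  # orthogonal predictor -> r-squared 0
  d2 <- tibble::tibble(gene = paste0("g", 1:4),
                       dr_aggregate = c(1, -1, 1, -1),
                       loeuf = c(1, 1, -1, -1),
                       gerp = c(5, 6, 7, 8))
  res2 <- gene_dr_regressions(d2)
  expect_equal(res2$r_squared[res2$model == "dr~loeuf"], 0, tolerance = 1e-12)
  # 5-point hand case: r^2 equals squared correlation
  d3 <- tibble::tibble(gene = paste0("g", 1:5),
                       dr_aggregate = c(30, 28, 35, 40, 25),
                       loeuf = c(0.2, 0.1, 0.8, 1.2, 0.05),
                       gerp = c(3, 4, 2, 1, 5))
  res3 <- gene_dr_regressions(d3)
  expect_equal(res3$r_squared[res3$model == "dr~loeuf"],
               cor(d3$dr_aggregate, d3$loeuf)^2)
  expect_error(gene_dr_regressions(d3[1:2, ]), "at least 3")
  expect_error(gene_dr_regressions(dplyr::mutate(d3, loeuf = 1)),
               "zero-variance")
})

test_that("residualization leaves mean-zero residuals uncorrelated with x", {
  withr::with_seed(40, {
    x <- rnorm(500)
    y <- 0.6 * x + rnorm(500)
  })
  r <- residualize(y, x)
  expect_equal(mean(r), 0, tolerance = 1e-9)
  expect_equal(cor(r, x), 0, tolerance = 1e-9)
})

test_that("gene-level DR aggregation averages exonic windows", {
  tr <- mk_track(10, scores = 1:10)
  w <- tidy(tr)
  exons <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L),
                          end = c(600L, 1400L), gene = c("gA", "gA"))
  agg <- aggregate_gene_dr(tr, exons)
  # windows 1-2 overlap [0,600); window 3 overlaps [1000,1400)
  covered <- unique(c(which(w$start < 600 & w$end > 0),
                      which(w$start < 1400 & w$end > 1000)))
  expect_equal(agg$dr_aggregate, mean(w$dr[covered]))
  expect_equal(agg$n_windows, length(covered))
})

test_that("dr_vs_distance yields rising DR for rising planted scores", {
  # windows ordered by distance from a single exon, scores increasing
  n <- 40
  tr <- mk_track(n, scores = seq_len(n))
  exons <- tibble::tibble(chrom = "chr1", start = 0L, end = 400L,
                          gene = "gA")
  prof <- dr_vs_distance(tr, exons, breaks = c(0, 2000, 6000, Inf))
  expect_gt(nrow(prof), 1)
  expect_true(all(diff(prof$mean_dr) > 0))
  expect_true(all(prof$ci_low <= prof$mean_dr | is.na(prof$ci_low)))
  # all windows exonic -> empty profile
  big_exon <- tibble::tibble(chrom = "chr1", start = 0L,
                             end = max(tidy(tr)$end), gene = "gA")
  expect_equal(nrow(dr_vs_distance(tr, big_exon)), 0)
  expect_error(dr_vs_distance(tr, exons[0, ]), "nonempty")
})
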