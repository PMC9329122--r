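# window enumeration, depletion scores, DR assignment, cohort restriction

test_that("enumerate_windows produces the step-aligned grid with the bp filter", {
  m <- full_genome_mask(c(chr1 = 1000L))
  w <- enumerate_windows(m)
  expect_equal(nrow(w), 11)
  expect_equal(w$start, seq(0L, 500L, by = 50L))
  expect_true(all(w$reliable_bp == 500L))
  # 449 reliable bases -> dropped
  m449 <- mask_from_intervals(tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 449L), c(chr1 = 500L))
  expect_equal(nrow(enumerate_windows(m449)), 0)
  m450 <- mask_from_intervals(tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 450L), c(chr1 = 500L))
  expect_equal(nrow(enumerate_windows(m450)), 1)
  # empty mask -> no windows; bad step -> error
  empty <- mask_from_intervals(
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    c(chr1 = 1000L))
  expect_equal(nrow(enumerate_windows(empty)), 0)
  expect_error(enumerate_windows(m, size = 100, step = 200), "step")
})

test_that("depletion score follows (O - E) / sqrt(E) with the quality filter", {
  g <- mk_genome(chr1 = strrep("A", 600))
  mask <- full_genome_mask(g)
  r <- tibble::tibble(partition = "all", heptamer = "AAAAAAA",
                      H = 594, S = 0, rate = 4 / 594)
  class(r) <- c("heptamer_rates", class(r))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 600L,
                      reliable_bp = 600L)
  # O = 0, E = 4 -> score -2
  v0 <- tibble::tibble(chrom = character(), pos = integer(),
                       ref = character(), alt = character())
  s0 <- score_windows(w, v0, g, r, mask)
  expect_equal(s0$O, 0)
  expect_equal(s0$E, 4)
  expect_equal(s0$score, -2)
  expect_true(s0$pass) # zero-variant windows pass the mean-quality filter
  # O = E -> score 0
  v4 <- tibble::tibble(chrom = "chr1", pos = c(50L, 150L, 250L, 350L),
                       ref = "A", alt = "G", aa_score = 0.95,
                       carrier_count = 1L)
  s4 <- score_windows(w, v4, g, r, mask)
  expect_equal(s4$score, 0)
  expect_equal(s4$mean_aa, 0.95)
  # low mean quality -> excluded with reason
  vlow <- dplyr::mutate(v4, aa_score = 0.6)
  slow <- score_windows(w, vlow, g, r, mask)
  expect_false(slow$pass)
  expect_equal(slow$reason, "low_mean_aa")
  # E = 0 window is unscorable
  rz <- dplyr::mutate(r, rate = 0)
  class(rz) <- class(r)
  sz <- score_windows(w, v4, g, rz, mask)
  expect_equal(sz$reason, "zero_expected")
})

test_that("window O and E equal the brute-force oracle on random instances", {
  withr::with_seed(66, {
    for (rep in 1:5) {
      cfg <- sim_config(seed = sample.int(1e6, 1),
                        chrom_lengths = c(chr1 = 4000L))
      g <- generate_genome(cfg)
      v <- generate_variants(g, cfg)
      mask <- mask_from_intervals(
        tibble::tibble(chrom = "chr1", start = 37L, end = 3890L),
        genome_lengths(g))
      rates <- tally_heptamer_variants(v, g, mask)
      w <- enumerate_windows(mask)
      w <- w[sample.int(nrow(w), 3), ]
      sw <- score_windows(w, v, g, rates, mask)
      for (i in seq_len(nrow(sw))) {
        want <- orc_window_oe("chr1", sw$start[i], sw$end[i], v, g, mask,
                              rates)
        expect_equal(sw$O[i], want$O)
        expect_equal(sw$E[i], want$E, tolerance = 1e-12)
      }
    }
  })
})

test_that("DR assignment follows 100(i - 0.5)/n with mean-rank ties", {
  # n = 1 -> DR = 50
  w1 <- tibble::tibble(chrom = "chr1", start = 0L, end = 500L, score = -1)
  expect_equal(assign_dr(w1)$dr, 50)
  # n = 100: lowest 0.5, highest 99.5
  w100 <- tibble::tibble(chrom = "chr1", start = seq(0L, by = 500L,
                                                     length.out = 100),
                         end = start + 500L, score = seq(-5, 5, length.out = 100))
  d100 <- assign_dr(w100)
  expect_equal(min(d100$dr), 0.5)
  expect_equal(max(d100$dr), 99.5)
  expect_equal(d100$dr[order(d100$score)], 100 * (1:100 - 0.5) / 100)
  # ties at positions 2,3 of n = 4 share DR 50
  wt <- tibble::tibble(chrom = "chr1", start = c(0L, 500L, 1000L, 1500L),
                       end = start + 500L, score = c(-2, 0, 0, 3))
  dt <- assign_dr(wt)
  expect_equal(sort(dt$dr), c(12.5, 50, 50, 87.5))
  expect_equal(mean(dt$dr), 50, tolerance = 1e-6)
  expect_error(assign_dr(w1[0, ]), "no scored windows")
})

test_that("DR is invariant to strictly monotone score transforms", {
  withr::with_seed(7, {
    w <- tibble::tibble(chrom = "chr1",
                        start = seq(0L, by = 500L, length.out = 200),
                        end = start + 500L, score = rnorm(200))
  })
  d1 <- assign_dr(w)$dr
  d2 <- assign_dr(dplyr::mutate(w, score = exp(score)))$dr
  d3 <- assign_dr(dplyr::mutate(w, score = 3 * score - 10))$dr
  expect_equal(d1, d2)
  expect_equal(d1, d3)
})

test_that("tidy/glance/autoplot expose the track", {
  withr::with_seed(8, {
    w <- tibble::tibble(chrom = "chr1",
                        start = seq(0L, by = 500L, length.out = 50),
                        end = start + 500L, score = rnorm(50))
  })
  tr <- assign_dr(w)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "dr_track"))
  gl <- glance(tr)
  expect_equal(gl$n_windows, 50)
  expect_equal(gl$mean_dr, 50)
  expect_s3_class(autoplot(tr), "ggplot")
})

test_that("cohort restriction refits rates; full cohort reproduces the track", {
  cfg <- sim_config(seed = 33, chrom_lengths = c(chr1 = 60000L),
                    cohort_fractions = c(XBI = 0.9, XAF = 0.35))
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)
  mask <- full_genome_mask(g)
  windows <- enumerate_windows(mask)
  # a synthetic cohort containing every variant reproduces the plain track
  v_all <- dplyr::mutate(v, cohorts = purrr::map(seq_len(nrow(v)), ~"ALL"))
  rates <- tally_heptamer_variants(v, g, mask)
  plain <- assign_dr(score_windows(windows, v, g, rates, mask))
  coh <- cohort_dr(v_all, "ALL", g, mask, windows = windows)
  expect_equal(tidy(coh)$dr, tidy(plain)$dr)
  expect_equal(attr(coh, "provenance")$cohort, "ALL")
  # restricted cohort still yields a mean-50 percentile track
  cafr <- cohort_dr(v, "XAF", g, mask, windows = windows)
  expect_equal(mean(cafr$dr), 50, tolerance = 1e-6)
  expect_gt(nrow(cafr), 0)
  expect_error(cohort_dr(v, "NOPE", g, mask), "unknown or empty")
  expect_error(cohort_dr(dplyr::select(v, -cohorts), "XBI", g, mask),
               "cohorts list-column")
})

test_that("DR tracks are deterministic and round trip through TSV/bedGraph", {
  cfg <- sim_config(seed = 44, chrom_lengths = c(chr1 = 40000L))
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)
  mask <- full_genome_mask(g)
  rates <- tally_heptamer_variants(v, g, mask)
  w <- enumerate_windows(mask)
  t1 <- assign_dr(score_windows(w, v, g, rates, mask))
  t2 <- assign_dr(score_windows(w, v, g, rates, mask))
  expect_identical(tidy(t1), tidy(t2))
  p <- withr::local_tempfile(fileext = ".tsv")
  pb <- withr::local_tempfile(fileext = ".bedgraph")
  write_dr_tsv(t1, p)
  write_dr_bedgraph(t1, pb)
  back <- read_dr_tsv(p)
  expect_equal(nrow(back), nrow(t1))
  expect_equal(back$dr, t1$dr, tolerance = 1e-5)
  bg <- readr::read_tsv(pb, col_names = c("chrom", "start", "end", "dr"),
                        show_col_types = FALSE)
  expect_equal(nrow(bg), nrow(t1))
})
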