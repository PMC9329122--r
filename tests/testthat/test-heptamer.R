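# strand-collapsed classification, canonical heptamers, H/S tallies, E

test_that("classify_snv applies the collapse and CpG split", {
  expect_equal(classify_snv("AAACGAA", "C", "T"), "CpG>TpG")
  expect_equal(classify_snv("AACGAAA", "G", "A"), "CpG>TpG")
  expect_equal(classify_snv("AAACAAA", "C", "T"), "C>T(non-CpG)")
  expect_equal(classify_snv("AAAAAAA", "A", "C"), "T>G")
  expect_equal(classify_snv("AAAAAAA", "A", "G"), "T>C")
  expect_equal(classify_snv("TTTTTTT", "T", "C"), "T>C")
  expect_equal(classify_snv("AAAGAAA", "G", "C"), "C>G")
  expect_error(classify_snv("AAANAAA", "N", "A"), "central")
  expect_error(classify_snv("AAACAAA", "C", "X"), "alt_base")
  expect_error(classify_snv("AAACAAA", "C", "C"), "differ")
})

test_that("canonical_heptamer fixes the central base to A or C", {
  expect_equal(canonical_heptamer("TTTGTTT"), "AAACAAA")
  expect_equal(canonical_heptamer("AAACAAA"), "AAACAAA")
  expect_equal(canonical_heptamer("NTTGTTT"), "AAACAAN")
  expect_error(canonical_heptamer("AAANAAA"), "central")
  expect_error(canonical_heptamer("ACGT"), "7 bases")
  # involution through the reverse complement
  withr::with_seed(5, {
    h <- replicate(50, paste(sample(c("A", "C", "G", "T"), 7, TRUE),
                             collapse = ""))
  })
  expect_equal(canonical_heptamer(h), canonical_heptamer(revcomp(h)))
})

test_that("H tally matches hand enumeration and handles empty masks", {
  g <- mk_genome(chr1 = strrep("A", 10))
  h <- tally_heptamers(g, full_genome_mask(g))
  expect_equal(nrow(h), 1)
  expect_equal(h$heptamer, "AAAAAAA")
  expect_equal(h$H, 4) # centers at 0-based 3..6
  empty <- mask_from_intervals(
    tibble::tibble(chrom = character(), start = integer(), end = integer()),
    c(chr1 = 10L))
  expect_equal(nrow(tally_heptamers(g, empty)), 0)
})

test_that("rates hit the trivial cases", {
  g <- mk_genome(chr1 = "TTTTCTTTT")
  mask <- full_genome_mask(g)
  v0 <- tibble::tibble(chrom = character(), pos = integer(),
                       ref = character(), alt = character())
  r0 <- tally_heptamer_variants(v0, g, mask)
  expect_true(all(r0$S == 0))
  expect_true(all(r0$rate == 0))
  # one variant at the only occurrence of its heptamer -> rate 1
  v1 <- tibble::tibble(chrom = "chr1", pos = 4L, ref = "C", alt = "T",
                       aa_score = 0.99, carrier_count = 1L)
  r1 <- tally_heptamer_variants(v1, g, mask)
  expect_equal(r1$rate[r1$heptamer == "TTTCTTT"], 1)
  # low-quality variants never enter S
  v2 <- dplyr::mutate(v1, aa_score = 0.4)
  r2 <- tally_heptamer_variants(v2, g, mask)
  expect_true(all(r2$S == 0))
  expect_equal(attr(r1, "skipped"), 0)
})

test_that("H and S tallies equal the per-position brute-force oracle", {
  withr::with_seed(77, {
    for (rep in 1:5) {
      cfg <- sim_config(seed = sample.int(1e6, 1),
                        chrom_lengths = c(chrA = 3000L, chrB = 2000L))
      g <- generate_genome(cfg)
      v <- generate_variants(g, cfg)
      iv <- tibble::tibble(chrom = c("chrA", "chrB"),
                           start = c(100L, 0L), end = c(2500L, 1500L))
      mask <- mask_from_intervals(iv, genome_lengths(g))
      got <- tally_heptamer_variants(v, g, mask)
      want_h <- orc_tally_h(g, mask)
      expect_equal(nrow(got), length(want_h))
      expect_equal(stats::setNames(got$H, got$heptamer)[names(want_h)],
                   unlist(want_h))
      want_s <- orc_tally_s(v, g, mask)
      s_named <- stats::setNames(got$S, got$heptamer)
      for (k in names(want_s)) expect_equal(s_named[[k]], want_s[[k]])
      expect_equal(sum(got$S), sum(unlist(want_s)))
    }
  })
})

test_that("tallies are strand symmetric", {
  cfg <- sim_config(seed = 31, chrom_lengths = c(chr1 = 4000L))
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)
  mask <- full_genome_mask(g)
  r_fwd <- tally_heptamer_variants(v, g, mask)
  # reverse complement the genome and remap variants
  L <- nchar(g[["chr1"]])
  g_rc <- stats::setNames(revcomp(g[["chr1"]]), "chr1")
  v_rc <- dplyr::mutate(v, pos = L - 1L - pos,
                        ref = chartr("ACGT", "TGCA", ref),
                        alt = chartr("ACGT", "TGCA", alt)) |>
    dplyr::arrange(pos)
  r_rc <- tally_heptamer_variants(v_rc, g_rc, full_genome_mask(g_rc))
  expect_equal(dplyr::arrange(tibble::as_tibble(r_fwd), heptamer),
               dplyr::arrange(tibble::as_tibble(r_rc), heptamer))
})

test_that("expected counts follow the closed form and the oracle", {
  # uniform rates: E = n_reliable_centers * r
  g <- mk_genome(chr1 = strrep("A", 600))
  mask <- full_genome_mask(g)
  r <- tibble::tibble(partition = "all", heptamer = "AAAAAAA",
                      H = 100, S = 25, rate = 0.25)
  class(r) <- c("heptamer_rates", class(r))
  w <- tibble::tibble(chrom = "chr1", start = 0L, end = 600L)
  e <- expected_window_variants(w, g, r, mask)
  expect_equal(e$E, 594 * 0.25) # 600 positions minus 3 clipped per edge
  w0 <- tibble::tibble(chrom = "chr1", start = 100L, end = 100L)
  expect_equal(expected_window_variants(w0, g, r, mask)$E, 0)

  withr::with_seed(55, {
    for (rep in 1:5) {
      cfg <- sim_config(seed = sample.int(1e6, 1),
                        chrom_lengths = c(chr1 = 3000L))
      g <- generate_genome(cfg)
      v <- generate_variants(g, cfg)
      mask <- mask_from_intervals(
        tibble::tibble(chrom = "chr1", start = 50L, end = 2700L),
        genome_lengths(g))
      rates <- tally_heptamer_variants(v, g, mask)
      st <- sample(0:1500, 1)
      wd <- sample(100:2000, 1)
      w <- tibble::tibble(chrom = "chr1", start = st, end = min(3000L, st + wd))
      got <- expected_window_variants(w, g, rates, mask)$E
      want <- orc_window_oe("chr1", w$start, w$end, v, g, mask, rates)$E
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("pooled S/H recovers a uniform simulated rate within 3 s.e.", {
  rate <- 0.02
  cfg <- sim_config(seed = 404, chrom_lengths = c(chr1 = 300000L),
                    base_mutation_rate = rate, cpg_rate_multiplier = 1,
                    cpg_island_density = 0)
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)
  mask <- full_genome_mask(g)
  rates <- tally_heptamer_variants(v, g, mask)
  pooled <- sum(rates$S) / sum(rates$H)
  se <- sqrt(rate * (1 - rate) / sum(rates$H))
  expect_lt(abs(pooled - rate), 3 * se)
})

test_that("sum of E over the fitting tiling conserves sum of S per partition", {
  cg <- tibble::tibble(chrom = "chr1", start = 20000L, end = 60000L)
  cfg <- sim_config(seed = 17, chrom_lengths = c(chr1 = 100000L),
                    cg_enriched_regions = cg)
  g <- generate_genome(cfg)
  v <- generate_variants(g, cfg)
  cov <- generate_coverage_stats(g, cfg)
  mask <- build_reliable_mask(cov, chrom_lengths = genome_lengths(g))
  rates <- tally_heptamer_variants(v, g, mask, partition_track = cg)
  expect_setequal(unique(rates$partition),
                  c("outside_CG_enriched", "inside_CG_enriched"))
  tw <- tiling_windows(g)
  tw <- expected_window_variants(tw, g, rates, mask, partition_track = cg)
  expect_equal(sum(tw$E), sum(rates$S), tolerance = 1e-6)
})
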