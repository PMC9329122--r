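# seeded synthetic-data generators: genome, variants, coverage, methylation,
# annotations. Every generator is a pure function of (config, seed); internal
# sub-seeds keep the generators independent of call order.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Identical
#' configurations (including `seed`) produce byte-identical outputs.
#'
#' @param seed Integer seed; all generator randomness derives from it.
#' @param chrom_lengths Named integer vector of chromosome lengths (bp).
#' @param gc_fraction Target GC fraction of the background sequence.
#' @param cpg_island_density Fraction of the genome covered by CpG islands
#'   (regions with elevated CpG dinucleotide density).
#' @param cpg_island_size Island width in bp.
#' @param base_mutation_rate Per-site probability that a site carries a
#'   segregating variant in the simulated cohort.
#' @param cpg_rate_multiplier Rate multiplier applied at CpG dinucleotide
#'   bases (both the C and the G), reflecting CpG>TpG hypermutability.
#' @param ts_fraction Probability that a drawn alternate allele is the
#'   transition partner (2/3 corresponds to a 2:1 transition:transversion
#'   draw before saturation).
#' @param constrained_regions Tibble `chrom,start,end,multiplier` of planted
#'   constrained regions; `multiplier` in `[0,1]` scales the local variant
#'   rate (0 = fully depleted).
#' @param cg_enriched_regions Tibble `chrom,start,end` of regions treated as
#'   C>G-enriched for rate-partitioning.
#' @param n_individuals Cohort size; carrier counts are truncated at it.
#' @param sfs_shape Exponent of the carrier-count spectrum: P(k) proportional
#'   to 1/k^sfs_shape, k = 1..n_individuals (1 gives the standard neutral
#'   1/k spectrum with its singleton excess).
#' @param coverage_mean,coverage_sd Targets for the per-base mean and s.d. of
#'   depth outside dropout patches.
#' @param dropout_patches Tibble `chrom,start,end` of coverage dropouts.
#' @param methylated_fraction Fraction of CpG dinucleotides truly methylated
#'   in the germline simulation.
#' @param methylation_depth Mean per-strand read depth per bisulfite sample.
#' @param n_testis,n_ovary Number of testis-like and ovary-like samples.
#' @param aa_beta Length-2 shape vector of the Beta distribution of variant
#'   quality scores (default Beta(9,1): ~98% of variants above 0.5).
#' @param loeuf_gerp_cor Target correlation between simulated gene-level
#'   LOEUF and GERP aggregates.
#' @param n_genes Number of simulated genes (default ~1 per 50 kb).
#' @param denovo_recurrence Mixture weight for sampling de novo sites from
#'   the existing variant set (recurrence) versus fresh sites.
#' @param n_denovo Number of de novo mutations to simulate.
#' @param cohort_fractions Optional named numeric vector of per-cohort
#'   presence probabilities (e.g. `c(XBI = 0.9, XAF = 0.3)`); when supplied,
#'   variants carry a `cohorts` list-column.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 200000L),
                       gc_fraction = 0.41,
                       cpg_island_density = 0.01,
                       cpg_island_size = 300L,
                       base_mutation_rate = 0.02,
                       cpg_rate_multiplier = 10,
                       ts_fraction = 2 / 3,
                       constrained_regions = NULL,
                       cg_enriched_regions = NULL,
                       n_individuals = 1000L,
                       sfs_shape = 1,
                       coverage_mean = 30,
                       coverage_sd = 6,
                       dropout_patches = NULL,
                       methylated_fraction = 0.8,
                       methylation_depth = 15,
                       n_testis = 2L,
                       n_ovary = 3L,
                       aa_beta = c(9, 1),
                       loeuf_gerp_cor = 0.5,
                       n_genes = NULL,
                       denovo_recurrence = 0.3,
                       n_denovo = 200L,
                       cohort_fractions = NULL) {
  if (length(chrom_lengths) == 0) abort("chrom_lengths must be nonempty")
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    abort("chrom_lengths must be named")
  }
  if (any(chrom_lengths <= 0)) abort("zero-length chromosome in chrom_lengths")
  chrom_lengths <- setNames(as.integer(chrom_lengths), names(chrom_lengths))
  for (p in c(gc_fraction, cpg_island_density, base_mutation_rate,
              methylated_fraction, denovo_recurrence)) {
    if (p < 0 || p > 1) abort("probabilities/proportions must lie in [0,1]")
  }
  if (cpg_rate_multiplier <= 0) abort("cpg_rate_multiplier must be positive")
  if (ts_fraction < 0 || ts_fraction > 1) abort("ts_fraction must lie in [0,1]")
  check_intervals_in_bounds(constrained_regions, chrom_lengths, "constrained_regions")
  if (!is.null(constrained_regions)) {
    if (!"multiplier" %in% names(constrained_regions)) {
      abort("constrained_regions must carry a multiplier column")
    }
    if (any(constrained_regions$multiplier < 0 | constrained_regions$multiplier > 1)) {
      abort("constraint multipliers must lie in [0,1]")
    }
  }
  check_intervals_in_bounds(cg_enriched_regions, chrom_lengths, "cg_enriched_regions")
  check_intervals_in_bounds(dropout_patches, chrom_lengths, "dropout_patches")
  if (n_individuals < 1) abort("n_individuals must be >= 1")
  structure(
    list(
      seed = as.integer(seed),
      chrom_lengths = chrom_lengths,
      gc_fraction = gc_fraction,
      cpg_island_density = cpg_island_density,
      cpg_island_size = as.integer(cpg_island_size),
      base_mutation_rate = base_mutation_rate,
      cpg_rate_multiplier = cpg_rate_multiplier,
      ts_fraction = ts_fraction,
      constrained_regions = constrained_regions,
      cg_enriched_regions = cg_enriched_regions,
      n_individuals = as.integer(n_individuals),
      sfs_shape = sfs_shape,
      coverage_mean = coverage_mean,
      coverage_sd = coverage_sd,
      dropout_patches = dropout_patches,
      methylated_fraction = methylated_fraction,
      methylation_depth = methylation_depth,
      n_testis = as.integer(n_testis),
      n_ovary = as.integer(n_ovary),
      aa_beta = aa_beta,
      loeuf_gerp_cor = loeuf_gerp_cor,
      n_genes = n_genes,
      denovo_recurrence = denovo_recurrence,
      n_denovo = as.integer(n_denovo),
      cohort_fractions = cohort_fractions
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|",
      length(x$chrom_lengths), "chromosome(s),",
      format(sum(as.numeric(x$chrom_lengths)), big.mark = ","), "bp |",
      "rate", x$base_mutation_rate, "x CpG", x$cpg_rate_multiplier, "\n")
  invisible(x)
}

#' Generate a synthetic reference genome
#'
#' Samples iid bases at the configured GC fraction, then plants CpG
#' dinucleotides at elevated density inside CpG islands. Island intervals are
#' attached as attribute `"cpg_islands"`.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(sub_seed(config$seed, 1L), {
    gc <- config$gc_fraction
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    islands <- list()
    genome <- purrr::imap_chr(as.list(config$chrom_lengths), function(L, ch) {
      codes <- sample.int(4L, L, replace = TRUE, prob = probs) - 1L
      isl_n <- floor(config$cpg_island_density * L / config$cpg_island_size)
      if (isl_n > 0 && L >= 2L * config$cpg_island_size) {
        cand <- seq(0L, L - config$cpg_island_size, by = config$cpg_island_size)
        starts <- sort(sample(cand, min(isl_n, length(cand))))
        islands[[ch]] <<- tibble(chrom = ch, start = starts,
                                 end = starts + config$cpg_island_size)
        for (s in starts) {
          # plant CpG pairs on a 2-bp lattice inside the island
          p <- seq(s + 1L, s + config$cpg_island_size - 1L, by = 2L)
          hit <- p[runif(length(p)) < 0.15]
          codes[hit] <- 1L
          codes[hit + 1L] <- 2L
        }
      }
      codes_to_string(codes)
    })
    attr(genome, "cpg_islands") <- if (length(islands)) bind_rows(islands) else NULL
    genome
  })
}

# per-position multiplier from constrained regions (length L, default 1)
constraint_multiplier <- function(config, chrom, L) {
  mult <- rep(1, L)
  cr <- config$constrained_regions
  if (is.null(cr)) return(mult)
  cr <- cr[cr$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(cr))) {
    s <- cr$start[[i]]; e <- min(L, cr$end[[i]])
    if (e > s) mult[(s + 1L):e] <- cr$multiplier[[i]]
  }
  mult
}

# CpG membership flags for integer base codes: TRUE at the C and the G of
# each reference CpG dinucleotide
cpg_member_flags <- function(codes) {
  L <- length(codes)
  nxt <- c(codes[-1L], NA_integer_)
  prv <- c(NA_integer_, codes[-L])
  is_c <- !is.na(codes) & codes == 1L & !is.na(nxt) & nxt == 2L
  is_g <- !is.na(codes) & codes == 2L & !is.na(prv) & prv == 1L
  is_c | is_g
}

#' Generate synthetic population variants
#'
#' Each site mutates independently with probability
#' `base_mutation_rate * cpg_multiplier * constraint_multiplier`; the
#' alternate allele is the transition partner with probability `ts_fraction`
#' else one of the two transversions; carrier counts follow the configured
#' truncated 1/k^shape spectrum and quality scores a Beta distribution.
#'
#' @param genome Genome from [generate_genome()] (or user-supplied).
#' @param config A [sim_config()].
#' @return Tibble of SNV records: `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `carrier_count`, `aa_score`, plus a `cohorts` list-column if
#'   `cohort_fractions` is configured.
#' @export
generate_variants <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  withr::with_seed(sub_seed(config$seed, 2L), {
    sfs_p <- (1 / seq_len(config$n_individuals))^config$sfs_shape
    sfs_p <- sfs_p / sum(sfs_p)
    out <- purrr::imap(as.list(genome), function(seq, ch) {
      codes <- encode_bases(seq)
      L <- length(codes)
      p <- config$base_mutation_rate *
        ifelse(cpg_member_flags(codes), config$cpg_rate_multiplier, 1) *
        constraint_multiplier(config, ch, L)
      p <- pmin(p, 1)
      p[is.na(codes)] <- 0
      hit <- which(runif(L) < p)
      if (length(hit) == 0) {
        return(tibble(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      carrier_count = integer(), aa_score = numeric()))
      }
      ref_c <- codes[hit]
      ts_alt <- (ref_c + 2L) %% 4L
      u <- runif(length(hit))
      # the two transversion partners of base b are the two codes other than
      # b and its transition partner
      tv_pick <- ifelse(u < config$ts_fraction, NA_integer_,
                        ifelse(u < config$ts_fraction + (1 - config$ts_fraction) / 2, 0L, 1L))
      alt_c <- ts_alt
      for (i in which(!is.na(tv_pick))) {
        others <- setdiff(0:3, c(ref_c[i], ts_alt[i]))
        alt_c[i] <- others[tv_pick[i] + 1L]
      }
      tibble(
        chrom = ch,
        pos = hit - 1L,
        ref = .code_base[ref_c + 1L],
        alt = .code_base[alt_c + 1L],
        carrier_count = sample.int(config$n_individuals, length(hit),
                                   replace = TRUE, prob = sfs_p),
        aa_score = rbeta(length(hit), config$aa_beta[[1]], config$aa_beta[[2]])
      )
    })
    v <- bind_rows(out) |> arrange(.data$chrom, .data$pos)
    if (!is.null(config$cohort_fractions)) {
      cf <- config$cohort_fractions
      mem <- vapply(names(cf), function(co) runif(nrow(v)) < cf[[co]],
                    logical(nrow(v)))
      if (nrow(v) == 1) mem <- matrix(mem, nrow = 1, dimnames = list(NULL, names(cf)))
      v$cohorts <- apply(mem, 1L, function(r) names(cf)[r], simplify = FALSE)
    }
    v
  })
}

#' Generate a per-base coverage summary track
#'
#' Mean depth fluctuates around `coverage_mean` (and collapses towards 0
#' inside dropout patches); s.d. depth fluctuates around `coverage_sd`.
#'
#' @param genome Genome.
#' @param config A [sim_config()].
#' @return Tibble `chrom`, `pos` (0-based), `mean_depth`, `sd_depth`.
#' @export
generate_coverage_stats <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  withr::with_seed(sub_seed(config$seed, 3L), {
    purrr::imap(as.list(genome), function(seq, ch) {
      L <- nchar(seq)
      mean_depth <- rnorm(L, config$coverage_mean, config$coverage_mean * 0.03)
      sd_depth <- pmax(rnorm(L, config$coverage_sd, config$coverage_sd * 0.08), 0.1)
      drop <- intervals_to_logical(config$dropout_patches, ch, L)
      if (any(drop)) {
        mean_depth[drop] <- runif(sum(drop), 0, 2)
        sd_depth[drop] <- runif(sum(drop), 0, 1)
      }
      tibble(chrom = ch, pos = seq_len(L) - 1L,
             mean_depth = pmax(mean_depth, 0), sd_depth = sd_depth)
    }) |> bind_rows()
  })
}

#' Generate bisulfite methylation count tables
#'
#' Produces per-sample bedMethyl-like tables for `n_testis` testis-like and
#' `n_ovary` ovary-like samples. Every reference CpG dinucleotide receives
#' counts on both strands; a `methylated_fraction` of CpGs is truly
#' methylated (read-level methylation ratio drawn near 0.9), the rest near
#' 0.1. The truth table is attached as attribute `"truth"`.
#'
#' @param genome Genome.
#' @param config A [sim_config()].
#' @return List with elements `testis` and `ovary`, each a list of tibbles
#'   `chrom`, `pos` (0-based), `strand`, `methylated_reads`, `total_reads`.
#' @export
generate_methylation_counts <- function(genome, config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  withr::with_seed(sub_seed(config$seed, 4L), {
    cpg <- purrr::imap(as.list(genome), function(seq, ch) {
      codes <- encode_bases(seq)
      nxt <- c(codes[-1L], NA_integer_)
      cpos <- which(!is.na(codes) & codes == 1L & !is.na(nxt) & nxt == 2L) - 1L
      tibble(chrom = ch, pos = cpos)
    }) |> bind_rows()
    n <- nrow(cpg)
    meth <- runif(n) < config$methylated_fraction
    true_ratio <- ifelse(meth, rbeta(n, 45, 5), rbeta(n, 5, 45))
    draw_sample <- function() {
      per_strand <- function(strand, pos_offset) {
        total <- rpois(n, config$methylation_depth)
        m <- rbinom(n, total, true_ratio)
        tibble(chrom = cpg$chrom, pos = cpg$pos + pos_offset, strand = strand,
               methylated_reads = m, total_reads = total)
      }
      bind_rows(per_strand("+", 0L), per_strand("-", 1L)) |>
        arrange(.data$chrom, .data$pos, .data$strand)
    }
    out <- list(
      testis = purrr::map(seq_len(config$n_testis), ~draw_sample()),
      ovary = purrr::map(seq_len(config$n_ovary), ~draw_sample())
    )
    attr(out, "truth") <- mutate(cpg, methylated = meth, true_ratio = true_ratio)
    out
  })
}

#' Generate synthetic annotation tracks, gene scores and a de novo list
#'
#' Plants genes (exons, UTRs, splice flanks, proximal upstream regions) on a
#' regular grid with jitter, random cCRE intervals, GWAS hit points, a gene
#' score table with LOEUF and GERP aggregates correlated at
#' `loeuf_gerp_cor`, and a de novo mutation list sampled as a mixture of
#' existing variant sites (weight `denovo_recurrence`) and fresh sites.
#'
#' @param genome Genome.
#' @param config A [sim_config()].
#' @param variants Optional variant tibble (from [generate_variants()]) used
#'   for the recurrent component of the de novo list.
#' @return List: `tracks` (named list of sorted interval tibbles plus `gwas`
#'   points), `genes` (tibble `gene`, `loeuf`, `gerp`), `denovo` (tibble
#'   `chrom`, `pos`, `ref`, `alt`).
#' @export
generate_annotations <- function(genome, config, variants = NULL) {
  stopifnot(inherits(config, "sim_config"))
  genome <- as_genome(genome)
  lens <- genome_lengths(genome)
  withr::with_seed(sub_seed(config$seed, 5L), {
    total <- sum(as.numeric(lens))
    n_genes <- config$n_genes %||% max(1L, floor(total / 50000))
    # distribute genes over chromosomes proportionally to length
    per_chrom <- setNames(pmax(1L, floor(n_genes * lens / total)), names(lens))
    gene_span <- 4000L
    gene_id <- 0L
    tracks <- list(exons = list(), utr5 = list(), utr3 = list(),
                   splice = list(), proximal = list())
    for (ch in names(lens)) {
      L <- lens[[ch]]
      ng <- if (L < gene_span + 3000L) 0L else per_chrom[[ch]]
      if (ng == 0L) next
      pitch <- (L - gene_span - 2500L) / max(ng, 1L)
      if (pitch < gene_span + 2500L) ng <- max(1L, floor((L - gene_span - 2500L) / (gene_span + 2500L)))
      starts <- floor(2300 + (seq_len(ng) - 1L) * max(pitch, gene_span + 2500) +
                        runif(ng, 0, min(200, pitch / 4)))
      for (s in starts) {
        gene_id <- gene_id + 1L
        g <- paste0("gene", gene_id)
        ex <- tibble(chrom = ch, gene = g,
                     start = as.integer(s + c(0L, 1700L, 3400L)),
                     end = as.integer(s + c(200L, 1900L, 3600L)))
        tracks$exons[[length(tracks$exons) + 1L]] <- ex
        tracks$utr5[[length(tracks$utr5) + 1L]] <-
          tibble(chrom = ch, gene = g, start = as.integer(s - 150L), end = as.integer(s))
        tracks$utr3[[length(tracks$utr3) + 1L]] <-
          tibble(chrom = ch, gene = g, start = as.integer(s + 3600L), end = as.integer(s + 3900L))
        sp <- bind_rows(
          tibble(chrom = ch, gene = g, start = ex$end, end = ex$end + 8L),
          tibble(chrom = ch, gene = g, start = ex$start - 8L, end = ex$start)
        )
        tracks$splice[[length(tracks$splice) + 1L]] <- sp
        tracks$proximal[[length(tracks$proximal) + 1L]] <-
          tibble(chrom = ch, gene = g, start = as.integer(max(0L, s - 2150L)), end = as.integer(s - 150L))
      }
    }
    tracks <- purrr::map(tracks, function(l) {
      if (length(l) == 0) {
        tibble(chrom = character(), gene = character(), start = integer(), end = integer())
      } else {
        bind_rows(l) |> arrange(.data$chrom, .data$start)
      }
    })
    # random non-overlapping cCRE intervals covering ~1% of the genome
    ccre <- purrr::imap(as.list(lens), function(L, ch) {
      w <- 200L
      nc <- floor(0.01 * L / w)
      if (nc == 0 || L < 2L * w) return(NULL)
      cand <- seq(0L, L - w, by = 2L * w)
      starts <- sort(sample(cand, min(nc, length(cand))))
      tibble(chrom = ch, start = starts, end = starts + w)
    }) |> bind_rows()
    tracks$ccre <- ccre
    gwas <- purrr::imap(as.list(lens), function(L, ch) {
      nh <- max(1L, floor(L / 20000))
      tibble(chrom = ch, pos = sort(sample.int(L, nh)) - 1L)
    }) |> bind_rows()
    tracks$gwas <- gwas
    # correlated gene scores: gerp ~ N(0,1), loeuf linear in gerp + noise;
    # scored genes cover all requested genes even when the genome hosts
    # fewer gene bodies
    rho <- config$loeuf_gerp_cor
    ng_tot <- max(gene_id, n_genes, 1L)
    gerp <- rnorm(ng_tot)
    loeuf <- rho * gerp + sqrt(1 - rho^2) * rnorm(ng_tot)
    genes <- tibble(gene = paste0("gene", seq_len(ng_tot)),
                    loeuf = 1 + 0.4 * loeuf, gerp = 2 + 1.5 * gerp)
    # de novo list: recurrence mixture
    n_rec <- if (!is.null(variants) && nrow(variants) > 0) {
      rbinom(1L, config$n_denovo, config$denovo_recurrence)
    } else 0L
    rec <- if (n_rec > 0) {
      variants[sample.int(nrow(variants), min(n_rec, nrow(variants))),
               c("chrom", "pos", "ref", "alt")]
    } else NULL
    n_fresh <- config$n_denovo - (if (is.null(rec)) 0L else nrow(rec))
    fresh <- if (n_fresh > 0) {
      ch <- sample(names(lens), n_fresh, replace = TRUE,
                   prob = lens / sum(lens))
      pos <- vapply(ch, function(c1) sample.int(lens[[c1]], 1L) - 1L, integer(1))
      ref <- substring(genome[ch], pos + 1L, pos + 1L)
      alt <- vapply(ref, function(r) {
        if (r %in% .code_base) sample(setdiff(.code_base, r), 1L) else "A"
      }, character(1), USE.NAMES = FALSE)
      keep <- ref %in% .code_base
      tibble(chrom = ch, pos = as.integer(pos), ref = ref, alt = alt)[keep, ]
    } else NULL
    denovo <- bind_rows(rec, fresh) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      arrange(.data$chrom, .data$pos)
    list(tracks = tracks, genes = genes, denovo = denovo)
  })
}
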