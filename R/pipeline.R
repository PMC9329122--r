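# pipeline orchestration: mask -> rates -> DR -> reports, with a manifest

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON path")
  config
}

#' Validate pipeline inputs
#'
#' Report-only checks: file existence, FASTA/VCF contig name agreement, BED
#' sortedness, and presence of the expected INFO keys in the VCF header.
#'
#' @param config List (or YAML/JSON path) with optional elements `fasta`,
#'   `vcf`, `beds` (character vector of BED paths), `aa_key`,
#'   `carrier_key`.
#' @return Tibble `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(config) {
  config <- read_pipeline_config(config)
  out <- list()
  note <- function(check, ok, detail = "") {
    out[[length(out) + 1L]] <<- tibble(check = check, ok = ok,
                                       detail = detail)
  }
  paths <- purrr::compact(config[c("fasta", "vcf")])
  for (nm in names(paths)) {
    note(paste0(nm, "_exists"), file.exists(paths[[nm]]),
         paths[[nm]])
  }
  if (!is.null(config$fasta) && !is.null(config$vcf) &&
      file.exists(config$fasta) && file.exists(config$vcf)) {
    fa_names <- names(read_genome_fasta(config$fasta))
    vcf_lines <- readLines(config$vcf, n = 5000L)
    body <- vcf_lines[!startsWith(vcf_lines, "#")]
    vcf_chroms <- unique(sub("\t.*$", "", body))
    missing <- setdiff(vcf_chroms, fa_names)
    detail <- if (length(missing)) {
      hint <- if (any(paste0("chr", missing) %in% fa_names) ||
                  any(sub("^chr", "", missing) %in% fa_names)) {
        " (chr-prefix mismatch? try renaming contigs)"
      } else ""
      paste0("VCF contigs absent from FASTA: ",
             paste(missing, collapse = ", "), hint)
    } else ""
    note("contig_agreement", length(missing) == 0, detail)
    header <- vcf_lines[startsWith(vcf_lines, "##")]
    aa_key <- config$aa_key %||% "AAScore"
    has_aa <- any(grepl(paste0("ID=", aa_key, "[,>]"), header))
    note("info_aa_key", has_aa,
         if (!has_aa) paste0("INFO key ", aa_key,
                             " missing; quality threshold inapplicable")
         else "")
  }
  for (bp in config$beds %||% character()) {
    ok <- FALSE
    detail <- "file missing"
    if (file.exists(bp)) {
      b <- read_bed(bp)
      ok <- !is.unsorted(order(b$chrom, b$start))
      srt <- b |> group_by(.data$chrom) |>
        summarise(s = !is.unsorted(.data$start), .groups = "drop")
      ok <- all(srt$s)
      detail <- if (!ok) "intervals not sorted by start within chromosome" else ""
    }
    note(paste0("bed_sorted:", basename(bp)), ok, detail)
  }
  if (length(out) == 0) {
    return(tibble(check = character(), ok = logical(), detail = character()))
  }
  bind_rows(out)
}

#' Run the full scan pipeline
#'
#' Orchestrates the stages in dependency order: simulate inputs (when the
#' config has a `simulate` section), build the reliability mask, fit
#' heptamer rates, score windows and assign DR, and compute the
#' mutation-class saturation report. Writes the DR track (bedGraph and
#' TSV), the rate table, the mask BED and a JSON manifest recording the
#' config hash, input digests and per-stage row counts. With
#' `resume = TRUE`, a rerun against an unchanged config reuses the cached
#' outputs.
#'
#' @param config List or YAML/JSON path. Either a `simulate` section
#'   (arguments to [sim_config()]) or paths `fasta`, `vcf`, `coverage`
#'   (TSV `chrom`, `pos`, `mean_depth`, `sd_depth`). Optional:
#'   `cg_regions` (BED), `mean_min`, `sd_max`, `aa_min`, `aa_min_mean`.
#' @param out_dir Output directory (created if needed).
#' @param resume Reuse cached outputs when the config hash matches.
#' @return The manifest list, invisibly; outputs under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, resume = TRUE) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  outputs <- file.path(out_dir, c("dr.bedgraph", "dr.tsv", "rates.tsv",
                                  "mask.bed", "saturation.tsv"))
  if (resume && file.exists(manifest_path) && all(file.exists(outputs))) {
    old <- jsonlite::read_json(manifest_path)
    if (identical(old$config_hash, cfg_hash)) {
      return(invisible(old))
    }
  }
  stages <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    stages[[name]] <<- list(elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }
  if (!is.null(config$simulate)) {
    sim <- timed("simulate", {
      sc <- do.call(sim_config, config$simulate)
      genome <- generate_genome(sc)
      list(sc = sc,
           genome = genome,
           variants = generate_variants(genome, sc),
           coverage = generate_coverage_stats(genome, sc))
    })
    genome <- sim$genome
    variants <- sim$variants
    coverage <- sim$coverage
    cg_regions <- sim$sc$cg_enriched_regions
    stages$simulate$n_variants <- nrow(variants)
  } else {
    for (p in c("fasta", "vcf", "coverage")) {
      if (is.null(config[[p]]) || !file.exists(config[[p]])) {
        abort(paste0("missing input: ", p), class = "drscan_missing_input")
      }
    }
    genome <- read_genome_fasta(config$fasta)
    variants <- tryCatch(
      read_snv_vcf(config$vcf),
      error = function(e) abort(paste0("failed to read VCF: ",
                                       conditionMessage(e)),
                                class = "drscan_missing_input"))
    coverage <- readr::read_tsv(config$coverage, show_col_types = FALSE)
    cg_regions <- if (!is.null(config$cg_regions)) read_bed(config$cg_regions)
  }
  mask <- timed("mask", build_reliable_mask(
    coverage,
    mean_min = config$mean_min %||% 20,
    sd_max = config$sd_max %||% 12,
    chrom_lengths = genome_lengths(genome)))
  stages$mask$reliable_bp <- reliable_bp(mask)
  rates <- timed("rates", tally_heptamer_variants(
    variants, genome, mask, partition_track = cg_regions,
    aa_min = config$aa_min %||% 0.5))
  stages$rates$n_heptamers <- nrow(rates)
  stages$rates$skipped_variant_sites <- attr(rates, "skipped")
  track <- timed("dr", {
    windows <- enumerate_windows(mask)
    scored <- score_windows(windows, variants, genome, rates, mask,
                            partition_track = cg_regions,
                            aa_min_mean = config$aa_min_mean %||% 0.85,
                            aa_min = config$aa_min %||% 0.5)
    assign_dr(scored)
  })
  stages$dr$n_windows <- nrow(track)
  sat <- timed("saturation", {
    v <- classify_variants(filter_qualifying_snvs(variants,
                                                  config$aa_min %||% 0.5),
                           genome)
    saturation(v, count_opportunities(genome, mask))
  })
  write_mask_bed(mask, file.path(out_dir, "mask.bed"))
  write_rates_tsv(rates, file.path(out_dir, "rates.tsv"))
  write_dr_bedgraph(track, file.path(out_dir, "dr.bedgraph"))
  write_dr_tsv(track, file.path(out_dir, "dr.tsv"))
  readr::write_tsv(as_tibble(sat), file.path(out_dir, "saturation.tsv"))
  manifest <- list(
    tool = "drscan",
    version = as.character(utils::packageVersion("drscan")),
    config_hash = cfg_hash,
    outputs = basename(outputs),
    output_md5 = as.list(tools::md5sum(outputs)),
    stages = stages
  )
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
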