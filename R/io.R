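# file interfaces: VCF, BED, bedGraph, gene/config tables

#' Write SNV records as VCF v4.2
#'
#' INFO carries `AAScore` (variant quality probability) and `NCARRIER`
#' (carrier count). Output is deterministic (fixed float formatting, LF
#' line endings).
#'
#' @param variants SNV tibble (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   optionally `aa_score`, `carrier_count`).
#' @param path Output path.
#' @param chrom_lengths Optional named lengths for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_snv_vcf <- function(variants, path, chrom_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=drscan",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##INFO=<ID=AAScore,Number=1,Type=Float,Description=\"Probability the variant is a true positive\">",
    "##INFO=<ID=NCARRIER,Number=1,Type=Integer,Description=\"Number of carriers\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  aa <- if ("aa_score" %in% names(variants)) {
    sprintf("AAScore=%.6g", variants$aa_score)
  } else rep("AAScore=1", nrow(variants))
  nc <- if ("carrier_count" %in% names(variants)) {
    sprintf("NCARRIER=%d", as.integer(variants$carrier_count))
  } else rep("NCARRIER=1", nrow(variants))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s;%s",
                  variants$chrom, variants$pos + 1L, variants$ref,
                  variants$alt, aa, nc)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read SNV records from a VCF
#'
#' Multiallelic records are decomposed into one row per alternate allele.
#' INFO keys for the quality score and carrier count are configurable.
#'
#' @param path VCF path.
#' @param aa_key,carrier_key INFO keys (defaults `AAScore`, `NCARRIER`).
#' @return SNV tibble `chrom`, `pos` (0-based), `ref`, `alt`, `aa_score`,
#'   `carrier_count`.
#' @export
read_snv_vcf <- function(path, aa_key = "AAScore", carrier_key = "NCARRIER") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), aa_score = numeric(),
                  carrier_count = integer()))
  }
  aa <- suppressWarnings(as.numeric(vcfR::extract.info(v, aa_key)))
  nc <- suppressWarnings(as.integer(vcfR::extract.info(v, carrier_key)))
  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L,
    ref = fix$REF,
    alt = fix$ALT,
    aa_score = aa,
    carrier_count = nc
  )
  # decompose multiallelics
  out |>
    mutate(alt = strsplit(.data$alt, ",", fixed = TRUE)) |>
    tidyr::unnest("alt") |>
    arrange(.data$chrom, .data$pos)
}

#' Write/read interval tables as BED (0-based half-open)
#'
#' @param intervals Tibble `chrom`, `start`, `end` and optionally a fourth
#'   name column.
#' @param path File path.
#' @param name_col Optional column written as the BED name field.
#' @return `path` (write) or an interval tibble (read).
#' @export
write_bed <- function(intervals, path, name_col = NULL) {
  d <- arrange(intervals, .data$chrom, .data$start)
  lines <- if (!is.null(name_col)) {
    sprintf("%s\t%d\t%d\t%s", d$chrom, d$start, d$end, d[[name_col]])
  } else {
    sprintf("%s\t%d\t%d", d$chrom, d$start, d$end)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  as_tibble(d)
}

#' Write/read the gene score table (gene, loeuf, gerp) as TSV
#' @param genes Gene tibble.
#' @param path File path.
#' @return `path` (write) or gene tibble (read).
#' @export
write_gene_tsv <- function(genes, path) {
  readr::write_tsv(genes, path)
  invisible(path)
}

#' @rdname write_gene_tsv
#' @export
read_gene_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
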