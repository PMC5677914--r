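# serialize one platform's calls as a multi-sample VCF 4.2 body.
# Genotypes are written as sorted unphased index pairs; per-sample
# quality travels in the standard FORMAT/FT field (LOWQ for
# quality-failed calls) so that a multi-sample file can carry the
# per-sample filter status a per-sample conversion would put in FILTER.
write_calls_vcf <- function(calls, panel, path, drop_loci = character()) {
  panel_tbl <- as_tibble(panel) |>
    filter(!.data$rsid %in% drop_loci) |>
    arrange(.data$chrom, .data$pos)
  samples <- sort(unique(calls$sample_id))
  header <- c(
    "##fileformat=VCFv4.2",
    "##reference=GRCh37",
    "##source=pgxcohort-synthetic",
    "##FILTER=<ID=LOWQ,Description=\"Low confidence call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-sample filter\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  cells <- calls |>
    filter(.data$rsid %in% panel_tbl$rsid) |>
    left_join(panel_tbl |> select("rsid", "ref", "alt"), by = "rsid") |>
    mutate(
      i1 = as.integer(.data$allele1 != .data$ref),
      i2 = as.integer(.data$allele2 != .data$ref),
      gt = case_when(
        .data$status == "missing" ~ "./.",
        TRUE ~ paste(pmin(.data$i1, .data$i2), pmax(.data$i1, .data$i2),
                     sep = "/")),
      dp = ifelse(is.na(.data$read_depth), ".",
                  as.character(.data$read_depth)),
      ad = ifelse(is.na(.data$ref_reads) | is.na(.data$alt_reads), ".",
                  paste0(.data$ref_reads, ",", .data$alt_reads)),
      ft = case_when(.data$status == "missing" ~ ".",
                     .data$status == "fail_quality" ~ "LOWQ",
                     TRUE ~ "PASS"),
      cell = paste(.data$gt, .data$dp, .data$ad, .data$ft, sep = ":"))
  wide <- cells |>
    select("sample_id", "rsid", "cell") |>
    pivot_wider(names_from = "sample_id", values_from = "cell")
  wide <- wide[match(panel_tbl$rsid, wide$rsid), , drop = FALSE]
  body <- paste(
    panel_tbl$chrom, panel_tbl$pos, panel_tbl$rsid, panel_tbl$ref,
    panel_tbl$alt, ".", "PASS", ".", "GT:DP:AD:FT",
    apply(as.matrix(wide[, samples, drop = FALSE]), 1, paste,
          collapse = "\t"),
    sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# wide targeted-genotyping table: one row per sample, one column per rsid
write_calls_targeted <- function(calls, panel, path) {
  panel_tbl <- as_tibble(panel) |> arrange(.data$chrom, .data$pos)
  wide <- calls |>
    mutate(cell = ifelse(.data$status == "pass",
                         paste0(.data$allele1, "/", .data$allele2), ".")) |>
    select("sample_id", "rsid", "cell") |>
    pivot_wider(names_from = "rsid", values_from = "cell") |>
    arrange(.data$sample_id)
  wide <- wide[, c("sample_id", panel_tbl$rsid)]
  write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Write a complete synthetic fixture set
#'
#' Emits every input file the pipeline consumes — a multi-sample WGS VCF,
#' a WES-dialect VCF (the capture omits the loci upstream of CYP2D6
#' exon 1 entirely), a wide targeted-genotyping TSV, the windowed
#' relative-coverage TSV and the ground-truth manifest as JSON — such
#' that re-reading the files with the package's readers reproduces the
#' simulation's in-memory call tables exactly, and identical
#' (config, seed) pairs produce byte-identical files.
#'
#' @param sim A `pgx_simulation` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param kb Knowledge base (panel used for locus order).
#' @return Named character vector of the file paths written.
#' @export
write_fixture_set <- function(sim, dir, kb = pgx_knowledge_base()) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory %s", dir,
                   class = "pgx_io_error")
  }
  paths <- c(wgs_vcf = file.path(dir, "wgs.vcf"),
             wes_vcf = file.path(dir, "wes.vcf"),
             targeted_tsv = file.path(dir, "targeted.tsv"),
             coverage_tsv = file.path(dir, "coverage.tsv"),
             manifest_json = file.path(dir, "manifest.json"))
  split_calls <- split(sim$calls, sim$calls$platform)
  if ("WGS" %in% names(split_calls)) {
    write_calls_vcf(split_calls$WGS, kb$panel, paths[["wgs_vcf"]])
  }
  if ("WES" %in% names(split_calls)) {
    write_calls_vcf(split_calls$WES, kb$panel, paths[["wes_vcf"]],
                    drop_loci = sim$config$wes_dropped_loci)
  }
  if ("TARGETED" %in% names(split_calls)) {
    write_calls_targeted(split_calls$TARGETED, kb$panel,
                         paths[["targeted_tsv"]])
  }
  write_tsv(sim$coverage, paths[["coverage_tsv"]], progress = FALSE)
  jsonlite::write_json(
    list(seed = sim$seed,
         n_samples = sim$config$n_samples,
         samples = sim$manifest$samples,
         diplotypes = sim$manifest$diplotypes,
         phenotypes = sim$manifest$phenotypes),
    paths[["manifest_json"]], auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  paths[exists_ok(paths)]
}

exists_ok <- function(paths) file.exists(paths)
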