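#' Read per-sample genotype calls from a VCF
#'
#' Extracts calls at the panel's loci from a (possibly multi-sample)
#' VCF 4.x on GRCh37 and returns the long genotype table used throughout
#' the package. Panel loci are matched by normalized chromosome
#' (`chr22`/`22` compare equal), position, and exact ref/alt strings;
#' records elsewhere in the file are ignored. Loci with no record for a
#' sample come back with `status = "missing"`; records failing the site
#' `FILTER` or a per-sample `FT` field come back as `fail_quality` with
#' their alleles retained; half-missing genotypes (`./0`) are
#' `fail_quality` as well. Phase separators are accepted and discarded:
#' genotypes are stored as unordered (sorted) allele pairs. Allelic depths
#' are captured from `AD` (and total depth from `DP`) when present.
#'
#' @param path VCF file (plain or gzipped).
#' @param panel A `pgx_panel`.
#' @param platform Platform tag recorded on every call (`"WGS"`, `"WES"`
#'   or `"TARGETED"`).
#' @return A genotype tibble with columns `sample_id`, `rsid`, `gene`,
#'   `platform`, `allele1`, `allele2`, `status`, `read_depth`,
#'   `ref_reads`, `alt_reads`; one row per (sample, panel locus).
#' @export
read_vcf_calls <- function(path, panel, platform = "WGS") {
  stopifnot(platform %in% platform_tags)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stopf("unparseable VCF %s: %s", path,
                                            conditionMessage(e),
                                            class = "pgx_format_error"))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record files drop dims
  fix <- as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  samples <- colnames(vcf@gt)[-1]
  if (is.null(samples) || length(samples) == 0) {
    stopf("VCF %s carries no sample columns", path,
          class = "pgx_format_error")
  }
  panel_tbl <- as_tibble(panel) |> mutate(chrom = norm_chrom(.data$chrom))

  calls <- NULL
  if (nrow(fix) > 0) {
    fix <- fix |>
      mutate(row = row_number(),
             CHROM = norm_chrom(.data$CHROM),
             POS = as.integer(.data$POS)) |>
      inner_join(panel_tbl, by = c(CHROM = "chrom", POS = "pos")) |>
      filter(.data$REF == .data$ref,
             .data$ALT == .data$alt | .data$ALT %in% c(".", NA))
    if (nrow(fix) > 0) {
      gt <- extract_fmt(vcf, "GT")[fix$row, , drop = FALSE]
      dp <- extract_fmt(vcf, "DP")[fix$row, , drop = FALSE]
      ad <- extract_fmt(vcf, "AD")[fix$row, , drop = FALSE]
      ft <- extract_fmt(vcf, "FT")[fix$row, , drop = FALSE]
      calls <- expand_grid(i = seq_len(nrow(fix)), sample_id = samples) |>
        mutate(
          rsid = fix$rsid[.data$i],
          gene = fix$gene[.data$i],
          ref = fix$ref[.data$i],
          alt = fix$alt[.data$i],
          site_fail = !(fix$FILTER[.data$i] %in% c("PASS", ".", NA)),
          gt = gt[cbind(.data$i, match(.data$sample_id, samples))],
          dp = dp[cbind(.data$i, match(.data$sample_id, samples))],
          ad = ad[cbind(.data$i, match(.data$sample_id, samples))],
          ft = ft[cbind(.data$i, match(.data$sample_id, samples))]
        ) |>
        parse_vcf_genotypes()
    }
  }

  complete_matrix(calls, panel_tbl, samples, platform)
}

# extract a FORMAT element as a variants x samples character matrix,
# NA-filled when the field is absent from the file
extract_fmt <- function(vcf, element) {
  out <- tryCatch(
    suppressWarnings(vcfR::extract.gt(vcf, element = element,
                                      convertNA = FALSE)),
    error = function(e) NULL)
  n_var <- nrow(vcf@fix)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(out)) {
    out <- matrix(NA_character_, nrow = n_var, ncol = length(samples))
  }
  out[out %in% c(".", "")] <- NA_character_
  out
}

parse_vcf_genotypes <- function(calls) {
  parts <- str_split(ifelse(is.na(calls$gt), "./.", calls$gt), "[/|]")
  a1i <- map_chr(parts, 1)
  a2i <- map_chr(parts, ~ if (length(.x) > 1) .x[2] else ".")
  idx_to_allele <- function(idx, ref, alt) {
    ifelse(idx == "0", ref, ifelse(idx == "1", alt, NA_character_))
  }
  a1 <- idx_to_allele(a1i, calls$ref, calls$alt)
  a2 <- idx_to_allele(a2i, calls$ref, calls$alt)
  n_missing <- (a1i == ".") + (a2i == ".")
  ad_parts <- str_split(ifelse(is.na(calls$ad), ",", calls$ad), ",")
  ref_reads <- suppressWarnings(as.integer(map_chr(ad_parts, 1)))
  alt_reads <- suppressWarnings(
    as.integer(map_chr(ad_parts, ~ if (length(.x) > 1) .x[2] else NA_character_)))
  status <- case_when(
    n_missing == 2 ~ "missing",
    n_missing == 1 ~ "fail_quality",
    calls$site_fail ~ "fail_quality",
    !is.na(calls$ft) & !(calls$ft %in% c("PASS")) ~ "fail_quality",
    TRUE ~ "pass"
  )
  sorted <- sort_allele_pair(a1, a2)
  calls |>
    mutate(allele1 = ifelse(status == "missing", NA_character_,
                            sorted$allele1),
           allele2 = ifelse(status == "missing", NA_character_,
                            sorted$allele2),
           status = status,
           read_depth = ifelse(status == "missing", NA_integer_,
                               suppressWarnings(as.integer(.data$dp))),
           ref_reads = ifelse(status == "missing", NA_integer_, ref_reads),
           alt_reads = ifelse(status == "missing", NA_integer_, alt_reads)) |>
    select("sample_id", "rsid", "gene", "allele1", "allele2", "status",
           "read_depth", "ref_reads", "alt_reads")
}

# fill the (sample x panel locus) grid, marking absent cells missing
complete_matrix <- function(calls, panel_tbl, samples, platform) {
  grid <- expand_grid(sample_id = samples,
                      panel_tbl |> select("rsid", "gene"))
  out <- grid |>
    left_join(calls %||% tibble(sample_id = character(), rsid = character(),
                                gene = character(), allele1 = character(),
                                allele2 = character(), status = character(),
                                read_depth = integer(),
                                ref_reads = integer(),
                                alt_reads = integer()),
              by = c("sample_id", "rsid", "gene")) |>
    mutate(status = replace_na(.data$status, "missing"),
           platform = platform) |>
    select("sample_id", "rsid", "gene", "platform", "allele1", "allele2",
           "status", "read_depth", "ref_reads", "alt_reads") |>
    arrange(.data$sample_id, .data$rsid)
  out
}

#' Read targeted-genotyping calls from a wide TSV
#'
#' Parses the wide genotype-table dialect used for targeted platforms: one
#' row per sample, one column per rsid, cells like `"A/G"` (any allele
#' order) or `"."` for a no-call. The platform delivers no read depths, so
#' depth fields are `NA`.
#'
#' @param path Wide TSV; first column `sample_id`.
#' @param panel A `pgx_panel`; every genotype column must resolve to a
#'   panel locus (aliases allowed).
#' @param platform Platform tag (default `"TARGETED"`).
#' @return A genotype tibble as in [read_vcf_calls()]; loci absent from
#'   the table come back `missing`.
#' @export
read_targeted_calls <- function(path, panel, platform = "TARGETED") {
  stopifnot(platform %in% platform_tags)
  wide <- tryCatch(
    read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
             col_types = cols(.default = col_character())),
    error = function(e) stopf("unparseable genotype table %s: %s", path,
                              conditionMessage(e),
                              class = "pgx_format_error"))
  if (names(wide)[1] != "sample_id") names(wide)[1] <- "sample_id"
  loci <- names(wide)[-1]
  canonical <- resolve_rsid(panel, loci)
  if (anyNA(canonical)) {
    stopf("genotype table column(s) not in panel: %s",
          paste(loci[is.na(canonical)], collapse = ", "),
          class = "pgx_validation_error")
  }
  names(wide)[-1] <- canonical
  long <- wide |>
    pivot_longer(-"sample_id", names_to = "rsid", values_to = "cell") |>
    mutate(cell = replace_na(.data$cell, "."))
  bad <- long |>
    filter(.data$cell != ".",
           !str_detect(.data$cell, "^[^/]+/[^/]+$"))
  if (nrow(bad) > 0) {
    stopf("malformed genotype cell(s): %s",
          paste(head(paste0(bad$sample_id, "@", bad$rsid, "='",
                            bad$cell, "'"), 5), collapse = ", "),
          class = "pgx_format_error")
  }
  parts <- str_split(long$cell, "/")
  a1 <- map_chr(parts, 1)
  a2 <- map_chr(parts, ~ if (length(.x) > 1) .x[2] else NA_character_)
  sorted <- sort_allele_pair(a1, a2)
  calls <- long |>
    mutate(allele1 = ifelse(.data$cell == ".", NA_character_,
                            sorted$allele1),
           allele2 = ifelse(.data$cell == ".", NA_character_,
                            sorted$allele2),
           status = ifelse(.data$cell == ".", "missing", "pass"),
           read_depth = NA_integer_, ref_reads = NA_integer_,
           alt_reads = NA_integer_) |>
    left_join(as_tibble(panel) |> select("rsid", "gene"), by = "rsid") |>
    select("sample_id", "rsid", "gene", "allele1", "allele2", "status",
           "read_depth", "ref_reads", "alt_reads")
  panel_tbl <- as_tibble(panel) |> mutate(chrom = norm_chrom(.data$chrom))
  complete_matrix(calls, panel_tbl, unique(wide$sample_id), platform)
}

#' Tally call quality per platform
#'
#' Per-platform accounting of `pass` / `fail_quality` / `missing` cells.
#' The three categories partition the samples-by-loci grid exactly, so
#' `n_pass + n_fail_quality + n_missing == n_total` always holds.
#'
#' @param calls A genotype tibble (any number of platforms).
#' @param digits Decimal places for the reported pass percentage
#'   (half-up; default 0).
#' @return A tibble with one row per platform: counts per category,
#'   `n_total`, and `pass_pct`.
#' @examples
#' # 6312 passing of 6566 cells report as 96%
#' round_half_up(100 * 6312 / 6566)   # 96
#' @export
call_accounting <- function(calls, digits = 0) {
  calls |>
    group_by(.data$platform) |>
    summarise(n_pass = sum(.data$status == "pass"),
              n_fail_quality = sum(.data$status == "fail_quality"),
              n_missing = sum(.data$status == "missing"),
              n_total = n(),
              .groups = "drop") |>
    mutate(pass_pct = pct_of(.data$n_pass, .data$n_total, digits))
}

#' Export a genotype table as long-format TSV
#'
#' @param calls A genotype tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotype_calls <- function(calls, path) {
  write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Merge calls across platforms with a preference order
#'
#' Consolidates one call per (sample, locus): the first platform in
#' `prefer` with a passing call wins; failing that, the first with any
#' call. The merged platform is tagged `"MERGED"`. This mirrors combining
#' a sequencing platform with targeted genotyping before phenotype
#' prediction.
#'
#' @param calls A genotype tibble covering one or more platforms.
#' @param prefer Platform preference order.
#' @return A genotype tibble with `platform = "MERGED"`.
#' @export
merge_platform_calls <- function(calls,
                                 prefer = c("TARGETED", "WGS", "WES")) {
  calls |>
    mutate(pref = match(.data$platform, prefer),
           rank = ifelse(.data$status == "pass", 0L, 1L)) |>
    filter(!is.na(.data$pref)) |>
    group_by(.data$sample_id, .data$rsid) |>
    arrange(.data$rank, .data$pref, .by_group = TRUE) |>
    slice(1) |>
    ungroup() |>
    mutate(platform = "MERGED") |>
    select(-"pref", -"rank") |>
    arrange(.data$sample_id, .data$rsid)
}
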