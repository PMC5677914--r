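new_concordance <- function(summary, discordant, extra = list()) {
  structure(c(list(summary = summary, discordant = discordant), extra),
            class = "pgx_concordance")
}

#' @export
glance.pgx_concordance <- function(x, ...) x$summary

#' @export
tidy.pgx_concordance <- function(x, ...) x$discordant

#' @export
print.pgx_concordance <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Concordance %s vs %s: %s%% (%d/%d comparable, %d excluded)\n",
              s$platform_a, s$platform_b,
              ifelse(is.na(s$concordance_pct), "NA",
                     format(s$concordance_pct)),
              s$n_concordant, s$n_comparable, s$n_excluded))
  if (nrow(x$discordant) > 0) {
    cat(sprintf("  %d discordant cell(s)\n", nrow(x$discordant)))
  }
  invisible(x)
}

#' Genotype concordance between two platforms
#'
#' Compares unordered allele pairs cell by cell over the shared
#' (sample, locus) grid. Cells without a passing call on both platforms
#' are excluded from the denominator and counted separately (strict mode,
#' behind `strict = TRUE`, counts them as discordant instead — a
#' sensitivity analysis, not the default methodology).
#'
#' @param calls Genotype tibble containing both platforms.
#' @param platforms Length-2 character vector naming the pair.
#' @param strict Count not-comparable cells as discordant (default
#'   FALSE).
#' @param digits Decimal places for the reported percentage (half-up,
#'   default 1).
#' @return A `pgx_concordance` object: `glance()` returns the one-row
#'   summary (`n_comparable`, `n_concordant`, `n_discordant`,
#'   `n_excluded`, `concordance_pct`, `NA` when nothing is comparable),
#'   `tidy()` the discordant cell list.
#' @export
genotype_concordance <- function(calls, platforms = c("WGS", "TARGETED"),
                                 strict = FALSE, digits = 1) {
  if (length(platforms) != 2 ||
      !all(platforms %in% unique(calls$platform))) {
    stopf("both platforms must be present in the call set: %s",
          paste(platforms, collapse = ", "),
          class = "pgx_parameter_error")
  }
  wide <- calls |>
    filter(.data$platform %in% platforms) |>
    mutate(key = pair_key(.data$allele1, .data$allele2),
           side = ifelse(.data$platform == platforms[1], "a", "b")) |>
    select("sample_id", "rsid", "gene", "side", "status", "key") |>
    pivot_wider(names_from = "side", values_from = c("status", "key"))
  wide <- wide |>
    filter(!is.na(.data$status_a), !is.na(.data$status_b)) |>
    mutate(comparable = .data$status_a == "pass" & .data$status_b == "pass",
           concordant = .data$comparable & .data$key_a == .data$key_b)
  n_comp <- sum(wide$comparable)
  n_conc <- sum(wide$concordant)
  n_excl <- sum(!wide$comparable)
  n_disc <- n_comp - n_conc
  if (strict) {
    n_disc <- n_disc + n_excl
    n_comp <- n_comp + n_excl
    n_excl <- 0L
  }
  summary <- tibble(platform_a = platforms[1], platform_b = platforms[2],
                    n_total = nrow(wide), n_comparable = n_comp,
                    n_concordant = n_conc, n_discordant = n_disc,
                    n_excluded = n_excl,
                    concordance_pct = pct_of(n_conc, n_comp, digits))
  discordant <- wide |>
    filter(.data$comparable, !.data$concordant) |>
    transmute(sample_id = .data$sample_id, rsid = .data$rsid,
              gene = .data$gene, call_a = .data$key_a,
              call_b = .data$key_b) |>
    arrange(.data$sample_id, .data$rsid)
  new_concordance(summary, discordant)
}

#' Copy-number concordance between two call sets
#'
#' Compares integer copy-number calls over the shared samples. Pairs
#' where exactly one side is inconclusive are not counted as discordant:
#' they are listed separately as resolved-by-the-other-platform, the
#' handling applied to samples whose coverage-based call was ambiguous
#' but whose targeted assay returned an integer.
#'
#' @param calls_a,calls_b `pgx_cnv_calls` tibbles (columns `sample_id`,
#'   `copy_number`, `conclusive`).
#' @param platforms Labels for the two call sets.
#' @param digits Decimal places for the percentage.
#' @return A `pgx_concordance` object with an extra `resolved_by_other`
#'   tibble.
#' @export
cnv_concordance <- function(calls_a, calls_b,
                            platforms = c("WGS", "TARGETED"), digits = 1) {
  joined <- inner_join(
    as_tibble(calls_a) |> select("sample_id", cn_a = "copy_number"),
    as_tibble(calls_b) |> select("sample_id", cn_b = "copy_number"),
    by = "sample_id")
  both <- joined |> filter(!is.na(.data$cn_a), !is.na(.data$cn_b))
  one_side <- joined |> filter(xor(is.na(.data$cn_a), is.na(.data$cn_b)))
  neither <- joined |> filter(is.na(.data$cn_a), is.na(.data$cn_b))
  n_comp <- nrow(both)
  n_conc <- sum(both$cn_a == both$cn_b)
  summary <- tibble(platform_a = platforms[1], platform_b = platforms[2],
                    n_total = nrow(joined), n_comparable = n_comp,
                    n_concordant = n_conc,
                    n_discordant = n_comp - n_conc,
                    n_excluded = nrow(one_side) + nrow(neither),
                    concordance_pct = pct_of(n_conc, n_comp, digits))
  discordant <- both |>
    filter(.data$cn_a != .data$cn_b) |>
    transmute(sample_id = .data$sample_id,
              call_a = as.character(.data$cn_a),
              call_b = as.character(.data$cn_b)) |>
    arrange(.data$sample_id)
  resolved <- one_side |>
    transmute(sample_id = .data$sample_id,
              inconclusive_on = ifelse(is.na(.data$cn_a), platforms[1],
                                       platforms[2]),
              resolved_copy_number = ifelse(is.na(.data$cn_a), .data$cn_b,
                                            .data$cn_a)) |>
    arrange(.data$sample_id)
  new_concordance(summary, discordant,
                  list(resolved_by_other = resolved))
}

#' Phenotype concordance between two record sets for one gene
#'
#' Compares predicted phenotype classes over the shared samples;
#' indeterminate phenotypes on either side are excluded from the
#' denominator and counted.
#'
#' @param records_a,records_b Phenotype record tibbles (see
#'   [assign_phenotypes()]).
#' @param gene Gene to compare.
#' @param platforms Labels for the two record sets.
#' @param digits Decimal places for the percentage.
#' @return A `pgx_concordance` object.
#' @export
phenotype_concordance <- function(records_a, records_b, gene = "CYP2D6",
                                  platforms = c("WGS", "TARGETED"),
                                  digits = 1) {
  pick <- function(r) {
    r |> filter(.data$gene == !!gene) |>
      select("sample_id", "phenotype_class")
  }
  joined <- inner_join(pick(records_a), pick(records_b), by = "sample_id",
                       suffix = c("_a", "_b"))
  comparable <- joined |>
    filter(.data$phenotype_class_a != "indeterminate",
           .data$phenotype_class_b != "indeterminate")
  n_comp <- nrow(comparable)
  n_conc <- sum(comparable$phenotype_class_a == comparable$phenotype_class_b)
  summary <- tibble(platform_a = platforms[1], platform_b = platforms[2],
                    n_total = nrow(joined), n_comparable = n_comp,
                    n_concordant = n_conc,
                    n_discordant = n_comp - n_conc,
                    n_excluded = nrow(joined) - n_comp,
                    concordance_pct = pct_of(n_conc, n_comp, digits))
  discordant <- comparable |>
    filter(.data$phenotype_class_a != .data$phenotype_class_b) |>
    transmute(sample_id = .data$sample_id,
              call_a = .data$phenotype_class_a,
              call_b = .data$phenotype_class_b) |>
    arrange(.data$sample_id)
  new_concordance(summary, discordant)
}

#' Write a concordance report
#'
#' Emits the one-row summary as JSON and, when present, the discordant
#' cell list as TSV next to it.
#'
#' @param report A `pgx_concordance` object.
#' @param path JSON output file; the discordance list goes to
#'   `<path>.discordant.tsv`.
#' @return `path`, invisibly.
#' @export
write_concordance <- function(report, path) {
  jsonlite::write_json(as.list(report$summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (nrow(report$discordant) > 0) {
    write_tsv(report$discordant, paste0(path, ".discordant.tsv"),
              progress = FALSE)
  }
  invisible(path)
}
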