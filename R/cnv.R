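#' Default relative-coverage classification bands
#'
#' Relative coverage is depth normalized under a diploid model (a value of
#' 1 means two copies). The default bands codify the qualitative
#' "close to" intervals used when classifying CYP2D6 copy number from a
#' 6 kb window: coverage within ±0.2 of 1 is two copies, within
#' \[0.4, 0.6\] one copy, \[1.4, 1.6\] three copies, at or below 0.1 zero
#' copies. From 1.8 upward the call snaps to the nearest half-unit grid
#' point (`k = round(2 * coverage)`), so 1.96 is four copies; every value
#' in a gap between bands is `inconclusive`. The bands form a partition:
#' each non-negative value maps to exactly one outcome.
#'
#' @return A list with a `bands` tibble (`copy_number`, `lower`, `upper`,
#'   inclusive bounds) and `high_copy_min`, the lower edge of the
#'   nearest-grid region.
#' @export
default_cnv_bands <- function() {
  list(
    bands = tibble(
      copy_number = c(0L, 1L, 2L, 3L),
      lower = c(0, 0.4, 0.8, 1.4),
      upper = c(0.1, 0.6, 1.2, 1.6)),
    high_copy_min = 1.8)
}

#' Classify CYP2D6 copy number from mean relative coverage
#'
#' @param mean_rel_cov Numeric vector of per-sample mean relative coverage
#'   values (must be non-negative).
#' @param bands Band configuration, see [default_cnv_bands()].
#' @return A tibble with one row per input: `mean_rel_cov`, `copy_number`
#'   (integer; `NA` when inconclusive), `conclusive`, and the `band` label
#'   applied.
#' @examples
#' classify_copy_number(c(1.96, 1.5, 1.0, 0.5, 0.75))$copy_number
#' # 4 3 2 1 NA
#' @export
classify_copy_number <- function(mean_rel_cov, bands = default_cnv_bands()) {
  if (any(is.na(mean_rel_cov)) || any(mean_rel_cov < 0)) {
    stopf("mean relative coverage must be non-negative and non-missing",
          class = "pgx_data_error")
  }
  b <- bands$bands
  cn <- rep(NA_integer_, length(mean_rel_cov))
  lab <- rep("inconclusive", length(mean_rel_cov))
  for (k in seq_len(nrow(b))) {
    hit <- mean_rel_cov >= b$lower[k] & mean_rel_cov <= b$upper[k]
    cn[hit] <- b$copy_number[k]
    lab[hit] <- sprintf("[%g,%g]", b$lower[k], b$upper[k])
  }
  high <- mean_rel_cov >= bands$high_copy_min
  cn[high] <- as.integer(round(2 * mean_rel_cov[high]))
  lab[high] <- sprintf(">=%g (nearest half-unit)", bands$high_copy_min)
  tibble(mean_rel_cov = mean_rel_cov, copy_number = cn,
         conclusive = !is.na(cn), band = lab)
}

#' Read windowed relative-coverage profiles
#'
#' @param path TSV with columns `sample_id`, `chrom`, `window_start`,
#'   `window_end`, `relative_coverage` (one row per 2 kb window; the
#'   default CYP2D6 region is three windows spanning
#'   chr22:42,522,000-42,528,000, 1-based GRCh37).
#' @return A coverage tibble.
#' @export
read_coverage_profiles <- function(path) {
  read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
           col_types = cols(sample_id = col_character(),
                            chrom = col_character(),
                            window_start = col_integer(),
                            window_end = col_integer(),
                            relative_coverage = col_double()))
}

#' Call copy number across a cohort of coverage profiles
#'
#' Averages the window values per sample (the classification statistic),
#' classifies each mean, and reports per-window dispersion as a QC field
#' that never changes the call.
#'
#' @param profiles A coverage tibble (see [read_coverage_profiles()]).
#' @param bands Band configuration.
#' @return A tibble of class `pgx_cnv_calls`: `sample_id`,
#'   `mean_rel_cov`, `window_sd`, `n_windows`, `copy_number`,
#'   `conclusive`, `band`. `glance()` gives the per-class summary
#'   histogram (inconclusive included).
#' @export
call_cohort_cnv <- function(profiles, bands = default_cnv_bands()) {
  means <- profiles |>
    group_by(.data$sample_id) |>
    summarise(mean_rel_cov = mean(.data$relative_coverage),
              window_sd = stats::sd(.data$relative_coverage),
              n_windows = n(), .groups = "drop")
  cls <- classify_copy_number(means$mean_rel_cov, bands)
  out <- bind_cols(means, cls |> select(-"mean_rel_cov")) |>
    arrange(.data$sample_id)
  class(out) <- c("pgx_cnv_calls", class(out))
  out
}

#' @export
glance.pgx_cnv_calls <- function(x, ...) {
  as_tibble(x) |>
    mutate(class = ifelse(.data$conclusive, as.character(.data$copy_number),
                          "inconclusive")) |>
    count(.data$class, name = "n_samples") |>
    arrange(.data$class)
}

# informative positions: passing het loci whose alleles distinguish the
# two haplotypes of a diplotype
informative_positions <- function(hap1, hap2, gene_calls, defs, panel,
                                  gene = "CYP2D6") {
  mat <- expected_allele_matrix(defs, as_tibble(panel), gene)
  e1 <- mat[hap1, ]
  e2 <- mat[hap2, ]
  loci <- colnames(mat)[e1 != e2]
  gene_calls |>
    filter(.data$rsid %in% loci, .data$status == "pass",
           .data$allele1 != .data$allele2)
}

#' Identify the duplicated haplotype of a three-copy sample
#'
#' In a heterozygous three-copy individual the duplicated haplotype
#' carries two of the three gene copies, so reads at informative positions
#' (passing heterozygous loci whose alleles distinguish the two
#' haplotypes) are expected to split 2:1 toward the duplicated
#' haplotype's allele. A position votes for a haplotype when that
#' haplotype's allele reaches the skew threshold (default: major-allele
#' fraction >= 0.6); unanimous votes across positions determine the
#' duplicated haplotype, conflicting or absent votes give
#' `indeterminate`. Only positions with read depth at or above
#' `min_depth` (default 75) are used. A one-sided binomial-test mode is
#' available behind `method = "binomial"`.
#'
#' @param diplotype One-row diplotype call (needs `sample_id`, `hap1`,
#'   `hap2`, and a `copy_number` of 3); haplotypes must differ.
#' @param gene_calls The sample's calls at the gene's loci, with
#'   `ref_reads`/`alt_reads` populated.
#' @param defs,panel Knowledge base.
#' @param min_depth Minimum total read count at an informative position.
#' @param skew_threshold Major-allele fraction required to call a side
#'   (fraction mode).
#' @param method `"fraction"` (default) or `"binomial"`.
#' @param alpha One-sided significance level for the binomial mode.
#' @param gene Gene symbol (default CYP2D6).
#' @return A one-row tibble: `sample_id`, `duplicated_star` (star name or
#'   `"indeterminate"`), `n_informative`, `informative_positions`
#'   (semicolon-joined `rsid:ref_reads:alt_reads`), `min_depth_used`.
#' @export
phase_duplication <- function(diplotype, gene_calls, defs, panel,
                              min_depth = 75, skew_threshold = 0.6,
                              method = c("fraction", "binomial"),
                              alpha = 0.05, gene = "CYP2D6") {
  method <- match.arg(method)
  cn <- diplotype$copy_number %||% NA_integer_
  if (is.na(cn) || cn != 3L) {
    stopf("duplication phasing requires an integer copy number of 3",
          class = "pgx_precondition_error")
  }
  if (diplotype$hap1 == diplotype$hap2) {
    stopf("duplication phasing requires a heterozygous diplotype",
          class = "pgx_precondition_error")
  }
  mk <- function(star, info) {
    tibble(sample_id = diplotype$sample_id, duplicated_star = star,
           n_informative = nrow(info),
           informative_positions = paste(
             sprintf("%s:%d:%d", info$rsid, info$ref_reads,
                     info$alt_reads), collapse = ";"),
           min_depth_used = min_depth)
  }
  info <- informative_positions(diplotype$hap1, diplotype$hap2, gene_calls,
                                defs, panel, gene) |>
    filter(!is.na(.data$ref_reads), !is.na(.data$alt_reads),
           .data$ref_reads + .data$alt_reads >= min_depth)
  if (nrow(info) == 0) return(mk("indeterminate", info))

  mat <- expected_allele_matrix(defs, as_tibble(panel), gene)
  panel_tbl <- as_tibble(panel)
  pl <- panel_tbl[match(info$rsid, panel_tbl$rsid), ]
  reads_for <- function(hap) {
    expected <- mat[hap, info$rsid]
    ifelse(expected == pl$ref, info$ref_reads,
           ifelse(expected == pl$alt, info$alt_reads, NA_integer_))
  }
  r1 <- reads_for(diplotype$hap1)
  r2 <- reads_for(diplotype$hap2)
  n <- r1 + r2
  vote <- if (method == "fraction") {
    case_when(r1 / n >= skew_threshold ~ "hap1",
              r2 / n >= skew_threshold ~ "hap2",
              TRUE ~ "none")
  } else {
    # one-sided binomial comparison against a balanced 1:1 split
    p1 <- pbinom(r1 - 1, n, 0.5, lower.tail = FALSE)
    p2 <- pbinom(r2 - 1, n, 0.5, lower.tail = FALSE)
    case_when(p1 < alpha & r1 > r2 ~ "hap1",
              p2 < alpha & r2 > r1 ~ "hap2",
              TRUE ~ "none")
  }
  sides <- unique(vote[vote != "none"])
  if (length(sides) != 1 || any(vote == "none")) {
    return(mk("indeterminate", info))
  }
  mk(if (sides == "hap1") diplotype$hap1 else diplotype$hap2, info)
}

#' Annotate diplotypes with copy number
#'
#' Joins cohort copy-number calls (and, optionally, duplication phasing
#' results) onto CYP2D6 diplotype calls. Two copies leave the diplotype
#' unchanged; one copy replaces the second haplotype of a
#' homozygous-appearing call with the deletion allele `*5`; three copies
#' with a phased duplication annotate the duplicated haplotype as
#' `starx2` (e.g. `*1x2/*4`), an unphased heterozygous duplication is
#' flagged `duplication_unassigned` (homozygous diplotypes need no
#' phasing), and four copies are annotated as a balanced duplication of
#' both haplotypes. An inconclusive copy number flags the sample for
#' reflex testing.
#'
#' @param diplotypes Diplotype tibble (CYP2D6 rows are annotated; other
#'   genes pass through with `copy_number = 2`).
#' @param cnv_calls A `pgx_cnv_calls` tibble.
#' @param phases Optional tibble from [phase_duplication()] rows.
#' @param gene Gene the copy-number calls refer to.
#' @return The diplotype tibble with `copy_number`, `cn_conclusive`,
#'   `duplicated_star` and `cn_flag` (`ok`, `duplication_unassigned`,
#'   `reflex_testing`, `cn_genotype_conflict`) columns, haplotype names
#'   rewritten where copy number dictates.
#' @export
integrate_copy_number <- function(diplotypes, cnv_calls, phases = NULL,
                                  gene = "CYP2D6") {
  phases <- phases %||% tibble(sample_id = character(),
                               duplicated_star = character())
  out <- diplotypes |>
    left_join(as_tibble(cnv_calls) |>
                select("sample_id", "copy_number", "conclusive"),
              by = "sample_id") |>
    left_join(phases |> select("sample_id", "duplicated_star"),
              by = "sample_id")
  target <- out$gene == gene
  out <- out |>
    mutate(
      copy_number = ifelse(target, .data$copy_number, 2L),
      cn_conclusive = ifelse(target, .data$conclusive, TRUE),
      duplicated_star = ifelse(target, .data$duplicated_star,
                               NA_character_)) |>
    select(-"conclusive")
  annotate_row <- function(hap1, hap2, state, cn, conclusive, dup) {
    if (!isTRUE(conclusive)) {
      return(list(hap1, hap2, dup = NA_character_, flag = "reflex_testing"))
    }
    if (is.na(hap1) || state == "no_call" || cn == 2L) {
      return(list(hap1, hap2, dup = NA_character_, flag = "ok"))
    }
    if (cn == 1L) {
      if (hap1 == hap2) return(list(hap1, "*5", dup = NA_character_,
                                    flag = "ok"))
      return(list(hap1, hap2, dup = NA_character_,
                  flag = "cn_genotype_conflict"))
    }
    if (cn == 3L) {
      if (hap1 == hap2) {
        return(list(paste0(hap1, "x2"), hap2, dup = hap1, flag = "ok"))
      }
      if (!is.na(dup) && dup == hap1) {
        return(list(paste0(hap1, "x2"), hap2, dup = dup, flag = "ok"))
      }
      if (!is.na(dup) && dup == hap2) {
        return(list(hap1, paste0(hap2, "x2"), dup = dup, flag = "ok"))
      }
      return(list(hap1, hap2, dup = NA_character_,
                  flag = "duplication_unassigned"))
    }
    if (cn == 4L) {
      return(list(paste0(hap1, "x2"), paste0(hap2, "x2"),
                  dup = NA_character_, flag = "ok"))
    }
    list(hap1, hap2, dup = NA_character_, flag = "reflex_testing")
  }
  ann <- pmap(list(out$hap1, out$hap2, out$state, out$copy_number,
                   out$cn_conclusive,
                   ifelse(is.na(out$duplicated_star), NA_character_,
                          out$duplicated_star),
                   target),
              function(h1, h2, st, cn, ok, dup, tgt) {
                if (!tgt) return(list(h1, h2, dup = NA_character_,
                                      flag = "ok"))
                annotate_row(h1, h2, st, cn, ok, dup)
              })
  out |>
    mutate(hap1 = map_chr(ann, ~ .x[[1]] %||% NA_character_),
           hap2 = map_chr(ann, ~ .x[[2]] %||% NA_character_),
           duplicated_star = map_chr(ann, "dup"),
           cn_flag = map_chr(ann, "flag"))
}

#' Export copy-number calls as TSV
#'
#' @param cnv_calls A `pgx_cnv_calls` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(cnv_calls, path) {
  write_tsv(as_tibble(cnv_calls), path, progress = FALSE)
  invisible(path)
}
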