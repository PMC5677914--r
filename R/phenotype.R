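#' Diplotype activity score
#'
#' Sum over the two haplotypes of the allele's activity value times its
#' copy multiplicity: `*1x2/*4` scores `1*2 + 0 = 2`, the deletion `*5`
#' contributes 0. An unknown activity value propagates as `NA` (the
#' phenotype becomes indeterminate, never an error).
#'
#' @param hap1,hap2 Character vectors of haplotype names, optionally
#'   copy-annotated (`"*1x2"`).
#' @param defs A `pgx_star_defs`.
#' @param gene Gene symbol (default CYP2D6, the activity-score gene).
#' @return Numeric vector of scores.
#' @examples
#' defs <- load_star_definitions()
#' activity_score("*1", "*1", defs)       # 2
#' activity_score("*1x2", "*4", defs)     # 2
#' activity_score("*4", "*5", defs)       # 0
#' @export
activity_score <- function(hap1, hap2, defs, gene = "CYP2D6") {
  act <- star_activity(defs) |> filter(.data$gene == !!gene)
  one <- function(h) {
    p <- parse_hap_multiplicity(h)
    v <- act$activity_value[match(p$star, act$star_name)]
    v * p$mult
  }
  out <- one(hap1) + one(hap2)
  out[is.na(hap1) | is.na(hap2)] <- NA_real_
  out
}

#' Translate a function score into a metabolizer phenotype
#'
#' Applies the per-gene cutpoint table: the phenotype whose threshold is
#' the greatest one satisfied by the score wins. The default (CYP2D6)
#' convention is: 0 poor, strictly between 0 and 1 intermediate, 1 to 2
#' extensive, above 2 ultrarapid.
#'
#' @param score Numeric vector of non-negative scores (`NA` gives
#'   `indeterminate`).
#' @param cutpoints Cutpoint tibble (see [load_phenotype_cutpoints()]);
#'   rows for `gene` are used.
#' @param gene Gene whose cutpoints apply (default CYP2D6).
#' @return Character vector of phenotype classes.
#' @examples
#' score_to_phenotype(c(0, 0.5, 2, 3))
#' # "poor" "intermediate" "extensive" "ultrarapid"
#' @export
score_to_phenotype <- function(score,
                               cutpoints = load_phenotype_cutpoints(),
                               gene = "CYP2D6") {
  # at equal thresholds the inclusive row is the weaker condition and
  # must sort first so the exclusive row can override it above the bound
  cp <- cutpoints |> filter(.data$gene == !!gene) |>
    arrange(.data$min_score, desc(.data$inclusive))
  if (nrow(cp) == 0) stopf("no phenotype cutpoints for gene %s", gene)
  map_chr(score, function(s) {
    if (is.na(s)) return("indeterminate")
    hit <- cp$min_score < s | (cp$min_score == s & cp$inclusive)
    if (!any(hit)) return("indeterminate")
    cp$phenotype_class[max(which(hit))]
  })
}

#' Phenotype single-marker genes from genotype calls
#'
#' Lookup-driven translation for genes typed through one tag SNP
#' (HLA-A*31:01 and HLA-B*57:01 tag alleles report carrier status;
#' VKORC1, SLCO1B1 and IFNL3 report function classes). A missing or
#' failed genotype at the tag yields `indeterminate`.
#'
#' @param calls Genotype tibble for one platform (or merged).
#' @param panel A `pgx_panel`.
#' @param marker_rules Marker translation table (see
#'   [load_marker_rules()]).
#' @return A tibble with one row per (sample, marker gene): `sample_id`,
#'   `gene`, `phenotype_class`, `basis = "marker"`.
#' @export
phenotype_other_genes <- function(calls, panel,
                                  marker_rules = load_marker_rules()) {
  panel_tbl <- as_tibble(panel)
  tags <- marker_rules |> distinct(.data$rsid, .data$gene_out)
  work <- calls |>
    inner_join(tags, by = "rsid") |>
    left_join(panel_tbl |> select("rsid", "ref", "alt"), by = "rsid") |>
    mutate(n_alt = (.data$allele1 == .data$alt) + (.data$allele2 == .data$alt),
           zyg = case_when(
             .data$status != "pass" ~ NA_character_,
             .data$n_alt == 0 ~ "hom_ref",
             .data$n_alt == 1 ~ "het",
             TRUE ~ "hom_alt"))
  classify <- function(rsid, zyg) {
    rules <- marker_rules[marker_rules$rsid == rsid, ]
    if (is.na(zyg)) return("indeterminate")
    for (k in seq_len(nrow(rules))) {
      p <- rules$pattern[k]
      if (p == "default" || p == zyg ||
          (p == "any_alt" && zyg %in% c("het", "hom_alt"))) {
        return(rules$phenotype_class[k])
      }
    }
    "indeterminate"
  }
  work |>
    mutate(phenotype_class = map2_chr(.data$rsid, .data$zyg, classify)) |>
    transmute(sample_id = .data$sample_id, gene = .data$gene_out,
              phenotype_class = .data$phenotype_class, basis = "marker") |>
    arrange(.data$sample_id, .data$gene)
}

#' Phenotype a cohort: star-allele genes plus marker genes
#'
#' Builds the per-sample, per-gene phenotype records the actionability
#' rules consume. Star-allele genes are translated through the function
#' score (activity values times copy multiplicity, summed over the
#' diplotype) and per-gene cutpoints; the activity score itself is
#' reported for CYP2D6 only, following the activity-score system. A
#' `no_call` diplotype, or a CYP2D6 copy number left inconclusive, yields
#' an `indeterminate` phenotype (and the sample is surfaced for reflex
#' testing by [categorize_samples()]).
#'
#' @param diplotypes Copy-number-annotated diplotype tibble for one
#'   platform (see [integrate_copy_number()]); plain
#'   [diplotype_cohort()] output is accepted and treated as two-copy.
#' @param calls Genotype tibble for the same platform (marker genes).
#' @param defs,panel,cutpoints,marker_rules Knowledge base.
#' @return A tibble with one row per (sample, gene): `sample_id`, `gene`,
#'   `diplotype` (`NA` for marker genes), `activity_score` (CYP2D6 only),
#'   `phenotype_class`, `basis`.
#' @export
assign_phenotypes <- function(diplotypes, calls, defs, panel,
                              cutpoints = load_phenotype_cutpoints(),
                              marker_rules = load_marker_rules()) {
  dip <- diplotypes
  if (!"cn_flag" %in% names(dip)) {
    dip <- dip |> mutate(copy_number = 2L, cn_conclusive = TRUE,
                         cn_flag = "ok")
  }
  star <- dip |>
    group_by(.data$gene) |>
    group_modify(function(rows, key) {
      g <- key$gene
      score <- activity_score(rows$hap1, rows$hap2, defs, gene = g)
      bad <- rows$state == "no_call" |
        rows$cn_flag %in% c("reflex_testing", "duplication_unassigned",
                            "cn_genotype_conflict")
      cls <- score_to_phenotype(score, cutpoints, gene = g)
      cls[bad] <- "indeterminate"
      tibble(sample_id = rows$sample_id,
             diplotype = ifelse(is.na(rows$hap1), NA_character_,
                                paste0(rows$hap1, "/", rows$hap2)),
             activity_score = if (g == "CYP2D6")
               ifelse(bad, NA_real_, score) else NA_real_,
             phenotype_class = cls,
             basis = "activity_score")
    }) |>
    ungroup() |>
    select("sample_id", "gene", "diplotype", "activity_score",
           "phenotype_class", "basis")
  marker <- phenotype_other_genes(calls, panel, marker_rules) |>
    mutate(diplotype = NA_character_, activity_score = NA_real_) |>
    select("sample_id", "gene", "diplotype", "activity_score",
           "phenotype_class", "basis")
  bind_rows(star, marker) |>
    arrange(.data$sample_id, .data$gene)
}

#' Assign actionability categories to samples
#'
#' Evaluates every drug-gene rule against each sample's phenotype
#' records: category 3 if any category-3 rule triggers, else 2 if any
#' category-2 rule triggers, else 1. Indeterminate phenotypes never
#' trigger rules; samples carrying any indeterminate record are flagged
#' for reflex testing instead.
#'
#' @param records Phenotype records from [assign_phenotypes()].
#' @param rules A `pgx_rules` tibble.
#' @return A tibble with one row per sample: `category`,
#'   `triggering_genes` (comma-joined), `specialties` (comma-joined union
#'   over triggered rules), `n_indeterminate`, `reflex_recommended`.
#' @export
categorize_samples <- function(records, rules = load_actionability_rules()) {
  rule_rows <- as_tibble(rules) |>
    mutate(trigger = .data$trigger) |>
    tidyr::unnest_longer("trigger", values_to = "phenotype_class")
  hits <- records |>
    filter(.data$phenotype_class != "indeterminate") |>
    inner_join(rule_rows, by = c("gene", "phenotype_class"))
  per_sample <- hits |>
    group_by(.data$sample_id) |>
    summarise(category = max(c(1L, .data$category)),
              triggering_genes = paste(str_sort(unique(.data$gene)),
                                       collapse = ","),
              specialties = paste(str_sort(unique(unlist(.data$specialties))),
                                  collapse = ","),
              .groups = "drop")
  indet <- records |>
    group_by(.data$sample_id) |>
    summarise(n_indeterminate = sum(.data$phenotype_class == "indeterminate"),
              .groups = "drop")
  indet |>
    left_join(per_sample, by = "sample_id") |>
    mutate(category = as.integer(replace_na(.data$category, 1L)),
           triggering_genes = replace_na(.data$triggering_genes, ""),
           specialties = replace_na(.data$specialties, ""),
           reflex_recommended = .data$n_indeterminate > 0) |>
    select("sample_id", "category", "triggering_genes", "specialties",
           "n_indeterminate", "reflex_recommended") |>
    arrange(.data$sample_id)
}

#' Summarise cohort actionability
#'
#' Category counts and the percentage of samples flagged per medical
#' specialty (full cohort as denominator, half-up rounding), overall and
#' restricted to category-3 (serious-risk) triggers.
#'
#' @param actionability Output of [categorize_samples()].
#' @param records Optional phenotype records; when given, category-3
#'   specialty percentages are derived from the triggered category-3
#'   rules.
#' @param rules A `pgx_rules` tibble (used with `records`).
#' @param digits Decimal places for percentages (default 0).
#' @return A list of class `pgx_cohort_summary`: `n_samples`,
#'   `category_counts` (tibble over categories 1-3),
#'   `specialty_pct` (tibble `specialty`, `n_samples`, `pct`),
#'   `pct_actionable` (samples in category 2 or 3).
#' @export
cohort_summary <- function(actionability, records = NULL,
                           rules = load_actionability_rules(),
                           digits = 0) {
  n_cohort <- nrow(actionability)
  counts <- tibble(category = 1:3) |>
    left_join(count(actionability, .data$category, name = "n_samples"),
              by = "category") |>
    mutate(n_samples = as.integer(replace_na(.data$n_samples, 0L)))
  spec <- actionability |>
    filter(.data$specialties != "") |>
    mutate(specialty = str_split(.data$specialties, ",")) |>
    tidyr::unnest("specialty") |>
    distinct(.data$sample_id, .data$specialty) |>
    count(.data$specialty, name = "n_samples") |>
    mutate(pct = pct_of(.data$n_samples, n_cohort, digits)) |>
    arrange(desc(.data$pct), .data$specialty)
  out <- list(n_samples = n_cohort,
              category_counts = counts,
              specialty_pct = spec,
              pct_actionable = pct_of(sum(actionability$category >= 2),
                                      n_cohort, digits))
  class(out) <- "pgx_cohort_summary"
  out
}

#' @export
tidy.pgx_cohort_summary <- function(x, ...) x$specialty_pct

#' @export
glance.pgx_cohort_summary <- function(x, ...) {
  tibble(n_samples = x$n_samples,
         n_category1 = x$category_counts$n_samples[1],
         n_category2 = x$category_counts$n_samples[2],
         n_category3 = x$category_counts$n_samples[3],
         pct_actionable = x$pct_actionable)
}

#' @export
print.pgx_cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort actionability summary (%d samples)\n", x$n_samples))
  cat(sprintf("  category counts: 1=%d 2=%d 3=%d (actionable %.4g%%)\n",
              x$category_counts$n_samples[1],
              x$category_counts$n_samples[2],
              x$category_counts$n_samples[3], x$pct_actionable))
  for (i in seq_len(nrow(x$specialty_pct))) {
    cat(sprintf("  %-20s %3d samples (%g%%)\n",
                x$specialty_pct$specialty[i],
                x$specialty_pct$n_samples[i], x$specialty_pct$pct[i]))
  }
  invisible(x)
}

#' Write a cohort summary as JSON
#'
#' @param summary A `pgx_cohort_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(summary, path) {
  jsonlite::write_json(
    list(n_samples = summary$n_samples,
         category_counts = summary$category_counts,
         specialty_pct = summary$specialty_pct,
         pct_actionable = summary$pct_actionable),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
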