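#' Phase every three-copy heterozygous sample in a cohort
#'
#' Applies [phase_duplication()] to each sample whose copy-number call is
#' a heterozygous three-copy duplication.
#'
#' @param diplotypes Diplotype tibble for one platform.
#' @param calls The matching genotype tibble (with allelic depths).
#' @param cnv_calls A `pgx_cnv_calls` tibble.
#' @param defs,panel Knowledge base.
#' @param ... Passed through to [phase_duplication()] (thresholds, mode).
#' @param gene Gene (default CYP2D6).
#' @return A tibble of phasing results, one row per phased sample (empty
#'   when no sample qualifies).
#' @export
phase_cohort_duplications <- function(diplotypes, calls, cnv_calls, defs,
                                      panel, ..., gene = "CYP2D6") {
  cn3 <- diplotypes |>
    filter(.data$gene == !!gene, .data$state != "no_call",
           !is.na(.data$hap1), .data$hap1 != .data$hap2) |>
    inner_join(as_tibble(cnv_calls) |>
                 filter(.data$copy_number %in% 3L) |>
                 select("sample_id", "copy_number"),
               by = "sample_id")
  if (nrow(cn3) == 0) {
    return(tibble(sample_id = character(), duplicated_star = character(),
                  n_informative = integer(),
                  informative_positions = character(),
                  min_depth_used = numeric()))
  }
  gene_calls <- calls |> filter(.data$gene == !!gene)
  map(seq_len(nrow(cn3)), function(i) {
    phase_duplication(cn3[i, ],
                      gene_calls |>
                        filter(.data$sample_id == cn3$sample_id[i]),
                      defs, panel, ..., gene = gene)
  }) |>
    list_rbind()
}

#' Run the full pharmacogenetic pipeline for one platform
#'
#' Chains every stage: star-allele diplotyping from the platform's calls,
#' copy-number classification from coverage profiles, duplication phasing
#' of three-copy heterozygotes, copy-number integration, phenotype
#' assignment and actionability categorisation.
#'
#' @param calls Genotype tibble for one platform.
#' @param coverage Optional coverage tibble (windowed relative coverage);
#'   when `NULL` every sample is treated as two-copy.
#' @param kb Knowledge base from [pgx_knowledge_base()].
#' @param freqs Optional star-frequency list for most-likely resolution.
#' @param bands Copy-number band configuration.
#' @param ... Passed to [phase_duplication()].
#' @return A list of class `pgx_pipeline`: `diplotypes` (copy-number
#'   integrated), `cnv_calls`, `phases`, `phenotypes`, `actionability`,
#'   `summary` (a `pgx_cohort_summary`).
#' @export
run_pipeline <- function(calls, coverage = NULL, kb = pgx_knowledge_base(),
                         freqs = NULL, bands = default_cnv_bands(), ...) {
  dips <- diplotype_cohort(calls, kb$defs, kb$panel, freqs = freqs)
  if (!is.null(coverage)) {
    cnv <- call_cohort_cnv(coverage, bands)
    phases <- phase_cohort_duplications(dips, calls, cnv, kb$defs,
                                        kb$panel, ...)
    dips <- integrate_copy_number(dips, cnv, phases)
  } else {
    cnv <- NULL
    phases <- NULL
    dips <- dips |> mutate(copy_number = 2L, cn_conclusive = TRUE,
                           duplicated_star = NA_character_,
                           cn_flag = "ok")
  }
  phen <- assign_phenotypes(dips, calls, kb$defs, kb$panel,
                            kb$cutpoints, kb$marker_rules)
  act <- categorize_samples(phen, kb$rules)
  structure(list(diplotypes = dips, cnv_calls = cnv, phases = phases,
                 phenotypes = phen, actionability = act,
                 summary = cohort_summary(act)),
            class = "pgx_pipeline")
}

#' @export
print.pgx_pipeline <- function(x, ...) {
  cat(sprintf("pgx pipeline result: %d samples, %d diplotype calls\n",
              n_distinct(x$diplotypes$sample_id), nrow(x$diplotypes)))
  print(x$summary)
  invisible(x)
}
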