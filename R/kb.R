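#' Load star-allele definitions
#'
#' Reads the tag-variant star-allele definition table and validates it
#' against a panel: every defining rsid must exist in the panel for that
#' gene, and every gene must carry the reference haplotype `*1` (empty
#' defining set). The CYP2D6 whole-gene deletion `*5` is kept for activity
#' lookup but is never matched from SNP data (copy-number integration
#' attaches it).
#'
#' @param path Definition TSV with columns `gene`, `star_name`, `rsid`
#'   (`.` for alleles with no defining variants), `required_allele`,
#'   `activity_value` (number or `unknown`). Defaults to the bundled
#'   table.
#' @param panel A `pgx_panel` used for validation (default: bundled
#'   panel).
#' @return A tibble of class `pgx_star_defs`, one row per (star, defining
#'   locus); `*1`/`*5` rows have `rsid = NA`. Attribute `star_order`
#'   records the canonical (file) order of star names per gene, used for
#'   deterministic pair ordering.
#' @examples
#' defs <- load_star_definitions()
#' subset(defs, gene == "CYP2D6" & star_name == "*4")$rsid   # rs3892097
#' @export
load_star_definitions <- function(path = pgx_extdata("star_alleles.tsv"),
                                  panel = load_panel()) {
  defs <- tryCatch(
    read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
             col_types = cols(.default = col_character())),
    error = function(e) stopf("malformed star definition file %s: %s",
                              path, conditionMessage(e),
                              class = "pgx_format_error")
  )
  required <- c("gene", "star_name", "rsid", "required_allele",
                "activity_value")
  miss <- setdiff(required, names(defs))
  if (length(miss) > 0) {
    stopf("star definition file lacks column(s): %s",
          paste(miss, collapse = ", "), class = "pgx_format_error")
  }
  defs <- defs |>
    mutate(rsid = na_if(.data$rsid, "."),
           required_allele = na_if(.data$required_allele, "."),
           activity_value = suppressWarnings(
             as.numeric(na_if(.data$activity_value, "unknown"))))
  validate_star_definitions(defs, panel)
  star_order <- defs |>
    distinct(.data$gene, .data$star_name)
  structure(defs, star_order = star_order,
            class = c("pgx_star_defs", class(defs)))
}

validate_star_definitions <- function(defs, panel) {
  tagged <- filter(defs, !is.na(.data$rsid))
  panel_tbl <- as_tibble(panel)
  bad <- anti_join(tagged, panel_tbl, by = c("gene", "rsid"))
  if (nrow(bad) > 0) {
    stopf("star definitions reference loci absent from the panel: %s",
          paste(unique(paste0(bad$gene, ":", bad$rsid)), collapse = ", "),
          class = "pgx_validation_error")
  }
  # the required allele must be the panel's ref or alt string
  chk <- tagged |>
    inner_join(panel_tbl, by = c("gene", "rsid")) |>
    filter(.data$required_allele != .data$ref &
             .data$required_allele != .data$alt)
  if (nrow(chk) > 0) {
    stopf("required alleles not in the panel's ref/alt set: %s",
          paste(unique(chk$rsid), collapse = ", "),
          class = "pgx_validation_error")
  }
  no_ref <- setdiff(unique(defs$gene),
                    defs$gene[defs$star_name == "*1" & is.na(defs$rsid)])
  if (length(no_ref) > 0) {
    stopf("gene(s) without a *1 reference haplotype: %s",
          paste(no_ref, collapse = ", "), class = "pgx_validation_error")
  }
  invisible(defs)
}

# genes with star-allele (diplotype-level) definitions
star_genes <- function(defs) unique(defs$gene)

# per-star activity values (one row per gene/star)
star_activity <- function(defs) {
  as_tibble(defs) |>
    distinct(.data$gene, .data$star_name, .data$activity_value)
}

#' Load metabolizer phenotype cutpoints
#'
#' Per-gene translation from a diplotype function score (sum of per-allele
#' activity values times copy multiplicity) to a metabolizer phenotype
#' class. A row applies when `score > min_score` (or equality with
#' `inclusive = TRUE`); the highest satisfied threshold wins.
#'
#' @param path Cutpoint TSV; defaults to the bundled table.
#' @return A tibble with columns `gene`, `phenotype_class`, `min_score`,
#'   `inclusive`.
#' @export
load_phenotype_cutpoints <- function(path = pgx_extdata("phenotype_cutpoints.tsv")) {
  read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
           col_types = cols(gene = col_character(),
                            phenotype_class = col_character(),
                            min_score = col_double(),
                            inclusive = readr::col_logical()))
}

#' Load single-marker phenotype translations
#'
#' Genotype-level phenotype rules for genes typed through one tag SNP
#' (HLA tag alleles, VKORC1, SLCO1B1, IFNL3): a zygosity pattern at the
#' tag maps directly to a phenotype class such as `carrier` or
#' `decreased_function`.
#'
#' @param path Rules TSV; defaults to the bundled table.
#' @return A tibble with columns `rsid`, `gene_out`, `pattern`,
#'   `phenotype_class`.
#' @export
load_marker_rules <- function(path = pgx_extdata("marker_phenotypes.tsv")) {
  read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
           col_types = cols(.default = col_character()))
}

specialty_vocabulary <- c("cardiology", "psychiatry", "infectious_diseases",
                          "neurology", "gastroenterology", "transplant",
                          "pain", "oncology")

#' Load drug-gene actionability rules
#'
#' Reads the YAML rule file mapping gene-level phenotype classes to
#' clinical actionability categories: category 2 = dosing/selection
#' benefit, category 3 = risk of a serious or life-threatening adverse
#' response (category 1 is the absence of any triggered rule). Category-3
#' rules must name at least one drug; specialty tags must come from the
#' closed vocabulary.
#'
#' @param path Rules YAML; defaults to the bundled file.
#' @return A tibble of class `pgx_rules` with columns `rule_id`, `gene`,
#'   `trigger` (list of phenotype classes), `category`, `drugs` (list),
#'   `specialties` (list), `source`.
#' @export
load_actionability_rules <- function(path = pgx_extdata("actionability.yaml")) {
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stopf("malformed rules YAML %s: %s",
                                            path, conditionMessage(e),
                                            class = "pgx_format_error"))
  rules <- raw$rules %||% raw
  out <- tibble(
    rule_id = seq_along(rules),
    gene = map_chr(rules, "gene"),
    trigger = map(rules, ~ as.character(.x$trigger)),
    category = map_int(rules, ~ as.integer(.x$category)),
    drugs = map(rules, ~ as.character(.x$drugs)),
    specialties = map(rules, ~ as.character(.x$specialties)),
    source = map_chr(rules, "source")
  )
  if (!all(out$category %in% 1:3)) {
    stopf("actionability categories must be 1, 2 or 3",
          class = "pgx_validation_error")
  }
  no_drug <- out$category == 3 & map_int(out$drugs, length) == 0
  if (any(no_drug)) {
    stopf("category-3 rule(s) without drugs: gene %s",
          paste(out$gene[no_drug], collapse = ", "),
          class = "pgx_validation_error")
  }
  bad_spec <- setdiff(unlist(out$specialties), specialty_vocabulary)
  if (length(bad_spec) > 0) {
    stopf("unknown specialty tag(s): %s", paste(bad_spec, collapse = ", "),
          class = "pgx_validation_error")
  }
  if (!all(out$source %in% c("CPIC", "DPWG", "FDA"))) {
    stopf("guideline source must be CPIC, DPWG or FDA",
          class = "pgx_validation_error")
  }
  structure(out, class = c("pgx_rules", class(out)))
}

#' Load the full bundled knowledge base
#'
#' One-call loader for the panel and every reference table, as consumed by
#' the pipeline functions and the synthetic cohort generator.
#'
#' @return A list with elements `panel`, `defs`, `cutpoints`,
#'   `marker_rules`, `rules`.
#' @export
pgx_knowledge_base <- function() {
  panel <- load_panel()
  list(panel = panel,
       defs = load_star_definitions(panel = panel),
       cutpoints = load_phenotype_cutpoints(),
       marker_rules = load_marker_rules(),
       rules = load_actionability_rules())
}
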