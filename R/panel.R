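#' Path to a bundled knowledge-base file
#'
#' Convenience accessor for the plain-text reference tables shipped with
#' the package (panel definition, star-allele definitions, phenotype
#' translations, actionability rules).
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
pgx_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pgxcohort")))
  }
  path <- system.file("extdata", file, package = "pgxcohort")
  if (!nzchar(path)) stopf("no bundled file '%s'", file)
  path
}

#' Load a pharmacogene variant panel
#'
#' Reads a tab-separated panel catalogue (one row per variant locus) and
#' validates it. The bundled default panel covers 67 SNP and indel loci in
#' 19 pharmacogenes on GRCh37 coordinates, 29 of them in *CYP2D6*.
#'
#' @param path Panel TSV with columns `rsid`, `aliases` (comma-separated
#'   synonyms, `.` for none), `gene`, `chrom`, `pos` (1-based GRCh37),
#'   `ref`, `alt`, `region_class` (`exonic`/`intronic`/`upstream`) and an
#'   optional free-text `label`. Defaults to the bundled panel.
#' @param name Panel name stored as an attribute.
#' @return A tibble of class `pgx_panel`, one row per locus.
#' @examples
#' panel <- load_panel()
#' nrow(panel)                       # 67
#' sum(panel$gene == "CYP2D6")       # 29
#' @export
load_panel <- function(path = pgx_extdata("panel_grch37.tsv"),
                       name = "pgx_panel_grch37") {
  if (!file.exists(path)) stopf("panel file not found: %s", path)
  panel <- tryCatch(
    read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
             col_types = cols(.default = col_character(),
                              pos = col_double())),
    error = function(e) stopf("malformed panel file %s: %s", path,
                              conditionMessage(e),
                              class = "pgx_format_error")
  )
  required <- c("rsid", "gene", "chrom", "pos", "ref", "alt", "region_class")
  miss <- setdiff(required, names(panel))
  if (length(miss) > 0) {
    stopf("panel file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "), class = "pgx_format_error")
  }
  if (!"aliases" %in% names(panel)) panel$aliases <- "."
  if (!"label" %in% names(panel)) panel$label <- "."
  panel <- panel |>
    mutate(pos = as.integer(.data$pos),
           chrom = norm_chrom(.data$chrom),
           aliases = ifelse(is.na(.data$aliases), ".", .data$aliases),
           label = ifelse(is.na(.data$label), ".", .data$label)) |>
    select(all_of(c(required[1], "aliases", required[-1], "label")))
  validate_panel(panel, path)
  structure(panel, name = name,
            class = c("pgx_panel", class(panel)))
}

validate_panel <- function(panel, path = "<panel>") {
  dup <- panel$rsid[duplicated(panel$rsid)]
  if (length(dup) > 0) {
    stopf("duplicate rsid(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "),
          class = "pgx_validation_error")
  }
  if (nrow(panel) > 0 && any(panel$pos <= 0 | is.na(panel$pos))) {
    stopf("panel %s has non-positive or missing positions", path,
          class = "pgx_validation_error")
  }
  if (any(panel$ref == panel$alt)) {
    stopf("panel %s has loci with ref == alt", path,
          class = "pgx_validation_error")
  }
  invisible(panel)
}

#' Write a panel back to TSV
#'
#' Inverse of [load_panel()]; `load_panel(write_panel(p, f))` reproduces
#' the same locus set.
#'
#' @param panel A `pgx_panel`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  header <- "# Pharmacogene variant panel; coordinates 1-based GRCh37."
  writeLines(header, path)
  out <- as_tibble(panel)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' Summarise a panel: loci per gene
#'
#' @param panel A `pgx_panel`.
#' @return A tibble with one row per gene (`gene`, `n_loci`), sorted by
#'   gene; the total locus count is `sum(count_panel(panel)$n_loci)` and is
#'   also attached as attribute `total`.
#' @examples
#' counts <- count_panel(load_panel())
#' sum(counts$n_loci)   # 67
#' @export
count_panel <- function(panel) {
  out <- as_tibble(panel) |>
    count(.data$gene, name = "n_loci") |>
    arrange(.data$gene)
  attr(out, "total") <- sum(out$n_loci)
  out
}

#' @export
glance.pgx_panel <- function(x, ...) {
  tibble(name = attr(x, "name") %||% NA_character_,
         n_loci = nrow(x),
         n_genes = n_distinct(x$gene),
         n_cyp2d6 = sum(x$gene == "CYP2D6"))
}

#' Resolve an rsid or alias to the panel's canonical rsid
#'
#' Some catalogue entries are known under two rsid synonyms; the canonical
#' id is the one in the `rsid` column, with synonyms in `aliases`.
#'
#' @param panel A `pgx_panel`.
#' @param ids Character vector of rsids or aliases.
#' @return Canonical rsids (`NA` for ids not in the panel).
#' @export
resolve_rsid <- function(panel, ids) {
  alias_map <- as_tibble(panel) |>
    filter(.data$aliases != ".") |>
    mutate(alias = str_split(.data$aliases, ",")) |>
    tidyr::unnest("alias") |>
    mutate(alias = trimws(.data$alias))
  hit_alias <- match(ids, alias_map$alias)
  ifelse(ids %in% panel$rsid, ids, alias_map$rsid[hit_alias])
}
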