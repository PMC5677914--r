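# canonical per-gene star order (order of appearance in the definition
# table); used everywhere a deterministic pair order or tie-break is needed
star_rank <- function(defs, gene) {
  ord <- attr(defs, "star_order")
  if (is.null(ord)) ord <- distinct(as_tibble(defs), .data$gene, .data$star_name)
  stars <- ord$star_name[ord$gene == gene]
  setNames(seq_along(stars), stars)
}

# expected allele matrix: stars x gene loci (defining allele, or the
# panel ref where the star imposes nothing); the CYP2D6 whole-gene
# deletion *5 is excluded - it is never matched from SNP data
expected_allele_matrix <- function(defs, panel, gene) {
  loci <- as_tibble(panel) |> filter(.data$gene == !!gene)
  stars <- names(star_rank(defs, gene))
  if (gene == "CYP2D6") stars <- setdiff(stars, "*5")
  mat <- matrix(rep(loci$ref, each = length(stars)),
                nrow = length(stars), ncol = nrow(loci),
                dimnames = list(stars, loci$rsid))
  tagged <- as_tibble(defs) |>
    filter(.data$gene == !!gene, !is.na(.data$rsid),
           .data$star_name %in% stars)
  if (nrow(tagged) > 0) {
    mat[cbind(match(tagged$star_name, stars), match(tagged$rsid, loci$rsid))] <-
      tagged$required_allele
  }
  mat
}

#' Enumerate star-allele pairs consistent with an unphased genotype
#'
#' Formalizes manual star-allele matching: a pair of haplotypes (a, b) is
#' consistent with the genotype iff, at every locus of the gene with a
#' passing call, the unordered pair of alleles implied by a and b (each
#' haplotype's defining allele, or the panel reference where it imposes
#' nothing) equals the observed allele pair. Loci with missing or failed
#' calls are unconstrained wildcards, so additional missingness can only
#' enlarge the candidate set.
#'
#' @param genotypes Calls for one sample at one gene: tibble with `rsid`,
#'   `allele1`, `allele2`, `status`.
#' @param defs A `pgx_star_defs`.
#' @param panel A `pgx_panel`.
#' @param gene Gene symbol; defaults to the single gene spanned by
#'   `genotypes`' loci.
#' @return A tibble of candidate pairs (`hap1`, `hap2`), deduplicated and
#'   in canonical order (haplotypes ordered by the definition table).
#' @examples
#' kb <- pgx_knowledge_base()
#' g <- reference_genotypes(kb$panel, "CYP2D6")       # all hom-ref
#' enumerate_candidates(g, kb$defs, kb$panel)          # *1/*1
#' @export
enumerate_candidates <- function(genotypes, defs, panel, gene = NULL) {
  panel_tbl <- as_tibble(panel)
  if (is.null(gene)) {
    gene <- unique(panel_tbl$gene[panel_tbl$rsid %in% genotypes$rsid])
    if (length(gene) != 1) {
      stopf("genotypes span %d genes; pass `gene` explicitly", length(gene))
    }
  }
  mat <- expected_allele_matrix(defs, panel_tbl, gene)
  loci <- colnames(mat)
  stars <- rownames(mat)
  g <- genotypes[match(loci, genotypes$rsid), ]
  constrained <- !is.na(g$rsid) & g$status %in% "pass"
  # observed alleles must come from the locus ref/alt set
  pl <- panel_tbl[match(loci, panel_tbl$rsid), ]
  in_alphabet <- function(a) !is.na(a) & (a == pl$ref | a == pl$alt)
  bad <- constrained & !(in_alphabet(g$allele1) & in_alphabet(g$allele2))
  if (any(bad)) {
    stopf("observed allele outside the locus ref/alt set at: %s",
          paste(loci[which(bad)], collapse = ", "),
          class = "pgx_data_error")
  }
  obs_key <- pair_key(g$allele1, g$allele2)
  idx <- which(constrained)
  pairs <- which(upper.tri(matrix(0, length(stars), length(stars)),
                           diag = TRUE), arr.ind = TRUE)
  ok <- vapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    all(pair_key(mat[i, idx], mat[j, idx]) == obs_key[idx])
  }, logical(1))
  tibble(hap1 = stars[pairs[ok, 1]], hap2 = stars[pairs[ok, 2]]) |>
    distinct() |>
    arrange(match(.data$hap1, stars), match(.data$hap2, stars))
}

#' All-reference genotypes for a gene (helper)
#'
#' Builds a hom-ref, all-passing genotype table for one gene — the
#' genotype of a `*1/*1` individual — useful as a starting point for
#' constructing examples.
#'
#' @param panel A `pgx_panel`.
#' @param gene Gene symbol.
#' @return A genotype tibble fragment (`rsid`, `allele1`, `allele2`,
#'   `status`).
#' @export
reference_genotypes <- function(panel, gene) {
  as_tibble(panel) |>
    filter(.data$gene == !!gene) |>
    transmute(rsid = .data$rsid, allele1 = .data$ref, allele2 = .data$ref,
              status = "pass")
}

#' Resolve a candidate set into a diplotype call
#'
#' Zero candidates yield `no_call` (contradictory genotype); a single
#' candidate is `resolved`. With several candidates the most likely pair
#' is picked — maximum product of star population frequencies when
#' `freqs` are given, then fewest non-`*1` haplotypes, then canonical
#' order — and the call is flagged `ambiguous` with the full candidate
#' list retained. When defining loci are missing, a missing locus is
#' treated as *key* (forcing `no_call` instead of a best guess) if the
#' candidate set spans more than `key_span` distinct activity scores,
#' i.e. when the missing data leave the phenotype materially undetermined.
#'
#' @param candidates Tibble of candidate pairs from
#'   [enumerate_candidates()].
#' @param defs A `pgx_star_defs` (activity values drive the key-position
#'   rule).
#' @param gene Gene symbol.
#' @param freqs Optional named numeric vector of per-star population
#'   frequencies.
#' @param missing_loci Character vector of the gene's defining loci with
#'   missing/failed calls.
#' @param key_span Maximum number of distinct candidate activity scores
#'   tolerated before a missing locus is declared key (default 3).
#' @return A one-row tibble: `hap1`, `hap2`, `state`
#'   (`resolved`/`ambiguous`/`no_call`), `candidates` (semicolon-joined),
#'   `missing_loci` (comma-joined), `reason`.
#' @export
resolve_diplotype <- function(candidates, defs, gene, freqs = NULL,
                              missing_loci = character(), key_span = 3) {
  mk <- function(h1, h2, state, reason = NA_character_) {
    tibble(hap1 = h1, hap2 = h2, state = state,
           candidates = paste(paste0(candidates$hap1, "/", candidates$hap2),
                              collapse = ";"),
           missing_loci = paste(missing_loci, collapse = ","),
           reason = reason)
  }
  if (nrow(candidates) == 0) {
    return(mk(NA_character_, NA_character_, "no_call",
              "no star-allele pair consistent with the genotype"))
  }
  if (nrow(candidates) == 1) {
    return(mk(candidates$hap1, candidates$hap2, "resolved"))
  }
  act <- star_activity(defs) |> filter(.data$gene == !!gene)
  score <- act$activity_value[match(candidates$hap1, act$star_name)] +
    act$activity_value[match(candidates$hap2, act$star_name)]
  if (length(missing_loci) > 0 &&
      n_distinct(score, na.rm = FALSE) > key_span) {
    return(mk(NA_character_, NA_character_, "no_call",
              "missing calls at key positions"))
  }
  rank <- star_rank(defs, gene)
  freq_of <- function(h) {
    if (is.null(freqs)) return(rep(0, length(h)))
    f <- unname(freqs[h])
    ifelse(is.na(f), 1e-6, f)
  }
  cand <- candidates |>
    mutate(n_nonref = (.data$hap1 != "*1") + (.data$hap2 != "*1"),
           neg_freq = -freq_of(.data$hap1) * freq_of(.data$hap2),
           r1 = rank[.data$hap1], r2 = rank[.data$hap2]) |>
    arrange(.data$neg_freq, .data$n_nonref, .data$r1, .data$r2)
  mk(cand$hap1[1], cand$hap2[1], "ambiguous")
}

#' Call star-allele diplotypes across a cohort
#'
#' Runs candidate enumeration and resolution for every (sample, gene,
#' platform) combination in a genotype table. Per-sample failures (e.g. an
#' observed allele outside the locus alphabet) become `no_call` rows with
#' a reason — a single bad sample never aborts the cohort. Identical
#' genotype signatures are resolved once and reused, so large cohorts
#' with few distinct genotypes stay fast.
#'
#' @param calls A genotype tibble (from the readers or the simulator).
#' @param defs A `pgx_star_defs`.
#' @param panel A `pgx_panel`.
#' @param genes Genes to call (default: every gene with star definitions).
#' @param freqs Optional named list `gene -> named star frequency vector`
#'   used by the most-likely resolution rule.
#' @param key_span See [resolve_diplotype()].
#' @return A tibble with one row per (sample, gene, platform): `hap1`,
#'   `hap2`, `state`, `candidates`, `missing_loci`, `reason`.
#' @export
diplotype_cohort <- function(calls, defs, panel,
                             genes = star_genes(defs), freqs = NULL,
                             key_span = 3) {
  panel_tbl <- as_tibble(panel)
  work <- calls |>
    filter(.data$gene %in% genes) |>
    left_join(panel_tbl |> select("rsid", "pos"), by = "rsid") |>
    arrange(.data$gene, .data$pos) |>
    mutate(cell = ifelse(.data$status == "pass",
                         pair_key(.data$allele1, .data$allele2), "*"))
  sig <- work |>
    group_by(.data$sample_id, .data$platform, .data$gene) |>
    summarise(signature = paste(.data$cell, collapse = "|"),
              .groups = "drop")
  uniq <- sig |> distinct(.data$gene, .data$signature)
  resolved <- uniq |>
    mutate(res = map2(.data$gene, .data$signature, function(g, s) {
      loci <- panel_tbl |> filter(.data$gene == g) |> arrange(.data$pos)
      cells <- str_split(s, "\\|")[[1]]
      alleles <- str_split(cells, "/")
      geno <- tibble(
        rsid = loci$rsid,
        allele1 = map_chr(alleles, 1),
        allele2 = map_chr(alleles, ~ if (length(.x) > 1) .x[2] else "*"),
        status = ifelse(cells == "*", "missing", "pass"))
      geno$allele1[geno$status != "pass"] <- NA_character_
      geno$allele2[geno$status != "pass"] <- NA_character_
      missing_loci <- geno$rsid[geno$status != "pass"]
      tryCatch({
        cand <- enumerate_candidates(geno, defs, panel_tbl, gene = g)
        resolve_diplotype(cand, defs, g, freqs = freqs[[g]],
                          missing_loci = missing_loci, key_span = key_span)
      }, error = function(e) {
        tibble(hap1 = NA_character_, hap2 = NA_character_,
               state = "no_call", candidates = "",
               missing_loci = paste(missing_loci, collapse = ","),
               reason = conditionMessage(e))
      })
    })) |>
    tidyr::unnest("res")
  sig |>
    left_join(resolved, by = c("gene", "signature")) |>
    select(-"signature") |>
    arrange(.data$platform, .data$sample_id, .data$gene)
}

#' Export diplotype calls as TSV
#'
#' @param diplotypes Output of [diplotype_cohort()] (optionally after
#'   copy-number integration).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diplotypes <- function(diplotypes, path) {
  write_tsv(diplotypes, path, progress = FALSE)
  invisible(path)
}
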