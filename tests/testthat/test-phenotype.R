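kb <- get_kb()

test_that("activity scores multiply by copy number and honour *5", {
  expect_equal(activity_score("*1", "*1", kb$defs), 2)
  expect_equal(activity_score("*4", "*5", kb$defs), 0)
  expect_equal(activity_score("*1x2", "*4", kb$defs), 2)
  expect_equal(activity_score("*1x2", "*1", kb$defs), 3)
  expect_equal(activity_score("*10", "*4", kb$defs), 0.5)
  expect_true(is.na(activity_score(NA, "*1", kb$defs)))
})

test_that("activity is additive over haplotype substitution", {
  withr::local_seed(99)
  act <- subset(tibble::as_tibble(kb$defs), gene == "CYP2D6")
  stars <- unique(act$star_name)
  for (trial in 1:20) {
    a <- sample(stars, 1)
    b <- sample(setdiff(stars, "*5"), 1)
    v_b <- act$activity_value[match(b, act$star_name)]
    expect_equal(activity_score(a, b, kb$defs),
                 activity_score(a, "*5", kb$defs) + v_b)
  }
})

test_that("scores translate to metabolizer classes at the cutpoints", {
  expect_equal(score_to_phenotype(c(0, 0.5, 1, 1.5, 2, 2.5, 3)),
               c("poor", "intermediate", "extensive", "extensive",
                 "extensive", "ultrarapid", "ultrarapid"))
  expect_equal(score_to_phenotype(NA_real_), "indeterminate")
  # gene-specific translations
  expect_equal(score_to_phenotype(1, gene = "CYP2C9"), "intermediate")
  expect_equal(score_to_phenotype(1, gene = "CYP3A5"), "intermediate")
  expect_equal(score_to_phenotype(2.5, gene = "CYP2C19"), "ultrarapid")
  expect_equal(score_to_phenotype(1, gene = "TPMT"), "intermediate")
})

marker_calls <- function(rsid, a1, a2, status = "pass",
                         sample = "P1") {
  panel <- tibble::as_tibble(get_kb()$panel)
  row <- panel[panel$rsid == rsid, ]
  tibble::tibble(sample_id = sample, rsid = rsid, gene = row$gene,
                 platform = "TARGETED", allele1 = a1, allele2 = a2,
                 status = status, read_depth = NA_integer_,
                 ref_reads = NA_integer_, alt_reads = NA_integer_)
}

test_that("marker genes translate genotypes to carrier/function classes", {
  calls <- dplyr::bind_rows(
    marker_calls("rs2395029", "G", "T"),          # HLA-B*57:01 tag het
    marker_calls("rs1061235", "A", "A"),          # HLA-A tag hom-ref
    marker_calls("rs9923231", "T", "T"),          # VKORC1 hom-alt
    marker_calls("rs12979860", "C", "C"),         # IFNL3 favourable
    marker_calls("rs4149056", NA, NA, "missing")) # SLCO1B1 no-call
  rec <- phenotype_other_genes(calls, kb$panel)
  cls <- setNames(rec$phenotype_class, rec$gene)
  expect_equal(cls[["HLA-B"]], "carrier")
  expect_equal(cls[["HLA-A"]], "non_carrier")
  expect_equal(cls[["VKORC1"]], "decreased_function")
  expect_equal(cls[["IFNL3"]], "normal_function")
  expect_equal(cls[["SLCO1B1"]], "indeterminate")
})

mk_record <- function(gene, class, sample = "P1") {
  tibble::tibble(sample_id = sample, gene = gene,
                 diplotype = NA_character_, activity_score = NA_real_,
                 phenotype_class = class, basis = "test")
}

test_that("diplotype-driven phenotyping covers the canonical cases", {
  dips <- tibble::tibble(
    sample_id = c("P1", "P1", "P2"),
    platform = "TARGETED",
    gene = c("CYP2C19", "TPMT", "CYP2D6"),
    hap1 = c("*1", "*1", "*1x2"),
    hap2 = c("*1", "*3A", "*1"),
    state = "resolved", candidates = "", missing_loci = "",
    reason = NA_character_)
  rec <- assign_phenotypes(dips, marker_calls("rs2395029", "T", "T"),
                           kb$defs, kb$panel)
  star_rec <- rec[rec$basis == "activity_score", ]
  cls <- setNames(star_rec$phenotype_class,
                  paste(star_rec$sample_id, star_rec$gene))
  expect_equal(cls[["P1 CYP2C19"]], "extensive")
  expect_equal(cls[["P1 TPMT"]], "intermediate")
  expect_equal(cls[["P2 CYP2D6"]], "ultrarapid")
  expect_equal(star_rec$activity_score[star_rec$sample_id == "P2"], 3)
})

test_that("categories follow the max-over-rules logic", {
  # nothing triggered: category 1
  recs <- dplyr::bind_rows(mk_record("CYP2C19", "extensive"),
                           mk_record("HLA-B", "non_carrier"))
  got <- categorize_samples(recs, kb$rules)
  expect_equal(got$category, 1L)
  expect_equal(got$triggering_genes, "")

  # HLA-B carrier: abacavir hypersensitivity, category 3
  got <- categorize_samples(mk_record("HLA-B", "carrier"), kb$rules)
  expect_equal(got$category, 3L)
  expect_match(got$specialties, "infectious_diseases")

  # a lone CYP2C19 intermediate: dosing benefit, category 2
  got <- categorize_samples(mk_record("CYP2C19", "intermediate"),
                            kb$rules)
  expect_equal(got$category, 2L)

  # indeterminate phenotypes trigger nothing but flag reflex testing
  got <- categorize_samples(mk_record("CYP2D6", "indeterminate"),
                            kb$rules)
  expect_equal(got$category, 1L)
  expect_true(got$reflex_recommended)

  # adding a triggered rule never lowers the category
  both <- dplyr::bind_rows(mk_record("CYP2C19", "intermediate"),
                           mk_record("HLA-B", "carrier"))
  expect_gte(categorize_samples(both, kb$rules)$category,
             categorize_samples(mk_record("CYP2C19", "intermediate"),
                                kb$rules)$category)
})

test_that("cohort summaries tally categories and specialties", {
  act <- tibble::tibble(
    sample_id = sprintf("P%d", 1:4),
    category = c(1L, 2L, 2L, 3L),
    triggering_genes = c("", "CYP2C19", "CYP2C19", "HLA-B"),
    specialties = c("", "cardiology,psychiatry", "cardiology",
                    "infectious_diseases"),
    n_indeterminate = 0L, reflex_recommended = FALSE)
  s <- cohort_summary(act)
  expect_equal(s$category_counts$n_samples, c(1L, 2L, 1L))
  expect_equal(s$pct_actionable, 75)
  spct <- setNames(s$specialty_pct$pct, s$specialty_pct$specialty)
  expect_equal(spct[["cardiology"]], 50)
  expect_equal(spct[["psychiatry"]], 25)
  g <- glance(s)
  expect_equal(g$n_category3, 1L)

  empty <- cohort_summary(act[0, ])
  expect_equal(empty$category_counts$n_samples, c(0L, 0L, 0L))
  expect_true(is.na(empty$pct_actionable))
})
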