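kb <- get_kb()

test_that("reference, single-variant and missing-data genotypes enumerate correctly", {
  g <- reference_genotypes(kb$panel, "CYP2D6")
  expect_equal(enumerate_candidates(g, kb$defs, kb$panel),
               tibble::tibble(hap1 = "*1", hap2 = "*1"))

  het4 <- g
  i <- het4$rsid == "rs3892097"
  het4$allele2[i] <- "T"
  cand <- enumerate_candidates(het4, kb$defs, kb$panel)
  expect_true(any(cand$hap1 == "*1" & cand$hap2 == "*4"))
  expect_equal(nrow(cand), 1)

  m <- g
  i <- m$rsid == "rs16947"
  m$status[i] <- "missing"
  m$allele1[i] <- NA
  m$allele2[i] <- NA
  cand <- enumerate_candidates(m, kb$defs, kb$panel)
  key <- paste(cand$hap1, cand$hap2)
  expect_setequal(key, c("*1 *1", "*1 *2", "*2 *2"))
})

test_that("alleles outside the locus alphabet raise a data error", {
  g <- reference_genotypes(kb$panel, "CYP2D6")
  g$allele1[g$rsid == "rs16947"] <- "X"
  expect_error(enumerate_candidates(g, kb$defs, kb$panel),
               class = "pgx_data_error")
})

test_that("enumeration is invariant to locus order and allele swap", {
  withr::local_seed(202)
  for (trial in 1:10) {
    g <- random_genotype(kb$panel, "CYP2C19")
    base <- enumerate_candidates(g, kb$defs, kb$panel, gene = "CYP2C19")
    shuffled <- g[sample(nrow(g)), ]
    expect_equal(enumerate_candidates(shuffled, kb$defs, kb$panel,
                                      gene = "CYP2C19"), base)
    swapped <- g
    tmp <- swapped$allele1
    swapped$allele1 <- swapped$allele2
    swapped$allele2 <- tmp
    expect_equal(enumerate_candidates(swapped, kb$defs, kb$panel,
                                      gene = "CYP2C19"), base)
  }
})

test_that("marking an extra locus missing never removes candidates", {
  withr::local_seed(303)
  for (trial in 1:10) {
    g <- random_genotype(kb$panel, "CYP2D6", p = c(0.6, 0.25, 0.15, 0))
    base <- enumerate_candidates(g, kb$defs, kb$panel)
    i <- sample(nrow(g), 1)
    g$status[i] <- "missing"
    g$allele1[i] <- NA
    g$allele2[i] <- NA
    more <- enumerate_candidates(g, kb$defs, kb$panel)
    expect_true(all(paste(base$hap1, base$hap2) %in%
                      paste(more$hap1, more$hap2)))
  }
})

test_that("enumeration matches the brute-force oracle on every gene table", {
  withr::local_seed(404)
  for (g in unique(kb$defs$gene)) {
    for (trial in 1:8) {
      geno <- random_genotype(kb$panel, g)
      mine <- enumerate_candidates(geno, kb$defs, kb$panel, gene = g)
      oracle <- oracle_enumerate(geno, kb$defs, kb$panel, g)
      expect_setequal(paste(mine$hap1, mine$hap2),
                      paste(oracle$hap1, oracle$hap2))
    }
  }
})

test_that("resolution applies the singleton / tie-break / empty rules", {
  one <- tibble::tibble(hap1 = "*1", hap2 = "*4")
  r <- resolve_diplotype(one, kb$defs, "CYP2D6")
  expect_equal(r$state, "resolved")
  expect_equal(c(r$hap1, r$hap2), c("*1", "*4"))

  two <- tibble::tibble(hap1 = c("*1", "*1"), hap2 = c("*1", "*2"))
  r <- resolve_diplotype(two, kb$defs, "CYP2D6",
                         missing_loci = "rs16947")
  expect_equal(r$state, "ambiguous")
  expect_equal(c(r$hap1, r$hap2), c("*1", "*1"))  # fewest non-*1
  expect_equal(r$candidates, "*1/*1;*1/*2")

  # frequency product overrides parsimony when frequencies are supplied
  r <- resolve_diplotype(two, kb$defs, "CYP2D6",
                         freqs = c("*1" = 0.2, "*2" = 0.8),
                         missing_loci = "rs16947")
  expect_equal(c(r$hap1, r$hap2), c("*1", "*2"))

  none <- tibble::tibble(hap1 = character(), hap2 = character())
  r <- resolve_diplotype(none, kb$defs, "CYP2D6")
  expect_equal(r$state, "no_call")
})

test_that("missing key positions force no_call when phenotypes diverge", {
  g <- reference_genotypes(kb$panel, "CYP2D6")
  for (rs in c("rs3892097", "rs1065852", "rs16947", "rs35742686")) {
    i <- g$rsid == rs
    g$status[i] <- "missing"
    g$allele1[i] <- NA
    g$allele2[i] <- NA
  }
  cand <- enumerate_candidates(g, kb$defs, kb$panel)
  r <- resolve_diplotype(cand, kb$defs, "CYP2D6",
                         missing_loci = c("rs3892097", "rs1065852",
                                          "rs16947", "rs35742686"))
  expect_equal(r$state, "no_call")
  expect_match(r$reason, "key positions")
  # the same candidate spread with a tighter span allowance still resolves
  r2 <- resolve_diplotype(cand, kb$defs, "CYP2D6",
                          missing_loci = "rs16947", key_span = 99)
  expect_equal(r2$state, "ambiguous")
})

test_that("cohort diplotyping is exhaustive, deterministic and robust", {
  sim <- simulate_cohort(noise_free_config(n_samples = 30), seed = 5,
                         kb = kb)
  tg <- dplyr::filter(sim$calls, platform == "TARGETED")
  dips <- diplotype_cohort(tg, kb$defs, kb$panel)
  expect_equal(nrow(dips), 30 * length(unique(kb$defs$gene)))
  expect_identical(dips, diplotype_cohort(tg, kb$defs, kb$panel))
  # no-CNV, no-missingness recovery: called pairs equal the manifest
  # (copy-number annotation aside)
  truth <- sim$manifest$diplotypes |>
    dplyr::mutate(true = paste0(sub("x2$", "", hap1), "/",
                                sub("x2$", "", hap2)))
  got <- dips |>
    dplyr::mutate(called = paste0(hap1, "/", hap2)) |>
    dplyr::inner_join(truth, by = c("sample_id", "gene"))
  no_cnv <- got$copy_number == 2 | got$gene != "CYP2D6"
  expect_true(all(got$called[no_cnv] == got$true[no_cnv]))

  # one sample, one gene in, exactly one call out
  single <- dplyr::filter(tg, sample_id == tg$sample_id[1],
                          gene == "CYP2D6")
  expect_equal(nrow(diplotype_cohort(single, kb$defs, kb$panel)), 1)
})
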