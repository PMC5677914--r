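kb <- get_kb()

test_that("configuration validation catches invalid inputs", {
  expect_error(simulation_config(n_samples = 0),
               class = "pgx_validation_error")
  bad_freqs <- default_star_freqs()
  bad_freqs$CYP2D6[1] <- bad_freqs$CYP2D6[1] + 0.5
  expect_error(simulation_config(star_freqs = bad_freqs),
               class = "pgx_validation_error")
  expect_error(simulation_config(cnv_probs = c("1" = 0.5, "2" = 0.5)),
               class = "pgx_validation_error")
  expect_error(simulation_config(ambiguity_given_star4 = 1.5),
               class = "pgx_validation_error")
  expect_error(simulation_config(coverage_noise_sd = -1),
               class = "pgx_validation_error")
})

test_that("a one-sample cohort yields one sample everywhere", {
  sim <- simulate_cohort(simulation_config(n_samples = 1), seed = 9,
                         kb = kb)
  expect_equal(dplyr::n_distinct(sim$calls$sample_id), 1)
  expect_equal(nrow(sim$manifest$samples), 1)
  expect_equal(nrow(sim$coverage), 3)
  paths <- write_fixture_set(sim, tempfile("one"), kb = kb)
  for (p in paths) expect_true(file.exists(p))
})

test_that("identical config and seed reproduce byte-identical outputs", {
  cfg <- simulation_config(n_samples = 12)
  s1 <- simulate_cohort(cfg, seed = 31, kb = kb)
  s2 <- simulate_cohort(cfg, seed = 31, kb = kb)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$coverage, s2$coverage)
  d1 <- write_fixture_set(s1, tempfile("da"), kb = kb)
  d2 <- write_fixture_set(s2, tempfile("db"), kb = kb)
  for (f in names(d1)) {
    expect_identical(unname(tools::md5sum(d1[[f]])),
                     unname(tools::md5sum(d2[[f]])))
  }
  s3 <- simulate_cohort(cfg, seed = 32, kb = kb)
  expect_false(identical(s1$calls, s3$calls))
})

test_that("simulated star frequencies calibrate to the configuration", {
  sim <- simulate_cohort(simulation_config(n_samples = 5000), seed = 41,
                         kb = kb)
  # 10,000 CYP2C19 haplotypes (CYP2D6 copy number complicates counting)
  dip <- sim$manifest$diplotypes
  h <- c(dip$hap1[dip$gene == "CYP2C19"], dip$hap2[dip$gene == "CYP2C19"])
  f <- default_star_freqs()$CYP2C19
  emp <- table(factor(h, levels = names(f))) / length(h)
  se <- sqrt(f * (1 - f) / length(h))
  expect_true(all(abs(as.numeric(emp) - f) <= 3 * se + 1e-12))
  # copy-number histogram within binomial tolerance of 7/81/9/1 per 98
  cnt <- table(factor(sim$manifest$samples$copy_number, levels = 1:4))
  p <- c(7, 81, 9, 1) / 98
  se_cn <- sqrt(p * (1 - p) * 5000)
  expect_true(all(abs(as.numeric(cnt) - 5000 * p) <= 3 * se_cn))
})

test_that("coverage calibrates to CN/2 and closure holds at non-missing loci", {
  sim <- simulate_cohort(simulation_config(n_samples = 400), seed = 43,
                         kb = kb)
  cov <- sim$coverage |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(m = mean(relative_coverage)) |>
    dplyr::inner_join(sim$manifest$samples, by = "sample_id")
  for (cn in unique(cov$copy_number)) {
    x <- cov$m[cov$copy_number == cn]
    se <- 0.05 / sqrt(3) / sqrt(length(x))
    expect_lt(abs(mean(x) - cn / 2), 3 * se + 1e-9)
  }
  # every non-missing genotype is consistent with the manifest diplotype
  dips <- sim$manifest$diplotypes |>
    dplyr::mutate(hap1 = sub("x2$", "", hap1), hap2 = sub("x2$", "", hap2))
  calls <- dplyr::filter(sim$calls, platform == "WGS",
                         gene %in% unique(kb$defs$gene),
                         status == "pass")
  panel <- tibble::as_tibble(kb$panel)
  for (g in unique(kb$defs$gene)) {
    mat <- pgxcohort:::expected_allele_matrix(kb$defs, panel, g)
    gc <- dplyr::filter(calls, gene == g) |>
      dplyr::inner_join(dips[dips$gene == g, ],
                        by = c("sample_id", "gene"))
    # CYP2D6 *5 is a whole-gene deletion: the remaining haplotype's
    # allele is observed twice
    del <- g == "CYP2D6"
    h1 <- ifelse(del & gc$hap1 == "*5", gc$hap2, gc$hap1)
    h2 <- ifelse(del & gc$hap2 == "*5", gc$hap1, gc$hap2)
    e1 <- mat[cbind(match(h1, rownames(mat)),
                    match(gc$rsid, colnames(mat)))]
    e2 <- mat[cbind(match(h2, rownames(mat)),
                    match(gc$rsid, colnames(mat)))]
    expect_true(all(paste(pmin(e1, e2), pmax(e1, e2)) ==
                      paste(gc$allele1, gc$allele2)))
  }
})

test_that("platform dialects behave as documented", {
  sim <- simulate_cohort(simulation_config(n_samples = 60), seed = 47,
                         kb = kb)
  paths <- write_fixture_set(sim, tempfile("dial"), kb = kb)
  wes <- read_vcf_calls(paths[["wes_vcf"]], kb$panel, "WES")
  upstream <- dplyr::filter(wes, rsid %in% c("rs28735595", "rs1080985"))
  expect_true(all(upstream$status == "missing"))
  # rs16947 drops out of WGS at the configured rate (60/98)
  wgs <- dplyr::filter(sim$calls, platform == "WGS", rsid == "rs16947")
  miss_rate <- mean(wgs$status == "missing")
  expect_gt(miss_rate, 0.45)
  expect_lt(miss_rate, 0.8)
  # the CYP2C19*9 locus carries fail_quality calls in WGS only
  lowq <- dplyr::filter(sim$calls, rsid == "rs17884712",
                        status == "fail_quality")
  expect_true(nrow(lowq) > 0)
  expect_equal(unique(lowq$platform), "WGS")
  # targeted delivers no read depths
  tg <- dplyr::filter(sim$calls, platform == "TARGETED")
  expect_true(all(is.na(tg$read_depth)))
})

test_that("written fixtures re-read into the in-memory matrices exactly", {
  sim <- simulate_cohort(simulation_config(n_samples = 15), seed = 53,
                         kb = kb)
  paths <- write_fixture_set(sim, tempfile("rt"), kb = kb)
  for (spec in list(list("wgs_vcf", "WGS", read_vcf_calls),
                    list("wes_vcf", "WES", read_vcf_calls),
                    list("targeted_tsv", "TARGETED",
                         function(p, panel, platform)
                           read_targeted_calls(p, panel)))) {
    back <- spec[[3]](paths[[spec[[1]]]], kb$panel, spec[[2]])
    mem <- dplyr::filter(sim$calls, platform == spec[[2]])
    expect_equal(as.data.frame(back), as.data.frame(mem))
  }
  manifest <- jsonlite::read_json(paths[["manifest_json"]],
                                  simplifyVector = TRUE)
  expect_equal(nrow(manifest$samples), 15)
})

test_that("the manifest is internally consistent with the phenotyper", {
  sim <- simulate_cohort(simulation_config(n_samples = 40), seed = 59,
                         kb = kb)
  d6 <- dplyr::filter(sim$manifest$diplotypes, gene == "CYP2D6")
  ph <- dplyr::filter(sim$manifest$phenotypes, gene == "CYP2D6")
  j <- dplyr::inner_join(d6, ph, by = c("sample_id", "gene"))
  expect_equal(score_to_phenotype(activity_score(j$hap1, j$hap2, kb$defs),
                                  kb$cutpoints),
               j$phenotype_class)
})
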