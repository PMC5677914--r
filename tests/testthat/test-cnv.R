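kb <- get_kb()

test_that("worked coverage values classify to their published copy numbers", {
  got <- classify_copy_number(c(1.96, 1.5, 1.0, 0.5, 0.75, 0.05, 1.7))
  expect_equal(got$copy_number,
               c(4L, 3L, 2L, 1L, NA_integer_, 0L, NA_integer_))
  expect_equal(got$conclusive, c(T, T, T, T, F, T, F))
  expect_error(classify_copy_number(-0.2), class = "pgx_data_error")
})

test_that("classification bands partition the half-line and are monotone", {
  grid <- seq(0, 5, by = 0.005)
  got <- classify_copy_number(grid)
  # exactly one outcome per value: conclusive xor inconclusive
  expect_equal(nrow(got), length(grid))
  expect_true(all(xor(got$conclusive, is.na(got$copy_number))))
  conclusive <- got[got$conclusive, ]
  expect_true(all(diff(conclusive$copy_number) >= 0))
})

test_that("cohort copy-number calling averages windows and summarises", {
  profiles <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 3),
    chrom = "22",
    window_start = rep(c(42522001L, 42524001L, 42526001L), 2),
    window_end = rep(c(42524000L, 42526000L, 42528000L), 2),
    relative_coverage = c(0.5, 0.5, 0.5, 0.9, 1.0, 1.1))
  calls <- call_cohort_cnv(profiles)
  expect_equal(calls$copy_number, c(1L, 2L))
  expect_equal(calls$mean_rel_cov, c(0.5, 1.0))
  h <- glance(calls)
  expect_equal(h$n_samples[h$class == "1"], 1)
  single <- call_cohort_cnv(profiles[1:3, ])
  expect_equal(nrow(single), 1)
})

test_that("coverage profiles round-trip through the TSV reader", {
  sim <- simulate_cohort(simulation_config(n_samples = 5), seed = 3,
                         kb = kb)
  path <- tempfile(fileext = ".tsv")
  readr::write_tsv(sim$coverage, path)
  expect_equal(as.data.frame(read_coverage_profiles(path)),
               as.data.frame(sim$coverage))
})

phase_input <- function(ref_reads, alt_reads, depth_ok = TRUE) {
  dip <- tibble::tibble(sample_id = "S1", gene = "CYP2D6", hap1 = "*1",
                        hap2 = "*4", state = "resolved", copy_number = 3L)
  calls <- tibble::tibble(
    sample_id = "S1", rsid = "rs3892097", gene = "CYP2D6",
    platform = "WGS", allele1 = "C", allele2 = "T", status = "pass",
    read_depth = ref_reads + alt_reads,
    ref_reads = ref_reads, alt_reads = alt_reads)
  list(dip = dip, calls = calls)
}

test_that("duplication phasing follows the read-ratio rules", {
  # 60 ref / 30 alt: ref belongs to *1 (hap1), fraction 0.667 >= 0.6
  x <- phase_input(60L, 30L)
  got <- phase_duplication(x$dip, x$calls, kb$defs, kb$panel)
  expect_equal(got$duplicated_star, "*1")
  # the skew is also one-sidedly significant under a binomial null
  expect_lt(pbinom(59, 90, 0.5, lower.tail = FALSE), 0.01)
  got_b <- phase_duplication(x$dip, x$calls, kb$defs, kb$panel,
                             method = "binomial")
  expect_equal(got_b$duplicated_star, "*1")

  # perfectly balanced reads are indeterminate
  x <- phase_input(45L, 45L)
  expect_equal(phase_duplication(x$dip, x$calls, kb$defs,
                                 kb$panel)$duplicated_star,
               "indeterminate")

  # depth below the floor is indeterminate by the min-depth rule
  x <- phase_input(27L, 13L)
  expect_equal(phase_duplication(x$dip, x$calls, kb$defs,
                                 kb$panel)$duplicated_star,
               "indeterminate")

  # skew toward the alternative allele votes for *4
  x <- phase_input(30L, 60L)
  expect_equal(phase_duplication(x$dip, x$calls, kb$defs,
                                 kb$panel)$duplicated_star, "*4")
})

test_that("conflicting informative positions give indeterminate", {
  dip <- tibble::tibble(sample_id = "S1", gene = "CYP2D6", hap1 = "*2",
                        hap2 = "*4", state = "resolved", copy_number = 3L)
  calls <- tibble::tibble(
    sample_id = "S1", rsid = c("rs16947", "rs3892097"), gene = "CYP2D6",
    platform = "WGS",
    allele1 = c("C", "C"), allele2 = c("T", "T"), status = "pass",
    read_depth = c(90L, 90L),
    ref_reads = c(30L, 30L), alt_reads = c(60L, 60L))
  # rs16947 alt favors *2 while rs3892097 alt favors *4: a conflict
  got <- phase_duplication(dip, calls, kb$defs, kb$panel)
  expect_equal(got$duplicated_star, "indeterminate")
  expect_equal(got$n_informative, 2L)
})

test_that("phasing preconditions are enforced", {
  x <- phase_input(60L, 30L)
  dip2 <- x$dip
  dip2$copy_number <- 2L
  expect_error(phase_duplication(dip2, x$calls, kb$defs, kb$panel),
               class = "pgx_precondition_error")
  hom <- x$dip
  hom$hap2 <- "*1"
  expect_error(phase_duplication(hom, x$calls, kb$defs, kb$panel),
               class = "pgx_precondition_error")
})

test_that("copy-number integration rewrites haplotypes as specified", {
  mk_dip <- function(h1, h2, sample = "S1") tibble::tibble(
    sample_id = sample, platform = "WGS", gene = "CYP2D6",
    hap1 = h1, hap2 = h2, state = "resolved", candidates = "",
    missing_loci = "", reason = NA_character_)
  mk_cnv <- function(cn, conclusive = TRUE) tibble::tibble(
    sample_id = "S1", copy_number = cn, conclusive = conclusive)

  r <- integrate_copy_number(mk_dip("*1", "*4"), mk_cnv(2L))
  expect_equal(c(r$hap1, r$hap2, r$cn_flag), c("*1", "*4", "ok"))

  r <- integrate_copy_number(mk_dip("*1", "*1"), mk_cnv(1L))
  expect_equal(c(r$hap1, r$hap2), c("*1", "*5"))

  r <- integrate_copy_number(mk_dip("*1", "*4"), mk_cnv(1L))
  expect_equal(r$cn_flag, "cn_genotype_conflict")

  phase <- tibble::tibble(sample_id = "S1", duplicated_star = "*1")
  r <- integrate_copy_number(mk_dip("*1", "*4"), mk_cnv(3L), phase)
  expect_equal(c(r$hap1, r$hap2), c("*1x2", "*4"))

  r <- integrate_copy_number(mk_dip("*1", "*4"), mk_cnv(3L))
  expect_equal(r$cn_flag, "duplication_unassigned")

  r <- integrate_copy_number(mk_dip("*2", "*2"), mk_cnv(3L))
  expect_equal(c(r$hap1, r$hap2), c("*2x2", "*2"))

  r <- integrate_copy_number(mk_dip("*1", "*4"), mk_cnv(4L))
  expect_equal(c(r$hap1, r$hap2), c("*1x2", "*4x2"))

  r <- integrate_copy_number(mk_dip("*1", "*4"),
                             mk_cnv(NA_integer_, FALSE))
  expect_equal(r$cn_flag, "reflex_testing")
})
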