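#' Default star-allele population frequencies for simulation
#'
#' Per-gene star frequencies used by the cohort generator, chosen to
#' represent a predominantly European-ancestry pediatric cohort. TPMT
#' `*3B` is kept at 0 by default: with only unphased tag SNPs a `*3B/*3C`
#' genotype is indistinguishable from `*1/*3A`, and `*3B` alone is rare;
#' setting a positive frequency is supported and exercises the ambiguity
#' machinery.
#'
#' @return Named list `gene -> named numeric vector` (each sums to 1).
#' @export
default_star_freqs <- function() {
  list(
    CYP2D6 = c("*1" = 0.37, "*2" = 0.27, "*4" = 0.19, "*10" = 0.06,
               "*17" = 0.04, "*35" = 0.02, "*9" = 0.02, "*3" = 0.01,
               "*29" = 0.01, "*6" = 0.005, "*7" = 0.0025, "*8" = 0.0025),
    CYP2C19 = c("*1" = 0.61, "*2" = 0.15, "*17" = 0.21, "*3" = 0.01,
                "*4" = 0.002, "*8" = 0.008, "*9" = 0.01),
    CYP2C9 = c("*1" = 0.79, "*2" = 0.13, "*3" = 0.07, "*5" = 0.005,
               "*6" = 0.005),
    CYP3A5 = c("*1" = 0.08, "*3" = 0.92),
    TPMT = c("*1" = 0.945, "*3A" = 0.035, "*3C" = 0.015, "*2" = 0.005),
    DPYD = c("*1" = 0.985, "*2A" = 0.01, "c.2846A>T" = 0.005)
  )
}

#' Default per-platform no-call probabilities
#'
#' Long-format missingness model: exact rsid rows take precedence over a
#' gene wildcard (`"CYP2D6:*"`), which takes precedence over the global
#' wildcard (`"*"`). Defaults mirror the observed platform behaviour of a
#' 98-sample cohort: rs16947 drops out of WGS in 60/98 samples, six more
#' CYP2D6 positions miss in >10% of samples, the targeted panel misses
#' 7 of 2842 CYP2D6 genotypes and one ABCG2 rs2231137 genotype.
#'
#' @return A tibble with columns `platform`, `target`, `prob`.
#' @export
default_missingness <- function() {
  high_miss <- c("rs1135840", "rs2837172", "rs1058164", "rs72549352",
                 "rs28735595", "rs1080985")
  bind_rows(
    tibble(platform = "WGS", target = "rs16947", prob = 60 / 98),
    tibble(platform = "WGS", target = high_miss, prob = 0.12),
    tibble(platform = "WGS", target = "CYP2D6:*", prob = 0.02),
    tibble(platform = "WGS", target = "*", prob = 0.002),
    tibble(platform = "TARGETED", target = "CYP2D6:*", prob = 7 / 2842),
    tibble(platform = "TARGETED", target = "rs2231137", prob = 1 / 98),
    tibble(platform = "TARGETED", target = "*", prob = 0),
    tibble(platform = "WES", target = "*", prob = 0)
  )
}

#' Default per-platform low-quality (FILTER-fail) probabilities
#'
#' Same long format as [default_missingness()]. The default reproduces a
#' low-confidence cluster at the CYP2C19 `*9` position (rs17884712) in
#' roughly 17/98 of WGS samples.
#'
#' @return A tibble with columns `platform`, `target`, `prob`.
#' @export
default_lowqual <- function() {
  tibble(platform = "WGS", target = "rs17884712", prob = 17 / 98)
}

#' Default alternate-allele frequencies for non-star loci
#'
#' @return Named numeric vector of per-rsid alternate allele frequencies;
#'   loci not listed fall back to the generator's `alt_freq_default`.
#' @export
default_marker_freqs <- function() {
  c(rs9923231 = 0.39, rs4149056 = 0.15, rs12979860 = 0.35,
    rs1061235 = 0.03, rs2395029 = 0.05, rs2231137 = 0.12,
    rs2231142 = 0.11)
}

#' Build and validate a simulation configuration
#'
#' The configuration defines the cohort the generator emulates. Defaults
#' reproduce the observed rates of a 98-sample pediatric sequencing
#' cohort: CYP2D6 copy-number prevalence 7/98 one copy, 81/98 two, 9/98
#' three, 1/98 four (about 17% CNV carriers); rs16947 WGS dropout in
#' 60/98; extra CYP2D6 no-calls when a `*4` haplotype is present; window
#' coverage Normal(CN/2, `coverage_noise_sd`) truncated at zero; allelic
#' read counts Binomial(depth, expected allele fraction) with depth
#' Poisson(`depth_mean` x CN/2) at CYP2D6 loci.
#'
#' @param n_samples Cohort size (default 98).
#' @param star_freqs Per-gene star frequencies (each must sum to 1).
#' @param cnv_probs Probabilities over CYP2D6 copy numbers 1-4.
#' @param alt_freqs Named alternate-allele frequencies for non-star loci.
#' @param alt_freq_default Fallback alternate-allele frequency (0.25).
#' @param missingness,lowqual Long-format probability tables (see
#'   [default_missingness()]).
#' @param ambiguity_given_star4 Extra WGS no-call probability at CYP2D6
#'   loci for carriers of the `*4` variant (default 0.1), a simple
#'   additive stand-in for the mapping interference seen around `*4`
#'   structural configurations.
#' @param coverage_noise_sd Standard deviation of window relative
#'   coverage around CN/2 (default 0.05).
#' @param depth_mean Mean diploid-equivalent read depth for allelic
#'   counts (default 120).
#' @param allelic_noise When `FALSE`, depths and allelic counts are
#'   deterministic expectations (noise-free mode).
#' @param platforms Platforms to emit.
#' @param wes_dropped_loci Loci structurally absent from the WES capture
#'   (default: the two loci upstream of CYP2D6 exon 1).
#' @return A validated list of class `pgx_sim_config`.
#' @export
simulation_config <- function(n_samples = 98,
                              star_freqs = default_star_freqs(),
                              cnv_probs = c("1" = 7 / 98, "2" = 81 / 98,
                                            "3" = 9 / 98, "4" = 1 / 98),
                              alt_freqs = default_marker_freqs(),
                              alt_freq_default = 0.25,
                              missingness = default_missingness(),
                              lowqual = default_lowqual(),
                              ambiguity_given_star4 = 0.1,
                              coverage_noise_sd = 0.05,
                              depth_mean = 120,
                              allelic_noise = TRUE,
                              platforms = c("WGS", "WES", "TARGETED"),
                              wes_dropped_loci = c("rs28735595",
                                                   "rs1080985")) {
  cfg <- list(n_samples = as.integer(n_samples), star_freqs = star_freqs,
              cnv_probs = cnv_probs, alt_freqs = alt_freqs,
              alt_freq_default = alt_freq_default,
              missingness = missingness, lowqual = lowqual,
              ambiguity_given_star4 = ambiguity_given_star4,
              coverage_noise_sd = coverage_noise_sd,
              depth_mean = depth_mean, allelic_noise = allelic_noise,
              platforms = platforms, wes_dropped_loci = wes_dropped_loci)
  validate_sim_config(cfg)
  structure(cfg, class = "pgx_sim_config")
}

validate_sim_config <- function(cfg) {
  if (is.na(cfg$n_samples) || cfg$n_samples < 1) {
    stopf("n_samples must be >= 1", class = "pgx_validation_error")
  }
  for (g in names(cfg$star_freqs)) {
    f <- cfg$star_freqs[[g]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) {
      stopf("star frequencies for %s must be non-negative and sum to 1",
            g, class = "pgx_validation_error")
    }
  }
  if (length(cfg$cnv_probs) != 4 ||
      !identical(names(cfg$cnv_probs), c("1", "2", "3", "4")) ||
      any(cfg$cnv_probs < 0) || abs(sum(cfg$cnv_probs) - 1) > 1e-8) {
    stopf("cnv_probs must be a named probability vector over 1..4",
          class = "pgx_validation_error")
  }
  probs <- c(cfg$missingness$prob, cfg$lowqual$prob,
             cfg$ambiguity_given_star4, cfg$alt_freqs,
             cfg$alt_freq_default)
  if (any(probs < 0 | probs > 1)) {
    stopf("all probabilities must lie in [0, 1]",
          class = "pgx_validation_error")
  }
  if (cfg$coverage_noise_sd < 0 || cfg$depth_mean <= 0) {
    stopf("coverage_noise_sd must be >= 0 and depth_mean > 0",
          class = "pgx_validation_error")
  }
  if (!all(cfg$platforms %in% platform_tags)) {
    stopf("platforms must be among %s",
          paste(platform_tags, collapse = ", "),
          class = "pgx_validation_error")
  }
  invisible(cfg)
}

#' Noise-free simulation configuration
#'
#' All missingness, low-quality and ambiguity rates zero, coverage noise
#' zero, deterministic depths: under this configuration the pipeline must
#' recover the ground-truth manifest exactly.
#'
#' @param n_samples Cohort size.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `pgx_sim_config`.
#' @export
noise_free_config <- function(n_samples = 98, ...) {
  zero <- function(tbl) mutate(tbl, prob = 0)
  simulation_config(n_samples = n_samples,
                    missingness = zero(default_missingness()),
                    lowqual = zero(default_lowqual()),
                    ambiguity_given_star4 = 0,
                    coverage_noise_sd = 0,
                    allelic_noise = FALSE, ...)
}

# per-(platform, locus) probability lookup honouring precedence
# rsid > gene wildcard > global wildcard
prob_lookup <- function(table, platform, rsid, gene, default = 0) {
  t_p <- table[table$platform == platform, ]
  out <- rep(default, length(rsid))
  glob <- t_p$prob[match("*", t_p$target)]
  if (!is.na(glob)) out[] <- glob
  gene_hit <- t_p$prob[match(paste0(gene, ":*"), t_p$target)]
  out <- ifelse(is.na(gene_hit), out, gene_hit)
  rs_hit <- t_p$prob[match(rsid, t_p$target)]
  ifelse(is.na(rs_hit), out, rs_hit)
}

#' Simulate a fully specified pharmacogenetic cohort
#'
#' Draws per-gene star-allele haplotypes, a CYP2D6 copy number (with the
#' duplicated haplotype chosen uniformly in three-copy samples and four
#' copies modelled as a balanced duplication of both haplotypes),
#' genotypes at every panel locus, windowed relative coverage, allelic
#' read depths, and platform-realistic call sets with injected no-calls
#' and low-quality calls — together with a ground-truth manifest whose
#' phenotypes and actionability categories are derived through the
#' package's own translation tables, so every pipeline stage has an exact
#' recovery target. All randomness flows from `seed`.
#'
#' @param config A `pgx_sim_config`.
#' @param seed Integer seed.
#' @param kb Knowledge base list from [pgx_knowledge_base()].
#' @return A list of class `pgx_simulation`: `calls` (all platforms, long
#'   genotype tibble), `coverage` (window tibble), `manifest` (list of
#'   `samples`, `diplotypes`, `phenotypes` tibbles), `config`, `seed`.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L,
                            kb = pgx_knowledge_base()) {
  validate_sim_config(config)
  local_seed(as.integer(seed))
  panel <- as_tibble(kb$panel)
  defs <- kb$defs
  n <- config$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  # --- haplotypes and CYP2D6 copy number -------------------------------
  cn <- as.integer(sample(names(config$cnv_probs), n, replace = TRUE,
                          prob = config$cnv_probs))
  haps <- imap(config$star_freqs, function(f, g) {
    h <- matrix(sample(names(f), 2 * n, replace = TRUE, prob = f),
                ncol = 2)
    rank <- star_rank(defs, g)
    swap <- rank[h[, 1]] > rank[h[, 2]]
    tibble(sample_id = samples, gene = g,
           hap1 = ifelse(swap, h[, 2], h[, 1]),
           hap2 = ifelse(swap, h[, 1], h[, 2]))
  }) |> list_rbind()
  d6 <- haps$gene == "CYP2D6"
  haps$hap2[d6][cn == 1L] <- "*5"
  # the *5 deletion haplotype sorts last by convention
  dup_side <- ifelse(cn == 3L, sample(1:2, n, replace = TRUE), NA)
  d6_h1 <- haps$hap1[d6]
  d6_h2 <- haps$hap2[d6]
  duplicated_star <- case_when(
    cn == 3L & dup_side == 1 ~ d6_h1,
    cn == 3L & dup_side == 2 ~ ifelse(d6_h2 == "*5", d6_h1, d6_h2),
    TRUE ~ NA_character_)
  # a CN-3 sample cannot carry *5; re-draw impossible combination is not
  # needed because *5 only enters at CN 1
  truth <- tibble(sample_id = samples, copy_number = cn,
                  duplicated_star = duplicated_star)

  # --- genotypes at every locus ---------------------------------------
  sg <- star_genes(defs)
  star_loci <- panel |> filter(.data$gene %in% sg)
  exp_mats <- setNames(lapply(sg, function(g)
    expected_allele_matrix(defs, panel, g)), sg)
  allele_of <- function(hap, gene, rsid) {
    star <- parse_hap_multiplicity(hap)$star
    out <- character(length(hap))
    for (g in unique(gene)) {
      i <- gene == g
      mat <- exp_mats[[g]]
      ref <- panel$ref[match(rsid[i], panel$rsid)]
      s <- star[i]
      a <- mat[cbind(match(s, rownames(mat)),
                     match(rsid[i], colnames(mat)))]
      out[i] <- ifelse(is.na(a), ref, a)
    }
    out
  }
  star_truth <- expand_grid(sample_id = samples,
                            star_loci |> select("rsid", "gene", "ref",
                                                "alt")) |>
    left_join(haps, by = c("sample_id", "gene")) |>
    left_join(truth, by = "sample_id") |>
    mutate(
      a1 = allele_of(.data$hap1, .data$gene, .data$rsid),
      a2raw = allele_of(.data$hap2, .data$gene, .data$rsid),
      # CN-1 samples are hemizygous: the diploid-style call repeats the
      # single haplotype's allele
      a2 = ifelse(.data$gene == "CYP2D6" & .data$hap2 == "*5", .data$a1,
                  .data$a2raw),
      cn_here = ifelse(.data$gene == "CYP2D6", .data$copy_number, 2L),
      n_alt_copies = (.data$a1 == .data$alt) + (.data$a2 == .data$alt) +
        case_when(
          .data$gene != "CYP2D6" ~ 0L,
          .data$copy_number == 3L ~
            as.integer(allele_of(.data$duplicated_star, .data$gene,
                                 .data$rsid) == .data$alt),
          .data$copy_number == 4L ~
            as.integer(.data$a1 == .data$alt) +
            as.integer(.data$a2 == .data$alt),
          TRUE ~ 0L),
      n_alt_copies = ifelse(.data$gene == "CYP2D6" & .data$copy_number == 1L,
                            as.integer(.data$a1 == .data$alt),
                            .data$n_alt_copies),
      alt_frac = .data$n_alt_copies / .data$cn_here)
  marker_loci <- panel |> filter(!.data$gene %in% sg)
  f <- unname(config$alt_freqs[marker_loci$rsid])
  f <- ifelse(is.na(f), config$alt_freq_default, f)
  marker_truth <- expand_grid(marker_loci |> select("rsid", "gene", "ref",
                                                    "alt"),
                              sample_id = samples)
  f_row <- rep(f, each = n)
  n_alt <- as.integer(runif(nrow(marker_truth)) < f_row) +
    as.integer(runif(nrow(marker_truth)) < f_row)
  marker_truth <- marker_truth |>
    mutate(n_alt_copies = n_alt,
           a1 = ifelse(.data$n_alt_copies == 2, .data$alt, .data$ref),
           a2 = ifelse(.data$n_alt_copies >= 1, .data$alt, .data$ref),
           cn_here = 2L,
           alt_frac = .data$n_alt_copies / 2)
  truth_calls <- bind_rows(
    star_truth |> select("sample_id", "rsid", "gene", "ref", "alt",
                         "a1", "a2", "cn_here", "alt_frac"),
    marker_truth |> select("sample_id", "rsid", "gene", "ref", "alt",
                           "a1", "a2", "cn_here", "alt_frac")) |>
    mutate(sorted1 = pmin(.data$a1, .data$a2),
           sorted2 = pmax(.data$a1, .data$a2)) |>
    arrange(.data$sample_id, .data$rsid)

  # --- coverage profiles (3 x 2 kb windows over CYP2D6) ----------------
  win_starts <- c(42522000L, 42524000L, 42526000L)
  coverage <- expand_grid(sample_id = samples, w = 1:3) |>
    left_join(truth, by = "sample_id") |>
    mutate(chrom = "22",
           window_start = win_starts[.data$w] + 1L,
           window_end = win_starts[.data$w] + 2000L,
           relative_coverage = pmax(0, .data$copy_number / 2 +
                                      rnorm(n() ) * config$coverage_noise_sd)) |>
    select("sample_id", "chrom", "window_start", "window_end",
           "relative_coverage") |>
    arrange(.data$sample_id, .data$window_start)

  # --- platform call sets ---------------------------------------------
  star4_carrier <- samples[d6_h1 == "*4" | d6_h2 == "*4"]
  calls <- list_rbind(lapply(config$platforms, function(p) {
    pc <- truth_calls |>
      mutate(platform = p, status = "pass")
    if (p %in% c("WGS", "WES")) {
      lambda <- config$depth_mean * pc$cn_here / 2
      if (config$allelic_noise) {
        depth <- rpois(nrow(pc), lambda)
        alt_reads <- rbinom(nrow(pc), depth, pc$alt_frac)
      } else {
        depth <- as.integer(round(lambda))
        alt_reads <- as.integer(round(depth * pc$alt_frac))
      }
      pc$read_depth <- as.integer(depth)
      pc$alt_reads <- as.integer(alt_reads)
      pc$ref_reads <- pc$read_depth - pc$alt_reads
    } else {
      pc$read_depth <- NA_integer_
      pc$ref_reads <- NA_integer_
      pc$alt_reads <- NA_integer_
    }
    p_miss <- prob_lookup(config$missingness, p, pc$rsid, pc$gene)
    miss <- runif(nrow(pc)) < p_miss
    if (p == "WGS" && config$ambiguity_given_star4 > 0) {
      extra <- pc$gene == "CYP2D6" & pc$sample_id %in% star4_carrier
      miss <- miss | (extra & runif(nrow(pc)) < config$ambiguity_given_star4)
    }
    p_lowq <- prob_lookup(config$lowqual, p, pc$rsid, pc$gene)
    lowq <- !miss & runif(nrow(pc)) < p_lowq
    if (p == "WES") miss <- miss | pc$rsid %in% config$wes_dropped_loci
    pc$status[lowq] <- "fail_quality"
    pc$status[miss] <- "missing"
    pc |>
      transmute(sample_id = .data$sample_id, rsid = .data$rsid,
                gene = .data$gene, platform = .data$platform,
                allele1 = ifelse(.data$status == "missing", NA_character_,
                                 .data$sorted1),
                allele2 = ifelse(.data$status == "missing", NA_character_,
                                 .data$sorted2),
                status = .data$status,
                read_depth = ifelse(.data$status == "missing", NA_integer_,
                                    .data$read_depth),
                ref_reads = ifelse(.data$status == "missing", NA_integer_,
                                   .data$ref_reads),
                alt_reads = ifelse(.data$status == "missing", NA_integer_,
                                   .data$alt_reads))
  })) |>
    arrange(.data$platform, .data$sample_id, .data$rsid)

  # --- ground-truth manifest ------------------------------------------
  manifest <- build_manifest(haps, truth, truth_calls, kb)

  structure(list(calls = calls, coverage = coverage, manifest = manifest,
                 config = config, seed = as.integer(seed)),
            class = "pgx_simulation")
}

# annotate true diplotypes with copy number exactly as the caller would,
# then derive true phenotypes and categories through the package's own
# translation tables (manifest invariant: internally consistent)
build_manifest <- function(haps, truth, truth_calls, kb) {
  dip <- haps |>
    left_join(truth, by = "sample_id") |>
    mutate(
      copy_number = ifelse(.data$gene == "CYP2D6", .data$copy_number, 2L),
      duplicated_star = ifelse(.data$gene == "CYP2D6",
                               .data$duplicated_star, NA_character_),
      hap1 = case_when(
        .data$gene == "CYP2D6" & .data$copy_number == 3L &
          .data$duplicated_star == .data$hap1 ~ paste0(.data$hap1, "x2"),
        .data$gene == "CYP2D6" & .data$copy_number == 4L ~
          paste0(.data$hap1, "x2"),
        TRUE ~ .data$hap1),
      hap2 = case_when(
        .data$gene == "CYP2D6" & .data$copy_number == 3L &
          !str_detect(.data$hap1, "x2$") ~ paste0(.data$hap2, "x2"),
        .data$gene == "CYP2D6" & .data$copy_number == 4L ~
          paste0(.data$hap2, "x2"),
        TRUE ~ .data$hap2),
      state = "resolved", cn_conclusive = TRUE, cn_flag = "ok",
      platform = "TRUTH")
  pass_calls <- truth_calls |>
    transmute(sample_id = .data$sample_id, rsid = .data$rsid,
              gene = .data$gene, platform = "TRUTH",
              allele1 = .data$sorted1, allele2 = .data$sorted2,
              status = "pass")
  phenotypes <- assign_phenotypes(dip, pass_calls, kb$defs, kb$panel,
                                  kb$cutpoints, kb$marker_rules)
  actionability <- categorize_samples(phenotypes, kb$rules)
  samples_tbl <- truth |>
    left_join(actionability |> select("sample_id", "category",
                                      "specialties"),
              by = "sample_id")
  list(samples = samples_tbl,
       diplotypes = dip |>
         select("sample_id", "gene", "hap1", "hap2", "copy_number",
                "duplicated_star"),
       phenotypes = phenotypes)
}

#' @export
print.pgx_simulation <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples, %d platforms, seed %d\n",
              x$config$n_samples, length(x$config$platforms), x$seed))
  print(count(x$manifest$samples, .data$copy_number))
  invisible(x)
}
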