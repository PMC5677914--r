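#!/usr/bin/env Rscript
# Generate a synthetic pharmacogenetic cohort fixture set (multi-sample
# WGS/WES VCFs, targeted genotype TSV, coverage TSV, ground-truth
# manifest JSON).
#
# Usage: Rscript scripts/simulate_cohort.R [--config cfg.yaml] \
#          [--n 98] --seed 1 --out dir/
#
# The optional YAML config may set any scalar simulation_config() field
# plus nested star_freqs (gene -> star -> frequency) and cnv_probs.

suppressPackageStartupMessages({
  library(optparse)
  library(pgxcohort)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--config", type = "character", default = NULL),
  make_option("--n", type = "integer", default = NULL),
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "cohort_fixtures")
)))

args <- list()
if (!is.null(opts$config)) {
  raw <- yaml::read_yaml(opts$config)
  if (!is.null(raw$star_freqs)) {
    raw$star_freqs <- lapply(raw$star_freqs, unlist)
  }
  if (!is.null(raw$cnv_probs)) raw$cnv_probs <- unlist(raw$cnv_probs)
  args <- raw
}
if (!is.null(opts$n)) args$n_samples <- opts$n

cfg <- do.call(simulation_config, args)
kb <- pgx_knowledge_base()
sim <- simulate_cohort(cfg, seed = opts$seed, kb = kb)
paths <- write_fixture_set(sim, opts$out, kb = kb)
for (p in paths) cat(p, "\n")
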