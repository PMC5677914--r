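---
title: "From genotype calls to actionable pharmacogenetics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genotype calls to actionable pharmacogenetics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxcohort)
library(dplyr)
```

pgxcohort turns per-sample genotype calls at a curated pharmacogene panel
into star-allele diplotypes, CYP2D6 copy-number calls, metabolizer
phenotypes and clinical actionability categories, and quantifies
agreement between testing platforms. This vignette explains the models
and procedures, the tunable parameters, what the synthetic cohort
generator does and does not emulate, and the design decisions taken where
the methodology was genuinely open.

## The panel model

The bundled panel covers 67 SNP and indel loci in 19 pharmacogenes on
1-based GRCh37 coordinates, 29 of them in *CYP2D6*. Table rows carry the
canonical rsid, any rsid synonyms (resolvable on lookup), gene, position,
ref/alt allele strings and a region class (exonic/intronic/upstream). Two
points deserve emphasis:

* **Reference convention.** The `ref` column is the allele carried by the
  star-nomenclature reference haplotype (`*1`), which at a small number
  of loci (e.g. rs776746 in *CYP3A5*, where the genome assembly carries
  the non-functional allele) differs from the genome reference. This
  keeps the invariant "all-reference genotype ⇒ `*1/*1`" exact.
* **HLA by proxy.** The two HLA risk alleles are represented by their tag
  SNPs (rs1061235 for HLA-A\*31:01, rs2395029 for HLA-B\*57:01); no HLA
  typing is performed, and phenotypes for these loci are carrier /
  non-carrier calls at the tag.

Star-allele definitions are *minimal tag definitions*: each star allele
is defined by the smallest set of panel variants that discriminates it on
this panel (e.g. `*4` by rs3892097 alone), and sub-alleles that share
tags collapse to the parent name. Full nomenclature haplotypes carry
additional linked variants; collapsing to tags is what any panel of this
size does implicitly, and it is declared in the definition file rather
than in code. The CYP2D6 whole-gene deletion `*5` appears in the table
for activity lookup but is never matched from SNP data — only
copy-number integration can introduce it.

## Genotype input and quality accounting

VCF input (multi-sample, GRCh37) is matched to the panel by normalized
chromosome, position and exact ref/alt strings. Calls are stored
**unphased** — phase separators are accepted and discarded, allele pairs
are kept sorted — because every supported platform delivers effectively
unphased genotypes; phase is inferred downstream only for duplications,
from allelic read ratios. Status assignment: absent record → `missing`;
site `FILTER` other than `PASS`, a per-sample `FT` other than `PASS`, or
a half-missing genotype (`./0`, i.e. only one allele confidently called)
→ `fail_quality`; otherwise `pass`. Allelic depths come from `AD`/`DP`
when present. Wide targeted-genotyping tables use `A/G`-style cells and
`.` for no-calls and carry no depths.

Accounting partitions every (sample, locus, platform) cell into exactly
one of pass / fail_quality / missing; reported percentages use half-up
rounding at the displayed precision throughout the package (96 and 99.8
style figures depend on this convention; base R's half-to-even would
disagree at the boundary).

## Diplotype inference from unphased genotypes

For a gene with star alleles $S$, a pair $(a, b) \in S \times S$ is
consistent with a genotype iff at every locus with a passing call the
multiset of alleles implied by $a$ and $b$ (each haplotype's defining
allele, or ref where it imposes nothing) equals the observed allele pair.
Loci with missing or failed calls are unconstrained wildcards — so
additional missingness can only enlarge the candidate set, never shrink
it (a tested invariant). Enumeration is exhaustive over all unordered
pairs; with panel-scale definition tables (≤ 13 alleles per gene) this is
at most ~90 pairs and is cross-checked in the tests against an
independent brute-force oracle.

Resolution formalizes what a reviewing clinician does by hand:

1. no candidates → `no_call` (the genotype contradicts every known pair;
   the offending pattern is reported rather than inventing a novel
   allele);
2. one candidate → `resolved`;
3. several candidates → pick the **most likely** pair: maximum product of
   star population frequencies when supplied, then fewest non-`*1`
   haplotypes, then canonical (definition-table) order; state
   `ambiguous`, full candidate list retained.

**Key positions.** Some missing-data patterns still permit a confident
assignment (all surviving candidates predict the same phenotype); others
do not. A missing locus is treated as *key* — forcing `no_call` instead
of a best guess — when the candidate set spans more than `key_span`
(default 3) distinct activity scores. This operational definition
reproduces the observed behaviour that diplotypes can be assigned for
many samples with missing calls, while samples missing
phenotype-critical positions (classically those around `*4`) are
reported as unassignable.

## CYP2D6 copy number from relative coverage

Relative coverage is depth normalized under a diploid model (1 = two
copies), averaged over three 2 kb windows spanning
chr22:42,522,000–42,528,000. The classification statistic is the window
mean; per-window dispersion is carried as a QC field but never changes
the call. Default bands:

| mean relative coverage | copy number |
|---|---|
| ≤ 0.1 | 0 |
| 0.4 – 0.6 | 1 |
| 0.8 – 1.2 | 2 |
| 1.4 – 1.6 | 3 |
| ≥ 1.8 | nearest half-unit grid point, `round(2 × coverage)` |
| anything else | inconclusive |

The edges codify "close to" language (±0.2 around 1; the worked examples
0.5 → 1 copy, 1.0 → 2, 1.5 → 3, 1.96 → 4, 0.75 → inconclusive all fall
out of these defaults). Above 1.8 a literal "within ±0.2·(k/2) of k/2"
rule would make adjacent high-copy bands overlap, so the implementation
snaps to the nearest half-unit instead — a true partition that agrees
with the banded rule wherever the latter is unambiguous. All edges live
in a configuration object, not in code.

## Phasing a duplication from allelic read ratios

In a heterozygous three-copy sample the duplicated haplotype contributes
two of three gene copies, so reads at *informative positions* (passing
heterozygous loci whose alleles distinguish the two haplotypes) are
expected to split 2:1. A position votes for the haplotype whose allele
reaches the skew threshold (default: major-allele fraction ≥ 0.6, a
codification of manual 2:1 inspection); unanimous votes determine the
duplicated allele, conflicts or the absence of votes give
`indeterminate`. Only positions with total depth ≥ 75 are used — the
depth floor below which a 2:1 vs 1:1 distinction is unreliable. A
one-sided binomial-test mode (`method = "binomial"`) is available behind
a flag for users who prefer a p-value criterion.

The thresholds have a simple power story: at depth $n$ and true fraction
2/3, the probability that the observed major fraction reaches 0.6 is
≈ 0.92 at $n = 75$ and ≈ 0.97 at $n = 150$; under a balanced 1:1 null the
probability of *spuriously* reaching 0.6 on either side is ≈ 3.6% at
$n = 120$. The depth floor, the 0.6 threshold, and deep coverage at
informative positions together make phasing both sensitive (≥ 95%
recovery in three-copy simulations) and conservative (≥ 95%
`indeterminate` under the two-copy null), which the acceptance suite
verifies by simulation.

Copy-number integration then rewrites the diplotype: one copy replaces
the second haplotype of a homozygous-appearing call with `*5` (a
heterozygous call with one copy is flagged as a conflict); three copies
annotate the phased duplicated haplotype as `starx2` (`*1x2/*4`), or
flag the duplication unassigned; four copies are annotated as a balanced
duplication of both haplotypes (`*1x2/*4x2`) — which haplotype carries
extra copies in a 3+1 configuration is not resolvable from coverage
alone, and no attempt is made; inconclusive coverage flags the sample
for reflex testing.

## Phenotypes and actionability

CYP2D6 uses the activity-score system: each haplotype contributes its
activity value (1 normal, 0.5 decreased, 0 none) times its copy
multiplicity; `*5` contributes 0. Scores translate as 0 → poor,
(0, 1) → intermediate, [1, 2] → extensive, > 2 → ultrarapid. Other
metabolizer genes (CYP2C19, CYP2C9, CYP3A5, TPMT, DPYD) use the same
function-sum machinery with per-gene cutpoints transcribed from the
published diplotype translations (e.g. CYP2C19 `*17` carries value 1.5 so
`*1/*17` lands above 2 and reports ultrarapid — the "rapid" class is
collapsed into ultrarapid; CYP3A5 expressors score ≥ 1 and report
extensive/intermediate). Single-marker genes (HLA tags, VKORC1, SLCO1B1,
IFNL3) use direct genotype→class lookup tables. All activity values,
cutpoints and lookup tables are versioned data files shipped with the
package, not code.

Actionability rules live in a YAML file mapping gene-level phenotype
classes to category 2 (guided dosing/selection benefit) or category 3
(risk of serious or life-threatening adverse response); a sample's
category is the maximum over triggered rules, and category 1 means
nothing triggered. Indeterminate phenotypes never trigger rules; samples
carrying any are flagged for reflex testing instead. Specialty
percentages use the full cohort as denominator. Developmental/ontogeny
effects on enzyme activity are deliberately not modelled: phenotypes are
genotype-derived only.

## Concordance methodology

Genotype concordance compares unordered allele pairs cell by cell; any
cell without a passing call on both platforms is excluded from the
denominator and counted separately (the comparison is over "positions
with passing quality calls"). A strict mode that counts such cells as
discordant exists behind a flag for sensitivity analysis. Copy-number
concordance lists inconclusive-vs-integer pairs separately as
resolved-by-the-other-platform rather than discordant; phenotype
concordance excludes indeterminate calls the same way. Percentages are
reported to one decimal, half-up.

## The synthetic cohort generator

Real cohort data of this kind are controlled-access, so the generator is
a first-class module, not a test convenience. Per gene it draws two
haplotypes from configurable star frequencies; CYP2D6 additionally draws
a copy number (default prevalence 7/98, 81/98, 9/98, 1/98 for one to
four copies — about 17% CNV carriers, matching reported CYP2D6 CNV
rates), chooses the duplicated haplotype uniformly in three-copy
samples, and models four copies as a balanced 2+2 duplication. Genotypes
follow deterministically; window coverage is Normal(CN/2, σ) truncated
at zero with σ = 0.05 by default; allelic read counts at each locus are
Binomial(depth, expected allele fraction) with depth ~
Poisson(`depth_mean` × CN/2). `depth_mean` defaults to 120× (diploid
equivalent), consistent with informative positions in three-copy
samples carrying read counts of 75 or more. Platform dialects: WGS
drops rs16947 in 60/98 of samples (its most frequently missed position),
misses six further CYP2D6 positions at 12%, fails quality at the
CYP2C19 `*9` position in ~17/98, and adds extra CYP2D6 no-calls for `*4`
carriers (default +10%) as a simple additive stand-in for the mapping
interference around `*4` structural configurations; WES omits the two
loci upstream of CYP2D6 exon 1 entirely; the targeted platform misses
7/2842 CYP2D6 genotypes and one ABCG2 genotype and carries no depths.

Every draw flows from a single integer seed; identical (config, seed)
pairs give byte-identical fixture files. The ground-truth manifest
(diplotypes, copy numbers, duplicated haplotypes, phenotypes,
categories) is derived through the package's own translation tables, so
recovery tests compare like with like.

What the generator does **not** emulate — and what passing recovery
tests therefore cannot show about real data: linkage between star
alleles across genes (genes are independent), CYP2D6/CYP2D7 hybrid
structural variants and complex tandem arrangements (which are precisely
the configurations suspected to underlie inconclusive real-world
coverage calls), GC- or mapping-driven coverage waviness (noise is
i.i.d. Gaussian per window), sub-allele diversity below the panel's tag
resolution, and genotyping error other than dropout (platform calls are
never *wrong* unless injected, only absent or quality-failed). A
negative-binomial depth mode exists behind the `allelic_noise` flag's
deterministic counterpart for noise-free recovery testing; noise-free
mode (`noise_free_config()`) zeroes all dropout, coverage noise and
count noise so end-to-end recovery must be exact.

## Numerical and testing choices

* Percentages: half-up rounding at the stated precision; ties at the
  rounding boundary are intentional behaviour, not accidents.
* Deterministic orderings everywhere: haplotype pairs in
  definition-table order, outputs sorted by (platform, sample, locus);
  re-running any stage on identical input is byte-identical.
* Degenerate inputs: empty panels, empty cohorts and all-indeterminate
  comparisons return well-formed zero-count results (`NA` percentages),
  never errors; per-sample failures inside cohort diplotyping degrade to
  `no_call` rows with a reason instead of aborting the cohort.
* Cohort diplotyping memoizes on genotype signatures, so 500-sample
  cohorts resolve in seconds despite exhaustive per-signature
  enumeration.
* Test problem sizes: recovery uses 500 noise-free samples end-to-end;
  copy-number class recovery uses 1000 samples at σ = 0.05; phasing
  power and null calibration use 600-sample three-copy cohorts and 1000
  balanced-read trials. These sizes give sub-percent standard errors on
  the verified proportions while keeping the default test run fast.

## Known limitations

* Diplotype resolution beyond the panel's tag resolution is impossible
  by construction; sub-allele calls collapse to parent stars.
* The `*5` deletion is only reachable through coverage evidence; a
  deletion in a sample without coverage data is invisible.
* CYP2D6/CYP2D7 hybrids are out of scope; real samples harbouring them
  will surface as inconclusive coverage or contradictory genotypes and
  are routed to reflex testing, which is the appropriate clinical
  disposition but not a detection.
* Actionability rules are a transcription of published guideline tables
  at one point in time; they are data files precisely so that updates
  require no code change.
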