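# shared fixtures and independent oracles; everything is built in code

kb_cache <- new.env(parent = emptyenv())
get_kb <- function() {
  if (is.null(kb_cache$kb)) kb_cache$kb <- pgx_knowledge_base()
  kb_cache$kb
}

# a tiny two-gene panel for unit tests (one SNP gene, one indel)
toy_panel <- function() {
  df <- tibble::tibble(
    rsid = c("rs100", "rs200", "rs300", "rs400"),
    aliases = c(".", "rs200alias", ".", "."),
    gene = c("GENEA", "GENEA", "GENEB", "GENEB"),
    chrom = c("1", "1", "2", "2"),
    pos = c(1000L, 2000L, 500L, 900L),
    ref = c("A", "C", "G", "TA"),
    alt = c("G", "T", "A", "T"),
    region_class = c("exonic", "intronic", "exonic", "exonic"),
    label = rep(".", 4))
  structure(df, name = "toy", class = c("pgx_panel", class(df)))
}

write_toy_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "SAMP1"), collapse = "\t"))
  writeLines(c(header, lines), path)
  path
}

# ---- independent brute-force oracles (no shared code with the package) --

# all star pairs consistent with an unphased genotype, by explicit loops
oracle_enumerate <- function(geno, defs, panel, gene) {
  defs <- as.data.frame(defs)
  panel <- as.data.frame(panel)
  loci <- panel[panel$gene == gene, ]
  stars <- unique(defs$star_name[defs$gene == gene])
  if (gene == "CYP2D6") stars <- setdiff(stars, "*5")
  exp_allele <- function(star, rs) {
    hit <- defs$gene == gene & defs$star_name == star &
      !is.na(defs$rsid) & defs$rsid == rs
    if (any(hit)) defs$required_allele[hit][1] else
      loci$ref[loci$rsid == rs]
  }
  out <- list()
  for (i in seq_along(stars)) {
    for (j in i:length(stars)) {
      ok <- TRUE
      for (k in seq_len(nrow(loci))) {
        rs <- loci$rsid[k]
        row <- geno[geno$rsid == rs, ]
        if (nrow(row) == 0 || row$status[1] != "pass") next
        expected <- sort(c(exp_allele(stars[i], rs),
                           exp_allele(stars[j], rs)))
        observed <- sort(c(row$allele1[1], row$allele2[1]))
        if (!identical(expected, observed)) {
          ok <- FALSE
          break
        }
      }
      if (ok) out[[length(out) + 1]] <- c(stars[i], stars[j])
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(hap1 = character(), hap2 = character()))
  }
  tibble::tibble(hap1 = vapply(out, `[`, "", 1),
                 hap2 = vapply(out, `[`, "", 2))
}

# random gene genotype: each locus hom-ref / het / hom-alt / missing
random_genotype <- function(panel, gene, p = c(0.55, 0.2, 0.1, 0.15)) {
  loci <- as.data.frame(panel)[as.data.frame(panel)$gene == gene, ]
  state <- sample(c("rr", "ra", "aa", "mm"), nrow(loci), replace = TRUE,
                  prob = p)
  a1 <- ifelse(state == "aa", loci$alt, loci$ref)
  a2 <- ifelse(state == "rr", loci$ref, loci$alt)
  tibble::tibble(
    rsid = loci$rsid,
    allele1 = ifelse(state == "mm", NA_character_, pmin(a1, a2)),
    allele2 = ifelse(state == "mm", NA_character_, pmax(a1, a2)),
    status = ifelse(state == "mm", "missing", "pass"))
}

# per-cell genotype concordance by explicit loops
oracle_concordance <- function(calls, platforms) {
  a <- as.data.frame(calls[calls$platform == platforms[1], ])
  b <- as.data.frame(calls[calls$platform == platforms[2], ])
  key <- function(r) paste(sort(c(r$allele1, r$allele2)), collapse = "/")
  n_comp <- 0L; n_conc <- 0L; n_excl <- 0L
  for (i in seq_len(nrow(a))) {
    j <- which(b$sample_id == a$sample_id[i] & b$rsid == a$rsid[i])
    if (length(j) != 1) next
    if (a$status[i] != "pass" || b$status[j] != "pass") {
      n_excl <- n_excl + 1L
      next
    }
    n_comp <- n_comp + 1L
    if (identical(key(a[i, ]), key(b[j, ]))) n_conc <- n_conc + 1L
  }
  list(n_comparable = n_comp, n_concordant = n_conc,
       n_discordant = n_comp - n_conc, n_excluded = n_excl)
}

# random two-platform call set over an n x m grid of the real panel loci
random_call_matrix <- function(n_samples, loci, p_missing = 0.15,
                               p_flip = 0.1) {
  grid <- tidyr::expand_grid(
    sample_id = sprintf("T%03d", seq_len(n_samples)),
    loci)
  base <- grid |>
    dplyr::mutate(gene = "PANEL",
                  g = sample(0:2, dplyr::n(), replace = TRUE))
  mk <- function(tbl, platform) {
    tbl |>
      dplyr::mutate(
        platform = platform,
        miss = stats::runif(dplyr::n()) < p_missing,
        allele1 = ifelse(.data$miss, NA,
                         ifelse(.data$g == 2, .data$alt, .data$ref)),
        allele2 = ifelse(.data$miss, NA,
                         ifelse(.data$g >= 1, .data$alt, .data$ref)),
        status = ifelse(.data$miss, "missing", "pass"),
        read_depth = NA_integer_, ref_reads = NA_integer_,
        alt_reads = NA_integer_) |>
      dplyr::select(-"miss")
  }
  a <- mk(base, "WGS")
  b <- mk(base |>
            dplyr::mutate(g = ifelse(stats::runif(dplyr::n()) < p_flip,
                                     sample(0:2, dplyr::n(),
                                            replace = TRUE),
                                     .data$g)),
          "TARGETED")
  dplyr::bind_rows(a, b) |>
    dplyr::mutate(s1 = pmin(.data$allele1, .data$allele2),
                  s2 = pmax(.data$allele1, .data$allele2),
                  allele1 = .data$s1, allele2 = .data$s2) |>
    dplyr::select(-"s1", -"s2", -"g")
}
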