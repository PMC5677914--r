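#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a fixed number of decimal places, the
#' convention used for every percentage this package reports (base R's
#' `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(2.5)        # 3
#' round_half_up(99.75, 1)   # 99.8
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# percentage of a count over a denominator, half-up rounded; NA when the
# denominator is zero (reported as not-applicable downstream)
pct_of <- function(n, d, digits = 0) {
  out <- round_half_up(100 * n / d, digits)
  out[!is.finite(out)] <- NA_real_
  out
}

# strip an optional "chr" prefix so chr22 and 22 compare equal
norm_chrom <- function(x) sub("^chr", "", as.character(x))

# sorted unordered allele pair as a single string key ("A/G")
pair_key <- function(a1, a2) {
  ifelse(is.na(a1) | is.na(a2), NA_character_,
         paste(pmin(a1, a2), pmax(a1, a2), sep = "/"))
}

# sort the two allele columns within each row (unphased storage order)
sort_allele_pair <- function(a1, a2) {
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  list(allele1 = ifelse(swap, a2, a1), allele2 = ifelse(swap, a1, a2))
}

`%||%` <- rlang::`%||%`

call_statuses <- c("pass", "fail_quality", "missing")
platform_tags <- c("WGS", "WES", "TARGETED")

stopf <- function(fmt, ..., class = "pgx_error") {
  abort(sprintf(fmt, ...), class = class)
}

# split a copy-annotated haplotype name ("*1x2") into star name and
# multiplicity; plain names have multiplicity 1
parse_hap_multiplicity <- function(hap) {
  safe <- ifelse(is.na(hap), "", hap)
  m <- regmatches(safe, regexec("^(.*?)(?:x([0-9]+))?$", safe))
  star <- map_chr(m, 2)
  mult <- map_chr(m, 3)
  list(star = ifelse(is.na(hap), NA_character_, star),
       mult = ifelse(mult == "", 1L, suppressWarnings(as.integer(mult))))
}
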