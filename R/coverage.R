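#' Clarke-Carbon clone number for genomic-library coverage
#'
#' The number of clones `N = ln(1 - P) / ln(1 - f)` required so that every
#' genome position is represented with probability `P`, where
#' `f = insert_bp / genome_bp` is the insert fraction of the genome.
#'
#' @param P Coverage probability, in `(0, 1)` (typically 0.95).
#' @param insert_bp Average insert size, bp.
#' @param genome_bp Genome size, bp (`> insert_bp`).
#' @return A list of class `coverage_spec`: `P`, `f`, `insert_bp`,
#'   `genome_bp`, `N` (real) and `N_ceiling`.
#' @examples
#' clarke_carbon_clones(0.95, 726, 3348625)$N  # ~13,817 clones
#' @export
clarke_carbon_clones <- function(P, insert_bp, genome_bp) {
  if (!is.numeric(P) || P <= 0 || P >= 1) stop("P must be in (0, 1)")
  if (!(insert_bp > 0 && insert_bp < genome_bp))
    stop("need 0 < insert_bp < genome_bp (so that 0 < f < 1)")
  f <- insert_bp / genome_bp
  N <- log(1 - P) / log(1 - f)
  structure(list(P = P, f = f, insert_bp = insert_bp, genome_bp = genome_bp,
                 N = N, N_ceiling = ceiling(N)), class = "coverage_spec")
}

# round to `digits` decimals with ties going away from zero (half-up),
# matching how the library tables round fold coverage
.round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Fold coverage of a library
#'
#' Actual clone count over the Clarke-Carbon requirement, reported at one
#' decimal (ties half-up) as in library summary tables; the unrounded value
#' is retained.
#'
#' @param n_clones Clones in the library.
#' @param required_clones Clarke-Carbon clone number at the stated `P`.
#' @return A list: `fold` (1 decimal), `fold_raw`.
#' @examples
#' fold_coverage(21733, 7505)$fold  # 2.9
#' @export
fold_coverage <- function(n_clones, required_clones) {
  if (!is.numeric(required_clones) || required_clones <= 0)
    stop("required_clones must be > 0")
  raw <- n_clones / required_clones
  list(fold = .round_half_up(raw, 1), fold_raw = raw)
}

#' Coverage probability of a library
#'
#' Inverse of the Clarke-Carbon relation: `P = 1 - (1 - f)^n`.
#'
#' @param n_clones Clones in the library (>= 0).
#' @param f Insert fraction of the genome, in `(0, 1)`.
#' @return Probability that every genome position is represented.
#' @export
coverage_probability <- function(n_clones, f) {
  if (!is.numeric(f) || f <= 0 || f >= 1) stop("f must be in (0, 1)")
  if (n_clones < 0) stop("n_clones must be >= 0")
  1 - (1 - f)^n_clones
}

#' Survival rate after a stress exposure
#'
#' `cfu_t / cfu_0 * 100`, the percentage of colony-forming units surviving
#' an exposure relative to the inoculum.
#'
#' @param cfu_0 Colony-forming units at t = 0 (> 0).
#' @param cfu_t Colony-forming units at the endpoint (>= 0).
#' @return Survival rate in percent.
#' @export
survival_rate <- function(cfu_0, cfu_t) {
  if (!is.numeric(cfu_0) || cfu_0 <= 0) stop("cfu_0 must be > 0")
  if (cfu_t < 0) stop("cfu_t must be >= 0")
  cfu_t / cfu_0 * 100
}

#' Fold change between two rates
#'
#' @param rate_a,rate_b Two rates on the same scale (`rate_b > 0`).
#' @return `rate_a / rate_b`.
#' @export
fold_change <- function(rate_a, rate_b) {
  if (!is.numeric(rate_b) || rate_b <= 0) stop("rate_b must be > 0")
  rate_a / rate_b
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = mapped_reads / (gene_length_bp / 1e3) / (library_mapped_total /
#' 1e6)`, the transcript-abundance normalization for strand-specific RNA-seq
#' counts.
#'
#' @param mapped_reads Reads mapped to the gene (>= 0).
#' @param gene_length_bp Gene length, bp (> 0).
#' @param library_mapped_total Total mapped reads in the library (> 0).
#' @return The RPKM value.
#' @examples
#' rpkm(50, 500, 2e6)  # 50
#' @export
rpkm <- function(mapped_reads, gene_length_bp, library_mapped_total) {
  if (!is.numeric(gene_length_bp) || gene_length_bp <= 0)
    stop("gene_length_bp must be > 0")
  if (!is.numeric(library_mapped_total) || library_mapped_total <= 0)
    stop("library_mapped_total must be > 0")
  if (mapped_reads < 0) stop("mapped_reads must be >= 0")
  mapped_reads / (gene_length_bp / 1e3) / (library_mapped_total / 1e6)
}

#' Catalog of the five genome-wide trap libraries
#'
#' Printed inputs for the library coverage table: average insert sizes and
#' entry-library clone counts as published, the published required clone
#' numbers at P = 0.95, and RefSeq total genome sizes (chromosome plus
#' plasmids) where an unambiguous assembly exists. The *C. pasteurianum*
#' genome size is `NA`: the published clone requirement back-calculates to a
#' size matching no public assembly, so its row relies on the published
#' requirement.
#'
#' @return `data.frame` with one row per library: `library`, `organism`,
#'   `insert_bp`, `genome_bp`, `n_clones`, `required_published`.
#' @export
library_catalog <- function() {
  data.frame(
    library = c("LPL-trap", "BSU-trap", "DRA-trap", "CPA-trap", "CAC-trap"),
    organism = c("Lactobacillus plantarum WCFS1", "Bacillus subtilis 168",
                 "Deinococcus radiodurans R1", "Clostridium pasteurianum",
                 "Clostridium acetobutylicum ATCC 824"),
    insert_bp = c(726, 1684, 736, 562, 267),
    genome_bp = c(3348625, 4215606, 3284156, NA, 4132880),
    n_clones = c(110000, 21733, 49140, 219350, 237260),
    required_published = c(13820, 7505, 13350, 26850, 46337),
    stringsAsFactors = FALSE)
}

#' Library coverage table
#'
#' Recomputes, for each library, the Clarke-Carbon clone requirement at `P`
#' (from genome size and insert size where the genome size is known,
#' otherwise from the published requirement) and the fold coverage of the
#' actual clone count.
#'
#' @param libraries `data.frame` in the shape of [library_catalog()]
#'   (the default).
#' @param P Coverage probability (default 0.95).
#' @param use_published_required Use the published clone requirements as the
#'   fold-coverage denominator (default `TRUE`, matching the published
#'   folds); `FALSE` recomputes the denominator from genome sizes.
#' @return `data.frame` with columns `library`, `insert_bp`, `n_clones`,
#'   `required_clones`, `required_computed`, `fold_coverage`.
#' @export
coverage_table <- function(libraries = library_catalog(), P = 0.95,
                           use_published_required = TRUE) {
  req_comp <- vapply(seq_len(nrow(libraries)), function(i) {
    gb <- libraries$genome_bp[i]
    if (is.na(gb)) return(NA_real_)
    clarke_carbon_clones(P, libraries$insert_bp[i], gb)$N
  }, numeric(1))
  req <- if (use_published_required) libraries$required_published else req_comp
  fold <- vapply(seq_len(nrow(libraries)), function(i)
    fold_coverage(libraries$n_clones[i], req[i])$fold, numeric(1))
  data.frame(library = libraries$library,
             insert_bp = libraries$insert_bp,
             n_clones = libraries$n_clones,
             required_clones = req,
             required_computed = req_comp,
             fold_coverage = fold,
             stringsAsFactors = FALSE)
}
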