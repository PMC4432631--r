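#' Parameters for the synthetic annotated-genome generator
#'
#' Defaults encode the statistical structure the trap model assumes of a
#' prokaryotic annotation: gene lengths log-normal around a 924 bp mean (the
#' average prokaryotic gene size) with coefficient of variation ~0.5, operon
#' sizes geometric with mean 1.7 genes, exponential intergenic gaps with a
#' 120 bp mean between units and fixed 20 bp gaps within units, and unit
#' strands drawn independently with probability `strand_bias` of `+`.
#'
#' @param n_units Number of transcription units (>= 0).
#' @param mean_gene_bp Mean gene length in bp (default 924).
#' @param gene_len_dispersion Coefficient of variation of gene length
#'   (default 0.5).
#' @param genes_per_unit_mean Mean operon size (geometric law on {1,2,...}).
#' @param intergenic_gap_mean Mean gap between units, bp (exponential).
#' @param intragenic_gap_bp Fixed gap between genes within a unit, bp.
#' @param strand_bias Probability that a unit lies on the `+` strand.
#' @param circular Logical.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   output.
#' @return A list of class `synthetic_genome_params`.
#' @export
synthetic_genome_params <- function(n_units, mean_gene_bp = 924,
                                    gene_len_dispersion = 0.5,
                                    genes_per_unit_mean = 1.7,
                                    intergenic_gap_mean = 120,
                                    intragenic_gap_bp = 20,
                                    strand_bias = 0.5,
                                    circular = TRUE, seed = 1) {
  stopifnot(n_units >= 0, mean_gene_bp > 0, gene_len_dispersion >= 0,
            genes_per_unit_mean >= 1, intergenic_gap_mean >= 0,
            intragenic_gap_bp >= 0, strand_bias >= 0, strand_bias <= 1)
  structure(list(n_units = as.integer(n_units), mean_gene_bp = mean_gene_bp,
                 gene_len_dispersion = gene_len_dispersion,
                 genes_per_unit_mean = genes_per_unit_mean,
                 intergenic_gap_mean = intergenic_gap_mean,
                 intragenic_gap_bp = intragenic_gap_bp,
                 strand_bias = strand_bias, circular = isTRUE(circular),
                 seed = as.integer(seed)),
            class = "synthetic_genome_params")
}

#' Generate a synthetic annotated genome
#'
#' Lays transcription units end to end, separated by exponential intergenic
#' gaps. All stochastic draws consume a single RNG stream seeded once from
#' `params$seed`, in documented order: (1) unit strands, (2) genes per unit,
#' (3) gene lengths (unit by unit, in transcription-unit order), (4)
#' intergenic gaps. The resulting annotation always satisfies the container
#' invariants (one promoter and one terminator per unit, placed at the unit's
#' first and last transcribed base).
#'
#' @param params A `synthetic_genome_params` object.
#' @param name Replicon name.
#' @return A `genome_annotation`.
#' @examples
#' g <- generate_genome(synthetic_genome_params(n_units = 20, seed = 7))
#' summarize_genome(g)$n_genes
#' @export
generate_genome <- function(params, name = "synthetic") {
  stopifnot(inherits(params, "synthetic_genome_params"))
  p <- params
  if (p$n_units > 2e6)
    stop("n_units = ", p$n_units, " would exceed practical memory")
  if (p$n_units == 0)
    return(genome_annotation(name, 1, p$circular, units = NULL, genes = NULL))
  withr::with_seed(p$seed, {
    strands <- ifelse(stats::runif(p$n_units) < p$strand_bias, "+", "-")
    ngenes <- 1L + stats::rgeom(p$n_units,
                                prob = 1 / p$genes_per_unit_mean)
    total_genes <- sum(ngenes)
    sdlog <- sqrt(log(1 + p$gene_len_dispersion^2))
    meanlog <- log(p$mean_gene_bp) - sdlog^2 / 2
    glen <- pmax(1L, as.integer(round(
      stats::rlnorm(total_genes, meanlog = meanlog, sdlog = sdlog))))
    gaps <- pmax(1L, as.integer(round(
      stats::rexp(p$n_units, rate = 1 / max(p$intergenic_gap_mean, 1e-9)))))
  })
  unit_of_gene <- rep(seq_len(p$n_units), times = ngenes)
  span <- as.numeric(tapply(glen, factor(unit_of_gene, seq_len(p$n_units)), sum)) +
    (ngenes - 1L) * p$intragenic_gap_bp
  ustart <- cumsum(c(0, span[-p$n_units] + gaps[-p$n_units])) + gaps[1]
  # trailing gap closes the circle (or pads the linear end)
  glength <- ustart[p$n_units] + span[p$n_units] +
    max(1, round(p$intergenic_gap_mean))
  uend <- ustart + span
  uid <- paste0("TU", seq_len(p$n_units))
  units <- data.frame(
    id = uid, strand = strands,
    promoter_id = paste0("P", seq_len(p$n_units)),
    promoter_pos = ifelse(strands == "+", ustart, uend - 1),
    terminator_id = paste0("T", seq_len(p$n_units)),
    terminator_pos = ifelse(strands == "+", uend - 1, ustart),
    read_through = 0, stringsAsFactors = FALSE)
  # genes placed left-to-right within each unit regardless of strand
  idx_in_unit <- sequence(ngenes)
  cum_prev <- unlist(lapply(split(glen, unit_of_gene), function(x)
    cumsum(c(0, x[-length(x)]))), use.names = FALSE)
  gstart <- ustart[unit_of_gene] + cum_prev +
    (idx_in_unit - 1L) * p$intragenic_gap_bp
  genes <- data.frame(
    id = paste0("g", seq_len(total_genes)),
    start = gstart, end = gstart + glen,
    strand = strands[unit_of_gene], unit_id = uid[unit_of_gene],
    stringsAsFactors = FALSE)
  genome_annotation(name, glength, p$circular, units, genes)
}

#' Write the generator parameter sidecar
#'
#' Plain-text `key = value` record of the seed and every generator parameter,
#' written beside a synthetic annotation so a run is self-describing.
#'
#' @param params A `synthetic_genome_params`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_params_sidecar <- function(params, path) {
  stopifnot(inherits(params, "synthetic_genome_params"))
  lines <- vapply(names(unclass(params)), function(k)
    paste0(k, " = ", format(params[[k]], scientific = FALSE)), character(1))
  writeLines(lines, path)
  invisible(path)
}
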