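#' Generator parameters for a synthetic L. plantarum-scale genome
#'
#' A synthetic stand-in calibrated once to published summary statistics of
#' the *Lactobacillus plantarum* WCFS1 annotation: total RefSeq size
#' 3,348,625 bp (chromosome plus three plasmids), about 3,052 genes, and the
#' 924 bp average prokaryotic gene length. With the default operon-size law
#' (geometric, mean 1.7 genes per unit) this gives 1,795 transcription units;
#' the intergenic-gap mean (283 bp) is the value closing the total length to
#' the RefSeq size given those gene counts. It is a synthetic emulation of
#' the real annotation's feature density, not the annotation itself.
#'
#' @param seed Integer seed passed to the generator.
#' @return A [synthetic_genome_params()] object.
#' @examples
#' g <- generate_genome(lpl_like_genome_params(seed = 1), name = "Lpl_synth")
#' summarize_genome(g)$genome_bp
#' @export
lpl_like_genome_params <- function(seed = 1) {
  synthetic_genome_params(
    n_units = 1795,           # ~3,052 genes / 1.7 genes per unit
    mean_gene_bp = 924,
    gene_len_dispersion = 0.5,
    genes_per_unit_mean = 1.7,
    intergenic_gap_mean = 283, # closes total length to ~3.35 Mb
    intragenic_gap_bp = 20,
    strand_bias = 0.5,
    circular = TRUE,
    seed = seed)
}
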