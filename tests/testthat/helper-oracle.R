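# Independent brute-force oracle for the exact GFP+ fraction.
#
# Deliberately avoids the package's offset/clearance machinery: every
# placement is materialized as its ordered list of covered positions in
# transcription direction, and the rules are applied by position matching.
# O(G * L) per genome; use on small genomes only.
#
# Boundary conventions (shared with the package and asserted against it):
# a promoter anywhere among the covered positions counts as inside; a
# terminator blocks a promoter iff it comes strictly later in transcription
# order, except that in orientation B the terminator occupying the insert's
# start coordinate (the reporter-proximal boundary) never blocks. In
# upstream_promoter mode any sense terminator among the covered positions
# blocks, in both orientations.
naive_gfp_fraction <- function(genome, mode, sigma, L) {
  G <- genome$length
  rec <- materialize_recognition(sigma, genome)
  pr <- promoters_of(genome)
  tm <- terminators_of(genome)
  starts <- if (genome$circular) 0:(G - 1) else 0:(G - L)
  fired <- 0L
  for (orient in c("A", "B")) {
    strand <- if (orient == "A") "+" else "-"
    p_pos <- pr$position[pr$strand == strand & rec[pr$id]]
    t_pos <- tm$position[tm$strand == strand]
    for (s in starts) {
      covered <- (s:(s + L - 1)) %% G
      ordered <- if (orient == "A") covered else rev(covered)
      if (mode$kind == "promoterless" ||
          (mode$kind == "upstream_promoter" && mode$internal_rescue)) {
        pi <- match(p_pos, ordered)
        ti <- match(t_pos, ordered)
        ti <- ti[!is.na(ti)]
        if (orient == "B") ti <- ti[ti < L]  # boundary terminator never blocks
        prom_ok <- any(vapply(pi[!is.na(pi)], function(i) !any(ti > i),
                              logical(1)))
      } else prom_ok <- FALSE
      if (mode$kind == "promoterless") {
        ok <- prom_ok
      } else {
        ok <- !any(t_pos %in% covered)
        if (mode$internal_rescue) ok <- ok || prom_ok
      }
      if (ok) fired <- fired + 1L
    }
  }
  fired / (2 * length(starts))
}

# small random annotated genome for property tests
random_small_genome <- function(seed, n_units = 10, circular = TRUE) {
  generate_genome(synthetic_genome_params(
    n_units = n_units, mean_gene_bp = 300, gene_len_dispersion = 0.6,
    genes_per_unit_mean = 1.5, intergenic_gap_mean = 80,
    circular = circular, seed = seed))
}
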