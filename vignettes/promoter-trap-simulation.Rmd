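---
title: "Modeling promoter-trap reporter libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling promoter-trap reporter libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promotrap)
```

## The screening problem

A promoter GFP-trap library is built by shearing genomic DNA into small
fragments, cloning each fragment upstream of a promoterless *gfp* gene, and
asking — clone by clone, via flow cytometry — whether transcription initiated
inside the fragment reaches the reporter. The fraction of fluorescent clones
measures how many of the donor genome's promoters the host RNA polymerase
(with whatever sigma factors it expresses) can fire. A control configuration
places an inducible promoter upstream of the insert instead, so the reporter
is expressed unless a transcriptional terminator inside the fragment blocks
read-through; this "lac-trap" configuration measures terminator content
rather than promoter recognition.

`promotrap` simulates both configurations on an annotated genome. The model
is deliberately topological: a genome is a circle (or line) carrying
transcription units — strand-aware operons with a promoter point at the
transcription start and a terminator point at the transcription end — and a
library insert is an interval with an orientation. No nucleotide sequence is
involved; whether a promoter fires is a property of the recognition model,
not of a motif.

## The classification rules

All coordinates are 0-based; gene and insert intervals are half-open.
For an insert starting at $s$ with length $L$ on a genome of length $G$, a
feature at position $x$ has offset $o = (x - s) \bmod G$ and lies in the
insert iff $0 \le o < L$. Orientation A reads the genome's plus strand
toward the reporter (reporter beyond offset $L - 1$); orientation B reads
the minus strand toward the reporter (reporter beyond offset $0$). The
"sense strand" of an insert is the strand read toward the reporter.

* **Promoterless trap.** GFP-positive iff some recognized sense-strand
  promoter in the insert has no sense-strand terminator strictly between it
  and the reporter-proximal insert end: in orientation A no terminator with
  $o_p < o_t < L$, in orientation B none with $0 < o_t < o_p$. A promoter
  exactly at the insert's start coordinate counts as inside; a terminator at
  the reporter-proximal boundary (offset 0 in orientation B; the half-open
  end itself is outside in orientation A) never blocks. When several
  promoters can fire, the reported cause is the reporter-proximal-most one.
* **Upstream-promoter (lac-)trap.** Transcription enters from the vector and
  must traverse the whole insert, so the rule is presence-based: any
  sense-strand terminator in the insert blocks. With *internal rescue*
  enabled, a blocked insert still scores positive when a recognized
  sense-strand promoter has a terminator-free path to the reporter — i.e.
  the promoterless rule fires. We deliberately define rescue through the
  clear-path condition rather than "downstream of the first blocking
  terminator": a promoter between two terminators would otherwise be allowed
  to fire through the second one, which has no physical reading.
* **Terminator read-through.** Each terminator carries a read-through
  probability $\rho$ (default 0, absolute termination). With $\rho > 0$ a
  transcript passes each intervening terminator independently with
  probability $\rho$; classification is then stochastic and seeded. Exact
  enumeration requires $\rho = 0$.

Recognition models: `all` (every promoter fires — the predicted-maximum
configuration), `none`, `subset` (an explicit id set), and `bernoulli`
(each promoter recognized independently with probability `p_rec`).
Recognition is a promoter property, so the Bernoulli coin is tossed once per
promoter per run from the model's own seed — not once per insert.

## Estimators

`gfp_fraction_exact()` enumerates every placement of a fixed-length
fragment — all $G$ starts on a circular genome ($G - L + 1$ on a linear
one) times both orientations — by marking, for each promoter (or
terminator), the contiguous run of start offsets for which it fires
(blocks). This is $O(\sum_i \min(L, c_i))$ rather than $O(G \cdot L)$, so it
is exact even on multi-megabase genomes. `estimate_gfp_fraction_mc()`
shears `n` inserts (uniform starts, Bernoulli(0.5) orientation — entry
cloning is non-directional — and lengths from a fixed or truncated-normal
model) and classifies them vectorially; it returns a binomial confidence
interval (Wald by default, Wilson as an option). The test suite holds the
Monte Carlo estimator to within three standard errors of exhaustive
enumeration, on the toy genome and on batches of randomized synthetic
genomes, and additionally checks the enumerator against an independent
brute-force oracle that materializes every placement position-by-position.

The truncated-normal shear model rejects the continuous draw against the
bounds *before* rounding to integer base pairs; rounding first would shift
the effective bounds by half a base and visibly bias the mean at
$n = 10^5$.

## The synthetic genome generator

Downstream stages are tested without downloads against synthetic
annotations with the statistical structure the trap model assumes:

| parameter | default | rationale |
|---|---|---|
| mean gene length | 924 bp | average prokaryotic gene size |
| gene-length law | log-normal, CV 0.5 | standard shape for prokaryotic gene lengths |
| operon size | geometric, mean 1.7 genes | matches observed operon-size decay |
| intergenic gap | exponential, mean 120 bp | brackets real intergenic densities |
| within-operon gap | fixed 20 bp | typical intra-operon spacing |
| strand of a unit | Bernoulli(0.5) | no strand bias unless configured |

Units are laid end to end; every unit gets its promoter at the first and
terminator at the last transcribed base. A single RNG stream is seeded once
and consumed in documented order (strands, operon sizes, gene lengths,
gaps), so a parameter set plus seed reproduces the GFF3 output
byte-for-byte. What the generator does **not** emulate: nucleotide
sequence and GC content, promoter/terminator strength or sequence motifs,
correlated operon structure (functional clustering, leading-strand bias),
overlapping genes, and regulon structure linking promoters to specific
sigma factors. Tests passing on synthetic genomes therefore validate the
interval arithmetic and the estimators, not the biological fidelity of any
particular annotation.

`lpl_like_genome_params()` is a calibrated stand-in for the *L. plantarum*
WCFS1 annotation, fixed once from published summary statistics: total
RefSeq size 3,348,625 bp (chromosome plus three plasmids), about 3,052
genes, 924 bp mean gene length. With the default operon-size law this gives
1,795 units; the intergenic-gap mean (283 bp) is the value that closes the
total length to the RefSeq size. It is a synthetic emulation of that
genome's feature density, not the annotation itself.

## Operon inference from real annotations

`read_genes_gff3()` converts GFF3 1-based inclusive gene records to the
internal convention, and `infer_transcription_units()` applies the standard
intergenic-gap heuristic: consecutive same-strand genes at most 50 bp apart
(configurable) join one unit; a strand switch always breaks. Overlapping
same-strand genes — common in real annotations — are merged into one unit
with a warning; only the unit span enters the trap model, so the overlap is
harmless. The first and last unit of a circular replicon are not joined
across the origin. Placing a promoter at every inferred unit start is a
reconstruction: curated promoter or terminator sets can be substituted by
building the `genome_annotation` directly.

## What the simulation does and does not reproduce

On the WCFS1-scale stand-in with 726 bp inserts and full recognition, the
package predicts (Monte Carlo, $n = 10^5$; exact enumeration agrees):
about **18%** GFP-positive for the promoterless trap and about **81%**
(87% with internal rescue) for the lac-trap. The published simulation
estimates for the corresponding library designs are 25% and 62%. The
direction of both gaps is informative: with one promoter and one terminator
per *operon* (about 0.9 sense-strand terminators per 3.3 kb per strand), a
726 bp window is terminator-free far too often. Matching 62% read-through
would require roughly one terminator per *gene* — or terminators blocking
in both orientations — and per-gene promoter density would likewise push the
promoterless fraction toward 25%. The original simulation's annotation
source (gene starts versus curated regulon data) is not recoverable from
the main text, so the package exposes the topology (gap threshold,
read-through, rescue) as parameters and reports both rescue variants rather
than tuning any of them to the published numbers; the corresponding
acceptance check is expected to fail under the default per-operon topology,
and does.

## Clarke–Carbon coverage statistics

Library sizing uses $N = \ln(1-P)/\ln(1-f)$, the number of clones giving
probability $P$ (0.95 throughout) that every genome position is
represented, with $f$ the insert-to-genome size ratio; the inverse
$P = 1-(1-f)^N$ and the small-$f$ form $N \approx -\ln(1-P)/f$ are also
provided. Fold coverage (clones over requirement) is reported at one
decimal, ties rounding half-up, matching the published table's precision;
unrounded values are retained. Recomputing the published clone requirements
from RefSeq total genome sizes agrees within 0.12% for the four organisms
with unambiguous assemblies; the *C. pasteurianum* requirement
back-calculates to a ~5.0 Mb genome matching no public assembly, so its
row uses the published requirement directly.

## Numerical and experimental-design choices

* **Recognized-fraction inference** is the clipped ratio observed/predicted
  maximum. Its recovery experiment (stage 4 and the acceptance suite) uses
  a genome of 2,000 units, 1,000 inserts per run, and a three-standard-error
  binomial band — the same band used for the Monte-Carlo-versus-oracle
  checks. A 95% interval would sit exactly at the 95%-of-runs coverage
  target it is checked against, and the per-promoter materialization of
  Bernoulli recognition adds between-run variance beyond insert sampling;
  the wider band absorbs both, and observed coverage is ~99%.
* **Problem sizes.** Exact enumeration is used up to the 3.35 Mb stand-in;
  Monte Carlo runs use $10^5$ inserts for headline estimates, $2 \times
  10^4$ for batch comparisons, $10^3$ per recovery run (300 runs).
* **Degenerate inputs.** Zero-unit genomes are valid (all counts zero);
  terminator-free units are allowed in hand-built annotations (`NA`
  terminator) and make the lac-trap fraction exactly 1; inserts wrapping a
  linear genome, fragments longer than the genome, and non-positive clone
  requirements are errors.

## Limitations

The model ignores promoter strength, reporter translation (RBS, codon
usage), partial terminator efficiencies beyond a single per-terminator
read-through probability, fluorescence intensity and sorting dynamics, and
growth burden of sigma-factor expression. It predicts endpoint fractions of
a library, not induction time courses.
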