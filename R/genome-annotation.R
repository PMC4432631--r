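#' Construct an annotated genome
#'
#' The central container of the package: a (circular or linear) genome carrying
#' transcription units. A transcription unit is a strand-aware operon — one or
#' more co-directional genes preceded by a single promoter point feature and
#' followed by a single terminator point feature in the direction of
#' transcription. All coordinates are internal convention: 0-based, half-open
#' for gene intervals, 0-based points for promoters/terminators.
#'
#' @param name Replicon name (used as the chromosome field in BED output).
#' @param length Genome length in bp (> 0).
#' @param circular Logical; whether fragment placements may wrap the origin.
#' @param units `data.frame` with one row per transcription unit and columns
#'   `id`, `strand` (`"+"`/`"-"`), `promoter_id`, `promoter_pos`,
#'   `terminator_id`, `terminator_pos`, `read_through`. Terminator columns may
#'   be `NA` for terminator-free units (hand-built annotations only; the
#'   synthetic generator always pairs promoter and terminator).
#'   `read_through` is the probability that transcription proceeds past the
#'   unit's terminator (0 = absolute termination).
#' @param genes `data.frame` with columns `id`, `start`, `end` (0-based
#'   half-open), `strand`, `unit_id`.
#' @param validate Run [validate_genome_annotation()] on the result.
#'
#' @return An object of class `genome_annotation`.
#' @seealso [infer_transcription_units()], [generate_genome()], [toy_genome()]
#' @export
genome_annotation <- function(name, length, circular, units, genes,
                              validate = TRUE) {
  units <- as.data.frame(units, stringsAsFactors = FALSE)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(units) > 0 && is.null(units$read_through)) units$read_through <- 0
  if (nrow(units) == 0) {
    units <- data.frame(id = character(), strand = character(),
                        promoter_id = character(), promoter_pos = integer(),
                        terminator_id = character(), terminator_pos = integer(),
                        read_through = numeric(), stringsAsFactors = FALSE)
  }
  if (nrow(genes) == 0) {
    genes <- data.frame(id = character(), start = integer(), end = integer(),
                        strand = character(), unit_id = character(),
                        stringsAsFactors = FALSE)
  }
  obj <- structure(
    list(name = as.character(name), length = as.numeric(length),
         circular = isTRUE(circular), units = units, genes = genes),
    class = "genome_annotation")
  if (validate) validate_genome_annotation(obj)
  obj
}

#' Validate a genome annotation
#'
#' Checks every structural invariant of the container: positive length,
#' feature coordinates within the genome, unique ids, strand consistency
#' between units and their genes, promoter before the first gene and
#' terminator after the last gene in the direction of transcription.
#' Overlapping same-strand genes within a unit are tolerated (real
#' annotations contain them; only the unit span enters the trap model).
#'
#' @param genome A `genome_annotation`.
#' @return Invisibly `TRUE`; errors on the first violated invariant.
#' @export
validate_genome_annotation <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  g <- genome
  if (!(is.numeric(g$length) && length(g$length) == 1 && g$length > 0))
    stop("genome length must be a single positive number")
  u <- g$units; gn <- g$genes
  if (anyDuplicated(u$id)) stop("duplicate transcription-unit ids")
  if (anyDuplicated(u$promoter_id)) stop("duplicate promoter ids")
  tid <- u$terminator_id[!is.na(u$terminator_id)]
  if (anyDuplicated(tid)) stop("duplicate terminator ids")
  if (anyDuplicated(gn$id)) stop("duplicate gene ids")
  if (!all(u$strand %in% c("+", "-"))) stop("unit strand must be '+' or '-'")
  if (!all(gn$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (nrow(u) > 0) {
    if (any(u$promoter_pos < 0 | u$promoter_pos >= g$length))
      stop("promoter position outside genome")
    tp <- u$terminator_pos
    if (any(!is.na(tp) & (tp < 0 | tp >= g$length)))
      stop("terminator position outside genome")
    if (any(u$read_through < 0 | u$read_through > 1))
      stop("read_through must be in [0, 1]")
  }
  if (nrow(gn) > 0) {
    if (any(gn$start < 0 | gn$start >= gn$end | gn$end > g$length))
      stop("gene interval violates 0 <= start < end <= genome length")
    if (!all(gn$unit_id %in% u$id)) stop("gene references unknown unit id")
  }
  for (i in seq_len(nrow(u))) {
    gi <- gn[gn$unit_id == u$id[i], , drop = FALSE]
    if (nrow(gi) == 0) stop("unit ", u$id[i], " has no genes")
    if (!all(gi$strand == u$strand[i]))
      stop("unit ", u$id[i], ": gene strand differs from unit strand")
    gi <- gi[order(gi$start), , drop = FALSE]
    # overlapping same-strand genes are tolerated within a unit: real
    # annotations contain them, and only the unit span enters the trap model
    if (u$strand[i] == "+") {
      ok_p <- u$promoter_pos[i] <= min(gi$start)
      ok_t <- is.na(u$terminator_pos[i]) || u$terminator_pos[i] >= max(gi$end) - 1
    } else {
      ok_p <- u$promoter_pos[i] >= max(gi$end) - 1
      ok_t <- is.na(u$terminator_pos[i]) || u$terminator_pos[i] <= min(gi$start)
    }
    if (!ok_p) stop("unit ", u$id[i], ": promoter does not precede first gene")
    if (!ok_t) stop("unit ", u$id[i], ": terminator does not follow last gene")
  }
  invisible(TRUE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %s bp, %s\n", x$name,
              format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  cat(sprintf("  %d transcription units (%d +, %d -), %d genes\n",
              nrow(x$units), sum(x$units$strand == "+"),
              sum(x$units$strand == "-"), nrow(x$genes)))
  invisible(x)
}

#' Promoter point features of a genome
#'
#' @param genome A `genome_annotation`.
#' @return `data.frame` with columns `id`, `position`, `strand`, `unit_id`.
#' @export
promoters_of <- function(genome) {
  u <- genome$units
  data.frame(id = u$promoter_id, position = u$promoter_pos,
             strand = u$strand, unit_id = u$id, stringsAsFactors = FALSE)
}

#' Terminator point features of a genome
#'
#' Units with `NA` terminator positions (terminator-free units) are omitted.
#'
#' @param genome A `genome_annotation`.
#' @return `data.frame` with columns `id`, `position`, `strand`, `unit_id`,
#'   `read_through`.
#' @export
terminators_of <- function(genome) {
  u <- genome$units[!is.na(genome$units$terminator_pos), , drop = FALSE]
  data.frame(id = u$terminator_id, position = u$terminator_pos,
             strand = u$strand, unit_id = u$id,
             read_through = u$read_through, stringsAsFactors = FALSE)
}

#' Summarize an annotated genome
#'
#' Per-strand feature counts and gene-length statistics, the analogues of a
#' library-features table for a single annotation.
#'
#' @param genome A `genome_annotation`.
#' @return A list with counts of units/genes/promoters/terminators (total and
#'   per strand), mean and median gene length, and genome length.
#' @export
summarize_genome <- function(genome) {
  stopifnot(inherits(genome, "genome_annotation"))
  u <- genome$units; gn <- genome$genes
  glen <- gn$end - gn$start
  strand_counts <- function(s) c(plus = sum(s == "+"), minus = sum(s == "-"))
  list(
    name = genome$name,
    genome_bp = genome$length,
    circular = genome$circular,
    n_units = nrow(u),
    n_genes = nrow(gn),
    n_promoters = nrow(u),
    n_terminators = sum(!is.na(u$terminator_pos)),
    units_by_strand = strand_counts(u$strand),
    genes_by_strand = strand_counts(gn$strand),
    mean_gene_bp = if (nrow(gn)) mean(glen) else NA_real_,
    median_gene_bp = if (nrow(gn)) stats::median(glen) else NA_real_
  )
}

#' Build a small single-unit genome by hand
#'
#' Convenience constructor for worked examples and oracle tests: one
#' transcription unit whose promoter and terminator are placed at stated
#' coordinates, with a single gene spanning the distance between them. The
#' default arguments give the canonical 1 kb circular toy genome with a `+`
#' strand promoter at 100 and terminator at 400.
#'
#' @param length Genome length in bp.
#' @param promoter Promoter point coordinate (0-based).
#' @param terminator Terminator point coordinate, or `NA` for a
#'   terminator-free unit (the gene then spans 300 bp from the promoter).
#' @param strand `"+"` or `"-"`.
#' @param circular Logical.
#' @param read_through Terminator read-through probability.
#' @return A `genome_annotation` with one unit.
#' @examples
#' g1 <- toy_genome()
#' summarize_genome(g1)$n_promoters
#' @export
toy_genome <- function(length = 1000, promoter = 100, terminator = 400,
                       strand = "+", circular = TRUE, read_through = 0) {
  if (strand == "+") {
    gstart <- promoter
    gend <- if (is.na(terminator)) promoter + 300 else terminator + 1
  } else {
    gend <- promoter + 1
    gstart <- if (is.na(terminator)) promoter - 300 else terminator
  }
  genome_annotation(
    name = "toy", length = length, circular = circular,
    units = data.frame(id = "U1", strand = strand,
                       promoter_id = "P1", promoter_pos = promoter,
                       terminator_id = if (is.na(terminator)) NA_character_ else "T1",
                       terminator_pos = terminator,
                       read_through = read_through,
                       stringsAsFactors = FALSE),
    genes = data.frame(id = "G1", start = gstart, end = gend,
                       strand = strand, unit_id = "U1",
                       stringsAsFactors = FALSE))
}
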