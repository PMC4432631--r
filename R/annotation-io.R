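#' Read gene features from a GFF3 annotation
#'
#' Imports `gene` records (falling back to `CDS` when the file annotates no
#' `gene` features) and converts coordinates from GFF3 1-based inclusive to
#' the package's 0-based half-open convention. Records without a strand are
#' rejected with a warning; coordinates beyond `genome_length` are an error.
#'
#' @param path GFF3 file.
#' @param genome_length Replicon length in bp; used to validate coordinates.
#' @param circular Logical, carried through to downstream constructors.
#' @return `data.frame` with columns `id`, `start`, `end` (0-based half-open),
#'   `strand`, sorted by `start`.
#' @export
read_genes_gff3 <- function(path, genome_length, circular = FALSE) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  keep <- type == "gene"
  if (!any(keep)) keep <- type == "CDS"
  gr <- gr[keep]
  if (length(gr) == 0) {
    return(data.frame(id = character(), start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  strand <- as.character(BiocGenerics::strand(gr))
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sum(bad), " record(s) without strand rejected")
    gr <- gr[!bad]
    strand <- strand[!bad]
  }
  id <- gr$ID
  if (is.null(id)) id <- gr$Name
  if (is.null(id)) id <- paste0("gene", seq_along(gr))
  id <- as.character(id)
  id[is.na(id)] <- paste0("gene", which(is.na(id)))
  start0 <- BiocGenerics::start(gr) - 1L
  end0 <- BiocGenerics::end(gr)
  if (any(end0 > genome_length) || any(start0 < 0))
    stop("gene coordinates exceed genome length (", genome_length, " bp)")
  out <- data.frame(id = id, start = start0, end = end0, strand = strand,
                    stringsAsFactors = FALSE)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Infer transcription units from sorted genes
#'
#' Operon inference by the standard intergenic-gap heuristic: consecutive
#' same-strand genes whose gap does not exceed `gap_threshold` are merged into
#' one transcription unit; a strand switch always starts a new unit.
#' Overlapping same-strand genes are merged into the same unit with a warning.
#' Each unit receives a promoter point at its transcription start and a
#' terminator point at its transcription end (first/last transcribed base).
#'
#' @param genes `data.frame` as returned by [read_genes_gff3()].
#' @param genome_length Genome length in bp.
#' @param circular Logical.
#' @param name Replicon name for the resulting annotation.
#' @param gap_threshold Maximum intergenic gap (bp) joining two genes into one
#'   unit; default 50, a common prokaryotic operon heuristic.
#' @param read_through Terminator read-through probability assigned to every
#'   unit (default 0, absolute termination).
#' @return A `genome_annotation`.
#' @export
infer_transcription_units <- function(genes, genome_length, circular = FALSE,
                                      name = "genome", gap_threshold = 50,
                                      read_through = 0) {
  if (!is.numeric(gap_threshold) || length(gap_threshold) != 1 ||
      gap_threshold < 0)
    stop("gap_threshold must be a single non-negative number")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) == 0) {
    return(genome_annotation(name, max(genome_length, 1), circular,
                             units = NULL, genes = NULL))
  }
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  n <- nrow(genes)
  new_unit <- rep(TRUE, n)
  if (n > 1) {
    same_strand <- genes$strand[-1] == genes$strand[-n]
    gap <- genes$start[-1] - genes$end[-n]
    new_unit[-1] <- !(same_strand & gap <= gap_threshold)
    if (any(!new_unit[-1] & gap < 0))
      warning("overlapping same-strand genes merged into one unit")
  }
  unit_idx <- cumsum(new_unit)
  nu <- max(unit_idx)
  ustrand <- genes$strand[new_unit]
  fu <- factor(unit_idx, levels = seq_len(nu))
  ustart <- as.numeric(tapply(genes$start, fu, min))
  uend <- as.numeric(tapply(genes$end, fu, max))
  uid <- paste0("TU", seq_len(nu))
  units <- data.frame(
    id = uid, strand = ustrand,
    promoter_id = paste0("P", seq_len(nu)),
    promoter_pos = ifelse(ustrand == "+", ustart, uend - 1),
    terminator_id = paste0("T", seq_len(nu)),
    terminator_pos = ifelse(ustrand == "+", uend - 1, ustart),
    read_through = read_through, stringsAsFactors = FALSE)
  genes$unit_id <- uid[unit_idx]
  genome_annotation(name, genome_length, circular, units, genes)
}

#' Write a genome annotation to GFF3
#'
#' Emits gene features plus promoter and terminator point features (1 bp),
#' converting back to GFF3 1-based inclusive coordinates. Reading the file
#' with [read_genes_gff3()] recovers the gene table exactly.
#'
#' @param genome A `genome_annotation`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genome_gff3 <- function(genome, path) {
  gn <- genome$genes
  u <- genome$units
  ut <- u[!is.na(u$terminator_pos), , drop = FALSE]
  mk <- function(start0, end0, type, id, strand) {
    if (length(start0) == 0) return(NULL)
    GenomicRanges::GRanges(
      seqnames = genome$name,
      ranges = IRanges::IRanges(start = start0 + 1, end = end0),
      strand = strand, type = type, ID = id)
  }
  parts <- list(
    mk(gn$start, gn$end, "gene", gn$id, gn$strand),
    mk(u$promoter_pos, u$promoter_pos + 1, "promoter", u$promoter_id, u$strand),
    mk(ut$terminator_pos, ut$terminator_pos + 1, "terminator",
       ut$terminator_id, ut$strand))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  gr <- if (length(parts)) do.call(c, parts) else
    GenomicRanges::GRanges()
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write classified inserts as BED6
#'
#' One line per insert (0-based half-open): the name column encodes the
#' classification (`GFP+`/`GFP-` plus the firing promoter id or the
#' read-through cause), the score column is `.`, and the strand column is the
#' insert orientation (`+` for orientation A, `-` for B). Inserts that wrap
#' the origin of a circular genome are emitted as two lines sharing one name.
#'
#' @param inserts `data.frame` with columns `start`, `length`, `orientation`
#'   (as produced by [shear()]).
#' @param classifications `data.frame` from [classify_inserts()] (same row
#'   order).
#' @param genome The `genome_annotation` the inserts were drawn from.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_inserts_bed <- function(inserts, classifications, genome, path) {
  n <- nrow(inserts)
  if (n == 0) {
    writeLines("# BED6: no inserts", path)
    return(invisible(path))
  }
  stopifnot(nrow(classifications) == n)
  cause <- ifelse(classifications$gfp_positive,
                  paste0("GFP+:", ifelse(classifications$cause == "promoter_fired",
                                         classifications$promoter_id,
                                         "read_through")),
                  "GFP-:none")
  strand <- ifelse(inserts$orientation == "A", "+", "-")
  s <- inserts$start
  e <- s + inserts$length
  G <- genome$length
  wraps <- e > G
  chrom <- genome$name
  row1 <- data.frame(chrom = chrom, start = s, end = pmin(e, G),
                     name = cause, score = ".", strand = strand,
                     stringsAsFactors = FALSE)
  if (any(wraps)) {
    if (!genome$circular) stop("insert wraps on a linear genome")
    row2 <- data.frame(chrom = chrom, start = 0, end = e[wraps] - G,
                       name = cause[wraps], score = ".",
                       strand = strand[wraps], stringsAsFactors = FALSE)
    out <- rbind(row1, row2)
    out <- out[order(c(seq_len(n), which(wraps) + 0.5)), , drop = FALSE]
  } else out <- row1
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
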