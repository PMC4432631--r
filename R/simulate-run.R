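#' Run a trap-library simulation and write a self-describing report
#'
#' High-level driver: shears, classifies, estimates the GFP-positive fraction
#' and, when `out_dir` is given, writes `report.tsv` and `report.json` (the
#' estimate, confidence interval, cause breakdown and the full resolved
#' configuration including the seed) plus optionally a BED6 file of the
#' classified inserts.
#'
#' @inheritParams estimate_gfp_fraction_mc
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @param write_bed Also write `inserts.bed` (BED6, one line per insert, two
#'   for origin-wrapping inserts).
#' @return The report as a list (invisibly identical to the JSON content),
#'   with the per-insert classification attached as attribute
#'   `"classification"`.
#' @export
run_trap_simulation <- function(genome, mode, sigma, length_model, n, seed,
                                ci_method = "normal", conf_level = 0.95,
                                out_dir = NULL, write_bed = FALSE) {
  inserts <- shear(genome, length_model, n, seed)
  cls <- classify_inserts(inserts, genome, mode, sigma,
                          seed = as.integer(seed) + 1L)
  k <- sum(cls$gfp_positive)
  causes <- table(cls$cause)
  ci <- binomial_ci(k, n, ci_method, conf_level)
  report <- list(
    genome = genome$name,
    genome_bp = genome$length,
    circular = genome$circular,
    mode = mode$kind,
    internal_rescue = mode$internal_rescue,
    sigma = sigma$kind,
    p_rec = sigma$p_rec,
    length_model = length_model$kind,
    mean_bp = length_model$mean_bp,
    sd_bp = length_model$sd_bp,
    min_bp = length_model$min_bp,
    max_bp = length_model$max_bp,
    n = n, seed = as.integer(seed),
    n_positive = k,
    gfp_fraction = k / n,
    ci_lower = ci[1], ci_upper = ci[2],
    ci_method = ci_method, conf_level = conf_level,
    causes = as.list(causes))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    flat <- report
    flat$causes <- NULL
    tsv <- data.frame(key = names(flat),
                      value = vapply(flat, function(v)
                        if (is.null(v)) "" else as.character(v), character(1)),
                      stringsAsFactors = FALSE)
    utils::write.table(tsv, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (write_bed)
      write_inserts_bed(inserts, cls, genome,
                        file.path(out_dir, "inserts.bed"))
  }
  attr(report, "classification") <- cls
  invisible(report)
}
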