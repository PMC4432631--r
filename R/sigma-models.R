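#' Trap-vector mode
#'
#' `promoterless`: the reporter has no promoter of its own, so a cell
#' fluoresces only when transcription initiates at a recognized promoter
#' inside the insert and reaches the reporter. `upstream_promoter`: an
#' inducible vector promoter upstream of the insert drives the reporter
#' unless a terminator in the insert blocks read-through (the lac-trap
#' control configuration). With `internal_rescue`, an insert blocked by a
#' terminator is still scored positive when a recognized sense-strand
#' promoter downstream of every blocking terminator re-initiates
#' transcription with a clear path to the reporter.
#'
#' @param kind `"promoterless"` or `"upstream_promoter"`.
#' @param internal_rescue Logical; meaningful only for `upstream_promoter`.
#' @return A list of class `vector_mode`.
#' @export
vector_mode <- function(kind = c("promoterless", "upstream_promoter"),
                        internal_rescue = FALSE) {
  kind <- match.arg(kind)
  if (kind == "promoterless" && isTRUE(internal_rescue))
    stop("internal_rescue is meaningful only for upstream_promoter")
  structure(list(kind = kind, internal_rescue = isTRUE(internal_rescue)),
            class = "vector_mode")
}

#' Sigma-factor promoter-recognition model
#'
#' Which of the genome's promoters the host RNA polymerase (with whatever
#' sigma factors it carries) can fire. `all` models a host recognizing every
#' promoter (the predicted-maximum configuration), `none` a host recognizing
#' no foreign promoter, `subset` an explicit recognized set (e.g. a curated
#' regulon), and `bernoulli` an independent per-promoter coin with success
#' probability `p_rec` — recognition is a promoter property, so the coin is
#' tossed once per promoter per run (seeded), not once per insert.
#'
#' @param kind One of `"all"`, `"none"`, `"subset"`, `"bernoulli"`.
#' @param recognized_ids Character vector of promoter ids (`subset` only).
#' @param p_rec Recognition probability in `[0, 1]` (`bernoulli` only).
#' @param seed Integer seed for the `bernoulli` materialization.
#' @return A list of class `sigma_model`.
#' @export
sigma_model <- function(kind = c("all", "none", "subset", "bernoulli"),
                        recognized_ids = NULL, p_rec = NULL, seed = 1) {
  kind <- match.arg(kind)
  if (kind == "subset") stopifnot(is.character(recognized_ids))
  if (kind == "bernoulli")
    stopifnot(is.numeric(p_rec), p_rec >= 0, p_rec <= 1)
  structure(list(kind = kind, recognized_ids = recognized_ids,
                 p_rec = p_rec, seed = as.integer(seed)),
            class = "sigma_model")
}

#' Materialize the recognized-promoter set of a genome
#'
#' Resolves a [sigma_model()] against a genome's promoters into a logical
#' vector (one entry per promoter, in `promoters_of()` order). The
#' `bernoulli` model is drawn once here from its own seed, so repeated calls
#' are reproducible.
#'
#' @param sigma A `sigma_model`.
#' @param genome A `genome_annotation`.
#' @return Named logical vector over promoter ids.
#' @export
materialize_recognition <- function(sigma, genome) {
  pr <- promoters_of(genome)
  rec <- switch(sigma$kind,
    all = rep(TRUE, nrow(pr)),
    none = rep(FALSE, nrow(pr)),
    subset = {
      if (!all(sigma$recognized_ids %in% pr$id))
        stop("recognized_ids contains unknown promoter ids")
      pr$id %in% sigma$recognized_ids
    },
    bernoulli = withr::with_seed(sigma$seed,
                                 stats::runif(nrow(pr)) < sigma$p_rec))
  names(rec) <- pr$id
  rec
}
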