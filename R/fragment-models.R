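#' Fragment (insert) length model
#'
#' Describes the size distribution of randomly sheared library inserts.
#' `fixed` gives every insert the same length; `truncated_normal` resamples a
#' normal until it lands within `[min_bp, max_bp]`, mimicking gel-purified
#' shearing bands (the 200-1,000 bp band typical of nebulized genomic DNA).
#'
#' @param kind `"fixed"` or `"truncated_normal"`.
#' @param mean_bp Mean insert length, bp (e.g. the 726 bp observed for an
#'   *L. plantarum* trap library).
#' @param sd_bp Normal standard deviation before truncation (ignored for
#'   `fixed`).
#' @param min_bp,max_bp Truncation bounds, bp.
#' @return A list of class `fragment_length_model`.
#' @export
fragment_length_model <- function(kind = c("fixed", "truncated_normal"),
                                  mean_bp, sd_bp = NULL,
                                  min_bp = 200, max_bp = 1000) {
  kind <- match.arg(kind)
  if (kind == "fixed") { min_bp <- mean_bp; max_bp <- mean_bp }
  stopifnot(min_bp <= mean_bp, mean_bp <= max_bp)
  if (kind == "truncated_normal") {
    stopifnot(is.numeric(sd_bp), sd_bp >= 0)
  }
  structure(list(kind = kind, mean_bp = mean_bp, sd_bp = sd_bp,
                 min_bp = min_bp, max_bp = max_bp),
            class = "fragment_length_model")
}

#' Mean of a truncated normal distribution
#'
#' Closed form `mu + sigma * (phi(a) - phi(b)) / (Phi(b) - Phi(a))` with
#' standardized bounds; used as the analytic check on sheared insert lengths.
#'
#' @param mean_bp,sd_bp Untruncated mean and standard deviation.
#' @param min_bp,max_bp Truncation bounds.
#' @return The truncated mean.
#' @export
truncated_normal_mean <- function(mean_bp, sd_bp, min_bp, max_bp) {
  if (sd_bp == 0) return(mean_bp)
  a <- (min_bp - mean_bp) / sd_bp
  b <- (max_bp - mean_bp) / sd_bp
  mean_bp + sd_bp * (stats::dnorm(a) - stats::dnorm(b)) /
    (stats::pnorm(b) - stats::pnorm(a))
}

#' Shear a genome into random library inserts
#'
#' Draws `n` inserts: start positions uniform over the genome (all positions
#' on a circular genome; positions leaving room for the fragment on a linear
#' one), lengths from the length model, and orientation A/B as a fair coin
#' (non-directional entry cloning). Orientation A reads the genome `+` strand
#' toward the reporter; B the reverse.
#'
#' @param genome A `genome_annotation`; must be longer than the model's
#'   maximum fragment.
#' @param length_model A [fragment_length_model()].
#' @param n Number of inserts (>= 1).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return `data.frame` with columns `start` (0-based), `length`,
#'   `orientation` (`"A"`/`"B"`).
#' @export
shear <- function(genome, length_model, n, seed) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(length_model, "fragment_length_model"))
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  G <- genome$length
  if (G <= length_model$max_bp)
    stop("genome (", G, " bp) must be longer than the maximum fragment (",
         length_model$max_bp, " bp)")
  withr::with_seed(as.integer(seed), {
    len <- if (length_model$kind == "fixed") rep(length_model$mean_bp, n)
    else {
      out <- numeric(n)
      todo <- seq_len(n)
      while (length(todo)) {
        draw <- stats::rnorm(length(todo), length_model$mean_bp,
                             length_model$sd_bp)
        ok <- draw >= length_model$min_bp & draw <= length_model$max_bp
        out[todo[ok]] <- draw[ok]
        todo <- todo[!ok]
      }
      round(out)
    }
    start <- if (genome$circular) floor(stats::runif(n, 0, G))
    else floor(stats::runif(n, 0, G - len + 1))
    orientation <- ifelse(stats::runif(n) < 0.5, "A", "B")
  })
  data.frame(start = start, length = len, orientation = orientation,
             stringsAsFactors = FALSE)
}
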