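#' Exact GFP-positive fraction by exhaustive enumeration
#'
#' Enumerates every fragment placement of fixed length `L` — all `G` starts
#' on a circular genome (or `G - L + 1` on a linear one) times both
#' orientations — and counts the placements the trap rules score
#' GFP-positive. Requires absolute termination (`read_through = 0` for every
#' terminator) so that classification is deterministic; serves as the oracle
#' for the Monte Carlo estimator.
#'
#' @param genome A `genome_annotation` (all terminators with
#'   `read_through = 0`).
#' @param mode A [vector_mode()].
#' @param sigma A [sigma_model()] (a `bernoulli` model is materialized once
#'   from its own seed).
#' @param L Fixed fragment length in bp (`1 <= L <= genome length`).
#' @return The exact GFP-positive fraction in `[0, 1]`.
#' @examples
#' g1 <- toy_genome() # circular 1 kb, + promoter at 100, terminator at 400
#' gfp_fraction_exact(g1, vector_mode("promoterless"), sigma_model("all"), 200)
#' @export
gfp_fraction_exact <- function(genome, mode, sigma, L) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(mode, "vector_mode"), inherits(sigma, "sigma_model"))
  G <- genome$length
  if (L > G) stop("L exceeds genome length")
  if (L < 1) stop("L must be >= 1")
  if (any(terminators_of(genome)$read_through > 0))
    stop("exact enumeration requires read_through = 0 for all terminators")
  rec <- materialize_recognition(sigma, genome)
  nS <- if (genome$circular) G else G - L + 1
  total_fired <- 0
  for (orient in c("A", "B")) {
    sf <- .sense_features(genome, orient)
    fired <- logical(nS)
    mark <- function(p, offsets) {
      # starts s = p - o (mod G if circular); offsets is an integer vector
      if (!length(offsets)) return()
      sidx <- if (genome$circular) (p - offsets) %% G
      else { v <- p - offsets; v[v >= 0 & v <= G - L] }
      fired[sidx + 1] <<- TRUE
    }
    fire_prom <- function() {
      prom <- sf$prom[rec[sf$prom$id], , drop = FALSE]
      for (k in seq_len(nrow(prom))) {
        D <- prom$clear[k]
        if (orient == "A") {
          lo <- max(0, L - min(D, L))
          if (lo <= L - 1) mark(prom$pos[k], lo:(L - 1))
        } else {
          hi <- min(D, L - 1)
          if (hi >= 0) mark(prom$pos[k], 0:hi)
        }
      }
    }
    if (mode$kind == "promoterless") {
      fire_prom()
    } else {
      blocked <- logical(nS)
      tpos <- sf$term$pos
      for (t in tpos) {
        sidx <- if (genome$circular) (t - 0:(L - 1)) %% G
        else { v <- t - 0:(L - 1); v[v >= 0 & v <= G - L] }
        blocked[sidx + 1] <- TRUE
      }
      fired <- !blocked
      if (mode$internal_rescue) fire_prom()
    }
    total_fired <- total_fired + sum(fired)
  }
  total_fired / (2 * nS)
}

#' Binomial confidence interval for a proportion
#'
#' @param k Successes.
#' @param n Trials.
#' @param method `"normal"` (Wald) or `"wilson"`.
#' @param conf_level Two-sided confidence level.
#' @return Numeric `c(lower, upper)`, clipped to `[0, 1]`.
#' @export
binomial_ci <- function(k, n, method = c("normal", "wilson"),
                        conf_level = 0.95) {
  method <- match.arg(method)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- k / n
  if (method == "normal") {
    hw <- z * sqrt(p * (1 - p) / n)
    ci <- c(p - hw, p + hw)
  } else {
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    ci <- c(ctr - hw, ctr + hw)
  }
  pmin(1, pmax(0, ci))
}

#' Monte Carlo estimate of the GFP-positive library fraction
#'
#' Shears `n` inserts from the genome, classifies each under the vector mode
#' and recognition model, and returns the GFP-positive fraction with a
#' binomial confidence interval and a cause breakdown. Deterministic given
#' `seed`.
#'
#' @inheritParams classify_inserts
#' @param length_model A [fragment_length_model()].
#' @param n Number of inserts (>= 1).
#' @param seed Integer seed (drives shearing and any stochastic
#'   read-through).
#' @param ci_method `"normal"` or `"wilson"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @return A list of class `gfp_estimate`: `fraction`, `ci` (lower/upper),
#'   `n`, `n_positive`, `causes` (named counts), plus the configuration.
#' @export
estimate_gfp_fraction_mc <- function(genome, mode, sigma, length_model, n,
                                     seed, ci_method = c("normal", "wilson"),
                                     conf_level = 0.95) {
  ci_method <- match.arg(ci_method)
  inserts <- shear(genome, length_model, n, seed)
  cls <- classify_inserts(inserts, genome, mode, sigma,
                          seed = as.integer(seed) + 1L)
  k <- sum(cls$gfp_positive)
  structure(list(
    fraction = k / n,
    ci = binomial_ci(k, n, ci_method, conf_level),
    n = n, n_positive = k,
    causes = table(cls$cause),
    mode = mode$kind, internal_rescue = mode$internal_rescue,
    sigma = sigma$kind, seed = as.integer(seed),
    conf_level = conf_level, ci_method = ci_method),
    class = "gfp_estimate")
}

#' @export
print.gfp_estimate <- function(x, ...) {
  cat(sprintf("GFP+ fraction: %.4f (%d/%d inserts; %.1f%% CI %.4f-%.4f)\n",
              x$fraction, x$n_positive, x$n, 100 * x$conf_level,
              x$ci[1], x$ci[2]))
  cat(sprintf("  mode: %s%s, sigma: %s\n", x$mode,
              if (x$internal_rescue) " (internal rescue)" else "", x$sigma))
  invisible(x)
}

#' Estimate the recognized-promoter fraction from observed expression
#'
#' The fraction of promoters a host recognizes, inferred as the ratio of the
#' observed GFP-positive library fraction to the predicted maximum (the
#' fraction under full recognition). For example, an observed 23%
#' GFP-positive population against a predicted maximum of 25% implies 92% of
#' promoters recognized.
#'
#' @param observed_fraction Observed GFP-positive fraction (>= 0).
#' @param predicted_max_fraction Predicted fraction under full recognition
#'   (in `(0, 1]`).
#' @return A list: `estimate` (ratio clipped to `[0, 1]`), `raw` (unclipped
#'   ratio), `clipped` (logical).
#' @examples
#' estimate_recognized_fraction(0.23, 0.25)$estimate  # 0.92
#' @export
estimate_recognized_fraction <- function(observed_fraction,
                                         predicted_max_fraction) {
  if (!is.numeric(predicted_max_fraction) || predicted_max_fraction <= 0 ||
      predicted_max_fraction > 1)
    stop("predicted_max_fraction must be in (0, 1]")
  if (observed_fraction < 0) stop("observed_fraction must be >= 0")
  raw <- observed_fraction / predicted_max_fraction
  est <- min(1, max(0, raw))
  list(estimate = est, raw = raw, clipped = !identical(est, raw))
}
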