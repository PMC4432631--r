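test_that("exact enumeration reproduces the hand-enumerated toy fractions", {
  pl <- vector_mode("promoterless"); all_s <- sigma_model("all")
  g1 <- toy_genome()
  expect_equal(gfp_fraction_exact(g1, pl, all_s, 200), 0.10)
  expect_equal(gfp_fraction_exact(toy_genome(terminator = 150), pl, all_s,
                                  200), 0.025)
  expect_equal(gfp_fraction_exact(g1, pl, sigma_model("none"), 200), 0)
  expect_equal(gfp_fraction_exact(toy_genome(terminator = NA),
                                  vector_mode("upstream_promoter"), all_s,
                                  350), 1)
  expect_error(gfp_fraction_exact(g1, pl, all_s, 2000), "exceeds")
})

test_that("exact enumeration agrees with the brute-force oracle", {
  set.seed(0)
  modes <- list(vector_mode("promoterless"),
                vector_mode("upstream_promoter"),
                vector_mode("upstream_promoter", internal_rescue = TRUE))
  for (seed in 1:4) {
    g <- random_small_genome(seed, n_units = 6)
    sig <- if (seed %% 2) sigma_model("all")
           else sigma_model("bernoulli", p_rec = 0.6, seed = seed)
    L <- c(120, 251)[seed %% 2 + 1]
    for (m in modes) {
      expect_equal(gfp_fraction_exact(g, m, sig, L),
                   naive_gfp_fraction(g, m, sig, L),
                   info = sprintf("seed %d mode %s", seed, m$kind))
    }
  }
  # linear genome: restricted start range
  glin <- random_small_genome(50, n_units = 5, circular = FALSE)
  for (m in modes[1:2]) {
    expect_equal(gfp_fraction_exact(glin, m, sigma_model("all"), 200),
                 naive_gfp_fraction(glin, m, sigma_model("all"), 200))
  }
})

test_that("Monte Carlo estimate matches the exact fraction within 3 s.e.", {
  g1 <- toy_genome()
  pl <- vector_mode("promoterless"); all_s <- sigma_model("all")
  p <- gfp_fraction_exact(g1, pl, all_s, 200)
  est <- estimate_gfp_fraction_mc(g1, pl, all_s,
                                  fragment_length_model("fixed", 200),
                                  1e5, seed = 21)
  expect_lt(abs(est$fraction - p), 3 * sqrt(p * (1 - p) / 1e5))
  expect_true(est$ci[1] <= est$fraction && est$fraction <= est$ci[2])
  # sigma = none is exactly zero
  est0 <- estimate_gfp_fraction_mc(g1, pl, sigma_model("none"),
                                   fragment_length_model("fixed", 200),
                                   1e4, seed = 21)
  expect_equal(est0$fraction, 0)
})

test_that("GFP+ fraction is monotone in promoter recognition", {
  g <- random_small_genome(7, n_units = 12)
  pl <- vector_mode("promoterless")
  ids <- promoters_of(g)$id
  u <- withr::with_seed(99, stats::runif(length(ids)))
  fractions <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(p) {
    rec <- ids[u <= p]  # nested subsets as p grows
    sig <- if (length(rec)) sigma_model("subset", recognized_ids = rec)
           else sigma_model("none")
    gfp_fraction_exact(g, pl, sig, 200)
  }, numeric(1))
  expect_equal(fractions[1], 0)  # p_rec = 0 -> nothing fires
  expect_true(all(diff(fractions) >= 0))
})

test_that("adding a terminator never increases the GFP+ fraction", {
  free <- toy_genome(terminator = NA)
  with_t <- toy_genome(terminator = 400)
  for (m in list(vector_mode("promoterless"),
                 vector_mode("upstream_promoter"))) {
    expect_lte(gfp_fraction_exact(with_t, m, sigma_model("all"), 300),
               gfp_fraction_exact(free, m, sigma_model("all"), 300))
  }
  # same comparison on a multi-unit genome, removing one terminator
  g <- random_small_genome(15, n_units = 8)
  g_less <- g
  g_less$units$terminator_pos[3] <- NA
  g_less$units$terminator_id[3] <- NA
  for (m in list(vector_mode("promoterless"),
                 vector_mode("upstream_promoter"))) {
    expect_lte(gfp_fraction_exact(g, m, sigma_model("all"), 250),
               gfp_fraction_exact(g_less, m, sigma_model("all"), 250))
  }
})

test_that("insert-length limits behave as the trap design predicts", {
  g <- random_small_genome(23, n_units = 8)
  pl_small <- gfp_fraction_exact(g, vector_mode("promoterless"),
                                 sigma_model("all"), 1)
  expect_lt(pl_small, 0.01)  # almost no fragment carries a promoter
  up_small <- gfp_fraction_exact(g, vector_mode("upstream_promoter"),
                                 sigma_model("all"), 1)
  expect_gt(up_small, 0.99)  # almost no fragment carries a terminator
  # and promoterless fractions grow with fragment length
  fr <- vapply(c(50, 200, 500), function(L)
    gfp_fraction_exact(g, vector_mode("promoterless"), sigma_model("all"), L),
    numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("recognized-fraction inference is the clipped observed/predicted ratio", {
  expect_equal(estimate_recognized_fraction(0.23, 0.25)$estimate, 0.92)
  expect_equal(estimate_recognized_fraction(0.065, 0.25)$estimate, 0.26)
  expect_equal(estimate_recognized_fraction(0.4, 0.4)$estimate, 1)
  over <- estimate_recognized_fraction(0.3, 0.25)
  expect_equal(over$estimate, 1)
  expect_true(over$clipped)
  expect_equal(over$raw, 1.2)
  expect_error(estimate_recognized_fraction(0.2, 0), "predicted_max")
})

test_that("run reports are reproducible and self-describing", {
  g1 <- toy_genome()
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  for (d in c(d1, d2))
    run_trap_simulation(g1, vector_mode("promoterless"), sigma_model("all"),
                        fragment_length_model("fixed", 200), 2000, seed = 31,
                        out_dir = d, write_bed = TRUE)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  rep <- jsonlite::read_json(file.path(d1, "report.json"))
  expect_equal(rep$seed, 31)
  expect_equal(rep$n, 2000)
  expect_equal(rep$gfp_fraction, rep$n_positive / rep$n)
  bed <- readLines(file.path(d1, "inserts.bed"))
  expect_gte(length(bed), 2000)  # wrapped inserts add lines
})
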