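test_that("fixed-length shearing gives constant lengths, uniform coverage", {
  g <- toy_genome(length = 5000)
  ins <- shear(g, fragment_length_model("fixed", 200), 1000, seed = 1)
  expect_true(all(ins$length == 200))
  expect_true(all(ins$start >= 0 & ins$start < 5000))
  expect_true(all(ins$orientation %in% c("A", "B")))
})

test_that("shearing is deterministic given the seed", {
  g <- toy_genome(length = 5000)
  lm <- fragment_length_model("truncated_normal", 726, sd_bp = 150)
  expect_identical(shear(g, lm, 500, seed = 3), shear(g, lm, 500, seed = 3))
  expect_false(identical(shear(g, lm, 500, seed = 3),
                         shear(g, lm, 500, seed = 4)))
})

test_that("truncated-normal lengths match the analytic truncated mean", {
  g <- toy_genome(length = 50000)
  lm <- fragment_length_model("truncated_normal", 726, sd_bp = 150,
                              min_bp = 200, max_bp = 1000)
  # pool several seeds so the check is on 3e5 draws
  len <- unlist(lapply(5:7, function(s) shear(g, lm, 1e5, seed = s)$length))
  expect_true(all(len >= 200 & len <= 1000))
  mu <- truncated_normal_mean(726, 150, 200, 1000)
  se <- stats::sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - mu), 3 * se)
})

test_that("shear rejects degenerate inputs", {
  g <- toy_genome(length = 900)  # shorter than the 1000 bp max fragment
  lm <- fragment_length_model("truncated_normal", 726, sd_bp = 150)
  expect_error(shear(g, lm, 10, seed = 1), "longer than")
  expect_error(shear(toy_genome(length = 5000), lm, 0, seed = 1), ">= 1")
})

test_that("linear genomes never yield wrapping inserts", {
  g <- toy_genome(length = 2000, circular = FALSE)
  ins <- shear(g, fragment_length_model("fixed", 300), 2000, seed = 8)
  expect_true(all(ins$start + ins$length <= 2000))
})

test_that("single-insert classification follows the trap rules", {
  g1 <- toy_genome()  # + promoter at 100, + terminator at 400, circular 1 kb
  pl <- vector_mode("promoterless")
  up <- vector_mode("upstream_promoter")
  all_s <- sigma_model("all")

  # no features inside -> negative
  r <- classify_insert(500, 200, "A", g1, pl, all_s)
  expect_false(r$gfp_positive); expect_equal(r$cause, "none")
  # sense promoter inside, no blocking terminator -> fires
  r <- classify_insert(50, 200, "A", g1, pl, all_s)
  expect_true(r$gfp_positive)
  expect_equal(r$cause, "promoter_fired")
  expect_equal(r$promoter_id, "P1")
  # upstream mode with a sense terminator inside -> blocked
  r <- classify_insert(300, 200, "A", g1, up, all_s)
  expect_false(r$gfp_positive)
  expect_equal(r$blocking_terminator, "T1")
  # no recognition -> never fires, promoters or not
  r <- classify_insert(50, 200, "A", g1, pl, sigma_model("none"))
  expect_false(r$gfp_positive)
  # antisense orientation sees no + promoter
  r <- classify_insert(50, 200, "B", g1, pl, all_s)
  expect_false(r$gfp_positive)
})

test_that("boundary conventions: promoter at start fires, terminator at the
           reporter-proximal boundary does not block", {
  g1 <- toy_genome()
  pl <- vector_mode("promoterless"); all_s <- sigma_model("all")
  # promoter exactly at the insert start offset counts as inside
  expect_true(classify_insert(100, 200, "A", g1, pl, all_s)$gfp_positive)
  # promoter just past the half-open end is outside
  expect_false(classify_insert(900, 200, "A", g1, pl, all_s)$gfp_positive)
  # terminator between promoter and reporter end blocks...
  gb <- toy_genome(terminator = 150)
  expect_false(classify_insert(60, 200, "A", gb, pl, all_s)$gfp_positive)
  # ...but an insert whose reporter-proximal end coincides with the
  # terminator point still fires (strict betweenness, half-open end)
  expect_true(classify_insert(-50 %% 1000, 200, "A", gb, pl,
                              all_s)$gfp_positive)
  # orientation B: terminator occupying the insert start coordinate is at
  # the reporter-proximal boundary and never blocks
  gm <- toy_genome(strand = "-", promoter = 400, terminator = 100)
  expect_true(classify_insert(100, 350, "B", gm, pl, all_s)$gfp_positive)
  expect_false(classify_insert(50, 400, "B", gm, pl, all_s)$gfp_positive)
})

test_that("wrapping inserts are classified on circular genomes only", {
  g1 <- toy_genome()
  r <- classify_insert(950, 200, "A", g1, vector_mode("promoterless"),
                       sigma_model("all"))
  expect_true(r$gfp_positive)  # wraps over the origin and covers 100
  glin <- toy_genome(circular = FALSE)
  expect_error(classify_insert(950, 200, "A", glin,
                               vector_mode("promoterless"),
                               sigma_model("all")),
               "linear")
})

test_that("read-through probability 1 makes terminators transparent", {
  g <- toy_genome(read_through = 1)
  up <- vector_mode("upstream_promoter")
  r <- classify_insert(300, 200, "A", g, up, sigma_model("all"), seed = 2)
  expect_true(r$gfp_positive)
})

test_that("internal rescue recovers blocked inserts with a clear promoter", {
  # insert containing terminator then (in transcription direction) a clear
  # promoter: blocked without rescue, positive with it
  g2 <- genome_annotation(
    name = "two", length = 2000, circular = TRUE,
    units = data.frame(id = c("U1", "U2"), strand = "+",
                       promoter_id = c("P1", "P2"),
                       promoter_pos = c(100, 700),
                       terminator_id = c("T1", "T2"),
                       terminator_pos = c(400, 1100), read_through = 0,
                       stringsAsFactors = FALSE),
    genes = data.frame(id = c("a", "b"), start = c(100, 700),
                       end = c(401, 1101), strand = "+",
                       unit_id = c("U1", "U2"), stringsAsFactors = FALSE))
  all_s <- sigma_model("all")
  ins <- c(start = 350, length = 400, orientation = "A")  # covers T1 and P2
  r0 <- classify_insert(350, 400, "A", g2, vector_mode("upstream_promoter"),
                        all_s)
  expect_false(r0$gfp_positive)
  r1 <- classify_insert(350, 400, "A", g2,
                        vector_mode("upstream_promoter",
                                    internal_rescue = TRUE), all_s)
  expect_true(r1$gfp_positive)
  expect_equal(r1$cause, "promoter_fired")
  expect_equal(r1$promoter_id, "P2")
})

test_that("subset and bernoulli sigma models materialize reproducibly", {
  g <- generate_genome(synthetic_genome_params(n_units = 50, seed = 6))
  sub <- sigma_model("subset", recognized_ids = c("P1", "P10"))
  rec <- materialize_recognition(sub, g)
  expect_equal(sum(rec), 2)
  expect_true(all(rec[c("P1", "P10")]))
  expect_error(materialize_recognition(
    sigma_model("subset", recognized_ids = "nope"), g), "unknown")
  b <- sigma_model("bernoulli", p_rec = 0.3, seed = 9)
  expect_identical(materialize_recognition(b, g),
                   materialize_recognition(b, g))
})
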