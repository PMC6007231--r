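test_that("detectability is a pure bounded function of the peptide string", {
  p <- c("PEPTIDEK", "AAAAAAA", "WWWWWWWWWW")
  expect_equal(predict_detectability(p), predict_detectability(p))
  set.seed(71)
  peps <- vapply(sample(5:40, 300, replace = TRUE),
                 function(L) random_aa(L), "")
  raw <- predict_detectability(peps)
  expect_true(all(raw >= 0 & raw <= 1))
  expect_error(predict_detectability("PEPB"), "invalid")
})

test_that("calibration recovers a monotone ground truth and stays monotone", {
  set.seed(72)
  peps <- vapply(sample(7:30, 4000, replace = TRUE),
                 function(L) random_aa(L), "")
  raw <- predict_detectability(peps)
  p_true <- detection_probability(peps)
  identified <- runif(length(peps)) < p_true
  tr <- calibrate_detectability(raw, identified)
  s_hat <- attr(tr, "bin_s")
  expect_false(is.unsorted(s_hat))           # PAVA contract
  expect_true(all(tr(runif(100)) >= 0 & tr(runif(100)) <= 1))
  # per-bin recovery of the true detection frequency
  expect_gt(cor(s_hat, seq_along(s_hat), method = "spearman"), 0.9)
})

test_that("degenerate calibrations fall back gracefully", {
  expect_warning(tr0 <- calibrate_detectability(numeric(0), logical(0)),
                 "identity")
  expect_equal(tr0(c(0.2, 0.9)), c(0.2, 0.9))
  # all peptides identified -> constant transform at 1
  tr1 <- calibrate_detectability(runif(50), rep(TRUE, 50))
  expect_true(all(tr1(runif(20)) == 1))
})

test_that("a single SAP produces the differing tryptic peptide pair in V and R", {
  # reference ...K | AAAWAAA | K... ; TGE swaps W -> C inside one peptide
  ref <- "MGGGKAAAWAAAKGGGDDDD"
  tge <- "MGGGKAAACAAAKGGGDDDD"
  aln <- align_local(tge, ref)
  ev <- extract_events(aln)
  expect_equal(ev$type, "SAP")
  sets <- build_peptide_sets(tge, ref, ev, aln)
  expect_equal(sets$V$peptide, "AAACAAAK")
  expect_equal(sets$R$peptide, "AAAWAAAK")
})

test_that("an identical pair has empty discriminating sets", {
  ref <- "MGGGKAAAWAAAKGGGDDDD"
  aln <- align_local(ref, ref)
  sets <- build_peptide_sets(ref, ref, extract_events(aln), aln)
  expect_equal(nrow(sets$V), 0)
  expect_equal(nrow(sets$R), 0)
  expect_error(score_variant_vs_reference(sets, c(), identity),
               "undefined")
})

test_that("the worked scoring example evaluates exactly", {
  # V = one identified peptide (q = 0.01), R = one unidentified (s = 0.8)
  sets <- list(V = data.frame(peptide = "AAAAAAAV", start = 1, end = 8),
               R = data.frame(peptide = "CCCCCCCC", start = 1, end = 8))
  sc <- score_variant_vs_reference(
    sets, identified_q = c(AAAAAAAV = 0.01),
    s_transform = identity,
    detectability = function(p) rep(0.8, length(p)))
  expect_equal(sc$score_variant, 0.545, tolerance = 1e-12)
  expect_equal(sc$score_reference, -0.17375, tolerance = 1e-12)
  expect_equal(sc$decision, "variant")
})

test_that("both-identified symmetric case lands undecided", {
  sets <- list(V = data.frame(peptide = "AAAAAAAV", start = 1, end = 8),
               R = data.frame(peptide = "CCCCCCCC", start = 1, end = 8))
  sc <- score_variant_vs_reference(
    sets, identified_q = c(AAAAAAAV = 0, CCCCCCCC = 0),
    s_transform = identity)
  expect_equal(sc$score_variant, 0.375, tolerance = 1e-12)
  expect_equal(sc$score_reference, 0.375, tolerance = 1e-12)
  expect_equal(sc$decision, "undecided")
})

test_that("score sum identity and bounds hold on random instances", {
  set.seed(73)
  for (k in 1:200) {
    inst <- random_score_instance()
    sc <- score_variant_vs_reference(inst$sets, inst$identified_q,
                                     inst$s_transform,
                                     detectability = inst$detectability)
    n <- sc$n_V + sc$n_R
    expect_equal(sc$score_variant + sc$score_reference,
                 0.75 * inst$q_sum_identified / n, tolerance = 1e-12)
    expect_gte(sc$score_variant, -0.25 - 1e-12)
    expect_lte(sc$score_variant, 1 + 1e-12)
    expect_gte(sc$score_reference, -0.25 - 1e-12)
    expect_lte(sc$score_reference, 1 + 1e-12)
  }
})

test_that("scores are antisymmetric when nothing is identified", {
  set.seed(74)
  for (k in 1:100) {
    inst <- random_score_instance()
    sc <- score_variant_vs_reference(inst$sets, c(), inst$s_transform,
                                     detectability = inst$detectability)
    expect_equal(sc$score_variant, -sc$score_reference, tolerance = 1e-12)
  }
})

test_that("score_variant is monotone in identification confidence and detectability", {
  sets <- list(V = data.frame(peptide = c("AAAAAAAV", "DDDDDDDD")),
               R = data.frame(peptide = "CCCCCCCC"))
  base_detect <- function(s_a) {
    function(p) ifelse(p == "DDDDDDDD", s_a, 0.5)
  }
  score_at <- function(q_a, s_a) {
    score_variant_vs_reference(
      sets, identified_q = c(AAAAAAAV = q_a), s_transform = identity,
      detectability = base_detect(s_a))$score_variant
  }
  # lower q for an identified variant peptide never decreases the score
  expect_gte(score_at(0.001, 0.5), score_at(0.009, 0.5))
  # higher s for an unidentified variant peptide never increases it
  expect_lte(score_at(0.005, 0.9), score_at(0.005, 0.1))
})

test_that("identified peptides above the FDR threshold count as unidentified", {
  sets <- list(V = data.frame(peptide = "AAAAAAAV"),
               R = data.frame(peptide = "CCCCCCCC"))
  sc <- score_variant_vs_reference(
    sets, identified_q = c(AAAAAAAV = 0.05),  # above the 0.01 default
    s_transform = identity, detectability = function(p) rep(0.4, length(p)))
  expect_equal(length(sc$A), 0)
  expect_equal(sc$A_prime, "AAAAAAAV")
})

test_that("the evidence rating ladder orders the evidence tiers", {
  expect_equal(rate_tge(TRUE, TRUE, "variant", TRUE), 5L)
  expect_equal(rate_tge(FALSE, TRUE, "undecided", TRUE), 4L)
  expect_equal(rate_tge(FALSE, FALSE, "variant", TRUE), 3L)
  expect_equal(rate_tge(FALSE, FALSE, "undecided", TRUE), 2L)
  expect_equal(rate_tge(FALSE, FALSE, NA_character_, FALSE), 1L)
})
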