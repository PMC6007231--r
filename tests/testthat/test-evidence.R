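psm_row <- function(id, pep, q = 0.001, score = NA_real_, decoy = FALSE) {
  data.frame(spectrum_id = id, peptide = pep, accessions = I(list("X")),
             q_value = q, search_score = score, is_decoy = decoy,
             stringsAsFactors = FALSE)
}

test_that("target-decoy q-values follow the cumulative-minimum FDR definition", {
  psms <- rbind(psm_row("t1", "AAAAAAA", score = 10),
                psm_row("d1", "CCCCCCC", score = 9, decoy = TRUE),
                psm_row("t2", "DDDDDDD", score = 8))
  out <- compute_qvalues(psms)
  expect_equal(nrow(out), 2)  # decoys removed
  expect_equal(out$q_value[out$spectrum_id == "t1"], 0)
  expect_equal(out$q_value[out$spectrum_id == "t2"], 1 / 2)
})

test_that("q-values without decoys are all zero; all-decoy input empties", {
  psms <- rbind(psm_row("t1", "AAAAAAA", score = 5),
                psm_row("t2", "CCCCCCC", score = 3))
  expect_equal(compute_qvalues(psms)$q_value, c(0, 0))
  decoys <- rbind(psm_row("d1", "AAAAAAA", score = 5, decoy = TRUE))
  expect_equal(nrow(compute_qvalues(decoys)), 0)
  expect_error(compute_qvalues(psm_row("t", "AAA")), "search_score")
})

orfs_fixture <- function() {
  data.frame(
    orf_id = c("o1.p1", "o2.p1", "o3.p1", "o4.p1"),
    transcript_id = c("o1", "o2", "o3", "o4"),
    aa_sequence = c("MAAAPEPTIDEKGGGWCDEFGHIK",   # two peptides
                    "MAAAPEPTIDEKGGGWCDEFGHIK",   # duplicate of o1
                    "MWWWPEPTIDEKVVVV",           # shares one peptide
                    "MHHHHHHNNNNNN"),             # no peptides
    completeness = c("complete", "5prime_partial", "complete", "complete"),
    stringsAsFactors = FALSE)
}

test_that("TGE retention demands >= 2 distinct peptides and merges duplicate ORFs", {
  psms <- rbind(psm_row("s1", "PEPTIDEK", q = 0.001),
                psm_row("s2", "WCDEFGHIK", q = 0.002),
                psm_row("s3", "PEPTIDEK", q = 0.005))
  ts <- build_tge_set(orfs_fixture(), psms)
  # o1+o2 merge into one TGE with two members; o3 has only one peptide
  expect_equal(nrow(ts$tges), 1)
  expect_equal(ts$tges$orf_ids, "o1.p1;o2.p1")
  expect_true(ts$tges$is_complete_orf)
  # peptide q is the minimum over contributing PSMs
  expect_equal(unique(ts$evidence$q_value[ts$evidence$peptide == "PEPTIDEK"]),
               0.001)
  # a peptide hitting both members of one merged TGE is still unique
  expect_true(all(ts$evidence$is_unique))
})

test_that("PSMs above the q-value threshold are excluded", {
  psms <- rbind(psm_row("s1", "PEPTIDEK", q = 0.011),
                psm_row("s2", "WCDEFGHIK", q = 0.002),
                psm_row("s3", "GGGWCDEFGHIK", q = 0.002))
  # PEPTIDEK at q = 0.011 does not survive the 1% threshold, so o1/o2
  # retain two peptides only through the overlapping GGG... peptide
  ts <- build_tge_set(orfs_fixture(), psms, q_threshold = 0.01)
  expect_false("PEPTIDEK" %in% ts$evidence$peptide)
  expect_equal(nrow(ts$tges), 1)
})

test_that("retention filters are monotone in their thresholds", {
  set.seed(51)
  ref <- make_reference(n_reference = 10, seed = 51)
  fx <- make_variant_tges(ref, c(SAP = 4, known_protein = 3), seed = 51)
  psms <- simulate_psms(fx$orfs, seed = 51)
  strict <- build_tge_set(fx$orfs, psms, q_threshold = 0.005,
                          min_peptides = 3)
  loose <- build_tge_set(fx$orfs, psms, q_threshold = 0.01, min_peptides = 2)
  expect_true(all(strict$tges$tge_id %in% loose$tges$tge_id))
})

test_that("ambiguity groups join identical peptide sets and strict subsets", {
  orfs <- data.frame(
    orf_id = c("a.p1", "b.p1", "c.p1"),
    transcript_id = c("a", "b", "c"),
    aa_sequence = c("MPEPTIDEKAAAWCDEFGHIKCCC",
                    "MPEPTIDEKGGGWCDEFGHIKCCC",     # same peptide set as a
                    "MPEPTIDEKTTTYYYYAAAAKWCDEFGHIKHHHHVVVK"),
    completeness = "complete", stringsAsFactors = FALSE)
  psms <- rbind(psm_row("s1", "PEPTIDEK"), psm_row("s2", "WCDEFGHIK"),
                psm_row("s3", "HHHHVVVK"))
  ts <- build_tge_set(orfs, psms)
  g <- setNames(ts$ambiguity_groups$group_id, ts$ambiguity_groups$tge_id)
  expect_equal(g[["a.p1"]], g[["b.p1"]])   # identical sets
  expect_equal(g[["a.p1"]], g[["c.p1"]])   # strict subset attached
})

test_that("variant-overlap and junction flags follow the interval rules", {
  # TGE of length 100 fully aligned with one SAP at position 50
  q <- paste0(strrep("A", 49), "W", strrep("A", 50))
  s <- strrep("A", 100)
  aln <- data.frame(query_id = "t", subject_id = "r", raw_score = 0,
                    bit_score = 0, e_value = 1e-60, q_start = 1, q_end = 100,
                    s_start = 1, s_end = 100, q_aln = q, s_aln = s,
                    midline = compute_midline(q, s), stringsAsFactors = FALSE)
  events <- extract_events(aln)
  ev <- data.frame(
    peptide = c("P1", "P2", "P3"), q_value = 0.001, tge_id = "t",
    start = c(45L, 30L, 50L), end = c(55L, 40L, 50L),
    is_unique = TRUE, overlaps_variant = FALSE, is_junction = FALSE,
    stringsAsFactors = FALSE)
  out <- flag_variant_peptides(ev, "t", events, NULL, aln, 100)
  expect_equal(out$overlaps_variant, c(TRUE, FALSE, TRUE))
  # spanning the SAP and identical sequence -> junction; the SAP alone -> not
  expect_equal(out$is_junction, c(TRUE, FALSE, FALSE))
})

test_that("terminal overhangs are variant regions; peptides inside them are not junctions", {
  # alignment covers 21..100 of the TGE: 1..20 is a novel N-overhang
  q <- strrep("A", 80)
  aln <- data.frame(query_id = "t", subject_id = "r", raw_score = 0,
                    bit_score = 0, e_value = 1e-60, q_start = 21, q_end = 100,
                    s_start = 1, s_end = 80, q_aln = q, s_aln = q,
                    midline = q, stringsAsFactors = FALSE)
  ev <- data.frame(
    peptide = c("P1", "P2", "P3"), q_value = 0.001, tge_id = "t",
    start = c(30L, 5L, 15L), end = c(40L, 12L, 30L),
    is_unique = TRUE, overlaps_variant = FALSE, is_junction = FALSE,
    stringsAsFactors = FALSE)
  out <- flag_variant_peptides(ev, "t", NULL, NULL, aln, 100)
  expect_equal(out$overlaps_variant, c(FALSE, TRUE, TRUE))
  expect_equal(out$is_junction, c(FALSE, FALSE, TRUE))
})

test_that("coverage is the union fraction of residues under peptides", {
  ev <- data.frame(peptide = c("X", "Y"), q_value = 0, tge_id = "t",
                   start = c(1L, 6L), end = c(10L, 10L), is_unique = TRUE,
                   overlaps_variant = FALSE, is_junction = FALSE,
                   stringsAsFactors = FALSE)
  expect_equal(coverage(100, ev, "t"), 0.10)  # overlap counted once
  expect_equal(coverage(100, ev[0, ], "t"), 0)
})
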