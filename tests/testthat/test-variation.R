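# build a gap-free alignment row covering both sequences fully
full_aln <- function(q, s, q_start = 1, s_start = 1) {
  data.frame(query_id = "q", subject_id = "s", raw_score = 0, bit_score = 0,
             e_value = 1e-40, q_start = q_start,
             q_end = q_start + nchar(gsub("-", "", q)) - 1,
             s_start = s_start,
             s_end = s_start + nchar(gsub("-", "", s)) - 1,
             q_aln = q, s_aln = s, midline = compute_midline(q, s),
             stringsAsFactors = FALSE)
}

test_that("a single substitution becomes SAP or SSAP according to BLOSUM80", {
  # D vs N scores positively in BLOSUM80, so this is a similar SAP
  expect_gt(blosum80()["D", "N"], 0)
  ev <- extract_events(full_aln("ACDEFG", "ACNEFG"))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SSAP")
  expect_equal(ev$tge_start, 3L)
  expect_equal(ev$tge_seq, "D")
  expect_equal(ev$ref_seq, "N")
  # G vs W scores negatively: a plain SAP
  ev2 <- extract_events(full_aln("ACGEFG", "ACWEFG"))
  expect_equal(ev2$type, "SAP")
})

test_that("substitution-run length draws the ALT/SALT/SV boundaries", {
  base <- strrep("A", 30)
  mk <- function(n) {
    # n mismatching columns in the middle against W (negative vs everything
    # aligned here)
    q <- paste0(strrep("A", 10), strrep("W", n), strrep("A", 20 - n),
                collapse = "")
    full_aln(q, base)
  }
  expect_equal(extract_events(mk(2))$type, "ALT")
  expect_equal(extract_events(mk(9))$type, "ALT")   # 9 is still ALT
  expect_equal(extract_events(mk(10))$type, "SV")   # 10 crosses into SV
})

test_that("an all-similar run is SALT, a mixed run ALT", {
  # L/I and D/N are positive pairs in BLOSUM80
  ev <- extract_events(full_aln("AALDAA", "AAINAA"))
  expect_equal(ev$type, "SALT")
  ev2 <- extract_events(full_aln("AALGAA", "AAIWAA"))  # G/W negative
  expect_equal(ev2$type, "ALT")
})

test_that("gap events carry the deletion/insertion anchor conventions", {
  ev <- extract_events(full_aln("AC-EF", "ACDEF"))
  expect_equal(ev$type, "DEL")
  expect_equal(ev$ref_seq, "D")
  expect_equal(ev$tge_seq, "")
  expect_equal(ev$tge_start, 2L)  # residue immediately left of the gap
  expect_equal(ev$tge_end, 2L)
  expect_equal(ev$ref_start, 3L)
  expect_equal(ev$ref_end, 3L)

  ev2 <- extract_events(full_aln("ACDEF", "AC-EF"))
  expect_equal(ev2$type, "INS")
  expect_equal(ev2$tge_seq, "D")
  expect_equal(ev2$tge_start, 3L)
  expect_equal(ev2$ref_start, 2L)  # reference anchor left of the gap

  # a >= 10 residue gap is splice-scale
  ev3 <- extract_events(full_aln(paste0("ACDEF", strrep("-", 10), "GHIKL"),
                                 paste0("ACDEF", strrep("W", 10), "GHIKL")))
  expect_equal(ev3$type, "SV")
  expect_equal(ev3$tge_seq, "")
})

test_that("event extraction equals the column-labelling oracle on random alignments", {
  set.seed(31)
  for (k in 1:500) {
    aln <- random_alignment(sample(20:60, 1))
    got <- extract_events(aln)
    want <- events_oracle(aln$q_aln, aln$s_aln, aln$q_start, aln$s_start)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = sprintf("random alignment %d", k))
  }
})

test_that("every non-identity column belongs to exactly one event", {
  set.seed(32)
  for (k in 1:50) {
    aln <- random_alignment(40)
    ev <- extract_events(aln)
    qc <- strsplit(aln$q_aln, "")[[1]]
    sc <- strsplit(aln$s_aln, "")[[1]]
    n_nonid <- sum(!(qc == sc))
    n_cols <- sum(pmax(nchar(ev$tge_seq), nchar(ev$ref_seq)))
    expect_equal(n_cols, n_nonid)
  }
})

test_that("SSAP corresponds exactly to positive BLOSUM80 pairs over all 380 ordered pairs", {
  m <- blosum80()
  aa <- rownames(m)[rownames(m) %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]]
  for (x in aa) {
    for (y in setdiff(aa, x)) {
      ev <- extract_events(full_aln(paste0("AAAA", x, "AAAA"),
                                    paste0("AAAA", y, "AAAA")))
      expect_equal(ev$type, if (m[x, y] > 0) "SSAP" else "SAP",
                   info = paste(x, y))
    }
  }
})

test_that("terminal classification follows the coordinate grid", {
  aln <- full_aln(strrep("A", 50), strrep("A", 50), q_start = 1, s_start = 21)
  t1 <- classify_terminals(aln, tge_len = 50, ref_len = 70)
  expect_equal(t1$kind, c("truncated", "identical"))
  expect_equal(t1$ref_overhang[1], 20L)

  aln2 <- full_aln(strrep("A", 40), strrep("A", 40), q_start = 5, s_start = 1)
  t2 <- classify_terminals(aln2, tge_len = 44, ref_len = 40)
  expect_equal(t2$kind[1], "extended")
  expect_equal(t2$tge_overhang[1], 4L)

  t3 <- classify_terminals(full_aln(strrep("A", 30), strrep("A", 30)),
                           tge_len = 30, ref_len = 30)
  expect_equal(t3$kind, c("identical", "identical"))

  expect_error(classify_terminals(aln, tge_len = 10, ref_len = 70), "bounds")
})

test_that("subclass assignment partitions candidates over the 17 labels", {
  term <- function(nk, ck) {
    data.frame(terminus = c("N", "C"), kind = c(nk, ck),
               tge_overhang = c(0L, 0L), ref_overhang = c(0L, 0L),
               stringsAsFactors = FALSE)
  }
  main <- list(label = "candidate_variant", best_hit = "R1")
  sap <- data.frame(type = "SAP", tge_start = 3L, tge_end = 3L,
                    ref_start = 3L, ref_end = 3L, tge_seq = "D",
                    ref_seq = "N", stringsAsFactors = FALSE)
  sv <- sap; sv$type <- "SV"

  r1 <- assign_subclass(main, sap, term("identical", "identical"))
  expect_equal(r1$main_class, "known_with_polymorphism")
  expect_true(is.na(r1$subclass))

  r2 <- assign_subclass(main, sv, term("identical", "identical"))
  expect_equal(r2$main_class, "novel_isoform")
  expect_equal(r2$subclass, "SV")

  kinds <- c("identical", "truncated", "extended", "alternative")
  labels <- character(0)
  for (nk in kinds) {
    for (ck in kinds) {
      if (nk == "identical" && ck == "identical") next
      r <- assign_subclass(main, sap[0, ], term(nk, ck))
      expect_equal(r$main_class, "novel_isoform")
      labels <- c(labels, r$subclass)
    }
  }
  expect_equal(length(unique(labels)), 15)  # the 15 terminal subclasses
  expect_true("N_alternative+C_truncated" %in% labels)
  expect_true("C_extended" %in% labels)

  expect_error(assign_subclass(list(label = "novel_tge", best_hit = NA),
                               sap, term("identical", "identical")),
               "candidate")
})

test_that("alternative starts are detected, discounted by K/R, and Met removal flagged", {
  ref <- paste0("M", strrep("A", 40), "K", "V", strrep("A", 30))  # K at 42
  aln <- full_aln(strrep("A", 20), strrep("A", 20), q_start = 1, s_start = 43)
  tge <- paste0("V", strrep("A", 19))
  r <- detect_alt_start(tge, aln, ref)
  expect_equal(r$category, "alt_start")
  expect_true(r$discounted)  # ref position 42 is lysine

  ref2 <- paste0("M", strrep("A", 40), "G", "V", strrep("A", 30))
  r2 <- detect_alt_start(tge, aln, ref2)
  expect_false(r2$discounted)
  expect_equal(r2$residue, "V")
  expect_equal(r2$ref_pos, 43L)

  # N-terminal Met removal: aligned from reference position 2
  ref3 <- paste0("MW", strrep("A", 30))
  aln3 <- full_aln(strrep("A", 10), strrep("A", 10), q_start = 1, s_start = 2)
  r3 <- detect_alt_start(paste0("W", strrep("A", 9)), aln3, ref3)
  expect_equal(r3$category, "met_removed")
  expect_false(r3$discounted)

  # a TGE starting with methionine aligned at reference position 1: nothing
  aln4 <- full_aln(strrep("A", 10), strrep("A", 10))
  expect_null(detect_alt_start(paste0("M", strrep("A", 9)), aln4,
                               paste0("M", strrep("A", 20))))
  # unaligned TGE start: nothing to report
  aln5 <- full_aln(strrep("A", 10), strrep("A", 10), q_start = 3, s_start = 1)
  expect_null(detect_alt_start(paste0("VV", strrep("A", 10)), aln5,
                               strrep("A", 20)))
})

test_that("replaying extracted events onto the reference reconstructs the TGE", {
  # round-trip identity for classified fixture TGEs
  ref <- make_reference(n_reference = 20, seed = 21)
  plan <- c(SAP = 3, SSAP = 3, ALT = 2, SALT = 2, INS = 3, DEL = 3, SV = 2)
  fx <- make_variant_tges(ref, plan, seed = 21)
  refseq <- setNames(ref$aa_sequence, ref$accession)
  for (i in seq_len(nrow(fx$orfs))) {
    tge <- fx$orfs$aa_sequence[i]
    acc <- fx$truth$ref_accession[i]
    aln <- align_local(tge, refseq[[acc]])
    ev <- extract_events(aln)
    # rebuild the aligned core from the reference using the events
    core <- substr(refseq[[acc]], aln$s_start, aln$s_end)
    if (nrow(ev) > 0) {
      o <- order(-ev$ref_start)
      for (k in o) {
        rs <- ev$ref_start[k] - aln$s_start + 1
        re <- ev$ref_end[k] - aln$s_start + 1
        if (ev$tge_seq[k] != "" && ev$ref_seq[k] == "") {
          core <- paste0(substr(core, 1, rs), ev$tge_seq[k],
                         substr(core, rs + 1, nchar(core)))
        } else if (ev$tge_seq[k] == "") {
          core <- paste0(substr(core, 1, rs - 1),
                         substr(core, re + 1, nchar(core)))
        } else {
          core <- paste0(substr(core, 1, rs - 1), ev$tge_seq[k],
                         substr(core, re + 1, nchar(core)))
        }
      }
    }
    rebuilt <- paste0(substr(tge, 1, aln$q_start - 1), core,
                      substr(tge, aln$q_end + 1, nchar(tge)))
    expect_equal(rebuilt, tge, info = fx$orfs$orf_id[i])
  }
})
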