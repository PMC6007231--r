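# 6-mer seeding prefilter: candidate reference subjects for each query are
# those sharing at least one k-mer (mirrors BLAST's word seeding; a query
# seeding no subject is aligned against nothing and falls through to novel)
.seed_candidates <- function(queries, subjects, k = 6) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(s)
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  idx <- new.env(parent = emptyenv())
  for (j in seq_along(subjects)) {
    for (km in kmers_of(subjects[j])) {
      assign(km, c(idx[[km]], j), envir = idx)
    }
  }
  lapply(queries, function(q) {
    hits <- unlist(lapply(kmers_of(q), function(km) idx[[km]]))
    sort(unique(hits))
  })
}

#' Align TGEs against a reference proteome
#'
#' Runs the internal local aligner for every TGE against every candidate
#' reference subject (candidates prefiltered by shared 6-mers, mirroring
#' BLAST seeding) and returns all positive-scoring alignments.
#'
#' @param tge_seqs Named character vector of TGE sequences.
#' @param reference Reference data frame.
#' @param gap_open,gap_extend,matrix Alignment parameters.
#' @return Alignment data frame.
#' @export
align_tges <- function(tge_seqs, reference, gap_open = 10, gap_extend = 1,
                       matrix = "BLOSUM80") {
  cand <- .seed_candidates(tge_seqs, reference$aa_sequence)
  per_subject <- vector("list", nrow(reference))
  for (j in seq_len(nrow(reference))) {
    qs <- which(vapply(cand, function(x) j %in% x, TRUE))
    if (length(qs) == 0) next
    per_subject[[j]] <- align_many(
      tge_seqs[qs], reference$aa_sequence[j],
      gap_open = gap_open, gap_extend = gap_extend, matrix = matrix,
      subject_id = reference$accession[j])
  }
  out <- do.call(rbind, per_subject[!vapply(per_subject, is.null, TRUE)])
  if (is.null(out)) {
    out <- .alignment_row(character(0), character(0), numeric(0),
                          integer(0), integer(0), integer(0), integer(0),
                          character(0), character(0), 1, 1)
  }
  out
}

.pct_identity <- function(aln) {
  mid <- strsplit(aln$midline, "")[[1]]
  100 * sum(mid %in% LETTERS) / length(mid)
}

#' Classify a retained TGE set against a reference proteome
#'
#' For each TGE: exact sequence equality against the reference decides known
#' protein / known isoform; otherwise the best qualifying alignment (e-value
#' at most `e_threshold`) makes it a candidate variant, resolved by event
#' extraction and terminal classification into known-with-polymorphism or a
#' novel-isoform subclass; no qualifying alignment means novel TGE.
#' Alternative starts are detected on the way.
#'
#' @param tge_set TGE set from [build_tge_set()].
#' @param reference Reference data frame.
#' @param alignments Optional precomputed alignment data frame (e.g. from
#'   [read_blast_xml()]); when supplied the internal aligner is skipped and
#'   the external e-values are authoritative.
#' @param e_threshold Qualifying e-value threshold (default 1e-30).
#' @param sv_min_length,alt_max_length Event-length thresholds.
#' @param gap_open,gap_extend,matrix Internal aligner parameters.
#' @return list of per-TGE records (`tge_id`, `main_class`, `subclass`,
#'   `best_hit`, `e_value`, `identity_pct`, `events`, `terminals`,
#'   `alt_start`, `aln`).
#' @export
classify_tges <- function(tge_set, reference, alignments = NULL,
                          e_threshold = 1e-30, sv_min_length = 10,
                          alt_max_length = 9, gap_open = 10, gap_extend = 1,
                          matrix = "BLOSUM80") {
  tges <- tge_set$tges
  seqs <- setNames(tges$aa_sequence, tges$tge_id)
  exact <- tges$aa_sequence %in% reference$aa_sequence
  if (is.null(alignments)) {
    alignments <- align_tges(seqs[!exact], reference, gap_open = gap_open,
                             gap_extend = gap_extend, matrix = matrix)
  }
  aln_by_query <- split(alignments, alignments$query_id)
  ref_seq_of <- setNames(reference$aa_sequence, reference$accession)

  lapply(seq_len(nrow(tges)), function(i) {
    id <- tges$tge_id[i]
    seq <- tges$aa_sequence[i]
    best <- best_hit(aln_by_query[[id]])
    main <- assign_main_class(seq, best, reference, e_threshold)
    rec <- list(tge_id = id, main_class = main$label, subclass = NA_character_,
                best_hit = main$best_hit,
                e_value = if (is.null(best)) NA_real_ else best$e_value,
                identity_pct = if (is.null(best)) NA_real_ else
                  .pct_identity(best),
                events = .empty_events(), terminals = NULL,
                alt_start = NULL, aln = best)
    if (main$label %in% c("known_protein", "known_isoform")) {
      rec$identity_pct <- 100
      rec$e_value <- NA_real_
      rec$aln <- NULL
      return(rec)
    }
    if (main$label == "novel_tge") return(rec)
    ref_seq <- ref_seq_of[[best$subject_id]]
    events <- extract_events(best, sv_min_length = sv_min_length,
                             alt_max_length = alt_max_length)
    terminals <- classify_terminals(best, nchar(seq), nchar(ref_seq))
    sub <- assign_subclass(main, events, terminals)
    rec$main_class <- sub$main_class
    rec$subclass <- sub$subclass
    rec$events <- events
    rec$terminals <- terminals
    rec$alt_start <- detect_alt_start(seq, best, ref_seq)
    rec
  })
}

#' Run the complete classification and confirmation pipeline
#'
#' Orchestrates all stages: TGE retention and peptide mapping
#' ([build_tge_set()]), homology classification ([classify_tges()]),
#' variant-peptide flagging ([flag_variant_peptides()]), detectability
#' calibration on the sample's known proteins
#' ([calibrate_detectability()]), variant-versus-reference scoring
#' ([score_variant_vs_reference()]) and evidence rating ([rate_tge()]).
#'
#' @param orfs ORF data frame or FASTA path.
#' @param psms PSM data frame or TSV path.
#' @param reference Reference data frame or FASTA path.
#' @param alignments Optional precomputed alignments (data frame or BLAST
#'   XML path); the internal aligner is skipped when supplied.
#' @param q_threshold Global PSM q-value threshold (default 0.01).
#' @param min_peptides Minimum distinct peptides per retained ORF (default 2).
#' @param e_threshold Homology e-value threshold (default 1e-30).
#' @param score_margin Decision margin of the scoring stage (default 0).
#' @param missed_cleavages,min_pep_len,max_pep_len Digestion parameters for
#'   candidate-peptide enumeration (defaults 0, 7, 45).
#' @param sv_min_length,alt_max_length Event-length thresholds (10, 9).
#' @param ref_denominator,undetected_denominator Scoring constants (4, 8).
#' @param detectability Raw detectability predictor (pluggable).
#' @param out_dir Optional directory; when given, report files are written
#'   via [write_reports()].
#' @return list with `classification` (one row per TGE, the
#'   classification.tsv schema), `events`, `evidence`, `ambiguity_groups`,
#'   `calibration` (the transform), and `summary` (per-class counts).
#' @export
run_pipeline <- function(orfs, psms, reference, alignments = NULL,
                         q_threshold = 0.01, min_peptides = 2,
                         e_threshold = 1e-30, score_margin = 0,
                         missed_cleavages = 0, min_pep_len = 7,
                         max_pep_len = 45, sv_min_length = 10,
                         alt_max_length = 9, ref_denominator = 4,
                         undetected_denominator = 8,
                         detectability = predict_detectability,
                         out_dir = NULL) {
  if (is.character(orfs)) orfs <- read_orf_fasta(orfs)
  if (is.character(psms)) psms <- read_psm_table(psms)
  if (is.character(reference)) reference <- read_reference_fasta(reference)
  if (is.character(alignments)) alignments <- read_blast_xml(alignments)

  tge_set <- build_tge_set(orfs, psms, q_threshold, min_peptides)
  recs <- classify_tges(tge_set, reference, alignments, e_threshold,
                        sv_min_length, alt_max_length)
  tges <- tge_set$tges
  evidence <- tge_set$evidence
  ref_seq_of <- setNames(reference$aa_sequence, reference$accession)

  for (rec in recs) {
    if (!is.null(rec$aln)) {
      evidence <- flag_variant_peptides(
        evidence, rec$tge_id, rec$events, rec$terminals, rec$aln,
        nchar(tges$aa_sequence[tges$tge_id == rec$tge_id]))
    }
  }

  # identified-peptide q map for the whole sample
  identified_q <- tapply(evidence$q_value, evidence$peptide, min)
  identified_q <- setNames(as.numeric(identified_q), names(identified_q))

  # calibration on known-protein TGEs: candidate tryptic peptides vs
  # whether each was identified in this sample
  known_ids <- vapply(recs, function(r) r$main_class == "known_protein", TRUE)
  known_seqs <- tges$aa_sequence[tges$tge_id %in%
                                 vapply(recs[known_ids], `[[`, "", "tge_id")]
  cal_pep <- unique(unlist(lapply(known_seqs, function(s) {
    digest_tryptic(s, missed_cleavages, min_pep_len, max_pep_len)$peptide
  })))
  calibration <- if (length(cal_pep) == 0) {
    calibrate_detectability(numeric(0), logical(0))
  } else {
    calibrate_detectability(
      detectability(cal_pep),
      cal_pep %in% names(identified_q)[identified_q <= q_threshold])
  }

  rows <- list()
  events_out <- list()
  for (rec in recs) {
    id <- rec$tge_id
    seq <- tges$aa_sequence[tges$tge_id == id]
    erows <- evidence[evidence$tge_id == id, , drop = FALSE]
    n_pep <- length(unique(erows$peptide))
    n_upep <- length(unique(erows$peptide[erows$is_unique]))
    n_vpep <- length(unique(erows$peptide[erows$overlaps_variant]))
    n_uvpep <- length(unique(erows$peptide[erows$overlaps_variant &
                                           erows$is_unique]))
    n_jpep <- length(unique(erows$peptide[erows$is_junction]))
    sv <- sr <- NA_real_
    decision <- NA_character_
    if (rec$main_class %in% c("known_with_polymorphism", "novel_isoform") &&
        !is.null(rec$aln)) {
      sets <- build_peptide_sets(seq, ref_seq_of[[rec$best_hit]],
                                 rec$events, rec$aln, missed_cleavages,
                                 min_pep_len, max_pep_len)
      if (length(unique(sets$V$peptide)) + length(unique(sets$R$peptide)) > 0) {
        sc <- score_variant_vs_reference(
          sets, identified_q, calibration, q_threshold, score_margin,
          ref_denominator, undetected_denominator, detectability)
        sv <- sc$score_variant; sr <- sc$score_reference
        decision <- sc$decision
      } else {
        decision <- "undecided"
      }
    }
    is_complete <- tges$is_complete_orf[tges$tge_id == id]
    rating <- rate_tge(n_uvpep > 0, n_vpep > 0, decision, is_complete)
    alt <- rec$alt_start
    rows[[length(rows) + 1L]] <- data.frame(
      tge_id = id, length = nchar(seq), main_class = rec$main_class,
      subclass = rec$subclass, best_hit = rec$best_hit,
      evalue = rec$e_value, identity_pct = rec$identity_pct,
      n_events = nrow(rec$events), n_peptides = n_pep,
      n_unique_peptides = n_upep, n_variant_peptides = n_vpep,
      n_unique_variant_peptides = n_uvpep, n_junction_peptides = n_jpep,
      score_variant = sv, score_reference = sr,
      decision = decision, rating = rating,
      alt_start_residue = if (is.null(alt)) NA_character_ else alt$residue,
      alt_start_ref_pos = if (is.null(alt)) NA_integer_ else alt$ref_pos,
      alt_start_category = if (is.null(alt)) NA_character_ else alt$category,
      alt_start_discounted = if (is.null(alt)) NA else alt$discounted,
      stringsAsFactors = FALSE)
    if (nrow(rec$events) > 0) {
      ev <- rec$events
      ev$tge_id <- id
      ev$event_index <- seq_len(nrow(ev))
      events_out[[length(events_out) + 1L]] <- ev
    }
  }
  classification <- do.call(rbind, rows)
  events <- if (length(events_out) > 0) {
    out <- do.call(rbind, events_out)
    out[, c("tge_id", "event_index", "type", "tge_start", "tge_end",
            "ref_start", "ref_end", "tge_seq", "ref_seq")]
  } else {
    cbind(data.frame(tge_id = character(0), event_index = integer(0)),
          .empty_events())
  }
  evidence <- evidence[, c("peptide", "q_value", "tge_id", "start", "end",
                           "is_unique", "overlaps_variant", "is_junction")]
  result <- list(classification = classification, events = events,
                 evidence = evidence,
                 ambiguity_groups = tge_set$ambiguity_groups,
                 calibration = calibration,
                 summary = summarize_classes(
                   classification,
                   tges$is_complete_orf[match(classification$tge_id,
                                              tges$tge_id)]))
  if (!is.null(out_dir)) {
    write_reports(classification, events, evidence,
                  setNames(tges$aa_sequence, tges$tge_id), out_dir)
  }
  result
}

#' Per-class summary counts
#'
#' Counts per main class (and subclass for novel isoforms): total TGEs,
#' TGEs from complete ORFs, TGEs with variant-specific peptide evidence,
#' with unique variant-specific peptide evidence, and score-confirmed TGEs.
#'
#' @param classification Classification table from [run_pipeline()].
#' @param is_complete_orf Logical vector aligned with the classification
#'   rows; defaults to all `FALSE` when unknown.
#' @return data frame of counts.
#' @export
summarize_classes <- function(classification,
                              is_complete_orf =
                                rep(FALSE, nrow(classification))) {
  key <- ifelse(is.na(classification$subclass),
                classification$main_class,
                paste(classification$main_class, classification$subclass,
                      sep = "/"))
  lev <- sort(unique(key))
  agg <- function(f) {
    as.integer(tapply(f, factor(key, levels = lev), sum))
  }
  data.frame(
    class = lev,
    total = as.integer(table(factor(key, levels = lev))),
    complete_orf = agg(is_complete_orf),
    with_specific_peptide = agg(classification$n_variant_peptides > 0),
    with_unique_specific_peptide =
      agg(classification$n_unique_variant_peptides > 0),
    score_confirmed = agg(!is.na(classification$decision) &
                          classification$decision == "variant"),
    stringsAsFactors = FALSE
  )
}
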