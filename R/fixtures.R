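#' @name fixtures
#' @title Synthetic ground-truth fixtures
#'
#' @description
#' The fixture generator produces a reference proteome, variant TGEs of
#' every class with ground-truth labels and edit records, and simulated PSM
#' tables, so that every pipeline stage can be exercised and its output
#' compared against known truth without any external data. All generators
#' are deterministic given a seed.
NULL

# the 15 terminal novel-isoform subclasses (4x4 grid minus identical/identical)
TERMINAL_SUBCLASSES <- local({
  kinds <- c("identical", "truncated", "extended", "alternative")
  out <- character(0)
  for (n in kinds) for (c in kinds) {
    if (n == "identical" && c == "identical") next
    parts <- character(0)
    if (n != "identical") parts <- c(parts, paste0("N_", n))
    if (c != "identical") parts <- c(parts, paste0("C_", c))
    out <- c(out, paste(parts, collapse = "+"))
  }
  out
})

POLYMORPHISM_CLASSES <- c("SAP", "SSAP", "ALT", "SALT", "INS", "DEL")

ALT_START_CLASSES <- c("alt_start_accepted", "alt_start_discounted",
                       "met_removed")

#' Full fixture class plan
#'
#' One entry per label the classifier can emit: known protein, known
#' isoform, the six polymorphism types, SV, the 15 terminal novel-isoform
#' subclasses, novel TGE and the three alternative-start cases.
#'
#' @param n TGEs per label (default 10).
#' @return Named integer vector usable as `class_plan`.
#' @export
fixture_plan_full <- function(n = 10) {
  labels <- c("known_protein", "known_isoform", POLYMORPHISM_CLASSES, "SV",
              TERMINAL_SUBCLASSES, "novel_tge", ALT_START_CLASSES)
  setNames(rep(as.integer(n), length(labels)), labels)
}

.rand_aa <- function(n, exclude = character(0)) {
  pool <- setdiff(AA20, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic reference proteome
#'
#' Random proteins starting with methionine, residues i.i.d. uniform over
#' the 20 standard letters; a configurable fraction of canonical entries
#' receive a derived isoform (accession suffix `-2`, sequence obtained by
#' swapping the C-terminal 30 residues for random sequence).
#'
#' @param n_reference Number of canonical proteins.
#' @param length_range Length range (residues), default 150-250.
#' @param isoform_fraction Fraction of canonicals with a derived isoform.
#' @param seed Random seed.
#' @return Reference data frame as from [read_reference_fasta()].
#' @export
make_reference <- function(n_reference = 30, length_range = c(150, 250),
                           isoform_fraction = 0.2, seed = 1) {
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n_reference, replace = TRUE)
  # every protein must be observable by tryptic MS: resample until the
  # digest yields several peptides inside the 7-45 residue window (a
  # protein without such peptides could never be identified, and a TGE
  # is by definition supported by at least two identified peptides)
  observable_seq <- function(L, min_obs = 4) {
    repeat {
      s <- paste0("M", .rand_aa(L - 1))
      if (nrow(digest_tryptic(s, 0, 7, 45)) >= min_obs) return(s)
    }
  }
  seqs <- vapply(lens, observable_seq, "")
  acc <- sprintf("REF%04d", seq_len(n_reference))
  n_iso <- round(isoform_fraction * n_reference)
  iso_rows <- list()
  if (n_iso > 0) {
    for (i in seq_len(n_iso)) {
      base <- seqs[i]
      L <- nchar(base)
      repeat {
        iso_seq <- paste0(substr(base, 1, L - 30), .rand_aa(30))
        if (nrow(digest_tryptic(iso_seq, 0, 7, 45)) >= 2) break
      }
      iso_rows[[i]] <- data.frame(
        accession = paste0(acc[i], "-2"), aa_sequence = iso_seq,
        is_isoform = TRUE, description = paste("isoform of", acc[i]),
        stringsAsFactors = FALSE)
    }
  }
  canon <- data.frame(accession = acc, aa_sequence = seqs,
                      is_isoform = FALSE,
                      description = paste("synthetic protein", acc),
                      stringsAsFactors = FALSE)
  out <- rbind(canon, do.call(rbind, iso_rows))
  rownames(out) <- NULL
  out
}

# pick a substitution partner for `res` with the requested BLOSUM80 sign;
# never K/R (to keep tryptic peptide structure stable across the edit) and
# never the residue itself. NULL when no partner with that sign exists.
.sub_partner <- function(res, positive, avoid_kr = TRUE) {
  m <- blosum80()
  cand <- setdiff(AA20, res)
  if (avoid_kr) cand <- setdiff(cand, c("K", "R"))
  sc <- m[res, cand]
  cand <- if (positive) cand[sc > 0] else cand[sc <= 0]
  if (length(cand) == 0) return(NULL)
  sample(cand, 1)
}

# positions eligible for an internal edit of `width` residues: away from the
# termini and with no K/R inside or flanking the edited window (so edits do
# not disturb tryptic cleavage sites)
.edit_positions <- function(seq, width, margin = 30) {
  L <- nchar(seq)
  lo <- margin + 1L
  hi <- L - margin - width
  if (hi < lo) return(integer(0))
  pos <- lo:hi
  ch <- strsplit(seq, "")[[1]]
  ok <- vapply(pos, function(p) {
    win <- ch[max(1, p - 1):min(L, p + width)]
    !any(win %in% c("K", "R"))
  }, TRUE)
  pos[ok]
}

# one planned TGE; returns list(seq, events, aligned ref window, overhangs)
# or NULL when the reference cannot realise the class (caller retries)
.make_one_tge <- function(label, ref_seq) {
  L <- nchar(ref_seq)
  ch <- strsplit(ref_seq, "")[[1]]
  ev <- function(type, tge_start, tge_end, ref_start, ref_end, tseq, rseq) {
    data.frame(type = type, tge_start = tge_start, tge_end = tge_end,
               ref_start = ref_start, ref_end = ref_end,
               tge_seq = tseq, ref_seq = rseq, stringsAsFactors = FALSE)
  }
  base <- list(seq = ref_seq, events = .empty_events(),
               ref_from = 1L, ref_to = L, n_extra = "", c_extra = "",
               completeness = "complete")
  # residues substituted column-wise, each non-identical, avoiding K/R;
  # `signs` gives the requested BLOSUM80 sign per column (TRUE = positive)
  sub_run <- function(pos, signs) {
    repl <- character(length(signs))
    for (i in seq_along(signs)) {
      p <- .sub_partner(ch[pos + i - 1L], signs[i])
      if (is.null(p)) return(NULL)
      repl[i] <- p
    }
    paste(repl, collapse = "")
  }
  # boundary-safe random overhang: every overhang residue scores strictly
  # negatively against every residue of the opposing reference region, so
  # the local alignment can never profit from creeping into the overhang,
  # at any shift or gap placement. NULL when no such residue exists for
  # this reference (caller resamples).
  safe_overhang <- function(n, against) {
    m <- blosum80()
    cand <- setdiff(AA20, c("K", "R"))
    if (length(against) > 0) {
      opp <- unique(against)
      cand <- cand[vapply(cand, function(r0) all(m[r0, opp] < 0), TRUE)]
    }
    if (length(cand) == 0) return(NULL)
    paste(sample(cand, n, replace = TRUE), collapse = "")
  }

  if (label %in% c("SAP", "SSAP", "ALT", "SALT", "SV", "INS", "DEL")) {
    width <- switch(label, SAP = 1L, SSAP = 1L, ALT = 5L, SALT = 5L,
                    SV = 12L, INS = 0L, DEL = 3L)
    pos_pool <- .edit_positions(ref_seq, max(width, 3L))
    if (length(pos_pool) == 0) return(NULL)
    for (attempt in seq_len(25)) {
      p <- sample(pos_pool, 1)
      if (label %in% c("SAP", "SSAP")) {
        r <- sub_run(p, label == "SSAP")
        if (is.null(r)) next
        out <- base
        out$seq <- paste0(substr(ref_seq, 1, p - 1), r,
                          substr(ref_seq, p + 1, L))
        out$events <- ev(label, p, p, p, p, r, ch[p])
        return(out)
      }
      if (label %in% c("ALT", "SALT")) {
        signs <- if (label == "SALT") rep(TRUE, width) else
          c(FALSE, sample(c(TRUE, FALSE), width - 1, replace = TRUE))
        r <- sub_run(p, signs)
        if (is.null(r)) next
        out <- base
        out$seq <- paste0(substr(ref_seq, 1, p - 1), r,
                          substr(ref_seq, p + width, L))
        out$events <- ev(label, p, p + width - 1L, p, p + width - 1L,
                         r, substr(ref_seq, p, p + width - 1L))
        return(out)
      }
      if (label == "SV") {
        # splice-scale replacement: every replacement residue must score
        # strictly negatively against all reference residues in and around
        # the replaced window, so the optimal alignment cannot split the
        # 12-column run by realigning the replacement at a shift (gap costs
        # always exceed any possible gain)
        m <- blosum80()
        nb <- unique(ch[max(1, p - 6):min(L, p + width + 5)])
        cand <- setdiff(AA20, c("K", "R"))
        cand <- cand[vapply(cand, function(r0) all(m[r0, nb] < 0), TRUE)]
        if (length(cand) == 0) next
        r <- paste(sample(cand, width, replace = TRUE), collapse = "")
        out <- base
        out$seq <- paste0(substr(ref_seq, 1, p - 1), r,
                          substr(ref_seq, p + width, L))
        out$events <- ev("SV", p, p + width - 1L, p, p + width - 1L,
                         r, substr(ref_seq, p, p + width - 1L))
        return(out)
      }
      if (label == "INS") {
        r <- .rand_aa(3, exclude = c("K", "R"))
        out <- base
        out$seq <- paste0(substr(ref_seq, 1, p), r, substr(ref_seq, p + 1, L))
        out$events <- ev("INS", p + 1L, p + 3L, p, p, r, "")
        return(out)
      }
      if (label == "DEL") {
        out <- base
        out$seq <- paste0(substr(ref_seq, 1, p - 1), substr(ref_seq, p + 3, L))
        out$events <- ev("DEL", p - 1L, p - 1L, p, p + 2L, "",
                         substr(ref_seq, p, p + 2))
        return(out)
      }
    }
    return(NULL)
  }

  if (label %in% TERMINAL_SUBCLASSES) {
    over <- 25L
    n_kind <- if (grepl("N_truncated", label)) "truncated"
      else if (grepl("N_extended", label)) "extended"
      else if (grepl("N_alternative", label)) "alternative"
      else "identical"
    c_kind <- if (grepl("C_truncated", label)) "truncated"
      else if (grepl("C_extended", label)) "extended"
      else if (grepl("C_alternative", label)) "alternative"
      else "identical"
    ref_from <- if (n_kind %in% c("truncated", "alternative")) over + 1L else 1L
    ref_to <- if (c_kind %in% c("truncated", "alternative")) L - over else L
    if (ref_to - ref_from < 80) return(NULL)
    n_against <- if (ref_from > 1) ch[1:(ref_from - 1)] else character(0)
    c_against <- if (ref_to < L) ch[(ref_to + 1):L] else character(0)
    n_extra <- ""
    if (n_kind %in% c("extended", "alternative")) {
      n_extra <- safe_overhang(over, n_against)
      if (is.null(n_extra)) return(NULL)
    }
    c_extra <- ""
    if (c_kind %in% c("extended", "alternative")) {
      c_extra <- safe_overhang(over, c_against)
      if (is.null(c_extra)) return(NULL)
    }
    core <- substr(ref_seq, ref_from, ref_to)
    out <- base
    out$seq <- paste0(n_extra, core, c_extra)
    out$ref_from <- ref_from; out$ref_to <- ref_to
    out$n_extra <- n_extra; out$c_extra <- c_extra
    out$completeness <- if (n_kind == "truncated") "5prime_partial" else "complete"
    return(out)
  }

  if (label == "novel_tge") {
    out <- base
    # must be retainable: at least two tryptic peptides in the observable
    # length window, otherwise the >= 2 peptide filter could never keep it
    repeat {
      out$seq <- paste0("M", .rand_aa(79))
      if (nrow(digest_tryptic(out$seq, 0, 7, 45)) >= 2) break
    }
    out$ref_from <- NA_integer_; out$ref_to <- NA_integer_
    return(out)
  }

  if (label %in% ALT_START_CLASSES) {
    # suffix truncation at position k chosen by the preceding reference
    # residue; k in the 40..70 window keeps a long aligned core
    ks <- 40:70
    pick <- switch(
      label,
      alt_start_accepted = ks[ch[ks - 1] == "G" &
                              !ch[ks] %in% c("M", "K", "R")],
      alt_start_discounted = ks[ch[ks - 1] %in% c("K", "R") &
                                !ch[ks] %in% c("M", "K", "R")],
      met_removed = if (ch[2] != "M") 2L else integer(0))
    if (length(pick) == 0) return(NULL)
    k <- if (length(pick) == 1) pick else sample(pick, 1)
    out <- base
    out$seq <- substr(ref_seq, k, L)
    out$ref_from <- k; out$ref_to <- L
    out$completeness <- "5prime_partial"
    return(out)
  }
  stop("unknown fixture label: ", label, call. = FALSE)
}

#' Generate variant TGEs with ground-truth labels
#'
#' Each TGE is a reference sequence edited to realise exactly one planned
#' class: a single substitution with a negative (SAP) or positive (SSAP)
#' BLOSUM80 partner; a 5-residue substitution run (ALT, SALT); a 12-residue
#' replacement (SV); 3-residue insertions and deletions; 25-residue terminal
#' truncations/extensions/alternatives for the 15 terminal subclasses;
#' an exact copy for known classes; random sequence for novel TGEs; and
#' suffix truncations at chosen reference positions for the
#' alternative-start cases. Edits avoid lysine/arginine at and around their
#' boundaries so tryptic peptide structure is stable across the edit, and
#' extension overhangs are built so that every overhang residue scores
#' non-positively against the reference residue it would sit across from
#' (the local alignment cannot creep into the overhang). Generated TGEs are
#' checked not to collide with any reference sequence or earlier TGE, and
#' resampled if they do.
#'
#' @param reference Reference data frame from [make_reference()].
#' @param class_plan Named integer vector, label -> count; see
#'   [fixture_plan_full()] for the label set.
#' @param seed Random seed.
#' @return list with `orfs` (data frame as from [read_orf_fasta()]) and
#'   `truth` (data frame with `tge_id`, `true_class`, `true_subclass`,
#'   `ref_accession`, `ref_from`, `ref_to`, `n_extra`, `c_extra`,
#'   `alt_category`, `alt_discounted`) and `truth_events` (planned
#'   polymorphism events per TGE).
#' @export
make_variant_tges <- function(reference, class_plan, seed = 1) {
  set.seed(seed + 1)
  canon <- reference[!reference$is_isoform, , drop = FALSE]
  isos <- reference[reference$is_isoform, , drop = FALSE]
  orf_rows <- list(); truth_rows <- list(); event_rows <- list()
  seen <- new.env(parent = emptyenv())
  for (s in reference$aa_sequence) assign(s, TRUE, envir = seen)
  counter <- 0L

  add <- function(label, seq, comp, ref_acc, ref_from, ref_to, n_extra,
                  c_extra, events, true_class, true_subclass,
                  alt_category = NA_character_, alt_discounted = NA) {
    counter <<- counter + 1L
    id <- sprintf("tge%04d.p1", counter)
    orf_rows[[counter]] <<- data.frame(
      orf_id = id, transcript_id = sprintf("tge%04d", counter),
      aa_sequence = seq, completeness = comp, stringsAsFactors = FALSE)
    truth_rows[[counter]] <<- data.frame(
      tge_id = id, true_class = true_class, true_subclass = true_subclass,
      ref_accession = ref_acc, ref_from = ref_from, ref_to = ref_to,
      n_extra = n_extra, c_extra = c_extra,
      alt_category = alt_category, alt_discounted = alt_discounted,
      stringsAsFactors = FALSE)
    if (nrow(events) > 0) {
      events$tge_id <- id
      event_rows[[length(event_rows) + 1L]] <<- events
    }
  }

  for (label in names(class_plan)) {
    n_wanted <- class_plan[[label]]
    if (n_wanted == 0) next
    if (label == "known_protein") {
      if (nrow(canon) < n_wanted) stop("not enough canonical references")
      for (i in seq_len(n_wanted)) {
        add(label, canon$aa_sequence[i], "complete", canon$accession[i],
            1L, nchar(canon$aa_sequence[i]), "", "", .empty_events(),
            "known_protein", NA_character_)
      }
      next
    }
    if (label == "known_isoform") {
      if (nrow(isos) < n_wanted) stop("not enough isoform references")
      for (i in seq_len(n_wanted)) {
        add(label, isos$aa_sequence[i], "complete", isos$accession[i],
            1L, nchar(isos$aa_sequence[i]), "", "", .empty_events(),
            "known_isoform", NA_character_)
      }
      next
    }
    made <- 0L
    guard <- 0L
    while (made < n_wanted) {
      guard <- guard + 1L
      if (guard > 200L * n_wanted) {
        stop("fixture generation stalled for label ", label, call. = FALSE)
      }
      ri <- sample(nrow(canon), 1)
      res <- .make_one_tge(label, canon$aa_sequence[ri])
      if (is.null(res)) next
      # the TGE itself must carry >= 2 observable tryptic peptides,
      # otherwise the retention filter could never keep it
      if (nrow(digest_tryptic(res$seq, 0, 7, 45)) < 2) next
      if (exists(res$seq, envir = seen, inherits = FALSE)) next
      assign(res$seq, TRUE, envir = seen)
      tc <- if (label %in% POLYMORPHISM_CLASSES) "known_with_polymorphism"
        else if (label == "SV") "novel_isoform"
        else if (label %in% TERMINAL_SUBCLASSES) "novel_isoform"
        else if (label %in% ALT_START_CLASSES) "novel_isoform"
        else "novel_tge"
      ts <- if (label == "SV") "SV"
        else if (label %in% TERMINAL_SUBCLASSES) label
        else if (label %in% ALT_START_CLASSES) "N_truncated"
        else NA_character_
      alt_cat <- if (label == "met_removed") "met_removed"
        else if (label %in% c("alt_start_accepted", "alt_start_discounted"))
          "alt_start" else NA_character_
      add(label, res$seq, res$completeness,
          if (label == "novel_tge") NA_character_ else canon$accession[ri],
          res$ref_from, res$ref_to, res$n_extra, res$c_extra, res$events,
          tc, ts, alt_cat,
          if (label == "alt_start_discounted") TRUE
          else if (is.na(alt_cat)) NA else FALSE)
      made <- made + 1L
    }
  }
  truth <- do.call(rbind, truth_rows)
  orfs <- do.call(rbind, orf_rows)
  rownames(truth) <- rownames(orfs) <- NULL
  truth_events <- if (length(event_rows) > 0) {
    do.call(rbind, event_rows)
  } else .empty_events()
  list(orfs = orfs, truth = truth, truth_events = truth_events)
}

#' Ground-truth peptide detection probability
#'
#' The probability model the PSM simulator draws from: a monotone function
#' of the raw detectability score with floor 0.05 and ceiling 0.95, so that
#' calibration has a non-trivial, recoverable target.
#'
#' @param peptides Character vector of peptides.
#' @return Detection probabilities in `[0.05, 0.95]`.
#' @export
detection_probability <- function(peptides) {
  0.05 + 0.9 * plogis(6 * (predict_detectability(peptides) - 0.45))
}

#' Simulate a PSM table for a set of TGEs
#'
#' Digests the sequence actually present in the simulated sample for each
#' TGE (by default the TGE sequence itself; pass `present_sequence` to
#' emulate an assembly artefact whose reference form is what the sample
#' really contains), draws each candidate peptide with its ground-truth
#' detection probability, assigns identified peptides q-values from a low-q
#' distribution, and optionally appends decoy PSMs with interleaved scores
#' so that target-decoy q-value computation can be exercised. Every TGE
#' intended to be retained is guaranteed at least `force_min` observed
#' peptides that occur in its ORF sequence.
#'
#' @param tges data frame with `tge_id`, `aa_sequence` and optionally
#'   `present_sequence`.
#' @param detect_prob Function peptide -> detection probability; default
#'   [detection_probability()].
#' @param q_max Upper bound of the uniform q-value distribution for true
#'   hits (default 0.009, inside a 1\% FDR threshold).
#' @param n_decoys Number of decoy PSMs to append (default 0).
#' @param force_min Minimum observed peptides per TGE (default 2).
#' @param missed_cleavages,min_len,max_len Digestion parameters.
#' @param seed Random seed.
#' @return PSM data frame in the shape of [read_psm_table()].
#' @export
simulate_psms <- function(tges, detect_prob = detection_probability,
                          q_max = 0.009, n_decoys = 0, force_min = 2,
                          missed_cleavages = 0, min_len = 7, max_len = 45,
                          seed = 1) {
  set.seed(seed + 2)
  if (!"tge_id" %in% names(tges) && "orf_id" %in% names(tges)) {
    tges$tge_id <- tges$orf_id
  }
  stopifnot(all(c("tge_id", "aa_sequence") %in% names(tges)))
  rows <- list()
  spec_i <- 0L
  emit <- function(pep, tge_id, q, score, decoy = FALSE) {
    spec_i <<- spec_i + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      spectrum_id = sprintf("spec%06d", spec_i),
      peptide = pep, accessions = I(list(tge_id)), q_value = q,
      search_score = score, is_decoy = decoy, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tges))) {
    present <- if ("present_sequence" %in% names(tges) &&
                   !is.na(tges$present_sequence[i])) {
      tges$present_sequence[i]
    } else {
      tges$aa_sequence[i]
    }
    cand <- digest_tryptic(present, missed_cleavages, min_len, max_len)
    if (nrow(cand) == 0) next
    p <- detect_prob(cand$peptide)
    obs <- runif(nrow(cand)) < p
    # forcing: peptides of the present form that also occur in the ORF
    mappable <- vapply(cand$peptide, function(pp) {
      grepl(pp, tges$aa_sequence[i], fixed = TRUE)
    }, TRUE)
    n_obs_mappable <- length(unique(cand$peptide[obs & mappable]))
    if (n_obs_mappable < force_min) {
      pool <- which(mappable & !obs)
      pool <- pool[order(-p[pool])]
      take <- head(pool, force_min - n_obs_mappable)
      obs[take] <- TRUE
    }
    for (j in which(obs)) {
      q <- runif(1, 0, q_max)
      emit(cand$peptide[j], tges$tge_id[i], q, 100 - 100 * q + runif(1))
    }
  }
  for (d in seq_len(n_decoys)) {
    emit(.rand_aa(sample(7:20, 1)), "DECOY", 1, runif(1, 0, 100),
         decoy = TRUE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reconstruct a TGE from its ground-truth record
#'
#' Replays the fixture's planned edits (aligned reference window, internal
#' events, terminal overhang strings) onto the reference sequence. Used as
#' the round-trip oracle: the reconstruction must equal the generated TGE
#' exactly.
#'
#' @param truth_row One row of the `truth` table from [make_variant_tges()].
#' @param events Planned events for that TGE (possibly empty).
#' @param ref_seq Reference sequence named by `truth_row$ref_accession`.
#' @return The reconstructed amino-acid sequence.
#' @export
replay_truth <- function(truth_row, events, ref_seq) {
  core_from <- truth_row$ref_from
  core_to <- truth_row$ref_to
  if (is.na(core_from)) stop("novel TGE has no reference window")
  # apply events right-to-left on reference coordinates
  core <- substr(ref_seq, core_from, core_to)
  if (nrow(events) > 0) {
    events <- events[order(-events$ref_start), , drop = FALSE]
    for (i in seq_len(nrow(events))) {
      rs <- events$ref_start[i] - core_from + 1L
      re <- events$ref_end[i] - core_from + 1L
      if (events$tge_seq[i] != "" && events$ref_seq[i] == "") {
        # insertion after reference anchor rs
        core <- paste0(substr(core, 1, rs), events$tge_seq[i],
                       substr(core, rs + 1, nchar(core)))
      } else if (events$tge_seq[i] == "") {
        core <- paste0(substr(core, 1, rs - 1),
                       substr(core, re + 1, nchar(core)))
      } else {
        core <- paste0(substr(core, 1, rs - 1), events$tge_seq[i],
                       substr(core, re + 1, nchar(core)))
      }
    }
  }
  paste0(truth_row$n_extra, core, truth_row$c_extra)
}
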