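MAIN_CLASSES <- c("known_protein", "known_isoform", "known_with_polymorphism",
                  "novel_isoform", "novel_tge", "candidate_variant")

TERMINAL_KINDS <- c("identical", "truncated", "extended", "alternative")

#' Assign the top-level homology class of a TGE
#'
#' A TGE whose sequence is exactly equal to a reference sequence is a known
#' protein (or known isoform when that reference entry is isoform-flagged),
#' regardless of which hit the aligner ranked best. A TGE with no qualifying
#' alignment (none at all, or best e-value above the threshold) is a novel
#' TGE. Everything else is a candidate variant, resolved downstream to
#' known-with-polymorphism or novel isoform by [assign_subclass()].
#'
#' @param tge_sequence Normalised TGE amino-acid sequence.
#' @param best One-row alignment data frame from [best_hit()], or `NULL`.
#' @param reference Reference data frame from [read_reference_fasta()].
#' @param e_threshold Qualifying-hit e-value threshold; a hit qualifies iff
#'   `e_value <= e_threshold` (default 1e-30).
#' @return list with `label` (one of the main classes or
#'   `candidate_variant`) and `best_hit` (accession or `NA`).
#' @export
assign_main_class <- function(tge_sequence, best, reference,
                              e_threshold = 1e-30) {
  stopifnot(e_threshold > 0)
  hit <- match(tge_sequence, reference$aa_sequence)
  if (!is.na(hit)) {
    # exact equality wins over any BLAST ranking; prefer a canonical entry
    # when both a canonical and an isoform record carry the same sequence
    idx <- which(reference$aa_sequence == tge_sequence)
    canon <- idx[!reference$is_isoform[idx]]
    if (length(canon) > 0) {
      return(list(label = "known_protein", best_hit = reference$accession[canon[1]]))
    }
    return(list(label = "known_isoform", best_hit = reference$accession[idx[1]]))
  }
  if (is.null(best) || nrow(best) == 0 || best$e_value > e_threshold) {
    return(list(label = "novel_tge",
                best_hit = if (is.null(best) || nrow(best) == 0) {
                  NA_character_
                } else best$subject_id))
  }
  list(label = "candidate_variant", best_hit = best$subject_id)
}

# empty event table, the common schema for extract_events output
.empty_events <- function() {
  data.frame(type = character(0), tge_start = integer(0),
             tge_end = integer(0), ref_start = integer(0),
             ref_end = integer(0), tge_seq = character(0),
             ref_seq = character(0), stringsAsFactors = FALSE)
}

#' Extract polymorphism events from an alignment
#'
#' Scans the aligned columns left to right and converts maximal runs of
#' non-identity columns into events:
#' \itemize{
#'   \item a run of substitution columns of length 1 is a SAP, or SSAP when
#'     the replacement scores positively in BLOSUM80 (midline `+`);
#'   \item length 2-9 is an ALT, or SALT when every column is `+`;
#'   \item length >= 10 is an SV (splice-scale variation);
#'   \item a run of subject-gap columns is an insertion (INS), a run of
#'     query-gap columns a deletion (DEL); runs of `sv_min_length` or more
#'     are likewise promoted to SV.
#' }
#' Runs of different mechanisms (substitution vs gap) are never merged.
#' Deletions have no extent on the TGE; their `tge_start`/`tge_end` anchor is
#' the residue immediately left of the gap (0 at the start). Insertions are
#' anchored on the reference the same way.
#'
#' @param aln One-row alignment data frame.
#' @param matrix Substitution matrix for the similarity (`+`) call.
#' @param sv_min_length Minimum aligned columns for an SV (default 10).
#' @param alt_max_length Maximum length of an ALT/SALT run (default 9).
#' @return data frame with columns `type`, `tge_start`, `tge_end`,
#'   `ref_start`, `ref_end`, `tge_seq`, `ref_seq`.
#' @export
extract_events <- function(aln, matrix = blosum80(), sv_min_length = 10,
                           alt_max_length = 9) {
  validate_alignment(aln)
  qc <- strsplit(aln$q_aln, "")[[1]]
  sc <- strsplit(aln$s_aln, "")[[1]]
  mid <- strsplit(compute_midline(aln$q_aln, aln$s_aln, matrix), "")[[1]]
  n <- length(qc)
  # column category: 0 identity, 1 substitution, 2 insertion (gap in subject),
  # 3 deletion (gap in query)
  cat <- integer(n)
  cat[qc != "-" & sc != "-" & qc != sc] <- 1L
  cat[sc == "-"] <- 2L
  cat[qc == "-"] <- 3L
  # ungapped positions before each column
  qpos <- aln$q_start - 1L + cumsum(qc != "-")
  spos <- aln$s_start - 1L + cumsum(sc != "-")
  r <- rle(cat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 0L) next
    i <- starts[k]; j <- ends[k]; len <- r$lengths[k]
    tseq <- paste(qc[i:j][qc[i:j] != "-"], collapse = "")
    rseq <- paste(sc[i:j][sc[i:j] != "-"], collapse = "")
    if (v == 1L) {
      type <- if (len >= sv_min_length) {
        "SV"
      } else if (len == 1L) {
        if (mid[i] == "+") "SSAP" else "SAP"
      } else if (len <= alt_max_length) {
        if (all(mid[i:j] == "+")) "SALT" else "ALT"
      } else {
        "SV"  # unreachable with default parameters (alt_max+1 == sv_min)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, tge_start = qpos[i], tge_end = qpos[j],
        ref_start = spos[i], ref_end = spos[j],
        tge_seq = tseq, ref_seq = rseq, stringsAsFactors = FALSE)
    } else if (v == 2L) {
      # insertion: residues in the TGE only; reference anchor left of gap
      anchor <- spos[i]  # subject cumsum has not advanced inside the gap
      rows[[length(rows) + 1L]] <- data.frame(
        type = if (len >= sv_min_length) "SV" else "INS",
        tge_start = qpos[i], tge_end = qpos[j],
        ref_start = anchor, ref_end = anchor,
        tge_seq = tseq, ref_seq = "", stringsAsFactors = FALSE)
    } else {
      # deletion: residues in the reference only; TGE anchor left of gap
      anchor <- qpos[i]
      rows[[length(rows) + 1L]] <- data.frame(
        type = if (len >= sv_min_length) "SV" else "DEL",
        tge_start = anchor, tge_end = anchor,
        ref_start = spos[i], ref_end = spos[j],
        tge_seq = "", ref_seq = rseq, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(.empty_events())
  do.call(rbind, rows)
}

#' Classify the N- and C-terminal relationship of a TGE to its reference
#'
#' Each terminus is classified from whether the alignment reaches the end of
#' the TGE and of the reference: reaching both is `identical`; reference
#' overhang only is `truncated` (the TGE is missing reference sequence);
#' TGE overhang only is `extended`; overhangs on both is `alternative`.
#'
#' @param aln One-row alignment data frame.
#' @param tge_len,ref_len Ungapped lengths of the TGE and reference.
#' @return data frame with two rows (`terminus` N and C) and columns `kind`,
#'   `tge_overhang`, `ref_overhang`.
#' @export
classify_terminals <- function(aln, tge_len, ref_len) {
  stopifnot(nrow(aln) == 1)
  if (aln$q_start < 1 || aln$q_end > tge_len ||
      aln$s_start < 1 || aln$s_end > ref_len) {
    stop("alignment coordinates outside sequence bounds", call. = FALSE)
  }
  kind_of <- function(tge_over, ref_over) {
    if (tge_over == 0 && ref_over == 0) "identical"
    else if (tge_over == 0) "truncated"
    else if (ref_over == 0) "extended"
    else "alternative"
  }
  n_t <- aln$q_start - 1L
  n_r <- aln$s_start - 1L
  c_t <- tge_len - aln$q_end
  c_r <- ref_len - aln$s_end
  data.frame(
    terminus = c("N", "C"),
    kind = c(kind_of(n_t, n_r), kind_of(c_t, c_r)),
    tge_overhang = c(n_t, c_t),
    ref_overhang = c(n_r, c_r),
    stringsAsFactors = FALSE
  )
}

#' Resolve a candidate variant to its final class and subclass
#'
#' A candidate variant whose alignment covers the full length of both the
#' TGE and the reference (both terminals `identical`) is a known protein
#' with polymorphism, unless it carries a splice-scale (SV) event, which
#' makes it a novel isoform with subclass `"SV"`. Any terminal overhang
#' makes it a novel isoform with a subclass named from the non-identical
#' terminals, e.g. `N_truncated`, `C_extended` or
#' `N_alternative+C_truncated` (the 15 non-identical combinations of the
#' 4 x 4 terminal grid); internal events are retained alongside.
#'
#' @param main Main-class list from [assign_main_class()]; must be a
#'   candidate variant.
#' @param events Event table from [extract_events()].
#' @param terminals Terminal table from [classify_terminals()].
#' @return list with `main_class`, `subclass` (or `NA`), and the inputs.
#' @export
assign_subclass <- function(main, events, terminals) {
  if (main$label != "candidate_variant") {
    stop("assign_subclass expects a candidate variant", call. = FALSE)
  }
  both_identical <- all(terminals$kind == "identical")
  has_sv <- any(events$type == "SV")
  if (both_identical && !has_sv) {
    return(list(main_class = "known_with_polymorphism", subclass = NA_character_,
                events = events, terminals = terminals, best_hit = main$best_hit))
  }
  if (both_identical && has_sv) {
    return(list(main_class = "novel_isoform", subclass = "SV",
                events = events, terminals = terminals, best_hit = main$best_hit))
  }
  parts <- character(0)
  for (i in seq_len(nrow(terminals))) {
    if (terminals$kind[i] != "identical") {
      parts <- c(parts, paste0(terminals$terminus[i], "_", terminals$kind[i]))
    }
  }
  list(main_class = "novel_isoform", subclass = paste(parts, collapse = "+"),
       events = events, terminals = terminals, best_hit = main$best_hit)
}

#' Detect an alternative translation start
#'
#' A TGE whose first residue participates in the alignment (`q_start = 1`)
#' and is not methionine is an alternative-start candidate. If the
#' reference residue preceding the aligned start is lysine or arginine the
#' candidate is discounted: a tryptic cleavage site at that position means
#' the apparent start could be an artefact of a truncated ORF whose
#' N-terminus coincides with a tryptic peptide boundary. A TGE aligned from
#' reference position 2 where the reference starts with methionine is
#' reported separately as N-terminal-Met-removed (co-translational Met
#' excision), and is never discounted by the K/R rule.
#'
#' @param tge_sequence TGE amino-acid sequence.
#' @param aln One-row alignment data frame (TGE vs reference).
#' @param ref_sequence Reference amino-acid sequence.
#' @return `NULL` when there is nothing to report, else a list with
#'   `category` (`"alt_start"` or `"met_removed"`), `residue` (the TGE start
#'   residue), `ref_pos` (aligned reference position of the TGE start) and
#'   `discounted`.
#' @export
detect_alt_start <- function(tge_sequence, aln, ref_sequence) {
  stopifnot(nrow(aln) == 1)
  if (aln$q_start > 1) return(NULL)
  first <- substr(tge_sequence, 1, 1)
  s0 <- aln$s_start
  if (s0 == 2 && substr(ref_sequence, 1, 1) == "M") {
    return(list(category = "met_removed", residue = first, ref_pos = 2L,
                discounted = FALSE))
  }
  if (first == "M") return(NULL)
  prev <- if (s0 > 1) substr(ref_sequence, s0 - 1, s0 - 1) else ""
  list(category = "alt_start", residue = first, ref_pos = as.integer(s0),
       discounted = s0 > 1 && prev %in% c("K", "R"))
}
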