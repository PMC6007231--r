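#' Compute PSM q-values by target-decoy competition
#'
#' PSMs are sorted by search score (descending); the FDR at rank i is the
#' number of decoys at or above i divided by the number of targets at or
#' above i, and the q-value is the cumulative minimum of the FDR taken from
#' the bottom of the list. Decoy PSMs are removed from the output.
#'
#' @param psms PSM data frame; every row must have `search_score` and
#'   `is_decoy`.
#' @return The target PSMs with `q_value` filled in.
#' @export
compute_qvalues <- function(psms) {
  if (any(is.na(psms$search_score))) {
    stop("compute_qvalues requires a search_score on every PSM", call. = FALSE)
  }
  if (nrow(psms) == 0) return(psms)
  o <- order(psms$search_score, decreasing = TRUE)
  psms <- psms[o, , drop = FALSE]
  n_decoy <- cumsum(psms$is_decoy)
  n_target <- cumsum(!psms$is_decoy)
  fdr <- ifelse(n_target == 0, 1, n_decoy / pmax(n_target, 1))
  q <- rev(cummin(rev(fdr)))
  psms$q_value <- pmin(q, 1)
  out <- psms[!psms$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all occurrences of `peptide` in `sequence` (1-based starts); fixed search
.find_occurrences <- function(peptide, sequence) {
  hits <- gregexpr(peptide, sequence, fixed = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Build the retained TGE set and peptide evidence from ORFs and PSMs
#'
#' Applies the retention filters used when turning putative ORFs into TGEs:
#' PSMs above the q-value threshold (default 1\% global PSM FDR) are
#' discarded; peptides are located in ORF sequences by exact substring
#' search (all occurrences; input accession lists are not trusted); only
#' ORFs with at least `min_peptides` distinct identified peptides are
#' retained; ORFs with identical amino-acid sequence are merged into a
#' single TGE listing all member ORF ids; and protein ambiguity groups are
#' formed from TGEs with identical identified-peptide sets, attaching TGEs
#' whose peptide set is a strict subset of a group's.
#'
#' @param orfs ORF data frame from [read_orf_fasta()].
#' @param psms PSM data frame with `q_value` filled.
#' @param q_threshold PSM q-value threshold (default 0.01).
#' @param min_peptides Minimum distinct peptides per retained ORF (default 2).
#' @return list with elements
#'   \describe{
#'     \item{tges}{data frame `tge_id`, `aa_sequence`, `orf_ids`
#'       (`;`-joined members), `completeness` (of the first member, with
#'       `complete` preferred), `is_complete_orf`.}
#'     \item{evidence}{data frame `peptide`, `q_value` (minimum over PSMs),
#'       `tge_id`, `start`, `end`, `is_unique` (peptide maps to exactly one
#'       TGE), plus placeholder `overlaps_variant`/`is_junction` columns
#'       filled by [flag_variant_peptides()].}
#'     \item{ambiguity_groups}{data frame `tge_id`, `group_id`.}
#'   }
#' @export
build_tge_set <- function(orfs, psms, q_threshold = 0.01, min_peptides = 2) {
  stopifnot(q_threshold > 0, q_threshold <= 1, min_peptides >= 1)
  keep <- !psms$is_decoy & psms$q_value <= q_threshold
  psms <- psms[keep, , drop = FALSE]
  if (nrow(psms) == 0) {
    stop("no PSMs pass the q-value threshold", call. = FALSE)
  }
  pep_q <- tapply(psms$q_value, psms$peptide, min)
  peptides <- names(pep_q)

  # peptide -> ORF occurrences by exact substring search
  occ <- lapply(orfs$aa_sequence, function(s) {
    lapply(peptides, .find_occurrences, sequence = s)
  })
  n_pep_per_orf <- vapply(occ, function(l) sum(lengths(l) > 0), 0L)
  retained <- which(n_pep_per_orf >= min_peptides)
  if (length(retained) == 0) {
    stop("no ORF retains >= ", min_peptides, " identified peptides",
         call. = FALSE)
  }
  ro <- orfs[retained, , drop = FALSE]
  ro <- ro[order(ro$orf_id), , drop = FALSE]

  # merge duplicate-sequence ORFs into one TGE (id = first member orf_id)
  grp <- split(seq_len(nrow(ro)), ro$aa_sequence)
  tge_rows <- lapply(grp, function(ix) {
    comp <- ro$completeness[ix]
    data.frame(
      tge_id = ro$orf_id[ix[1]],
      aa_sequence = ro$aa_sequence[ix[1]],
      orf_ids = paste(ro$orf_id[ix], collapse = ";"),
      completeness = if ("complete" %in% comp) "complete" else comp[1],
      is_complete_orf = "complete" %in% comp,
      stringsAsFactors = FALSE)
  })
  tges <- do.call(rbind, tge_rows)
  tges <- tges[order(tges$tge_id), , drop = FALSE]
  rownames(tges) <- NULL

  ev_rows <- list()
  for (t in seq_len(nrow(tges))) {
    for (p in seq_along(peptides)) {
      starts <- .find_occurrences(peptides[p], tges$aa_sequence[t])
      for (s in starts) {
        ev_rows[[length(ev_rows) + 1L]] <- data.frame(
          peptide = peptides[p], q_value = unname(pep_q[p]),
          tge_id = tges$tge_id[t], start = s,
          end = s + nchar(peptides[p]) - 1L, stringsAsFactors = FALSE)
      }
    }
  }
  evidence <- do.call(rbind, ev_rows)
  n_tges_hit <- tapply(evidence$tge_id, evidence$peptide,
                       function(x) length(unique(x)))
  evidence$is_unique <- unname(n_tges_hit[evidence$peptide]) == 1L
  evidence$overlaps_variant <- FALSE
  evidence$is_junction <- FALSE

  # protein ambiguity groups: identical peptide sets, then strict subsets
  pep_sets <- lapply(split(evidence$peptide, evidence$tge_id),
                     function(x) sort(unique(x)))
  pep_sets <- pep_sets[tges$tge_id]
  set_key <- vapply(pep_sets, paste, "", collapse = "|")
  group_of <- match(set_key, set_key)  # identical-set grouping
  uniq_groups <- sort(unique(group_of))
  sizes <- lengths(pep_sets)
  for (g in uniq_groups) {
    members <- which(group_of == g)
    gset <- pep_sets[[members[1]]]
    for (h in uniq_groups) {
      if (h == g) next
      hset <- pep_sets[[which(group_of == h)[1]]]
      if (length(gset) < length(hset) && all(gset %in% hset)) {
        group_of[members] <- h  # attach strict-subset group to its superset
        break
      }
    }
  }
  ambiguity <- data.frame(tge_id = tges$tge_id,
                          group_id = paste0("PAG", match(group_of,
                                                         sort(unique(group_of)))),
                          stringsAsFactors = FALSE)
  list(tges = tges, evidence = evidence, ambiguity_groups = ambiguity)
}

# variant regions of one TGE as an IRanges: event intervals on the TGE
# (deletions contribute the two residues flanking the anchor) plus terminal
# overhangs from the best alignment
.variant_ranges <- function(events, terminals, aln, tge_len) {
  starts <- integer(0); ends <- integer(0)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      if (events$tge_seq[i] == "" && events$ref_seq[i] != "") {
        a <- events$tge_start[i]  # deletion anchor
        starts <- c(starts, max(1L, a))
        ends <- c(ends, min(tge_len, a + 1L))
      } else {
        starts <- c(starts, events$tge_start[i])
        ends <- c(ends, events$tge_end[i])
      }
    }
  }
  if (!is.null(aln) && nrow(aln) == 1) {
    if (aln$q_start > 1) { starts <- c(starts, 1L); ends <- c(ends, aln$q_start - 1L) }
    if (aln$q_end < tge_len) { starts <- c(starts, aln$q_end + 1L); ends <- c(ends, tge_len) }
  }
  if (length(starts) == 0) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = starts, end = pmin(ends, tge_len)))
}

# TGE positions sitting in identity columns of the alignment
.identical_ranges <- function(aln) {
  if (is.null(aln) || nrow(aln) != 1) return(IRanges::IRanges())
  qc <- strsplit(aln$q_aln, "")[[1]]
  sc <- strsplit(aln$s_aln, "")[[1]]
  qpos <- aln$q_start - 1L + cumsum(qc != "-")
  idn <- qc != "-" & qc == sc
  if (!any(idn)) return(IRanges::IRanges())
  IRanges::reduce(IRanges::IRanges(start = qpos[idn], width = 1L))
}

#' Flag variant-overlapping and junction peptides
#'
#' The variant region of a TGE is the union of its event intervals (for
#' deletions, the two residues flanking the anchor) and its terminal
#' overhangs. A peptide occurrence overlaps the variant when its interval
#' intersects any variant region; it is a junction peptide when it covers at
#' least one residue inside a variant region and at least one residue inside
#' an aligned-identical region, i.e. it spans a variation boundary.
#'
#' @param evidence Evidence data frame from [build_tge_set()].
#' @param tge_id TGE whose occurrences to flag.
#' @param events Event table for that TGE.
#' @param terminals Terminal table for that TGE.
#' @param aln Best alignment row for that TGE (or `NULL`).
#' @param tge_len TGE length.
#' @return The evidence data frame with `overlaps_variant` / `is_junction`
#'   updated for the occurrences of `tge_id`.
#' @export
flag_variant_peptides <- function(evidence, tge_id, events, terminals, aln,
                                  tge_len) {
  vr <- .variant_ranges(events, terminals, aln, tge_len)
  ir <- .identical_ranges(aln)
  rows <- which(evidence$tge_id == tge_id)
  if (length(rows) == 0 || length(vr) == 0) return(evidence)
  occ <- IRanges::IRanges(start = evidence$start[rows],
                          end = evidence$end[rows])
  evidence$overlaps_variant[rows] <-
    IRanges::overlapsAny(occ, vr)
  evidence$is_junction[rows] <-
    evidence$overlaps_variant[rows] & IRanges::overlapsAny(occ, ir)
  evidence
}

#' Peptide coverage of a TGE
#'
#' Fraction of TGE residues covered by at least one identified peptide
#' occurrence (union semantics: overlapping peptides count each residue
#' once).
#'
#' @param tge_len TGE length.
#' @param evidence Evidence data frame restricted by `tge_id`.
#' @param tge_id TGE identifier.
#' @return A fraction in `[0, 1]`.
#' @export
coverage <- function(tge_len, evidence, tge_id) {
  rows <- evidence$tge_id == tge_id
  if (!any(rows)) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = evidence$start[rows],
                                         end = pmin(evidence$end[rows], tge_len)))
  sum(IRanges::width(ir)) / tge_len
}
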