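#' @name alignment
#' @title Local protein alignment against the reference proteome
#'
#' @description
#' TGE-versus-reference comparisons are based on optimal local alignments
#' under BLOSUM80 with affine gap costs (default open 10, extend 1, i.e. a
#' gap of length L costs 10 + L). Alignments are represented as one row of a
#' data frame with the aligned (gapped) query and subject strings, a
#' BLAST-style midline, 1-based inclusive coordinates on both ungapped
#' sequences, a bit score and an e-value.
#'
#' The e-value is estimated from the Karlin-Altschul formula
#' E = K * m * n * exp(-lambda * S) with gapped BLOSUM80/(10,1) parameters
#' lambda = 0.299, K = 0.071 (values from the NCBI BLAST source
#' distribution's precomputed table; approximate, since composition-based
#' adjustments are not applied). When alignments are instead ingested from
#' BLAST XML, BLAST's own statistics are authoritative.
NULL

# Karlin-Altschul gapped parameters for BLOSUM80, gap open 10 / extend 1
KA_LAMBDA_B80 <- 0.299
KA_K_B80 <- 0.071

.ka_evalue <- function(score, m, n) {
  KA_K_B80 * as.numeric(m) * as.numeric(n) * exp(-KA_LAMBDA_B80 * score)
}

.ka_bitscore <- function(score) {
  (KA_LAMBDA_B80 * score - log(KA_K_B80)) / log(2)
}

.alignment_row <- function(query_id, subject_id, score, q_start, q_end,
                           s_start, s_end, q_aln, s_aln, m, n) {
  data.frame(
    query_id = query_id, subject_id = subject_id,
    raw_score = score,
    bit_score = .ka_bitscore(score),
    e_value = .ka_evalue(score, m, n),
    q_start = q_start, q_end = q_end, s_start = s_start, s_end = s_end,
    q_aln = q_aln, s_aln = s_aln,
    midline = if (length(q_aln) == 0) character(0) else
      compute_midline(q_aln, s_aln),
    stringsAsFactors = FALSE
  )
}

#' Compute the BLAST-style midline of an alignment
#'
#' Per aligned column: identical letters give the letter itself, a
#' substitution with positive BLOSUM80 score gives `+` (a conservative,
#' chemically similar replacement), anything else (negative/zero-scoring
#' substitution or a gap) gives a space.
#'
#' @param q_aln,s_aln Aligned query/subject strings of equal length, with
#'   `-` for gaps. A column may not be gap-versus-gap.
#' @param matrix Substitution matrix; defaults to BLOSUM80.
#' @return A character scalar of the same length as the inputs.
#' @export
compute_midline <- function(q_aln, s_aln, matrix = blosum80()) {
  if (nchar(q_aln) != nchar(s_aln)) {
    stop("aligned strings differ in length", call. = FALSE)
  }
  qc <- strsplit(q_aln, "")[[1]]
  sc <- strsplit(s_aln, "")[[1]]
  if (any(qc == "-" & sc == "-")) {
    stop("gap aligned to gap", call. = FALSE)
  }
  out <- rep(" ", length(qc))
  idn <- qc == sc & qc != "-"
  out[idn] <- qc[idn]
  sub <- !idn & qc != "-" & sc != "-"
  if (any(sub)) {
    qs <- qc[sub]
    ss <- sc[sub]
    ok <- qs %in% rownames(matrix) & ss %in% colnames(matrix)
    sc_ok <- rep(FALSE, length(qs))
    sc_ok[ok] <- matrix[cbind(qs[ok], ss[ok])] > 0
    out[sub][sc_ok] <- "+"
  }
  paste(out, collapse = "")
}

#' Optimal local alignment of one query against one subject
#'
#' Smith-Waterman style local alignment with BLOSUM80 and affine gaps,
#' computed with [Biostrings::pairwiseAlignment()]. Returns `NULL` when no
#' alignment with positive score exists (e.g. homopolymers of residues that
#' only score negatively against each other).
#'
#' @param query,subject Amino-acid strings (20 standard letters plus X).
#' @param gap_open,gap_extend Affine gap parameters; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param matrix Substitution matrix name or matrix; default BLOSUM80.
#' @param query_id,subject_id Identifiers carried into the result.
#' @return One-row alignment data frame (see [alignment]) or `NULL`.
#' @examples
#' align_local("ACDEFGHIK", "ACDEFGHIK")$midline
#' @export
align_local <- function(query, subject, gap_open = 10, gap_extend = 1,
                        matrix = "BLOSUM80",
                        query_id = "query", subject_id = "subject") {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("empty sequence", call. = FALSE)
  }
  .assert_aa(c(query, subject))
  res <- align_many(setNames(query, query_id), subject,
                    gap_open = gap_open, gap_extend = gap_extend,
                    matrix = matrix, subject_id = subject_id)
  if (nrow(res) == 0) NULL else res
}

#' Local alignment of many queries against one subject
#'
#' Vectorised form of [align_local()]; queries with no positive-scoring local
#' alignment are dropped from the result.
#'
#' @param queries Named character vector of query sequences (names are
#'   query identifiers).
#' @param subject Subject sequence.
#' @inheritParams align_local
#' @return Alignment data frame with zero or more rows.
#' @export
align_many <- function(queries, subject, gap_open = 10, gap_extend = 1,
                       matrix = "BLOSUM80", subject_id = "subject") {
  stopifnot(length(queries) >= 1, !is.null(names(queries)))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(unname(queries)),
    subject = subject,
    type = "local",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(pa)
  keep <- which(sc > 0)
  if (length(keep) == 0) {
    return(.alignment_row(character(0), character(0), numeric(0),
                          integer(0), integer(0), integer(0), integer(0),
                          character(0), character(0), 1, 1))
  }
  qa <- as.character(Biostrings::alignedPattern(pa))[keep]
  sa <- as.character(Biostrings::alignedSubject(pa))[keep]
  rows <- lapply(seq_along(keep), function(j) {
    i <- keep[j]
    .alignment_row(
      query_id = names(queries)[i], subject_id = subject_id,
      score = sc[i],
      q_start = IRanges::start(Biostrings::pattern(pa))[i],
      q_end = IRanges::end(Biostrings::pattern(pa))[i],
      s_start = IRanges::start(Biostrings::subject(pa))[i],
      s_end = IRanges::end(Biostrings::subject(pa))[i],
      q_aln = qa[j], s_aln = sa[j],
      m = nchar(queries[i]), n = nchar(subject)
    )
  })
  do.call(rbind, rows)
}

#' Select the best reference hit for one TGE
#'
#' The best hit is the alignment with the smallest e-value; ties are broken
#' by the larger bit score, then the lexicographically smallest subject
#' accession, so the result does not depend on input order.
#'
#' @param alignments Alignment data frame, all rows sharing one `query_id`.
#' @return One-row alignment data frame, or `NULL` for empty input.
#' @export
best_hit <- function(alignments) {
  if (is.null(alignments) || nrow(alignments) == 0) {
    return(NULL)
  }
  if (length(unique(alignments$query_id)) > 1) {
    stop("best_hit: alignments for more than one query", call. = FALSE)
  }
  o <- order(alignments$e_value, -alignments$bit_score, alignments$subject_id)
  alignments[o[1], , drop = FALSE]
}

#' Validate internal consistency of an alignment row
#'
#' Checks equal aligned-string lengths, coordinate/width agreement on both
#' sequences and ordered start/end pairs. Called by consumers of alignments
#' read from external BLAST XML.
#'
#' @param aln One-row alignment data frame.
#' @return Invisibly `TRUE`; stops with a validation error otherwise.
#' @export
validate_alignment <- function(aln) {
  stopifnot(nrow(aln) == 1)
  if (nchar(aln$q_aln) != nchar(aln$s_aln)) {
    stop("alignment strings differ in length", call. = FALSE)
  }
  q_res <- nchar(gsub("-", "", aln$q_aln))
  s_res <- nchar(gsub("-", "", aln$s_aln))
  if (aln$q_start > aln$q_end || aln$s_start > aln$s_end) {
    stop("alignment coordinates out of order", call. = FALSE)
  }
  if (q_res != aln$q_end - aln$q_start + 1) {
    stop("query aligned string inconsistent with coordinates", call. = FALSE)
  }
  if (s_res != aln$s_end - aln$s_start + 1) {
    stop("subject aligned string inconsistent with coordinates", call. = FALSE)
  }
  invisible(TRUE)
}
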