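#' Read ORF sequences from FASTA
#'
#' Reads amino-acid ORFs in the Transdecoder header dialect. The completeness
#' tag is taken from a `type:<tag>` token in the header and defaults to
#' `complete` when absent. Sequences are uppercased and trailing `*` stop
#' symbols stripped.
#'
#' @param path FASTA file of amino-acid ORF sequences.
#' @return data frame with columns `orf_id`, `transcript_id`, `aa_sequence`,
#'   `completeness`.
#' @export
read_orf_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  if (anyDuplicated(ids)) {
    stop("duplicate orf_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  comp <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("type:\\S+", h))
    if (length(m) == 0) "complete" else sub("^type:", "", m)
  }, "", USE.NAMES = FALSE)
  allowed <- c("complete", "5prime_partial", "3prime_partial", "internal")
  bad <- setdiff(unique(comp), allowed)
  if (length(bad) > 0) {
    stop("unknown completeness tag: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  aa <- .normalise_aa(as.character(seqs))
  if (any(!nzchar(aa))) {
    stop("empty ORF sequence: ", paste(ids[!nzchar(aa)], collapse = ", "),
         call. = FALSE)
  }
  .assert_aa(aa, "ORF FASTA")
  data.frame(
    orf_id = ids,
    # Transdecoder ids are <transcript>.p<n>; keep the transcript part
    transcript_id = sub("\\.p\\d+$", "", ids),
    aa_sequence = unname(aa),
    completeness = comp,
    stringsAsFactors = FALSE
  )
}

#' Read a reference proteome from FASTA
#'
#' Accessions are parsed from UniProt-style headers (`sp|ACC|NAME` or
#' `tr|ACC|NAME`), falling back to the first whitespace-delimited token. A
#' record is flagged as an isoform when its accession carries a UniProt
#' isoform suffix (`-<digits>`) or its description contains the token
#' "isoform" (case-insensitive); the accession rule is configurable.
#'
#' @param path FASTA file of reference protein sequences.
#' @param isoform_regex Regular expression applied to the accession to detect
#'   isoform entries.
#' @return data frame with columns `accession`, `aa_sequence`, `is_isoform`,
#'   `description`.
#' @export
read_reference_fasta <- function(path, isoform_regex = "^[^-]+-\\d+$") {
  seqs <- Biostrings::readAAStringSet(path)
  headers <- names(seqs)
  first_tok <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  acc <- vapply(first_tok, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2 && parts[1] %in% c("sp", "tr")) parts[2] else tok
  }, "", USE.NAMES = FALSE)
  if (anyDuplicated(acc)) {
    stop("duplicate accession in reference FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  desc <- sub("^\\S+\\s*", "", headers)
  aa <- .normalise_aa(as.character(seqs))
  .assert_aa(aa, "reference FASTA")
  data.frame(
    accession = acc,
    aa_sequence = unname(aa),
    is_isoform = grepl(isoform_regex, acc) |
      grepl("\\bisoform\\b", desc, ignore.case = TRUE),
    description = desc,
    stringsAsFactors = FALSE
  )
}

#' Read FASTA in a chosen role
#'
#' Thin dispatcher over [read_orf_fasta()] and [read_reference_fasta()].
#'
#' @param path FASTA file.
#' @param role `"orf"` or `"reference"`.
#' @param ... Passed to the role-specific reader.
#' @return See the role-specific reader.
#' @export
read_fasta <- function(path, role = c("orf", "reference"), ...) {
  role <- match.arg(role)
  switch(role,
         orf = read_orf_fasta(path, ...),
         reference = read_reference_fasta(path, ...))
}

# strip bracketed / parenthesised modification mass annotations, e.g.
# "PEPT[+79.96]IDE" or "AC(UniMod:4)DK" -> plain residue letters
.strip_mods <- function(pep) {
  gsub("\\[[^]]*\\]|\\([^)]*\\)", "", toupper(pep))
}

#' Read a peptide-spectrum-match table
#'
#' Reads the tab-separated PSM dialect with mandatory columns
#' `spectrum_id`, `peptide`, `accessions` (`;`-separated) and `q_value`, and
#' optional `search_score` (or `score`) and `is_decoy`. Peptides are
#' uppercased and bracketed modification annotations removed, so all
#' downstream peptide-to-sequence mapping is on plain residue letters.
#'
#' @param path TSV file.
#' @return data frame with columns `spectrum_id`, `peptide`, `accessions`
#'   (list column), `q_value`, `search_score`, `is_decoy`.
#' @export
read_psm_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if ("score" %in% names(tab) && !"search_score" %in% names(tab)) {
    names(tab)[names(tab) == "score"] <- "search_score"
  }
  need <- c("spectrum_id", "peptide", "accessions", "q_value")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("PSM table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  q <- as.numeric(tab$q_value)
  if (any(is.na(q) | q < 0 | q > 1)) {
    stop("q_value outside [0,1] in PSM table", call. = FALSE)
  }
  pep <- .strip_mods(tab$peptide)
  if (any(!nzchar(pep))) stop("empty peptide in PSM table", call. = FALSE)
  .assert_aa(pep, "PSM peptides")
  data.frame(
    spectrum_id = tab$spectrum_id,
    peptide = pep,
    accessions = I(strsplit(tab$accessions, ";", fixed = TRUE)),
    q_value = q,
    search_score = if ("search_score" %in% names(tab)) {
      as.numeric(tab$search_score)
    } else NA_real_,
    is_decoy = if ("is_decoy" %in% names(tab)) {
      tolower(tab$is_decoy) %in% c("true", "t", "1", "yes")
    } else FALSE,
    stringsAsFactors = FALSE
  )
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]; used by the fixture generator and for
#' round-trip testing.
#'
#' @param psms PSM data frame as returned by [read_psm_table()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_psm_table <- function(psms, path) {
  out <- data.frame(
    spectrum_id = psms$spectrum_id,
    peptide = psms$peptide,
    accessions = vapply(psms$accessions, paste, "", collapse = ";"),
    q_value = psms$q_value,
    search_score = psms$search_score,
    is_decoy = psms$is_decoy,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pairwise alignments from NCBI BLAST XML
#'
#' Parses blastp output format 5 (one query Iteration, several Hits, several
#' HSPs each) into one alignment row per HSP, carrying the aligned strings
#' and midline verbatim together with 1-based inclusive coordinates, e-value
#' and bit score.
#'
#' @param path BLAST XML file (outfmt 5).
#' @return Alignment data frame (see [alignment]) with one row per HSP.
#' @export
read_blast_xml <- function(path) {
  doc <- xml2::read_xml(path)
  its <- xml2::xml_find_all(doc, ".//Iteration")
  rows <- list()
  for (it in its) {
    qdef <- xml2::xml_text(xml2::xml_find_first(it, "./Iteration_query-def"))
    qid <- strsplit(qdef, "\\s+")[[1]][1]
    for (hit in xml2::xml_find_all(it, ".//Hit")) {
      hdef <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_def"))
      hacc <- xml2::xml_text(xml2::xml_find_first(hit, "./Hit_accession"))
      sid <- strsplit(hdef, "\\s+")[[1]][1]
      if (is.na(sid) || !nzchar(sid)) sid <- hacc
      for (hsp in xml2::xml_find_all(hit, ".//Hsp")) {
        gv <- function(tag) {
          xml2::xml_text(xml2::xml_find_first(hsp, paste0("./", tag)))
        }
        mid <- gv("Hsp_midline")
        if (is.na(mid)) {
          stop("BLAST XML HSP without Hsp_midline", call. = FALSE)
        }
        qseq <- gv("Hsp_qseq")
        hseq <- gv("Hsp_hseq")
        if (nchar(qseq) != nchar(hseq) || nchar(qseq) != nchar(mid)) {
          stop("BLAST XML HSP aligned-string length mismatch", call. = FALSE)
        }
        row <- data.frame(
          query_id = qid, subject_id = sid,
          raw_score = as.numeric(gv("Hsp_score")),
          bit_score = as.numeric(gv("Hsp_bit-score")),
          e_value = as.numeric(gv("Hsp_evalue")),
          q_start = as.integer(gv("Hsp_query-from")),
          q_end = as.integer(gv("Hsp_query-to")),
          s_start = as.integer(gv("Hsp_hit-from")),
          s_end = as.integer(gv("Hsp_hit-to")),
          q_aln = qseq, s_aln = hseq, midline = mid,
          stringsAsFactors = FALSE
        )
        validate_alignment(row)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0) {
    stop("no HSPs found in BLAST XML", call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Read q-values from a minimal mzIdentML subset
#'
#' Reads SpectrumIdentificationResult/SpectrumIdentificationItem elements of
#' an mzIdentML 1.1 file, keeping the peptide sequence, associated database
#' accessions and the PSM-level q-value cvParam
#' (`MS:1002354`, "PSM-level q-value"). Full mzIdentML semantics (protein
#' detection lists, thresholds, modifications beyond sequence letters) are
#' out of scope.
#'
#' @param path mzIdentML file.
#' @return PSM data frame in the same shape as [read_psm_table()].
#' @export
read_mzid <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  peps <- xml2::xml_find_all(doc, ".//Peptide")
  pep_seq <- setNames(
    vapply(peps, function(p) {
      xml2::xml_text(xml2::xml_find_first(p, "./PeptideSequence"))
    }, ""),
    xml2::xml_attr(peps, "id")
  )
  dbseqs <- xml2::xml_find_all(doc, ".//DBSequence")
  db_acc <- setNames(xml2::xml_attr(dbseqs, "accession"),
                     xml2::xml_attr(dbseqs, "id"))
  pevs <- xml2::xml_find_all(doc, ".//PeptideEvidence")
  pev_pep <- setNames(xml2::xml_attr(pevs, "peptide_ref"),
                      xml2::xml_attr(pevs, "id"))
  pev_db <- setNames(xml2::xml_attr(pevs, "dBSequence_ref"),
                     xml2::xml_attr(pevs, "id"))
  rows <- list()
  for (res in xml2::xml_find_all(doc, ".//SpectrumIdentificationResult")) {
    sid <- xml2::xml_attr(res, "spectrumID")
    for (item in xml2::xml_find_all(res, "./SpectrumIdentificationItem")) {
      qv <- xml2::xml_find_first(
        item, "./cvParam[@accession='MS:1002354']")
      q <- if (inherits(qv, "xml_missing")) NA_real_ else
        as.numeric(xml2::xml_attr(qv, "value"))
      pref <- xml2::xml_attr(item, "peptide_ref")
      evs <- xml2::xml_attr(
        xml2::xml_find_all(item, "./PeptideEvidenceRef"),
        "peptideEvidence_ref")
      accs <- unique(unname(db_acc[pev_db[evs]]))
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = sid,
        peptide = .strip_mods(pep_seq[[pref]]),
        accessions = I(list(accs)),
        q_value = q,
        search_score = NA_real_,
        is_decoy = FALSE,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) stop("no spectrum identifications in mzIdentML",
                              call. = FALSE)
  out <- do.call(rbind, rows)
  if (any(is.na(out$q_value) | out$q_value < 0 | out$q_value > 1)) {
    stop("missing or out-of-range PSM q-value in mzIdentML", call. = FALSE)
  }
  out
}

#' Write FASTA
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write the pipeline report files
#'
#' Writes `classification.tsv`, `variation_events.tsv`,
#' `peptide_evidence.tsv` and `novel_tges.fasta` into `out_dir` with
#' deterministic row order (sorted by `tge_id`, then positional columns).
#'
#' @param classification Classification table (one row per TGE).
#' @param events Variation-event table.
#' @param evidence Peptide-evidence table.
#' @param tge_sequences Named character vector of TGE sequences (used for the
#'   novel-TGE FASTA).
#' @param out_dir Output directory; created if needed.
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(classification, events, evidence, tge_sequences,
                          out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  cls <- classification[order(classification$tge_id), , drop = FALSE]
  wt(cls, "classification.tsv")
  ev <- events[order(events$tge_id, events$event_index), , drop = FALSE]
  wt(ev, "variation_events.tsv")
  pe <- evidence[order(evidence$tge_id, evidence$peptide, evidence$start), ,
                 drop = FALSE]
  wt(pe, "peptide_evidence.tsv")
  novel <- cls$tge_id[cls$main_class == "novel_tge"]
  fa <- file.path(out_dir, "novel_tges.fasta")
  write_fasta(tge_sequences[novel], fa)
  invisible(file.path(out_dir, c("classification.tsv", "variation_events.tsv",
                                 "peptide_evidence.tsv", "novel_tges.fasta")))
}
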