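# Kyte-Doolittle hydropathy scale; X (unknown) treated as neutral
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2, X = 0)

CHARGED_RESIDUES <- c("D", "E", "K", "R", "H")

# fixed coefficients of the default detectability model (logistic link):
# intercept, length penalty outside 8-25, mean KD hydropathy, charged
# fraction, proline count
DETECT_COEF <- c(intercept = 0.6, len_pen = -0.45, hydropathy = 0.30,
                 charged = -2.2, proline = -0.35)

#' Predict raw peptide detectability
#'
#' A deterministic, sequence-only detectability model: a logistic function
#' of peptide length (bell-shaped penalty outside the 8-25 residue window
#' favoured by LC-MS/MS), mean Kyte-Doolittle hydropathy, the fraction of
#' charged residues (D, E, K, R, H) and the proline count. The coefficients
#' are fixed constants (`DETECT_COEF` in the source). Absolute values are
#' secondary: downstream scoring always passes raw scores through the
#' sample-specific calibration of [calibrate_detectability()], and any
#' external predictor can be plugged in via the `detectability` argument of
#' the scoring functions.
#'
#' @param peptides Character vector of peptide sequences.
#' @return Numeric vector of raw scores in `[0, 1]`.
#' @export
predict_detectability <- function(peptides) {
  .assert_aa(peptides, "peptides")
  vapply(peptides, function(p) {
    ch <- strsplit(p, "")[[1]]
    len <- length(ch)
    len_pen <- max(0, 8 - len) + max(0, len - 25)
    hyd <- mean(KD_HYDROPATHY[ch])
    charged <- mean(ch %in% CHARGED_RESIDUES)
    pro <- sum(ch == "P")
    unname(plogis(DETECT_COEF["intercept"] +
                  DETECT_COEF["len_pen"] * len_pen +
                  DETECT_COEF["hydropathy"] * hyd +
                  DETECT_COEF["charged"] * charged +
                  DETECT_COEF["proline"] * pro))
  }, 0, USE.NAMES = FALSE)
}

#' Calibrate raw detectability to a sample-specific detection score
#'
#' Builds the monotone transform raw -> s from the sample's own
#' known-protein identifications: all candidate tryptic peptides of
#' known-protein TGEs are binned into deciles of raw score; each bin's s is
#' the fraction of its peptides actually identified in the sample; the bin
#' means are regularised to be monotone non-decreasing by
#' pool-adjacent-violators (isotonic regression, [stats::isoreg()]) and the
#' transform interpolates linearly between bin centres (constant beyond
#' them). With no known-protein peptides the identity transform is returned
#' with a warning; with degenerate bins the transform is constant.
#'
#' @param raw Raw detectability scores of known-protein candidate peptides.
#' @param identified Logical vector: was the peptide identified in the
#'   sample?
#' @param n_bins Number of quantile bins (default 10).
#' @return A function mapping raw scores to calibrated s in `[0, 1]`,
#'   with attributes `bin_centers` and `bin_s`.
#' @export
calibrate_detectability <- function(raw, identified, n_bins = 10) {
  if (length(raw) == 0) {
    warning("no known-protein peptides: identity detectability transform")
    f <- function(x) pmin(pmax(x, 0), 1)
    attr(f, "bin_centers") <- numeric(0)
    attr(f, "bin_s") <- numeric(0)
    return(f)
  }
  stopifnot(length(raw) == length(identified))
  br <- unique(quantile(raw, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE))
  if (length(br) < 3) {
    s0 <- mean(identified)
    f <- function(x) rep(s0, length(x))
    attr(f, "bin_centers") <- mean(raw)
    attr(f, "bin_s") <- s0
    return(f)
  }
  bin <- cut(raw, breaks = br, include.lowest = TRUE, labels = FALSE)
  centers <- tapply(raw, bin, mean)
  freq <- tapply(identified, bin, mean)
  o <- order(centers)
  centers <- as.numeric(centers[o])
  freq <- as.numeric(freq[o])
  iso <- isoreg(centers, freq)  # pool-adjacent-violators
  fitted <- iso$yf
  f <- function(x) {
    approx(centers, fitted, xout = x, rule = 2, ties = "ordered")$y
  }
  attr(f, "bin_centers") <- centers
  attr(f, "bin_s") <- fitted
  f
}

#' Build the variant (V) and reference (R) peptide sets of a TGE
#'
#' V contains the tryptic peptides of the TGE whose interval overlaps any
#' variant region, minus any peptide sequence also produced by digesting the
#' reference; R contains the tryptic peptides of the reference overlapping
#' the reference-side projection of the variant regions (event reference
#' intervals, with insertions contributing the two residues flanking their
#' reference anchor, plus reference terminal overhangs), minus any peptide
#' sequence also produced by digesting the TGE. Only peptides not shared
#' between the two sequences can discriminate them.
#'
#' @param tge_seq,ref_seq TGE and reference amino-acid sequences.
#' @param events Event table from [extract_events()].
#' @param aln Best alignment row.
#' @param missed_cleavages,min_len,max_len Digestion parameters (defaults
#'   0, 7, 45).
#' @return list with data frames `V` and `R` (`peptide`, `start`, `end`).
#' @export
build_peptide_sets <- function(tge_seq, ref_seq, events, aln,
                               missed_cleavages = 0, min_len = 7,
                               max_len = 45) {
  tge_len <- nchar(tge_seq)
  ref_len <- nchar(ref_seq)
  tge_pep <- digest_tryptic(tge_seq, missed_cleavages, min_len, max_len)
  ref_pep <- digest_tryptic(ref_seq, missed_cleavages, min_len, max_len)

  vr_tge <- .variant_ranges(events, NULL, aln, tge_len)
  # reference-side projection: event ref intervals (insertions -> flanks of
  # the reference anchor) plus reference terminal overhangs
  starts <- integer(0); ends <- integer(0)
  if (!is.null(events) && nrow(events) > 0) {
    for (i in seq_len(nrow(events))) {
      if (events$ref_seq[i] == "" && events$tge_seq[i] != "") {
        a <- events$ref_start[i]
        starts <- c(starts, max(1L, a)); ends <- c(ends, min(ref_len, a + 1L))
      } else {
        starts <- c(starts, events$ref_start[i])
        ends <- c(ends, events$ref_end[i])
      }
    }
  }
  if (aln$s_start > 1) { starts <- c(starts, 1L); ends <- c(ends, aln$s_start - 1L) }
  if (aln$s_end < ref_len) { starts <- c(starts, aln$s_end + 1L); ends <- c(ends, ref_len) }
  vr_ref <- if (length(starts) == 0) IRanges::IRanges() else
    IRanges::reduce(IRanges::IRanges(start = starts, end = pmin(ends, ref_len)))

  pick <- function(pep, vr, other_seqs) {
    if (nrow(pep) == 0 || length(vr) == 0) {
      return(pep[integer(0), , drop = FALSE])
    }
    occ <- IRanges::IRanges(start = pep$start, end = pep$end)
    hit <- IRanges::overlapsAny(occ, vr)
    out <- pep[hit, , drop = FALSE]
    out <- out[!out$peptide %in% other_seqs, , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  list(V = pick(tge_pep, vr_tge, ref_pep$peptide),
       R = pick(ref_pep, vr_ref, tge_pep$peptide))
}

#' Score a variant against its reference by peptide evidence
#'
#' Implements the detectability-calibrated variant-versus-reference score.
#' With A/B the identified and A'/B' the unidentified subsets of V
#' (variant-describing) and R (reference-describing) peptides:
#' \deqn{score_{variant} = \frac{1}{|V|+|R|}\Big(\sum_{a \in A}(1-q_a)
#'   - \sum_{b \in B}\frac{1-q_b}{4} + \sum_{b \in B'}\frac{s_b}{8}
#'   - \sum_{a \in A'}\frac{s_a}{8}\Big)}
#' and symmetrically for \eqn{score_{reference}}. Identified peptides
#' contribute their identification confidence (1 - q, q the minimum q-value
#' over the peptide's PSMs); unidentified peptides contribute their
#' calibrated detectability s. The denominator 4 keeps the score difference
#' small when both variant- and reference-specific peptides are observed
#' (both forms present); the denominator 8 reflects an anticipated LC-MS/MS
#' peptide coverage of 12.5\%, so missing peptides are only weak evidence of
#' absence. Both constants are overridable.
#'
#' @param sets list with `V` and `R` data frames from [build_peptide_sets()].
#' @param identified_q Named numeric vector: minimum q-value per identified
#'   peptide sequence in the sample. Peptides with q above `q_threshold`
#'   count as unidentified.
#' @param s_transform Calibrated detectability transform from
#'   [calibrate_detectability()].
#' @param q_threshold Identification q-value cut-off (default 0.01).
#' @param margin Decision margin on the score difference (default 0): the
#'   decision is `variant` iff `score_variant - score_reference > margin`,
#'   `reference` iff the reverse difference exceeds it, else `undecided`.
#' @param ref_denominator,undetected_denominator The constants 4 and 8.
#' @param detectability Raw-score predictor, defaulting to
#'   [predict_detectability()]; any function peptide -> `[0,1]` can be
#'   plugged in.
#' @return list with `score_variant`, `score_reference`, `decision`, the
#'   peptide bookkeeping (`A`, `B`, `A_prime`, `B_prime` peptide vectors)
#'   and set sizes.
#' @export
score_variant_vs_reference <- function(sets, identified_q, s_transform,
                                       q_threshold = 0.01, margin = 0,
                                       ref_denominator = 4,
                                       undetected_denominator = 8,
                                       detectability = predict_detectability) {
  V <- unique(sets$V$peptide)
  R <- unique(sets$R$peptide)
  nVR <- length(V) + length(R)
  if (nVR == 0) {
    stop("scoring undefined: V and R both empty", call. = FALSE)
  }
  idq <- identified_q[identified_q <= q_threshold]
  A <- V[V %in% names(idq)]
  B <- R[R %in% names(idq)]
  A_prime <- setdiff(V, A)
  B_prime <- setdiff(R, B)
  s_of <- function(p) {
    if (length(p) == 0) return(numeric(0))
    s_transform(detectability(p))
  }
  q_of <- function(p) unname(idq[p])
  sA <- sum(1 - q_of(A))
  sB <- sum(1 - q_of(B))
  sAp <- sum(s_of(A_prime))
  sBp <- sum(s_of(B_prime))
  score_variant <- (sA - sB / ref_denominator +
                    sBp / undetected_denominator -
                    sAp / undetected_denominator) / nVR
  score_reference <- (sB - sA / ref_denominator +
                      sAp / undetected_denominator -
                      sBp / undetected_denominator) / nVR
  decision <- if (score_variant - score_reference > margin) {
    "variant"
  } else if (score_reference - score_variant > margin) {
    "reference"
  } else {
    "undecided"
  }
  list(score_variant = score_variant, score_reference = score_reference,
       decision = decision, A = A, B = B, A_prime = A_prime,
       B_prime = B_prime, n_V = length(V), n_R = length(R))
}

#' Rate a TGE by the rigour of its evidence
#'
#' Five-level ladder, highest rating first:
#' \enumerate{
#'   \item[5] at least one unique peptide occurrence overlapping a variant
#'     region;
#'   \item[4] at least one (possibly shared) peptide overlapping a variant
#'     region;
#'   \item[3] confirmed as variant by the scoring model without any
#'     variant-overlapping peptide;
#'   \item[2] retained TGE from a complete ORF without variant evidence;
#'   \item[1] any other retained TGE.
#' }
#' Known proteins and known isoforms have no variant region, so they land on
#' 2 or 1 by ORF completeness.
#'
#' @param has_unique_variant_peptide,has_variant_peptide Logicals from the
#'   evidence flags.
#' @param score_decision `"variant"`, `"reference"`, `"undecided"` or `NA`.
#' @param is_complete_orf Logical.
#' @return Integer rating 1-5.
#' @export
rate_tge <- function(has_unique_variant_peptide, has_variant_peptide,
                     score_decision, is_complete_orf) {
  if (isTRUE(has_unique_variant_peptide)) return(5L)
  if (isTRUE(has_variant_peptide)) return(4L)
  if (identical(score_decision, "variant")) return(3L)
  if (isTRUE(is_complete_orf)) return(2L)
  1L
}
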