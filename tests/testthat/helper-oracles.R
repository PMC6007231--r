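# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or direct definition, sharing no code with the
# package implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Gotoh three-matrix local alignment score with affine gaps costing
# open + L * ext for a gap of length L. Returns the best score (0 when no
# positive-scoring alignment exists).
sw_affine_oracle_score <- function(q, s, matrix = tgeclass::blosum80(),
                                   open = 10, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (query residue inserted)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- matrix[qc[i], sc[j]]
      M[i + 1, j + 1] <- max(0, sub + max(M[i, j], Ix[i, j], Iy[i, j]))
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# brute-force tryptic digestion: enumerate all cleavage-site subsets by
# taking every (i, j) fragment window directly from the site list
digest_oracle <- function(seq, mc = 0, min_len = 1, max_len = Inf,
                          suppress_proline = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sites <- integer(0)
  for (i in seq_len(n - 1)) {
    if (ch[i] %in% c("K", "R") && !(suppress_proline && ch[i + 1] == "P")) {
      sites <- c(sites, i)
    }
  }
  b <- c(0, sites, n)
  out <- list()
  for (i in seq_len(length(b) - 1)) {
    for (skip in 0:mc) {
      j <- i + skip
      if (j > length(b) - 1) break
      st <- b[i] + 1; en <- b[j + 1]
      if (en - st + 1 >= min_len && en - st + 1 <= max_len) {
        out[[length(out) + 1]] <- data.frame(
          peptide = substr(seq, st, en), start = st, end = en,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# independent per-column labelling + grouping oracle for event extraction
events_oracle <- function(q_aln, s_aln, q_start, s_start,
                          matrix = tgeclass::blosum80(),
                          sv_min = 10, alt_max = 9) {
  qc <- strsplit(q_aln, "")[[1]]
  sc <- strsplit(s_aln, "")[[1]]
  lab <- character(length(qc))
  for (i in seq_along(qc)) {
    lab[i] <- if (qc[i] == "-") "del"
      else if (sc[i] == "-") "ins"
      else if (qc[i] == sc[i]) "id"
      else "sub"
  }
  out <- list()
  qp <- q_start - 1; sp <- s_start - 1
  i <- 1
  while (i <= length(lab)) {
    j <- i
    while (j < length(lab) && lab[j + 1] == lab[i]) j <- j + 1
    qp_before <- qp; sp_before <- sp
    for (k in i:j) {
      if (qc[k] != "-") qp <- qp + 1
      if (sc[k] != "-") sp <- sp + 1
    }
    len <- j - i + 1
    if (lab[i] == "sub") {
      plus <- vapply(i:j, function(k) matrix[qc[k], sc[k]] > 0, TRUE)
      type <- if (len >= sv_min) "SV"
        else if (len == 1) { if (plus[1]) "SSAP" else "SAP" }
        else if (len <= alt_max) { if (all(plus)) "SALT" else "ALT" }
        else "SV"
      out[[length(out) + 1]] <- data.frame(
        type = type, tge_start = qp_before + 1, tge_end = qp,
        ref_start = sp_before + 1, ref_end = sp,
        tge_seq = paste(qc[i:j], collapse = ""),
        ref_seq = paste(sc[i:j], collapse = ""), stringsAsFactors = FALSE)
    } else if (lab[i] == "ins") {
      out[[length(out) + 1]] <- data.frame(
        type = if (len >= sv_min) "SV" else "INS",
        tge_start = qp_before + 1, tge_end = qp,
        ref_start = sp_before, ref_end = sp_before,
        tge_seq = paste(qc[i:j], collapse = ""), ref_seq = "",
        stringsAsFactors = FALSE)
    } else if (lab[i] == "del") {
      out[[length(out) + 1]] <- data.frame(
        type = if (len >= sv_min) "SV" else "DEL",
        tge_start = qp_before, tge_end = qp_before,
        ref_start = sp_before + 1, ref_end = sp,
        tge_seq = "", ref_seq = paste(sc[i:j], collapse = ""),
        stringsAsFactors = FALSE)
    }
    i <- j + 1
  }
  if (length(out) == 0) {
    return(data.frame(type = character(0), tge_start = integer(0),
                      tge_end = integer(0), ref_start = integer(0),
                      ref_end = integer(0), tge_seq = character(0),
                      ref_seq = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# random gapped alignment with local-alignment invariants (no terminal
# gaps, no gap-vs-gap columns) as a one-row data frame
random_alignment <- function(ncol = 40) {
  repeat {
    types <- sample(c("id", "sub", "ins", "del"), ncol, replace = TRUE,
                    prob = c(0.6, 0.2, 0.1, 0.1))
    if (types[1] %in% c("id", "sub") && types[ncol] %in% c("id", "sub")) break
  }
  qc <- sc <- character(ncol)
  for (i in seq_len(ncol)) {
    if (types[i] == "id") {
      qc[i] <- sc[i] <- sample(AA, 1)
    } else if (types[i] == "sub") {
      pair <- sample(AA, 2)
      qc[i] <- pair[1]; sc[i] <- pair[2]
    } else if (types[i] == "ins") {
      qc[i] <- sample(AA, 1); sc[i] <- "-"
    } else {
      qc[i] <- "-"; sc[i] <- sample(AA, 1)
    }
  }
  q_start <- sample(1:25, 1); s_start <- sample(1:25, 1)
  n_q <- sum(qc != "-"); n_s <- sum(sc != "-")
  data.frame(
    query_id = "q", subject_id = "s", raw_score = 0, bit_score = 0,
    e_value = 1e-40,
    q_start = q_start, q_end = q_start + n_q - 1,
    s_start = s_start, s_end = s_start + n_s - 1,
    q_aln = paste(qc, collapse = ""), s_aln = paste(sc, collapse = ""),
    midline = tgeclass::compute_midline(paste(qc, collapse = ""),
                                        paste(sc, collapse = "")),
    stringsAsFactors = FALSE)
}

# rank-based AUC (Wilcoxon statistic)
wilcox_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# random scoring instance fed through score_variant_vs_reference with an
# identity transform and a lookup detectability, so q and s values are
# fully controlled
random_score_instance <- function() {
  n_v <- sample(0:6, 1); n_r <- sample(0:6, 1)
  if (n_v + n_r == 0) n_v <- 1
  peps <- replicate(n_v + n_r, random_aa(sample(7:20, 1)))
  while (anyDuplicated(peps) > 0) {
    peps <- replicate(n_v + n_r, random_aa(sample(7:20, 1)))
  }
  V <- head(peps, n_v); R <- tail(peps, n_r)
  identified <- peps[runif(n_v + n_r) < 0.5]
  q <- setNames(runif(length(identified), 0, 0.0099), identified)
  s_raw <- setNames(runif(n_v + n_r), peps)
  pepdf <- function(p) {
    data.frame(peptide = p, start = rep(1L, length(p)),
               end = rep(1L, length(p)), stringsAsFactors = FALSE)
  }
  list(
    sets = list(V = pepdf(V), R = pepdf(R)),
    identified_q = q,
    s_transform = identity,
    detectability = function(p) unname(s_raw[p]),
    q_sum_identified = sum(1 - q)
  )
}
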