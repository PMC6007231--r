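#' In-silico tryptic digestion
#'
#' Enumerates tryptic peptides of a protein sequence: trypsin cleaves after
#' lysine or arginine, except when the next residue is proline (the classic
#' KP/RP suppression, configurable). Peptides with up to `missed_cleavages`
#' internal cleavage sites and lengths within `[min_len, max_len]` are
#' returned with 1-based inclusive coordinates.
#'
#' @param sequence Amino-acid string.
#' @param missed_cleavages Maximum number of internal uncut sites (default 0).
#' @param min_len,max_len Peptide length bounds (defaults 1 and `Inf`; the
#'   scoring stage uses 7-45, the typical MS-observable window).
#' @param suppress_proline Apply the KP/RP rule (default `TRUE`).
#' @return data frame with columns `peptide`, `start`, `end`.
#' @examples
#' digest_tryptic("MKRAGKP")  # KP is not cleaved
#' @export
digest_tryptic <- function(sequence, missed_cleavages = 0, min_len = 1,
                           max_len = Inf, suppress_proline = TRUE) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  stopifnot(missed_cleavages >= 0, min_len >= 1, min_len <= max_len)
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  # cleavage after position i
  cut <- which(chars %in% c("K", "R"))
  cut <- cut[cut < n]
  if (suppress_proline) cut <- cut[chars[cut + 1] != "P"]
  bounds <- c(0L, cut, n)  # fragment i spans bounds[i]+1 .. bounds[i+1]
  nfrag <- length(bounds) - 1L
  rows <- vector("list", 0L)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + missed_cleavages)
    for (j in i:jmax) {
      s <- bounds[i] + 1L
      e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len >= min_len && len <= max_len) {
        rows[[length(rows) + 1L]] <- c(s, e)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(peptide = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, rows)
  data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
             start = as.integer(m[, 1]), end = as.integer(m[, 2]),
             stringsAsFactors = FALSE)
}
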