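#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom methods as is
NULL

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# all 61 sense codons
sense_codons <- function() {
  cod <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
               1L, paste0, collapse = "")
  setdiff(cod, STOP_CODONS)
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

translate_nt <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: %s)",
                  what, x[which(bad)[1L]]))
  }
  invisible(x)
}

# derive a stage-specific RNG seed from the run seed; stays < 2^31
stage_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) %% 2^27) * 8 + offset)
}

# fraction of quality characters (Phred+33) at or above min_q, per string
phred_pass_fraction <- function(qual, min_q) {
  thr <- as.integer(min_q) + 33L
  vapply(qual, function(s) mean(utf8ToInt(s) >= thr), numeric(1),
         USE.NAMES = FALSE)
}

# Hamming distance between equal-length strings (vectorised over y)
hamming <- function(x, y) {
  xi <- utf8ToInt(x)
  vapply(y, function(s) sum(utf8ToInt(s) != xi), integer(1), USE.NAMES = FALSE)
}

# do two sequences share an exact common substring of length >= w?
shares_window <- function(a, b, w) {
  if (nchar(a) < w || nchar(b) < w) return(FALSE)
  ka <- substring(a, seq_len(nchar(a) - w + 1L), seq_len(nchar(a) - w + 1L) + w - 1L)
  kb <- substring(b, seq_len(nchar(b) - w + 1L), seq_len(nchar(b) - w + 1L) + w - 1L)
  length(intersect(ka, kb)) > 0L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
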