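# Paired-end read synthesis and FASTQ handling
#
# Read 1 covers the light-chain end of the amplicon, read 2 is the reverse
# complement of the heavy-chain end (so both mates read their chain in sense
# orientation). Substitution errors are injected at a uniform per-base rate;
# qualities follow a MiSeq-like profile whose mean declines linearly across
# the read. Ground truth (source clones, droplet, chimera flag) is serialized
# as key=value tokens in the read header.

#' Synthesize paired-end reads from assemblies
#'
#' @param assemblies an assembly tibble ([simulate_emulsion()], optionally
#'   after [apply_nested_pcr_chimeras()]).
#' @param config a [validate_config()] list; uses `simulation$read_length`,
#'   `seq_error_rate` and the `quality` profile block.
#' @param fastq1,fastq2 output FASTQ paths (gzip-compressed when the file name
#'   ends in `.gz`).
#' @return invisibly, a list with `n_pairs`, `n_skipped` (amplicons shorter
#'   than the read length) and the two paths.
#' @export
synthesize_reads <- function(assemblies, config, fastq1, fastq2) {
  cfg <- validate_config(config)
  sim <- cfg$simulation
  rl <- as.integer(sim$read_length)

  keep <- nchar(assemblies$amplicon) >= rl
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("synthesize_reads: skipped %d amplicon(s) shorter than %d nt",
                    n_skipped, rl))
  }
  a <- assemblies[keep, ]
  n <- nrow(a)

  withr::with_seed(stage_seed(cfg$seed, 4L), {
    r1 <- substr(a$amplicon, 1L, rl)
    r2 <- revcomp(substr(a$amplicon, nchar(a$amplicon) - rl + 1L,
                         nchar(a$amplicon)))
    if (n > 0 && sim$seq_error_rate > 0) {
      seqs <- inject_errors(c(r1, r2), sim$seq_error_rate)
      r1 <- seqs[seq_len(n)]
      r2 <- seqs[n + seq_len(n)]
    }
    q <- quality_strings(2L * max(n, 0L), rl, sim$quality)

    ids <- sprintf("rp%07d hc=%s lc=%s droplet=%s chim=%d",
                   seq_len(n), a$hc_source, a$lc_source,
                   ifelse(is.na(a$droplet_id), "NA", a$droplet_id),
                   as.integer(a$is_chimeric))
    write_fastq(r1, q[seq_len(n)], ids, fastq1)
    write_fastq(r2, q[n + seq_len(n)], ids, fastq2)
  })
  invisible(list(n_pairs = n, n_skipped = n_skipped,
                 fastq1 = fastq1, fastq2 = fastq2))
}

# substitution errors at a uniform per-base rate, over a vector of
# equal-length reads; operates on one concatenated raw vector for speed
inject_errors <- function(reads, rate) {
  nc <- nchar(reads)
  big <- charToRaw(paste(reads, collapse = ""))
  hit <- which(stats::runif(length(big)) < rate)
  if (length(hit)) {
    code <- as.integer(charToRaw(paste(BASES, collapse = "")))
    map <- integer(256)
    map[code] <- 1:4
    cur <- map[as.integer(big[hit])]
    new <- (cur - 1L + sample.int(3L, length(hit), replace = TRUE)) %% 4L + 1L
    big[hit] <- as.raw(code[new])
  }
  ends <- cumsum(nc)
  substring(rawToChar(big), c(1L, utils::head(ends, -1L) + 1L), ends)
}

quality_strings <- function(n_reads, rl, profile) {
  if (n_reads == 0) return(character(0))
  mu <- seq(profile$q_start, profile$q_end, length.out = rl)
  q <- rep(mu, n_reads)
  if (profile$q_sd > 0) q <- q + stats::rnorm(length(q), 0, profile$q_sd)
  q <- pmin(40L, pmax(2L, as.integer(round(q))))
  big <- rawToChar(as.raw(q + 33L))
  substring(big, (seq_len(n_reads) - 1L) * rl + 1L, seq_len(n_reads) * rl)
}

write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a pair of FASTQ files into a tibble
#'
#' @param fastq1,fastq2 mate-1 and mate-2 FASTQ paths (plain or gzipped).
#' @return a tibble with `read_id` (full header of mate 1), `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  rd <- function(p) {
    tryCatch(Biostrings::readDNAStringSet(p, format = "fastq",
                                          with.qualities = TRUE),
             error = function(e) abort(sprintf("malformed FASTQ '%s': %s",
                                               p, conditionMessage(e))))
  }
  r1 <- rd(fastq1)
  r2 <- rd(fastq2)
  if (length(r1) != length(r2)) {
    abort(sprintf("desynchronized FASTQ pair: %d vs %d records",
                  length(r1), length(r2)))
  }
  id1 <- sub("\\s.*$", "", names(r1))
  id2 <- sub("\\s.*$", "", names(r2))
  bad <- which(id1 != id2)
  if (length(bad)) {
    abort(sprintf("desynchronized FASTQ pair at record %d: '%s' vs '%s'",
                  bad[1], id1[bad[1]], id2[bad[1]]))
  }
  tibble(
    read_id = names(r1),
    seq1 = unname(as.character(r1)),
    qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
    seq2 = unname(as.character(r2)),
    qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities))
  )
}

#' Parse ground-truth tags from simulated read headers
#'
#' @param read_id character vector of read headers carrying `key=value`
#'   tokens (`hc=`, `lc=`, `droplet=`, `chim=`).
#' @return a tibble with `truth_hc`, `truth_lc`, `truth_droplet`,
#'   `truth_chimeric`; fields absent from a header are NA.
#' @export
parse_truth_tags <- function(read_id) {
  grab <- function(key) {
    m <- regmatches(read_id, regexpr(sprintf("%s=[^ ]+", key), read_id))
    out <- rep(NA_character_, length(read_id))
    out[grepl(sprintf("%s=", key), read_id)] <- sub(".*=", "", m)
    out
  }
  tibble(
    truth_hc = grab("hc"),
    truth_lc = grab("lc"),
    truth_droplet = suppressWarnings(as.integer(grab("droplet"))),
    truth_chimeric = grab("chim") == "1"
  )
}
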