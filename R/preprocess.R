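# Read-pair preprocessing
#
# Three gates, in order: (1) a per-mate Phred quality filter (a pair is kept
# when, in each mate, at least `min_frac` of the bases reach `min_q`;
# boundaries inclusive); (2) a constant-region scan of both mates and both
# strands for the IgM/IgG/IgK tags; (3) structure classification, keeping only
# pairs with one heavy-constant mate and one kappa-constant mate.

C_SEED_NT <- 20L  # constant-region scan seed length

#' Per-mate Phred quality filter
#'
#' A pair passes when, in each mate separately, the fraction of bases with
#' quality at least `min_q` is at least `min_frac` (both boundaries
#' inclusive: with defaults, exactly half the bases at exactly Q10 passes).
#'
#' @param qual1,qual2 Phred+33 quality strings of the two mates (vectorized).
#' @param min_q minimum base quality.
#' @param min_frac minimum fraction of bases at or above `min_q`.
#' @return logical vector, TRUE where the pair is retained.
#' @export
quality_filter <- function(qual1, qual2, min_q = 10, min_frac = 0.5) {
  phred_pass_fraction(qual1, min_q) >= min_frac &
    phred_pass_fraction(qual2, min_q) >= min_frac
}

#' Scan sequences for constant-region tags
#'
#' Seed-and-extend search of each sequence (both strands) for the 20-nt seed
#' of every constant-region segment in the reference, tolerating up to
#' `max_mismatch` substitutions. The best hit per sequence is the one with the
#' fewest mismatches, ties broken by earliest position, then by isotype order
#' (IgM, IgG, IgK), then by plus strand.
#'
#' @param seqs character vector of nucleotide sequences.
#' @param ref a `germline_reference` containing C segments.
#' @param max_mismatch maximum substitutions tolerated in the seed.
#' @return a tibble with one row per sequence: `isotype`, `c_call`,
#'   `mismatches`, `position` (1-based start of the seed match), `strand`
#'   (`"+"`/`"-"`); all NA when no tag matches.
#' @export
scan_constant_region <- function(seqs, ref, max_mismatch = 2) {
  ctags <- ref_segments(ref, segment_class = "C")
  if (nrow(ctags) == 0) abort("reference contains no C segments")
  ord <- order(match(ctags$family, c("IgM", "IgG", "IgK")))
  ctags <- ctags[ord, ]
  n <- length(seqs)
  empty <- tibble(isotype = rep(NA_character_, n), c_call = NA_character_,
                  mismatches = NA_integer_, position = NA_integer_,
                  strand = NA_character_)
  if (n == 0) return(empty)
  subj <- Biostrings::DNAStringSet(ifelse(nchar(seqs) == 0, "N", seqs))

  combos <- tidyr::expand_grid(tag = seq_len(nrow(ctags)), strand = c("+", "-"))
  mm_mat <- matrix(NA_integer_, n, nrow(combos))
  pos_mat <- matrix(NA_integer_, n, nrow(combos))
  for (k in seq_len(nrow(combos))) {
    seed <- substr(ctags$sequence[combos$tag[k]], 1L, C_SEED_NT)
    if (combos$strand[k] == "-") seed <- revcomp(seed)
    for (mm in 0:max_mismatch) {
      todo <- which(is.na(mm_mat[, k]) & nchar(seqs) >= C_SEED_NT)
      if (!length(todo)) break
      cnt <- Biostrings::vcountPattern(seed, subj[todo], max.mismatch = mm)
      mm_mat[todo[cnt > 0L], k] <- mm
    }
    found <- which(!is.na(mm_mat[, k]))
    if (length(found)) {
      hits <- Biostrings::vmatchPattern(seed, subj[found],
                                        max.mismatch = max_mismatch)
      pos_mat[found, k] <- vapply(Biostrings::startIndex(hits), function(s) {
        as.integer(min(s))
      }, integer(1))
    }
  }

  best <- apply(mm_mat, 1L, function(r) if (all(is.na(r))) NA_integer_ else min(r, na.rm = TRUE))
  out <- empty
  hit_rows <- which(!is.na(best))
  for (i in hit_rows) {
    cand <- which(mm_mat[i, ] == best[i])
    cand <- cand[order(pos_mat[i, cand], cand)]  # earliest, then IgM/IgG/IgK, then +
    k <- cand[1L]
    out$isotype[i] <- ctags$family[combos$tag[k]]
    out$c_call[i] <- ctags$id[combos$tag[k]]
    out$mismatches[i] <- mm_mat[i, k]
    out$position[i] <- pos_mat[i, k]
    out$strand[i] <- combos$strand[k]
  }
  out
}

#' Classify amplicon structure of read pairs
#'
#' Applies [scan_constant_region()] to both mates and maps every pair to one
#' of `HC_LC` (one heavy-constant mate, one kappa mate), `HC_HC`, `LC_LC`, or
#' `NO_CONSTANT` (at least one mate without a tag). For `HC_LC` pairs the two
#' mates are reoriented to sense strand (constant tag on the plus strand) and
#' exposed as `heavy_seq` / `light_seq`.
#'
#' @param pairs a tibble with `seq1` and `seq2` columns (e.g. from
#'   [read_fastq_pairs()]).
#' @param ref a `germline_reference`.
#' @param max_mismatch maximum seed substitutions for the tag scan.
#' @return `pairs` with added columns `structure_class`, `heavy_mate` (1 or
#'   2), `heavy_isotype`, `heavy_seq`, `light_seq` (NA unless `HC_LC`).
#' @export
classify_structure <- function(pairs, ref, max_mismatch = 2) {
  s1 <- scan_constant_region(pairs$seq1, ref, max_mismatch)
  s2 <- scan_constant_region(pairs$seq2, ref, max_mismatch)
  heavy1 <- s1$isotype %in% c("IgM", "IgG")
  heavy2 <- s2$isotype %in% c("IgM", "IgG")
  kappa1 <- s1$isotype %in% "IgK"
  kappa2 <- s2$isotype %in% "IgK"

  cls <- dplyr::case_when(
    (heavy1 & kappa2) | (kappa1 & heavy2) ~ "HC_LC",
    heavy1 & heavy2 ~ "HC_HC",
    kappa1 & kappa2 ~ "LC_LC",
    TRUE ~ "NO_CONSTANT"
  )
  heavy_mate <- ifelse(cls == "HC_LC", ifelse(heavy1, 1L, 2L), NA_integer_)
  sense <- function(seq, strand) ifelse(strand == "-", revcomp(seq), seq)
  hc_lc <- cls == "HC_LC"
  heavy_seq <- light_seq <- rep(NA_character_, nrow(pairs))
  heavy_isotype <- rep(NA_character_, nrow(pairs))
  if (any(hc_lc)) {
    m1 <- hc_lc & heavy_mate == 1L
    m2 <- hc_lc & heavy_mate == 2L
    heavy_seq[m1] <- sense(pairs$seq1[m1], s1$strand[m1])
    light_seq[m1] <- sense(pairs$seq2[m1], s2$strand[m1])
    heavy_seq[m2] <- sense(pairs$seq2[m2], s2$strand[m2])
    light_seq[m2] <- sense(pairs$seq1[m2], s1$strand[m2])
    heavy_isotype[m1] <- s1$isotype[m1]
    heavy_isotype[m2] <- s2$isotype[m2]
  }
  pairs |>
    mutate(structure_class = cls, heavy_mate = heavy_mate,
           heavy_isotype = heavy_isotype,
           heavy_seq = heavy_seq, light_seq = light_seq)
}

#' Run the full preprocessing stage on a FASTQ pair
#'
#' Reads the two mates, applies the quality filter, scans and classifies the
#' survivors, and retains only `HC_LC` pairs. The report satisfies the
#' accounting identity `input_pairs = fail_quality + sum(class counts)` and
#' `retained_pairs = count(HC_LC)`; input order is preserved.
#'
#' @param fastq1,fastq2 input FASTQ paths.
#' @param ref a `germline_reference`.
#' @param min_q,min_frac quality-filter parameters (see [quality_filter()]).
#' @param max_c_mismatch tag-scan mismatch tolerance.
#' @return a list with `pairs` (retained HC_LC pairs, sense-oriented heavy and
#'   light sequences) and `report` (a `preprocess_report`; see
#'   [glance.preprocess_report()]).
#' @export
preprocess_run <- function(fastq1, fastq2, ref, min_q = 10, min_frac = 0.5,
                           max_c_mismatch = 2) {
  pairs <- read_fastq_pairs(fastq1, fastq2)
  bad <- which(nchar(pairs$seq1) != nchar(pairs$qual1) |
                 nchar(pairs$seq2) != nchar(pairs$qual2))
  if (length(bad)) {
    abort(sprintf("sequence/quality length mismatch at record %d", bad[1]))
  }
  n <- nrow(pairs)
  classes <- c("HC_LC", "HC_HC", "LC_LC", "NO_CONSTANT")
  if (n == 0) {
    report <- new_preprocess_report(0L, 0L, stats::setNames(rep(0L, 4), classes))
    return(list(pairs = pairs[0, ], report = report))
  }
  ok <- quality_filter(pairs$qual1, pairs$qual2, min_q, min_frac)
  classified <- classify_structure(pairs[ok, , drop = FALSE], ref, max_c_mismatch)
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(classified$structure_class == cl), integer(1)),
    classes)
  report <- new_preprocess_report(n, sum(!ok), counts)
  list(pairs = classified[classified$structure_class == "HC_LC", , drop = FALSE],
       report = report)
}

new_preprocess_report <- function(input_pairs, fail_quality, class_counts) {
  structure(list(input_pairs = as.integer(input_pairs),
                 fail_quality = as.integer(fail_quality),
                 class_counts = class_counts,
                 retained_pairs = unname(class_counts["HC_LC"])),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf("Preprocess report: %d pairs in, %d failed quality, %d retained (HC_LC)\n",
              x$input_pairs, x$fail_quality, x$retained_pairs))
  cat("  class counts:",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Summarize a preprocess report as a one-row tibble
#'
#' @param x a `preprocess_report`.
#' @param ... unused.
#' @return a one-row tibble with the filter funnel counts.
#' @export
glance.preprocess_report <- function(x, ...) {
  tibble(input_pairs = x$input_pairs, fail_quality = x$fail_quality,
         hc_lc = unname(x$class_counts["HC_LC"]),
         hc_hc = unname(x$class_counts["HC_HC"]),
         lc_lc = unname(x$class_counts["LC_LC"]),
         no_constant = unname(x$class_counts["NO_CONSTANT"]),
         retained_pairs = x$retained_pairs)
}
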