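# Shared fixtures and independent brute-force oracles.
# Oracles are written from the definitions, independently of the package's
# implementation paths, so tests compare two routes to the same quantity.

`%||%` <- function(x, y) if (is.null(x)) y else x

test_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- build_toy_reference(7, 6, seed = 42)
    ref
  }
})

sim_cfg <- function(..., seed = 7) {
  validate_config(list(seed = seed, simulation = list(...)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# ---- brute-force oracles ---------------------------------------------------

# minimal Hamming mismatches of `pattern` over every window of `seq`, both
# strands; returns list(mismatches, position, strand) or NAs
bf_seed_scan <- function(seq, pattern) {
  best <- list(mismatches = NA_integer_, position = NA_integer_,
               strand = NA_character_)
  for (strand in c("+", "-")) {
    pat <- if (strand == "-") rc(pattern) else pattern
    np <- nchar(pat)
    if (nchar(seq) < np) next
    p <- utf8ToInt(pat)
    for (start in seq_len(nchar(seq) - np + 1L)) {
      mm <- sum(utf8ToInt(substr(seq, start, start + np - 1L)) != p)
      if (is.na(best$mismatches) || mm < best$mismatches) {
        best <- list(mismatches = mm, position = start, strand = strand)
      }
    }
  }
  best
}

# best ungapped local alignment score (+1 match / -1 mismatch) of read vs ref,
# maximized over all offsets (Kadane over the match/mismatch profile)
bf_local_score <- function(read, refseq) {
  r <- utf8ToInt(read)
  s <- utf8ToInt(refseq)
  best <- 0
  for (off in (-(length(s) - 1L)):(length(r) - 1L)) {
    i <- max(1L, 1L + off):min(length(r), length(s) + off)
    if (!length(i)) next
    v <- ifelse(r[i] == s[i - off], 1, -1)
    run <- 0
    for (x in v) {
      run <- max(0, run + x)
      best <- max(best, run)
    }
  }
  best
}

# expected mispair fraction by explicit enumeration over droplet compositions:
# j co-occupants (Poisson(lambda), j <= kmax), each independently from clone
# fractions w; the light template is uniform over the j+1 occupants
bf_expected_mispair <- function(lambda, w, kmax = 6) {
  w <- w / sum(w)
  total <- 0
  for (j in seq_len(kmax)) {
    pj <- stats::dpois(j, lambda)
    # composition of the j co-occupants over clones, conditional on my clone c
    for (c in seq_along(w)) {
      # expected number of co-occupants not from clone c is j * (1 - w[c]);
      # enumerate the count explicitly instead of using the expectation
      for (d in 0:j) {
        pd <- stats::dbinom(d, j, 1 - w[c])
        total <- total + w[c] * pj * pd * d / (j + 1)
      }
    }
  }
  total
}

# elementwise Hamming distance between two equal-length string vectors
hamming_pairs <- function(x, y) {
  mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)), x, y,
         USE.NAMES = FALSE)
}

# Levenshtein distance by textbook dynamic programming
bf_edit_distance <- function(a, b) {
  x <- utf8ToInt(a)
  y <- utf8ToInt(b)
  d <- matrix(0L, length(x) + 1L, length(y) + 1L)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1L, length(y) + 1L]
}

# ---- fixture builders ------------------------------------------------------

write_test_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
  out <- character(4L * length(ids))
  out[seq(1, length(out), 4)] <- paste0("@", ids)
  out[seq(2, length(out), 4)] <- seqs
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- quals
  writeLines(out, path)
  path
}

good_qual <- function(n = 250) strrep("I", n)                  # Q40 throughout
bad_qual <- function(n = 250) {                                # 48% at Q30
  k <- ceiling(0.52 * n)
  paste0(strrep("#", k), strrep("?", n - k))
}

# read pairs of planted structure classes built from clone cassettes;
# returns tibble(id, seq1, seq2, qual1, qual2, class, fail_quality)
make_planted_pairs <- function(ref, n_per_class, seed = 99,
                               n_fail_quality = 0) {
  cfg <- sim_cfg(n_clones = 6, abundance_exponent = 0, secretion_sd = 0,
                 seed = seed)
  clones <- simulate_repertoire(cfg, ref)
  withr::with_seed(seed, {
    hc_read <- function() substr(sample(clones$hc_chain_nt, 1), 1, 250)
    lc_read <- function() substr(sample(clones$lc_chain_nt, 1), 1, 250)
    one <- function(class) {
      switch(class,
             HC_LC = list(seq1 = lc_read(), seq2 = hc_read()),
             HC_HC = list(seq1 = hc_read(), seq2 = hc_read()),
             LC_LC = list(seq1 = lc_read(), seq2 = lc_read()),
             NO_CONSTANT = list(seq1 = rand_dna(250), seq2 = rand_dna(250)))
    }
    classes <- rep(names(n_per_class), n_per_class)
    rows <- lapply(classes, one)
    n <- length(rows)
    fail <- rep(FALSE, n)
    fail[seq_len(min(n_fail_quality, n))] <- TRUE
    tibble::tibble(
      id = sprintf("fx%05d", seq_len(n)),
      seq1 = vapply(rows, `[[`, "", "seq1"),
      seq2 = vapply(rows, `[[`, "", "seq2"),
      qual1 = ifelse(fail, bad_qual(), good_qual()),
      qual2 = good_qual(),
      class = classes,
      fail_quality = fail
    )[sample(n), ]
  })
}
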