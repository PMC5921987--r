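ref <- test_ref()

test_that("align_segment matches exhaustive scoring and makes no spurious calls", {
  vh <- ref_segments(ref, "heavy", "V")
  withr::with_seed(3, {
    # exact copy of a V segment: full-length score
    v1 <- vh$sequence[1]
    hit <- align_segment(v1, ref, "heavy", "V")
    expect_equal(hit$segment_id, vh$id[1])
    expect_equal(hit$score, nchar(v1))

    # read with 3 substitutions against its source V; every other candidate
    # is much further away; verify the winner against brute-force scoring of
    # all candidates
    read <- v1
    for (p in c(10, 60, 140)) {
      substr(read, p, p) <- setdiff(c("A", "C", "G", "T"), substr(read, p, p))[1]
    }
    hit <- align_segment(read, ref, "heavy", "V")
    bf_scores <- vapply(vh$sequence, function(s) bf_local_score(read, s),
                        numeric(1))
    expect_equal(hit$segment_id, vh$id[which.max(bf_scores)])
    expect_equal(hit$score, max(bf_scores))
    expect_equal(hit$segment_id, vh$id[1])

    # random non-Ig sequence: no call
    expect_true(is.na(align_segment(rand_dna(250), ref, "heavy", "V")$segment_id))
  })
})

test_that("batch alignment agrees with single-read exhaustive alignment", {
  cfg <- sim_cfg(n_clones = 8, n_cells = 120, seq_error_rate = 0.005, seed = 9)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  pp <- preprocess_run(f1, f2, ref)
  seqs <- utils::head(pp$pairs$heavy_seq, 30)
  batch <- pairem:::align_batch(seqs, ref_segments(ref, "heavy", "V"), 60)
  for (i in seq_along(seqs)) {
    single <- align_segment(seqs[i], ref, "heavy", "V")
    expect_identical(batch$segment_id[i], single$segment_id)
    expect_identical(batch$score[i], single$score)
  }
})

test_that("CDR3 extraction recovers planted junctions and handles boundaries", {
  cfg <- sim_cfg(n_clones = 10, n_cells = 150, seq_error_rate = 0,
                 force_single_occupancy = TRUE, seed = 10)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  pp <- preprocess_run(f1, f2, ref)
  truth <- parse_truth_tags(pp$pairs$read_id)
  planted <- clones$cdr3_heavy_nt[match(truth$truth_hc, clones$clone_id)]
  got <- vapply(seq_len(nrow(pp$pairs)), function(i) {
    cl <- clones[clones$clone_id == truth$truth_hc[i], ]
    extract_cdr3(pp$pairs$heavy_seq[i], cl$v_heavy, cl$j_heavy, ref)
  }, character(1))
  expect_identical(got, planted)

  # read truncated before the J anchor: no CDR3
  cl <- clones[1, ]
  v <- ref[ref$id == cl$v_heavy, ]
  short <- substr(cl$hc_chain_nt, 1, 3 * v$cys_anchor + 3)
  expect_true(is.na(extract_cdr3(short, cl$v_heavy, cl$j_heavy, ref)))

  # minimal junction: V cys codon directly followed by the J anchor codon
  j <- ref[ref$id == cl$j_heavy, ]
  cys <- substr(v$sequence, 3 * v$cys_anchor + 1, 3 * v$cys_anchor + 3)
  minimal <- paste0(substr(v$sequence, 1, 3 * v$cys_anchor), cys,
                    substr(j$sequence, 3 * j$fr4_anchor + 1, nchar(j$sequence)))
  got_min <- extract_cdr3(minimal, cl$v_heavy, cl$j_heavy, ref)
  expect_equal(nchar(got_min), 6)
  expect_equal(got_min, paste0(cys, substr(j$sequence, 3 * j$fr4_anchor + 1,
                                           3 * j$fr4_anchor + 3)))
})

test_that("translation flags frameshifts and stop codons", {
  worked <- translate_and_check("TGTGCAAGACAAGCCGACAACTGGTTCGACCCCTGG")
  expect_equal(worked$cdr3_aa, "CARQADNWFDPW")
  expect_true(worked$productive)

  expect_false(translate_and_check(strrep("A", 35))$productive)  # frameshift
  withstop <- translate_and_check("TGTGCATAAGGGTGG")
  expect_false(withstop$productive)
  expect_error(translate_and_check("TGTNNNTGG"), "non-ACGT")
})

test_that("pair annotation is orientation-agnostic and rejects junk chains", {
  cfg <- sim_cfg(n_clones = 4, n_cells = 30, seq_error_rate = 0, seed = 11)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  pair <- tibble::tibble(seq1 = substr(asm$amplicon[1], 1, 250),
                         seq2 = rc(substr(asm$amplicon[1],
                                          nchar(asm$amplicon[1]) - 249,
                                          nchar(asm$amplicon[1]))))
  ann <- annotate_pair(pair, ref)
  expect_equal(nrow(ann), 1)
  cl <- clones[clones$clone_id == asm$hc_source[1], ]
  expect_equal(ann$junction_h, cl$cdr3_heavy_nt)
  expect_equal(ann$v_call_h, cl$v_heavy)

  # swapping mates or reverse-complementing one leaves the annotation alone
  cols <- setdiff(names(ann), "sequence_id")
  swapped <- annotate_pair(tibble::tibble(seq1 = pair$seq2, seq2 = pair$seq1), ref)
  expect_equal(swapped[cols], ann[cols])
  flipped <- annotate_pair(tibble::tibble(seq1 = pair$seq1, seq2 = rc(pair$seq2)),
                           ref)
  expect_equal(flipped[cols], ann[cols])

  # heavy mate replaced by random sequence: rejected
  withr::with_seed(12, {
    junk <- annotate_pair(tibble::tibble(seq1 = pair$seq1, seq2 = rand_dna(250)),
                          ref)
    expect_equal(nrow(junk), 0)
  })
})

test_that("error-free annotation recovers all planted V/J/CDR3 assignments", {
  cfg <- sim_cfg(n_clones = 12, n_cells = 200, seq_error_rate = 0,
                 force_single_occupancy = TRUE, seed = 13)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  pp <- preprocess_run(f1, f2, ref)
  ann <- annotate_run(pp$pairs, ref)
  expect_equal(nrow(ann), nrow(pp$pairs))
  truth <- parse_truth_tags(ann$sequence_id)
  idx <- match(truth$truth_hc, clones$clone_id)
  expect_identical(ann$v_call_h, clones$v_heavy[idx])
  expect_identical(ann$j_call_h, clones$j_heavy[idx])
  expect_identical(ann$junction_h, clones$cdr3_heavy_nt[idx])
  idx_k <- match(truth$truth_lc, clones$clone_id)
  expect_identical(ann$v_call_k, clones$v_light[idx_k])
  expect_identical(ann$junction_k, clones$cdr3_light_nt[idx_k])
  expect_true(all(ann$productive_h & ann$productive_k))
  expect_true(all(ann$anchored_h & ann$anchored_k))

  airr <- as_airr(ann)
  expect_equal(nrow(airr), 2 * nrow(ann))
  expect_setequal(unique(airr$locus), c("IGH", "IGK"))
})
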