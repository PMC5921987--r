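ref <- test_ref()

mk_groups <- function(seqs, counts, v_family = "VH1", j_call = "IGHJ4") {
  tibble::tibble(v_family = v_family, j_call = j_call, cdr3_nt = seqs,
                 read_count = counts)
}

test_that("PCR-error absorption follows the count-ratio and mismatch rules", {
  a <- "TGTGCAAGACAAGCCGACAACTGG"
  a1 <- sub("^TGTG", "TGTC", a)            # 1 mismatch from a
  a2 <- sub("^TGTGC", "TGTCA", a)          # 2 mismatches from a

  # minor absorbed into dominant major
  res <- cluster_cdr3(mk_groups(c(a, a1), c(100, 3)))
  expect_equal(nrow(res), 1)
  expect_equal(res$cdr3_nt, a)
  expect_equal(res$read_count, 103)

  # two mismatches apart: kept separate
  res2 <- cluster_cdr3(mk_groups(c(a, a2), c(100, 3)))
  expect_equal(nrow(res2), 2)
  expect_equal(sum(res2$read_count), 103)

  # insufficient ratio: kept separate
  res3 <- cluster_cdr3(mk_groups(c(a, a1), c(5, 5)))
  expect_equal(nrow(res3), 2)

  # different V family blocks absorption
  res4 <- cluster_cdr3(dplyr::bind_rows(
    mk_groups(a, 100, v_family = "VH1"),
    mk_groups(a1, 3, v_family = "VH2")))
  expect_equal(nrow(res4), 2)
})

test_that("clustering conserves read counts and ignores input order", {
  withr::with_seed(20, {
    for (rep in 1:5) {
      base <- vapply(1:8, function(i) rand_dna(24), character(1))
      variants <- vapply(base, function(s) {
        p <- sample(24, 1)
        substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
        s
      }, character(1))
      counts <- sample(c(sample(50:500, 8), sample(1:4, 8, replace = TRUE)))
      g <- mk_groups(c(base, variants), counts)
      res <- cluster_cdr3(g)
      expect_equal(sum(res$read_count), sum(counts))
      # permutation invariance (unique counts not guaranteed for minors, so
      # compare the aggregated table)
      perm <- g[sample(nrow(g)), ]
      expect_equal(as.data.frame(cluster_cdr3(perm)), as.data.frame(res))
    }
  })
})

test_that("paired clonotype table keys, orders and normalizes correctly", {
  cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 120, seq_error_rate = 0,
                 force_single_occupancy = TRUE, seed = 21)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  ann <- annotate_run(preprocess_run(f1, f2, ref)$pairs, ref)
  pairs <- build_paired_clonotypes(ann)
  filtered <- filter_clonotypes(pairs)

  # three clean clones, no contamination: exactly three pairs post-filter
  expect_equal(nrow(filtered), 3)
  expect_setequal(filtered$cdr3_nt_h, clones$cdr3_heavy_nt)
  expect_setequal(filtered$cdr3_nt_k, clones$cdr3_light_nt)
  expect_equal(sum(pairs$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(filtered$frequency), 1, tolerance = 1e-9)
  expect_equal(sum(pairs$read_count), nrow(ann))
  # deterministic ordering by descending count
  expect_true(all(diff(filtered$read_count) <= 0))
})

test_that("planted repertoire is recovered exactly at zero error rate", {
  cfg <- sim_cfg(n_clones = 100, n_cells = 4000, seq_error_rate = 0,
                 force_single_occupancy = TRUE, abundance_exponent = 0.8,
                 seed = 22)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  ann <- annotate_run(preprocess_run(f1, f2, ref)$pairs, ref)
  pairs <- build_paired_clonotypes(ann)

  planted_keys <- paste(clones$cdr3_heavy_nt, clones$cdr3_light_nt)
  observed_keys <- paste(pairs$cdr3_nt_h, pairs$cdr3_nt_k)
  # every observed pair is a planted cognate pair (single occupancy, no error)
  expect_true(all(observed_keys %in% planted_keys))
  # and the recovered set equals the planted set of sampled clones
  truth <- parse_truth_tags(ann$sequence_id)
  sampled <- planted_keys[clones$clone_id %in% truth$truth_hc]
  expect_setequal(observed_keys, sampled)
})

test_that("read-support filter keeps >= min_reads productive pairs only", {
  tbl <- build_paired_clonotypes(tibble::tibble(
    sequence_id = sprintf("r%d", 1:5),
    c_call_h = "IGHG", isotype = "IgG",
    v_call_h = "IGHV1-1", j_call_h = "IGHJ4", v_family_h = "VH1",
    v_score_h = 1, j_score_h = 1,
    junction_h = c(rep("TGTAAATGG", 3), "TGTCCCTGG", "TGTCCCTGG"),
    junction_aa_h = "", productive_h = TRUE, anchored_h = TRUE,
    c_call_k = "IGKC",
    v_call_k = "IGKV1-1", j_call_k = "IGKJ1", v_family_k = "VK1",
    v_score_k = 1, j_score_k = 1,
    junction_k = c(rep("TGTAAATTC", 3), "TGTCCCTTC", "TGTAAATTC"),
    junction_aa_k = "", productive_k = TRUE, anchored_k = TRUE
  ))
  expect_equal(nrow(tbl), 3)
  kept <- filter_clonotypes(tbl, min_reads = 2)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$read_count, 3)
  expect_equal(kept$frequency, 1)
  # boundary: a pair with exactly min_reads reads is kept
  kept2 <- filter_clonotypes(tbl, min_reads = 1)
  expect_equal(nrow(kept2), 3)
  # empty input
  expect_equal(nrow(filter_clonotypes(tbl[0, ], 2)), 0)
})

test_that("unproductive junctions are dropped by the filter", {
  base <- tibble::tibble(
    v_family_h = "VH1", j_call_h = "IGHJ4",
    cdr3_nt_h = c("TGTAAATGG", "TGTTAATGG"), cdr3_aa_h = c("CKW", "C*W"),
    productive_h = c(TRUE, FALSE),
    v_family_k = "VK1", j_call_k = "IGKJ1",
    cdr3_nt_k = "TGTAAATTC", cdr3_aa_k = "CKF", productive_k = TRUE,
    isotype = "IgM", read_count = c(10L, 10L), frequency = c(0.5, 0.5))
  out <- filter_clonotypes(base, min_reads = 2)
  expect_equal(nrow(out), 1)
  expect_true(out$productive_h)
})

test_that("error-rate > 0: clustering shrinks spurious clonotypes, never below truth", {
  cfg <- sim_cfg(n_clones = 10, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 1500, seq_error_rate = 0.005,
                 force_single_occupancy = TRUE, seed = 23)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, f1, f2)
  ann <- annotate_run(preprocess_run(f1, f2, ref)$pairs, ref)

  exact_heavy <- dplyr::n_distinct(paste(ann$v_family_h, ann$j_call_h,
                                         ann$junction_h))
  clustered <- cluster_cdr3(tibble::tibble(v_family = ann$v_family_h,
                                           j_call = ann$j_call_h,
                                           cdr3_nt = ann$junction_h))
  expect_lt(nrow(clustered), exact_heavy)
  expect_gte(nrow(clustered), 10)
  expect_equal(sum(clustered$read_count), nrow(ann))
})
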