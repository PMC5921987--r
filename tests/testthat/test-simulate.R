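ref <- test_ref()

test_that("repertoire abundances follow the configured skew and constraints", {
  one <- simulate_repertoire(sim_cfg(n_clones = 1), ref)
  expect_equal(nrow(one), 1)
  expect_equal(one$cell_fraction, 1)

  spiked <- simulate_repertoire(sim_cfg(n_clones = 50, spike_in_fraction = 0.005),
                                ref)
  expect_equal(sum(spiked$is_spike_in), 1)
  expect_equal(spiked$cell_fraction[spiked$is_spike_in], 0.005)
  expect_equal(sum(spiked$cell_fraction), 1, tolerance = 1e-12)

  # a larger exponent concentrates more mass in the top-10 clones
  flat <- simulate_repertoire(sim_cfg(n_clones = 1000, abundance_exponent = 0.5),
                              ref)
  steep <- simulate_repertoire(sim_cfg(n_clones = 1000, abundance_exponent = 1.5),
                               ref)
  top10 <- function(x) sum(sort(x$cell_fraction, decreasing = TRUE)[1:10])
  expect_gte(top10(steep), top10(flat))

  # determinism per seed
  expect_identical(simulate_repertoire(sim_cfg(n_clones = 20, seed = 3), ref),
                   simulate_repertoire(sim_cfg(n_clones = 20, seed = 3), ref))
})

test_that("simulated clones are productive with distinct anchored junctions", {
  clones <- simulate_repertoire(sim_cfg(n_clones = 40), ref)
  for (col in c("cdr3_heavy_nt", "cdr3_light_nt")) {
    expect_false(anyDuplicated(clones[[col]]) > 0)
    tr <- translate_and_check(clones[[col]])
    expect_true(all(tr$productive))
    expect_true(all(startsWith(tr$cdr3_aa, "C")))
    expect_true(all(grepl("[WF]$", tr$cdr3_aa)))
  }
})

test_that("forced single occupancy yields zero mispaired assemblies", {
  cfg <- sim_cfg(n_clones = 5, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 2000, force_single_occupancy = TRUE)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  expect_gt(nrow(asm), 0)
  expect_equal(sum(asm$is_chimeric), 0)
  expect_false(anyDuplicated(asm$droplet_id) > 0)
})

test_that("emulsion mispair fraction matches the enumeration oracle", {
  lambda <- 0.2
  cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 20000, microsomes_per_cell_mean = 1,
                 droplet_lambda = lambda, seed = 21)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  p_hat <- mean(asm$is_chimeric)
  p_exp <- bf_expected_mispair(lambda, rep(1 / 3, 3))
  sigma <- sqrt(p_exp * (1 - p_exp) / nrow(asm))
  expect_lt(abs(p_hat - p_exp), 3 * sigma)
  # the package's closed-form prediction agrees with the enumeration
  expect_equal(expected_mispair_fraction(lambda, rep(1 / 3, 3)), p_exp,
               tolerance = 1e-12)
})

test_that("mispair fraction is monotone non-decreasing in droplet occupancy", {
  clones <- simulate_repertoire(
    sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
            n_cells = 15000, seed = 8), ref)
  rates <- vapply(c(0.01, 0.05, 0.2, 1.0), function(lambda) {
    cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                   n_cells = 15000, droplet_lambda = lambda, seed = 8)
    mean(simulate_emulsion(clones, cfg)$is_chimeric)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("open mode pairs chains independently of droplet structure", {
  cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                 mode = "open", n_assemblies = 9000, seed = 12)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  expect_equal(nrow(asm), 9000)
  expect_true(all(is.na(asm$droplet_id)))
  tab <- table(asm$hc_source, asm$lc_source)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})

test_that("chimera step is a no-op at base rate zero and obeys the planted rate", {
  cfg0 <- sim_cfg(n_clones = 4, abundance_exponent = 0, secretion_sd = 0,
                  n_cells = 1000, chimera_base_rate = 0)
  asm <- simulate_emulsion(simulate_repertoire(cfg0, ref), cfg0)
  expect_identical(apply_nested_pcr_chimeras(asm, cfg0, ref), asm)

  # two species with the same HC V gene: chimeric fraction ~ base rate
  clones <- simulate_repertoire(
    sim_cfg(n_clones = 2, abundance_exponent = 0, secretion_sd = 0), ref)
  clones$v_heavy <- clones$v_heavy[1]   # same V gene for both species
  cfg <- sim_cfg(n_clones = 2, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 20000, chimera_base_rate = 0.2,
                 force_single_occupancy = TRUE, seed = 31)
  asm <- apply_nested_pcr_chimeras(simulate_emulsion(clones, cfg), cfg, ref)
  p_hat <- mean(asm$is_chimeric)
  sigma <- sqrt(0.2 * 0.8 / nrow(asm))
  expect_lt(abs(p_hat - 0.2), 3 * sigma)
  # chimera truth flags count exactly the LC-swap events here
  expect_identical(asm$is_chimeric, asm$lc_swapped)
})

test_that("same-superfamily amplicons form chimeras at a higher rate", {
  clones <- make_defined_clones(ref, seed = 2)
  cfg <- sim_cfg(n_clones = 4, chimera_base_rate = 0.12, seed = 14)
  asm <- pairem:::pure_assemblies(clones, 3000)
  out <- apply_nested_pcr_chimeras(asm, cfg, ref)
  v <- ref[ref$segment_class == "V", ]
  sf <- setNames(v$superfamily[match(clones$v_heavy, v$id)], clones$clone_id)
  big_sf <- names(sort(table(sf), decreasing = TRUE))[1]
  clone_rate <- tapply(out$is_chimeric, out$hc_source, mean)
  expect_gt(min(clone_rate[names(sf)[sf == big_sf]]),
            max(clone_rate[names(sf)[sf != big_sf]]))
})

test_that("error-free reads are exact substrings of the amplicon", {
  cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 50, seq_error_rate = 0, seed = 4)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  fq1 <- withr::local_tempfile(fileext = ".fastq")
  fq2 <- withr::local_tempfile(fileext = ".fastq")
  synthesize_reads(asm, cfg, fq1, fq2)
  pairs <- read_fastq_pairs(fq1, fq2)
  expect_true(all(nchar(pairs$seq1) == 250))
  expect_true(all(nchar(pairs$seq2) == 250))
  expect_identical(pairs$seq1, substr(asm$amplicon, 1, 250))
  expect_identical(pairs$seq2,
                   rc(substr(asm$amplicon, nchar(asm$amplicon) - 249,
                             nchar(asm$amplicon))))
})

test_that("sequencing errors land at the configured substitution rate", {
  rate <- 0.01
  cfg <- sim_cfg(n_clones = 3, abundance_exponent = 0, secretion_sd = 0,
                 n_cells = 300, seq_error_rate = rate, seed = 5)
  clones <- simulate_repertoire(cfg, ref)
  asm <- simulate_emulsion(clones, cfg)
  cfg0 <- cfg
  cfg0$simulation$seq_error_rate <- 0
  fq <- replicate(4, withr::local_tempfile(fileext = ".fastq"))
  synthesize_reads(asm, cfg, fq[1], fq[2])
  synthesize_reads(asm, cfg0, fq[3], fq[4])
  err <- read_fastq_pairs(fq[1], fq[2])
  tru <- read_fastq_pairs(fq[3], fq[4])
  mism <- sum(hamming_pairs(err$seq1, tru$seq1)) +
    sum(hamming_pairs(err$seq2, tru$seq2))
  n_bases <- 2 * 250 * nrow(err)
  expect_gt(n_bases, 100000)
  sigma <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(mism / n_bases - rate), 3 * sigma)
})

test_that("read synthesis is byte-identical for a fixed seed", {
  cfg <- sim_cfg(n_clones = 5, n_cells = 200, seed = 17)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  f <- replicate(4, withr::local_tempfile(fileext = ".fastq"))
  synthesize_reads(asm, cfg, f[1], f[2])
  synthesize_reads(asm, cfg, f[3], f[4])
  expect_identical(unname(tools::md5sum(f[1])), unname(tools::md5sum(f[3])))
  expect_identical(unname(tools::md5sum(f[2])), unname(tools::md5sum(f[4])))
})

test_that("amplicons shorter than the read length are skipped with a count", {
  cfg <- sim_cfg(n_clones = 2, n_cells = 20, seed = 6)
  asm <- simulate_emulsion(simulate_repertoire(cfg, ref), cfg)
  asm$amplicon[1] <- substr(asm$amplicon[1], 1, 100)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  expect_message(info <- synthesize_reads(asm, cfg, f1, f2), "skipped 1")
  expect_equal(info$n_skipped, 1)
  expect_equal(info$n_pairs, nrow(asm) - 1)
})
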