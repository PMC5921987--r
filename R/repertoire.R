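# Clonal repertoire simulation
#
# A B-cell clone is one heavy/kappa rearrangement pair. Abundances follow a
# rank power law (fraction of clone i proportional to i^-a), emulating
# repertoires strongly skewed towards the most frequent HC-LC pairs; the
# per-clone microsome yield is log-normal, reflecting that cells with larger
# secretory ER volumes contribute disproportionally many templates.

LINKER_NT <- "GGTGGAGGCGGTTCAGGCGGAGGTGGCTCT"  # overlap-extension linker

# CDR3 total codon counts, anchors included
CDR3_CODONS_HEAVY <- 11:13
CDR3_CODONS_KAPPA <- 9:11

# junction = V cys codon + random sense codons + J anchor codon
random_junction <- function(v_seq, cys_anchor, j_seq, fr4_anchor, n_codons) {
  cys <- substr(v_seq, 3 * cys_anchor + 1, 3 * cys_anchor + 3)
  fr4 <- substr(j_seq, 3 * fr4_anchor + 1, 3 * fr4_anchor + 3)
  inner <- paste(sample(sense_codons(), n_codons - 2L, replace = TRUE),
                 collapse = "")
  paste0(cys, inner, fr4)
}

# full chain cassette: V up to the cys codon, junction, J after the anchor,
# then the constant-region tag
chain_cassette <- function(v_seq, cys_anchor, junction, j_seq, fr4_anchor, c_seq) {
  paste0(substr(v_seq, 1, 3 * cys_anchor), junction,
         substr(j_seq, 3 * (fr4_anchor + 1) + 1, nchar(j_seq)), c_seq)
}

#' Simulate a clonal B-cell repertoire
#'
#' Draws `n_clones` clones with distinct heavy and kappa CDR3 junctions,
#' power-law cell fractions (`cell_fraction[i] proportional to
#' i^-abundance_exponent`), log-normal secretion weights, and isotypes from
#' `isotype_mix`. When `spike_in_fraction > 0` exactly one extra IgG control
#' clone (`clone_id = "SPIKE"`) is added at that cell fraction and the rest
#' are rescaled. Heavy V genes are assigned without replacement while clones
#' are fewer than V families, so small mixtures (e.g. the three-hybridoma
#' scenario) get mutually distinct V genes.
#'
#' @param config a [validate_config()] list (or anything it accepts).
#' @param ref a `germline_reference`.
#' @return a tibble with one row per clone: `clone_id`, `isotype`,
#'   `v_heavy`, `j_heavy`, `cdr3_heavy_nt`, `v_light`, `j_light`,
#'   `cdr3_light_nt`, `cell_fraction`, `secretion_weight`, `is_spike_in`,
#'   plus the full amplifiable chain cassettes `hc_chain_nt` / `lc_chain_nt`
#'   (V through constant tag).
#' @examples
#' ref <- build_toy_reference(seed = 1)
#' clones <- simulate_repertoire(list(simulation = list(n_clones = 5)), ref)
#' sum(clones$cell_fraction)
#' @export
simulate_repertoire <- function(config, ref) {
  cfg <- validate_config(config)
  sim <- cfg$simulation
  validate_reference(ref)
  n <- as.integer(sim$n_clones)
  min_inner <- min(CDR3_CODONS_KAPPA) - 2L
  if (n > length(sense_codons())^min_inner) {
    abort("simulation.n_clones exceeds the achievable junction diversity")
  }

  vh <- ref_segments(ref, "heavy", "V"); jh <- ref_segments(ref, "heavy", "J")
  vk <- ref_segments(ref, "kappa", "V"); jk <- ref_segments(ref, "kappa", "J")
  ctags <- ref_segments(ref, segment_class = "C")
  c_seq <- stats::setNames(ctags$sequence, ctags$family)  # family = isotype tag

  withr::with_seed(stage_seed(cfg$seed, 1L), {
    n_spike <- as.integer(sim$spike_in_fraction > 0)
    n_all <- n + n_spike

    pick_v <- function(v_tbl, k) {
      if (k <= nrow(v_tbl)) sample(v_tbl$id, k) else sample(v_tbl$id, k, replace = TRUE)
    }
    v_heavy <- pick_v(vh, n_all)
    v_light <- pick_v(vk, n_all)
    j_heavy <- sample(jh$id, n_all, replace = TRUE)
    j_light <- sample(jk$id, n_all, replace = TRUE)

    draw_junctions <- function(v_ids, j_ids, v_tbl, j_tbl, codon_range) {
      out <- character(length(v_ids))
      for (i in seq_along(v_ids)) {
        v <- v_tbl[v_tbl$id == v_ids[i], ]
        j <- j_tbl[j_tbl$id == j_ids[i], ]
        for (try in 1:100) {
          cand <- random_junction(v$sequence, v$cys_anchor, j$sequence,
                                  j$fr4_anchor, sample(codon_range, 1L))
          if (!cand %in% out[seq_len(i - 1L)]) break
          if (try == 100) abort("could not draw distinct CDR3 junctions")
        }
        out[i] <- cand
      }
      out
    }
    cdr3_h <- draw_junctions(v_heavy, j_heavy, vh, jh, CDR3_CODONS_HEAVY)
    cdr3_k <- draw_junctions(v_light, j_light, vk, jk, CDR3_CODONS_KAPPA)

    fr <- seq_len(n)^(-sim$abundance_exponent)
    fr <- fr / sum(fr)
    isotype <- sample(names(sim$isotype_mix), n_all, replace = TRUE,
                      prob = sim$isotype_mix)
    weight <- if (sim$secretion_sd > 0) {
      stats::rlnorm(n_all, meanlog = 0, sdlog = sim$secretion_sd)
    } else rep(1, n_all)

    clone_id <- sprintf("C%04d", seq_len(n))
    is_spike <- rep(FALSE, n)
    if (n_spike == 1L) {
      clone_id <- c(clone_id, "SPIKE")
      isotype[n_all] <- "IgG"
      weight[n_all] <- 1
      fr <- c(fr * (1 - sim$spike_in_fraction), sim$spike_in_fraction)
      is_spike <- c(is_spike, TRUE)
    }

    clones <- tibble(
      clone_id = clone_id,
      isotype = isotype,
      v_heavy = v_heavy, j_heavy = j_heavy, cdr3_heavy_nt = cdr3_h,
      v_light = v_light, j_light = j_light, cdr3_light_nt = cdr3_k,
      cell_fraction = fr,
      secretion_weight = weight,
      is_spike_in = is_spike
    )
    seg <- function(ids, tbl, col) tbl[[col]][match(ids, tbl$id)]
    clones$hc_chain_nt <- chain_cassette(
      seg(clones$v_heavy, vh, "sequence"), seg(clones$v_heavy, vh, "cys_anchor"),
      clones$cdr3_heavy_nt,
      seg(clones$j_heavy, jh, "sequence"), seg(clones$j_heavy, jh, "fr4_anchor"),
      c_seq[clones$isotype])
    clones$lc_chain_nt <- chain_cassette(
      seg(clones$v_light, vk, "sequence"), seg(clones$v_light, vk, "cys_anchor"),
      clones$cdr3_light_nt,
      seg(clones$j_light, jk, "sequence"), seg(clones$j_light, jk, "fr4_anchor"),
      c_seq["IgK"])
    clones
  })
}
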