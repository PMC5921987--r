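# Microsome encapsulation and HC-LC assembly
#
# The encapsulated unit is the microsome, not the cell: each cell sheds a
# Poisson number of microsomes (scaled by its clone's secretion weight), and
# microsomes fall into emulsion droplets with Poisson(lambda) occupancy. One
# assembly is produced per microsome: its heavy chain comes from the microsome
# itself, its light chain template is drawn uniformly from the occupants of
# the same droplet (including itself), so mispairing arises only from
# co-encapsulation of microsomes from distinct clones. Open mode removes the
# compartments: heavy and light templates are drawn independently from the
# pooled marginals.

#' Simulate droplet encapsulation and HC-LC assembly
#'
#' @param clones a clone tibble from [simulate_repertoire()].
#' @param config a [validate_config()] list; the relevant fields are
#'   `simulation$n_cells`, `microsomes_per_cell_mean`, `droplet_lambda`,
#'   `mode`, `n_assemblies` (open mode), `force_single_occupancy` and
#'   `ambient_contamination_rate`.
#' @return an assembly tibble: `assembly_id`, `droplet_id` (NA in open mode),
#'   `hc_source`, `lc_source`, `hc_v`, `amplicon` (light cassette, overlap
#'   linker, reverse-complemented heavy cassette), `lc_len`, `lc_swapped`
#'   (always FALSE here; set by [apply_nested_pcr_chimeras()]) and
#'   `is_chimeric` (`hc_source != lc_source`).
#' @export
simulate_emulsion <- function(clones, config) {
  cfg <- validate_config(config)
  sim <- cfg$simulation
  if (nrow(clones) == 0) abort("no clones supplied")

  withr::with_seed(stage_seed(cfg$seed, 2L), {
    if (identical(sim$mode, "open")) {
      w <- clones$cell_fraction * clones$secretion_weight
      w <- w / sum(w)
      n <- sim$n_assemblies %||%
        round(sim$n_cells * sim$microsomes_per_cell_mean)
      hc <- sample(clones$clone_id, n, replace = TRUE, prob = w)
      lc <- sample(clones$clone_id, n, replace = TRUE, prob = w)
      return(finish_assemblies(hc, lc, rep(NA_integer_, n), clones))
    }

    # cells per clone, then microsomes per cell
    n_cells_clone <- as.vector(stats::rmultinom(1, sim$n_cells,
                                                clones$cell_fraction))
    micro_clone_idx <- unlist(lapply(seq_len(nrow(clones)), function(i) {
      if (n_cells_clone[i] == 0) return(integer(0))
      k <- stats::rpois(n_cells_clone[i],
                        sim$microsomes_per_cell_mean * clones$secretion_weight[i])
      rep.int(i, sum(k))
    }))
    m <- length(micro_clone_idx)
    if (m == 0) {
      warn("zero microsomes produced; returning empty assembly table")
      return(finish_assemblies(character(0), character(0), integer(0), clones))
    }
    micro_clone_idx <- sample(micro_clone_idx)  # shuffle before encapsulation

    if (isTRUE(sim$force_single_occupancy)) {
      droplet <- seq_len(m)
    } else {
      n_droplets <- max(1L, round(m / sim$droplet_lambda))
      droplet <- sample.int(n_droplets, m, replace = TRUE)
    }

    # light-chain template: uniform over the occupants of the same droplet
    ord <- order(droplet)
    runs <- rle(droplet[ord])
    lc_idx <- integer(m)
    lc_idx[ord] <- ord  # singleton droplets pair with themselves
    pos <- cumsum(c(1L, runs$lengths))
    multi <- which(runs$lengths > 1L)
    for (g in multi) {
      members <- ord[pos[g]:(pos[g + 1L] - 1L)]
      lc_idx[members] <- members[sample.int(length(members), length(members),
                                            replace = TRUE)]
    }

    hc <- clones$clone_id[micro_clone_idx]
    lc <- clones$clone_id[micro_clone_idx[lc_idx]]

    # ambient cross-contamination: free template drawn from the pooled mix
    if (sim$ambient_contamination_rate > 0) {
      hit <- which(stats::runif(m) < sim$ambient_contamination_rate)
      if (length(hit)) {
        lc[hit] <- clones$clone_id[sample(micro_clone_idx, length(hit),
                                          replace = TRUE)]
      }
    }
    finish_assemblies(hc, lc, droplet, clones)
  })
}

finish_assemblies <- function(hc, lc, droplet, clones) {
  lc_cas <- clones$lc_chain_nt[match(lc, clones$clone_id)]
  hc_rc <- revcomp(clones$hc_chain_nt)[match(hc, clones$clone_id)]
  tibble(
    assembly_id = sprintf("A%07d", seq_along(hc)),
    droplet_id = droplet,
    hc_source = hc,
    lc_source = lc,
    hc_v = clones$v_heavy[match(hc, clones$clone_id)],
    amplicon = if (length(hc)) paste0(lc_cas, LINKER_NT, hc_rc) else character(0),
    lc_len = nchar(lc_cas),
    lc_swapped = logical(length(hc)),
    is_chimeric = hc != lc
  )
}

#' Apply identity-dependent nested-PCR chimera formation
#'
#' Models template switching during the bulk (non-emulsion) PCR stage as a
#' light-chain partner swap: each amplicon recombines with probability
#' `chimera_base_rate` when at least one amplicon from a *different* source
#' clone shares an exact-match window of at least `chimera_identity_window`
#' nucleotides between the two heavy-chain V genes; amplicons whose V gene
#' shares no such window with any other clone's V gene recombine at a residual
#' rate of `chimera_base_rate / 30`. A recombinant takes the light cassette of
#' a partner drawn uniformly from its eligible pool (pre-swap state; a single
#' recombination round).
#'
#' @param assemblies an assembly tibble from [simulate_emulsion()].
#' @param config a [validate_config()] list.
#' @param ref the `germline_reference` used to build the clones.
#' @return the assembly tibble with swapped light chains; `lc_swapped` marks
#'   the recombination events and `is_chimeric` is recomputed as
#'   `hc_source != lc_source`.
#' @export
apply_nested_pcr_chimeras <- function(assemblies, config, ref) {
  cfg <- validate_config(config)
  sim <- cfg$simulation
  base <- sim$chimera_base_rate
  if (base == 0 || nrow(assemblies) == 0) return(assemblies)

  vseq <- ref_segments(ref, segment_class = "V")
  genes <- unique(assemblies$hc_v)
  gs <- stats::setNames(vseq$sequence[match(genes, vseq$id)], genes)
  share <- outer(genes, genes,
                 Vectorize(function(a, b) shares_window(gs[[a]], gs[[b]],
                                                        sim$chimera_identity_window)))
  dimnames(share) <- list(genes, genes)

  withr::with_seed(stage_seed(cfg$seed, 3L), {
    pre <- assemblies  # partners come from the pre-swap pool
    out <- assemblies
    for (cl in unique(pre$hc_source)) {
      own <- which(pre$hc_source == cl)
      g <- pre$hc_v[own[1L]]
      window_pool <- which(pre$hc_source != cl & share[g, pre$hc_v])
      if (length(window_pool)) {
        p <- base
        pool <- window_pool
      } else {
        pool <- which(pre$hc_source != cl)
        p <- base / 30
      }
      if (!length(pool)) next
      hit <- own[stats::runif(length(own)) < p]
      if (!length(hit)) next
      partner <- pool[sample.int(length(pool), length(hit), replace = TRUE)]
      out$lc_source[hit] <- pre$lc_source[partner]
      out$amplicon[hit] <- paste0(
        substr(pre$amplicon[partner], 1L, pre$lc_len[partner]),
        substr(pre$amplicon[hit], pre$lc_len[hit] + 1L,
               nchar(pre$amplicon[hit])))
      out$lc_len[hit] <- pre$lc_len[partner]
      out$lc_swapped[hit] <- TRUE
    }
    out$is_chimeric <- out$hc_source != out$lc_source
    out
  })
}

#' Expected droplet mispairing fraction
#'
#' Closed-form model prediction for the fraction of mispaired assemblies in
#' emulsion mode: conditioning on a microsome, the number of co-encapsulated
#' microsomes is Poisson(`lambda`) and the light template is uniform over the
#' droplet occupants, so the mispair probability is
#' `sum_j dpois(j, lambda) * j/(j+1) * (1 - sum(w^2))` with `w` the microsome
#' clone fractions, truncated at `kmax` co-occupants.
#'
#' @param lambda mean droplet occupancy.
#' @param weights clone fractions of the microsome pool (normalized internally).
#' @param kmax truncation of the co-occupant count enumeration.
#' @return the expected mispaired fraction.
#' @examples
#' expected_mispair_fraction(0.05, rep(1 / 3, 3))
#' @export
expected_mispair_fraction <- function(lambda, weights, kmax = 6) {
  w <- weights / sum(weights)
  q <- 1 - sum(w^2)
  j <- seq_len(kmax)
  sum(stats::dpois(j, lambda) * j / (j + 1)) * q
}
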