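# Defined-amplicon chimera quantification
#
# Mirrors the wet-lab design: a small set of defined clonal HC-LC amplicons is
# sequenced individually (purity control) and as a pool after a bulk PCR round
# (chimera measurement). Each read's heavy and light CDR3 are assigned to the
# nearest defined clone by edit distance; a read whose heavy and light chains
# come from different clones is chimeric. Rates are stratified by whether the
# two clones' heavy V genes belong to the same superfamily, since template
# switching needs stretches of shared sequence.

#' Assign annotated reads to defined source clones
#'
#' Each chain is assigned to the defined clone whose CDR3 has minimal
#' Levenshtein distance to the read's junction; reads with a distance tie or
#' with minimal distance above `max_dist_frac` times the junction length are
#' excluded (counted in the `report` attribute).
#'
#' @param annotations output of [annotate_run()].
#' @param clones defined clone tibble (needs `clone_id`, `cdr3_heavy_nt`,
#'   `cdr3_light_nt`; e.g. from [simulate_repertoire()]).
#' @param max_dist_frac assignment threshold as a fraction of CDR3 length.
#' @return a tibble `sequence_id`, `hc_source`, `lc_source` for assignable
#'   reads; the `"report"` attribute counts exclusions.
#' @export
assign_sources <- function(annotations, clones, max_dist_frac = 0.25) {
  if (nrow(clones) < 1) abort("no defined clones supplied")
  if (anyDuplicated(clones$cdr3_heavy_nt) || anyDuplicated(clones$cdr3_light_nt)) {
    abort("defined clones must have mutually distinguishable CDR3s")
  }
  nearest <- function(junctions, targets) {
    d <- utils::adist(junctions, targets)
    best <- apply(d, 1L, which.min)
    dmin <- d[cbind(seq_along(junctions), best)]
    tied <- rowSums(d == dmin) > 1L
    ok <- !tied & dmin <= max_dist_frac * nchar(junctions)
    list(clone = ifelse(ok, clones$clone_id[best], NA_character_),
         excluded_tie = tied, excluded_dist = !tied & !ok)
  }
  h <- nearest(annotations$junction_h, clones$cdr3_heavy_nt)
  k <- nearest(annotations$junction_k, clones$cdr3_light_nt)
  ok <- !is.na(h$clone) & !is.na(k$clone)
  out <- tibble(sequence_id = annotations$sequence_id[ok],
                hc_source = h$clone[ok], lc_source = k$clone[ok])
  structure(out, report = list(
    n_input = nrow(annotations), n_assigned = sum(ok),
    n_excluded_tie = sum((h$excluded_tie | k$excluded_tie)),
    n_excluded_distance = sum(!(h$excluded_tie | k$excluded_tie) &
                                (h$excluded_dist | k$excluded_dist))
  ))
}

#' Chimera rates from per-read source assignments
#'
#' A read is chimeric when its assigned heavy and light source clones differ.
#' Per ordered source pair (A, B), the rate is the percentage of reads with
#' heavy source A that carry B's light chain. Two aggregates are reported
#' (the read-weighted total and the unweighted mean over off-diagonal pairs)
#' together with rates stratified by heavy V gene superfamily identity.
#'
#' @param assignments output of [assign_sources()].
#' @param clones the defined clone tibble (for `v_heavy`).
#' @param ref the `germline_reference` (for V superfamilies).
#' @return a `chimera_report` list: `pair_rates` (tibble of ordered source
#'   pairs with read counts and rates), `average_pct` (chimeric / assigned
#'   reads), `average_pairwise_pct` (unweighted mean of off-diagonal pair
#'   rates), `strata` (same- vs cross-superfamily rates), `n_assigned`,
#'   `n_chimeric`.
#' @export
chimera_rates <- function(assignments, clones, ref) {
  if (length(unique(assignments$hc_source)) < 1) {
    abort("no assigned reads")
  }
  v <- ref_segments(ref, segment_class = "V")
  sfam <- stats::setNames(v$superfamily[match(clones$v_heavy, v$id)],
                          clones$clone_id)
  hc_totals <- assignments |> count(.data$hc_source, name = "hc_reads")
  pair_rates <- assignments |>
    count(.data$hc_source, .data$lc_source, name = "reads") |>
    left_join(hc_totals, by = "hc_source") |>
    mutate(rate_pct = 100 * .data$reads / .data$hc_reads,
           chimeric = .data$hc_source != .data$lc_source,
           same_superfamily = sfam[.data$hc_source] == sfam[.data$lc_source])

  off <- pair_rates[pair_rates$chimeric, , drop = FALSE]
  n_assigned <- nrow(assignments)
  n_chimeric <- sum(off$reads)

  stratum_rate <- function(same) {
    rows <- off[off$same_superfamily == same, , drop = FALSE]
    if (nrow(rows) == 0) return(NA_real_)
    hc_in <- unique(rows$hc_source)
    100 * sum(rows$reads) / sum(hc_totals$hc_reads[hc_totals$hc_source %in% hc_in])
  }

  structure(list(
    pair_rates = pair_rates |> select(-"same_superfamily"),
    average_pct = 100 * n_chimeric / n_assigned,
    average_pairwise_pct = if (nrow(off)) mean(off$rate_pct) else 0,
    strata = c(same_superfamily = stratum_rate(TRUE),
               cross_superfamily = stratum_rate(FALSE)),
    n_assigned = n_assigned,
    n_chimeric = n_chimeric
  ), class = "chimera_report")
}

#' @export
print.chimera_report <- function(x, ...) {
  cat(sprintf("Chimera report: %d/%d reads chimeric (%.2f%%)\n",
              x$n_chimeric, x$n_assigned, x$average_pct))
  cat(sprintf("  unweighted pairwise mean: %.2f%%\n", x$average_pairwise_pct))
  cat(sprintf("  same-superfamily: %s%%, cross-superfamily: %s%%\n",
              format(x$strata[["same_superfamily"]], digits = 3),
              format(x$strata[["cross_superfamily"]], digits = 3)))
  invisible(x)
}

#' Per-pair chimera rates as a tibble
#' @param x a `chimera_report`.
#' @param ... unused.
#' @return the ordered source-pair rate table.
#' @export
tidy.chimera_report <- function(x, ...) as_tibble(x$pair_rates)

#' One-row summary of a chimera report
#' @param x a `chimera_report`.
#' @param ... unused.
#' @return a one-row tibble with the aggregates and strata.
#' @export
glance.chimera_report <- function(x, ...) {
  tibble(n_assigned = x$n_assigned, n_chimeric = x$n_chimeric,
         average_pct = x$average_pct,
         average_pairwise_pct = x$average_pairwise_pct,
         same_superfamily_pct = x$strata[["same_superfamily"]],
         cross_superfamily_pct = x$strata[["cross_superfamily"]])
}

#' Defined clones for the chimera experiment
#'
#' Builds four defined HC-LC clones in the layout of the chimera study: three
#' with heavy V genes from distinct families of the same superfamily, one from
#' the other superfamily.
#'
#' @param ref a `germline_reference` (needs >= 3 VH families in one
#'   superfamily and >= 1 in another).
#' @param seed integer seed.
#' @return a 4-row clone tibble (`clone_id` Top1..Top4; Top2 is the
#'   cross-superfamily clone).
#' @export
make_defined_clones <- function(ref, seed = 1) {
  vh <- ref_segments(ref, "heavy", "V")
  by_sf <- split(vh$id, vh$superfamily)
  by_sf <- by_sf[order(-lengths(by_sf))]
  if (length(by_sf) < 2 || lengths(by_sf)[1] < 3) {
    abort("reference needs one VH superfamily with >= 3 families plus another superfamily")
  }
  base <- simulate_repertoire(
    list(seed = seed,
         simulation = list(n_clones = 4, abundance_exponent = 0,
                           secretion_sd = 0, isotype_mix = c(IgM = 0, IgG = 1))),
    ref)
  clones <- base
  clones$clone_id <- c("Top1", "Top2", "Top3", "Top4")
  target_v <- c(by_sf[[1]][1], by_sf[[2]][1], by_sf[[1]][2], by_sf[[1]][3])
  # rebuild heavy cassettes on the assigned V genes, keeping junction tails
  for (i in 1:4) {
    v <- vh[vh$id == target_v[i], ]
    cys <- substr(v$sequence, 3 * v$cys_anchor + 1, 3 * v$cys_anchor + 3)
    clones$v_heavy[i] <- v$id
    clones$cdr3_heavy_nt[i] <- paste0(cys, substr(base$cdr3_heavy_nt[i], 4,
                                                  nchar(base$cdr3_heavy_nt[i])))
    j <- ref[ref$id == clones$j_heavy[i], ]
    ctag <- ref[ref$id == "IGHG", ]
    clones$hc_chain_nt[i] <- chain_cassette(v$sequence, v$cys_anchor,
                                            clones$cdr3_heavy_nt[i],
                                            j$sequence, j$fr4_anchor,
                                            ctag$sequence)
  }
  clones
}

# equal-count pure assemblies of given clones (defined-amplicon pool)
pure_assemblies <- function(clones, n_per_clone) {
  idx <- rep(seq_len(nrow(clones)), each = n_per_clone)
  finish_assemblies(clones$clone_id[idx], clones$clone_id[idx],
                    rep(NA_integer_, length(idx)), clones)
}

#' Run the defined-amplicon chimera experiment end to end
#'
#' Simulates the purity control (each defined clone sequenced individually,
#' no bulk PCR round) and the pooled measurement (all clones pooled, chimera
#' step applied), pushes both through preprocessing, annotation and source
#' assignment, and reports chimera rates for each.
#'
#' @param config a [validate_config()] list; `simulation$chimera_base_rate`
#'   and `chimera_identity_window` drive the pooled round.
#' @param ref a `germline_reference`.
#' @param n_per_clone reads simulated per defined clone.
#' @param clones optionally, a defined clone tibble (default:
#'   [make_defined_clones()] on the config seed).
#' @return a list with `control` and `pooled` `chimera_report`s and the
#'   `clones` used.
#' @export
run_chimera_experiment <- function(config, ref, n_per_clone = 4000,
                                   clones = NULL) {
  cfg <- validate_config(config)
  clones <- clones %||% make_defined_clones(ref, seed = cfg$seed)

  run_arm <- function(assemblies, seed_offset) {
    arm_cfg <- cfg
    arm_cfg$seed <- stage_seed(cfg$seed, seed_offset)
    fq1 <- tempfile(fileext = "_1.fastq")
    fq2 <- tempfile(fileext = "_2.fastq")
    on.exit(unlink(c(fq1, fq2)))
    synthesize_reads(assemblies, arm_cfg, fq1, fq2)
    pp <- preprocess_run(fq1, fq2, ref,
                         min_q = cfg$preprocess$min_q,
                         min_frac = cfg$preprocess$min_frac,
                         max_c_mismatch = cfg$preprocess$max_c_mismatch)
    ann <- annotate_run(pp$pairs, ref,
                        min_v_score = cfg$annotate$min_v_score,
                        min_j_score = cfg$annotate$min_j_score)
    chimera_rates(assign_sources(ann, clones), clones, ref)
  }

  control <- run_arm(pure_assemblies(clones, n_per_clone), 5L)
  pooled_assemblies <- apply_nested_pcr_chimeras(
    pure_assemblies(clones, n_per_clone), cfg, ref)
  pooled <- run_arm(pooled_assemblies, 6L)
  list(control = control, pooled = pooled, clones = clones)
}
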