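# End-to-end pipeline
#
# run_all() drives simulate -> preprocess -> annotate -> clonotype -> stats
# from a single validated config, writing every stage artifact plus a
# MANIFEST of file checksums into the run directory. A rerun with the same
# config and seed is byte-identical (the FASTQ, TSV and JSON outputs carry no
# timestamps).

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

write_tsv_plain <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  path
}

write_json_plain <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  path
}

#' Run the full simulation and analysis pipeline
#'
#' Builds (or reads) the germline reference, simulates the clonal repertoire
#' and the emulsion (or open) assembly reaction, applies the nested-PCR
#' chimera step when configured, writes paired FASTQ with truth tags, then
#' runs preprocessing, annotation, paired clonotype construction and the
#' repertoire statistics. Every stage output lands in `config$out_dir`; a
#' MANIFEST.tsv records the md5 of each artifact and the completion state of
#' each stage (partial outputs are preserved on failure).
#'
#' @param config a [validate_config()] input with non-NULL `out_dir`.
#' @return invisibly, a list with the run directory, the stage objects
#'   (`reference`, `clones`, `assemblies` summary, `preprocess_report`,
#'   `annotations`, `clonotypes`, `stats`) and the artifact paths.
#' @export
run_all <- function(config) {
  cfg <- validate_config(config)
  if (is.null(cfg$out_dir)) abort("config$out_dir is required by run_all()")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(...) file.path(cfg$out_dir, ...)

  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stages_done <- character(0)
  artifacts <- character(0)
  result <- list(out_dir = cfg$out_dir)

  finalize <- function(status) {
    writeLines(log_lines, path("run.log"))
    existing <- artifacts[file.exists(artifacts)]
    manifest <- tibble(
      file = basename(existing),
      md5 = unname(tools::md5sum(existing)),
      stage_status = status
    )
    write_tsv_plain(manifest, path("MANIFEST.tsv"))
  }

  run_stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      note("stage %s FAILED: %s", name, conditionMessage(e))
      finalize(sprintf("failed at %s (done: %s)", name,
                       paste(stages_done, collapse = ",")))
      abort(sprintf("pipeline failed at stage '%s': %s", name,
                    conditionMessage(e)))
    })
    stages_done <<- c(stages_done, name)
    out
  }

  # --- simulate -------------------------------------------------------------
  ref <- run_stage("reference", {
    r <- if (!is.null(cfg$reference$path)) {
      read_reference(cfg$reference$path)
    } else {
      build_toy_reference(cfg$reference$n_vh_families,
                          cfg$reference$n_vk_families, seed = cfg$seed)
    }
    write_reference(r, path("reference.fasta"))
    note("reference: %d segments", nrow(r))
    r
  })
  artifacts <- c(artifacts, path("reference.fasta"))

  clones <- run_stage("repertoire", {
    cl <- simulate_repertoire(cfg, ref)
    write_tsv_plain(cl, path("clones.tsv"))
    note("repertoire: %d clones (spike-in: %s)", nrow(cl),
         any(cl$is_spike_in))
    cl
  })
  artifacts <- c(artifacts, path("clones.tsv"))

  assemblies <- run_stage("emulsion", {
    a <- simulate_emulsion(clones, cfg)
    if (cfg$simulation$chimera_base_rate > 0) {
      a <- apply_nested_pcr_chimeras(a, cfg, ref)
    }
    write_tsv_plain(
      a[c("assembly_id", "droplet_id", "hc_source", "lc_source",
          "lc_swapped", "is_chimeric")], path("truth.tsv"))
    note("emulsion (%s mode): %d assemblies, %d mispaired/chimeric",
         cfg$simulation$mode, nrow(a), sum(a$is_chimeric))
    a
  })
  artifacts <- c(artifacts, path("truth.tsv"))

  fq1 <- path("reads_1.fastq")
  fq2 <- path("reads_2.fastq")
  run_stage("reads", {
    info <- synthesize_reads(assemblies, cfg, fq1, fq2)
    note("reads: %d pairs written (%d skipped)", info$n_pairs, info$n_skipped)
    info
  })
  artifacts <- c(artifacts, fq1, fq2)

  # --- analyse --------------------------------------------------------------
  pp <- run_stage("preprocess", {
    p <- preprocess_run(fq1, fq2, ref,
                        min_q = cfg$preprocess$min_q,
                        min_frac = cfg$preprocess$min_frac,
                        max_c_mismatch = cfg$preprocess$max_c_mismatch)
    write_json_plain(glance(p$report), path("preprocess_report.json"))
    note("preprocess: %d in, %d retained", p$report$input_pairs,
         p$report$retained_pairs)
    p
  })
  artifacts <- c(artifacts, path("preprocess_report.json"))

  ann <- run_stage("annotate", {
    a <- annotate_run(pp$pairs, ref,
                      min_v_score = cfg$annotate$min_v_score,
                      min_j_score = cfg$annotate$min_j_score)
    write_tsv_plain(as_airr(a), path("rearrangements.tsv"))
    note("annotate: %d/%d pairs annotated", nrow(a), nrow(pp$pairs))
    a
  })
  artifacts <- c(artifacts, path("rearrangements.tsv"))

  clonotypes <- run_stage("clonotype", {
    all_pairs <- build_paired_clonotypes(ann,
                                         max_mismatch = cfg$clonotype$max_mismatch,
                                         ratio = cfg$clonotype$ratio)
    filtered <- filter_clonotypes(all_pairs, min_reads = cfg$clonotype$min_reads)
    write_tsv_plain(all_pairs, path("clonotypes_unfiltered.tsv"))
    write_tsv_plain(filtered, path("clonotypes.tsv"))
    note("clonotype: %d pairs pre-filter, %d post-filter",
         nrow(all_pairs), nrow(filtered))
    list(unfiltered = all_pairs, filtered = filtered)
  })
  artifacts <- c(artifacts, path("clonotypes_unfiltered.tsv"),
                 path("clonotypes.tsv"))

  stats_out <- run_stage("stats", {
    ct <- clonotypes$filtered
    if (nrow(ct) == 0) {
      note("stats: no clonotypes survive filtering; skipping statistics")
      s <- list(n_clonotype_pairs = 0L)
      write_json_plain(s, path("stats.json"))
      return(s)
    }
    pm <- pairing_matrix(ct)
    write_tsv_plain(pm, path("pairing_matrix.tsv"))
    s <- list(
      n_clonotype_pairs = nrow(ct),
      total_reads = sum(ct$read_count),
      top_share_pct = top_share(ct, cfg$stats$top_n),
      top_n = cfg$stats$top_n,
      promiscuous_lc_pct = promiscuous_lc_fraction(ct)
    )
    spike <- clones[clones$is_spike_in, ]
    if (nrow(spike) == 1 &&
        spike$cdr3_heavy_nt %in% ct$cdr3_nt_h) {
      s$spike_in_accuracy_pct <- spike_in_accuracy(
        ct, spike$cdr3_heavy_nt, spike$cdr3_light_nt)
    }
    if (length(cfg$stats$known_cdr3)) {
      s$known_cdr3_matches <- nrow(match_known_cdr3(ct, cfg$stats$known_cdr3))
    }
    write_json_plain(s, path("stats.json"))
    note("stats: top-%d share %.1f%%, promiscuous LC %.1f%%",
         cfg$stats$top_n, s$top_share_pct, s$promiscuous_lc_pct)
    s
  })
  artifacts <- c(artifacts, path("stats.json"), path("pairing_matrix.tsv"))

  finalize("complete")
  invisible(list(
    out_dir = cfg$out_dir, config = cfg, reference = ref, clones = clones,
    preprocess_report = pp$report, annotations = ann,
    clonotypes = clonotypes$filtered,
    clonotypes_unfiltered = clonotypes$unfiltered,
    stats = stats_out,
    paths = stats::setNames(artifacts, basename(artifacts))
  ))
}
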