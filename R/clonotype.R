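# Clonotype construction with PCR-error correction
#
# Reads first collapse into exact-sequence groups keyed by (V family, J gene,
# CDR3 nucleotide sequence). PCR/sequencing-error absorption then merges a
# minor group into a major one when the CDR3s have equal length and differ by
# at most `max_mismatch` substitutions, the keys otherwise agree, and the
# major/minor count ratio is at least `ratio`. Absorption is a single pass
# with majors visited in descending count order (original counts; a minor
# joins the first qualifying major and cannot absorb others afterwards), so
# read counts are conserved by construction.

# per-row representative CDR3 after absorption; df has v_family, j_call,
# cdr3_nt and a count column (one row per distinct sequence)
absorb_groups <- function(groups, max_mismatch, ratio) {
  groups$rep <- groups$cdr3_nt
  key <- paste(groups$v_family, groups$j_call, nchar(groups$cdr3_nt))
  for (block_rows in split(seq_len(nrow(groups)), key)) {
    if (length(block_rows) < 2) next
    b <- block_rows[order(-groups$count[block_rows], groups$cdr3_nt[block_rows])]
    m <- do.call(rbind, lapply(groups$cdr3_nt[b], utf8ToInt))
    counts <- groups$count[b]
    absorbed <- logical(length(b))
    for (i in seq_along(b)) {
      if (absorbed[i]) next
      for (j in seq_along(b)) {
        if (j <= i || absorbed[j]) next
        if (counts[i] / counts[j] >= ratio &&
            sum(m[i, ] != m[j, ]) <= max_mismatch) {
          absorbed[j] <- TRUE
          groups$rep[b[j]] <- groups$cdr3_nt[b[i]]
        }
      }
    }
  }
  groups
}

#' Cluster CDR3 sequences into clonotypes
#'
#' @param annotations a tibble of same-chain assignments with columns
#'   `v_family`, `j_call`, `cdr3_nt` -- one row per read, or pre-aggregated
#'   rows with a `read_count` column.
#' @param max_mismatch maximum substitutions for a minor group to be absorbed.
#' @param ratio minimum major/minor count ratio for absorption.
#' @return a tibble of clonotypes (`v_family`, `j_call`, `cdr3_nt`,
#'   `cdr3_aa`, `read_count`), sorted by descending count; total read counts
#'   are conserved.
#' @examples
#' x <- tibble::tibble(v_family = "VH1", j_call = "IGHJ4",
#'                     cdr3_nt = c("TGTAAATGG", "TGTAAGTGG"),
#'                     read_count = c(100, 3))
#' cluster_cdr3(x)
#' @export
cluster_cdr3 <- function(annotations, max_mismatch = 1, ratio = 10) {
  df <- as_tibble(annotations)
  if (!"read_count" %in% names(df)) df$read_count <- 1L
  groups <- df |>
    group_by(.data$v_family, .data$j_call, .data$cdr3_nt) |>
    summarise(count = sum(.data$read_count), .groups = "drop")
  if (nrow(groups) == 0) {
    return(tibble(v_family = character(), j_call = character(),
                  cdr3_nt = character(), cdr3_aa = character(),
                  read_count = integer()))
  }
  groups <- absorb_groups(groups, max_mismatch, ratio)
  groups |>
    group_by(.data$v_family, .data$j_call, cdr3_nt = .data$rep) |>
    summarise(read_count = sum(.data$count), .groups = "drop") |>
    mutate(cdr3_aa = translate_and_check(.data$cdr3_nt)$cdr3_aa,
           .after = "cdr3_nt") |>
    arrange(desc(.data$read_count), .data$v_family, .data$j_call,
            .data$cdr3_nt)
}

# representative CDR3 per input row, chain given by column suffix
assign_representatives <- function(ann, suffix, max_mismatch, ratio) {
  df <- tibble(v_family = ann[[paste0("v_family_", suffix)]],
               j_call = ann[[paste0("j_call_", suffix)]],
               cdr3_nt = ann[[paste0("junction_", suffix)]])
  groups <- df |> count(.data$v_family, .data$j_call, .data$cdr3_nt,
                        name = "count")
  groups <- absorb_groups(groups, max_mismatch, ratio)
  key <- paste(df$v_family, df$j_call, df$cdr3_nt)
  groups$rep[match(key, paste(groups$v_family, groups$j_call, groups$cdr3_nt))]
}

#' Build the paired clonotype table
#'
#' Clusters heavy and kappa CDR3s separately (with PCR-error absorption), then
#' keys every read pair by its (heavy clonotype, light clonotype) combination.
#' Frequencies are read counts over all annotated reads; ordering is
#' descending count, then key, so output is deterministic.
#'
#' @param annotations output of [annotate_run()].
#' @param max_mismatch,ratio absorption parameters, see [cluster_cdr3()].
#' @return a `paired_clonotypes` tibble: `v_family_h`, `j_call_h`,
#'   `cdr3_nt_h`, `cdr3_aa_h`, `productive_h`, the `_k` counterparts,
#'   `isotype`, `read_count`, `frequency`.
#' @export
build_paired_clonotypes <- function(annotations, max_mismatch = 1, ratio = 10) {
  ann <- as_tibble(annotations)
  if (nrow(ann) == 0) {
    out <- tibble(v_family_h = character(), j_call_h = character(),
                  cdr3_nt_h = character(), cdr3_aa_h = character(),
                  productive_h = logical(), v_family_k = character(),
                  j_call_k = character(), cdr3_nt_k = character(),
                  cdr3_aa_k = character(), productive_k = logical(),
                  isotype = character(), read_count = integer(),
                  frequency = numeric())
    return(structure(out, total_reads = 0L,
                     class = c("paired_clonotypes", class(out))))
  }
  ann$rep_h <- assign_representatives(ann, "h", max_mismatch, ratio)
  ann$rep_k <- assign_representatives(ann, "k", max_mismatch, ratio)
  total <- nrow(ann)
  out <- ann |>
    group_by(.data$v_family_h, .data$j_call_h, cdr3_nt_h = .data$rep_h,
             .data$v_family_k, .data$j_call_k, cdr3_nt_k = .data$rep_k) |>
    summarise(isotype = names(which.max(table(.data$isotype))),
              read_count = dplyr::n(), .groups = "drop")
  tr_h <- translate_and_check(out$cdr3_nt_h)
  tr_k <- translate_and_check(out$cdr3_nt_k)
  out <- out |>
    mutate(cdr3_aa_h = tr_h$cdr3_aa, productive_h = tr_h$productive,
           cdr3_aa_k = tr_k$cdr3_aa, productive_k = tr_k$productive,
           frequency = .data$read_count / total) |>
    select("v_family_h", "j_call_h", "cdr3_nt_h", "cdr3_aa_h", "productive_h",
           "v_family_k", "j_call_k", "cdr3_nt_k", "cdr3_aa_k", "productive_k",
           "isotype", "read_count", "frequency") |>
    arrange(desc(.data$read_count), .data$v_family_h, .data$cdr3_nt_h,
            .data$v_family_k, .data$cdr3_nt_k)
  structure(out, total_reads = total,
            class = c("paired_clonotypes", class(out)))
}

#' Filter paired clonotypes by read support and productivity
#'
#' Keeps pairs supported by at least `min_reads` reads whose heavy and light
#' junctions are both productive, then renormalizes frequencies over the
#' retained pairs.
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @param min_reads minimum reads per pair.
#' @return the filtered table (frequencies re-sum to 1 unless empty).
#' @export
filter_clonotypes <- function(pairs, min_reads = 2) {
  keep <- pairs$read_count >= min_reads &
    pairs$productive_h & pairs$productive_k
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) > 0) out$frequency <- out$read_count / sum(out$read_count)
  attr(out, "total_reads") <- attr(pairs, "total_reads")
  out
}
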