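# Repertoire-level statistics
#
# All functions take the paired clonotype table (read counts per HC-LC pair)
# and compute read-level descriptive statistics: the VH-VK family pairing
# matrix behind the heat maps, top-N clonal share, light-chain promiscuity,
# spike-in pairing accuracy, longitudinal clonotype tracking, known-CDR3
# lookup, and the 2^(-deltaCt) qPCR utility.

#' VH-VK family pairing matrix
#'
#' Percentage of aligned reads falling in each (VH family, VK family)
#' combination; cells sum to 100.
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @return a `pairing_matrix` tibble in long form: `v_family_h`,
#'   `v_family_k`, `reads`, `percent`.
#' @export
pairing_matrix <- function(pairs) {
  if (nrow(pairs) == 0) abort("empty clonotype table")
  out <- pairs |>
    group_by(.data$v_family_h, .data$v_family_k) |>
    summarise(reads = sum(.data$read_count), .groups = "drop") |>
    mutate(percent = 100 * .data$reads / sum(.data$reads)) |>
    arrange(.data$v_family_h, .data$v_family_k)
  structure(out, class = c("pairing_matrix", class(out)))
}

#' Spread a pairing matrix to wide (heat-map) form
#'
#' @param x a `pairing_matrix`.
#' @return a numeric matrix, VH families in rows, VK families in columns.
#' @export
pairing_matrix_wide <- function(x) {
  wide <- tidyr::pivot_wider(as_tibble(x)[c("v_family_h", "v_family_k", "percent")],
                             names_from = "v_family_k",
                             values_from = "percent", values_fill = 0)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$v_family_h
  m[order(rownames(m)), order(colnames(m)), drop = FALSE]
}

#' Heat map of a VH-VK pairing matrix
#'
#' @param object a `pairing_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.pairing_matrix <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$v_family_k, y = .data$v_family_h,
                               fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% reads") +
    ggplot2::labs(x = "VK family", y = "VH family",
                  title = "Paired VH-VK gene family usage") +
    ggplot2::theme_minimal()
}

#' Cumulative read share of the top clonotype pairs
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @param n number of top pairs (by read count; ties broken by the table's
#'   deterministic ordering).
#' @return percentage of all reads carried by the `n` most abundant pairs.
#' @export
top_share <- function(pairs, n = 10) {
  if (nrow(pairs) == 0) abort("top_share is undefined on an empty table")
  counts <- sort(pairs$read_count, decreasing = TRUE)
  100 * sum(counts[seq_len(min(n, length(counts)))]) / sum(counts)
}

#' Fraction of promiscuous light chains
#'
#' A light-chain clonotype (keyed by CDR3, V family and J gene -- or by CDR3
#' amino-acid sequence with `level = "aa"`) is promiscuous when it appears
#' paired with more than one distinct heavy-chain clonotype.
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @param level `"nt"` (default) or `"aa"` clonotype identity.
#' @return percentage of distinct light clonotypes that are promiscuous.
#' @export
promiscuous_lc_fraction <- function(pairs, level = c("nt", "aa")) {
  level <- match.arg(level)
  if (nrow(pairs) == 0) return(0)
  lc <- if (level == "nt") {
    paste(pairs$cdr3_nt_k, pairs$v_family_k, pairs$j_call_k)
  } else pairs$cdr3_aa_k
  hc <- paste(pairs$cdr3_nt_h, pairs$v_family_h, pairs$j_call_h)
  n_hc <- tapply(hc, lc, function(x) length(unique(x)))
  100 * mean(n_hc > 1)
}

#' Spike-in control pairing accuracy
#'
#' Among reads whose heavy CDR3 is the known control heavy chain, the
#' percentage paired with the known control light chain.
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @param control_hc,control_lc control clone CDR3 sequences (nucleotide by
#'   default, amino acid with `level = "aa"`).
#' @param level `"nt"` or `"aa"`.
#' @return pairing accuracy in percent.
#' @export
spike_in_accuracy <- function(pairs, control_hc, control_lc,
                              level = c("nt", "aa")) {
  level <- match.arg(level)
  hcol <- if (level == "nt") "cdr3_nt_h" else "cdr3_aa_h"
  kcol <- if (level == "nt") "cdr3_nt_k" else "cdr3_aa_k"
  hit <- pairs[[hcol]] == control_hc
  if (!any(hit)) abort("control heavy chain not found in the clonotype table")
  100 * sum(pairs$read_count[hit & pairs[[kcol]] == control_lc]) /
    sum(pairs$read_count[hit])
}

#' Track clonotypes shared between two samples
#'
#' Intersects the heavy CDR3 amino-acid sequences of two paired clonotype
#' tables (e.g. pre- and post-immunization) and reports, for the shared heavy
#' clonotypes, how often the most-frequent light CDR3 amino-acid partner is
#' identical in both samples.
#'
#' @param pre,post `paired_clonotypes` tibbles of the same isotype.
#' @return a list with `n_shared`, `lc_concordance_pct` (NA when no heavy
#'   clonotype is shared) and `shared`, a tibble with the top light partner in
#'   each sample and a `concordant` flag.
#' @export
track_shared_clonotypes <- function(pre, post) {
  top_lc <- function(tab) {
    tab |>
      group_by(hc = .data$cdr3_aa_h) |>
      arrange(desc(.data$read_count), .data$cdr3_aa_k, .by_group = TRUE) |>
      summarise(lc = dplyr::first(.data$cdr3_aa_k), .groups = "drop")
  }
  a <- top_lc(pre)
  b <- top_lc(post)
  shared <- inner_join(a, b, by = "hc", suffix = c("_pre", "_post")) |>
    mutate(concordant = .data$lc_pre == .data$lc_post) |>
    rename(cdr3_aa_h = "hc")
  list(
    n_shared = nrow(shared),
    lc_concordance_pct = if (nrow(shared)) 100 * mean(shared$concordant) else NA_real_,
    shared = shared
  )
}

#' Match known heavy CDR3 amino-acid sequences
#'
#' Exact (case-normalized) amino-acid matching of heavy CDR3s against a list
#' of previously reported sequences, returning the matching pairs with their
#' light-chain partners.
#'
#' @param pairs a `paired_clonotypes` tibble.
#' @param known character vector of known CDR3 amino-acid sequences.
#' @return the matching rows of `pairs`, with a `matched_known` column.
#' @export
match_known_cdr3 <- function(pairs, known) {
  if (length(known) == 0) abort("known CDR3 list is empty")
  known <- toupper(known)
  hit <- toupper(pairs$cdr3_aa_h) %in% known
  out <- pairs[hit, , drop = FALSE]
  out$matched_known <- toupper(out$cdr3_aa_h)
  out
}

#' Relative template abundance from qPCR threshold cycles
#'
#' Computes `2^-(mean(ct) - reference_ct)`, the standard 2^(-deltaCt)
#' relative-abundance estimate, together with the replicate spread.
#'
#' @param ct_replicates numeric vector of threshold cycles (>= 1 value).
#' @param reference_ct reference threshold cycle.
#' @return a one-row tibble: `relative_abundance`, `delta_ct`, `ct_mean`,
#'   `ct_sd`, `n_replicates`.
#' @examples
#' qpcr_relative_abundance(c(20, 20.2, 19.8), reference_ct = 18)
#' @export
qpcr_relative_abundance <- function(ct_replicates, reference_ct) {
  if (length(ct_replicates) == 0 || !is.numeric(ct_replicates)) {
    abort("ct_replicates must contain at least one numeric Ct value")
  }
  delta <- mean(ct_replicates) - reference_ct
  tibble(relative_abundance = 2^(-delta), delta_ct = delta,
         ct_mean = mean(ct_replicates),
         ct_sd = stats::sd(ct_replicates),
         n_replicates = length(ct_replicates))
}
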