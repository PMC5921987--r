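# Toy germline V/J/C reference
#
# A miniature stand-in for an IMGT-style germline set, small enough to ship
# and simulate against, but carrying everything the pipeline needs:
#  * V segments with the conserved CDR3-start cysteine as an explicit
#    0-based codon anchor (last codon of the segment),
#  * J segments with the conserved FR4 Trp/Phe anchor (first codon),
#  * constant-region tags that distinguish IgM, IgG and IgK,
#  * VH/VK families grouped into superfamilies that share a fixed exact
#    sequence window, so identity-dependent PCR chimerism is controllable.

V_CODONS <- 50L   # V segment length in codons; Cys anchor is the last codon
J_CODONS <- 12L   # J segment length in codons; FR4 anchor is the first codon
C_TAG_NT <- 60L   # constant-region tag length
SF_WINDOW_NT <- 49:96   # 1-based nt positions shared exactly within a superfamily
FAMILY_MUT_RATE <- 0.10 # per-nt divergence of a family from its superfamily ancestor

reference_columns <- c("id", "chain", "segment_class", "family", "superfamily",
                       "sequence", "cys_anchor", "fr4_anchor")

new_reference <- function(segments) {
  segments <- as_tibble(segments)[, reference_columns]
  class(segments) <- c("germline_reference", class(segments))
  segments
}

#' Build a toy germline reference
#'
#' Generates a deterministic miniature germline gene set with `n_vh_families`
#' heavy-chain V families (VH1, VH2, ...) and `n_vk_families` kappa V families,
#' two J segments and the constant-region tags (IgM, IgG, IgK) per locus.
#' Families are grouped into two superfamilies per chain; members of one
#' superfamily are derived from a common ancestor and keep a fixed 48-nt
#' exact-match window, so sequence identity within a superfamily is strictly
#' higher than between superfamilies.
#'
#' @param n_vh_families,n_vk_families number of V gene families per chain.
#' @param seed integer seed; the same seed reproduces the same reference.
#' @return A tibble of class `germline_reference` with one row per segment and
#'   columns `id`, `chain`, `segment_class`, `family`, `superfamily`,
#'   `sequence`, `cys_anchor` (V only, 0-based codon index) and `fr4_anchor`
#'   (J only, 0-based codon index).
#' @examples
#' ref <- build_toy_reference(7, 6, seed = 1)
#' dplyr::count(ref, chain, segment_class)
#' @export
build_toy_reference <- function(n_vh_families = 7, n_vk_families = 6, seed = 1) {
  if (!is.numeric(n_vh_families) || !is.numeric(n_vk_families) ||
      n_vh_families < 1 || n_vk_families < 1) {
    abort("n_vh_families and n_vk_families must be >= 1")
  }
  n_vh_families <- as.integer(n_vh_families)
  n_vk_families <- as.integer(n_vk_families)

  withr::with_seed(stage_seed(seed, 0L), {
    vh <- make_v_family_set(n_vh_families, chain = "heavy")
    vk <- make_v_family_set(n_vk_families, chain = "kappa")
    jh <- make_j_segments(chain = "heavy")
    jk <- make_j_segments(chain = "kappa")
    cc <- make_c_segments()
    new_reference(bind_rows(vh, jh, vk, jk, cc))
  })
}

make_v_ancestor <- function(anchor_codon) {
  codons <- sample(sense_codons(), V_CODONS, replace = TRUE)
  codons[V_CODONS] <- anchor_codon
  paste(codons, collapse = "")
}

mutate_outside_window <- function(seq, protected_nt) {
  nt <- strsplit(seq, "")[[1]]
  mutable <- setdiff(seq_along(nt), protected_nt)
  hit <- mutable[stats::runif(length(mutable)) < FAMILY_MUT_RATE]
  for (i in hit) nt[i] <- sample(setdiff(BASES, nt[i]), 1L)
  paste(nt, collapse = "")
}

make_v_family_set <- function(n_families, chain) {
  prefix <- if (chain == "heavy") "IGHV" else "IGKV"
  fam_prefix <- if (chain == "heavy") "VH" else "VK"
  sf_prefix <- if (chain == "heavy") "SFH" else "SFK"
  # first half of the families share superfamily 1, the rest superfamily 2
  sf_index <- ifelse(seq_len(n_families) <= ceiling(n_families / 2), 1L, 2L)
  ancestors <- vapply(1:2, function(i) make_v_ancestor("TGT"), character(1))
  protected <- c(SF_WINDOW_NT, (V_CODONS * 3L - 2L):(V_CODONS * 3L))
  purrr::map_dfr(seq_len(n_families), function(f) {
    tibble(
      id = sprintf("%s%d-1", prefix, f),
      chain = chain,
      segment_class = "V",
      family = sprintf("%s%d", fam_prefix, f),
      superfamily = sprintf("%s%d", sf_prefix, sf_index[f]),
      sequence = mutate_outside_window(ancestors[sf_index[f]], protected),
      cys_anchor = V_CODONS - 1L,
      fr4_anchor = NA_integer_
    )
  })
}

make_j_segments <- function(chain) {
  anchor <- if (chain == "heavy") "TGG" else "TTC"
  ids <- if (chain == "heavy") c("IGHJ4", "IGHJ6") else c("IGKJ1", "IGKJ2")
  fam <- if (chain == "heavy") "JH" else "JK"
  purrr::map_dfr(ids, function(id) {
    codons <- sample(sense_codons(), J_CODONS, replace = TRUE)
    codons[1L] <- anchor
    tibble(
      id = id, chain = chain, segment_class = "J", family = fam,
      superfamily = NA_character_,
      sequence = paste(codons, collapse = ""),
      cys_anchor = NA_integer_, fr4_anchor = 0L
    )
  })
}

make_c_segments <- function() {
  specs <- tibble(
    id = c("IGHM", "IGHG", "IGKC"),
    chain = c("heavy", "heavy", "kappa"),
    family = c("IgM", "IgG", "IgK")
  )
  repeat {
    seqs <- vapply(seq_len(nrow(specs)), function(i) random_dna(C_TAG_NT),
                   character(1))
    seeds <- substr(seqs, 1L, 20L)
    d <- utils::combn(seeds, 2, function(p) hamming(p[1], p[2]))
    if (min(d) >= 8L) break  # keep the scan seeds clearly distinguishable
  }
  specs |>
    mutate(segment_class = "C", superfamily = NA_character_, sequence = seqs,
           cys_anchor = NA_integer_, fr4_anchor = NA_integer_) |>
    select(all_of(reference_columns))
}

#' Subset a germline reference
#'
#' @param ref a `germline_reference` tibble.
#' @param chain optionally `"heavy"` or `"kappa"`.
#' @param segment_class optionally `"V"`, `"J"` or `"C"`.
#' @return the matching segment rows.
#' @export
ref_segments <- function(ref, chain = NULL, segment_class = NULL) {
  out <- ref
  if (!is.null(chain)) out <- out[out$chain == chain, ]
  if (!is.null(segment_class)) out <- out[out$segment_class == segment_class, ]
  out
}

c_tag_isotype <- function(id) {
  c(IGHM = "IgM", IGHG = "IgG", IGKC = "IgK")[[id]]
}

#' Validate a germline reference
#'
#' Checks the structural invariants of a reference: unique ids, at least one
#' V, J and C segment per chain, ACGT-only sequences, anchors inside the
#' segment, and anchor codons translating to Cys (V) or Trp/Phe (J).
#'
#' @param ref a `germline_reference` tibble.
#' @return `ref`, invisibly; aborts with the offending record otherwise.
#' @export
validate_reference <- function(ref) {
  if (nrow(ref) == 0) abort("empty reference")
  if (anyDuplicated(ref$id)) abort("duplicate segment ids in reference")
  assert_dna(ref$sequence, "reference sequence")
  for (ch in unique(ref$chain)) {
    have <- unique(ref$segment_class[ref$chain == ch])
    if (!all(c("V", "J", "C") %in% have)) {
      abort(sprintf("chain '%s' lacks one of V/J/C segments", ch))
    }
  }
  v <- ref[ref$segment_class == "V", ]
  if (any(is.na(v$cys_anchor)) ||
      any(3 * (v$cys_anchor + 1) > nchar(v$sequence))) {
    abort("V segment with missing or out-of-range cys_anchor")
  }
  cys <- substr(v$sequence, 3 * v$cys_anchor + 1, 3 * v$cys_anchor + 3)
  if (any(translate_nt(cys) != "C")) {
    abort(sprintf("cys_anchor codon does not encode C in %s",
                  v$id[translate_nt(cys) != "C"][1]))
  }
  j <- ref[ref$segment_class == "J", ]
  if (any(is.na(j$fr4_anchor)) ||
      any(3 * (j$fr4_anchor + 1) > nchar(j$sequence))) {
    abort("J segment with missing or out-of-range fr4_anchor")
  }
  fr4 <- substr(j$sequence, 3 * j$fr4_anchor + 1, 3 * j$fr4_anchor + 3)
  if (!all(translate_nt(fr4) %in% c("W", "F"))) {
    abort(sprintf("fr4_anchor codon does not encode W/F in %s",
                  j$id[!translate_nt(fr4) %in% c("W", "F")][1]))
  }
  invisible(ref)
}

#' Write a germline reference to FASTA
#'
#' Headers carry the segment metadata as pipe-delimited `key=value` fields,
#' e.g. `IGHV1-1|chain=heavy|class=V|family=VH1|superfamily=SFH1|cys_anchor=49`,
#' keeping the reference in plain FASTA while preserving the CDR3 anchors.
#'
#' @param ref a `germline_reference` tibble.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  hdr <- vapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    fields <- c(
      sprintf("chain=%s", r$chain),
      sprintf("class=%s", r$segment_class),
      sprintf("family=%s", r$family),
      if (!is.na(r$superfamily)) sprintf("superfamily=%s", r$superfamily),
      if (!is.na(r$cys_anchor)) sprintf("cys_anchor=%d", r$cys_anchor),
      if (!is.na(r$fr4_anchor)) sprintf("fr4_anchor=%d", r$fr4_anchor)
    )
    paste(c(r$id, fields), collapse = "|")
  }, character(1))
  seqs <- Biostrings::DNAStringSet(ref$sequence)
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read a germline reference from FASTA
#'
#' Inverse of [write_reference()]; the write -> read round trip is the
#' identity.
#'
#' @param path FASTA file with pipe-delimited `key=value` headers.
#' @return a validated `germline_reference` tibble.
#' @export
read_reference <- function(path) {
  seqs <- tryCatch(Biostrings::readDNAStringSet(path, format = "fasta"),
                   error = function(e) abort(sprintf(
                     "cannot read reference FASTA '%s': %s", path,
                     conditionMessage(e))))
  if (length(seqs) == 0) abort(sprintf("empty reference file: %s", path))
  rows <- purrr::map_dfr(seq_along(seqs), function(i) {
    hdr <- names(seqs)[i]
    parts <- strsplit(hdr, "|", fixed = TRUE)[[1]]
    if (length(parts) < 4) {
      abort(sprintf("malformed reference header (record %d): %s", i, hdr))
    }
    kv <- strsplit(parts[-1], "=", fixed = TRUE)
    if (any(lengths(kv) != 2)) {
      abort(sprintf("malformed key=value field in header (record %d): %s",
                    i, hdr))
    }
    f <- stats::setNames(vapply(kv, `[`, character(1), 2),
                         vapply(kv, `[`, character(1), 1))
    need <- c("chain", "class", "family")
    if (!all(need %in% names(f))) {
      abort(sprintf("header missing %s (record %d): %s",
                    paste(setdiff(need, names(f)), collapse = "/"), i, hdr))
    }
    if (f[["class"]] == "V" && !"cys_anchor" %in% names(f)) {
      abort(sprintf("V record without cys_anchor (record %d): %s", i, hdr))
    }
    if (f[["class"]] == "J" && !"fr4_anchor" %in% names(f)) {
      abort(sprintf("J record without fr4_anchor (record %d): %s", i, hdr))
    }
    sq <- as.character(seqs[[i]])
    if (grepl("[^ACGT]", sq)) {
      abort(sprintf("non-ACGT sequence in record %d (%s)", i, parts[1]))
    }
    tibble(
      id = parts[1], chain = f[["chain"]], segment_class = f[["class"]],
      family = f[["family"]],
      superfamily = if ("superfamily" %in% names(f)) f[["superfamily"]] else NA_character_,
      sequence = sq,
      cys_anchor = if ("cys_anchor" %in% names(f)) as.integer(f[["cys_anchor"]]) else NA_integer_,
      fr4_anchor = if ("fr4_anchor" %in% names(f)) as.integer(f[["fr4_anchor"]]) else NA_integer_
    )
  })
  validate_reference(new_reference(rows))
}
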