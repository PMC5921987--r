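# Pipeline configuration
#
# One nested list drives every stage. validate_config() fills defaults,
# checks constraints with key-path error messages, and is idempotent.

config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    reference = list(
      path = NULL,            # read an existing FASTA instead of building one
      n_vh_families = 7L,
      n_vk_families = 6L
    ),
    simulation = list(
      n_clones = 100L,
      abundance_exponent = 1.2,     # rank-frequency power-law skew
      n_cells = 10000L,
      microsomes_per_cell_mean = 1,
      droplet_lambda = 0.05,        # Poisson occupancy per droplet
      mode = "emulsion",            # or "open" (no compartments, random pairing)
      n_assemblies = NULL,          # open mode only; default = microsome count
      force_single_occupancy = FALSE,
      chimera_base_rate = 0,
      chimera_identity_window = 30L,
      ambient_contamination_rate = 0,
      seq_error_rate = 0.001,
      read_length = 250L,
      spike_in_fraction = 0,
      isotype_mix = c(IgM = 0.5, IgG = 0.5),
      secretion_sd = 0.5,           # sdlog of the log-normal microsome yield
      quality = list(q_start = 35, q_end = 25, q_sd = 3)
    ),
    preprocess = list(min_q = 10L, min_frac = 0.5, max_c_mismatch = 2L),
    annotate = list(min_v_score = 60, min_j_score = 20),
    clonotype = list(max_mismatch = 1L, ratio = 10, min_reads = 2L),
    stats = list(top_n = 10L, known_cdr3 = character(0))
  )
}

deep_merge <- function(base, user, path = character()) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    warn(sprintf("unknown config key(s): %s",
                 paste(paste(c(path, ""), collapse = "."), unknown,
                       sep = "", collapse = ", ")))
    user <- user[setdiff(names(user), unknown)]
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]]))) {
      base[k] <- list(deep_merge(base[[k]], user[[k]], c(path, k)))
    } else {
      base[k] <- list(user[[k]])  # list-assignment keeps explicit NULLs
    }
  }
  base
}

#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a nested list, fills every missing field
#' from the documented defaults, and checks all constraints. Validation
#' errors are collected and reported together, each naming the offending
#' key path. `validate_config(validate_config(x))` equals
#' `validate_config(x)`.
#'
#' @param config a file path (`.yaml`/`.yml`/`.json`) or a nested list; an
#'   empty list yields the all-defaults configuration.
#' @return the normalized configuration list, of class `pairem_config`.
#' @examples
#' cfg <- validate_config(list(seed = 7, simulation = list(n_clones = 3)))
#' cfg$simulation$droplet_lambda
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a list or a path to a YAML/JSON file")
  cfg <- deep_merge(config_defaults(), unclass(config))
  sim <- cfg$simulation
  if (!is.null(names(sim$isotype_mix)) || is.list(sim$isotype_mix)) {
    sim$isotype_mix <- unlist(sim$isotype_mix)
  }
  cfg$simulation <- sim

  errors <- character(0)
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)

  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed: must be a single integer")
  chk(sim$n_clones >= 1, "simulation.n_clones: must be >= 1")
  chk(sim$abundance_exponent >= 0, "simulation.abundance_exponent: must be >= 0")
  chk(sim$n_cells >= 1, "simulation.n_cells: must be >= 1")
  chk(sim$microsomes_per_cell_mean > 0, "simulation.microsomes_per_cell_mean: must be > 0")
  chk(sim$mode %in% c("emulsion", "open"), "simulation.mode: must be 'emulsion' or 'open'")
  if (identical(sim$mode, "emulsion")) {
    chk(is.numeric(sim$droplet_lambda) && sim$droplet_lambda > 0,
        "simulation.droplet_lambda: must be > 0 in emulsion mode")
  }
  for (p in c("chimera_base_rate", "ambient_contamination_rate",
              "seq_error_rate", "spike_in_fraction")) {
    chk(is.numeric(sim[[p]]) && sim[[p]] >= 0 && sim[[p]] <= 1,
        sprintf("simulation.%s: must be a probability in [0, 1]", p))
  }
  chk(sim$chimera_identity_window >= 1, "simulation.chimera_identity_window: must be >= 1")
  chk(sim$read_length >= 100, "simulation.read_length: must be >= 100")
  chk(all(sim$isotype_mix >= 0) && abs(sum(sim$isotype_mix) - 1) < 1e-9 &&
        all(names(sim$isotype_mix) %in% c("IgM", "IgG")),
      "simulation.isotype_mix: must be named IgM/IgG proportions summing to 1")
  chk(sim$secretion_sd >= 0, "simulation.secretion_sd: must be >= 0")
  chk(cfg$preprocess$min_q >= 0, "preprocess.min_q: must be >= 0")
  chk(cfg$preprocess$min_frac >= 0 && cfg$preprocess$min_frac <= 1,
      "preprocess.min_frac: must be in [0, 1]")
  chk(cfg$preprocess$max_c_mismatch >= 0, "preprocess.max_c_mismatch: must be >= 0")
  chk(cfg$clonotype$max_mismatch >= 0, "clonotype.max_mismatch: must be >= 0")
  chk(cfg$clonotype$ratio > 0, "clonotype.ratio: must be > 0")
  chk(cfg$clonotype$min_reads >= 1, "clonotype.min_reads: must be >= 1")
  chk(cfg$stats$top_n >= 1, "stats.top_n: must be >= 1")
  if (!is.null(cfg$reference$path)) {
    chk(file.exists(cfg$reference$path),
        sprintf("reference.path: file not found (%s)", cfg$reference$path))
  } else {
    chk(cfg$reference$n_vh_families >= 1, "reference.n_vh_families: must be >= 1")
    chk(cfg$reference$n_vk_families >= 1, "reference.n_vk_families: must be >= 1")
  }

  if (length(errors)) {
    abort(paste(c("invalid configuration:", paste0("  - ", errors)),
                collapse = "\n"))
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pairem_config", "list"))
}
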