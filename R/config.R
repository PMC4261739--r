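# Run configuration: one flat list of every tunable with its default.

.CONFIG_DEFAULTS <- list(
  cap_sd = 3,                 # standardisation cap, z-units
  min_fraction = 0.5,         # variability coverage mask
  mpc = 0.10,                 # max chain fraction dropped by full-matrix
  pearson_cluster_cut = 0.01, # flat-cut height for thermal grouping
  min_separation = 30,        # correlated-pair sequence separation
  top_k = 25,                 # correlated pairs reported
  dscore_cutoff = 0.9,        # distinct-pocket Dscore cutoff
  pocket_t = 5,               # distinct-pocket structures kept
  contact_cutoff = 5.0,       # protein/crystal contact cutoff, Angstrom
  ligand_cutoff = 4.5,        # ligand contact cutoff, Angstrom
  rmsf_window = 5,            # sliding-window width, residues
  seed = 1
)

#' Run configuration
#'
#' All pipeline tunables in one flat list. Defaults are the standard
#' operating point of the methodology (see each function's documentation
#' for what the numbers mean). Unknown names are rejected.
#'
#' @param ... overrides, e.g. `run_config(mpc = 0.2)`.
#' @return named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(bad)) stop("unknown config option(s): ",
                        paste(bad, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration (YAML)
#'
#' The round trip `load_config(save_config(cfg, f))` reproduces `cfg`
#' exactly.
#' @param cfg a `"run_config"`.
#' @param path YAML file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
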