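# Run configuration: flat TOML-style key = value files with optional
# [section] headers flattened to "section.key".  Unknown keys are rejected;
# every run writes a JSON provenance record (config hash, package version,
# seed) next to its outputs.

.KNOWN_KEYS <- c(
  "task", "seed", "output_dir",
  "scf.xyz", "scf.basis", "scf.functional", "scf.grid_preset",
  "scf.mm_table", "scf.conv_energy", "scf.conv_error", "scf.max_iter",
  "rt.dt", "rt.nsteps", "rt.propagator", "rt.magnus_order",
  "rt.kick_strength", "rt.kick_direction", "rt.damping_fs", "rt.isotropic",
  "md.backend", "md.nsteps", "md.dt", "md.temperature", "md.gamma",
  "md.sample_every", "md.mass_amu", "md.barrier_kcal", "md.well_sep",
  "umbrella.rc0", "umbrella.k_umb", "umbrella.i", "umbrella.j",
  "umbrella.k", "umbrella.l",
  "wham.manifest", "wham.nbins", "wham.tol", "wham.temperature",
  "ir.trace", "ir.dt", "ir.max_lag", "ir.window",
  "ensemble.manifest", "ensemble.lambda_min", "ensemble.lambda_max",
  "ensemble.lambda_step"
)

.parse_value <- function(v) {
  v <- trimws(v)
  if (grepl('^".*"$', v)) return(sub('^"(.*)"$', "\\1", v))
  if (v %in% c("true", "TRUE")) return(TRUE)
  if (v %in% c("false", "FALSE")) return(FALSE)
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}

#' Read a run configuration file
#'
#' Flat TOML-style dialect: `key = value` lines, `#` comments, optional
#' `[section]` headers whose keys become `section.key`.  Unknown keys are an
#' error.
#'
#' @param path config file path
#' @return named list of class `run_config`
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  cfg <- list()
  section <- ""
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      next
    }
    if (!grepl("=", ln))
      stop("config parse error at line ", i, ": expected key = value")
    key <- trimws(sub("=.*$", "", ln))
    if (nzchar(section)) key <- paste0(section, ".", key)
    if (!key %in% .KNOWN_KEYS)
      stop("unknown config key '", key, "'")
    cfg[[key]] <- .parse_value(sub("^[^=]*=", "", ln))
  }
  structure(cfg, class = "run_config", path = path)
}

.cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

#' Write a JSON provenance record for a run
#'
#' @param cfg `run_config` (or list)
#' @param output_dir directory the record is written into
#' @param seed RNG seed actually used
#' @param extra named list of additional fields
#' @return path of the record
#' @export
write_provenance <- function(cfg, output_dir, seed, extra = list()) {
  rec <- c(list(
    package = "picodft",
    version = as.character(utils::packageVersion("picodft")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(cfg),
    config_hash = if (!is.null(attr(cfg, "path")) &&
                      file.exists(attr(cfg, "path")))
      unname(tools::md5sum(attr(cfg, "path"))) else NA
  ), extra)
  path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}
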