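#' Run configuration bundle
#'
#' Collects the system choice, engine, bias, SCPS and success-criteria
#' settings into a single serializable object.  Round-trips through JSON
#' bit-exactly and carries a content hash that run directories embed for
#' provenance.
#'
#' @param system system name ("double-well", "mueller-brown", "hairpin",
#'   "fibril").
#' @param engine an [engine_config()].
#' @param scps list of SCPS parameters (n_c, iterations, tol, n_traj,
#'   lambda_mode, w_indexed).
#' @param criteria a [success_criteria()].
#' @param seed base RNG seed.
#' @return a \code{run_config}.
#' @export
run_config <- function(system = "double-well", engine = engine_config(),
                       scps = list(n_c = 10L, iterations = 2L, tol = 1e-3,
                                   n_traj = 20L, lambda_mode = "reciprocal",
                                   w_indexed = FALSE),
                       criteria = success_criteria(), seed = 1L) {
  cfg <- list(system = system, engine = engine, scps = scps,
              criteria = unclass(criteria), seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Serialize / restore a run configuration
#' @param cfg a [run_config()].
#' @param path JSON file path.
#' @return \code{write_run_config}: the path; \code{read_run_config}: the
#'   restored \code{run_config}.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("dt", "friction", "temperature", "k_r", "k_s", "k_w"))
    cfg$engine[[nm]] <- as.numeric(cfg$engine[[nm]])
  cfg$engine$n_steps <- as.integer(cfg$engine$n_steps)
  cfg$engine$save_stride <- as.integer(cfg$engine$save_stride)
  cfg$criteria <- unclass(do.call(success_criteria, cfg$criteria[
    !vapply(cfg$criteria, is.null, logical(1))]))
  structure(cfg, class = "run_config")
}

#' Content hash of a run configuration
#' @param cfg a [run_config()].
#' @return md5 hex string of the canonical JSON serialization.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  cfg <- unclass(cfg)
  cfg <- lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Reference settings for all-atom applications
#'
#' The force constants and schedule appropriate to explicit-solvent all-atom
#' applications of this method family (contact maps over heavy atoms, energies
#' in kJ/mol): kept for documentation and comparison; the package's toy-system
#' defaults are scaled to the reduced-unit CV magnitudes instead.
#'
#' @return a named list of settings.
#' @export
allatom_reference_settings <- function() {
  list(r0 = 7.5, rc = 12,
       k_r = 5e-5, k_s = 1.5e-5, k_w = 3e-5,   # kJ/mol per squared CV unit
       n_steps_folding = 1.5e6, n_steps_elongation = 3e6,
       save_stride = 500, timestep_fs = 2,
       rmsd_th = 3, e_th = 0.3, n_traj = 20, n_c = 10,
       atom_index_exclusion = 35,
       restraint_k = 1e3)                       # kJ/mol/nm^2
}
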