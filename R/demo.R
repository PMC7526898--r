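#' Built-in demo systems with study conditions
#'
#' Assembles a ready-to-run setup for one of the package's toy systems: the
#' system object, the initial configuration (reactant), the target reference,
#' tuned engine defaults and success criteria.  These are the conditions used
#' throughout the examples and the validation suite.
#'
#' @param name one of "double-well", "mueller-brown", "hairpin", "fibril".
#' @param quick shrink step counts for smoke tests.
#' @param seed seed used for fixture generation (fibril initial conditions).
#' @return list with components \code{system}, \code{initial}, \code{ref},
#'   \code{config}, \code{criteria}, plus system-specific extras (\code{model},
#'   \code{fixture}, \code{restraints}, ...).
#' @export
demo_system <- function(name = c("double-well", "mueller-brown", "hairpin",
                                 "fibril"),
                        quick = FALSE, seed = 1L) {
  name <- match.arg(name)
  shrink <- function(n) if (quick) as.integer(n / 4) else as.integer(n)
  if (name == "double-well") {
    surf <- build_double_well()
    cfg <- engine_config(dt = 0.005, friction = 1, temperature = 0.12,
                         n_steps = shrink(20000L), save_stride = 20L,
                         k_r = 50, k_s = 300, k_w = 150)
    list(system = surf, initial = surf$minima$reactant,
         ref = surf$minima$product, config = cfg,
         criteria = success_criteria(rmsd_th = 0.3, e_th = 0.1))
  } else if (name == "mueller-brown") {
    surf <- build_mueller_brown()
    cfg <- engine_config(dt = 5e-4, friction = 10, temperature = 12,
                         n_steps = shrink(40000L), save_stride = 40L,
                         k_r = 1000, k_s = 8000, k_w = 4000)
    list(system = surf, initial = surf$minima$reactant,
         ref = surf$minima$product, config = cfg,
         criteria = success_criteria(rmsd_th = 0.3, e_th = 0.1))
  } else if (name == "hairpin") {
    native <- build_toy_hairpin()
    model <- build_go_model(native)
    ref <- reference_structure(native)
    cfg <- engine_config(dt = 0.01, friction = 1, temperature = 0.35,
                         n_steps = shrink(60000L), save_stride = 100L,
                         k_r = 20, k_s = 800, k_w = 400)
    list(system = model, initial = NULL, ref = ref, config = cfg,
         criteria = success_criteria(rmsd_th = 3, e_th = 0.3),
         model = model, native = native)
  } else {
    fx <- build_toy_fibril(n_subunits = 3, residues_per_rung = 5, seed = seed)
    model <- fibril_go_model(fx, eps_scale = c("inter-rung" = 0.25,
                                               "monomer-fibril" = 1.5))
    ref <- reference_structure(fx$coords)
    template <- which(fx$chains != fx$converting)
    monomer <- subunit_indices(fx, fx$converting)
    anchored_lab <- if (fx$converting > 1) "N-rung" else "C-rung"
    anchored_rung <- monomer[fx$rung[monomer] == anchored_lab]
    cfg <- engine_config(dt = 0.01, friction = 1, temperature = 0.4,
                         n_steps = shrink(150000L), save_stride = 100L,
                         k_r = 20, k_s = 2000, k_w = 5)
    restr <- restraint_set(template, fx$coords[template, , drop = FALSE],
                           k = 50)
    list(system = model, initial = NULL, ref = ref, config = cfg,
         criteria = success_criteria(rmsd_th = 3, e_th = 0.3,
                                     align = template, calc = monomer),
         model = model, fixture = fx, restraints = restr,
         template = template, monomer = monomer,
         anchored_rung = anchored_rung)
  }
}

#' Extended (unfolded) starting configuration for a Go model
#'
#' Deterministic near-straight chain with a gentle helical twist, used as the
#' unfolded reactant of folding demos.
#'
#' @param model a \code{go_model}.
#' @param spacing bond spacing of the extended chain (Angstrom).
#' @return n x 3 coordinate matrix with Q ~ 0.
#' @export
extended_configuration <- function(model, spacing = 3.6) {
  n <- model$n
  i <- seq_len(n)
  cbind(2.2 * cos(i * 0.7), (i - 1) * spacing * 0.95, 2.2 * sin(i * 0.7))
}

#' End-to-end demo workflow
#'
#' Runs a compact version of the full pipeline on a chosen system: biased
#' (rMD) ensemble from the reactant, success classification, one SCPS
#' refinement where at least one trajectory succeeded, and a short analysis
#' report (success counts, path-similarity of the biased ensemble within
#' itself).
#'
#' @param system system name (see [demo_system()]).
#' @param quick use reduced step counts.
#' @param seed base RNG seed.
#' @param out optional output directory (trajectory store + config + report).
#' @return list with the ensembles, paths and the report text, invisibly.
#' @export
demo_workflow <- function(system = "double-well", quick = TRUE, seed = 1L,
                          out = NULL) {
  d <- demo_system(system, quick = quick, seed = seed)
  initial <- d$initial
  if (system %in% c("hairpin", "fibril")) {
    if (system == "hairpin") initial <- extended_configuration(d$model)
    else {
      ics <- generate_unfolded_initial_conditions(
        d$model, d$fixture, n_conditions = 1,
        n_steps = if (quick) 30000L else 150000L, seed = seed)
      initial <- ics[[1]]
    }
  }
  hist <- run_scps(d$system, initial, d$ref,
                   n_traj = if (quick) 6 else 20, config = d$config,
                   max_iterations = 2, criteria = d$criteria,
                   restraints = d$restraints, seed = seed)
  report <- utils::capture.output(print(hist))
  # within-ensemble similarity of the last iteration (bead systems)
  last <- hist$iterations[[length(hist$iterations)]]$ensemble
  if (d$system$kind == "beads" && sum(last$success) >= 2) {
    oms <- lapply(which(last$success), function(i)
      order_matrix(contact_formation_times(
        last$trajectories[[i]], pairs = d$model$native_pairs)))
    sims <- similarity_distributions(oms, n_random_sets = 2, seed = seed)
    report <- c(report,
                sprintf("self-similarity A: mean %.3f over %d pairs",
                        mean(sims$A), length(sims$A)))
  }
  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    cfg <- run_config(system = system, engine = d$config,
                      criteria = d$criteria, seed = seed)
    write_run_config(cfg, file.path(out, "config.json"))
    writeLines(c(report, paste("config_hash:", config_hash(cfg))),
               file.path(out, "report.txt"))
    saveRDS(hist, file.path(out, "history.rds"))
  }
  message(paste(report, collapse = "\n"))
  invisible(list(history = hist, report = report))
}
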