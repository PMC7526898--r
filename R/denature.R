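#' Unstructured initial conditions by restrained thermal denaturation
#'
#' Runs high-temperature dynamics with the template subunits held by
#' positional restraints and the converting monomer free, and harvests
#' configurations in which the free monomer has lost its native structure
#' (fraction of native contacts Q < \code{q_max}) while the restrained
#' subunits remain close to the fixture.  The default denaturation
#' temperature is five times the model's folding temperature.
#'
#' @param model a \code{go_model} of the fixture (see [fibril_go_model()]).
#' @param fixture the \code{fibril_fixture}.
#' @param n_conditions number of initial conditions to harvest.
#' @param restrained_subunits subunits to restrain (must exclude the
#'   converting monomer); default: all template subunits.
#' @param high_temperature denaturation temperature (reduced units).
#' @param q_max monomer Q threshold defining "unstructured".
#' @param restraint_k restraint force constant.
#' @param n_steps step budget of the denaturation run.
#' @param spacing minimum number of saved frames between harvested conditions.
#' @param proximity optional template-proximal seeding filter:
#'   \code{list(indices =, max_distance =)} keeps only frames in which the
#'   centroid of the given monomer beads lies within \code{max_distance}
#'   Angstrom of its native centroid, so elongation starts on the
#'   template-proximal side.
#' @param seed RNG seed.
#' @param config optional [engine_config()] override (temperature and steps
#'   are replaced by the arguments above).
#' @return list of configurations (n x 3 matrices) with attributes
#'   \code{monomer_q} and \code{template_rmsd}.
#' @export
generate_unfolded_initial_conditions <- function(model, fixture,
    n_conditions = 2, restrained_subunits = NULL, high_temperature = NULL,
    q_max = 0.1, restraint_k = 50, n_steps = 200000L, spacing = 20L,
    proximity = NULL, seed = 1L, config = NULL) {
  conv <- fixture$converting
  if (is.null(restrained_subunits))
    restrained_subunits <- setdiff(seq_len(fixture$n_subunits), conv)
  if (conv %in% restrained_subunits)
    stop("restrained_subunits must exclude the converting monomer")
  if (is.null(high_temperature))
    high_temperature <- 5 * model$folding_temperature
  if (is.null(config)) config <- engine_config()
  config$temperature <- high_temperature
  config$n_steps <- as.integer(n_steps)

  ridx <- unlist(lapply(restrained_subunits, subunit_indices,
                        fixture = fixture))
  restr <- restraint_set(ridx, fixture$coords[ridx, , drop = FALSE],
                         k = restraint_k)
  mono_idx <- subunit_indices(fixture, conv)
  mono_pairs <- model$native_pairs[
    model$native_pairs[, 1] %in% mono_idx |
    model$native_pairs[, 2] %in% mono_idx, , drop = FALSE]

  tr <- run_trajectory(model, fixture$coords, config, bias = "none",
                       restraints = restr, seed = seed)
  q <- q_fraction(tr$frames, model, pairs = mono_pairs)
  burn <- ceiling(nrow(tr$frames) * 0.1)
  keep <- q < q_max & seq_along(q) > burn
  if (!is.null(proximity)) {
    idx <- proximity$indices
    anchor <- colMeans(fixture$coords[idx, , drop = FALSE])
    cen <- t(vapply(seq_len(nrow(tr$frames)), function(f) {
      X <- frame_coords(tr, f)
      colMeans(X[idx, , drop = FALSE])
    }, numeric(3)))
    keep <- keep & sqrt(rowSums(sweep(cen, 2, anchor)^2)) <=
      proximity$max_distance
  }
  ok <- which(keep)
  picked <- integer(0)
  for (f in ok) {
    if (length(picked) == n_conditions) break
    if (!length(picked) || f - tail(picked, 1) >= spacing) picked <- c(picked, f)
  }
  if (length(picked) < n_conditions) {
    stop(sprintf(paste0("thermal denaturation failed to produce %d conditions ",
                        "with monomer Q < %.2f within the step budget ",
                        "(best Q achieved: %.3f)"),
                 n_conditions, q_max, min(q[-seq_len(burn)])))
  }
  rms <- cpp_rmsd_frames(tr$frames[picked, , drop = FALSE], fixture$coords,
                         ridx - 1L, ridx - 1L)
  out <- lapply(seq_along(picked), function(s) {
    X <- frame_coords(tr, picked[s])
    attr(X, "monomer_q") <- q[picked[s]]
    attr(X, "template_rmsd") <- rms[s]
    X
  })
  attr(out, "frames") <- picked
  out
}
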