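#' Positional restraint set
#'
#' Harmonic anchors tying selected beads to fixed positions, the analogue of
#' heavy-atom position restraints in all-atom simulations.
#'
#' @param indices bead indices (1-based).
#' @param anchors matching anchor coordinates (length(indices) x 3).
#' @param k force constant (energy / Angstrom^2), >= 0.
#' @return a \code{restraint_set}.
#' @export
restraint_set <- function(indices, anchors, k = 50) {
  anchors <- as.matrix(anchors)
  stopifnot(length(indices) == nrow(anchors), k >= 0)
  structure(list(indices = as.integer(indices), anchors = anchors, k = k),
            class = "restraint_set")
}

#' Engine configuration
#'
#' @param dt integration time step (reduced units).
#' @param friction Langevin friction (1/time); must be > 0 for sampling.
#' @param temperature reduced temperature (k_B = 1).
#' @param n_steps number of integration steps.
#' @param save_stride save every this many steps (frame 0 always saved).
#' @param scheme "baoab" (underdamped; reduces to velocity Verlet at zero
#'   friction) or "overdamped" (Euler-Maruyama on the overdamped equation).
#' @param k_r,k_s,k_w ratchet force constants for the z, s and w channels.
#' @return a plain list of validated engine parameters.
#' @export
engine_config <- function(dt = 0.01, friction = 1, temperature = 0.5,
                          n_steps = 10000L, save_stride = 100L,
                          scheme = c("baoab", "overdamped"),
                          k_r = 100, k_s = 500, k_w = 500) {
  scheme <- match.arg(scheme)
  stopifnot(dt > 0, friction >= 0, temperature >= 0, n_steps >= 1,
            save_stride >= 1)
  list(dt = dt, friction = friction, temperature = temperature,
       n_steps = as.integer(n_steps), save_stride = as.integer(save_stride),
       scheme = scheme, k_r = k_r, k_s = k_s, k_w = k_w)
}

# internal: assemble the engine list consumed by C++
engine_list <- function(config, bias_mode, restraints = NULL,
                        mem_init = c(NA_real_, NA_real_)) {
  e <- config
  e$bias_mode <- c(none = 0L, rmd = 1L, scps = 2L)[[bias_mode]]
  e$mem1_init <- mem_init[1]
  e$mem2_init <- mem_init[2]
  if (!is.null(restraints)) {
    e$restraint_idx <- matrix(restraints$indices - 1L, ncol = 1)
    e$restraint_anchor <- restraints$anchors
    e$restraint_k <- restraints$k
  } else {
    e$restraint_idx <- NULL
  }
  e
}

#' Run one (possibly biased) Langevin trajectory
#'
#' Propagates the system for a fixed number of steps and returns all saved
#' frames together with per-frame CV values and ratchet memories.  The
#' trajectory always runs to completion; success is classified afterwards
#' with [check_success()].  The ratchet memories are initialized from the
#' first frame and updated after each force evaluation, so the biasing force
#' at a step always uses the memory of the previous step.
#'
#' @param system a \code{go_model} or \code{analytic_surface}.
#' @param initial initial configuration (n x 3, or length-2 for surfaces).
#' @param config an [engine_config()].
#' @param bias "none", "rmd" (ratchet on z) or "scps" (double ratchet on
#'   s_lambda and on the off-path distance d = -w_lambda).
#' @param cv for "rmd": a [reference_structure()] (or target point for
#'   surfaces); for "scps": a \code{mean_path} with lambda set.
#' @param restraints optional [restraint_set()].
#' @param seed if non-NULL, \code{set.seed(seed)} is called first.
#' @param velocities optional initial velocities (drawn from the Maxwell
#'   distribution when omitted and the scheme is underdamped).
#' @param mem_init optional initial ratchet memories (default: first frame).
#' @return an \code{scps_trajectory}: frame matrix (one row per saved frame),
#'   CV and memory traces, bias work bookkeeping and the run configuration.
#' @export
run_trajectory <- function(system, initial, config = engine_config(),
                           bias = c("none", "rmd", "scps"), cv = NULL,
                           restraints = NULL, seed = NULL, velocities = NULL,
                           mem_init = c(NA_real_, NA_real_)) {
  bias <- match.arg(bias)
  if (!is.null(seed)) set.seed(seed)
  X0 <- if (system$kind == "surface") matrix(as.numeric(initial), nrow = 1)
        else as.matrix(initial)
  cvspec <- list()
  if (bias == "rmd") {
    if (is.null(cv)) stop("bias 'rmd' needs cv = reference structure / target")
    cvspec <- cv_spec_rmd(cv)
  } else if (bias == "scps") {
    if (!inherits(cv, "mean_path")) stop("bias 'scps' needs cv = mean_path")
    cvspec <- cv_spec_scps(cv)
  }
  eng <- engine_list(config, bias, restraints, mem_init)
  res <- cpp_run_trajectory(system$cpp, cvspec, eng, X0,
                            if (is.null(velocities)) NULL
                            else as.matrix(velocities))
  if (res$error)
    warning("non-finite state encountered; trajectory truncated at frame ",
            res$n_saved)
  structure(list(frames = res$frames,
                 cv = data.frame(frame = seq_len(nrow(res$frames)) - 1L,
                                 cv1 = as.numeric(res$cv1),
                                 cv2 = as.numeric(res$cv2),
                                 mem1 = as.numeric(res$mem1),
                                 mem2 = as.numeric(res$mem2)),
                 bias = bias,
                 bias_work_total = res$bias_work_total,
                 bias_work_latent = res$bias_work_latent,
                 n_bias_active = res$n_bias_active,
                 error = res$error,
                 velocities = res$velocities,
                 system_kind = system$kind,
                 dim = if (system$kind == "surface") 2L else 3L,
                 n_beads = nrow(X0),
                 config = config, seed = seed),
            class = "scps_trajectory")
}

#' @export
print.scps_trajectory <- function(x, ...) {
  cat("<scps_trajectory> ", nrow(x$frames), " frames, bias = ", x$bias,
      if (x$error) " [TRUNCATED: non-finite state]" else "", "\n", sep = "")
  invisible(x)
}

#' Coordinates of one saved frame
#' @param traj an \code{scps_trajectory}.
#' @param frame frame number (1-based row of the frame matrix).
#' @return n x dim coordinate matrix.
#' @export
frame_coords <- function(traj, frame) {
  matrix(traj$frames[frame, ], ncol = traj$dim, byrow = TRUE)
}

#' Single Langevin step
#'
#' One step of the integrator (thin wrapper over the trajectory runner with
#' \code{n_steps = 1}); useful for stepwise tests and custom loops.
#'
#' @inheritParams run_trajectory
#' @param state list with \code{coords} and optional \code{velocities}.
#' @return updated state: \code{coords}, \code{velocities}, \code{cv},
#'   \code{mem}.
#' @export
step_langevin <- function(system, state, config = engine_config(),
                          bias = "none", cv = NULL, restraints = NULL,
                          mem_init = c(NA_real_, NA_real_)) {
  config$n_steps <- 1L
  config$save_stride <- 1L
  tr <- run_trajectory(system, state$coords, config, bias, cv, restraints,
                       seed = NULL, velocities = state$velocities,
                       mem_init = mem_init)
  list(coords = frame_coords(tr, nrow(tr$frames)),
       velocities = tr$velocities,
       cv = c(tr$cv$cv1[nrow(tr$cv)], tr$cv$cv2[nrow(tr$cv)]),
       mem = c(tr$cv$mem1[nrow(tr$cv)], tr$cv$mem2[nrow(tr$cv)]))
}

#' Ratchet-and-pawl biasing force (single channel)
#'
#' The history-dependent bias
#' \deqn{F = -k_R \nabla z \, (z - z_m)\,\theta(z - z_m)}
#' with \eqn{\theta(0) = 0} (zero force exactly on the boundary), followed by
#' the memory update \eqn{z_m \leftarrow \min(z_m, z)}.  When the CV improves
#' the bias is latent and the dynamics is plain MD.
#'
#' @param value current CV value z(X).
#' @param gradient CV gradient (any shape).
#' @param ratchet list with \code{memory} (best CV so far; NA initializes from
#'   this evaluation) and \code{k} (force constant).
#' @return list: \code{force} (same shape as gradient), updated
#'   \code{ratchet}, logical \code{active}.
#' @export
rmd_bias_force <- function(value, gradient, ratchet) {
  if (is.na(ratchet$memory)) ratchet$memory <- value
  active <- value > ratchet$memory && ratchet$k != 0
  force <- if (active) -ratchet$k * (value - ratchet$memory) * gradient
           else gradient * 0
  ratchet$memory <- min(ratchet$memory, value)
  list(force = force, ratchet = ratchet, active = active)
}

#' Double-ratchet SCPS biasing force
#'
#' Applies the single-channel ratchet independently to the progress CV
#' \code{s_lambda} (memory = running minimum, constant \code{k_s}) and to the
#' off-path distance \code{d = -w_lambda} (memory = running minimum, constant
#' \code{k_w}); each channel is zero whenever its CV does not exceed its
#' memory.
#'
#' @param s,grad_s progress CV value and gradient.
#' @param d,grad_d off-path distance value and gradient.
#' @param ratchet list with \code{s_m}, \code{d_m}, \code{k_s}, \code{k_w}.
#' @return list: total \code{force}, per-channel forces, updated
#'   \code{ratchet}.
#' @export
scps_bias_force <- function(s, grad_s, d, grad_d, ratchet) {
  ch_s <- rmd_bias_force(s, grad_s,
                         list(memory = ratchet$s_m, k = ratchet$k_s))
  ch_d <- rmd_bias_force(d, grad_d,
                         list(memory = ratchet$d_m, k = ratchet$k_w))
  ratchet$s_m <- ch_s$ratchet$memory
  ratchet$d_m <- ch_d$ratchet$memory
  list(force = ch_s$force + ch_d$force,
       force_s = ch_s$force, force_d = ch_d$force,
       ratchet = ratchet, active = c(s = ch_s$active, d = ch_d$active))
}

#' Export a bead trajectory as plain-text XYZ
#'
#' @param traj an \code{scps_trajectory} from a bead system.
#' @param path output file.
#' @param element element symbol written for every bead.
#' @export
write_xyz <- function(traj, path, element = "CA") {
  stopifnot(traj$dim == 3L)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nrow(traj$frames))) {
    X <- frame_coords(traj, f)
    writeLines(c(as.character(nrow(X)), paste("frame", f - 1L)), con)
    writeLines(sprintf("%s %.4f %.4f %.4f", element, X[, 1], X[, 2], X[, 3]),
               con)
  }
  invisible(path)
}
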