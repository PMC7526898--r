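#' Success criteria for reactive trajectories
#'
#' A trajectory has reached the target state if some frame n has
#' RMSD(n) < \code{rmsd_th} and the root-mean-square of the over-threshold
#' excursions over frames n..N_F (only frames above the threshold contribute,
#' the denominator is all remaining frames) stays below the tolerance
#' \code{e_th}.
#'
#' @param rmsd_th closeness threshold (Angstrom; surface systems: distance
#'   units of the surface).
#' @param e_th excursion tolerance, 0 < e_th < rmsd_th.
#' @param align optional bead indices used for superposition (default: all;
#'   fibril workflows use the template subunits).
#' @param calc optional bead indices over which the RMSD is computed
#'   (default: all beads).
#' @return a \code{success_criteria} object.
#' @export
success_criteria <- function(rmsd_th = 3, e_th = 0.3, align = NULL,
                             calc = NULL) {
  if (!(rmsd_th > e_th && e_th > 0))
    stop("invalid success criteria: need rmsd_th > e_th > 0")
  structure(list(rmsd_th = as.numeric(rmsd_th), e_th = as.numeric(e_th),
                 align = if (is.null(align)) NULL else as.integer(align),
                 calc = if (is.null(calc)) NULL else as.integer(calc)),
            class = "success_criteria")
}

#' Per-frame RMSD of a trajectory to a reference
#'
#' Bead systems: Kabsch superposition on the alignment subset, RMSD over the
#' calculation subset.  Surface systems: Euclidean distance to the target
#' point.
#'
#' @param traj an \code{scps_trajectory} (or a frame matrix).
#' @param ref a [reference_structure()], coordinate matrix, or target point.
#' @param criteria a [success_criteria()] supplying the subsets.
#' @return numeric vector, one value per frame.
#' @export
rmsd_trace <- function(traj, ref, criteria = success_criteria()) {
  frames <- if (inherits(traj, "scps_trajectory")) traj$frames else as.matrix(traj)
  dim <- if (inherits(traj, "scps_trajectory")) traj$dim
         else if (inherits(ref, "reference_structure") || is.matrix(ref)) 3L
         else 2L
  if (dim == 2L) {
    tgt <- as.numeric(ref)
    return(sqrt((frames[, 1] - tgt[1])^2 + (frames[, 2] - tgt[2])^2))
  }
  refX <- if (inherits(ref, "reference_structure")) ref$coords else as.matrix(ref)
  n <- nrow(refX)
  align <- if (is.null(criteria$align)) seq_len(n) else criteria$align
  calc <- if (is.null(criteria$calc)) seq_len(n) else criteria$calc
  as.numeric(cpp_rmsd_frames(frames, refX, align - 1L, calc - 1L))
}

#' Classify a trajectory as successful or failed
#'
#' @inheritParams rmsd_trace
#' @param rmsd optional precomputed RMSD trace (skips recomputation).
#' @return list: \code{success}, \code{first_frame} (1-based saved-frame row
#'   of the earliest qualifying frame, NA on failure), \code{rmsd} trace,
#'   \code{min_rmsd} (closest approach).
#' @export
check_success <- function(traj, ref, criteria = success_criteria(),
                          rmsd = NULL) {
  if (is.null(rmsd)) rmsd <- rmsd_trace(traj, ref, criteria)
  nf <- length(rmsd)
  if (nf == 0) stop("empty trajectory")
  exc <- pmax(rmsd - criteria$rmsd_th, 0)^2
  suffix <- rev(cumsum(rev(exc)))                  # sum_{k >= n} excursions^2
  rms <- sqrt(suffix / (nf - seq_len(nf) + 1))
  ok <- rmsd < criteria$rmsd_th & rms < criteria$e_th
  first <- if (any(ok)) which(ok)[1] else NA_integer_
  list(success = any(ok), first_frame = first, rmsd = rmsd,
       min_rmsd = min(rmsd))
}

#' Run an ensemble of same-length trajectories from one initial condition
#'
#' @inheritParams run_trajectory
#' @param n_traj number of trajectories.
#' @param ref reference used for success classification (and for the rMD CV
#'   when \code{bias = "rmd"}).
#' @param criteria a [success_criteria()].
#' @param seed base seed; trajectory i uses \code{seed + i}.
#' @return an \code{scps_ensemble} with per-trajectory success flags and
#'   first-hit frames.
#' @export
run_ensemble <- function(system, initial, ref, n_traj = 20,
                         config = engine_config(),
                         bias = c("rmd", "scps", "none"), cv = NULL,
                         criteria = success_criteria(), restraints = NULL,
                         seed = 1L) {
  bias <- match.arg(bias)
  if (bias == "rmd" && is.null(cv))
    cv <- if (inherits(ref, "reference_structure")) ref else as.numeric(ref)
  trajs <- vector("list", n_traj)
  succ <- logical(n_traj); first <- integer(n_traj); minr <- numeric(n_traj)
  for (i in seq_len(n_traj)) {
    tr <- run_trajectory(system, initial, config, bias, cv, restraints,
                         seed = seed + i)
    cs <- check_success(tr, ref, criteria)
    tr$success <- cs$success
    tr$first_frame <- cs$first_frame
    tr$rmsd <- cs$rmsd
    trajs[[i]] <- tr
    succ[i] <- cs$success; first[i] <- ifelse(is.na(cs$first_frame), NA, cs$first_frame)
    minr[i] <- cs$min_rmsd
  }
  structure(list(trajectories = trajs,
                 success = succ, first_frame = first, min_rmsd = minr,
                 bias = bias, ref = ref, criteria = criteria,
                 initial = initial, config = config, seed = seed),
            class = "scps_ensemble")
}

#' @export
print.scps_ensemble <- function(x, ...) {
  cat("<scps_ensemble> ", length(x$trajectories), " trajectories (bias = ",
      x$bias, "), ", sum(x$success), " successful\n", sep = "")
  invisible(x)
}

# internal: feature matrix (frames x features) of one trajectory
trajectory_features <- function(traj, params, pairs) {
  if (traj$system_kind == "surface") return(traj$frames)
  cpp_contact_frames(traj$frames, pairs[, 1] - 1L, pairs[, 2] - 1L,
                     params$r0, params$rc)
}

#' Iso-time mean path of an ensemble
#'
#' Frame-wise arithmetic mean of the contact maps of the successful
#' trajectories only (all trajectories share the same frame count, so the
#' average at frame t is over configurations at equal simulation time).
#'
#' @param ensemble an \code{scps_ensemble} with at least one success.
#' @param params a [contact_map_params()] (bead systems).
#' @param w_indexed store the Eq-8 variant flag on the path (see
#'   [w_lambda()]).
#' @return a full-resolution \code{mean_path} (one map per frame).
#' @export
compute_mean_path <- function(ensemble, params = contact_map_params(),
                              w_indexed = FALSE) {
  ok <- which(ensemble$success)
  if (!length(ok))
    stop("no successful trajectories: cannot compute a mean path")
  t1 <- ensemble$trajectories[[ok[1]]]
  surface <- t1$system_kind == "surface"
  pairs <- if (surface) NULL else eligible_pairs(t1$n_beads, params)
  acc <- NULL
  for (i in ok) {
    fm <- trajectory_features(ensemble$trajectories[[i]], params, pairs)
    acc <- if (is.null(acc)) fm else acc + fm
  }
  maps <- acc / length(ok)
  structure(list(maps = maps, params = if (surface) NULL else params,
                 pairs = pairs, n_traj = length(ok),
                 system_kind = t1$system_kind,
                 lambda = NULL, w_indexed = w_indexed,
                 frame_index = seq_len(nrow(maps)), downsampled = FALSE),
            class = "mean_path")
}

#' @export
print.mean_path <- function(x, ...) {
  cat("<mean_path> ", nrow(x$maps), " maps x ", ncol(x$maps), " features (",
      x$system_kind, if (x$downsampled) ", downsampled" else "",
      if (!is.null(x$lambda)) sprintf(", lambda = %.4g", x$lambda) else "",
      ")\n", sep = "")
  invisible(x)
}

# internal: reference feature vector matching a path's feature space
ref_features <- function(ref, path = NULL) {
  if (inherits(ref, "reference_structure")) ref$map$values
  else if (inherits(ref, "contact_map")) ref$values
  else as.numeric(ref)
}

#' z of every mean-path map against the target
#' @param path a \code{mean_path}.
#' @param ref a [reference_structure()] (or target point for surfaces).
#' @return numeric vector of squared contact-map distances.
#' @export
path_z <- function(path, ref) {
  rf <- ref_features(ref, path)
  colSums((t(path$maps) - rf)^2)
}

#' Downsample a mean path to maps equally spaced in z
#'
#' Selects the maps whose z (squared contact-map distance to the target) is
#' nearest to \code{n_c} values equally spaced between the z of the first and
#' last maps; both endpoints are always kept, ties resolve to the earlier
#' frame, and the output is ordered by decreasing z.
#'
#' @param path a full-resolution \code{mean_path}.
#' @param ref the target [reference_structure()] (or surface target point).
#' @param n_c number of maps to keep (>= 2).
#' @return the downsampled \code{mean_path} (lambda cleared; call
#'   [set_lambda()] afterwards).
#' @export
downsample_mean_path <- function(path, ref, n_c = 10) {
  stopifnot(inherits(path, "mean_path"), n_c >= 2)
  nfull <- nrow(path$maps)
  if (nfull <= n_c) {
    sel <- seq_len(nfull)
  } else {
    z <- path_z(path, ref)
    targets <- seq(z[1], z[nfull], length.out = n_c)
    sel <- vapply(targets, function(tz) which.min(abs(z - tz)), integer(1))
    sel[1] <- 1L; sel[n_c] <- nfull
    sel <- unique(sel)
    sel <- sel[order(-z[sel], sel)]
  }
  path$maps <- path$maps[sel, , drop = FALSE]
  path$frame_index <- path$frame_index[sel]
  path$downsampled <- TRUE
  path$lambda <- NULL
  path
}

#' One SCPS iteration
#'
#' Runs the biased ensemble (rMD on z when no previous path is given, the
#' double ratchet on s_lambda / w_lambda otherwise), classifies successes,
#' and builds the new downsampled mean path with lambda refreshed.
#'
#' @inheritParams run_ensemble
#' @param previous_path previous \code{mean_path} or NULL (iteration 0).
#' @param n_c number of downsampled maps.
#' @param params contact-map parameters for the mean path.
#' @param lambda_mode passed to [set_lambda()].
#' @param w_indexed Eq-8 variant flag for the new path.
#' @return list with the \code{ensemble} and the new \code{path}.
#' @export
scps_iteration <- function(system, initial, ref, n_traj = 20,
                           config = engine_config(), previous_path = NULL,
                           n_c = 10, criteria = success_criteria(),
                           params = contact_map_params(), restraints = NULL,
                           lambda_mode = "reciprocal", w_indexed = FALSE,
                           seed = 1L) {
  bias <- if (is.null(previous_path)) "rmd" else "scps"
  ens <- run_ensemble(system, initial, ref, n_traj, config, bias,
                      cv = previous_path, criteria = criteria,
                      restraints = restraints, seed = seed)
  if (!any(ens$success)) {
    stop(sprintf(paste0("no successful trajectories in this iteration; ",
                        "closest approaches (RMSD): %s"),
                 paste(sprintf("%.2f", ens$min_rmsd), collapse = ", ")))
  }
  full <- compute_mean_path(ens, params, w_indexed = w_indexed)
  path <- downsample_mean_path(full, ref, n_c)
  path <- set_lambda(path, mode = lambda_mode)
  list(ensemble = ens, path = path)
}

#' Self-consistent path sampling loop
#'
#' Iterates [scps_iteration()] from one initial condition until the mean
#' squared contact-map distance between corresponding maps of successive
#' downsampled paths falls below \code{tol} (a quantitative surrogate for
#' visual convergence of the landscape), or until \code{max_iterations}.
#'
#' @inheritParams scps_iteration
#' @param max_iterations maximum number of iterations (iteration 1 is rMD).
#' @param tol convergence tolerance on the inter-iteration path distance
#'   (squared-norm units).
#' @return an \code{scps_history}: per-iteration ensembles and paths, the
#'   convergence trace, and the \code{converged} flag.
#' @export
run_scps <- function(system, initial, ref, n_traj = 20,
                     config = engine_config(), max_iterations = 3,
                     n_c = 10, tol = 1e-3, criteria = success_criteria(),
                     params = contact_map_params(), restraints = NULL,
                     lambda_mode = "reciprocal", w_indexed = FALSE,
                     seed = 1L) {
  stopifnot(max_iterations >= 1)
  iterations <- list()
  trace <- numeric(0)
  prev <- NULL
  converged <- FALSE
  failure <- NULL
  for (it in seq_len(max_iterations)) {
    res <- tryCatch(
      scps_iteration(system, initial, ref, n_traj, config,
                     previous_path = prev, n_c = n_c,
                     criteria = criteria, params = params,
                     restraints = restraints, lambda_mode = lambda_mode,
                     w_indexed = w_indexed,
                     seed = seed + 10000L * (it - 1L)),
      error = function(e) e)
    if (inherits(res, "error")) {
      if (it == 1L) stop(res)
      failure <- conditionMessage(res)
      warning("iteration ", it, " produced no successful trajectories; ",
              "returning the history up to iteration ", it - 1L)
      break
    }
    delta <- if (is.null(prev)) NA_real_ else path_delta(prev, res$path)
    iterations[[it]] <- list(ensemble = res$ensemble, path = res$path,
                             delta = delta)
    trace <- c(trace, delta)
    prev <- res$path
    if (!is.na(delta) && delta < tol) { converged <- TRUE; break }
  }
  structure(list(iterations = iterations, trace = trace,
                 converged = converged, failure = failure, seed = seed),
            class = "scps_history")
}

#' @export
print.scps_history <- function(x, ...) {
  cat("<scps_history> ", length(x$iterations), " iterations, converged = ",
      x$converged, "\n", sep = "")
  for (i in seq_along(x$iterations)) {
    it <- x$iterations[[i]]
    cat(sprintf("  iter %d: %d/%d successes, delta = %s\n", i,
                sum(it$ensemble$success), length(it$ensemble$trajectories),
                ifelse(is.na(it$delta), "-", sprintf("%.3g", it$delta))))
  }
  invisible(x)
}

#' Mean squared distance between corresponding maps of two paths
#' @param a,b \code{mean_path} objects (compared over their common length).
#' @return mean over map index k of the squared contact-map distance.
#' @export
path_delta <- function(a, b) {
  k <- min(nrow(a$maps), nrow(b$maps))
  mean(vapply(seq_len(k), function(i)
    sum((a$maps[i, ] - b$maps[i, ])^2), numeric(1)))
}
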