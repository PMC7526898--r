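#' Structure-based C-alpha Go model
#'
#' Builds a coarse-grained force field from a reference (native) structure:
#' harmonic bonds and angles and a cosine dihedral term at their native values,
#' 12-10 Lennard-Jones attraction for native contact pairs (minimum at the
#' native distance, depth \code{eps}), and WCA repulsion between all other
#' nonbonded pairs.  Native contacts are the pairs with residue separation
#' \code{>= min_separation} whose native C-alpha distance is
#' \code{<= contact_cutoff}.  Because every nonnative eligible pair is farther
#' than the contact cutoff in the native state, the WCA cutoff (well below the
#' contact cutoff) makes the total force identically zero at the reference
#' configuration.
#'
#' @param reference n x 3 native C-alpha coordinates (Angstrom), n >= 4.
#' @param contact_cutoff native-contact distance criterion (Angstrom).
#' @param min_separation smallest \code{|i - j|} eligible as a native contact.
#' @param eps energy per native contact (reduced units; sets the energy scale).
#' @param contact_eps optional vector of per-contact well depths overriding
#'   \code{eps} (length = number of native contacts).
#' @param kb,ka bond / angle force constants.
#' @param kd1,kd3 dihedral force constants (1-fold and 3-fold terms).
#' @param eps_rep,wca_cutoff repulsion strength and its cutoff distance
#'   (force and energy exactly zero beyond the cutoff).
#' @param chains optional integer vector of chain ids per bead; bonded terms
#'   are only built within a chain.
#' @return a \code{go_model}; carries a warning flag if the native pair list
#'   is empty.
#' @export
build_go_model <- function(reference, contact_cutoff = 7.5, min_separation = 3L,
                           eps = 1, kb = 100, ka = 20, kd1 = 1, kd3 = 0.5,
                           eps_rep = 1, wca_cutoff = 4, chains = NULL,
                           contact_eps = NULL) {
  X <- as.matrix(reference)
  if (nrow(X) < 4) stop("a Go model needs at least 4 beads")
  stopifnot(contact_cutoff > 0, ncol(X) == 3)
  n <- nrow(X)
  if (is.null(chains)) chains <- rep(1L, n)
  stopifnot(length(chains) == n)

  same_chain <- function(i, j) chains[i] == chains[j]
  # bonded terms along each chain
  bi <- which(diff(chains) == 0 & TRUE)  # i, i+1 within chain
  bonds <- cbind(bi, bi + 1L)
  bonds <- bonds[chains[bonds[, 1]] == chains[bonds[, 2]], , drop = FALSE]
  bond_r0 <- sqrt(rowSums((X[bonds[, 1], , drop = FALSE] -
                           X[bonds[, 2], , drop = FALSE])^2))
  tri <- cbind(seq_len(n - 2), seq_len(n - 2) + 1L, seq_len(n - 2) + 2L)
  tri <- tri[chains[tri[, 1]] == chains[tri[, 3]], , drop = FALSE]
  ang_th0 <- apply(tri, 1, function(t3) bead_angle(X[t3[1], ], X[t3[2], ], X[t3[3], ]))
  quad <- cbind(seq_len(max(n - 3, 0)), seq_len(max(n - 3, 0)) + 1L,
                seq_len(max(n - 3, 0)) + 2L, seq_len(max(n - 3, 0)) + 3L)
  quad <- quad[chains[quad[, 1]] == chains[quad[, 4]], , drop = FALSE]
  dih_phi0 <- if (nrow(quad)) apply(quad, 1, function(q)
    bead_dihedral(X[q[1], ], X[q[2], ], X[q[3], ], X[q[4], ])) else numeric(0)

  # native contacts: |i-j| >= min_separation (or cross-chain), r <= cutoff
  pr <- t(utils::combn(n, 2))
  sep_ok <- (pr[, 2] - pr[, 1] >= min_separation) |
            (chains[pr[, 1]] != chains[pr[, 2]])
  d <- sqrt(rowSums((X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE])^2))
  native <- sep_ok & d <= contact_cutoff
  contacts <- pr[native, , drop = FALSE]
  con_sig <- d[native]
  no_contacts <- nrow(contacts) == 0
  if (no_contacts)
    warning("Go model has zero native contacts under the given cutoff")

  # repulsive pairs: all nonbonded, non-native pairs (|i-j| > 2 within chain)
  nonbonded <- (pr[, 2] - pr[, 1] > 2) | (chains[pr[, 1]] != chains[pr[, 2]])
  rep_pairs <- pr[nonbonded & !native, , drop = FALSE]

  if (is.null(contact_eps)) contact_eps <- rep(eps, nrow(contacts))
  stopifnot(length(contact_eps) == nrow(contacts))
  cpp <- list(kind = "beads", n = n,
              bonds = bonds - 1L, bond_r0 = bond_r0, kb = kb,
              angles = tri - 1L, ang_th0 = as.numeric(ang_th0), ka = ka,
              dihs = quad - 1L, dih_phi0 = as.numeric(dih_phi0),
              kd1 = kd1, kd3 = kd3,
              contacts = contacts - 1L, con_sig = con_sig,
              con_eps = as.numeric(contact_eps),
              repulsive = rep_pairs - 1L,
              eps_rep = eps_rep, sig_wca = wca_cutoff / 2^(1 / 6),
              has_container = FALSE)
  structure(list(kind = "beads", n = n, reference = X, chains = chains,
                 contact_cutoff = contact_cutoff,
                 min_separation = as.integer(min_separation),
                 native_pairs = contacts, native_distances = con_sig,
                 eps = eps, contact_eps = as.numeric(contact_eps),
                 no_contacts = no_contacts,
                 folding_temperature = 0.6 * eps, cpp = cpp),
            class = "go_model")
}

#' @export
print.go_model <- function(x, ...) {
  cat("<go_model> ", x$n, " beads, ", nrow(x$native_pairs),
      " native contacts (cutoff ", x$contact_cutoff, " A, |i-j| >= ",
      x$min_separation, ")\n", sep = "")
  invisible(x)
}

#' Potential energy and forces of a system
#'
#' @param system a \code{go_model} or \code{analytic_surface}.
#' @param X configuration: n x 3 matrix (Go model) or length-2 point (surface).
#' @return list with \code{energy} and \code{forces} (same shape as X).
#' @export
system_forces <- function(system, X) {
  X <- if (system$kind == "surface") matrix(as.numeric(X), nrow = 1)
       else as.matrix(X)
  cpp_system_forces(system$cpp, X)
}

#' Add a flat-bottom spherical container to a Go model
#'
#' Harmonic wall active only outside radius \code{radius} from \code{center};
#' keeps a released monomer from diffusing away during thermal denaturation and
#' recapture runs.
#'
#' @param model a \code{go_model}.
#' @param radius container radius (Angstrom).
#' @param center sphere center (defaults to the native centroid).
#' @param k wall force constant.
#' @return the modified \code{go_model}.
#' @export
with_container <- function(model, radius, center = colMeans(model$reference),
                           k = 5) {
  model$cpp$has_container <- TRUE
  model$cpp$container_center <- as.numeric(center)
  model$cpp$container_radius <- radius
  model$cpp$container_k <- k
  model
}

# internal geometry helpers
bead_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
}

bead_dihedral <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(pracma_cross(n1, n2) * b2) / sqrt(sum(b2^2))
  atan2(y, x)
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Fraction of native contacts Q
#'
#' Per-frame fraction of a model's native contacts whose instantaneous
#' C-alpha distance is within \code{factor} times the native distance
#' (standard folding progress variable).
#'
#' @param frames frame matrix (n_frames x 3n) or a single n x 3 configuration.
#' @param model a \code{go_model}.
#' @param pairs optional subset of native pairs (2-column, 1-based).
#' @param factor distance tolerance factor relative to the native distance.
#' @return numeric vector of Q in \[0, 1\], one per frame.
#' @export
q_fraction <- function(frames, model, pairs = NULL, factor = 1.2) {
  fr <- as_frame_matrix(frames)
  if (is.null(pairs)) {
    pairs <- model$native_pairs
    sig <- model$native_distances
  } else {
    key <- paste(model$native_pairs[, 1], model$native_pairs[, 2])
    idx <- match(paste(pairs[, 1], pairs[, 2]), key)
    if (anyNA(idx)) stop("pairs must be a subset of the model's native pairs")
    sig <- model$native_distances[idx]
  }
  if (nrow(pairs) == 0) return(rep(NA_real_, nrow(fr)))
  d <- cpp_pair_distances(fr, pairs[, 1] - 1L, pairs[, 2] - 1L)
  rowMeans(sweep(d, 2, factor * sig, "<="))
}

# internal: accept n x 3 configuration or frames matrix
as_frame_matrix <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 3) matrix(t(x), nrow = 1) else x
}
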