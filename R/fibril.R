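#' Synthetic two-rung beta-solenoid fibril fixture
#'
#' Idealized amyloid geometry: each subunit contributes two rectangular-
#' cross-section rungs (an N-terminal and a C-terminal winding) connected by a
#' short loop; subunits stack along the fibril axis with a fixed inter-rung spacing,
#' so template subunits are exact translated copies of each other.  One subunit
#' (by default the last, at the growing end) is designated the converting
#' monomer for templated-elongation experiments.
#'
#' @param n_subunits number of subunits (>= 2): template plus converting
#'   monomer.
#' @param residues_per_rung beads per rung (>= 4).
#' @param rise stacking distance between consecutive rungs (Angstrom).
#' @param bead_spacing arc spacing of beads along a rung (Angstrom).
#' @param n_loop beads in the connecting loop.
#' @param aspect aspect ratio of the rectangular rung cross-section; values
#'   away from 1 break the rotational symmetry of the cross-section.
#' @param converting which subunit is the converting monomer.
#' @param seed recorded for provenance; construction is deterministic.
#' @return a \code{fibril_fixture} with coordinates, per-residue rung labels,
#'   chain (subunit) ids and the converting-monomer index.
#' @export
build_toy_fibril <- function(n_subunits = 3, residues_per_rung = 5,
                             rise = 4.8, bead_spacing = 3.8, n_loop = 2,
                             aspect = 1.6, converting = n_subunits,
                             seed = 1L) {
  if (n_subunits < 2) stop("a fibril fixture needs at least 2 subunits")
  stopifnot(residues_per_rung >= 4, converting >= 1, converting <= n_subunits)
  rpr <- as.integer(residues_per_rung)

  # bead xy positions equally spaced along a rectangular perimeter; the
  # aspect ratio breaks the rotational symmetry of the cross-section so a
  # register-shifted docking of the monomer is penalized by the contact map
  perim <- rpr * bead_spacing
  b <- perim / (2 * (1 + aspect))
  a <- aspect * b
  sq_xy <- function(t) { # arc length t (mod perim) -> (x, y), centred at 0
    t <- t %% perim
    if (t < a)              c(-a / 2 + t, -b / 2)
    else if (t < a + b)     c(a / 2, -b / 2 + (t - a))
    else if (t < 2 * a + b) c(a / 2 - (t - a - b), b / 2)
    else                    c(-a / 2, b / 2 - (t - 2 * a - b))
  }
  rung_xy <- t(vapply((seq_len(rpr) - 1) * bead_spacing, sq_xy, numeric(2)))

  per_sub <- 2L * rpr + n_loop
  sub_coords <- function(level0) {
    z1 <- level0 * rise
    z2 <- (level0 + 1) * rise
    r1 <- cbind(rung_xy, z1)
    r2 <- cbind(rung_xy, z2)
    # loop bridges the last bead of rung 1 to the first bead of rung 2,
    # bulged radially outward to keep bond lengths reasonable
    a <- r1[rpr, ]; b <- r2[1, ]
    frac <- seq_len(n_loop) / (n_loop + 1)
    loop <- t(vapply(frac, function(f) {
      p <- a + f * (b - a)
      rad <- p[1:2]
      nr <- sqrt(sum(rad^2))
      p[1:2] <- rad * (nr + 2.5) / max(nr, 1e-9)
      p
    }, numeric(3)))
    rbind(r1, loop, r2)
  }
  coords <- do.call(rbind, lapply(seq_len(n_subunits) - 1L,
                                  function(s) sub_coords(2L * s)))
  rung <- rep(c(rep("N-rung", rpr), rep("loop", n_loop), rep("C-rung", rpr)),
              n_subunits)
  chains <- rep(seq_len(n_subunits), each = per_sub)
  resno <- rep(seq_len(per_sub), n_subunits)
  structure(list(coords = coords, n_subunits = as.integer(n_subunits),
                 residues_per_rung = rpr, per_subunit = per_sub,
                 rung = rung, chains = chains, resno = resno,
                 converting = as.integer(converting),
                 polarity = "N-to-C", rise = rise, seed = as.integer(seed)),
            class = "fibril_fixture")
}

#' @export
print.fibril_fixture <- function(x, ...) {
  cat("<fibril_fixture> ", x$n_subunits, " subunits x ", x$per_subunit,
      " residues (", x$residues_per_rung, "/rung), converting monomer: subunit ",
      x$converting, "\n", sep = "")
  invisible(x)
}

#' Bead indices of a fibril subunit
#' @param fixture a \code{fibril_fixture}.
#' @param subunit subunit number (1-based).
#' @return integer vector of global bead indices.
#' @export
subunit_indices <- function(fixture, subunit) {
  which(fixture$chains == subunit)
}

#' Go model of a fibril fixture
#'
#' Convenience wrapper: builds the structure-based model over all subunits
#' (bonded terms within chains only), applies contact-class-specific well
#' depths, and installs a flat-bottom container around the fibril so a
#' released monomer stays in the simulation region.
#'
#' The default class scaling emulates templated conversion: rung-stacking
#' interfaces within a monomer (\code{inter-rung}) are weak, so an isolated
#' monomer is only marginally structured, while the stacking interface onto
#' the fibril end (\code{monomer-fibril}) is strong; ordering of the incoming
#' monomer therefore requires the template scaffold, as in amyloid growth.
#'
#' @param fixture a \code{fibril_fixture}.
#' @param container_radius radius of the confining sphere (Angstrom).
#' @param eps_scale named multipliers of the contact well depth per contact
#'   class (see [classify_contacts()]); unnamed classes keep scale 1.
#' @param ... passed to [build_go_model()].
#' @return a \code{go_model}.
#' @export
fibril_go_model <- function(fixture, container_radius = NULL,
                            eps_scale = c("inter-rung" = 0.5,
                                          "monomer-fibril" = 1.5), ...) {
  m <- build_go_model(fixture$coords, chains = fixture$chains, ...)
  cls <- classify_contacts(m, fixture)
  scale <- rep(1, length(cls))
  for (nm in names(eps_scale)) scale[cls == nm] <- eps_scale[[nm]]
  m$contact_eps <- m$contact_eps * scale
  m$cpp$con_eps <- m$contact_eps
  m$contact_class <- cls
  if (is.null(container_radius)) {
    ext <- max(sqrt(rowSums(sweep(fixture$coords, 2,
                                  colMeans(fixture$coords))^2)))
    container_radius <- ext + 15
  }
  with_container(m, radius = container_radius)
}

#' Classify native contacts of a fibril model
#'
#' Labels each native contact pair as \code{intra-rung} (both residues in the
#' same rung of the same subunit), \code{inter-rung} (same subunit, different
#' rung or loop), \code{monomer-fibril} (between the converting monomer and a
#' template subunit) or \code{inter-subunit} (between two template subunits).
#'
#' @param model a \code{go_model} built on the fixture coordinates.
#' @param fixture the \code{fibril_fixture}.
#' @return character vector, one label per native contact pair.
#' @export
classify_contacts <- function(model, fixture) {
  p <- model$native_pairs
  ci <- fixture$chains[p[, 1]]; cj <- fixture$chains[p[, 2]]
  ri <- fixture$rung[p[, 1]];   rj <- fixture$rung[p[, 2]]
  lab <- ifelse(ci == cj & ri == rj & ri != "loop", "intra-rung",
         ifelse(ci == cj, "inter-rung",
         ifelse(ci == fixture$converting | cj == fixture$converting,
                "monomer-fibril", "inter-subunit")))
  lab
}

#' Toy beta-hairpin reference structure
#'
#' Small two-stranded C-alpha hairpin used as a desk-scale folding system:
#' two antiparallel zigzag strands joined by a turn, with cross-strand native
#' contacts inside the default 7.5 Angstrom cutoff.
#'
#' @param n_per_strand beads per strand.
#' @param strand_sep inter-strand distance (Angstrom).
#' @return n x 3 coordinate matrix.
#' @export
build_toy_hairpin <- function(n_per_strand = 7, strand_sep = 5) {
  m <- n_per_strand
  z <- 0.6 * (-1)^(seq_len(m))
  s1 <- cbind(0, (seq_len(m) - 1) * 3.4, z)
  s2 <- cbind(strand_sep, rev((seq_len(m) - 1) * 3.4), rev(z))
  turny <- (m - 1) * 3.4
  turn <- rbind(c(strand_sep * 0.15, turny + 2.8, 0.8),
                c(strand_sep * 0.85, turny + 2.8, -0.8))
  rbind(s1, turn, s2)
}

#' Per-trajectory rung incorporation statistics
#'
#' For every successful trajectory of a templated-elongation ensemble,
#' computes the reaction progress Q at which each rung of the converting
#' monomer incorporates into the fibril.  With the default \code{"rmsd"}
#' metric a rung incorporates at the first frame opening a run of more than
#' \code{persistence} consecutive frames in which the rung's RMSD to its
#' native position (after superposition on the template subunits) stays below
#' \code{rmsd_th}: incorporation means occupying the rung's position in the
#' fibril lattice, not merely collapsing its contacts.  The
#' \code{"contacts"} metric instead uses per-residue saturation of the
#' stack-defining contacts ([rung_stack_pairs()]), medianized over the rung's
#' residues.  Q is the fraction of native contacts involving the monomer.
#'
#' @param ensemble an \code{scps_ensemble} over the fibril system.
#' @param model the fibril \code{go_model}.
#' @param fixture the \code{fibril_fixture}.
#' @param metric "rmsd" (positional, default) or "contacts".
#' @param rmsd_th rung RMSD threshold (Angstrom) for the positional metric.
#' @param threshold,factor contact-saturation parameters for the
#'   \code{"contacts"} metric (see [incorporation_order()]).
#' @param persistence minimum run length (saved frames).
#' @return data frame with one row per successful trajectory: the event frames
#'   and reaction progress \code{q_anchored} (template-proximal rung) /
#'   \code{q_distal}, and \code{anchored_first} (decided on event frames).
#' @export
rung_incorporation <- function(ensemble, model, fixture,
                               metric = c("rmsd", "contacts"),
                               rmsd_th = 3, threshold = 0.7,
                               persistence = 5L, factor = 1.2) {
  metric <- match.arg(metric)
  mono <- subunit_indices(fixture, fixture$converting)
  template <- which(fixture$chains != fixture$converting)
  anchored_lab <- if (fixture$converting > 1) "N-rung" else "C-rung"
  distal_lab <- setdiff(c("N-rung", "C-rung"), anchored_lab)
  nr <- mono[fixture$rung[mono] == anchored_lab]
  cr <- mono[fixture$rung[mono] == distal_lab]
  pairs <- model$native_pairs
  sp <- rung_stack_pairs(model, fixture)
  mono_pairs <- pairs[pairs[, 1] %in% mono | pairs[, 2] %in% mono, ,
                      drop = FALSE]
  first_persistent <- function(ok) {
    rl <- rle(ok)
    st <- cumsum(c(1L, head(rl$lengths, -1L)))
    hit <- which(rl$values & rl$lengths > persistence)
    if (length(hit)) st[hit[1]] else NA_integer_
  }
  ok <- which(ensemble$success)
  rows <- lapply(ok, function(i) {
    tr <- ensemble$trajectories[[i]]
    qtr <- q_fraction(tr$frames, model, pairs = mono_pairs)
    if (metric == "rmsd") {
      frung <- function(res_set) {
        rms <- as.numeric(cpp_rmsd_frames(tr$frames, model$reference,
                                          template - 1L, res_set - 1L))
        first_persistent(rms < rmsd_th)
      }
    } else {
      d <- cpp_pair_distances(tr$frames, pairs[, 1] - 1L, pairs[, 2] - 1L)
      formed <- sweep(d, 2, factor * model$native_distances, "<=")
      frung <- function(res_set) {
        v <- vapply(res_set, function(r) {
          frac <- rowMeans(formed[, sp[[r]], drop = FALSE])
          as.numeric(first_persistent(frac >= threshold))
        }, numeric(1))
        as.integer(round(median(v, na.rm = TRUE)))
      }
    }
    fa <- frung(nr); fd <- frung(cr)
    # order decided on event frames; Q reported at those frames
    data.frame(trajectory = i,
               frame_anchored = fa, frame_distal = fd,
               q_anchored = if (is.na(fa)) NA_real_ else qtr[fa],
               q_distal = if (is.na(fd)) NA_real_ else qtr[fd],
               anchored_first = !is.na(fa) && !is.na(fd) && fa < fd)
  })
  do.call(rbind, rows)
}

#' Rung RMSD samples for landscape histograms
#'
#' Per-frame RMSD of the converting monomer's two rungs to the target state,
#' after superposition on the template subunits (the converting monomer is
#' excluded from the alignment), pooled over the successful trajectories.
#'
#' @param ensemble an \code{scps_ensemble} over the fibril system.
#' @param fixture the \code{fibril_fixture}.
#' @param ref the target [reference_structure()].
#' @return matrix with columns \code{anchored}, \code{distal}, one row per
#'   pooled frame.
#' @export
rung_rmsd_samples <- function(ensemble, fixture, ref) {
  template <- which(fixture$chains != fixture$converting)
  mono <- subunit_indices(fixture, fixture$converting)
  anchored_lab <- if (fixture$converting > 1) "N-rung" else "C-rung"
  nr <- mono[fixture$rung[mono] == anchored_lab]
  cr <- mono[fixture$rung[mono] != anchored_lab &
             fixture$rung[mono] != "loop"]
  refX <- if (inherits(ref, "reference_structure")) ref$coords else ref
  out <- lapply(which(ensemble$success), function(i) {
    fr <- ensemble$trajectories[[i]]$frames
    cbind(anchored = as.numeric(cpp_rmsd_frames(fr, refX, template - 1L,
                                                nr - 1L)),
          distal = as.numeric(cpp_rmsd_frames(fr, refX, template - 1L,
                                              cr - 1L)))
  })
  do.call(rbind, out)
}
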