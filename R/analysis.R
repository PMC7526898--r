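#' Contact formation times along a trajectory
#'
#' A native contact counts as formed at the first frame opening a run of at
#' least \code{persistence} consecutive frames in which the bead-bead distance
#' is at or below \code{threshold}.  Contacts that never satisfy the rule get
#' NA.
#'
#' @param traj an \code{scps_trajectory} (bead system) or a frames x contacts
#'   distance matrix.
#' @param pairs native-contact pairs (2-column, 1-based); ignored when a
#'   distance matrix is supplied.
#' @param persistence minimum run length in frames (>= 1).
#' @param threshold distance criterion (Angstrom).
#' @return integer vector of formation frames (1-based), NA if never formed.
#' @export
contact_formation_times <- function(traj, pairs = NULL, persistence = 5L,
                                    threshold = 7.5) {
  stopifnot(persistence >= 1)
  d <- if (inherits(traj, "scps_trajectory")) {
    stopifnot(!is.null(pairs))
    cpp_pair_distances(traj$frames, pairs[, 1] - 1L, pairs[, 2] - 1L)
  } else as.matrix(traj)
  nf <- nrow(d)
  if (nf < persistence) {
    warning("trajectory shorter than the persistence window: no contact forms")
    return(rep(NA_integer_, ncol(d)))
  }
  apply(d <= threshold, 2, function(ok) {
    r <- rle(ok)
    starts <- cumsum(c(1L, head(r$lengths, -1L)))
    hit <- which(r$values & r$lengths >= persistence)
    if (length(hit)) starts[hit[1]] else NA_integer_
  })
}

#' Pairwise contact-formation order matrix
#'
#' Encodes, for every pair of native contacts (i < j), whether contact i
#' formed before (1), after (0) or at the same frame (1/2) as contact j.
#' Pairs involving a never-formed contact are marked non-evaluable.
#'
#' @param times formation-time vector from [contact_formation_times()].
#' @return an \code{order_matrix}: upper-triangular value matrix, the times,
#'   and the evaluable mask.
#' @export
order_matrix <- function(times) {
  n <- length(times)
  M <- matrix(NA_real_, n, n)
  ok <- !is.na(times)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ok[i] && ok[j])
        M[i, j] <- if (times[i] < times[j]) 1
                   else if (times[i] > times[j]) 0 else 0.5
    }
  }
  structure(list(M = M, times = times, formed = ok, n = n),
            class = "order_matrix")
}

#' Path similarity from contact-formation order
#'
#' \deqn{s(k,k') = \frac{2}{N(N-1)} \sum_{i<j} \delta[M_{ij}(k)-M_{ij}(k')]}
#' the fraction of ordered contact pairs on which the two trajectories agree
#' exactly (ties agree only with ties).  Pairs where either contact never
#' formed in either trajectory are excluded and the normalization is the count
#' of evaluable pairs.
#'
#' @param a,b \code{order_matrix} objects over the same contact universe.
#' @return similarity in \[0, 1\]; 1 for identical formation order, 0 for
#'   completely reversed order.
#' @export
path_similarity <- function(a, b) {
  stopifnot(inherits(a, "order_matrix"), inherits(b, "order_matrix"))
  if (a$n != b$n) stop("order matrices over different contact sets")
  ut <- upper.tri(a$M)
  va <- a$M[ut]; vb <- b$M[ut]
  ev <- !is.na(va) & !is.na(vb)
  if (!any(ev)) return(NA_real_)
  mean(va[ev] == vb[ev])
}

#' Self-, cross- and random-similarity distributions
#'
#' \code{A}: similarity over all unordered pairs of reference trajectories
#' (self-pairs excluded).  \code{R}: all reference x query pairs (identical
#' pairs excluded when the ensembles coincide).  \code{R_r}: reference
#' trajectories against random order matrices whose formation times are i.i.d.
#' uniform (ties have probability zero).
#'
#' @param reference list of \code{order_matrix} objects (>= 2 for A).
#' @param query optional list of \code{order_matrix} objects.
#' @param n_random number of random matrices per reference replicate.
#' @param n_random_sets how many random reference distributions to draw.
#' @param seed RNG seed for the random matrices.
#' @return list with samples \code{A}, \code{R} (NULL if no query) and a list
#'   \code{R_r} of random cross-similarity sample vectors.
#' @export
similarity_distributions <- function(reference, query = NULL,
                                     n_random = length(reference),
                                     n_random_sets = 20, seed = 1L) {
  stopifnot(length(reference) >= 1)
  nref <- length(reference)
  A <- if (nref >= 2) unlist(lapply(seq_len(nref - 1), function(i)
    vapply((i + 1):nref, function(j)
      path_similarity(reference[[i]], reference[[j]]), numeric(1))))
  else NULL
  R <- NULL
  if (!is.null(query)) {
    same <- identical(reference, query)
    R <- unlist(lapply(seq_along(reference), function(i)
      vapply(seq_along(query), function(j) {
        if (same && i == j) return(NA_real_)
        path_similarity(reference[[i]], query[[j]])
      }, numeric(1))))
    R <- R[!is.na(R)]
  }
  set.seed(seed)
  n_contacts <- reference[[1]]$n
  R_r <- lapply(seq_len(n_random_sets), function(s) {
    rand <- lapply(seq_len(n_random), function(k)
      order_matrix(runif(n_contacts)))
    as.numeric(unlist(lapply(reference, function(ref)
      vapply(rand, function(rm) path_similarity(ref, rm), numeric(1)))))
  })
  list(A = as.numeric(A), R = R, R_r = R_r)
}

#' Kullback-Leibler divergence between similarity distributions (bits)
#'
#' Discrete estimate of \eqn{\int_0^1 a(x)\log_2[a(x)/r(x)]\,dx} from shared
#' equal-width histograms on \[0, 1\], with an additive pseudo-mass per bin
#' protecting against empty-bin divergences.
#'
#' @param a,b sample vectors in \[0, 1\], or (with \code{masses = TRUE})
#'   already-normalized histogram masses on shared bins.
#' @param n_bins number of equal bins on \[0, 1\].
#' @param pseudocount counts added to every bin before normalization.
#' @param masses treat \code{a}, \code{b} as histogram masses directly.
#' @return divergence in bits (>= 0 up to regularization effects).
#' @export
kl_divergence <- function(a, b, n_bins = 20, pseudocount = 0.5,
                          masses = FALSE) {
  if (masses) {
    p <- a / sum(a); q <- b / sum(b)
  } else {
    if (!length(a) || !length(b)) stop("empty distribution")
    br <- seq(0, 1, length.out = n_bins + 1)
    cut_ab <- function(x) {
      h <- tabulate(findInterval(pmin(pmax(x, 0), 1), br,
                                 rightmost.closed = TRUE), nbins = n_bins)
      h + pseudocount
    }
    p <- cut_ab(a); q <- cut_ab(b)
    p <- p / sum(p); q <- q / sum(q)
  }
  keep <- p > 0
  sum(p[keep] * log2(p[keep] / q[keep]))
}

#' Reactive segments of a Q trace
#'
#' Maximal frame intervals starting at the last frame with Q < \code{low}
#' before the first subsequent frame with Q > \code{high} (folding events);
#' unfolding events are detected on the reversed trace and returned
#' time-reversed when requested.
#'
#' @param q per-frame fraction of native contacts.
#' @param low,high thresholds defining the reactive window.
#' @param unfolding also detect and return time-reversed unfolding events.
#' @return list of integer vectors \code{c(start, end)} (1-based frames) with
#'   attribute \code{direction}.
#' @export
reactive_segments <- function(q, low = 0.1, high = 0.9, unfolding = FALSE) {
  scan <- function(tr) {
    out <- list()
    last_low <- NA_integer_
    for (f in seq_along(tr)) {
      if (tr[f] < low) last_low <- f
      else if (tr[f] > high && !is.na(last_low)) {
        out[[length(out) + 1]] <- c(start = last_low, end = f)
        last_low <- NA_integer_
      }
    }
    out
  }
  segs <- lapply(scan(q), `attr<-`, "direction", "folding")
  if (unfolding) {
    n <- length(q)
    rsegs <- lapply(scan(rev(q)), function(s) {
      v <- c(start = n - s[["end"]] + 1L, end = n - s[["start"]] + 1L)
      attr(v, "direction") <- "unfolding"
      v
    })
    segs <- c(segs, rsegs)
  }
  segs
}

#' Two-dimensional landscape histogram and -ln P
#'
#' Normalized frequency histogram of a coordinate pair (e.g. the RMSDs of the
#' two rungs of a converting monomer, or two principal components) and
#' G = -ln P on the occupied bins.  This is a projection of path density, not
#' an equilibrium free energy: biased reactive trajectories are intrinsically
#' out of equilibrium.
#'
#' @param samples n x 2 matrix of coordinate pairs.
#' @param bins number of bins per axis, or list of two break vectors.
#' @return a \code{landscape_histogram}: bin edges, probability masses P
#'   (summing to 1) and G (NA on empty bins).
#' @export
landscape_histogram <- function(samples, bins = 30) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) >= 1, ncol(samples) == 2)
  if (is.list(bins)) {
    bx <- bins[[1]]; by <- bins[[2]]
  } else {
    pad <- function(v) {
      r <- range(v); if (diff(r) == 0) r <- r + c(-0.5, 0.5)
      seq(r[1], r[2], length.out = bins + 1)
    }
    bx <- pad(samples[, 1]); by <- pad(samples[, 2])
  }
  ix <- findInterval(samples[, 1], bx, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(samples[, 2], by, rightmost.closed = TRUE, all.inside = TRUE)
  P <- matrix(0, length(bx) - 1, length(by) - 1)
  for (k in seq_len(nrow(samples))) P[ix[k], iy[k]] <- P[ix[k], iy[k]] + 1
  P <- P / sum(P)
  G <- ifelse(P > 0, -log(P), NA_real_)
  structure(list(x_breaks = bx, y_breaks = by, P = P, G = G,
                 n = nrow(samples)),
            class = "landscape_histogram")
}

#' @export
print.landscape_histogram <- function(x, ...) {
  cat("<landscape_histogram> ", nrow(x$P), "x", ncol(x$P), " bins, ",
      sum(x$P > 0), " occupied, n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' @export
plot.landscape_histogram <- function(x, ...) {
  mx <- (head(x$x_breaks, -1) + tail(x$x_breaks, -1)) / 2
  my <- (head(x$y_breaks, -1) + tail(x$y_breaks, -1)) / 2
  graphics::image(mx, my, x$G, xlab = "coordinate 1", ylab = "coordinate 2",
                  main = "-ln P", ...)
  invisible(x)
}

#' Per-residue incorporation order versus reaction progress Q
#'
#' A residue is "structured" in a frame when at least \code{threshold} of its
#' native contacts are formed (distance within \code{factor} times native); it
#' incorporates at the first frame opening a run of more than
#' \code{persistence} consecutive structured frames, and that frame is mapped
#' to the trajectory's Q.  Medians and quartiles are taken across the
#' successful trajectories of the ensemble; residues that never stabilize in a
#' trajectory are flagged and excluded from that trajectory's statistics.
#'
#' @param ensemble an \code{scps_ensemble} over a bead system.
#' @param model the \code{go_model} (supplies native contacts and Q).
#' @param residues residue (bead) indices to report (default: all with native
#'   contacts).
#' @param grouping optional named labels per residue (e.g. rung assignment),
#'   returned alongside.
#' @param threshold fraction of a residue's native contacts required.
#' @param persistence run length in frames.
#' @param factor distance tolerance factor for a formed contact.
#' @param q_pairs optional native-pair subset used for the Q trace.
#' @param pair_subset optional list, indexed by residue, of native-pair row
#'   indices defining that residue's "structured" criterion (e.g. only the
#'   contacts to the strand it stacks on, the beta-strand surrogate for
#'   solenoids from [rung_stack_pairs()]); default: all pairs touching the
#'   residue.
#' @return data frame: residue, group, n_observed, median_q, q25, q75.
#' @export
incorporation_order <- function(ensemble, model, residues = NULL,
                                grouping = NULL, threshold = 0.7,
                                persistence = 5L, factor = 1.2,
                                q_pairs = NULL, pair_subset = NULL) {
  pairs <- model$native_pairs
  touched <- sort(unique(c(pairs)))
  if (is.null(residues)) residues <- touched
  skipped <- setdiff(residues, touched)
  if (length(skipped))
    warning("residues with zero native contacts excluded: ",
            paste(skipped, collapse = ", "))
  residues <- intersect(residues, touched)
  ok <- which(ensemble$success)
  per_traj <- lapply(ok, function(i) {
    tr <- ensemble$trajectories[[i]]
    d <- cpp_pair_distances(tr$frames, pairs[, 1] - 1L, pairs[, 2] - 1L)
    formed <- sweep(d, 2, factor * model$native_distances, "<=")
    qtr <- q_fraction(tr$frames, model, pairs = q_pairs)
    vapply(residues, function(res) {
      sel <- if (!is.null(pair_subset) && !is.null(pair_subset[[res]]))
        pair_subset[[res]] else which(pairs[, 1] == res | pairs[, 2] == res)
      frac <- rowMeans(formed[, sel, drop = FALSE])
      ok2 <- frac >= threshold
      r <- rle(ok2)
      starts <- cumsum(c(1L, head(r$lengths, -1L)))
      hit <- which(r$values & r$lengths > persistence)
      if (length(hit)) qtr[starts[hit[1]]] else NA_real_
    }, numeric(1))
  })
  qmat <- do.call(rbind, per_traj)     # trajectories x residues
  data.frame(residue = residues,
             group = if (is.null(grouping)) NA_character_
                     else as.character(grouping[residues]),
             n_observed = colSums(!is.na(qmat)),
             median_q = apply(qmat, 2, median, na.rm = TRUE),
             q25 = apply(qmat, 2, quantile, probs = 0.25, na.rm = TRUE),
             q75 = apply(qmat, 2, quantile, probs = 0.75, na.rm = TRUE),
             row.names = NULL)
}

#' PCA of contact maps over a trajectory ensemble
#'
#' Centered principal component analysis of the contact-map features of the
#' successful trajectories (each trajectory downsampled to at most
#' \code{downsample} frames), with per-contact-set contributions of each
#' component computed as normalized sums of squared loadings.
#'
#' @param ensemble an \code{scps_ensemble} over a bead system.
#' @param pairs contact pairs defining the feature space (2-column, 1-based).
#' @param set_labels optional character vector, one label per pair (e.g.
#'   intra-rung / inter-rung / monomer-fibril from [classify_contacts()]).
#' @param params contact-map parameters.
#' @param downsample frames kept per trajectory.
#' @param n_components components to report.
#' @return a \code{cm_pca}: loadings, per-frame projections, explained
#'   variance fractions and per-set contribution fractions.
#' @export
pca_contact_maps <- function(ensemble, pairs, set_labels = NULL,
                             params = contact_map_params(),
                             downsample = 300L, n_components = 2L) {
  ok <- which(ensemble$success)
  if (!length(ok)) stop("no successful trajectories")
  feats <- lapply(ok, function(i) {
    tr <- ensemble$trajectories[[i]]
    f <- cpp_contact_frames(tr$frames, pairs[, 1] - 1L, pairs[, 2] - 1L,
                            params$r0, params$rc)
    if (nrow(f) > downsample)
      f <- f[round(seq(1, nrow(f), length.out = downsample)), , drop = FALSE]
    f
  })
  Xf <- do.call(rbind, feats)
  traj_id <- rep(ok, vapply(feats, nrow, integer(1)))
  if (nrow(Xf) < 2) stop("need at least 2 frames after downsampling")
  keep <- apply(Xf, 2, function(v) stats::var(v) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant contact feature(s) dropped")
    Xf <- Xf[, keep, drop = FALSE]
    pairs <- pairs[keep, , drop = FALSE]
    if (!is.null(set_labels)) set_labels <- set_labels[keep]
  }
  pc <- prcomp(Xf, center = TRUE, scale. = FALSE)
  nc <- min(n_components, ncol(pc$rotation))
  evar <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- NULL
  if (!is.null(set_labels)) {
    labs_f <- factor(set_labels)
    contrib <- vapply(seq_len(nc), function(k) {
      w <- pc$rotation[, k]^2
      as.numeric(tapply(w, labs_f, sum, default = 0)) / sum(w)
    }, numeric(nlevels(labs_f)))
    contrib <- matrix(contrib, nrow = nlevels(labs_f),
                      dimnames = list(levels(labs_f),
                                      paste0("PC", seq_len(nc))))
  }
  structure(list(loadings = pc$rotation[, seq_len(nc), drop = FALSE],
                 projections = pc$x[, seq_len(nc), drop = FALSE],
                 traj_id = traj_id,
                 explained_variance = evar[seq_len(nc)],
                 set_contributions = contrib,
                 pairs = pairs, set_labels = set_labels),
            class = "cm_pca")
}

#' @export
print.cm_pca <- function(x, ...) {
  cat("<cm_pca> ", nrow(x$projections), " frames x ", nrow(x$loadings),
      " contact features\n  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$set_contributions)) {
    cat("  set contributions (PC1):\n")
    for (s in rownames(x$set_contributions))
      cat(sprintf("    %-14s %.2f\n", s, x$set_contributions[s, 1]))
  }
  invisible(x)
}

#' Stack-defining native contacts per fibril residue
#'
#' The beta-strand surrogate for solenoid rungs: a rung residue counts as
#' structured through its intra-rung contacts plus its contacts to the rung it
#' stacks on (one level towards the fibril), mirroring a backbone-level
#' secondary-structure call in which a strand is formed when paired with the
#' strand beneath.  Loop residues keep all their native contacts.
#'
#' @param model a \code{go_model} from [fibril_go_model()].
#' @param fixture the \code{fibril_fixture}.
#' @return list indexed by residue: native-pair row indices.
#' @export
rung_stack_pairs <- function(model, fixture) {
  pairs <- model$native_pairs
  out <- vector("list", model$n)
  for (r in seq_len(model$n)) {
    touch <- which(pairs[, 1] == r | pairs[, 2] == r)
    if (!length(touch)) next
    rung_r <- fixture$rung[r]
    if (rung_r == "loop") { out[[r]] <- touch; next }
    ch <- fixture$chains[r]
    partner <- ifelse(pairs[touch, 1] == r, pairs[touch, 2], pairs[touch, 1])
    same_rung <- fixture$chains[partner] == ch & fixture$rung[partner] == rung_r
    below <- if (rung_r == "N-rung")
      fixture$chains[partner] == ch - 1L   # stacks on the subunit below
    else
      fixture$chains[partner] == ch & fixture$rung[partner] == "N-rung"
    keep <- touch[same_rung | below]
    out[[r]] <- if (length(keep)) keep else touch
  }
  out
}
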