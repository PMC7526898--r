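#' Contact-map parameters
#'
#' Parameters of the smoothed contact function
#' \deqn{C_{ij} = \frac{1-(r_{ij}/r_0)^6}{1-(r_{ij}/r_0)^{10}}}
#' with a hard cutoff \code{r_c} beyond which entries are exactly zero, and a
#' minimum residue-index separation excluding trivially formed bonded contacts.
#' The removable singularity at \code{r = r_0} is evaluated by its limit, 3/5.
#'
#' @param r0 reference distance in Angstrom; a pair at this distance scores 3/5.
#' @param rc hard cutoff in Angstrom; entries are exactly 0 beyond it.
#' @param min_separation smallest \code{|i - j|} included in contact sums.
#' @return an object of class \code{cm_params}.
#' @export
contact_map_params <- function(r0 = 7.5, rc = 12, min_separation = 3L) {
  stopifnot(r0 > 0, rc > r0, min_separation >= 1)
  structure(list(r0 = r0, rc = rc, min_separation = as.integer(min_separation)),
            class = "cm_params")
}

#' Eligible residue pairs for contact-map sums
#'
#' @param n number of beads.
#' @param params a [contact_map_params()] object.
#' @return two-column integer matrix of 1-based pairs with \code{i < j} and
#'   \code{j - i >= min_separation}.
#' @export
eligible_pairs <- function(n, params = contact_map_params()) {
  idx <- which(outer(seq_len(n), seq_len(n),
                     function(i, j) j - i >= params$min_separation),
               arr.ind = TRUE)
  m <- cbind(i = idx[, 1], j = idx[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Smoothed contact map of a configuration
#'
#' @param X n x 3 coordinate matrix (Angstrom).
#' @param params a [contact_map_params()] object.
#' @param pairs optional pair matrix (defaults to [eligible_pairs()]).
#' @return a \code{contact_map}: continuous entries in \[0, 1\] over the
#'   eligible pairs.
#' @export
contact_map <- function(X, params = contact_map_params(), pairs = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), ncol(X) == 3, all(is.finite(X)))
  if (is.null(pairs)) pairs <- eligible_pairs(nrow(X), params)
  d <- sqrt(rowSums((X[pairs[, 1], , drop = FALSE] -
                     X[pairs[, 2], , drop = FALSE])^2))
  if (any(d == 0))
    warning("coincident beads: contact entries set to the limit value 1")
  v <- cpp_contact_values(X, pairs[, 1] - 1L, pairs[, 2] - 1L,
                          params$r0, params$rc)
  structure(list(values = as.numeric(v), pairs = pairs, params = params,
                 n = nrow(X)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$n, " beads, ", nrow(x$pairs), " eligible pairs, ",
      sum(x$values > 0.5), " entries > 0.5\n", sep = "")
  invisible(x)
}

#' Squared contact-map distance
#'
#' The squared norm \eqn{\sum_{ij} (a_{ij} - b_{ij})^2} used both as the CV
#' \code{z} and as the metric entering the path CVs.
#'
#' @param a,b \code{contact_map} objects or plain numeric feature vectors.
#' @return non-negative scalar; zero iff the maps are identical.
#' @export
cm_distance <- function(a, b) {
  av <- if (inherits(a, "contact_map")) a$values else as.numeric(a)
  bv <- if (inherits(b, "contact_map")) b$values else as.numeric(b)
  if (inherits(a, "contact_map") && inherits(b, "contact_map") &&
      !identical(a$pairs, b$pairs))
    stop("contact maps have different eligible-pair lists")
  if (length(av) != length(bv)) stop("feature vectors of different length")
  sum((av - bv)^2)
}

#' Reference structure with its precomputed contact map
#'
#' @param X n x 3 coordinates of the target-state structure (Angstrom).
#' @param params a [contact_map_params()] object.
#' @return a \code{reference_structure} holding the coordinates and the target
#'   contact map used by [z_of()] and the rMD bias.
#' @export
reference_structure <- function(X, params = contact_map_params()) {
  X <- as.matrix(X)
  structure(list(coords = X, map = contact_map(X, params), params = params),
            class = "reference_structure")
}

#' @export
print.reference_structure <- function(x, ...) {
  cat("<reference_structure> ", nrow(x$coords), " beads\n", sep = "")
  invisible(x)
}

# internal: CV spec list consumed by the C++ engine
cv_spec_rmd <- function(ref) {
  if (inherits(ref, "reference_structure")) {
    m <- ref$map
    list(is_surface = FALSE,
         pi = m$pairs[, 1] - 1L, pj = m$pairs[, 2] - 1L,
         r0 = m$params$r0, rc = m$params$rc, cref = m$values, path = NULL)
  } else { # numeric target point on an analytic surface
    list(is_surface = TRUE, cref = as.numeric(ref), path = NULL)
  }
}

cv_spec_scps <- function(path) {
  stopifnot(inherits(path, "mean_path"))
  if (is.null(path$lambda)) stop("mean path has no lambda; call set_lambda()")
  if (path$system_kind == "surface") {
    list(is_surface = TRUE, path = path$maps, lambda = path$lambda,
         w_indexed = isTRUE(path$w_indexed), cref = NULL)
  } else {
    list(is_surface = FALSE,
         pi = path$pairs[, 1] - 1L, pj = path$pairs[, 2] - 1L,
         r0 = path$params$r0, rc = path$params$rc,
         path = path$maps, lambda = path$lambda,
         w_indexed = isTRUE(path$w_indexed), cref = NULL)
  }
}

#' Contact-map overlap CV z(X) with analytic gradient
#'
#' \eqn{z(X) = \sum_{ij} [C_{ij}(X) - C_{ij}(X_{Ref})]^2} over eligible pairs.
#' Decreases towards 0 as the configuration approaches the target's contact
#' pattern.
#'
#' @param X n x 3 coordinates.
#' @param ref a [reference_structure()] with matching bead count.
#' @return list with \code{value} (scalar >= 0) and \code{gradient} (n x 3).
#' @export
z_of <- function(X, ref) {
  X <- as.matrix(X)
  stopifnot(inherits(ref, "reference_structure"))
  if (nrow(X) != nrow(ref$coords))
    stop("bead count of X does not match the reference structure")
  cpp_z_grad(X, cv_spec_rmd(ref))
}

#' Path progress CV s_lambda with analytic gradient
#'
#' Softmax-weighted mean-path index, rescaled so that (in the large-lambda
#' limit) the first mean-path map evaluates to 1 (unfolded end) and the last
#' to 0 (target end).
#'
#' @param X n x 3 coordinates, or a \code{contact_map} / numeric feature vector
#'   (map-space evaluation, no gradient).
#' @param path a mean path with lambda set (see [set_lambda()]).
#' @param lambda optional override of \code{path$lambda}.
#' @return coordinates in: list(value, gradient); map in: scalar value.
#' @export
s_lambda <- function(X, path, lambda = NULL) {
  pc <- path_cvs(X, path, lambda)
  if (is.list(pc)) list(value = pc$s, gradient = pc$grad_s) else pc[["s"]]
}

#' Off-path distance CV w_lambda with analytic gradient
#'
#' \eqn{w_\lambda = \frac{1}{\lambda}\ln\sum_k e^{-\lambda\|C(X)-\langle C\rangle_k\|^2}},
#' evaluated in log-sum-exp form; in the large-lambda limit \eqn{-w_\lambda}
#' converges to the smallest contact-map distance from the mean path.
#'
#' @inheritParams s_lambda
#' @return coordinates in: list(value, gradient); map in: scalar value.
#' @export
w_lambda <- function(X, path, lambda = NULL) {
  pc <- path_cvs(X, path, lambda)
  if (is.list(pc)) list(value = pc$w, gradient = pc$grad_w) else pc[["w"]]
}

# internal: both path CVs at once
path_cvs <- function(X, path, lambda = NULL) {
  stopifnot(inherits(path, "mean_path"))
  if (!is.null(lambda)) { path$lambda <- lambda }
  if (is.null(path$lambda)) stop("mean path has no lambda; call set_lambda()")
  if (nrow(path$maps) < 2) stop("a mean path needs at least 2 maps")
  if (is.matrix(X) && !inherits(X, "contact_map") &&
      path$system_kind != "surface" && ncol(X) == 3) {
    return(cpp_path_cvs(as.matrix(X), cv_spec_scps(path)))
  }
  if (path$system_kind == "surface" && is.numeric(X) && !inherits(X, "contact_map")) {
    Xm <- matrix(as.numeric(X), nrow = 1)
    return(cpp_path_cvs(Xm, cv_spec_scps(path)))
  }
  # map-space evaluation
  f <- if (inherits(X, "contact_map")) X$values else as.numeric(X)
  if (length(f) != ncol(path$maps)) stop("feature vector does not match path")
  d <- colSums((t(path$maps) - f)^2)
  lam <- path$lambda
  q <- exp(-lam * (d - min(d)))
  NC <- length(d)
  k <- seq_len(NC) - 1
  m <- sum(k * q) / sum(q)
  s <- 1 - m / (NC - 1)
  w <- if (isTRUE(path$w_indexed)) log(sum((k + 1) * q)) / lam - min(d)
       else log(sum(q)) / lam - min(d)
  c(s = s, w = w, d = -w)
}

#' Set the path-CV smoothing parameter lambda from a mean path
#'
#' Default convention: the reciprocal of the mean squared-norm distance between
#' neighboring mean-path maps (so that \eqn{\lambda \|\cdot\|^2} is
#' dimensionless); the literal reading (lambda equal to the mean neighbor
#' distance itself) is selectable.
#'
#' @param path a mean path (see [compute_mean_path()]).
#' @param mode "reciprocal" (default) or "literal".
#' @param eps floor for the mean neighbor distance of degenerate paths.
#' @return the path with \code{lambda} (and \code{lambda_mode}) set.
#' @export
set_lambda <- function(path, mode = c("reciprocal", "literal"), eps = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(inherits(path, "mean_path"), nrow(path$maps) >= 2)
  nd <- neighbor_distances(path)
  mu <- mean(nd)
  if (mu < eps) {
    warning("degenerate mean path: neighbor distances ~ 0; lambda floored")
    mu <- eps
  }
  path$lambda <- if (mode == "reciprocal") 1 / mu else mu
  path$lambda_mode <- mode
  path
}

# internal
neighbor_distances <- function(path) {
  NC <- nrow(path$maps)
  vapply(seq_len(NC - 1), function(k)
    sum((path$maps[k, ] - path$maps[k + 1, ])^2), numeric(1))
}
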