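#' Mueller-Brown benchmark surface
#'
#' The standard four-Gaussian 2-D test potential
#' \deqn{V(x,y)=\sum_{t=1}^4 A_t \exp[a_t(x-x_t)^2+b_t(x-x_t)(y-y_t)+c_t(y-y_t)^2]}
#' with its three minima located by local refinement.  The deepest minimum is
#' labeled \code{reactant}, the minimum in the opposite basin \code{product};
#' the shallow middle minimum is \code{intermediate}.
#'
#' @return an \code{analytic_surface} with \code{potential(x)} and
#'   \code{gradient(x)} functions and named, refined minima.
#' @export
build_mueller_brown <- function() {
  terms <- cbind(A  = c(-200, -100, -170, 15),
                 a  = c(-1, -1, -6.5, 0.7),
                 b  = c(0, 0, 11, 0.6),
                 c  = c(-10, -10, -6.5, 0.7),
                 x0 = c(1, 0, -0.5, -1),
                 y0 = c(0, 0.5, 1.5, 1))
  surf <- analytic_surface(surface_kind = "gaussians", terms = terms)
  starts <- list(reactant = c(-0.55, 1.45),
                 intermediate = c(-0.05, 0.47),
                 product = c(0.6, 0.03))
  surf$minima <- lapply(starts, function(x0)
    optim(x0, surf$potential, surf$gradient, method = "BFGS",
          control = list(reltol = 1e-14))$par)
  # reactant must be the deepest minimum
  vals <- vapply(surf$minima, surf$potential, numeric(1))
  stopifnot(names(which.min(vals)) == "reactant")
  surf
}

#' Two-channel double-well benchmark surface
#'
#' \eqn{V(x,y)=(x^2-1)^2 + k_y y^2 + h\,e^{-x^2/s_x-(y-y_0)^2/s_y}}:
#' quartic wells at \eqn{x=\pm 1} separated by a barrier carrying a Gaussian
#' bump, so transitions can pass on either side of the bump (two channels).
#' With \code{y0 > 0} the lower channel is energetically favored, giving a
#' dominant transition mechanism.
#'
#' @param ky transverse stiffness.
#' @param h,sx,sy,y0 bump height, widths and vertical offset.
#' @return an \code{analytic_surface} with minima \code{reactant} at x = -1 and
#'   \code{product} at x = +1.
#' @export
build_double_well <- function(ky = 2, h = 4, sx = 0.15, sy = 0.3, y0 = 0.25) {
  surf <- analytic_surface(surface_kind = "doublewell",
                           dw_params = c(ky, h, sx, sy, y0))
  surf$minima <- lapply(list(reactant = c(-1, 0), product = c(1, 0)),
                        function(x0)
    optim(x0, surf$potential, surf$gradient, method = "BFGS",
          control = list(reltol = 1e-14))$par)
  surf
}

# internal constructor
analytic_surface <- function(surface_kind, terms = NULL, dw_params = NULL) {
  cpp <- list(kind = "surface", surface_kind = surface_kind,
              terms = terms, dw_params = dw_params)
  potential <- function(x) {
    cpp_system_forces(cpp, matrix(as.numeric(x), nrow = 1))$energy
  }
  gradient <- function(x) {
    -as.numeric(cpp_system_forces(cpp, matrix(as.numeric(x), nrow = 1))$forces)
  }
  structure(list(kind = "surface", dim = 2L, cpp = cpp,
                 potential = potential, gradient = gradient, minima = NULL),
            class = "analytic_surface")
}

#' @export
print.analytic_surface <- function(x, ...) {
  cat("<analytic_surface> ", x$cpp$surface_kind, "\n", sep = "")
  for (nm in names(x$minima))
    cat(sprintf("  %-12s (%+.4f, %+.4f)  V = %.4f\n", nm,
                x$minima[[nm]][1], x$minima[[nm]][2],
                x$potential(x$minima[[nm]])))
  invisible(x)
}

#' Zero-temperature string (minimum-energy path) on an analytic surface
#'
#' Independent string-method computation used to validate converged SCPS mean
#' paths: steepest-descent relaxation of a chain of images with tangential
#' reparametrization to equal arc length after every step.
#'
#' @param surface an \code{analytic_surface}.
#' @param from,to endpoint coordinates (default reactant and product minima).
#' @param n_images number of images along the string.
#' @param step descent step size.
#' @param n_iter relaxation iterations.
#' @return matrix \code{n_images x 2} of image coordinates.
#' @export
string_method <- function(surface, from = surface$minima$reactant,
                          to = surface$minima$product,
                          n_images = 40, step = 1e-4, n_iter = 4000) {
  s <- seq(0, 1, length.out = n_images)
  path <- cbind(from[1] + s * (to[1] - from[1]),
                from[2] + s * (to[2] - from[2]))
  for (it in seq_len(n_iter)) {
    g <- t(apply(path, 1, surface$gradient))
    path <- path - step * g
    path[1, ] <- from; path[n_images, ] <- to
    # reparametrize to equal arc length
    seg <- sqrt(rowSums(diff(path)^2))
    al <- c(0, cumsum(seg)) / sum(seg)
    path <- cbind(stats::approx(al, path[, 1], xout = s)$y,
                  stats::approx(al, path[, 2], xout = s)$y)
  }
  path
}
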