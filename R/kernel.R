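#' Kurtosis of the two-dimensional generalized-normal dispersal kernel
#'
#' For the radially symmetric kernel \eqn{\exp(-(d/a)^b)} in two dimensions,
#' the distance moments are \eqn{E[d^m] = a^m \Gamma((2+m)/b) / \Gamma(2/b)},
#' so the kurtosis \eqn{\kappa = E[d^4]/E[d^2]^2} depends on the shape
#' \eqn{b} alone:
#' \deqn{\kappa(b) = \Gamma(6/b)\,\Gamma(2/b) / \Gamma(4/b)^2.}
#' \code{b = 1} gives \eqn{\kappa = 10/3} (exponential kernel);
#' \code{b = 2} gives \eqn{\kappa = 2} (Gaussian).
#'
#' @param b shape parameter, > 0.
#' @return the kurtosis.
#' @export
kernel_kurtosis <- function(b) {
  if (any(b <= 0)) stop("'b' must be positive")
  # direct Gamma ratio where it cannot overflow (exact at integer arguments,
  # e.g. kappa(1) = 120/36 = 10/3); log-scale otherwise
  ifelse(6 / b < 170,
         gamma(6 / b) * gamma(2 / b) / gamma(4 / b)^2,
         exp(lgamma(6 / b) + lgamma(2 / b) - 2 * lgamma(4 / b)))
}

#' Solve the kernel shape parameter from a kurtosis target
#'
#' Inverts the monotone map \code{\link{kernel_kurtosis}} by bracketing:
#' returns \code{b} with \eqn{\kappa(b)} equal to the requested kurtosis.
#' \eqn{\kappa(b)} decreases from very heavy-tailed shapes (small \code{b})
#' towards its infimum as \code{b} grows; a kurtosis outside the attainable
#' range is an error.
#'
#' @param kappa target kurtosis.
#' @param interval search bracket for \code{b}.
#' @param tol root tolerance.
#' @return the shape \code{b}.
#' @export
#' @examples
#' solve_kernel_shape(10 / 3)  # exponential: b = 1
#' solve_kernel_shape(2)       # Gaussian:    b = 2
solve_kernel_shape <- function(kappa, interval = c(0.05, 50), tol = 1e-10) {
  if (length(kappa) != 1L || is.na(kappa)) stop("'kappa' must be a single number")
  g <- function(b) log(kernel_kurtosis(b)) - log(kappa)
  lo <- g(interval[1]); hi <- g(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop(sprintf("kurtosis %.6g is not attainable for b in [%g, %g]",
                 kappa, interval[1], interval[2]))
  stats::uniroot(g, interval, tol = tol)$root
}

#' Solve the kernel scale parameter from a standard-deviation target
#'
#' Given the shape \code{b}, returns the scale \code{a} such that the
#' kernel's second distance moment equals \eqn{\sigma^2}:
#' \deqn{a = \sigma \sqrt{\Gamma(2/b)/\Gamma(4/b)}.}
#'
#' @param sigma standard deviation of the kernel, > 0, in grid units.
#' @param b shape parameter, > 0.
#' @return the scale \code{a} in grid units.
#' @export
solve_kernel_scale <- function(sigma, b) {
  if (length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (length(b) != 1L || is.na(b) || b <= 0) stop("'b' must be positive")
  sigma * exp(0.5 * (lgamma(2 / b) - lgamma(4 / b)))
}

#' Landscape diagonal used for relative kernel widths
#'
#' The kernel standard deviation is conventionally quoted as a multiple of
#' the diagonal of the landscape, \eqn{D = L_{size}\sqrt{2}} grid units
#' (\eqn{\approx 141.4} for the default 100 x 100 grid), so that a given
#' \code{sigma_d} means the same thing relative to the extent of any grid.
#'
#' @param l_size landscape side length.
#' @return the diagonal \eqn{L_{size}\sqrt{2}}.
#' @export
landscape_diagonal <- function(l_size = 100) l_size * sqrt(2)

#' Build a dispersal-kernel specification
#'
#' Resolves the (kurtosis, standard deviation) parameterisation of the
#' two-dimensional generalized-normal kernel \eqn{\exp(-(d/a)^b)} into its
#' internal (scale, shape) form. Give the width either as \code{sigma_d}
#' (a multiple of the reference diagonal \eqn{D = 100\sqrt 2}, the
#' convention used throughout) or as \code{sigma} in absolute grid units.
#'
#' @param kappa kernel kurtosis; the default \code{10/3} is the exponential
#'   shape, giving substantial link probability at short distances.
#' @param sigma_d kernel standard deviation as a multiple of the landscape
#'   diagonal \eqn{D = L_{size}\sqrt 2}.
#' @param sigma kernel standard deviation in grid units (alternative).
#' @param l_size landscape side, used to resolve \code{sigma_d}.
#' @return object of class \code{"kernel_spec"}: list with \code{kappa},
#'   \code{sigma} (grid units), \code{b}, \code{a}.
#' @export
#' @examples
#' kernel_spec(kappa = 10/3, sigma_d = 0.1)
kernel_spec <- function(kappa = 10 / 3, sigma_d = NULL, sigma = NULL,
                        l_size = 100) {
  if (is.null(sigma) == is.null(sigma_d))
    stop("give exactly one of 'sigma_d' (relative to D) or 'sigma' (grid units)")
  if (is.null(sigma)) sigma <- sigma_d * landscape_diagonal(l_size)
  b <- solve_kernel_shape(kappa)
  a <- solve_kernel_scale(sigma, b)
  structure(list(kappa = kappa, sigma = sigma, b = b, a = a),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf(
    "Dispersal kernel exp(-(d/a)^b): kappa = %.4g, sigma = %.4g, b = %.6g, a = %.6g\n",
    x$kappa, x$sigma, x$b, x$a))
  invisible(x)
}
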