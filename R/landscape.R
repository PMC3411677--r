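#' Generate a Gaussian random field
#'
#' Draws an \code{l_size} x \code{l_size} matrix of independent
#' Normal(0.5, 2) values. This white-noise field is the raw material for the
#' spectrally scaled node landscape: its flat power spectrum is reshaped by
#' [spectral_scale()] and the top cells become node positions via
#' [place_nodes()].
#'
#' @param l_size side length of the square grid (>= 2).
#' @param seed optional integer seed; the same seed reproduces the field.
#' @return numeric \code{l_size} x \code{l_size} matrix.
#' @seealso [spectral_scale()], [place_nodes()]
#' @export
#' @examples
#' f <- generate_random_field(32, seed = 1)
#' dim(f)
generate_random_field <- function(l_size, seed = NULL) {
  l_size <- as.integer(l_size)
  if (length(l_size) != 1L || is.na(l_size) || l_size < 2L)
    stop("'l_size' must be a single integer >= 2")
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(l_size * l_size, mean = 0.5, sd = 2), l_size, l_size)
}

# Two-sided FFT frequencies for a length-n axis, in cycles per sample:
# 0, 1/n, ..., floor(n/2)/n, then the negative frequencies.
fft_freq <- function(n) {
  k <- 0:(n - 1L)
  k[k > n %/% 2] <- k[k > n %/% 2] - n
  k / n
}

#' Spectrally scale a random field to a 1/f^gamma landscape
#'
#' Transforms the field to the frequency domain with the FFT, multiplies each
#' Fourier coefficient by \eqn{f^{-\gamma/2}} (where \eqn{f} is the radial
#' frequency of the coefficient, so that spectral *power* scales as
#' \eqn{f^{-\gamma}}), and returns the real part of the inverse transform.
#' The zero-frequency (DC) coefficient is left unscaled. \code{gamma = 0}
#' leaves the field unchanged (white noise, spatially random); larger values
#' concentrate power at low frequencies, producing an aggregated, clumped
#' landscape.
#'
#' @param field numeric square matrix, e.g. from [generate_random_field()].
#' @param gamma continuity parameter, >= 0.
#' @return numeric matrix of the same shape.
#' @export
#' @examples
#' f <- generate_random_field(64, seed = 1)
#' s <- spectral_scale(f, gamma = 2)
spectral_scale <- function(field, gamma) {
  if (!is.matrix(field) || nrow(field) != ncol(field))
    stop("'field' must be a square matrix")
  if (length(gamma) != 1L || is.na(gamma) || gamma < 0)
    stop("'gamma' must be a single non-negative number")
  n <- nrow(field)
  fr <- fft_freq(n)
  f <- sqrt(outer(fr^2, fr^2, `+`))
  scale <- ifelse(f == 0, 1, f^(-gamma / 2))
  x <- stats::fft(field)
  Re(stats::fft(x * scale, inverse = TRUE)) / (n * n)
}

#' Place nodes on the highest cells of a landscape
#'
#' Digitises a scaled field into node coordinates by selecting the \code{n}
#' grid cells with the largest values; ties are broken uniformly at random.
#' Each node occupies a distinct cell, so co-located nodes cannot occur.
#'
#' @param field numeric square matrix (the scaled landscape).
#' @param n number of nodes, \code{n <= length(field)}.
#' @param seed optional integer seed for the random tie-break.
#' @return object of class \code{"specnet_landscape"}: a list with
#'   \code{coords} (an \code{n} x 2 integer matrix of 0-based
#'   \code{(row, col)} pairs), \code{l_size} and \code{gamma} (if known).
#' @export
place_nodes <- function(field, n, seed = NULL) {
  if (!is.matrix(field)) stop("'field' must be a matrix")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("'n' must be a positive integer")
  if (n > length(field)) stop("'n' exceeds the number of grid cells")
  if (!is.null(seed)) set.seed(seed)
  ord <- order(field, stats::runif(length(field)), decreasing = TRUE)
  idx <- ord[seq_len(n)] - 1L                    # 0-based linear, column-major
  l <- nrow(field)
  coords <- cbind(row = idx %% l, col = idx %/% l)
  structure(list(coords = coords, l_size = l, gamma = attr(field, "gamma")),
            class = "specnet_landscape")
}

#' Generate a node landscape in one call
#'
#' Convenience pipeline: Gaussian random field -> spectral 1/f^gamma scaling
#' -> top-\code{n} cell selection.
#'
#' @inheritParams generate_random_field
#' @inheritParams spectral_scale
#' @param n number of nodes.
#' @param seed optional integer seed (field and tie-break share it).
#' @return a \code{"specnet_landscape"} (see [place_nodes()]).
#' @export
#' @examples
#' ls <- node_landscape(n = 50, l_size = 100, gamma = 2, seed = 1)
#' head(ls$coords)
node_landscape <- function(n, l_size = 100, gamma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fld <- generate_random_field(l_size)
  scl <- spectral_scale(fld, gamma)
  out <- place_nodes(scl, n)
  out$gamma <- gamma
  out
}

#' @export
print.specnet_landscape <- function(x, ...) {
  cat(sprintf("Node landscape: %d nodes on a %dx%d toroidal grid (gamma = %s)\n",
              nrow(x$coords), x$l_size, x$l_size,
              if (is.null(x$gamma)) "?" else format(x$gamma)))
  invisible(x)
}
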