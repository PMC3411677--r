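#' Toroidal (periodic-boundary) Euclidean distance
#'
#' Distance between grid points with wrap-around on both axes: each axis
#' difference is replaced by \code{min(|delta|, l_size - |delta|)}. Periodic
#' boundaries remove edge effects from the link-formation kernel.
#'
#' @param p,q length-2 coordinate vectors (or matrices of rows of them).
#' @param l_size grid side length.
#' @return numeric distance(s).
#' @export
#' @examples
#' torus_distance(c(0, 0), c(99, 99), 100)  # sqrt(2)
torus_distance <- function(p, q, l_size) {
  p <- rbind(p); q <- rbind(q)
  d <- abs(p - q)
  d <- pmin(d, l_size - d)
  unname(sqrt(rowSums(d^2)))
}

# Full n x n toroidal distance matrix for coords (n x 2, 0-based).
torus_distance_matrix <- function(coords, l_size) {
  dx <- abs(outer(coords[, 1], coords[, 1], `-`))
  dx <- pmin(dx, l_size - dx)
  dy <- abs(outer(coords[, 2], coords[, 2], `-`))
  dy <- pmin(dy, l_size - dy)
  sqrt(dx * dx + dy * dy)
}

# Upper-triangle (i < j) pair index table for n nodes, column-major order,
# matching which(upper.tri(...)). Cached per n within a session.
pair_index <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    j <- rep.int(seq_len(n), pmax(seq_len(n) - 1L, 0L))
    i <- sequence(pmax(seq_len(n) - 1L, 0L))
    out <- cbind(i = i, j = j)
    if (n <= 4000L) cache[[key]] <- out
    out
  }
})

#' Number of links implied by a link density
#'
#' \eqn{L = \mathrm{round}(l_d \cdot n(n-1)/2)}, rounded half-up so the rule
#' is deterministic.
#'
#' @param n node count.
#' @param l_d link density in \code{[0, 1]}.
#' @return integer link count.
#' @export
#' @examples
#' num_links(500, 0.01)  # 1248
num_links <- function(n, l_d) {
  if (length(l_d) != 1L || is.na(l_d) || l_d < 0 || l_d > 1)
    stop("'l_d' must be in [0, 1]")
  as.integer(floor(l_d * n * (n - 1) / 2 + 0.5))
}

#' Randomly assign focal nodes
#'
#' Flags exactly \code{round(f * n)} nodes (half-up) as focal, chosen
#' uniformly without replacement. Focal nodes model hubs such as farms
#' trading large numbers of animals; their connections to regular nodes are
#' up-weighted during link formation, which drives assortativity negative.
#'
#' @param n node count.
#' @param f focal fraction in \code{[0, 1]}.
#' @param seed optional integer seed.
#' @return logical vector of length \code{n}.
#' @export
assign_focal <- function(n, f, seed = NULL) {
  if (length(f) != 1L || is.na(f) || f < 0 || f > 1) stop("'f' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(floor(f * n + 0.5))
  focal <- logical(n)
  if (k > 0L) focal[sample.int(n, k)] <- TRUE
  focal
}

#' Link-probability weights for all node pairs
#'
#' For each unordered pair \eqn{(i, j)} the weight is the kernel value
#' \eqn{\exp(-(d_{ij}/a)^b)} at the toroidal distance, multiplied by the
#' focal scale factor \code{fsf} when exactly one endpoint is focal, and
#' normalised so the weights sum to one (the normalising constant K).
#'
#' @param landscape a \code{"specnet_landscape"} (or bare 0-based coordinate
#'   matrix plus \code{l_size}).
#' @param focal logical vector of per-node focal flags.
#' @param kernel a [kernel_spec()].
#' @param fsf focal scale factor, >= 1.
#' @param l_size grid side (taken from \code{landscape} when available).
#' @return list with \code{pairs} (m x 2 index matrix, i < j) and \code{w}
#'   (normalised weights summing to 1).
#' @export
pair_weights <- function(landscape, focal, kernel, fsf = 1, l_size = NULL) {
  coords <- if (inherits(landscape, "specnet_landscape")) landscape$coords else landscape
  if (is.null(l_size) && inherits(landscape, "specnet_landscape"))
    l_size <- landscape$l_size
  n <- nrow(coords)
  if (is.null(n) || n < 2L) stop("need at least two nodes")
  if (fsf < 1) stop("'fsf' must be >= 1")
  dm <- torus_distance_matrix(coords, l_size)
  ut <- upper.tri(dm)
  w <- exp(-(dm[ut] / kernel$a)^kernel$b)
  if (any(focal) && fsf != 1) {
    mixed <- outer(focal, focal, xor)[ut]
    w[mixed] <- w[mixed] * fsf
  }
  list(pairs = pair_index(n), w = w / sum(w))
}

#' Draw links by sequential weighted sampling without replacement
#'
#' Links are added one by one: each draw picks a pair with probability
#' proportional to its current weight, the drawn pair's weight is set to
#' zero and the remainder renormalised. The implementation uses the
#' exponential-keys formulation (draw \eqn{E_i/w_i} with \eqn{E_i} standard
#' exponential and keep the \code{l} smallest keys), which yields exactly
#' the same joint distribution as the literal renormalisation loop in a
#' single vectorised pass.
#'
#' @param weights output of [pair_weights()] (or a bare numeric vector, in
#'   which case the drawn indices are returned).
#' @param l number of links to draw.
#' @param seed optional integer seed.
#' @return m x 2 integer edge matrix (i < j), or drawn indices for a bare
#'   weight vector.
#' @export
draw_links <- function(weights, l, seed = NULL) {
  w <- if (is.list(weights)) weights$w else weights
  l <- as.integer(l)
  pos <- which(w > 0)
  if (l > length(pos))
    stop(sprintf("cannot draw %d links: only %d pairs have positive weight",
                 l, length(pos)))
  if (!is.null(seed)) set.seed(seed)
  if (l == 0L) {
    sel <- integer(0)
  } else {
    keys <- stats::rexp(length(pos)) / w[pos]
    sel <- pos[order(keys)[seq_len(l)]]
  }
  if (is.list(weights)) weights$pairs[sel, , drop = FALSE] else sel
}

#' Generate a spatial spectral network
#'
#' The full generator: synthesise a 1/f^gamma node landscape
#' ([node_landscape()]), assign focal nodes ([assign_focal()]), resolve the
#' dispersal kernel ([kernel_spec()]), weight every node pair
#' ([pair_weights()]) and draw \code{num_links(n, l_d)} links sequentially
#' without replacement ([draw_links()]). The result is a simple undirected
#' graph; isolated nodes are allowed.
#'
#' Three independent seed streams (landscape, focal assignment, link draws)
#' are derived from \code{seed}, so the components vary independently.
#'
#' @param n number of nodes.
#' @param l_d link density: realised links as a proportion of
#'   \eqn{n(n-1)/2}; fixes the mean degree \eqn{(n-1) l_d}.
#' @param gamma landscape continuity parameter (0 = random placement,
#'   larger = aggregated clumps).
#' @param sigma_d kernel standard deviation as a multiple of the landscape
#'   diagonal \eqn{D = L_{size}\sqrt 2}; use \code{sigma} for grid units
#'   instead.
#' @param fsf focal scale factor (>= 1): multiplies the link weight of
#'   regular-focal pairs.
#' @param f fraction of focal nodes in \code{[0, 1]}.
#' @param kappa kernel kurtosis (default exponential shape, 10/3).
#' @param l_size landscape side length.
#' @param seed optional integer seed for full reproducibility.
#' @param sigma kernel standard deviation in absolute grid units
#'   (alternative to \code{sigma_d}).
#' @return object of class \code{"specnet"}: list with \code{n},
#'   \code{edges} (m x 2, 1-based, i < j), \code{coords} (n x 2, 0-based
#'   grid), \code{focal} (logical), \code{params}, \code{seed}.
#' @seealso [network_measures()], [simulate.specnet()], [specnet_sweep()],
#'   [specnet_fit()]
#' @export
#' @examples
#' net <- specnet(n = 100, l_d = 0.05, gamma = 1, sigma_d = 0.1,
#'                fsf = 10, f = 0.1, seed = 42)
#' net
#' summary(net)
specnet <- function(n = 500, l_d = 0.01, gamma = 0, sigma_d = 0.1,
                    fsf = 10, f = 0, kappa = 10 / 3, l_size = 100,
                    seed = NULL, sigma = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2")
  if (n > l_size^2) stop("'n' exceeds the number of landscape cells")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max, 3L)

  ls <- node_landscape(n = n, l_size = l_size, gamma = gamma,
                       seed = streams[1])
  focal <- assign_focal(n, f, seed = streams[2])
  kern <- if (is.null(sigma))
    kernel_spec(kappa = kappa, sigma_d = sigma_d, l_size = l_size)
  else kernel_spec(kappa = kappa, sigma = sigma)
  wts <- pair_weights(ls, focal, kern, fsf = fsf)
  edges <- draw_links(wts, num_links(n, l_d), seed = streams[3])
  dimnames(edges) <- NULL
  if (nrow(edges))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]

  structure(list(
    n = n, edges = edges, coords = ls$coords, focal = focal,
    params = list(n = n, l_d = l_d, gamma = gamma,
                  sigma_d = if (is.null(sigma)) sigma_d else NULL,
                  sigma = kern$sigma, fsf = fsf, f = f, kappa = kappa,
                  l_size = l_size, b = kern$b, a = kern$a),
    seed = seed), class = "specnet")
}

#' Construct a network object from an edge list
#'
#' Wraps a bare edge list (and optional node attributes) in the same class
#' returned by [specnet()], so the measures and IO functions apply to
#' externally supplied graphs too. Validates simplicity: no self-loops, no
#' duplicate edges.
#'
#' @param n node count.
#' @param edges m x 2 matrix of 1-based node indices.
#' @param coords optional n x 2 coordinate matrix.
#' @param focal optional logical vector.
#' @param params optional parameter list.
#' @return a \code{"specnet"} object.
#' @export
as_specnet <- function(n, edges, coords = NULL, focal = NULL, params = NULL) {
  n <- as.integer(n)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  structure(list(n = n, edges = edges, coords = coords, focal = focal,
                 params = params, seed = NULL), class = "specnet")
}

#' @export
print.specnet <- function(x, ...) {
  cat(sprintf("Spatial spectral network: %d nodes, %d links (density %.4g)",
              x$n, nrow(x$edges), nrow(x$edges) / (x$n * (x$n - 1) / 2)))
  if (!is.null(x$focal) && any(x$focal))
    cat(sprintf(", %d focal nodes", sum(x$focal)))
  cat("\n")
  if (!is.null(x$params) && !is.null(x$params$gamma))
    cat(sprintf("  gamma = %g, sigma = %.4g grid units, fsf = %g, f = %g\n",
                x$params$gamma, x$params$sigma, x$params$fsf, x$params$f))
  invisible(x)
}

#' @export
summary.specnet <- function(object, ...) {
  m <- network_measures(object)
  structure(list(net = object, measures = m), class = "summary.specnet")
}

#' @export
print.summary.specnet <- function(x, ...) {
  print(x$net)
  m <- x$measures
  cat(sprintf("  clustering     %8.4f\n", m$clustering))
  cat(sprintf("  assortativity  %8.4f\n", m$assortativity))
  cat(sprintf("  fragmentation  %8.4f\n", m$fragmentation))
  cat(sprintf("  mean degree    %8.4f\n", m$mean_degree))
  invisible(x)
}

#' Plot a spatial network
#'
#' Draws nodes at their landscape coordinates (focal nodes filled) and the
#' links between them. Links that wrap around the torus are drawn clipped.
#'
#' @param x a \code{"specnet"} with coordinates.
#' @param ... passed to [graphics::plot()].
#' @export
plot.specnet <- function(x, ...) {
  if (is.null(x$coords)) stop("this network has no spatial coordinates")
  co <- x$coords
  graphics::plot(co[, 2], co[, 1], pch = ifelse(isTRUE(x$focal), 19, 1),
                 xlab = "col", ylab = "row", asp = 1, ...)
  if (nrow(x$edges))
    graphics::segments(co[x$edges[, 1], 2], co[x$edges[, 1], 1],
                       co[x$edges[, 2], 2], co[x$edges[, 2], 1],
                       col = grDevices::adjustcolor("grey40", 0.5))
  graphics::points(co[x$focal, 2], co[x$focal, 1], pch = 19, col = "red")
  invisible(x)
}

#' Simulate replicate networks from a fitted or constructed generator
#'
#' Regenerates \code{nsim} independent networks with the same parameters as
#' \code{object}, using fresh derived seeds.
#'
#' @param object a \code{"specnet"} created by [specnet()].
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return list of \code{"specnet"} objects.
#' @export
simulate.specnet <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$params
  if (is.null(p)) stop("'object' carries no generator parameters")
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seeds, function(s)
    specnet(n = p$n, l_d = p$l_d, gamma = p$gamma, sigma = p$sigma,
            fsf = p$fsf, f = p$f, kappa = p$kappa, l_size = p$l_size,
            seed = s))
}

#' Per-node degrees
#'
#' @param net a \code{"specnet"}.
#' @return integer vector of length \code{net$n}, order preserved.
#' @export
degree_sequence_of <- function(net) {
  tabulate(net$edges, nbins = net$n)
}
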