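#' Average local clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient
#' \eqn{c_i = 2T_i / (k_i (k_i - 1))}, where \eqn{T_i} is the number of
#' links among the neighbours of node \eqn{i}. Nodes of degree 0 or 1 have
#' no neighbour pairs; by default they contribute \eqn{c_i = 0} and are
#' included in the average, which keeps the measure defined for networks
#' with isolated nodes. Set \code{isolates = "exclude"} to average over
#' nodes of degree >= 2 only.
#'
#' Triangles are counted through the sparse adjacency matrix:
#' \eqn{2T_i = (A^3)_{ii}}.
#'
#' @param net a \code{"specnet"} object (see [as_specnet()]).
#' @param isolates \code{"zero"} (default) or \code{"exclude"}.
#' @return average clustering in \code{[0, 1]}.
#' @export
#' @examples
#' tri <- as_specnet(3, rbind(c(1, 2), c(2, 3), c(1, 3)))
#' avg_clustering(tri)  # 1
avg_clustering <- function(net, isolates = c("zero", "exclude")) {
  isolates <- match.arg(isolates)
  n <- net$n
  k <- degree_sequence_of(net)
  if (nrow(net$edges) == 0L)
    return(if (isolates == "zero") 0 else NaN)
  A <- Matrix::sparseMatrix(i = c(net$edges[, 1], net$edges[, 2]),
                            j = c(net$edges[, 2], net$edges[, 1]),
                            x = 1, dims = c(n, n))
  twoT <- Matrix::rowSums((A %*% A) * A)   # (A^3)_ii = 2 * triangles at i
  ci <- numeric(n)
  deg2 <- k >= 2L
  ci[deg2] <- twoT[deg2] / (k[deg2] * (k[deg2] - 1))
  if (isolates == "zero") mean(ci)
  else if (any(deg2)) mean(ci[deg2]) else NaN
}

#' Degree assortativity (Newman's r)
#'
#' Pearson correlation of the degrees at the two ends of each link,
#' symmetrised over the two orientations of every undirected link. Values
#' near 1 mean similar-degree nodes connect to each other; values near -1
#' mean hubs connect to leaves. Undefined (returned as \code{NA}) when the
#' degrees at link ends have zero variance, e.g. in regular graphs.
#'
#' @param net a \code{"specnet"} object.
#' @return correlation in \code{[-1, 1]}, or \code{NA} when undefined.
#' @export
#' @examples
#' star <- as_specnet(4, rbind(c(1, 2), c(1, 3), c(1, 4)))
#' degree_assortativity(star)  # -1
degree_assortativity <- function(net) {
  if (nrow(net$edges) == 0L) return(NA_real_)
  k <- degree_sequence_of(net)
  x <- c(k[net$edges[, 1]], k[net$edges[, 2]])
  y <- c(k[net$edges[, 2]], k[net$edges[, 1]])
  sx <- stats::sd(x)
  if (sx == 0) return(NA_real_)
  # symmetric pairing: sd(x) == sd(y)
  mean((x - mean(x)) * (y - mean(y))) / (sx^2 * (length(x) - 1) / length(x))
}

# Connected-component labels by breadth-first search over adjacency lists.
component_labels <- function(net) {
  n <- net$n
  adj <- vector("list", n)
  if (nrow(net$edges)) {
    ends <- c(net$edges[, 1], net$edges[, 2])
    nbrs <- c(net$edges[, 2], net$edges[, 1])
    adj[sort(unique(ends))] <- split(nbrs, ends)
  }
  comp <- integer(n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v]) next
    cur <- cur + 1L
    frontier <- v
    comp[v] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  comp
}

#' Fragmentation index
#'
#' The proportion of node pairs that cannot reach each other:
#' \deqn{F = 1 - \sum_c s_c (s_c - 1) / (n (n - 1))}
#' over connected components \eqn{c} with sizes \eqn{s_c}. 0 means the
#' network is a single connected component; 1 means no links at all. The
#' component-size form weighs large components more, exactly as counting
#' unreachable ordered pairs does.
#'
#' @param net a \code{"specnet"} object with \code{n >= 2}.
#' @return fragmentation in \code{[0, 1]}.
#' @export
#' @examples
#' g <- as_specnet(5, rbind(c(1, 2), c(2, 3), c(4, 5)))
#' fragmentation_index(g)  # 1 - (6 + 2)/20 = 0.6
fragmentation_index <- function(net) {
  if (net$n < 2L) stop("fragmentation requires at least two nodes")
  sizes <- tabulate(component_labels(net))
  1 - sum(sizes * (sizes - 1)) / (net$n * (net$n - 1))
}

#' Mean degree and link density
#'
#' Mean degree \eqn{2|E|/n} and link density \eqn{|E| / (n(n-1)/2)}; they
#' satisfy \eqn{\bar k = (n - 1) \, l_d}.
#'
#' @param net a \code{"specnet"} object.
#' @return named list with \code{mean_degree} and \code{link_density}.
#' @export
mean_degree_and_density <- function(net) {
  m <- nrow(net$edges)
  list(mean_degree = 2 * m / net$n,
       link_density = m / (net$n * (net$n - 1) / 2))
}

#' All four structure measures of a network
#'
#' One-row data frame with the average clustering coefficient, degree
#' assortativity, fragmentation index, mean degree and link density.
#'
#' @param net a \code{"specnet"} object.
#' @param isolates clustering convention for degree < 2 nodes, see
#'   [avg_clustering()].
#' @return one-row \code{data.frame}.
#' @export
#' @examples
#' net <- specnet(n = 100, l_d = 0.05, seed = 1)
#' network_measures(net)
network_measures <- function(net, isolates = "zero") {
  md <- mean_degree_and_density(net)
  data.frame(clustering = avg_clustering(net, isolates = isolates),
             assortativity = degree_assortativity(net),
             fragmentation = fragmentation_index(net),
             mean_degree = md$mean_degree,
             link_density = md$link_density)
}
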