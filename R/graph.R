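#' Build a pixel-similarity graph
#'
#' Substrate for the Markov-chain random walkers: a k-nearest-neighbour graph
#' over pixels under correlation distance (1 - Pearson r between pixel
#' feature vectors), symmetrized by union. Edge weights are a Gaussian kernel
#' `exp(-d^2 / (2 sigma^2))` of the distance; `sigma` is the median
#' neighbour distance when `bandwidth = "auto"`. Edges whose weight
#' underflows to zero are dropped (weights must be strictly positive); nodes
#' left without any edge are flagged isolated.
#'
#' @param matrix a [build_pixel_matrix()] `pixel_matrix`, or a plain numeric
#'   matrix (rows = pixels).
#' @param k neighbours per node; must be smaller than the number of pixels.
#' @param bandwidth kernel bandwidth, or `"auto"` for the median
#'   nearest-neighbour distance.
#' @return object of class `similarity_graph`: list with `n`, `edges`
#'   (data frame `i`, `j`, `d`, `w` with `i < j`), `sigma`, `k`, `isolated`
#'   (logical per node) and `dist` (the full correlation-distance matrix,
#'   kept for deterministic seed selection).
#' @export
build_similarity_graph <- function(matrix, k = 8, bandwidth = "auto") {
  values <- if (inherits(matrix, "pixel_matrix")) matrix$values else as.matrix(matrix)
  n <- nrow(values)
  if (n < 2) stop("need at least 2 pixels")
  if (k >= n) stop("k must be smaller than the number of pixels")
  if (k < 1) stop("k must be >= 1")
  d <- correlation_distances(values)
  # k nearest neighbours per node, ties broken by lowest index
  nn <- lapply(seq_len(n), function(i) {
    others <- seq_len(n)[-i]
    others[order(d[i, others], others)][seq_len(k)]
  })
  pairs <- unique(do.call(rbind, lapply(seq_len(n), function(i) {
    js <- nn[[i]]
    cbind(pmin(i, js), pmax(i, js))
  })))
  dd <- d[pairs]
  sigma <- if (identical(bandwidth, "auto")) {
    s <- stats::median(unlist(lapply(seq_len(n), function(i) d[i, nn[[i]]])))
    if (!is.finite(s) || s <= 0) 1 else s
  } else {
    if (!is.numeric(bandwidth) || bandwidth <= 0) stop("bandwidth must be positive or 'auto'")
    bandwidth
  }
  w <- exp(-dd^2 / (2 * sigma^2))
  keep <- w > 0
  edges <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                      d = dd[keep], w = w[keep])
  degree <- tabulate(c(edges$i, edges$j), nbins = n)
  structure(list(n = n, edges = edges, sigma = sigma, k = k,
                 isolated = degree == 0, dist = d),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("similarity_graph: %d nodes, %d edges, sigma %.4g, %d isolated\n",
              x$n, nrow(x$edges), x$sigma, sum(x$isolated)))
  invisible(x)
}

# Dense symmetric weight matrix of a similarity graph.
graph_weights <- function(graph) {
  W <- matrix(0, graph$n, graph$n)
  W[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$w
  W[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$w
  W
}

# Connected components (vector of component ids, 1-based).
graph_components <- function(graph) {
  if (nrow(graph$edges) == 0) return(seq_len(graph$n))
  g <- igraph::graph_from_edgelist(as.matrix(graph$edges[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, graph$n - igraph::vcount(g)))
  igraph::components(g)$membership
}
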