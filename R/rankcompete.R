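#' Competing random-walker bisection of a similarity graph
#'
#' The split function of the divisive segmentation: two random walkers, each
#' personalized on one seed pixel, rank every node of the similarity graph by
#' the stationary distribution of a restart random walk, and each pixel joins
#' the walker that ranks it higher.
#'
#' Each walker's rank vector solves the restart-walk fixed point
#' `r = (1 - alpha) * t(P) r + alpha * e_seed`, where `P` is the
#' row-normalized edge-weight matrix of the graph and `e_seed` the indicator
#' of the walker's seed; it is computed by power iteration to an L1 residual
#' below `tol`. Ranks are non-negative and sum to 1 at every iteration.
#' Ties in the final comparison go to the first walker; each seed always
#' belongs to its own walker's segment, so both segments are non-empty.
#'
#' @param graph a [build_similarity_graph()] object; should be connected
#'   (walkers cannot compete across components).
#' @param seeds integer pair of node indices, or `"auto"` to use the two
#'   nodes at maximal correlation distance (ties broken by lowest index).
#' @param restart_prob restart probability alpha in (0, 1).
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter maximum iterations; non-convergence is an error carrying
#'   the last residual.
#' @return list with `segments` (integer vector of 1/2 labels), `ranks`
#'   (two rank vectors), `seeds`, `iterations`, `residual`.
#' @export
rankcompete_split <- function(graph, seeds = "auto", restart_prob = 0.15,
                              tol = 1e-10, max_iter = 10000L) {
  stopifnot(inherits(graph, "similarity_graph"))
  if (restart_prob <= 0 || restart_prob >= 1) stop("restart_prob must be in (0, 1)")
  n <- graph$n
  if (identical(seeds, "auto")) {
    d <- graph$dist
    idx <- which(d == max(d), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    seeds <- c(idx[1, 1], idx[1, 2])
    seeds <- c(min(seeds), max(seeds))
  }
  seeds <- as.integer(seeds)
  if (length(seeds) != 2 || anyNA(seeds) || seeds[1] == seeds[2]) {
    stop("seeds must be two distinct node indices")
  }
  W <- graph_weights(graph)
  deg <- rowSums(W)
  # isolated nodes hold the walker in place (self-loop)
  P <- W / ifelse(deg > 0, deg, 1)
  iso <- which(deg == 0)
  P[cbind(iso, iso)] <- 1
  Pt <- t(P)
  alpha <- restart_prob
  walk <- function(seed) {
    e <- numeric(n); e[seed] <- 1
    r <- e
    for (it in seq_len(max_iter)) {
      r_new <- (1 - alpha) * as.numeric(Pt %*% r) + alpha * e
      res <- sum(abs(r_new - r))
      r <- r_new
      if (res < tol) return(list(rank = r, iterations = it, residual = res))
    }
    stop(sprintf("random-walk ranking did not converge in %d iterations (residual %.3e)",
                 max_iter, res))
  }
  w1 <- walk(seeds[1])
  w2 <- walk(seeds[2])
  segments <- ifelse(w1$rank >= w2$rank, 1L, 2L)
  segments[seeds[1]] <- 1L
  segments[seeds[2]] <- 2L
  list(segments = segments,
       ranks = list(w1$rank, w2$rank),
       seeds = seeds,
       restart_prob = alpha,
       iterations = max(w1$iterations, w2$iterations),
       residual = max(w1$residual, w2$residual))
}
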