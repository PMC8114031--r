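# Shared builders for small test objects.

# A pixel_matrix built directly from a values matrix, bypassing preprocessing.
toy_pixel_matrix <- function(values, mz = NULL) {
  n <- nrow(values)
  mz <- mz %||% seq(600, by = 10, length.out = ncol(values))
  pixels <- data.frame(x = seq_len(n) * 150, y = 0, row = 0L,
                       col = seq_len(n) - 1L, pixel_id = seq_len(n),
                       all_zero = rowSums(values) == 0)
  rownames(values) <- paste0("px", seq_len(n))
  colnames(values) <- sprintf("mz_%.4f", mz)
  structure(list(values = values, mz = mz, pixels = pixels, params = list()),
            class = "pixel_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A similarity_graph assembled from an explicit edge list (i, j, w).
toy_graph <- function(n, edges_ij, w = 1, d = 0) {
  edges <- data.frame(i = pmin(edges_ij[, 1], edges_ij[, 2]),
                      j = pmax(edges_ij[, 1], edges_ij[, 2]),
                      d = d, w = w)
  degree <- tabulate(c(edges$i, edges$j), nbins = n)
  structure(list(n = n, edges = edges, sigma = 1, k = NA_integer_,
                 isolated = degree == 0, dist = NULL),
            class = "similarity_graph")
}

# Random connected weighted graph with at most max_n nodes: a random spanning
# ring plus random extra edges, weights uniform in (0.1, 1].
random_small_graph <- function(max_n = 8) {
  n <- sample(3:max_n, 1)
  ring <- cbind(seq_len(n), c(seq_len(n)[-1], 1))
  extra_n <- sample(0:3, 1)
  extra <- if (extra_n > 0) {
    t(replicate(extra_n, sample(n, 2)))
  } else NULL
  ij <- rbind(ring, extra)
  ij <- unique(cbind(pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2])))
  toy_graph(n, ij, w = stats::runif(nrow(ij), 0.1, 1))
}

# Dense rank-vector oracle: direct linear solve of the restart-walk fixed
# point (I - (1 - alpha) t(P)) r = alpha e_seed.
solve_rank_oracle <- function(graph, seed, alpha = 0.15) {
  W <- matrix(0, graph$n, graph$n)
  W[cbind(graph$edges$i, graph$edges$j)] <- graph$edges$w
  W[cbind(graph$edges$j, graph$edges$i)] <- graph$edges$w
  deg <- rowSums(W)
  P <- W / ifelse(deg > 0, deg, 1)
  iso <- which(deg == 0)
  P[cbind(iso, iso)] <- 1
  e <- numeric(graph$n); e[seed] <- 1
  as.numeric(solve(diag(graph$n) - (1 - alpha) * t(P), alpha * e))
}

# Random peak list for filter oracles.
random_peaklist <- function(n_peaks) {
  mz <- sort(stats::runif(n_peaks, 550, 2000))
  intensity <- stats::rexp(n_peaks, rate = 1 / 50)
  spotMSI:::new_peaklist(mz = mz, intensity = intensity,
                         base_peak_intensity = if (n_peaks) max(intensity) else 0,
                         spectrum = list(x = 0, y = 0, row = 0L, col = 0L))
}

table1_path <- function() {
  system.file("extdata", "ev_protein_ratios_cd9_cd63_peptides.tsv",
              package = "spotMSI")
}
table2_path <- function() {
  system.file("extdata", "ev_protein_ratios_cd9ko_wt.tsv", package = "spotMSI")
}
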