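#' Divisive segmentation with competing random walkers
#'
#' Top-down segmentation of the pixel matrix in the spirit of divisive
#' analysis clustering (DIANA), with the competing-random-walker bisection of
#' [rankcompete_split()] as split function. Starting from the connected
#' components of the full similarity graph (walkers cannot compete across
#' components, so components are forced top-level segments), the segment with
#' the largest DIANA diameter -- the maximum over its pixels of the average
#' correlation distance to the rest of the segment -- is bisected, until a
#' stopping rule fires: `max_segments` reached, no candidate split leaves
#' both children with at least `min_segment_size` pixels (one spot = 9 pixels
#' by default), or the relative reduction in total within-segment
#' dissimilarity falls below `min_split_gain`. Segments whose pixels are all
#' identical (diameter 0) are never split.
#'
#' @param matrix a [build_pixel_matrix()] `pixel_matrix` (or plain matrix).
#' @param max_segments maximum number of final segments.
#' @param min_segment_size minimum pixels per final segment.
#' @param min_split_gain minimum relative reduction (against the current
#'   total within-segment dissimilarity) for a split to be accepted.
#' @param k,bandwidth similarity-graph construction parameters, see
#'   [build_similarity_graph()].
#' @param restart_prob,tol,max_iter walker parameters, see
#'   [rankcompete_split()].
#' @return object of class `segmentation_result`: list with `labels`
#'   (integer segment id per pixel, in matrix row order), `tree` (list of
#'   split records with rank vectors and split quality), `segment_means`
#'   (segments x features), `colours` (see [color_segments()]), `pixels`,
#'   `params`.
#' @export
diana_rankcompete <- function(matrix, max_segments = 8, min_segment_size = 9,
                              min_split_gain = 0.01, k = 8,
                              bandwidth = "auto", restart_prob = 0.15,
                              tol = 1e-10, max_iter = 10000L) {
  values <- if (inherits(matrix, "pixel_matrix")) matrix$values else as.matrix(matrix)
  pixels <- if (inherits(matrix, "pixel_matrix")) matrix$pixels else NULL
  n <- nrow(values)
  if (n < 2) stop("need at least 2 pixels")
  D <- correlation_distances(values)
  within_sum <- function(idx) if (length(idx) < 2) 0 else sum(D[idx, idx]) / 2
  diameter <- function(idx) {
    if (length(idx) < 2) return(0)
    max(rowSums(D[idx, idx, drop = FALSE]) / (length(idx) - 1))
  }

  full_graph <- build_similarity_graph(values, k = min(k, n - 1), bandwidth = bandwidth)
  comp <- graph_components(full_graph)
  leaves <- lapply(sort(unique(comp)), function(cc) which(comp == cc))
  # deterministic order: by lowest member pixel
  leaves <- leaves[order(vapply(leaves, min, numeric(1)))]
  splits <- list()
  if (length(leaves) > 1) {
    splits[[1]] <- list(type = "components", children = leaves)
  }
  unsplittable <- rep(FALSE, length(leaves))

  while (length(leaves) < max_segments) {
    diams <- vapply(leaves, diameter, numeric(1))
    eligible <- !unsplittable & diams > 0 &
      vapply(leaves, length, integer(1)) >= 2 * min_segment_size
    if (!any(eligible)) break
    cand <- which(eligible)
    pick <- cand[order(-diams[cand],
                       vapply(leaves[cand], min, numeric(1)))][1]
    idx <- leaves[[pick]]
    sub_k <- min(k, length(idx) - 1)
    sub_graph <- build_similarity_graph(values[idx, , drop = FALSE],
                                        k = sub_k, bandwidth = bandwidth)
    sub_comp <- graph_components(sub_graph)
    if (max(sub_comp) > 1) {
      # forced split: first component against the rest
      part <- ifelse(sub_comp == sub_comp[1], 1L, 2L)
      split_rec <- list(type = "forced", ranks = NULL)
    } else {
      dsub <- D[idx, idx, drop = FALSE]
      mx <- which(dsub == max(dsub), arr.ind = TRUE)
      mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE]
      seeds <- sort(c(mx[1, 1], mx[1, 2]))
      rc <- rankcompete_split(sub_graph, seeds = seeds,
                              restart_prob = restart_prob, tol = tol,
                              max_iter = max_iter)
      part <- rc$segments
      split_rec <- list(type = "rankcompete", ranks = rc$ranks,
                        seeds = idx[rc$seeds])
    }
    a <- idx[part == 1L]; b <- idx[part == 2L]
    total_within <- sum(vapply(leaves, within_sum, numeric(1)))
    gain_abs <- within_sum(idx) - within_sum(a) - within_sum(b)
    gain <- if (total_within > 0) gain_abs / total_within else 0
    ok_size <- length(a) >= min_segment_size && length(b) >= min_segment_size
    ok_gain <- split_rec$type == "forced" || gain >= min_split_gain
    if (!ok_size || !ok_gain) {
      unsplittable[pick] <- TRUE
      next
    }
    split_rec$parent <- idx
    split_rec$children <- list(a, b)
    split_rec$gain <- gain
    split_rec$diameter <- diams[pick]
    splits[[length(splits) + 1]] <- split_rec
    leaves <- c(leaves[-pick], list(a), list(b))
    unsplittable <- c(unsplittable[-pick], FALSE, FALSE)
    ord <- order(vapply(leaves, min, numeric(1)))
    leaves <- leaves[ord]
    unsplittable <- unsplittable[ord]
  }

  labels <- integer(n)
  for (s in seq_along(leaves)) labels[leaves[[s]]] <- s
  means <- do.call(rbind, lapply(leaves, function(idx) {
    colMeans(values[idx, , drop = FALSE])
  }))
  rownames(means) <- paste0("segment", seq_along(leaves))
  res <- structure(
    list(labels = labels,
         tree = list(splits = splits, leaves = leaves),
         segment_means = means,
         colours = NULL,
         pixels = pixels,
         params = list(max_segments = max_segments,
                       min_segment_size = min_segment_size,
                       min_split_gain = min_split_gain, k = k,
                       bandwidth = bandwidth, restart_prob = restart_prob)),
    class = "segmentation_result")
  res$colours <- color_segments(res)
  res
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result: %d pixels in %d segments (sizes: %s)\n",
              length(x$labels), length(x$tree$leaves),
              paste(tabulate(x$labels), collapse = ", ")))
  invisible(x)
}

#' Correlation-based segment colouring
#'
#' Assigns each segment a colour value in `[0, 1]` from the pairwise
#' correlations between segment mean spectra: the two segments with the
#' lowest correlation occupy the two extremes of the scale (0 and 1, the
#' lower-indexed one at 0), and the remaining segments are placed so that
#' segments with more similar average spectra receive closer colours. The
#' placement orders segments along a path with the minimal-correlation pair
#' at its ends, choosing (exhaustively, for up to 9 segments) the ordering
#' that minimizes the stress between colour distances and the
#' `1 - correlation` distances; colour values are cumulative path distances
#' rescaled to `[0, 1]`.
#'
#' @param result a [diana_rankcompete()] `segmentation_result`, or a plain
#'   matrix of segment mean spectra (rows = segments).
#' @return numeric colour per segment in `[0, 1]`.
#' @export
color_segments <- function(result) {
  means <- if (inherits(result, "segmentation_result")) result$segment_means
           else as.matrix(result)
  kseg <- nrow(means)
  if (kseg == 1) {
    warning("single segment: colour set to 0.5")
    return(0.5)
  }
  D <- correlation_distances(means)
  if (kseg == 2) return(c(0, 1))
  mx <- which(D == max(D), arr.ind = TRUE)
  mx <- mx[order(mx[, 1], mx[, 2]), , drop = FALSE]
  ends <- sort(c(mx[1, 1], mx[1, 2]))
  if (max(D) == 0) {
    warning("all segment mean spectra identical: colours set to 0.5")
    return(rep(0.5, kseg))
  }
  inner <- setdiff(seq_len(kseg), ends)
  path_positions <- function(ord) {
    cumsum(c(0, D[cbind(ord[-length(ord)], ord[-1])]))
  }
  stress <- function(ord) {
    pos <- path_positions(ord)
    pos_of <- numeric(kseg); pos_of[ord] <- pos
    s <- 0
    for (i in seq_len(kseg - 1)) for (j in (i + 1):kseg) {
      s <- s + (abs(pos_of[i] - pos_of[j]) - D[i, j])^2
    }
    s
  }
  orderings <- if (length(inner) <= 7) {
    perms <- permutations_of(inner)
    lapply(perms, function(p) c(ends[1], p, ends[2]))
  } else {
    # large-K fallback: intermediates sorted by distance to the first extreme
    list(c(ends[1], inner[order(D[ends[1], inner], inner)], ends[2]))
  }
  best <- orderings[[which.min(vapply(orderings, stress, numeric(1)))]]
  pos <- path_positions(best)
  if (max(pos) == 0) pos <- seq(0, 1, length.out = kseg)
  colours <- numeric(kseg)
  colours[best] <- pos / max(pos)
  colours
}

# All permutations of a vector (small n), in lexicographic order of indices.
permutations_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations_of(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

#' Principal components of the pixel matrix
#'
#' Mean-centred principal components analysis of the pixel-by-feature
#' matrix, the ordination applied to the preprocessed array data.
#'
#' @param matrix a `pixel_matrix` or plain numeric matrix.
#' @param n_components number of components to return, at most
#'   `min(pixels, features)`.
#' @return list with `scores` (pixels x components), `loadings`
#'   (features x components), `explained_variance` (component variances,
#'   non-increasing) and `explained_variance_ratio`.
#' @export
pca_embed <- function(matrix, n_components = 2) {
  values <- if (inherits(matrix, "pixel_matrix")) matrix$values else as.matrix(matrix)
  if (nrow(values) == 0 || ncol(values) == 0) stop("empty matrix")
  if (n_components > min(dim(values))) {
    stop("n_components must be <= min(pixels, features)")
  }
  p <- stats::prcomp(values, center = TRUE, scale. = FALSE)
  idx <- seq_len(n_components)
  var_all <- p$sdev^2
  list(scores = p$x[, idx, drop = FALSE],
       loadings = p$rotation[, idx, drop = FALSE],
       explained_variance = var_all[idx],
       explained_variance_ratio = var_all[idx] / sum(var_all))
}
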