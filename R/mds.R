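#' Leading-logFC multidimensional scaling of samples
#'
#' The between-sample distance is the root-mean-square of the `top_n`
#' largest absolute logCPM differences for that pair of samples (the
#' "leading log fold changes" - the genes that most distinguish the pair).
#' Samples are then embedded by classical MDS: double-centering of the
#' squared distance matrix, eigendecomposition, and coordinates scaled by
#' the square roots of the top `k` eigenvalues. The sign of each axis is
#' fixed by making the first sample's coordinate non-negative, so results
#' are deterministic.
#'
#' @param logcpm numeric matrix of log2 CPM values, genes x samples (e.g.
#'   `cpm(cm, log = TRUE)`).
#' @param top_n number of top gene differences per pair (default 500,
#'   capped at the number of genes).
#' @param k number of dimensions (default 2). If the distance matrix
#'   supports fewer positive eigenvalues, the result is truncated with a
#'   warning.
#' @return A list of class `"mds_result"`: `points` (samples x k),
#'   `eig` (eigenvalues), `distance` (the leading-logFC distance matrix).
#' @export
mds_leading_logfc <- function(logcpm, top_n = 500, k = 2) {
  ns <- ncol(logcpm)
  if (ns < 3L) stop("MDS needs at least 3 samples")
  top_n <- min(top_n, nrow(logcpm))
  d <- matrix(0, ns, ns, dimnames = list(colnames(logcpm),
                                         colnames(logcpm)))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      diffs <- abs(logcpm[, i] - logcpm[, j])
      lead <- sort(diffs, decreasing = TRUE)[seq_len(top_n)]
      d[i, j] <- d[j, i] <- sqrt(mean(lead ^ 2))
    }
  }
  fit <- cmdscale(as.dist(d), k = min(k, ns - 1L), eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive dimensions available; ",
            "requested ", k)
  }
  # deterministic axis orientation
  for (ax in seq_len(ncol(pts))) {
    if (pts[1L, ax] < 0) pts[, ax] <- -pts[, ax]
  }
  structure(list(points = pts, eig = fit$eig, distance = d),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat("Leading-logFC MDS of", nrow(x$points), "samples,",
      ncol(x$points), "dimensions\n")
  print(round(x$points, 4))
  invisible(x)
}

#' Scatter plot of an MDS embedding
#'
#' @param x an `"mds_result"`.
#' @param groups optional factor colouring the samples.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @method plot mds_result
#' @export
plot.mds_result <- function(x, groups = NULL, ...) {
  col <- if (is.null(groups)) 1L else as.integer(factor(groups)) + 1L
  plot(x$points[, 1L], x$points[, 2L], col = col, pch = 19,
       xlab = "Leading logFC dim 1", ylab = "Leading logFC dim 2", ...)
  text(x$points[, 1L], x$points[, 2L], rownames(x$points),
       pos = 3, cex = 0.8, col = col)
  invisible(x)
}
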