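#' Principal-component projection of a representation
#'
#' Projects mean-centered data onto its top principal components. To make
#' scores reproducible, each component's sign is fixed so that its
#' largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (rows = samples).
#' @param dims 1 or 2 output dimensions.
#' @param labels Optional aligned binary labels carried into the result.
#' @param source_space Tag recorded in the result (`"feature"`,
#'   `"latent"`, `"decoded"` or `"residual"`).
#' @return An object of class `"embedding"`: list with `coordinates`
#'   (rows x dims), `method = "pca"`, `labels`, `sdev` (component standard
#'   deviations) and `source_space`.
#' @export
pca_project <- function(x, dims = 2L, labels = NULL, source_space = "feature") {
  x <- as.matrix(x)
  dims <- as.integer(dims)
  stopifnot(dims %in% c(1L, 2L))
  if (nrow(x) < dims + 1L) stop("need at least dims + 1 rows", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite entries", call. = FALSE)
  if (all(apply(x, 2L, var) == 0)) stop("constant matrix has no principal components", call. = FALSE)
  p <- prcomp(x, center = TRUE, scale. = FALSE, rank. = dims)
  rot <- p$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1L))
  coords <- sweep(p$x[, seq_len(dims), drop = FALSE], 2L, flip, "*")
  structure(list(coordinates = coords, method = "pca", labels = labels,
                 sdev = p$sdev[seq_len(dims)], source_space = source_space),
            class = "embedding")
}

#' t-SNE projection of a representation
#'
#' Exact (quadratic-time) t-distributed stochastic neighbor embedding into
#' two dimensions, with perplexity calibrated per point by bisection,
#' early exaggeration, and momentum gradient descent. Purely a diagnostic
#' visualization: scores and model selection never depend on it.
#'
#' @param x Numeric matrix (rows = samples, at least 5).
#' @param seed Integer seed; identical input and seed give identical
#'   coordinates.
#' @param perplexity Target perplexity (default 30, clamped to
#'   `(rows - 1) / 3`).
#' @param max_iter Gradient-descent iterations (default 500).
#' @param labels,source_space Carried into the result, as in
#'   [pca_project()].
#' @return An `"embedding"` with rows x 2 `coordinates` and
#'   `method = "tsne"`.
#' @export
tsne_project <- function(x, seed = 1L, perplexity = 30, max_iter = 500L,
                         labels = NULL, source_space = "feature") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 5L) stop("t-SNE needs at least 5 rows", call. = FALSE)
  perplexity <- min(perplexity, (n - 1) / 3)
  if (perplexity < 2) {
    stop("too few rows for a usable perplexity; supply more samples", call. = FALSE)
  }
  P <- tsne_affinities(x, perplexity)
  coords <- with_seed(seed, {
    y <- matrix(rnorm(n * 2L, sd = 1e-4), n, 2L)
    vel <- y * 0
    eta <- 200
    for (iter in seq_len(max_iter)) {
      exag <- if (iter <= 100L) 12 else 1
      momentum <- if (iter <= 250L) 0.5 else 0.8
      d2 <- as.matrix(dist(y))^2
      qnum <- 1 / (1 + d2)
      diag(qnum) <- 0
      Q <- pmax(qnum / sum(qnum), 1e-12)
      W <- (exag * P - Q) * qnum
      grad <- 4 * (diag(rowSums(W)) %*% y - W %*% y)
      vel <- momentum * vel - eta * grad
      y <- y + vel
      y <- sweep(y, 2L, colMeans(y))
    }
    y
  })
  rownames(coords) <- rownames(x)
  structure(list(coordinates = coords, method = "tsne", labels = labels,
                 perplexity = perplexity, source_space = source_space),
            class = "embedding")
}

# Symmetrized high-dimensional affinities at a given perplexity.
tsne_affinities <- function(x, perplexity) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))  # Shannon entropy = log perplexity
      if (abs(h - target) < 1e-5) break
      if (h > target) {           # too flat -> sharpen
        lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else {
        hi <- beta
        beta <- (beta + lo) / 2
      }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Generalized contrast-to-noise ratio (GCNR) of two sample sets
#'
#' Builds equal-width histograms for the two samples over their pooled
#' min-max range, normalizes each histogram to sum 1, and returns
#' `1 - sum_i min(h_pos_i, h_neg_i)` — one minus the histogram overlap.
#' A score of 1 means the class distributions are perfectly separable, 0
#' that they coincide.
#'
#' @param samples_pos,samples_neg Non-empty numeric vectors (e.g. 1-D
#'   projection scores of the two classes).
#' @param bins Number of histogram bins over the pooled range (default
#'   100). The choice is not critical for well-sampled data; report it
#'   alongside the score.
#' @return GCNR score in `[0, 1]`.
#' @examples
#' gcnr(rnorm(1000, 3), rnorm(1000, 0))
#' @export
gcnr <- function(samples_pos, samples_neg, bins = 100L) {
  if (length(samples_pos) == 0L || length(samples_neg) == 0L) {
    stop("both sample sets must be non-empty", call. = FALSE)
  }
  pooled <- range(c(samples_pos, samples_neg))
  if (pooled[1L] == pooled[2L]) return(0)  # all mass in one bin: full overlap
  breaks <- seq(pooled[1L], pooled[2L], length.out = bins + 1L)
  h_pos <- tabulate(findInterval(samples_pos, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins)
  h_neg <- tabulate(findInterval(samples_neg, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = bins)
  ovl <- sum(pmin(h_pos / sum(h_pos), h_neg / sum(h_neg)))
  1 - ovl
}

#' 1D-PCA-GCNR separability score of a multivariate representation
#'
#' Projects the representation onto its first principal component and
#' scores the overlap of the two class distributions of the projected
#' scores with [gcnr()].
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels Binary 0/1 labels, both classes present.
#' @param bins Histogram bins for [gcnr()].
#' @param source_space Tag recorded in the report: `"feature"`,
#'   `"latent"`, `"decoded"` or `"residual"`.
#' @return An object of class `"separability_report"`: list with `gcnr`,
#'   `bins`, `n_pos`, `n_neg`, `source_space`.
#' @export
pca1d_gcnr <- function(x, labels, bins = 100L, source_space = "feature") {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    stop("labels must be 0/1 with both classes present", call. = FALSE)
  }
  emb <- pca_project(x, dims = 1L, labels = labels, source_space = source_space)
  scores <- emb$coordinates[, 1L]
  structure(list(gcnr = gcnr(scores[labels == 1L], scores[labels == 0L], bins = bins),
                 bins = as.integer(bins),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
                 source_space = source_space),
            class = "separability_report")
}

#' Separability of feature, decoded, and residual spaces of a fitted model
#'
#' Computes the 1D-PCA-GCNR score of the original feature space `X`, the
#' decoder output `X' = Dec(Enc(X))`, and the residual `X - X'`, all with
#' the same labels and bin count. A well-behaved joint fit concentrates
#' class information in the latent/decoded geometry and leaves a residual
#' that carries little class signal.
#'
#' @param object A `"deeplse"` fit.
#' @param newdata Feature matrix; defaults to the training data.
#' @param labels Binary labels aligned with `newdata`; defaults to the
#'   training labels.
#' @param bins Histogram bins for [gcnr()].
#' @return Named list of `"separability_report"`s: `feature`, `decoded`,
#'   `residual` (plus `latent` for convenience).
#' @export
residual_report <- function(object, newdata = object$x, labels = object$y,
                            bins = 100L) {
  stopifnot(inherits(object, "deeplse"))
  rec <- reconstruct(object, newdata)
  list(feature = pca1d_gcnr(newdata, labels, bins, "feature"),
       latent = pca1d_gcnr(encode_latent(object, newdata), labels, bins, "latent"),
       decoded = pca1d_gcnr(rec$decoded, labels, bins, "decoded"),
       residual = pca1d_gcnr(rec$residual, labels, bins, "residual"))
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("1D-PCA-GCNR [%s]: %.3f (%d bins, %d pos / %d neg)\n",
              x$source_space, x$gcnr, x$bins, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("%s embedding of %d samples into %d dimension(s) [%s]\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates), x$source_space))
  invisible(x)
}

#' Scatter plot of a 2-D embedding, colored by class
#'
#' @param x An `"embedding"` from [pca_project()] or [tsne_project()].
#' @param ... Passed to [plot()].
#' @export
plot.embedding <- function(x, ...) {
  co <- x$coordinates
  if (ncol(co) < 2L) co <- cbind(co, 0)
  cols <- if (is.null(x$labels)) "grey30" else ifelse(x$labels == 1L, "firebrick", "steelblue")
  plot(co[, 1L], co[, 2L], col = cols, pch = 19, cex = 0.6,
       xlab = paste(x$method, "1"), ylab = paste(x$method, "2"), ...)
  if (!is.null(x$labels)) {
    legend("topright", c("antioxidant", "non-antioxidant"), col = c("firebrick", "steelblue"),
           pch = 19, bty = "n")
  }
  invisible(x)
}

#' Export an embedding as a CSV table
#'
#' Columns: `id`, `dim1` (and `dim2`), `label`, `source_space`.
#'
#' @param embedding An `"embedding"`.
#' @param path Output CSV path.
#' @export
write_embedding <- function(embedding, path) {
  co <- embedding$coordinates
  df <- data.frame(id = rownames(co) %||% seq_len(nrow(co)), dim1 = co[, 1L])
  if (ncol(co) > 1L) df$dim2 <- co[, 2L]
  df$label <- if (is.null(embedding$labels)) NA_integer_ else embedding$labels
  df$source_space <- embedding$source_space
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
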