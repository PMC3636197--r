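# ---- principal-component chemical-space mapping ----

#' Fit a PCA chemical-space model
#'
#' Mean-centered principal component analysis of a descriptor matrix via
#' eigendecomposition of the sample covariance (through [stats::prcomp()]).
#' Descriptors are not scaled by default, matching the convention of
#' fitting chemical space on raw descriptor units so that high-variance
#' descriptors (molecular weight above all) dominate the leading
#' components. The sign of each component is fixed so that its
#' largest-magnitude loading is positive, making output reproducible
#' across eigensolvers.
#'
#' @param x numeric matrix or data frame of descriptors (rows = molecules);
#'   conventionally the eight-column panel in [DESCRIPTOR_COLS] order.
#' @param k number of components to retain (default 3).
#' @param scale divide columns by their standard deviation first
#'   (default `FALSE`).
#' @return object of class `np_pca`: `loadings` (p x k),
#'   `explained_variance_fraction` (length k),
#'   `explained_all` (all p fractions, summing to 1), `training_means`,
#'   `training_sd` (NULL unless `scale`), `k`.
#' @export
fit_pca <- function(x, k = 3, scale = FALSE) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("descriptor matrix must be numeric", call. = FALSE)
  if (k > ncol(x)) stop("k exceeds the number of descriptors", call. = FALSE)
  if (nrow(x) < k + 1) stop("need at least k+1 molecules", call. = FALSE)
  if (scale && any(apply(x, 2, stats::sd) == 0)) {
    stop("constant descriptor column cannot be scaled", call. = FALSE)
  }
  p <- stats::prcomp(x, center = TRUE, scale. = scale)
  expl <- p$sdev^2 / sum(p$sdev^2)
  load <- p$rotation[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive in each component
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  structure(list(loadings = load,
                 explained_variance_fraction = expl[seq_len(k)],
                 explained_all = expl,
                 training_means = p$center,
                 training_sd = if (scale) p$scale else NULL,
                 k = k),
            class = "np_pca")
}

#' @export
print.np_pca <- function(x, ...) {
  cat("PCA chemical-space model:", nrow(x$loadings), "descriptors,",
      x$k, "components\n")
  cat("explained variance fractions:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}

#' Project descriptors into a fitted chemical space
#'
#' @param model `np_pca` model from [fit_pca()].
#' @param x descriptor matrix with the same columns the model was fit on.
#' @return score matrix (rows = molecules, columns = components).
#' @export
pca_project <- function(model, x) {
  stopifnot(inherits(model, "np_pca"))
  x <- as.matrix(x)
  if (ncol(x) != nrow(model$loadings)) {
    stop("descriptor matrix has ", ncol(x), " columns; model expects ",
         nrow(model$loadings), call. = FALSE)
  }
  xc <- sweep(x, 2, model$training_means, "-")
  if (!is.null(model$training_sd)) xc <- sweep(xc, 2, model$training_sd, "/")
  xc %*% model$loadings
}

#' Chemical-space overlap of two score clouds
#'
#' Fraction of each cloud's points falling inside the axis-aligned
#' percentile bounding box (1st-99th by default) of the other cloud. The
#' percentile trim makes the box robust to the extreme outliers that large
#' compound libraries always contain.
#'
#' @param scores_a,scores_b score matrices with identical column count,
#'   each with at least 10 points.
#' @param lower,upper percentile bounds of the box (defaults 0.01, 0.99).
#' @return list with `fraction_a_in_b` and `fraction_b_in_a`, both in
#'   `[0, 1]`.
#' @export
chemspace_overlap <- function(scores_a, scores_b, lower = 0.01, upper = 0.99) {
  a <- as.matrix(scores_a); b <- as.matrix(scores_b)
  if (ncol(a) != ncol(b)) stop("score dimensionality differs", call. = FALSE)
  if (nrow(a) < 10 || nrow(b) < 10) {
    stop("need at least 10 points per cloud", call. = FALSE)
  }
  inside_box <- function(pts, ref) {
    lo <- apply(ref, 2, stats::quantile, probs = lower, names = FALSE)
    hi <- apply(ref, 2, stats::quantile, probs = upper, names = FALSE)
    ok <- rep(TRUE, nrow(pts))
    for (j in seq_len(ncol(pts))) {
      ok <- ok & pts[, j] >= lo[j] & pts[, j] <= hi[j]
    }
    mean(ok)
  }
  list(fraction_a_in_b = inside_box(a, b),
       fraction_b_in_a = inside_box(b, a))
}
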