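# Unsupervised chemometrics: PCA and the interclass PCA Monte-Carlo test.

#' Principal component analysis of a metabolite matrix
#'
#' Thin wrapper around the singular value decomposition with the scaling
#' conventions used throughout the package (mean centering plus unit
#' variance or Pareto scaling).
#'
#' @param x numeric matrix, samples x variables.
#' @param scale_mode `"uv"`, `"pareto"` or `"none"`.
#' @param center center columns before decomposition (default `TRUE`).
#' @return object of class `pca_model`: `scores`, `loadings` (orthonormal
#'   columns), `explained_variance` (percent, non-increasing), `sdev`,
#'   `center`, `scale`.
#' @export
fit_pca <- function(x, scale_mode = c("uv", "pareto", "none"), center = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (ncol(x) < 1L) stop("need at least 1 variable")
  sc <- .scale_matrix(x, match.arg(scale_mode), center = center)
  sv <- svd(sc$x)
  k <- length(sv$d)
  scores <- sv$u %*% diag(sv$d, k, k)
  dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(k)))
  dimnames(sv$v) <- list(colnames(x), paste0("PC", seq_len(k)))
  eig <- sv$d^2 / (nrow(x) - 1)
  structure(
    list(scores = scores, loadings = sv$v,
         explained_variance = 100 * eig / sum(eig),
         sdev = sqrt(eig), center = sc$center, scale = sc$scale,
         scale_mode = match.arg(scale_mode)),
    class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("PCA model:", nrow(x$scores), "samples,", nrow(x$loadings), "variables\n")
  ev <- utils::head(x$explained_variance, 5)
  cat("explained variance (%):", paste(sprintf("%.1f", ev), collapse = " "), "\n")
  invisible(x)
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  .apply_scaling(newdata, object$center, object$scale) %*% object$loadings
}

# Between-class inertia / total inertia for a processed matrix.
.interclass_stat <- function(xc, labels) {
  tot <- sum(xc^2)
  gm <- rowsum(xc, labels)                 # class sums
  ns <- as.vector(table(labels)[rownames(gm)])
  between <- sum((gm / ns)^2 * ns)
  between / tot
}

#' Interclass PCA Monte-Carlo test
#'
#' Tests whether a two-class grouping explains more of the total inertia of
#' the (centered, scaled) matrix than expected by chance, by permuting the
#' class labels. The statistic is the ratio of between-class inertia to
#' total inertia, in `[0, 1]`; the p-value uses the standard
#' add-one permutation estimator.
#'
#' @param x numeric matrix, samples x variables.
#' @param labels two-class factor/vector, one per sample, each class with
#'   at least 2 samples.
#' @param n_perm number of label permutations (default 999).
#' @param seed optional integer seed.
#' @param scale_mode column scaling, as in [fit_pca()].
#' @param pair optional pairing factor (e.g. horse id), one per sample.
#'   When given, permutations flip the two class labels within each pair
#'   instead of shuffling freely — the exchangeability structure of a
#'   paired design.
#' @return object of class `mc_test`: `statistic`, `p_value`, `perm_stats`.
#' @export
interclass_pca_test <- function(x, labels, n_perm = 999, seed = NULL,
                                scale_mode = c("uv", "pareto", "none"),
                                pair = NULL) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L)
    stop("labels must contain exactly two classes")
  if (any(table(labels) < 2L)) stop("each class needs at least 2 samples")
  if (!is.null(seed)) set.seed(seed)
  shuffle <- .label_shuffler(labels, pair)
  xc <- .scale_matrix(x, match.arg(scale_mode))$x
  obs <- .interclass_stat(xc, labels)
  perm <- vapply(seq_len(n_perm),
                 function(i) .interclass_stat(xc, shuffle()),
                 numeric(1))
  structure(
    list(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1),
         perm_stats = perm, n_perm = n_perm),
    class = "mc_test")
}

#' @export
print.mc_test <- function(x, ...) {
  cat("interclass inertia ratio:", format(x$statistic, digits = 4),
      " p =", format(x$p_value, digits = 4),
      sprintf("(%d permutations)\n", x$n_perm))
  invisible(x)
}

#' Per-peak one-way ANOVA with Bonferroni correction
#'
#' Univariate complement to the multivariate discrimination: a one-way
#' ANOVA per peak across the group labels, with Bonferroni-corrected
#' p-values (`min(1, p * m)` across the m peaks tested) and a significance
#' call at corrected p < 0.05. Peaks with zero within-group variance are
#' flagged degenerate with p = 0.
#'
#' @param peaks a [peak_table()] or numeric samples x peaks matrix.
#' @param labels group label per sample (2 or more groups).
#' @param alpha significance level on the corrected p-value.
#' @return data frame: `peak`, `F`, `p`, `p_corrected`, `significant`,
#'   `degenerate`.
#' @export
anova_bonferroni <- function(peaks, labels, alpha = 0.05) {
  x <- if (inherits(peaks, "peak_table")) peaks$intensities else as.matrix(peaks)
  if (is.null(colnames(x))) colnames(x) <- sprintf("pk%02d", seq_len(ncol(x)))
  labels <- as.factor(labels)
  k <- nlevels(droplevels(labels))
  if (k < 2L) stop("need at least 2 groups")
  n <- nrow(x)
  ns <- as.vector(table(labels))
  gs <- rowsum(x, labels)                   # group sums, k x p
  gm <- gs / ns
  grand <- colMeans(x)
  ssb <- colSums((gm - rep(grand, each = k))^2 * ns)
  sst <- colSums(sweep(x, 2L, grand, "-")^2)
  ssw <- sst - ssb
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  degenerate <- ssw < .Machine$double.eps^0.5 * pmax(sst, 1)
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  p[degenerate] <- 0
  m <- ncol(x)
  pc <- pmin(1, p * m)
  data.frame(peak = colnames(x), F = f, p = p, p_corrected = pc,
             significant = pc < alpha, degenerate = degenerate,
             row.names = NULL)
}
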