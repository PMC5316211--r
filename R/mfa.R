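# Multiple factor analysis of several omic tables measured on the same
# individuals, with RV coefficients between tables.

#' Fit a multiple factor analysis
#'
#' Three steps: (1) each table is centered/scaled and divided by the first
#' singular value of its own PCA, balancing the tables' variances; (2) the
#' weighted tables are concatenated into a grand table analyzed by a
#' non-normalized PCA; (3) each individual is projected separately with
#' each table (partial scores), whose average across tables is the global
#' (barycentric) score.
#'
#' @param tables named list of numeric matrices, samples x variables, with
#'   identical row sets and order.
#' @param center center columns within table (default `TRUE`).
#' @param scale unit-variance scale columns within table (default `TRUE`,
#'   the convention for quantitative groups).
#' @return object of class `mfa`: `global_scores` (samples x dims),
#'   `partial_scores` (list per table), `loadings` (grand-table right
#'   singular vectors), `variable_correlations` (variable x dims, the
#'   correlation of each original variable with each global dimension),
#'   `eigenvalues`, `explained_variance` (percent), `group_weights`
#'   (1/sigma1 per table), `group_contributions` (table x dims), `rv`
#'   (table x table RV matrix), `blocks` (variable index per table).
#' @export
fit_mfa <- function(tables, center = TRUE, scale = TRUE) {
  stopifnot(is.list(tables), length(tables) >= 1L)
  if (is.null(names(tables)))
    names(tables) <- paste0("table", seq_along(tables))
  n <- nrow(tables[[1L]])
  if (any(vapply(tables, nrow, 0L) != n))
    stop("all tables must share the same samples")
  rn <- rownames(tables[[1L]])
  for (k in seq_along(tables)) {
    if (!is.null(rn) && !is.null(rownames(tables[[k]])) &&
        !identical(rownames(tables[[k]]), rn))
      stop("sample order differs between tables")
  }
  mode <- if (scale) "uv" else "none"
  proc <- lapply(tables, function(x) .scale_matrix(x, mode, center = center)$x)
  sig1 <- vapply(proc, function(z) svd(z, nu = 0, nv = 0)$d[1L], numeric(1))
  if (any(sig1 < .Machine$double.eps)) stop("a table has rank 0")
  weighted <- Map(function(z, s) z / s, proc, sig1)
  grand <- do.call(cbind, weighted)
  sv <- svd(grand)
  keep <- sv$d > max(sv$d) * 1e-12
  d <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  dims <- paste0("Dim", seq_along(d))
  global <- u %*% diag(d, length(d), length(d))
  dimnames(global) <- list(rn, dims)
  nk <- length(tables)
  p_per <- vapply(weighted, ncol, 0L)
  block <- rep(seq_len(nk), p_per)
  partial <- vector("list", nk)
  names(partial) <- names(tables)
  contrib <- matrix(0, nk, length(d),
                    dimnames = list(names(tables), dims))
  for (k in seq_len(nk)) {
    vk <- v[block == k, , drop = FALSE]
    pk <- nk * weighted[[k]] %*% vk
    dimnames(pk) <- list(rn, dims)
    partial[[k]] <- pk
    contrib[k, ] <- colSums(vk^2)
  }
  varcor <- do.call(rbind, lapply(tables, function(x) {
    suppressWarnings(stats::cor(as.matrix(x), global))
  }))
  rv <- matrix(1, nk, nk, dimnames = list(names(tables), names(tables)))
  if (nk > 1L) {
    for (i in seq_len(nk - 1L)) for (j in (i + 1L):nk) {
      rv[i, j] <- rv[j, i] <- rv_coefficient(proc[[i]], proc[[j]])
    }
  }
  structure(
    list(global_scores = global, partial_scores = partial,
         loadings = v, variable_correlations = varcor,
         eigenvalues = d^2,
         explained_variance = 100 * d^2 / sum(d^2),
         group_weights = 1 / sig1,
         group_contributions = contrib,
         rv = rv, blocks = block, n_tables = nk,
         singular_values = d),
    class = "mfa")
}

#' @export
print.mfa <- function(x, ...) {
  cat("MFA:", x$n_tables, "tables,", nrow(x$global_scores), "samples\n")
  ev <- utils::head(x$explained_variance, 5)
  cat("explained variance (%):", paste(sprintf("%.1f", ev), collapse = " "), "\n")
  if (x$n_tables > 1L) {
    cat("RV matrix:\n")
    print(round(x$rv, 3))
  }
  invisible(x)
}

#' RV coefficient between two tables
#'
#' Matrix correlation in `[0, 1]`: the total co-inertia of the two
#' column-centered tables divided by the square root of the product of
#' their squared total inertias,
#' `trace(XX'YY') / sqrt(trace((XX')^2) trace((YY')^2))`. Moves toward 1
#' as the co-structure grows; 0 means no shared structure. Invariant to
#' orthogonal rotation and global rescaling of either table.
#'
#' @param x,y numeric matrices with the same rows (columns are centered
#'   internally).
#' @return RV coefficient in `[0, 1]`.
#' @export
rv_coefficient <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("tables must share the same samples")
  x <- sweep(x, 2L, colMeans(x), "-")
  y <- sweep(y, 2L, colMeans(y), "-")
  nx <- sum(crossprod(x)^2)
  ny <- sum(crossprod(y)^2)
  if (nx < .Machine$double.eps || ny < .Machine$double.eps)
    stop("RV coefficient undefined for a zero (or constant) matrix")
  sum(crossprod(x, y)^2) / sqrt(nx * ny)
}

#' High-weight variables on an MFA dimension
#'
#' Variables whose absolute correlation with the requested global
#' dimension strictly exceeds the threshold, sorted by decreasing
#' magnitude.
#'
#' @param m an [fit_mfa()] model.
#' @param dim dimension index (default 1).
#' @param threshold correlation magnitude cut (default 0.80, strict).
#' @return data frame `variable`, `correlation`, ordered by
#'   `|correlation|` descending, with attributes `dimension` and
#'   `threshold`.
#' @export
high_weight_variables <- function(m, dim = 1, threshold = 0.80) {
  stopifnot(inherits(m, "mfa"))
  if (dim < 1 || dim > ncol(m$variable_correlations))
    stop("dimension out of range")
  r <- m$variable_correlations[, dim]
  sel <- which(abs(r) > threshold)
  sel <- sel[order(-abs(r[sel]))]
  out <- data.frame(variable = rownames(m$variable_correlations)[sel],
                    correlation = unname(r[sel]), row.names = NULL)
  attr(out, "dimension") <- dim
  attr(out, "threshold") <- threshold
  out
}

#' Per-table contributions to the MFA dimensions
#'
#' Fraction of each dimension's inertia carried by each table; columns sum
#' to one across tables.
#'
#' @param m an [fit_mfa()] model.
#' @return matrix, tables x dimensions.
#' @export
group_contributions <- function(m) {
  stopifnot(inherits(m, "mfa"))
  m$group_contributions
}
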