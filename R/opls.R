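# OPLS: orthogonal signal correction + single predictive PLS component,
# with stratified k-fold cross-validation, permutation validation and
# jack-knife variable selection.
#
# The predictive weight w is proportional to X'y; orthogonal components are
# extracted from the predictive loading's y-uncorrelated remainder and
# deflated from X (NIPALS O-PLS). Deflation leaves X'y unchanged, so with
# zero orthogonal components the model is exactly one-component PLS.

.opls_core <- function(x, y, n_ortho) {
  w <- crossprod(x, y)
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps) stop("response is orthogonal to every predictor")
  w <- w / nw
  w_o <- p_o <- t_o <- NULL
  xf <- x
  if (n_ortho > 0) {
    for (i in seq_len(n_ortho)) {
      t1 <- xf %*% w
      p1 <- crossprod(xf, t1) / sum(t1^2)
      wo <- p1 - c(crossprod(w, p1)) * w
      nwo <- sqrt(sum(wo^2))
      if (nwo < 1e-10) break                 # nothing orthogonal left
      wo <- wo / nwo
      to <- xf %*% wo
      po <- crossprod(xf, to) / sum(to^2)
      xf <- xf - tcrossprod(to, po)
      w_o <- cbind(w_o, wo); p_o <- cbind(p_o, po); t_o <- cbind(t_o, to)
    }
  }
  t1 <- xf %*% w
  tt <- sum(t1^2)
  p1 <- crossprod(xf, t1) / tt
  q <- sum(y * t1) / tt
  list(w = c(w), p = c(p1), q = q, t = c(t1),
       w_ortho = w_o, p_ortho = p_o, t_ortho = t_o,
       fitted = c(t1) * q)
}

.opls_filter_new <- function(fit, xnew) {
  if (!is.null(fit$w_ortho)) {
    for (i in seq_len(ncol(fit$w_ortho))) {
      to <- xnew %*% fit$w_ortho[, i]
      xnew <- xnew - tcrossprod(to, fit$p_ortho[, i])
    }
  }
  xnew
}

# Map a two-class response to the -1/+1 coding (first sorted level = -1,
# so with T0/T1 labels a positive loading means higher at T1).
.code_y <- function(y) {
  if (is.numeric(y) && all(y %in% c(-1, 1)) && length(unique(y)) == 2L)
    return(list(y = as.numeric(y), levels = c("-1", "1")))
  f <- factor(y)
  if (nlevels(f) != 2L) stop("y must have exactly two classes")
  list(y = ifelse(as.integer(f) == 1L, -1, 1), levels = levels(f))
}

# Stratified fold assignment: within each class, shuffled round-robin.
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit an OPLS discriminant model
#'
#' Orthogonal projections to latent structures for a two-class response:
#' predictor variation orthogonal to the class vector is removed (orthogonal
#' signal correction), then a single predictive PLS component is fitted.
#' With `cv = TRUE` (default) a stratified k-fold cross-validation is run
#' and stored, providing Q2, RMSEP and per-fold predictive loadings for
#' jack-knife variable selection.
#'
#' @param x numeric matrix, samples x variables.
#' @param y two-class response (factor, or numeric -1/+1). The first sorted
#'   level is coded -1, so with T0/T1 labels a positive predictive loading
#'   marks a variable elevated at T1.
#' @param n_ortho number of orthogonal components to remove (default 1);
#'   `0` gives exactly one-component PLS.
#' @param scale_mode `"uv"` (default), `"pareto"` or `"none"`.
#' @param center center columns (default `TRUE`).
#' @param cv run and store k-fold cross-validation (default `TRUE`).
#' @param k number of CV folds (default 10, capped at the sample count).
#' @param seed integer seed for the CV fold assignment.
#' @return object of class `opls` with predictive weights/loadings/scores
#'   (`w`, `p`, `t`, `q`), orthogonal components (`w_ortho`, `p_ortho`,
#'   `t_ortho`), `R2`, and a `cv` element (`Q2`, `RMSEP`, `fold_loadings`,
#'   `predictions`) when `cv = TRUE`.
#' @export
fit_opls <- function(x, y, n_ortho = 1, scale_mode = c("uv", "pareto", "none"),
                     center = TRUE, cv = TRUE, k = 10, seed = NULL) {
  x <- as.matrix(x)
  scale_mode <- match.arg(scale_mode)
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  cy <- .code_y(y)
  sc <- .scale_matrix(x, scale_mode, center = center)
  if (n_ortho >= qr(sc$x)$rank)
    stop("n_ortho must be smaller than the rank of the predictor matrix")
  y_center <- mean(cy$y)
  yc <- cy$y - y_center
  fit <- .opls_core(sc$x, yc, n_ortho)
  r2 <- 1 - sum((yc - fit$fitted)^2) / sum(yc^2)
  m <- structure(
    c(fit,
      list(n_ortho = n_ortho, center = sc$center, scale = sc$scale,
           scale_mode = scale_mode, centered = center,
           y = cy$y, y_center = y_center, y_levels = cy$levels,
           R2 = r2, variables = colnames(x), cv = NULL)),
    class = "opls")
  if (cv) {
    m$cv <- cross_validate(x, y, n_ortho = n_ortho, k = min(k, nrow(x)),
                           seed = seed, scale_mode = scale_mode,
                           center = center)
  }
  m
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS model: 1 predictive + %d orthogonal component(s), %d variables\n",
              if (is.null(x$w_ortho)) 0L else ncol(x$w_ortho),
              length(x$w)))
  cat(sprintf("R2 = %.3f", x$R2))
  if (!is.null(x$cv))
    cat(sprintf("  Q2 = %.3f  RMSEP = %.3f (%d-fold CV)",
                x$cv$Q2, x$cv$RMSEP, x$cv$k))
  cat("\n")
  invisible(x)
}

#' @export
coef.opls <- function(object, ...) {
  stats::setNames(object$p, object$variables)
}

#' @export
summary.opls <- function(object, ...) {
  print(object)
  if (!is.null(object$cv)) {
    sel <- select_discriminant_variables(object)
    cat(sum(sel$selected), "of", nrow(sel),
        "variables with jack-knife CI excluding zero\n")
  }
  invisible(object)
}

#' Predict from an OPLS model
#'
#' @param object an [fit_opls()] model.
#' @param newdata samples x variables matrix with the training columns.
#' @param type `"response"` for the continuous score on the -1/+1 scale,
#'   `"class"` for the decoded class label.
#' @param ... unused.
#' @export
predict.opls <- function(object, newdata,
                         type = c("response", "class"), ...) {
  type <- match.arg(type)
  xn <- .apply_scaling(as.matrix(newdata), object$center, object$scale)
  xn <- .opls_filter_new(object, xn)
  yhat <- c(xn %*% object$w) * object$q + object$y_center
  if (type == "response") return(yhat)
  object$y_levels[ifelse(yhat >= 0, 2L, 1L)]
}

#' @export
residuals.opls <- function(object, ...) {
  object$y - (object$fitted + object$y_center)
}

#' Cross-validate an OPLS model
#'
#' Stratified k-fold cross-validation. Scaling and the orthogonal filter
#' are re-estimated inside each training fold (no leakage into the held-out
#' samples). Q2 = 1 - PRESS/TSS over the held-out predictions, with TSS the
#' total sum of squares of the coded response around its mean; RMSEP =
#' sqrt(PRESS/n).
#'
#' @inheritParams fit_opls
#' @return list with `R2` (full-data fit), `Q2`, `RMSEP`, `k`,
#'   `fold_loadings` (k x variables predictive loadings),
#'   `predictions` (held-out predictions in sample order), `folds`.
#' @export
cross_validate <- function(x, y, n_ortho = 1, k = 10, seed = NULL,
                           scale_mode = c("uv", "pareto", "none"),
                           center = TRUE) {
  x <- as.matrix(x)
  scale_mode <- match.arg(scale_mode)
  cy <- .code_y(y)
  n <- nrow(x)
  if (k > n) stop("k must not exceed the number of samples")
  if (!is.null(seed)) set.seed(seed)
  fold <- .stratified_folds(cy$y, k)
  yhat <- numeric(n)
  fl <- matrix(NA_real_, k, ncol(x),
               dimnames = list(NULL, colnames(x)))
  for (f in seq_len(k)) {
    test <- fold == f
    sc <- .scale_matrix(x[!test, , drop = FALSE], scale_mode, center = center)
    ytr <- cy$y[!test]
    fit <- .opls_core(sc$x, ytr - mean(ytr), n_ortho)
    fl[f, ] <- fit$p
    xt <- .apply_scaling(x[test, , drop = FALSE], sc$center, sc$scale)
    xt <- .opls_filter_new(fit, xt)
    yhat[test] <- c(xt %*% fit$w) * fit$q + mean(ytr)
  }
  press <- sum((cy$y - yhat)^2)
  tss <- sum((cy$y - mean(cy$y))^2)
  scf <- .scale_matrix(x, scale_mode, center = center)
  yc <- cy$y - mean(cy$y)
  full <- .opls_core(scf$x, yc, n_ortho)
  list(R2 = 1 - sum((yc - full$fitted)^2) / sum(yc^2),
       Q2 = 1 - press / tss,
       RMSEP = sqrt(press / n),
       k = k, fold_loadings = fl, predictions = yhat, folds = fold)
}

#' Permutation validation of an OPLS model
#'
#' The class labels are shuffled `n` times (the identity permutation is
#' excluded) and the full cross-validation is re-run for each replicate.
#' The p-value is the add-one fraction of permuted Q2 values at or above
#' the observed Q2; permuted R2/Q2/RMSEP are summarized as mean and sd.
#'
#' @inheritParams fit_opls
#' @param n number of permutations (default 1000).
#' @param pair optional pairing factor (e.g. horse id); permutations then
#'   flip labels within pairs, the valid scheme for paired cohorts.
#' @return object of class `opls_permtest`: `observed` (R2, Q2, RMSEP),
#'   `permuted` (n x 3 matrix), `p_value`, `summary` (mean and sd rows).
#' @export
permutation_validate <- function(x, y, n = 1000, seed = NULL, n_ortho = 1,
                                 k = 10, scale_mode = c("uv", "pareto", "none"),
                                 pair = NULL) {
  stopifnot(n >= 1)
  x <- as.matrix(x)
  scale_mode <- match.arg(scale_mode)
  if (!is.null(seed)) set.seed(seed)
  cy <- .code_y(y)
  shuffle <- .label_shuffler(cy$y, pair)
  k <- min(k, nrow(x))
  obs <- cross_validate(x, cy$y, n_ortho = n_ortho, k = k,
                        scale_mode = scale_mode)
  perm <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("R2", "Q2", "RMSEP")))
  for (i in seq_len(n)) {
    yp <- shuffle()
    tries <- 0L
    while (all(yp == cy$y) && tries < 100L) { yp <- shuffle(); tries <- tries + 1L }
    cvp <- cross_validate(x, yp, n_ortho = n_ortho, k = k,
                          scale_mode = scale_mode)
    perm[i, ] <- c(cvp$R2, cvp$Q2, cvp$RMSEP)
  }
  structure(
    list(observed = c(R2 = obs$R2, Q2 = obs$Q2, RMSEP = obs$RMSEP),
         permuted = perm,
         p_value = (1 + sum(perm[, "Q2"] >= obs$Q2)) / (n + 1),
         summary = rbind(mean = colMeans(perm), sd = apply(perm, 2, stats::sd)),
         n = n),
    class = "opls_permtest")
}

#' @export
print.opls_permtest <- function(x, ...) {
  cat(sprintf("observed: R2 = %.2f  Q2 = %.2f  RMSEP = %.2f\n",
              x$observed["R2"], x$observed["Q2"], x$observed["RMSEP"]))
  cat(sprintf("permuted (n = %d): R2 = %.2f +/- %.2f  Q2 = %.2f +/- %.2f  RMSEP = %.2f +/- %.2f\n",
              x$n,
              x$summary["mean", "R2"], x$summary["sd", "R2"],
              x$summary["mean", "Q2"], x$summary["sd", "Q2"],
              x$summary["mean", "RMSEP"], x$summary["sd", "RMSEP"]))
  cat("p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Select discriminant variables by jack-knife confidence interval
#'
#' A variable contributes to the discrimination when the jack-knife
#' confidence interval of its predictive loading, estimated across the
#' stored cross-validation folds, excludes zero. The loading sign gives the
#' direction (positive = elevated in the second class, T1 under the T0/T1
#' coding).
#'
#' @param m an [fit_opls()] model fitted with `cv = TRUE`.
#' @param ci_level confidence level (default 0.95).
#' @return data frame: `variable`, `loading` (full-model predictive
#'   loading), `lower`, `upper`, `direction` (`"up"`/`"down"` at the
#'   second class), `selected`.
#' @export
select_discriminant_variables <- function(m, ci_level = 0.95) {
  stopifnot(inherits(m, "opls"))
  if (is.null(m$cv)) stop("model was fitted without stored CV rounds")
  fl <- m$cv$fold_loadings
  k <- nrow(fl)
  mu <- colMeans(fl)
  se <- sqrt((k - 1) / k * colSums(sweep(fl, 2L, mu, "-")^2))
  # delete-fold estimates are strongly correlated, so the jack-knife
  # t-ratio has far fewer effective degrees of freedom than k - 1;
  # a conservative k/3 keeps the interval honest
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = max(2, floor(k / 3)))
  lower <- mu - tcrit * se
  upper <- mu + tcrit * se
  vars <- m$variables
  if (is.null(vars)) vars <- paste0("V", seq_along(mu))
  data.frame(variable = vars,
             loading = m$p,
             lower = lower, upper = upper,
             direction = ifelse(m$p > 0, "up", "down"),
             selected = lower * upper > 0,
             row.names = NULL)
}
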