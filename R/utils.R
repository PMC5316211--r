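# Internal helpers shared across modules.

# Column-process a numeric matrix for multivariate analysis.
# method: "uv" (unit variance), "pareto" (sqrt sd), "none".
# Returns list(x, center, scale). Constant columns under "uv" are an error
# because they carry no information and would divide by zero.
.scale_matrix <- function(x, method = c("uv", "pareto", "none"), center = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(x)
  ctr <- if (center) colMeans(x) else rep(0, ncol(x))
  xc <- sweep(x, 2L, ctr, "-")
  scl <- rep(1, ncol(x))
  if (method != "none") {
    sds <- sqrt(colSums(xc^2) / (nrow(xc) - 1))
    bad <- sds < .Machine$double.eps^0.5
    if (any(bad)) {
      nm <- colnames(x)[bad]
      if (is.null(nm)) nm <- which(bad)
      stop("constant variable(s) under '", method, "' scaling: ",
           paste(utils::head(nm, 5), collapse = ", "))
    }
    scl <- if (method == "uv") sds else sqrt(sds)
    xc <- sweep(xc, 2L, scl, "/")
  }
  list(x = xc, center = ctr, scale = scl)
}

# Apply a stored center/scale to new data.
.apply_scaling <- function(x, center, scale) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

# Deterministic per-stage seed derivation from one top-level seed.
# Keeps results within 32-bit integer range.
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483629L)
}

# Returns a closure producing permuted class labels: free shuffling, or
# within-pair label flips when a pairing factor is supplied (the valid
# exchangeability structure for paired cohorts).
.label_shuffler <- function(labels, pair = NULL) {
  if (is.null(pair)) return(function() sample(labels))
  pair <- as.factor(pair)
  stopifnot(length(pair) == length(labels))
  idx <- split(seq_along(labels), pair)
  if (any(lengths(idx) != 2L))
    stop("each pair must contain exactly 2 samples")
  if (any(vapply(idx, function(i) labels[i[1]] == labels[i[2]], logical(1))))
    stop("each pair must contain one sample of each class")
  function() {
    out <- labels
    flip <- stats::runif(length(idx)) < 0.5
    for (j in which(flip)) out[idx[[j]]] <- out[rev(idx[[j]])]
    out
  }
}

# Trapezoidal integral of y over x (both sorted by x).
.trapz <- function(x, y) {
  n <- length(x)
  if (n == 1L) return(y)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Benjamini-Hochberg step-up adjustment (module surface; delegates to the
# reference implementation in stats).
#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a p-value vector. Order
#' preserving with the input; values are capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`. `NaN` is rejected.
#' @return vector of BH-adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.nan(p))) stop("NaN p-values are not allowed")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
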