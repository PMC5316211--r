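# Regulatory impact factors: differential co-expression scoring of
# candidate regulators (TFs and miRNAs) against the DE gene set.
#
# Condition 1 is T0 and condition 2 is T1 throughout, so a positive
# phenotype impact factor means the gene is more abundant at T0.

#' Phenotype impact factor of DE genes
#'
#' `PIF_j = a_j * d_j`, the product of a gene's average abundance across
#' the two conditions, `a_j = (e1_j + e2_j)/2`, and its expression
#' difference, `d_j = e1_j - e2_j` (condition means on the log2 scale).
#'
#' @param expr_c1,expr_c2 samples x genes matrices for the two conditions.
#' @param genes gene ids to score (default: all shared columns).
#' @return named numeric vector of PIF values.
#' @export
compute_pif <- function(expr_c1, expr_c2, genes = NULL) {
  expr_c1 <- as.matrix(expr_c1); expr_c2 <- as.matrix(expr_c2)
  if (is.null(genes)) genes <- intersect(colnames(expr_c1), colnames(expr_c2))
  missing <- setdiff(genes, intersect(colnames(expr_c1), colnames(expr_c2)))
  if (length(missing))
    stop("gene(s) absent from a condition: ", paste(missing, collapse = ", "))
  e1 <- colMeans(expr_c1[, genes, drop = FALSE])
  e2 <- colMeans(expr_c2[, genes, drop = FALSE])
  (e1 + e2) / 2 * (e1 - e2)
}

# Correlation of each regulator with each DE gene within one condition;
# constant regulators get zero correlations with a warning.
.reg_cor <- function(reg, de) {
  flat <- apply(reg, 2L, stats::sd) < .Machine$double.eps
  r <- suppressWarnings(stats::cor(reg, de))
  if (any(flat)) {
    warning(sum(flat), " constant regulator(s) in a condition; ",
            "their correlations set to 0")
  }
  r[is.na(r)] <- 0
  r
}

#' Regulatory impact factor scores
#'
#' For each regulator f and the DE genes j, with per-condition Pearson
#' correlations `r1`, `r2` and differential co-expression
#' `dCo = r1 - r2`:
#' `RIF1_f = mean_j( PIF_j * dCo_fj^2 )` rewards regulators consistently
#' differentially co-expressed with abundant, strongly changing genes;
#' `RIF2_f = mean_j( (e1_j * r1_fj)^2 - (e2_j * r2_fj)^2 )` captures the
#' change in the regulator's ability to predict DE-gene abundance. Both
#' raw scores are z-standardized across regulators.
#'
#' @param expr_c1,expr_c2 samples x genes expression matrices for
#'   condition 1 (T0) and condition 2 (T1), log2 scale, at least 3 samples
#'   each.
#' @param de_genes character vector of DE gene ids (columns of the
#'   expression matrices).
#' @param regulators character vector of candidate regulator ids; looked
#'   up among the gene columns and, if supplied, the extra matrices.
#' @param extra_c1,extra_c2 optional samples x features matrices carrying
#'   regulators measured on another platform (e.g. miRNAs), rows aligned
#'   with the condition's samples.
#' @param kind optional named vector labelling each regulator (e.g.
#'   `"tf"`/`"mirna"`), carried into the output.
#' @return data frame of class `rif_scores`: `regulator`, `kind`,
#'   `rif1_raw`, `rif2_raw`, `rif1_z`, `rif2_z`, sorted as supplied.
#' @export
compute_rif <- function(expr_c1, expr_c2, de_genes, regulators,
                        extra_c1 = NULL, extra_c2 = NULL, kind = NULL) {
  expr_c1 <- as.matrix(expr_c1); expr_c2 <- as.matrix(expr_c2)
  if (length(de_genes) == 0L) stop("no DE genes to score against")
  if (nrow(expr_c1) < 3L || nrow(expr_c2) < 3L)
    stop("need at least 3 samples per condition")
  de_genes <- intersect(de_genes, intersect(colnames(expr_c1),
                                            colnames(expr_c2)))
  if (length(de_genes) == 0L) stop("DE genes not found in expression matrices")
  pool1 <- expr_c1
  pool2 <- expr_c2
  if (!is.null(extra_c1)) {
    stopifnot(nrow(extra_c1) == nrow(expr_c1),
              nrow(extra_c2) == nrow(expr_c2))
    pool1 <- cbind(pool1, as.matrix(extra_c1))
    pool2 <- cbind(pool2, as.matrix(extra_c2))
  }
  missing <- setdiff(regulators, intersect(colnames(pool1), colnames(pool2)))
  if (length(missing))
    stop("regulator(s) not measured: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
  de1 <- expr_c1[, de_genes, drop = FALSE]
  de2 <- expr_c2[, de_genes, drop = FALSE]
  e1 <- colMeans(de1); e2 <- colMeans(de2)
  pif <- (e1 + e2) / 2 * (e1 - e2)
  r1 <- .reg_cor(pool1[, regulators, drop = FALSE], de1)
  r2 <- .reg_cor(pool2[, regulators, drop = FALSE], de2)
  dco <- r1 - r2
  n_de <- length(de_genes)
  rif1 <- c(dco^2 %*% pif) / n_de
  rif2 <- c(r1^2 %*% e1^2 - r2^2 %*% e2^2) / n_de
  z <- function(v) if (length(v) > 1L && stats::sd(v) > 0)
    (v - mean(v)) / stats::sd(v) else rep(0, length(v))
  out <- data.frame(regulator = regulators,
                    kind = if (is.null(kind)) NA_character_ else
                      unname(kind[regulators]),
                    rif1_raw = rif1, rif2_raw = rif2,
                    rif1_z = z(rif1), rif2_z = z(rif2),
                    row.names = NULL)
  class(out) <- c("rif_scores", "data.frame")
  out
}

#' @export
print.rif_scores <- function(x, n = 10, ...) {
  cat("RIF scores for", nrow(x), "regulators",
      "(condition 1 = T0, condition 2 = T1; positive PIF = higher at T0)\n")
  top <- x[order(-pmax(abs(x$rif1_z), abs(x$rif2_z))), ]
  print.data.frame(utils::head(top, n), digits = 3)
  invisible(x)
}
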