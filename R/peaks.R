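# NMR metabolite peak tables: construction, filtering, assignment, areas.

#' Construct a peak table
#'
#' A peak table holds one row per sample and one column per NMR peak, with
#' the chemical shift (ppm) of each peak and, optionally, the ppm window the
#' peak spans. Intensities are normalized areas in arbitrary units.
#'
#' @param intensities numeric matrix, samples x peaks, non-negative. Row
#'   names are sample ids, column names peak ids (generated when absent).
#' @param ppm numeric vector of chemical shifts, one per peak, in `[0, 12]`.
#' @param ppm_range optional two-column matrix (low, high) per peak.
#' @return an object of class `peak_table` with elements `sample_ids`,
#'   `peak_ids`, `intensities`, `ppm`, `ppm_range`.
#' @export
peak_table <- function(intensities, ppm, ppm_range = NULL) {
  intensities <- as.matrix(intensities)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- sprintf("s%02d", seq_len(nrow(intensities)))
  if (is.null(colnames(intensities)))
    colnames(intensities) <- sprintf("pk%02d", seq_len(ncol(intensities)))
  if (ncol(intensities) != length(ppm))
    stop("length(ppm) must equal the number of peak columns")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (any(ppm < 0 | ppm > 12)) stop("ppm outside the plausible [0, 12] window")
  if (anyDuplicated(colnames(intensities)))
    stop("duplicate peak ids")
  if (!is.null(ppm_range)) {
    ppm_range <- as.matrix(ppm_range)
    stopifnot(nrow(ppm_range) == ncol(intensities), ncol(ppm_range) == 2L)
    if (any(ppm_range[, 1L] > ppm_range[, 2L]))
      stop("ppm_range low must not exceed high")
  }
  structure(
    list(sample_ids = rownames(intensities),
         peak_ids = colnames(intensities),
         intensities = intensities,
         ppm = stats::setNames(as.numeric(ppm), colnames(intensities)),
         ppm_range = ppm_range),
    class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat("peak_table:", length(x$sample_ids), "samples x",
      length(x$peak_ids), "peaks\n")
  if (length(x$peak_ids))
    cat("ppm range:", format(min(x$ppm), digits = 4), "-",
        format(max(x$ppm), digits = 4), "\n")
  invisible(x)
}

.subset_peaks <- function(t, keep) {
  peak_table(t$intensities[, keep, drop = FALSE],
             t$ppm[keep],
             if (is.null(t$ppm_range)) NULL else t$ppm_range[keep, , drop = FALSE])
}

#' Filter peaks by detection
#'
#' Removes single mass events (peaks with exactly one non-zero intensity)
#' and peaks detected in fewer than `min_detect_frac` of samples. The 50%
#' default threshold is inclusive: a peak detected in exactly that fraction
#' of samples is retained. "Detected" means intensity strictly above
#' `detect_floor` (default 0).
#'
#' @param t a [peak_table()].
#' @param min_detect_frac minimum fraction of samples a peak must be
#'   detected in, in `(0, 1]`.
#' @param detect_floor intensity at or below which a measurement counts as
#'   undetected.
#' @return a `peak_table` with the surviving peaks, sample set and peak
#'   order unchanged.
#' @export
filter_peaks <- function(t, min_detect_frac = 0.5, detect_floor = 0) {
  stopifnot(inherits(t, "peak_table"))
  if (length(t$peak_ids) == 0L || length(t$sample_ids) == 0L)
    stop("empty peak table")
  if (min_detect_frac <= 0 || min_detect_frac > 1)
    stop("min_detect_frac must lie in (0, 1]")
  n_detect <- colSums(t$intensities > detect_floor)
  keep <- n_detect != 1L & n_detect >= min_detect_frac * nrow(t$intensities)
  if (!any(keep)) warning("all peaks removed by detection filtering")
  .subset_peaks(t, keep)
}

#' Assign peaks to reference chemical shifts
#'
#' Each peak is matched to the reference entry minimizing the absolute ppm
#' difference; the match is accepted when that difference is at most
#' `tol_ppm`, otherwise the peak is "unassigned". Distance ties are broken
#' toward the lower reference ppm. Relative abundances (peak areas) are
#' computed for every peak via [peak_area()].
#'
#' @param t a [peak_table()].
#' @param ref data frame with columns `metabolite`, `reference_ppm` (and
#'   optionally `multiplicity`).
#' @param tol_ppm shift tolerance in ppm (default 0.005).
#' @return `t` with added elements `assignment` (metabolite name or
#'   `"unassigned"` per peak) and `relative_abundance` (samples x peaks).
#' @export
assign_peaks <- function(t, ref, tol_ppm = 0.005) {
  stopifnot(inherits(t, "peak_table"), tol_ppm > 0)
  assignment <- rep("unassigned", length(t$peak_ids))
  if (is.null(ref) || nrow(ref) == 0L) {
    warning("empty reference table: all peaks unassigned")
  } else {
    ord <- order(ref$reference_ppm)          # lower ppm wins ties
    rppm <- ref$reference_ppm[ord]
    rname <- as.character(ref$metabolite)[ord]
    for (i in seq_along(t$ppm)) {
      d <- abs(t$ppm[i] - rppm)
      j <- which.min(d)                      # first minimum = lower ref ppm
      if (d[j] <= tol_ppm) assignment[i] <- rname[j]
    }
  }
  names(assignment) <- t$peak_ids
  t$assignment <- assignment
  ra <- vapply(t$peak_ids, function(pk) peak_area(t, pk),
               numeric(length(t$sample_ids)))
  if (is.null(dim(ra))) ra <- matrix(ra, nrow = length(t$sample_ids),
                                     dimnames = list(t$sample_ids, t$peak_ids))
  t$relative_abundance <- ra
  class(t) <- c("assigned_peak_table", "peak_table")
  t
}

#' Per-sample peak area
#'
#' When the peak has a ppm window, the area is the trapezoidal integral of
#' the intensities of all peaks whose ppm falls inside that window, taken
#' along the ppm axis. Without a window the stored intensity is already a
#' binned area and is returned as is.
#'
#' @param t a [peak_table()].
#' @param peak_id a peak id present in `t`.
#' @return numeric vector of per-sample areas, named by sample id.
#' @export
peak_area <- function(t, peak_id) {
  stopifnot(inherits(t, "peak_table"))
  j <- match(peak_id, t$peak_ids)
  if (is.na(j)) stop("unknown peak id: ", peak_id)
  if (is.null(t$ppm_range) || any(is.na(t$ppm_range[j, ]))) {
    return(stats::setNames(t$intensities[, j], t$sample_ids))
  }
  lo <- t$ppm_range[j, 1L]; hi <- t$ppm_range[j, 2L]
  idx <- which(t$ppm >= lo & t$ppm <= hi)
  idx <- idx[order(t$ppm[idx])]
  if (length(idx) <= 1L)
    return(stats::setNames(t$intensities[, j], t$sample_ids))
  area <- apply(t$intensities[, idx, drop = FALSE], 1L,
                function(y) .trapz(t$ppm[idx], y))
  stats::setNames(area, t$sample_ids)
}

#' Total-area normalization
#'
#' Scales each sample's intensities so every row sums to `total`.
#'
#' @param t a [peak_table()].
#' @param total target row sum (default 100).
#' @return a normalized `peak_table`.
#' @export
normalize_total_area <- function(t, total = 100) {
  stopifnot(inherits(t, "peak_table"))
  rs <- rowSums(t$intensities)
  if (any(rs <= 0)) stop("samples with zero total intensity cannot be normalized")
  t$intensities <- t$intensities / rs * total
  t
}
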