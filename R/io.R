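# Plain-text serialization of the pipeline's data structures.

#' Write / read a peak table as CSV
#'
#' `peaks.csv` holds `sample_id` plus one intensity column per peak; the
#' sidecar `peaks_meta.csv` holds `peak_id, ppm, ppm_low, ppm_high`.
#'
#' @param t a [peak_table()].
#' @param path path of `peaks.csv`; the sidecar is written next to it.
#' @return the main path, invisibly.
#' @export
write_peaks <- function(t, path) {
  stopifnot(inherits(t, "peak_table"))
  df <- data.frame(sample_id = t$sample_ids, t$intensities,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- data.frame(peak_id = t$peak_ids, ppm = unname(t$ppm),
                     ppm_low = if (is.null(t$ppm_range)) NA else t$ppm_range[, 1],
                     ppm_high = if (is.null(t$ppm_range)) NA else t$ppm_range[, 2])
  utils::write.csv(meta, sub("\\.csv$", "_meta.csv", path), row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- utils::read.csv(sub("\\.csv$", "_meta.csv", path))
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$sample_id
  rng <- if (all(is.na(meta$ppm_low))) NULL else
    cbind(meta$ppm_low, meta$ppm_high)
  peak_table(x, meta$ppm, rng)
}

#' Write / read an expression matrix as TSV
#'
#' Samples x features orientation with a leading `sample_id` column;
#' `orient = "features"` transposes on the way in/out.
#'
#' @param x samples x features numeric matrix.
#' @param path TSV path.
#' @param orient `"samples"` (rows are samples) or `"features"`.
#' @export
write_expression <- function(x, path, orient = c("samples", "features")) {
  orient <- match.arg(orient)
  if (orient == "features") x <- t(x)
  df <- data.frame(sample_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path, orient = c("samples", "features")) {
  orient <- match.arg(orient)
  df <- utils::read.delim(path, check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df[[1]]
  if (orient == "features") x <- t(x)
  x
}

#' Write / read a pathway database as JSON
#'
#' Format: `{pathway_id: {name, genes: [...], metabolites: [...],
#' edges: [[src, dst], ...]}}`.
#'
#' @param db a [pathway_db()].
#' @param path JSON path.
#' @export
write_pathway_db <- function(db, path) {
  stopifnot(inherits(db, "pathway_db"))
  obj <- lapply(db$pathways, function(p) {
    list(name = p$name, genes = p$genes, metabolites = p$metabolites,
         edges = if (nrow(p$edges)) unname(apply(p$edges, 1L, c, simplify = FALSE))
                 else list())
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_pathway_db
#' @export
read_pathway_db <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  pathway_db(lapply(obj, function(p) {
    list(name = p$name, genes = as.character(p$genes),
         metabolites = as.character(p$metabolites),
         edges = if (length(p$edges))
           do.call(rbind, lapply(p$edges, as.character))
         else matrix(character(0), 0, 2))
  }))
}

#' Write / read ground truth as JSON
#' @param truth the `truth` element of [generate_cohort()].
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, pretty = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$metabolite_gene_pairs <- as.data.frame(tr$metabolite_gene_pairs)
  tr$regulator_targets <- as.data.frame(tr$regulator_targets)
  tr$metabolite_direction <- unlist(tr$metabolite_direction)
  tr
}
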