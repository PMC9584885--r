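# Shared data model: abundance matrices, gene set collections, sample alignment.

#' Construct a features x samples abundance matrix
#'
#' `omics_matrix` is the package's container for log2-scale abundance data
#' (proteins or transcripts): a numeric matrix with unique feature row names
#' and sample column names, plus optional per-feature metadata (gene symbol,
#' genomic location, feature class). Missing values are `NA`; infinite values
#' are rejected. Genomic intervals in `feature_meta` are stored 0-based
#' half-open internally (file readers/writers convert from/to the 1-based
#' closed convention used on disk).
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames set.
#' @param feature_meta optional `data.frame` with columns `feature_id`,
#'   `gene_symbol`, `chromosome`, `start`, `end` and optionally `class`;
#'   one row per feature, matched by `feature_id`.
#' @return An object of class `omics_matrix`: list with elements `values`
#'   and `feature_meta`.
#' @export
omics_matrix <- function(values, feature_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) stopf("'values' must have row and column names")
  if (anyDuplicated(fid)) {
    stopf("duplicate feature_id: %s", fid[duplicated(fid)][1L])
  }
  if (anyDuplicated(sid)) {
    stopf("duplicate sample_id: %s", sid[duplicated(sid)][1L])
  }
  if (any(is.infinite(values))) stopf("'values' must be finite or NA")
  if (!is.null(feature_meta)) {
    if (!all(c("feature_id") %in% names(feature_meta))) {
      stopf("feature_meta must contain a 'feature_id' column")
    }
    if (!setequal(feature_meta$feature_id, fid)) {
      stopf("feature_meta does not match matrix features")
    }
    feature_meta <- feature_meta[match(fid, feature_meta$feature_id), , drop = FALSE]
    rownames(feature_meta) <- NULL
  }
  structure(list(values = values, feature_meta = feature_meta),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

sample_ids <- function(x) colnames(x$values)
feature_ids <- function(x) rownames(x$values)

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (feature/gene identifiers).
#' @param descriptions optional character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) stopf("sets must be named")
  if (anyDuplicated(names(sets))) stopf("duplicate set names")
  for (nm in names(sets)) {
    if (length(sets[[nm]]) == 0L) stopf("gene set '%s' is empty", nm)
    if (anyDuplicated(sets[[nm]])) {
      warnf("gene set '%s' contains duplicate members; deduplicated", nm)
      sets[[nm]] <- unique(sets[[nm]])
    }
  }
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets (sizes %s)\n", length(x$sets),
              paste(vapply(x$sets, length, integer(1)), collapse = ", ")))
  invisible(x)
}

#' Restrict omics components to a common ordered sample list
#'
#' Aligns any mix of `omics_matrix` objects, sample-annotated data frames
#' (with a `sample_id` column), and splice event tables to the same ordered
#' set of samples. Idempotent; errors if a requested sample is absent from
#' any component.
#'
#' @param components named list of components to align.
#' @param samples character vector of sample identifiers (order preserved).
#' @return list of aligned components, in input order.
#' @export
subset_align <- function(components, samples) {
  stopifnot(is.list(components), length(samples) > 0)
  lapply(components, function(x) {
    if (inherits(x, "omics_matrix")) {
      missing <- setdiff(samples, sample_ids(x))
      if (length(missing)) stopf("unknown sample id: %s", missing[1L])
      omics_matrix(x$values[, samples, drop = FALSE], x$feature_meta)
    } else if (inherits(x, "splice_event_table")) {
      subset_events(x, samples)
    } else if (is.data.frame(x) && "sample_id" %in% names(x)) {
      missing <- setdiff(samples, x$sample_id)
      if (length(missing)) stopf("unknown sample id: %s", missing[1L])
      out <- x[match(samples, x$sample_id), , drop = FALSE]
      rownames(out) <- NULL
      out
    } else if (is.matrix(x)) {
      missing <- setdiff(samples, colnames(x))
      if (length(missing)) stopf("unknown sample id: %s", missing[1L])
      x[, samples, drop = FALSE]
    } else {
      stopf("cannot align component of class %s", paste(class(x), collapse = "/"))
    }
  })
}
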