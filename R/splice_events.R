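# Splice event container: per-event inclusion/skip junction counts.

#' Construct a splice event table
#'
#' Holds exon-centric alternative splicing events with per-sample inclusion
#' and skip junction counts plus effective lengths, the inputs for PSI
#' quantification.
#'
#' @param events data.frame with columns `event_id`, `category` (one of
#'   SE, A3SS, A5SS, RI, MXE), `incl_len`, `skip_len`.
#' @param incl,skip integer matrices events x samples of inclusion and skip
#'   junction counts, with matching dimnames.
#' @return An object of class `splice_event_table`.
#' @export
splice_event_table <- function(events, incl, skip) {
  need <- c("event_id", "category", "incl_len", "skip_len")
  if (!all(need %in% names(events))) {
    stopf("events table must have columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(events$event_id)) stopf("duplicate event_id")
  bad_cat <- setdiff(unique(events$category), c("SE", "A3SS", "A5SS", "RI", "MXE"))
  if (length(bad_cat)) stopf("unknown event category: %s", bad_cat[1L])
  if (any(events$incl_len <= 0) || any(events$skip_len <= 0)) {
    stopf("effective lengths must be positive")
  }
  for (nm in c("incl", "skip")) {
    m <- get(nm)
    if (!is.matrix(m) || nrow(m) != nrow(events)) {
      stopf("'%s' must be an events x samples matrix", nm)
    }
    if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
      bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)[1L, ]
      stopf("schema error: %s counts must be non-negative integers (event %s, sample %s)",
            nm, rownames(m)[bad[1L]] %||% bad[1L], colnames(m)[bad[2L]] %||% bad[2L])
    }
  }
  if (!identical(colnames(incl), colnames(skip))) stopf("incl/skip sample order mismatch")
  rownames(incl) <- rownames(skip) <- events$event_id
  structure(list(events = events, incl = incl, skip = skip),
            class = "splice_event_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.splice_event_table <- function(x, ...) {
  cat(sprintf("splice_event_table: %d events x %d samples (%s)\n",
              nrow(x$events), ncol(x$incl),
              paste(names(table(x$events$category)),
                    table(x$events$category), sep = ":", collapse = " ")))
  invisible(x)
}

subset_events <- function(x, samples) {
  missing <- setdiff(samples, colnames(x$incl))
  if (length(missing)) stopf("unknown sample id: %s", missing[1L])
  splice_event_table(x$events,
                     x$incl[, samples, drop = FALSE],
                     x$skip[, samples, drop = FALSE])
}
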