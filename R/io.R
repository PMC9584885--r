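# Readers and writers for the package's plain-text interchange formats.
# All tables are tab-separated; missing values are literal "NA". Genomic
# intervals are 1-based closed on disk and 0-based half-open in memory.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stopf("missing file: %s", path)
  lines <- readLines(path)
  if (!length(lines)) stopf("empty file: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields[[1L]])
  bad <- which(vapply(fields, length, integer(1)) != n)
  if (length(bad)) stopf("ragged row %d in %s", bad[1L], path)
  fields
}

parse_numeric_cell <- function(x, path, row, col) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & x != "NA")
  if (length(bad)) {
    stopf("schema error in %s: non-numeric cell at row %d, column %s",
          path, row[bad[1L]], col[bad[1L]])
  }
  out
}

#' Read a feature x sample abundance matrix from TSV
#'
#' Expects a header `feature_id<TAB>sample1<TAB>...`; cells are numeric or
#' `NA`. Duplicate feature or sample identifiers and ragged or non-numeric
#' rows are rejected with the offending location.
#'
#' @param path matrix TSV path.
#' @param meta_path optional feature metadata TSV
#'   (`feature_id, gene_symbol, chromosome, start, end[, class]`).
#' @return An [omics_matrix()].
#' @export
load_matrix <- function(path, meta_path = NULL) {
  fields <- read_tsv_strict(path)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stopf("duplicate sample_id in %s: %s", path, samples[duplicated(samples)][1L])
  }
  body <- fields[-1L]
  fid <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(fid)) {
    stopf("duplicate feature_id in %s: %s", path, fid[duplicated(fid)][1L])
  }
  vals <- matrix(NA_real_, length(body), length(samples),
                 dimnames = list(fid, samples))
  for (i in seq_along(body)) {
    cells <- body[[i]][-1L]
    vals[i, ] <- parse_numeric_cell(cells, path, rep(i + 1L, length(cells)), samples)
  }
  meta <- if (!is.null(meta_path)) load_feature_meta(meta_path) else NULL
  omics_matrix(vals, meta)
}

load_feature_meta <- function(path) {
  meta <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("feature_id", "gene_symbol", "chromosome", "start", "end")
  if (!all(need %in% names(meta))) {
    stopf("feature metadata %s must have columns %s", path, paste(need, collapse = ", "))
  }
  # 1-based closed -> 0-based half-open
  meta$start <- meta$start - 1L
  meta
}

write_feature_meta <- function(meta, path) {
  out <- meta
  out$start <- out$start + 1L  # back to 1-based closed
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write an abundance matrix (and metadata) to TSV
#'
#' @param x an [omics_matrix()].
#' @param path output matrix TSV path.
#' @param meta_path optional output path for feature metadata.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, meta_path = NULL) {
  df <- data.frame(feature_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path) && !is.null(x$feature_meta)) {
    write_feature_meta(x$feature_meta, meta_path)
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#' Lines with fewer than three fields are rejected; duplicate members within
#' a line are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return A [gene_set_collection()].
#' @export
load_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(short)) stopf("GMT line %d has fewer than 3 fields", short[1L])
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  desc <- setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  gene_set_collection(sets, desc)
}

#' Write gene sets to a GMT file
#' @param gsc a [gene_set_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

read_events_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  incl_cols <- grep("^incl:", names(df), value = TRUE)
  skip_cols <- grep("^skip:", names(df), value = TRUE)
  samples <- sub("^incl:", "", incl_cols)
  if (!identical(samples, sub("^skip:", "", skip_cols))) {
    stopf("incl:/skip: sample columns disagree in %s", path)
  }
  incl <- as.matrix(df[, incl_cols, drop = FALSE])
  skip <- as.matrix(df[, skip_cols, drop = FALSE])
  colnames(incl) <- colnames(skip) <- samples
  splice_event_table(df[, c("event_id", "category", "incl_len", "skip_len")],
                     incl, skip)
}

write_events_tsv <- function(ev, path) {
  incl <- ev$incl; skip <- ev$skip
  colnames(incl) <- paste0("incl:", colnames(incl))
  colnames(skip) <- paste0("skip:", colnames(skip))
  df <- cbind(ev$events, as.data.frame(incl, check.names = FALSE),
              as.data.frame(skip, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bundle_files <- c(
  annotation = "annotation.tsv",
  protein = "protein.tsv", protein_meta = "protein_meta.tsv",
  mrna = "mrna.tsv", mrna_meta = "mrna_meta.tsv",
  events = "events.tsv",
  exon_quant = "exon_quant.tsv", exon_map = "exon_map.tsv",
  gene_sets = "gene_sets.gmt",
  lymph = "lymphocytes.tsv", drug = "drug_screen.tsv"
)

#' Write a cohort bundle to a directory
#'
#' Serializes every component of a [simulate_cohort()] bundle as TSV/GMT
#' files and writes `manifest.json` listing each file with its MD5 checksum.
#'
#' @param bundle a `cohort_bundle`.
#' @param directory output directory (created if absent).
#' @return Invisibly, the manifest as a data.frame (`file`, `md5`).
#' @export
write_bundle <- function(bundle, directory) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (is.null(directory) || !nzchar(directory)) stopf("empty directory path")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  utils::write.table(bundle$annotation, p("annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix(bundle$protein, p("protein.tsv"), p("protein_meta.tsv"))
  write_matrix(bundle$mrna, p("mrna.tsv"), p("mrna_meta.tsv"))
  write_events_tsv(bundle$events, p("events.tsv"))
  eq <- data.frame(feature_id = rownames(bundle$exon_quant), bundle$exon_quant,
                   check.names = FALSE)
  utils::write.table(eq, p("exon_quant.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$exon_map, p("exon_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(bundle$gene_sets, p("gene_sets.gmt"))
  utils::write.table(bundle$lymph_series, p("lymphocytes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$drug_plate, p("drug_screen.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = unname(bundle_files),
                         md5 = unname(tools::md5sum(p(bundle_files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort bundle from a directory
#'
#' Reconstructs the bundle written by [write_bundle()], validating the
#' manifest and that every component carries the same ordered sample list.
#'
#' @param directory bundle directory containing `manifest.json`.
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  if (!file.exists(man_path)) stopf("missing manifest: %s", man_path)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  missing <- manifest$file[!file.exists(file.path(directory, manifest$file))]
  if (length(missing)) stopf("missing file: %s", missing[1L])
  p <- function(f) file.path(directory, f)
  annotation <- utils::read.delim(p("annotation.tsv"), check.names = FALSE,
                                  stringsAsFactors = FALSE)
  protein <- load_matrix(p("protein.tsv"), p("protein_meta.tsv"))
  mrna <- load_matrix(p("mrna.tsv"), p("mrna_meta.tsv"))
  events <- read_events_tsv(p("events.tsv"))
  eq <- utils::read.delim(p("exon_quant.tsv"), check.names = FALSE,
                          stringsAsFactors = FALSE)
  exon_quant <- as.matrix(eq[, -1L, drop = FALSE])
  rownames(exon_quant) <- eq$feature_id
  exon_map <- utils::read.delim(p("exon_map.tsv"), check.names = FALSE,
                                stringsAsFactors = FALSE)
  gene_sets <- load_gmt(p("gene_sets.gmt"))
  lymph <- utils::read.delim(p("lymphocytes.tsv"), check.names = FALSE,
                             stringsAsFactors = FALSE)
  drug <- utils::read.delim(p("drug_screen.tsv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
  bundle <- new_cohort_bundle(annotation, protein, mrna, events, exon_quant,
                              exon_map, drug, lymph, gene_sets)
  validate_bundle(bundle)
  bundle
}

new_cohort_bundle <- function(annotation, protein, mrna, events, exon_quant,
                              exon_map, drug_plate, lymph_series, gene_sets,
                              config = NULL) {
  structure(list(
    annotation = annotation, protein = protein, mrna = mrna, events = events,
    exon_quant = exon_quant, exon_map = exon_map, drug_plate = drug_plate,
    lymph_series = lymph_series, gene_sets = gene_sets,
    truth = setNames(annotation$true_group, annotation$sample_id),
    config = config
  ), class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("cohort_bundle: %d samples, %d proteins, %d transcripts, %d splice events\n",
              nrow(x$annotation), nrow(x$protein$values), nrow(x$mrna$values),
              nrow(x$events$events)))
  print(table(x$truth))
  invisible(x)
}

validate_bundle <- function(bundle) {
  sid <- bundle$annotation$sample_id
  for (comp in c("protein", "mrna")) {
    have <- sample_ids(bundle[[comp]])
    absent <- setdiff(sid, have)
    if (length(absent)) {
      stopf("sample %s present in annotation but absent from %s matrix",
            absent[1L], comp)
    }
    if (!identical(have, sid)) stopf("sample order mismatch in %s matrix", comp)
  }
  if (!identical(colnames(bundle$events$incl), sid)) {
    stopf("sample order mismatch in splice events")
  }
  if (!identical(colnames(bundle$exon_quant), sid)) {
    stopf("sample order mismatch in exon quantification")
  }
  known <- unique(c(feature_ids(bundle$protein),
                    bundle$protein$feature_meta$gene_symbol))
  for (nm in names(bundle$gene_sets$sets)) {
    bad <- setdiff(bundle$gene_sets$sets[[nm]], known)
    if (length(bad)) stopf("gene set '%s' member %s not in feature metadata", nm, bad[1L])
  }
  invisible(bundle)
}
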