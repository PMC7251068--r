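# Subject x region value container (SUVR or probabilities) with provenance.

#' Construct a regional matrix
#'
#' The package's subject x region container for SUVR values or tau-positive
#' probabilities. Carries a provenance record of the transformation and
#' confound strategy applied, so downstream reports can state how values
#' were derived.
#'
#' @param values Numeric matrix, subjects in rows, regions in columns.
#' @param subjects Character vector of subject ids (defaults to rownames).
#' @param regions Character vector of region names (defaults to colnames).
#' @param provenance Named list; recognized fields: `transformation`
#'   (`"raw_suvr"`, `"mixture_probability"`, `"minmax"`,
#'   `"reference_ecdf"`), `confound_strategy` (`"none"`, `"residualize"`,
#'   `"wscore"`), `pvc` (logical), `region_set`.
#' @return A `regional_matrix`.
#' @export
regional_matrix <- function(values, subjects = rownames(values),
                            regions = colnames(values),
                            provenance = list()) {
  values <- as.matrix(values)
  if (is.null(subjects)) subjects <- paste0("sub", seq_len(nrow(values)))
  if (is.null(regions)) stopf("region names required")
  if (anyNA(values)) stopf("regional matrix must not contain missing values")
  stopifnot(length(subjects) == nrow(values),
            length(regions) == ncol(values))
  dimnames(values) <- list(subjects, regions)
  prov <- utils::modifyList(
    list(transformation = "raw_suvr", confound_strategy = "none",
         pvc = FALSE, region_set = "unspecified"),
    provenance)
  if (prov$transformation != "raw_suvr" &&
      (any(values < 0) || any(values > 1))) {
    stopf("probability-transformed values must lie in [0, 1]")
  }
  structure(list(values = values, subjects = subjects, regions = regions,
                 provenance = prov),
            class = "regional_matrix")
}

#' @export
print.regional_matrix <- function(x, ...) {
  cat(sprintf("Regional matrix: %d subjects x %d regions (%s, confounds: %s)\n",
              nrow(x$values), ncol(x$values),
              x$provenance$transformation, x$provenance$confound_strategy))
  cat(sprintf("  value range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.regional_matrix <- function(x) dim(x$values)

#' @export
as.matrix.regional_matrix <- function(x, ...) x$values

# Internal: replace values, keep/update provenance.
set_values <- function(x, values, ...) {
  upd <- list(...)
  regional_matrix(values, rownames(values) %||% x$subjects,
                  colnames(values) %||% x$regions,
                  utils::modifyList(x$provenance, upd))
}

#' Read or write regional and connectome matrices
#'
#' CSV or TSV (chosen by file extension) with a header row of region
#' names. Regional files carry the subject id in the first column;
#' connectome files carry region names in the first column. When a region
#' table is supplied, columns are checked against it and reordered to its
#' order (with a message) if needed; unknown region names are an error.
#'
#' @param path File path; `.tsv`/`.txt` parse as tab-separated, otherwise
#'   comma-separated.
#' @param kind `"regional"` or `"connectome"`.
#' @param regions Optional `region_table` to validate and order against.
#' @return `read_matrix()` returns a `regional_matrix` or `connectome`;
#'   `write_matrix()` returns `path` invisibly.
#' @export
read_matrix <- function(path, kind = c("regional", "connectome"),
                        regions = NULL) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stopf("duplicate %s ids in %s",
          if (kind == "regional") "subject" else "region", path)
  }
  body <- raw[, -1, drop = FALSE]
  if (!all(vapply(body, is.numeric, logical(1)))) {
    stopf("non-numeric cells in %s", path)
  }
  vals <- as.matrix(body)
  rownames(vals) <- ids
  if (!is.null(regions)) {
    unknown <- setdiff(colnames(vals), regions$name)
    if (length(unknown)) {
      stopf("region name(s) not in region table: %s",
            paste(unknown, collapse = ", "))
    }
    want <- intersect(regions$name, colnames(vals))
    if (!identical(colnames(vals), want)) {
      message("reordering matrix columns to region-table order")
      vals <- vals[, want, drop = FALSE]
    }
  }
  if (kind == "regional") {
    sidecar <- paste0(path, ".json")
    prov <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
    } else {
      list()
    }
    regional_matrix(vals, provenance = prov)
  } else {
    if (is.null(regions)) stopf("connectome reading requires a region table")
    vals <- vals[regions$name, regions$name]
    new_connectome(vals, regions, "structural", list(source = path))
  }
}

#' @rdname read_matrix
#' @param x A `regional_matrix` or `connectome`.
#' @export
write_matrix <- function(x, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  if (inherits(x, "regional_matrix")) {
    df <- data.frame(subject = x$subjects, x$values, check.names = FALSE)
    jsonlite::write_json(x$provenance, paste0(path, ".json"),
                         auto_unbox = TRUE)
  } else if (inherits(x, "connectome")) {
    df <- data.frame(region = rownames(x$weights), x$weights,
                     check.names = FALSE)
  } else {
    stopf("unsupported object of class %s", class(x)[1])
  }
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
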