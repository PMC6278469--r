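#' Mark a data frame as a descriptor table
#'
#' A descriptor table is the package's central input: one row per instance,
#' one numeric column per molecular (or other) descriptor, one binary label
#' column (1 = positive, e.g. "yields reactive metabolites") and optionally an
#' identifier column. Descriptor values are used raw — no scaling, weighting
#' or normalization is applied anywhere in the pipeline, so models remain
#' interpretable on the original descriptor scales.
#'
#' @param data A data frame or tibble.
#' @param label Name of the label column. Accepted encodings: numeric 0/1,
#'   logical, `"true"`/`"false"` (case-insensitive), or any two-valued
#'   categorical together with `positive`.
#' @param id Optional name of an identifier column; ids must be unique. When
#'   absent, row numbers are used.
#' @param positive For a two-valued categorical label, the level to map to 1.
#' @return A tibble of class `efo_table` with attributes recording the label,
#'   id and descriptor columns. All non-label, non-id columns are descriptors
#'   and must be numeric with no missing entries.
#' @examples
#' d <- tibble::tibble(id = c("a", "b", "c", "d"),
#'                     x1 = c(1, 2, 3, 4), x2 = c(0.5, 0.1, 0.9, 0.2),
#'                     label = c(0, 1, 0, 1))
#' tab <- as_efo_table(d, label = "label", id = "id")
#' n_positive(tab)
#' @export
as_efo_table <- function(data, label = "label", id = NULL, positive = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  data <- tibble::as_tibble(data)
  if (!label %in% names(data)) {
    abort(paste0("Label column '", label, "' not found."))
  }
  if (!is.null(id)) {
    if (!id %in% names(data)) abort(paste0("Id column '", id, "' not found."))
    ids <- as.character(data[[id]])
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      abort(paste0("Duplicate instance ids: ", paste(head(dup, 5), collapse = ", ")))
    }
  }
  desc <- setdiff(names(data), c(label, id))
  if (length(desc) == 0L) abort("No descriptor columns found.")
  if (anyDuplicated(desc)) abort("Duplicate descriptor names.")
  for (nm in desc) {
    col <- data[[nm]]
    if (!is.numeric(col)) {
      abort(paste0("Descriptor column '", nm, "' is not numeric."))
    }
    if (anyNA(col)) {
      abort(paste0("Missing value in column '", nm, "', row ",
                   which(is.na(col))[1], "."))
    }
  }
  data[[label]] <- coerce_labels(data[[label]], label, positive)
  structure(data,
            class = c("efo_table", class(tibble::tibble())),
            efo_label = label, efo_id = id, efo_descriptors = desc)
}

coerce_labels <- function(x, label, positive = NULL) {
  if (anyNA(x)) {
    abort(paste0("Missing value in label column '", label, "', row ",
                 which(is.na(x))[1], "."))
  }
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      abort(paste0("Label column '", label, "' must be binary (0/1); found ",
                   paste(head(setdiff(unique(x), c(0, 1)), 3), collapse = ", "), "."))
    }
    return(as.integer(x))
  }
  x <- trimws(as.character(x)) # ARFF nominal values may carry padding
  lev <- unique(x)
  low <- tolower(lev)
  if (all(low %in% c("true", "false"))) return(as.integer(tolower(x) == "true"))
  if (length(lev) > 2L) {
    abort(paste0("Label column '", label, "' has ", length(lev),
                 " distinct values; a binary label is required."))
  }
  if (is.null(positive)) {
    abort(paste0("Categorical label '", label, "' needs `positive` to name ",
                 "the positive class (levels: ", paste(lev, collapse = ", "), ")."))
  }
  if (!positive %in% lev) {
    abort(paste0("Positive class '", positive, "' not among label values (",
                 paste(lev, collapse = ", "), ")."))
  }
  as.integer(x == positive)
}

#' Accessors for descriptor tables
#'
#' @param x An `efo_table`.
#' @return `descriptor_names()` the character vector of descriptor columns;
#'   `descriptor_matrix()` the numeric instance-by-descriptor matrix;
#'   `efo_labels()` the integer 0/1 label vector; `efo_ids()` instance
#'   identifiers; `n_instances()` and `n_positive()` the instance and
#'   positive counts.
#' @name efo_table-accessors
NULL

#' @rdname efo_table-accessors
#' @export
descriptor_names <- function(x) attr(x, "efo_descriptors")

#' @rdname efo_table-accessors
#' @export
descriptor_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, descriptor_names(x), drop = FALSE])
  rownames(m) <- efo_ids(x)
  m
}

#' @rdname efo_table-accessors
#' @export
efo_labels <- function(x) as.integer(x[[attr(x, "efo_label")]])

#' @rdname efo_table-accessors
#' @export
efo_ids <- function(x) {
  id <- attr(x, "efo_id")
  if (is.null(id)) as.character(seq_len(nrow(x))) else as.character(x[[id]])
}

#' @rdname efo_table-accessors
#' @export
n_instances <- function(x) nrow(x)

#' @rdname efo_table-accessors
#' @export
n_positive <- function(x) sum(efo_labels(x))

assert_fit_ready <- function(x) {
  p <- n_positive(x)
  if (p == 0L || p == n_instances(x)) {
    abort("Fitting needs both positive and negative instances (0 < n_positive < n_total).")
  }
  invisible(x)
}

#' @export
print.efo_table <- function(x, ...) {
  cat("# Descriptor table: ", n_instances(x), " instances x ",
      length(descriptor_names(x)), " descriptors, ",
      n_positive(x), " positive (",
      sprintf("%.1f%%", 100 * n_positive(x) / n_instances(x)), ")\n", sep = "")
  NextMethod()
}

#' Read a descriptor table from CSV, TSV or ARFF
#'
#' Missing values anywhere in the file are an error (they would silently
#' corrupt rankings); the error names the offending row and column.
#'
#' @param path Path to the file.
#' @param label Name of the label column (for ARFF, the class attribute).
#' @param dialect One of `"auto"` (by file extension), `"csv"`, `"tsv"`,
#'   `"arff"`.
#' @param id,positive Passed to [as_efo_table()].
#' @return An `efo_table`.
#' @export
read_descriptor_table <- function(path, label,
                                  dialect = c("auto", "csv", "tsv", "arff"),
                                  id = NULL, positive = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", tab = "tsv", arff = "arff", "csv")
  }
  raw <- switch(dialect,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    arff = tibble::as_tibble(foreign::read.arff(path)))
  as_efo_table(raw, label = label, id = id, positive = positive)
}

#' Write a descriptor table to CSV
#'
#' @param x An `efo_table`.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_descriptor_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(x)
}
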