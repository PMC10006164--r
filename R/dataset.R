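#' Declare one variable of a tabular schema
#'
#' A schema entry fixing a column's name, type, category set (for
#' categorical variables) and projection weight. Booleans are represented as
#' two-level categoricals internally; dates are embedded as days since
#' 1970-01-01 for all distance computations and decoded back on output.
#'
#' @param name column name.
#' @param vtype one of `"continuous"`, `"categorical"`, `"boolean"`,
#'   `"date"`.
#' @param categories ordered character vector of allowed levels
#'   (categorical only, at least two distinct labels).
#' @param weight positive projection weight for the variable (default 1).
#' @return an object of class `variable_spec`.
#' @export
variable_spec <- function(name, vtype, categories = NULL, weight = 1) {
  vtype <- match.arg(vtype, c("continuous", "categorical", "boolean", "date"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    avt_stop("variable name must be a non-empty string", "avt_schema_error")
  if (!is.numeric(weight) || length(weight) != 1L || !is.finite(weight) || weight <= 0)
    avt_stop(sprintf("weight for '%s' must be a positive real", name), "avt_schema_error")
  if (vtype == "categorical") {
    categories <- as.character(categories)
    if (length(unique(categories)) < 2L)
      avt_stop(sprintf("categorical variable '%s' needs >= 2 distinct labels", name),
               "avt_schema_error")
    if (anyDuplicated(categories))
      avt_stop(sprintf("duplicate category labels in '%s'", name), "avt_schema_error")
  } else if (vtype == "boolean") {
    categories <- c("FALSE", "TRUE")
  } else {
    categories <- NULL
  }
  structure(list(name = name, vtype = vtype, categories = categories,
                 weight = as.numeric(weight)),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s: %s", x$name, x$vtype))
  if (!is.null(x$categories) && x$vtype == "categorical")
    cat(" {", paste(x$categories, collapse = ", "), "}")
  if (x$weight != 1) cat(sprintf(" (weight %g)", x$weight))
  cat("\n")
  invisible(x)
}

is_iso_date <- function(x) {
  grepl("^\\d{4}-\\d{2}-\\d{2}$", x) & !is.na(suppressWarnings(as.Date(x, format = "%Y-%m-%d")))
}

# Infer a schema from character (or already-typed) columns.
# Rules: logical / {0,1} / true-false -> boolean; all ISO-8601 -> date;
# numeric -> continuous; otherwise categorical when the number of distinct
# labels is at most `max_levels` (levels in sorted order, so inference is
# deterministic).
infer_schema <- function(df, max_levels = 10) {
  specs <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.logical(x)) return(variable_spec(nm, "boolean"))
    if (inherits(x, "Date")) return(variable_spec(nm, "date"))
    xc <- trimws(as.character(x))
    if (all(toupper(xc) %in% c("TRUE", "FALSE", "T", "F")))
      return(variable_spec(nm, "boolean"))
    if (all(is_iso_date(xc))) return(variable_spec(nm, "date"))
    num <- suppressWarnings(as.numeric(xc))
    if (!anyNA(num)) {
      if (all(num %in% c(0, 1)) && length(unique(num)) == 2L)
        return(variable_spec(nm, "boolean"))
      return(variable_spec(nm, "continuous"))
    }
    lev <- sort(unique(xc))
    if (length(lev) > max_levels)
      avt_stop(sprintf(
        "column '%s' has %d distinct non-numeric values (cap %d); supply an explicit schema",
        nm, length(lev), max_levels), "avt_inference_error")
    variable_spec(nm, "categorical", categories = lev)
  })
  names(specs) <- names(df)
  specs
}

coerce_column <- function(x, spec) {
  nm <- spec$name
  xc <- if (is.factor(x)) as.character(x) else x
  bad_row <- function(ok, what) {
    if (!all(ok))
      avt_stop(sprintf("unparseable %s value in column '%s', row %d",
                       what, nm, which(!ok)[1L]), "avt_parse_error")
  }
  switch(spec$vtype,
    continuous = {
      v <- suppressWarnings(as.numeric(xc))
      bad_row(!is.na(v), "numeric")
      v
    },
    date = {
      if (inherits(xc, "Date")) return(xc)
      v <- suppressWarnings(as.Date(trimws(as.character(xc)), format = "%Y-%m-%d"))
      bad_row(!is.na(v), "ISO-8601 date")
      v
    },
    boolean = {
      if (is.logical(xc)) return(xc)
      s <- toupper(trimws(as.character(xc)))
      v <- ifelse(s %in% c("TRUE", "T", "1"), TRUE,
                  ifelse(s %in% c("FALSE", "F", "0"), FALSE, NA))
      bad_row(!is.na(v), "boolean")
      as.logical(v)
    },
    categorical = {
      s <- as.character(xc)
      ok <- s %in% spec$categories
      if (!all(ok))
        avt_stop(sprintf("value '%s' in column '%s' (row %d) is not in the declared categories",
                         s[which(!ok)[1L]], nm, which(!ok)[1L]), "avt_parse_error")
      factor(s, levels = spec$categories)
    })
}

#' Construct a typed tabular dataset
#'
#' Wraps a data frame in a validated, typed container. Columns are coerced
#' according to `schema`; when `schema` is `NULL` it is inferred (see
#' [read_dataset()] for the inference rules). Missing values are rejected:
#' the generator and all metrics assume complete data.
#'
#' @param df a data frame (values may be character, as read from CSV).
#' @param schema optional list of [variable_spec()] entries, in column order.
#' @param max_levels distinct-value cap used during schema inference.
#' @return an object of class `tabular_dataset` with fields `data`
#'   (typed data frame), `schema`, `n`, `p`.
#' @export
tabular_dataset <- function(df, schema = NULL, max_levels = 10) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    miss <- is.na(df[[j]]) | (is.character(df[[j]]) & trimws(df[[j]]) == "")
    if (any(miss))
      avt_stop(sprintf("missing value in column '%s', row %d",
                       names(df)[j], which(miss)[1L]), "avt_missing_value_error")
  }
  if (nrow(df) < 2L)
    avt_stop("a dataset needs at least 2 rows", "avt_shape_error")
  if (is.null(schema)) {
    schema <- infer_schema(df, max_levels = max_levels)
  } else {
    schema <- lapply(schema, function(s) {
      if (!inherits(s, "variable_spec"))
        s <- variable_spec(s$name, s$vtype, s$categories, s$weight %||% 1)
      s
    })
    nms <- unname(vapply(schema, `[[`, "", "name"))
    if (!identical(nms, names(df)))
      avt_stop("schema column names/order do not match the data", "avt_schema_error")
    names(schema) <- nms
  }
  for (nm in names(df)) df[[nm]] <- coerce_column(df[[nm]], schema[[nm]])
  structure(list(data = df, schema = schema, n = nrow(df), p = ncol(df)),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset> %d rows x %d columns\n", x$n, x$p))
  types <- vapply(x$schema, `[[`, "", "vtype")
  cat(paste(sprintf("  %s <%s>", names(types), types), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.data.frame.tabular_dataset <- function(x, ...) x$data

# Row subset preserving schema (used by the sampling protocols).
ds_subset <- function(ds, idx) {
  df <- ds$data[idx, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(data = df, schema = ds$schema, n = length(idx), p = ds$p),
            class = "tabular_dataset")
}

#' Read a delimited dataset with optional schema control
#'
#' Reads an RFC-4180 CSV with a header row into a [tabular_dataset()]. When
#' no schema is given, types are inferred per column: logical or 0/1 values
#' become boolean, ISO-8601 strings become dates, numeric columns become
#' continuous, and other columns become categorical (sorted levels) provided
#' they have at most `max_levels` distinct labels. Ordinal grades stored as
#' integers (for instance 1-10 imaging scores) infer as continuous; pass an
#' explicit schema to override.
#'
#' @param path CSV file path.
#' @param schema optional schema (list of [variable_spec()], or a YAML path
#'   readable by [read_schema()]).
#' @param max_levels distinct-value cap for inferring categorical columns.
#' @return a `tabular_dataset`.
#' @export
read_dataset <- function(path, schema = NULL, max_levels = 10) {
  if (!file.exists(path))
    avt_stop(sprintf("file not found: %s", path), "avt_io_error")
  if (is.character(schema) && length(schema) == 1L) schema <- read_schema(schema)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        stringsAsFactors = FALSE)
  tabular_dataset(df, schema = schema, max_levels = max_levels)
}

#' Write a dataset to CSV
#'
#' Continuous values are serialized with 17 significant digits so that
#' [read_dataset()] round-trips them exactly; dates are written as ISO-8601.
#'
#' @param data a `tabular_dataset`.
#' @param path output CSV path.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "tabular_dataset"))
  out <- data$data
  for (nm in names(out)) {
    v <- out[[nm]]
    out[[nm]] <- switch(data$schema[[nm]]$vtype,
      continuous = vapply(v, function(z) sprintf("%.17g", z), ""),
      date = format(v, "%Y-%m-%d"),
      boolean = ifelse(v, "TRUE", "FALSE"),
      categorical = as.character(v))
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok)
    avt_stop(sprintf("cannot write to '%s'", path), "avt_io_error")
  invisible(NULL)
}

#' Validate a dataset against a reference schema
#'
#' Checks the structural-similarity contract of synthetic output: identical
#' column names and order, identical variable types, and categorical values
#' restricted to the reference category sets. Problems are returned, not
#' raised.
#'
#' @param data a `tabular_dataset`.
#' @param reference_schema schema list to validate against.
#' @return list with `valid` (logical) and `issues` (character vector).
#' @export
validate_against <- function(data, reference_schema) {
  issues <- character()
  ref_names <- unname(vapply(reference_schema, `[[`, "", "name"))
  got_names <- unname(vapply(data$schema, `[[`, "", "name"))
  if (!identical(got_names, ref_names)) {
    issues <- c(issues, sprintf("column names/order differ: got [%s], expected [%s]",
                                paste(got_names, collapse = ","),
                                paste(ref_names, collapse = ",")))
  } else {
    for (i in seq_along(ref_names)) {
      ref <- reference_schema[[i]]; got <- data$schema[[i]]
      if (!identical(got$vtype, ref$vtype)) {
        issues <- c(issues, sprintf("column '%s': type %s, expected %s",
                                    ref$name, got$vtype, ref$vtype))
      } else if (ref$vtype == "categorical") {
        vals <- unique(as.character(data$data[[ref$name]]))
        extra <- setdiff(vals, ref$categories)
        if (length(extra))
          issues <- c(issues, sprintf("column '%s': values outside reference categories: %s",
                                      ref$name, paste(extra, collapse = ",")))
      }
    }
  }
  list(valid = length(issues) == 0L, issues = issues)
}

#' Read / write a schema as YAML
#'
#' The schema file is a YAML list of `{name, vtype, categories?, weight?}`
#' entries in column order.
#'
#' @param path YAML file path.
#' @return `read_schema()` returns a list of [variable_spec()].
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- lapply(raw, function(s)
    variable_spec(s$name, s$vtype, categories = s$categories, weight = s$weight %||% 1))
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

#' @rdname read_schema
#' @param schema schema list to serialize.
#' @export
write_schema <- function(schema, path) {
  out <- lapply(schema, function(s) {
    e <- list(name = s$name, vtype = s$vtype)
    if (s$vtype == "categorical") e$categories <- as.list(s$categories)
    if (s$weight != 1) e$weight <- s$weight
    e
  })
  yaml::write_yaml(unname(out), path)
  invisible(NULL)
}
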