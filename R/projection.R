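#' Fit a factor model for mixed data (FAMD)
#'
#' Builds one Euclidean space for continuous, categorical, boolean and date
#' columns. Continuous (and date) columns are standardized to mean 0 /
#' standard deviation 1. Each categorical level is one-hot encoded, the
#' indicator divided by the square root of the level proportion and
#' centered, which is the standard FAMD construction: with only continuous
#' columns the model reduces to PCA on z-scores, with only categorical
#' columns to multiple correspondence analysis up to a global scaling.
#' Axes are the right singular vectors of the encoded matrix and the model
#' keeps full rank, so [famd_inverse_transform()] is exact on full-rank
#' coordinates.
#'
#' @param data a [tabular_dataset()].
#' @param column_weights optional named positive weights (one per variable)
#'   multiplying the encoded columns; unnamed variables default to the
#'   weight recorded in the schema.
#' @return an object of class `famd_model` with fields `centers`, `scales`,
#'   `proportions`, `axes` (encoded-dim x ncomp, orthonormal),
#'   `explained_variance` (non-increasing ratios), `ncomp`, `column_map`,
#'   `schema`, `component_sd`.
#' @export
fit_famd <- function(data, column_weights = NULL) {
  stopifnot(inherits(data, "tabular_dataset"))
  enc <- build_encoder(data, column_weights)
  Z <- encode_dataset(enc, data)
  sv <- svd(Z)
  tol <- max(dim(Z)) * .Machine$double.eps * sv$d[1L]
  r <- sum(sv$d > tol)
  if (r < 1L) avt_stop("encoded matrix has rank 0", "avt_fit_error")
  d <- sv$d[seq_len(r)]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(d, r)
  model <- structure(c(enc, list(
    axes = sv$v[, seq_len(r), drop = FALSE],
    explained_variance = d^2 / sum(sv$d^2),
    ncomp = r,
    component_sd = apply(scores, 2L, stats::sd),
    n_fit = data$n
  )), class = "famd_model")
  model
}

# Encoder state shared by fit/transform/inverse: per encoded column a
# center, a scale (sd for numeric, sqrt(level proportion) for indicators)
# and the variable weight; column_map ties encoded columns back to schema
# variables.
build_encoder <- function(data, column_weights = NULL) {
  schema <- data$schema
  w <- vapply(schema, `[[`, 1, "weight")
  if (!is.null(column_weights)) {
    if (is.null(names(column_weights)) || !all(names(column_weights) %in% names(schema)))
      avt_stop("column_weights must be named after schema variables", "avt_schema_error")
    if (any(!is.finite(column_weights)) || any(column_weights <= 0))
      avt_stop("column_weights must be positive", "avt_schema_error")
    w[names(column_weights)] <- column_weights
  }
  centers <- c(); scales <- c(); props <- c(); weights <- c()
  column_map <- list()
  enc_names <- character()
  for (nm in names(schema)) {
    sp <- schema[[nm]]
    if (sp$vtype %in% c("continuous", "date")) {
      x <- numeric_values(data$data[[nm]], sp)
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0)
        avt_stop(sprintf("continuous column '%s' has zero variance; cannot standardize", nm),
                 "avt_fit_error")
      centers <- c(centers, mean(x)); scales <- c(scales, s)
      props <- c(props, NA_real_); weights <- c(weights, w[[nm]])
      column_map[[nm]] <- list(vtype = sp$vtype, cols = length(enc_names) + 1L)
      enc_names <- c(enc_names, nm)
    } else {
      levs <- level_set(sp)
      f <- factor(as.character(data$data[[nm]]), levels = levs)
      p <- as.numeric(table(f)) / data$n
      if (any(p == 0))
        avt_stop(sprintf("column '%s': level '%s' has zero frequency in the fitting data",
                         nm, levs[which(p == 0)[1L]]), "avt_fit_error")
      if (length(levs) < 2L || any(p == 1))
        avt_stop(sprintf("column '%s' has a single observed level", nm), "avt_fit_error")
      idx <- length(enc_names) + seq_along(levs)
      centers <- c(centers, p)           # indicator mean = level proportion
      scales <- c(scales, sqrt(p))
      props <- c(props, p)
      weights <- c(weights, rep(w[[nm]], length(levs)))
      column_map[[nm]] <- list(vtype = sp$vtype, cols = idx, levels = levs)
      enc_names <- c(enc_names, paste(nm, levs, sep = "="))
    }
  }
  list(schema = schema, centers = centers, scales = scales,
       proportions = props, weights = weights, column_map = column_map,
       encoded_names = enc_names)
}

numeric_values <- function(x, sp) {
  if (sp$vtype == "date") as.numeric(as.Date(x)) else as.numeric(x)
}

level_set <- function(sp) {
  if (sp$vtype == "boolean") c("FALSE", "TRUE") else sp$categories
}

# Encode a dataset with a fitted encoder (centers/scales are NOT refitted).
encode_dataset <- function(enc, data) {
  n <- data$n
  Z <- matrix(0, n, length(enc$centers),
              dimnames = list(NULL, enc$encoded_names))
  for (nm in names(enc$column_map)) {
    cm <- enc$column_map[[nm]]
    sp <- enc$schema[[nm]]
    if (cm$vtype %in% c("continuous", "date")) {
      Z[, cm$cols] <- numeric_values(data$data[[nm]], sp)
    } else {
      vals <- if (cm$vtype == "boolean") ifelse(data$data[[nm]], "TRUE", "FALSE")
              else as.character(data$data[[nm]])
      pos <- match(vals, cm$levels)
      if (anyNA(pos))
        avt_stop(sprintf("column '%s': unseen category label '%s'",
                         nm, vals[which(is.na(pos))[1L]]), "avt_transform_error")
      Z[cbind(seq_len(n), cm$cols[pos])] <- 1
    }
  }
  sweep(sweep(sweep(Z, 2L, enc$centers, "-"), 2L, enc$scales, "/"),
        2L, enc$weights, "*")
}

#' Project a dataset into a fitted FAMD space
#'
#' Rows are encoded with the model's stored centers and scales and projected
#' onto the model's axes; nothing is refitted, so original, avatar and
#' holdout data all live in the same space.
#'
#' @param model a `famd_model`.
#' @param data a `tabular_dataset` conforming to the model's schema.
#' @return numeric matrix of component scores (n x ncomp).
#' @export
famd_transform <- function(model, data) {
  stopifnot(inherits(model, "famd_model"), inherits(data, "tabular_dataset"))
  chk <- validate_against(data, model$schema)
  if (!chk$valid)
    avt_stop(paste("data does not match the model schema:",
                   paste(chk$issues, collapse = "; ")), "avt_transform_error")
  encode_dataset(model, data) %*% model$axes
}

#' Reconstruct schema values from FAMD coordinates
#'
#' Inverts the projection: encoded values are `coords %*% t(axes)`, then
#' un-scaled and un-centered. Continuous columns come back as reals, dates
#' are rounded to integer days and decoded, and each categorical column is
#' set to the level with the largest reconstructed indicator (ties broken by
#' higher training proportion, then by label order). On full-rank
#' coordinates the round trip is exact up to floating point.
#'
#' @param model a `famd_model`.
#' @param coords numeric matrix of coordinates in the model's space.
#' @return a `tabular_dataset` with the model's schema.
#' @export
famd_inverse_transform <- function(model, coords) {
  coords <- as.matrix(coords)
  if (!all(is.finite(coords)))
    avt_stop("coordinates contain non-finite values", "avt_transform_error")
  if (ncol(coords) != model$ncomp)
    avt_stop(sprintf("coordinates have %d columns; model has %d components",
                     ncol(coords), model$ncomp), "avt_transform_error")
  Zhat <- coords %*% t(model$axes)
  raw <- sweep(sweep(Zhat, 2L, model$weights, "/"), 2L, model$scales, "*")
  raw <- sweep(raw, 2L, model$centers, "+")
  decode_encoded(model, raw)
}

decode_encoded <- function(model, raw) {
  out <- list()
  for (nm in names(model$column_map)) {
    cm <- model$column_map[[nm]]
    sp <- model$schema[[nm]]
    if (cm$vtype == "continuous") {
      out[[nm]] <- as.numeric(raw[, cm$cols])
    } else if (cm$vtype == "date") {
      out[[nm]] <- as.Date(round(raw[, cm$cols]), origin = "1970-01-01")
    } else {
      ind <- raw[, cm$cols, drop = FALSE]
      prop <- model$proportions[cm$cols]
      pick <- apply_argmax(ind, prop, cm$levels)
      out[[nm]] <- if (cm$vtype == "boolean") pick == "TRUE"
                   else factor(pick, levels = cm$levels)
    }
  }
  df <- as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  structure(list(data = df, schema = model$schema, n = nrow(df), p = ncol(df)),
            class = "tabular_dataset")
}

# Argmax over reconstructed indicators; ties favor the likelier level, then
# the earlier label in sorted order.
apply_argmax <- function(ind, prop, levels) {
  vapply(seq_len(nrow(ind)), function(i) {
    v <- ind[i, ]
    best <- which(v == max(v))
    if (length(best) > 1L) {
      best <- best[prop[best] == max(prop[best])]
      if (length(best) > 1L) best <- best[order(levels[best])]
    }
    levels[best[1L]]
  }, "")
}

#' Number of components covering a cumulative explained-variance target
#'
#' @param model a `famd_model`.
#' @param target cumulative explained-variance ratio (default 0.90).
#' @return smallest component count whose cumulative ratio reaches `target`,
#'   capped at `ncomp`.
#' @export
choose_nd <- function(model, target = 0.90) {
  cum <- cumsum(model$explained_variance)
  idx <- which(cum >= target)
  if (length(idx)) min(idx[1L], model$ncomp) else model$ncomp
}

#' Persist / reload a fitted FAMD model
#'
#' The model is stored as a single JSON document (centers, scales,
#' proportions, axes, column map) at full floating-point precision, so a
#' reloaded model transforms identically to within the last bit.
#'
#' @param model a `famd_model`.
#' @param path JSON file path.
#' @export
write_famd_model <- function(model, path) {
  doc <- list(
    schema = lapply(unname(model$schema), function(s)
      list(name = s$name, vtype = s$vtype, categories = s$categories, weight = s$weight)),
    centers = model$centers, scales = model$scales,
    proportions = model$proportions, weights = model$weights,
    column_map = model$column_map, encoded_names = model$encoded_names,
    axes = model$axes, explained_variance = model$explained_variance,
    ncomp = model$ncomp, component_sd = model$component_sd, n_fit = model$n_fit)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(NULL)
}

#' @rdname write_famd_model
#' @export
read_famd_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- lapply(seq_len(nrow(doc$schema)), function(i) {
    s <- doc$schema[i, ]
    variable_spec(s$name, s$vtype,
                  categories = if (s$vtype == "categorical") unlist(s$categories),
                  weight = s$weight)
  })
  names(schema) <- vapply(schema, `[[`, "", "name")
  cmap <- lapply(doc$column_map, function(cm) {
    cm$cols <- as.integer(unlist(cm$cols))
    if (!is.null(cm$levels)) cm$levels <- as.character(unlist(cm$levels))
    cm
  })
  structure(list(
    schema = schema, centers = as.numeric(doc$centers),
    scales = as.numeric(doc$scales), proportions = as.numeric(doc$proportions),
    weights = as.numeric(doc$weights), column_map = cmap,
    encoded_names = as.character(doc$encoded_names),
    axes = matrix(unlist(doc$axes), nrow = length(doc$centers), byrow = FALSE),
    explained_variance = as.numeric(doc$explained_variance),
    ncomp = as.integer(doc$ncomp),
    component_sd = as.numeric(doc$component_sd),
    n_fit = as.integer(doc$n_fit)), class = "famd_model")
}

#' @export
print.famd_model <- function(x, ...) {
  cat(sprintf("<famd_model> %d encoded columns, %d components\n",
              length(x$centers), x$ncomp))
  cat(sprintf("  cumulative explained variance: %s\n",
              paste(sprintf("%.2f", cumsum(x$explained_variance)[seq_len(min(5, x$ncomp))]),
                    collapse = " ")))
  invisible(x)
}
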