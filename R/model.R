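#' Linear scoring models
#'
#' An `efo_model` is an ordered set of descriptor names with matching real
#' coefficients, a score threshold separating predicted positives from
#' negatives, and training metadata. The score of an instance is the plain
#' linear combination `sum(coefficients * descriptor values)`; there is no
#' intercept because adding a constant cannot change a ranking. By convention
#' the first coefficient is normalized to +1 or -1 (dividing all coefficients
#' by `|coefficients[1]|` leaves every ranking unchanged).
#'
#' @param variables Character vector of descriptor names.
#' @param coefficients Numeric vector, same length as `variables`.
#' @param threshold Score cut-off; instances scoring `>= threshold` are
#'   predicted positive. `NA` until set (see [set_threshold()]).
#' @param cluster_size Cluster size used during fitting, if any.
#' @param train_quality Value of the ranking-quality function on the training
#'   data, if fitted.
#' @param seed RNG seed recorded at fit time.
#' @param profile Optional [probability_profile()] for score-based
#'   probabilities.
#' @return An object of class `efo_model`.
#' @examples
#' m <- efo_model(c("x1", "x2"), c(1, 2.47))
#' tidy(m)
#' @export
efo_model <- function(variables, coefficients, threshold = NA_real_,
                      cluster_size = NA_integer_, train_quality = NA_real_,
                      seed = NA_integer_, profile = NULL) {
  variables <- as.character(variables)
  coefficients <- as.double(coefficients)
  if (length(variables) != length(coefficients)) {
    abort("`variables` and `coefficients` must have the same length.")
  }
  if (length(variables) == 0L) abort("A model needs at least one variable.")
  if (anyDuplicated(variables)) abort("Duplicate variable names in model.")
  if (anyNA(coefficients)) abort("Coefficients must not be missing.")
  m <- structure(
    list(variables = variables, coefficients = coefficients,
         threshold = as.double(threshold),
         cluster_size = as.integer(cluster_size),
         train_quality = as.double(train_quality),
         seed = seed, profile = profile),
    class = "efo_model")
  normalize_model(m, warn = FALSE)
}

# Divide all coefficients by |c1| so the leading coefficient is +/-1; if the
# leading coefficient vanishes, rotate the largest-magnitude one to the front.
normalize_model <- function(m, warn = TRUE) {
  c0 <- abs(m$coefficients[1])
  if (c0 < 1e-12) {
    j <- which.max(abs(m$coefficients))
    if (abs(m$coefficients[j]) < 1e-12) {
      abort("All model coefficients are (numerically) zero.")
    }
    ord <- c(j, setdiff(seq_along(m$coefficients), j))
    inform(paste0("Leading coefficient is zero; moving '", m$variables[j],
                  "' to the front before normalizing."))
    m$variables <- m$variables[ord]
    m$coefficients <- m$coefficients[ord]
    c0 <- abs(m$coefficients[1])
  }
  if (c0 != 1) {
    if (warn) {
      warn(paste0("Leading coefficient has |c1| = ", format(c0),
                  "; renormalizing so that |c1| = 1 (rankings unchanged)."))
    }
    m$coefficients <- m$coefficients / c0
  }
  m
}

#' @export
print.efo_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g %s", x$coefficients, x$variables),
                 collapse = " ")
  cat("EFO linear model: score =", terms, "\n")
  cat("  threshold:", format(x$threshold),
      " cluster_size:", x$cluster_size,
      " train_quality:", format(x$train_quality), "\n")
  if (!is.null(x$profile)) cat("  probability profile:",
                               nrow(x$profile), "bins\n")
  invisible(x)
}

#' @describeIn efo_model One row per model term: `term`, `estimate`.
#' @param x,object An `efo_model`.
#' @param ... Unused.
#' @export
tidy.efo_model <- function(x, ...) {
  tibble::tibble(term = x$variables, estimate = x$coefficients)
}

#' @describeIn efo_model One-row summary: number of terms, threshold,
#'   cluster size and training quality.
#' @export
glance.efo_model <- function(x, ...) {
  tibble::tibble(n_terms = length(x$variables), threshold = x$threshold,
                 cluster_size = x$cluster_size,
                 train_quality = x$train_quality,
                 has_profile = !is.null(x$profile))
}

#' Serialize a model to JSON / read it back
#'
#' The JSON stores variable names explicitly (not column positions) so a model
#' transfers across tables with different column orders. The round trip
#' `read_efo_model(write_efo_model(m))` is exact. A file whose leading
#' coefficient is not +/-1 is accepted but renormalized with a warning.
#'
#' @param model An `efo_model`.
#' @param path File path.
#' @return `write_efo_model()` returns `model` invisibly; `read_efo_model()`
#'   returns an `efo_model`.
#' @export
write_efo_model <- function(model, path) {
  stopifnot(inherits(model, "efo_model"))
  obj <- list(variables = model$variables,
              coefficients = model$coefficients,
              threshold = model$threshold,
              cluster_size = model$cluster_size,
              train_quality = model$train_quality,
              seed = model$seed)
  if (!is.null(model$profile)) obj$profile <- as.data.frame(model$profile)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(model)
}

#' @rdname write_efo_model
#' @export
read_efo_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort(paste0("Malformed model file: ",
                                                   conditionMessage(e))))
  if (is.null(obj$variables) || is.null(obj$coefficients)) {
    abort("Malformed model file: needs 'variables' and 'coefficients'.")
  }
  profile <- NULL
  if (!is.null(obj$profile)) {
    profile <- structure(tibble::as_tibble(obj$profile),
                         class = c("efo_profile", class(tibble::tibble())))
  }
  m <- structure(
    list(variables = as.character(obj$variables),
         coefficients = as.double(obj$coefficients),
         threshold = as.double(obj$threshold %||% NA_real_),
         cluster_size = as.integer(obj$cluster_size %||% NA_integer_),
         train_quality = as.double(obj$train_quality %||% NA_real_),
         seed = obj$seed %||% NA_integer_, profile = profile),
    class = "efo_model")
  if (length(m$variables) != length(m$coefficients)) {
    abort("Malformed model file: variables/coefficients length mismatch.")
  }
  normalize_model(m, warn = TRUE)
}
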