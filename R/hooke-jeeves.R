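#' Hooke-Jeeves pattern search
#'
#' Derivative-free maximization by the classic exploratory-move /
#' pattern-move scheme, suitable for non-smooth and piecewise-constant
#' objectives such as ranking quality (where the objective only changes when
#' two instances swap order). Exploratory moves probe each coordinate in turn
#' by `+step` then `-step`, keeping strict improvements; after a successful
#' sweep the search extrapolates along the move (pattern move) and explores
#' around the extrapolated point. When a sweep around the base point fails,
#' every step is halved. The search stops when the root-mean-square of the
#' step vector drops below `rms_tol` or the evaluation budget is exhausted.
#'
#' @param fn Objective function of a numeric vector, returning a single
#'   finite number.
#' @param x0 Numeric start vector.
#' @param step0 Initial step per coordinate; default `0.25 * |x0|` with a
#'   floor of 0.1.
#' @param iterations Maximum number of objective evaluations (default 5000).
#' @param rms_tol Convergence tolerance on the RMS step length (default
#'   0.001).
#' @param maximize If `FALSE`, minimize instead.
#' @return A list: `par` (best point found), `value` (objective there,
#'   always at least as good as at `x0`), `evaluations`, `converged` (`TRUE`
#'   when the step-size criterion was met within budget).
#' @examples
#' hooke_jeeves(function(x) -(x - 3)^2, x0 = 0)$par
#' @export
hooke_jeeves <- function(fn, x0, step0 = NULL, iterations = 5000,
                         rms_tol = 0.001, maximize = TRUE) {
  x0 <- as.double(x0)
  k <- length(x0)
  if (k == 0L) abort("`x0` must be non-empty.")
  step <- if (is.null(step0)) pmax(0.25 * abs(x0), 0.1) else {
    s <- as.double(step0)
    if (length(s) == 1L) s <- rep(s, k)
    if (length(s) != k || any(s <= 0)) abort("`step0` must be positive, length 1 or length(x0).")
    s
  }
  sgn <- if (maximize) 1 else -1
  evals <- 0L
  eval_fn <- function(x) {
    evals <<- evals + 1L
    v <- sgn * fn(x)
    if (!is.finite(v)) v <- -Inf
    v
  }

  explore <- function(x, f) {
    # one exploratory sweep: perturb each coordinate, keep strict gains
    for (j in seq_len(k)) {
      if (evals >= iterations) break
      xt <- x; xt[j] <- x[j] + step[j]
      ft <- eval_fn(xt)
      if (ft > f) {
        x <- xt; f <- ft
      } else if (evals < iterations) {
        xt[j] <- x[j] - step[j]
        ft <- eval_fn(xt)
        if (ft > f) {
          x <- xt; f <- ft
        }
      }
    }
    list(x = x, f = f)
  }

  xb <- x0
  fb <- eval_fn(xb)
  converged <- FALSE
  while (evals < iterations) {
    if (sqrt(mean(step^2)) < rms_tol) {
      converged <- TRUE
      break
    }
    ex <- explore(xb, fb)
    if (ex$f > fb) {
      # pattern moves: extrapolate while exploration around the
      # extrapolated point keeps improving
      xp <- xb
      xb <- ex$x; fb <- ex$f
      repeat {
        if (evals >= iterations) break
        xt <- xb + (xb - xp)
        ft <- eval_fn(xt)
        ex2 <- explore(xt, ft)
        if (ex2$f > fb) {
          xp <- xb
          xb <- ex2$x; fb <- ex2$f
        } else break
      }
    } else {
      step <- step / 2
    }
  }
  if (!converged && sqrt(mean(step^2)) < rms_tol) converged <- TRUE
  list(par = xb, value = sgn * fb, evaluations = evals, converged = converged)
}
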