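#' Five-parameter logistic performance curve
#'
#' Constructs a parameter object for the five-parameter logistic (5PL)
#' performance curve
#' \deqn{P_{NEW}(x) = d + \frac{a - d}{\left(1 + (x/c)^b\right)^e}}
#' which models the probability of classifying a test stimulus as novel as a
#' function of its dissimilarity \eqn{x \in [0, 1]} to the study list.
#' Parameter \code{a} primarily controls the lower asymptote (the false-alarm
#' rate on old items), \code{b} the steepness, \code{c} the horizontal shift,
#' \code{d} the upper asymptote (the hit rate on the most distinct new items)
#' and \code{e} the asymmetry of the curve.
#'
#' @param a lower-asymptote-controlling parameter; \code{P(0) == a} exactly.
#' @param b steepness, strictly positive.
#' @param c horizontal shift, strictly positive.
#' @param d upper-asymptote-controlling parameter.
#' @param e asymmetry, strictly positive.
#'
#' @return An object of class \code{"five_pl"}: a named list with elements
#'   \code{a}, \code{b}, \code{c}, \code{d}, \code{e}.
#' @examples
#' p <- five_pl(a = 0.1, b = 2, c = 0.5, d = 0.9, e = 1)
#' pnew_eval(p, c(0, 0.5, 1))
#' @export
five_pl <- function(a, b, c, d, e) {
  for (nm in c("a", "b", "c", "d", "e")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("five_pl parameter '", nm, "' must be a single finite number",
           call. = FALSE)
    }
  }
  if (b <= 0) stop("five_pl parameter 'b' must be strictly positive", call. = FALSE)
  if (c <= 0) stop("five_pl parameter 'c' must be strictly positive", call. = FALSE)
  if (e <= 0) stop("five_pl parameter 'e' must be strictly positive", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, e = e), class = "five_pl")
}

#' @export
print.five_pl <- function(x, ...) {
  cat("Five-parameter logistic curve P_NEW(x) = d + (a-d)/(1+(x/c)^b)^e\n")
  cat(sprintf("  a=%.4g  b=%.4g  c=%.4g  d=%.4g  e=%.4g\n",
              x$a, x$b, x$c, x$d, x$e))
  invisible(x)
}

#' Evaluate the five-parameter logistic curve
#'
#' Evaluates \eqn{P_{NEW}(x) = d + (a-d)/(1+(x/c)^b)^e} at dissimilarity
#' values \code{x}. The evaluation is carried out in log space so that large
#' values of \eqn{(x/c)^b} (steep curves, \code{b} up to 100) do not
#' overflow. At \code{x == 0} the curve returns exactly \code{a}.
#'
#' @param params a \code{\link{five_pl}} object (or a named list/vector with
#'   elements a, b, c, d, e).
#' @param x numeric vector of dissimilarity values, typically in \eqn{[0,1]}.
#'
#' @return Numeric vector of curve values, same length as \code{x}.
#' @export
pnew_eval <- function(params, x) {
  p <- as_five_pl(params)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  out <- numeric(length(x))
  zero <- x == 0
  out[zero] <- p$a
  if (any(!zero)) {
    xs <- x[!zero]
    if (any(xs < 0)) stop("dissimilarity must be non-negative", call. = FALSE)
    # log((x/c)^b) = b*(log x - log c); (1+u)^e computed as exp(e*log1p(u))
    t <- p$b * (log(xs) - log(p$c))
    # log(1 + e^t), stable for large |t|
    log1pe <- ifelse(t > 35, t, log1p(exp(pmin(t, 35))))
    out[!zero] <- p$d + (p$a - p$d) * exp(-p$e * log1pe)
  }
  out
}

# Coerce a named list/vector to five_pl, validating as it goes.
as_five_pl <- function(params) {
  if (inherits(params, "five_pl")) return(params)
  if (is.numeric(params)) params <- as.list(params)
  if (!all(c("a", "b", "c", "d", "e") %in% names(params))) {
    stop("parameters must contain a, b, c, d, e", call. = FALSE)
  }
  five_pl(params$a, params$b, params$c, params$d, params$e)
}

#' Recognition index Delta
#'
#' The overall recognition memory index \eqn{\Delta = P_{NEW}(1) -
#' P_{NEW}(0)}: the probability of correctly classifying the most dissimilar
#' stimuli as new minus the probability of misclassifying old stimuli as new.
#' The value is not clamped to \eqn{[0,1]}; raw values are propagated so that
#' downstream linear analyses are undistorted.
#'
#' @param params a \code{\link{five_pl}} object.
#' @return A single number.
#' @export
delta_index <- function(params) {
  p <- as_five_pl(params)
  pnew_eval(p, 1) - pnew_eval(p, 0)
}

# Composite Simpson quadrature of f on [0, 1] with n_nodes equally spaced
# nodes (n_nodes odd). Deterministic; exact for cubics. The default node
# count resolves the steepest admissible 5PL (b = 100, c = 0.01) to well
# below 1e-6 absolute error.
simpson_01 <- function(f, n_nodes = 8193L) {
  if (n_nodes %% 2L == 0L) n_nodes <- n_nodes + 1L
  x <- seq(0, 1, length.out = n_nodes)
  y <- f(x)
  if (any(!is.finite(y))) {
    stop("quadrature failed: non-finite integrand values", call. = FALSE)
  }
  h <- x[2] - x[1]
  w <- rep(c(4, 2), length.out = n_nodes - 2L)
  (h / 3) * (y[1] + y[n_nodes] + sum(w * y[2:(n_nodes - 1L)]))
}

#' Area between the performance curve and its value at dissimilarity 1
#'
#' Computes \eqn{A = P_{NEW}(1) - \int_0^1 P_{NEW}(x)\,dx} by composite
#' Simpson quadrature with 8193 equally spaced nodes. For a non-decreasing
#' curve \eqn{A \ge 0}; small \eqn{A} means the curve reaches its maximum
#' already at low dissimilarity (good mnemonic discrimination).
#'
#' @param params a \code{\link{five_pl}} object.
#' @param n_nodes number of quadrature nodes (odd; default 8193).
#' @return A single number.
#' @export
area_above_curve <- function(params, n_nodes = 8193L) {
  p <- as_five_pl(params)
  pnew_eval(p, 1) - simpson_01(function(x) pnew_eval(p, x), n_nodes)
}

#' Mnemonic discrimination index lambda
#'
#' The curve-based mnemonic discrimination index \eqn{\lambda = 1 - A/\Delta}
#' with \eqn{A = P_{NEW}(1) - \int_0^1 P_{NEW}(x)\,dx}. A participant whose
#' performance curve jumps to its maximum at small dissimilarity (perfect
#' discrimination of even highly similar lures) has \eqn{A \approx 0} and
#' \eqn{\lambda \approx 1}; a linear ramp gives \eqn{\lambda = 0.5}.
#'
#' When \eqn{|\Delta|} is at or below \code{delta_floor} the ratio is
#' numerically meaningless (flat curve) and \eqn{\lambda} is reported as
#' undefined (\code{NA} with \code{defined = FALSE}).
#'
#' @param params a \code{\link{five_pl}} object.
#' @param delta_floor smallest \eqn{|\Delta|} for which \eqn{\lambda} is
#'   considered defined (default 0.01).
#' @return A list with elements \code{lambda} (number or \code{NA}),
#'   \code{defined} (logical), \code{area_A} and \code{delta}.
#' @export
lambda_index <- function(params, delta_floor = 0.01) {
  p <- as_five_pl(params)
  delta <- delta_index(p)
  A <- area_above_curve(p)
  if (!is.finite(delta) || abs(delta) <= delta_floor) {
    return(list(lambda = NA_real_, defined = FALSE, area_A = A, delta = delta))
  }
  list(lambda = 1 - A / delta, defined = TRUE, area_A = A, delta = delta)
}
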