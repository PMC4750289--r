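#' Membership functions
#'
#' A membership function maps a crisp measurement to a degree of belief in
#' \code{[0, 1]} for one linguistic category.  Six parametric shapes are
#' supported: increasing and decreasing sigmoids, Gaussian bumps, triangles,
#' trapezoids and singletons (for categorical encodings).
#'
#' @param c Inflection point of a sigmoid; degree is exactly 0.5 there.
#' @param a Sigmoid slope, must be positive.
#' @param mean,sd Center and width of a Gaussian; degree is 1 at \code{mean}.
#' @param left,peak,right Feet and apex of a triangle,
#'   \code{left <= peak <= right}.
#' @param lf,ls,rs,rf Left foot, left shoulder, right shoulder and right foot
#'   of a trapezoid (degree 1 on \code{[ls, rs]}, 0 outside \code{[lf, rf]}).
#' @param location Singleton location; degree is 1 within \code{tol} of it.
#' @param tol Singleton matching tolerance.  The default 0.5 makes integer
#'   category codes match exactly their own singleton and no other.
#'
#' @return An object of class \code{oncofuzz_mf}.
#' @examples
#' mf <- mf_gaussian(0, 0.15)
#' evaluate_membership(mf, 0)      # 1
#' evaluate_membership(mf, 0.15)   # exp(-1/2)
#' @name membership
NULL

new_mf <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "oncofuzz_mf")
}

#' @rdname membership
#' @export
mf_sigmoid_increasing <- function(c, a) {
  stopifnot(is.finite(c), is.finite(a))
  if (a <= 0) stop("sigmoid slope 'a' must be > 0", call. = FALSE)
  new_mf("sigmoid_increasing", list(c = c, a = a))
}

#' @rdname membership
#' @export
mf_sigmoid_decreasing <- function(c, a) {
  stopifnot(is.finite(c), is.finite(a))
  if (a <= 0) stop("sigmoid slope 'a' must be > 0", call. = FALSE)
  new_mf("sigmoid_decreasing", list(c = c, a = a))
}

#' @rdname membership
#' @export
mf_gaussian <- function(mean, sd) {
  stopifnot(is.finite(mean), is.finite(sd))
  if (sd <= 0) stop("gaussian 'sd' must be > 0", call. = FALSE)
  new_mf("gaussian", list(mean = mean, sd = sd))
}

#' @rdname membership
#' @export
mf_triangle <- function(left, peak, right) {
  stopifnot(is.finite(left), is.finite(peak), is.finite(right))
  if (!(left <= peak && peak <= right))
    stop("triangle requires left <= peak <= right", call. = FALSE)
  new_mf("triangle", list(left = left, peak = peak, right = right))
}

#' @rdname membership
#' @export
mf_trapezoid <- function(lf, ls, rs, rf) {
  stopifnot(is.finite(lf), is.finite(ls), is.finite(rs), is.finite(rf))
  if (!(lf <= ls && ls <= rs && rs <= rf))
    stop("trapezoid requires lf <= ls <= rs <= rf", call. = FALSE)
  new_mf("trapezoid", list(lf = lf, ls = ls, rs = rs, rf = rf))
}

#' @rdname membership
#' @export
mf_singleton <- function(location, tol = 0.5) {
  stopifnot(is.finite(location), is.finite(tol), tol > 0)
  new_mf("singleton", list(location = location, tol = tol))
}

#' @export
print.oncofuzz_mf <- function(x, ...) {
  cat(sprintf("<membership %s(%s)>\n", x$kind,
              paste(sprintf("%s=%g", names(x$params), unlist(x$params)),
                    collapse = ", ")))
  invisible(x)
}

#' Evaluate a membership function
#'
#' @param mf A membership function created by one of the \code{mf_*}
#'   constructors.
#' @param x Numeric vector of crisp values; all must be finite.
#' @return Degrees in \code{[0, 1]}, same length as \code{x}.
#' @export
evaluate_membership <- function(mf, x) {
  if (!inherits(mf, "oncofuzz_mf"))
    stop("'mf' must be an oncofuzz_mf object", call. = FALSE)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  p <- mf$params
  d <- switch(mf$kind,
    sigmoid_increasing = 1 / (1 + exp(-p$a * (x - p$c))),
    sigmoid_decreasing = 1 / (1 + exp(p$a * (x - p$c))),
    gaussian = exp(-(x - p$mean)^2 / (2 * p$sd^2)),
    triangle = {
      up <- (x - p$left) / max(p$peak - p$left, .Machine$double.eps)
      down <- (p$right - x) / max(p$right - p$peak, .Machine$double.eps)
      pmax(0, pmin(up, down, 1))
    },
    trapezoid = {
      up <- (x - p$lf) / max(p$ls - p$lf, .Machine$double.eps)
      down <- (p$rf - x) / max(p$rf - p$rs, .Machine$double.eps)
      pmax(0, pmin(up, down, 1))
    },
    singleton = as.numeric(abs(x - p$location) < p$tol),
    stop("unknown membership kind: ", mf$kind, call. = FALSE)
  )
  pmin(1, pmax(0, d))
}

#' Sigmoid slope matching a Gaussian of a given width
#'
#' Converts a standard deviation into the sigmoid slope whose transition
#' approximates a Gaussian bump of that standard deviation:
#' \code{sqrt(8 * log(2)) / std}.  The numerator is the Gaussian full width at
#' half maximum per unit standard deviation, so wider Gaussians yield shallower
#' sigmoids.  Used when turning tertile summary statistics into the low/high
#' expression sigmoids.
#'
#' @param std Positive standard deviation.
#' @return The slope, a positive scalar (vectorized over \code{std}).
#' @export
slope_from_std <- function(std) {
  if (!is.numeric(std) || anyNA(std) || any(!is.finite(std)) || any(std <= 0))
    stop("'std' must be finite and > 0", call. = FALSE)
  sqrt(8 * log(2)) / std
}
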