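#' Mamdani inference
#'
#' Rule firing and centroid defuzzification.  \code{AND} combines leaf degrees
#' by minimum, \code{OR} by maximum; a rule's activation is the degree of its
#' antecedent; consequent membership curves are clipped at the activation
#' (min) and accumulated pointwise by maximum (union); the crisp score is the
#' centroid of the accumulated curve, computed by trapezoidal quadrature on a
#' uniform grid over the output domain.
#'
#' @name inference
NULL

eval_expr <- function(e, inputs, variables) {
  if (e$op == "is") {
    x <- inputs[[e$variable]]
    if (is.null(x))
      stop(sprintf("missing crisp input for variable '%s'", e$variable),
           call. = FALSE)
    return(evaluate_membership(variables[[e$variable]]$categories[[e$category]],
                               x))
  }
  vals <- lapply(e$children, eval_expr, inputs = inputs, variables = variables)
  if (e$op == "and") do.call(pmin, vals) else do.call(pmax, vals)
}

#' Fire all rules of a rule base on crisp inputs
#'
#' @param rb An \code{oncofuzz_rulebase}.
#' @param inputs Named list (or single-row named numeric vector) of crisp
#'   values, one per input variable referenced by the rules.  Each entry may
#'   be a vector; vectors are recycled to a common length so that many
#'   observations are fuzzified in one call.
#' @return A numeric matrix of activations in \code{[0, 1]} with one row per
#'   observation and one column per rule.
#' @export
fire_rules <- function(rb, inputs) {
  stopifnot(inherits(rb, "oncofuzz_rulebase"))
  if (is.numeric(inputs)) inputs <- as.list(inputs)
  if (!is.list(inputs) || is.null(names(inputs)))
    stop("'inputs' must be a named list or named numeric vector",
         call. = FALSE)
  n <- max(lengths(inputs), 1L)
  inputs <- lapply(inputs, rep_len, length.out = n)
  acts <- vapply(rb$rules, function(r) {
    rep_len(eval_expr(r$antecedent, inputs, rb$inputs), n)
  }, numeric(n))
  if (n == 1L) acts <- matrix(acts, nrow = 1L)
  colnames(acts) <- vapply(rb$rules, function(r)
    if (is.na(r$number)) "" else as.character(r$number), character(1))
  acts
}

# symmetric uniform grid over [lo, hi]; for a symmetric domain the grid is
# exactly sign-symmetric so mirrored curves defuzzify to exactly opposite
# scores
output_grid <- function(domain, resolution) {
  lo <- domain[1]; hi <- domain[2]
  if (lo == -hi) {
    if (resolution %% 2L == 0L) resolution <- resolution + 1L
    half <- seq(0, hi, length.out = (resolution + 1L) %/% 2L)
    c(-rev(half[-1L]), half)
  } else {
    seq(lo, hi, length.out = resolution)
  }
}

# per-category membership curves of the output variable on the grid,
# grid-points x categories
output_curves <- function(rb, resolution) {
  grid <- output_grid(rb$output$domain, resolution)
  M <- vapply(rb$output$categories, function(mf) evaluate_membership(mf, grid),
              numeric(length(grid)))
  list(grid = grid, curves = M)
}

#' Aggregate fired rules and defuzzify by centroid
#'
#' @param rb An \code{oncofuzz_rulebase}.
#' @param activations Activation degrees: a vector with one entry per rule, or
#'   a matrix (observations x rules) as returned by [fire_rules()].
#' @param resolution Number of grid points over the output domain
#'   (>= 101; default 2001).  For symmetric domains an even value is bumped to
#'   the next odd one so the grid contains 0 and is sign-symmetric.
#' @return Centroid score(s) within the output domain, one per observation.
#'   An identically-zero accumulated curve (no rule fired) defuzzifies to 0,
#'   the neutral no-effect score.
#' @export
aggregate_and_defuzzify <- function(rb, activations, resolution = 2001L) {
  stopifnot(inherits(rb, "oncofuzz_rulebase"))
  if (!is.numeric(resolution) || length(resolution) != 1L || resolution < 101)
    stop("'resolution' must be a single integer >= 101", call. = FALSE)
  if (is.null(dim(activations))) activations <- matrix(activations, nrow = 1L)
  if (ncol(activations) != length(rb$rules))
    stop("one activation per rule required", call. = FALSE)
  if (anyNA(activations) || any(activations < 0 | activations > 1))
    stop("activations must lie in [0, 1]", call. = FALSE)
  oc <- output_curves(rb, as.integer(resolution))
  cons <- vapply(rb$rules, `[[`, character(1), "consequent")
  cat_names <- names(rb$output$categories)
  # union absorbs duplicates: only each category's maximum activation matters
  cat_act <- vapply(cat_names, function(nm) {
    cols <- which(cons == nm)
    if (length(cols) == 0L) return(numeric(nrow(activations)))
    do.call(pmax, lapply(cols, function(j) activations[, j]))
  }, numeric(nrow(activations)))
  if (nrow(activations) == 1L) cat_act <- matrix(cat_act, nrow = 1L)
  # trapezoidal quadrature weights (uniform grid: only the endpoints differ)
  w <- rep(1, length(oc$grid))
  w[c(1L, length(w))] <- 0.5
  vapply(seq_len(nrow(activations)), function(i) {
    agg <- numeric(length(oc$grid))
    for (k in seq_along(cat_names)) {
      a <- cat_act[i, k]
      if (a > 0) agg <- pmax(agg, pmin(a, oc$curves[, k]))
    }
    s <- sum(w * agg)
    if (s == 0) 0 else sum(w * oc$grid * agg) / s
  }, numeric(1))
}
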