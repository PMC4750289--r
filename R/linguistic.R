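#' Linguistic variables
#'
#' A linguistic variable is a named quantity (e.g. \code{Expression}) with a
#' closed real domain and a set of overlapping categories, each described by a
#' membership function.
#'
#' @param name Variable identifier.
#' @param domain Numeric length-2 vector \code{c(lo, hi)}, \code{lo < hi}.
#' @param categories Named list of \code{oncofuzz_mf} objects; names are the
#'   category labels and must be unique.
#' @return An object of class \code{oncofuzz_variable}.
#' @export
linguistic_variable <- function(name, domain, categories) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(domain) || length(domain) != 2L || !all(is.finite(domain)) ||
      domain[1] >= domain[2])
    stop("'domain' must be c(lo, hi) with lo < hi", call. = FALSE)
  if (!is.list(categories) || length(categories) == 0L ||
      is.null(names(categories)) || anyDuplicated(names(categories)) ||
      any(!nzchar(names(categories))))
    stop("'categories' must be a uniquely named non-empty list", call. = FALSE)
  ok <- vapply(categories, inherits, logical(1), what = "oncofuzz_mf")
  if (!all(ok))
    stop("all categories must be oncofuzz_mf objects", call. = FALSE)
  structure(list(name = name, domain = as.numeric(domain),
                 categories = categories),
            class = "oncofuzz_variable")
}

#' @export
print.oncofuzz_variable <- function(x, ...) {
  cat(sprintf("<variable %s on [%g, %g]: %s>\n", x$name,
              x$domain[1], x$domain[2],
              paste(names(x$categories), collapse = ", ")))
  invisible(x)
}

# Antecedent expression trees -------------------------------------------------
#
# Leaves are atomic predicates (variable IS category); inner nodes combine
# children with "and" (minimum) or "or" (maximum).

atom <- function(variable, category) {
  structure(list(op = "is", variable = variable, category = category),
            class = "oncofuzz_expr")
}

node <- function(op, children) {
  stopifnot(op %in% c("and", "or"), length(children) >= 2L)
  structure(list(op = op, children = children), class = "oncofuzz_expr")
}

#' Construct a fuzzy rule
#'
#' @param antecedent Expression tree whose leaves are \code{variable IS
#'   category} predicates combined with AND/OR (built by the FCL parser or the
#'   internal helpers).
#' @param consequent Category label of the output variable.
#' @param number Optional rule number used for reporting.
#' @return An object of class \code{oncofuzz_rule}.
#' @keywords internal
fuzzy_rule <- function(antecedent, consequent, number = NA_integer_) {
  stopifnot(inherits(antecedent, "oncofuzz_expr"),
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedent = antecedent, consequent = consequent,
                 number = as.integer(number)),
            class = "oncofuzz_rule")
}

expr_leaves <- function(e) {
  if (e$op == "is") return(list(e))
  do.call(c, lapply(e$children, expr_leaves))
}

#' Assemble a rule base
#'
#' A rule base couples input linguistic variables, exactly one output
#' linguistic variable and an ordered collection of IF/THEN rules.  Every rule
#' leaf must reference a declared variable and one of its categories, and every
#' consequent must be a declared output category.
#'
#' @param inputs Named list of input \code{oncofuzz_variable}s.
#' @param output The output \code{oncofuzz_variable}.
#' @param rules List of \code{oncofuzz_rule}s.
#' @return An object of class \code{oncofuzz_rulebase}.
#' @export
rulebase <- function(inputs, output, rules) {
  if (!is.list(inputs) || length(inputs) == 0L)
    stop("'inputs' must be a non-empty list of variables", call. = FALSE)
  names(inputs) <- vapply(inputs, `[[`, character(1), "name")
  if (anyDuplicated(names(inputs)))
    stop("duplicate input variable names", call. = FALSE)
  stopifnot(inherits(output, "oncofuzz_variable"))
  if (output$name %in% names(inputs))
    stop("output variable name collides with an input", call. = FALSE)
  for (r in rules) {
    stopifnot(inherits(r, "oncofuzz_rule"))
    for (leaf in expr_leaves(r$antecedent)) {
      v <- inputs[[leaf$variable]]
      if (is.null(v))
        stop(sprintf("rule %s references undeclared variable '%s'",
                     r$number, leaf$variable), call. = FALSE)
      if (!leaf$category %in% names(v$categories))
        stop(sprintf("rule %s references unknown category '%s' of '%s'",
                     r$number, leaf$category, leaf$variable), call. = FALSE)
    }
    if (!r$consequent %in% names(output$categories))
      stop(sprintf("rule %s has unknown output category '%s'",
                   r$number, r$consequent), call. = FALSE)
  }
  structure(list(inputs = inputs, output = output, rules = rules),
            class = "oncofuzz_rulebase")
}

#' @export
print.oncofuzz_rulebase <- function(x, ...) {
  cat(sprintf("<rulebase: %d rules; inputs %s; output %s (%d categories)>\n",
              length(x$rules), paste(names(x$inputs), collapse = ", "),
              x$output$name, length(x$output$categories)))
  invisible(x)
}

#' Replace one variable of a rule base
#'
#' Used to substitute the per-gene fitted expression variable (or a custom
#' copy-number variable) into the shared rule base before scoring.
#'
#' @param rb A rule base.
#' @param variable An \code{oncofuzz_variable} whose name matches an existing
#'   input.
#' @return The modified rule base.
#' @export
set_variable <- function(rb, variable) {
  stopifnot(inherits(rb, "oncofuzz_rulebase"),
            inherits(variable, "oncofuzz_variable"))
  if (!variable$name %in% names(rb$inputs))
    stop(sprintf("no input variable named '%s'", variable$name),
         call. = FALSE)
  # rule leaves must keep resolving; reuse rulebase() for re-validation
  inputs <- rb$inputs
  inputs[[variable$name]] <- variable
  rulebase(inputs, rb$output, rb$rules)
}
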