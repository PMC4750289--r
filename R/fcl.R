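#' Read and write rule bases in Fuzzy Control Language
#'
#' The rule base travels as text in a subset of IEC 61131-7 Fuzzy Control
#' Language (FCL): \code{VAR_INPUT}/\code{VAR_OUTPUT} declarations,
#' \code{FUZZIFY}/\code{DEFUZZIFY} blocks holding \code{RANGE} and \code{TERM}
#' definitions, and a \code{RULEBLOCK} of numbered
#' \code{RULE n: IF ... THEN <out> IS <category>;} lines.  Term shapes:
#' \code{SIGM a c} (negative \code{a} gives a decreasing sigmoid),
#' \code{GAUSS mean sd}, \code{TRIAN l p r}, \code{TRAPE lf ls rs rf} and
#' \code{SINGLETON loc}.  \code{AND} combines by minimum and \code{OR} by
#' maximum; \code{AND : MIN}, \code{OR : MAX}, \code{ACT : MIN} and
#' \code{ACCU : MAX} operator declarations are accepted (anything else is
#' rejected, as no other operator family is implemented).
#'
#' @param text Character: either a file path or FCL source (a vector of lines
#'   or a single string with newlines).
#' @return \code{parse_rulebase} returns an \code{oncofuzz_rulebase};
#'   \code{format_fcl} returns a character vector of FCL lines.
#' @seealso [default_rulebase()]
#' @export
parse_rulebase <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  toks <- fcl_tokenize(lines)
  fcl_parse(toks)
}

# tokenizer: identifiers, numbers, punctuation; tracks line numbers ----------
fcl_tokenize <- function(lines) {
  # strip // and (* *) comments (the latter only within a line)
  lines <- sub("//.*$", "", lines)
  lines <- gsub("\\(\\*.*?\\*\\)", " ", lines)
  pat <- "[A-Za-z_][A-Za-z0-9_]*|[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?|:=|\\.\\.|[():;,]"
  out_val <- character(0); out_line <- integer(0)
  for (i in seq_along(lines)) {
    m <- gregexpr(pat, lines[i])[[1]]
    if (m[1] == -1) {
      leftover <- gsub("\\s", "", lines[i])
      if (nzchar(leftover))
        stop(sprintf("FCL parse error at line %d: unrecognized text '%s'",
                     i, leftover), call. = FALSE)
      next
    }
    vals <- regmatches(lines[i], gregexpr(pat, lines[i]))[[1]]
    leftover <- gsub("\\s", "", do.call(paste0,
      as.list(regmatches(lines[i], gregexpr(pat, lines[i]), invert = TRUE)[[1]])))
    if (nzchar(leftover))
      stop(sprintf("FCL parse error at line %d: unrecognized text '%s'",
                   i, leftover), call. = FALSE)
    out_val <- c(out_val, vals)
    out_line <- c(out_line, rep.int(i, length(vals)))
  }
  list(val = out_val, line = out_line, pos = 1L)
}

tk_peek <- function(st) if (st$pos <= length(st$val)) st$val[st$pos] else NA_character_
tk_line <- function(st) if (st$pos <= length(st$val)) st$line[st$pos] else st$line[length(st$line)]
tk_stop <- function(st, msg) {
  stop(sprintf("FCL parse error at line %d: %s", tk_line(st), msg),
       call. = FALSE)
}

# keywords are case-insensitive; identifiers (term/variable names) are not
tk_is_kw <- function(st, kw) {
  v <- tk_peek(st)
  !is.na(v) && toupper(v) == kw
}
tk_expect_kw <- function(st, kw) {
  if (!tk_is_kw(st, kw)) tk_stop(st, sprintf("expected '%s', got '%s'", kw, tk_peek(st)))
  st$pos <- st$pos + 1L
  st
}
tk_expect_sym <- function(st, sym) {
  v <- tk_peek(st)
  if (is.na(v) || v != sym) tk_stop(st, sprintf("expected '%s', got '%s'", sym, v))
  st$pos <- st$pos + 1L
  st
}
fcl_parse <- function(st) {
  st <- as.environment(st)
  inputs <- list(); output_name <- NULL; input_names <- character(0)
  terms <- list(); ranges <- list(); rules <- list(); rule_numbers <- integer(0)

  take_ident <- function(what = "identifier") {
    v <- tk_peek(st)
    if (is.na(v) || !grepl("^[A-Za-z_]", v)) tk_stop(st, sprintf("expected %s", what))
    st$pos <- st$pos + 1L
    v
  }
  take_number <- function() {
    v <- tk_peek(st)
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) tk_stop(st, sprintf("expected a number, got '%s'", v))
    st$pos <- st$pos + 1L
    n
  }

  parse_var_block <- function(is_output) {
    st$pos <- st$pos + 1L  # VAR_INPUT / VAR_OUTPUT
    repeat {
      if (tk_is_kw(st, "END_VAR")) { st$pos <- st$pos + 1L; break }
      if (is.na(tk_peek(st))) tk_stop(st, "unterminated VAR block")
      nm <- take_ident("variable name")
      tk_expect_sym(st, ":")
      take_ident("type")            # REAL, ignored
      tk_expect_sym(st, ";")
      if (is_output) {
        if (!is.null(output_name))
          tk_stop(st, "more than one output variable declared")
        output_name <<- nm
      } else input_names <<- c(input_names, nm)
    }
  }

  parse_term <- function() {
    st$pos <- st$pos + 1L  # TERM
    nm <- take_ident("term name")
    tk_expect_sym(st, ":=")
    shape <- toupper(take_ident("term shape"))
    mf <- switch(shape,
      SIGM = {
        a <- take_number(); c <- take_number()
        if (a == 0) tk_stop(st, "SIGM slope must be nonzero")
        if (a > 0) mf_sigmoid_increasing(c, a) else mf_sigmoid_decreasing(c, -a)
      },
      GAUSS = mf_gaussian(take_number(), take_number()),
      TRIAN = mf_triangle(take_number(), take_number(), take_number()),
      TRAPE = mf_trapezoid(take_number(), take_number(), take_number(),
                           take_number()),
      SINGLETON = mf_singleton(take_number()),
      tk_stop(st, sprintf("unknown term shape '%s'", shape))
    )
    tk_expect_sym(st, ";")
    list(name = nm, mf = mf)
  }

  parse_fuzzify <- function(kw) {
    st$pos <- st$pos + 1L  # FUZZIFY / DEFUZZIFY
    var <- take_ident("variable name")
    tlist <- list(); rng <- NULL
    endkw <- paste0("END_", kw)
    repeat {
      if (tk_is_kw(st, endkw)) { st$pos <- st$pos + 1L; break }
      if (is.na(tk_peek(st))) tk_stop(st, sprintf("unterminated %s block", kw))
      if (tk_is_kw(st, "TERM")) {
        tm <- parse_term()
        if (tm$name %in% names(tlist))
          tk_stop(st, sprintf("duplicate term '%s' in %s", tm$name, var))
        tlist[[tm$name]] <- tm$mf
      } else if (tk_is_kw(st, "RANGE")) {
        st$pos <- st$pos + 1L
        tk_expect_sym(st, ":="); tk_expect_sym(st, "(")
        lo <- take_number(); tk_expect_sym(st, ".."); hi <- take_number()
        tk_expect_sym(st, ")"); tk_expect_sym(st, ";")
        rng <- c(lo, hi)
      } else if (tk_is_kw(st, "METHOD")) {
        st$pos <- st$pos + 1L; tk_expect_sym(st, ":")
        m <- toupper(take_ident("defuzzification method")); tk_expect_sym(st, ";")
        if (m != "COG") tk_stop(st, sprintf("unsupported method '%s' (only COG)", m))
      } else if (tk_is_kw(st, "DEFAULT")) {
        st$pos <- st$pos + 1L; tk_expect_sym(st, ":="); take_number()
        tk_expect_sym(st, ";")
      } else tk_stop(st, sprintf("unexpected token '%s' in %s block",
                                 tk_peek(st), kw))
    }
    if (length(tlist) == 0L) tk_stop(st, sprintf("no TERMs for '%s'", var))
    list(var = var, terms = tlist, range = rng)
  }

  # antecedent grammar: OR is lowest precedence, AND binds tighter
  parse_or <- function() {
    e <- parse_and()
    kids <- list(e)
    while (tk_is_kw(st, "OR")) {
      st$pos <- st$pos + 1L
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) e else node("or", kids)
  }
  parse_and <- function() {
    e <- parse_primary()
    kids <- list(e)
    while (tk_is_kw(st, "AND")) {
      st$pos <- st$pos + 1L
      kids[[length(kids) + 1L]] <- parse_primary()
    }
    if (length(kids) == 1L) e else node("and", kids)
  }
  parse_primary <- function() {
    if (identical(tk_peek(st), "(")) {
      st$pos <- st$pos + 1L
      e <- parse_or()
      tk_expect_sym(st, ")")
      return(e)
    }
    v <- take_ident("variable name")
    tk_expect_kw(st, "IS")
    cat <- take_ident("category label")
    atom(v, cat)
  }

  parse_ruleblock <- function() {
    st$pos <- st$pos + 1L  # RULEBLOCK
    take_ident("rule block name")
    repeat {
      if (tk_is_kw(st, "END_RULEBLOCK")) { st$pos <- st$pos + 1L; break }
      if (is.na(tk_peek(st))) tk_stop(st, "unterminated RULEBLOCK")
      if (tk_is_kw(st, "RULE")) {
        st$pos <- st$pos + 1L
        num <- as.integer(take_number())
        if (num %in% rule_numbers)
          tk_stop(st, sprintf("duplicate rule number %d", num))
        tk_expect_sym(st, ":")
        tk_expect_kw(st, "IF")
        ante <- parse_or()
        tk_expect_kw(st, "THEN")
        outv <- take_ident("output variable")
        tk_expect_kw(st, "IS")
        cons <- take_ident("output category")
        tk_expect_sym(st, ";")
        if (!is.null(output_name) && outv != output_name)
          tk_stop(st, sprintf("rule %d concludes on '%s', not the output '%s'",
                              num, outv, output_name))
        rule_numbers <<- c(rule_numbers, num)
        rules[[length(rules) + 1L]] <<- fuzzy_rule(ante, cons, num)
      } else if (tk_is_kw(st, "AND") || tk_is_kw(st, "OR") ||
                 tk_is_kw(st, "ACT") || tk_is_kw(st, "ACCU")) {
        which <- toupper(take_ident())
        tk_expect_sym(st, ":")
        op <- toupper(take_ident("operator"))
        tk_expect_sym(st, ";")
        ok <- switch(which, AND = "MIN", OR = "MAX", ACT = "MIN", ACCU = "MAX")
        if (op != ok)
          tk_stop(st, sprintf("unsupported %s operator '%s' (only %s)",
                              which, op, ok))
      } else tk_stop(st, sprintf("unexpected token '%s' in RULEBLOCK",
                                 tk_peek(st)))
    }
  }

  while (!is.na(tk_peek(st))) {
    if (tk_is_kw(st, "FUNCTION_BLOCK")) {
      st$pos <- st$pos + 1L; take_ident("block name")
    } else if (tk_is_kw(st, "END_FUNCTION_BLOCK")) {
      st$pos <- st$pos + 1L
    } else if (tk_is_kw(st, "VAR_INPUT")) {
      parse_var_block(FALSE)
    } else if (tk_is_kw(st, "VAR_OUTPUT")) {
      parse_var_block(TRUE)
    } else if (tk_is_kw(st, "FUZZIFY")) {
      b <- parse_fuzzify("FUZZIFY")
      terms[[b$var]] <- b$terms; ranges[[b$var]] <- b$range
    } else if (tk_is_kw(st, "DEFUZZIFY")) {
      b <- parse_fuzzify("DEFUZZIFY")
      terms[[b$var]] <- b$terms; ranges[[b$var]] <- b$range
    } else if (tk_is_kw(st, "RULEBLOCK")) {
      parse_ruleblock()
    } else tk_stop(st, sprintf("unexpected token '%s'", tk_peek(st)))
  }

  if (is.null(output_name))
    stop("FCL parse error: no VAR_OUTPUT declared", call. = FALSE)
  if (length(rules) == 0L)
    stop("FCL parse error: no rules declared", call. = FALSE)
  mkvar <- function(nm) {
    if (is.null(terms[[nm]]))
      stop(sprintf("FCL parse error: no FUZZIFY/DEFUZZIFY block for '%s'", nm),
           call. = FALSE)
    rng <- ranges[[nm]]
    if (is.null(rng)) rng <- default_range(terms[[nm]])
    linguistic_variable(nm, rng, terms[[nm]])
  }
  rulebase(lapply(input_names, mkvar), mkvar(output_name), rules)
}

# fallback domain when a block omits RANGE: span of all term supports
default_range <- function(terms) {
  lims <- vapply(terms, function(mf) {
    p <- mf$params
    switch(mf$kind,
      triangle = c(p$left, p$right),
      trapezoid = c(p$lf, p$rf),
      gaussian = c(p$mean - 4 * p$sd, p$mean + 4 * p$sd),
      singleton = c(p$location - 1, p$location + 1),
      c(p$c - 4 / p$a, p$c + 4 / p$a))
  }, numeric(2))
  c(min(lims[1, ]), max(lims[2, ]))
}

# serializer ------------------------------------------------------------------

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

fmt_mf <- function(mf) {
  p <- mf$params
  switch(mf$kind,
    sigmoid_increasing = paste("SIGM", fmt_num(p$a), fmt_num(p$c)),
    sigmoid_decreasing = paste("SIGM", fmt_num(-p$a), fmt_num(p$c)),
    gaussian = paste("GAUSS", fmt_num(p$mean), fmt_num(p$sd)),
    triangle = paste("TRIAN", fmt_num(p$left), fmt_num(p$peak),
                     fmt_num(p$right)),
    trapezoid = paste("TRAPE", fmt_num(p$lf), fmt_num(p$ls), fmt_num(p$rs),
                      fmt_num(p$rf)),
    singleton = paste("SINGLETON", fmt_num(p$location)))
}

fmt_expr <- function(e, top = FALSE) {
  if (e$op == "is") return(sprintf("(%s IS %s)", e$variable, e$category))
  sep <- if (e$op == "and") " AND " else " OR "
  inner <- paste(vapply(e$children, fmt_expr, character(1)), collapse = sep)
  if (top) inner else paste0("(", inner, ")")
}

#' @rdname parse_rulebase
#' @param rb A rule base to serialize.
#' @export
format_fcl <- function(rb) {
  stopifnot(inherits(rb, "oncofuzz_rulebase"))
  out <- c("FUNCTION_BLOCK gene_activity", "", "VAR_INPUT")
  for (nm in names(rb$inputs)) out <- c(out, sprintf("    %s : REAL;", nm))
  out <- c(out, "END_VAR", "", "VAR_OUTPUT",
           sprintf("    %s : REAL;", rb$output$name), "END_VAR", "")
  for (nm in names(rb$inputs)) {
    v <- rb$inputs[[nm]]
    out <- c(out, sprintf("FUZZIFY %s", nm),
             sprintf("    RANGE := (%s .. %s);", fmt_num(v$domain[1]),
                     fmt_num(v$domain[2])),
             vapply(names(v$categories), function(tn)
               sprintf("    TERM %s := %s;", tn, fmt_mf(v$categories[[tn]])),
               character(1)),
             "END_FUZZIFY", "")
  }
  v <- rb$output
  out <- c(out, sprintf("DEFUZZIFY %s", v$name),
           sprintf("    RANGE := (%s .. %s);", fmt_num(v$domain[1]),
                   fmt_num(v$domain[2])),
           vapply(names(v$categories), function(tn)
             sprintf("    TERM %s := %s;", tn, fmt_mf(v$categories[[tn]])),
             character(1)),
           "    METHOD : COG;",
           "END_DEFUZZIFY", "",
           "RULEBLOCK rules",
           "    AND : MIN;",
           "    OR : MAX;",
           "    ACT : MIN;",
           "    ACCU : MAX;")
  for (r in rb$rules)
    out <- c(out, sprintf("    RULE %d: IF %s THEN %s IS %s;", r$number,
                          fmt_expr(r$antecedent, top = TRUE), rb$output$name,
                          r$consequent))
  c(out, "END_RULEBLOCK", "", "END_FUNCTION_BLOCK")
}

#' The shipped default rule base
#'
#' Loads the package's default 30-rule base linking mutation class, hotspot
#' recurrence, expression level and copy-number state to a seven-category
#' gene-activity output on \code{[-1, 1]}.  Rules 1--18 cover activating
#' (missense / in-frame indel) variants, 19--27 truncating variants and
#' 28--30 unmutated genes.  The \code{Expression} variable in the file is a
#' generic placeholder that [score_cohort()] replaces per gene with the
#' tertile fit from [fit_expression_memberships()].
#'
#' @return An \code{oncofuzz_rulebase} with 30 rules.
#' @export
default_rulebase <- function() {
  path <- system.file("extdata", "gene_activity.fcl", package = "oncofuzz",
                      mustWork = TRUE)
  parse_rulebase(path)
}
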