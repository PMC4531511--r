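# Boolean expression trees used for all update rules.
#
# An expression is a nested list with an `op` field:
#   "lit"   - list(op = "lit", name = <node id>)
#   "not"   - list(op = "not", arg = <expr>)
#   "and"   - list(op = "and", args = list(<expr>, ...))   (n-ary)
#   "or"    - list(op = "or",  args = list(<expr>, ...))   (n-ary)
#   "true"  - list(op = "true")
#   "false" - list(op = "false")
# Constructors simplify constants so that e.g. conjoining a TRUE availability
# term leaves a rule structurally unchanged.

#' Boolean expression constructors
#'
#' Build the expression trees used as update-rule right-hand sides. `b_and()`
#' and `b_or()` are n-ary, flatten nested calls of the same operator and
#' simplify constants (`b_and()` drops TRUE factors and collapses to FALSE if
#' any factor is FALSE; `b_or()` dually). An empty `b_and()` is TRUE and an
#' empty `b_or()` is FALSE, so rules built from empty producer/contingency
#' sets take their conventional values.
#'
#' @param name Node id referenced by a literal.
#' @param e,... Expressions.
#' @return An object of class `bool_expr`.
#' @examples
#' b_and(b_lit("A"), b_not(b_lit("B")))
#' @export
b_lit <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(op = "lit", name = name), class = "bool_expr")
}

#' @rdname b_lit
#' @export
b_true <- function() structure(list(op = "true"), class = "bool_expr")

#' @rdname b_lit
#' @export
b_false <- function() structure(list(op = "false"), class = "bool_expr")

#' @rdname b_lit
#' @export
b_not <- function(e) {
  stopifnot(inherits(e, "bool_expr"))
  if (e$op == "true") return(b_false())
  if (e$op == "false") return(b_true())
  if (e$op == "not") return(e$arg)
  structure(list(op = "not", arg = e), class = "bool_expr")
}

collect_args <- function(dots, op) {
  out <- list()
  for (e in dots) {
    if (is.null(e)) next
    stopifnot(inherits(e, "bool_expr"))
    if (e$op == op) out <- c(out, e$args) else out <- c(out, list(e))
  }
  out
}

#' @rdname b_lit
#' @export
b_and <- function(...) {
  args <- collect_args(list(...), "and")
  args <- Filter(function(e) e$op != "true", args)
  if (any(vapply(args, function(e) e$op == "false", logical(1)))) {
    return(b_false())
  }
  if (length(args) == 0L) return(b_true())
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "and", args = args), class = "bool_expr")
}

#' @rdname b_lit
#' @export
b_or <- function(...) {
  args <- collect_args(list(...), "or")
  args <- Filter(function(e) e$op != "false", args)
  if (any(vapply(args, function(e) e$op == "true", logical(1)))) {
    return(b_true())
  }
  if (length(args) == 0L) return(b_false())
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "or", args = args), class = "bool_expr")
}

#' Literals referenced by an expression
#'
#' @param e A `bool_expr`.
#' @return Character vector of distinct node ids, in first-appearance order.
#' @export
expr_vars <- function(e) {
  switch(e$op,
    lit = e$name,
    not = expr_vars(e$arg),
    and = ,
    or = unique(unlist(lapply(e$args, expr_vars))),
    character(0)
  )
}

#' Evaluate an expression over a state matrix
#'
#' @param e A `bool_expr`.
#' @param state A logical matrix with one column per node (named), or a named
#'   logical vector for a single state.
#' @return Logical vector with one entry per row of `state`.
#' @export
expr_eval <- function(e, state) {
  if (!is.matrix(state)) state <- matrix(state, nrow = 1L, dimnames = list(NULL, names(state)))
  f <- expr_compile(e)
  f(state)
}

# Compile an expression to a fast function(state_matrix) -> logical vector.
# Literals become column lookups by position resolved at call time via names.
expr_compile <- function(e) {
  body <- expr_build_call(e)
  f <- eval(call("function", as.pairlist(alist(S = )), body), baseenv())
  # constant expressions must still return nrow(S) values
  if (e$op %in% c("true", "false")) {
    val <- e$op == "true"
    f <- function(S) rep(val, nrow(S))
  }
  f
}

expr_build_call <- function(e) {
  switch(e$op,
    lit = substitute(S[, nm], list(nm = e$name)),
    not = call("!", expr_build_call(e$arg)),
    and = Reduce(function(a, b) call("&", a, b), lapply(e$args, expr_build_call)),
    or = Reduce(function(a, b) call("|", a, b), lapply(e$args, expr_build_call)),
    true = TRUE,
    false = FALSE
  )
}

#' Render an expression as text
#'
#' @param e A `bool_expr`.
#' @param dialect `"ascii"` uses `& | !`; `"booleannet"` uses `and or not`;
#'   `"boolnet"` uses `& | !` with constants `1`/`0`.
#' @param rename Optional named character vector mapping node ids to output
#'   names (used by the file writers for sanitized identifiers).
#' @return A single string.
#' @export
expr_to_string <- function(e, dialect = c("ascii", "booleannet", "boolnet"),
                           rename = NULL) {
  dialect <- match.arg(dialect)
  ops <- switch(dialect,
    ascii = c(and = " & ", or = " | ", not = "!", true = "TRUE", false = "FALSE"),
    booleannet = c(and = " and ", or = " or ", not = "not ", true = "True", false = "False"),
    boolnet = c(and = " & ", or = " | ", not = "!", true = "1", false = "0")
  )
  render <- function(e, parent) {
    switch(e$op,
      lit = if (!is.null(rename) && e$name %in% names(rename)) rename[[e$name]] else e$name,
      true = ops[["true"]],
      false = ops[["false"]],
      not = {
        inner <- render(e$arg, "not")
        if (e$arg$op %in% c("and", "or")) inner <- paste0("(", inner, ")")
        paste0(ops[["not"]], inner)
      },
      and = ,
      or = {
        parts <- vapply(e$args, render, character(1), parent = e$op)
        s <- paste(parts, collapse = ops[[e$op]])
        if ((parent %in% c("and", "or") && parent != e$op) || parent == "not") {
          s <- paste0("(", s, ")")
        }
        s
      }
    )
  }
  render(e, "top")
}

#' @export
format.bool_expr <- function(x, ...) expr_to_string(x)

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", expr_to_string(x), "\n", sep = "")
  invisible(x)
}

#' Truth-table equivalence of two expressions
#'
#' Compares two expressions over all assignments of their (combined) literals.
#' Intended for model verification and tests; exponential in the number of
#' distinct literals.
#'
#' @param a,b Expressions.
#' @param vars Optional character vector of variables to enumerate; defaults
#'   to the union of the literals of `a` and `b`.
#' @return TRUE/FALSE.
#' @export
expr_equivalent <- function(a, b, vars = NULL) {
  if (is.null(vars)) vars <- union(expr_vars(a), expr_vars(b))
  if (length(vars) == 0L) {
    return(isTRUE(expr_eval(a, matrix(logical(0), nrow = 1))[1] ==
                    expr_eval(b, matrix(logical(0), nrow = 1))[1]))
  }
  if (length(vars) > 20L) stop("too many variables for truth-table comparison")
  tt <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(vars))))
  colnames(tt) <- vars
  all(expr_eval(a, tt) == expr_eval(b, tt))
}
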