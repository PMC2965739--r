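# Boolean regulatory-rule language: parser, evaluator, MILP linearization.
#
# Rules are Boolean expressions over transcription factors, genes,
# environmental predicates ("leu-L(e)>0": metabolite available in the
# medium), and flux predicates ("Growth>0", "AGMT>0": a reaction carries
# flux). Operator precedence is NOT > AND > OR; unparenthesized chains of the
# same operator are flattened into one n-ary node.

bx_const <- function(value) {
  structure(list(kind = "const", value = isTRUE(value)), class = "bool_expr")
}

bx_ref <- function(name, kind = c("symbol", "env", "flux"), threshold = NA_real_) {
  kind <- match.arg(kind)
  structure(list(kind = "ref",
                 ref = list(name = name, kind = kind, threshold = threshold)),
            class = "bool_expr")
}

bx_not <- function(x) structure(list(kind = "not", args = list(x)), class = "bool_expr")

bx_op <- function(op, args) {
  stopifnot(length(args) >= 2)
  structure(list(kind = op, args = args), class = "bool_expr")
}

#' Canonical assignment key of a symbol reference
#'
#' Plain symbols are keyed by name; environmental predicates as
#' `"<met>(e)><threshold>"`; flux predicates as `"<rxn>><threshold>"`. These
#' keys index truth assignments in [evaluate_rule()].
#'
#' @param ref A reference payload (list with `name`, `kind`, `threshold`).
#' @return A single string.
#' @export
symbol_key <- function(ref) {
  switch(ref$kind,
         symbol = ref$name,
         env = sprintf("%s(e)>%s", ref$name, format(ref$threshold)),
         flux = sprintf("%s>%s", ref$name, format(ref$threshold)))
}

# ---- tokenizer -------------------------------------------------------------

rule_tokenize <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  name_re <- "^[A-Za-z0-9_'.-]+"
  while (i <= n) {
    rest <- substr(text, i, n)
    ws <- regmatches(rest, regexpr("^[[:space:]]+", rest))
    if (length(ws)) { i <- i + nchar(ws); next }
    ch <- substr(text, i, i)
    if (ch == "(") {
      tokens[[length(tokens) + 1L]] <- list(type = "lparen", pos = i); i <- i + 1L; next
    }
    if (ch == ")") {
      tokens[[length(tokens) + 1L]] <- list(type = "rparen", pos = i); i <- i + 1L; next
    }
    if (ch == "\"") {
      m <- regmatches(rest, regexpr("^\"[^\"]*\"", rest))
      if (!length(m)) stop("rule syntax error at character ", i,
                           ": unterminated quoted symbol", call. = FALSE)
      nm <- substr(m, 2, nchar(m) - 1L)
      if (!nzchar(nm)) stop("rule syntax error at character ", i,
                            ": empty quoted symbol", call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "name", value = nm, pos = i)
      i <- i + nchar(m); next
    }
    # environmental predicate: <met>(e) with optional ><number>
    m <- regmatches(rest, regexpr("^[A-Za-z0-9_'.-]+\\(e\\)([[:space:]]*>[[:space:]]*-?[0-9.]+)?", rest))
    if (length(m)) {
      met <- sub("\\(e\\).*$", "", m)
      thr_txt <- regmatches(m, regexpr(">[[:space:]]*-?[0-9.]+", m))
      thr <- if (length(thr_txt)) as.numeric(sub(">", "", gsub("[[:space:]]", "", thr_txt))) else 0
      tokens[[length(tokens) + 1L]] <- list(type = "env", value = met, threshold = thr, pos = i)
      i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr(name_re, rest))
    if (length(m)) {
      after <- substr(text, i + nchar(m), n)
      thr_m <- regmatches(after, regexpr("^[[:space:]]*>[[:space:]]*-?[0-9.]+", after))
      if (length(thr_m) && !m %in% c("NOT", "AND", "OR", "ON", "OFF")) {
        thr <- as.numeric(sub(">", "", gsub("[[:space:]]", "", thr_m)))
        tokens[[length(tokens) + 1L]] <- list(type = "flux", value = m, threshold = thr, pos = i)
        i <- i + nchar(m) + nchar(thr_m); next
      }
      type <- switch(m, NOT = "not", AND = "and", OR = "or",
                     ON = "on", OFF = "off", "name")
      tokens[[length(tokens) + 1L]] <- list(type = type, value = m, pos = i)
      i <- i + nchar(m); next
    }
    stop("rule syntax error at character ", i, ": unexpected '", ch, "'", call. = FALSE)
  }
  tokens
}

# ---- parser ----------------------------------------------------------------

#' Parse a Boolean regulatory rule
#'
#' Parses rule text such as `"(NOT ArgR) OR (arg-L(e)>0)"` into an abstract
#' syntax tree. Operator precedence is NOT > AND > OR; `ON`/`OFF` are the
#' Boolean constants; `"quoted names"` are atomic symbols; `met(e)>0` (or
#' bare `met(e)`) is an environmental predicate and `RXN>0` a flux predicate.
#' A warning is raised when an unparenthesized operand of `OR` is an `AND`
#' chain, since precedence then decides the reading.
#'
#' @param text A single non-empty rule string with balanced parentheses.
#' @return A `bool_expr` AST.
#' @examples
#' parse_rule("(NOT ArgR) OR (arg-L(e)>0)")
#' parse_rule("(ON)")
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!nzchar(trimws(text))) stop("empty rule text", call. = FALSE)
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  inq <- FALSE
  for (k in seq_along(chars)) {
    if (chars[k] == "\"") inq <- !inq
    if (inq) next
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L) stop("rule syntax error at character ", k,
                         ": unbalanced ')'", call. = FALSE)
  }
  if (depth != 0L) stop("rule syntax error at character ", nchar(text),
                        ": ", depth, " unclosed '('", call. = FALSE)

  tokens <- rule_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$tokens <- tokens
  st$i <- 1L
  st$warned <- FALSE

  peek <- function() if (st$i <= length(st$tokens)) st$tokens[[st$i]] else NULL
  advance <- function() { tk <- peek(); st$i <- st$i + 1L; tk }
  fail <- function(tk, what) {
    pos <- if (is.null(tk)) nchar(text) + 1L else tk$pos
    stop("rule syntax error at character ", pos, ": ", what, call. = FALSE)
  }

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) fail(tk, "unexpected end of rule (empty operand)")
    if (tk$type == "lparen") {
      advance()
      e <- parse_or()
      tk2 <- peek()
      if (is.null(tk2) || tk2$type != "rparen") fail(tk2, "expected ')'")
      advance()
      attr(e, "paren") <- TRUE
      return(e)
    }
    if (tk$type == "not") { advance(); return(bx_not(parse_primary())) }
    if (tk$type == "on") { advance(); return(bx_const(TRUE)) }
    if (tk$type == "off") { advance(); return(bx_const(FALSE)) }
    if (tk$type == "name") { advance(); return(bx_ref(tk$value, "symbol")) }
    if (tk$type == "env") { advance(); return(bx_ref(tk$value, "env", tk$threshold)) }
    if (tk$type == "flux") { advance(); return(bx_ref(tk$value, "flux", tk$threshold)) }
    fail(tk, paste0("unexpected '", tk$type, "' (dangling operator or empty operand)"))
  }

  parse_and <- function() {
    args <- list(parse_primary())
    while (!is.null(peek()) && peek()$type == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_primary()
    }
    if (length(args) == 1L) args[[1L]] else bx_op("and", args)
  }

  parse_or <- function() {
    args <- list(parse_and())
    while (!is.null(peek()) && peek()$type == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) return(args[[1L]])
    unparen_and <- vapply(args, function(a) {
      a$kind == "and" && !isTRUE(attr(a, "paren"))
    }, logical(1))
    if (any(unparen_and) && !st$warned) {
      st$warned <- TRUE
      warning("rule mixes AND and OR without parentheses; ",
              "reading with precedence NOT > AND > OR", call. = FALSE)
    }
    bx_op("or", args)
  }

  e <- parse_or()
  tk <- peek()
  if (!is.null(tk)) fail(tk, "trailing input after complete rule")
  attr(e, "paren") <- NULL
  e
}

#' Render a rule AST back to text
#'
#' Produces a fully parenthesized canonical form; `parse_rule(deparse_rule(x))`
#' is structurally identical to `x`.
#'
#' @param expr A `bool_expr`.
#' @return A single string.
#' @export
deparse_rule <- function(expr) {
  wrap <- function(e) {
    txt <- go(e)
    if (e$kind %in% c("and", "or", "not")) paste0("(", txt, ")") else txt
  }
  go <- function(e) {
    switch(e$kind,
           const = if (e$value) "ON" else "OFF",
           ref = {
             r <- e$ref
             if (r$kind == "symbol") {
               if (grepl("[^A-Za-z0-9_'.-]", r$name)) paste0("\"", r$name, "\"") else r$name
             } else if (r$kind == "env") {
               sprintf("%s(e)>%s", r$name, format(r$threshold))
             } else {
               sprintf("%s>%s", r$name, format(r$threshold))
             }
           },
           not = paste0("NOT ", wrap(e$args[[1L]])),
           and = paste(vapply(e$args, wrap, character(1)), collapse = " AND "),
           or = paste(vapply(e$args, wrap, character(1)), collapse = " OR "))
  }
  go(expr)
}

#' @export
print.bool_expr <- function(x, ...) {
  cat("<bool_expr> ", deparse_rule(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a rule under a truth assignment
#'
#' @param expr A `bool_expr`.
#' @param assignment Named logical vector (or list) keyed by [symbol_key()]
#'   values; every symbol occurring in `expr` must be present.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_rule <- function(expr, assignment = logical()) {
  go <- function(e) {
    switch(e$kind,
           const = e$value,
           ref = {
             key <- symbol_key(e$ref)
             if (!key %in% names(assignment)) {
               stop("unresolved symbol in rule: '", key, "'", call. = FALSE)
             }
             isTRUE(as.logical(assignment[[key]]))
           },
           not = !go(e$args[[1L]]),
           and = all(vapply(e$args, go, logical(1))),
           or = any(vapply(e$args, go, logical(1))))
  }
  go(expr)
}

#' List the distinct symbols referenced by a rule
#'
#' @param expr A `bool_expr`.
#' @return A tibble with columns `key`, `name`, `kind`, `threshold`; one row
#'   per distinct reference.
#' @export
free_symbols <- function(expr) {
  acc <- list()
  go <- function(e) {
    if (e$kind == "ref") {
      acc[[symbol_key(e$ref)]] <<- e$ref
    } else if (e$kind != "const") {
      for (a in e$args) go(a)
    }
  }
  go(expr)
  if (!length(acc)) {
    return(tibble::tibble(key = character(), name = character(),
                          kind = character(), threshold = numeric()))
  }
  tibble::tibble(
    key = names(acc),
    name = unname(vapply(acc, `[[`, character(1), "name")),
    kind = unname(vapply(acc, `[[`, character(1), "kind")),
    threshold = unname(vapply(acc, function(r) as.numeric(r$threshold), numeric(1)))
  )
}

#' Linearize a rule into MILP constraints
#'
#' Adds to `p` an exact mixed-integer encoding tying the binary variable
#' `out_var` to the value of `expr`: for every 0/1 assignment of the leaf
#' variables, the unique feasible value of `out_var` equals
#' [evaluate_rule()]. NOT is encoded by complement, AND/OR by the standard
#' min/max inequalities with one auxiliary binary per internal node.
#'
#' @param p A `milp_problem` (modified in place).
#' @param expr A `bool_expr`.
#' @param out_var Name of an existing binary variable in `p`.
#' @param leaf_var Function mapping a reference payload to the name of an
#'   existing binary variable in `p`.
#' @return `out_var`, invisibly.
#' @export
linearize_rule <- function(p, expr, out_var, leaf_var) {
  # returns the variable name carrying the value of e
  lin <- function(e) {
    switch(e$kind,
           const = {
             z <- milp_fresh_name(p, "const")
             v <- if (e$value) 1 else 0
             milp_add_var(p, z, lb = v, ub = v, binary = TRUE)
             z
           },
           ref = leaf_var(e$ref),
           not = {
             a <- lin(e$args[[1L]])
             z <- milp_fresh_name(p, "not")
             milp_add_var(p, z, binary = TRUE)
             milp_add_con(p, stats::setNames(c(1, 1), c(z, a)), "=", 1)
             z
           },
           and = {
             avars <- vapply(e$args, lin, character(1))
             z <- milp_fresh_name(p, "and")
             milp_add_var(p, z, binary = TRUE)
             for (a in avars) {
               milp_add_con(p, stats::setNames(c(1, -1), c(z, a)), "<=", 0)
             }
             milp_add_con(p, stats::setNames(c(1, rep(-1, length(avars))), c(z, avars)),
                          ">=", 1 - length(avars))
             z
           },
           or = {
             avars <- vapply(e$args, lin, character(1))
             z <- milp_fresh_name(p, "or")
             milp_add_var(p, z, binary = TRUE)
             for (a in avars) {
               milp_add_con(p, stats::setNames(c(1, -1), c(z, a)), ">=", 0)
             }
             milp_add_con(p, stats::setNames(c(1, rep(-1, length(avars))), c(z, avars)),
                          "<=", 0)
             z
           })
  }
  z <- lin(expr)
  if (!identical(z, out_var)) {
    milp_add_con(p, stats::setNames(c(1, -1), c(out_var, z)), "=", 0)
  }
  invisible(out_var)
}
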