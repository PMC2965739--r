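test_that("published rule strings parse to the expected structure", {
  e <- parse_rule("(NOT ArgR) OR (arg-L(e)>0)")
  expect_equal(e$kind, "or")
  expect_length(e$args, 2)
  expect_equal(e$args[[1]]$kind, "not")
  expect_equal(e$args[[1]]$args[[1]]$ref$name, "ArgR")
  expect_equal(e$args[[2]]$ref,
               list(name = "arg-L", kind = "env", threshold = 0))

  expect_equal(parse_rule("(ON)")$kind, "const")
  expect_true(parse_rule("(ON)")$value)
  expect_false(parse_rule("OFF")$value)

  # NOT binds tighter than AND
  e <- parse_rule("NOT A AND B")
  expect_equal(e$kind, "and")
  expect_equal(e$args[[1]]$kind, "not")
  expect_equal(e$args[[2]]$ref$name, "B")

  # flux predicates, quoted symbols, bare environmental atoms
  e <- parse_rule("(NOT (AGMT>0))")
  expect_equal(e$args[[1]]$ref, list(name = "AGMT", kind = "flux", threshold = 0))
  e <- parse_rule('("CRP noMAN") AND NOT(ArcA)')
  expect_equal(e$args[[1]]$ref$name, "CRP noMAN")
  e <- parse_rule("(man(e))")
  expect_equal(e$ref, list(name = "man", kind = "env", threshold = 0))
})

test_that("syntax errors carry a character offset", {
  expect_error(parse_rule("(A OR B"), "character")
  expect_error(parse_rule("A OR )B("), "unbalanced")
  expect_error(parse_rule("A AND"), "empty operand|end of rule")
  expect_error(parse_rule("AND A"), "dangling|unexpected")
  expect_error(parse_rule(""), "empty")
})

test_that("unparenthesized AND under OR triggers the precedence warning", {
  expect_warning(parse_rule("NOT a OR b AND c"), "precedence")
  expect_silent(parse_rule("(NOT a) OR (b AND c)"))
})

test_that("evaluation implements Boolean semantics and flags unresolved symbols", {
  e <- parse_rule("(NOT ArgR) OR (arg-L(e)>0)")
  expect_true(evaluate_rule(e, c(ArgR = TRUE, `arg-L(e)>0` = TRUE)))
  expect_false(evaluate_rule(e, c(ArgR = TRUE, `arg-L(e)>0` = FALSE)))
  expect_true(evaluate_rule(parse_rule("(ON)")))
  expect_error(evaluate_rule(e, c(ArgR = TRUE)), "arg-L")
})

test_that("free_symbols returns the distinct reference set", {
  s <- free_symbols(parse_rule("(RhaR OR (RhaR AND Crp))"))
  expect_setequal(s$name, c("RhaR", "Crp"))
  expect_equal(nrow(free_symbols(parse_rule("(ON)"))), 0)
  s <- free_symbols(parse_rule("(NOT (PurR AND Crp))"))
  expect_setequal(s$name, c("PurR", "Crp"))
  s <- free_symbols(parse_rule("(x(e)>0) AND (R1>0) AND TF"))
  expect_setequal(s$kind, c("env", "flux", "symbol"))
})

test_that("round-trip is the identity on every published table rule", {
  fix <- system.file("extdata", "ecoli_styphimurium_rules.tsv",
                     package = "geneforce")
  lines <- readLines(fix)
  body <- lines[!grepl("^#", lines) & nzchar(lines)][-1]
  rules <- vapply(strsplit(body, "\t"), `[[`, character(1), 2)
  expect_gt(length(rules), 50)
  for (r in rules) {
    e1 <- suppressWarnings(parse_rule(r))
    e2 <- suppressWarnings(parse_rule(deparse_rule(e1)))
    expect_identical(strip_paren_attrs(e1), strip_paren_attrs(e2), label = r)
  }
})

test_that("linearization is exact for every leaf assignment (random ASTs)", {
  set.seed(7)
  random_ast <- function(depth, syms) {
    if (depth == 0 || runif(1) < 0.3) {
      if (runif(1) < 0.1) return(parse_rule(sample(c("ON", "OFF"), 1)))
      return(parse_rule(sample(syms, 1)))
    }
    op <- sample(c("not", "and", "or"), 1)
    if (op == "not") {
      e <- random_ast(depth - 1, syms)
      return(parse_rule(paste0("NOT (", deparse_rule(e), ")")))
    }
    k <- sample(2:3, 1)
    kids <- vapply(replicate(k, random_ast(depth - 1, syms), simplify = FALSE),
                   function(e) paste0("(", deparse_rule(e), ")"), character(1))
    parse_rule(paste(kids, collapse = if (op == "and") " AND " else " OR "))
  }
  syms <- c("s1", "s2", "s3", "s4", "s5", "s6")
  for (i in 1:150) {
    ast <- random_ast(sample(2:5, 1), syms)
    leaves <- free_symbols(ast)$name
    nl <- length(leaves)
    masks <- if (nl <= 4) 0:(2^nl - 1) else sample(0:(2^nl - 1), 12)
    for (mask in masks) {
      vals <- as.numeric(bitwAnd(bitwShiftR(mask, seq_len(max(nl, 1)) - 1), 1L))[seq_len(nl)]
      p <- milp_new("max")
      for (j in seq_len(nl)) {
        milp_add_var(p, leaves[j], lb = vals[j], ub = vals[j], binary = TRUE)
      }
      milp_add_var(p, "out", binary = TRUE)
      linearize_rule(p, ast, "out", function(ref) ref$name)
      want <- as.numeric(evaluate_rule(ast, stats::setNames(as.logical(vals), leaves)))
      milp_set_objective(p, c(out = 1), sense = "max")
      expect_equal(milp_solve(p)$objective, want, tolerance = 1e-7)
      milp_set_objective(p, c(out = 1), sense = "min")
      expect_equal(milp_solve(p)$objective, want, tolerance = 1e-7)
    }
  }
})
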