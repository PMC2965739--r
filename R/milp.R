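# Bounded-variable LP / MILP layer.
#
# All optimization in the package goes through this minimal interface:
# variables with finite bounds (continuous or binary), dense linear
# constraints, a linear objective, and branch-and-bound on the binaries.
# Problems in this package are small (tens to a few hundred variables), so a
# dense two-phase tableau simplex with bound rows is adequate and keeps the
# package dependency-light.

#' Create an empty optimization problem
#'
#' Builds a mutable problem object to which variables and constraints are
#' added with [milp_add_var()] and [milp_add_con()], then solved with
#' [milp_solve()]. Continuous variables must have finite bounds (metabolic
#' fluxes are always bounded in this package, by default at
#' +/-1000 mmol/gDW/hr).
#'
#' @param sense "max" or "min".
#' @return An object of class `milp_problem`.
#' @keywords internal
#' @export
milp_new <- function(sense = c("max", "min")) {
  sense <- match.arg(sense)
  p <- new.env(parent = emptyenv())
  p$sense <- sense
  p$var_names <- character()
  p$lb <- numeric()
  p$ub <- numeric()
  p$obj <- numeric()
  p$binary <- logical()
  p$cons <- list()     # each: list(idx, coef, dir, rhs)
  p$fresh_counter <- 0L
  class(p) <- "milp_problem"
  p
}

#' @export
print.milp_problem <- function(x, ...) {
  cat(sprintf("<milp_problem: %d vars (%d binary), %d constraints, sense=%s>\n",
              length(x$var_names), sum(x$binary), length(x$cons), x$sense))
  invisible(x)
}

#' Add a variable to an optimization problem
#'
#' @param p A `milp_problem`.
#' @param name Unique variable name.
#' @param lb,ub Finite bounds. Binary variables are clamped to \[0, 1\].
#' @param binary Declare the variable integer in \{0, 1\}.
#' @param obj Objective coefficient.
#' @return The variable name, invisibly usable as an id.
#' @keywords internal
#' @export
milp_add_var <- function(p, name, lb = 0, ub = 1, binary = FALSE, obj = 0) {
  stopifnot(inherits(p, "milp_problem"))
  if (name %in% p$var_names) {
    stop("duplicate variable name: ", name, call. = FALSE)
  }
  if (!is.finite(lb) || !is.finite(ub)) {
    stop("variable '", name, "' must have finite bounds", call. = FALSE)
  }
  if (lb > ub) stop("variable '", name, "' has lb > ub", call. = FALSE)
  if (binary) {
    lb <- max(0, lb)
    ub <- min(1, ub)
  }
  p$var_names <- c(p$var_names, name)
  p$lb <- c(p$lb, lb)
  p$ub <- c(p$ub, ub)
  p$obj <- c(p$obj, obj)
  p$binary <- c(p$binary, binary)
  invisible(name)
}

#' Generate a fresh auxiliary variable name
#' @keywords internal
#' @export
milp_fresh_name <- function(p, prefix = "aux") {
  p$fresh_counter <- p$fresh_counter + 1L
  sprintf(".%s%d", prefix, p$fresh_counter)
}

#' Add a linear constraint
#'
#' @param p A `milp_problem`.
#' @param coefs Named numeric vector: names are variable names.
#' @param dir One of `"<="`, `">="`, `"="`.
#' @param rhs Right-hand side.
#' @keywords internal
#' @export
milp_add_con <- function(p, coefs, dir, rhs) {
  stopifnot(inherits(p, "milp_problem"))
  dir <- match.arg(dir, c("<=", ">=", "="))
  idx <- match(names(coefs), p$var_names)
  if (anyNA(idx)) {
    stop("constraint references unknown variable(s): ",
         paste(names(coefs)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  # aggregate repeated references to the same variable
  u <- unique(idx)
  co <- vapply(u, function(j) sum(coefs[idx == j]), numeric(1))
  keep <- co != 0
  p$cons[[length(p$cons) + 1L]] <-
    list(idx = u[keep], coef = unname(co[keep]), dir = dir, rhs = rhs)
  invisible(p)
}

#' Replace the objective vector
#'
#' @param p A `milp_problem`.
#' @param coefs Named numeric vector (variables not named get coefficient 0).
#' @param sense Optionally switch between "max" and "min".
#' @keywords internal
#' @export
milp_set_objective <- function(p, coefs, sense = NULL) {
  stopifnot(inherits(p, "milp_problem"))
  obj <- numeric(length(p$var_names))
  idx <- match(names(coefs), p$var_names)
  if (anyNA(idx)) stop("objective references unknown variable(s)", call. = FALSE)
  for (k in seq_along(idx)) obj[idx[k]] <- obj[idx[k]] + coefs[k]
  p$obj <- obj
  if (!is.null(sense)) p$sense <- match.arg(sense, c("max", "min"))
  invisible(p)
}

# Two-phase dense tableau simplex with Bland's anti-cycling rule.
#
# Minimizes obj over { A x (dir) b, x >= 0 }. dirs in {"<=", ">=", "="},
# b >= 0 required (callers normalize). Returns list(status, x, objective).
dense_simplex <- function(A, b, dirs, obj, tol = 1e-9) {
  m <- nrow(A); n0 <- ncol(A)
  if (m == 0L) {
    # unconstrained non-negative minimization: 0 if obj >= 0 else unbounded
    if (any(obj < -tol)) return(list(status = "unbounded"))
    return(list(status = "optimal", x = numeric(n0), objective = 0))
  }
  n_slack <- sum(dirs != "=")
  n_art <- sum(dirs != "<=")
  n <- n0 + n_slack + n_art
  Tm <- matrix(0, m, n)
  Tm[, seq_len(n0)] <- A
  basis <- integer(m)
  art_cols <- integer(0)
  sl <- n0; ar <- n0 + n_slack
  for (i in seq_len(m)) {
    if (dirs[i] == "<=") {
      sl <- sl + 1L; Tm[i, sl] <- 1; basis[i] <- sl
    } else if (dirs[i] == ">=") {
      sl <- sl + 1L; Tm[i, sl] <- -1
      ar <- ar + 1L; Tm[i, ar] <- 1; basis[i] <- ar
      art_cols <- c(art_cols, ar)
    } else {
      ar <- ar + 1L; Tm[i, ar] <- 1; basis[i] <- ar
      art_cols <- c(art_cols, ar)
    }
  }
  xb <- b
  max_iter <- 2000L + 200L * (m + n)

  run_phase <- function(cost, banned) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return("iteration_limit")
      # reduced costs r = cost - cost[basis] %*% Tm
      r <- cost - as.numeric(crossprod(cost[basis], Tm))
      r[banned] <- Inf
      cand <- which(r < -tol)
      if (!length(cand)) return("optimal")
      q <- cand[1L]  # Bland: smallest index
      col <- Tm[, q]
      pos <- which(col > tol)
      if (!length(pos)) return("unbounded")
      ratio <- xb[pos] / col[pos]
      best <- min(ratio)
      ties <- pos[ratio <= best + tol]
      p <- ties[which.min(basis[ties])]  # Bland tie-break
      piv <- Tm[p, q]
      Tm[p, ] <<- Tm[p, ] / piv
      xb[p] <<- xb[p] / piv
      other <- setdiff(seq_len(m), p)
      if (length(other)) {
        f <- Tm[other, q]
        Tm[other, ] <<- Tm[other, , drop = FALSE] - outer(f, Tm[p, ])
        xb[other] <<- xb[other] - f * xb[p]
      }
      basis[p] <<- q
      xb[xb < 0 & xb > -1e-9] <<- 0
    }
  }

  if (n_art > 0L) {
    cost1 <- numeric(n); cost1[art_cols] <- 1
    st <- run_phase(cost1, banned = integer(0))
    if (st != "optimal") return(list(status = st))
    if (sum(xb[basis %in% art_cols]) > 1e-7) {
      return(list(status = "infeasible"))
    }
    # pivot remaining (degenerate) artificials out where possible
    for (i in which(basis %in% art_cols)) {
      row <- Tm[i, seq_len(n0 + n_slack)]
      j <- which(abs(row) > tol)
      if (length(j)) {
        q <- j[1L]
        piv <- Tm[i, q]
        Tm[i, ] <- Tm[i, ] / piv
        xb[i] <- xb[i] / piv
        other <- setdiff(seq_len(m), i)
        f <- Tm[other, q]
        Tm[other, ] <- Tm[other, , drop = FALSE] - outer(f, Tm[i, ])
        xb[other] <- xb[other] - f * xb[i]
        basis[i] <- q
      }
      # else: redundant row; leave the zero-level artificial basic but ban it
    }
  }
  cost2 <- c(obj, numeric(n - n0))
  st <- run_phase(cost2, banned = art_cols)
  if (st != "optimal") return(list(status = st))
  x <- numeric(n)
  x[basis] <- xb
  x0 <- x[seq_len(n0)]
  list(status = "optimal", x = x0, objective = sum(obj * x0))
}

# Solve the LP relaxation with variable bounds lb/ub (overrides), returning
# list(status, objective, x). Variables are shifted to t = x - lb >= 0 and
# upper bounds become <=-rows; right-hand sides are normalized non-negative.
lp_solve_bounded <- function(obj, cons, lb, ub, sense, ...) {
  n <- length(obj)
  shift <- lb
  span <- ub - lb

  rows <- list(); dirs <- character(); rhs <- numeric()
  for (cn in cons) {
    row <- numeric(n)
    row[cn$idx] <- cn$coef
    b <- cn$rhs - sum(row * shift)
    dir <- cn$dir
    if (all(row == 0)) {
      ok <- switch(dir,
                   "<=" = b >= -1e-9,
                   ">=" = b <= 1e-9,
                   "="  = abs(b) <= 1e-9)
      if (!ok) return(list(status = "infeasible", objective = NA_real_, x = NULL))
      next
    }
    if (b < 0) {
      row <- -row; b <- -b
      dir <- switch(dir, "<=" = ">=", ">=" = "<=", "=" = "=")
    }
    rows[[length(rows) + 1L]] <- row
    dirs <- c(dirs, dir)
    rhs <- c(rhs, b)
  }
  # upper-bound rows t_i <= span_i (span >= 0 by construction); skip fixed
  # variables (span 0), which the non-negativity of t already pins
  for (i in seq_len(n)) {
    if (span[i] <= 0) next
    row <- numeric(n); row[i] <- 1
    rows[[length(rows) + 1L]] <- row
    dirs <- c(dirs, "<=")
    rhs <- c(rhs, span[i])
  }
  A <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, n)
  # fixed variables: force t = 0 by dropping their columns
  fixed <- span <= 0
  if (any(fixed)) {
    if (nrow(A) > 0) A <- A[, !fixed, drop = FALSE]
    obj_red <- obj[!fixed]
  } else {
    obj_red <- obj
  }
  eff_obj <- if (sense == "max") -obj_red else obj_red
  res <- dense_simplex(A, rhs, dirs, eff_obj)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_, x = NULL))
  }
  t <- numeric(n)
  t[!fixed] <- res$x
  x <- t + shift
  list(status = "optimal", objective = sum(obj * x), x = x)
}

#' Solve an optimization problem
#'
#' Continuous problems are solved directly; problems with binary variables by
#' branch-and-bound on the most fractional binary, depth-first with
#' best-bound pruning. Deterministic for a fixed problem.
#'
#' @param p A `milp_problem`.
#' @param int_tol Integrality tolerance on binaries.
#' @param gap_tol Absolute pruning tolerance on the objective.
#' @param node_limit Safety cap on branch-and-bound nodes.
#' @return A list with `status` ("optimal", "infeasible", or an error status),
#'   `objective`, and `solution` (named numeric vector; binaries rounded).
#' @keywords internal
#' @export
milp_solve <- function(p, int_tol = 1e-6, gap_tol = 1e-9, node_limit = 200000L) {
  stopifnot(inherits(p, "milp_problem"))
  n <- length(p$var_names)
  if (n == 0L) {
    return(list(status = "optimal", objective = 0,
                solution = stats::setNames(numeric(0), character(0))))
  }
  sense <- p$sense
  sgn <- if (sense == "max") 1 else -1
  bin_idx <- which(p$binary)

  solve_relax <- function(lb, ub) {
    r <- lp_solve_bounded(p$obj, p$cons, lb, ub, sense)
    if (r$status == "iteration_limit") {
      r <- lp_solve_bounded(p$obj, p$cons, lb, ub, sense, n_iter_mult = 600)
    }
    r
  }

  incumbent <- NULL
  incumbent_val <- -Inf  # in max-equivalent (sgn * objective) space

  stack <- list(list(lb = p$lb, ub = p$ub))
  nodes <- 0L
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) {
      stop("branch-and-bound node limit reached (", node_limit, ")", call. = FALSE)
    }
    r <- solve_relax(node$lb, node$ub)
    if (r$status == "infeasible") next
    if (r$status != "optimal") {
      stop("LP subproblem failed with status: ", r$status, call. = FALSE)
    }
    bound <- sgn * r$objective
    if (bound <= incumbent_val + gap_tol) next
    frac <- abs(r$x[bin_idx] - round(r$x[bin_idx]))
    if (!length(bin_idx) || max(frac) <= int_tol) {
      x <- r$x
      x[bin_idx] <- round(x[bin_idx])
      incumbent <- x
      incumbent_val <- bound
      next
    }
    j <- bin_idx[which.max(frac)]
    xj <- r$x[j]
    lo <- node; hi <- node
    lo$ub[j] <- 0
    hi$lb[j] <- 1
    # dive first into the branch nearer the relaxation value
    if (xj >= 0.5) {
      stack[[length(stack) + 1L]] <- lo
      stack[[length(stack) + 1L]] <- hi
    } else {
      stack[[length(stack) + 1L]] <- hi
      stack[[length(stack) + 1L]] <- lo
    }
  }

  if (is.null(incumbent)) {
    return(list(status = "infeasible", objective = NA_real_, solution = NULL))
  }
  list(status = "optimal",
       objective = sgn * incumbent_val,
       solution = stats::setNames(incumbent, p$var_names))
}
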