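# Brute-force oracles, independent of the MILP encodings: exhaustive
# enumeration of rule-consistent Boolean states with one LP per state, and
# exhaustive violation-subset search. Only valid for models without flux
# predicates (asserted).

assert_no_flux_predicates <- function(imodel) {
  for (e in c(imodel$regulatory$rules, imodel$metabolic$gpr_ast)) {
    if (is.null(e)) next
    stopifnot(!any(free_symbols(e)$kind == "flux"))
  }
}

# all rule-consistent 0/1 assignments over genes + TFs
consistent_states <- function(imodel, env_truth, knockouts = character()) {
  m <- imodel
  genes <- m$metabolic$genes
  tfs <- m$tfs
  syms <- c(genes, tfs)
  n <- length(syms)
  rules <- m$regulatory$rules
  out <- list()
  for (mask in 0:(2^n - 1)) {
    vals <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    asg <- c(stats::setNames(as.list(vals), syms), as.list(env_truth))
    if (any(vals[match(intersect(knockouts, syms), syms)])) next
    ok <- TRUE
    for (tgt in names(rules)) {
      if (tgt %in% knockouts) next
      if (!isTRUE(evaluate_rule(rules[[tgt]], asg) == asg[[tgt]])) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- stats::setNames(vals, syms)
  }
  out
}

# LP optimum of the bounded model with reactions closed under an expression
# state (gating by direct bound manipulation, not by the MILP encoding)
state_lp_mu <- function(bounded_imodel, expressed) {
  m <- bounded_imodel
  met <- m$metabolic
  for (i in seq_len(nrow(met$reactions))) {
    gpr <- met$gpr_ast[[met$reactions$id[i]]]
    if (!gpr_available(gpr, expressed)) {
      met$reactions$lb[i] <- 0
      met$reactions$ub[i] <- 0
    }
  }
  m$metabolic <- met
  maximize_growth(m)$objective
}

# exhaustive SR-FBA optimum: max over consistent states of the per-state LP
oracle_srfba_mu <- function(imodel, cond, knockouts = character()) {
  assert_no_flux_predicates(imodel)
  ap <- apply_condition(imodel, cond)
  states <- consistent_states(imodel, ap$env_truth, knockouts)
  if (!length(states)) return(NA_real_)  # no consistent Boolean state
  best <- 0
  bounded <- if (length(knockouts)) apply_knockouts(ap$model, knockouts) else ap$model
  for (st in states) best <- max(best, state_lp_mu(bounded, st))
  best
}

# exhaustive minimum violation subsets: smallest V (over ruled, non-deleted
# metabolic genes) such that some consistent state y with expressed = y | V
# reaches the growth threshold
oracle_min_violations <- function(imodel, cond, knockouts = character(),
                                  threshold_fraction = 0.1, max_k = 4) {
  assert_no_flux_predicates(imodel)
  mu_fba <- maximize_growth(imodel, cond, knockouts)$objective
  stopifnot(mu_fba > 1e-6)
  thr <- threshold_fraction * mu_fba
  ap <- apply_condition(imodel, cond)
  bounded <- if (length(knockouts)) apply_knockouts(ap$model, knockouts) else ap$model
  states <- consistent_states(imodel, ap$env_truth, knockouts)
  ruled <- setdiff(intersect(names(imodel$regulatory$rules),
                             imodel$metabolic$genes), knockouts)
  feasible <- function(V) {
    for (st in states) {
      expressed <- st
      expressed[V] <- TRUE
      if (state_lp_mu(bounded, expressed) >= thr - 1e-7) return(TRUE)
    }
    FALSE
  }
  for (k in 0:max_k) {
    sets <- if (k == 0) list(character()) else
      apply(utils::combn(ruled, k), 2, identity, simplify = FALSE)
    hits <- Filter(feasible, sets)
    if (length(hits)) {
      return(list(k = k, sets = lapply(hits, sort)))
    }
  }
  list(k = NA_integer_, sets = list())
}

sort_sets <- function(sets) {
  sets <- lapply(sets, sort)
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}
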