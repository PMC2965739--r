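# Steady-state regulatory FBA (SR-FBA): one MILP in which stoichiometric,
# bound, GPR, and Boolean regulatory constraints hold simultaneously.
#
# Encoding: each reaction with a GPR is split into non-negative forward and
# backward components gated by a big-M indicator equal to the linearized GPR
# value over gene-expression binaries. Every regulatory rule contributes a
# fixed-point constraint (target indicator = linearized rule value).
# Environmental predicates are binaries fixed by the condition; flux
# predicates are free binaries coupled to the forward flux component
# (b = 1 implies v >= threshold + eps_flux, b = 0 implies v <= threshold).

#' Solver settings for the integrated MILPs
#'
#' @param big_m Big-M flux constant; must dominate every absolute flux bound.
#' @param eps_flux Activation threshold implementing the strict `>` of flux
#'   predicates (mmol/gDW/hr); must exceed the LP feasibility tolerance.
#' @param int_tol Integrality tolerance for branch-and-bound.
#' @param node_limit Branch-and-bound node cap.
#' @return A `solver_settings` object.
#' @export
solver_settings <- function(big_m = 1000, eps_flux = 1e-4, int_tol = 1e-6,
                            node_limit = 200000L) {
  stopifnot(big_m > 0, eps_flux > 1e-9)
  structure(list(big_m = big_m, eps_flux = eps_flux, int_tol = int_tol,
                 node_limit = as.integer(node_limit)),
            class = "solver_settings")
}

# variable-name helpers (single namespace inside one milp_problem)
v_gene <- function(g) paste0("y|", g)
v_surr <- function(g) paste0("yp|", g)
v_tf <- function(tf) paste0("x|", tf)
v_env <- function(key) paste0("e|", key)
v_fluxpred <- function(key) paste0("b|", key)
v_gate <- function(r) paste0("z|", r)
v_fwd <- function(r) paste0("vf|", r)
v_bwd <- function(r) paste0("vb|", r)

# Build the integrated MILP. Returns list(p, met, env_truth, ruled_genes,
# genes, tfs). With surrogate = TRUE, reaction gating reads the surrogate
# indicators y' for genes that have regulatory rules, and y' >= y rows are
# added; force_express genes are gated as constitutively available.
build_integrated_problem <- function(imodel, cond, knockouts, settings,
                                     surrogate = FALSE,
                                     force_express = character()) {
  stopifnot(inherits(settings, "solver_settings"))
  pr <- prepare_metabolic(imodel, cond, knockouts)
  m <- pr$model
  met <- m$metabolic
  env_truth <- pr$env_truth
  knockouts <- m$knockouts
  M <- settings$big_m
  maxb <- max(abs(c(met$reactions$lb, met$reactions$ub)))
  if (M < maxb) {
    stop("big_m (", M, ") must be at least the largest absolute flux bound (",
         maxb, ")", call. = FALSE)
  }
  unknown_force <- setdiff(force_express, met$genes)
  if (length(unknown_force)) {
    stop("force_express names unknown gene(s): ",
         paste(unknown_force, collapse = ", "), call. = FALSE)
  }

  p <- milp_new("max")
  # flux variables
  for (i in seq_len(nrow(met$reactions))) {
    milp_add_var(p, met$reactions$id[i], lb = met$reactions$lb[i],
                 ub = met$reactions$ub[i],
                 obj = as.numeric(met$reactions$id[i] == met$biomass))
  }
  for (mm in met$metabolites$id) {
    rows <- met$stoich[met$stoich$met == mm, , drop = FALSE]
    if (nrow(rows)) milp_add_con(p, stats::setNames(rows$coef, rows$rxn), "=", 0)
  }

  # gene / TF / surrogate binaries
  ruled_genes <- intersect(names(m$regulatory$rules), met$genes)
  for (g in met$genes) {
    fixed <- g %in% knockouts
    milp_add_var(p, v_gene(g), lb = 0, ub = if (fixed) 0 else 1, binary = TRUE)
  }
  if (surrogate) {
    for (g in ruled_genes) {
      fixed <- g %in% knockouts
      milp_add_var(p, v_surr(g), lb = 0, ub = if (fixed) 0 else 1, binary = TRUE)
      if (!fixed) {
        milp_add_con(p, stats::setNames(c(1, -1), c(v_surr(g), v_gene(g))), ">=", 0)
      }
    }
  }
  for (tf in m$tfs) {
    # a knocked-out TF-encoding gene fixes the TF inactive
    milp_add_var(p, v_tf(tf), lb = 0, ub = if (tf %in% knockouts) 0 else 1,
                 binary = TRUE)
  }

  # environmental predicate binaries, fixed by the condition
  for (key in names(env_truth)) {
    val <- as.numeric(env_truth[[key]])
    milp_add_var(p, v_env(key), lb = val, ub = val, binary = TRUE)
  }

  # forward/backward split for a reaction; memoized
  split_done <- new.env(parent = emptyenv())
  ensure_split <- function(r) {
    if (!is.null(split_done[[r]])) return(invisible(NULL))
    i <- match(r, met$reactions$id)
    lb <- met$reactions$lb[i]; ub <- met$reactions$ub[i]
    milp_add_var(p, v_fwd(r), lb = 0, ub = max(ub, 0))
    milp_add_var(p, v_bwd(r), lb = 0, ub = max(-lb, 0))
    milp_add_con(p, stats::setNames(c(1, -1, 1), c(r, v_fwd(r), v_bwd(r))), "=", 0)
    split_done[[r]] <- TRUE
    invisible(NULL)
  }

  # flux-predicate binaries, coupled to forward components
  fluxpred_done <- new.env(parent = emptyenv())
  ensure_fluxpred <- function(ref) {
    key <- symbol_key(ref)
    if (!is.null(fluxpred_done[[key]])) return(v_fluxpred(key))
    rxn <- if (identical(ref$name, "Growth")) met$biomass else ref$name
    if (!rxn %in% met$reactions$id) {
      stop("flux predicate references unknown reaction: ", ref$name, call. = FALSE)
    }
    ensure_split(rxn)
    b <- v_fluxpred(key)
    milp_add_var(p, b, binary = TRUE)
    tau <- max(ref$threshold, 0)
    # b = 1  =>  vf >= tau + eps ;  b = 0  =>  vf <= tau
    milp_add_con(p, stats::setNames(c(-1, tau + settings$eps_flux),
                                    c(v_fwd(rxn), b)), "<=", 0)
    milp_add_con(p, stats::setNames(c(1, -M), c(v_fwd(rxn), b)), "<=", tau)
    fluxpred_done[[key]] <- TRUE
    b
  }

  # leaf mapping for regulatory rules (read the rule-determined indicators)
  rule_leaf <- function(ref) {
    if (ref$kind == "env") {
      key <- symbol_key(ref)
      if (!key %in% names(env_truth)) {
        # predicate present in a GPR or added rule but not seen at
        # condition time: absent metabolite semantics
        milp_add_var(p, v_env(key), lb = 0, ub = 0, binary = TRUE)
        env_truth[[key]] <<- FALSE
      }
      return(v_env(key))
    }
    if (ref$kind == "flux") return(ensure_fluxpred(ref))
    nm <- resolve_alias(ref$name, m$aliases)
    if (nm %in% met$genes) return(v_gene(nm))
    if (nm %in% m$tfs || nm %in% names(m$regulatory$rules)) return(v_tf(nm))
    stop("rule references unresolvable symbol: ", ref$name, call. = FALSE)
  }

  # fixed-point constraints for every rule (skipped for knocked-out genes)
  for (tgt in names(m$regulatory$rules)) {
    nm <- resolve_alias(tgt, m$aliases)
    if (nm %in% knockouts) next
    out <- if (nm %in% met$genes) v_gene(nm) else v_tf(nm)
    linearize_rule(p, m$regulatory$rules[[tgt]], out, rule_leaf)
  }

  # constitutive-availability leaves for forced expression
  one_var <- NULL
  gate_leaf <- function(ref) {
    nm <- resolve_alias(ref$name, m$aliases)
    if (ref$kind != "symbol" || !nm %in% met$genes) return(rule_leaf(ref))
    if (nm %in% force_express && !nm %in% knockouts) {
      if (is.null(one_var)) {
        one_var <<- milp_fresh_name(p, "one")
        milp_add_var(p, one_var, lb = 1, ub = 1, binary = TRUE)
      }
      return(one_var)
    }
    if (surrogate && nm %in% ruled_genes) return(v_surr(nm)) else return(v_gene(nm))
  }

  # GPR gating with big-M on split components
  for (r in met$reactions$id) {
    gpr <- met$gpr_ast[[r]]
    if (is.null(gpr)) next
    z <- v_gate(r)
    milp_add_var(p, z, binary = TRUE)
    linearize_rule(p, gpr, z, gate_leaf)
    ensure_split(r)
    milp_add_con(p, stats::setNames(c(1, -M), c(v_fwd(r), z)), "<=", 0)
    milp_add_con(p, stats::setNames(c(1, -M), c(v_bwd(r), z)), "<=", 0)
  }

  list(p = p, model = m, met = met, env_truth = env_truth,
       ruled_genes = ruled_genes, knockouts = knockouts)
}

extract_boolean_state <- function(built, sol) {
  met <- built$met
  m <- built$model
  take <- function(vn) unname(round(sol[vn]))
  rows <- list()
  if (length(met$genes)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = met$genes, type = "gene", value = take(v_gene(met$genes)))
  }
  if (length(m$tfs)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = m$tfs, type = "tf", value = take(v_tf(m$tfs)))
  }
  env_keys <- names(built$env_truth)
  if (length(env_keys)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = env_keys, type = "env", value = as.numeric(unlist(built$env_truth)))
  }
  flux_keys <- grep("^b\\|", names(sol), value = TRUE)
  if (length(flux_keys)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      symbol = sub("^b\\|", "", flux_keys), type = "flux",
      value = unname(round(sol[flux_keys])))
  }
  dplyr::bind_rows(rows)
}

#' Solve the steady-state regulatory FBA problem
#'
#' Maximizes biomass flux subject to mass balance, flux bounds, GPR gating
#' (a reaction can carry flux only if its GPR evaluates true under the gene
#' expression state), and the fixed-point consistency of every Boolean
#' regulatory rule. Knocked-out genes are fixed unexpressed. An infeasible
#' integrated model is returned as a no-growth call, not an error.
#'
#' @param imodel An `integrated_model`.
#' @param cond Optional `condition`.
#' @param knockouts Character vector of deleted genes.
#' @param settings A [solver_settings()] object.
#' @param force_express Genes whose reactions are gated as constitutively
#'   available regardless of their expression state (used to re-simulate a
#'   violation set).
#' @return An `srfba_solution`: list with `flux` (a `flux_solution`) and
#'   `state` (tibble of gene / TF / predicate indicator values).
#' @export
solve_srfba <- function(imodel, cond = NULL, knockouts = character(),
                        settings = solver_settings(),
                        force_express = character()) {
  built <- build_integrated_problem(imodel, cond, knockouts, settings,
                                    surrogate = FALSE,
                                    force_express = force_express)
  r <- milp_solve(built$p, int_tol = settings$int_tol,
                  node_limit = settings$node_limit)
  met <- built$met
  if (r$status == "infeasible") {
    fs <- new_flux_solution(0, tibble::tibble(reaction = met$reactions$id,
                                              flux = NA_real_),
                            "infeasible", met$biomass)
    return(structure(list(flux = fs, state = NULL), class = "srfba_solution"))
  }
  fluxes <- tibble::tibble(reaction = met$reactions$id,
                           flux = unname(r$solution[met$reactions$id]))
  fs <- new_flux_solution(r$objective, fluxes, "optimal", met$biomass)
  structure(list(flux = fs, state = extract_boolean_state(built, r$solution)),
            class = "srfba_solution")
}

#' @export
print.srfba_solution <- function(x, ...) {
  cat(sprintf("<srfba_solution: mu = %.6g (%s), status = %s>\n",
              x$flux$objective, x$flux$growth, x$flux$status))
  invisible(x)
}
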