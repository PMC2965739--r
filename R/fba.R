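# Flux balance analysis: LP growth maximization and flux variability.

#' Growth-call tolerance
#'
#' Maximum growth rates above this value (model units, 1/hr) are called
#' growth "+"; separates numerical noise from a genuine positive optimum.
#' @keywords internal
EPS_GROWTH <- 1e-6

new_flux_solution <- function(mu, fluxes, status, biomass) {
  growth <- if (identical(status, "optimal") && mu > EPS_GROWTH) "+" else "-"
  structure(list(objective = mu, fluxes = fluxes, status = status,
                 growth = growth, biomass = biomass),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution: mu = %.6g (%s), status = %s>\n",
              x$objective, x$growth, x$status))
  invisible(x)
}

# shared: build the pure-LP FBA problem from a bounded metabolic model
build_fba_problem <- function(met) {
  p <- milp_new("max")
  for (i in seq_len(nrow(met$reactions))) {
    milp_add_var(p, met$reactions$id[i], lb = met$reactions$lb[i],
                 ub = met$reactions$ub[i],
                 obj = as.numeric(met$reactions$id[i] == met$biomass))
  }
  for (m in met$metabolites$id) {
    rows <- met$stoich[met$stoich$met == m, , drop = FALSE]
    if (!nrow(rows)) next
    milp_add_con(p, stats::setNames(rows$coef, rows$rxn), "=", 0)
  }
  p
}

prepare_metabolic <- function(imodel, cond, knockouts) {
  stopifnot(inherits(imodel, "integrated_model"))
  env_truth <- logical()
  if (!is.null(cond)) {
    ap <- apply_condition(imodel, cond)
    imodel <- ap$model
    env_truth <- ap$env_truth
  }
  if (length(knockouts)) imodel <- apply_knockouts(imodel, knockouts)
  list(model = imodel, env_truth = env_truth)
}

#' Maximize growth rate by flux balance analysis
#'
#' Solves the LP: maximize biomass flux subject to steady-state mass balance
#' (S v = 0) and flux bounds, with reactions whose GPR evaluates false under
#' the knockouts closed. Regulatory rules are ignored (see [solve_srfba()]
#' for the integrated model).
#'
#' @param imodel An `integrated_model`.
#' @param cond Optional `condition` applied before solving.
#' @param knockouts Character vector of deleted genes.
#' @return A `flux_solution` with the maximum growth rate `objective`, the
#'   flux vector as a tibble in `fluxes`, the growth call (`"+"`/`"-"`), and
#'   the solver status. Infeasible media give growth `"-"` with `mu = 0`.
#' @export
maximize_growth <- function(imodel, cond = NULL, knockouts = character()) {
  pr <- prepare_metabolic(imodel, cond, knockouts)
  met <- pr$model$metabolic
  p <- build_fba_problem(met)
  r <- milp_solve(p)
  if (r$status == "infeasible") {
    return(new_flux_solution(0, tibble::tibble(reaction = met$reactions$id,
                                               flux = NA_real_),
                             "infeasible", met$biomass))
  }
  if (r$status != "optimal") {
    stop("FBA solver failure: status ", r$status, call. = FALSE)
  }
  fluxes <- tibble::tibble(reaction = met$reactions$id,
                           flux = unname(r$solution[met$reactions$id]))
  new_flux_solution(r$objective, fluxes, "optimal", met$biomass)
}

#' Flux variability analysis
#'
#' For each reaction, computes the minimum and maximum feasible flux subject
#' to the biomass flux staying at or above `fraction_of_optimum` times the
#' FBA optimum. One LP is reused with objective swaps.
#'
#' @param imodel An `integrated_model`.
#' @param cond Optional `condition`.
#' @param fraction_of_optimum Fraction in (0, 1] of the growth optimum to
#'   retain.
#' @param knockouts Character vector of deleted genes.
#' @param reactions Reaction ids to analyze (default all).
#' @return A tibble with columns `reaction`, `min`, `max` (NA for per-
#'   reaction LP failures, which do not abort the table).
#' @export
flux_variability <- function(imodel, cond = NULL, fraction_of_optimum = 1,
                             knockouts = character(), reactions = NULL) {
  stopifnot(fraction_of_optimum > 0, fraction_of_optimum <= 1)
  pr <- prepare_metabolic(imodel, cond, knockouts)
  met <- pr$model$metabolic
  opt <- maximize_growth(pr$model)
  if (opt$growth != "+") {
    stop("flux variability requires a positive growth optimum (mu = ",
         format(opt$objective), ")", call. = FALSE)
  }
  p <- build_fba_problem(met)
  milp_add_con(p, stats::setNames(1, met$biomass), ">=",
               fraction_of_optimum * opt$objective)
  if (is.null(reactions)) reactions <- met$reactions$id
  res <- purrr::map_dfr(reactions, function(rid) {
    one <- function(sense) {
      milp_set_objective(p, stats::setNames(1, rid), sense = sense)
      r <- milp_solve(p)
      if (r$status == "optimal") r$objective else NA_real_
    }
    mn <- tryCatch(one("min"), error = function(e) NA_real_)
    mx <- tryCatch(one("max"), error = function(e) NA_real_)
    tibble::tibble(reaction = rid, min = mn, max = mx)
  })
  res
}

#' Write a flux-variability table as TSV
#'
#' @param fva Tibble from [flux_variability()].
#' @param path Output file.
#' @export
write_fva_tsv <- function(fva, path) {
  utils::write.table(fva, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
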