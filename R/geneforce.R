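# Minimal regulatory-rule violation: find the smallest set of genes that
# must be forced to an expressed state (surrogate indicator y' = 1 while the
# rule-determined indicator y = 0) for the integrated model to reach a
# threshold growth rate, and enumerate alternative optimal violation sets
# with integer cuts.

new_geneforce_solution <- function(genes_tbl, objective, mu, mu_threshold,
                                   mu_fba, threshold_fraction, status,
                                   alternates = list(), truncated = FALSE,
                                   condition_id = NA_character_,
                                   knockouts = character()) {
  structure(list(genes = genes_tbl, objective = objective, mu = mu,
                 mu_threshold = mu_threshold, mu_fba = mu_fba,
                 threshold_fraction = threshold_fraction, status = status,
                 alternates = alternates, truncated = truncated,
                 condition_id = condition_id, knockouts = knockouts),
            class = "geneforce_solution")
}

#' @export
print.geneforce_solution <- function(x, ...) {
  v <- violation_set(x)
  cat(sprintf("<geneforce_solution: %d violation(s)%s; mu = %.6g >= threshold %.6g (%s)>\n",
              x$objective,
              if (length(v)) paste0(" {", paste(v, collapse = ", "), "}") else "",
              x$mu, x$mu_threshold, x$status))
  if (length(x$alternates)) {
    cat("  alternates:",
        paste(vapply(x$alternates, function(a) paste0("{", paste(a, collapse = ","), "}"),
                     character(1)), collapse = " "),
        if (x$truncated) "(truncated)" else "", "\n")
  }
  invisible(x)
}

#' Violated genes of a solution
#'
#' Genes with rule-determined indicator 0 whose surrogate indicator was
#' forced to 1, sorted lexicographically.
#'
#' @param x A `geneforce_solution`.
#' @return Character vector.
#' @export
violation_set <- function(x) {
  stopifnot(inherits(x, "geneforce_solution"))
  sort(x$genes$gene[x$genes$violated])
}

geneforce_extract <- function(built, r) {
  ruled <- built$ruled_genes
  y <- round(unname(r$solution[v_gene(ruled)]))
  yp <- round(unname(r$solution[v_surr(ruled)]))
  tibble::tibble(gene = ruled, y = y, y_prime = yp,
                 violated = y == 0 & yp == 1)
}

add_integer_cut <- function(p, ruled, violated) {
  # exclude this exact violation set: over the incumbent's violated genes
  # (all with y = 0), the difference y' - y may not again reach |V|
  coefs <- c(stats::setNames(rep(1, length(violated)), v_surr(violated)),
             stats::setNames(rep(-1, length(violated)), v_gene(violated)))
  milp_add_con(p, coefs, "<=", length(violated) - 1)
  invisible(p)
}

#' Minimal set of regulatory-rule violations enabling growth
#'
#' Solves the rule-violation MILP: the SR-FBA system in which reaction
#' availability is gated by surrogate expression indicators y' (with
#' y' >= y, and y' = 0 for knocked-out genes), subject to the biomass flux
#' reaching at least `threshold_fraction` times the pure-FBA optimum, while
#' minimizing the number of violations sum(y' - y). An objective of 0 means
#' the integrated model already reaches the threshold; a positive objective
#' identifies the genes whose regulatory rules block growth.
#'
#' @param imodel An `integrated_model`.
#' @param cond Optional `condition`.
#' @param knockouts Character vector of deleted genes (never violated).
#' @param threshold_fraction Growth threshold as a fraction of the metabolic
#'   (FBA) optimum; default 0.1.
#' @param settings A [solver_settings()].
#' @param weights Optional named per-gene violation weights (default 1).
#' @return A `geneforce_solution` with the per-gene indicator table
#'   (`genes`), the violation count (`objective`), the achieved growth rate
#'   (`mu`), the threshold used, and the FBA optimum.
#' @export
minimal_violations <- function(imodel, cond = NULL, knockouts = character(),
                               threshold_fraction = 0.1,
                               settings = solver_settings(),
                               weights = NULL) {
  stopifnot(threshold_fraction >= 0)
  fba <- maximize_growth(imodel, cond, knockouts)
  if (fba$growth != "+") {
    stop("not a rule-violation case: the metabolic model does not grow here ",
         "(mu_FBA = ", format(fba$objective), ")", call. = FALSE)
  }
  mu_threshold <- threshold_fraction * fba$objective

  built <- build_integrated_problem(imodel, cond, knockouts, settings,
                                    surrogate = TRUE)
  p <- built$p
  met <- built$met
  ruled <- built$ruled_genes
  milp_add_con(p, stats::setNames(1, met$biomass), ">=", mu_threshold)
  w <- stats::setNames(rep(1, length(ruled)), ruled)
  if (!is.null(weights)) {
    hit <- intersect(names(weights), ruled)
    w[hit] <- weights[hit]
  }
  free_ruled <- setdiff(ruled, built$knockouts)
  obj <- c(stats::setNames(w[free_ruled], v_surr(free_ruled)),
           stats::setNames(-w[free_ruled], v_gene(free_ruled)))
  milp_set_objective(p, obj, sense = "min")

  r <- milp_solve(p, int_tol = settings$int_tol, node_limit = settings$node_limit)
  if (r$status == "infeasible") {
    # y' = 1 everywhere reproduces the FBA optimum, so with mu_FBA above the
    # threshold the only remaining cause is an inconsistent Boolean system
    return(new_geneforce_solution(
      tibble::tibble(gene = ruled, y = NA_real_, y_prime = NA_real_,
                     violated = NA),
      objective = NA_real_, mu = 0, mu_threshold = mu_threshold,
      mu_fba = fba$objective, threshold_fraction = threshold_fraction,
      status = "metabolically impossible",
      condition_id = if (is.null(cond)) NA_character_ else cond$id,
      knockouts = knockouts))
  }
  genes_tbl <- geneforce_extract(built, r)
  new_geneforce_solution(
    genes_tbl,
    objective = sum(genes_tbl$violated),
    mu = unname(r$solution[met$biomass]),
    mu_threshold = mu_threshold, mu_fba = fba$objective,
    threshold_fraction = threshold_fraction, status = "optimal",
    condition_id = if (is.null(cond)) NA_character_ else cond$id,
    knockouts = knockouts)
}

#' Enumerate all minimum-cardinality violation sets
#'
#' Repeatedly re-solves the rule-violation MILP, each time excluding the
#' incumbent violation set with an integer cut over its violation difference
#' variables, until the optimum exceeds the minimum cardinality k (or
#' `max_solutions` is reached, which sets the `truncated` flag).
#'
#' @inheritParams minimal_violations
#' @param max_solutions Enumeration cap.
#' @return A `geneforce_solution` whose `alternates` field lists every
#'   violation set of cardinality k (including the first solution's own set,
#'   as its `genes` table).
#' @export
enumerate_alternates <- function(imodel, cond = NULL, knockouts = character(),
                                 threshold_fraction = 0.1,
                                 settings = solver_settings(),
                                 max_solutions = 50L) {
  first <- minimal_violations(imodel, cond, knockouts, threshold_fraction,
                              settings)
  if (first$status != "optimal") return(first)
  k <- first$objective
  if (k == 0) {
    first$alternates <- list(character())
    return(first)
  }

  fba <- maximize_growth(imodel, cond, knockouts)
  built <- build_integrated_problem(imodel, cond, knockouts, settings,
                                    surrogate = TRUE)
  p <- built$p
  met <- built$met
  ruled <- built$ruled_genes
  free_ruled <- setdiff(ruled, built$knockouts)
  milp_add_con(p, stats::setNames(1, met$biomass), ">=", first$mu_threshold)
  milp_set_objective(p, c(stats::setNames(rep(1, length(free_ruled)), v_surr(free_ruled)),
                          stats::setNames(rep(-1, length(free_ruled)), v_gene(free_ruled))),
                     sense = "min")

  sets <- list()
  truncated <- FALSE
  repeat {
    r <- milp_solve(p, int_tol = settings$int_tol, node_limit = settings$node_limit)
    if (r$status == "infeasible") break
    tbl <- geneforce_extract(built, r)
    v <- sort(tbl$gene[tbl$violated])
    if (length(v) > k + 1e-9) break
    sets[[length(sets) + 1L]] <- v
    if (length(sets) >= max_solutions) { truncated <- TRUE; break }
    add_integer_cut(p, ruled, v)
  }
  # deterministic report order: lexicographic on the joined gene ids
  ord <- order(vapply(sets, paste, character(1), collapse = ","))
  first$alternates <- sets[ord]
  first$truncated <- truncated
  first
}

#' Violation objective across growth thresholds
#'
#' Runs [minimal_violations()] at each threshold fraction and tabulates the
#' objective and violation set; the standard sensitivity check (the
#' violation count is non-decreasing in the fraction, and typically flat
#' between 5% and 50%).
#'
#' @inheritParams minimal_violations
#' @param fractions Numeric vector of threshold fractions.
#' @return A tibble (class `geneforce_sweep`) with columns `fraction`,
#'   `objective`, `mu`, and list-column `violations`.
#' @export
threshold_sweep <- function(imodel, cond = NULL, knockouts = character(),
                            fractions = c(0.05, 0.1, 0.25, 0.5),
                            settings = solver_settings()) {
  rows <- purrr::map(fractions, function(f) {
    s <- minimal_violations(imodel, cond, knockouts, f, settings)
    tibble::tibble(fraction = f, objective = s$objective, mu = s$mu,
                   violations = list(violation_set(s)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("geneforce_sweep", class(out))
  out
}

#' Write a solution as TSV (gene, y, y', violated)
#'
#' @param x A `geneforce_solution`.
#' @param path Output file.
#' @export
write_solution_tsv <- function(x, path) {
  stopifnot(inherits(x, "geneforce_solution"))
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a solution as JSON
#'
#' @param x A `geneforce_solution`.
#' @param path Output file.
#' @export
write_solution_json <- function(x, path) {
  stopifnot(inherits(x, "geneforce_solution"))
  out <- list(objective = x$objective,
              violations = as.list(violation_set(x)),
              mu = x$mu, mu_threshold = x$mu_threshold, mu_fba = x$mu_fba,
              threshold_fraction = x$threshold_fraction,
              status = x$status,
              condition = x$condition_id,
              knockouts = as.list(x$knockouts),
              alternates = lapply(x$alternates, as.list),
              genes = x$genes)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
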