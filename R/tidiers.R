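# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a flux solution
#'
#' @param x A `flux_solution`.
#' @param ... Unused.
#' @return Tibble with columns `reaction`, `flux`.
#' @export
tidy.flux_solution <- function(x, ...) x$fluxes

#' @rdname tidy.flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(mu = x$objective, growth = x$growth, status = x$status,
                 biomass = x$biomass)
}

#' Tidy an SR-FBA solution
#'
#' @param x An `srfba_solution`.
#' @param what `"state"` for the Boolean indicator table, `"flux"` for the
#'   flux vector.
#' @param ... Unused.
#' @export
tidy.srfba_solution <- function(x, what = c("state", "flux"), ...) {
  what <- match.arg(what)
  if (what == "flux") x$flux$fluxes
  else if (is.null(x$state)) tibble::tibble(symbol = character(),
                                            type = character(),
                                            value = numeric())
  else x$state
}

#' @rdname tidy.srfba_solution
#' @export
glance.srfba_solution <- function(x, ...) {
  tibble::tibble(mu = x$flux$objective, growth = x$flux$growth,
                 status = x$flux$status)
}

#' Tidy a rule-violation solution
#'
#' @param x A `geneforce_solution`.
#' @param ... Unused.
#' @return The per-gene table: `gene`, `y`, `y_prime`, `violated`.
#' @export
tidy.geneforce_solution <- function(x, ...) x$genes

#' @rdname tidy.geneforce_solution
#' @export
glance.geneforce_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective, mu = x$mu,
                 mu_threshold = x$mu_threshold, mu_fba = x$mu_fba,
                 threshold_fraction = x$threshold_fraction,
                 status = x$status, n_alternates = length(x$alternates),
                 truncated = x$truncated)
}

#' Plot a rule-violation solution
#'
#' Shows, per regulated gene, the rule-determined indicator y and the
#' surrogate indicator y'; violated genes (y = 0, y' = 1) are highlighted.
#'
#' @param object A `geneforce_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.geneforce_solution <- function(object, ...) {
  d <- tidyr::pivot_longer(object$genes, c("y", "y_prime"),
                           names_to = "indicator", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$indicator, y = .data$gene,
                                  fill = factor(.data$value))) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::scale_fill_manual(values = c(`0` = "grey85", `1` = "#2c7fb8"),
                               name = "state") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d rule violation(s); mu = %.3g",
                                  object$objective, object$mu))
}

#' Plot a threshold sweep
#'
#' @param object A `geneforce_sweep` tibble from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot of the violation objective against the threshold
#'   fraction.
#' @export
autoplot.geneforce_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fraction, y = .data$objective)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "growth threshold (fraction of FBA optimum)",
                  y = "minimum rule violations")
}

#' Plot a phenotype comparison grid
#'
#' @param object A `phenotype_grid` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot tile map of case classes over mutants and conditions.
#' @export
autoplot.phenotype_grid <- function(object, ...) {
  ggplot2::ggplot(object$cases,
                  ggplot2::aes(x = .data$condition, y = .data$mutant,
                               fill = .data$class)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::labs(x = "condition", y = "mutant") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
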