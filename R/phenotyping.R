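# Growth calling, the three-way experiment/metabolic/integrated comparison
# grid, case classification, and aggregation of violation candidates.

#' Call growth from raw OD readings
#'
#' Subtracts the plate negative control from each reading and applies a
#' cutoff (default 0.1): corrected OD at or above the cutoff is growth "+".
#' Corrected values below minus the cutoff are flagged as suspect wells with
#' a warning.
#'
#' @param od Non-negative OD600 readings (vector).
#' @param negative_control Negative-control OD600 (scalar or vector).
#' @param cutoff Growth cutoff on the corrected OD; default 0.1.
#' @return Character vector of `"+"`/`"-"` calls with attribute `suspect`
#'   (logical vector).
#' @export
call_growth_from_od <- function(od, negative_control, cutoff = 0.1) {
  stopifnot(all(od >= 0), all(negative_control >= 0))
  corrected <- od - negative_control
  call <- ifelse(corrected >= cutoff, "+", "-")
  suspect <- corrected < -cutoff
  if (any(suspect)) {
    warning(sum(suspect), " suspect well(s): corrected OD below -cutoff",
            call. = FALSE)
  }
  attr(call, "suspect") <- suspect
  call
}

#' Convert plate-reader OD to 1-cm-pathlength OD600
#'
#' Affine calibration of Tecan microplate absorbance against a
#' spectrophotometer: OD600 = 2.566 * OD_Tecan + 0.0028.
#'
#' @param od_tecan Non-negative plate-reader readings.
#' @return OD600 values.
#' @export
convert_tecan_od <- function(od_tecan) {
  stopifnot(all(od_tecan >= 0))
  2.566 * od_tecan + 0.0028
}

#' Growth calls for a Biolog-style plate table
#'
#' @param plate Tibble/data frame with columns `well`, `od`, and `control`
#'   (the id of the negative-control well whose OD is subtracted).
#' @param cutoff Growth cutoff (default 0.1).
#' @return The input with added columns `corrected`, `call`, `suspect`.
#' @export
biolog_calls <- function(plate, cutoff = 0.1) {
  stopifnot(all(c("well", "od", "control") %in% names(plate)))
  ctrl_od <- plate$od[match(plate$control, plate$well)]
  if (anyNA(ctrl_od)) {
    stop("control well id(s) not present in plate: ",
         paste(unique(plate$control[is.na(ctrl_od)]), collapse = ", "),
         call. = FALSE)
  }
  call <- suppressWarnings(call_growth_from_od(plate$od, ctrl_od, cutoff))
  dplyr::mutate(tibble::as_tibble(plate),
                corrected = .data$od - ctrl_od,
                call = as.character(call),
                suspect = attr(call, "suspect"))
}

#' Classify an experiment/metabolic/integrated call triple
#'
#' `(+,+,-)` is a rule-correction case (experiment and the unregulated
#' metabolic model grow but the integrated model does not: evidence of an
#' incorrect rule or a missing isozyme/pathway); `(-,+,-)` is a
#' rescue-non-growth case (regulation correctly blocks a metabolically
#' possible growth: violations propose over-expression targets); any triple
#' with experimental equal to integrated is a correct prediction; remaining
#' triples are labeled by their literal pattern.
#'
#' @param exp,met,integrated Vectors of `"+"`/`"-"` calls.
#' @return Character vector of class labels.
#' @export
classify_case <- function(exp, met, integrated) {
  stopifnot(all(exp %in% c("+", "-")), all(met %in% c("+", "-")),
            all(integrated %in% c("+", "-")))
  dplyr::case_when(
    exp == "+" & met == "+" & integrated == "-" ~ "rule_correction",
    exp == "-" & met == "+" & integrated == "-" ~ "rescue_non_growth",
    exp == integrated ~ "correct",
    TRUE ~ paste(exp, met, integrated, sep = "/"))
}

#' Prediction accuracy over comparison cases
#'
#' A case is correct when the experimental call equals the integrated-model
#' call. Cases with a missing experimental call are excluded from the
#' denominator.
#'
#' @param cases Tibble with columns `experimental`, `metabolic`,
#'   `integrated` (and optionally `class`).
#' @return One-row tibble: `total`, `correct`, `accuracy`,
#'   `rule_correction_cases`, `rescue_cases`.
#' @export
accuracy <- function(cases) {
  stopifnot(nrow(cases) > 0)
  ok <- !is.na(cases$experimental)
  cases <- cases[ok, , drop = FALSE]
  if (!nrow(cases)) stop("no cases with an experimental call", call. = FALSE)
  cls <- classify_case(cases$experimental, cases$metabolic, cases$integrated)
  tibble::tibble(
    total = nrow(cases),
    correct = sum(cases$experimental == cases$integrated),
    accuracy = sum(cases$experimental == cases$integrated) / nrow(cases),
    rule_correction_cases = sum(cls == "rule_correction"),
    rescue_cases = sum(cls == "rescue_non_growth"))
}

parse_mutant <- function(mutant) {
  if (is.na(mutant) || !nzchar(mutant) || toupper(mutant) == "WT") return(character())
  strsplit(mutant, "[,/]")[[1]] |> trimws()
}

#' Run the three-way phenotype comparison grid
#'
#' For every (mutant, condition) cell: computes the FBA growth call, the
#' SR-FBA growth call, and the case class; invokes the rule-violation
#' minimization on every rule-correction case (and, when `rescue = TRUE`, on
#' rescue-non-growth cases, labeling the output genes as over-expression
#' candidates rather than corrections); and aggregates violated-gene
#' frequencies by mutant and by condition. Per-cell solver failures are
#' logged and the run continues.
#'
#' @param imodel An `integrated_model`.
#' @param phenotypes Tibble with columns `mutant` (comma/slash-separated
#'   gene ids; `""` or `"WT"` for wild type), `condition` (id matching
#'   `names(conditions)`), `call` (`"+"`, `"-"`, or `NA` for missing).
#' @param conditions Named list of `condition` objects.
#' @param settings A [solver_settings()].
#' @param threshold_fraction Growth threshold fraction passed to
#'   [minimal_violations()].
#' @param rescue Also run the violation minimization on rescue cases.
#' @param alternates When `TRUE`, enumerate alternative optimal violation
#'   sets per analyzed cell and record their count.
#' @param blacklist Condition ids excluded from the grid (with reason
#'   recorded); empty by default.
#' @return A list of class `phenotype_grid`: `cases` (one row per cell) and
#'   `report` (candidate violation frequencies per gene and scope).
#' @export
run_grid <- function(imodel, phenotypes, conditions,
                     settings = solver_settings(), threshold_fraction = 0.1,
                     rescue = FALSE, alternates = FALSE,
                     blacklist = character()) {
  stopifnot(all(c("mutant", "condition", "call") %in% names(phenotypes)))
  missing_conds <- setdiff(unique(phenotypes$condition), names(conditions))
  if (length(missing_conds)) {
    stop("phenotype conditions without a condition object: ",
         paste(missing_conds, collapse = ", "), call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(phenotypes)), function(i) {
    mut <- phenotypes$mutant[i]
    cid <- phenotypes$condition[i]
    expc <- phenotypes$call[i]
    base <- tibble::tibble(mutant = mut, condition = cid, experimental = expc,
                           metabolic = NA_character_, integrated = NA_character_,
                           class = NA_character_, n_violations = NA_real_,
                           violated = list(character()), n_alternates = NA_integer_,
                           status = "ok")
    if (cid %in% blacklist) {
      base$class <- "blacklisted_condition"
      base$status <- "excluded"
      return(base)
    }
    ko <- parse_mutant(mut)
    cond <- conditions[[cid]]
    res <- tryCatch({
      fba <- maximize_growth(imodel, cond, ko)
      sr <- solve_srfba(imodel, cond, ko, settings)
      base$metabolic <- fba$growth
      base$integrated <- sr$flux$growth
      if (is.na(expc)) {
        base$class <- "missing_experimental"
      } else {
        base$class <- classify_case(expc, fba$growth, sr$flux$growth)
      }
      analyze <- identical(base$class, "rule_correction") ||
        (rescue && identical(base$class, "rescue_non_growth"))
      if (analyze) {
        if (alternates) {
          gf <- enumerate_alternates(imodel, cond, ko, threshold_fraction,
                                     settings)
          base$n_alternates <- length(gf$alternates)
        } else {
          gf <- minimal_violations(imodel, cond, ko, threshold_fraction,
                                   settings)
        }
        base$n_violations <- gf$objective
        base$violated <- list(violation_set(gf))
      }
      base
    }, error = function(e) {
      base$class <- "unevaluated"
      base$status <- paste0("error: ", conditionMessage(e))
      base
    })
    res
  })
  cases <- dplyr::bind_rows(rows)

  long <- cases |>
    dplyr::filter(lengths(.data$violated) > 0) |>
    tidyr::unnest_longer("violated", values_to = "gene")
  report <- dplyr::bind_rows(
    long |> dplyr::count(.data$gene, scope = .data$mutant, name = "n_cases") |>
      dplyr::mutate(scope_type = "mutant"),
    long |> dplyr::count(.data$gene, scope = .data$condition, name = "n_cases") |>
      dplyr::mutate(scope_type = "condition")) |>
    dplyr::arrange(dplyr::desc(.data$n_cases), .data$gene) |>
    dplyr::select("gene", "scope_type", "scope", "n_cases")

  structure(list(cases = cases, report = report), class = "phenotype_grid")
}

#' @export
print.phenotype_grid <- function(x, ...) {
  cls <- table(x$cases$class)
  cat(sprintf("<phenotype_grid: %d cells (%s)>\n", nrow(x$cases),
              paste(sprintf("%s=%d", names(cls), as.integer(cls)), collapse = ", ")))
  invisible(x)
}

#' Replace a regulatory rule (apply a correction)
#'
#' @param imodel An `integrated_model`.
#' @param target Rule target (gene or TF).
#' @param rule New rule text (e.g. `"(ON)"`) or a `bool_expr`.
#' @return The modified (re-validated) `integrated_model`.
#' @export
set_rule <- function(imodel, target, rule) {
  stopifnot(inherits(imodel, "integrated_model"))
  reg <- imodel$regulatory
  expr <- if (inherits(rule, "bool_expr")) rule else parse_rule(rule)
  reg$rules[[target]] <- expr
  reg$rule_text[target] <- deparse_rule(expr)
  attr(reg, "aliases") <- NULL
  out <- integrated_model(imodel$metabolic, reg, imodel$aliases)
  out$knockouts <- imodel$knockouts
  out
}

#' Audit the effect of a correction on a comparison grid
#'
#' Compares the case tables before and after a rule edit: counts targeted
#' rule-correction cells that flipped to correct predictions, and newly
#' created false positives (rescue or other `-` experimental cells whose
#' integrated call turned `+`).
#'
#' @param before,after `phenotype_grid` objects (or their `cases` tibbles)
#'   over the same cells.
#' @return One-row tibble: `fixed`, `new_false_positives`, `unchanged`.
#' @export
audit_correction <- function(before, after) {
  cb <- if (inherits(before, "phenotype_grid")) before$cases else before
  ca <- if (inherits(after, "phenotype_grid")) after$cases else after
  key <- function(d) paste(d$mutant, d$condition, sep = "\r")
  stopifnot(identical(key(cb), key(ca)))
  fixed <- sum(cb$class == "rule_correction" & ca$class == "correct", na.rm = TRUE)
  nfp <- sum(!is.na(cb$experimental) & cb$experimental == "-" &
               cb$integrated == "-" & ca$integrated == "+", na.rm = TRUE)
  changed <- sum(cb$class != ca$class, na.rm = TRUE)
  tibble::tibble(fixed = fixed, new_false_positives = nfp,
                 unchanged = nrow(cb) - changed)
}

#' Read a phenotype matrix from TSV
#'
#' @param path TSV with columns mutant, condition, call (`+`, `-`, or empty
#'   for missing).
#' @return A tibble.
#' @export
read_phenotypes_tsv <- function(path) {
  tab <- read_tsv_table(path)
  stopifnot(all(c("mutant", "condition", "call") %in% names(tab)))
  tab$call[!tab$call %in% c("+", "-")] <- NA_character_
  tab
}
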