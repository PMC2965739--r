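# Cross-organism regulatory rule transfer through an ortholog map.
#
# Rules for source genes whose metabolic ortholog is absent in the target
# are dropped; rules referencing any TF (or gene symbol) without an ortholog
# are dropped whole, leaving the target gene unregulated; surviving rules
# are rewritten with target ids. Environmental and flux predicates transfer
# unchanged but must resolve against the target metabolic model.

rename_symbols <- function(expr, map) {
  go <- function(e) {
    if (e$kind == "ref") {
      if (e$ref$kind == "symbol" && e$ref$name %in% names(map)) {
        e$ref$name <- map[[e$ref$name]]
      }
      return(e)
    }
    if (e$kind != "const") e$args <- lapply(e$args, go)
    e
  }
  go(expr)
}

#' Transfer regulatory rules to another organism
#'
#' @param source_reg Source `regulatory_model`.
#' @param ortholog_map Named character vector or two-column data frame
#'   (`source`, `target`) mapping source gene/TF ids to target ids; entities
#'   absent from the map have no ortholog.
#' @param target_genes Metabolic gene ids of the target organism.
#' @param target_met Optional target `metabolic_model` used to resolve
#'   environmental/flux predicates (rules with unresolvable predicates are
#'   dropped and reported separately).
#' @param source_genes Optional source metabolic gene ids, used to classify
#'   rule targets as genes versus TFs; by default every rule target mapped
#'   into `target_genes` is treated as a gene rule and the rest as TF rules.
#' @return A list of class `rule_transfer`: `regulatory` (the chimeric
#'   `regulatory_model`), `report` (per-rule tibble with `status` one of
#'   transferred / dropped_missing_gene / dropped_missing_tf /
#'   dropped_unresolved_predicate), and `summary` (one-row tibble with
#'   counts and the fraction transferred).
#' @export
transfer_rules <- function(source_reg, ortholog_map, target_genes,
                           target_met = NULL, source_genes = NULL) {
  stopifnot(inherits(source_reg, "regulatory_model"))
  if (is.data.frame(ortholog_map)) {
    stopifnot(ncol(ortholog_map) >= 2)
    map <- stats::setNames(as.character(ortholog_map[[2]]),
                           as.character(ortholog_map[[1]]))
  } else {
    map <- ortholog_map
  }
  if (anyDuplicated(names(map))) {
    stop("ortholog map is not functional on the source side: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(map)) {
    dup <- unique(map[duplicated(map)])
    stop("target id collision(s) in ortholog map: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  ext_mets <- if (!is.null(target_met)) {
    sub("\\(e\\)$", "",
        target_met$metabolites$id[target_met$metabolites$compartment == "e"])
  } else NULL

  targets <- names(source_reg$rules)
  report <- list()
  new_rules <- list()
  for (tgt in targets) {
    expr <- source_reg$rules[[tgt]]
    is_gene_rule <- if (!is.null(source_genes)) tgt %in% source_genes
                    else (tgt %in% names(map) && map[[tgt]] %in% target_genes) ||
                         !(tgt %in% names(map))
    # (a) target entity must have an ortholog; gene rules additionally a
    # metabolic ortholog present in the target network
    if (!tgt %in% names(map) ||
        (is_gene_rule && !map[[tgt]] %in% target_genes)) {
      report[[tgt]] <- "dropped_missing_gene"
      next
    }
    syms <- free_symbols(expr)
    plain <- syms$name[syms$kind == "symbol"]
    unmapped <- setdiff(plain, names(map))
    if (length(unmapped)) {
      report[[tgt]] <- "dropped_missing_tf"
      next
    }
    if (!is.null(ext_mets)) {
      env <- syms$name[syms$kind == "env"]
      flx <- syms$name[syms$kind == "flux"]
      bad_env <- setdiff(env, ext_mets)
      bad_flx <- setdiff(setdiff(flx, "Growth"), target_met$reactions$id)
      if (length(bad_env) || length(bad_flx)) {
        report[[tgt]] <- "dropped_unresolved_predicate"
        next
      }
    }
    new_rules[[map[[tgt]]]] <- rename_symbols(expr, map)
    report[[tgt]] <- "transferred"
  }

  status <- unlist(report)
  rep_tbl <- tibble::tibble(source_target = names(status),
                            target = ifelse(names(status) %in% names(map),
                                            unname(map[names(status)]),
                                            NA_character_),
                            status = unname(status))
  mapped_tfs <- unname(map[intersect(source_reg$tfs, names(map))])
  chimera <- regulatory_model(new_rules, tfs = mapped_tfs)
  n <- length(targets)
  summary <- tibble::tibble(
    source_rules = n,
    transferred = sum(status == "transferred"),
    dropped_missing_gene = sum(status == "dropped_missing_gene"),
    dropped_missing_tf = sum(status == "dropped_missing_tf"),
    dropped_unresolved_predicate = sum(status == "dropped_unresolved_predicate"),
    fraction_transferred = if (n) sum(status == "transferred") / n else NA_real_)
  structure(list(regulatory = chimera, report = rep_tbl, summary = summary),
            class = "rule_transfer")
}

#' @export
print.rule_transfer <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<rule_transfer: %d/%d rules transferred (%.0f%%); dropped: %d missing gene, %d missing TF, %d unresolved predicate>\n",
              s$transferred, s$source_rules, 100 * s$fraction_transferred,
              s$dropped_missing_gene, s$dropped_missing_tf,
              s$dropped_unresolved_predicate))
  invisible(x)
}

#' Read a two-column ortholog map from TSV
#'
#' @param path TSV with columns source, target (header optional).
#' @return Named character vector (source -> target).
#' @export
read_ortholog_map_tsv <- function(path) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) && grepl("^source\t", body[1])) body <- body[-1]
  f <- strsplit(body, "\t", fixed = TRUE)
  stats::setNames(vapply(f, `[[`, character(1), 2),
                  vapply(f, `[[`, character(1), 1))
}
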