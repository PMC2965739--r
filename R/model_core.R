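# Integrated model data structures and I/O.
#
# A metabolic model holds the stoichiometric matrix (as a triplet table),
# flux bounds, gene-protein-reaction (GPR) associations, and the biomass
# reaction. A regulatory model holds one Boolean rule per gene or
# transcription factor. An integrated model joins the two with an alias
# table for symbol normalization.
#
# TSV dialect: reactions.tsv with columns id / equation / lb / ub / gpr,
# equations in "A(c) + 2 B(c) -> C(c)" notation ("<=>" for reversible; one
# empty side for exchanges and drains); metabolites.tsv with columns id /
# compartment; rules.tsv with columns target / rule. Directive lines
# "#! biomass <id>", "#! tf <name>", "#! alias <from> <to>" are honored;
# other "#" lines are comments.

DEFAULT_FLUX_BOUND <- 1000

# ---- equation parsing ------------------------------------------------------

parse_equation <- function(eq, rxn_id) {
  eq <- trimws(eq)
  rev_split <- regexpr("<=>|<->", eq)
  irr_split <- regexpr("->", eq)
  if (rev_split > 0) {
    reversible <- TRUE
    lhs <- substr(eq, 1, rev_split - 1)
    rhs <- substr(eq, rev_split + 3, nchar(eq))
  } else if (irr_split > 0) {
    reversible <- FALSE
    lhs <- substr(eq, 1, irr_split - 1)
    rhs <- substr(eq, irr_split + 2, nchar(eq))
  } else {
    stop("reaction '", rxn_id, "': equation lacks '->' or '<=>': ", eq, call. = FALSE)
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(NULL)
    terms <- strsplit(side, "\\s*\\+\\s*")[[1]]
    out <- lapply(terms, function(tm) {
      tm <- trimws(tm)
      m <- regmatches(tm, regexec("^([0-9.]+)\\s+(.+)$", tm))[[1]]
      if (length(m)) {
        list(met = m[3], coef = sign * as.numeric(m[2]))
      } else {
        list(met = tm, coef = sign * 1)
      }
    })
    out
  }
  terms <- c(parse_side(lhs, -1), parse_side(rhs, +1))
  if (!length(terms)) {
    stop("reaction '", rxn_id, "': empty equation", call. = FALSE)
  }
  mets <- vapply(terms, `[[`, character(1), "met")
  coefs <- vapply(terms, `[[`, numeric(1), "coef")
  # merge duplicated metabolites (appears on both sides)
  agg <- tapply(coefs, mets, sum)
  tibble::tibble(rxn = rxn_id, met = names(agg), coef = as.numeric(agg),
                 reversible = reversible)
}

met_compartment <- function(ids) {
  comp <- rep("c", length(ids))
  comp[grepl("\\(e\\)$", ids)] <- "e"
  comp
}

format_equation <- function(stoich_rows, reversible) {
  sub_side <- function(rows) {
    if (!nrow(rows)) return("")
    paste(vapply(seq_len(nrow(rows)), function(i) {
      cf <- abs(rows$coef[i])
      if (cf == 1) rows$met[i] else paste(format(cf), rows$met[i])
    }, character(1)), collapse = " + ")
  }
  rows <- stoich_rows[order(stoich_rows$met), , drop = FALSE]
  lhs <- sub_side(rows[rows$coef < 0, , drop = FALSE])
  rhs <- sub_side(rows[rows$coef > 0, , drop = FALSE])
  arrow <- if (reversible) "<=>" else "->"
  trimws(paste(lhs, arrow, rhs))
}

# ---- metabolic model -------------------------------------------------------

new_metabolic_model <- function(reactions, stoich, metabolites, biomass) {
  exch <- vapply(reactions$id, function(r) {
    rows <- stoich[stoich$rxn == r, , drop = FALSE]
    nrow(rows) == 1L && met_compartment(rows$met) == "e"
  }, logical(1))
  reactions$exchange <- unname(exch)
  gpr_ast <- lapply(stats::setNames(reactions$gpr, reactions$id), function(g) {
    if (is.na(g) || !nzchar(trimws(g))) NULL else parse_rule(g)
  })
  genes <- sort(unique(unlist(lapply(gpr_ast, function(a) {
    if (is.null(a)) character() else free_symbols(a)$name
  }))))
  structure(list(reactions = reactions, stoich = stoich,
                 metabolites = metabolites, biomass = biomass,
                 gpr_ast = gpr_ast, genes = genes),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model: %d reactions (%d exchanges), %d metabolites, %d genes; biomass = %s>\n",
              nrow(x$reactions), sum(x$reactions$exchange),
              nrow(x$metabolites), length(x$genes), x$biomass))
  invisible(x)
}

read_directives <- function(lines) {
  dl <- lines[grepl("^#!", lines)]
  out <- list(biomass = NULL, tf = character(), alias = character())
  for (d in dl) {
    parts <- strsplit(trimws(sub("^#!", "", d)), "\\s+")[[1]]
    if (!length(parts)) next
    key <- parts[1]
    if (key == "biomass" && length(parts) >= 2) out$biomass <- parts[2]
    if (key == "tf" && length(parts) >= 2) out$tf <- c(out$tf, parts[-1])
    if (key == "alias" && length(parts) >= 3) {
      out$alias[parts[2]] <- parts[3]
    }
  }
  out
}

read_tsv_table <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  rows <- lapply(body[-1], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    length(f) <- length(header)
    f
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  tibble::as_tibble(df)
}

#' Read a metabolic model from the TSV dialect
#'
#' @param reactions_file Path to `reactions.tsv` (columns id, equation, lb,
#'   ub, gpr; lb/ub may be empty for defaults). A `#! biomass <id>` directive
#'   names the biomass reaction; otherwise the first reaction id matching
#'   "biomass" or "growth" (case-insensitively) is used.
#' @param metabolites_file Optional `metabolites.tsv` (columns id,
#'   compartment); when absent, metabolites are derived from the equations.
#' @return A `metabolic_model`.
#' @export
read_metabolic_tsv <- function(reactions_file, metabolites_file = NULL) {
  lines <- readLines(reactions_file)
  dirs <- read_directives(lines)
  tab <- read_tsv_table(reactions_file)
  need <- c("id", "equation")
  if (!all(need %in% names(tab))) {
    stop("reactions.tsv must have at least columns id and equation", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "), call. = FALSE)
  }
  stoich <- dplyr::bind_rows(lapply(seq_len(nrow(tab)), function(i) {
    parse_equation(tab$equation[i], tab$id[i])
  }))
  reversible <- vapply(tab$id, function(r) {
    stoich$reversible[match(r, stoich$rxn)]
  }, logical(1))
  num_or <- function(x, default) {
    if (is.null(x)) return(default)
    v <- suppressWarnings(as.numeric(x))
    ifelse(is.na(v), default, v)
  }
  lb <- num_or(tab$lb, ifelse(reversible, -DEFAULT_FLUX_BOUND, 0))
  ub <- num_or(tab$ub, DEFAULT_FLUX_BOUND)
  if (any(lb > ub)) {
    stop("lb > ub for reaction(s): ",
         paste(tab$id[lb > ub], collapse = ", "), call. = FALSE)
  }
  gpr <- if ("gpr" %in% names(tab)) ifelse(is.na(tab$gpr), "", tab$gpr) else rep("", nrow(tab))
  reactions <- tibble::tibble(id = tab$id,
                              equation = tab$equation,
                              lb = unname(lb), ub = unname(ub),
                              reversible = unname(reversible),
                              gpr = gpr)
  met_ids <- sort(unique(stoich$met))
  if (!is.null(metabolites_file)) {
    mt <- read_tsv_table(metabolites_file)
    missing <- setdiff(met_ids, mt$id)
    if (length(missing)) {
      stop("equation metabolite(s) not declared in metabolites.tsv: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    metabolites <- tibble::tibble(id = mt$id, compartment = met_compartment(mt$id))
  } else {
    metabolites <- tibble::tibble(id = met_ids, compartment = met_compartment(met_ids))
  }
  biomass <- dirs$biomass
  if (is.null(biomass)) {
    hit <- grep("biomass|growth", tab$id, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) stop("no biomass reaction: add a '#! biomass <id>' directive",
                           call. = FALSE)
    biomass <- hit[1]
  }
  if (!biomass %in% tab$id) {
    stop("biomass reaction '", biomass, "' not among reactions", call. = FALSE)
  }
  stoich$reversible <- NULL
  new_metabolic_model(reactions, stoich, metabolites, biomass)
}

#' Read a regulatory model from a rule file
#'
#' The file is tab-separated with columns `target` and `rule` (header
#' optional), `#` comment lines, `#! tf <name>` declarations for
#' transcription factors without rules, and `#! alias <from> <to>` symbol
#' normalization entries. A rule target that is not a metabolic gene is
#' treated as a transcription factor.
#'
#' @param path Rule file path.
#' @return A `regulatory_model` (alias table attached as attribute `aliases`).
#' @export
read_rules_tsv <- function(path) {
  lines <- readLines(path)
  dirs <- read_directives(lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) && grepl("^target\t", body[1])) body <- body[-1]
  targets <- character()
  rule_text <- character()
  for (l in body) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("rule file line lacks a tab-separated rule: ", l, call. = FALSE)
    targets <- c(targets, trimws(f[1]))
    rule_text <- c(rule_text, trimws(f[2]))
  }
  if (anyDuplicated(targets)) {
    stop("duplicate rule target(s): ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "), call. = FALSE)
  }
  rules <- lapply(rule_text, parse_rule)
  names(rules) <- targets
  rm <- structure(list(rules = rules,
                       rule_text = stats::setNames(rule_text, targets),
                       tfs = unique(dirs$tf)),
                  class = "regulatory_model")
  attr(rm, "aliases") <- dirs$alias
  rm
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat(sprintf("<regulatory_model: %d rules, %d declared TFs>\n",
              length(x$rules), length(x$tfs)))
  invisible(x)
}

#' Construct a regulatory model in code
#'
#' @param rules Named character vector or named list of rule strings /
#'   `bool_expr` objects; names are the rule targets.
#' @param tfs Declared transcription-factor names (targets that are not
#'   metabolic genes are classified as TFs automatically at integration).
#' @return A `regulatory_model`.
#' @export
regulatory_model <- function(rules = character(), tfs = character()) {
  if (length(rules)) {
    parsed <- lapply(rules, function(r) if (inherits(r, "bool_expr")) r else parse_rule(r))
    txt <- vapply(parsed, deparse_rule, character(1))
  } else {
    parsed <- list(); txt <- character()
  }
  structure(list(rules = parsed,
                 rule_text = stats::setNames(txt, names(parsed)),
                 tfs = unique(tfs)),
            class = "regulatory_model")
}

# ---- integrated model ------------------------------------------------------

resolve_alias <- function(name, aliases) {
  if (length(aliases) && name %in% names(aliases)) aliases[[name]] else name
}

#' Join metabolic and regulatory models into an integrated model
#'
#' Validates all cross-references: every GPR gene must exist, and every plain
#' symbol in a regulatory rule must resolve (after aliasing) to a rule
#' target, a declared TF, or a metabolic gene. Environmental predicates must
#' name an extracellular metabolite of the model and flux predicates a
#' reaction (or the biomass function).
#'
#' @param metabolic A `metabolic_model`.
#' @param regulatory A `regulatory_model`.
#' @param aliases Named character vector mapping alias spellings to canonical
#'   symbols.
#' @return An `integrated_model`.
#' @export
integrated_model <- function(metabolic, regulatory = regulatory_model(),
                             aliases = character()) {
  stopifnot(inherits(metabolic, "metabolic_model"),
            inherits(regulatory, "regulatory_model"))
  if (is.null(aliases)) aliases <- character()
  file_aliases <- attr(regulatory, "aliases")
  if (length(file_aliases)) aliases <- c(aliases, file_aliases)

  targets <- names(regulatory$rules)
  gene_targets <- intersect(targets, metabolic$genes)
  tf_targets <- setdiff(targets, metabolic$genes)
  tfs <- union(regulatory$tfs, tf_targets)

  known <- c(targets, tfs, metabolic$genes)
  audit <- list()
  ext_mets <- sub("\\(e\\)$", "", metabolic$metabolites$id[metabolic$metabolites$compartment == "e"])
  for (tgt in targets) {
    syms <- free_symbols(regulatory$rules[[tgt]])
    for (i in seq_len(nrow(syms))) {
      if (syms$kind[i] == "symbol") {
        nm <- resolve_alias(syms$name[i], aliases)
        if (!nm %in% known) {
          audit[[length(audit) + 1L]] <- tibble::tibble(
            target = tgt, symbol = syms$name[i], kind = "symbol",
            problem = "not a rule target, declared TF, or metabolic gene")
        }
      } else if (syms$kind[i] == "env") {
        if (!syms$name[i] %in% ext_mets) {
          audit[[length(audit) + 1L]] <- tibble::tibble(
            target = tgt, symbol = syms$name[i], kind = "env",
            problem = "no such extracellular metabolite")
        }
      } else if (syms$kind[i] == "flux") {
        ok <- syms$name[i] %in% metabolic$reactions$id ||
          identical(syms$name[i], "Growth") || identical(syms$name[i], metabolic$biomass)
        if (!ok) {
          audit[[length(audit) + 1L]] <- tibble::tibble(
            target = tgt, symbol = syms$name[i], kind = "flux",
            problem = "no such reaction")
        }
      }
    }
  }
  if (length(audit)) {
    aud <- dplyr::bind_rows(audit)
    stop("unresolved symbols in regulatory rules:\n",
         paste(sprintf("  rule '%s': %s symbol '%s' (%s)", aud$target, aud$kind,
                       aud$symbol, aud$problem), collapse = "\n"),
         call. = FALSE)
  }
  structure(list(metabolic = metabolic, regulatory = regulatory,
                 aliases = aliases, tfs = tfs,
                 gene_targets = gene_targets,
                 knockouts = character()),
            class = "integrated_model")
}

#' @export
print.integrated_model <- function(x, ...) {
  print(x$metabolic)
  cat(sprintf("  + %d regulatory rules (%d gene rules, %d TF rules), %d TFs",
              length(x$regulatory$rules), length(x$gene_targets),
              length(x$regulatory$rules) - length(x$gene_targets), length(x$tfs)))
  if (length(x$knockouts)) cat("; knockouts:", paste(x$knockouts, collapse = ","))
  cat("\n")
  invisible(x)
}

#' Load an integrated model from files
#'
#' @param metabolic_source Path to `reactions.tsv` or an SBML (.xml/.sbml)
#'   file.
#' @param rules_source Optional rule file path.
#' @param metabolites_file Optional metabolites.tsv (TSV dialect only).
#' @return An `integrated_model`.
#' @export
load_model <- function(metabolic_source, rules_source = NULL,
                       metabolites_file = NULL) {
  is_sbml <- grepl("\\.(xml|sbml)$", metabolic_source, ignore.case = TRUE)
  met <- if (is_sbml) read_metabolic_sbml(metabolic_source)
         else read_metabolic_tsv(metabolic_source, metabolites_file)
  reg <- if (is.null(rules_source)) regulatory_model() else read_rules_tsv(rules_source)
  integrated_model(met, reg)
}

# ---- conditions ------------------------------------------------------------

#' Standard screening uptake constants (mmol/gDW/hr)
#'
#' Ammonia 10, pyruvate 11.3 (as carbon source when testing nitrogen
#' sources), oxygen 10.
#' @name uptake_defaults
#' @keywords internal
AMMONIA_UPTAKE <- 10
PYRUVATE_UPTAKE <- 11.3
OXYGEN_UPTAKE <- 10

#' Define a growth condition
#'
#' @param id Condition identifier.
#' @param uptake Named non-negative numeric vector: names are extracellular
#'   metabolite base names (without the `(e)` suffix), values are maximum
#'   uptake rates in mmol/gDW/hr (applied as lower bound = -uptake on the
#'   exchange reaction).
#' @param aerobic Logical; when `TRUE` an `o2` uptake of `o2_uptake` is added.
#' @param o2_uptake Oxygen uptake bound used when `aerobic`.
#' @return A `condition` object.
#' @export
condition <- function(id, uptake = numeric(), aerobic = FALSE,
                      o2_uptake = OXYGEN_UPTAKE) {
  stopifnot(all(uptake >= 0))
  structure(list(id = id, uptake = uptake,
                 present = names(uptake),
                 aerobic = isTRUE(aerobic), o2_uptake = o2_uptake),
            class = "growth_condition")
}

#' @export
print.growth_condition <- function(x, ...) {
  cat(sprintf("<condition '%s': %s%s>\n", x$id,
              if (length(x$uptake)) paste(sprintf("%s=%g", names(x$uptake), x$uptake),
                                          collapse = ", ") else "empty medium",
              if (x$aerobic) sprintf(", aerobic (o2=%g)", x$o2_uptake) else ""))
  invisible(x)
}

#' Carbon-source test condition
#'
#' Builds the standard condition used when screening carbon sources: the test
#' compound plus ammonia as nitrogen source at 10 mmol/gDW/hr, aerobic with
#' oxygen at 10 mmol/gDW/hr.
#'
#' @param carbon Extracellular metabolite base name of the carbon source.
#' @param uptake Uptake bound for the carbon source.
#' @param ammonia Base name of the ammonia metabolite in the model.
#' @param extra Additional named uptakes (essential nutrients).
#' @param aerobic Logical.
#' @return A `condition`.
#' @export
carbon_source_condition <- function(carbon, uptake = 10, ammonia = "nh4",
                                    extra = numeric(), aerobic = TRUE) {
  up <- c(stats::setNames(uptake, carbon), stats::setNames(AMMONIA_UPTAKE, ammonia), extra)
  condition(id = paste0(carbon, " (C)"), uptake = up, aerobic = aerobic)
}

#' Nitrogen-source test condition
#'
#' Pyruvate is the carbon source at 11.3 mmol/gDW/hr; the test compound is the
#' nitrogen source; aerobic with oxygen at 10 mmol/gDW/hr.
#'
#' @param nitrogen Extracellular metabolite base name of the nitrogen source.
#' @param uptake Uptake bound for the nitrogen source.
#' @param pyruvate Base name of the pyruvate metabolite in the model.
#' @param extra Additional named uptakes.
#' @param aerobic Logical.
#' @return A `condition`.
#' @export
nitrogen_source_condition <- function(nitrogen, uptake = 10, pyruvate = "pyr",
                                      extra = numeric(), aerobic = TRUE) {
  up <- c(stats::setNames(uptake, nitrogen), stats::setNames(PYRUVATE_UPTAKE, pyruvate), extra)
  condition(id = paste0(nitrogen, " (N)"), uptake = up, aerobic = aerobic)
}

exchange_of <- function(metabolic, met_base) {
  full <- paste0(met_base, "(e)")
  ex_rxns <- metabolic$reactions$id[metabolic$reactions$exchange]
  for (r in ex_rxns) {
    rows <- metabolic$stoich[metabolic$stoich$rxn == r, , drop = FALSE]
    if (nrow(rows) == 1L && rows$met == full) return(r)
  }
  NA_character_
}

#' Apply a condition to an integrated model
#'
#' Sets exchange lower bounds to minus the uptake for present metabolites and
#' to zero for absent extracellular metabolites, and fixes the truth of every
#' environmental predicate occurring in the regulatory rules: `m(e)>tau` is
#' true iff `m` is present in the medium (medium-composition semantics —
#' flux-dependent logic is expressed with flux predicates instead).
#'
#' @param imodel An `integrated_model`.
#' @param cond A `condition`.
#' @return A list with `model` (bounded `integrated_model`, the applied
#'   condition recorded in `$condition`) and `env_truth` (named logical over
#'   environmental-predicate keys).
#' @export
apply_condition <- function(imodel, cond) {
  stopifnot(inherits(imodel, "integrated_model"), inherits(cond, "growth_condition"))
  met <- imodel$metabolic
  uptake <- cond$uptake
  if (cond$aerobic) {
    if (!"o2" %in% names(uptake)) uptake <- c(uptake, o2 = cond$o2_uptake)
  }
  for (m in names(uptake)) {
    if (is.na(exchange_of(met, m))) {
      stop("condition '", cond$id, "': no exchange reaction for metabolite '",
           m, "'", call. = FALSE)
    }
  }
  # reset, then open exchanges in the medium
  for (i in which(met$reactions$exchange)) {
    r <- met$reactions$id[i]
    rows <- met$stoich[met$stoich$rxn == r, , drop = FALSE]
    base <- sub("\\(e\\)$", "", rows$met)
    met$reactions$lb[i] <- if (base %in% names(uptake)) -uptake[[base]] else 0
  }
  # environmental predicate truth from medium composition
  env_truth <- logical()
  for (tgt in names(imodel$regulatory$rules)) {
    syms <- free_symbols(imodel$regulatory$rules[[tgt]])
    env <- syms[syms$kind == "env", , drop = FALSE]
    for (i in seq_len(nrow(env))) {
      env_truth[[env$key[i]]] <- env$name[i] %in% names(uptake)
    }
  }
  out <- imodel
  out$metabolic <- met
  out$condition <- cond
  list(model = out, env_truth = env_truth)
}

#' Write a condition as TSV
#'
#' Two columns (metabolite, uptake) plus `#! id`, `#! aerobic`, and
#' `#! o2_uptake` directives.
#'
#' @param cond A `condition`.
#' @param path Output file.
#' @export
write_condition_tsv <- function(cond, path) {
  stopifnot(inherits(cond, "growth_condition"))
  writeLines(c(paste0("#! id ", cond$id),
               paste0("#! aerobic ", tolower(as.character(cond$aerobic))),
               paste0("#! o2_uptake ", format(cond$o2_uptake, trim = TRUE,
                                              scientific = FALSE)),
               "metabolite\tuptake",
               if (length(cond$uptake))
                 sprintf("%s\t%s", names(cond$uptake),
                         format(cond$uptake, trim = TRUE, scientific = FALSE))),
             path)
  invisible(path)
}

#' Read a condition from TSV
#'
#' @param path Condition file written by [write_condition_tsv()] (or
#'   hand-authored in the same layout).
#' @return A `condition`.
#' @export
read_condition_tsv <- function(path) {
  lines <- readLines(path)
  id <- "condition"; aerobic <- FALSE; o2 <- OXYGEN_UPTAKE
  for (d in lines[grepl("^#!", lines)]) {
    parts <- strsplit(trimws(sub("^#!", "", d)), "\\s+")[[1]]
    if (parts[1] == "id" && length(parts) >= 2) id <- paste(parts[-1], collapse = " ")
    if (parts[1] == "aerobic") aerobic <- identical(parts[2], "true")
    if (parts[1] == "o2_uptake") o2 <- as.numeric(parts[2])
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) && grepl("^metabolite\t", body[1])) body <- body[-1]
  uptake <- numeric()
  for (l in body) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    uptake[trimws(f[1])] <- as.numeric(f[2])
  }
  condition(id, uptake = uptake, aerobic = aerobic, o2_uptake = o2)
}

# ---- knockouts -------------------------------------------------------------

#' Evaluate a GPR under a gene expression state
#'
#' @param gpr A `bool_expr` over gene symbols (or `NULL` for no association).
#' @param expressed Named logical over genes; genes absent from the vector
#'   default to expressed.
#' @return Logical: is the reaction available?
#' @keywords internal
#' @export
gpr_available <- function(gpr, expressed = logical()) {
  if (is.null(gpr)) return(TRUE)
  syms <- free_symbols(gpr)
  asg <- stats::setNames(rep(TRUE, nrow(syms)), syms$key)
  hit <- intersect(names(expressed), names(asg))
  asg[hit] <- expressed[hit]
  evaluate_rule(gpr, asg)
}

#' Apply gene knockouts to an integrated model
#'
#' Deleted genes are recorded on the model (all solvers fix their expression
#' indicators to 0, and they are excluded from the violation candidate set —
#' a knockout can never be force-expressed), and reactions whose GPR
#' evaluates false under the deletion (with all other genes expressed) get
#' bounds \[0, 0\] for pure-FBA use.
#'
#' @param imodel An `integrated_model`.
#' @param genes Character vector of gene ids to delete.
#' @return The modified `integrated_model`.
#' @export
apply_knockouts <- function(imodel, genes) {
  stopifnot(inherits(imodel, "integrated_model"))
  genes <- unique(genes)
  if (!length(genes)) return(imodel)
  known <- c(imodel$metabolic$genes, imodel$tfs, names(imodel$regulatory$rules))
  unknown <- setdiff(genes, known)
  if (length(unknown)) {
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  met <- imodel$metabolic
  met_genes <- intersect(genes, met$genes)
  expressed <- stats::setNames(rep(FALSE, length(met_genes)), met_genes)
  for (i in seq_len(nrow(met$reactions))) {
    gpr <- met$gpr_ast[[met$reactions$id[i]]]
    if (!gpr_available(gpr, expressed)) {
      met$reactions$lb[i] <- 0
      met$reactions$ub[i] <- 0
    }
  }
  out <- imodel
  out$metabolic <- met
  out$knockouts <- union(imodel$knockouts, genes)
  out
}

# ---- writers ---------------------------------------------------------------

#' Write an integrated model in the TSV dialect
#'
#' The writer is byte-stable: writing, reading, and writing again produces an
#' identical file.
#'
#' @param imodel An `integrated_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_model_tsv <- function(imodel, dir) {
  stopifnot(inherits(imodel, "integrated_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  met <- imodel$metabolic
  rxn_path <- file.path(dir, "reactions.tsv")
  met_path <- file.path(dir, "metabolites.tsv")
  rule_path <- file.path(dir, "rules.tsv")

  eqs <- vapply(met$reactions$id, function(r) {
    format_equation(met$stoich[met$stoich$rxn == r, , drop = FALSE],
                    met$reactions$reversible[match(r, met$reactions$id)])
  }, character(1))
  lines <- c(paste0("#! biomass ", met$biomass),
             "id\tequation\tlb\tub\tgpr",
             sprintf("%s\t%s\t%s\t%s\t%s", met$reactions$id, eqs,
                     format(met$reactions$lb, trim = TRUE, scientific = FALSE),
                     format(met$reactions$ub, trim = TRUE, scientific = FALSE),
                     met$reactions$gpr))
  writeLines(lines, rxn_path)
  ord <- order(met$metabolites$id)
  writeLines(c("id\tcompartment",
               sprintf("%s\t%s", met$metabolites$id[ord], met$metabolites$compartment[ord])),
             met_path)
  reg <- imodel$regulatory
  rl <- c(if (length(imodel$tfs)) paste0("#! tf ", sort(imodel$tfs)),
          if (length(imodel$aliases)) sprintf("#! alias %s %s", names(imodel$aliases),
                                              unname(imodel$aliases)),
          "target\trule",
          if (length(reg$rules)) sprintf("%s\t%s", names(reg$rules),
                                         vapply(reg$rules, deparse_rule, character(1))))
  writeLines(rl, rule_path)
  invisible(c(rxn_path, met_path, rule_path))
}

# ---- SBML reader -----------------------------------------------------------

#' Read a metabolic model from SBML Level 3 with the fbc package
#'
#' A minimal reader covering species, compartments, reactions with
#' reactant/product stoichiometry, fbc flux bounds (via parameter
#' references), fbc gene-product associations, and the active fbc objective
#' (taken as the biomass reaction). Species ids are mapped to the internal
#' `"name(compartment)"` convention, stripping a trailing `_<compartment>`
#' and an optional `M_` prefix.
#'
#' @param path SBML file path.
#' @return A `metabolic_model`.
#' @export
read_metabolic_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

  internal_met <- function(id, comp) {
    id <- sub("^M_", "", id)
    id <- sub(paste0("_", comp, "$"), "", id)
    paste0(id, "(", comp, ")")
  }
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  sp_comp <- xml2::xml_attr(sp, "compartment")
  met_map <- stats::setNames(mapply(internal_met, sp_id, sp_comp), sp_id)

  par <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par, "value")),
                             xml2::xml_attr(par, "id"))

  gp <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_label <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  gpa_to_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lab <- gp_label[[ref]]
      if (is.null(lab) || is.na(lab)) ref else lab
    } else if (nm %in% c("and", "or")) {
      kids <- xml2::xml_children(node)
      parts <- vapply(kids, gpa_to_text, character(1))
      paste0("(", paste(parts, collapse = paste0(" ", toupper(nm), " ")), ")")
    } else {
      stop("unsupported geneProductAssociation node: ", nm, call. = FALSE)
    }
  }

  # fbc attributes may surface with or without their namespace prefix
  fbc_attr <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (is.na(v)) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  rows <- list(); st <- list()
  for (node in rx) {
    id <- xml2::xml_attr(node, "id")
    reversible <- identical(xml2::xml_attr(node, "reversible"), "true")
    lb_ref <- fbc_attr(node, "lowerFluxBound")
    ub_ref <- fbc_attr(node, "upperFluxBound")
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_val)) par_val[[lb_ref]]
          else if (reversible) -DEFAULT_FLUX_BOUND else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_val)) par_val[[ub_ref]]
          else DEFAULT_FLUX_BOUND
    side <- function(xp, sign) {
      refs <- xml2::xml_find_all(node, xp, ns)
      if (!length(refs)) return(NULL)
      tibble::tibble(rxn = id,
                     met = unname(met_map[xml2::xml_attr(refs, "species")]),
                     coef = sign * as.numeric(ifelse(is.na(xml2::xml_attr(refs, "stoichiometry")),
                                                     1, xml2::xml_attr(refs, "stoichiometry"))))
    }
    st[[length(st) + 1L]] <- dplyr::bind_rows(side(".//s:listOfReactants/s:speciesReference", -1),
                                              side(".//s:listOfProducts/s:speciesReference", +1))
    gpa <- xml2::xml_find_first(node, ".//fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpa, "xml_missing")) "" else gpa_to_text(xml2::xml_child(gpa))
    rows[[length(rows) + 1L]] <- tibble::tibble(id = id, lb = lb, ub = ub,
                                                reversible = reversible, gpr = gpr)
  }
  reactions <- dplyr::bind_rows(rows)
  stoich <- dplyr::bind_rows(st)
  # consolidate duplicated metabolite entries within a reaction
  stoich <- dplyr::summarise(dplyr::group_by(stoich, .data$rxn, .data$met),
                             coef = sum(.data$coef), .groups = "drop")
  reactions$equation <- vapply(reactions$id, function(r) {
    format_equation(stoich[stoich$rxn == r, , drop = FALSE],
                    reactions$reversible[match(r, reactions$id)])
  }, character(1))
  reactions <- reactions[, c("id", "equation", "lb", "ub", "reversible", "gpr")]

  obj <- xml2::xml_find_first(
    doc, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj, "xml_missing")) {
    stop("SBML file has no fbc objective (biomass reaction)", call. = FALSE)
  }
  biomass <- fbc_attr(obj, "reaction")

  met_ids <- sort(unique(stoich$met))
  metabolites <- tibble::tibble(id = met_ids, compartment = met_compartment(met_ids))
  new_metabolic_model(reactions, stoich, metabolites, biomass)
}
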