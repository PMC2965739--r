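# Synthetic fixtures: the two-gene/two-TF worked example and randomized
# planted-error integrated models for validation.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' The two-gene, two-TF example model
#'
#' A five-step network: uptake of extracellular A, conversion A -> B -> C
#' with the B -> C step gated by gene G1, a branch A -> D gated by gene G2,
#' and a biomass drain on C. The regulatory layer has TF1 activating G1 but
#' inactivated by the presence of A, and TF2 (constitutively active)
#' repressing G2. In a medium containing A the unregulated metabolic model
#' grows, the integrated model does not (G1 unexpressed blocks the essential
#' B -> C step), and the minimal rule violation is forcing G1 on.
#'
#' @param isozyme If `TRUE`, the B -> C reaction carries an isozyme gene G1b
#'   with its own (equally repressed) rule, creating two alternative optimal
#'   singleton violation sets.
#' @return An `integrated_model`.
#' @export
toy_model <- function(isozyme = FALSE) {
  bc_gpr <- if (isozyme) "(G1 OR G1b)" else "(G1)"
  reactions <- tibble::tibble(
    id = c("EX_A", "T_A", "R_AB", "R_BC", "R_AD", "EX_D", "Biomass"),
    equation = c("A(e) <=>", "A(e) -> A(c)", "A(c) -> B(c)", "B(c) -> C(c)",
                 "A(c) -> D(e)", "D(e) ->", "C(c) ->"),
    lb = c(-10, 0, 0, 0, 0, 0, 0),
    ub = rep(1000, 7),
    reversible = c(TRUE, rep(FALSE, 6)),
    gpr = c("", "", "", bc_gpr, "(G2)", "", ""))
  stoich <- dplyr::bind_rows(lapply(seq_len(nrow(reactions)), function(i) {
    parse_equation(reactions$equation[i], reactions$id[i])[, c("rxn", "met", "coef")]
  }))
  met_ids <- sort(unique(stoich$met))
  met <- new_metabolic_model(reactions, stoich,
                             tibble::tibble(id = met_ids,
                                            compartment = met_compartment(met_ids)),
                             biomass = "Biomass")
  rules <- c(G1 = "(TF1)", TF1 = "(NOT A(e)>0)", G2 = "(NOT TF2)", TF2 = "(ON)")
  if (isozyme) rules <- c(rules, G1b = "(TF1)")
  integrated_model(met, regulatory_model(rules))
}

#' Medium for the example model: A available at 10 mmol/gDW/hr
#'
#' @return A `condition`.
#' @export
toy_condition <- function() {
  condition("A medium", uptake = c(A = 10), aerobic = FALSE)
}

# pick a rule string over the TF layer with a prescribed truth value
make_gene_rule <- function(target_truth, true_tfs, false_tfs) {
  pick <- function(v) v[sample.int(length(v), 1)]
  tpl <- sample.int(4, 1)
  if (target_truth) {
    switch(tpl,
           sprintf("(%s)", pick(true_tfs)),
           sprintf("(NOT %s)", pick(false_tfs)),
           sprintf("(%s AND %s)", pick(true_tfs), pick(true_tfs)),
           sprintf("(%s OR %s)", pick(true_tfs), pick(false_tfs)))
  } else {
    switch(tpl,
           sprintf("(%s)", pick(false_tfs)),
           sprintf("(NOT %s)", pick(true_tfs)),
           sprintf("(%s AND %s)", pick(false_tfs), pick(true_tfs)),
           sprintf("(%s OR %s)", pick(false_tfs), pick(false_tfs)))
  }
}

#' Generate a planted-error integrated model
#'
#' Builds a linear-pathway scaffold (substrate S taken up at 10 mmol/gDW/hr,
#' converted through `n_genes` essential gene-gated steps into biomass; all
#' stoichiometric coefficients 1) plus optional structure: an alternative
#' substrate S2 (uptake 5) whose transporter carries its own rule, and
#' non-essential gated side branches. `k_planted` pathway genes receive
#' regulatory rules that wrongly evaluate false under the designated
#' condition; every other rule evaluates true. Each planted gene is
#' essential, so the planted set is the unique minimum violation set when
#' `isozyme_rate = 0`; with isozymes, each duplicated planted gene yields an
#' alternative optimal set. Some branch genes are left without rules (free
#' indicators). Generation is deterministic given `seed`.
#'
#' @param n_genes Number of essential pathway steps (>= 1).
#' @param n_tfs Number of transcription factors (>= 2).
#' @param k_planted Number of planted incorrect rules (0 <= k <= n_genes).
#' @param isozyme_rate Probability that a planted gene gets an equally
#'   repressed isozyme.
#' @param seed Integer seed.
#' @param second_source Include the alternative substrate S2 with a random
#'   true/false transporter rule.
#' @param n_branches Number of non-essential gated side branches.
#' @return A `planted_truth`: list with `model` (`integrated_model`),
#'   `condition`, `planted` (character), `seed`, and `params`.
#' @export
generate_planted_model <- function(n_genes = 6, n_tfs = 3, k_planted = 1,
                                   isozyme_rate = 0, seed = 1,
                                   second_source = TRUE, n_branches = 2) {
  stopifnot(n_genes >= 1, n_tfs >= 2, k_planted >= 0, k_planted <= n_genes)
  with_seed(seed, {
    genes <- sprintf("g%02d", seq_len(n_genes))
    planted <- sort(sample(genes, k_planted))

    rxn <- list()
    add_rxn <- function(id, eq, lb, ub, gpr = "") {
      rxn[[length(rxn) + 1L]] <<- tibble::tibble(id = id, equation = eq,
                                                 lb = lb, ub = ub, gpr = gpr)
    }
    add_rxn("EX_S", "S(e) <=>", -10, 1000)
    add_rxn("T_S", "S(e) -> m00(c)", 0, 1000)
    # signal-only metabolite X: absent from the designated condition, so
    # rules conditioned on X(e)>0 evaluate false there
    add_rxn("EX_X", "X(e) <=>", 0, 1000)
    for (i in seq_len(n_genes)) {
      add_rxn(sprintf("R%02d", i),
              sprintf("m%02d(c) -> m%02d(c)", i - 1L, i),
              0, 1000, sprintf("(%s)", genes[i]))
    }
    add_rxn("Biomass", sprintf("m%02d(c) ->", n_genes), 0, 1000)

    # TF layer: TF truth fixed by the medium (S present, X absent)
    tfs <- sprintf("tf%02d", seq_len(n_tfs))
    tf_truth <- c(TRUE, FALSE,
                  if (n_tfs > 2) sample(c(TRUE, FALSE), n_tfs - 2, replace = TRUE))
    tf_rules <- ifelse(tf_truth, "(S(e)>0)", "(X(e)>0)")
    true_tfs <- tfs[tf_truth]
    false_tfs <- tfs[!tf_truth]

    rules <- stats::setNames(as.list(tf_rules), tfs)
    for (g in genes) {
      rules[[g]] <- make_gene_rule(!(g %in% planted), true_tfs, false_tfs)
    }

    # second substrate with its own (random-truth) transporter gene
    extra_genes <- character()
    if (second_source) {
      add_rxn("EX_S2", "S2(e) <=>", -5, 1000)
      add_rxn("T_S2", "S2(e) -> m00(c)", 0, 1000, "(gS2)")
      extra_genes <- c(extra_genes, "gS2")
      if (stats::runif(1) < 0.5) {
        rules[["gS2"]] <- make_gene_rule(sample(c(TRUE, FALSE), 1),
                                         true_tfs, false_tfs)
      } # else: free indicator (no rule)
    }

    # non-essential side branches draining an intermediate
    for (b in seq_len(n_branches)) {
      pos <- sample.int(n_genes, 1) - 1L
      gb <- sprintf("gbr%02d", b)
      add_rxn(sprintf("BR%02d", b),
              sprintf("m%02d(c) -> w%02d(e)", pos, b), 0, 1000,
              sprintf("(%s)", gb))
      add_rxn(sprintf("EX_W%02d", b), sprintf("w%02d(e) ->", b), 0, 1000)
      extra_genes <- c(extra_genes, gb)
      if (stats::runif(1) < 0.6) {
        rules[[gb]] <- make_gene_rule(sample(c(TRUE, FALSE), 1),
                                      true_tfs, false_tfs)
      }
    }

    # isozymes for planted genes
    iso_of <- character()
    for (g in planted) {
      if (stats::runif(1) < isozyme_rate) {
        giso <- paste0(g, "b")
        i <- match(sprintf("R%02d", match(g, genes)), vapply(rxn, function(r) r$id, character(1)))
        rxn[[i]]$gpr <- sprintf("(%s OR %s)", g, giso)
        rules[[giso]] <- make_gene_rule(FALSE, true_tfs, false_tfs)
        iso_of <- c(iso_of, stats::setNames(giso, g))
      }
    }

    reactions <- dplyr::bind_rows(rxn)
    stoich <- dplyr::bind_rows(lapply(seq_len(nrow(reactions)), function(i) {
      parse_equation(reactions$equation[i], reactions$id[i])[, c("rxn", "met", "coef")]
    }))
    reactions$reversible <- vapply(reactions$id, function(r) {
      grepl("<=>", reactions$equation[match(r, reactions$id)])
    }, logical(1))
    reactions <- reactions[, c("id", "equation", "lb", "ub", "reversible", "gpr")]
    met_ids <- sort(unique(stoich$met))
    met <- new_metabolic_model(reactions, stoich,
                               tibble::tibble(id = met_ids,
                                              compartment = met_compartment(met_ids)),
                               biomass = "Biomass")
    model <- integrated_model(met, regulatory_model(unlist(rules)))
    cond <- condition("planted", uptake = c(S = 10, if (second_source) c(S2 = 5)),
                      aerobic = FALSE)
    structure(list(model = model, condition = cond, planted = planted,
                   isozymes = iso_of, seed = seed,
                   params = list(n_genes = n_genes, n_tfs = n_tfs,
                                 k_planted = k_planted,
                                 isozyme_rate = isozyme_rate,
                                 second_source = second_source,
                                 n_branches = n_branches)),
              class = "planted_truth")
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("<planted_truth: seed %d, %d pathway genes, planted {%s}>\n",
              x$seed, x$params$n_genes, paste(x$planted, collapse = ", ")))
  invisible(x)
}

#' Write a synthetic fixture to disk
#'
#' Writes the TSV model dialect (reactions.tsv, metabolites.tsv, rules.tsv)
#' plus condition.tsv and planted.json for a generated model; byte-identical
#' across runs with the same seed.
#'
#' @param pt A `planted_truth`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_fixture <- function(pt, dir) {
  stopifnot(inherits(pt, "planted_truth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_model_tsv(pt$model, dir)
  write_condition_tsv(pt$condition, file.path(dir, "condition.tsv"))
  jsonlite::write_json(list(seed = pt$seed, planted = as.list(pt$planted),
                            params = pt$params),
                       file.path(dir, "planted.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
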