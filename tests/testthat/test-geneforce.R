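test_that("the worked example needs exactly one violation, G1, leaving G2 alone", {
  m <- toy_model()
  cond <- toy_condition()
  gf <- minimal_violations(m, cond, threshold_fraction = 0.1)
  expect_equal(gf$status, "optimal")
  expect_equal(gf$objective, 1)
  expect_equal(violation_set(gf), "G1")
  expect_equal(gf$genes$y_prime[gf$genes$gene == "G2"], 0)
  expect_equal(gf$genes$y[gf$genes$gene == "G1"], 0)
  expect_gte(gf$mu, gf$mu_threshold - 1e-9)
  expect_equal(gf$mu_threshold, 0.1 * 10, tolerance = 1e-9)
})

test_that("a model already reaching the threshold needs no violations", {
  met <- toy_model()$metabolic
  m <- integrated_model(met, regulatory_model(
    c(G1 = "(ON)", G2 = "(NOT TF2)", TF2 = "(ON)"), tfs = "TF2"))
  gf <- minimal_violations(m, toy_condition())
  expect_equal(gf$objective, 0)
  expect_length(violation_set(gf), 0)
})

test_that("two independently repressed essential genes force a planted pair", {
  pt <- generate_planted_model(n_genes = 6, n_tfs = 3, k_planted = 2,
                               isozyme_rate = 0, seed = 21)
  gf <- minimal_violations(pt$model, pt$condition)
  expect_equal(gf$objective, 2)
  expect_equal(violation_set(gf), pt$planted)
  # brute-force confirmation over all subsets
  oracle <- oracle_min_violations(pt$model, pt$condition)
  expect_equal(oracle$k, 2)
  expect_equal(sort_sets(oracle$sets), list(pt$planted))
})

test_that("the precondition (metabolic growth) is enforced", {
  m <- toy_model()
  expect_error(minimal_violations(m, condition("empty")), "does not grow")
})

test_that("alternative optima enumeration finds exactly the isozyme family", {
  m <- toy_model(isozyme = TRUE)
  gf <- enumerate_alternates(m, toy_condition())
  expect_equal(gf$objective, 1)
  expect_equal(sort_sets(gf$alternates), list("G1", "G1b"))
  expect_false(gf$truncated)
  # unique-solution variant returns a single set
  gf1 <- enumerate_alternates(toy_model(), toy_condition())
  expect_equal(sort_sets(gf1$alternates), list("G1"))
  # every returned set has the minimum cardinality
  expect_true(all(lengths(gf$alternates) == gf$objective))
})

test_that("max_solutions truncation is flagged", {
  m <- toy_model(isozyme = TRUE)
  gf <- enumerate_alternates(m, toy_condition(), max_solutions = 1L)
  expect_length(gf$alternates, 1)
  expect_true(gf$truncated)
})

test_that("the violation set is insensitive to the threshold fraction on the example", {
  sw <- threshold_sweep(toy_model(), toy_condition(),
                        fractions = c(0.05, 0.1, 0.25, 0.5))
  expect_equal(sw$objective, rep(1L, 4))
  expect_true(all(vapply(sw$violations, identical, logical(1), "G1")))
  # fraction 0: zero growth needs no violation
  sw0 <- threshold_sweep(toy_model(), toy_condition(), fractions = 0)
  expect_equal(sw0$objective, 0L)
})

test_that("the objective is non-decreasing in the threshold fraction", {
  # adversarial fixture: a low-yield bypass lets the model reach low
  # thresholds with one violation, but the full optimum needs two
  d <- withr::local_tempdir()
  writeLines(c("#! biomass BIO", "id\tequation\tlb\tub\tgpr",
               "EX_A\tA(e) <=>\t-10\t1000\t",
               "T\tA(e) -> A(c)\t0\t1000\t",
               "FULL\tA(c) -> B(c)\t0\t1000\t(gFull)",
               "LOW\tA(c) -> B(c)\t0\t2\t(gLow)",
               "FIN\tB(c) -> C(c)\t0\t1000\t(gFin)",
               "BIO\tC(c) ->\t0\t1000\t"),
             file.path(d, "reactions.tsv"))
  met <- read_metabolic_tsv(file.path(d, "reactions.tsv"))
  m <- integrated_model(met, regulatory_model(
    c(gFull = "(OFF)", gLow = "(ON)", gFin = "(OFF)")))
  cond <- condition("A", uptake = c(A = 10))
  sw <- threshold_sweep(m, cond, fractions = c(0.05, 0.1, 0.25, 0.5))
  expect_equal(sw$objective, c(1L, 1L, 2L, 2L))  # bypass capacity 2 of 10
  expect_true(all(diff(sw$objective) >= 0))
})

test_that("re-simulating with the returned violations reaches the threshold (soundness)", {
  for (seed in c(31, 32, 33)) {
    pt <- generate_planted_model(n_genes = 5, n_tfs = 3,
                                 k_planted = 1 + seed %% 3, seed = seed)
    gf <- minimal_violations(pt$model, pt$condition)
    v <- violation_set(gf)
    sr <- solve_srfba(pt$model, pt$condition, force_express = v)
    expect_gte(sr$flux$objective, gf$mu_threshold - 1e-6)
  }
})

test_that("violations only ever turn genes on, never off (conservatism)", {
  for (seed in c(41, 42)) {
    pt <- generate_planted_model(n_genes = 5, n_tfs = 3, k_planted = 2,
                                 seed = seed)
    gf <- minimal_violations(pt$model, pt$condition)
    expect_true(all(gf$genes$y_prime >= gf$genes$y))
    expect_true(all(gf$genes$y[gf$genes$violated] == 0))
    # genes without rules never appear in the violation set
    unruled <- setdiff(pt$model$metabolic$genes,
                       names(pt$model$regulatory$rules))
    expect_length(intersect(violation_set(gf), unruled), 0)
  }
})

test_that("knocked-out genes are never force-expressed", {
  # delete the planted gene: its reaction is closed, FBA cannot grow, and
  # the case is rejected as a non-geneforce case
  pt <- generate_planted_model(n_genes = 5, n_tfs = 2, k_planted = 1,
                               seed = 51, second_source = FALSE)
  expect_error(minimal_violations(pt$model, pt$condition,
                                  knockouts = pt$planted),
               "does not grow")
  # deleting a non-essential ruled gene keeps it out of the violation set
  m <- toy_model(isozyme = TRUE)
  gf <- enumerate_alternates(m, toy_condition(), knockouts = "G1b")
  expect_equal(sort_sets(gf$alternates), list("G1"))
})

test_that("solution writers emit the per-gene table and violation list", {
  gf <- minimal_violations(toy_model(), toy_condition())
  f_tsv <- withr::local_tempfile(fileext = ".tsv")
  f_json <- withr::local_tempfile(fileext = ".json")
  write_solution_tsv(gf, f_tsv)
  tab <- utils::read.delim(f_tsv)
  expect_equal(tab$gene, c("G1", "G2"))
  expect_equal(tab$y_prime, c(1, 0))
  write_solution_json(gf, f_json)
  j <- jsonlite::read_json(f_json)
  expect_equal(j$objective, 1L)
  expect_equal(unlist(j$violations), "G1")
})
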