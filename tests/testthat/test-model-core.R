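toy_dir <- system.file("extdata", "toy", package = "geneforce")

test_that("the packaged example model loads with the expected structure", {
  m <- load_model(file.path(toy_dir, "reactions.tsv"),
                  file.path(toy_dir, "rules.tsv"),
                  file.path(toy_dir, "metabolites.tsv"))
  expect_s3_class(m, "integrated_model")
  expect_setequal(m$metabolic$genes, c("G1", "G2"))
  expect_setequal(m$tfs, c("TF1", "TF2"))
  expect_length(m$gene_targets, 2)
  expect_equal(m$metabolic$biomass, "Biomass")
  # structurally equal to the in-code constructor
  m2 <- toy_model()
  expect_equal(m$metabolic$stoich[order(m$metabolic$stoich$rxn, m$metabolic$stoich$met), ],
               m2$metabolic$stoich[order(m2$metabolic$stoich$rxn, m2$metabolic$stoich$met), ])
  expect_equal(m$metabolic$reactions[, c("id", "lb", "ub")],
               m2$metabolic$reactions[, c("id", "lb", "ub")])
})

test_that("SBML and TSV encodings of the same network are structurally equal", {
  ms <- read_metabolic_sbml(file.path(toy_dir, "toy.xml"))
  mt <- read_metabolic_tsv(file.path(toy_dir, "reactions.tsv"),
                           file.path(toy_dir, "metabolites.tsv"))
  expect_equal(ms$reactions$id, mt$reactions$id)
  expect_equal(ms$reactions$lb, mt$reactions$lb)
  expect_equal(ms$reactions$ub, mt$reactions$ub)
  expect_equal(ms$biomass, mt$biomass)
  ord <- function(s) s[order(s$rxn, s$met), c("rxn", "met", "coef")]
  expect_equal(ord(ms$stoich), ord(mt$stoich))
  # GPR structure (text may differ in parenthesization)
  for (r in ms$reactions$id) {
    a <- ms$gpr_ast[[r]]; b <- mt$gpr_ast[[r]]
    expect_equal(is.null(a), is.null(b))
    if (!is.null(a)) {
      expect_identical(strip_paren_attrs(a), strip_paren_attrs(b))
    }
  }
})

test_that("rules referencing undeclared symbols fail validation by name", {
  met <- toy_model()$metabolic
  expect_error(
    integrated_model(met, regulatory_model(c(G1 = "(NoSuchTF)"))),
    "NoSuchTF")
  expect_error(
    integrated_model(met, regulatory_model(c(G1 = "(nope(e)>0)"))),
    "no such extracellular metabolite")
  expect_error(
    integrated_model(met, regulatory_model(c(G1 = "(NOPE_RXN>0)"))),
    "no such reaction")
})

test_that("write-read round trip is byte-stable", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m <- toy_model()
  write_model_tsv(m, d1)
  m2 <- load_model(file.path(d1, "reactions.tsv"), file.path(d1, "rules.tsv"),
                   file.path(d1, "metabolites.tsv"))
  write_model_tsv(m2, d2)
  for (f in c("reactions.tsv", "metabolites.tsv", "rules.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("condition TSV round trip preserves the condition", {
  f <- withr::local_tempfile()
  cond <- condition("test", uptake = c(glc = 10, nh4 = 10), aerobic = TRUE,
                    o2_uptake = 10)
  write_condition_tsv(cond, f)
  c2 <- read_condition_tsv(f)
  expect_equal(c2$id, cond$id)
  expect_equal(c2$uptake, cond$uptake)
  expect_equal(c2$aerobic, cond$aerobic)
})

# a small network with ammonia / pyruvate / oxygen exchanges to exercise the
# standard-condition constants
nutrient_model <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(c("#! biomass BIO", "id\tequation\tlb\tub\tgpr",
               "EX_glc\tglc(e) <=>\t0\t1000\t",
               "EX_pyr\tpyr(e) <=>\t0\t1000\t",
               "EX_nh4\tnh4(e) <=>\t0\t1000\t",
               "EX_o2\to2(e) <=>\t0\t1000\t",
               "T_C\tglc(e) + nh4(e) -> x(c)\t0\t1000\t",
               "T_P\tpyr(e) + nh4(e) -> x(c)\t0\t1000\t",
               "BIO\tx(c) ->\t0\t1000\t"),
             file.path(d, "reactions.tsv"))
  load_model(file.path(d, "reactions.tsv"))
}

test_that("standard conditions apply the screening uptake constants", {
  m <- nutrient_model()
  ap <- apply_condition(m, carbon_source_condition("glc", uptake = 10))
  rx <- ap$model$metabolic$reactions
  expect_equal(rx$lb[rx$id == "EX_nh4"], -10)   # ammonia fixed at 10
  expect_equal(rx$lb[rx$id == "EX_o2"], -10)    # aerobic oxygen at 10
  expect_equal(rx$lb[rx$id == "EX_glc"], -10)
  expect_equal(rx$lb[rx$id == "EX_pyr"], 0)     # absent nutrient closed

  ap2 <- apply_condition(m, nitrogen_source_condition("nh4"))
  rx2 <- ap2$model$metabolic$reactions
  expect_equal(rx2$lb[rx2$id == "EX_pyr"], -11.3)  # pyruvate carbon source

  # idempotence / full override: re-applying a different condition resets
  ap3 <- apply_condition(ap2$model, carbon_source_condition("glc", uptake = 5))
  rx3 <- ap3$model$metabolic$reactions
  expect_equal(rx3$lb[rx3$id == "EX_pyr"], 0)
  expect_equal(rx3$lb[rx3$id == "EX_glc"], -5)
  ap4 <- apply_condition(ap3$model, carbon_source_condition("glc", uptake = 5))
  expect_equal(ap4$model$metabolic$reactions, rx3)
})

test_that("environmental predicates follow medium composition", {
  m <- toy_model()
  ap <- apply_condition(m, toy_condition())
  expect_true(ap$env_truth[["A(e)>0"]])
  ap0 <- apply_condition(m, condition("empty"))
  expect_false(ap0$env_truth[["A(e)>0"]])
  rx <- ap0$model$metabolic$reactions
  expect_equal(rx$lb[rx$id == "EX_A"], 0)
  expect_error(apply_condition(m, condition("bad", uptake = c(zz = 1))),
               "no exchange reaction")
})

test_that("knockouts respect isozyme OR-logic and close multi-gene losses", {
  # two isozymes for one essential reaction: single deletions survive, the
  # double deletion closes the reaction
  d <- withr::local_tempdir()
  writeLines(c("#! biomass BIO", "id\tequation\tlb\tub\tgpr",
               "EX_A\tA(e) <=>\t-10\t1000\t",
               "T\tA(e) -> A(c)\t0\t1000\t",
               "ISO\tA(c) -> B(c)\t0\t1000\t(rpiA OR rpiB)",
               "BIO\tB(c) ->\t0\t1000\t"),
             file.path(d, "reactions.tsv"))
  m <- load_model(file.path(d, "reactions.tsv"))
  bounds <- function(mod) {
    rx <- mod$metabolic$reactions
    c(rx$lb[rx$id == "ISO"], rx$ub[rx$id == "ISO"])
  }
  expect_equal(bounds(apply_knockouts(m, "rpiA")), c(0, 1000))
  expect_equal(bounds(apply_knockouts(m, "rpiB")), c(0, 1000))
  expect_equal(bounds(apply_knockouts(m, c("rpiA", "rpiB"))), c(0, 0))
  expect_error(apply_knockouts(m, "nope"), "unknown gene")
  # growth consequence: only the double deletion is lethal
  cond <- condition("A", uptake = c(A = 10))
  expect_equal(maximize_growth(m, cond, "rpiA")$growth, "+")
  expect_equal(maximize_growth(m, cond, c("rpiA", "rpiB"))$growth, "-")
})
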