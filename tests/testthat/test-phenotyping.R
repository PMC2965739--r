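test_that("OD growth calls subtract the control and apply the cutoff", {
  expect_equal(as.character(call_growth_from_od(0.30, 0.05)), "+")  # 0.25
  expect_equal(as.character(call_growth_from_od(0.12, 0.05)), "-")  # 0.07
  expect_equal(as.character(call_growth_from_od(0.05, 0.05)), "-")  # 0
  expect_warning(out <- call_growth_from_od(c(0.3, 0.0), c(0.05, 0.2)),
                 "suspect")
  expect_equal(attr(out, "suspect"), c(FALSE, TRUE))
  # cutoff is a parameter
  expect_equal(as.character(call_growth_from_od(0.12, 0.05, cutoff = 0.05)), "+")
})

test_that("plate-reader conversion is the printed affine map", {
  expect_equal(convert_tecan_od(0), 0.0028)
  expect_equal(convert_tecan_od(1.0), 2.5688)
  # affine identity f(a) + f(b) - f(0) = f(a + b)
  a <- 0.21; b <- 0.49
  expect_equal(convert_tecan_od(a) + convert_tecan_od(b) - convert_tecan_od(0),
               convert_tecan_od(a + b), tolerance = 1e-12)
})

test_that("biolog plate tables yield per-well calls", {
  plate <- tibble::tibble(well = c("A1", "A2", "A3"),
                          od = c(0.05, 0.40, 0.10),
                          control = c("A1", "A1", "A1"))
  out <- biolog_calls(plate)
  expect_equal(out$call, c("-", "+", "-"))
  expect_equal(out$corrected, c(0, 0.35, 0.05))
  expect_error(biolog_calls(tibble::tibble(well = "A1", od = 1, control = "zz")),
               "control well")
})

test_that("classification covers all eight call triples deterministically", {
  grid <- expand.grid(e = c("+", "-"), m = c("+", "-"), i = c("+", "-"),
                      stringsAsFactors = FALSE)
  got <- classify_case(grid$e, grid$m, grid$i)
  want <- character(8)
  for (k in seq_len(8)) {
    want[k] <- if (grid$e[k] == "+" && grid$m[k] == "+" && grid$i[k] == "-") {
      "rule_correction"
    } else if (grid$e[k] == "-" && grid$m[k] == "+" && grid$i[k] == "-") {
      "rescue_non_growth"
    } else if (grid$e[k] == grid$i[k]) "correct"
    else paste(grid$e[k], grid$m[k], grid$i[k], sep = "/")
  }
  expect_equal(got, want)
  expect_error(classify_case("x", "+", "-"))
})

test_that("accuracy counts correct predictions over measured cells", {
  cases <- tibble::tibble(
    experimental = c("+", "+", "-", "-"),
    metabolic    = c("+", "+", "+", "-"),
    integrated   = c("+", "-", "-", "-"))
  a <- accuracy(cases)
  expect_equal(a$accuracy, 0.75)
  expect_equal(a$correct, 3)
  expect_equal(a$rule_correction_cases, 1)
  expect_equal(a$rescue_cases, 1)
  expect_equal(accuracy(dplyr::mutate(cases, integrated = experimental))$accuracy, 1)
  # missing experimental cells drop out of the denominator
  cases$experimental[1] <- NA
  expect_equal(accuracy(cases)$total, 3)
})

test_that("a 1x1 grid on the worked example attributes the violation to G1", {
  grid <- run_grid(toy_model(),
                   tibble::tibble(mutant = "WT", condition = "A medium",
                                  call = "+"),
                   conditions = list("A medium" = toy_condition()))
  expect_equal(grid$cases$class, "rule_correction")
  expect_equal(grid$cases$violated[[1]], "G1")
  expect_equal(grid$report$gene, rep("G1", 2))
  expect_setequal(grid$report$scope_type, c("mutant", "condition"))
  expect_equal(grid$report$n_cases, c(1L, 1L))
})

test_that("a concordant grid yields an empty candidate report", {
  grid <- run_grid(toy_model(),
                   tibble::tibble(mutant = "WT", condition = "empty",
                                  call = "-"),
                   conditions = list(empty = condition("empty")))
  expect_equal(grid$cases$class, "correct")
  expect_equal(nrow(grid$report), 0)
})

# a 5 x 4 grid built by hand around one planted bad rule: gene gS (required
# for substrate S uptake) is wrongly ruled OFF; gS2 (substrate S2 uptake) is
# correctly ruled ON; gU gates a non-essential drain and has no rule.
grid_model <- function() {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(c("#! biomass BIO", "id\tequation\tlb\tub\tgpr",
               "EX_S\tS(e) <=>\t-10\t1000\t",
               "T_S\tS(e) -> M(c)\t0\t1000\t(gS)",
               "EX_S2\tS2(e) <=>\t-5\t1000\t",
               "T_S2\tS2(e) -> M(c)\t0\t1000\t(gS2)",
               "DRAIN\tM(c) -> W(e)\t0\t1000\t(gU)",
               "EX_W\tW(e) ->\t0\t1000\t",
               "BIO\tM(c) ->\t0\t1000\t"),
             file.path(d, "reactions.tsv"))
  met <- read_metabolic_tsv(file.path(d, "reactions.tsv"))
  integrated_model(met, regulatory_model(c(gS = "(OFF)", gS2 = "(ON)")))
}

planted_grid <- function() {
  model <- grid_model()
  conds <- list(
    both = condition("both", uptake = c(S = 10, S2 = 5)),
    S_only = condition("S_only", uptake = c(S = 10)),
    S2_only = condition("S2_only", uptake = c(S2 = 5)),
    empty = condition("empty"))
  # experimental calls as if gS were really expressed (its rule is wrong):
  # growth wherever an intact uptake path exists; gU row carries the rescue
  # cell (S_only called "-") and one missing measurement
  calls <- tibble::tribble(
    ~mutant, ~condition, ~call,
    "WT", "both", "+",  "WT", "S_only", "+",  "WT", "S2_only", "+",  "WT", "empty", "-",
    "gS", "both", "+",  "gS", "S_only", "-",  "gS", "S2_only", "+",  "gS", "empty", "-",
    "gS2", "both", "+", "gS2", "S_only", "+", "gS2", "S2_only", "-", "gS2", "empty", "-",
    "gS,gS2", "both", "-", "gS,gS2", "S_only", "-", "gS,gS2", "S2_only", "-", "gS,gS2", "empty", "-",
    "gU", "both", "+",  "gU", "S_only", "-",  "gU", "S2_only", "+",  "gU", "empty", NA)
  list(model = model, calls = calls, conds = conds, pg = "gS")
}

test_that("grid bookkeeping partitions the cases and flags the planted gene", {
  g <- planted_grid()
  grid <- run_grid(g$model, g$calls, g$conds)
  cases <- grid$cases
  expect_equal(nrow(cases), 20)
  evaluated <- cases[!cases$class %in% c("missing_experimental", "unevaluated",
                                         "blacklisted_condition"), ]
  expect_equal(nrow(evaluated), 19)
  n_rc <- sum(evaluated$class == "rule_correction")
  n_rescue <- sum(evaluated$class == "rescue_non_growth")
  n_correct <- sum(evaluated$class == "correct")
  n_other <- nrow(evaluated) - n_rc - n_rescue - n_correct
  expect_equal(n_rc + n_rescue + n_correct + n_other, nrow(evaluated))
  # hand tally: (+,+,-) at WT/S_only, gS2/both, gS2/S_only; (-,+,-) at
  # gU/S_only; everything else agrees
  expect_equal(n_rc, 3)
  expect_equal(n_rescue, 1)
  expect_equal(n_correct, 15)
  expect_equal(n_other, 0)
  acc <- accuracy(evaluated)
  # rescue cells are correct predictions (exp == int == "-"): 15 + 1 of 19
  expect_equal(acc$accuracy, 16 / 19)
  expect_equal(acc$correct,
               sum(evaluated$experimental == evaluated$integrated))
  # each rule-correction cell pins the planted gene
  expect_true(all(vapply(cases$violated[cases$class == "rule_correction"],
                         function(v) identical(v, g$pg), logical(1))))
  # per-condition frequency table is topped by the planted gene
  cond_rep <- grid$report[grid$report$scope_type == "condition", ]
  expect_equal(cond_rep$gene[which.max(cond_rep$n_cases)], g$pg)
  expect_equal(sum(grid$report$n_cases[grid$report$scope_type == "mutant"]), 3)
})

test_that("applying a reported correction flips the targeted cells and counts new false positives", {
  g <- planted_grid()
  before <- run_grid(g$model, g$calls, g$conds)
  fixed_model <- set_rule(g$model, g$pg, "(ON)")
  after <- run_grid(fixed_model, g$calls, g$conds)
  flipped <- before$cases$class == "rule_correction" &
    after$cases$class == "correct"
  expect_equal(sum(flipped), 3)  # all targeted (+,+,-) cells now (+,+,+)
  audit <- audit_correction(before, after)
  expect_equal(audit$fixed, 3)
  # hand count: the rescue cell gU/S_only becomes (-,+,+)
  expect_equal(audit$new_false_positives, 1)
})

test_that("blacklisted conditions and solver failures do not abort the grid", {
  g <- planted_grid()
  grid <- run_grid(g$model, g$calls, g$conds, blacklist = "empty")
  expect_equal(sum(grid$cases$class == "blacklisted_condition"), 5)
  # a condition naming an unknown metabolite fails only its own cells
  conds2 <- c(g$conds, list(bad = condition("bad", uptake = c(nope = 1))))
  calls2 <- dplyr::bind_rows(g$calls,
                             tibble::tibble(mutant = "WT", condition = "bad",
                                            call = "+"))
  grid2 <- run_grid(g$model, calls2, conds2)
  expect_equal(sum(grid2$cases$class == "unevaluated"), 1)
  expect_equal(nrow(grid2$cases), 21)
})

test_that("rescue cases are analyzed only on request and labeled by flag", {
  g <- planted_grid()
  grid_off <- run_grid(g$model, g$calls, g$conds)
  rescue_rows <- grid_off$cases$class == "rescue_non_growth"
  expect_true(all(is.na(grid_off$cases$n_violations[rescue_rows])))
  grid_on <- run_grid(g$model, g$calls, g$conds, rescue = TRUE)
  rr <- grid_on$cases[grid_on$cases$class == "rescue_non_growth", ]
  expect_equal(rr$n_violations, 1)          # over-expressing gS rescues
  expect_equal(rr$violated[[1]], "gS")
})
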