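write_prop_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("property tables load, validate and report malformed rows", {
  one <- data.frame(compound_id = "A", property = "fu", subtype = "fu",
                    value = 0.3, source = "measured", MW = 250)
  tab <- load_property_table(write_prop_csv(one))
  expect_length(tab, 1)
  expect_s3_class(tab$A, "htpbk_compound")
  expect_identical(nrow(tab$A$records), 1L)

  empty <- one[0, ]
  expect_identical(load_property_table(write_prop_csv(empty)), list())

  expect_error(load_property_table(write_prop_csv(one[, -2])),
               "missing mandatory column")
  bad <- one; bad$value <- "not-a-number"
  expect_error(load_property_table(write_prop_csv(bad)), "row")
})

test_that("duplicate (compound, property, subtype, source) rows are averaged", {
  dup <- data.frame(compound_id = "A", property = "fu", subtype = "fu",
                    value = c(0.2, 0.4), source = "measured", MW = 250)
  expect_warning(tab <- load_property_table(write_prop_csv(dup)), "averaged")
  expect_equal(tab$A$records$value, 0.3)
})

test_that("declared units are converted to canonical units at load", {
  tab <- data.frame(
    compound_id = "A",
    property = c("solubility", "permeability", "clearance"),
    subtype = c("aqueous", "CACO2", "plasma_CL"),
    value = c(0.001, 1e-4, 100),      # mol/L, cm/s, ml/min
    source = "x", MW = 200,
    unit = c("mol/L", "cm/s", "ml/min"))
  recs <- load_property_table(write_prop_csv(tab))$A$records
  expect_equal(recs$value[recs$property == "solubility"], 200)   # mg/L
  expect_equal(recs$value[recs$property == "permeability"], 6e-3) # cm/min
  expect_equal(recs$value[recs$property == "clearance"], 6)      # L/h
})

test_that("consensus_value is the arithmetic mean and guards its inputs", {
  rec <- function(v) data.frame(property = rep("lipophilicity", length(v)),
                                subtype = rep("LogP", length(v)),
                                value = v, source = letters[seq_along(v)])
  expect_equal(consensus_value(rec(2)), 2)
  expect_equal(consensus_value(rec(c(1, 3))), 2)
  expect_equal(consensus_value(rec(c(1, 2, 6))), 3)
  expect_equal(consensus_value(rec(c(6, 1, 2))), 3)   # permutation-invariant
  expect_error(consensus_value(rec(numeric(0))), "empty")
  mixed <- rbind(rec(1), data.frame(property = "lipophilicity",
                                    subtype = "LogD", value = 2, source = "z"))
  expect_error(consensus_value(mixed), "single property/subtype")
})

test_that("lipophilicity conversion applies the configured linear map", {
  expect_equal(convert_lipophilicity(
    3.2, list(input_subtype = "LogP", slope = 1, intercept = 0), "LogP"), 3.2)
  expect_equal(convert_lipophilicity(
    -5, list(input_subtype = "LogP", slope = 0, intercept = 1.7), "LogP"), 1.7)
  expect_error(convert_lipophilicity(
    2, list(input_subtype = "LogP", slope = 1, intercept = 0), "LogD"),
    "expects LogP")
  # shipped config: value follows the configured regression line exactly
  ct <- lipophilicity_conversions()
  yun <- as.list(ct[ct$name == "yun_logp", ])
  expect_equal(convert_lipophilicity(3, yun, "LogP"),
               yun$slope * 3 + yun$intercept)
})

test_that("resolve_inputs copies single-source slots through", {
  cmp <- fixture_compound()
  p <- resolve_inputs(cmp, fixture_strategy(), "iv")
  expect_equal(p$lipophilicity$value, 2.1)
  expect_identical(p$lipophilicity$subtype, "LogD")
  expect_equal(p$fu, 0.25)
  expect_equal(p$clearance$value, 12)
  expect_identical(p$clearance$mode, "plasma")
  expect_equal(nrow(p$pka), 2)
})

test_that("pka_source 'none' resolves to an empty pKa set (neutral)", {
  p <- resolve_inputs(fixture_compound(), fixture_strategy(pka_source = "none"),
                      "iv")
  expect_identical(nrow(p$pka), 0L)
})

test_that("lipophilicity consensus takes the mean of the named sources", {
  strat <- fixture_strategy(
    lipophilicity_sources = c("BayerLogD", "BayerLogMA"),
    lipophilicity_consensus = TRUE)
  p <- resolve_inputs(fixture_compound(), strat, "iv")
  expect_equal(p$lipophilicity$value, mean(c(2.1, 2.7)))
  expect_identical(p$lipophilicity$subtype, "mixed")
})

test_that("missing slots fail with compound and source named", {
  cmp <- fixture_compound()
  expect_error(resolve_inputs(cmp, fixture_strategy(fu_source = "nope"), "iv"),
               "CPD1.*fu.*nope")
  expect_error(resolve_inputs(cmp, fixture_strategy(clearance_mode = "intrinsic",
                                                    clearance_source = "in vivo"),
                              "iv"),
               "hepatocyte_CLint")
  no_po <- fixture_strategy(solubility_source = NULL,
                            permeability_source = NULL)
  expect_error(resolve_inputs(cmp, no_po, "po"), "PO route requires")
})

test_that("resolution is invariant to record order", {
  cmp <- fixture_compound()
  shuffled <- cmp
  set.seed(7)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  strat <- fixture_strategy(lipophilicity_sources = c("BayerLogD", "BayerLogMA"),
                            lipophilicity_consensus = TRUE)
  a <- resolve_inputs(cmp, strat, "po")
  b <- resolve_inputs(shuffled, strat, "po")
  a$pka <- a$pka[order(a$pka$value), ]; b$pka <- b$pka[order(b$pka$value), ]
  rownames(a$pka) <- rownames(b$pka) <- NULL
  expect_equal(a, b)
})

test_that("strategy documents round-trip through JSON and ship with the package", {
  strat <- fixture_strategy(label = "rt")
  path <- withr::local_tempfile(fileext = ".json")
  write_strategy(strat, path)
  expect_equal(read_strategy(path), strat)
  for (name in c("best_overall", "best_insilico_proprietary",
                 "best_insilico_free")) {
    s <- read_strategy(name)
    expect_s3_class(s, "htpbk_strategy")
    expect_identical(s$label, name)
  }
  # the shipped full strategies resolve a synthetic-style compound only when
  # its sources exist; unknown names error
  expect_error(read_strategy("not_a_strategy"), "no such strategy")
})
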