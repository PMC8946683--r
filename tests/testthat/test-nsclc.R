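test_that("the checkpoint model has the expected structure", {
  b <- nsclc_cached()
  m <- b$model
  expect_equal(m$n, 32L)
  expect_equal(sum(m$nodes$kind == "input"), 1L)
  expect_equal(m$nodes$name[m$nodes$kind == "input"], "DNA_Damage")
  expect_equal(sort(m$nodes$symbol[m$nodes$kind == "output"]),
               c("Apoptosis", "Proliferation", "Senescence"))
  # miR-34a silences its eight published targets
  mir_targets <- sort(m$edges$target[m$edges$source == "miR34a" &
                                       m$edges$sign == -1L])
  expect_true(all(c("Myc", "HDAC1", "Sirt1", "E2F1", "Cdc25A", "BCL2",
                    "CDK46_CycD", "CDK2_CycE") %in% mir_targets))
  # both lncRNAs sponge miR-34a, EZH2 assists
  expect_equal(sort(m$edges$source[m$edges$target == "miR34a" &
                                     m$edges$sign == -1L]),
               c("ANRIL", "EZH2", "UFC1"))
  # sponge drivers: E2F1 -> UFC1, E2F1/Myc -> ANRIL
  expect_equal(m$edges$source[m$edges$target == "UFC1"], "E2F1")
  expect_equal(sort(m$edges$source[m$edges$target == "ANRIL"]),
               c("E2F1", "Myc"))
  # the model passes every structural invariant (validated on load)
  expect_silent(validate_model(m))
})

test_that("wild-type dynamics has exactly three fixed points", {
  b <- nsclc_cached()
  fps <- b$fixed_points
  expect_equal(nrow(fps), 3L)
  ph <- apply(fps, 1, function(s) classify_attractor(b$model, s))
  expect_equal(sort(ph), c("Apoptosis", "Proliferation", "Senescence"))
  pro <- fps[ph == "Proliferation", ]
  expect_equal(unname(pro["DNA_Damage"]), 0L)
  expect_true(all(pro[c("CDK46_CycD", "CDK2_CycE", "Cdc25A", "Myc",
                        "ANRIL", "UFC1")] == 1L))
  expect_equal(unname(pro["miR34a"]), 0L)
  sen <- fps[ph == "Senescence", ]
  apo <- fps[ph == "Apoptosis", ]
  expect_true(sen["DNA_Damage"] == 1 && sen["p53A"] == 1 && sen["p21"] == 1)
  expect_true(apo["DNA_Damage"] == 1 && apo["p53K"] == 1 && apo["Casp3"] == 1)
  # at most one output ON in every fixed point
  outs <- fps[, b$model$nodes$kind == "output", drop = FALSE]
  expect_true(all(rowSums(outs) <= 1L))
})

test_that("scenario resolution returns clamps, input and expectations", {
  b <- nsclc_cached()
  sc <- nsclc_scenario(b, "UFC1_KO_miR34a_E1")
  expect_equal(sc$input, 1L)
  expect_setequal(names(sc$perturbation), c("miR34a", "UFC1"))
  expect_equal(unname(unclass(sc$perturbation)[c("UFC1", "miR34a")]),
               c(0L, 1L))
  sc0 <- nsclc_scenario(b, "WT_no_damage")
  expect_equal(sc0$input, 0L)
  expect_equal(length(sc0$perturbation), 0L)
  sc36 <- nsclc_scenario(b, "ANRIL_KO_UFC1_KO")
  expect_equal(unname(unclass(sc36$perturbation)[c("ANRIL", "UFC1")]),
               c(0L, 0L))
  expect_error(nsclc_scenario(b, "nope"), "unknown scenario")
  # 17 named experiments + 24 circuit-screen rows
  expect_equal(length(b$scenarios), 41L)
})

test_that("the sponge perturbation battery reproduces the mutant fates", {
  b <- nsclc_cached()
  cases <- list(
    UFC1_KO = c("Apoptosis", "Senescence"),
    ANRIL_KO = c("Apoptosis", "Senescence"),
    ANRIL_KO_UFC1_KO = c("Apoptosis", "Senescence"),
    UFC1_E1 = "Apoptosis", ANRIL_E1 = "Apoptosis",
    UFC1_KO_miR34a_KO = "Apoptosis", ANRIL_KO_miR34a_KO = "Apoptosis",
    miR34a_KO = "Apoptosis",
    miR34a_E1 = c("Apoptosis", "Senescence"),
    Myc_KO = c("Apoptosis", "Senescence"), Myc_E1 = "Apoptosis")
  for (nm in names(cases)) {
    fp <- scenario_fixed_points(b, nm)
    expect_equal(sort(unique(attr(fp, "phenotype"))), sort(cases[[nm]]),
                 info = nm)
  }
  # lncRNA loss derepresses miR-34a in every damage fixed point
  for (nm in c("UFC1_KO", "ANRIL_KO", "ANRIL_KO_UFC1_KO"))
    expect_true(all(scenario_fixed_points(b, nm)[, "miR34a"] == 1L))
  # sponge excess or Myc excess silences it
  for (nm in c("UFC1_E1", "ANRIL_E1", "Myc_E1"))
    expect_true(all(scenario_fixed_points(b, nm)[, "miR34a"] == 0L))
  # miR-34a excess / Myc loss shuts both lncRNAs down
  for (nm in c("miR34a_E1", "Myc_KO")) {
    fp <- scenario_fixed_points(b, nm)
    expect_true(all(fp[, c("ANRIL", "UFC1")] == 0L))
  }
  # over-expressed sponges keep the proliferative state without damage
  for (nm in c("UFC1_E1_no_damage", "ANRIL_E1_no_damage")) {
    fp <- scenario_fixed_points(b, nm)
    expect_equal(attr(fp, "phenotype"), "Proliferation")
  }
})

test_that("the full calibration check passes", {
  expect_true(check_nsclc_calibration(nsclc_cached()))
})

test_that("scenario runs start from the perturbed proliferative state", {
  b <- nsclc_cached()
  root <- nsclc_root_state(b, input = 1L, perturbation(UFC1 = 0))
  expect_equal(unname(root["DNA_Damage"]), 1L)
  expect_equal(unname(root["UFC1"]), 0L)
  expect_equal(unname(root["Myc"]), 1L)   # proliferative background
})

test_that("Monte Carlo and exact absorption agree on a small scenario", {
  b <- nsclc_cached()
  ex <- run_scenario(b, "Myc_E1", method = "exact")
  mc <- run_scenario(b, "Myc_E1", n_runs = 5000, seed = 3)
  expect_equal(ex$phenotype, "Apoptosis")
  expect_equal(ex$probability, 1)
  expect_equal(mc$probability[mc$phenotype == "Apoptosis"], 1)
})
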