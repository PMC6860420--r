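test_that("the integrated network has the documented structure", {
  mm <- cached_macro()
  rep <- structural_report(mm$model)
  expect_equal(rep$n_nodes, 80)
  expect_equal(rep$n_reactions, 130)
  expect_equal(rep$n_groups, 34)
  expect_length(rep$params_unused, 0)
  # every sensitivity-ranked parameter label resolves
  ranked <- c("k127", "kf63", "kr70", "kf64", "kf17", "k33", "k61", "k77",
              "k45", "kf44", "kf42", "k37", "k99", "kr42", "k78", "kf8",
              "kr44", "kf95", "k71", "kf13", "ka77", "kf7", "kf52",
              "kf70", "kr64")
  expect_length(setdiff(ranked, names(mm$model$parameters)), 0)
  # marker panels: six M1, three M2, CXCL10 reported at mRNA level
  expect_length(mm$model$marker_panels$m1, 6)
  expect_length(mm$model$marker_panels$m2, 3)
  expect_true("CXCL10" %in% mm$model$marker_panels$m1)
  cx <- mm$model$species[mm$model$species$group == "CXCL10", ]
  expect_true("CXCL10_mRNA" %in% cx$id)
})

test_that("the untreated steady state is admissible and near-stationary", {
  mm <- cached_macro()
  expect_lt(attr(mm$state, "residual"), 1e-8)
  # assembled derivative at the steady state is negligible
  rhs <- assemble_rhs(mm$model)
  dy <- rhs(0, mm$state, NULL)[[1]]
  expect_lt(max(abs(dy) / pmax(as.numeric(mm$state), 1)), 1e-8)
  # all 34 group totals inside the 0.5x-2x copy-number band
  adm <- check_initial_conditions(mm$model, macrophage_priors(),
                                  state = mm$state)
  expect_equal(nrow(adm), 34)
  expect_true(all(adm$pass))
})

test_that("receptor ligation cycles conserve mass when turnover is disabled", {
  mm <- cached_macro()
  # freeze IFN-gamma receptor synthesis/turnover and SOCS-route removal:
  # the remaining ligation/activation/recycling cycle conserves receptor
  m <- mm$model
  # identify the reactions by annotation instead of hard-coding numbers
  ann <- vapply(m$reactions, `[[`, "", "annotation")
  syn <- m$reactions[[grep("receptor/JAK synthesis", ann)]]$params[1]
  deg <- m$reactions[[grep("^receptor turnover$", ann)[1]]]$params[1]
  rec <- m$reactions[[grep("recycled, bound ligand degraded",
                           ann)]]$params[1]
  s1deg <- m$reactions[[grep("JAK sequestered", ann)]]$params[1]
  parms <- setNames(rep(0, 4), c(syn, deg, rec, s1deg))
  st <- mm$state
  sim <- run_scenario(m, events = list(mp_stimulus("IFNg", 10, 17000)),
                      horizon = 24, state0 = st, parms = parms,
                      n_out = 49)
  rsp <- c("R_I", "R_I_lig", "R_I_act", "R_I_S1", "R_I_S3")
  totals <- rowSums(sim$mat[, rsp]) + sim$mat[, "S1dock"]
  expect_lt(diff(range(totals)) / totals[1], 1e-6)
})

test_that("HIF-1beta is conserved across its dimerization cycle", {
  mm <- cached_macro()
  sim <- run_scenario(mm$model, oxygen = mp_oxygen(2), horizon = 48,
                      state0 = mm$state, n_out = 49)
  totals <- sim$mat[, "HIF1b"] + sim$mat[, "HIF1_n"] + sim$mat[, "HIF2_n"]
  expect_lt(diff(range(totals)) / totals[1], 1e-6)
})

test_that("stimulus responses reproduce the canonical polarization picture", {
  mm <- cached_macro()
  m <- mm$model; st <- mm$state
  at <- function(sim, sp, t = 24) approx(sim$times, sim$mat[, sp],
                                         xout = t)$y

  s_ifng <- run_scenario(m, events = list(mp_stimulus("IFNg", 10, 17000)),
                         horizon = 48, state0 = st)
  # transient peak then decay of nuclear phospho-STAT1
  ps <- s_ifng$mat[, "pSTAT1d_n"]
  expect_gt(max(ps), 5 * ps[1])
  expect_lt(tail(ps, 1), 0.5 * max(ps))
  # M1 markers up at 24 h, more sustained than the phospho-STAT peak
  for (mk in c("iNOS", "TNFa", "IL12", "CXCL9", "CXCL10"))
    expect_gt(at(s_ifng, mk) / st[[mk]], 1.5)
  # IFN-gamma lowers miR-3473b and de-suppresses PTEN
  expect_lt(at(s_ifng, "miR3473b") / st[["miR3473b"]], 0.9)
  expect_gt(at(s_ifng, "PTEN", 36) / st[["PTEN"]], 1.05)

  s_il4 <- run_scenario(m, events = list(mp_stimulus("IL4", 10, 14000)),
                        horizon = 48, state0 = st)
  ps6 <- s_il4$mat[, "pSTAT6d_n"]
  expect_gt(max(ps6), 5 * ps6[1])
  expect_lt(tail(ps6, 1), 0.5 * max(ps6))
  for (mk in c("Arg1", "IL10", "VEGF"))
    expect_gt(at(s_il4, mk) / st[[mk]], 1.5)
  expect_gt(at(s_il4, "IRF4") / st[["IRF4"]], 1.5)
  expect_gt(at(s_il4, "pAKT") / st[["pAKT"]], 2)
})

test_that("dose response is monotone into the low ng/ml range", {
  mm <- cached_macro()
  at24 <- function(dose, sp) {
    sim <- run_scenario(mm$model,
                        events = list(mp_stimulus(
                          if (sp == "iNOS") "IFNg" else "IL4", dose,
                          if (sp == "iNOS") 17000 else 14000)),
                        horizon = 26, state0 = mm$state, n_out = 40)
    approx(sim$times, sim$mat[, sp], xout = 24)$y
  }
  inos <- vapply(c(0.01, 0.1, 1, 10), at24, numeric(1), sp = "iNOS")
  arg1 <- vapply(c(0.01, 0.1, 1, 10), at24, numeric(1), sp = "Arg1")
  expect_true(all(diff(inos) > 0))
  expect_true(all(diff(arg1) > 0))
  # evident induction already at 1 ng/ml relative to the 0.01 baseline
  expect_gt(inos[3] / inos[1], 1.2)
  expect_gt(arg1[3] / arg1[1], 1.2)
})
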