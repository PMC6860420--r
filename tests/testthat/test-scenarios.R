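test_that("perturbation edits follow the stated genetic semantics", {
  mm <- cached_macro()
  m <- mm$model; st <- mm$state

  # overexpression: principal node at 50x baseline, parameters untouched
  oe <- apply_perturbations(m, st, mp_perturbation("overexpress", "SOCS1"))
  expect_equal(oe$state0[["SOCS1"]], 50 * st[["SOCS1"]])
  expect_equal(as.numeric(oe$model$parameters),
               as.numeric(m$parameters))

  # silencing: zero initial and zero production for the whole group
  si <- apply_perturbations(m, st, mp_perturbation("silence", "SOCS3"))
  expect_equal(unname(si$state0[["SOCS3"]]), 0)
  prod_labs <- vapply(macpol:::production_reactions(m, "SOCS3"),
                      function(r) r$params[1], "")
  expect_true(all(si$model$parameters[prod_labs] == 0))
  other <- setdiff(names(m$parameters), prod_labs)
  expect_equal(as.numeric(si$model$parameters[other]),
               as.numeric(m$parameters[other]))

  # production_scale touches exactly the synthesis rate constants
  ps <- apply_perturbations(m, st,
                            mp_perturbation("production_scale", "IFNg", 0.1))
  ifng_labs <- vapply(macpol:::production_reactions(m, "IFNg"),
                      function(r) r$params[1], "")
  expect_equal(as.numeric(ps$model$parameters[ifng_labs]),
               0.1 * as.numeric(m$parameters[ifng_labs]))
  expect_equal(as.numeric(ps$model$parameters[setdiff(other, ifng_labs)]),
               as.numeric(m$parameters[setdiff(other, ifng_labs)]))

  # rate_scale touches exactly the named parameter
  rs <- apply_perturbations(m, st, mp_perturbation("rate_scale", "kf63", 0.1))
  expect_equal(rs$model$parameters[["kf63"]], 0.1 * m$parameters[["kf63"]])
  diffs <- which(as.numeric(rs$model$parameters) !=
                 as.numeric(m$parameters))
  expect_equal(names(m$parameters)[diffs], "kf63")
})

test_that("perturbations are composable, order-independent and conflict-checked", {
  mm <- cached_macro()
  specs <- list(mp_perturbation("production_scale", "IFNg", 0.1),
                mp_perturbation("production_scale", "HIF1a", 0.1),
                mp_perturbation("rate_scale", "kf70", 0.5))
  for (ord in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    a <- apply_perturbations(mm$model, mm$state, specs)
    b <- apply_perturbations(mm$model, mm$state, specs[ord])
    expect_equal(as.numeric(a$model$parameters),
                 as.numeric(b$model$parameters))
    expect_equal(a$state0, b$state0)
  }
  expect_error(
    apply_perturbations(mm$model, mm$state,
                        list(mp_perturbation("rate_scale", "kf70", 0.1),
                             mp_perturbation("rate_scale", "kf70", 2))),
    "conflicting")
  expect_error(
    apply_perturbations(mm$model, mm$state,
                        mp_perturbation("silence", "NotAGroup")),
    "unknown perturbation target")
  expect_error(mp_perturbation("silence", "SOCS1", factor = 2),
               "no factor")
})

test_that("silenced groups stay identically zero under any stimulation", {
  mm <- cached_macro()
  for (g in c("SOCS1", "SOCS3", "miR93")) {
    p <- apply_perturbations(mm$model, mm$state,
                             mp_perturbation("silence", g))
    sim <- run_scenario(p$model,
                        events = list(mp_stimulus("IFNg", 10, 17000),
                                      mp_stimulus("IL4", 10, 14000,
                                                  time = 2)),
                        oxygen = mp_oxygen(2), horizon = 24,
                        state0 = p$state0, n_out = 49)
    gs <- p$model$species$id[p$model$species$group == g]
    expect_equal(max(sim$mat[, gs]), 0)
  }
})

test_that("normalization modes behave as documented", {
  t <- 0:10
  v <- c(5, 6, 8, 10, 9, 8, 7, 6, 5.5, 5.2, 5)
  expect_equal(macpol:::normalize_series(t, rep(3, 11), mp_norm("to_t0")),
               rep(1, 11))
  expect_equal(max(macpol:::normalize_series(t, v, mp_norm("to_max"))), 1)
  expect_equal(macpol:::normalize_series(t, v,
                                         mp_norm("to_reference_time", 3)),
               v / 10)
  expect_equal(
    macpol:::normalize_series(t, c(2, 16, rep(2, 9)),
                              mp_norm("log2_fold"))[2], 3)
  expect_error(macpol:::normalize_series(t, c(0, v[-1]), mp_norm("to_t0")),
               "strictly positive")
})

test_that("marker extraction normalizes panels per species", {
  mm <- cached_macro()
  sim <- run_scenario(mm$model,
                      events = list(mp_stimulus("IFNg", 10, 17000)),
                      horizon = 24, state0 = mm$state, n_out = 49)
  mk <- extract_markers(sim, "m1", mp_norm("to_t0"))
  expect_setequal(unique(mk$species), mm$model$marker_panels$m1)
  expect_equal(mk$value[mk$time == 0], rep(1, 6))
  mx <- extract_markers(sim, c("iNOS", "TNFa"), mp_norm("to_max"))
  expect_equal(as.numeric(tapply(mx$value, mx$species, max)), c(1, 1))
  expect_error(extract_markers(sim, "NotASpecies"), "unknown marker")
})

test_that("the M1/M2 score is the six-over-three product ratio", {
  # direct arithmetic on a hand-built simulation object
  fake_sim <- function(vals) {
    mat <- matrix(rep(vals, each = 3), nrow = 3,
                  dimnames = list(NULL, names(vals)))
    structure(list(times = c(0, 24, 48), mat = mat,
                   model = list(marker_panels = list())),
              class = "mp_sim")
  }
  nine <- c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1, x = 1, y = 1, z = 1)
  m1 <- letters[1:6]; m2 <- c("x", "y", "z")
  expect_equal(m1m2_score(fake_sim(nine), m1, m2), 1)
  two <- nine; two[["a"]] <- 2
  expect_equal(m1m2_score(fake_sim(two), m1, m2), 2)
  half <- nine; half[["y"]] <- 2
  expect_equal(m1m2_score(fake_sim(half), m1, m2), 0.5)
  set.seed(42)
  for (i in 1:20) {
    vals <- setNames(runif(9, 0.1, 100), names(nine))
    expect_equal(m1m2_score(fake_sim(vals), m1, m2),
                 prod(vals[m1]) / prod(vals[m2]))
  }
  expect_error(m1m2_score(fake_sim(nine), m1[1:5], m2), "6 M1")
  zero <- nine; zero[["b"]] <- 0
  expect_error(m1m2_score(fake_sim(zero), m1, m2), "non-positive")
})
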