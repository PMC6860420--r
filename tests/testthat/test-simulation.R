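test_that("dose conversion matches independent arithmetic and is linear", {
  # (10e-9 g/ml / 17000 g/mol) * N_A / 1e6 cells/ml, computed by hand
  expect_equal(dose_to_copies(10, 17000, 1e6),
               10e-9 / 17000 * 6.02214076e23 / 1e6, tolerance = 1e-12)
  expect_equal(dose_to_copies(10, 17000), 354243.5, tolerance = 1e-4)
  expect_equal(dose_to_copies(0, 17000), 0)
  expect_equal(dose_to_copies(20, 17000), 2 * dose_to_copies(10, 17000))
  expect_error(dose_to_copies(10, -5), "mol_weight")
  expect_error(dose_to_copies(10, 17000, 0), "cell_density")
})

test_that("equilibration finds closed-form steady states", {
  # production/degradation: s/d
  st <- equilibrate(toy_pd$model)
  expect_equal(unname(st[["X"]]), unname(toy_pd$oracle$steady_state[["X"]]),
               tolerance = 1e-6)
  expect_lt(attr(st, "residual"), 1e-8)

  # cascade: iterated closed form
  cas <- make_toy("linear_cascade", size = 5)
  st2 <- equilibrate(cas$model)
  expect_equal(unname(st2[cas$model$species$id]),
               unname(cas$oracle$steady_state), tolerance = 1e-6)

  # independent damped-Newton root solve on the assembled RHS (cascade
  # topology: no conservation laws, so the equilibrium is an isolated root)
  lrs <- make_toy("linear_cascade", size = 4)
  st3 <- equilibrate(lrs$model)
  rhs <- assemble_rhs(lrs$model)
  f <- function(x) rhs(0, pmax(x, 0), NULL)[[1]]
  x <- pmax(as.numeric(st3) * runif(length(st3), 0.5, 1.5), 1e-6)
  for (iter in 1:200) {
    J <- numeric_jacobian(f, x)
    step <- tryCatch(solve(J, -f(x)), error = function(e) -0.1 * f(x))
    lam <- 1
    repeat {
      xn <- pmax(x + lam * step, 0)
      if (sum(f(xn)^2) < sum(f(x)^2) || lam < 1e-4) break
      lam <- lam / 2
    }
    x <- xn
    if (max(abs(f(x))) < 1e-10) break
  }
  expect_equal(unname(as.numeric(st3)), unname(x), tolerance = 1e-4)
})

test_that("scenarios reproduce closed-form trajectories and stay at equilibria", {
  # pure exponential decay: X(t) = X0 exp(-d t), half-life ln2/d
  d <- 0.35
  m <- mp_model(mp_species("X", initial = 1000),
                list(mp_reaction("deg", reactants = c(X = 1),
                                 kind = "mass_action_irreversible",
                                 params = "d")),
                mp_parameters(c(d = d)))
  sim <- run_scenario(m, horizon = 20, state0 = c(X = 1000))
  expect_equal(sim$mat[, "X"], 1000 * exp(-d * sim$times),
               tolerance = 1e-6)
  thalf <- approx(sim$mat[, "X"], sim$times, xout = 500)$y
  expect_equal(thalf, log(2) / d, tolerance = 1e-4)

  # no events, start at equilibrium: constant over 48 h
  st <- equilibrate(toy_pd$model)
  sim2 <- run_scenario(toy_pd$model, horizon = 48, state0 = st)
  expect_lt(max(abs(sim2$mat[, "X"] - st[["X"]])) / st[["X"]], 1e-6)
})

test_that("stiff integration matches a fine-step RK4 reference", {
  lrs <- make_toy("ligand_receptor_stat")
  st <- equilibrate(lrs$model)
  sim <- run_scenario(lrs$model,
                      events = mp_stimulus("L", copies = 5e4),
                      horizon = 10, state0 = st, n_out = 21,
                      rtol = 1e-9, atol = 1e-8)
  # hand-written classical RK4 at fixed small step
  rhs <- assemble_rhs(lrs$model)
  f <- function(y) rhs(0, y, NULL)[[1]]
  y <- as.numeric(st); y[1] <- y[1] + 5e4
  h <- 0.0005
  ref <- matrix(NA, 21, length(y))
  ref[1, ] <- y
  tgrid <- seq(0, 10, length.out = 21)
  ti <- 0; k <- 2
  while (k <= 21) {
    k1 <- f(y); k2 <- f(y + h / 2 * k1); k3 <- f(y + h / 2 * k2)
    k4 <- f(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    ti <- ti + h
    if (abs(ti - tgrid[k]) < h / 2) { ref[k, ] <- y; k <- k + 1 }
  }
  rel <- abs(sim$mat - ref) / pmax(abs(ref), 1)
  expect_lt(max(rel), 1e-4)
})

test_that("event ordering does not affect trajectories and grids contain event times", {
  lrs <- make_toy("ligand_receptor_stat")
  st <- equilibrate(lrs$model)
  e1 <- mp_stimulus("L", copies = 2e4, time = 2)
  e2 <- mp_stimulus("L", copies = 4e4, time = 5)
  s12 <- run_scenario(lrs$model, events = list(e1, e2), horizon = 12,
                      state0 = st)
  s21 <- run_scenario(lrs$model, events = list(e2, e1), horizon = 12,
                      state0 = st)
  expect_equal(s12$mat, s21$mat)
  expect_true(all(c(2, 5) %in% s12$times))
  expect_true(all(diff(s12$times) > 0))
  # doses add to the current pool rather than replacing it
  iL <- which(colnames(s12$mat) == "L")
  before <- s12$mat[max(which(s12$times < 5)), iL]
  after <- s12$mat[min(which(s12$times > 5)), iL]
  expect_gt(after, before + 0.8 * 4e4)
  expect_error(run_scenario(lrs$model, events = list(e2), horizon = 3,
                            state0 = st), "horizon")
})

test_that("oxygen conditions rescale the buffered oxygen species linearly", {
  mm <- cached_macro()
  sim <- run_scenario(mm$model, oxygen = mp_oxygen(3), horizon = 2,
                      state0 = mm$state, n_out = 5)
  expect_equal(unique(sim$mat[, "O2"]), 3 / 21 * 2.1e5)
  expect_error(mp_oxygen(0), "percent")
  expect_error(mp_oxygen(25), "percent")
})

test_that("tightening tolerances leaves marker trajectories unchanged", {
  mm <- cached_macro()
  ev <- list(mp_stimulus("IFNg", 10, 17000))
  a <- run_scenario(mm$model, events = ev, horizon = 24,
                    state0 = mm$state, n_out = 25)
  b <- run_scenario(mm$model, events = ev, horizon = 24,
                    state0 = mm$state, n_out = 25,
                    rtol = 1e-7, atol = 1e-4)
  mk <- c(mm$model$marker_panels$m1, mm$model$marker_panels$m2)
  rel <- abs(a$mat[, mk] - b$mat[, mk]) / pmax(b$mat[, mk], 1)
  expect_lt(max(rel), 1e-3)
})
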