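# Shared fixtures: toy models and a cached full-model equilibrium so the
# expensive objects are built once per test run.

toy_pd <- make_toy("production_degradation")
toy_cycle <- make_toy("conserved_cycle")

cached_macro <- local({
  model <- NULL; state <- NULL
  function() {
    if (is.null(model)) {
      model <<- macrophage_model()
      state <<- equilibrate(model)
    }
    list(model = model, state = state)
  }
})

# random toy network generator used by the RHS oracle equivalence suite:
# <= 8 species, <= 10 reactions drawn over all four rate-law kinds
random_toy_network <- function(seed) {
  set.seed(seed)
  ns <- sample(2:8, 1)
  ids <- paste0("S", seq_len(ns))
  species <- do.call(rbind, lapply(ids, function(i)
    mp_species(i, initial = runif(1, 0, 100))))
  nr <- sample(2:10, 1)
  params <- c(); reactions <- list()
  for (j in seq_len(nr)) {
    nreac <- sample(0:2, 1)
    reac <- if (nreac > 0)
      setNames(sample(1:2, nreac, replace = TRUE),
               sample(ids, nreac)) else c()
    nprod <- if (nreac == 0) sample(1:2, 1) else sample(0:2, 1)
    prod <- if (nprod > 0)
      setNames(sample(1:2, nprod, replace = TRUE),
               sample(ids, nprod)) else c()
    if (length(reac) == 0 && length(prod) == 0) prod <- setNames(1, ids[1])
    pool <- setdiff(ids, names(reac))
    kinds <- c("mass_action_irreversible", "mass_action_reversible",
               if (length(pool) > 0) c("hill_activation",
                                       "hill_inhibition"))
    kind <- sample(kinds, 1)
    nmods <- sample(0:min(2, length(pool)), 1)
    mods <- pool[sample.int(length(pool), nmods)]
    if (kind %in% c("hill_activation", "hill_inhibition") &&
        length(mods) == 0)
      mods <- pool[sample.int(length(pool), 1)]
    labs <- switch(kind,
      mass_action_irreversible = sprintf("k%d", j),
      mass_action_reversible = sprintf(c("kf%d", "kr%d"), j),
      sprintf(c("v%d", "K%d", "n%d"), j))
    vals <- switch(kind,
      mass_action_irreversible = runif(1, 0.01, 2),
      mass_action_reversible = runif(2, 0.01, 2),
      c(runif(1, 0.1, 10), runif(1, 1, 50), sample(1:4, 1)))
    params <- c(params, setNames(vals, labs))
    reactions[[j]] <- mp_reaction(paste0("r", j), reactants = reac,
                                  products = prod, kind = kind,
                                  params = labs, modifiers = mods)
  }
  mp_model(species, reactions, mp_parameters(params),
           name = paste0("random", seed))
}

# independent brute-force oracle: per-reaction rate summation written
# directly from the rate-law definitions, no shared code with the engine
oracle_rhs <- function(model, y) {
  p <- setNames(as.numeric(model$parameters), names(model$parameters))
  y <- pmax(y, 0)
  dy <- setNames(numeric(nrow(model$species)), model$species$id)
  for (r in model$reactions) {
    if (r$kind == "mass_action_irreversible") {
      v <- p[[r$params[1]]]
      for (sp in names(r$reactants)) v <- v * y[[sp]]^r$reactants[[sp]]
      for (sp in r$modifiers) v <- v * y[[sp]]
    } else if (r$kind == "mass_action_reversible") {
      fwd <- p[[r$params[1]]]; rev <- p[[r$params[2]]]
      for (sp in names(r$reactants)) fwd <- fwd * y[[sp]]^r$reactants[[sp]]
      for (sp in names(r$products)) rev <- rev * y[[sp]]^r$products[[sp]]
      v <- fwd - rev
      for (sp in r$modifiers) v <- v * y[[sp]]
    } else {
      vmax <- p[[r$params[1]]]; K <- p[[r$params[2]]]
      n <- if (length(r$params) == 3) p[[r$params[3]]] else 1
      X <- y[[r$modifiers[1]]]
      frac <- if (r$kind == "hill_activation")
        X^n / (K^n + X^n) else K^n / (K^n + X^n)
      if (!is.finite(frac)) frac <- 0
      v <- vmax * frac
      for (sp in r$modifiers[-1]) v <- v * y[[sp]]
      for (sp in names(r$reactants)) v <- v * y[[sp]]^r$reactants[[sp]]
    }
    for (sp in names(r$reactants)) dy[[sp]] <- dy[[sp]] - r$reactants[[sp]] * v
    for (sp in names(r$products)) dy[[sp]] <- dy[[sp]] + r$products[[sp]] * v
  }
  dy[model$species$buffered] <- 0
  dy
}

# central-difference Jacobian for the damped-Newton steady-state oracle
numeric_jacobian <- function(f, x, h = 1e-4) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hp <- max(h, h * abs(x[j]))
    xp <- x; xm <- x
    xp[j] <- xp[j] + hp; xm[j] <- max(xm[j] - hp, 0)
    J[, j] <- (f(xp) - f(xm)) / (xp[j] - xm[j])
  }
  J
}

group_cols <- function(model, group) {
  model$species$id[model$species$group == group]
}
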