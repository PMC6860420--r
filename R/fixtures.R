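# Toy networks with known behavior, and synthetic calibration data.
# These are first-class generators: every simulator feature is exercised
# against a closed-form or brute-force reference attached here.

#' Generate a toy reaction network with an analytic reference
#'
#' Supported topologies:
#' \describe{
#'   \item{production_degradation}{one species with zero-order synthesis
#'     `s` and first-order degradation `d`; steady state s/d and full
#'     closed-form trajectory attached.}
#'   \item{linear_cascade}{`size` species; X1 has zero-order synthesis,
#'     each Xi is produced at `k * X(i-1)` (catalytic) and degraded
#'     first-order; closed-form steady state attached.}
#'   \item{ligand_receptor_stat}{ligand-receptor binding activating a
#'     STAT-like species, with an induced SOCS-like inhibitor that removes
#'     active receptor complex; exhibits peak-then-decay of the
#'     phosphorylated STAT under step stimulation.}
#'   \item{conserved_cycle}{closed 3-species conversion cycle A->B->C->A
#'     with no synthesis or degradation; the conserved total is attached.}
#' }
#'
#' @param topology one of the above.
#' @param size number of species for `linear_cascade`.
#' @param rates optional named numeric overriding default rate values.
#' @return list with elements `model` (an `mp_model`) and `oracle` (a list
#'   of closed-form references; contents depend on the topology).
#' @export
make_toy <- function(topology = c("production_degradation", "linear_cascade",
                                  "ligand_receptor_stat", "conserved_cycle"),
                     size = 3, rates = NULL) {
  topology <- match.arg(topology)
  switch(topology,
    production_degradation = .toy_prod_deg(rates),
    linear_cascade = .toy_cascade(size, rates),
    ligand_receptor_stat = .toy_lrs(rates),
    conserved_cycle = .toy_cycle(rates))
}

.override <- function(defaults, rates) {
  if (is.null(rates)) return(defaults)
  bad <- setdiff(names(rates), names(defaults))
  if (length(bad)) stop("unknown rate(s): ", paste(bad, collapse = ", "))
  defaults[names(rates)] <- rates
  defaults
}

.toy_prod_deg <- function(rates) {
  p <- .override(c(s = 100, d = 0.1), rates)
  model <- mp_model(
    species = mp_species("X", initial = 0),
    reactions = list(
      mp_reaction("syn", products = c(X = 1),
                  kind = "mass_action_irreversible", params = "s"),
      mp_reaction("deg", reactants = c(X = 1),
                  kind = "mass_action_irreversible", params = "d")),
    parameters = mp_parameters(p, provenance = "synthetic"),
    name = "toy_production_degradation")
  ss <- p[["s"]] / p[["d"]]
  list(model = model,
       oracle = list(
         steady_state = c(X = ss),
         trajectory = function(t, X0 = 0)
           ss + (X0 - ss) * exp(-p[["d"]] * t)))
}

.toy_cascade <- function(size, rates) {
  stopifnot(size >= 2)
  ids <- paste0("X", seq_len(size))
  defaults <- c(k0 = 50, setNames(rep(0.8, size - 1),
                                  paste0("k", seq_len(size - 1))),
                setNames(rep(0.5, size), paste0("d", seq_len(size))))
  p <- .override(defaults, rates)
  reactions <- list(
    mp_reaction("syn1", products = c(X1 = 1),
                kind = "mass_action_irreversible", params = "k0"))
  for (i in seq_len(size)) {
    if (i > 1)
      reactions <- c(reactions, list(mp_reaction(
        paste0("syn", i), products = setNames(1, ids[i]),
        kind = "mass_action_irreversible", params = paste0("k", i - 1),
        modifiers = ids[i - 1],
        annotation = "catalytic production by upstream species")))
    reactions <- c(reactions, list(mp_reaction(
      paste0("deg", i), reactants = setNames(1, ids[i]),
      kind = "mass_action_irreversible", params = paste0("d", i))))
  }
  species <- do.call(rbind, lapply(ids, mp_species))
  ss <- numeric(size)
  ss[1] <- p[["k0"]] / p[["d1"]]
  for (i in seq_len(size)[-1])
    ss[i] <- p[[paste0("k", i - 1)]] * ss[i - 1] / p[[paste0("d", i)]]
  list(model = mp_model(species, reactions,
                        mp_parameters(p, provenance = "synthetic"),
                        name = "toy_linear_cascade"),
       oracle = list(steady_state = setNames(ss, ids)))
}

.toy_lrs <- function(rates) {
  p <- .override(c(kf = 2e-4, kr = 0.2, kact = 5e-4, kdeph = 0.5,
                   kind_i = 2e-3, kdeg_i = 0.3, kfb = 1e-3), rates)
  species <- rbind(
    mp_species("L", compartment = "extracellular", initial = 0),
    mp_species("R", compartment = "membrane", initial = 2000),
    mp_species("C", compartment = "membrane", initial = 0),
    mp_species("S", initial = 10000),
    mp_species("pS", initial = 0),
    mp_species("I", initial = 0))
  reactions <- list(
    mp_reaction("bind", reactants = c(L = 1, R = 1), products = c(C = 1),
                kind = "mass_action_reversible", params = c("kf", "kr"),
                annotation = "ligand-receptor ligation"),
    mp_reaction("act", reactants = c(S = 1), products = c(pS = 1),
                kind = "mass_action_irreversible", params = "kact",
                modifiers = "C", annotation = "STAT-like activation"),
    mp_reaction("deph", reactants = c(pS = 1), products = c(S = 1),
                kind = "mass_action_irreversible", params = "kdeph"),
    mp_reaction("induce", products = c(I = 1),
                kind = "mass_action_irreversible", params = "kind_i",
                modifiers = "pS", annotation = "SOCS-like induction"),
    mp_reaction("deg_i", reactants = c(I = 1),
                kind = "mass_action_irreversible", params = "kdeg_i"),
    mp_reaction("fb", reactants = c(I = 1, C = 1),
                kind = "mass_action_irreversible", params = "kfb",
                annotation = "negative feedback removes active complex"))
  list(model = mp_model(species, reactions,
                        mp_parameters(p, provenance = "synthetic"),
                        name = "toy_ligand_receptor_stat"),
       oracle = list(terminal = "pS", stimulus_species = "L"))
}

.toy_cycle <- function(rates) {
  p <- .override(c(k1 = 1, k2 = 0.7, k3 = 0.4), rates)
  species <- rbind(mp_species("A", initial = 600),
                   mp_species("B", initial = 300),
                   mp_species("C", initial = 100))
  reactions <- list(
    mp_reaction("ab", reactants = c(A = 1), products = c(B = 1),
                kind = "mass_action_irreversible", params = "k1"),
    mp_reaction("bc", reactants = c(B = 1), products = c(C = 1),
                kind = "mass_action_irreversible", params = "k2"),
    mp_reaction("ca", reactants = c(C = 1), products = c(A = 1),
                kind = "mass_action_irreversible", params = "k3"))
  list(model = mp_model(species, reactions,
                        mp_parameters(p, provenance = "synthetic"),
                        name = "toy_conserved_cycle"),
       oracle = list(conserved_total = 1000))
}

#' Generate synthetic calibration datasets from a model
#'
#' Simulates the given scenarios at the model's nominal parameters, samples
#' the stated observables on the stated grids, and applies multiplicative
#' lognormal noise with coefficient of variation `noise_cv` (expression
#' measurements are positive, so the noise model is multiplicative). The
#' result is a list of calibration datasets consumable by [objective()].
#'
#' @param model validated `mp_model`.
#' @param scenarios list of scenario descriptors, each a list with fields
#'   `id`, `observable` (species id), `times` (sampling grid, h), and
#'   optionally `events` (list of [mp_stimulus()]), `oxygen`
#'   ([mp_oxygen()]), `horizon`, `normalization` ([mp_norm()]), `weight`.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives noiseless self-consistent data).
#' @param seed integer seed (datasets are reproducible from it).
#' @param state0 optional pre-equilibrated baseline (computed if omitted).
#' @return list of `mp_dataset` objects.
#' @export
make_synthetic_datasets <- function(model, scenarios, noise_cv = 0.05,
                                    seed = 1, state0 = NULL) {
  stopifnot(noise_cv >= 0)
  set.seed(seed)
  if (is.null(state0)) state0 <- equilibrate(model)
  sdlog <- sqrt(log(1 + noise_cv^2))
  lapply(scenarios, function(sc) {
    horizon <- sc$horizon %||% max(sc$times)
    sim <- run_scenario(model, events = sc$events %||% list(),
                        oxygen = sc$oxygen, horizon = horizon,
                        state0 = state0)
    traj <- sim$mat[, sc$observable]
    vals <- approx(sim$times, traj, xout = sc$times)$y
    norm <- sc$normalization %||% mp_norm("to_t0")
    obs <- normalize_series(sc$times, vals, norm,
                            baseline = traj[1])
    if (noise_cv > 0)
      obs <- obs * exp(rnorm(length(obs), -sdlog^2 / 2, sdlog))
    mp_dataset(id = sc$id, observable = sc$observable,
               points = data.frame(time = sc$times, value = obs),
               events = sc$events %||% list(), oxygen = sc$oxygen,
               horizon = horizon, normalization = norm,
               weight = sc$weight %||% (1 / length(sc$times)),
               source = "synthetic")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
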