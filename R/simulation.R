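# Stiff ODE integration: steady-state pre-equilibration, event-based
# stimulus scheduling, and dose / oxygen unit conversion.

AVOGADRO <- 6.02214076e23

#' Convert a mass dose to molecules per cell
#'
#' Converts a ligand dose in ng/ml to average exposure per cell, assuming a
#' known plating density (default one million cells per ml of medium).
#'
#' @param dose dose in ng/ml (>= 0).
#' @param mol_weight molecular weight in g/mol (> 0).
#' @param cell_density plating density in cells/ml (> 0).
#' @return molecules per cell (numeric).
#' @examples
#' dose_to_copies(10, 17000)   # ~3.5e5 molecules/cell
#' @export
dose_to_copies <- function(dose, mol_weight, cell_density = 1e6) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be >= 0")
  if (!is.finite(mol_weight) || mol_weight <= 0)
    stop("mol_weight must be > 0")
  if (!is.finite(cell_density) || cell_density <= 0)
    stop("cell_density must be > 0")
  dose * 1e-9 / mol_weight * AVOGADRO / cell_density
}

#' Define a stimulus event
#'
#' @param ligand unique-species group id of the ligand (e.g. "IFNg", "IL4",
#'   or a miR group for mimic transfection).
#' @param dose dose in ng/ml (ignored when `copies` is given).
#' @param mol_weight molecular weight in g/mol (required for mass doses).
#' @param time addition time in hours (>= 0).
#' @param copies optional direct copy-number dose (e.g. miR mimics), taking
#'   precedence over `dose`.
#' @param cell_density plating density used for the unit conversion.
#' @return object of class `mp_stimulus`.
#' @export
mp_stimulus <- function(ligand, dose = 0, mol_weight = NA, time = 0,
                        copies = NULL, cell_density = 1e6) {
  stopifnot(time >= 0, dose >= 0)
  if (is.null(copies)) {
    if (!is.finite(mol_weight) || mol_weight <= 0)
      stop("mol_weight must be > 0 for a mass-based dose")
    copies <- dose_to_copies(dose, mol_weight, cell_density)
  }
  structure(list(ligand = ligand, dose = dose, mol_weight = mol_weight,
                 time = time, copies = copies),
            class = "mp_stimulus")
}

#' Define an oxygen condition
#'
#' Percent oxygen is mapped linearly onto the model's buffered oxygen
#' species, with 21\% corresponding to the normoxic value the model was
#' equilibrated with.
#'
#' @param percent percent O2, in (0, 21]. 21 = normoxia.
#' @param time application time in hours.
#' @return object of class `mp_oxygen`.
#' @export
mp_oxygen <- function(percent, time = 0) {
  if (!is.finite(percent) || percent <= 0 || percent > 21)
    stop("percent O2 must be in (0, 21]")
  structure(list(percent = percent, time = time), class = "mp_oxygen")
}

# extracellular node of a ligand group (the pool doses are added to)
ligand_species <- function(model, group) {
  sp <- model$species
  cand <- sp$id[sp$group == group & sp$compartment == "extracellular"]
  if (length(cand) == 0L) cand <- sp$id[sp$group == group]
  if (length(cand) == 0L)
    stop("no species found for ligand group '", group, "'")
  cand[[1L]]
}

oxygen_species <- function(model) {
  sp <- model$species
  cand <- sp$id[sp$group %in% c("O2", "oxygen", "Oxygen")]
  if (length(cand) != 1L)
    stop("model has no unique oxygen species (group 'O2')")
  cand
}

#' Pre-equilibrate a model to its untreated steady state
#'
#' Integrates the unstimulated model over successively longer horizons until
#' the scaled residual max(|dX/dt| / max(X, 1)) falls below `tol` (per
#' hour). The resulting state is the physiological baseline used as t = 0
#' for every scenario.
#'
#' @param model validated `mp_model`.
#' @param state0 optional start state (defaults to the model's initial
#'   copy numbers).
#' @param parms optional parameter overrides (named numeric).
#' @param tol residual tolerance in 1/h.
#' @param max_time horizon cap in hours.
#' @param rtol,atol integrator tolerances.
#' @param maxsteps integrator step budget per convergence check.
#' @return named steady-state vector with attribute `residual`.
#' @export
equilibrate <- function(model, state0 = NULL, parms = NULL, tol = 1e-8,
                        max_time = 2e5, rtol = 1e-8, atol = 1e-6,
                        maxsteps = 20000) {
  rhs <- assemble_rhs(model)
  y <- if (is.null(state0)) model_state0(model) else
    state0[model$species$id]
  chunk <- 250
  total <- 0
  resid <- Inf
  while (total < max_time) {
    sol <- try(suppressWarnings(
      deSolve::ode(y = y, times = c(0, chunk), func = rhs,
                   parms = parms, method = "lsoda",
                   rtol = rtol, atol = atol, maxsteps = maxsteps)),
      silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < 2 ||
        any(!is.finite(sol[nrow(sol), -1])))
      stop("equilibration failed: integrator error before t = ", total)
    y <- pmax(sol[nrow(sol), -1], 0)
    total <- total + chunk
    chunk <- min(chunk * 2, max_time)
    dy <- rhs(0, y, parms)[[1]]
    resid <- max(abs(dy) / pmax(y, 1))
    if (resid < tol) {
      attr(y, "residual") <- resid
      attr(y, "time") <- total
      return(y)
    }
  }
  stop("equilibration did not converge within ", max_time,
       " h; residual = ", format(resid, digits = 3))
}

#' Simulate a stimulation scenario
#'
#' Integrates the model from an equilibrated baseline with event-based
#' stimulus addition. Ligand doses are added to the current extracellular
#' pool at their event times (no media change); an oxygen condition
#' replaces the buffered oxygen species value. The integrator is
#' stiff-capable (lsoda).
#'
#' @param model validated `mp_model`.
#' @param events list of [mp_stimulus()] objects.
#' @param oxygen optional [mp_oxygen()] condition.
#' @param horizon simulation horizon in hours (must cover all event times).
#' @param state0 equilibrated baseline state; computed by [equilibrate()]
#'   when omitted.
#' @param parms optional parameter overrides (named numeric).
#' @param n_out number of regular output points (event times are always
#'   included in the grid).
#' @param rtol,atol relative / absolute integrator tolerance (absolute
#'   tolerance in molecules).
#' @return object of class `mp_sim`: list with `times`, `mat` (time x
#'   species matrix), `events` log, `model`, and solver diagnostics.
#' @export
run_scenario <- function(model, events = list(), oxygen = NULL,
                         horizon = 48, state0 = NULL, parms = NULL,
                         n_out = 193, rtol = 1e-6, atol = 1e-3) {
  if (inherits(events, "mp_stimulus")) events <- list(events)
  etimes <- vapply(events, `[[`, 0, "time")
  if (length(etimes) && horizon < max(etimes))
    stop("horizon must cover all event times")
  y <- if (is.null(state0)) equilibrate(model, parms = parms) else
    state0[model$species$id]
  y <- setNames(as.numeric(y), model$species$id)

  evlog <- list()
  eventdat <- NULL
  o2sp <- NULL
  if (!is.null(oxygen)) {
    o2sp <- oxygen_species(model)
    o2val <- oxygen$percent / 21 * model_state0(model)[[o2sp]]
    if (oxygen$time <= 0) {
      y[[o2sp]] <- o2val
    } else {
      eventdat <- rbind(eventdat, data.frame(
        var = o2sp, time = oxygen$time, value = o2val, method = "rep"))
    }
    evlog <- c(evlog, list(list(kind = "oxygen", species = o2sp,
                                time = max(oxygen$time, 0), value = o2val)))
  }
  for (ev in events) {
    spid <- ligand_species(model, ev$ligand)
    if (ev$time <= 0) {
      y[[spid]] <- y[[spid]] + ev$copies
    } else {
      eventdat <- rbind(eventdat, data.frame(
        var = spid, time = ev$time, value = ev$copies, method = "add"))
    }
    evlog <- c(evlog, list(list(kind = "stimulus", species = spid,
                                time = max(ev$time, 0), value = ev$copies)))
  }
  times <- sort(unique(c(seq(0, horizon, length.out = n_out),
                         etimes[etimes > 0],
                         if (!is.null(oxygen) && oxygen$time > 0)
                           oxygen$time)))
  rhs <- assemble_rhs(model)
  if (!is.null(eventdat))
    eventdat <- eventdat[order(eventdat$time), , drop = FALSE]
  evarg <- if (!is.null(eventdat)) list(data = eventdat) else NULL
  sol <- try(deSolve::ode(y = y, times = times, func = rhs, parms = parms,
                          method = "lsoda", rtol = rtol, atol = atol,
                          events = evarg, maxsteps = 50000), silent = TRUE)
  if (inherits(sol, "try-error"))
    stop("integration failed: ", attr(sol, "condition")$message)
  mat <- unname(sol[, -1, drop = FALSE])
  colnames(mat) <- model$species$id
  if (nrow(mat) < length(times))
    stop("integration stopped early at t = ", max(sol[, 1]),
         " h (last good state retained in error object)")
  # negative-state policy: clamp solver undershoot, fail on real violations
  floor_ok <- -max(10 * atol, 1e-9 * max(mat))
  if (min(mat) < floor_ok)
    stop("negative state beyond solver tolerance: min = ", min(mat))
  mat[mat < 0] <- 0
  structure(list(times = times, mat = mat, events = evlog, model = model,
                 diagnostics = list(istate = attr(sol, "istate"),
                                    rtol = rtol, atol = atol)),
            class = "mp_sim")
}

#' @export
print.mp_sim <- function(x, ...) {
  cat("<mp_sim> ", length(x$times), " time points over ",
      max(x$times), " h, ", ncol(x$mat), " species, ",
      length(x$events), " events\n", sep = "")
  invisible(x)
}

#' Tidy trajectories of a simulation
#'
#' @param sim an `mp_sim`.
#' @param species optional species ids to keep.
#' @return long `data.frame` with columns time, species, value.
#' @export
sim_trajectories <- function(sim, species = NULL) {
  ids <- colnames(sim$mat)
  if (!is.null(species)) {
    bad <- setdiff(species, ids)
    if (length(bad))
      stop("unknown species: ", paste(bad, collapse = ", "))
    ids <- species
  }
  data.frame(time = rep(sim$times, length(ids)),
             species = rep(ids, each = length(sim$times)),
             value = as.vector(sim$mat[, ids]),
             stringsAsFactors = FALSE)
}

# per-group totals of a state vector
group_totals <- function(model, state) {
  tapply(as.numeric(state[model$species$id]), model$species$group, sum)
}
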