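# Calibration machinery: normalized-dataset objective, copy-number
# admissibility, derivative-free pattern search and bootstrap uncertainty.

#' Define a calibration dataset
#'
#' One literature-style measurement series: a stimulation scenario, an
#' observable, normalized data points, a normalization mode matching how
#' the source reported its values, and a weight.
#'
#' @param id dataset label.
#' @param observable species id measured.
#' @param points `data.frame` with columns time (h) and value (normalized).
#' @param events list of [mp_stimulus()] for the dataset's scenario.
#' @param oxygen optional [mp_oxygen()].
#' @param horizon scenario horizon (h), must cover all point times.
#' @param normalization an [mp_norm()].
#' @param weight positive dataset weight in the objective.
#' @param source citation tag.
#' @return object of class `mp_dataset`.
#' @export
mp_dataset <- function(id, observable, points, events = list(),
                       oxygen = NULL, horizon = max(points$time),
                       normalization = mp_norm("to_t0"), weight = 1,
                       source = "") {
  stopifnot(is.data.frame(points), nrow(points) >= 1L,
            all(c("time", "value") %in% names(points)))
  if (any(points$time > horizon))
    stop("dataset '", id, "': point times exceed the scenario horizon")
  if (!is.finite(weight) || weight <= 0)
    stop("dataset '", id, "': weight must be > 0")
  structure(list(id = id, observable = observable, points = points,
                 events = events, oxygen = oxygen, horizon = horizon,
                 normalization = normalization, weight = weight,
                 source = source),
            class = "mp_dataset")
}

#' Define copy-number priors with an admissibility band
#'
#' @param copies named numeric of literature copy numbers per
#'   unique-species group (> 0).
#' @param band admissibility multipliers, default `c(0.5, 2)`.
#' @return object of class `mp_prior`.
#' @export
mp_prior <- function(copies, band = c(0.5, 2)) {
  stopifnot(is.numeric(copies), !is.null(names(copies)), all(copies > 0),
            length(band) == 2L, band[1] < band[2])
  structure(list(copies = copies, band = band), class = "mp_prior")
}

# simulate one dataset's scenario and return the normalized model series
# at the dataset's time points
simulate_dataset <- function(model, ds, state0, parms = NULL) {
  sim <- run_scenario(model, events = ds$events, oxygen = ds$oxygen,
                      horizon = ds$horizon, state0 = state0,
                      parms = parms, n_out = 97)
  traj <- sim$mat[, ds$observable]
  vals <- approx(sim$times, traj, xout = ds$points$time)$y
  normalize_series(ds$points$time, vals, ds$normalization,
                   baseline = traj[1])
}

#' Weighted sum-of-squares calibration objective
#'
#' For each dataset, simulates its scenario, normalizes the model series
#' with the dataset's own normalization mode, and accumulates
#' weight * sum((sim - obs)^2). When a copy-number prior is supplied, a
#' smooth admissibility penalty (quadratic in log-distance outside the
#' band) is added; with `strict = TRUE` any band violation instead returns
#' a large finite penalty (the hard initial-condition check). Simulation
#' failures contribute `fail_penalty` and are logged as an attribute,
#' keeping derivative-free search alive at pathological parameter sets.
#'
#' @param model validated `mp_model`.
#' @param datasets list of [mp_dataset()] objects.
#' @param parms optional named parameter overrides.
#' @param prior optional [mp_prior()].
#' @param strict logical: hard-reject admissibility violations.
#' @param penalty_weight weight of the smooth admissibility penalty.
#' @param fail_penalty objective contribution of a failed simulation.
#' @return non-negative scalar with attribute `n_failed`.
#' @export
objective <- function(model, datasets, parms = NULL, prior = NULL,
                      strict = FALSE, penalty_weight = 1,
                      fail_penalty = 1e6) {
  st <- tryCatch(equilibrate(model, parms = parms, tol = 1e-6),
                 error = function(e) NULL)
  if (is.null(st)) {
    out <- fail_penalty * (length(datasets) + 1)
    attr(out, "n_failed") <- length(datasets)
    return(out)
  }
  total <- 0
  n_failed <- 0L
  for (ds in datasets) {
    simv <- tryCatch(simulate_dataset(model, ds, st, parms),
                     error = function(e) NULL)
    if (is.null(simv) || any(!is.finite(simv))) {
      total <- total + fail_penalty
      n_failed <- n_failed + 1L
      next
    }
    total <- total + ds$weight * sum((simv - ds$points$value)^2)
  }
  if (!is.null(prior)) {
    ratios <- check_initial_conditions(model, parms = parms,
                                       prior = prior, state = st)$margin
    lo <- prior$band[1]; hi <- prior$band[2]
    viol <- pmax(log(lo / ratios), log(ratios / hi), 0)
    if (strict && any(viol > 0)) total <- total + fail_penalty
    else total <- total + penalty_weight * sum(viol^2)
  }
  attr(total, "n_failed") <- n_failed
  total
}

#' Check steady-state copy numbers against literature priors
#'
#' Compares each unique-species group's equilibrated total against the
#' admissibility band (default 0.5x-2x) around its prior copy number.
#'
#' @param model validated `mp_model`.
#' @param prior an [mp_prior()].
#' @param parms optional parameter overrides.
#' @param state optional pre-equilibrated state (computed if omitted).
#' @return `data.frame` with columns group, steady, prior, margin
#'   (steady / prior) and pass.
#' @export
check_initial_conditions <- function(model, prior, parms = NULL,
                                     state = NULL) {
  if (is.null(state)) state <- equilibrate(model, parms = parms)
  totals <- group_totals(model, state)
  groups <- intersect(names(prior$copies), names(totals))
  if (length(groups) == 0L) stop("prior groups not found in model")
  margin <- as.numeric(totals[groups]) / prior$copies[groups]
  data.frame(group = groups, steady = as.numeric(totals[groups]),
             prior = as.numeric(prior$copies[groups]), margin = margin,
             pass = margin >= prior$band[1] & margin <= prior$band[2],
             row.names = NULL)
}

# Compass pattern search on log-scale parameters: polls +/- step on each
# coordinate in fixed order, accepts improvements, expands on success and
# contracts otherwise. Derivative-free, bound-respecting, deterministic
# given the start point.
pattern_search <- function(f, x0, lower, upper, step0 = 0.5,
                           step_tol = 1e-3, max_eval = 400) {
  lx <- log(x0); llo <- log(lower); lup <- log(upper)
  lx <- pmin(pmax(lx, llo), lup)
  fx <- f(exp(lx))
  n_eval <- 1L
  step <- step0
  trace <- fx
  while (step > step_tol && n_eval < max_eval) {
    improved <- FALSE
    for (j in seq_along(lx)) {
      for (sgn in c(1, -1)) {
        cand <- lx
        cand[j] <- min(max(cand[j] + sgn * step, llo[j]), lup[j])
        if (cand[j] == lx[j]) next
        fc <- f(exp(cand))
        n_eval <- n_eval + 1L
        if (fc < fx) {
          lx <- cand; fx <- fc; improved <- TRUE
          trace <- c(trace, fx)
          break
        }
        if (n_eval >= max_eval) break
      }
      if (n_eval >= max_eval) break
    }
    step <- if (improved) min(step * 2, 1) else step / 2
  }
  list(par = exp(lx), value = as.numeric(fx), n_eval = n_eval,
       trace = as.numeric(trace))
}

#' Fit free parameters by derivative-free pattern search
#'
#' Minimizes [objective()] over the chosen parameter subset with a
#' bound-respecting compass/pattern search on log scale (no gradients;
#' monotone over accepted iterations; deterministic given seed and start).
#' Several seeded multistarts are polled and the best kept.
#'
#' @param model validated `mp_model`.
#' @param datasets list of [mp_dataset()] objects.
#' @param free_params character vector of parameter labels to fit.
#' @param lower,upper named bounds (default nominal /100 and x100).
#' @param prior optional [mp_prior()] admissibility term.
#' @param seed integer seed controlling the multistart jitter.
#' @param n_starts number of multistarts (first start is the nominal
#'   point itself).
#' @param start optional named start values overriding the nominal point.
#' @param max_eval objective-evaluation budget per start.
#' @param step_tol mesh-size convergence tolerance (log10-scale).
#' @return object of class `mp_fit`: optimized parameter set, objective
#'   value, per-dataset residuals, admissibility table and optimizer trace.
#' @export
fit <- function(model, datasets, free_params, lower = NULL, upper = NULL,
                prior = NULL, seed = 1, n_starts = 3, start = NULL,
                max_eval = 400, step_tol = 1e-3) {
  params <- as.numeric(model$parameters)
  names(params) <- names(model$parameters)
  bad <- setdiff(free_params, names(params))
  if (length(bad))
    stop("free parameters not in the model: ", paste(bad, collapse = ", "))
  nominal <- params[free_params]
  if (length(free_params) == 0L) {
    val <- objective(model, datasets, prior = prior)
    return(structure(list(par = params, value = as.numeric(val),
                          trace = as.numeric(val), n_eval = 1L,
                          residuals = NULL, admissibility = NULL),
                     class = "mp_fit"))
  }
  lower <- (lower %||% nominal / 100)[free_params]
  upper <- (upper %||% nominal * 100)[free_params]
  if (any(!is.finite(lower)) || any(lower <= 0) || any(lower >= upper))
    stop("bounds must satisfy 0 < lower < upper")
  fobj <- function(x) {
    objective(model, datasets,
              parms = setNames(x, free_params), prior = prior)
  }
  x0s <- list(if (is.null(start)) nominal else start[free_params])
  set.seed(seed)
  if (n_starts > 1)
    for (i in seq_len(n_starts - 1))
      x0s <- c(x0s, list(pmin(pmax(
        x0s[[1]] * exp(rnorm(length(nominal), 0, 0.5)), lower), upper)))
  best <- NULL
  for (x0 in x0s) {
    res <- pattern_search(fobj, x0, lower, upper,
                          max_eval = max_eval, step_tol = step_tol)
    if (is.null(best) || res$value < best$value) best <- res
  }
  params[free_params] <- best$par
  st <- tryCatch(equilibrate(model, parms = params, tol = 1e-6),
                 error = function(e) NULL)
  resid <- if (!is.null(st)) lapply(datasets, function(ds) {
    simv <- tryCatch(simulate_dataset(model, ds, st, params),
                     error = function(e) rep(NA_real_, nrow(ds$points)))
    data.frame(dataset = ds$id, time = ds$points$time,
               residual = simv - ds$points$value)
  }) else NULL
  adm <- if (!is.null(prior) && !is.null(st))
    check_initial_conditions(model, prior, parms = params, state = st)
  else NULL
  structure(list(par = params, value = best$value, trace = best$trace,
                 n_eval = best$n_eval,
                 residuals = if (!is.null(resid)) do.call(rbind, resid),
                 admissibility = adm),
            class = "mp_fit")
}

#' @export
print.mp_fit <- function(x, ...) {
  cat("<mp_fit> objective ", format(x$value, digits = 6), " after ",
      x$n_eval, " evaluations\n", sep = "")
  invisible(x)
}

#' Bootstrap parameter uncertainty
#'
#' Resamples the calibration datasets with replacement (dataset-level
#' resampling: points within a series are correlated), refits the free
#' parameter subset on each replicate and collects the estimates.
#'
#' @param model validated `mp_model`.
#' @param datasets list of [mp_dataset()] objects.
#' @param free_params labels to refit (the study design used an
#'   11-parameter subset; any subset is accepted).
#' @param n_boot number of replicates (>= 2; default 50).
#' @param seed integer seed.
#' @param start_jitter lognormal sd of each replicate's seeded start
#'   displacement. Independent starts let practically non-identifiable
#'   (flat) directions show up as bootstrap spread instead of every
#'   replicate inheriting the nominal value.
#' @param ... passed to [fit()] (bounds, prior, max_eval, ...).
#' @return `data.frame` of estimates, one row per successful replicate and
#'   one column per free parameter, with attribute `n_dropped`.
#' @export
bootstrap_fit <- function(model, datasets, free_params, n_boot = 50,
                          seed = 1, start_jitter = 0.3, ...) {
  stopifnot(n_boot >= 2)
  set.seed(seed)
  draws <- matrix(sample.int(length(datasets),
                             length(datasets) * n_boot, replace = TRUE),
                  nrow = n_boot)
  fit_seeds <- sample.int(1e6, n_boot)
  nominal <- setNames(as.numeric(model$parameters),
                      names(model$parameters))[free_params]
  rows <- list(); dropped <- 0L
  for (b in seq_len(n_boot)) {
    set.seed(fit_seeds[b])
    start_b <- nominal * exp(rnorm(length(nominal), 0, start_jitter))
    res <- tryCatch(
      fit(model, datasets[draws[b, ]], free_params,
          seed = fit_seeds[b], n_starts = 1, start = start_b, ...),
      error = function(e) NULL)
    if (is.null(res)) { dropped <- dropped + 1L; next }
    rows <- c(rows, list(as.data.frame(as.list(res$par[free_params]))))
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- dropped
  out
}
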