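# Global sensitivity analysis: Latin hypercube sampling over log-uniform
# parameter ranges and partial rank correlation coefficients with
# significance testing.

#' Define a sampling plan
#'
#' @param labels parameter labels to vary.
#' @param nominal named numeric of nominal values (e.g. the model's
#'   parameter set); ranges default to nominal / `span` .. nominal *
#'   `span`, log-uniform.
#' @param span half-range multiplier (default 10, i.e. x/÷10).
#' @param lo,hi optional explicit named bounds overriding the span.
#' @param n_samples number of samples (>= number of parameters + 2, so the
#'   partial-correlation degrees of freedom stay positive).
#' @param seed integer seed.
#' @return object of class `mp_plan`.
#' @export
mp_plan <- function(labels, nominal, span = 10, lo = NULL, hi = NULL,
                    n_samples = 5000, seed = 1) {
  nominal <- nominal[labels]
  if (anyNA(nominal)) stop("nominal values missing for some labels")
  lo <- if (is.null(lo)) nominal / span else lo[labels]
  hi <- if (is.null(hi)) nominal * span else hi[labels]
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(lo <= 0) ||
      any(lo >= hi))
    stop("degenerate sampling range: need 0 < lo < hi for every label")
  if (n_samples < length(labels) + 2)
    stop("n_samples must be >= number of parameters + 2")
  structure(list(labels = labels, lo = setNames(as.numeric(lo), labels),
                 hi = setNames(as.numeric(hi), labels),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "mp_plan")
}

#' Latin hypercube sample of a plan
#'
#' Each parameter column is a stratified sample of its log-uniform range:
#' exactly one draw falls in each of `n_samples` equal-probability strata.
#' Reproducible from the plan's seed.
#'
#' @param plan an [mp_plan()].
#' @return numeric matrix `n_samples x n_params` with labelled columns.
#' @export
lhs_sample <- function(plan) {
  stopifnot(inherits(plan, "mp_plan"))
  set.seed(plan$seed)
  u <- lhs::randomLHS(plan$n_samples, length(plan$labels))
  X <- sapply(seq_along(plan$labels), function(j) {
    exp(log(plan$lo[j]) + u[, j] * (log(plan$hi[j]) - log(plan$lo[j])))
  })
  X <- matrix(X, nrow = plan$n_samples)
  colnames(X) <- plan$labels
  X
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms the parameter matrix and the output, then for each
#' parameter computes the correlation between the residuals of that
#' parameter and of the output after removing the rank-linear influence of
#' all remaining parameters. Significance is assessed with the standard
#' t statistic on n - 2 - (p - 1) degrees of freedom. Ties receive average
#' ranks. Being rank-based, the result is invariant to strictly monotone
#' transformations of the output.
#'
#' @param X numeric matrix (samples x parameters), columns labelled.
#' @param y output vector aligned with the rows of `X`.
#' @return `data.frame` with columns label, prcc, p_value, ordered as the
#'   columns of `X`. Constant columns yield `NA` coefficients.
#' @export
prcc <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("rows of X must align with y")
  if (n < p + 3) stop("need at least p + 3 samples for PRCC")
  labs <- colnames(X) %||% paste0("x", seq_len(p))
  Xr <- apply(X, 2, rank, ties.method = "average")
  yr <- rank(y, ties.method = "average")
  df <- n - 2 - (p - 1)
  out <- lapply(seq_len(p), function(j) {
    if (length(unique(X[, j])) == 1L)
      return(data.frame(label = labs[j], prcc = NA_real_,
                        p_value = NA_real_))
    Z <- cbind(1, Xr[, -j, drop = FALSE])
    # residualize the j-th ranked parameter and the ranked output on the
    # remaining ranked parameters (least squares via QR)
    qz <- qr(Z)
    rj <- qr.resid(qz, Xr[, j])
    ry <- qr.resid(qz, yr)
    r <- sum(rj * ry) / sqrt(sum(rj^2) * sum(ry^2))
    r <- max(-1, min(1, r))
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    data.frame(label = labs[j], prcc = r,
               p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
  })
  do.call(rbind, out)
}

#' PRCC sensitivity of the M1/M2 score
#'
#' Simulates a scenario once per sampled parameter set, evaluates the M1/M2
#' score at `t_eval`, and returns the PRCC table sorted by coefficient.
#' Each sample is equilibrated under its own parameters before stimulation
#' so the baseline is consistent with the sampled kinetics. Failed
#' simulations are dropped and counted; the analysis aborts if more than
#' `max_fail_frac` of the runs fail.
#'
#' @param model validated `mp_model`.
#' @param plan an [mp_plan()] over the model's parameter labels.
#' @param events,oxygen,horizon scenario definition (see [run_scenario()]).
#' @param t_eval score evaluation time (h).
#' @param output optional function(sim) -> scalar replacing the M1/M2
#'   score as the output of interest.
#' @param max_fail_frac abort threshold for the failed-run fraction.
#' @return `data.frame` (label, prcc, p_value) sorted decreasing by
#'   coefficient, with attributes `n_failed` and `n_used`.
#' @export
score_sensitivity <- function(model, plan, events = list(), oxygen = NULL,
                              horizon = 48, t_eval = 24, output = NULL,
                              max_fail_frac = 0.05) {
  X <- lhs_sample(plan)
  outfun <- output %||% function(sim) m1m2_score(sim, t_eval = t_eval)
  # warm-start each sample's equilibration from the nominal steady state
  # and cap the per-sample effort so pathologically stiff draws fail fast
  # instead of dominating the runtime; the residual acceptance is relaxed
  # relative to equilibrate()'s default because a sub-percent-per-hour
  # baseline drift is invisible to a rank-based statistic, while truly
  # divergent draws still fail and are dropped
  st0 <- equilibrate(model)
  y <- rep(NA_real_, nrow(X))
  for (i in seq_len(nrow(X))) {
    parms <- setNames(X[i, ], colnames(X))
    y[i] <- tryCatch({
      st <- equilibrate(model, state0 = st0, parms = parms, tol = 5e-3,
                        max_time = 3e4, rtol = 1e-6, atol = 1e-3)
      sim <- run_scenario(model, events = events, oxygen = oxygen,
                          horizon = horizon, state0 = st, parms = parms,
                          n_out = 97)
      outfun(sim)
    }, error = function(e) NA_real_)
  }
  ok <- is.finite(y)
  n_failed <- sum(!ok)
  if (n_failed > max_fail_frac * nrow(X))
    stop("sensitivity analysis aborted: ", n_failed, " of ", nrow(X),
         " simulations failed")
  res <- prcc(X[ok, , drop = FALSE], y[ok])
  res <- res[order(-res$prcc), ]
  rownames(res) <- NULL
  attr(res, "n_failed") <- n_failed
  attr(res, "n_used") <- sum(ok)
  res
}
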