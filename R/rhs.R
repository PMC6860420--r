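# Assembly of the ODE right-hand side from a declarative model.

# Flatten reactions into index arrays consumed by the compiled evaluator.
encode_model <- function(model) {
  ids <- model$species$id
  plabs <- names(model$parameters)
  sidx <- setNames(seq_along(ids) - 1L, ids)   # 0-based
  pidx0 <- setNames(seq_along(plabs) - 1L, plabs)
  nr <- length(model$reactions)
  kind <- integer(nr)
  pidx <- matrix(-1L, nr, 3L)
  r_idx <- integer(0); r_coef <- numeric(0); r_off <- integer(nr + 1L)
  pr_idx <- integer(0); pr_coef <- numeric(0); pr_off <- integer(nr + 1L)
  m_idx <- integer(0); m_off <- integer(nr + 1L)
  kindmap <- c(mass_action_irreversible = 0L, mass_action_reversible = 1L,
               hill_activation = 2L, hill_inhibition = 3L)
  for (j in seq_len(nr)) {
    r <- model$reactions[[j]]
    kind[j] <- kindmap[[r$kind]]
    pp <- pidx0[r$params]
    pidx[j, seq_along(pp)] <- pp
    r_off[j] <- length(r_idx)
    r_idx <- c(r_idx, unname(sidx[names(r$reactants)]))
    r_coef <- c(r_coef, unname(r$reactants))
    pr_off[j] <- length(pr_idx)
    pr_idx <- c(pr_idx, unname(sidx[names(r$products)]))
    pr_coef <- c(pr_coef, unname(r$products))
    m_off[j] <- length(m_idx)
    m_idx <- c(m_idx, unname(sidx[r$modifiers]))
  }
  r_off[nr + 1L] <- length(r_idx)
  pr_off[nr + 1L] <- length(pr_idx)
  m_off[nr + 1L] <- length(m_idx)
  list(kind = kind, pidx = pidx,
       r_off = r_off, r_idx = r_idx, r_coef = r_coef,
       pr_off = pr_off, pr_idx = pr_idx, pr_coef = pr_coef,
       m_off = m_off, m_idx = m_idx,
       buffered = model$species$buffered,
       species = ids, plabs = plabs)
}

#' Assemble the ODE right-hand side of a model
#'
#' Builds a derivative function `f(t, state, parms)` in the form deSolve
#' expects: the derivative of each species is the stoichiometry-weighted sum
#' of reaction rates (mass-action or Hill, see [mp_reaction()]). Buffered
#' species get derivative zero. Negative state entries are clamped to zero
#' for rate evaluation, guarding mass-action positivity against solver
#' undershoot.
#'
#' @param model validated `mp_model`.
#' @return function `(t, state, parms)` returning `list(dstate)`. `parms`
#'   may be omitted (model's own parameter set), or a full named numeric
#'   replacement, or a named subset overriding individual labels.
#' @export
assemble_rhs <- function(model) {
  validate_model(model)
  enc <- encode_model(model)
  pdefault <- as.numeric(model$parameters)
  plabs <- enc$plabs
  function(t, state, parms = NULL) {
    p <- pdefault
    if (!is.null(parms) && length(parms)) {
      if (is.null(names(parms)) && length(parms) == length(p)) {
        p <- as.numeric(parms)
      } else {
        idx <- match(names(parms), plabs)
        if (anyNA(idx))
          stop("unknown parameter label: ",
               paste(names(parms)[is.na(idx)], collapse = ", "))
        p[idx] <- as.numeric(parms)
      }
    }
    dy <- mp_rhs_eval(as.numeric(state), p,
                      enc$kind, enc$pidx,
                      enc$r_off, enc$r_idx, enc$r_coef,
                      enc$pr_off, enc$pr_idx, enc$pr_coef,
                      enc$m_off, enc$m_idx, enc$buffered)
    list(dy)
  }
}

# Pure-R reference evaluation of per-reaction rates at one state; returns the
# rate vector (used by the structural report and by diagnostic tooling).
reaction_rates <- function(model, state, parms = NULL) {
  p <- as.numeric(model$parameters)
  names(p) <- names(model$parameters)
  if (!is.null(parms)) p[names(parms)] <- parms
  y <- pmax(as.numeric(state), 0)
  names(y) <- model$species$id
  vapply(model$reactions, function(r) {
    if (r$kind %in% c("mass_action_irreversible", "mass_action_reversible")) {
      v <- p[[r$params[1]]] * prod(y[names(r$reactants)] ^ r$reactants)
      if (r$kind == "mass_action_reversible")
        v <- v - p[[r$params[2]]] * prod(y[names(r$products)] ^ r$products)
      v * prod(y[r$modifiers])
    } else {
      n <- if (length(r$params) == 3L) p[[r$params[3]]] else 1
      K <- p[[r$params[2]]]; X <- y[[r$modifiers[1]]]
      frac <- if (r$kind == "hill_activation")
        X^n / (K^n + X^n) else K^n / (K^n + X^n)
      if (!is.finite(frac)) frac <- 0
      p[[r$params[1]]] * frac * prod(y[r$modifiers[-1]]) *
        prod(y[names(r$reactants)] ^ r$reactants)
    }
  }, numeric(1))
}
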