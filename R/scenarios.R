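# Perturbation engine (genetic / pharmacological edit semantics), output
# normalization, marker-panel extraction and the M1/M2 score.

#' Define a perturbation
#'
#' Typed edits of the model and its equilibrated baseline:
#' \describe{
#'   \item{overexpress}{target group's principal node set to `factor`
#'     (default 50) times its baseline level, production left unchanged.}
#'   \item{silence}{target group's nodes set to 0, every synthesis
#'     reaction producing into the group zeroed, and any complex able to
#'     release a group member on dissociation zeroed as well; the group
#'     then stays identically zero under any stimulation.}
#'   \item{production_scale}{all synthesis-reaction rate constants of the
#'     target group scaled by `factor` (e.g. 0.1 models synthesis
#'     inhibition, 10 models overproduction).}
#'   \item{rate_scale}{one named kinetic parameter scaled by `factor`
#'     (e.g. a binding rate reduced to 10\%).}
#'   \item{initial_scale}{target group's baseline levels scaled by
#'     `factor` with no parameter change.}
#' }
#'
#' @param kind edit kind (above).
#' @param target species group id (or parameter label for `rate_scale`).
#' @param factor non-negative scale factor; must be omitted for `silence`.
#' @return object of class `mp_perturbation`.
#' @export
mp_perturbation <- function(kind = c("overexpress", "silence",
                                     "production_scale", "rate_scale",
                                     "initial_scale"),
                            target, factor = NULL) {
  kind <- match.arg(kind)
  if (kind == "silence") {
    if (!is.null(factor)) stop("silence admits no factor (it implies 0/0)")
    factor <- 0
  }
  if (kind == "overexpress" && is.null(factor)) factor <- 50
  if (is.null(factor))
    stop("perturbation '", kind, "' requires a factor")
  if (!is.finite(factor) || factor < 0)
    stop("perturbation factor must be finite and >= 0")
  structure(list(kind = kind, target = target, factor = factor),
            class = "mp_perturbation")
}

# synthesis reactions of a group: reactions with no reactants whose products
# lie (partly) in the group -- transcription, translation, basal secretion.
production_reactions <- function(model, group) {
  gs <- group_species(model, group)
  if (length(gs) == 0L)
    stop("unknown perturbation target '", group, "'")
  keep <- vapply(model$reactions, function(r)
    length(r$reactants) == 0L && any(names(r$products) %in% gs),
    logical(1))
  model$reactions[keep]
}

#' Apply perturbations to a model and its baseline state
#'
#' Edits are composable and order-independent; two perturbations touching
#' the same kinetic parameter raise an error rather than silently
#' overriding each other.
#'
#' @param model validated `mp_model`.
#' @param state0 equilibrated baseline state vector.
#' @param specs list of [mp_perturbation()] objects (a single spec is
#'   accepted too).
#' @return list with edited `model` and `state0`.
#' @export
apply_perturbations <- function(model, state0, specs) {
  if (inherits(specs, "mp_perturbation")) specs <- list(specs)
  state0 <- setNames(as.numeric(state0[model$species$id]),
                     model$species$id)
  params <- as.numeric(model$parameters)
  names(params) <- names(model$parameters)
  touched <- character(0)
  touch <- function(labs) {
    dup <- intersect(labs, touched)
    if (length(dup))
      stop("conflicting perturbations on parameter(s): ",
           paste(dup, collapse = ", "))
    touched <<- c(touched, labs)
  }
  groups <- unique(model$species$group)
  for (sp in specs) {
    if (!inherits(sp, "mp_perturbation"))
      stop("perturbations must be mp_perturbation objects")
    if (sp$kind == "rate_scale") {
      if (!sp$target %in% names(params))
        stop("unknown parameter label '", sp$target, "'")
      touch(sp$target)
      params[[sp$target]] <- params[[sp$target]] * sp$factor
      next
    }
    if (!sp$target %in% groups)
      stop("unknown perturbation target '", sp$target, "'")
    gs <- group_species(model, sp$target)
    if (sp$kind %in% c("silence", "production_scale")) {
      prods <- production_reactions(model, sp$target)
      labs <- vapply(prods, function(r) r$params[1], "")
      touch(labs)
      params[labs] <- params[labs] *
        if (sp$kind == "silence") 0 else sp$factor
    }
    if (sp$kind == "silence") {
      # zero the group plus the closure of complexes that could release a
      # group member on dissociation/decay (complexes form from their
      # members, so they cannot re-form once the group is zeroed)
      zset <- gs
      repeat {
        leak <- unique(unlist(lapply(model$reactions, function(r) {
          sides <- list(list(from = names(r$reactants),
                             to = names(r$products)))
          if (r$kind == "mass_action_reversible")
            sides <- c(sides, list(list(from = names(r$products),
                                        to = names(r$reactants))))
          unlist(lapply(sides, function(sd) {
            if (length(sd$from) && !any(sd$from %in% zset) &&
                !any(r$modifiers %in% zset) && any(sd$to %in% zset))
              sd$from
          }))
        })))
        leak <- setdiff(leak, zset)
        if (length(leak) == 0L) break
        zset <- c(zset, leak)
      }
      state0[zset] <- 0
    }
    if (sp$kind == "initial_scale") state0[gs] <- state0[gs] * sp$factor
    if (sp$kind == "overexpress") {
      main <- principal_species(model, sp$target)
      state0[[main]] <- state0[[main]] * sp$factor
    }
  }
  # rebuild directly: perturbations may legitimately zero parameters
  model$parameters <- structure(params, class = c("mp_parameters",
                                                  "numeric"),
                                provenance = "user")
  validate_model(model)
  list(model = model, state0 = state0)
}

# principal node of a group for overexpression: the free/unmodified form.
# Convention: a species whose id equals the group id if present, else the
# group member with the largest baseline initial value.
principal_species <- function(model, group) {
  gs <- group_species(model, group)
  if (group %in% gs) return(group)
  gs[[which.max(model$species$initial[match(gs, model$species$id)])]]
}

#' Define a normalization mode
#'
#' @param mode one of `to_t0` (divide by the value at the first time
#'   point), `to_untreated` (divide by an externally supplied untreated
#'   baseline), `to_max` (divide by the series maximum),
#'   `to_reference_time` (divide by the value at `reference` hours), or
#'   `log2_fold` (log2 of the t0-normalized series).
#' @param reference reference time (h) for `to_reference_time`.
#' @return object of class `mp_norm`.
#' @export
mp_norm <- function(mode = c("to_t0", "to_untreated", "to_max",
                             "to_reference_time", "log2_fold"),
                    reference = NULL) {
  mode <- match.arg(mode)
  if (mode == "to_reference_time" && is.null(reference))
    stop("to_reference_time needs a reference time")
  structure(list(mode = mode, reference = reference), class = "mp_norm")
}

# normalize one series; baseline supplies the untreated/t0 denominator
normalize_series <- function(times, values, norm, baseline = NULL) {
  denom <- switch(norm$mode,
    to_t0 = values[[1L]],
    to_untreated = baseline %||% values[[1L]],
    to_max = max(values),
    to_reference_time = {
      i <- which.min(abs(times - norm$reference))
      values[[i]]
    },
    log2_fold = baseline %||% values[[1L]])
  if (!is.finite(denom) || denom <= 0)
    stop("normalization denominator is not strictly positive")
  out <- values / denom
  if (norm$mode == "log2_fold") out <- log2(out)
  out
}

#' Extract normalized marker trajectories from a simulation
#'
#' @param sim an `mp_sim`.
#' @param panel character vector of species ids (a marker panel), or the
#'   name of a panel stored in the model's `marker_panels`.
#' @param mode an [mp_norm()] normalization mode.
#' @param baseline optional named vector of untreated baseline values
#'   (defaults to the t = 0 row of the simulation).
#' @return long `data.frame` with columns time, species, value (normalized).
#' @export
extract_markers <- function(sim, panel, mode = mp_norm("to_t0"),
                            baseline = NULL) {
  model <- sim$model
  if (is.character(panel) && length(panel) == 1L &&
      panel %in% names(model$marker_panels))
    panel <- model$marker_panels[[panel]]
  bad <- setdiff(panel, colnames(sim$mat))
  if (length(bad))
    stop("unknown marker species: ", paste(bad, collapse = ", "))
  out <- lapply(panel, function(spid) {
    base <- if (!is.null(baseline)) baseline[[spid]] else
      sim$mat[1L, spid]
    vals <- tryCatch(
      normalize_series(sim$times, sim$mat[, spid], mode, baseline = base),
      error = function(e)
        stop("normalization failed for species '", spid, "': ",
             conditionMessage(e)))
    data.frame(time = sim$times, species = spid, value = vals,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' M1/M2 polarization score
#'
#' Composite statistic quantifying position within the M1-M2 spectrum: the
#' product of six M1 marker levels divided by the product of three M2
#' marker levels, evaluated at one time point (default 24 h). Marker values
#' enter as raw copy numbers; because the score is a ratio, baseline
#' scaling cancels when scores are compared across scenarios.
#'
#' @param sim an `mp_sim`.
#' @param m1_panel six species ids (defaults to the model's `m1` panel).
#' @param m2_panel three species ids (defaults to the model's `m2` panel).
#' @param t_eval evaluation time in hours.
#' @return positive scalar score.
#' @export
m1m2_score <- function(sim, m1_panel = NULL, m2_panel = NULL, t_eval = 24) {
  model <- sim$model
  m1_panel <- m1_panel %||% model$marker_panels$m1
  m2_panel <- m2_panel %||% model$marker_panels$m2
  if (length(m1_panel) != 6L || length(m2_panel) != 3L)
    stop("score needs 6 M1 markers and 3 M2 markers")
  at <- function(spid) approx(sim$times, sim$mat[, spid], xout = t_eval)$y
  m1 <- vapply(m1_panel, at, numeric(1))
  m2 <- vapply(m2_panel, at, numeric(1))
  if (any(!is.finite(c(m1, m2))) || any(c(m1, m2) <= 0))
    stop("non-positive marker value at t_eval; score undefined")
  prod(m1) / prod(m2)
}
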