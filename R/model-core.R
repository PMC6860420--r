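# Declarative reaction-network representation: species, rate laws,
# reactions, parameter sets, and whole-model validation.

RATE_KINDS <- c("mass_action_irreversible", "mass_action_reversible",
                "hill_activation", "hill_inhibition")
COMPARTMENTS <- c("cytoplasm", "nucleus", "membrane", "extracellular")

#' Define one model species (node)
#'
#' A species is one node of the reaction network: a molecular state such as a
#' free protein, a phosphorylated form, a complex, an mRNA or a miR. Several
#' nodes belong to one "unique species" group (e.g. all STAT1 states form the
#' STAT1 group); group totals are what copy-number priors refer to.
#'
#' @param id unique short label.
#' @param group label of the parent unique-species group. Defaults to `id`.
#' @param compartment one of cytoplasm, nucleus, membrane, extracellular.
#' @param initial initial copy number (molecules per cell; molecules per
#'   cell-equivalent medium volume for extracellular species). Must be >= 0.
#' @param buffered logical; buffered species are held constant during
#'   simulation (zero net derivative), e.g. oxygen under a fixed condition.
#' @param display human-readable name.
#' @param note free-text annotation.
#' @return a `data.frame` with one row, suitable for `rbind`ing into a
#'   species table.
#' @export
mp_species <- function(id, group = id, compartment = "cytoplasm",
                       initial = 0, buffered = FALSE, display = id,
                       note = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!compartment %in% COMPARTMENTS)
    stop("unknown compartment '", compartment, "' for species '", id, "'")
  if (!is.finite(initial) || initial < 0)
    stop("initial copy number of species '", id, "' must be >= 0")
  data.frame(id = id, group = group, compartment = compartment,
             initial = as.numeric(initial), buffered = isTRUE(buffered),
             display = display, note = note, stringsAsFactors = FALSE)
}

#' Define one reaction
#'
#' Reactions carry integer stoichiometry and one of four rate-law kinds:
#' \describe{
#'   \item{mass_action_irreversible}{rate = k * prod(reactant^coef) *
#'     prod(modifiers). One parameter label (k).}
#'   \item{mass_action_reversible}{rate = (kf * prod(reactant^coef) -
#'     kr * prod(product^coef)) * prod(modifiers). Two labels (kf, kr).}
#'   \item{hill_activation}{rate = v * X^n / (K^n + X^n) * prod(other
#'     modifiers), where X is the first modifier (the regulator). Labels
#'     (v, K) or (v, K, n); a missing n label means n = 1.}
#'   \item{hill_inhibition}{rate = v * K^n / (K^n + X^n) * prod(other
#'     modifiers).}
#' }
#' Modifiers act catalytically and are never consumed. Pure synthesis
#' (no reactants) and pure degradation (no products) are allowed.
#'
#' @param id reaction label.
#' @param reactants,products named numeric vectors of positive integer
#'   stoichiometric coefficients, e.g. `c(A = 1, B = 2)`. May be empty.
#' @param kind rate-law kind (see above).
#' @param params character vector of parameter labels, in the order the
#'   rate-law kind expects.
#' @param modifiers species ids entering the rate multiplicatively (for Hill
#'   kinds the first modifier is the Hill regulator X).
#' @param annotation free text describing the biochemical step.
#' @return an object of class `mp_reaction`.
#' @export
mp_reaction <- function(id, reactants = c(), products = c(), kind, params,
                        modifiers = character(), annotation = "") {
  stopifnot(is.character(id), length(id) == 1L)
  if (!kind %in% RATE_KINDS)
    stop("malformed rate law in reaction '", id, "': unknown kind '",
         kind, "'")
  reactants <- .norm_stoich(reactants, id)
  products <- .norm_stoich(products, id)
  if (length(reactants) == 0L && length(products) == 0L)
    stop("reaction '", id, "' has neither reactants nor products")
  nparam <- length(params)
  ok <- switch(kind,
    mass_action_irreversible = nparam == 1L,
    mass_action_reversible   = nparam == 2L,
    hill_activation          = nparam %in% c(2L, 3L),
    hill_inhibition          = nparam %in% c(2L, 3L))
  if (!ok)
    stop("malformed rate law in reaction '", id, "': kind '", kind,
         "' expects ", switch(kind,
           mass_action_irreversible = "1 parameter label",
           mass_action_reversible = "2 parameter labels (kf, kr)",
           "2 or 3 parameter labels (v, K[, n])"),
         ", got ", nparam)
  if (kind %in% c("hill_activation", "hill_inhibition") &&
      length(modifiers) == 0L)
    stop("malformed rate law in reaction '", id,
         "': Hill kinds need a regulator as first modifier")
  structure(list(id = id, reactants = reactants, products = products,
                 kind = kind, params = as.character(params),
                 modifiers = as.character(modifiers),
                 annotation = annotation),
            class = "mp_reaction")
}

.norm_stoich <- function(x, id) {
  if (length(x) == 0L) return(setNames(numeric(0), character(0)))
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("stoichiometry in reaction '", id, "' must be a named vector")
  if (any(x <= 0) || any(x != round(x)))
    stop("stoichiometric coefficients in reaction '", id,
         "' must be positive integers")
  storage.mode(x) <- "double"
  x
}

#' Define a parameter set
#'
#' @param values named numeric vector of strictly positive parameter values
#'   (zeros may only be introduced later by perturbations).
#' @param units optional named character vector of unit metadata.
#' @param provenance one of "S1_table", "optimized", "user", "synthetic".
#' @return object of class `mp_parameters` (a named numeric with attributes).
#' @export
mp_parameters <- function(values, units = NULL, provenance = "user") {
  stopifnot(is.numeric(values), !is.null(names(values)),
            all(nzchar(names(values))))
  if (anyDuplicated(names(values)))
    stop("duplicate parameter labels: ",
         paste(unique(names(values)[duplicated(names(values))]),
               collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop("parameter values must be finite and >= 0")
  structure(values, units = units, provenance = provenance,
            class = c("mp_parameters", "numeric"))
}

#' Assemble and validate a model definition
#'
#' @param species a species table (rbind of [mp_species()] rows).
#' @param reactions list of [mp_reaction()] objects.
#' @param parameters an [mp_parameters()] set resolving every label
#'   referenced by the reactions.
#' @param marker_panels named list of species-id character vectors (e.g.
#'   `m1`, `m2` marker panels).
#' @param name model name.
#' @return validated object of class `mp_model`.
#' @export
mp_model <- function(species, reactions, parameters,
                     marker_panels = list(), name = "model") {
  stopifnot(is.data.frame(species))
  if (is.null(parameters)) parameters <- mp_parameters(c(.dummy = 1))
  m <- structure(list(species = species, reactions = reactions,
                      parameters = parameters,
                      marker_panels = marker_panels, name = name),
                 class = "mp_model")
  validate_model(m)
  m
}

#' Validate a model definition
#'
#' Checks species-id uniqueness, cross-references from reactions to species
#' and from rate laws to parameter labels, stoichiometry signs and rate-law
#' arity. Called by [mp_model()]; exported for re-validation after edits.
#'
#' @param model an `mp_model`.
#' @return the model, invisibly; stops with a definition error otherwise.
#' @export
validate_model <- function(model) {
  sp <- model$species
  if (nrow(sp) > 0 && anyDuplicated(sp$id))
    stop("duplicate species id: ",
         paste(unique(sp$id[duplicated(sp$id)]), collapse = ", "))
  if (nrow(sp) > 0 && any(sp$initial < 0))
    stop("negative initial copy number for: ",
         paste(sp$id[sp$initial < 0], collapse = ", "))
  ids <- sp$id
  plabs <- names(model$parameters)
  for (r in model$reactions) {
    if (!inherits(r, "mp_reaction"))
      stop("reactions must be mp_reaction objects")
    refs <- c(names(r$reactants), names(r$products), r$modifiers)
    bad <- setdiff(refs, ids)
    if (length(bad))
      stop("reaction '", r$id, "' references unknown species: ",
           paste(bad, collapse = ", "))
    badp <- setdiff(r$params, plabs)
    if (length(badp))
      stop("unresolved parameter label in reaction '", r$id, "': ",
           paste(badp, collapse = ", "))
    over <- intersect(r$modifiers, names(r$reactants))
    if (length(over))
      stop("reaction '", r$id, "' lists consumed species as modifiers: ",
           paste(over, collapse = ", "))
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids))
    stop("duplicate reaction id: ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (pn in names(model$marker_panels)) {
    bad <- setdiff(model$marker_panels[[pn]], ids)
    if (length(bad))
      stop("marker panel '", pn, "' references unknown species: ",
           paste(bad, collapse = ", "))
  }
  invisible(model)
}

#' @export
print.mp_model <- function(x, ...) {
  cat("<mp_model> ", x$name, ": ", nrow(x$species), " nodes (",
      length(unique(x$species$group)), " groups), ",
      length(x$reactions), " reactions, ",
      length(x$parameters), " parameters\n", sep = "")
  invisible(x)
}

#' Structural report of a model
#'
#' Reports node/reaction/group counts, which parameter labels are used or
#' orphaned, and species lacking production or consumption (useful to spot
#' transcription dead-ends when editing the network).
#'
#' @param model validated `mp_model`.
#' @return list with `n_nodes`, `n_reactions`, `n_groups`, `params_used`,
#'   `params_unused`, `no_production`, `no_consumption`.
#' @export
structural_report <- function(model) {
  validate_model(model)
  used <- unique(unlist(lapply(model$reactions, `[[`, "params")))
  produced <- unique(unlist(lapply(model$reactions,
                                   function(r) names(r$products))))
  consumed <- unique(unlist(lapply(model$reactions,
                                   function(r) names(r$reactants))))
  ids <- model$species$id
  buf <- ids[model$species$buffered]
  list(n_nodes = nrow(model$species),
       n_reactions = length(model$reactions),
       n_groups = length(unique(model$species$group)),
       params_used = sort(used),
       params_unused = sort(setdiff(names(model$parameters), used)),
       no_production = setdiff(ids, c(produced, buf)),
       no_consumption = setdiff(ids, c(consumed, buf)))
}

# species ids belonging to a group
group_species <- function(model, group) {
  model$species$id[model$species$group == group]
}

# initial state vector in species order
model_state0 <- function(model) {
  setNames(model$species$initial, model$species$id)
}
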