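# Model serialization: a three-table TSV dialect (species / reactions /
# parameters, transcribable cell-by-cell from printed model tables) and
# SBML level 3 version 1 read/write built on xml2.

.stoich_to_string <- function(x) {
  if (length(x) == 0L) return("")
  paste(ifelse(x == 1, names(x), paste(x, names(x))), collapse = " + ")
}

.string_to_stoich <- function(s) {
  s <- trimws(s)
  if (is.na(s) || !nzchar(s)) return(c())
  parts <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)\\s+(\\S+)$", p))[[1]]
    if (length(m) == 3L) {
      out[m[3]] <- as.numeric(m[2])
    } else {
      out[p] <- 1
    }
  }
  out
}

#' Write a model to the three-table TSV dialect
#'
#' Produces `<prefix>_species.tsv` (id, group, compartment, initial,
#' buffered), `<prefix>_reactions.tsv` (id, reactants, products, kind,
#' params, modifiers, annotation; stoichiometry as "A + 2 B" strings) and
#' `<prefix>_parameters.tsv` (label, value, provenance).
#'
#' @param model validated `mp_model`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix (defaults to the model name).
#' @return invisibly, the three file paths.
#' @export
write_model_tsv <- function(model, dir, prefix = model$name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_",
                                 c("species", "reactions", "parameters"),
                                 ".tsv"))
  sp <- model$species[, c("id", "group", "compartment", "initial",
                          "buffered")]
  write.table(sp, paths[1], sep = "\t", row.names = FALSE, quote = FALSE)
  rx <- do.call(rbind, lapply(model$reactions, function(r)
    data.frame(id = r$id,
               reactants = .stoich_to_string(r$reactants),
               products = .stoich_to_string(r$products),
               kind = r$kind,
               params = paste(r$params, collapse = ","),
               modifiers = paste(r$modifiers, collapse = ","),
               annotation = r$annotation, stringsAsFactors = FALSE)))
  write.table(rx, paths[2], sep = "\t", row.names = FALSE, quote = FALSE)
  pr <- data.frame(label = names(model$parameters),
                   value = as.numeric(model$parameters),
                   provenance = attr(model$parameters, "provenance") %||%
                     "user")
  write.table(pr, paths[3], sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a model from the three-table TSV dialect
#'
#' @param species_file,reactions_file,parameters_file paths to the three
#'   tables written by [write_model_tsv()].
#' @param name model name.
#' @param marker_panels optional named list of marker panels.
#' @return validated `mp_model`.
#' @export
read_model_tsv <- function(species_file, reactions_file, parameters_file,
                           name = "model", marker_panels = list()) {
  sp <- read.delim(species_file, stringsAsFactors = FALSE)
  rx <- read.delim(reactions_file, stringsAsFactors = FALSE,
                   na.strings = NULL)
  pr <- read.delim(parameters_file, stringsAsFactors = FALSE)
  species <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i)
    mp_species(sp$id[i], group = sp$group[i],
               compartment = sp$compartment[i], initial = sp$initial[i],
               buffered = isTRUE(sp$buffered[i]))))
  split_csv <- function(s)
    if (is.na(s) || !nzchar(s)) character(0) else
      trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  reactions <- lapply(seq_len(nrow(rx)), function(i)
    mp_reaction(rx$id[i],
                reactants = .string_to_stoich(rx$reactants[i]),
                products = .string_to_stoich(rx$products[i]),
                kind = rx$kind[i],
                params = split_csv(rx$params[i]),
                modifiers = split_csv(rx$modifiers[i]),
                annotation = if ("annotation" %in% names(rx) &&
                                 !is.na(rx$annotation[i]))
                  rx$annotation[i] else ""))
  params <- mp_parameters(setNames(pr$value, pr$label),
                          provenance = pr$provenance[1] %||% "user")
  mp_model(species, reactions, params, marker_panels = marker_panels,
           name = name)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MACPOL_NS <- "https://macpol.invalid/ratelaw"

.mathml_rate <- function(r) {
  # human-auditable MathML for the kinetic law (informational; the
  # authoritative rate-law encoding travels in the annotation)
  ci <- function(x) paste0("<ci>", x, "</ci>")
  times <- function(xs) {
    xs <- xs[nzchar(xs)]
    if (length(xs) == 1L) xs else
      paste0("<apply><times/>", paste(xs, collapse = ""), "</apply>")
  }
  pw <- function(sp, co) if (co == 1) ci(sp) else
    paste0("<apply><power/>", ci(sp), "<cn>", co, "</cn></apply>")
  mods <- vapply(r$modifiers, ci, "")
  body <- switch(r$kind,
    mass_action_irreversible =
      times(c(ci(r$params[1]),
              mapply(pw, names(r$reactants), r$reactants), mods)),
    mass_action_reversible = paste0(
      "<apply><minus/>",
      times(c(ci(r$params[1]),
              mapply(pw, names(r$reactants), r$reactants), mods)),
      times(c(ci(r$params[2]),
              mapply(pw, names(r$products), r$products), mods)),
      "</apply>"),
    {
      n <- if (length(r$params) == 3L) ci(r$params[3]) else "<cn>1</cn>"
      X <- ci(r$modifiers[1]); K <- ci(r$params[2])
      Xn <- paste0("<apply><power/>", X, n, "</apply>")
      Kn <- paste0("<apply><power/>", K, n, "</apply>")
      numer <- if (r$kind == "hill_activation") Xn else Kn
      times(c(ci(r$params[1]),
              paste0("<apply><divide/>", numer,
                     "<apply><plus/>", Kn, Xn, "</apply></apply>"),
              if (length(r$modifiers) > 1L)
                vapply(r$modifiers[-1], ci, ""),
              if (length(r$reactants))
                mapply(pw, names(r$reactants), r$reactants)))
    })
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         body, "</math>")
}

#' Export a model as SBML
#'
#' Writes an SBML level 3 version 1 document with global parameters,
#' per-species initial amounts (buffered species marked constant and
#' boundary), and reactions carrying both a MathML kinetic law and a
#' package annotation encoding the declarative rate law, so
#' [read_sbml()] round-trips exactly.
#'
#' @param model validated `mp_model`.
#' @param path output file path (.xml).
#' @return invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  validate_model(model)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  comps <- unique(model$species$compartment)
  if (length(comps) == 0L) comps <- "cytoplasm"
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<sbml xmlns=\"%s\" xmlns:mpk=\"%s\" level=\"3\" version=\"1\">",
            SBML_NS, MACPOL_NS),
    sprintf("<model id=\"%s\">", gsub("[^A-Za-z0-9_]", "_", model$name)),
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\" size=\"1\"/>", comps),
    "</listOfCompartments>")
  if (nrow(model$species)) {
    lines <- c(lines, "<listOfSpecies>",
      sprintf(paste0("<species id=\"%s\" compartment=\"%s\"",
                     " initialAmount=\"%.17g\" hasOnlySubstanceUnits=\"true\"",
                     " boundaryCondition=\"%s\" constant=\"%s\"",
                     " mpk:group=\"%s\"/>"),
              model$species$id, model$species$compartment,
              model$species$initial,
              ifelse(model$species$buffered, "true", "false"),
              ifelse(model$species$buffered, "true", "false"),
              model$species$group),
      "</listOfSpecies>")
  }
  if (length(model$parameters)) {
    lines <- c(lines, "<listOfParameters>",
      sprintf("<parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
              names(model$parameters), as.numeric(model$parameters)),
      "</listOfParameters>")
  }
  if (length(model$reactions)) {
    lines <- c(lines, "<listOfReactions>")
    for (r in model$reactions) {
      rev <- r$kind == "mass_action_reversible"
      lines <- c(lines, sprintf(
        "<reaction id=\"%s\" reversible=\"%s\" name=\"%s\">",
        r$id, if (rev) "true" else "false", esc(r$annotation)))
      lines <- c(lines, sprintf(
        "<annotation><mpk:rateLaw kind=\"%s\" params=\"%s\" modifiers=\"%s\"/></annotation>",
        r$kind, paste(r$params, collapse = ","),
        paste(r$modifiers, collapse = ",")))
      if (length(r$reactants))
        lines <- c(lines, "<listOfReactants>",
          sprintf(paste0("<speciesReference species=\"%s\"",
                         " stoichiometry=\"%g\" constant=\"true\"/>"),
                  names(r$reactants), r$reactants),
          "</listOfReactants>")
      if (length(r$products))
        lines <- c(lines, "<listOfProducts>",
          sprintf(paste0("<speciesReference species=\"%s\"",
                         " stoichiometry=\"%g\" constant=\"true\"/>"),
                  names(r$products), r$products),
          "</listOfProducts>")
      if (length(r$modifiers))
        lines <- c(lines, "<listOfModifiers>",
          sprintf("<modifierSpeciesReference species=\"%s\"/>",
                  r$modifiers),
          "</listOfModifiers>")
      lines <- c(lines, "<kineticLaw>", .mathml_rate(r), "</kineticLaw>",
                 "</reaction>")
    }
    lines <- c(lines, "</listOfReactions>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path)
  # fail fast on malformed output
  invisible({xml2::read_xml(path); path})
}

#' Read a model from SBML
#'
#' Reads SBML level 2 or level 3 core documents. Documents written by
#' [write_sbml()] restore the exact declarative rate laws from the
#' package annotation; for foreign documents without that annotation,
#' reactions fall back to mass-action kinetics (reversible where flagged)
#' with parameters taken from the kinetic law's referenced global
#' parameters in order.
#'
#' @param path SBML file path.
#' @param name model name (defaults to the SBML model id).
#' @param marker_panels optional named list of marker panels.
#' @return validated `mp_model`.
#' @export
read_sbml <- function(path, name = NULL, marker_panels = list()) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (is.na(xml2::xml_name(mnode))) stop("no <model> element found")
  name <- name %||% xml2::xml_attr(mnode, "id") %||% "sbml_model"
  spn <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  known_comps <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfCompartments/compartment"), "id")
  species <- if (length(spn)) do.call(rbind, lapply(spn, function(s) {
    comp <- xml2::xml_attr(s, "compartment")
    if (!comp %in% COMPARTMENTS) comp <- "cytoplasm"
    init <- as.numeric(xml2::xml_attr(s, "initialAmount"))
    if (is.na(init)) init <- 0
    mp_species(xml2::xml_attr(s, "id"),
               group = xml2::xml_attr(s, "group") %||%
                 xml2::xml_attr(s, "id"),
               compartment = comp, initial = init,
               buffered = identical(xml2::xml_attr(s, "constant"), "true") ||
                 identical(xml2::xml_attr(s, "boundaryCondition"), "true"))
  })) else mp_species("x")[0, ]
  pn <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  params <- setNames(as.numeric(xml2::xml_attr(pn, "value")),
                     xml2::xml_attr(pn, "id"))
  rn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rn, function(r) {
    id <- xml2::xml_attr(r, "id")
    getside <- function(which) {
      refs <- xml2::xml_find_all(
        r, sprintf("./listOf%s/speciesReference", which))
      if (length(refs) == 0L) return(c())
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      setNames(st, xml2::xml_attr(refs, "species"))
    }
    mods <- xml2::xml_attr(
      xml2::xml_find_all(r, "./listOfModifiers/modifierSpeciesReference"),
      "species")
    ann <- xml2::xml_find_first(r, "./annotation/*[1]")
    if (!is.na(xml2::xml_name(ann)) &&
        grepl("rateLaw$", xml2::xml_name(ann))) {
      kind <- xml2::xml_attr(ann, "kind")
      plist <- trimws(strsplit(xml2::xml_attr(ann, "params"), ",")[[1]])
      mstr <- xml2::xml_attr(ann, "modifiers")
      mods <- if (nzchar(mstr %||% ""))
        trimws(strsplit(mstr, ",")[[1]]) else character(0)
    } else {
      rev <- identical(xml2::xml_attr(r, "reversible"), "true")
      kind <- if (rev) "mass_action_reversible" else
        "mass_action_irreversible"
      kl <- xml2::xml_find_first(r, "./kineticLaw")
      cis <- if (!is.na(xml2::xml_name(kl)))
        xml2::xml_text(xml2::xml_find_all(kl, ".//ci")) else character(0)
      plist <- intersect(unique(trimws(cis)), names(params))
      need <- if (rev) 2L else 1L
      if (length(plist) < need)
        stop("malformed rate law in reaction '", id,
             "': cannot identify its rate parameters")
      plist <- plist[seq_len(need)]
    }
    mp_reaction(id, reactants = getside("Reactants"),
                products = getside("Products"), kind = kind,
                params = plist, modifiers = mods,
                annotation = xml2::xml_attr(r, "name") %||% "")
  })
  used <- unique(unlist(lapply(reactions, `[[`, "params")))
  missing <- setdiff(used, names(params))
  if (length(missing))
    stop("unresolved parameter label(s) in SBML document: ",
         paste(missing, collapse = ", "))
  if (length(params) == 0L) params <- c(.unused = 1)
  mp_model(species, reactions, mp_parameters(params, provenance = "user"),
           marker_panels = marker_panels, name = name)
}

#' Load a model definition
#'
#' Single entry point dispatching on source type: an SBML document
#' (`.xml`/`.sbml`) or the TSV dialect (pass the species table path; the
#' sibling `*_reactions.tsv` / `*_parameters.tsv` files are inferred).
#'
#' @param source path to an SBML file or to a `*_species.tsv` table.
#' @param ... passed to [read_sbml()] or [read_model_tsv()].
#' @return validated `mp_model`.
#' @export
load_model <- function(source, ...) {
  if (!file.exists(source)) stop("source file not found: ", source)
  if (grepl("\\.(xml|sbml)$", source, ignore.case = TRUE))
    return(read_sbml(source, ...))
  if (grepl("_species\\.tsv$", source)) {
    base <- sub("_species\\.tsv$", "", source)
    return(read_model_tsv(source, paste0(base, "_reactions.tsv"),
                          paste0(base, "_parameters.tsv"), ...))
  }
  stop("unrecognized model source: ", source,
       " (expected .xml/.sbml or *_species.tsv)")
}
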