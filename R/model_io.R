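#' Read and write metabolic models
#'
#' Two dialects are supported: a JSON dialect (the package's native fixture
#' format, a direct serialization of the [metabolic_model()] fields) and
#' SBML Level 3 Version 1 with the FBC version 2 package (compartments,
#' species with chemical formula and charge, reactions with flux bounds as
#' shared parameters, an FBC objective). Subsystems travel in reaction
#' `<notes>`; biomass/maintenance reaction roles in model `<notes>`. The
#' SBML subset implemented is the subset the package itself writes.
#'
#' @param path file path; dialect is guessed from the extension
#'   (".json"/".xml"/".sbml") unless given.
#' @param dialect `"json"` or `"sbml"`.
#' @return `read_model`: a `metabolic_model`; `write_model`: `path`,
#'   invisibly.
#' @export
read_model <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop("model file not found: ", path)
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
         json = read_model_json(path),
         sbml = read_model_sbml(path),
         stop("unknown model dialect '", dialect, "'"))
}

#' @rdname read_model
#' @param model a `metabolic_model`.
#' @export
write_model <- function(model, path, dialect = NULL) {
  dialect <- dialect %||% guess_dialect(path)
  switch(dialect,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path),
         stop("unknown model dialect '", dialect, "'"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json"
  else if (ext %in% c("xml", "sbml")) "sbml"
  else stop("cannot guess model dialect from '", path, "'")
}

read_model_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("metabolites", "reactions", "stoichiometry"))
    if (is.null(raw[[f]])) stop("model file lacks '", f, "' (", path, ")")
  st <- lapply(raw$stoichiometry, function(s) unlist(s))
  if (is.null(raw$maintenance_id) ||
      !raw$maintenance_id %in% raw$reactions$id)
    stop("model has no maintenance reaction; refusing to load")
  m <- metabolic_model(
    id = raw$id %||% "model",
    compartments = unlist(raw$compartments),
    metabolites = raw$metabolites,
    reactions = raw$reactions,
    stoichiometry = st[raw$reactions$id],
    biomass_ids = raw$biomass_ids,
    maintenance_id = raw$maintenance_id,
    objective = list(reaction = raw$objective$reaction,
                     direction = raw$objective$direction),
    pseudo_ids = raw$pseudo_ids %||% character(0))
  if (!is.null(raw$po_nadh)) m$po_nadh <- raw$po_nadh
  if (!is.null(raw$essential_aas))
    m$essential_aas <- unlist(raw$essential_aas)
  m
}

write_model_json <- function(model, path) {
  out <- list(id = model$id,
              compartments = as.list(model$compartments),
              metabolites = model$metabolites,
              reactions = model$reactions,
              stoichiometry = lapply(model$stoichiometry, as.list),
              biomass_ids = model$biomass_ids,
              maintenance_id = model$maintenance_id,
              objective = model$objective,
              pseudo_ids = model$pseudo_ids)
  if (!is.null(model$po_nadh)) out$po_nadh <- model$po_nadh
  if (!is.null(model$essential_aas))
    out$essential_aas <- model$essential_aas
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x))
  sid <- function(x) paste0("R_", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">', esc(model$id)),
    sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>biomass:%s</p><p>maintenance:%s</p><p>pseudo:%s</p><p>essential:%s</p></body></notes>',
            paste(model$biomass_ids, collapse = ","),
            model$maintenance_id,
            paste(model$pseudo_ids, collapse = ","),
            paste(model$essential_aas %||% character(0), collapse = ",")),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" name="%s" constant="true"/>',
            names(model$compartments), esc(model$compartments)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  met <- model$metabolites
  lines <- c(lines,
    sprintf('<species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false" fbc:charge="%d" fbc:chemicalFormula="%s"/>',
            met$id, esc(met$name), met$compartment,
            as.integer(met$charge), met$formula),
    "</listOfSpecies>",
    "<listOfParameters>")
  rxn <- model$reactions
  lines <- c(lines,
    sprintf('<parameter id="lb_%s" value="%.17g" constant="true"/>',
            rxn$id, rxn$lower_bound),
    sprintf('<parameter id="ub_%s" value="%.17g" constant="true"/>',
            rxn$id, rxn$upper_bound),
    "</listOfParameters>",
    "<listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    id <- rxn$id[i]
    st <- model$stoichiometry[[id]]
    reac <- st[st < 0]; prod <- st[st > 0]
    body <- character(0)
    if (nzchar(rxn$subsystem[i]))
      body <- sprintf('<notes><body xmlns="http://www.w3.org/1999/xhtml"><p>subsystem:%s</p></body></notes>',
                      esc(rxn$subsystem[i]))
    if (length(reac))
      body <- c(body, "<listOfReactants>",
        sprintf('<speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                names(reac), -unname(reac)),
        "</listOfReactants>")
    if (length(prod))
      body <- c(body, "<listOfProducts>",
        sprintf('<speciesReference species="M_%s" stoichiometry="%.17g" constant="true"/>',
                names(prod), unname(prod)),
        "</listOfProducts>")
    lines <- c(lines,
      sprintf('<reaction id="%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="lb_%s" fbc:upperFluxBound="ub_%s">',
              sid(id), esc(rxn$name[i]),
              tolower(rxn$lower_bound[i] < 0), id, id),
      body, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>",
    sprintf('<fbc:listOfObjectives fbc:activeObjective="obj"><fbc:objective fbc:id="obj" fbc:type="%s"><fbc:listOfFluxObjectives><fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/></fbc:listOfFluxObjectives></fbc:objective></fbc:listOfObjectives>',
            if (model$objective$direction == "max") "maximize" else "minimize",
            sid(model$objective$reaction)),
    "</model>", "</sbml>")
  writeLines(lines, path)
}

read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  notes <- xml2::xml_text(
    xml2::xml_find_all(mod, "./s:notes//*[local-name()='p']", ns))
  pick <- function(tag) {
    hit <- grep(paste0("^", tag, ":"), notes, value = TRUE)
    if (!length(hit)) return(character(0))
    val <- sub(paste0("^", tag, ":"), "", hit[1])
    if (!nzchar(val)) character(0) else strsplit(val, ",")[[1]]
  }
  comp_nodes <- xml2::xml_find_all(mod, ".//s:compartment", ns)
  compartments <- stats::setNames(xml2::xml_attr(comp_nodes, "name"),
                                  xml2::xml_attr(comp_nodes, "id"))
  sp <- xml2::xml_find_all(mod, ".//s:species", ns)
  metabolites <- data.frame(
    id = sub("^M_", "", xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula", ns),
    charge = as.numeric(xml2::xml_attr(sp, "charge", ns)))
  metabolites$formula[is.na(metabolites$formula)] <- ""
  par_nodes <- xml2::xml_find_all(mod, ".//s:parameter", ns)
  pars <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                          xml2::xml_attr(par_nodes, "id"))
  rx <- xml2::xml_find_all(mod, ".//s:listOfReactions/s:reaction", ns)
  ids <- sub("^R_", "", xml2::xml_attr(rx, "id"))
  stoich <- list()
  subsystem <- character(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    sref <- function(xp, sign) {
      nodes <- xml2::xml_find_all(r, xp, ns)
      stats::setNames(sign * as.numeric(xml2::xml_attr(nodes, "stoichiometry")),
                      sub("^M_", "", xml2::xml_attr(nodes, "species")))
    }
    st <- c(sref("./s:listOfReactants/s:speciesReference", -1),
            sref("./s:listOfProducts/s:speciesReference", 1))
    if (anyNA(names(st)) || !all(names(st) %in% metabolites$id))
      stop("reaction '", ids[i], "' references an unknown species")
    stoich[[ids[i]]] <- st
    note <- xml2::xml_text(
      xml2::xml_find_all(r, "./s:notes//*[local-name()='p']", ns))
    hit <- grep("^subsystem:", note, value = TRUE)
    subsystem[i] <- if (length(hit)) sub("^subsystem:", "", hit[1]) else ""
  }
  lb <- unname(pars[paste0("lb_", ids)])
  ub <- unname(pars[paste0("ub_", ids)])
  if (anyNA(lb) || anyNA(ub)) stop("missing flux-bound parameter in ", path)
  is_ex <- vapply(stoich, function(s) length(s) == 1L, logical(1))
  reactions <- data.frame(id = ids, name = xml2::xml_attr(rx, "name"),
                          lower_bound = lb, upper_bound = ub,
                          subsystem = subsystem, is_exchange = unname(is_ex))
  obj_node <- xml2::xml_find_first(mod, ".//fbc:fluxObjective", ns)
  obj_type <- xml2::xml_attr(
    xml2::xml_find_first(mod, ".//fbc:objective", ns), "type", ns)
  maint <- pick("maintenance")
  if (!length(maint) || !maint %in% ids)
    stop("model has no maintenance reaction; refusing to load")
  ess <- pick("essential")
  out <- metabolic_model(
    id = xml2::xml_attr(mod, "id"),
    compartments = compartments,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoich[ids],
    biomass_ids = pick("biomass"),
    maintenance_id = maint,
    objective = list(
      reaction = sub("^R_", "", xml2::xml_attr(obj_node, "reaction", ns)),
      direction = if (identical(obj_type, "minimize")) "min" else "max"),
    pseudo_ids = pick("pseudo"))
  if (length(ess)) out$essential_aas <- ess
  out
}
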