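## SBML Level 3 export of a transfection network.  The document is plain
## XML assembled here (one compartment, amount-based species, mass-action
## kinetic laws in MathML, the wash as a discrete event at t_inc) and can be
## structurally re-imported with read_sbml_structure().

.sbml_id <- function(x) gsub("\\*", "star", x)

.mm_ci <- function(x) paste0("<ci> ", .sbml_id(x), " </ci>")
.mm_cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")
.mm_apply <- function(op, ...)
  paste0("<apply> <", op, "/> ", paste(c(...), collapse = " "), " </apply>")
.mm_time <-
  '<csymbol encoding="text" definitionURL="http://www.sbml.org/sbml/symbols/time"> t </csymbol>'

.rate_param_of_role <- c(
  attach = "k_A", attach_new = "k_A", attach_join = "k_A", wash = "k_W",
  endocytosis = "k_E", lysis = "k_L", endosome_degradation = "d_E",
  unpack = "k_U", lipoplex_degradation = "d_L", mRNA_degradation = "d_M",
  translation = "k_TL", maturation = "k_M", gfp_degradation = "d_G")

.sbml_kinetic_math <- function(r, net) {
  p <- .rate_param_of_role[[r$role]]
  pit_sp <- grep("^P_\\d+$", net$species, value = TRUE)
  if (r$role %in% c("attach_new", "attach_join")) {
    kAX <- .mm_apply("divide", .mm_ci(p),
                     .mm_apply("plus", vapply(pit_sp, .mm_ci, ""),
                               .mm_cn(1)))
    terms <- c(kAX, .mm_ci("L_ex"))
    if (r$role == "attach_join")
      terms <- c(terms, .mm_ci(setdiff(names(r$reactants), "L_ex")))
    return(.mm_apply("times", terms))
  }
  if (r$role == "wash") {
    on_ <- .mm_apply("times", .mm_ci(p), .mm_ci("L_ex"))
    return(paste0("<piecewise> <piece> ", .mm_cn(0), " ",
                  .mm_apply("lt", .mm_time, .mm_ci("t_inc")),
                  " </piece> <otherwise> ", on_, " </otherwise> </piecewise>"))
  }
  .mm_apply("times", .mm_ci(p), .mm_ci(names(r$reactants)[1]))
}

#' Export a transfection network as an SBML Level 3 document
#'
#' Writes one compartment, all species with their initial amounts (the
#' rounded dose for `L_ex`, zero elsewhere), the rate constants and `t_inc`
#' as parameters, every reaction with its mass-action (or pit-normalised
#' attach-channel, or piecewise wash) kinetic law in MathML, and a discrete
#' event that removes the remaining external lipoplexes at the incubation
#' time (the large-`k_W` limit used by the simulators).
#'
#' @param network a [build_network()] network.
#' @param path output file.
#' @return The path, invisibly.
#' @seealso [read_sbml_structure()] for a structural re-import.
#' @export
export_sbml <- function(network, path) {
  net <- network
  des <- net$design
  xml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
    sprintf('<model id="lipoplex_transfection_%s" substanceUnits="item" timeUnits="hour" extentUnits="item">',
            net$variant),
    '<listOfCompartments>',
    '<compartment id="cell" spatialDimensions="3" size="1" constant="true"/>',
    '</listOfCompartments>',
    '<listOfSpecies>')
  for (sp in net$species) {
    init <- if (sp == "L_ex") round(des$L_ex0) else 0
    xml <- c(xml, sprintf(
      '<species id="%s" name="%s" compartment="cell" initialAmount="%.17g" hasOnlySubstanceUnits="true" boundaryCondition="false" constant="false"/>',
      .sbml_id(sp), sp, init))
  }
  xml <- c(xml, '</listOfSpecies>', '<listOfParameters>')
  for (nm in names(net$rates))
    xml <- c(xml, sprintf(
      '<parameter id="%s" value="%.17g" constant="true"/>', nm,
      net$rates[[nm]]))
  xml <- c(xml, sprintf(
    '<parameter id="t_inc" value="%.17g" constant="true"/>', des$t_inc),
    '</listOfParameters>', '<listOfReactions>')

  pit_sp <- grep("^P_\\d+$", net$species, value = TRUE)
  for (j in seq_along(net$reactions)) {
    r <- net$reactions[[j]]
    xml <- c(xml, sprintf(
      '<reaction id="R%02d" name="%s" reversible="false">', j,
      gsub("[<>&]", "", r$label)))
    if (length(r$reactants)) {
      xml <- c(xml, "<listOfReactants>")
      for (nm in names(r$reactants))
        xml <- c(xml, sprintf(
          '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
          .sbml_id(nm), r$reactants[[nm]]))
      xml <- c(xml, "</listOfReactants>")
    }
    if (length(r$products)) {
      xml <- c(xml, "<listOfProducts>")
      for (nm in names(r$products))
        xml <- c(xml, sprintf(
          '<speciesReference species="%s" stoichiometry="%g" constant="true"/>',
          .sbml_id(nm), r$products[[nm]]))
      xml <- c(xml, "</listOfProducts>")
    }
    if (r$role %in% c("attach_new", "attach_join")) {
      mods <- setdiff(pit_sp, c(names(r$reactants), names(r$products)))
      if (length(mods)) {
        xml <- c(xml, "<listOfModifiers>",
                 sprintf('<modifierSpeciesReference species="%s"/>',
                         vapply(mods, .sbml_id, "")),
                 "</listOfModifiers>")
      }
    }
    xml <- c(xml,
             '<kineticLaw>',
             '<math xmlns="http://www.w3.org/1998/Math/MathML">',
             .sbml_kinetic_math(r, net),
             '</math>', '</kineticLaw>', '</reaction>')
  }
  xml <- c(xml, '</listOfReactions>',
    '<listOfEvents>',
    '<event id="wash_event" useValuesFromTriggerTime="true">',
    '<trigger initialValue="true" persistent="true">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">',
    .mm_apply("geq", .mm_time, .mm_ci("t_inc")),
    '</math>', '</trigger>', '<listOfEventAssignments>',
    '<eventAssignment variable="L_ex">',
    '<math xmlns="http://www.w3.org/1998/Math/MathML">', .mm_cn(0),
    '</math>', '</eventAssignment>', '</listOfEventAssignments>',
    '</event>', '</listOfEvents>', '</model>', '</sbml>')
  writeLines(xml, path)
  # parse check: malformed XML throws here
  invisible(xml2::read_xml(path))
  invisible(path)
}

#' Structural re-import of an SBML document
#'
#' Parses an SBML file and returns its species, parameters, reaction count
#' and event count, checking that every species reference points at a
#' declared species.
#'
#' @param path SBML file.
#' @return List with `species`, `parameters`, `n_reactions`, `n_events`,
#'   `ok`.
#' @export
read_sbml_structure <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"),
                            "id")
  pars <- xml2::xml_attr(xml2::xml_find_all(doc,
                                            ".//listOfParameters/parameter"),
                         "id")
  rxn <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  refs <- xml2::xml_attr(xml2::xml_find_all(doc, ".//speciesReference"),
                         "species")
  events <- xml2::xml_find_all(doc, ".//listOfEvents/event")
  list(species = species, parameters = pars, n_reactions = length(rxn),
       n_events = length(events), ok = all(refs %in% species))
}
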