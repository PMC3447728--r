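SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub('"', "&quot;", x, fixed = TRUE)
}

# shortest decimal representation that survives a read-back
format_num <- function(x) {
  vapply(x, function(v) {
    if (v == round(v) && abs(v) < 1e15) return(sprintf("%d", as.integer(v)))
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

# sanitize to SBML SIds; returns named vector original -> sanitized
sanitize_ids <- function(ids, prefix) {
  s <- gsub("[^A-Za-z0-9_]", "_", ids)
  s <- paste0(prefix, s)
  s <- make.unique(s, sep = "_dup")
  stats::setNames(s, ids)
}

#' Write a model as SBML Level 3 with flux-balance constraints
#'
#' Emits SBML L3V1 + fbc-v2: one species per metabolite
#' (`boundaryCondition="true"` for external species), one reaction per model
#' reaction with stoichiometry, reversibility and bounds (as fbc flux-bound
#' parameters), and the objective as an fbc objective. The reaction kind and
#' the original (pre-sanitization) identifier are carried in each element's
#' notes, so the document round-trips through [read_sbml()] without loss.
#' Identifiers that are not valid SBML SIds (e.g. starting with a digit) are
#' sanitized reversibly — the original id is recorded in the notes, never
#' dropped. Flux values, when supplied, are embedded per-reaction in notes.
#'
#' @param model A valid `metabolic_model`.
#' @param fluxes Optional `flux_distribution` (or named numeric) to embed.
#' @param path Output file path; `NULL` returns the document text instead.
#' @return The path (invisibly), or the SBML text when `path` is `NULL`.
#' @export
write_sbml <- function(model, fluxes = NULL, path = NULL) {
  validate_model(model)
  if (inherits(fluxes, "flux_distribution")) fluxes <- fluxes$fluxes
  met <- model$metabolites
  rxn <- model$reactions
  mid <- sanitize_ids(met$id, "M_")
  rid <- sanitize_ids(rxn$id, "R_")

  species <- sprintf(
    paste0('      <species id="%s" name="%s" compartment="c" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="%s" ',
           'constant="false"%s><notes>',
           '<body xmlns="http://www.w3.org/1999/xhtml">',
           '<p>original_id: %s</p></body></notes></species>'),
    mid[met$id], xml_escape(met$name),
    ifelse(met$external, "true", "false"),
    ifelse(is.na(met$formula), "",
           sprintf(' fbc:chemicalFormula="%s"', xml_escape(met$formula))),
    xml_escape(met$id))

  bounds <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  pid <- stats::setNames(sprintf("fb_%d", seq_along(bounds)),
                         format_num(bounds))
  params <- sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                    pid, names(pid))

  rx_chunks <- vapply(seq_len(nrow(rxn)), function(i) {
    s <- rxn$stoichiometry[[i]]
    side <- function(sel, tag) {
      if (!any(sel)) return("")
      refs <- sprintf(
        paste0('          <speciesReference species="%s" ',
               'stoichiometry="%s" constant="true"/>'),
        mid[names(s)[sel]], format_num(abs(unname(s[sel]))))
      sprintf('        <listOf%s>\n%s\n        </listOf%s>',
              tag, paste(refs, collapse = "\n"), tag)
    }
    notes <- c(sprintf("<p>original_id: %s</p>", xml_escape(rxn$id[i])),
               sprintf("<p>kind: %s</p>", rxn$kind[i]))
    if (!is.null(fluxes) && rxn$id[i] %in% names(fluxes) &&
        !is.na(fluxes[[rxn$id[i]]])) {
      notes <- c(notes, sprintf("<p>flux: %s</p>",
                                format_num(fluxes[[rxn$id[i]]])))
    }
    paste0(
      sprintf(paste0('      <reaction id="%s" name="%s" reversible="%s" ',
                     'fast="false" fbc:lowerFluxBound="%s" ',
                     'fbc:upperFluxBound="%s">\n'),
              rid[rxn$id[i]], xml_escape(rxn$name[i]),
              ifelse(rxn$reversible[i], "true", "false"),
              pid[format_num(rxn$lower_bound[i])],
              pid[format_num(rxn$upper_bound[i])]),
      sprintf(paste0('        <notes><body xmlns="http://www.w3.org/1999/',
                     'xhtml">%s</body></notes>\n'),
              paste(notes, collapse = "")),
      paste(Filter(nzchar, c(side(s < 0, "Reactants"),
                             side(s > 0, "Products"))), collapse = "\n"),
      "\n      </reaction>")
  }, character(1))

  objective <- ""
  if (!is.null(model$objective)) {
    co <- model$objective$coefficients
    fo <- sprintf(
      '          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
      rid[names(co)], format_num(unname(co)))
    objective <- sprintf(
      paste0('    <fbc:listOfObjectives fbc:activeObjective="obj1">\n',
             '      <fbc:objective fbc:id="obj1" fbc:type="%s">\n',
             '        <fbc:listOfFluxObjectives>\n%s\n',
             '        </fbc:listOfFluxObjectives>\n',
             '      </fbc:objective>\n',
             '    </fbc:listOfObjectives>\n'),
      model$objective$direction, paste(fo, collapse = "\n"))
  }

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" ',
                   'fbc:required="false">\n'), SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" name="%s" fbc:strict="false">\n',
            sanitize_ids(model$id, "")[[1]], xml_escape(model$id)),
    sprintf(paste0('    <notes><body xmlns="http://www.w3.org/1999/xhtml">',
                   '<p>original_id: %s</p><p>organism: %s</p>',
                   '</body></notes>\n'),
            xml_escape(model$id),
            xml_escape(if (is.na(model$organism)) "" else model$organism)),
    '    <listOfCompartments>\n',
    '      <compartment id="c" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n', paste(species, collapse = "\n"), "\n",
    '    </listOfSpecies>\n',
    '    <listOfParameters>\n', paste(params, collapse = "\n"), "\n",
    '    </listOfParameters>\n',
    '    <listOfReactions>\n', paste(rx_chunks, collapse = "\n"), "\n",
    '    </listOfReactions>\n',
    objective,
    '  </model>\n</sbml>\n')

  # refuse to emit malformed XML, whatever the ids contained
  xml2::read_xml(doc)
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(path)
}

# attribute lookup tolerant of namespace prefixes
xattr <- function(node, names_) {
  at <- xml2::xml_attrs(node)
  for (nm in names_) if (nm %in% names(at)) return(at[[nm]])
  base <- sub("^.*:", "", names_)
  hit <- which(sub("^.*:", "", names(at)) %in% base)
  if (length(hit)) return(at[[hit[1]]])
  NA_character_
}

# "key: value" pairs from an element's <notes>
notes_fields <- function(node) {
  ps <- xml2::xml_find_all(node, "./notes//p")
  txt <- xml2::xml_text(ps)
  kv <- regmatches(txt, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", txt))
  kv <- kv[vapply(kv, length, integer(1)) == 3]
  stats::setNames(lapply(kv, `[[`, 3), vapply(kv, `[[`, character(1), 2))
}

#' Read an SBML model
#'
#' Auto-detects the dialect: SBML Level 3 with fbc flux bounds and
#' objectives (the package's own write format), or 2012-era legacy Level 2
#' where bounds, objective coefficients and flux values live in kinetic-law
#' parameters named `LOWER_BOUND` / `UPPER_BOUND` / `OBJECTIVE_COEFFICIENT`
#' / `FLUX_VALUE`. Bounds are searched in that order: fbc attributes, then
#' kinetic-law parameters, then notes; reactions with no bound information
#' get reversibility-based defaults with a warning. Original identifiers
#' and reaction kinds recorded in notes by [write_sbml()] are restored;
#' foreign files fall back to heuristics (exchange kinds inferred from
#' one-sided stoichiometry).
#'
#' @param path SBML file path or literal XML string.
#' @return A `metabolic_model`. Embedded flux values, if any, are returned
#'   in `model$notes$flux_values` (named numeric); the sanitized-to-original
#'   id mapping in `model$notes$id_map`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "sbml") {
    abort("not an SBML document (root element is not <sbml>)")
  }
  level <- xattr(doc, "level")
  xml2::xml_ns_strip(doc)
  mnode <- xml2::xml_find_first(doc, "./model")
  if (inherits(mnode, "xml_missing")) abort("SBML document has no <model>")
  mn <- notes_fields(mnode)
  model_id <- mn$original_id %||% xattr(mnode, "id")
  if (is.na(model_id)) model_id <- "model"
  organism <- mn$organism %||% NA_character_
  if (!is.null(organism) && identical(organism, "")) organism <- NA_character_

  sp <- xml2::xml_find_all(mnode, "./listOfSpecies/species")
  sp_rows <- purrr::map_dfr(sp, function(nd) {
    nf <- notes_fields(nd)
    sid <- xattr(nd, "id")
    tibble(sbml_id = sid,
           id = nf$original_id %||% sid,
           name = xattr(nd, "name") %||% sid,
           formula = xattr(nd, c("fbc:chemicalFormula", "chemicalFormula")),
           external = identical(xattr(nd, "boundaryCondition"), "true"))
  })
  sp_rows$name[is.na(sp_rows$name)] <- sp_rows$id[is.na(sp_rows$name)]
  id_of <- stats::setNames(sp_rows$id, sp_rows$sbml_id)

  pnodes <- xml2::xml_find_all(mnode, "./listOfParameters/parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(pnodes, "value")),
                           xml2::xml_attr(pnodes, "id"))

  rx <- xml2::xml_find_all(mnode, "./listOfReactions/reaction")
  flux_vals <- numeric(0)
  obj_l2 <- numeric(0)
  warned_default <- FALSE
  rx_rows <- purrr::map_dfr(rx, function(nd) {
    nf <- notes_fields(nd)
    sid <- xattr(nd, "id")
    orig <- nf$original_id %||% sid
    rev <- !identical(xattr(nd, "reversible"), "false")
    refs <- function(xp, sign) {
      rr <- xml2::xml_find_all(nd, xp)
      if (!length(rr)) return(numeric(0))
      st <- as.numeric(xml2::xml_attr(rr, "stoichiometry"))
      st[is.na(st)] <- 1
      stats::setNames(sign * st, id_of[xml2::xml_attr(rr, "species")])
    }
    raw <- c(refs("./listOfReactants/speciesReference", -1),
             refs("./listOfProducts/speciesReference", +1))
    s <- tapply(raw, names(raw), sum)
    s <- stats::setNames(as.numeric(s), names(s))
    s <- s[s != 0]
    # bounds: fbc, then kinetic law, then notes, then defaults
    lbp <- xattr(nd, c("fbc:lowerFluxBound", "lowerFluxBound"))
    ubp <- xattr(nd, c("fbc:upperFluxBound", "upperFluxBound"))
    lb <- if (!is.na(lbp)) pvals[[lbp]] else NA_real_
    ub <- if (!is.na(ubp)) pvals[[ubp]] else NA_real_
    klp <- xml2::xml_find_all(nd, "./kineticLaw//parameter")
    if (length(klp)) {
      kl <- stats::setNames(as.numeric(xml2::xml_attr(klp, "value")),
                            dplyr::coalesce(xml2::xml_attr(klp, "id"),
                                            xml2::xml_attr(klp, "name")))
      if (is.na(lb) && "LOWER_BOUND" %in% names(kl)) lb <- kl[["LOWER_BOUND"]]
      if (is.na(ub) && "UPPER_BOUND" %in% names(kl)) ub <- kl[["UPPER_BOUND"]]
      if ("OBJECTIVE_COEFFICIENT" %in% names(kl) &&
          kl[["OBJECTIVE_COEFFICIENT"]] != 0) {
        obj_l2[[orig]] <<- kl[["OBJECTIVE_COEFFICIENT"]]
      }
      if ("FLUX_VALUE" %in% names(kl)) flux_vals[[orig]] <<- kl[["FLUX_VALUE"]]
    }
    if (is.na(lb) && !is.null(nf$lower_bound)) lb <- as.numeric(nf$lower_bound)
    if (is.na(ub) && !is.null(nf$upper_bound)) ub <- as.numeric(nf$upper_bound)
    if (is.na(lb) || is.na(ub)) {
      if (!warned_default) {
        warn(paste0("reaction ", orig, " (and possibly others) has no bound",
                    " information; applying reversibility defaults"))
        warned_default <<- TRUE
      }
      if (is.na(lb)) lb <- if (rev) -FD_BIG else 0
      if (is.na(ub)) ub <- FD_BIG
    }
    if (lb < 0) rev <- TRUE
    if (!is.null(nf$flux)) flux_vals[[orig]] <<- as.numeric(nf$flux)
    kind <- nf$kind %||% if (all(s > 0)) "inflow" else if (all(s < 0))
      "outflow" else "intracellular"
    tibble(sbml_id = sid, id = orig, name = xattr(nd, "name") %||% orig,
           stoichiometry = list(s), reversible = rev,
           lower_bound = lb, upper_bound = ub, kind = kind,
           ec_numbers = list(character()))
  })
  rx_rows$name[is.na(rx_rows$name)] <- rx_rows$id[is.na(rx_rows$name)]

  objective <- NULL
  fo <- xml2::xml_find_all(mnode, ".//*[local-name()='fluxObjective']")
  if (length(fo)) {
    act <- xml2::xml_find_first(mnode, ".//*[local-name()='objective']")
    dirn <- xattr(act, c("fbc:type", "type"))
    rmap <- stats::setNames(rx_rows$id, rx_rows$sbml_id)
    co <- stats::setNames(
      as.numeric(vapply(fo, xattr, character(1),
                        c("fbc:coefficient", "coefficient"))),
      rmap[vapply(fo, xattr, character(1), c("fbc:reaction", "reaction"))])
    objective <- list(coefficients = co,
                      direction = if (identical(dirn, "minimize"))
                        "minimize" else "maximize")
  } else if (length(obj_l2)) {
    objective <- list(coefficients = obj_l2, direction = "maximize")
  }

  model <- metabolic_model(
    id = model_id, organism = organism,
    metabolites = sp_rows[c("id", "name", "formula", "external")],
    reactions = rx_rows[c("id", "name", "stoichiometry", "reversible",
                          "lower_bound", "upper_bound", "kind", "ec_numbers")],
    objective = objective
  )
  model$notes$id_map <- c(stats::setNames(sp_rows$id, sp_rows$sbml_id),
                          stats::setNames(rx_rows$id, rx_rows$sbml_id))
  model$notes$sbml_level <- level
  if (length(flux_vals)) model$notes$flux_values <- flux_vals
  model
}
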