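#' Parse a KGML pathway document
#'
#' Reads the reaction entries of a KEGG Markup Language (KGML) pathway file:
#' each `<reaction>` element contributes its reaction id(s), its
#' directionality (`type` attribute) and its substrate/product compound
#' lists. The `rn:` and `cpd:` prefixes used by KEGG are stripped. KGML
#' carries no stoichiometric coefficients, so drafting takes stoichiometry
#' from a reaction-definition table ([parse_reaction_table()]) and uses the
#' KGML lists only for orientation checks.
#'
#' @param document KGML as a file path, literal XML string, or `xml2`
#'   document.
#' @return A `kgml_pathway` object: `pathway_id`, `organism`, and
#'   `reactions` (tibble with columns `reaction_id`, `type`, `substrates`,
#'   `products`; the last two are list-columns of compound ids).
#' @export
parse_kgml <- function(document) {
  doc <- if (inherits(document, "xml_document")) document else
    xml2::read_xml(document)
  root <- xml2::xml_find_first(doc, "/pathway")
  if (inherits(root, "xml_missing")) abort("not a KGML document: no <pathway> root")
  pathway_id <- sub("^path:", "", xml2::xml_attr(doc, "name"))
  organism <- xml2::xml_attr(doc, "org")
  nodes <- xml2::xml_find_all(doc, "//reaction")
  rows <- purrr::map_dfr(nodes, function(nd) {
    ids <- strsplit(xml2::xml_attr(nd, "name"), "\\s+")[[1]]
    ids <- sub("^rn:", "", ids)
    bad <- ids[!grepl("^R\\d{5}$", ids)]
    if (length(bad)) {
      abort(paste0("KGML reaction id not of form R#####: ", bad[1]))
    }
    type <- xml2::xml_attr(nd, "type")
    if (is.na(type)) {
      warn(paste0("KGML reaction ", ids[1],
                  " has no type attribute; assuming reversible"))
      type <- "reversible"
    }
    subs <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(nd, "./substrate"), "name"))
    prods <- sub("^cpd:", "", xml2::xml_attr(
      xml2::xml_find_all(nd, "./product"), "name"))
    tibble(reaction_id = ids, type = type,
           substrates = rep(list(subs), length(ids)),
           products = rep(list(prods), length(ids)))
  })
  if (nrow(rows) == 0) {
    rows <- tibble(reaction_id = character(), type = character(),
                   substrates = list(), products = list())
  }
  structure(list(pathway_id = pathway_id, organism = organism,
                 reactions = rows),
            class = "kgml_pathway")
}

#' @export
print.kgml_pathway <- function(x, ...) {
  cat("<kgml_pathway> ", x$pathway_id, " [", x$organism, "], ",
      nrow(x$reactions), " reaction entries\n", sep = "")
  invisible(x)
}

#' Parse a KEGG-LIGAND-style reaction equation
#'
#' Grammar: terms `"[coef] C#####"` joined by `" + "`, sides joined by
#' `"<=>"` (or `"=>"`). Left-side coefficients come out negative, right-side
#' positive; an omitted coefficient is 1; a compound appearing on both sides
#' nets out (and is dropped at net zero). Equations the grammar cannot
#' commit to — non-numeric coefficients such as `n` or `(n+1)` (repeat
#' units/polymers) and glycan `G#####` terms — return `NULL` with a
#' `"reason"` attribute rather than a guessed stoichiometry.
#'
#' @param equation Equation string, e.g.
#'   `"C00031 + C00002 <=> C00092 + C00008"`.
#' @return Named numeric stoichiometry vector, or `NULL` when unparsable
#'   (the rejection reason is available via
#'   `attr(parse_equation(x, detail = TRUE), "reason")`).
#' @param detail If `TRUE`, failures return an empty numeric vector carrying
#'   a `reason` attribute instead of `NULL`.
#' @export
parse_equation <- function(equation, detail = FALSE) {
  fail <- function(reason) {
    if (detail) structure(numeric(0), reason = reason) else NULL
  }
  sides <- strsplit(equation, "<=>|=>", perl = TRUE)[[1]]
  if (length(sides) != 2) {
    return(fail("equation must have exactly one '<=>' (or '=>') separator"))
  }
  acc <- numeric(0)
  for (k in 1:2) {
    sign <- if (k == 1) -1 else 1
    terms <- strsplit(trimws(sides[k]), "\\s\\+\\s")[[1]]
    terms <- trimws(terms)
    if (!length(terms) || any(!nzchar(terms))) {
      return(fail("empty side of equation"))
    }
    for (term in terms) {
      m <- regmatches(term,
                      regexec("^(?:(\\d+(?:\\.\\d+)?)\\s+)?([A-Z]\\d{5})$",
                              term))[[1]]
      if (!length(m)) {
        return(fail(paste0("unparsable term '", term,
                           "' (non-numeric coefficient or non-compound id)")))
      }
      cid <- m[3]
      if (!startsWith(cid, "C")) {
        return(fail(paste0("non-compound term '", cid,
                           "' (glycans are not drafted)")))
      }
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      acc[cid] <- (if (cid %in% names(acc)) acc[[cid]] else 0) + sign * coef
    }
  }
  acc <- acc[acc != 0]
  if (!any(acc < 0) || !any(acc > 0)) {
    return(fail("equation nets to a one-sided reaction"))
  }
  acc
}

#' Parse a reaction-definition table
#'
#' Accepts either KEGG LIGAND flat-file records (fields `ENTRY`, `NAME`,
#' `EQUATION`, records separated by `///`, continuation lines indented) or a
#' 3-column TSV fallback (`id`, `name`, `equation`, no header). Parse
#' failures are flagged per record (`parse_ok = FALSE` with a reason), never
#' fatal; duplicate ids keep the first record with a warning.
#'
#' @param text Table as a single string, character vector of lines, or a
#'   file path.
#' @return Tibble with columns `reaction_id`, `name`, `equation`,
#'   `stoichiometry` (list-column), `parse_ok`, `reason`.
#' @export
parse_reaction_table <- function(text) {
  lines <- if (length(text) == 1 && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines)) | grepl("^///", lines)]
  recs <- if (any(grepl("\t", lines))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    purrr::map(parts, function(p) {
      list(id = trimws(p[1]), name = trimws(p[2]), equation = trimws(p[3]))
    })
  } else {
    parse_ligand_records(lines)
  }
  rows <- purrr::map_dfr(recs, function(r) {
    s <- parse_equation(r$equation, detail = TRUE)
    ok <- length(s) > 0
    tibble(reaction_id = r$id, name = r$name %||% r$id,
           equation = r$equation,
           stoichiometry = list(if (ok) s else NULL),
           parse_ok = ok,
           reason = if (ok) NA_character_ else attr(s, "reason"))
  })
  dup <- duplicated(rows$reaction_id)
  if (any(dup)) {
    warn(paste0("duplicate reaction definition(s) dropped (first kept): ",
                paste(unique(rows$reaction_id[dup]), collapse = ", ")))
    rows <- rows[!dup, , drop = FALSE]
  }
  rows
}

# split LIGAND flat-file lines into records and extract ENTRY/NAME/EQUATION
parse_ligand_records <- function(lines) {
  rec_idx <- cumsum(grepl("^///", c("", lines[-length(lines)])))
  recs <- split(lines, rec_idx)
  recs <- purrr::map(recs, function(ls) {
    ls <- ls[!grepl("^///", ls)]
    if (!length(ls)) return(NULL)
    # continuation lines (leading whitespace) belong to the previous field
    field <- character(length(ls)); value <- character(length(ls))
    cur <- ""
    for (i in seq_along(ls)) {
      if (grepl("^\\S", ls[i])) {
        cur <- sub("^(\\S+).*$", "\\1", ls[i])
        field[i] <- cur
        value[i] <- trimws(sub("^\\S+\\s*", "", ls[i]))
      } else {
        field[i] <- cur
        value[i] <- trimws(ls[i])
      }
    }
    getf <- function(f) {
      v <- value[field == f]
      if (!length(v)) NULL else paste(v, collapse = " ")
    }
    entry <- getf("ENTRY")
    if (is.null(entry)) return(NULL)
    list(id = sub("^(\\S+).*$", "\\1", entry),
         name = getf("NAME"),
         equation = getf("EQUATION") %||% "")
  })
  recs[!vapply(recs, is.null, logical(1))]
}

#' Assemble an organism draft model from pathways and definitions
#'
#' Takes the union of reaction ids across the supplied KGML pathways
#' (deduplicated — a reaction appearing on several maps enters once), looks
#' up each id's stoichiometry in the reaction-definition table, and builds a
#' draft `metabolic_model`. Reversibility comes from the KGML `type`
#' attribute; when maps disagree the reaction is kept reversible (least
#' restrictive — users can tighten it during reconstruction). Reactions with
#' no definition or an unparsable equation are skipped and listed in the
#' draft report (`model$notes$draft_report`). When the KGML substrate list
#' disagrees with the LIGAND equation's left side, the LIGAND orientation is
#' kept and a warning is logged.
#'
#' @param pathways List of `kgml_pathway` objects (one organism).
#' @param definitions Tibble from [parse_reaction_table()].
#' @param organism Organism code; must match all pathways.
#' @return A draft `metabolic_model` (kind `"intracellular"` throughout)
#'   with a skipped-reaction report in `notes$draft_report`.
#' @export
assemble_draft <- function(pathways, definitions, organism) {
  if (inherits(pathways, "kgml_pathway")) pathways <- list(pathways)
  orgs <- unique(vapply(pathways, `[[`, character(1), "organism"))
  if (!all(orgs == organism)) {
    abort(paste0("pathway organism mismatch: expected ", organism,
                 ", found ", paste(setdiff(orgs, organism), collapse = ", ")))
  }
  entries <- purrr::map_dfr(pathways, function(p) {
    cbind(p$reactions, tibble(pathway = rep(p$pathway_id,
                                            nrow(p$reactions))))
  })
  if (nrow(entries) == 0) abort("empty draft: no reactions in supplied pathways")
  merged <- entries |>
    group_by(.data$reaction_id) |>
    summarise(
      reversible = any(.data$type == "reversible"),
      n_maps = dplyr::n(),
      substrates = list(unique(unlist(.data$substrates))),
      .groups = "drop"
    ) |>
    arrange(.data$reaction_id)
  skipped <- tibble(reaction_id = character(), reason = character())
  keep <- logical(nrow(merged)); stoich <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    rid <- merged$reaction_id[i]
    j <- match(rid, definitions$reaction_id)
    if (is.na(j)) {
      skipped <- bind_rows(skipped, tibble(reaction_id = rid,
                                           reason = "no definition"))
    } else if (!definitions$parse_ok[j]) {
      skipped <- bind_rows(skipped, tibble(
        reaction_id = rid,
        reason = paste0("definition unparsable: ", definitions$reason[j])))
    } else {
      s <- definitions$stoichiometry[[j]]
      kg_sub <- merged$substrates[[i]]
      lig_sub <- names(s)[s < 0]
      if (length(kg_sub) && !any(kg_sub %in% lig_sub) &&
          any(kg_sub %in% names(s)[s > 0])) {
        warn(paste0("reaction ", rid, ": KGML substrate list matches the ",
                    "LIGAND product side; keeping LIGAND orientation"))
      }
      keep[i] <- TRUE
      stoich[[i]] <- s
    }
  }
  if (!any(keep)) abort("empty draft: no includable reactions")
  inc <- merged[keep, , drop = FALSE]
  stoich <- stoich[keep]
  def_ix <- match(inc$reaction_id, definitions$reaction_id)
  rxns <- tibble(
    id = inc$reaction_id,
    name = definitions$name[def_ix],
    stoichiometry = stoich,
    reversible = inc$reversible,
    lower_bound = ifelse(inc$reversible, -FD_BIG, 0),
    upper_bound = FD_BIG,
    kind = "intracellular",
    ec_numbers = rep(list(character()), nrow(inc))
  )
  mets <- sort(unique(unlist(lapply(stoich, names))))
  model <- metabolic_model(
    id = paste0(organism, "_draft"), organism = organism,
    metabolites = tibble(id = mets, name = mets,
                         formula = NA_character_, external = FALSE),
    reactions = rxns
  )
  model$notes$draft_report <- skipped
  model
}
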