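#' Render a metabolic network as SVG
#'
#' Draws the bipartite metabolite/reaction graph: metabolites as circles on
#' an outer ring, reactions as squares on an inner ring, with directed edges
#' following the sign convention (substrate -> reaction -> product;
#' reversible reactions get unmarked ends). The layout is a deterministic
#' function of the sorted identifiers, so the same model renders to
#' byte-identical SVG every time. When a flux distribution is supplied,
#' edge stroke width scales with `|flux|` and zero-flux edges are dashed.
#' Models with more than `label_limit` nodes are drawn without text labels.
#'
#' @param model A valid `metabolic_model`.
#' @param fluxes Optional `flux_distribution` or named numeric vector.
#' @param path Output file; `NULL` returns the SVG text.
#' @param width,height Canvas size in pixels.
#' @param label_limit Node-count threshold above which labels are omitted.
#' @return The path (invisibly), or SVG text when `path` is `NULL`.
#' @export
render_network_svg <- function(model, fluxes = NULL, path = NULL,
                               width = 1000, height = 1000,
                               label_limit = 2000) {
  validate_model(model)
  if (inherits(fluxes, "flux_distribution")) fluxes <- fluxes$fluxes
  mets <- sort(model$metabolites$id)
  rxns <- sort(model$reactions$id)
  n_nodes <- length(mets) + length(rxns)
  labels <- n_nodes <= label_limit
  cx <- width / 2; cy <- height / 2
  r_out <- 0.45 * min(width, height)
  r_in <- 0.28 * min(width, height)
  pos <- function(ids, r) {
    th <- 2 * pi * (seq_along(ids) - 1) / max(1, length(ids)) - pi / 2
    tibble(id = ids, x = round(cx + r * cos(th), 2),
           y = round(cy + r * sin(th), 2))
  }
  mp <- pos(mets, r_out); rp <- pos(rxns, r_in)
  mxy <- stats::setNames(split(cbind(mp$x, mp$y), seq_len(nrow(mp))), mp$id)
  rxy <- stats::setNames(split(cbind(rp$x, rp$y), seq_len(nrow(rp))), rp$id)

  max_flux <- if (!is.null(fluxes)) max(abs(fluxes), 1e-12, na.rm = TRUE) else NA
  edges <- character(0)
  ord <- match(rxns, model$reactions$id)
  for (i in ord) {
    rid <- model$reactions$id[i]
    s <- model$reactions$stoichiometry[[i]]
    fl <- if (!is.null(fluxes) && rid %in% names(fluxes)) fluxes[[rid]] else NA
    sw <- if (!is.na(fl)) round(0.5 + 4 * abs(fl) / max_flux, 3) else 1
    dash <- if (!is.na(fl) && abs(fl) < 1e-9) ' stroke-dasharray="4 3"' else ""
    for (mid2 in names(s)) {
      a <- mxy[[mid2]]; b <- rxy[[rid]]
      # substrate edges run metabolite -> reaction, product edges reverse
      p <- if (s[[mid2]] < 0) c(a, b) else c(b, a)
      edges <- c(edges, sprintf(
        paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" ',
               'stroke-width="%s"%s/>'),
        p[1], p[2], p[3], p[4],
        if (s[[mid2]] < 0) "#666666" else "#1f6fb4", sw, dash))
    }
  }

  met_nodes <- sprintf(
    '<circle cx="%s" cy="%s" r="6" fill="%s" stroke="#333333"/>',
    mp$x, mp$y,
    ifelse(model$metabolites$external[match(mp$id, model$metabolites$id)],
           "#f4c542", "#9ecae1"))
  rxn_nodes <- sprintf(
    '<rect x="%s" y="%s" width="8" height="8" fill="#de7065" stroke="#333333"/>',
    rp$x - 4, rp$y - 4)
  texts <- if (labels) {
    c(sprintf('<text x="%s" y="%s" font-size="9" dx="8">%s</text>',
              mp$x, mp$y, xml_escape(mp$id)),
      sprintf('<text x="%s" y="%s" font-size="8" dx="8" fill="#8c2d04">%s</text>',
              rp$x, rp$y, xml_escape(rp$id)))
  } else character(0)

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">\n'),
            width, height, width, height),
    sprintf('<title>%s</title>\n', xml_escape(model$id)),
    '<g id="edges">\n', paste(edges, collapse = "\n"), '\n</g>\n',
    '<g id="metabolites">\n', paste(met_nodes, collapse = "\n"), '\n</g>\n',
    '<g id="reactions">\n', paste(rxn_nodes, collapse = "\n"), '\n</g>\n',
    if (length(texts)) paste0('<g id="labels">\n',
                              paste(texts, collapse = "\n"), '\n</g>\n')
    else "",
    '</svg>\n')
  xml2::read_xml(doc)  # guarantee well-formedness
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(path)
}
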