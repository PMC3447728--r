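#' Generate a synthetic KEGG-like organism with known ground truth
#'
#' Emits syntactically valid KGML pathway documents plus a LIGAND-style
#' reaction table for a fully synthetic organism, together with the exact
#' model that drafting them should produce. This stands in for a KEGG
#' download so parsing and drafting can be tested offline against a known
#' answer. The network always contains an irreversible backbone path from a
#' designated substrate compound to a designated product compound, so FBA on
#' the draft is feasible once exchanges are added; backbone records are
#' never corrupted.
#'
#' `n_reactions` counts pathway entries including cross-map duplicates:
#' `round(overlap_fraction * n_reactions)` entries are repeats of a reaction
#' on a second map, so the distinct (and ground-truth) reaction count is
#' `n_reactions` minus the overlap count. `round(corrupt_fraction * distinct)`
#' non-backbone reaction records get polymer-style equations that the
#' drafting grammar must reject; the ground-truth model excludes them.
#'
#' @param seed Integer seed; the same seed reproduces byte-identical output.
#' @param n_pathways Number of KGML maps.
#' @param n_reactions Total pathway entries (including overlaps).
#' @param overlap_fraction Fraction of entries that are cross-map repeats.
#' @param corrupt_fraction Fraction of distinct records corrupted in the
#'   reaction table.
#' @return A list: `kgml` (named character vector, pathway id -> XML text),
#'   `reaction_table` (LIGAND flat-file text), `ground_truth` (the
#'   `metabolic_model` drafting must reproduce), and `annotations` (list
#'   with `substrate`, `product`, `backbone`, `corrupted`, `overlaps`,
#'   `orphans`, `pathway_of`).
#' @export
generate_fixture_organism <- function(seed, n_pathways = 4L,
                                      n_reactions = 60L,
                                      overlap_fraction = 0.1,
                                      corrupt_fraction = 0) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("overlap_fraction must be in [0, 1]")
  }
  if (corrupt_fraction < 0 || corrupt_fraction > 1) {
    abort("corrupt_fraction must be in [0, 1]")
  }
  n_overlap <- round(overlap_fraction * n_reactions)
  n_distinct <- n_reactions - n_overlap
  if (n_distinct < n_pathways || n_distinct < 3) {
    abort("too few distinct reactions for the requested pathways")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  org <- "syn"

  n_back <- max(3L, round(n_distinct * 0.25))
  back_cpds <- sprintf("C%05d", 10000 + seq_len(n_back + 1))
  n_extra <- ceiling(n_distinct * 0.8)
  extra_cpds <- sprintf("C%05d", 20000 + seq_len(n_extra))
  pool <- c(back_cpds, extra_cpds)

  rids <- sprintf("R%05d", seq_len(n_distinct))
  stoich <- vector("list", n_distinct)
  revsd <- logical(n_distinct)
  for (i in seq_len(n_back)) {
    stoich[[i]] <- stats::setNames(c(-1, 1), back_cpds[c(i, i + 1)])
    revsd[i] <- FALSE
  }
  for (i in seq(n_back + 1, n_distinct)) {
    ns <- sample(1:2, 1); np <- sample(1:2, 1)
    picks <- sample(pool, ns + np)
    coefs <- ifelse(stats::runif(ns + np) < 0.2, 2, 1)
    stoich[[i]] <- stats::setNames(c(-coefs[seq_len(ns)],
                                     coefs[ns + seq_len(np)]), picks)
    revsd[i] <- stats::runif(1) < 0.3
  }

  # pathway assignment: each pathway seeded with one reaction, rest random
  pathway_of <- integer(n_distinct)
  pathway_of[seq_len(n_pathways)] <- seq_len(n_pathways)
  if (n_distinct > n_pathways) {
    pathway_of[(n_pathways + 1):n_distinct] <-
      sample(n_pathways, n_distinct - n_pathways, replace = TRUE)
  }
  overlaps <- tibble(reaction_id = character(), pathway = integer())
  if (n_overlap > 0) {
    ov_ids <- sample(rids, n_overlap)
    ov_pw <- vapply(ov_ids, function(r) {
      home <- pathway_of[match(r, rids)]
      if (n_pathways == 1) home else sample(setdiff(seq_len(n_pathways), home), 1)
    }, integer(1))
    overlaps <- tibble(reaction_id = ov_ids, pathway = unname(ov_pw))
  }

  # corruption: non-backbone records only
  n_corrupt <- round(corrupt_fraction * n_distinct)
  corrupt_ids <- character(0)
  if (n_corrupt > 0) {
    eligible <- rids[-seq_len(n_back)]
    if (n_corrupt > length(eligible)) {
      abort("corrupt_fraction too high: would corrupt backbone reactions")
    }
    corrupt_ids <- sort(sample(eligible, n_corrupt))
  }

  eq_of <- function(i) {
    s <- stoich[[i]]
    term <- function(ids) {
      paste(ifelse(abs(s[ids]) == 1, ids,
                   paste(abs(s[ids]), ids)), collapse = " + ")
    }
    paste(term(names(s)[s < 0]), "<=>", term(names(s)[s > 0]))
  }
  equations <- vapply(seq_len(n_distinct), eq_of, character(1))
  equations[match(corrupt_ids, rids)] <-
    paste(pool[1], "+ n C99999 <=>", pool[2])

  table_text <- paste(vapply(seq_len(n_distinct), function(i) {
    paste0("ENTRY       ", rids[i], "                      Reaction\n",
           "NAME        synthetic reaction ", i, "\n",
           "EQUATION    ", equations[i], "\n///")
  }, character(1)), collapse = "\n")

  kgml_entry <- function(i, entry_id) {
    s <- stoich[[i]]
    subs <- paste(sprintf('    <substrate id="%d" name="cpd:%s"/>',
                          seq_along(names(s)[s < 0]), names(s)[s < 0]),
                  collapse = "\n")
    prods <- paste(sprintf('    <product id="%d" name="cpd:%s"/>',
                           seq_along(names(s)[s > 0]), names(s)[s > 0]),
                   collapse = "\n")
    sprintf(paste0('  <reaction id="%d" name="rn:%s" type="%s">\n%s\n%s\n',
                   '  </reaction>'),
            entry_id, rids[i],
            if (revsd[i]) "reversible" else "irreversible", subs, prods)
  }
  pw_ids <- sprintf("%s%05d", org, seq_len(n_pathways))
  kgml <- vapply(seq_len(n_pathways), function(p) {
    members <- which(pathway_of == p)
    extra <- match(overlaps$reaction_id[overlaps$pathway == p], rids)
    members <- c(members, extra)
    body <- paste(vapply(seq_along(members), function(k) {
      kgml_entry(members[k], k)
    }, character(1)), collapse = "\n")
    sprintf(paste0('<?xml version="1.0"?>\n',
                   '<pathway name="path:%s" org="%s" number="%05d" ',
                   'title="synthetic pathway %d">\n%s\n</pathway>\n'),
            pw_ids[p], org, p, p, body)
  }, character(1))
  names(kgml) <- pw_ids

  # ground truth: what assemble_draft must reproduce (corrupted excluded)
  inc <- which(!rids %in% corrupt_ids)
  ord <- inc[order(rids[inc])]
  gt_rxns <- tibble(
    id = rids[ord],
    name = paste("synthetic reaction", ord),
    stoichiometry = stoich[ord],
    reversible = revsd[ord],
    lower_bound = ifelse(revsd[ord], -FD_BIG, 0),
    upper_bound = FD_BIG,
    kind = "intracellular",
    ec_numbers = rep(list(character()), length(ord))
  )
  gt_mets <- sort(unique(unlist(lapply(stoich[ord], names))))
  ground_truth <- metabolic_model(
    id = paste0(org, "_draft"), organism = org,
    metabolites = tibble(id = gt_mets, name = gt_mets,
                         formula = NA_character_, external = FALSE),
    reactions = gt_rxns
  )
  ground_truth$notes$draft_report <-
    tibble(reaction_id = corrupt_ids,
           reason = rep("definition unparsable: unparsable term 'n C99999' (non-numeric coefficient or non-compound id)",
                        length(corrupt_ids)))

  # orphan (dead-end) bookkeeping, computed from the generator's own records
  produced <- consumed <- character(0)
  for (i in ord) {
    s <- stoich[[i]]
    if (revsd[i]) {
      produced <- c(produced, names(s)); consumed <- c(consumed, names(s))
    } else {
      produced <- c(produced, names(s)[s > 0])
      consumed <- c(consumed, names(s)[s < 0])
    }
  }
  orphans <- sort(gt_mets[!(gt_mets %in% produced) | !(gt_mets %in% consumed)])

  list(
    kgml = kgml,
    reaction_table = table_text,
    ground_truth = ground_truth,
    annotations = list(
      substrate = back_cpds[1], product = back_cpds[n_back + 1],
      backbone = rids[seq_len(n_back)],
      corrupted = corrupt_ids,
      overlaps = overlaps,
      orphans = orphans,
      pathway_of = stats::setNames(pw_ids[pathway_of], rids)
    )
  )
}

#' Compare two metabolic models for structural equality
#'
#' Order-insensitive equality over metabolites, reactions (ids, canonicalised
#' stoichiometries, reversibility, bounds, kinds) and the objective. Used by
#' the drafting round-trip and SBML round-trip checks.
#'
#' @param a,b `metabolic_model` objects.
#' @return `TRUE`/`FALSE`; on `FALSE` the reason is attached as attribute
#'   `"why"`.
#' @export
model_equal <- function(a, b) {
  no <- function(why) { out <- FALSE; attr(out, "why") <- why; out }
  ma <- arrange(a$metabolites, .data$id); mb <- arrange(b$metabolites, .data$id)
  if (!identical(ma$id, mb$id)) return(no("metabolite id sets differ"))
  if (!identical(ma$external, mb$external)) return(no("external flags differ"))
  ra <- arrange(a$reactions, .data$id); rb <- arrange(b$reactions, .data$id)
  if (!identical(ra$id, rb$id)) return(no("reaction id sets differ"))
  for (i in seq_len(nrow(ra))) {
    sa <- ra$stoichiometry[[i]]; sa <- sa[order(names(sa))]
    sb <- rb$stoichiometry[[i]]; sb <- sb[order(names(sb))]
    if (!isTRUE(all.equal(sa, sb, tolerance = 1e-12))) {
      return(no(paste0("stoichiometry differs for ", ra$id[i])))
    }
  }
  if (!identical(ra$reversible, rb$reversible)) {
    return(no("reversibility flags differ"))
  }
  if (!isTRUE(all.equal(ra$lower_bound, rb$lower_bound, tolerance = 1e-12)) ||
      !isTRUE(all.equal(ra$upper_bound, rb$upper_bound, tolerance = 1e-12))) {
    return(no("bounds differ"))
  }
  if (!identical(ra$kind, rb$kind)) return(no("reaction kinds differ"))
  oa <- a$objective; ob <- b$objective
  if (is.null(oa) != is.null(ob)) return(no("objective presence differs"))
  if (!is.null(oa)) {
    ca <- oa$coefficients[order(names(oa$coefficients))]
    cb <- ob$coefficients[order(names(ob$coefficients))]
    if (!isTRUE(all.equal(ca, cb, tolerance = 1e-12)) ||
        oa$direction != ob$direction) {
      return(no("objectives differ"))
    }
  }
  TRUE
}
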