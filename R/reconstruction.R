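#' Add an inflow (uptake) exchange reaction
#'
#' An inflow is an unbalanced source `∅ -> target` describing nutrient
#' transport from the medium into the network; its flux is the uptake rate.
#' The target may be any internal metabolite, so a lumped step like
#' "glucose -> G6P" can feed glucose-6-phosphate directly.
#'
#' @param model A `metabolic_model`.
#' @param target_metabolite Metabolite id receiving the inflow (created if
#'   absent).
#' @param reaction_id Id for the new exchange reaction.
#' @param upper_bound Maximal uptake rate (mmol/g DCW/h).
#' @param fixed If given, the flux is pinned: `lb = ub = fixed`.
#' @param name Optional display name.
#' @return The model with the inflow added.
#' @export
add_inflow <- function(model, target_metabolite, reaction_id,
                       upper_bound = FD_BIG, fixed = NULL,
                       name = NULL) {
  add_exchange(model, target_metabolite, reaction_id, +1, "inflow",
               upper_bound, fixed, name)
}

#' Add an outflow (secretion) exchange reaction
#'
#' Mirror of [add_inflow()]: an unbalanced sink `source -> ∅` whose flux is
#' the secretion rate of a product into the medium.
#'
#' @inheritParams add_inflow
#' @param source_metabolite Metabolite id drained by the outflow.
#' @return The model with the outflow added.
#' @export
add_outflow <- function(model, source_metabolite, reaction_id,
                        upper_bound = FD_BIG, fixed = NULL,
                        name = NULL) {
  add_exchange(model, source_metabolite, reaction_id, -1, "outflow",
               upper_bound, fixed, name)
}

add_exchange <- function(model, metabolite, reaction_id, sign, kind,
                         upper_bound, fixed, name) {
  if (reaction_id %in% model$reactions$id) {
    abort(paste0("reaction id already in model: ", reaction_id))
  }
  model <- ensure_metabolites(model, metabolite)
  lb <- 0; ub <- upper_bound
  if (!is.null(fixed)) { lb <- fixed; ub <- fixed }
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = reaction_id,
           name = name %||% reaction_id,
           stoichiometry = list(stats::setNames(sign, metabolite)),
           reversible = lb < 0,
           lower_bound = lb, upper_bound = ub,
           kind = kind, ec_numbers = list(character()))
  )
  validate_model(model)
  model
}

#' Add a reaction (heterologous pathway step or manual gap fill)
#'
#' Adds a user-authored reaction — typically a heterologous enzyme the
#' organism does not encode, or a manually identified gap-filling step.
#' Participant metabolites not yet in the model are registered automatically.
#'
#' @param model A `metabolic_model`.
#' @param id Fresh reaction id.
#' @param stoichiometry Named numeric vector, negative = consumed,
#'   positive = produced.
#' @param reversible Logical.
#' @param lower_bound,upper_bound Flux bounds; defaults follow the
#'   reversibility convention.
#' @param kind `"heterologous"` (default), `"gap_fill"` or
#'   `"intracellular"`.
#' @param name Optional display name.
#' @return The model with the reaction added.
#' @export
add_reaction <- function(model, id, stoichiometry, reversible = FALSE,
                         lower_bound = NULL, upper_bound = FD_BIG,
                         kind = "heterologous", name = NULL) {
  if (id %in% model$reactions$id) {
    abort(paste0("reaction id already in model: ", id))
  }
  if (!length(stoichiometry)) abort("empty stoichiometry")
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (!length(stoichiometry)) abort("empty stoichiometry")
  model <- ensure_metabolites(model, names(stoichiometry))
  lb <- lower_bound %||% if (reversible) -FD_BIG else 0
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = id, name = name %||% id,
           stoichiometry = list(stoichiometry),
           reversible = reversible,
           lower_bound = lb, upper_bound = upper_bound,
           kind = kind, ec_numbers = list(character()))
  )
  validate_model(model)
  model
}

#' Knock out reactions
#'
#' Simulates gene knockouts by pinning the named reactions' bounds to
#' `[0, 0]`. Reactions are retained (not deleted) so reports still show them
#' and the knockout can be reversed by restoring bounds.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Character vector of reaction ids.
#' @return The model with the knockouts applied.
#' @export
knockout <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("unknown reaction(s): ", paste(unknown, collapse = ", ")))
  }
  i <- match(reaction_ids, model$reactions$id)
  model$reactions$lower_bound[i] <- 0
  model$reactions$upper_bound[i] <- 0
  model
}

#' Modify a reaction's direction or participants
#'
#' Direction `"forward"` keeps the stored stoichiometry and forbids reverse
#' flux; `"backward"` negates the stored coefficients and makes the reaction
#' irreversible, so stored stoichiometry always reads left-to-right;
#' `"reversible"` reopens the lower bound. Participant edits replace
#' coefficients or (with `NA`) delete participants.
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @param new_direction Optional `"forward"`, `"backward"` or
#'   `"reversible"`.
#' @param participant_edits Optional named numeric vector:
#'   `metabolite id -> new coefficient`, `NA` deletes the participant.
#' @return The modified model.
#' @export
modify_reaction <- function(model, reaction_id, new_direction = NULL,
                            participant_edits = NULL) {
  i <- rxn_index(model, reaction_id)
  s <- model$reactions$stoichiometry[[i]]
  if (!is.null(participant_edits)) {
    for (mid in names(participant_edits)) {
      v <- participant_edits[[mid]]
      if (is.na(v) || v == 0) s <- s[setdiff(names(s), mid)] else s[mid] <- v
    }
    if (!any(s < 0) || !any(s > 0)) {
      abort("edit would leave the reaction without substrates or products")
    }
    model <- ensure_metabolites(model, names(s))
  }
  if (!is.null(new_direction)) {
    ub <- model$reactions$upper_bound[i]
    big <- max(FD_BIG, abs(ub))
    if (new_direction == "forward") {
      model$reactions$reversible[i] <- FALSE
      model$reactions$lower_bound[i] <- 0
    } else if (new_direction == "backward") {
      s <- -s
      model$reactions$reversible[i] <- FALSE
      model$reactions$lower_bound[i] <- 0
      model$reactions$upper_bound[i] <- big
    } else if (new_direction == "reversible") {
      model$reactions$reversible[i] <- TRUE
      model$reactions$lower_bound[i] <- -big
    } else {
      abort("new_direction must be forward, backward or reversible")
    }
  }
  model$reactions$stoichiometry[[i]] <- s
  validate_model(model)
  model
}

#' Define a biomass composition
#'
#' @param demands Named numeric vector: building-block metabolite id ->
#'   demand in mmol per g DCW (all >= 0, at least one > 0).
#' @param gam Growth-associated maintenance, mmol ATP per g DCW.
#' @param atp_id,adp_id,pi_id,h2o_id Energy-couple metabolite ids (defaults
#'   are KEGG compound ids).
#' @return A `biomass_composition` list for [set_biomass()].
#' @export
biomass_composition <- function(demands, gam = 0,
                                atp_id = "C00002", adp_id = "C00008",
                                pi_id = "C00009", h2o_id = "C00001") {
  if (!length(demands) || any(demands < 0)) {
    abort("demands must be a non-empty vector of non-negative values")
  }
  if (!is.finite(gam) || gam < 0) abort("gam must be finite and >= 0")
  structure(list(demands = demands[demands > 0], gam = gam,
                 atp_id = atp_id, adp_id = adp_id,
                 pi_id = pi_id, h2o_id = h2o_id),
            class = "biomass_composition")
}

#' Install a biomass reaction from a composition
#'
#' Creates (or replaces) a biomass pseudo-reaction that consumes each
#' building block in its measured proportion (mmol per g DCW) plus `gam`
#' ATP + H2O hydrolysed to ADP + Pi, and produces one unit of a synthetic
#' `biomass` species drained by a paired outflow. Because demands are per
#' gram dry cell weight, the biomass flux is the specific growth rate in
#' 1/h.
#'
#' @param model A `metabolic_model`.
#' @param composition A [biomass_composition()].
#' @param reaction_id Id of the biomass reaction.
#' @param biomass_species Id of the synthetic biomass metabolite.
#' @return The model with biomass reaction and drain installed and the
#'   composition recorded in `model$notes`.
#' @export
set_biomass <- function(model, composition, reaction_id = "BIOMASS",
                        biomass_species = "biomass") {
  stopifnot(inherits(composition, "biomass_composition"))
  missing <- setdiff(names(composition$demands), model$metabolites$id)
  if (length(missing)) {
    abort(paste0("biomass demand metabolite(s) not in model: ",
                 paste(missing, collapse = ", ")))
  }
  s <- -composition$demands
  if (composition$gam > 0) {
    ids <- c(composition$atp_id, composition$h2o_id,
             composition$adp_id, composition$pi_id)
    miss <- setdiff(ids, model$metabolites$id)
    if (length(miss)) {
      abort(paste0("energy-couple metabolite(s) not in model: ",
                   paste(miss, collapse = ", ")))
    }
    gam_terms <- stats::setNames(
      c(-composition$gam, -composition$gam,
        composition$gam, composition$gam), ids)
    # merge in case a demand metabolite coincides with the couple
    for (mid in names(gam_terms)) {
      s[mid] <- (if (mid %in% names(s)) s[[mid]] else 0) + gam_terms[[mid]]
    }
    s <- s[s != 0]
  }
  model <- ensure_metabolites(model, biomass_species)
  s[biomass_species] <- 1
  drain_id <- paste0(reaction_id, "_drain")
  keep <- !model$reactions$id %in% c(reaction_id, drain_id)
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = reaction_id, name = "biomass production",
           stoichiometry = list(s), reversible = FALSE,
           lower_bound = 0, upper_bound = FD_BIG,
           kind = "biomass", ec_numbers = list(character())),
    tibble(id = drain_id, name = "biomass drain",
           stoichiometry = list(stats::setNames(-1, biomass_species)),
           reversible = FALSE, lower_bound = 0, upper_bound = FD_BIG,
           kind = "outflow", ec_numbers = list(character()))
  )
  model$notes$biomass_composition <- composition
  validate_model(model)
  model
}

#' Install a non-growth-associated maintenance (NGAM) reaction
#'
#' Adds (or replaces) the constant ATP hydrolysis `ATP + H2O -> ADP + Pi`
#' with flux pinned at `ngam` mmol ATP/g DCW/h, representing cellular upkeep
#' independent of growth.
#'
#' @param model A `metabolic_model`.
#' @param ngam Maintenance flux, mmol ATP/g DCW/h (>= 0).
#' @param reaction_id Id of the maintenance reaction.
#' @param atp_id,adp_id,pi_id,h2o_id Energy-couple metabolite ids.
#' @return The model with maintenance installed.
#' @export
set_maintenance <- function(model, ngam, reaction_id = "ATPM",
                            atp_id = "C00002", adp_id = "C00008",
                            pi_id = "C00009", h2o_id = "C00001") {
  if (!is.finite(ngam) || ngam < 0) abort("ngam must be finite and >= 0")
  ids <- c(atp_id, adp_id, pi_id, h2o_id)
  miss <- setdiff(ids, model$metabolites$id)
  if (length(miss)) {
    abort(paste0("energy-couple metabolite(s) not in model: ",
                 paste(miss, collapse = ", ")))
  }
  s <- stats::setNames(c(-1, -1, 1, 1), c(atp_id, h2o_id, adp_id, pi_id))
  model$reactions <- model$reactions[model$reactions$id != reaction_id, ,
                                     drop = FALSE]
  model$reactions <- bind_rows(
    model$reactions,
    tibble(id = reaction_id, name = "non-growth-associated maintenance",
           stoichiometry = list(s), reversible = FALSE,
           lower_bound = ngam, upper_bound = ngam,
           kind = "maintenance", ec_numbers = list(character()))
  )
  validate_model(model)
  model
}

# --- edit scripts -----------------------------------------------------------

edit_directives <- c("add_inflow", "add_outflow", "add_reaction", "knockout",
                     "modify_reaction", "set_bounds", "set_biomass",
                     "set_maintenance", "set_objective", "fix_flux")

#' Apply an ordered, atomic edit script to a model
#'
#' An edit script is an ordered list of directives (the YAML on-disk form is
#' read by [read_edit_script()]). Each directive is a named list with an
#' `op` field naming one of the reconstruction operations and the remaining
#' fields as that operation's arguments. The script is applied in order and
#' atomically: if any directive fails, the error names its position and the
#' input model is returned unchanged (no partial edits escape).
#'
#' @param model A `metabolic_model`.
#' @param script List of directives, or a file path to a YAML script.
#' @return The edited model.
#' @export
apply_edit_script <- function(model, script) {
  if (is.character(script) && length(script) == 1) {
    script <- read_edit_script(script)
  }
  out <- model
  for (k in seq_along(script)) {
    d <- script[[k]]
    op <- d$op
    if (is.null(op) || !op %in% edit_directives) {
      abort(paste0("edit script directive ", k, ": unknown op '",
                   op %||% "<missing>", "'"))
    }
    args <- d[setdiff(names(d), "op")]
    if (op == "add_reaction" && !is.null(args$stoichiometry)) {
      args$stoichiometry <- unlist(args$stoichiometry)
    }
    if (op == "set_biomass" && !inherits(args$composition,
                                         "biomass_composition")) {
      cargs <- args$composition
      cargs$demands <- unlist(cargs$demands)
      args$composition <- do.call(biomass_composition, cargs)
    }
    if (op == "set_objective" && !is.null(args$coefficients) &&
        is.list(args$coefficients)) {
      args$coefficients <- unlist(args$coefficients)
    }
    out <- tryCatch(
      do.call(op, c(list(out), args)),
      error = function(e) {
        abort(paste0("edit script failed at directive ", k, " (", op, "): ",
                     conditionMessage(e)))
      }
    )
  }
  out
}

#' Read a YAML edit script
#'
#' The on-disk format is a single YAML document with a top-level `edits:`
#' sequence; each element is a mapping with an `op` key and the operation's
#' arguments, e.g.
#' ```yaml
#' edits:
#'   - op: add_inflow
#'     target_metabolite: C00092
#'     reaction_id: glc_in
#'     fixed: 11.0
#'   - op: set_objective
#'     coefficients: {BIOMASS: 1}
#' ```
#'
#' @param path YAML file path.
#' @return A list of directives for [apply_edit_script()].
#' @export
read_edit_script <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$edits)) abort("edit script must have a top-level 'edits:' list")
  doc$edits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
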