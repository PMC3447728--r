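#' @importFrom rlang .data abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# conventional "effectively unbounded" flux cap, mmol/g DCW/h
FD_BIG <- 1000

#' Construct a metabolic model
#'
#' A `metabolic_model` is the package's central container: two tibbles (one
#' row per metabolite, one per reaction) plus an objective specification.
#' Stoichiometry is stored per reaction as a named numeric vector with the
#' sign convention negative = consumed, positive = produced. Reversibility is
#' mirrored in the bounds: a reversible reaction defaults to
#' `[-big, big]`, an irreversible one to `[0, big]`.
#'
#' @param id Model identifier.
#' @param organism Organism code or free text (e.g. a KEGG 3-letter code).
#' @param metabolites Tibble with columns `id`, `name`, `formula`,
#'   `external`; missing columns are filled with defaults.
#' @param reactions Tibble with columns `id`, `name`, `stoichiometry`
#'   (list-column of named numeric vectors), `reversible`, `lower_bound`,
#'   `upper_bound`, `kind`, `ec_numbers` (list-column).
#' @param objective List with `coefficients` (named numeric, names are
#'   reaction ids) and `direction` (`"maximize"` or `"minimize"`), or `NULL`.
#' @param big Flux cap used to fill missing bounds (mmol/g DCW/h).
#'
#' @return A validated `metabolic_model` object.
#' @export
metabolic_model <- function(id, organism = NA_character_,
                            metabolites = NULL, reactions = NULL,
                            objective = NULL, big = FD_BIG) {
  metabolites <- complete_metabolites(metabolites)
  reactions <- complete_reactions(reactions, big = big)
  m <- structure(
    list(id = id, organism = organism, metabolites = metabolites,
         reactions = reactions, objective = objective,
         notes = list()),
    class = "metabolic_model"
  )
  validate_model(m)
}

complete_metabolites <- function(metabolites) {
  if (is.null(metabolites) || nrow(as_tibble(metabolites)) == 0) {
    return(tibble(id = character(), name = character(),
                  formula = character(), external = logical()))
  }
  metabolites <- as_tibble(metabolites)
  has <- names(metabolites)
  if (!"name" %in% has) metabolites$name <- metabolites$id
  if (!"formula" %in% has) metabolites$formula <- NA_character_
  if (!"external" %in% has) metabolites$external <- FALSE
  metabolites[c("id", "name", "formula", "external")]
}

complete_reactions <- function(reactions, big = FD_BIG) {
  if (is.null(reactions) || nrow(as_tibble(reactions)) == 0) {
    return(tibble(id = character(), name = character(),
                  stoichiometry = list(), reversible = logical(),
                  lower_bound = double(), upper_bound = double(),
                  kind = character(), ec_numbers = list()))
  }
  reactions <- as_tibble(reactions)
  has <- names(reactions)
  if (!"name" %in% has) reactions$name <- reactions$id
  if (!"reversible" %in% has) reactions$reversible <- FALSE
  if (!"kind" %in% has) reactions$kind <- "intracellular"
  if (!"lower_bound" %in% has) {
    reactions$lower_bound <- ifelse(reactions$reversible, -big, 0)
  }
  if (!"upper_bound" %in% has) reactions$upper_bound <- big
  if (!"ec_numbers" %in% has) {
    reactions$ec_numbers <- rep(list(character()), nrow(reactions))
  }
  reactions[c("id", "name", "stoichiometry", "reversible",
              "lower_bound", "upper_bound", "kind", "ec_numbers")]
}

reaction_kinds <- c("intracellular", "inflow", "outflow", "biomass",
                    "maintenance", "gap_fill", "heterologous")

#' Validate a metabolic model's structural invariants
#'
#' Checks id uniqueness, stoichiometric references, sign/bound consistency
#' and objective references; errors with an informative message on the first
#' violation, otherwise returns the model invisibly so it can be piped.
#'
#' @param model A `metabolic_model`.
#' @return The model, invisibly.
#' @export
validate_model <- function(model) {
  met <- model$metabolites
  rxn <- model$reactions
  if (anyDuplicated(met$id)) {
    abort(paste0("duplicate metabolite id: ",
                 met$id[duplicated(met$id)][1]))
  }
  if (anyDuplicated(rxn$id)) {
    abort(paste0("duplicate reaction id: ", rxn$id[duplicated(rxn$id)][1]))
  }
  if (any(!nzchar(met$id))) abort("empty metabolite id")
  if (any(!rxn$kind %in% reaction_kinds)) {
    abort(paste0("unknown reaction kind: ",
                 setdiff(rxn$kind, reaction_kinds)[1]))
  }
  for (i in seq_len(nrow(rxn))) {
    s <- rxn$stoichiometry[[i]]
    if (!length(s)) abort(paste0("reaction ", rxn$id[i], ": empty stoichiometry"))
    if (any(s == 0)) abort(paste0("reaction ", rxn$id[i], ": zero coefficient stored"))
    missing <- setdiff(names(s), met$id)
    if (length(missing)) {
      abort(paste0("reaction ", rxn$id[i],
                   " references unknown metabolite: ",
                   paste(missing, collapse = ", ")))
    }
  }
  if (any(!rxn$reversible & rxn$lower_bound < 0)) {
    bad <- rxn$id[!rxn$reversible & rxn$lower_bound < 0][1]
    abort(paste0("irreversible reaction ", bad, " has negative lower bound"))
  }
  if (any(rxn$lower_bound > rxn$upper_bound)) {
    bad <- rxn$id[rxn$lower_bound > rxn$upper_bound][1]
    abort(paste0("reaction ", bad, ": lower bound exceeds upper bound"))
  }
  if (!is.null(model$objective)) {
    co <- model$objective$coefficients
    if (!length(co) || all(co == 0)) abort("objective has no nonzero coefficient")
    missing <- setdiff(names(co), rxn$id)
    if (length(missing)) {
      abort(paste0("objective references unknown reaction: ",
                   paste(missing, collapse = ", ")))
    }
    if (!model$objective$direction %in% c("maximize", "minimize")) {
      abort("objective direction must be maximize or minimize")
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  n_int <- sum(!x$metabolites$external)
  cat("<metabolic_model> ", x$id,
      if (!is.na(x$organism)) paste0(" [", x$organism, "]"), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", n_int, " internal)\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions), "\n", sep = "")
  kinds <- table(x$reactions$kind)
  if (length(kinds)) {
    cat("    ", paste(names(kinds), kinds, sep = ": ", collapse = ", "),
        "\n", sep = "")
  }
  if (!is.null(x$objective)) {
    cat("  objective:   ", x$objective$direction, " ",
        paste(sprintf("%+g %s", x$objective$coefficients,
                      names(x$objective$coefficients)), collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Build the stoichiometric matrix S
#'
#' Rows are internal metabolites, columns are reactions, both in sorted-id
#' order so repeated calls are bit-identical. External (boundary) metabolites
#' are excluded: their mass balance is not enforced, matching the semantics
#' of inflow/outflow exchange with the medium.
#'
#' @param model A valid `metabolic_model`.
#' @return A sparse `Matrix::dgCMatrix` with metabolite ids as rownames and
#'   reaction ids as colnames.
#' @export
build_stoichiometric_matrix <- function(model) {
  validate_model(model)
  mets <- sort(model$metabolites$id[!model$metabolites$external])
  rxns <- sort(model$reactions$id)
  ord <- match(rxns, model$reactions$id)
  triplets <- purrr::map2_dfr(
    model$reactions$stoichiometry[ord], seq_along(rxns),
    function(s, j) tibble(met = names(s), j = j, coef = unname(s))
  )
  triplets <- triplets[triplets$met %in% mets, , drop = FALSE]
  S <- Matrix::sparseMatrix(
    i = match(triplets$met, mets), j = triplets$j, x = triplets$coef,
    dims = c(length(mets), length(rxns)), dimnames = list(mets, rxns)
  )
  S
}

#' Find dead-end metabolites
#'
#' An internal metabolite is a dead end when it is only ever produced or only
#' ever consumed; such metabolites flag gaps in a draft network. A reversible
#' reaction counts as both a producer and a consumer of every participant.
#'
#' @param model A `metabolic_model`.
#' @return Character vector of dead-end metabolite ids (sorted).
#' @export
find_dead_end_metabolites <- function(model) {
  internal <- model$metabolites$id[!model$metabolites$external]
  produced <- consumed <- character()
  for (i in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoichiometry[[i]]
    rev <- model$reactions$reversible[i]
    if (rev) {
      produced <- c(produced, names(s))
      consumed <- c(consumed, names(s))
    } else {
      produced <- c(produced, names(s)[s > 0])
      consumed <- c(consumed, names(s)[s < 0])
    }
  }
  touched <- internal[internal %in% c(produced, consumed)]
  sort(touched[!(touched %in% produced) | !(touched %in% consumed)])
}

# --- mass balance -----------------------------------------------------------

# Parse a plain elemental formula ("C6H12O6", "H3PO4") into element counts.
# Anything outside the strict element-count grammar (repeat units like
# "(C5H8O4)n", R-groups, "*") returns NULL: the caller reports "unchecked"
# rather than guessing.
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  if (grepl("[^A-Za-z0-9]", formula)) return(NULL)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) return(NULL)
  el <- sub("[0-9]*$", "", toks)
  ct <- as.numeric(sub("^[A-Z][a-z]?", "", toks))
  ct[is.na(ct)] <- 1
  tapply(ct, el, sum)
}

#' Check elemental mass balance of reactions
#'
#' For each reaction, sums coefficient times element count over all
#' participants using the metabolite `formula` column. Reactions with any
#' participant lacking a parsable formula are reported `"unchecked"` —
#' exchange, biomass and maintenance pseudo-reactions are intrinsically
#' unbalanced and are reported as such, not hidden.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Optional subset of reaction ids.
#' @return A tibble with columns `reaction_id`, `status` (`"balanced"`,
#'   `"unbalanced"`, `"unchecked"`) and `deltas` (list-column of named
#'   per-element imbalances, NULL when unchecked).
#' @export
check_mass_balance <- function(model, reaction_ids = NULL) {
  rxn <- model$reactions
  if (!is.null(reaction_ids)) {
    unknown <- setdiff(reaction_ids, rxn$id)
    if (length(unknown)) abort(paste0("unknown reaction: ", unknown[1]))
    rxn <- rxn[rxn$id %in% reaction_ids, , drop = FALSE]
  }
  formulas <- stats::setNames(model$metabolites$formula, model$metabolites$id)
  out <- purrr::map(rxn$stoichiometry, function(s) {
    parsed <- lapply(formulas[names(s)], parse_formula)
    if (any(vapply(parsed, is.null, logical(1)))) {
      return(list(status = "unchecked", deltas = NULL))
    }
    all_el <- sort(unique(unlist(lapply(parsed, names))))
    delta <- stats::setNames(numeric(length(all_el)), all_el)
    for (i in seq_along(s)) {
      p <- parsed[[i]]
      delta[names(p)] <- delta[names(p)] + s[[i]] * p
    }
    list(status = if (all(abs(delta) < 1e-9)) "balanced" else "unbalanced",
         deltas = delta)
  })
  tibble(
    reaction_id = rxn$id,
    status = vapply(out, `[[`, character(1), "status"),
    deltas = lapply(out, `[[`, "deltas")
  )
}

# --- small accessors used across modules ------------------------------------

rxn_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) abort(paste0("unknown reaction: ", reaction_id))
  i
}

# register metabolites that are not yet in the model
ensure_metabolites <- function(model, ids, external = FALSE) {
  new <- setdiff(ids, model$metabolites$id)
  if (length(new)) {
    model$metabolites <- bind_rows(
      model$metabolites,
      tibble(id = new, name = new, formula = NA_character_,
             external = external)
    )
  }
  model
}

#' Set the optimization objective of a model
#'
#' @param model A `metabolic_model`.
#' @param coefficients Named numeric vector of objective coefficients
#'   (names are reaction ids), or a single reaction id string as shorthand
#'   for coefficient 1 on that reaction.
#' @param direction `"maximize"` (default) or `"minimize"`.
#' @return The model with its objective replaced.
#' @export
set_objective <- function(model, coefficients, direction = "maximize") {
  if (is.character(coefficients) && length(coefficients) == 1 &&
      is.null(names(coefficients))) {
    coefficients <- stats::setNames(1, coefficients)
  }
  model$objective <- list(coefficients = coefficients, direction = direction)
  validate_model(model)
  model
}

#' Set flux bounds on a reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @param lower,upper New bounds; `NULL` leaves a bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, reaction_id, lower = NULL, upper = NULL) {
  i <- rxn_index(model, reaction_id)
  if (!is.null(lower)) model$reactions$lower_bound[i] <- lower
  if (!is.null(upper)) model$reactions$upper_bound[i] <- upper
  if (model$reactions$lower_bound[i] < 0) model$reactions$reversible[i] <- TRUE
  validate_model(model)
  model
}
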