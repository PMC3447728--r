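#' Solve a flux balance analysis problem
#'
#' Formulates the steady-state constraint `S v = 0` over internal metabolites
#' with box bounds `lb <= v <= ub` and optimizes the linear objective with
#' the package's bounded-variable simplex ([lp_solve()]). Flux units are
#' mmol/g DCW/h; a biomass pseudo-reaction carries the specific growth rate
#' in 1/h.
#'
#' @param model A valid `metabolic_model` with an objective (or one supplied
#'   here).
#' @param objective Optional objective overriding `model$objective`: a named
#'   coefficient vector or single reaction id (see [set_objective()]).
#' @param direction Direction when `objective` is given as an id/vector.
#' @return A `flux_distribution` object: fields `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value`, and `fluxes` (named
#'   numeric over all reactions). Use [generics::tidy()] for a per-reaction
#'   tibble and [generics::glance()] for a one-row summary.
#' @export
solve_fba <- function(model, objective = NULL, direction = "maximize") {
  if (!is.null(objective)) {
    model <- set_objective(model, objective, direction)
  }
  if (is.null(model$objective)) {
    abort("no objective set; use set_objective() or pass `objective`")
  }
  validate_model(model)
  S <- build_stoichiometric_matrix(model)
  rxns <- colnames(S)
  ord <- match(rxns, model$reactions$id)
  lb <- model$reactions$lower_bound[ord]
  ub <- model$reactions$upper_bound[ord]
  co <- stats::setNames(numeric(length(rxns)), rxns)
  co[names(model$objective$coefficients)] <- model$objective$coefficients
  res <- lp_solve(unname(co), S, rep(0, nrow(S)), lb, ub,
                  maximize = model$objective$direction == "maximize")
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$x, rxns)[model$reactions$id]
  } else {
    stats::setNames(rep(NA_real_, nrow(model$reactions)),
                    model$reactions$id)
  }
  structure(
    list(status = res$status,
         objective_value = if (res$status == "optimal") res$objective else NA_real_,
         fluxes = fluxes,
         direction = model$objective$direction,
         objective = model$objective$coefficients,
         model_id = model$id),
    class = "flux_distribution"
  )
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> model ", x$model_id, ": ", x$status, sep = "")
  if (x$status == "optimal") {
    cat(", ", x$direction, "d objective = ",
        format(x$objective_value, digits = 7), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @rdname solve_fba
#' @param x A `flux_distribution`.
#' @param model Optional originating model; adds bounds/kind columns.
#' @param ... Unused.
#' @export
tidy.flux_distribution <- function(x, model = NULL, ...) {
  out <- tibble(reaction_id = names(x$fluxes), flux = unname(x$fluxes))
  if (!is.null(model)) {
    out <- left_join(
      out,
      model$reactions[c("id", "name", "lower_bound", "upper_bound", "kind")],
      by = c(reaction_id = "id")
    )
  }
  out
}

#' @rdname solve_fba
#' @export
glance.flux_distribution <- function(x, ...) {
  tibble(status = x$status, objective_value = x$objective_value,
         direction = x$direction, n_reactions = length(x$fluxes))
}

#' Fix a reaction's flux to an exact value
#'
#' Sets lower and upper bound to `value`, the standard way of imposing a
#' measured uptake or secretion rate before FBA.
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @param value Flux value (mmol/g DCW/h). Negative values are rejected for
#'   irreversible reactions.
#' @return The modified model.
#' @export
fix_flux <- function(model, reaction_id, value) {
  i <- rxn_index(model, reaction_id)
  if (value < 0 && !model$reactions$reversible[i]) {
    abort(paste0("cannot fix irreversible reaction ", reaction_id,
                 " at negative flux ", value))
  }
  model$reactions$lower_bound[i] <- value
  model$reactions$upper_bound[i] <- value
  validate_model(model)
  model
}

#' Solve under temporary bounds, leaving the model untouched
#'
#' Convenience for scenario analysis: apply a set of temporary bound
#' overrides, solve, and report. The input model is never modified.
#'
#' @param model A `metabolic_model`.
#' @param fixes Named list: `reaction id -> c(lb, ub)` (or a single number to
#'   fix the flux exactly).
#' @param objective,direction Optional objective override as in [solve_fba()].
#' @return A `flux_distribution` for the constrained scenario.
#' @export
constrain_and_resolve <- function(model, fixes = list(), objective = NULL,
                                  direction = "maximize") {
  scenario <- model
  for (rid in names(fixes)) {
    v <- fixes[[rid]]
    if (length(v) == 1) v <- c(v, v)
    i <- rxn_index(scenario, rid)
    scenario$reactions$lower_bound[i] <- v[1]
    scenario$reactions$upper_bound[i] <- v[2]
    if (v[1] < 0) scenario$reactions$reversible[i] <- TRUE
  }
  solve_fba(scenario, objective = objective, direction = direction)
}

# --- growth-associated maintenance -----------------------------------------

#' Set the growth-associated maintenance of a biomass reaction
#'
#' Replaces the GAM energy terms of the biomass reaction: `gam` mmol ATP
#' (plus water) hydrolysed to ADP and phosphate per g DCW formed. Non-GAM
#' ATP demands belong in the building-block synthesis reactions, so the
#' biomass reaction's ATP coefficient equals the GAM — which is also how
#' [fit_gam()] varies it.
#'
#' @param model A `metabolic_model` with a biomass reaction.
#' @param gam GAM in mmol ATP/g DCW (>= 0).
#' @param biomass_id Biomass reaction id; defaults to the first objective
#'   reaction.
#' @inheritParams fit_gam
#' @return The model with the biomass energy terms replaced.
#' @export
apply_gam <- function(model, gam, biomass_id = NULL,
                      atp_id = "C00002", adp_id = "C00008",
                      pi_id = "C00009", h2o_id = "C00001") {
  if (!is.finite(gam) || gam < 0) abort("gam must be finite and >= 0")
  if (is.null(biomass_id)) biomass_id <- names(model$objective$coefficients)[1]
  m <- set_gam(model, gam, biomass_id, atp_id, adp_id, pi_id, h2o_id)
  validate_model(m)
  m
}

# Replace the GAM energy terms of the biomass reaction: gam mmol ATP (+H2O)
# consumed and gam ADP (+Pi) produced per g DCW formed. Non-GAM energy
# demands belong in the building-block syntheses, so the biomass reaction's
# ATP coefficient is the GAM itself.
set_gam <- function(model, gam, biomass_id,
                    atp_id = "C00002", adp_id = "C00008",
                    pi_id = "C00009", h2o_id = "C00001") {
  i <- rxn_index(model, biomass_id)
  s <- model$reactions$stoichiometry[[i]]
  ids <- c(atp_id, h2o_id, adp_id, pi_id)
  s <- s[setdiff(names(s), ids)]
  if (gam > 0) {
    missing <- setdiff(ids, model$metabolites$id)
    if (length(missing)) {
      abort(paste0("energy-couple metabolite not in model: ",
                   paste(missing, collapse = ", ")))
    }
    add <- stats::setNames(c(-gam, -gam, gam, gam), ids)
    s <- c(s, add)
  }
  model$reactions$stoichiometry[[i]] <- s
  model
}

#' Fit the growth-associated maintenance (GAM) to a measured growth rate
#'
#' GAM is the ATP cost (mmol ATP per g DCW) embedded in the biomass
#' reaction; raising it diverts substrate from biomass to energy, so the FBA
#' growth rate is monotone non-increasing in GAM. This routine scans that
#' relationship and bisects to the GAM whose predicted growth matches a
#' measured rate, mirroring the usual calibration of draft models against a
#' chemostat growth measurement (substrate uptake must already be fixed on
#' the model).
#'
#' @param model A `metabolic_model` whose objective maximizes the biomass
#'   reaction.
#' @param target_growth Measured specific growth rate (1/h).
#' @param gam_range Bracket `c(low, high)` in mmol ATP/g DCW.
#' @param tolerance Convergence tolerance on growth (1/h).
#' @param biomass_id Biomass reaction id; defaults to the first objective
#'   reaction.
#' @param atp_id,adp_id,pi_id,h2o_id Metabolite ids of the energy couple
#'   (defaults are the KEGG compound ids for ATP/ADP/orthophosphate/water).
#' @param max_iter Bisection iteration cap.
#' @param n_curve Number of GAM values sampled across the bracket for the
#'   returned growth-vs-GAM curve.
#' @return A `gam_fit` object: `gam` (fitted value), `growth` (growth at the
#'   fit), `target_growth`, and `curve` (tibble of sampled `(gam, growth)`).
#'   `tidy()` returns the curve; `glance()` the fit summary; `autoplot()`
#'   draws the curve with the fitted point marked.
#' @export
fit_gam <- function(model, target_growth, gam_range = c(0, 1000),
                    tolerance = 1e-4, biomass_id = NULL,
                    atp_id = "C00002", adp_id = "C00008",
                    pi_id = "C00009", h2o_id = "C00001",
                    max_iter = 60L, n_curve = 9L) {
  if (is.null(biomass_id)) biomass_id <- names(model$objective$coefficients)[1]
  growth_at <- function(gam) {
    m <- set_gam(model, gam, biomass_id, atp_id, adp_id, pi_id, h2o_id)
    sol <- solve_fba(m)
    if (sol$status != "optimal") {
      abort(paste0("FBA not optimal (", sol$status, ") at GAM = ", gam))
    }
    sol$objective_value
  }
  lo <- gam_range[1]; hi <- gam_range[2]
  g_lo <- growth_at(lo); g_hi <- growth_at(hi)
  if (target_growth > g_lo + tolerance || target_growth < g_hi - tolerance) {
    abort(sprintf(
      "target growth %.4g outside achievable range [%.4g, %.4g] over GAM bracket",
      target_growth, g_hi, g_lo))
  }
  curve <- tibble(gam = seq(lo, hi, length.out = n_curve))
  curve$growth <- vapply(curve$gam, growth_at, numeric(1))
  gam <- lo; g <- g_lo
  if (abs(g_hi - target_growth) <= tolerance) { gam <- hi; g <- g_hi }
  if (abs(g_lo - target_growth) > tolerance &&
      abs(g_hi - target_growth) > tolerance) {
    for (it in seq_len(max_iter)) {
      gam <- (lo + hi) / 2
      g <- growth_at(gam)
      if (abs(g - target_growth) <= tolerance) break
      if (g > target_growth) lo <- gam else hi <- gam
    }
  }
  structure(
    list(gam = gam, growth = g, target_growth = target_growth,
         tolerance = tolerance, curve = curve, biomass_id = biomass_id),
    class = "gam_fit"
  )
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("<gam_fit> GAM = ", format(x$gam, digits = 6),
      " mmol ATP/g DCW  (growth ", format(x$growth, digits = 4),
      " vs target ", format(x$target_growth, digits = 4), " 1/h)\n", sep = "")
  invisible(x)
}

#' @rdname fit_gam
#' @param x A `gam_fit`.
#' @param ... Unused.
#' @export
tidy.gam_fit <- function(x, ...) x$curve

#' @rdname fit_gam
#' @export
glance.gam_fit <- function(x, ...) {
  tibble(gam = x$gam, growth = x$growth, target_growth = x$target_growth,
         residual = x$growth - x$target_growth)
}

#' @rdname fit_gam
#' @param object A `gam_fit`.
#' @export
autoplot.gam_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$gam, .data$growth)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$target_growth, linetype = 2) +
    ggplot2::geom_point(data = tibble(gam = object$gam, growth = object$growth),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "GAM (mmol ATP/g DCW)",
                  y = expression(growth~rate~(h^-1)))
}

# --- production envelope ----------------------------------------------------

#' Compute a growth-versus-product trade-off curve
#'
#' For a uniform grid of growth rates from 0 up to the unconstrained FBA
#' maximum, fixes the biomass flux at each grid value and maximizes the
#' target reaction's flux — the classic production envelope showing how much
#' product the network can deliver at each growth rate.
#'
#' @param model A `metabolic_model` with a biomass-maximizing objective.
#' @param target_reaction Reaction id whose flux is maximized (typically a
#'   product outflow).
#' @param n_points Number of grid points.
#' @param biomass_id Biomass reaction id; defaults to the first objective
#'   reaction.
#' @return A `tradeoff_curve` object wrapping a tibble with columns
#'   `growth_rate` (1/h, strictly increasing) and `optimal_flux`
#'   (mmol/g DCW/h). `tidy()` extracts the tibble; `autoplot()` plots it.
#' @export
production_envelope <- function(model, target_reaction, n_points = 20L,
                                biomass_id = NULL) {
  rxn_index(model, target_reaction)
  if (is.null(biomass_id)) biomass_id <- names(model$objective$coefficients)[1]
  base <- solve_fba(model)
  if (base$status != "optimal") {
    abort(paste0("model is not solvable (", base$status,
                 "); cannot compute envelope"))
  }
  mu_max <- base$objective_value
  grid <- seq(0, mu_max, length.out = n_points)
  flux <- vapply(grid, function(mu) {
    sol <- constrain_and_resolve(
      model, fixes = stats::setNames(list(c(mu, mu)), biomass_id),
      objective = target_reaction, direction = "maximize")
    if (sol$status != "optimal") NA_real_ else sol$objective_value
  }, numeric(1))
  structure(
    list(points = tibble(growth_rate = grid, optimal_flux = flux),
         target = target_reaction, mu_max = mu_max),
    class = "tradeoff_curve"
  )
}

#' @export
print.tradeoff_curve <- function(x, ...) {
  cat("<tradeoff_curve> target ", x$target, ", ",
      nrow(x$points), " growth points up to ",
      format(x$mu_max, digits = 4), " 1/h\n", sep = "")
  invisible(x)
}

#' @rdname production_envelope
#' @param x A `tradeoff_curve`.
#' @param ... Unused.
#' @export
tidy.tradeoff_curve <- function(x, ...) x$points

#' @rdname production_envelope
#' @param object A `tradeoff_curve`.
#' @export
autoplot.tradeoff_curve <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(.data$growth_rate, .data$optimal_flux)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(growth~rate~(h^-1)),
                  y = paste0("max ", object$target, " flux (mmol/g DCW/h)"))
}
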