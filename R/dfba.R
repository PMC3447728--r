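#' Specify a dynamic FBA time course
#'
#' Dynamic FBA by the static optimization approach splits the fermentation
#' time course into intervals; each interval is solved as a conventional
#' steady-state FBA ("mini-FBA") under time-dependent exchange bounds, and
#' biomass and tracked substrate pools are integrated between intervals.
#' Bounds can come from measured piecewise-constant profiles or from Monod
#' kinetics on a tracked substrate.
#'
#' Units: biomass g DCW/L, substrate concentrations mmol/L, fluxes
#' mmol/g DCW/h — so `dS/dt = -v * X` is dimensionally consistent.
#'
#' @param t_end End time (h).
#' @param dt Interval width (h), > 0.
#' @param initial_biomass Starting biomass (g DCW/L), > 0.
#' @param t0 Start time (h), default 0.
#' @param profiles Optional piecewise-constant bound table: tibble/data
#'   frame with columns `time`, `reaction_id`, `lb`, `ub`. Each value holds
#'   from its breakpoint until the next (left-closed step function).
#' @param monod Optional named list `reaction id -> list(vmax, ks)` giving
#'   Monod uptake kinetics `ub = vmax * S / (ks + S)` on the substrate
#'   tracked for that reaction (vmax mmol/g DCW/h >= 0, ks mmol/L > 0).
#' @param tracked Optional tracked substrates: tibble/data frame with
#'   columns `metabolite_id`, `initial_conc` (mmol/L) and
#'   `uptake_reaction` (the inflow whose flux drains the pool).
#' @return A validated `dfba_spec` object.
#' @export
dfba_spec <- function(t_end, dt, initial_biomass, t0 = 0,
                      profiles = NULL, monod = NULL, tracked = NULL) {
  if (dt <= 0) abort("dt must be > 0")
  if (t_end <= t0) abort("t_end must exceed t0")
  if (initial_biomass <= 0) abort("initial_biomass must be > 0")
  if (!is.null(profiles)) {
    profiles <- as_tibble(profiles)
    need <- c("time", "reaction_id", "lb", "ub")
    if (!all(need %in% names(profiles))) {
      abort("profiles needs columns time, reaction_id, lb, ub")
    }
    if (any(profiles$time < t0 | profiles$time > t_end)) {
      abort("profile breakpoints must lie within [t0, t_end]")
    }
  }
  if (!is.null(tracked)) {
    tracked <- as_tibble(tracked)
    need <- c("metabolite_id", "initial_conc", "uptake_reaction")
    if (!all(need %in% names(tracked))) {
      abort("tracked needs columns metabolite_id, initial_conc, uptake_reaction")
    }
    if (any(tracked$initial_conc < 0)) abort("initial_conc must be >= 0")
  }
  if (!is.null(monod)) {
    for (rid in names(monod)) {
      ms <- monod[[rid]]
      if (is.null(ms$vmax) || is.null(ms$ks) || ms$vmax < 0 || ms$ks <= 0) {
        abort(paste0("Monod spec for ", rid,
                     " needs vmax >= 0 and ks > 0"))
      }
      if (is.null(tracked) || !rid %in% tracked$uptake_reaction) {
        abort(paste0("Monod-bounded reaction ", rid,
                     " must be the uptake reaction of a tracked substrate"))
      }
    }
  }
  structure(list(t0 = t0, t_end = t_end, dt = dt,
                 initial_biomass = initial_biomass,
                 profiles = profiles, monod = monod, tracked = tracked),
            class = "dfba_spec")
}

#' Resolve the flux bounds of a reaction at a time point
#'
#' Piecewise-constant profiles return the value of the last breakpoint at or
#' before `t`; Monod-bounded uptakes return `lb = 0`,
#' `ub = vmax * S / (ks + S)` from the current tracked concentration.
#'
#' @param spec A [dfba_spec()].
#' @param reaction_id Reaction id with a profile or Monod spec.
#' @param t Time (h), inside `[t0, t_end]`.
#' @param state Named numeric of current tracked concentrations
#'   (metabolite id -> mmol/L); only needed for Monod bounds.
#' @return Numeric `c(lb, ub)`.
#' @export
resolve_bounds <- function(spec, reaction_id, t, state = NULL) {
  if (t < spec$t0 || t > spec$t_end) {
    abort(sprintf("t = %g outside the time course [%g, %g]",
                  t, spec$t0, spec$t_end))
  }
  if (!is.null(spec$monod) && reaction_id %in% names(spec$monod)) {
    ms <- spec$monod[[reaction_id]]
    row <- spec$tracked[spec$tracked$uptake_reaction == reaction_id, ]
    S <- state[[row$metabolite_id[1]]]
    return(c(0, ms$vmax * S / (ms$ks + S)))
  }
  if (!is.null(spec$profiles)) {
    pr <- spec$profiles[spec$profiles$reaction_id == reaction_id, ]
    pr <- pr[pr$time <= t + 1e-12, , drop = FALSE]
    if (nrow(pr)) {
      k <- which.max(pr$time)
      return(c(pr$lb[k], pr$ub[k]))
    }
  }
  abort(paste0("no bound profile or Monod spec for reaction ", reaction_id))
}

#' Run dynamic FBA by the static optimization approach
#'
#' For each interval `[t_k, t_k + dt)` the exchange bounds are resolved at
#' `t_k` (profile lookup, or Monod from the current substrate pool), one
#' mini-FBA is solved, and the pools are integrated: biomass grows
#' exponentially at the interval's growth rate,
#' `X_{k+1} = X_k * exp(mu_k * dt)` (exact for constant `mu`), and each
#' tracked substrate is depleted by its uptake flux times the
#' interval-average biomass, clamped at zero. An infeasible interval
#' terminates the simulation gracefully with the partial trajectory — late
#' infeasibility usually means the model cannot meet maintenance once the
#' substrate is gone, which is biologically meaningful.
#'
#' @param model A `metabolic_model` with a biomass-maximizing objective.
#' @param spec A [dfba_spec()].
#' @return A `dfba_trajectory`: `times` (grid, h), `biomass` (g DCW/L at
#'   grid points), `substrate` (tibble, one concentration column per tracked
#'   metabolite), `intervals` (tibble with per-interval `t`, `mu`,
#'   `objective`, `status`), `solutions` (list of `flux_distribution`),
#'   `terminated_early`, `reason`. `tidy()` gives a long per-time tibble;
#'   `autoplot()` plots biomass and substrate curves.
#' @export
run_dfba <- function(model, spec) {
  stopifnot(inherits(spec, "dfba_spec"))
  if (is.null(model$objective)) abort("model needs a biomass objective")
  profiled <- unique(c(
    if (!is.null(spec$profiles)) spec$profiles$reaction_id,
    names(spec$monod)
  ))
  unknown <- setdiff(profiled, model$reactions$id)
  if (length(unknown)) {
    abort(paste0("spec references reaction(s) not in model: ",
                 paste(unknown, collapse = ", ")))
  }
  biomass_id <- names(model$objective$coefficients)[1]
  grid <- seq(spec$t0, spec$t_end, by = spec$dt)
  if (grid[length(grid)] < spec$t_end - 1e-12) grid <- c(grid, spec$t_end)
  n_int <- length(grid) - 1L

  X <- spec$initial_biomass
  conc <- if (!is.null(spec$tracked)) {
    stats::setNames(spec$tracked$initial_conc, spec$tracked$metabolite_id)
  } else stats::setNames(numeric(0), character(0))

  biomass <- c(X, rep(NA_real_, n_int))
  conc_hist <- matrix(NA_real_, n_int + 1L, length(conc),
                      dimnames = list(NULL, names(conc)))
  if (length(conc)) conc_hist[1, ] <- conc
  ints <- tibble(t = grid[seq_len(n_int)], mu = NA_real_,
                 objective = NA_real_, status = NA_character_)
  sols <- vector("list", n_int)
  terminated <- FALSE; reason <- NA_character_

  for (k in seq_len(n_int)) {
    tk <- grid[k]; dtk <- grid[k + 1] - grid[k]
    scenario <- model
    for (rid in profiled) {
      bb <- resolve_bounds(spec, rid, tk, conc)
      i <- rxn_index(scenario, rid)
      scenario$reactions$lower_bound[i] <- bb[1]
      scenario$reactions$upper_bound[i] <- bb[2]
    }
    sol <- solve_fba(scenario)
    ints$status[k] <- sol$status
    sols[[k]] <- sol
    if (sol$status != "optimal") {
      terminated <- TRUE
      reason <- paste0("mini-FBA ", sol$status, " at t = ", tk, " h")
      break
    }
    mu <- unname(sol$fluxes[biomass_id])
    ints$mu[k] <- mu
    ints$objective[k] <- sol$objective_value
    X_new <- X * exp(mu * dtk)
    X_bar <- if (mu > 1e-12) (X_new - X) / (mu * dtk) else X
    if (length(conc)) {
      for (j in seq_len(nrow(spec$tracked))) {
        v <- unname(sol$fluxes[spec$tracked$uptake_reaction[j]])
        mid <- spec$tracked$metabolite_id[j]
        conc[mid] <- max(0, conc[mid] - v * X_bar * dtk)
      }
      conc_hist[k + 1L, ] <- conc
    }
    X <- X_new
    biomass[k + 1L] <- X
  }

  done <- !is.na(biomass)
  structure(
    list(times = grid[done],
         biomass = biomass[done],
         substrate = as_tibble(conc_hist[done, , drop = FALSE]),
         intervals = ints[seq_len(sum(done) - 1L), , drop = FALSE],
         solutions = sols[seq_len(sum(done) - 1L)],
         terminated_early = terminated,
         reason = reason,
         biomass_id = biomass_id),
    class = "dfba_trajectory"
  )
}

#' @export
print.dfba_trajectory <- function(x, ...) {
  cat("<dfba_trajectory> ", length(x$times) - 1L, " intervals over [",
      x$times[1], ", ", x$times[length(x$times)], "] h; final biomass ",
      format(x$biomass[length(x$biomass)], digits = 5), " g DCW/L",
      if (x$terminated_early) paste0("\n  terminated early: ", x$reason),
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_dfba
#' @param x A `dfba_trajectory`.
#' @param ... Unused.
#' @export
tidy.dfba_trajectory <- function(x, ...) {
  out <- tibble(time = x$times, biomass = x$biomass)
  bind_cols(out, x$substrate)
}

#' @rdname run_dfba
#' @export
glance.dfba_trajectory <- function(x, ...) {
  tibble(t_end = x$times[length(x$times)],
         final_biomass = x$biomass[length(x$biomass)],
         n_intervals = length(x$solutions),
         terminated_early = x$terminated_early)
}

#' @rdname run_dfba
#' @param object A `dfba_trajectory`.
#' @export
autoplot.dfba_trajectory <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(-"time", names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL)
}
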