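# Shared builders and the independent LP oracle used across the suite.

# Independent FBA oracle on boot::simplex. Deliberately takes a different
# formulation path from the package engine: constraints are assembled
# directly from the stoichiometry list-column (not via
# build_stoichiometric_matrix), variables are shifted to x = v - lb >= 0,
# upper bounds become explicit inequality rows, and equality rows are
# sign-flipped to keep the right-hand side non-negative.
oracle_fba <- function(model, objective = NULL, direction = "maximize") {
  if (is.null(objective)) {
    stopifnot(!is.null(model$objective))
    objective <- model$objective$coefficients
    direction <- model$objective$direction
  } else if (is.character(objective)) {
    objective <- stats::setNames(1, objective)
  }
  rxn <- model$reactions
  internal <- sort(model$metabolites$id[!model$metabolites$external])
  n <- nrow(rxn)
  A <- matrix(0, length(internal), n,
              dimnames = list(internal, rxn$id))
  for (j in seq_len(n)) {
    s <- rxn$stoichiometry[[j]]
    s <- s[names(s) %in% internal]
    A[names(s), j] <- s
  }
  lb <- rxn$lower_bound; ub <- rxn$upper_bound
  obj <- stats::setNames(numeric(n), rxn$id)
  obj[names(objective)] <- objective
  b3 <- -as.vector(A %*% lb)
  flip <- b3 < 0
  A3 <- A; A3[flip, ] <- -A3[flip, ]; b3[flip] <- -b3[flip]
  maxi <- direction == "maximize"
  r <- boot::simplex(a = if (maxi) obj else -obj,
                     A1 = diag(n), b1 = ub - lb,
                     A3 = A3, b3 = b3, maxi = maxi,
                     n.iter = 50 * (2 * n + length(internal)))
  if (r$solved != 1) return(list(status = "infeasible", objective = NA_real_))
  off <- sum(obj * lb)
  val <- unname(if (maxi) r$value + off else -r$value + off)
  list(status = "optimal", objective = val, x = as.vector(r$soln) + lb)
}

# minimal linear chain: inflow -> A -> B -> outflow, maximize the outflow
chain_model <- function(inflow_ub = 5) {
  metabolic_model(
    "chain",
    metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(
      id = c("in_A", "A2B", "out_B"),
      stoichiometry = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
      kind = c("inflow", "intracellular", "outflow"),
      upper_bound = c(inflow_ub, 1000, 1000)),
    objective = list(coefficients = c(out_B = 1), direction = "maximize"))
}

# two redundant routes A -> B; knocking either out leaves the optimum alone
two_path_model <- function() {
  metabolic_model(
    "twopath",
    metabolites = tibble::tibble(id = c("A", "B")),
    reactions = tibble::tibble(
      id = c("in_A", "p1", "p2", "out_B"),
      stoichiometry = list(c(A = 1), c(A = -1, B = 1),
                           c(A = -1, B = 1), c(B = -1)),
      kind = c("inflow", "intracellular", "intracellular", "outflow"),
      upper_bound = c(4, 1000, 1000, 1000)),
    objective = list(coefficients = c(out_B = 1), direction = "maximize"))
}

# small ATP-coupled model with closed-form growth(gam) = 2 u / (2 + gam):
# substrate either burns to 2 ATP or is drawn into biomass, which also
# hydrolyses gam ATP per unit growth
gam_toy_model <- function(u = 10) {
  metabolic_model(
    "gamtoy",
    metabolites = tibble::tibble(id = c("S", "ATP_", "ADP_", "PI_", "H2O_")),
    reactions = tibble::tibble(
      id = c("s_in", "catab", "GROW", "pi_out", "h2o_in"),
      stoichiometry = list(
        c(S = 1),
        c(S = -1, ADP_ = -2, ATP_ = 2),
        c(S = -1),                      # gam terms added via fit_gam
        c(PI_ = -1), c(H2O_ = 1)),
      kind = c("inflow", "intracellular", "biomass", "outflow", "inflow"),
      lower_bound = c(u, 0, 0, 0, 0),
      upper_bound = c(u, 1000, 1000, 1000, 1000)),
    objective = list(coefficients = c(GROW = 1), direction = "maximize"))
}

# randomized small feasible FBA model for property tests: a linear backbone
# with an inflow cap, a biomass drain partway down, plus random extra edges
random_fba_model <- function(seed) {
  set.seed(seed)
  n_mets <- sample(4:7, 1)
  mets <- paste0("m", seq_len(n_mets))
  rxns <- tibble::tibble(
    id = "in_1", stoichiometry = list(stats::setNames(1, mets[1])),
    kind = "inflow", upper_bound = runif(1, 2, 10))
  for (i in seq_len(n_mets - 1)) {
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = paste0("b", i),
      stoichiometry = list(stats::setNames(c(-1, 1), mets[c(i, i + 1)])),
      kind = "intracellular", upper_bound = 1000))
  }
  n_extra <- sample(0:3, 1)
  for (k in seq_len(n_extra)) {
    pick <- sample(mets, 2)
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = paste0("x", k),
      stoichiometry = list(stats::setNames(c(-1, sample(1:2, 1)), pick)),
      kind = "intracellular", upper_bound = 1000))
  }
  drain <- sample(mets[-1], 1)
  rxns <- dplyr::bind_rows(
    rxns,
    tibble::tibble(id = "BIOMASS",
                   stoichiometry = list(stats::setNames(-1, drain)),
                   kind = "biomass", upper_bound = 1000),
    tibble::tibble(id = "out_n",
                   stoichiometry = list(stats::setNames(-1, mets[n_mets])),
                   kind = "outflow", upper_bound = 1000))
  rxns$reversible <- FALSE
  rxns$lower_bound <- 0
  metabolic_model(paste0("rand", seed),
                  metabolites = tibble::tibble(id = mets),
                  reactions = rxns,
                  objective = list(coefficients = c(BIOMASS = 1),
                                   direction = "maximize"))
}

# 1:1 Monod chain for dFBA: uptake feeds growth directly (yield 1)
monod_chain_model <- function() {
  metabolic_model(
    "monodchain",
    metabolites = tibble::tibble(id = "S"),
    reactions = tibble::tibble(
      id = c("upt", "GROW"),
      stoichiometry = list(c(S = 1), c(S = -1)),
      kind = c("inflow", "biomass"),
      lower_bound = 0, upper_bound = c(1000, 1000)),
    objective = list(coefficients = c(GROW = 1), direction = "maximize"))
}

expect_model_equal <- function(a, b) {
  eq <- model_equal(a, b)
  expect_true(isTRUE(eq), info = attr(eq, "why"))
}
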