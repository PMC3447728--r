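#' Solve a bounded-variable linear program
#'
#' Solves `optimize c'x subject to A x = b, lb <= x <= ub` with a two-phase
#' primal simplex method for bounded variables (explicit basis inverse with
#' periodic refactorisation, Dantzig pricing with a Bland's-rule fallback
#' against cycling). This is the engine behind [solve_fba()]; flux-balance
#' problems are equality-constrained LPs with finite box bounds, which is
#' exactly the form handled here.
#'
#' All bounds must be finite. Redundant equality rows are tolerated (their
#' artificial variables simply stay basic at zero).
#'
#' @param obj Numeric objective coefficient vector (length n).
#' @param A Constraint matrix (m x n), dense or sparse (`Matrix`).
#' @param b Right-hand side vector (length m).
#' @param lb,ub Finite lower/upper bound vectors (length n).
#' @param maximize Logical; maximize (default) or minimize.
#' @param tol Numerical tolerance for pricing and ratio tests.
#' @param max_iter Simplex iteration cap across both phases.
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `objective` (on the original maximize/minimize scale)
#'   and `x`, the optimal point (`NA` unless optimal).
#' @export
#' @examples
#' # max x1 + x2  s.t.  x1 + x2 = 1,  0 <= x <= 1
#' lp_solve(c(1, 1), matrix(c(1, 1), 1, 2), 1, c(0, 0), c(1, 1))
lp_solve <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("lp_solve requires finite bounds; cap unbounded fluxes explicitly")
  }
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  sense <- if (maximize) 1 else -1

  if (m == 0L) {
    # pure box problem: each variable sits at whichever bound favours it
    x <- ifelse(sense * obj > 0, ub, lb)
    return(list(status = "optimal", objective = sum(obj * x), x = x))
  }

  # augment with one artificial per row, signed so artificials start >= 0
  ntot <- n + m
  lbx <- c(lb, rep(0, m))
  ubx <- c(ub, rep(Inf, m))

  # nonbasic start: each structural variable at its bound of smaller magnitude
  at_upper <- abs(ub) < abs(lb)
  x <- ifelse(at_upper, ub, lb)
  resid <- b - as.vector(A %*% x)
  art_sign <- ifelse(resid >= 0, 1, -1)
  Aaug <- cbind(A, diag(art_sign, m, m))

  st <- new.env(parent = emptyenv())
  st$basis <- (n + 1L):(n + m)           # basic variable indices
  st$xB <- abs(resid)                    # values of basic variables
  st$Binv <- diag(1 / art_sign, m, m)
  st$status_nb <- integer(ntot)          # -1 at lb, +1 at ub (nonbasic only)
  st$status_nb[seq_len(n)] <- ifelse(at_upper, 1L, -1L)
  st$x <- c(x, abs(resid))
  st$iter <- 0L

  refactor <- function() {
    Bm <- Aaug[, st$basis, drop = FALSE]
    st$Binv <- tryCatch(solve(Bm), error = function(e) MASS_ginv(Bm))
    nb <- setdiff(seq_len(ntot), st$basis)
    resid <- b - as.vector(Aaug[, nb, drop = FALSE] %*% st$x[nb])
    st$xB <- drop(st$Binv %*% resid)
    st$x[st$basis] <- st$xB
  }

  run_phase <- function(cost, bland_after) {
    degen <- 0L
    repeat {
      if (st$iter >= max_iter) return("iterlimit")
      st$iter <- st$iter + 1L
      if (st$iter %% 200L == 0L) refactor()
      cB <- cost[st$basis]
      y <- drop(crossprod(st$Binv, cB))
      nb <- setdiff(seq_len(ntot), st$basis)
      dj <- cost[nb] - drop(y %*% Aaug[, nb, drop = FALSE])
      snb <- st$status_nb[nb]
      # minimization: improve by raising a var at lb with dj<0, or lowering
      # a var at ub with dj>0
      viol <- ifelse(snb == -1L, -dj, dj)
      elig <- which(viol > tol & (ubx[nb] - lbx[nb]) > 0)
      if (!length(elig)) return("optimal")
      pick <- if (degen > bland_after) elig[which.min(nb[elig])] else
        elig[which.max(viol[elig])]
      j <- nb[pick]
      dir <- if (st$status_nb[j] == -1L) 1 else -1
      w <- drop(st$Binv %*% Aaug[, j])
      # ratio test
      tmax <- ubx[j] - lbx[j]
      leave <- 0L; leave_to <- 0L
      step <- dir * w
      for (k in seq_len(m)) {
        if (step[k] > tol) {
          r <- (st$xB[k] - lbx[st$basis[k]]) / step[k]
          if (r < tmax - 1e-12) { tmax <- r; leave <- k; leave_to <- -1L }
        } else if (step[k] < -tol) {
          r <- (st$xB[k] - ubx[st$basis[k]]) / step[k]
          if (r < tmax - 1e-12) { tmax <- r; leave <- k; leave_to <- 1L }
        }
      }
      if (!is.finite(tmax)) return("unbounded")
      tmax <- max(tmax, 0)
      degen <- if (tmax < 1e-11) degen + 1L else 0L
      st$xB <- st$xB - tmax * step
      st$x[st$basis] <- st$xB
      newval <- st$x[j] + dir * tmax
      if (leave == 0L) {
        # bound flip: entering variable crosses to its other bound
        st$x[j] <- newval
        st$status_nb[j] <- -st$status_nb[j]
      } else {
        out <- st$basis[leave]
        st$x[out] <- if (leave_to == -1L) lbx[out] else ubx[out]
        st$status_nb[out] <- leave_to
        st$basis[leave] <- j
        st$x[j] <- newval
        # eta update of the explicit inverse
        piv <- w[leave]
        Brow <- st$Binv[leave, ] / piv
        st$Binv <- st$Binv - outer(w, Brow)
        st$Binv[leave, ] <- Brow
        st$xB <- st$x[st$basis]
      }
    }
  }

  bland_after <- 2L * ntot
  res1 <- run_phase(c(rep(0, n), rep(1, m)), bland_after)
  if (res1 == "iterlimit") stop("lp_solve: iteration limit reached in phase 1")
  phase1_obj <- sum(st$x[(n + 1L):ntot])
  if (phase1_obj > 1e-6 * (1 + max(abs(b)))) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  # pin artificials to zero for phase 2
  ubx[(n + 1L):ntot] <- 0
  st$x[(n + 1L):ntot][st$x[(n + 1L):ntot] < 1e-9] <- 0
  st$xB <- st$x[st$basis]
  res2 <- run_phase(c(-sense * obj, rep(0, m)), bland_after)
  if (res2 == "iterlimit") stop("lp_solve: iteration limit reached in phase 2")
  if (res2 == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  xout <- st$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * xout), x = xout)
}

# pseudo-inverse fallback for a numerically singular basis (redundant rows)
MASS_ginv <- function(X, tol = sqrt(.Machine$double.eps)) {
  s <- svd(X)
  pos <- s$d > max(tol * s$d[1], 0)
  if (!any(pos)) return(array(0, dim(X)[2:1]))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
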