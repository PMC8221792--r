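#' Solve a bounded linear program
#'
#' Solves `max/min c'x` subject to `A x = b` and `lb <= x <= ub` with a
#' two-phase primal simplex that keeps variables at their bounds
#' (bounded-variable simplex, full-tableau form with periodic
#' refactorization). All flux-balance computations in the package go through
#' this routine, so it is written for determinism: no randomization, Dantzig
#' pricing with a Bland fallback against cycling, and a fixed tie-break in
#' the ratio test.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n), dense.
#' @param b right-hand side (length m).
#' @param lb,ub finite variable bounds.
#' @param maximize logical; minimize when `FALSE`.
#' @param tol feasibility/optimality tolerance on reduced costs and residuals.
#' @param max_iter pivot cap across both phases.
#' @return list with `status` ("optimal", "infeasible", "unbounded"),
#'   `x` (length n solution), and `objective`.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = TRUE,
                     tol = 1e-9, max_iter = 20000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m,
            length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("solve_lp requires finite variable bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  ub <- pmax(ub, lb)

  K <- n + m
  x <- numeric(K)
  x[1:n] <- lb
  r <- b - as.vector(A %*% lb)
  sg <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  x[n + seq_len(m)] <- abs(r)

  basis <- n + seq_len(m)
  stat <- rep(1L, K)          # 1 at lb, 2 at ub, 0 basic
  stat[basis] <- 0L
  Tt <- sg * A                # rows scaled; artificial block is identity
  Tt <- cbind(Tt, diag(m))

  iter <- 0L
  bland <- FALSE
  piv_tol <- 1e-10

  refactor <- function() {
    B <- Afull[, basis, drop = FALSE]
    Tt <<- solve(B, Afull)
    xN <- numeric(K)
    nb <- which(stat != 0L)
    xN[nb] <- ifelse(stat[nb] == 2L, UB[nb], LB[nb])
    x[basis] <<- as.vector(solve(B, b - Afull %*% xN))
  }

  run_phase <- function(cc) {
    stall <- 0L
    repeat {
      if (iter > max_iter) stop("simplex iteration limit reached")
      iter <<- iter + 1L
      d <- cc - as.vector(crossprod(Tt, cc[basis]))
      free_span <- UB - LB > tol
      elig <- which(((stat == 1L & d > tol) | (stat == 2L & d < -tol)) & free_span)
      if (!length(elig)) return("optimal")
      j <- if (bland) elig[1L] else elig[which.max(abs(d[elig]))]
      sdir <- if (stat[j] == 1L) 1 else -1
      w <- Tt[, j]
      dw <- sdir * w
      lim <- rep(Inf, m)
      up <- dw > piv_tol
      dn <- dw < -piv_tol
      if (any(up)) lim[up] <- (x[basis[up]] - LB[basis[up]]) / dw[up]
      if (any(dn)) lim[dn] <- (x[basis[dn]] - UB[basis[dn]]) / dw[dn]
      flip <- UB[j] - LB[j]
      delta <- min(c(lim, flip))
      if (!is.finite(delta)) return("unbounded")
      delta <- max(delta, 0)
      if (flip <= delta + 1e-12 && flip <= min(lim)) {
        # bound flip, basis unchanged
        stat[j] <<- if (stat[j] == 1L) 2L else 1L
        x[j] <<- if (stat[j] == 2L) UB[j] else LB[j]
        x[basis] <<- x[basis] - sdir * flip * w
        next
      }
      cand <- which(lim <= delta + 1e-9)
      istar <- cand[which.max(abs(dw[cand]))]
      if (bland) istar <- cand[which.min(basis[cand])]
      leave <- basis[istar]
      x[j] <<- x[j] + sdir * delta
      x[basis] <<- x[basis] - sdir * delta * w
      x[leave] <<- if (dw[istar] > 0) LB[leave] else UB[leave]
      stat[leave] <<- if (dw[istar] > 0) 1L else 2L
      stat[j] <<- 0L
      basis[istar] <<- j
      # pivot update
      p <- Tt[istar, j]
      prow <- Tt[istar, ] / p
      colj <- Tt[, j]; colj[istar] <- 0
      Tt <<- Tt - outer(colj, prow)
      Tt[istar, ] <<- prow
      Tt[, j] <<- 0; Tt[istar, j] <<- 1
      if (delta <= 1e-12) stall <- stall + 1L else stall <- 0L
      if (stall > 2L * K) bland <<- TRUE
      if (iter %% 80L == 0L) refactor()
    }
  }

  # phase 1: drive artificials to zero
  if (sum(x[n + seq_len(m)]) > tol) {
    c1 <- c(rep(0, n), rep(-1, m))
    st <- run_phase(c1)
    if (st == "unbounded") stop("phase-1 unbounded: internal error")
    refactor()
    if (sum(pmax(x[n + seq_len(m)], 0)) > 1e-7)
      return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  UB[n + seq_len(m)] <- 0
  x[n + seq_len(m)][stat[n + seq_len(m)] != 0L] <- 0

  c2 <- c(if (maximize) obj else -obj, rep(0, m))
  bland <- FALSE
  st <- run_phase(c2)
  if (st == "unbounded")
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = NA_real_))
  refactor()
  xs <- pmin(pmax(x[1:n], lb), ub)
  val <- sum(obj * xs)
  list(status = "optimal", x = xs, objective = val)
}
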