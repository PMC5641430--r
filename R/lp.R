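# Bounded-variable primal simplex.
#
# Solves   maximize c'x   subject to   A x = b,   0 <= x <= u   (u finite).
# Two phases with artificial variables; Bland's rule throughout, so the method
# terminates on degenerate problems (flux polytopes at zero are highly
# degenerate). Problems here are small (tens of variables), so the basis is
# refactorised with solve() at every pivot for numerical simplicity.
#
# Returns list(status = "optimal"|"infeasible", objective, x).
lp_max <- function(c_obj, A, b, u, tol = 1e-9, max_iter = 20000L) {
  n <- length(c_obj)
  m <- if (is.null(A)) 0L else nrow(A)
  stopifnot(length(u) == n, all(is.finite(u)), all(u >= -tol))
  u <- pmax(u, 0)

  if (m == 0L) {
    x <- ifelse(c_obj > tol, u, 0)
    return(list(status = "optimal", objective = sum(c_obj * x), x = x))
  }
  stopifnot(ncol(A) == n, length(b) == m)

  sgn <- ifelse(b >= 0, 1, -1)
  Af <- cbind(A, diag(sgn, m))
  uf <- c(u, rep(Inf, m))
  nf <- n + m
  basis <- n + seq_len(m)
  xB <- abs(b)
  at_upper <- rep(FALSE, nf)      # bound status of nonbasic variables

  run_phase <- function(cost, basis, xB, at_upper, uf) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      B <- Af[, basis, drop = FALSE]
      y <- solve(t(B), cost[basis])
      nonbasic <- setdiff(seq_len(nf), basis)
      red <- cost[nonbasic] - as.numeric(crossprod(Af[, nonbasic, drop = FALSE], y))
      movable <- uf[nonbasic] > tol   # fixed (u=0) variables cannot improve
      elig <- movable &
        ((!at_upper[nonbasic] & red > tol) | (at_upper[nonbasic] & red < -tol))
      if (!any(elig)) {
        return(list(basis = basis, xB = xB, at_upper = at_upper,
                    value = sum(cost[basis] * xB) +
                      sum(cost[nonbasic][at_upper[nonbasic]] *
                            uf[nonbasic][at_upper[nonbasic]])))
      }
      j <- min(nonbasic[elig])                       # Bland: smallest index
      dir <- if (at_upper[j]) -1 else 1
      w <- solve(B, Af[, j])                         # xB moves by -dir*t*w
      dw <- dir * w
      # step limits from basic variables leaving their bounds
      t_best <- uf[j]                                # bound-flip span
      leave <- 0L                                    # 0 = bound flip
      for (i in seq_along(basis)) {
        ti <- Inf
        if (dw[i] > tol) ti <- xB[i] / dw[i]                   # hits 0
        else if (dw[i] < -tol && is.finite(uf[basis[i]])) {
          ti <- (uf[basis[i]] - xB[i]) / (-dw[i])              # hits upper
        }
        if (ti < t_best - tol ||
            (ti < t_best + tol && leave != 0L && basis[i] < basis[leave])) {
          t_best <- ti
          leave <- i
        }
      }
      if (!is.finite(t_best)) stop("LP unbounded")   # cannot happen: u finite
      t_best <- max(t_best, 0)
      xB <- xB - t_best * dw
      if (leave == 0L) {                             # entering flips bound
        at_upper[j] <- !at_upper[j]
      } else {
        lv <- basis[leave]
        hit_upper <- dw[leave] < 0
        basis[leave] <- j
        xB[leave] <- (if (at_upper[j]) uf[j] else 0) + dir * t_best
        at_upper[j] <- FALSE
        at_upper[lv] <- hit_upper
      }
      xB[xB < 0 & xB > -1e-7] <- 0
    }
  }

  # Phase 1: drive artificials to zero
  cost1 <- c(rep(0, n), rep(-1, m))
  ph1 <- run_phase(cost1, basis, xB, at_upper, uf)
  if (ph1$value < -1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = rep(NA_real_, n)))
  }
  uf[n + seq_len(m)] <- 0                            # pin artificials
  cost2 <- c(c_obj, rep(0, m))
  ph2 <- run_phase(cost2, ph1$basis, ph1$xB, ph1$at_upper, uf)

  x <- numeric(nf)
  x[ph2$basis] <- ph2$xB
  nb <- setdiff(seq_len(nf), ph2$basis)
  x[nb][ph2$at_upper[nb]] <- uf[nb][ph2$at_upper[nb]]
  x <- pmin(pmax(x[seq_len(n)], 0), u)
  list(status = "optimal", objective = sum(c_obj * x), x = x)
}
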