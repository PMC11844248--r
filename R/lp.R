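#' @title Dense bounded-variable linear programming
#'
#' @description
#' A self-contained two-phase revised simplex for problems of the form
#' \deqn{\min c^T x \quad \text{s.t.} \quad A x = b, \; l \le x \le u}
#' with possibly infinite bounds. Community flux balance problems at the scale
#' this package targets (tens to a few hundred reactions) are small and dense,
#' so the implementation favours transparency and numerical robustness
#' (explicit basis inverse, periodic refactorisation, Bland's rule fallback)
#' over sparse-matrix performance.
#'
#' @param obj numeric objective coefficients, length `n`.
#' @param A dense constraint matrix (`m` x `n`); rows are equalities.
#' @param b right-hand side, length `m`.
#' @param lb,ub variable bounds (may be `-Inf` / `Inf`).
#' @param maximize if `TRUE`, maximise instead of minimise.
#' @param tol pivot / feasibility tolerance.
#'
#' @return a list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution at a vertex), and `objective`.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = FALSE, tol = 1e-9) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  cost <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # initial nonbasic values: finite bound closest to zero, free vars at 0
  x0 <- numeric(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j]) && is.finite(ub[j])) {
      x0[j] <- if (abs(lb[j]) <= abs(ub[j])) lb[j] else ub[j]
    } else if (is.finite(lb[j])) x0[j] <- lb[j]
    else if (is.finite(ub[j])) x0[j] <- ub[j]
    else x0[j] <- 0
  }
  r <- b - as.vector(A %*% x0)
  sgn <- ifelse(r >= 0, 1, -1)
  Afull <- cbind(A, diag(sgn, nrow = m, ncol = m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xval <- c(x0, abs(r))
  stat <- c(
    ifelse(is.finite(lb) & x0 == lb, "L",
      ifelse(is.finite(ub) & x0 == ub, "U", "F")),
    rep("B", m)
  )
  basis <- n + seq_len(m)
  Binv <- diag(1 / sgn, nrow = m, ncol = m)

  run_phase <- function(cost_f, basis, stat, xval, Binv, lbf, ubf, phase) {
    ntot <- length(cost_f)
    it <- 0L
    bland_after <- 40L * (m + ntot)
    max_it <- 200L * (m + ntot) + 20000L
    repeat {
      it <- it + 1L
      if (it > max_it) stop("simplex iteration limit reached (", max_it, ")")
      if (it %% 60L == 0L) { # refactorise for numerical hygiene
        Bmat <- Afull[, basis, drop = FALSE]
        Binv <- tryCatch(solve(Bmat), error = function(e) qr.solve(Bmat))
        nb <- setdiff(seq_len(ntot), basis)
        xval[basis] <- as.vector(Binv %*% (b - Afull[, nb, drop = FALSE] %*% xval[nb]))
      }
      y <- as.vector(crossprod(Binv, cost_f[basis]))  # duals
      d <- cost_f - as.vector(crossprod(Afull, y))    # reduced costs
      nonbasic <- which(stat != "B")
      cand_dir <- numeric(0); cand <- integer(0)
      for (j in nonbasic) {
        if (lbf[j] >= ubf[j] - 1e-15 && is.finite(lbf[j]) && is.finite(ubf[j])) next
        if ((stat[j] == "L" || stat[j] == "F") && d[j] < -tol) {
          cand <- c(cand, j); cand_dir <- c(cand_dir, 1)
        } else if ((stat[j] == "U" || stat[j] == "F") && d[j] > tol) {
          cand <- c(cand, j); cand_dir <- c(cand_dir, -1)
        }
      }
      if (!length(cand)) {
        return(list(status = "optimal", basis = basis, stat = stat, xval = xval,
                    Binv = Binv, objective = sum(cost_f * xval)))
      }
      pick <- if (it > bland_after) which.min(cand) else which.max(abs(d[cand]))
      j <- cand[pick]; dir <- cand_dir[pick]

      w <- as.vector(Binv %*% Afull[, j])
      g <- dir * w                      # basic i decreases at rate g_i per unit t
      t_enter <- if (is.finite(lbf[j]) && is.finite(ubf[j])) ubf[j] - lbf[j] else Inf
      t_best <- t_enter; leave <- 0L; leave_to <- ""
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (g[i] > tol) {
          if (is.finite(lbf[bi])) {
            ti <- (xval[bi] - lbf[bi]) / g[i]
            if (ti < t_best - 1e-12) { t_best <- ti; leave <- i; leave_to <- "L" }
          }
        } else if (g[i] < -tol) {
          if (is.finite(ubf[bi])) {
            ti <- (ubf[bi] - xval[bi]) / (-g[i])
            if (ti < t_best - 1e-12) { t_best <- ti; leave <- i; leave_to <- "U" }
          }
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, stat = stat, xval = xval,
                    Binv = Binv, objective = -Inf))
      }
      t_best <- max(t_best, 0)
      # apply step
      xval[basis] <- xval[basis] - t_best * g
      xval[j] <- xval[j] + dir * t_best
      if (leave == 0L) {
        # entering variable flips to its opposite bound; basis unchanged
        stat[j] <- if (dir > 0) "U" else "L"
        xval[j] <- if (dir > 0) ubf[j] else lbf[j]
      } else {
        out <- basis[leave]
        stat[out] <- leave_to
        xval[out] <- if (leave_to == "L") lbf[out] else ubf[out]
        stat[j] <- "B"
        basis[leave] <- j
        # product-form update of Binv
        piv <- w[leave]
        if (abs(piv) < 1e-12) {
          Bmat <- Afull[, basis, drop = FALSE]
          Binv <- tryCatch(solve(Bmat), error = function(e) qr.solve(Bmat))
        } else {
          Brow <- Binv[leave, ] / piv
          Binv <- Binv - outer(w, Brow)
          Binv[leave, ] <- Brow
        }
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, basis, stat, xval, Binv, lbf, ubf, 1L)
  if (ph1$status != "optimal" || ph1$objective > 1e-7) {
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))
  }
  # phase 2: artificials pinned at zero
  ubf2 <- ubf; ubf2[n + seq_len(m)] <- 0
  c2 <- c(cost, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$stat, ph1$xval, ph1$Binv, lbf, ubf2, 2L)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = rep(NA_real_, n), objective = if (maximize) Inf else -Inf))
  }
  x <- ph2$xval[seq_len(n)]
  # snap tiny bound violations from floating point noise
  x <- pmin(pmax(x, lb - 1e-7), ub + 1e-7)
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}
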