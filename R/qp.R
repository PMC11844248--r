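#' Minimum-norm point in the convex hull of a point set (Wolfe's algorithm)
#'
#' Solves `min || P %*% lambda ||^2` over the probability simplex exactly, by
#' maintaining an affinely independent "corral" of points and repeatedly
#' solving the equality-constrained least-squares subproblem. Used as the
#' master solve of the fully corrective Frank-Wolfe iteration in
#' [cooperative_tradeoff()]; dimensions here are tiny (number of community
#' members by a handful of vertices), so dense linear algebra is exact enough.
#'
#' @param P matrix whose columns are the points.
#' @param tol numerical tolerance.
#' @return list with `x` (the min-norm point) and `lambda` (hull weights).
#' @keywords internal
wolfe_mnp <- function(P, tol = 1e-12) {
  P <- as.matrix(P)
  k <- ncol(P)
  norms <- colSums(P^2)
  S <- which.min(norms)
  lambda <- 1
  scale <- max(1, max(norms))

  affine_min <- function(Ps) {
    s <- ncol(Ps)
    if (s == 1L) return(1)
    M <- crossprod(Ps)
    K <- rbind(cbind(M, rep(1, s)), c(rep(1, s), 0))
    rhs <- c(rep(0, s), 1)
    sol <- tryCatch(solve(K, rhs), error = function(e) {
      # affinely dependent corral: ridge-stabilised fallback
      qr.solve(K + diag(1e-12, s + 1L), rhs)
    })
    sol[seq_len(s)]
  }

  for (major in seq_len(200L)) {
    x <- as.vector(P[, S, drop = FALSE] %*% lambda)
    ip <- as.vector(crossprod(P, x))
    jstar <- which.min(ip)
    if (ip[jstar] >= sum(x * x) - tol * scale) break
    if (jstar %in% S) break  # numerically stalled; x is optimal to tolerance
    S <- c(S, jstar); lambda <- c(lambda, 0)
    for (minor in seq_len(200L)) {
      mu <- affine_min(P[, S, drop = FALSE])
      if (all(mu >= -tol)) { lambda <- pmax(mu, 0); lambda <- lambda / sum(lambda); break }
      neg <- which(mu < -tol & lambda - mu > tol)
      theta <- min(1, min(lambda[neg] / (lambda[neg] - mu[neg])))
      lambda <- (1 - theta) * lambda + theta * mu
      drop_i <- which(lambda <= tol)
      if (length(drop_i)) {
        keep <- setdiff(seq_along(S), drop_i[which.min(mu[drop_i])])
        S <- S[keep]; lambda <- lambda[keep]
        lambda <- pmax(lambda, 0); lambda <- lambda / sum(lambda)
      }
    }
  }
  x <- as.vector(P[, S, drop = FALSE] %*% lambda)
  lam_full <- numeric(k); lam_full[S] <- lambda
  list(x = x, lambda = lam_full)
}

#' Minimise a convex quadratic over a flux polytope via Frank-Wolfe
#'
#' Fully corrective Frank-Wolfe on the projection of the feasible flux space
#' onto a small set of coordinates (here: the member biomass fluxes). Each
#' linear minimisation oracle is one simplex solve; the master step computes
#' the exact minimum-norm point over the hull of vertices collected so far,
#' so the iteration terminates finitely on polytopes.
#'
#' @param oracle function(gradient) -> list(mu = projected vertex, x = full
#'   vertex) minimising `gradient . mu` over the feasible set.
#' @param mu0 a feasible starting projection.
#' @param tol duality-gap tolerance (on the squared-norm objective).
#' @return list with `mu` (argmin of `sum(mu^2)`), `gap`, `iterations`.
#' @keywords internal
fw_min_norm <- function(oracle, mu0, tol = 1e-12, max_iter = 200L) {
  V <- matrix(mu0, ncol = 1)
  x <- mu0
  gap <- Inf
  for (it in seq_len(max_iter)) {
    gvec <- 2 * x
    vert <- oracle(gvec)
    gap <- sum(gvec * (x - vert$mu))
    if (gap <= tol * max(1, sum(x^2))) {
      return(list(mu = x, gap = gap, iterations = it))
    }
    V <- cbind(V, vert$mu)
    res <- wolfe_mnp(V)
    x <- res$x
    keep <- res$lambda > 1e-12
    keep[length(keep)] <- TRUE
    V <- V[, keep, drop = FALSE]
  }
  list(mu = x, gap = gap, iterations = max_iter)
}
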