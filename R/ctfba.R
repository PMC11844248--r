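#' @keywords internal
community_lp <- function(cm) {
  list(A = cm$S, b = numeric(nrow(cm$S)),
       lb = cm$reactions$lb, ub = cm$reactions$ub)
}

#' @keywords internal
new_flux_solution <- function(cm, fluxes, objective, tol = 1e-6) {
  fluxes <- stats::setNames(as.numeric(fluxes), cm$reactions$id)
  fluxes[abs(fluxes) < tol] <- 0  # report-level rounding at the numerical tolerance
  bio <- cm$members$biomass
  mg <- stats::setNames(fluxes[bio], cm$members$id)
  structure(list(fluxes = fluxes,
                 member_growth = mg,
                 community_growth = sum(cm$members$abundance * mg),
                 objective = objective, tol = tol, status = "optimal"),
            class = "ct_flux_solution")
}

#' @export
print.ct_flux_solution <- function(x, ...) {
  cat("<ct_flux_solution> community growth:", signif(x$community_growth, 6),
      "1/h; member growth:\n")
  print(signif(x$member_growth, 6))
  invisible(x)
}

#' Maximise abundance-weighted community growth (stage 1)
#'
#' Linear program: maximise `sum(a_i * mu_i)` subject to steady state
#' (`S v = 0`) and flux bounds.
#'
#' @param cm a [build_community()] model, normally after [apply_medium()].
#' @return list with `mu_star` (the community optimum), `solution` (a witness
#'   `ct_flux_solution`), and `status`.
#' @export
maximize_community_growth <- function(cm) {
  stopifnot(inherits(cm, "ct_community"))
  lp <- community_lp(cm)
  res <- solve_lp(cm$objective, lp$A, lp$b, lp$lb, lp$ub, maximize = TRUE)
  if (res$status == "infeasible") {
    bad <- cm$reactions$id[cm$reactions$lb > 0 | cm$reactions$ub < 0]
    stop("community model infeasible; reactions with forced non-zero flux ",
         "are the usual blockers: ",
         if (length(bad)) paste(bad, collapse = ", ") else "(none; check medium)")
  }
  if (res$status == "unbounded") stop("community growth is unbounded; missing medium caps?")
  list(mu_star = res$objective,
       solution = new_flux_solution(cm, res$x, res$objective),
       status = res$status)
}

#' Cooperative trade-off allocation of member growth (stage 2)
#'
#' Given the community optimum `mu_star`, finds the member growth vector of
#' minimal Euclidean norm (`min sum(mu_i^2)`) that still achieves the fraction
#' `f` of it: `sum(a_i mu_i) >= f * mu_star`. The quadratic program is solved
#' by fully corrective Frank-Wolfe over the projection of the flux polytope
#' onto member growth coordinates, with each linear oracle a simplex solve;
#' this terminates at the exact vertex/face optimum for these polytopes.
#' Minimising the distance from the zero-growth (inoculation) point selects
#' the "shortest path" allocation between inoculation and maximal growth.
#'
#' @param cm a `ct_community` with medium applied.
#' @param f trade-off fraction in `(0, 1]`.
#' @param weighted if `TRUE`, minimise `sum(a_i * mu_i^2)` instead of the
#'   unweighted norm (alternative regulariser; default `FALSE`).
#' @return list of class `ct_tradeoff` with `f`, `mu_star`, `member_growth`
#'   (named), `community_growth`, `status`.
#' @export
cooperative_tradeoff <- function(cm, f = 0.5, weighted = FALSE) {
  stopifnot(inherits(cm, "ct_community"), f > 0, f <= 1)
  st1 <- maximize_community_growth(cm)
  mu_star <- st1$mu_star
  a <- cm$members$abundance
  bio_idx <- match(cm$members$biomass, cm$reactions$id)
  lp <- community_lp(cm)
  n <- ncol(lp$A)
  # trade-off row: sum(a_i mu_i) - slack = f * mu_star, slack >= 0
  row <- numeric(n); row[bio_idx] <- a
  A2 <- rbind(cbind(lp$A, 0), c(row, -1))
  b2 <- c(lp$b, f * mu_star)
  lb2 <- c(lp$lb, 0); ub2 <- c(lp$ub, Inf)
  wts <- if (weighted) a else rep(1, length(a))

  oracle <- function(grad_mu) {
    cost <- numeric(n + 1L)
    cost[bio_idx] <- grad_mu * wts
    r <- solve_lp(cost, A2, b2, lb2, ub2, maximize = FALSE)
    if (r$status != "optimal") stop("trade-off oracle LP ", r$status)
    list(mu = r$x[bio_idx], x = r$x)
  }
  mu0 <- unname(st1$solution$fluxes[cm$members$biomass])
  fw <- if (mu_star > 1e-12) {
    if (weighted) {
      # reparametrise z = sqrt(a) mu so the objective is an unweighted norm
      sa <- sqrt(wts)
      or2 <- function(gz) { r <- oracle(gz * sa / wts); list(mu = r$mu * sa) }
      res <- fw_min_norm(or2, mu0 * sa)
      list(mu = res$mu / sa, gap = res$gap, iterations = res$iterations)
    } else {
      fw_min_norm(oracle, mu0)
    }
  } else {
    list(mu = rep(0, length(a)), gap = 0, iterations = 0L)
  }
  mg <- stats::setNames(pmax(fw$mu, 0), cm$members$id)
  structure(list(f = f, mu_star = mu_star, member_growth = mg,
                 community_growth = sum(a * mg),
                 objective_sq = sum(wts * mg^2),
                 status = "optimal"),
            class = "ct_tradeoff")
}

#' @export
print.ct_tradeoff <- function(x, ...) {
  cat("<ct_tradeoff> f =", x$f, " mu* =", signif(x$mu_star, 6),
      " community growth =", signif(x$community_growth, 6), "\n")
  print(signif(x$member_growth, 6))
  invisible(x)
}

#' @keywords internal
growth_fixed_bounds <- function(cm, tr, delta) {
  lb <- cm$reactions$lb; ub <- cm$reactions$ub
  bio_idx <- match(cm$members$biomass, cm$reactions$id)
  for (k in seq_along(bio_idx)) {
    mu <- unname(tr$member_growth[k])
    slack <- delta * max(1, abs(mu))
    lb[bio_idx[k]] <- max(lb[bio_idx[k]], mu - slack)
    ub[bio_idx[k]] <- min(ub[bio_idx[k]], mu + slack)
  }
  list(lb = lb, ub = ub)
}

#' Parsimonious environmental exchange solution (stage 3)
#'
#' With every member growth rate pinned to its trade-off value (within a
#' relative tolerance `delta`), minimises the total absolute flux through the
#' environmental exchange reactions, imposing parsimonious usage of
#' environmental resources. Absolute values are linearised by splitting each
#' environmental exchange into uptake and release parts.
#'
#' @param cm a `ct_community` with medium applied.
#' @param tr a `ct_tradeoff` from [cooperative_tradeoff()].
#' @param delta relative growth-fixing tolerance (default `1e-6`; pass 0 to
#'   pin growth exactly).
#' @param tol report-level flux rounding threshold (default `1e-6`).
#' @return a `ct_flux_solution`; `objective` is the minimised total
#'   environmental exchange flux.
#' @export
parsimonious_exchange_solution <- function(cm, tr, delta = 1e-6, tol = 1e-6) {
  stopifnot(inherits(cm, "ct_community"), inherits(tr, "ct_tradeoff"))
  gb <- growth_fixed_bounds(cm, tr, delta)
  env <- which(cm$reactions$type == "env_exchange")
  mex <- which(cm$reactions$type == "member_exchange")
  split <- c(env, mex)
  n <- ncol(cm$S)
  # split exchange columns: v_e = p_e - q_e, p,q >= 0
  Apos <- cm$S[, split, drop = FALSE]
  A2 <- cbind(cm$S, Apos, -Apos)
  lb2 <- c(gb$lb, rep(0, 2 * length(split)))
  ub2 <- c(gb$ub, pmax(gb$ub[split], 0), pmax(-gb$lb[split], 0))
  # original split columns are retired in favour of the pairs
  lb2[split] <- 0; ub2[split] <- 0
  is_env <- c(numeric(n), rep(as.numeric(split %in% env), 2))
  cost1 <- is_env
  r <- solve_lp(cost1, A2, numeric(nrow(A2)), lb2, ub2, maximize = FALSE)
  if (r$status != "optimal") {
    stop("parsimonious exchange LP ", r$status,
         " at growth-fixing tolerance delta = ", delta,
         "; a larger delta may restore feasibility")
  }
  env_total <- r$objective
  # lexicographic tie-break: among solutions with minimal environmental
  # exchange, minimise total member-lumen exchange. This removes degenerate
  # futile shuttling loops without affecting the reported minimum.
  A3 <- rbind(cbind(A2, 0), c(cost1, 1))
  b3 <- c(numeric(nrow(A2)), env_total)
  lb3 <- c(lb2, 0); ub3 <- c(ub2, Inf)
  cost2 <- c(1 - is_env, 0)
  cost2[seq_len(n)] <- 0
  r2 <- solve_lp(cost2, A3, b3, lb3, ub3, maximize = FALSE)
  if (r2$status == "optimal") r <- list(x = r2$x[seq_len(length(lb2))], status = "optimal")
  v <- r$x[seq_len(n)]
  p <- r$x[n + seq_along(split)]
  q <- r$x[n + length(split) + seq_along(split)]
  v[split] <- p - q
  sol <- new_flux_solution(cm, v, objective = env_total, tol = tol)
  sol$f <- tr$f
  sol
}

#' Minimal medium supporting the trade-off growth regime
#'
#' The uptake components of the parsimonious exchange solution: every lumen
#' metabolite whose environmental exchange runs in the uptake direction
#' (flux below `-tol`), reported as positive maximum-uptake capacities.
#' Minimality is in total uptake flux, not component count.
#'
#' @inheritParams parsimonious_exchange_solution
#' @return named numeric vector (a medium): metabolite -> uptake flux.
#' @export
minimal_medium <- function(cm, tr, delta = 1e-6, tol = 1e-6) {
  sol <- parsimonious_exchange_solution(cm, tr, delta = delta, tol = tol)
  env <- cm$reactions$type == "env_exchange"
  flux <- sol$fluxes[cm$reactions$id[env]]
  met <- cm$reactions$metabolite[env]
  up <- flux < -tol
  stats::setNames(-unname(flux[up]), met[up])
}

#' Flux range at fixed member growth
#'
#' Minimum and maximum flux a reaction can carry while every member grows at
#' its trade-off rate (within `delta`): the achievable flux space consistent
#' with the obtained growth rates.
#'
#' @inheritParams parsimonious_exchange_solution
#' @param reaction_id a community reaction id.
#' @return numeric `c(min, max)` (may be infinite for uncapped secretions).
#' @export
flux_range <- function(cm, reaction_id, tr, delta = 1e-6) {
  stopifnot(inherits(cm, "ct_community"), inherits(tr, "ct_tradeoff"))
  j <- match(reaction_id, cm$reactions$id)
  if (is.na(j)) stop("unknown reaction: ", reaction_id)
  gb <- growth_fixed_bounds(cm, tr, delta)
  cost <- numeric(ncol(cm$S)); cost[j] <- 1
  lo <- solve_lp(cost, cm$S, numeric(nrow(cm$S)), gb$lb, gb$ub, maximize = FALSE)
  hi <- solve_lp(cost, cm$S, numeric(nrow(cm$S)), gb$lb, gb$ub, maximize = TRUE)
  if (lo$status == "infeasible" || hi$status == "infeasible") {
    stop("flux_range: growth-fixed model infeasible at delta = ", delta)
  }
  c(min = if (lo$status == "unbounded") -Inf else lo$objective,
    max = if (hi$status == "unbounded") Inf else hi$objective)
}

#' Mass-balance residual of a flux solution
#' @param cm a `ct_community`.
#' @param sol a `ct_flux_solution`.
#' @return the largest absolute metabolite-row residual of `S v`.
#' @export
mass_balance_residual <- function(cm, sol) {
  max(abs(cm$S %*% sol$fluxes[cm$reactions$id]))
}

#' Write a flux solution as TSV
#'
#' One row per reaction: `reaction`, `member`, `metabolite` (lumen metabolite
#' for exchange rows, empty otherwise), `flux` with the export-positive sign
#' convention (negative = uptake, positive = release).
#'
#' @param sol a `ct_flux_solution`.
#' @param cm the community it was computed on.
#' @param path output TSV path.
#' @export
write_solution_tsv <- function(sol, cm, path) {
  d <- data.frame(reaction = cm$reactions$id, member = cm$reactions$member,
                  metabolite = ifelse(is.na(cm$reactions$metabolite), "",
                                      cm$reactions$metabolite),
                  flux = unname(sol$fluxes[cm$reactions$id]),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a trade-off summary as JSON
#' @param tr a `ct_tradeoff`.
#' @param path output JSON path.
#' @export
write_tradeoff_json <- function(tr, path) {
  jsonlite::write_json(list(mu_star = tr$mu_star, f = tr$f,
                            community_growth = tr$community_growth,
                            member_growth = as.list(tr$member_growth),
                            status = tr$status),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
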