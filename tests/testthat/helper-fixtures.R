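# Shared fixtures: tiny yield-1 member models, the two-member worked
# communities, a brute-force LP vertex-enumeration oracle, and randomised
# small communities for property tests.

yield_toy <- function(id, mu_max = 10) {
  metabolic_model(
    id,
    metabolite("s_e", compartment = "e"),
    list(reaction("EX_s_e", c(s_e = -1), -1000, 1000),
         reaction("GROW", c(s_e = -1), 0, mu_max)),
    objective = "GROW")
}

symmetric_community <- function() {
  cm <- build_community(list(A = yield_toy("A"), B = yield_toy("B")),
                        c(A = 0.5, B = 0.5))
  apply_medium(cm, c(s_e = 10))
}

asymmetric_community <- function() {
  cm <- build_community(list(A = yield_toy("A"), B = yield_toy("B", mu_max = 2)),
                        c(A = 0.5, B = 0.5))
  apply_medium(cm, c(s_e = 10))
}

benchmark_models <- function() {
  list(M = make_toy_member("methanogen"),
       S = make_toy_member("aa_fermenter"),
       L = make_toy_member("rg_bacterium"))
}

# Exhaustive vertex enumeration for min c'x s.t. Ax = b, l <= x <= u with all
# finite bounds: every basis choice x every bound assignment of the nonbasic
# variables. Independent of the simplex code path.
lp_enumerate <- function(obj, A, b, lb, ub, maximize = FALSE) {
  A <- as.matrix(A); m <- nrow(A); n <- ncol(A)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  sgn <- if (maximize) -1 else 1
  best <- Inf; best_x <- NULL
  for (Bc in utils::combn(n, m, simplify = FALSE)) {
    Bm <- A[, Bc, drop = FALSE]
    if (abs(det(Bm)) < 1e-10) next
    Nc <- setdiff(seq_len(n), Bc)
    grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(Nc)))
    if (!length(Nc)) grid <- data.frame(row.names = 1)
    for (gi in seq_len(nrow(grid))) {
      xN <- ifelse(unlist(grid[gi, ]), lb[Nc], ub[Nc])
      xB <- solve(Bm, b - A[, Nc, drop = FALSE] %*% xN)
      if (all(xB >= lb[Bc] - 1e-9) && all(xB <= ub[Bc] + 1e-9)) {
        x <- numeric(n); x[Bc] <- xB; x[Nc] <- xN
        val <- sgn * sum(obj * x)
        if (val < best - 1e-12) { best <- val; best_x <- x }
      }
    }
  }
  if (is.null(best_x)) return(list(status = "infeasible"))
  list(status = "optimal", objective = sgn * best, x = best_x)
}

# Random feasible small communities built from jittered archetypes.
random_community <- function(seed) {
  set.seed(seed)
  archetypes <- c("methanogen", "aa_fermenter", "rg_bacterium")
  k <- sample(2:3, 1)
  picks <- sample(archetypes, k)
  if (!"methanogen" %in% picks) picks[1] <- "methanogen" # keep a CO2 sink
  models <- lapply(picks, make_toy_member)
  names(models) <- vapply(models, `[[`, character(1), "id")
  # jitter internal capacities (never below operating feasibility floor)
  for (mb in names(models)) {
    for (rid in names(models[[mb]]$reactions)) {
      r <- models[[mb]]$reactions[[rid]]
      if (startsWith(rid, "EX_")) next
      f <- stats::runif(1, 0.7, 1.3)
      models[[mb]]$reactions[[rid]]$lower_bound <- r$lower_bound * f
      models[[mb]]$reactions[[rid]]$upper_bound <- r$upper_bound * f
    }
  }
  a <- stats::runif(length(models), 0.05, 1)
  a <- a / sum(a); names(a) <- names(models)
  lab <- sample(c("Ac90/CO2_10", "Ac50/CO2_50", "CO2_100"), 1)
  med <- make_scenario(lab, c_tot = stats::runif(1, 5, 20))$medium
  apply_medium(build_community(models, a, abundance_threshold = 0.01), med)
}
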