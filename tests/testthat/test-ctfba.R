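test_that("worked two-member toys match the hand-derived LP/QP solutions", {
  sym <- symmetric_community()
  expect_equal(maximize_community_growth(sym)$mu_star, 10, tolerance = 1e-9)
  tr <- cooperative_tradeoff(sym, 0.5)
  expect_equal(unname(tr$member_growth), c(5, 5), tolerance = 1e-9)
  sol <- parsimonious_exchange_solution(sym, tr, delta = 0)
  expect_equal(sol$objective, 5, tolerance = 1e-9)
  expect_equal(minimal_medium(sym, tr, delta = 0), c(s_e = 5), tolerance = 1e-9)

  asym <- asymmetric_community()
  expect_equal(maximize_community_growth(asym)$mu_star, 6, tolerance = 1e-9)
  tra <- cooperative_tradeoff(asym, 0.5)
  expect_equal(unname(tra$member_growth), c(4, 2), tolerance = 1e-9)
  expect_equal(sum(tra$member_growth^2), 20, tolerance = 1e-8)
  tra1 <- cooperative_tradeoff(asym, 1)
  expect_equal(unname(tra1$member_growth), c(10, 2), tolerance = 1e-9)
})

test_that("closed medium gives zero growth and empty exchange", {
  cm <- apply_medium(symmetric_community(),
                     stats::setNames(numeric(0), character(0)))
  expect_equal(maximize_community_growth(cm)$mu_star, 0, tolerance = 1e-12)
  tr <- cooperative_tradeoff(cm, 0.5)
  expect_equal(unname(tr$member_growth), c(0, 0))
  sol <- parsimonious_exchange_solution(cm, tr)
  env <- cm$reactions$id[cm$reactions$type == "env_exchange"]
  expect_true(all(sol$fluxes[env] == 0))
  expect_length(minimal_medium(cm, tr), 0)
})

test_that("stage-1/3 LP results match exhaustive vertex enumeration", {
  # small instances (<= 6 reactions): symmetric community with finite bounds
  cm <- symmetric_community()
  lp <- ctfba:::community_lp(cm)
  ub <- pmin(lp$ub, 1000); lb <- pmax(lp$lb, -1000)
  ours <- ctfba:::solve_lp(cm$objective, lp$A, lp$b, lb, ub, maximize = TRUE)
  ref <- lp_enumerate(cm$objective, lp$A, lp$b, lb, ub, maximize = TRUE)
  expect_equal(ours$objective, ref$objective, tolerance = 1e-9)
  # random small LPs with equality structure
  set.seed(5)
  for (k in 1:25) {
    n <- 6; m <- 3
    A <- matrix(stats::rnorm(m * n), m)
    x0 <- stats::runif(n, 0, 2)
    b <- as.vector(A %*% x0)
    obj <- stats::rnorm(n)
    lb <- rep(0, n); ub <- rep(3, n)
    ours <- ctfba:::solve_lp(obj, A, b, lb, ub)
    ref <- lp_enumerate(obj, A, b, lb, ub)
    expect_equal(ours$objective, ref$objective, tolerance = 1e-9)
  }
})

test_that("trade-off stages respect ordering and monotonicity invariants", {
  for (seed in c(11, 12, 13)) {
    cm <- random_community(seed)
    st1 <- maximize_community_growth(cm)
    prev_sq <- Inf
    for (f in c(1, 0.8, 0.5, 0.2)) {
      tr <- cooperative_tradeoff(cm, f)
      expect_gte(tr$community_growth, f * st1$mu_star - 1e-9)
      sq <- sum(tr$member_growth^2)
      # decreasing f can only shrink the minimised norm
      expect_lte(sq, prev_sq + 1e-8)
      prev_sq <- sq
      sol <- parsimonious_exchange_solution(cm, tr)
      expect_lte(mass_balance_residual(cm, sol), 1e-6)
    }
  }
  # in a homogeneous community (one substrate, identical economics) the
  # minimal total exchange is proportional to growth, hence monotone in f.
  # (In heterogeneous communities reallocating growth across members with
  # different byproduct economics can break this, so it is asserted only
  # where it provably holds.)
  for (cm in list(symmetric_community(), asymmetric_community())) {
    prev_uptake <- Inf
    for (f in c(1, 0.7, 0.4, 0.1)) {
      tr <- cooperative_tradeoff(cm, f)
      sol <- parsimonious_exchange_solution(cm, tr, delta = 0)
      expect_lte(sol$objective, prev_uptake + 1e-9)
      prev_uptake <- sol$objective
    }
  }
})

test_that("adding a redundant uptake route keeps the minimal total", {
  base <- symmetric_community()
  tr <- cooperative_tradeoff(base, 0.5)
  sol <- parsimonious_exchange_solution(base, tr, delta = 0)
  # same substrate importable through a second, stoichiometrically identical
  # member reaction
  dup <- yield_toy("A")
  dup$reactions[["GROW2"]] <- reaction("GROW2", c(s_e = -1), 0, 10)
  cm2 <- apply_medium(build_community(list(A = dup, B = yield_toy("B")),
                                      c(A = 0.5, B = 0.5)),
                      c(s_e = 10))
  tr2 <- cooperative_tradeoff(cm2, 0.5)
  sol2 <- parsimonious_exchange_solution(cm2, tr2, delta = 0)
  expect_equal(sol2$objective, sol$objective, tolerance = 1e-9)
})

test_that("minimal medium components are individually necessary", {
  models <- list(M = make_toy_member("methanogen"))
  cm <- apply_medium(build_community(models, c(M = 1)),
                     c(h2_e = 40, co2_e = 10, nh3_e = 100, h2o_e = 1000))
  tr <- cooperative_tradeoff(cm, 0.5)
  med <- minimal_medium(cm, tr, delta = 0)
  expect_true(all(c("h2_e", "co2_e") %in% names(med)))
  # removing any reported component makes the fixed-growth LP infeasible
  for (drop in names(med)) {
    cmx <- apply_medium(cm, med[setdiff(names(med), drop)])
    expect_error(parsimonious_exchange_solution(cmx, tr, delta = 0),
                 "infeasible")
  }
})

test_that("flux ranges bracket the parsimonious solution", {
  cm <- apply_medium(build_community(benchmark_models(),
                                     c(M = 0.85, S = 0.09, L = 0.06)),
                     make_scenario("Ac90/CO2_10")$medium)
  tr <- cooperative_tradeoff(cm, 0.5)
  sol <- parsimonious_exchange_solution(cm, tr)
  for (rid in c("L__EX_for_e", "M__EX_ch4_e", "L__RG")) {
    fr <- flux_range(cm, rid, tr)
    expect_lte(fr["min"], sol$fluxes[rid] + 1e-6)
    expect_gte(fr["max"], sol$fluxes[rid] - 1e-6)
  }
  # L's formate exchange is export-favoured under acetate-rich feeding
  fr_for <- flux_range(cm, "L__EX_for_e", tr)
  expect_gt(mean(fr_for), 0)
  # a fully determined reaction has a point range
  frb <- flux_range(cm, "M__BIOMASS", tr, delta = 0)
  expect_equal(unname(frb["min"]), unname(frb["max"]), tolerance = 1e-7)
  expect_error(flux_range(cm, "NOPE", tr), "unknown reaction")
})

test_that("solution writers emit the documented layouts", {
  cm <- symmetric_community()
  tr <- cooperative_tradeoff(cm, 0.5)
  sol <- parsimonious_exchange_solution(cm, tr, delta = 0)
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_solution_tsv(sol, cm, tp)
  d <- utils::read.delim(tp)
  expect_identical(names(d), c("reaction", "member", "metabolite", "flux"))
  expect_equal(d$flux[d$reaction == "EX_s_e_m"], -5, tolerance = 1e-9)
  jp <- withr::local_tempfile(fileext = ".json")
  write_tradeoff_json(tr, jp)
  js <- jsonlite::fromJSON(jp)
  expect_equal(js$mu_star, 10, tolerance = 1e-9)
  expect_equal(js$member_growth$A, 5, tolerance = 1e-9)
})
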