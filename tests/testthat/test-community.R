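test_that("community assembly wires abundances into objective and lumen", {
  cm <- symmetric_community()
  expect_equal(unname(cm$objective[cm$members$biomass]), c(0.5, 0.5))
  # namespacing and typed reaction table
  expect_true(all(c("A__GROW", "A__EX_s_e", "EX_s_e_m") %in% cm$reactions$id))
  expect_identical(cm$reactions$type[cm$reactions$id == "A__EX_s_e"],
                   "member_exchange")
  # lumen coupling carries the abundance weight
  expect_equal(cm$S["s_e", "A__EX_s_e"], 0.5)
  expect_equal(cm$S["A__s_e", "A__EX_s_e"], -1)
  # objective coefficients equal abundances for uneven split
  cm2 <- build_community(list(A = yield_toy("A"), B = yield_toy("B")),
                         c(A = 0.6, B = 0.4))
  expect_equal(unname(cm2$objective[cm2$members$biomass]), c(0.6, 0.4))
})

test_that("threshold filtering drops members and renormalises", {
  mods <- list(A = yield_toy("A"), B = yield_toy("B"), C = yield_toy("C"))
  expect_warning(
    cm <- build_community(mods, c(A = 0.7, B = 0.2, C = 0.005),
                          abundance_threshold = 0.01),
    "dropping")
  expect_identical(cm$members$id, c("A", "B"))
  expect_equal(cm$members$abundance, c(7 / 9, 2 / 9), tolerance = 1e-12)
  expect_equal(sum(cm$members$abundance), 1, tolerance = 1e-12)
  expect_error(build_community(mods, c(A = 1e-4, B = 1e-4, C = 1e-4)),
               "empty community")
  expect_error(build_community(list(A = yield_toy("A"), A = yield_toy("A")),
                               c(A = 0.5)), "duplicate")
})

test_that("community size matches a hand count on the toy trio", {
  mods <- benchmark_models()
  cm <- build_community(mods, c(M = 0.85, S = 0.09, L = 0.06))
  n_member_rxns <- sum(vapply(mods, function(m) length(m$reactions), integer(1)))
  expect_identical(ncol(cm$S), n_member_rxns + length(cm$lumen))
  n_member_mets <- sum(vapply(mods, function(m) nrow(m$metabolites), integer(1)))
  expect_identical(nrow(cm$S), n_member_mets + length(cm$lumen))
  # lumen metabolites are exactly the union of exchanged species
  expect_setequal(cm$lumen,
                  c("h2_e", "co2_e", "ch4_e", "for_e", "h2o_e", "nh3_e",
                    "asp_e", "ac_e"))
})

test_that("apply_medium opens listed uptakes and closes the rest", {
  cm <- build_community(benchmark_models(), c(M = 0.85, S = 0.09, L = 0.06))
  cm <- apply_medium(cm, c(co2_e = 10, h2_e = 40))
  rx <- cm$reactions
  expect_equal(rx$lb[rx$id == "EX_co2_e_m"], -10)
  expect_equal(rx$lb[rx$id == "EX_h2_e_m"], -40)
  expect_equal(rx$lb[rx$id == "EX_ac_e_m"], 0)
  expect_true(all(is.infinite(rx$ub[rx$type == "env_exchange"])))
  # empty medium: everything closed
  cm0 <- apply_medium(cm, stats::setNames(numeric(0), character(0)))
  expect_true(all(cm0$reactions$lb[cm0$reactions$type == "env_exchange"] == 0))
  expect_warning(apply_medium(cm, c(unobtainium = 5)), "skipped")
  expect_error(apply_medium(cm, c(co2_e = -1)), "non-negative")
  # scenario medium caps match the generator's arithmetic
  sc <- make_scenario("Ac90/CO2_10", c_tot = 10)
  cms <- apply_medium(cm, sc$medium)
  expect_equal(cms$reactions$lb[cms$reactions$id == "EX_ac_e_m"], -4.5)
  expect_equal(cms$reactions$lb[cms$reactions$id == "EX_co2_e_m"], -1)
  expect_equal(cms$reactions$lb[cms$reactions$id == "EX_h2_e_m"], -4)
})

test_that("member_exchanges lists exactly the member-lumen reactions", {
  cm <- build_community(benchmark_models(), c(M = 0.85, S = 0.09, L = 0.06))
  mx <- member_exchanges(cm, "M")
  expect_setequal(mx$metabolite,
                  c("h2_e", "co2_e", "ch4_e", "for_e", "h2o_e", "nh3_e", "asp_e"))
  all_mx <- do.call(rbind, lapply(cm$members$id, member_exchanges, cm = cm))
  expect_setequal(all_mx$reaction,
                  cm$reactions$id[cm$reactions$type == "member_exchange"])
  expect_error(member_exchanges(cm, "Z"), "unknown member")
})

test_that("a single member at a = 1 reproduces the member optimum", {
  m <- make_toy_member("methanogen")
  med <- c(h2_e = 40, co2_e = 10, nh3_e = 100, h2o_e = 1000)
  solo <- fba(m, medium = med)
  cm <- apply_medium(build_community(list(M = m), c(M = 1)), med)
  st <- maximize_community_growth(cm)
  expect_equal(st$mu_star, solo$objective, tolerance = 1e-9)
  # and plain FBA + parsimonious exchange is the f = 1 ctFBA special case
  tr <- cooperative_tradeoff(cm, f = 1)
  expect_equal(unname(tr$member_growth["M"]), solo$objective, tolerance = 1e-9)
})

test_that("lumen mass balance holds row-wise at solver optima", {
  for (seed in c(101, 202)) {
    cm <- random_community(seed)
    tr <- cooperative_tradeoff(cm, 0.6)
    sol <- parsimonious_exchange_solution(cm, tr)
    v <- sol$fluxes[cm$reactions$id]
    for (met in cm$lumen) {
      expect_lt(abs(sum(cm$S[met, ] * v)), 1e-9)
    }
  }
})

test_that("scenario config files round-trip through the reader", {
  p <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(label = "CO2_100",
                            medium = list(co2_e = 10, h2_e = 40),
                            bound_overrides = list(list(reaction = "EX_ch4_e_m",
                                                        lb = 0, ub = 5))),
                       p, auto_unbox = TRUE)
  cfg <- read_scenario_config(p)
  expect_equal(cfg$medium, c(co2_e = 10, h2_e = 40))
  cm <- apply_medium(build_community(benchmark_models(),
                                     c(M = 0.85, S = 0.09, L = 0.06)),
                     cfg$medium)
  cm <- set_bounds(cm, cfg$bound_overrides$reaction[1],
                   lb = cfg$bound_overrides$lb[1], ub = cfg$bound_overrides$ub[1])
  i <- match("EX_ch4_e_m", cm$reactions$id)
  expect_equal(cm$reactions$ub[i], 5)
})
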