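test_that("reaction scores follow GPR semantics on the linear scale", {
  m <- metabolic_model(
    "x", metabolite(c("a_c", "b_c")),
    list(reaction("R1", c(a_c = -1, b_c = 1), 0, 10, gpr = "g1 or g2"),
         reaction("R2", c(a_c = -1, b_c = 1), 0, 10, gpr = "g1 and g2"),
         reaction("R3", c(a_c = -1, b_c = 1), 0, 10, gpr = "(g1 and g2) or g3"),
         reaction("R4", c(b_c = -1), 0, 10)),
    objective = "R1")
  # log2 values whose linear back-transform (2^x - 1) is 3 and 5
  expr <- c(g1 = log2(4), g2 = log2(6), g3 = log2(2))
  sc <- reaction_expression_scores(m, expr)
  expect_equal(sc[["R1"]], 8)          # 3 + 5
  expect_equal(sc[["R2"]], 3)          # min(3, 5)
  expect_equal(sc[["R3"]], 4)          # min(3,5) + 1
  expect_false("R4" %in% names(sc))    # no GPR, no score
  # hand-checked five-reaction toy: scores on the methanogen
  mm <- make_toy_member("methanogen")
  e2 <- c(mcrA = log2(3), fdhM = log2(5), aspC = log2(2))
  s2 <- reaction_expression_scores(mm, e2)
  expect_equal(unname(s2[c("MCR", "FDH", "ASPS")]), c(2, 4, 1))
})

test_that("expression_bounds scales by w = min(1, (E/E_ref)^alpha)", {
  m <- make_toy_member("rg_bacterium")
  sc <- c(RG = 1, FOR_SYN = 4)
  # reference = 75th percentile of (1, 4) = 3.25
  p1 <- integration_params(alpha = 1)
  m1 <- expression_bounds(m, sc, p1)
  expect_equal(m1$reactions[["RG"]]$upper_bound, 54 * (1 / 3.25))
  expect_equal(m1$reactions[["RG"]]$lower_bound, -54 * (1 / 3.25))
  expect_equal(m1$reactions[["FOR_SYN"]]$upper_bound, 20) # capped at 1
  # E_r = E_ref leaves bounds unchanged at any alpha
  sc_eq <- c(RG = 2, FOR_SYN = 2)
  for (al in c(0.2, 1, 5)) {
    mq <- expression_bounds(m, sc_eq, integration_params(alpha = al))
    expect_equal(mq$reactions[["RG"]]$upper_bound, 54)
  }
  # quarter expression at alpha = 1 quarters the bounds
  m4 <- expression_bounds(m, c(RG = 1, FOR_SYN = 1e9),
                          integration_params(alpha = 1))
  e_ref <- stats::quantile(c(1, 1e9), 0.75, names = FALSE)
  expect_equal(m4$reactions[["RG"]]$upper_bound, 54 * (1 / e_ref))
  expect_error(expression_bounds(m, c(RG = 0, FOR_SYN = 0)), "zero")
})

test_that("alpha -> 0 recovers the unintegrated optimum", {
  bm <- make_benchmark(seed = 3, n_replicates = 1)
  ds <- bm$datasets[[1]]
  cm0 <- apply_medium(build_community(ds$models, ds$abundances), ds$medium)
  mu0 <- maximize_community_growth(cm0)$mu_star
  scaled <- ds$models
  for (mb in names(scaled)) {
    sc <- reaction_expression_scores(scaled[[mb]], ds$expression[[mb]])
    scaled[[mb]] <- expression_bounds(scaled[[mb]], sc,
                                      integration_params(alpha = 1e-9))
  }
  cmx <- apply_medium(build_community(scaled, ds$abundances), ds$medium)
  expect_equal(maximize_community_growth(cmx)$mu_star, mu0, tolerance = 1e-9)
})

test_that("expression_bounds is monotone in gene expression", {
  m <- make_toy_member("methanogen")
  base_expr <- c(mcrA = 5, fdhM = 5, aspC = 5)
  p <- integration_params(alpha = 2)
  for (g in names(base_expr)) {
    lower <- base_expr; lower[g] <- 3
    mb_hi <- expression_bounds(m, reaction_expression_scores(m, base_expr), p)
    mb_lo <- expression_bounds(m, reaction_expression_scores(m, lower), p)
    for (rid in names(m$reactions)) {
      expect_lte(abs(mb_lo$reactions[[rid]]$upper_bound),
                 abs(mb_hi$reactions[[rid]]$upper_bound) + 1e-12)
      expect_lte(abs(mb_lo$reactions[[rid]]$lower_bound),
                 abs(mb_hi$reactions[[rid]]$lower_bound) + 1e-12)
    }
  }
})

test_that("calibration is deterministic and exact self-fit gives r = 1", {
  bm <- make_benchmark(seed = 5, n_replicates = 1)
  # self-consistent measurements: measured == prediction at (0.5, alpha grid pt)
  ds <- bm$datasets
  for (k in seq_along(ds)) ds[[k]]$measured_growth <- bm$truth$predicted_growth[k]
  # evaluate on a tiny grid containing the generating point's alpha = 1
  cal <- calibrate(ds, f_grid = c(0.25, 0.5), alpha_grid = c(1))
  expect_equal(cal$best$f, 0.5)
  expect_equal(cal$best$r, 1, tolerance = 1e-6)
  expect_equal(cal$best$rmse, 0, tolerance = 1e-8)
  cal2 <- calibrate(ds, f_grid = c(0.25, 0.5), alpha_grid = c(1))
  expect_identical(cal$grid, cal2$grid)
})

test_that("two datasets only warn and give degenerate correlation", {
  bm <- make_benchmark(seed = 6, n_replicates = 1)
  ds <- bm$datasets[1:2]
  expect_warning(cal <- calibrate(ds, f_grid = 0.5, alpha_grid = c(0.5, 1)),
                 "fewer than 3")
  expect_true(all(abs(abs(cal$grid$r[!is.na(cal$grid$r)]) - 1) < 1e-9))
})

test_that("calibration reports are written", {
  bm <- make_benchmark(seed = 6, n_replicates = 1)
  ds <- bm$datasets
  for (k in seq_along(ds)) ds[[k]]$measured_growth <- bm$truth$predicted_growth[k]
  cal <- calibrate(ds, f_grid = c(0.5, 1), alpha_grid = 1)
  g <- withr::local_tempfile(fileext = ".tsv")
  b <- withr::local_tempfile(fileext = ".json")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_calibration(cal, g, b, p)
  expect_identical(names(utils::read.delim(g)), c("f", "alpha", "r", "rmse"))
  expect_equal(jsonlite::fromJSON(b)$f, cal$best$f)
  expect_identical(nrow(utils::read.delim(p)), 3L)
})
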