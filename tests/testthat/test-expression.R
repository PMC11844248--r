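toy_counts <- function() {
  counts <- matrix(c(10, 20, 100, 200, 5, 0, 7, 3), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  count_matrix(counts,
               gene_lengths = c(g1 = 500, g2 = 1000, g3 = 2000, g4 = 100),
               gene_member = c(g1 = "A", g2 = "A", g3 = "B", g4 = "B"))
}

test_that("split_counts_by_member partitions genes and concatenates back", {
  cm <- toy_counts()
  parts <- split_counts_by_member(cm)
  expect_setequal(names(parts), c("A", "B"))
  expect_identical(rownames(parts$A$counts), c("g1", "g2"))
  expect_identical(rownames(parts$B$counts), c("g3", "g4"))
  recombined <- do.call(rbind, lapply(parts, function(p) p$counts))
  expect_equal(recombined[rownames(cm$counts), ], cm$counts)
  # all genes in one member: identity
  one <- count_matrix(cm$counts[1:2, ], cm$gene_lengths[1:2],
                      c(g1 = "A", g2 = "A"))
  expect_identical(names(split_counts_by_member(one)), "A")
  expect_equal(split_counts_by_member(one)$A$counts, one$counts)
  # generated benchmark: member gene counts match the manifest
  bm <- make_benchmark(seed = 7)
  parts_bm <- split_counts_by_member(bm$counts)
  for (mb in names(parts_bm)) {
    expect_identical(sort(rownames(parts_bm[[mb]]$counts)),
                     sort(names(bm$truth$base_means[
                       bm$counts$gene_member == mb])))
  }
})

test_that("size factors match the hand-computed median-of-ratios", {
  counts <- matrix(c(10, 20, 100, 200), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors(counts)
  # geometric means: sqrt(200), sqrt(20000); ratios all 1/sqrt(2) and sqrt(2)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(round(unname(sf), 4), c(0.7071, 1.4142))
  # single sample: ratio to its own geometric mean is 1
  expect_equal(unname(size_factors(counts[, 1, drop = FALSE])), 1)
  # doubling one column doubles its factor relative to the others (the
  # median-of-ratios denominator renormalises, so equivariance is up to a
  # common constant)
  c2 <- counts; c2[, 2] <- c2[, 2] * 2
  sf2 <- size_factors(c2)
  expect_equal(sf2[["s2"]] / sf2[["s1"]], 2 * sf[["s2"]] / sf[["s1"]],
               tolerance = 1e-12)
  # zero-containing genes are excluded, all-zero-free requirement enforced
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2)), "all-positive")
})

test_that("size factors recover generating factors on simulated counts", {
  # exact on noise-free multiplicative scaling
  base <- matrix(rep(c(50, 200, 10, 1000), 3), nrow = 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  scaled <- sweep(base, 2, c(1, 2, 0.5), `*`)
  sf <- size_factors(scaled)
  expect_equal(unname(sf / sf[1]), c(1, 2, 0.5), tolerance = 1e-12)
  # within 5% relative error on negative-binomial counts at n = 1000 genes
  set.seed(11)
  true_sf <- c(s1 = 1, s2 = 2, s3 = 0.6, s4 = 1.4)
  genes <- paste0("g", 1:1000)
  base_means <- stats::setNames(exp(stats::rnorm(1000, log(200), 1)), genes)
  cm <- simulate_counts(base_means, true_sf,
                        stats::setNames(rep("c1", 4), names(true_sf)),
                        gene_lengths = stats::setNames(rep(1000, 1000), genes),
                        gene_member = stats::setNames(rep("A", 1000), genes),
                        dispersion = 0.05, seed = 99)
  est <- size_factors(cm)
  est <- est / exp(mean(log(est)))
  ref <- true_sf / exp(mean(log(true_sf)))
  expect_lt(max(abs(est / ref - 1)), 0.05)
})

test_that("nfpk and log_normalize apply the documented formulas", {
  counts <- matrix(c(100, 0, 3), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), "s1"))
  cm <- count_matrix(counts, c(g1 = 500, g2 = 800, g3 = 1000),
                     c(g1 = "A", g2 = "A", g3 = "A"))
  sf <- c(s1 = 2)
  out <- nfpk(cm, sf)
  expect_equal(out["g1", "s1"], (100 / 2) / 0.5) # = 100
  expect_equal(out["g2", "s1"], 0)
  # s = 1, length 1000: nFPK equals the raw count
  expect_equal(nfpk(cm, c(s1 = 1))["g3", "s1"], 3)
  # log transform
  lg <- log_normalize(cm, c(s1 = 1))
  expect_equal(lg["g2", "s1"], 0)
  expect_equal(lg["g3", "s1"], 2) # log2(3 + 1)
  # invariance: scaling a sample's counts and its factor together
  cm2 <- count_matrix(counts * 5, cm$gene_lengths, cm$gene_member)
  expect_equal(nfpk(cm2, c(s1 = 10)), nfpk(cm, sf))
  expect_equal(log_normalize(cm2, c(s1 = 5)), log_normalize(cm, c(s1 = 1)))
  expect_error(nfpk(cm, c(other = 1)), "missing")
})

test_that("growth rate estimation is exact on exponentials", {
  # two points: ln(4)/48
  g <- growth_curve(c(0, 48), c(0.05, 0.20))
  expect_equal(growth_rate_from_od(g)$rate, log(4) / 48, tolerance = 1e-12)
  # constant OD
  flat <- growth_curve(seq(0, 10, 2), rep(0.3, 6))
  expect_equal(growth_rate_from_od(flat)$rate, 0)
  # noiseless exponential from the generator, mu recovered to 1e-12
  sim <- simulate_od(mu = 0.1, od0 = 0.05, times = seq(0, 30, 3), noise_sd = 0)
  fit <- growth_rate_from_od(sim)
  expect_equal(fit$rate, 0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # time-unit equivariance: minutes instead of hours scales the rate by 60
  sim_min <- growth_curve(sim$times * 60, sim$od)
  expect_equal(growth_rate_from_od(sim_min)$rate * 60, 0.1, tolerance = 1e-12)
  # explicit window; too narrow a window errors
  expect_error(growth_rate_from_od(sim, window = c(100, 200)), "fewer than 2")
  expect_equal(growth_rate_from_od(sim, window = c(0, 9))$rate, 0.1,
               tolerance = 1e-12)
  # automatic window skips a stationary tail
  tt <- c(0:5, 6:9)
  od <- c(0.05 * exp(0.2 * 0:5), rep(0.05 * exp(1), 4))
  fit2 <- growth_rate_from_od(growth_curve(tt, od))
  expect_equal(fit2$rate, 0.2, tolerance = 1e-9)
})

test_that("absolute abundance is the OD-weighted fraction", {
  expect_equal(absolute_abundance(2, c(A = 0.8, B = 0.2)), c(A = 1.6, B = 0.4))
  expect_equal(unname(absolute_abundance(0, c(A = 0.5))), 0)
  ra <- c(A = 0.3, B = 0.25, C = 0.1)
  expect_equal(sum(absolute_abundance(1.7, ra)), 1.7 * sum(ra))
  expect_error(absolute_abundance(1, c(A = 0.9, B = 0.3)), "sum")
})

test_that("count and OD TSV readers round-trip generator output", {
  cm <- toy_counts()
  cp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(cm$counts), cm$counts,
                                check.names = FALSE),
                     cp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = names(cm$gene_lengths),
                                length_bp = unname(cm$gene_lengths),
                                member = unname(cm$gene_member)),
                     mp, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts_tsv(cp, mp)
  expect_equal(back$counts, cm$counts)
  expect_equal(back$gene_lengths, cm$gene_lengths)
  od <- simulate_od(0.08, times = 0:10, noise_sd = 0.01, seed = 3,
                    reactor = "R2", condition = "CO2_100")
  op <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(time_h = od$times, od = od$od,
                                reactor = od$reactor, condition = od$condition),
                     op, sep = "\t", quote = FALSE, row.names = FALSE)
  curves <- read_od_tsv(op)
  expect_identical(names(curves), "R2")
  expect_equal(curves$R2$od, od$od)
})
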