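ATP_F <- "C10H16N5O13P3"
ADP_F <- "C10H15N5O10P2"
PI_F <- "H3PO4"

#' Build a toy community member model
#'
#' Small (about a dozen reactions), elementally consistent lumped models of
#' the three trophic roles of a CO2-to-CH4 consortium:
#'
#' * `"methanogen"` (M): hydrogenotrophic methanogenesis `4 H2 + CO2 -> CH4`
#'   with ATP coupling, a reversible formate dehydrogenase
#'   (`formate <-> CO2 + H2`) so formate can substitute for H2/CO2, aspartate
#'   biosynthesis, and a biomass reaction with a fixed aspartate overflow
#'   (0.25 mol exported per 1.25 mol used) feeding amino-acid fermenters.
#' * `"rg_bacterium"` (L): a syntrophic acetate oxidiser whose reductive
#'   glycine pathway is lumped into one reversible reaction
#'   `acetate + H2O + ADP + Pi <-> 2 formate + 2 H2 + ATP`, plus an
#'   irreversible formate synthesis from CO2 + H2 (the oxidoreductase route)
#'   and biomass on acetate. Growth on acetate forces formate + H2 export.
#' * `"aa_fermenter"` (S): aspartate fermentation to acetate via fumarate and
#'   succinate (`aspartase`, fumarate reductase, succinate oxidation lump
#'   with substrate-level ATP), biomass on aspartate; no growth without it.
#'
#' Whole pathways are single reactions with rational coefficients so that
#' the worked community optimisation examples have exact rational solutions.
#' Internal enzyme capacities are deliberately close to the fluxes the
#' feeding scenarios demand, so that transcript-scaled bounds can become
#' limiting (enzymes operating near capacity).
#'
#' @param archetype `"methanogen"`, `"rg_bacterium"`, or `"aa_fermenter"`.
#' @return a validated [metabolic_model()].
#' @export
make_toy_member <- function(archetype = c("methanogen", "rg_bacterium", "aa_fermenter")) {
  archetype <- match.arg(archetype)
  energy <- rbind(metabolite("atp_c", "ATP", "c", ATP_F),
                  metabolite("adp_c", "ADP", "c", ADP_F),
                  metabolite("pi_c", "phosphate", "c", PI_F),
                  metabolite("biomass_c", "biomass", "c"))
  ex <- function(met) reaction(paste0("EX_", met), stats::setNames(-1, met), -1000, 1000)
  if (archetype == "methanogen") {
    mets <- rbind(
      metabolite("h2_e", "hydrogen", "e", "H2"),
      metabolite("co2_e", "carbon dioxide", "e", "CO2"),
      metabolite("ch4_e", "methane", "e", "CH4"),
      metabolite("for_e", "formate", "e", "CH2O2"),
      metabolite("h2o_e", "water", "e", "H2O"),
      metabolite("nh3_e", "ammonia", "e", "NH3"),
      metabolite("asp_e", "aspartate", "e", "C4H7NO4"),
      metabolite("asp_c", "aspartate", "c", "C4H7NO4"),
      energy)
    rxns <- list(
      ex("h2_e"), ex("co2_e"), ex("ch4_e"), ex("for_e"), ex("h2o_e"),
      ex("nh3_e"), ex("asp_e"),
      reaction("MCR", c(h2_e = -4, co2_e = -1, adp_c = -1, pi_c = -1,
                        ch4_e = 1, h2o_e = 3, atp_c = 1), 0, 6, "mcrA"),
      reaction("FDH", c(for_e = -1, co2_e = 1, h2_e = 1), -20, 20, "fdhM"),
      reaction("ASPS", c(co2_e = -4, h2_e = -6, nh3_e = -1, atp_c = -1,
                         asp_c = 1, adp_c = 1, pi_c = 1, h2o_e = 3), 0, 20, "aspC"),
      reaction("BIOMASS", c(asp_c = -1.25, atp_c = -2, h2o_e = -2,
                            biomass_c = 1, adp_c = 2, pi_c = 2, asp_e = 0.25), 0, 10),
      reaction("DM_biomass", c(biomass_c = -1), 0, 10))
    return(metabolic_model("M", mets, rxns, objective = "BIOMASS"))
  }
  if (archetype == "rg_bacterium") {
    mets <- rbind(
      metabolite("ac_e", "acetate", "e", "C2H4O2"),
      metabolite("for_e", "formate", "e", "CH2O2"),
      metabolite("h2_e", "hydrogen", "e", "H2"),
      metabolite("co2_e", "carbon dioxide", "e", "CO2"),
      metabolite("h2o_e", "water", "e", "H2O"),
      metabolite("nh3_e", "ammonia", "e", "NH3"),
      energy)
    rxns <- list(
      ex("ac_e"), ex("for_e"), ex("h2_e"), ex("co2_e"), ex("h2o_e"), ex("nh3_e"),
      reaction("RG", c(ac_e = -1, h2o_e = -1, adp_c = -1, pi_c = -1,
                       for_e = 2, h2_e = 2, atp_c = 1), -54, 54, "fhs"),
      reaction("FOR_SYN", c(co2_e = -1, h2_e = -1, for_e = 1), 0, 20, "fdhL"),
      reaction("BIOMASS", c(ac_e = -2, nh3_e = -1, atp_c = -3, h2o_e = -3,
                            biomass_c = 1, adp_c = 3, pi_c = 3), 0, 20),
      reaction("DM_biomass", c(biomass_c = -1), 0, 20))
    return(metabolic_model("L", mets, rxns, objective = "BIOMASS"))
  }
  mets <- rbind(
    metabolite("asp_e", "aspartate", "e", "C4H7NO4"),
    metabolite("ac_e", "acetate", "e", "C2H4O2"),
    metabolite("co2_e", "carbon dioxide", "e", "CO2"),
    metabolite("nh3_e", "ammonia", "e", "NH3"),
    metabolite("h2_e", "hydrogen", "e", "H2"),
    metabolite("h2o_e", "water", "e", "H2O"),
    metabolite("fum_c", "fumarate", "c", "C4H4O4"),
    metabolite("succ_c", "succinate", "c", "C4H6O4"),
    energy)
  rxns <- list(
    ex("asp_e"), ex("ac_e"), ex("co2_e"), ex("nh3_e"), ex("h2_e"), ex("h2o_e"),
    reaction("ASPA", c(asp_e = -1, fum_c = 1, nh3_e = 1), 0, 40, "aspA"),
    reaction("FRD", c(fum_c = -1, h2_e = -1, succ_c = 1), 0, 40, "frdA"),
    reaction("SUCOX", c(succ_c = -1, h2o_e = -1, adp_c = -1, pi_c = -1,
                        ac_e = 1, co2_e = 2, h2_e = 3, atp_c = 1), 0, 40, "aarC"),
    reaction("BIOMASS", c(asp_e = -2, atp_c = -3, h2o_e = -3,
                          biomass_c = 1, adp_c = 3, pi_c = 3), 0, 10),
    reaction("DM_biomass", c(biomass_c = -1), 0, 10))
  metabolic_model("S", mets, rxns, objective = "BIOMASS")
}

#' Build a feeding scenario medium
#'
#' The three main scenarios provide the same total carbon-mole feed split
#' between acetate (2 C per molecule) and CO2, with H2 always fed at 4 times
#' the CO2 cap (the 1:4 CO2:H2 feeding ratio); `"formate_only"` feeds the
#' same carbon moles entirely as formate. Ammonia and water are included as
#' unrestricted auxiliary nutrients.
#'
#' @param label one of `"Ac90/CO2_10"`, `"Ac50/CO2_50"`, `"CO2_100"`,
#'   `"formate_only"`.
#' @param c_tot total carbon-mole feed rate (mmol C/gDW/h), default 10.
#' @return list of class `ct_scenario` with `label`, `c_tot`, `medium`.
#' @export
make_scenario <- function(label = c("Ac90/CO2_10", "Ac50/CO2_50", "CO2_100",
                                    "formate_only"), c_tot = 10) {
  label <- match.arg(label)
  stopifnot(c_tot > 0)
  aux <- c(nh3_e = 100, h2o_e = 1000)
  frac_ac <- switch(label, "Ac90/CO2_10" = 0.9, "Ac50/CO2_50" = 0.5,
                    "CO2_100" = 0, "formate_only" = NA_real_)
  medium <- if (label == "formate_only") {
    c(for_e = c_tot, h2_e = 0, co2_e = 0, ac_e = 0, aux)
  } else {
    co2 <- (1 - frac_ac) * c_tot
    c(ac_e = frac_ac * c_tot / 2, co2_e = co2, h2_e = 4 * co2, for_e = 0, aux)
  }
  structure(list(label = label, c_tot = c_tot, medium = medium),
            class = "ct_scenario")
}

#' Simulate an RNA fragment count matrix
#'
#' Negative-binomial counts with mean
#' `s_j * q_g * FC[g, condition(j)]` and dispersion `phi`
#' (`phi = 0` degenerates to Poisson), reproducible per seed.
#'
#' @param base_means named per-gene expected counts at size factor 1.
#' @param sf named per-sample size factors.
#' @param sample_conditions named character: sample -> condition label.
#' @param fold_changes gene x condition matrix of fold changes (missing genes
#'   or conditions default to 1).
#' @param gene_lengths,gene_member per-gene metadata (named).
#' @param dispersion NB dispersion `phi` (variance `mu + phi mu^2`).
#' @param seed integer seed.
#' @return a [count_matrix()].
#' @export
simulate_counts <- function(base_means, sf, sample_conditions,
                            fold_changes = NULL, gene_lengths, gene_member,
                            dispersion = 0.05, seed = 1) {
  stopifnot(all(base_means > 0), all(sf > 0), dispersion >= 0)
  genes <- names(base_means); samples <- names(sample_conditions)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  counts <- matrix(0L, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    cond <- sample_conditions[[j]]
    fc <- rep(1, length(genes))
    if (!is.null(fold_changes) && cond %in% colnames(fold_changes)) {
      hit <- intersect(genes, rownames(fold_changes))
      fc[match(hit, genes)] <- fold_changes[hit, cond]
    }
    mu <- sf[[j]] * base_means * fc
    counts[, j] <- if (dispersion > 0) {
      stats::rnbinom(length(genes), mu = mu, size = 1 / dispersion)
    } else {
      stats::rpois(length(genes), lambda = mu)
    }
  }
  count_matrix(counts, gene_lengths, gene_member)
}

#' Simulate an OD growth curve
#'
#' `od(t) = od0 * exp(mu * t) * exp(eps)`, `eps ~ N(0, noise_sd)`, seeded.
#'
#' @param mu specific growth rate (1/h).
#' @param od0 initial optical density.
#' @param times sampling times (h).
#' @param noise_sd log-scale noise standard deviation.
#' @param seed integer seed.
#' @param reactor,condition labels passed to [growth_curve()].
#' @return a [growth_curve()].
#' @export
simulate_od <- function(mu, od0 = 0.05, times = seq(0, 48, by = 6),
                        noise_sd = 0, seed = 1, reactor = "R1", condition = "") {
  stopifnot(mu >= 0, od0 > 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  eps <- stats::rnorm(length(times), 0, noise_sd)
  growth_curve(times, od0 * exp(mu * times) * exp(eps),
               reactor = reactor, condition = condition)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate the seeded community benchmark with known ground truth
#'
#' A three-member community (dominant methanogen M at 85%, aspartate
#' fermenter S at 9%, acetate-oxidising RG bacterium L at 6%, echoing the
#' dominant-archaeon structure of thermophilic biogas-upgrading consortia)
#' observed under the three feeding scenarios with three replicates each.
#' For every sample a count matrix column is simulated; condition fold
#' changes under-express L's acetate-oxidation lump when no acetate is fed
#' (shifting L toward CO2 use) and S's fermentation pathway likewise, while
#' the methanogenesis gene is mildly lower under acetate-rich feeding.
#' Replicate-to-replicate variation comes from the counting noise. Measured
#' community growth is the model's own ctFBA prediction at the generating
#' parameters `(f* = 0.5, alpha* = 1)` perturbed by 5% log-normal noise.
#'
#' @param seed integer seed controlling counts, size factors, gene lengths
#'   and growth noise.
#' @param c_tot total carbon feed (default 10 mmol C/gDW/h).
#' @param n_replicates replicates per scenario (default 3).
#' @param noise_sd log-scale sd of the growth measurement noise (default 0.05).
#' @param f_star,alpha_star generating trade-off fraction and expression
#'   penalty (defaults 0.5 and 1.0).
#' @return list with `models`, `abundances`, `scenarios`, `counts`
#'   (a [count_matrix()] over all samples), `sample_info`, `datasets` (ready
#'   for [calibrate()], each with `measured_growth`), `annotations` (marker
#'   table), and `truth` (all generating parameters).
#' @export
make_benchmark <- function(seed = 1, c_tot = 10, n_replicates = 3,
                           noise_sd = 0.05, f_star = 0.5, alpha_star = 1.0) {
  models <- list(M = make_toy_member("methanogen"),
                 S = make_toy_member("aa_fermenter"),
                 L = make_toy_member("rg_bacterium"))
  abundances <- c(M = 0.85, S = 0.09, L = 0.06)
  scen_labels <- c("Ac90/CO2_10", "Ac50/CO2_50", "CO2_100")
  scenarios <- lapply(scen_labels, make_scenario, c_tot = c_tot)
  names(scenarios) <- scen_labels

  # gene inventory: model genes plus housekeeping filler genes per member
  model_genes <- lapply(models, `[[`, "genes")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- character(0); member_of <- character(0); base <- numeric(0)
  for (mb in names(models)) {
    g <- paste0(mb, "_", model_genes[[mb]])
    genes <- c(genes, g); member_of <- c(member_of, rep(mb, length(g)))
    base <- c(base, rep(100, length(g)))
    fill <- paste0(mb, "_hk", sprintf("%02d", seq_len(40)))
    genes <- c(genes, fill); member_of <- c(member_of, rep(mb, 40))
    base <- c(base, exp(stats::rnorm(40, log(100), 1)))
  }
  # a weakly expressed fhs copy in the fermenter (marker-gene contrast)
  genes <- c(genes, "S_fhs"); member_of <- c(member_of, "S"); base <- c(base, 10)
  names(base) <- genes
  lengths <- stats::setNames(round(stats::runif(length(genes), 300, 3000)), genes)
  lengths[c("L_fhs", "S_fhs")] <- 900
  member_of <- stats::setNames(member_of, genes)

  fc <- matrix(1, nrow = length(genes), ncol = length(scen_labels),
               dimnames = list(genes, scen_labels))
  fc["M_mcrA", ] <- c(0.7, 0.85, 1.0)
  fc["L_fhs", ] <- c(1.0, 0.5, 0.25)
  fc[c("S_aspA", "S_frdA", "S_aarC"), ] <- rep(c(1.0, 0.7, 0.4), each = 3)

  samples <- as.vector(outer(seq_len(n_replicates), scen_labels,
                             function(r, s) paste0(s, "_rep", r)))
  sample_cond <- stats::setNames(rep(scen_labels, each = n_replicates), samples)
  true_sf <- stats::setNames(stats::runif(length(samples), 0.6, 1.6), samples)
  counts <- simulate_counts(base, true_sf, sample_cond, fc, lengths, member_of,
                            dispersion = 0.05, seed = seed + 1000L)

  # per-member normalisation, then per-sample log-expression vectors keyed by
  # the model's own gene ids
  by_member <- split_counts_by_member(counts)
  log_expr <- lapply(by_member, function(x) log_normalize(x))
  datasets <- list()
  for (j in samples) {
    expr <- lapply(names(models), function(mb) {
      le <- log_expr[[mb]][, j]
      ids <- sub(paste0("^", mb, "_"), "", names(le))
      keep <- ids %in% model_genes[[mb]]
      stats::setNames(le[keep], ids[keep])
    })
    names(expr) <- names(models)
    datasets[[j]] <- list(models = models, abundances = abundances,
                          medium = scenarios[[sample_cond[[j]]]]$medium,
                          expression = expr, condition = sample_cond[[j]])
  }

  # measured growth = prediction at the generating parameters + 5% noise
  p_star <- integration_params(alpha = alpha_star)
  noise <- stats::rnorm(length(samples), 0, noise_sd)
  predicted <- numeric(length(samples))
  for (k in seq_along(samples)) {
    ds <- datasets[[k]]
    scaled <- ds$models
    for (mb in names(scaled)) {
      sc <- reaction_expression_scores(scaled[[mb]], ds$expression[[mb]])
      scaled[[mb]] <- expression_bounds(scaled[[mb]], sc, p_star)
    }
    cmx <- apply_medium(build_community(scaled, ds$abundances), ds$medium)
    predicted[k] <- cooperative_tradeoff(cmx, f_star)$community_growth
    datasets[[k]]$measured_growth <- predicted[k] * exp(noise[k])
  }

  annotations <- data.frame(
    member = c("L", "S"), gene = c("L_fhs", "S_fhs"), symbol = "fhs",
    stringsAsFactors = FALSE)

  list(models = models, abundances = abundances, scenarios = scenarios,
       counts = counts,
       sample_info = data.frame(sample = samples,
                                condition = unname(sample_cond),
                                replicate = rep(seq_len(n_replicates),
                                                times = length(scen_labels)),
                                stringsAsFactors = FALSE),
       datasets = datasets, annotations = annotations,
       truth = list(seed = seed, f_star = f_star, alpha_star = alpha_star,
                    abundances = abundances, size_factors = true_sf,
                    fold_changes = fc, base_means = base,
                    gene_lengths = lengths, noise_sd = noise_sd,
                    predicted_growth = stats::setNames(predicted, samples)))
}
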