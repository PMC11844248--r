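#' Define a metabolic pathway for completeness scoring
#'
#' @param name pathway name.
#' @param steps named list; each element a non-empty character vector of
#'   alternative gene/ortholog symbols that can carry that step.
#' @return list of class `ct_pathway`.
#' @export
pathway_definition <- function(name, steps) {
  if (!length(steps)) stop("pathway definition needs at least one step")
  if (any(!vapply(steps, length, integer(1)))) stop("steps must have alternatives")
  structure(list(name = name, steps = steps), class = "ct_pathway")
}

#' Built-in Wood-Ljungdahl and reductive-glycine pathway definitions
#'
#' Gene symbols follow the plain-symbol namespace of MAG annotations. The WL
#' definition requires both the methyl branch (fdh, fhs, folD) and the
#' carbonyl-branch CODH/ACS complex (acsA-E), plus acetate activation
#' (pta-ackA module or AMP-forming acetyl-CoA synthetase ACSS). The RG
#' definition joins the methyl branch to the glycine cleavage system through
#' serine: acetate activation, acetyl-CoA/pyruvate interconversion (por, pdh
#' or pfl), serine dehydratase (sda), serine hydroxymethyltransferase, the
#' GCS subunits plus dihydrolipoyl dehydrogenase, and the C1 handling
#' enzymes. `rg_grd` is the alternative entry through the glycine reductase
#' complex (grdABE), bypassing the pyruvate/serine arm.
#'
#' @return named list of [pathway_definition()] objects: `wl`, `rg`, `rg_grd`.
#' @export
builtin_pathways <- function() {
  act <- list(acetate_kinase = c("ackA", "ACSS"),
              phosphotransacetylase = c("pta", "ACSS"))
  methyl <- list(formate_dehydrogenase = "fdh",
                 formate_thf_ligase = "fhs",
                 methylene_thf_dehydrogenase = "folD")
  gcs <- list(gcs_p_protein = "gcvP", gcs_h_protein = "gcvH",
              gcs_t_protein = "gcvT", dihydrolipoyl_dehydrogenase = "dld")
  list(
    wl = pathway_definition("wl", c(act,
      list(codh_acs_alpha = "acsA", codh_acs_beta = "acsB", codh_acs_gamma = "acsC",
           codh_acs_delta = "acsD", codh_acs_epsilon = "acsE"), methyl)),
    rg = pathway_definition("rg", c(act,
      list(acetylcoa_pyruvate = c("por", "pdh", "pfl"),
           serine_dehydratase = "sda",
           serine_hydroxymethyltransferase = c("glyA", "SHMT")),
      gcs, methyl)),
    rg_grd = pathway_definition("rg_grd", c(
      list(acetate_kinase = "ackA",
           glycine_reductase_A = "grdA", glycine_reductase_B = "grdB",
           glycine_reductase_E = "grdE"),
      gcs, methyl))
  )
}

#' Score pathway completeness per community member
#'
#' A step is present when any of its alternative genes appears in the
#' member's annotation; the pathway is complete when every step is present.
#'
#' @param annotations named list: member -> character vector of gene symbols.
#' @param defs list of [pathway_definition()]s (default [builtin_pathways()]).
#' @return `data.frame` with columns `member`, `pathway`, `fraction`,
#'   `complete`; the per-step presence matrix is attached as attribute
#'   `"steps"` (long `data.frame`: member, pathway, step, present).
#' @export
pathway_completeness <- function(annotations, defs = builtin_pathways()) {
  if (inherits(defs, "ct_pathway")) defs <- list(defs)
  rows <- list(); steps_long <- list()
  for (mb in names(annotations)) {
    genes <- annotations[[mb]]
    for (d in defs) {
      present <- vapply(d$steps, function(alts) any(alts %in% genes), logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        member = mb, pathway = d$name,
        fraction = mean(present), complete = all(present),
        stringsAsFactors = FALSE)
      steps_long[[length(steps_long) + 1L]] <- data.frame(
        member = mb, pathway = d$name, step = names(d$steps),
        present = unname(present), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "steps") <- do.call(rbind, steps_long)
  out
}

#' Marker-gene expression per member and sample
#'
#' Reports non-normalised FPK (count / gene length in kb) for a marker gene,
#' summed over the member's copies, so that both taxon abundance and
#' transcription contribute to the read-out (the convention for activity
#' markers such as the formate-tetrahydrofolate ligase gene *fhs*).
#'
#' @param cm a [count_matrix()].
#' @param annotations `data.frame` with columns `member`, `gene` (gene id as
#'   in `cm`), `symbol`.
#' @param marker_gene the marker's gene symbol (e.g. `"fhs"`).
#' @return member x sample matrix of FPK values (zero rows with a warning if
#'   the marker is annotated nowhere).
#' @export
marker_expression <- function(cm, annotations, marker_gene) {
  stopifnot(inherits(cm, "ct_counts"),
            all(c("member", "gene", "symbol") %in% names(annotations)))
  hits <- annotations[annotations$symbol == marker_gene &
                        annotations$gene %in% rownames(cm$counts), , drop = FALSE]
  if (!nrow(hits)) {
    warning("marker gene ", marker_gene, " not annotated in any member")
    return(matrix(numeric(0), nrow = 0, ncol = ncol(cm$counts),
                  dimnames = list(character(0), colnames(cm$counts))))
  }
  f <- fpk(cm)[hits$gene, , drop = FALSE]
  rowsum(f, group = hits$member)
}

#' The built-in oxidative reductive-glycine stoichiometric network
#'
#' A lumped single-compartment network for substrate-level ATP accounting of
#' acetate oxidation to C1 units: acetate kinase (1 ATP invested),
#' phosphotransacetylase, pyruvate synthase (por, reverse: 2 reduced
#' ferredoxin invested), serine dehydratase (reverse), serine
#' hydroxymethyltransferase, glycine cleavage (oxidative), methylene-THF
#' dehydrogenase/cyclohydrolase, formate-THF ligase (reverse: 1 ATP
#' recovered per C1 released as formate), and the alternative glycine
#' reductase entry (reverse). Electron carriers (ferredoxin, NAD(P)H,
#' thioredoxin) are closed by free redox sinks - a hydrogen-evolution
#' surrogate - so the computed yield isolates substrate-level
#' phosphorylation and excludes any chemiosmotic contribution. The direction
#' of the glycine reductase step in vivo is uncertain (it requires reducing
#' a thioredoxin); here thioredoxin is a free sink, which is the permissive
#' assumption.
#'
#' @return a [metabolic_model()] whose objective is the ATP drain.
#' @export
rg_network <- function() {
  mets <- rbind(
    metabolite("ac_e", "acetate", "e", "C2H4O2"),
    metabolite("for_e", "formate", "e", "CH2O2"),
    metabolite("co2_e", "carbon dioxide", "e", "CO2"),
    metabolite("nh3_e", "ammonia", "e", "NH3"),
    metabolite("h2o_e", "water", "e", "H2O"),
    metabolite(c("atp_c", "adp_c", "pi_c", "acp_c", "accoa_c", "pyr_c", "ser_c",
                 "gly_c", "thf_c", "mlthf_c", "forthf_c", "fdred_c", "fdox_c",
                 "nad_c", "nadh_c", "nadp_c", "nadph_c", "trxo_c", "trxr_c"),
               compartment = "c"))
  irr <- function(id, st, gpr = NULL) reaction(id, st, 0, 1000, gpr)
  rev <- function(id, st, gpr = NULL) reaction(id, st, -1000, 1000, gpr)
  rxns <- list(
    reaction("EX_ac_e", c(ac_e = -1), -1000, 1000),
    irr("EX_for_e", c(for_e = -1)),
    rev("EX_co2_e", c(co2_e = -1)),
    rev("EX_nh3_e", c(nh3_e = -1)),
    rev("EX_h2o_e", c(h2o_e = -1)),
    irr("ACK", c(ac_e = -1, atp_c = -1, acp_c = 1, adp_c = 1), "ackA"),
    irr("PTA", c(acp_c = -1, accoa_c = 1, pi_c = 1), "pta"),
    irr("POR", c(accoa_c = -1, co2_e = -1, fdred_c = -2, pyr_c = 1, fdox_c = 2), "por"),
    irr("SDA", c(pyr_c = -1, nh3_e = -1, ser_c = 1), "sda"),
    irr("SHMT", c(ser_c = -1, thf_c = -1, gly_c = 1, mlthf_c = 1, h2o_e = 1), "glyA"),
    irr("GCS", c(gly_c = -1, thf_c = -1, nad_c = -1,
                 mlthf_c = 1, co2_e = 1, nh3_e = 1, nadh_c = 1),
        "gcvP and gcvH and gcvT and dld"),
    irr("FOLD", c(mlthf_c = -1, nadp_c = -1, forthf_c = 1, nadph_c = 1), "folD"),
    irr("FHS", c(forthf_c = -1, adp_c = -1, pi_c = -1,
                 for_e = 1, thf_c = 1, atp_c = 1), "fhs"),
    irr("GRD", c(acp_c = -1, nh3_e = -1, trxo_c = -1,
                 gly_c = 1, pi_c = 1, trxr_c = 1), "grdA and grdB and grdE"),
    irr("ATPM", c(atp_c = -1, h2o_e = -1, adp_c = 1, pi_c = 1)),
    rev("FDSINK", c(fdred_c = -1, fdox_c = 1)),
    rev("NADSINK", c(nadh_c = -1, nad_c = 1)),
    rev("NADPSINK", c(nadph_c = -1, nadp_c = 1)),
    rev("TRXSINK", c(trxr_c = -1, trxo_c = 1))
  )
  metabolic_model("rg_network", mets, rxns, objective = "ATPM")
}

#' Net substrate-level ATP yield of the reductive-glycine pathway
#'
#' FBA maximum of the ATP drain with acetate uptake fixed at 1 mmol/gDW/h on
#' [rg_network()], with the entry reactions of the non-selected branch
#' closed: the `"canonical"` variant (through pyruvate and serine) closes the
#' glycine reductase, the `"grd"` variant closes phosphotransacetylase and
#' pyruvate synthase. The canonical branch recovers 2 ATP from two C1 units
#' against 1 invested in acetate activation (net +1); the grd branch
#' releases one carbon as CO2 before the THF arm and breaks even (net 0).
#'
#' @param variant `"canonical"` or `"grd"`.
#' @return net ATP per acetate (a single number).
#' @export
rg_atp_yield <- function(variant = c("canonical", "grd")) {
  variant <- match.arg(variant)
  model <- rg_network()
  model$reactions[["EX_ac_e"]]$lower_bound <- -1
  model$reactions[["EX_ac_e"]]$upper_bound <- -1
  closed <- if (variant == "canonical") "GRD" else c("PTA", "POR")
  for (rid in closed) {
    model$reactions[[rid]]$lower_bound <- 0
    model$reactions[[rid]]$upper_bound <- 0
  }
  res <- fba(model, objective = "ATPM", maximize = TRUE)
  if (res$status != "optimal") {
    stop("RG network infeasible for variant '", variant, "' (status: ",
         res$status, ")")
  }
  res$objective
}

#' Write a pathway completeness matrix as TSV
#' @param comp output of [pathway_completeness()].
#' @param path destination TSV.
#' @export
write_completeness_tsv <- function(comp, path) {
  utils::write.table(comp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
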