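#' Assemble an abundance-weighted community model
#'
#' Member models are namespaced (`memberId__` prefix on metabolites and
#' reactions) and coupled through a shared extracellular lumen: each member
#' exchange reaction transfers its metabolite between the member and the
#' lumen, with the lumen side scaled by the member's relative abundance
#' `a_i`, so that member fluxes stay per gDW of that member while lumen
#' balances are per gDW of community. One environmental exchange reaction per
#' lumen metabolite connects the lumen to the outside (closed for uptake
#' until [apply_medium()] is called). The community objective is the
#' abundance-weighted growth rate `sum(a_i * mu_i)`.
#'
#' @param models named list of [metabolic_model()] objects (names = member
#'   ids), or an unnamed list (model ids are used).
#' @param abundances named numeric vector of relative abundances in `(0, 1]`.
#' @param abundance_threshold members below this fraction are dropped with a
#'   warning and the rest renormalised to sum to 1 (default 0.01).
#' @return a list of class `ct_community`.
#' @export
build_community <- function(models, abundances, abundance_threshold = 0.01) {
  if (is.null(names(models))) {
    names(models) <- vapply(models, `[[`, character(1), "id")
  }
  if (anyDuplicated(names(models))) stop("duplicate member ids")
  missing_a <- setdiff(names(models), names(abundances))
  if (length(missing_a)) stop("abundance missing for members: ",
                              paste(missing_a, collapse = ", "))
  abundances <- abundances[names(models)]
  keep <- abundances >= abundance_threshold
  if (!any(keep)) stop("no member above the abundance threshold; empty community")
  if (any(!keep)) {
    warning("dropping members below abundance threshold ", abundance_threshold,
            ": ", paste(names(models)[!keep], collapse = ", "))
  }
  models <- models[keep]
  a <- abundances[keep] / sum(abundances[keep])

  rxn_id <- character(0); rxn_member <- character(0)
  rxn_lb <- numeric(0); rxn_ub <- numeric(0)
  rxn_type <- character(0); rxn_met <- character(0)
  stoich_entries <- list()  # list of (met, rxn_index, coef)
  lumen <- character(0)
  biomass <- character(0)

  add_rxn <- function(id, member, lb, ub, type, met, st) {
    rxn_id <<- c(rxn_id, id); rxn_member <<- c(rxn_member, member)
    rxn_lb <<- c(rxn_lb, lb); rxn_ub <<- c(rxn_ub, ub)
    rxn_type <<- c(rxn_type, type); rxn_met <<- c(rxn_met, met)
    stoich_entries[[length(stoich_entries) + 1L]] <<- st
  }

  for (mid in names(models)) {
    mod <- models[[mid]]
    ns <- function(x) paste0(mid, "__", x)
    for (r in mod$reactions) {
      if (is_exchange(r, mod$metabolites)) {
        met <- names(r$stoichiometry)
        coef <- unname(r$stoichiometry[[1]])
        st <- stats::setNames(c(coef, -coef * a[[mid]]), c(ns(met), met))
        lumen <- union(lumen, met)
        add_rxn(ns(r$id), mid, r$lower_bound, r$upper_bound, "member_exchange", met, st)
      } else {
        st <- stats::setNames(unname(r$stoichiometry), ns(names(r$stoichiometry)))
        add_rxn(ns(r$id), mid, r$lower_bound, r$upper_bound, "internal", NA_character_, st)
      }
    }
    biomass[mid] <- ns(mod$objective)
  }
  for (met in lumen) {
    add_rxn(paste0("EX_", met, "_m"), "environment", 0, Inf, "env_exchange", met,
            stats::setNames(-1, met))
  }

  mets <- unique(unlist(lapply(stoich_entries, names)))
  S <- matrix(0, nrow = length(mets), ncol = length(rxn_id),
              dimnames = list(mets, rxn_id))
  for (k in seq_along(stoich_entries)) {
    st <- stoich_entries[[k]]
    S[names(st), k] <- S[names(st), k] + unname(st)
  }

  objective <- stats::setNames(numeric(length(rxn_id)), rxn_id)
  objective[biomass] <- unname(a)

  structure(list(
    members = data.frame(id = names(models), abundance = unname(a),
                         biomass = unname(biomass), stringsAsFactors = FALSE),
    models = models,
    S = S,
    reactions = data.frame(id = rxn_id, member = rxn_member, lb = rxn_lb,
                           ub = rxn_ub, type = rxn_type, metabolite = rxn_met,
                           stringsAsFactors = FALSE),
    lumen = lumen,
    objective = objective
  ), class = "ct_community")
}

#' @export
print.ct_community <- function(x, ...) {
  cat("<ct_community>", nrow(x$members), "members,",
      ncol(x$S), "reactions,", nrow(x$S), "metabolites,",
      length(x$lumen), "lumen metabolites\n")
  m <- x$members
  cat(paste0("  ", m$id, " (a=", signif(m$abundance, 4), ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Apply an environmental medium to a community model
#'
#' Sets every environmental exchange's uptake capacity: listed metabolites get
#' lower bound `-max_uptake`, all other environmental uptakes are closed;
#' secretion stays unbounded. Exchange sign convention throughout the package:
#' negative = uptake, positive = release.
#'
#' @param cm a `ct_community`.
#' @param medium named non-negative numeric vector: maximum community uptake
#'   flux (mmol/gDW/h) per lumen metabolite.
#' @return the modified `ct_community`.
#' @export
apply_medium <- function(cm, medium) {
  stopifnot(inherits(cm, "ct_community"))
  if (any(medium < 0)) stop("medium uptake capacities must be non-negative")
  unknown <- setdiff(names(medium), cm$lumen)
  if (length(unknown)) {
    warning("medium metabolites not in community lumen (skipped): ",
            paste(unknown, collapse = ", "))
    medium <- medium[setdiff(names(medium), unknown)]
  }
  env <- cm$reactions$type == "env_exchange"
  cm$reactions$lb[env] <- 0
  cm$reactions$ub[env] <- Inf
  idx <- which(env & cm$reactions$metabolite %in% names(medium))
  cm$reactions$lb[idx] <- -unname(medium[cm$reactions$metabolite[idx]])
  cm$medium <- medium
  cm
}

#' Override individual reaction bounds
#'
#' Escape hatch for microenvironmental constraints that are not part of the
#' medium proper (e.g. capping a secretion or forcing a maintenance flux).
#'
#' @param cm a `ct_community`.
#' @param reaction_id namespaced community reaction id.
#' @param lb,ub new bounds (either may be `NULL` to keep the current value).
#' @return the modified `ct_community`.
#' @export
set_bounds <- function(cm, reaction_id, lb = NULL, ub = NULL) {
  stopifnot(inherits(cm, "ct_community"))
  i <- match(reaction_id, cm$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  if (!is.null(lb)) cm$reactions$lb[i] <- lb
  if (!is.null(ub)) cm$reactions$ub[i] <- ub
  if (cm$reactions$lb[i] > cm$reactions$ub[i]) stop("lb > ub for ", reaction_id)
  cm
}

#' Member-to-lumen exchange reactions of one member
#'
#' @param cm a `ct_community`.
#' @param member_id a member id.
#' @return `data.frame` with columns `reaction` and `metabolite` (lumen id).
#' @export
member_exchanges <- function(cm, member_id) {
  stopifnot(inherits(cm, "ct_community"))
  if (!member_id %in% cm$members$id) stop("unknown member: ", member_id)
  sel <- cm$reactions$type == "member_exchange" & cm$reactions$member == member_id
  data.frame(reaction = cm$reactions$id[sel], metabolite = cm$reactions$metabolite[sel],
             stringsAsFactors = FALSE)
}

#' Read a member abundance table
#' @param path TSV with columns `member`, `condition`, `fraction`.
#' @return the table as a `data.frame`.
#' @export
read_abundance_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("member", "condition", "fraction") %in% names(d)))
  d
}

#' Read a scenario/medium configuration file
#'
#' JSON with fields `label`, `c_tot` (optional), `medium` (mapping metabolite
#' to max uptake), and optional `bound_overrides` (list of
#' `{reaction, lb, ub}` records for microenvironmental constraints).
#'
#' @param path JSON file path.
#' @return list with `label`, `medium` (named numeric), `bound_overrides`.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  stopifnot(!is.null(cfg$medium))
  cfg$medium <- unlist(cfg$medium)
  cfg
}
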