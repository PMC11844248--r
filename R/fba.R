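#' Flux balance analysis on a single model
#'
#' Maximises the model's objective reaction subject to steady state and
#' bounds; optionally constrains exchange uptake by a medium first
#' (uptake of unlisted exchanged metabolites is closed, secretion is left
#' untouched).
#'
#' @param model a [metabolic_model()].
#' @param medium optional named vector: extracellular metabolite -> maximum
#'   uptake flux.
#' @param objective reaction id to optimise (default the model's objective).
#' @param maximize direction (default `TRUE`).
#' @return list with `objective` (optimal value), `fluxes` (named), `status`.
#' @export
fba <- function(model, medium = NULL, objective = model$objective, maximize = TRUE) {
  rxns <- model$reactions
  if (!is.null(medium)) {
    if (any(medium < 0)) stop("medium uptake capacities must be non-negative")
    for (i in seq_along(rxns)) {
      r <- rxns[[i]]
      if (is_exchange(r, model$metabolites)) {
        met <- names(r$stoichiometry)
        rxns[[i]]$lower_bound <- if (met %in% names(medium)) -unname(medium[[met]]) else 0
      }
    }
  }
  mets <- model$metabolites$id
  S <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, names(rxns)))
  for (k in seq_along(rxns)) {
    st <- rxns[[k]]$stoichiometry
    S[names(st), k] <- unname(st)
  }
  lb <- vapply(rxns, `[[`, numeric(1), "lower_bound")
  ub <- vapply(rxns, `[[`, numeric(1), "upper_bound")
  cost <- numeric(length(rxns))
  j <- match(objective, names(rxns))
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  cost[j] <- 1
  res <- solve_lp(cost, S, numeric(nrow(S)), lb, ub, maximize = maximize)
  if (res$status != "optimal") {
    return(list(objective = NA_real_, fluxes = NULL, status = res$status))
  }
  list(objective = res$objective,
       fluxes = stats::setNames(res$x, names(rxns)), status = res$status)
}
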