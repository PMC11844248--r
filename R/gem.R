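#' Construct a metabolite table
#'
#' @param id,name,compartment,formula,charge vectors (recycled to common
#'   length). `compartment` is the single-letter convention of draft models
#'   (`"c"` cytosol, `"e"` extracellular); `formula`/`charge` may be `NA`.
#' @return a `data.frame` with one row per metabolite.
#' @export
metabolite <- function(id, name = id, compartment = "c", formula = NA_character_,
                       charge = NA_integer_) {
  data.frame(id = id, name = name, compartment = compartment,
             formula = formula, charge = as.integer(charge),
             stringsAsFactors = FALSE)
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param stoichiometry named numeric vector mapping metabolite ids to
#'   coefficients (negative = consumed). Must be non-empty.
#' @param lower_bound,upper_bound flux bounds in mmol/gDW/h.
#' @param gpr gene-protein-reaction rule: a string in the `"(g1 and g2) or g3"`
#'   dialect, a `gpr` object, or `NULL`.
#' @return a list of class `ct_reaction`.
#' @export
reaction <- function(id, stoichiometry, lower_bound = -1000, upper_bound = 1000,
                     gpr = NULL) {
  if (!length(stoichiometry)) stop("reaction ", id, ": empty stoichiometry")
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry)))) {
    stop("reaction ", id, ": stoichiometry must be a named vector")
  }
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  structure(list(id = id, stoichiometry = stoichiometry,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 gpr = gpr), class = "ct_reaction")
}

#' Construct a single-taxon genome-scale model
#'
#' @param id model (taxon/MAG) identifier.
#' @param metabolites a metabolite `data.frame` from [metabolite()] (rows may
#'   be concatenated with `rbind`).
#' @param reactions a list of [reaction()] objects.
#' @param objective id of the biomass (objective) reaction.
#' @param genes optional character vector; defaults to the union of all genes
#'   referenced by GPR rules.
#' @param validate if `TRUE` (default), error-severity findings from
#'   [validate_model()] abort construction; set to `FALSE` to build a model
#'   for inspection of its validation report.
#' @return a list of class `ct_model`.
#' @export
metabolic_model <- function(id, metabolites, reactions, objective, genes = NULL,
                            validate = TRUE) {
  names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions, function(r) gpr_genes(r$gpr)))))
  }
  m <- structure(list(id = id, metabolites = metabolites, reactions = reactions,
                      objective = objective, genes = genes), class = "ct_model")
  if (validate) {
    rep <- validate_model(m)
    errs <- rep[rep$severity == "error", , drop = FALSE]
    if (nrow(errs)) {
      stop("invalid model '", id, "':\n  ",
           paste(errs$message, collapse = "\n  "))
    }
  }
  m
}

#' @export
print.ct_model <- function(x, ...) {
  cat("<ct_model>", x$id, "\n",
      " metabolites:", nrow(x$metabolites),
      " reactions:", length(x$reactions),
      " genes:", length(x$genes), "\n",
      " objective:", x$objective, "\n")
  invisible(x)
}

#' Is a reaction an exchange pseudo-reaction?
#'
#' Deterministic classification used throughout: exchanges carry the `EX_`
#' prefix and move exactly one extracellular (compartment `"e"`) metabolite
#' across the model boundary.
#'
#' @param rxn a `ct_reaction`.
#' @param metabolites the model's metabolite table.
#' @return `TRUE`/`FALSE`.
#' @export
is_exchange <- function(rxn, metabolites) {
  if (length(rxn$stoichiometry) != 1L) return(FALSE)
  if (!startsWith(rxn$id, "EX_")) return(FALSE)
  met <- names(rxn$stoichiometry)
  comp <- metabolites$compartment[match(met, metabolites$id)]
  isTRUE(comp == "e")
}

#' Parse a chemical formula into element counts
#' @param formula e.g. `"C2H4O2"`; two-letter elements supported.
#' @return named numeric vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula)) {
    return(NULL)  # unparseable formula: treat as absent
  }
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)
}

#' Validate a metabolic model
#'
#' Produces findings rather than raising errors: identifier uniqueness,
#' non-empty compartments, resolvable stoichiometry, bound ordering, objective
#' existence, GPR gene bookkeeping, exchange shape, and elemental balance of
#' internal reactions whenever every participating metabolite carries a
#' formula (pseudo-species such as biomass typically do not, which exempts
#' biomass and demand reactions).
#'
#' @param model a `ct_model` (or an un-validated bare list with the same
#'   fields).
#' @return a `data.frame` with columns `severity` (`"error"`/`"warning"`),
#'   `element`, `message`; zero rows for a clean model.
#' @export
validate_model <- function(model) {
  findings <- list()
  add <- function(severity, element, message) {
    findings[[length(findings) + 1L]] <<- data.frame(
      severity = severity, element = element, message = message,
      stringsAsFactors = FALSE)
  }
  mets <- model$metabolites
  if (anyDuplicated(mets$id)) {
    add("error", "metabolites", paste("duplicate metabolite ids:",
        paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  bad_comp <- is.na(mets$compartment) | !nzchar(mets$compartment)
  if (any(bad_comp)) {
    add("error", "metabolites", paste("metabolites with empty compartment:",
        paste(mets$id[bad_comp], collapse = ", ")))
  }
  rids <- vapply(model$reactions, `[[`, character(1), "id")
  if (anyDuplicated(rids)) {
    add("error", "reactions", paste("duplicate reaction ids:",
        paste(unique(rids[duplicated(rids)]), collapse = ", ")))
  }
  if (!model$objective %in% rids) {
    add("error", "objective", paste("objective reaction", model$objective, "not found"))
  }
  formulas <- lapply(stats::setNames(mets$formula, mets$id), parse_formula)
  for (r in model$reactions) {
    if (r$lower_bound > r$upper_bound) {
      add("error", r$id, paste0("reaction ", r$id, ": lower_bound (", r$lower_bound,
          ") exceeds upper_bound (", r$upper_bound, ")"))
    }
    unknown <- setdiff(names(r$stoichiometry), mets$id)
    if (length(unknown)) {
      add("error", r$id, paste0("reaction ", r$id, ": unknown metabolites ",
          paste(unknown, collapse = ", ")))
    }
    extra_genes <- setdiff(gpr_genes(r$gpr), model$genes)
    if (length(extra_genes)) {
      add("error", r$id, paste0("reaction ", r$id, ": GPR genes not in model gene list: ",
          paste(extra_genes, collapse = ", ")))
    }
    if (startsWith(r$id, "EX_") && length(r$stoichiometry) != 1L) {
      add("error", r$id, paste0("exchange reaction ", r$id,
          " must touch exactly one metabolite"))
    }
    # elemental balance (internal reactions, all formulas known)
    if (!is_exchange(r, mets) && !length(unknown)) {
      fl <- formulas[names(r$stoichiometry)]
      if (!any(vapply(fl, is.null, logical(1)))) {
        bal <- Reduce(function(acc, i) {
          f <- fl[[i]] * r$stoichiometry[[i]]
          for (e in names(f)) acc[e] <- (if (e %in% names(acc)) acc[e] else 0) + f[e]
          acc
        }, seq_along(fl), init = numeric(0))
        off <- bal[abs(bal) > 1e-6]
        if (length(off)) {
          add("error", r$id, paste0("reaction ", r$id, " is elementally unbalanced: ",
              paste(names(off), round(off, 4), sep = ":", collapse = ", ")))
        }
      }
    }
  }
  if (!length(findings)) {
    return(data.frame(severity = character(0), element = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}
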