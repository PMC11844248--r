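#' Load a genome-scale model
#'
#' Reads the JSON dialect of the COBRA community or an SBML Level 3 (core +
#' fbc) subset, the two formats draft-model pipelines such as gapseq emit.
#' Identifiers are preserved verbatim (the conventional `R_`/`M_`/`G_` SBML
#' prefixes are stripped symmetrically on read and added on write).
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; default guessed from the extension.
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Save a genome-scale model
#'
#' @param model a `ct_model`.
#' @param path destination file.
#' @param format `"json"` or `"sbml"`.
#' @return `path`, invisibly. `load_model(save_model(m))` reproduces `m`
#'   field-for-field for both formats.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("JSON parse failure in ", path, ": ",
                                           conditionMessage(e)))
  req <- function(x, f, what) {
    if (is.null(x[[f]])) stop("JSON model ", path, ": ", what, " missing field '", f, "'")
    x[[f]]
  }
  mets <- do.call(rbind, lapply(req(doc, "metabolites", "model"), function(m) {
    metabolite(id = req(m, "id", "metabolite"),
               name = if (is.null(m$name)) m$id else m$name,
               compartment = req(m, "compartment", paste0("metabolite ", m$id)),
               formula = if (is.null(m$formula)) NA_character_ else m$formula,
               charge = if (is.null(m$charge)) NA_integer_ else m$charge)
  }))
  objective <- NULL
  rxns <- lapply(req(doc, "reactions", "model"), function(r) {
    st <- unlist(req(r, "metabolites", paste0("reaction ", r$id)))
    if (!is.null(r$objective_coefficient) && r$objective_coefficient != 0) {
      objective <<- r$id
    }
    reaction(id = req(r, "id", "reaction"), stoichiometry = st,
             lower_bound = req(r, "lower_bound", paste0("reaction ", r$id)),
             upper_bound = req(r, "upper_bound", paste0("reaction ", r$id)),
             gpr = if (is.null(r$gene_reaction_rule)) NULL else r$gene_reaction_rule)
  })
  if (is.null(objective)) stop("JSON model ", path, ": no reaction carries a ",
                               "non-zero objective_coefficient")
  genes <- vapply(if (is.null(doc$genes)) list() else doc$genes,
                  function(g) g$id, character(1))
  metabolic_model(id = req(doc, "id", "model"), metabolites = mets,
                  reactions = rxns, objective = objective,
                  genes = if (length(genes)) genes else NULL)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(model$reactions, function(r) {
    list(id = r$id, metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = deparse_gpr(r$gpr),
         objective_coefficient = if (r$id == model$objective) 1 else 0)
  })
  doc <- list(id = model$id, metabolites = mets, reactions = unname(rxns),
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

strip_sid <- function(x, prefix) ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)

sbml_num <- function(x) {
  if (is.infinite(x)) (if (x > 0) "INF" else "-INF") else sprintf("%.17g", x)
}

sbml_parse_num <- function(s) {
  if (is.na(s)) return(NA_real_)
  if (s == "INF") return(Inf)
  if (s == "-INF") return(-Inf)
  as.numeric(s)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e)))
  ln <- function(node, name) xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
  model_node <- ln(doc, "model")
  if (!length(model_node)) stop("SBML file ", path, ": no <model> element")
  model_node <- model_node[[1]]
  # attribute lookup by local name, tolerant of namespace prefixes (fbc:...)
  attr_of <- function(node, name) {
    at <- xml2::xml_attrs(node)
    hits <- which(sub("^.*:", "", names(at)) == name)
    if (!length(hits)) NA_character_ else unname(at[[hits[1]]])
  }

  sp <- ln(model_node, "species")
  mets <- do.call(rbind, lapply(sp, function(s) {
    comp <- attr_of(s, "compartment")
    if (is.na(comp) || !nzchar(comp)) {
      stop("SBML file ", path, ": species ", attr_of(s, "id"), " has no compartment")
    }
    metabolite(id = strip_sid(attr_of(s, "id"), "M_"),
               name = ifelse(is.na(attr_of(s, "name")), strip_sid(attr_of(s, "id"), "M_"),
                             attr_of(s, "name")),
               compartment = comp,
               formula = attr_of(s, "chemicalFormula"),
               charge = suppressWarnings(as.integer(attr_of(s, "charge"))))
  }))
  params <- ln(model_node, "parameter")
  pvals <- stats::setNames(vapply(params, function(p) sbml_parse_num(attr_of(p, "value")),
                                  numeric(1)),
                           vapply(params, function(p) attr_of(p, "id"), character(1)))
  gps <- ln(model_node, "geneProduct")
  gene_labels <- stats::setNames(
    vapply(gps, function(g) {
      lb <- attr_of(g, "label")
      if (is.na(lb)) strip_sid(attr_of(g, "id"), "G_") else lb
    }, character(1)),
    vapply(gps, function(g) attr_of(g, "id"), character(1)))

  parse_assoc <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      gid <- attr_of(node, "geneProduct")
      lab <- if (gid %in% names(gene_labels)) gene_labels[[gid]] else strip_sid(gid, "G_")
      return(structure(list(op = "gene", gene = lab), class = "gpr"))
    }
    kids <- lapply(xml2::xml_children(node), parse_assoc)
    kids <- kids[!vapply(kids, is.null, logical(1))]
    if (!length(kids)) return(NULL)
    structure(list(op = nm, children = kids), class = "gpr")
  }

  rxn_nodes <- ln(model_node, "reaction")
  rxns <- lapply(rxn_nodes, function(rn) {
    rid <- strip_sid(attr_of(rn, "id"), "R_")
    st <- numeric(0)
    for (sr in ln(rn, "speciesReference")) {
      parent <- xml2::xml_name(xml2::xml_parent(sr))
      coef <- sbml_parse_num(attr_of(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (parent == "listOfReactants") coef <- -coef
      met <- strip_sid(attr_of(sr, "species"), "M_")
      st[met] <- (if (met %in% names(st)) st[[met]] else 0) + coef
    }
    lbp <- attr_of(rn, "lowerFluxBound"); ubp <- attr_of(rn, "upperFluxBound")
    lb <- if (!is.na(lbp) && lbp %in% names(pvals)) pvals[[lbp]] else -Inf
    ub <- if (!is.na(ubp) && ubp %in% names(pvals)) pvals[[ubp]] else Inf
    assoc <- ln(rn, "geneProductAssociation")
    gpr <- if (length(assoc)) {
      kids <- xml2::xml_children(assoc[[1]])
      if (length(kids)) parse_assoc(kids[[1]]) else NULL
    } else NULL
    reaction(id = rid, stoichiometry = st, lower_bound = lb, upper_bound = ub, gpr = gpr)
  })

  fo <- ln(model_node, "fluxObjective")
  objective <- NULL
  for (f in fo) {
    coef <- sbml_parse_num(attr_of(f, "coefficient"))
    if (!is.na(coef) && coef != 0) objective <- strip_sid(attr_of(f, "reaction"), "R_")
  }
  if (is.null(objective)) stop("SBML file ", path, ": no active flux objective found")
  metabolic_model(id = attr_of(model_node, "id"), metabolites = mets,
                  reactions = rxns, objective = objective,
                  genes = unname(gene_labels))
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_CORE_NS, SBML_FBC_NS),
    sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))
  comps <- unique(model$metabolites$compartment)
  lines <- c(lines, "    <listOfCompartments>",
             sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
             "    </listOfCompartments>", "    <listOfSpecies>")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    extra <- ""
    if (!is.na(m$formula)) extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"', esc(m$formula)))
    if (!is.na(m$charge)) extra <- paste0(extra, sprintf(' fbc:charge="%d"', m$charge))
    lines <- c(lines, sprintf(
      '      <species id="M_%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      esc(m$id), esc(m$name), esc(m$compartment), extra))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfParameters>")
  for (r in model$reactions) {
    lines <- c(lines,
      sprintf('      <parameter id="R_%s_lb" value="%s" constant="true"/>', esc(r$id), sbml_num(r$lower_bound)),
      sprintf('      <parameter id="R_%s_ub" value="%s" constant="true"/>', esc(r$id), sbml_num(r$upper_bound)))
  }
  lines <- c(lines, "    </listOfParameters>", "    <listOfReactions>")
  assoc_xml <- function(rule, indent) {
    pad <- strrep(" ", indent)
    if (rule$op == "gene") {
      return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', pad, esc(rule$gene)))
    }
    tag <- if (rule$op == "and") "fbc:and" else "fbc:or"
    c(sprintf("%s<%s>", pad, tag),
      unlist(lapply(rule$children, assoc_xml, indent = indent + 2L)),
      sprintf("%s</%s>", pad, tag))
  }
  for (r in model$reactions) {
    rev <- if (r$lower_bound < 0) "true" else "false"
    open <- sprintf(
      '      <reaction id="R_%s" reversible="%s" fast="false" fbc:lowerFluxBound="R_%s_lb" fbc:upperFluxBound="R_%s_ub"',
      esc(r$id), rev, esc(r$id), esc(r$id))
    body <- character(0)
    reac <- r$stoichiometry[r$stoichiometry < 0]
    prod <- r$stoichiometry[r$stoichiometry > 0]
    if (length(reac)) {
      body <- c(body, "        <listOfReactants>",
        sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                esc(names(reac)), vapply(-reac, sbml_num, character(1))),
        "        </listOfReactants>")
    }
    if (length(prod)) {
      body <- c(body, "        <listOfProducts>",
        sprintf('          <speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                esc(names(prod)), vapply(prod, sbml_num, character(1))),
        "        </listOfProducts>")
    }
    if (!is.null(r$gpr)) {
      body <- c(body, "        <fbc:geneProductAssociation>",
                assoc_xml(r$gpr, 10L), "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, paste0(open, ">"), body, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>",
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>', esc(model$objective)),
    "        </fbc:listOfFluxObjectives>", "      </fbc:objective>",
    "    </fbc:listOfObjectives>")
  if (length(model$genes)) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              esc(model$genes), esc(model$genes)),
      "    </fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}
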