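#' Parse a gene-protein-reaction rule
#'
#' Parses the textual boolean dialect used by draft genome-scale models, e.g.
#' `"(g1 and g2) or g3"`, into an expression tree. `and` marks enzyme
#' complexes, `or` marks isozymes; both keywords are case-insensitive.
#'
#' @param text a single rule string; `NA` or `""` yields `NULL` (no rule).
#' @return an object of class `gpr`: either a gene leaf
#'   (`list(op = "gene", gene = <id>)`) or an internal node
#'   (`list(op = "and"|"or", children = list(...))`).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L }

  parse_or <- function() {
    node <- parse_and()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      kids[[length(kids) + 1L]] <- parse_and()
    }
    if (length(kids) == 1L) kids[[1L]] else structure(list(op = "or", children = kids), class = "gpr")
  }
  parse_and <- function() {
    node <- parse_atom()
    kids <- list(node)
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      kids[[length(kids) + 1L]] <- parse_atom()
    }
    if (length(kids) == 1L) kids[[1L]] else structure(list(op = "and", children = kids), class = "gpr")
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) stop("malformed GPR rule: unexpected end of input in ", sQuote(text))
    if (tk == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("malformed GPR rule: missing ')' in ", sQuote(text))
      advance()
      return(node)
    }
    if (tk == ")" || tolower(tk) %in% c("and", "or")) {
      stop("malformed GPR rule: unexpected token ", sQuote(tk), " in ", sQuote(text))
    }
    advance()
    structure(list(op = "gene", gene = tk), class = "gpr")
  }

  out <- parse_or()
  if (pos <= length(toks)) {
    stop("malformed GPR rule: trailing tokens after position ", pos, " in ", sQuote(text))
  }
  out
}

#' Genes referenced by a rule
#' @param rule a `gpr` object (or `NULL`).
#' @return character vector of gene identifiers.
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_genes)))
}

#' Render a rule back to its textual form
#' @param rule a `gpr` object.
#' @return a single string, `""` for `NULL`.
#' @export
deparse_gpr <- function(rule) {
  if (is.null(rule)) return("")
  if (rule$op == "gene") return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    s <- deparse_gpr(ch)
    if (ch$op != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Evaluate a GPR rule on gene scores
#'
#' Complexes (`and`) are limited by their scarcest subunit and evaluate to the
#' minimum of the child scores; isozymes (`or`) act in parallel and evaluate
#' to the sum. Genes absent from `gene_scores` are filled according to
#' `missing_policy`.
#'
#' @param rule a `gpr` object from [parse_gpr()]; must be non-empty.
#' @param gene_scores named non-negative numeric vector of per-gene scores
#'   (linear scale, e.g. back-transformed normalised expression).
#' @param missing_policy one of `"median"` (default: impute the median of
#'   `gene_scores`), `"zero"`, or a single numeric value.
#' @return a single numeric score.
#' @examples
#' evaluate_gpr(parse_gpr("g1 and g2"), c(g1 = 2, g2 = 4)) # 2
#' evaluate_gpr(parse_gpr("g1 or g2"), c(g1 = 2, g2 = 4))  # 6
#' @export
evaluate_gpr <- function(rule, gene_scores, missing_policy = "median") {
  if (is.null(rule)) stop("empty GPR rule cannot be evaluated")
  if (is.character(rule)) rule <- parse_gpr(rule)
  stopifnot(all(gene_scores >= 0))
  fill <- if (is.numeric(missing_policy)) {
    missing_policy
  } else if (identical(missing_policy, "zero")) {
    0
  } else if (identical(missing_policy, "median")) {
    if (length(gene_scores)) stats::median(gene_scores) else 0
  } else stop("unknown missing_policy: ", missing_policy)

  eval_node <- function(node) {
    if (node$op == "gene") {
      if (node$gene %in% names(gene_scores)) return(unname(gene_scores[[node$gene]]))
      return(fill)
    }
    vals <- vapply(node$children, eval_node, numeric(1))
    if (node$op == "and") min(vals) else sum(vals)
  }
  eval_node(rule)
}
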