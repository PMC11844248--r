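#' Per-member exchange flux table
#'
#' One record per member-lumen exchange with |flux| at or above the reporting
#' tolerance, in mmol per gDW of that member per hour, export-positive
#' (negative = uptake, positive = release). Environmental exchanges are
#' appended under the pseudo-member `"environment"` with the sign flipped to
#' the environment's own perspective, so that for every metabolite the
#' abundance-weighted member fluxes plus the environment row sum to zero
#' (lumen balance).
#'
#' @param sol a `ct_flux_solution` computed on `cm`.
#' @param cm the `ct_community`.
#' @param condition optional condition label copied into the table.
#' @return `data.frame` with columns `member`, `metabolite`, `flux`,
#'   `condition`.
#' @export
exchange_table <- function(sol, cm, condition = "") {
  stopifnot(inherits(sol, "ct_flux_solution"), inherits(cm, "ct_community"))
  if (!all(cm$reactions$id %in% names(sol$fluxes))) {
    stop("flux solution does not match this community model")
  }
  tau <- sol$tol
  ex <- cm$reactions[cm$reactions$type == "member_exchange", , drop = FALSE]
  v <- unname(sol$fluxes[ex$id])
  keep <- abs(v) >= tau
  out <- data.frame(member = ex$member[keep], metabolite = ex$metabolite[keep],
                    flux = v[keep], stringsAsFactors = FALSE)
  env <- cm$reactions[cm$reactions$type == "env_exchange", , drop = FALSE]
  ve <- -unname(sol$fluxes[env$id])  # environment-side perspective
  keepe <- abs(ve) >= tau
  out <- rbind(out, data.frame(member = "environment",
                               metabolite = env$metabolite[keepe],
                               flux = ve[keepe], stringsAsFactors = FALSE))
  out$condition <- condition
  rownames(out) <- NULL
  out
}

#' Extract the producer-to-consumer cross-feeding network
#'
#' For every lumen metabolite with at least one exporting and one importing
#' member, edges connect each (exporter, importer) pair. The transferable
#' community-weighted amount `min(total weighted export, total weighted
#' import)` is allocated to pairs proportionally to each party's share of its
#' side's total; flux that instead comes from or goes to the environment
#' creates no member edge. Edges never connect a member to itself and edges
#' below the tolerance are dropped, so the network is a pure function of the
#' flux solution.
#'
#' @inheritParams exchange_table
#' @return `data.frame` with columns `producer`, `consumer`, `metabolite`,
#'   `flux` (community-weighted, mmol/gDW_community/h).
#' @export
crossfeeding_network <- function(sol, cm) {
  stopifnot(inherits(sol, "ct_flux_solution"), inherits(cm, "ct_community"))
  tau <- sol$tol
  ex <- cm$reactions[cm$reactions$type == "member_exchange", , drop = FALSE]
  a <- stats::setNames(cm$members$abundance, cm$members$id)
  v <- unname(sol$fluxes[ex$id])
  w <- v * a[ex$member]  # community-weighted member exchange
  edges <- list()
  for (met in unique(ex$metabolite)) {
    sel <- ex$metabolite == met
    exp_i <- which(sel & w > tau)
    imp_i <- which(sel & w < -tau)
    if (!length(exp_i) || !length(imp_i)) next
    tot_exp <- sum(w[exp_i]); tot_imp <- sum(-w[imp_i])
    transfer <- min(tot_exp, tot_imp)
    for (p in exp_i) {
      for (q in imp_i) {
        if (ex$member[p] == ex$member[q]) next
        fl <- transfer * (w[p] / tot_exp) * (-w[q] / tot_imp)
        if (fl > tau) {
          edges[[length(edges) + 1L]] <- data.frame(
            producer = ex$member[p], consumer = ex$member[q], metabolite = met,
            flux = fl, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(edges)) {
    return(data.frame(producer = character(0), consumer = character(0),
                      metabolite = character(0), flux = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, edges)
}

#' Compare exchange fluxes across conditions
#'
#' Aligns exchange tables over replicates and conditions: per member and
#' metabolite, the mean and standard deviation over replicates within each
#' condition, plus pairwise condition deltas of the means.
#'
#' @param tables named list: condition -> list of exchange tables (one per
#'   replicate), or condition -> a single table.
#' @return list with `summary` (member x metabolite x condition mean/sd) and
#'   `deltas` (pairwise differences of condition means; empty with a single
#'   condition).
#' @export
compare_conditions <- function(tables) {
  stopifnot(length(tables) >= 1L)
  conds <- names(tables)
  rows <- list()
  for (cd in conds) {
    reps <- tables[[cd]]
    if (is.data.frame(reps)) reps <- list(reps)
    allr <- do.call(rbind, lapply(seq_along(reps), function(i) {
      d <- reps[[i]]; d$replicate <- i; d
    }))
    agg <- stats::aggregate(flux ~ member + metabolite, data = allr,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                                n = length(x)))
    rows[[cd]] <- data.frame(condition = cd, member = agg$member,
                             metabolite = agg$metabolite,
                             mean = agg$flux[, "mean"],
                             sd = ifelse(is.na(agg$flux[, "sd"]), 0, agg$flux[, "sd"]),
                             n = agg$flux[, "n"], stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  member_sets <- lapply(rows, function(r) unique(r$member))
  if (length(conds) > 1L && length(Reduce(intersect, member_sets)) == 0L) {
    warning("conditions share no members; outer join with missing markers")
  }
  deltas <- NULL
  if (length(conds) > 1L) {
    pairs <- utils::combn(conds, 2, simplify = FALSE)
    deltas <- do.call(rbind, lapply(pairs, function(pr) {
      m1 <- rows[[pr[1]]]; m2 <- rows[[pr[2]]]
      mg <- merge(m1[, c("member", "metabolite", "mean")],
                  m2[, c("member", "metabolite", "mean")],
                  by = c("member", "metabolite"), all = TRUE,
                  suffixes = c("_1", "_2"))
      data.frame(condition_1 = pr[1], condition_2 = pr[2],
                 member = mg$member, metabolite = mg$metabolite,
                 mean_1 = mg$mean_1, mean_2 = mg$mean_2,
                 delta = mg$mean_1 - mg$mean_2, stringsAsFactors = FALSE)
    }))
  } else {
    deltas <- data.frame(condition_1 = character(0), condition_2 = character(0),
                         member = character(0), metabolite = character(0),
                         mean_1 = numeric(0), mean_2 = numeric(0),
                         delta = numeric(0), stringsAsFactors = FALSE)
  }
  list(summary = summary, deltas = deltas)
}

#' Export a cross-feeding network
#'
#' @param edges output of [crossfeeding_network()].
#' @param path destination; `.graphml` writes GraphML via igraph, anything
#'   else a TSV edge list (`producer`, `metabolite`, `consumer`, `flux`).
#' @export
write_crossfeeding <- function(edges, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$producer, to = edges$consumer,
                 metabolite = edges$metabolite, flux = edges$flux),
      directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    utils::write.table(edges[, c("producer", "metabolite", "consumer", "flux")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
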