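#' Integration parameters for transcriptomics-constrained bounds
#'
#' @param alpha steepness of the expression penalty, searched over
#'   `[0.1, 10]` during calibration.
#' @param beta cap scale of the bound weight (fixed at 1.0: expression never
#'   boosts a reaction above its base bounds).
#' @param reference_quantile member-wise quantile of reaction scores used as
#'   the "fully expressed" reference (default 0.75, robust to the
#'   dominant-methanogen expression skew).
#' @return list of class `ct_integration_params`.
#' @export
integration_params <- function(alpha = 1, beta = 1, reference_quantile = 0.75) {
  stopifnot(alpha > 0, beta > 0, reference_quantile > 0, reference_quantile < 1)
  structure(list(alpha = alpha, beta = beta, reference_quantile = reference_quantile),
            class = "ct_integration_params")
}

#' Reaction-level expression scores from member log expression
#'
#' Log-scale normalised expression (from [log_normalize()], restricted to one
#' member's genes) is back-transformed to the linear scale
#' (`2^x - pseudocount`, clipped at 0) and propagated through each reaction's
#' GPR rule (complex = min, isozymes = sum). Scoring on the linear scale
#' keeps the isozyme sum additive in transcript abundance. Reactions without
#' a GPR get no score.
#'
#' @param model a member [metabolic_model()].
#' @param member_log_expr named numeric vector: gene -> log2-scale value.
#' @param pseudocount the pseudocount used in the log transform (default 1).
#' @param missing_policy passed to [evaluate_gpr()] for genes missing from
#'   `member_log_expr`.
#' @return named numeric vector: reaction id -> linear-scale score.
#' @export
reaction_expression_scores <- function(model, member_log_expr, pseudocount = 1,
                                       missing_policy = "median") {
  linear <- pmax(2^member_log_expr - pseudocount, 0)
  scored <- Filter(function(r) !is.null(r$gpr), model$reactions)
  vapply(scored, function(r) evaluate_gpr(r$gpr, linear, missing_policy),
         numeric(1))
}

#' Scale reaction bounds by expression weight
#'
#' Each scored reaction's bounds are multiplied by
#' `w_r = beta * min(1, (E_r / E_ref)^alpha)` where `E_ref` is the member-wise
#' `reference_quantile` of the reaction scores. Under-expressed reactions are
#' penalised; nothing is ever boosted above its base bounds, and unscored
#' reactions (no GPR) are untouched. Signs are preserved, so a reversible
#' reaction shrinks symmetrically.
#'
#' @param model a member [metabolic_model()].
#' @param scores output of [reaction_expression_scores()].
#' @param params an [integration_params()].
#' @return the model with scaled bounds.
#' @export
expression_bounds <- function(model, scores, params = integration_params()) {
  stopifnot(inherits(params, "ct_integration_params"))
  if (!length(scores)) return(model)
  e_ref <- stats::quantile(scores, params$reference_quantile, names = FALSE)
  if (e_ref <= 0) stop("expression_bounds: all reaction scores are zero; no reference")
  for (rid in names(scores)) {
    if (!rid %in% names(model$reactions)) next
    w <- params$beta * min(1, (scores[[rid]] / e_ref)^params$alpha)
    model$reactions[[rid]]$lower_bound <- model$reactions[[rid]]$lower_bound * w
    model$reactions[[rid]]$upper_bound <- model$reactions[[rid]]$upper_bound * w
  }
  model
}

#' Calibrate the trade-off fraction and expression penalty
#'
#' Grid search over `(f, alpha)`: for every grid point, each dataset's member
#' models get expression-scaled bounds, the community is rebuilt, ctFBA is
#' run, and the predicted community growth `sum(a_i mu_i)` is recorded. The
#' point maximising Pearson correlation between predicted and measured
#' community growth rates is selected.
#'
#' Because the stage-2 trade-off constraint always binds, predictions at a
#' fixed `alpha` are exactly proportional across `f` and Pearson's r cannot
#' separate `f` values on its own; correlation ties (within `1e-9`) are
#' therefore broken by the smaller root-mean-square error between predicted
#' and measured growth, then by smaller `alpha` (the weaker constraint), then
#' by larger `f`.
#'
#' @param datasets a list; each element a list with `models` (named list of
#'   member models), `abundances` (named), `medium` (named numeric),
#'   `expression` (named list: member -> named log2 expression vector), and
#'   `measured_growth` (a single number, 1/h).
#' @param f_grid trade-off fractions (default `seq(0.1, 1, by = 0.1)`).
#' @param alpha_grid penalty steepness values (default 10 log-spaced points
#'   in `[0.1, 10]`).
#' @param params base [integration_params()]; `alpha` is overridden by the grid.
#' @param abundance_threshold passed to [build_community()].
#' @return list of class `ct_calibration`: `grid` (data.frame `f`, `alpha`,
#'   `r`, `rmse`), `best` (list `f`, `alpha`), `predictions` (data.frame with
#'   per-dataset predicted and measured growth at the best point).
#' @export
calibrate <- function(datasets, f_grid = seq(0.1, 1, by = 0.1),
                      alpha_grid = 10^seq(-1, 1, length.out = 10),
                      params = integration_params(),
                      abundance_threshold = 0.01) {
  stopifnot(length(f_grid) >= 1, length(alpha_grid) >= 1)
  nd <- length(datasets)
  if (nd < 3L) warning("fewer than 3 datasets: Pearson correlation is degenerate")
  measured <- vapply(datasets, `[[`, numeric(1), "measured_growth")

  # mu_star depends on alpha (through the scaled bounds) but not on f
  mu_star_tab <- matrix(NA_real_, nrow = length(alpha_grid), ncol = nd)
  pred <- array(NA_real_, dim = c(length(f_grid), length(alpha_grid), nd))
  for (ai in seq_along(alpha_grid)) {
    p <- integration_params(alpha = alpha_grid[ai], beta = params$beta,
                            reference_quantile = params$reference_quantile)
    for (di in seq_len(nd)) {
      ds <- datasets[[di]]
      scaled <- ds$models
      for (mb in names(scaled)) {
        expr <- ds$expression[[mb]]
        if (is.null(expr)) next
        sc <- reaction_expression_scores(scaled[[mb]], expr)
        scaled[[mb]] <- expression_bounds(scaled[[mb]], sc, p)
      }
      cmx <- apply_medium(
        build_community(scaled, ds$abundances, abundance_threshold), ds$medium)
      for (fi in seq_along(f_grid)) {
        tr <- cooperative_tradeoff(cmx, f_grid[fi])
        pred[fi, ai, di] <- tr$community_growth
        mu_star_tab[ai, di] <- tr$mu_star
      }
    }
  }

  grid <- expand.grid(f = f_grid, alpha = alpha_grid, KEEP.OUT.ATTRS = FALSE)
  grid$r <- NA_real_; grid$rmse <- NA_real_
  for (k in seq_len(nrow(grid))) {
    fi <- match(grid$f[k], f_grid); ai <- match(grid$alpha[k], alpha_grid)
    p <- pred[fi, ai, ]
    grid$rmse[k] <- sqrt(mean((p - measured)^2))
    if (stats::sd(p) > 1e-12 && stats::sd(measured) > 1e-12) {
      grid$r[k] <- stats::cor(p, measured)
    } # else: constant predictions, r undefined -> stays NA, never best
  }
  if (all(is.na(grid$r))) stop("calibration failed: r undefined at every grid point")
  rmax <- max(grid$r, na.rm = TRUE)
  cand <- which(!is.na(grid$r) & grid$r >= rmax - 1e-9)
  cand <- cand[order(grid$rmse[cand], grid$alpha[cand], -grid$f[cand])]
  best <- cand[1]
  fi <- match(grid$f[best], f_grid); ai <- match(grid$alpha[best], alpha_grid)
  structure(list(
    grid = grid,
    best = list(f = grid$f[best], alpha = grid$alpha[best],
                r = grid$r[best], rmse = grid$rmse[best]),
    predictions = data.frame(dataset = seq_len(nd),
                             predicted = pred[fi, ai, ],
                             measured = measured)
  ), class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat("<ct_calibration> best: f =", x$best$f, " alpha =", signif(x$best$alpha, 4),
      " (r =", signif(x$best$r, 4), ", rmse =", signif(x$best$rmse, 4), ")\n")
  invisible(x)
}

#' Write calibration outputs
#' @param cal a `ct_calibration`.
#' @param grid_path TSV destination for the (f, alpha, r) grid.
#' @param best_path JSON destination for the chosen parameters.
#' @param pred_path optional TSV of predicted vs measured growth.
#' @export
write_calibration <- function(cal, grid_path, best_path, pred_path = NULL) {
  utils::write.table(cal$grid, grid_path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cal$best, best_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(pred_path)) {
    utils::write.table(cal$predictions, pred_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(cal)
}
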