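#' Construct an RNA fragment count matrix
#'
#' @param counts gene x sample matrix of non-negative integer fragment counts
#'   (rownames = gene ids, colnames = sample ids).
#' @param gene_lengths named vector of gene lengths in bp (> 0), covering all
#'   genes.
#' @param gene_member named character vector mapping every gene to the
#'   community member (MAG) it belongs to.
#' @return a list of class `ct_counts`.
#' @export
count_matrix <- function(counts, gene_lengths, gene_member) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  genes <- rownames(counts)
  missing_len <- setdiff(genes, names(gene_lengths))
  if (length(missing_len)) stop("genes without length: ", paste(missing_len, collapse = ", "))
  if (any(gene_lengths[genes] <= 0)) stop("gene lengths must be > 0")
  missing_mem <- setdiff(genes, names(gene_member))
  if (length(missing_mem)) stop("genes without member assignment: ",
                                paste(missing_mem, collapse = ", "))
  structure(list(counts = counts, gene_lengths = gene_lengths[genes],
                 gene_member = gene_member[genes]), class = "ct_counts")
}

#' @export
print.ct_counts <- function(x, ...) {
  cat("<ct_counts>", nrow(x$counts), "genes x", ncol(x$counts), "samples;",
      length(unique(x$gene_member)), "members\n")
  invisible(x)
}

#' Split a count matrix by community member
#'
#' Per-MAG count tables are processed separately downstream so that shifts in
#' taxonomic composition do not masquerade as transcriptional changes within
#' a taxon.
#'
#' @param cm a [count_matrix()].
#' @return named list of `ct_counts`, one per member; genes are partitioned.
#' @export
split_counts_by_member <- function(cm) {
  stopifnot(inherits(cm, "ct_counts"))
  members <- unique(cm$gene_member)
  out <- lapply(members, function(mb) {
    g <- names(cm$gene_member)[cm$gene_member == mb]
    count_matrix(cm$counts[g, , drop = FALSE], cm$gene_lengths[g], cm$gene_member[g])
  })
  stats::setNames(out, members)
}

#' Median-of-ratios size factors
#'
#' For each sample j, `s_j` is the median over genes of the ratio of the
#' gene's count to its geometric mean across samples; genes with any zero
#' count are excluded (they have no finite log geometric mean). This is the
#' standard sequencing-depth/composition correction for count matrices.
#'
#' @param cm a [count_matrix()] (or a bare numeric matrix).
#' @return named positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(cm) {
  counts <- if (inherits(cm, "ct_counts")) cm$counts else as.matrix(cm)
  pos <- rowSums(counts == 0) == 0L
  if (!any(pos)) stop("size_factors: no gene has all-positive counts")
  lc <- log(counts[pos, , drop = FALSE])
  logmeans <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - logmeans)))
  if (any(!is.finite(sf) | sf <= 0)) stop("size_factors: non-positive factor computed")
  sf
}

#' Normalised fragments per kilobase
#'
#' `nFPK[g, j] = (count[g, j] / s_j) / (length_g / 1000)`: counts are first
#' depth-normalised with size factors, then divided by gene length in kb.
#'
#' @param cm a [count_matrix()].
#' @param sf size factors covering every sample (default: computed from `cm`).
#' @return gene x sample numeric matrix.
#' @export
nfpk <- function(cm, sf = size_factors(cm)) {
  stopifnot(inherits(cm, "ct_counts"))
  missing_s <- setdiff(colnames(cm$counts), names(sf))
  if (length(missing_s)) stop("size factors missing for samples: ",
                              paste(missing_s, collapse = ", "))
  if (any(cm$gene_lengths == 0)) stop("zero gene length")
  sweep(sweep(cm$counts, 2, sf[colnames(cm$counts)], `/`),
        1, cm$gene_lengths / 1000, `/`)
}

#' Non-normalised fragments per kilobase (FPK)
#'
#' Count divided by gene length in kb, without size-factor correction. Used
#' for marker-gene activity read-outs where both taxon abundance and
#' expression should contribute.
#'
#' @inheritParams nfpk
#' @return gene x sample numeric matrix.
#' @export
fpk <- function(cm) {
  stopifnot(inherits(cm, "ct_counts"))
  sweep(cm$counts, 1, cm$gene_lengths / 1000, `/`)
}

#' Log-scale normalised counts
#'
#' `log2(count / s_j + pseudocount)`, the logarithmic transform applied before
#' expression integration into metabolic models.
#'
#' @inheritParams nfpk
#' @param pseudocount positive offset, default 1 (so zero counts map to 0).
#' @return gene x sample numeric matrix.
#' @export
log_normalize <- function(cm, sf = size_factors(cm), pseudocount = 1) {
  stopifnot(inherits(cm, "ct_counts"), pseudocount > 0)
  missing_s <- setdiff(colnames(cm$counts), names(sf))
  if (length(missing_s)) stop("size factors missing for samples: ",
                              paste(missing_s, collapse = ", "))
  log2(sweep(cm$counts, 2, sf[colnames(cm$counts)], `/`) + pseudocount)
}

#' Construct an OD growth curve
#'
#' @param times sampling times in hours, strictly increasing (>= 2 points).
#' @param od optical densities, all positive.
#' @param reactor,condition labels.
#' @return list of class `ct_growth_curve`.
#' @export
growth_curve <- function(times, od, reactor = "R1", condition = "") {
  stopifnot(length(times) == length(od), length(times) >= 2L)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(od <= 0)) stop("OD values must be positive")
  structure(list(times = times, od = od, reactor = reactor, condition = condition),
            class = "ct_growth_curve")
}

#' Growth rate by semi-logarithmic interpolation of OD
#'
#' Least-squares slope of `ln(OD)` against time within a window. When no
#' window is given, the widest contiguous window whose ln-linear fit reaches
#' R^2 >= `r2_min` is used (ties broken by higher R^2), which targets the
#' exponential growth phase.
#'
#' @param curve a [growth_curve()].
#' @param window optional numeric `c(t_min, t_max)` in hours.
#' @param r2_min minimum R^2 for the automatic window (default 0.98).
#' @return list with `rate` (1/h), `r_squared`, `window`, `n_points`.
#' @export
growth_rate_from_od <- function(curve, window = NULL, r2_min = 0.98) {
  stopifnot(inherits(curve, "ct_growth_curve"))
  t <- curve$times; y <- log(curve$od)
  fit_win <- function(idx) {
    tt <- t[idx]; yy <- y[idx]
    slope <- if (stats::var(tt) == 0) 0 else stats::cov(tt, yy) / stats::var(tt)
    pred <- mean(yy) + slope * (tt - mean(tt))
    ssr <- sum((yy - pred)^2); sst <- sum((yy - mean(yy))^2)
    r2 <- if (sst < 1e-30) 1 else 1 - ssr / sst
    list(rate = slope, r_squared = r2, window = range(tt), n_points = length(idx))
  }
  if (!is.null(window)) {
    idx <- which(t >= window[1] & t <= window[2])
    if (length(idx) < 2L) stop("window selects fewer than 2 OD points")
    return(fit_win(idx))
  }
  n <- length(t)
  best <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      f <- fit_win(i:j)
      if (f$r_squared >= r2_min - 1e-12) {
        if (is.null(best) || f$n_points > best$n_points ||
            (f$n_points == best$n_points && f$r_squared > best$r_squared)) {
          best <- f
        }
      }
    }
  }
  if (is.null(best)) best <- fit_win(seq_len(n)) # no ln-linear stretch: fall back to full fit
  best
}

#' Absolute abundance from OD and relative abundances
#'
#' Member-wise product of community optical density and relative abundance,
#' a proxy for absolute biomass per taxon.
#'
#' @param od a single non-negative OD value.
#' @param relative_abundances named vector of fractions in `[0, 1]`.
#' @return named vector, same names, `od * fraction`.
#' @export
absolute_abundance <- function(od, relative_abundances) {
  stopifnot(od >= 0, all(relative_abundances >= 0), all(relative_abundances <= 1))
  if (sum(relative_abundances) > 1 + 1e-6) {
    stop("relative abundances sum to more than 1")
  }
  od * relative_abundances
}

#' Read a count matrix from TSV files
#'
#' @param counts_path TSV with a `gene` column then one column per sample.
#' @param meta_path TSV with columns `gene`, `length_bp`, `member`.
#' @return a [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, meta_path) {
  ct <- utils::read.delim(counts_path, check.names = FALSE)
  meta <- utils::read.delim(meta_path, check.names = FALSE)
  stopifnot("gene" %in% names(ct), all(c("gene", "length_bp", "member") %in% names(meta)))
  m <- as.matrix(ct[, setdiff(names(ct), "gene"), drop = FALSE])
  rownames(m) <- ct$gene
  count_matrix(m, stats::setNames(meta$length_bp, meta$gene),
               stats::setNames(meta$member, meta$gene))
}

#' Read OD time series from TSV
#'
#' @param path TSV with columns `time_h`, `od`, `reactor`, `condition`.
#' @return named list of [growth_curve()] objects, one per reactor.
#' @export
read_od_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot(all(c("time_h", "od", "reactor", "condition") %in% names(d)))
  out <- lapply(split(d, d$reactor), function(g) {
    g <- g[order(g$time_h), ]
    growth_curve(g$time_h, g$od, reactor = g$reactor[1], condition = g$condition[1])
  })
  out
}
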