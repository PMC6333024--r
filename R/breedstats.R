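#' Selective accuracy of genomic selection
#'
#' Converts predictive capacity (GEBV-phenotype correlation) to selective
#' accuracy (GEBV-breeding-value correlation) by dividing out the square
#' root of the heritability: \code{r_gg = r_gy / sqrt(h2)}. When the
#' predictive capacity is not positive the accuracy is undefined and NA is
#' returned — the convention of leaving such entries blank.
#'
#' @param r_gy Predictive capacity.
#' @param h2 Heritability in (0, 1], normally the genomic heritability.
#' @return Accuracy, or NA when \code{r_gy <= 0}.
#' @export
accuracy_gs <- function(r_gy, h2) {
  if (any(h2 <= 0) || any(h2 > 1)) stop("h2 must be in (0, 1]", call. = FALSE)
  ifelse(r_gy > 0, r_gy / sqrt(h2), NA_real_)
}

#' Effective number of QTL controlling a trait
#'
#' Back-calculated from accuracy, population size and heritability:
#' \code{nQTL = (1 - r_gg^2) N h2 / r_gg^2}.
#'
#' @param r_gg Selective accuracy in (0, 1].
#' @param n Population size.
#' @param h2 Individual heritability.
#' @return Effective QTL number (positive real; round for display).
#' @export
n_qtl <- function(r_gg, n, h2) {
  if (any(r_gg <= 0) || any(r_gg > 1))
    stop("r_gg must be in (0, 1]", call. = FALSE)
  (1 - r_gg^2) * n * h2 / r_gg^2
}

#' Population size required for a target accuracy
#'
#' The inverse of \code{\link{n_qtl}}: \code{Ni = r_ggd^2 nQTL /
#' ((1 - r_ggd^2) h2)}, monotone increasing in the target accuracy and
#' diverging as it approaches 1.
#'
#' @param r_ggd Target accuracy in (0, 1).
#' @param n_qtl Number of QTL controlling the trait.
#' @param h2 Individual heritability.
#' @return Required number of individuals (positive real).
#' @export
n_individuals <- function(r_ggd, n_qtl, h2) {
  if (any(r_ggd < 0) || any(r_ggd >= 1))
    stop("r_ggd must be in [0, 1)", call. = FALSE)
  r_ggd^2 * n_qtl / ((1 - r_ggd^2) * h2)
}

#' Selective efficiency of genomic over phenotypic selection
#'
#' Gain per unit time of GS relative to phenotypic selection:
#' \code{Ef = (r_gg L_f) / (r_yy L_GS)}, with L_f the phenotypic and
#' L_GS the genomic selection-cycle length in years. Ef > 1 means GS
#' gains more per year.
#'
#' @param r_gg GS selective accuracy.
#' @param r_yy Phenotypic selective accuracy (> 0).
#' @param L_f Phenotypic cycle length in years (default 24: four 6-year
#'   cycles).
#' @param L_GS GS cycle length in years (12 = four 3-year cycles, or 24).
#' @return Efficiency ratio.
#' @export
efficiency <- function(r_gg, r_yy, L_f = 24, L_GS = 12) {
  if (any(r_yy <= 0)) stop("r_yy must be positive", call. = FALSE)
  if (any(L_GS <= 0)) stop("L_GS must be positive", call. = FALSE)
  (r_gg * L_f) / (r_yy * L_GS)
}

#' Chromosome-stratified marker subsample
#'
#' Representative subsampling for the density experiment: the requested
#' panel size is allocated to chromosome groups proportionally to their
#' marker counts (largest-remainder rounding), then markers are drawn
#' uniformly within each group.
#'
#' @param map Marker map (marker_id, chromosome).
#' @param size Number of markers to keep.
#' @param seed Integer seed.
#' @return Character vector of retained marker ids.
#' @export
subsample_markers <- function(map, size, seed = 1L) {
  if (size > nrow(map)) stop("size exceeds available markers", call. = FALSE)
  set.seed(as.integer(seed))
  counts <- table(map$chromosome)
  exact <- size * as.numeric(counts) / nrow(map)
  take <- floor(exact)
  rem <- size - sum(take)
  if (rem > 0) {
    ord <- order(exact - take, decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1L
  }
  take <- pmin(take, as.numeric(counts))
  shortfall <- size - sum(take)   # groups saturated by the +1 round
  ids <- unlist(lapply(seq_along(counts), function(k) {
    pool <- map$marker_id[map$chromosome == names(counts)[k]]
    sample(pool, take[k])
  }), use.names = FALSE)
  if (shortfall > 0)
    ids <- c(ids, sample(setdiff(map$marker_id, ids), shortfall))
  ids
}

#' Marker-density response of predictive accuracy
#'
#' Reruns the cross-validation on chromosome-stratified subpanels of
#' increasing size and reports predictive capacity and selective accuracy
#' per size — the density response of the prediction machinery.
#'
#' @param panel A QC'd \code{marker_panel}.
#' @param y Named corrected phenotypes.
#' @param sizes Panel sizes to evaluate (the full panel size may be
#'   included).
#' @param h2 Heritability used both for the shrinkage variances and for
#'   converting r_gy to accuracy.
#' @param n_folds,strategy,families Passed to \code{\link{make_folds}}.
#' @param seed Integer seed (drives both subsampling and folds).
#' @return Data frame with columns size, r_gy, sd_r, b, r_gg.
#' @export
density_experiment <- function(panel, y, sizes, h2, n_folds = 13L,
                               strategy = "random", families = NULL,
                               seed = 1L) {
  W <- impute_missing(panel$genotypes)
  vy <- stats::var(y)
  sigma_g2 <- h2 * vy; sigma_e2 <- (1 - h2) * vy
  folds <- make_folds(rownames(W), n_folds, strategy, families, seed = seed)
  out <- lapply(sizes, function(s) {
    ids <- if (s == ncol(W)) colnames(W)
           else subsample_markers(panel$map, s, seed = seed + s)
    cv <- cv_run(W[, ids, drop = FALSE], y, folds, sigma_g2, sigma_e2)
    data.frame(size = s, r_gy = cv$r_gy, sd_r = cv$sd_r, b = cv$b,
               r_gg = accuracy_gs(cv$r_gy, h2))
  })
  do.call(rbind, out)
}

#' Assemble the per-trait summary tables
#'
#' Combines the phenotypic (h2_phen, r_yy), genomic (ha2, r_gy, sd_r, b,
#' sd_b) and derived statistics into one row per trait: accuracy r_gg,
#' effective nQTL, required population sizes at the target accuracies, and
#' the selective efficiencies at the two GS cycle lengths. Traits with
#' non-positive predictive capacity get NA (rendered "-") in every derived
#' column.
#'
#' @param stats_list List of per-trait lists with elements \code{trait},
#'   \code{h2_phen}, \code{r_yy}, \code{ha2}, \code{r_gy}, \code{sd_r},
#'   \code{b}, \code{sd_b}.
#' @param n Population size.
#' @param targets Target accuracies for the required-population columns.
#' @param L_f,L_GS Cycle lengths; \code{L_GS} may be a vector.
#' @return A \code{derived_stats} data frame, one row per trait.
#' @export
build_tables <- function(stats_list, n, targets = c(0.5, 0.6, 0.7, 0.8, 0.9),
                         L_f = 24, L_GS = c(12, 24)) {
  rows <- lapply(stats_list, function(s) {
    r_gg <- accuracy_gs(s$r_gy, s$ha2)
    # the chain is left blank when the accuracy is undefined or exceeds 1
    # (a boundary heritability estimate below the squared capacity)
    bad <- is.na(r_gg) || r_gg > 1
    nq <- if (bad) NA_real_ else n_qtl(r_gg, n, s$ha2)
    ni <- if (bad) rep(NA_real_, length(targets))
          else n_individuals(targets, nq, s$ha2)
    ef <- if (bad || s$r_yy <= 0) rep(NA_real_, length(L_GS))
          else efficiency(r_gg, s$r_yy, L_f, L_GS)
    row <- data.frame(trait = s$trait, h2_phen = s$h2_phen, r_yy = s$r_yy,
                      ha2 = s$ha2, r_gy = s$r_gy, sd_r = s$sd_r,
                      b = s$b, sd_b = s$sd_b, r_gg = r_gg, n_qtl = nq,
                      stringsAsFactors = FALSE)
    for (k in seq_along(targets))
      row[[paste0("Ni_", targets[k])]] <- ni[k]
    for (k in seq_along(L_GS))
      row[[paste0("Ef_", L_GS[k])]] <- ef[k]
    row
  })
  if (length(rows) == 0) {
    cols <- c("trait", "h2_phen", "r_yy", "ha2", "r_gy", "sd_r", "b", "sd_b",
              "r_gg", "n_qtl", paste0("Ni_", targets), paste0("Ef_", L_GS))
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)),
                                         cols))
    out$trait <- character(0)
  } else out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("derived_stats", "data.frame")
  out
}

#' Render a derived-statistics table for display
#'
#' Correlations and ratios to two decimals, counts rounded to integers
#' with thousands separators, NA cells as "-".
#'
#' @param x A \code{derived_stats} data frame.
#' @return Character data frame ready for printing or export.
#' @export
format_derived_stats <- function(x) {
  fmt <- function(v, count = FALSE)
    ifelse(is.na(v), "-",
           if (count) formatC(round(v), format = "d", big.mark = ",")
           else formatC(v, format = "f", digits = 2))
  out <- data.frame(trait = x$trait, stringsAsFactors = FALSE)
  for (nm in setdiff(names(x), "trait"))
    out[[nm]] <- fmt(x[[nm]], count = grepl("^(n_qtl|Ni_)", nm))
  out
}
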