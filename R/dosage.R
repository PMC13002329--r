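# Dosage-balance statistics: subfamily-on-total regressions and slope
# ratio, 1-D k-means high/low copy split with group tests, receptor
# correlation, ploidy contrasts and subfamily expression comparison.

#' Subfamily-versus-total dosage regression
#'
#' Fits ordinary least squares of the ASMT count on the total copy number
#' and of the COMT count on the total. Because the two responses sum to the
#' predictor, the two slopes sum to one exactly — the identity that makes
#' the slope ratio an interpretable measure of which subfamily absorbs
#' copy-number growth. Pearson and Spearman correlations of the ASMT
#' proportion against the total quantify the proportion-vs-total trend.
#'
#' @param table copy-number data.frame with columns `asmt`, `comt`, `total`.
#' @return object of class `dosage_regression` with slopes, intercepts,
#'   `slope_ratio` (ASMT slope / COMT slope, `NA` when the COMT slope is
#'   zero), correlation estimates and p-values.
#' @examples
#' tab <- simulate_copy_number_table(200, asmt_share = 0.6, seed = 7)
#' subfamily_regression(tab)
#' @export
subfamily_regression <- function(table) {
  stopifnot(all(c("asmt", "comt", "total") %in% names(table)),
            nrow(table) >= 3)
  if (length(unique(table$total)) < 2) {
    stop("totals are all equal; regression on total is undefined")
  }
  fa <- stats::lm(asmt ~ total, data = table)
  fc <- stats::lm(comt ~ total, data = table)
  sa <- unname(stats::coef(fa)["total"])
  sc <- unname(stats::coef(fc)["total"])
  pa <- summary(fa)$coefficients["total", "Pr(>|t|)"]
  prop <- table$asmt / table$total
  pear <- suppressWarnings(stats::cor.test(prop, table$total,
                                           method = "pearson"))
  spear <- suppressWarnings(stats::cor.test(prop, table$total,
                                            method = "spearman",
                                            exact = FALSE))
  structure(list(
    slope_asmt = sa, slope_comt = sc,
    intercept_asmt = unname(stats::coef(fa)[1]),
    intercept_comt = unname(stats::coef(fc)[1]),
    slope_ratio = if (sc == 0) NA_real_ else sa / sc,
    slope_p = pa,
    pearson_r = unname(pear$estimate), pearson_p = pear$p.value,
    spearman_rho = unname(spear$estimate), spearman_p = spear$p.value,
    n = nrow(table)
  ), class = "dosage_regression")
}

#' @export
print.dosage_regression <- function(x, ...) {
  cat(sprintf("Dosage regression over %d species\n", x$n))
  cat(sprintf("  ASMT slope = %.3f, COMT slope = %.3f, ratio = %s\n",
              x$slope_asmt, x$slope_comt,
              if (is.na(x$slope_ratio)) "undefined"
              else sprintf("%.3f", x$slope_ratio)))
  cat(sprintf("  ASMT-share trend: Pearson r = %.3f (p = %.3g), ",
              x$pearson_r, x$pearson_p))
  cat(sprintf("Spearman rho = %.3f (p = %.3g)\n",
              x$spearman_rho, x$spearman_p))
  invisible(x)
}

#' @export
coef.dosage_regression <- function(object, ...) {
  c(slope_asmt = object$slope_asmt, slope_comt = object$slope_comt,
    intercept_asmt = object$intercept_asmt,
    intercept_comt = object$intercept_comt)
}

#' Split species into high- and low-copy groups by 1-D k-means
#'
#' Lloyd's algorithm with k = 2 on the total copy numbers, initialized
#' deterministically at the two extreme values; in one dimension this
#' converges to a single threshold rule, so every low-group total is below
#' every high-group total. When a per-species statistic is supplied
#' (typically a subfamily proportion), the groups are compared by a Welch
#' two-sided t-test and a Mann-Whitney U test (normal approximation with
#' tie correction).
#'
#' @param totals per-species total copy numbers (>= 4 values, >= 2
#'   distinct).
#' @param statistic optional per-species statistic to compare between
#'   groups.
#' @return object of class `group_split`: `assignment` ("high"/"low"
#'   per input), `boundary` (largest low total, smallest high total),
#'   `centers`, and — when `statistic` is given — `t_test` and
#'   `mann_whitney` htest results.
#' @export
split_high_low <- function(totals, statistic = NULL) {
  stopifnot(length(totals) >= 4)
  if (length(unique(totals)) < 2) {
    stop("totals are all identical; no split exists")
  }
  centers <- c(min(totals), max(totals))
  repeat {
    assign_high <- abs(totals - centers[2]) < abs(totals - centers[1])
    new_centers <- c(mean(totals[!assign_high]), mean(totals[assign_high]))
    if (isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  grp <- ifelse(assign_high, "high", "low")
  out <- list(
    assignment = grp,
    boundary = c(low_max = max(totals[grp == "low"]),
                 high_min = min(totals[grp == "high"])),
    centers = c(low = centers[1], high = centers[2]),
    n = c(low = sum(grp == "low"), high = sum(grp == "high"))
  )
  if (!is.null(statistic)) {
    stopifnot(length(statistic) == length(totals))
    out$t_test <- stats::t.test(statistic[grp == "high"],
                                statistic[grp == "low"])
    out$mann_whitney <- suppressWarnings(
      stats::wilcox.test(statistic[grp == "high"], statistic[grp == "low"],
                         exact = FALSE, correct = TRUE))
  }
  structure(out, class = "group_split")
}

#' @export
print.group_split <- function(x, ...) {
  cat(sprintf("High/low copy split: %d high (total >= %s), %d low (total <= %s)\n",
              x$n["high"], x$boundary["high_min"],
              x$n["low"], x$boundary["low_max"]))
  if (!is.null(x$t_test)) {
    cat(sprintf("  Welch t = %.3f (p = %.3g); Mann-Whitney U = %.1f (p = %.3g)\n",
                x$t_test$statistic, x$t_test$p.value,
                x$mann_whitney$statistic, x$mann_whitney$p.value))
  }
  invisible(x)
}

#' Receptor copy-number correlation
#'
#' Spearman rank correlation (tie-corrected normal approximation) between
#' melatonin-receptor copy number and the ASMT/COMT total, the test of
#' whether receptor dosage tracks enzyme dosage.
#'
#' @param table copy-number data.frame with columns `receptor` and `total`.
#' @return list with `rho`, `p`, `n`; a constant receptor column yields
#'   `rho = NA` with `reason = "constant_receptor"` rather than an error
#'   (receptors typically sit near two copies in most species).
#' @export
receptor_correlation <- function(table) {
  stopifnot(all(c("receptor", "total") %in% names(table)))
  if (nrow(table) < 10) stop("need at least 10 species")
  if (length(unique(table$receptor)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = nrow(table),
                reason = "constant_receptor"))
  }
  ct <- suppressWarnings(stats::cor.test(table$receptor, table$total,
                                         method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = nrow(table),
       reason = NA_character_)
}

#' Compare copy numbers between two ploidy groups
#'
#' Contrasts two copy-number tables (e.g. hexaploid wheat varieties versus
#' diploid Ae. tauschii accessions): fold change of mean totals plus Welch
#' t-tests and Mann-Whitney U tests on the totals and on the ASMT share.
#'
#' @param table_a,table_b copy-number data.frames with `asmt`, `comt`,
#'   `total` columns; the fold change is mean(`table_a`) / mean(`table_b`).
#' @return object of class `ploidy_comparison` with `mean_total` (both
#'   groups), `fold_change`, `share_mean`, and the four htest results.
#' @export
ploidy_comparison <- function(table_a, table_b) {
  for (tb in list(table_a, table_b)) {
    stopifnot(is.data.frame(tb), nrow(tb) >= 1,
              all(c("asmt", "total") %in% names(tb)))
  }
  mb <- mean(table_b$total)
  if (mb == 0) stop("mean total of table_b is zero; fold change undefined")
  share_a <- table_a$asmt / table_a$total
  share_b <- table_b$asmt / table_b$total
  structure(list(
    mean_total = c(a = mean(table_a$total), b = mb),
    fold_change = mean(table_a$total) / mb,
    share_mean = c(a = mean(share_a), b = mean(share_b)),
    total_t = stats::t.test(table_a$total, table_b$total),
    total_mw = suppressWarnings(stats::wilcox.test(table_a$total,
                                                   table_b$total,
                                                   exact = FALSE)),
    share_t = stats::t.test(share_a, share_b),
    share_mw = suppressWarnings(stats::wilcox.test(share_a, share_b,
                                                   exact = FALSE))
  ), class = "ploidy_comparison")
}

#' @export
print.ploidy_comparison <- function(x, ...) {
  cat(sprintf("Ploidy contrast: mean totals %.2f vs %.2f (fold %.2f)\n",
              x$mean_total["a"], x$mean_total["b"], x$fold_change))
  cat(sprintf("  totals: t p = %.3g, Mann-Whitney p = %.3g\n",
              x$total_t$p.value, x$total_mw$p.value))
  cat(sprintf("  ASMT share %.1f%% vs %.1f%%: t p = %.3g, Mann-Whitney p = %.3g\n",
              100 * x$share_mean["a"], 100 * x$share_mean["b"],
              x$share_t$p.value, x$share_mw$p.value))
  invisible(x)
}

#' Compare pooled FPKM expression between subfamilies
#'
#' Pools all per-gene, per-sample FPKM values within each subfamily,
#' excludes values below `fpkm_min` (weakly expressed measurements), removes
#' outliers by Tukey fences (`outlier_k` times the IQR beyond the quartiles,
#' per subfamily), and compares the two pools with a two-sided Mann-Whitney
#' test.
#'
#' @param fpkm numeric matrix, genes x samples.
#' @param subfamily character vector of "ASMT"/"COMT" labels, one per row
#'   of `fpkm` (names, if present, must match rownames).
#' @param fpkm_min exclusion threshold; values strictly below it are
#'   dropped.
#' @param outlier_k Tukey fence multiplier; `Inf` disables outlier removal.
#' @return list with per-subfamily summaries (n, median, quartiles), the
#'   `mann_whitney` htest, and `comt_higher` (logical: COMT median above
#'   ASMT median).
#' @export
expression_compare <- function(fpkm, subfamily, fpkm_min = 1,
                               outlier_k = 1.5) {
  stopifnot(is.matrix(fpkm), nrow(fpkm) == length(subfamily))
  if (!is.null(names(subfamily)) && !is.null(rownames(fpkm))) {
    stopifnot(identical(names(subfamily), rownames(fpkm)))
  }
  pools <- lapply(c(ASMT = "ASMT", COMT = "COMT"), function(sf) {
    v <- as.numeric(fpkm[subfamily == sf, , drop = FALSE])
    v <- v[v >= fpkm_min]
    if (length(v) == 0) {
      stop("subfamily ", sf, " has no values left after the FPKM filter")
    }
    if (is.finite(outlier_k)) {
      q <- stats::quantile(v, c(0.25, 0.75))
      iqr <- q[2] - q[1]
      v <- v[v >= q[1] - outlier_k * iqr & v <= q[2] + outlier_k * iqr]
    }
    v
  })
  summarise <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75))
    c(n = length(v), q1 = unname(q[1]), median = unname(q[2]),
      q3 = unname(q[3]))
  }
  mw <- suppressWarnings(stats::wilcox.test(pools$COMT, pools$ASMT,
                                            exact = FALSE))
  list(asmt = summarise(pools$ASMT),
       comt = summarise(pools$COMT),
       mann_whitney = mw,
       comt_higher = unname(stats::median(pools$COMT) >
                              stats::median(pools$ASMT)))
}
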