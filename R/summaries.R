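# Population-level summaries: depth profiles, modulation-vs-selectivity
# correlations, gDSI-stratified comparisons and cell-class contrasts.
# Standard two-sample distribution tests (Kolmogorov-Smirnov) and rank
# tests (Mann-Whitney) come from stats; the bespoke bootstrap lives with
# the tuning statistics.

DEPTH_BIN_EDGES <- c(0, 50, 90, 150, Inf)
DEPTH_BIN_LABELS <- c("superficial", "60um", "120um", "180um")

#' Depth-binned selectivity and modulation profile
#'
#' Partitions cells into imaging-depth bins (defaults: [0,50), [50,90),
#' [90,150), [150,Inf) um, labeled superficial / 60 um / 120 um / 180 um)
#' and summarizes gDSI and the surround modulation indices per (bin, class),
#' with pairwise Kolmogorov-Smirnov tests between bins within each class.
#'
#' @param results An `sc_cell_summary` (needs `depth_um`, `cell_class`,
#'   `gdsi`, `mi_same`, `mi_opp`).
#' @param edges Depth-bin edges (um), left-closed.
#' @param labels Bin labels.
#' @return List with `summary` (per bin x class: `n`, medians of gDSI and
#'   MIs), `values` (per-cell rows with their bin), `tests` (pairwise KS
#'   p-values per class for gdsi and mi_opp; empty bins are flagged and
#'   excluded from tests).
#' @export
depth_profile <- function(results, edges = DEPTH_BIN_EDGES,
                          labels = DEPTH_BIN_LABELS) {
  if (is.null(results$depth_um)) stop("depths unavailable", call. = FALSE)
  bin <- cut(results$depth_um, breaks = edges, labels = labels,
             right = FALSE, include.lowest = TRUE)
  values <- cbind(results, depth_bin = bin)
  summ <- do.call(rbind, lapply(split(values,
                                      list(values$depth_bin,
                                           values$cell_class),
                                      drop = FALSE), function(d) {
    data.frame(depth_bin = if (nrow(d)) as.character(d$depth_bin[1]) else
                 NA_character_,
               cell_class = if (nrow(d)) d$cell_class[1] else NA_character_,
               n = nrow(d),
               median_gdsi = stats::median(d$gdsi, na.rm = TRUE),
               median_mi_same = stats::median(d$mi_same, na.rm = TRUE),
               median_mi_opp = stats::median(d$mi_opp, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  empty <- summ[summ$n == 0, c("depth_bin", "cell_class")]
  tests <- list()
  for (cl in unique(values$cell_class)) {
    d <- values[values$cell_class == cl, ]
    bins <- levels(bin)[table(d$depth_bin) > 1]
    if (length(bins) < 2) next
    for (i in seq_len(length(bins) - 1)) {
      for (j in seq(i + 1, length(bins))) {
        a <- d[d$depth_bin == bins[i], ]
        b <- d[d$depth_bin == bins[j], ]
        for (var in c("gdsi", "mi_opp")) {
          va <- a[[var]][is.finite(a[[var]])]
          vb <- b[[var]][is.finite(b[[var]])]
          if (length(va) < 2 || length(vb) < 2) next
          p <- suppressWarnings(stats::ks.test(va, vb)$p.value)
          tests[[length(tests) + 1]] <- data.frame(
            cell_class = cl, variable = var, bin_a = bins[i],
            bin_b = bins[j], ks_p = p)
        }
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  list(summary = summ, values = values, tests = tests,
       empty_bins = empty)
}

#' Correlation between modulation index and direction selectivity
#'
#' Pearson correlation of the surround modulation index with gDSI across
#' cells of one class.
#'
#' @param results An `sc_cell_summary`.
#' @param class Cell class to subset (`NULL` = all cells).
#' @param surround `"opposite"` or `"same"` surround MI.
#' @return List with `r`, `p`, `n`.
#' @export
mi_gdsi_correlation <- function(results, class = NULL,
                                surround = c("opposite", "same")) {
  surround <- match.arg(surround)
  mi <- if (surround == "opposite") results$mi_opp else results$mi_same
  keep <- is.finite(mi) & is.finite(results$gdsi)
  if (!is.null(class)) keep <- keep & results$cell_class == class
  x <- results$gdsi[keep]
  y <- mi[keep]
  if (length(x) < 3) stop("need at least 3 cells", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Modulation by gDSI stratum
#'
#' Splits cells at a gDSI threshold (default 0.5) and summarizes the same-
#' and opposite-surround modulation indices per stratum, with Mann-Whitney
#' tests between strata.
#'
#' @param results An `sc_cell_summary` (typically the inhibitory subset).
#' @param threshold gDSI split point.
#' @return List with `summary` (stratum x surround: n, mean, sem) and
#'   `tests` (per surround: Mann-Whitney p between strata); empty strata
#'   are flagged in `summary` (`n = 0`) and excluded from tests.
#' @export
gdsi_split_comparison <- function(results, threshold = 0.5) {
  keep <- is.finite(results$gdsi)
  d <- results[keep, ]
  d$stratum <- ifelse(d$gdsi >= threshold, "high", "low")
  summ <- expand.grid(stratum = c("low", "high"),
                      surround = c("same", "opposite"),
                      stringsAsFactors = FALSE)
  summ$n <- NA_integer_
  summ$mean_mi <- NA_real_
  summ$sem_mi <- NA_real_
  tests <- list()
  for (s in c("same", "opposite")) {
    mi <- if (s == "same") d$mi_same else d$mi_opp
    for (st in c("low", "high")) {
      v <- mi[d$stratum == st & is.finite(mi)]
      k <- summ$stratum == st & summ$surround == s
      summ$n[k] <- length(v)
      summ$mean_mi[k] <- if (length(v)) mean(v) else NA_real_
      summ$sem_mi[k] <- sem(v)
    }
    lo <- mi[d$stratum == "low" & is.finite(mi)]
    hi <- mi[d$stratum == "high" & is.finite(mi)]
    if (length(lo) > 1 && length(hi) > 1) {
      tests[[s]] <- suppressWarnings(
        stats::wilcox.test(lo, hi)$p.value)
    }
  }
  list(summary = summ, tests = tests)
}

#' Cell-class comparison of modulation
#'
#' Four-way response-category percentages per cell class (the percentages
#' partition each class and sum to 100), plus a Kolmogorov-Smirnov
#' comparison of the opposite-surround MI distributions between classes
#' when both classes are present.
#'
#' @param results An `sc_cell_summary`.
#' @return List with `categories` (class x category percentage table),
#'   `counts`, and `tests` (KS p for mi_opp and mi_same between classes, or
#'   `NULL` for single-class input).
#' @export
class_comparison <- function(results) {
  cats <- c("non_responsive", "non_modulated", "potentiated", "suppressed")
  classes <- sort(unique(results$cell_class))
  counts <- table(factor(results$cell_class, levels = classes),
                  factor(results$category, levels = cats))
  pct <- 100 * prop.table(counts, margin = 1)
  tests <- NULL
  if (length(classes) == 2) {
    tests <- list()
    for (var in c("mi_opp", "mi_same")) {
      a <- results[[var]][results$cell_class == classes[1]]
      b <- results[[var]][results$cell_class == classes[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      if (length(a) > 1 && length(b) > 1) {
        tests[[var]] <- suppressWarnings(stats::ks.test(a, b)$p.value)
      }
    }
  }
  list(categories = pct, counts = counts, tests = tests)
}
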