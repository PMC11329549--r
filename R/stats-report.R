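## Nonparametric cohort statistics and publication-style summary tables.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties averaged). The p-value uses the
#' exact permutation null distribution of the rank statistic for n <= 10
#' without ties, and the t-approximation otherwise.
#'
#' @param x,y numeric vectors of equal length (>= 3)
#' @param names optional length-2 character vector naming the pair
#' @return list of class \code{CorrelationReport}: \code{pair},
#'   \code{spearman_r}, \code{p_value}, \code{n}, \code{method}
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))$spearman_r  # 0.8
#' @export
spearmanCorrelation <- function(x, y, names = c("x", "y")) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || length(y) != n) stop("need equal-length vectors with n >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    return(structure(list(pair = names, spearman_r = NA_real_,
                          p_value = NA_real_, n = n,
                          method = "undefined (constant input)"),
                     class = "CorrelationReport"))
  }
  rx <- rank(x); ry <- rank(y)
  r <- cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    S <- sum((rx - ry)^2)
    cnt <- cpp_spearman_s_null(n)
    smax <- length(cnt) - 1L
    ## two-sided: S and its mirror (the null is symmetric about smax/2)
    lo <- min(S, smax - S); hi <- max(S, smax - S)
    p <- (sum(cnt[seq_len(lo + 1)]) +
            sum(cnt[seq(hi + 1, smax + 1)])) / sum(cnt)
    p <- min(1, p)
    method <- "exact permutation"
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  structure(list(pair = names, spearman_r = r, p_value = p, n = n,
                 method = method),
            class = "CorrelationReport")
}

#' @method print CorrelationReport
#' @param x a report object
#' @param ... ignored
#' @export
print.CorrelationReport <- function(x, ...) {
  cat(sprintf("Spearman correlation %s vs %s: R = %s, p = %s (n = %d, %s)\n",
              x$pair[1], x$pair[2],
              ifelse(is.na(x$spearman_r), "NA", sprintf("%.3f", x$spearman_r)),
              ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3)),
              x$n, x$method))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U from rank sums with mid-rank tie handling. The two-sided p-value is
#' exact (distribution-based enumeration) when there are no ties and
#' n1*n2 <= 400, and a normal approximation with tie correction and
#' continuity correction otherwise. Group means with t-based 95%
#' confidence intervals and significance markers at p < 0.05 / 0.01 /
#' 0.001 are attached.
#'
#' @param a,b numeric vectors (both nonempty)
#' @param labels optional group labels
#' @return list of class \code{GroupComparisonReport}: \code{U} (for group
#'   a), \code{p_value}, \code{exact}, group summaries, \code{marker}
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
#' @export
mannWhitneyU <- function(a, b, labels = c("a", "b")) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (!ties && n1 * n2 <= 400) {
    ## exact two-sided p from the null distribution of U
    pLow <- pwilcox(U, n1, n2)
    pHigh <- 1 - pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pLow, pHigh))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tab <- table(c(a, b))
    tieTerm <- sum(tab^3 - tab) / (nt * (nt - 1))
    sig <- sqrt(n1 * n2 / 12 * (nt + 1 - tieTerm))
    z <- (U - mu - sign(U - mu) * 0.5) / sig
    p <- 2 * pnorm(-abs(z))
    exact <- FALSE
  }
  ci <- function(x) if (length(x) >= 2) meanCI95(x)
                    else c(mean = mean(x), lo = NA, hi = NA)
  structure(list(labels = labels, U = U, n1 = n1, n2 = n2,
                 p_value = p, exact = exact,
                 groupA = ci(a), groupB = ci(b),
                 marker = significanceMarker(p)),
            class = "GroupComparisonReport")
}

#' @method print GroupComparisonReport
#' @param x a report object
#' @param ... ignored
#' @export
print.GroupComparisonReport <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: %s (n=%d) vs %s (n=%d)\n", x$labels[1], x$n1,
              x$labels[2], x$n2))
  cat(sprintf("  U = %.1f, p = %s%s (%s)\n", x$U,
              format.pval(x$p_value, digits = 3),
              ifelse(nchar(x$marker), paste0(" ", x$marker), ""),
              ifelse(x$exact, "exact", "normal approximation")))
  cat(sprintf("  means (95%% CI): %.4g (%.4g-%.4g) vs %.4g (%.4g-%.4g)\n",
              x$groupA[1], x$groupA[2], x$groupA[3],
              x$groupB[1], x$groupB[2], x$groupB[3]))
  invisible(x)
}

#' Significance marker
#'
#' Publication-style marker for a p-value: one symbol for p < 0.05, two
#' for p < 0.01, three for p < 0.001, empty otherwise.
#'
#' @param p p-value
#' @param symbol marker symbol
#' @return character
#' @export
significanceMarker <- function(p, symbol = "*") {
  if (!is.finite(p)) return("")
  if (p < 0.001) strrep(symbol, 3)
  else if (p < 0.01) strrep(symbol, 2)
  else if (p < 0.05) symbol
  else ""
}

#' Mean with t-based 95% confidence interval
#'
#' @param x numeric vector, n >= 2
#' @return named numeric: \code{mean}, \code{lo}, \code{hi}
#' @examples
#' meanCI95(1:5)  # 3 +/- 1.963
#' @export
meanCI95 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(x)
  hw <- qt(0.975, n - 1) * sd(x) / sqrt(n)
  c(mean = m, lo = m - hw, hi = m + hw)
}

#' Holm-adjust p-values in a correlation table
#'
#' Optional multiple-testing correction (off by default everywhere, since
#' the reporting convention applies none).
#'
#' @param tab data.frame with a \code{p_value} column
#' @return the table with an added \code{p_holm} column
#' @export
holmAdjust <- function(tab) {
  tab$p_holm <- stats::p.adjust(tab$p_value, method = "holm")
  tab
}

#' Build publication-style summary tables
#'
#' From a per-sample cohort table (ground-truth or fitted parameters plus
#' measured partitions), builds: (i) a parameter table of group means with
#' 95% CIs and between-location Mann-Whitney markers per imaging method;
#' (ii) a partition table with combined partitions (computed per sample
#' and then averaged) and two marker families (single-vs-dual within
#' location; between locations within method); (iii) the full Spearman
#' correlation table between the five parameters and all partitions, per
#' imaging method.
#'
#' @param cohort data.frame with columns \code{location}, \code{method},
#'   \code{E_f0}, \code{E_feps}, \code{E_nf}, \code{k0}, \code{M},
#'   \code{partition_Ta}, and for dual rows \code{partition_I},
#'   \code{partition_combined}
#' @param holm also report Holm-adjusted p-values in the correlation table
#' @return list with \code{parameters}, \code{partitions},
#'   \code{correlations} data.frames
#' @export
buildSummaryTables <- function(cohort, holm = FALSE) {
  pars <- c("E_f0", "E_feps", "E_nf", "k0", "M")
  need <- c("location", "method", pars, "partition_Ta")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "))
  locs <- unique(cohort$location)
  meths <- unique(cohort$method)

  fmtCI <- function(x, digits = 2) {
    if (length(x[is.finite(x)]) < 2) return("absent")
    ci <- meanCI95(x)
    sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
            ci[1], ci[2], ci[3])
  }

  ## Table-1 style: parameters by method x location
  rows <- list()
  for (me in meths) {
    sub <- cohort[cohort$method == me, ]
    for (lo in locs) {
      g <- sub[sub$location == lo, ]
      row <- list(method = me, location = lo, n = nrow(g))
      for (pv in pars) {
        vals <- g[[pv]]
        scl <- if (pv == "k0") 1e15 else 1
        row[[pv]] <- if (nrow(g) >= 2) mean(vals) else NA_real_
        mk <- ""
        if (length(locs) == 2 && all(table(sub$location) >= 2)) {
          other <- sub[sub$location != lo, ][[pv]]
          if (length(vals) && length(other))
            mk <- significanceMarker(mannWhitneyU(vals, other)$p_value)
        }
        row[[paste0(pv, "_fmt")]] <-
          if (nrow(g) >= 2)
            paste0(fmtCI(vals * scl, 2), mk) else "absent"
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  parameters <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))

  ## Table-2 style: partitions
  prow <- list()
  for (lo in locs) {
    for (me in meths) {
      g <- cohort[cohort$location == lo & cohort$method == me, ]
      if (!nrow(g)) next
      markTa <- markI <- markC <- ""
      if (length(locs) == 2) {
        other <- cohort[cohort$location != lo & cohort$method == me, ]
        if (nrow(other) >= 2 && nrow(g) >= 2) {
          markTa <- significanceMarker(
            mannWhitneyU(g$partition_Ta, other$partition_Ta)$p_value, "▲")
          if (me == "dual" && "partition_I" %in% names(g)) {
            markI <- significanceMarker(
              mannWhitneyU(g$partition_I, other$partition_I)$p_value, "▲")
            markC <- significanceMarker(
              mannWhitneyU(g$partition_combined,
                           other$partition_combined)$p_value, "▲")
          }
        }
      }
      markMeth <- ""
      if (all(c("single", "dual") %in% meths)) {
        om <- setdiff(c("single", "dual"), me)
        other <- cohort[cohort$location == lo & cohort$method == om, ]
        if (nrow(other) >= 2 && nrow(g) >= 2)
          markMeth <- significanceMarker(
            mannWhitneyU(g$partition_Ta, other$partition_Ta)$p_value, "†")
      }
      hasI <- me == "dual" && "partition_I" %in% names(g) &&
        sum(is.finite(g$partition_I)) >= 2
      prow[[length(prow) + 1]] <- data.frame(
        location = lo, method = me, n = nrow(g),
        partition_Ta = mean(g$partition_Ta),
        partition_Ta_fmt = paste0(fmtCI(g$partition_Ta, 1), "%",
                                  markMeth, markTa),
        partition_I = if (hasI) mean(g$partition_I) else NA_real_,
        partition_I_fmt = if (hasI)
          paste0(fmtCI(g$partition_I, 1), "%", markI) else "",
        partition_combined = if (hasI) mean(g$partition_combined) else NA_real_,
        partition_combined_fmt = if (hasI)
          paste0(fmtCI(g$partition_combined, 1), markC) else "",
        stringsAsFactors = FALSE)
    }
  }
  partitions <- do.call(rbind, prow)

  ## correlation table (per method, partitions vs parameters, pooled
  ## across locations as in the reporting convention)
  crow <- list()
  for (me in meths) {
    g <- cohort[cohort$method == me, ]
    pvars <- c("partition_Ta",
               if (me == "dual") c("partition_I", "partition_combined"))
    for (pv in pvars) {
      if (!pv %in% names(g)) next
      for (pr in pars) {
        if (sum(is.finite(g[[pv]]) & is.finite(g[[pr]])) < 3) next
        sc <- spearmanCorrelation(g[[pv]], g[[pr]], names = c(pv, pr))
        crow[[length(crow) + 1]] <- data.frame(
          method = me, partition = pv, parameter = pr,
          spearman_r = sc$spearman_r, p_value = sc$p_value, n = sc$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  correlations <- do.call(rbind, crow)
  if (holm && !is.null(correlations)) correlations <- holmAdjust(correlations)

  list(parameters = parameters, partitions = partitions,
       correlations = correlations)
}
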