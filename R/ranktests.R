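# Rank-based group comparison, implemented directly from the classical
# formulas so the tie-corrected statistic and Dunn's z are fully auditable.
# (stats::kruskal.test serves as an independent cross-check in the test
# suite, never as the implementation.)

pooled_ranks <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_field("values", "must be finite")
  }
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(values)  # mid-ranks for ties
  list(values = values, g = g, r = r, N = length(values),
       n = lengths(groups),
       rbar = tapply(r, g, mean),
       tie_sum = {
         t <- table(values)
         sum(t^3 - t)
       })
}

#' Kruskal-Wallis rank test with tie correction
#'
#' Omnibus comparison of two or more groups of expression-domain fractions.
#' The statistic is
#' `H = [12 / (N(N+1)) * sum(n_i * rbar_i^2)] - 3(N+1)` divided by the tie
#' correction `1 - sum(t^3 - t) / (N^3 - N)`; the p-value is the chi-square
#' upper tail with `k - 1` degrees of freedom. With all pooled values
#' identical, `H = 0` and `p = 1`.
#'
#' @param groups named list of numeric vectors (domain fractions in percent,
#'   one observation per sample-unit image), at least two groups and three
#'   observations in total.
#' @return an object of class `kw_result` with `H`, `df`, `p_value`,
#'   `mean_ranks` and `n`.
#' @examples
#' kruskal_wallis(list(a = c(1, 2, 3), b = c(10, 20, 30)))
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop_field("groups", "need at least 2 groups")
  }
  if (any(lengths(groups) < 1L)) stop_field("groups", "empty group")
  p <- pooled_ranks(groups)
  if (p$N < 3L) stop_field("groups", "need total N >= 3")
  C <- 1 - p$tie_sum / (p$N^3 - p$N)
  if (C <= 0) {
    # all pooled values identical: no evidence of any difference
    H <- 0
    pval <- 1
  } else {
    H_raw <- 12 / (p$N * (p$N + 1)) * sum(p$n * p$rbar^2) - 3 * (p$N + 1)
    H <- H_raw / C
    pval <- stats::pchisq(H, df = length(groups) - 1L, lower.tail = FALSE)
  }
  structure(list(H = H, df = length(groups) - 1L, p_value = pval,
                 mean_ranks = as.numeric(p$rbar), n = p$n,
                 labels = names(groups) %||%
                   paste0("group", seq_along(groups))),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p_value))
  invisible(x)
}

#' Dunn's multiple-comparison post hoc test
#'
#' All pairwise rank comparisons following a Kruskal-Wallis test:
#' `z_ij = (rbar_i - rbar_j) / sqrt((N(N+1)/12 - sumT/(12(N-1))) *
#' (1/n_i + 1/n_j))` with tie sum `sumT = sum(t^3 - t)`; two-sided p-values
#' from the standard normal, adjusted by default with Bonferroni over the
#' `k(k-1)/2` comparisons.
#'
#' @inheritParams kruskal_wallis
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @param adjust `"bonferroni"` (default), `"holm"` or `"none"`.
#' @return an object of class `dunn_result`: a data.frame with one row per
#'   pair (`group1`, `group2`, `z`, `p_raw`, `p_adj`, `significant`).
#' @export
dunns_test <- function(groups, alpha = 0.05,
                       adjust = c("bonferroni", "holm", "none")) {
  adjust <- match.arg(adjust)
  if (!is.list(groups) || length(groups) < 2L) {
    stop_field("groups", "need at least 2 groups")
  }
  p <- pooled_ranks(groups)
  if (p$N < 3L) stop_field("groups", "need total N >= 3")
  k <- length(groups)
  labels <- names(groups) %||% paste0("group", seq_len(k))
  var_term <- p$N * (p$N + 1) / 12 - p$tie_sum / (12 * (p$N - 1))
  pairs <- utils::combn(k, 2)
  z <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    denom <- sqrt(var_term * (1 / p$n[i] + 1 / p$n[j]))
    if (denom == 0) 0 else (p$rbar[i] - p$rbar[j]) / denom
  })
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = adjust)
  out <- data.frame(group1 = labels[pairs[1, ]], group2 = labels[pairs[2, ]],
                    z = z, p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("dunn_result", "data.frame")
  attr(out, "adjust") <- adjust
  out
}

#' Compare expression domains across stages and ROIs
#'
#' Groups sample-unit domain-fraction observations by stage/ROI and, per
#' factor, runs the Kruskal-Wallis omnibus test followed by Dunn's post hoc
#' comparisons, emitting one tidy row per group pair. Each sample-unit
#' image's fraction counts as one observation; sample units from the same
#' photomicrograph are not independent, a pseudo-replication caveat noted in
#' the report attribute `caveat`.
#'
#' @param measurements data.frame with columns named by `factor_col`,
#'   `group_cols` and `value_col` — typically one row per sample-unit image.
#' @param value_col column holding the fraction (percent).
#' @param group_cols columns whose interaction defines the comparison groups
#'   (default stage and roi).
#' @param factor_col column naming the stained factor.
#' @param alpha significance level (default 0.05).
#' @param adjust p-adjustment method for Dunn's test.
#' @return data.frame with columns `factor`, `group1`, `group2`, `z`,
#'   `p_raw`, `p_adj`, `significant`, `kw_H`, `kw_p`.
#' @export
compare_domains <- function(measurements, value_col = "fraction",
                            group_cols = c("stage", "roi"),
                            factor_col = "factor", alpha = 0.05,
                            adjust = "bonferroni") {
  needed <- c(value_col, group_cols, factor_col)
  if (!all(needed %in% names(measurements))) {
    stop_field("measurements", paste("missing columns:",
               paste(setdiff(needed, names(measurements)), collapse = ", ")))
  }
  out <- do.call(rbind, lapply(split(measurements, measurements[[factor_col]]),
    function(d) {
      grp <- interaction(d[group_cols], drop = TRUE, sep = ":")
      if (nlevels(grp) < 2L) {
        stop_field("measurements", "need at least 2 groups after grouping")
      }
      groups <- split(d[[value_col]], grp)
      kw <- kruskal_wallis(groups)
      dn <- dunns_test(groups, alpha = alpha, adjust = adjust)
      cbind(factor = d[[factor_col]][1], as.data.frame(dn),
            kw_H = kw$H, kw_p = kw$p_value)
    }))
  rownames(out) <- NULL
  attr(out, "caveat") <-
    "sample units from one photomicrograph are treated as independent observations"
  out
}
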