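#' Kruskal-Wallis test across groups
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation on k-1 degrees of freedom (delegated to
#' [stats::kruskal.test()]).  When all values are identical the statistic
#' is 0 and p = 1 (not an error).
#'
#' @param values numeric vector, or a list of per-group numeric vectors.
#' @param groups grouping vector (ignored when `values` is a list).
#' @return List with `H` and `p`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  g <- factor(groups)
  if (nlevels(g) < 2 || any(tabulate(g) == 0))
    stop("need at least 2 nonempty groups")
  keep <- !is.na(values)
  values <- values[keep]; g <- droplevels(g[keep])
  if (length(unique(values)) == 1L) return(list(H = 0, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

star_map <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("****", "***", "**", "*", "ns"))
}

#' Post hoc pairwise Mann-Whitney U tests with Bonferroni correction
#'
#' Pairwise tests are run only when the Kruskal-Wallis gate passes
#' (p <= `gate_p`); otherwise the pairwise section is empty and flagged
#' `gated`.  P-values are exact by enumeration when both groups have at
#' most 8 observations (and no ties), and use the normal approximation
#' with tie and continuity correction otherwise.  The Bonferroni family
#' is the set of pairwise comparisons within this variable (6 for four
#' groups); adjusted p = min(1, raw p x number of pairs).  Significance
#' stars: * p<0.05, ** p<0.01, *** p<0.001, **** p<0.0001, ns otherwise
#' (on the adjusted p).
#'
#' @inheritParams kruskal_wallis
#' @param gate_p Kruskal-Wallis significance gate (default 0.05).
#' @param variable optional variable name carried into the output.
#' @return An object of class `group_test`: list with `variable`, `H`,
#'   `p`, `gated`, and `pairs` (data.frame `group1`, `group2`, `U`,
#'   `p_raw`, `p_adj`, `stars`).
#' @export
posthoc_mwu <- function(values, groups = NULL, gate_p = 0.05,
                        variable = NA_character_) {
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values)
  }
  g <- factor(groups)
  kw <- kruskal_wallis(values, g)
  empty <- data.frame(group1 = character(0), group2 = character(0),
                      U = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), stars = character(0))
  if (kw$p > gate_p)
    return(structure(list(variable = variable, H = kw$H, p = kw$p,
                          gated = TRUE, pairs = empty),
                     class = "group_test"))
  lv <- levels(g)
  cb <- utils::combn(length(lv), 2)
  rows <- apply(cb, 2, function(pr) {
    x1 <- values[g == lv[pr[1]]]; x2 <- values[g == lv[pr[2]]]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    exact <- length(x1) <= 8 && length(x2) <= 8
    wt <- suppressWarnings(stats::wilcox.test(x1, x2, exact = exact,
                                              correct = TRUE))
    data.frame(group1 = lv[pr[1]], group2 = lv[pr[2]],
               U = unname(wt$statistic), p_raw = wt$p.value)
  })
  pairs <- do.call(rbind, rows)
  pairs$p_adj <- stats::p.adjust(pairs$p_raw, method = "bonferroni")
  pairs$stars <- as.character(star_map(pairs$p_adj))
  structure(list(variable = variable, H = kw$H, p = kw$p, gated = FALSE,
                 pairs = pairs),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("<group_test> %s: H = %.3f, p = %.4g%s\n",
              x$variable %||% "", x$H, x$p,
              if (x$gated) " [gated: no post hoc]" else ""))
  if (nrow(x$pairs)) print(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Group tests for many variables of a cohort
#'
#' Runs [posthoc_mwu()] per variable against the category groups; the
#' Bonferroni family is the pairwise comparisons within each variable.
#'
#' @param cohort data.frame.
#' @param vars variable names.
#' @param group grouping column (default `"category"`).
#' @param gate_p Kruskal-Wallis gate.
#' @return data.frame with one row per variable x pair (plus gated
#'   variables with `NA` pair columns).
#' @export
cohort_tests <- function(cohort, vars, group = "category", gate_p = 0.05) {
  out <- lapply(vars, function(v) {
    r <- posthoc_mwu(cohort[[v]], cohort[[group]], gate_p = gate_p,
                     variable = v)
    if (!nrow(r$pairs))
      return(data.frame(variable = v, H = r$H, p_kw = r$p, gated = r$gated,
                        group1 = NA, group2 = NA, U = NA, p_raw = NA,
                        p_adj = NA, stars = NA))
    cbind(data.frame(variable = v, H = r$H, p_kw = r$p, gated = FALSE),
          r$pairs)
  })
  do.call(rbind, out)
}

#' Pairwise-complete Pearson correlation map
#'
#' Pearson correlations over pairwise-complete observations, intended for
#' the post-matching, post-imputation table.  Zero-variance variables
#' yield `NA` entries for their pairs.
#'
#' @param data data.frame.
#' @param vars variable names (numeric columns).
#' @return An object of class `correlation_map`: list with `r`
#'   (correlation matrix, unit diagonal), `n` (pairwise-complete counts).
#' @export
pearson_map <- function(data, vars) {
  x <- as.matrix(data[vars])
  if (ncol(x) < 2) stop("need at least 2 variables")
  npair <- crossprod(!is.na(x))
  if (any(npair < 3))
    stop("need at least 3 complete pairs per variable pair")
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs",
                                   method = "pearson"))
  diag(r) <- 1
  structure(list(r = r, n = npair), class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat("<correlation_map> ", ncol(x$r), " variables\n", sep = "")
  print(round(x$r, 2))
  invisible(x)
}

#' Plot a correlation map as a heat map
#'
#' Uses pheatmap when available, otherwise a base-graphics image.
#'
#' @param x a `correlation_map`.
#' @param ... passed to the underlying heat map function.
#' @export
plot.correlation_map <- function(x, ...) {
  if (requireNamespace("pheatmap", quietly = TRUE)) {
    pheatmap::pheatmap(x$r, cluster_rows = FALSE, cluster_cols = FALSE,
                       breaks = seq(-1, 1, length.out = 101), ...)
  } else {
    graphics::image(seq_len(ncol(x$r)), seq_len(ncol(x$r)), t(x$r[rev(seq_len(nrow(x$r))), ]),
                    zlim = c(-1, 1), xlab = "", ylab = "", axes = FALSE, ...)
    graphics::axis(1, seq_len(ncol(x$r)), colnames(x$r), las = 2)
    graphics::axis(2, seq_len(nrow(x$r)), rev(rownames(x$r)), las = 2)
  }
  invisible(x)
}
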