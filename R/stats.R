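#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error control for the planned post hoc comparisons: p-values
#' are ordered, the i-th smallest is multiplied by `m - i + 1`, running
#' maxima enforce monotonicity and the result is capped at 1. Uniformly at
#' least as powerful as plain Bonferroni.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_bonferroni <- function(p) p.adjust(p, method = "holm")

#' Cohen's d effect size
#'
#' `d = (mean(x1) - mean(x2)) / s`, with `s` the pooled SD
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))` by default, or the
#' control-group SD (`sd(x2)`, Glass's delta) when `method = "glass"`.
#' The sign follows group 1 minus group 2.
#'
#' @param x1,x2 Numeric samples (each n >= 2).
#' @param method `"pooled"` (default) or `"glass"`.
#' @return An object of class `effect_size` with `d`, `mean_diff`,
#'   `sd_pooled`, `n1`, `n2`.
#' @export
cohens_d <- function(x1, x2, method = c("pooled", "glass")) {
  method <- match.arg(method)
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop_bsq("need at least 2 observations per group")
  s <- if (method == "pooled") {
    sqrt(((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2))
  } else sd(x2)
  if (s == 0) stop_bsq("zero variance; effect size undefined")
  md <- mean(x1) - mean(x2)
  structure(list(d = md / s, mean_diff = md, sd_pooled = s,
                 n1 = n1, n2 = n2, method = method),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.4g (mean diff %.4g / %s SD %.4g; n = %d, %d)\n",
              x$d, x$mean_diff,
              if (x$method == "pooled") "pooled" else "control",
              x$sd_pooled, x$n1, x$n2))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_bsq("x and y must have equal length")
  if (length(x) < 3) stop_bsq("need at least 3 paired observations")
  if (var(x) == 0 || var(y) == 0) stop_bsq("constant input; r undefined")
  cor(x, y, method = "pearson")
}

#' Compare two Pearson correlations via Fisher's transformation
#'
#' Each coefficient is transformed with `z' = atanh(r)`, and the difference
#' is scaled by its standard error to give a standard-normal comparison
#' statistic: `z = (z1' - z2') / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value.
#'
#' @param r1,r2 Pearson coefficients with `|r| < 1`.
#' @param n1,n2 Sample sizes (each > 3).
#' @return An object of class `correlation_comparison` with `r1`, `r2`,
#'   `n1`, `n2`, `z1p`, `z2p`, `z`, `p`.
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_bsq("|r| must be < 1 for Fisher's transformation")
  if (n1 <= 3 || n2 <= 3) stop_bsq("need n > 3 in both samples")
  z1p <- atanh(r1); z2p <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (z1p - z2p) / se
  structure(list(r1 = r1, r2 = r2, n1 = n1, n2 = n2,
                 z1p = z1p, z2p = z2p, z = z, p = 2 * pnorm(-abs(z))),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("Fisher r-to-z comparison: r1 = %.3f (n=%d) vs r2 = %.3f (n=%d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("  z = %.4g, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}

subset_cells <- function(table, where) {
  keep <- rep(TRUE, nrow(table))
  for (nm in names(where)) keep <- keep & table[[nm]] %in% where[[nm]]
  table[keep, , drop = FALSE]
}

#' ANOVA with Holm-Bonferroni post hoc t-tests
#'
#' Fits a factorial ANOVA (group x age with interaction when both factors
#' are present; factors treated as categorical) and runs the planned
#' pairwise comparisons as two-sample t-tests (Welch by default), adjusting
#' their p-values with the Holm-Bonferroni step-down procedure. Cohen's d
#' is reported alongside each comparison.
#'
#' @param table Long-format data.frame with a `value` column and the factor
#'   columns named in `factors`.
#' @param factors Character vector of factor column names (1 or 2).
#' @param comparisons List of planned comparisons, each
#'   `list(between = <factor>, pair = c(level1, level2), where = <named
#'   list of filters>)`. `where` may be empty.
#' @param value_col Name of the measurement column.
#' @param posthoc `"welch"` (default) or `"student"` two-sample t-tests.
#' @return A list of class `anova_posthoc` with `omnibus` (term, df, F, p)
#'   and `posthoc` (one row per comparison: means, t, df, raw and
#'   Holm-adjusted p, Cohen's d).
#' @export
anova_with_posthoc <- function(table, factors = c("group", "age"),
                               comparisons = list(), value_col = "value",
                               posthoc = c("welch", "student")) {
  posthoc <- match.arg(posthoc)
  if (!value_col %in% names(table)) stop_bsq("no column '", value_col, "'")
  factors <- factors[factors %in% names(table)]
  if (!length(factors)) stop_bsq("no factor columns found")
  for (f in factors) {
    if (length(unique(table[[f]])) < 2)
      stop_bsq("factor '", f, "' needs >= 2 levels")
    table[[f]] <- factor(table[[f]])
  }
  counts <- table(table[factors])
  if (any(counts < 2))
    stop_bsq("every design cell needs >= 2 observations")
  fml <- stats::as.formula(paste(value_col, "~",
                                 paste(factors, collapse = " * ")))
  fit <- aov(fml, data = table)
  at <- summary(fit)[[1]]
  terms <- trimws(rownames(at))
  omnibus <- data.frame(term = terms[terms != "Residuals"],
                        df = at$Df[terms != "Residuals"],
                        F = at$`F value`[terms != "Residuals"],
                        p = at$`Pr(>F)`[terms != "Residuals"],
                        stringsAsFactors = FALSE)
  post <- NULL
  if (length(comparisons)) {
    rows <- lapply(comparisons, function(cmp) {
      sub <- subset_cells(table, cmp$where %||% list())
      x1 <- sub[[value_col]][sub[[cmp$between]] == cmp$pair[1]]
      x2 <- sub[[value_col]][sub[[cmp$between]] == cmp$pair[2]]
      if (length(x1) < 2 || length(x2) < 2)
        stop_bsq("comparison ", cmp$pair[1], " vs ", cmp$pair[2],
                 " has an empty or singleton cell")
      if (sd(x1) == 0 && sd(x2) == 0) {
        tt <- list(statistic = c(t = 0), parameter = c(df = length(x1) + length(x2) - 2),
                   p.value = 1)
        d <- 0
      } else {
        tt <- t.test(x1, x2, var.equal = posthoc == "student")
        d <- cohens_d(x1, x2)$d
      }
      data.frame(between = cmp$between,
                 level1 = cmp$pair[1], level2 = cmp$pair[2],
                 where = paste(names(cmp$where %||% list()),
                               vapply(cmp$where %||% list(), paste,
                                      "", collapse = "/"),
                               sep = "=", collapse = ";"),
                 mean1 = mean(x1), mean2 = mean(x2),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d, stringsAsFactors = FALSE)
    })
    post <- do.call(rbind, rows)
    post$p_adjusted <- holm_bonferroni(post$p)
  }
  structure(list(omnibus = omnibus, posthoc = post, test = posthoc),
            class = "anova_posthoc")
}

#' @export
print.anova_posthoc <- function(x, ...) {
  cat("Omnibus ANOVA:\n"); print(x$omnibus)
  if (!is.null(x$posthoc)) {
    cat("\nPost hoc", x$test, "t-tests (Holm-Bonferroni adjusted):\n")
    print(x$posthoc)
  }
  invisible(x)
}
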