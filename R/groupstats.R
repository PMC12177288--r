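# Multi-group comparisons: one-way ANOVA with Waller-Duncan or Tukey
# letters, Kruskal-Wallis with Dunn / Benjamini-Hochberg, logit
# normalisation of percentages, and compact letter displays.

#' Logit normalisation of percentages
#'
#' \eqn{\mathrm{logit}(q) = \ln(q/(1-q))} with \eqn{q = p/100}, used to pull
#' percentage data toward normality before means analysis. Boundary values
#' (0 or 100) are handled either by the empirical adjustment
#' \eqn{q' = (q(n-1)+0.5)/n} when a sample size `n_adjust` is supplied, or
#' by clamping to `[eps, 1-eps]`.
#'
#' @param p percentages in `[0, 100]` (vectorised).
#' @param n_adjust optional sample size for the empirical adjustment.
#' @param eps clamping bound used when `n_adjust` is absent.
#' @return logit-transformed values.
#' @export
logit_transform <- function(p, n_adjust = NULL, eps = 1e-6) {
  assert_that(all(p >= 0 & p <= 100), "logit_transform",
              "percentages must lie in [0, 100]")
  q <- p / 100
  if (!is.null(n_adjust)) {
    q <- (q * (n_adjust - 1) + 0.5) / n_adjust
  } else if (any(q <= 0 | q >= 1)) {
    message("logit_transform: boundary percentages clamped to [",
            format(eps), ", ", format(1 - eps), "]")
    q <- pmin(pmax(q, eps), 1 - eps)
  }
  log(q / (1 - q))
}

#' Waller-Duncan k-ratio critical t value
#'
#' The minimum-average-risk critical value of the Bayesian k-ratio t test
#' for pairwise mean comparisons. Under the component-of-variance model the
#' observed F ratio carries the information about the between- to
#' within-group variance ratio; the posterior of the two variance
#' components (scaled inverse-chi-squared from the two mean squares,
#' truncated so the between component is at least the within component) is
#' integrated numerically, and the additive-loss three-decision boundary
#' (declare a sign when the posterior expected gain outweighs `k_ratio - 1`
#' times the expected loss of a wrong assertion) is solved for t.
#' `k_ratio = 100` corresponds loosely to a 5% comparisonwise level.
#'
#' @param f_value observed one-way ANOVA F statistic.
#' @param df_treat,df_error numerator and denominator degrees of freedom.
#' @param k_ratio Bayesian loss ratio (50, 100 or 500 conventionally).
#' @param ngrid quadrature points per variance component.
#' @return the critical t value; `Inf` when F carries no evidence of
#'   between-group variance (the test then separates nothing).
#' @export
waller_critical_t <- function(f_value, df_treat, df_error, k_ratio = 100,
                              ngrid = 64L) {
  st <- "waller_critical_t"
  assert_that(df_treat >= 1 && df_error >= 1, st, "degrees of freedom must be >= 1")
  if (!is.finite(f_value) || f_value <= 0) return(Inf)
  q <- df_treat; f <- df_error
  pp <- (seq_len(ngrid) - 0.5) / ngrid
  # v1 | MSE ~ f*MSE/chisq_f, v2 | MSB ~ q*MSB/chisq_q (Jeffreys priors),
  # with MSE = 1, MSB = F; equal-weight quantile grids sample the posterior
  a <- qchisq(pp, f)
  b <- qchisq(pp, q)
  gr <- expand.grid(a = a, b = b)
  v1 <- f / gr$a
  v2 <- q * f_value / gr$b
  keep <- v2 >= v1
  if (!any(keep)) return(Inf)
  v1 <- v1[keep]; v2 <- v2[keep]
  rho <- 1 - v1 / v2
  gain_minus_loss <- function(t) {
    w <- t * sqrt(rho / v1)
    s <- sqrt(rho * v1)
    up <- sum(s * (w * pnorm(w) + dnorm(w)))     # E[max(delta, 0)]
    dn <- sum(s * (-w * pnorm(-w) + dnorm(w)))   # E[max(-delta, 0)]
    up - (k_ratio - 1) * dn
  }
  if (gain_minus_loss(50) < 0) return(Inf)
  if (gain_minus_loss(1e-8) > 0) return(0)
  uniroot(gain_minus_loss, c(1e-8, 50), tol = 1e-8)$root
}

# compact letter display from a logical "significantly different" matrix
# (named square matrix); groups ordered by decreasing centre
cld_letters <- function(centres, sig) {
  gn <- names(centres)[order(-centres)]
  cols <- list(gn)  # each column: set of group names sharing a letter
  for (i in seq_along(gn)) {
    for (j in seq_along(gn)) {
      if (j <= i) next
      if (!sig[gn[i], gn[j]]) next
      newcols <- list()
      for (col in cols) {
        if (gn[i] %in% col && gn[j] %in% col) {
          newcols <- c(newcols, list(setdiff(col, gn[i])),
                       list(setdiff(col, gn[j])))
        } else {
          newcols <- c(newcols, list(col))
        }
      }
      # absorb columns contained in another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) {
        for (b in seq_along(newcols)) {
          if (a != b && keep[b] &&
              all(newcols[[a]] %in% newcols[[b]]) &&
              (length(newcols[[a]]) < length(newcols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- newcols[keep]
    }
  }
  # order columns by their highest-ranked member, assign letters
  first <- vapply(cols, function(col) min(match(col, gn)), 0)
  cols <- cols[order(first)]
  out <- stats::setNames(rep("", length(gn)), gn)
  for (k in seq_along(cols)) {
    for (g in cols[[k]]) out[g] <- paste0(out[g], letters[k])
  }
  out[names(centres)]
}

check_group_table <- function(table, metric) {
  st <- "group_table"
  assert_that(all(c("sample_id", "group", "metric", "value") %in% names(table)),
              st, "table must have columns sample_id, group, metric, value")
  tb <- table[table$metric == metric & !is.na(table$value), , drop = FALSE]
  assert_that(nrow(tb) > 0, st,
              paste0("no observations for metric '", metric, "'"))
  cnt <- table(tb$group)
  cnt <- cnt[cnt >= 2]
  assert_that(length(cnt) >= 2, st,
              "need at least 2 groups with at least 2 observations each")
  tb[tb$group %in% names(cnt), , drop = FALSE]
}

#' One-way ANOVA with Waller-Duncan or Tukey letters
#'
#' Fits a one-way ANOVA on one metric of a tidy group table (optionally
#' after logit normalisation of percentages) and assigns homogeneous-group
#' letters using either the Waller-Duncan k-ratio Bayesian LSD
#' ([waller_critical_t()]) or Tukey's HSD. Groups sharing a letter are not
#' significantly separated by the chosen post hoc rule.
#'
#' @param table data frame with columns `sample_id`, `group`, `metric`,
#'   `value` (long format).
#' @param metric metric name to analyse.
#' @param posthoc `"waller_duncan"` or `"tukey"`.
#' @param alpha significance level for Tukey letters (Waller-Duncan is
#'   governed by `k_ratio`, not alpha).
#' @param transform `"none"` or `"logit"` (applied before testing).
#' @param k_ratio Waller-Duncan loss ratio (default 100).
#' @return object of class `comparison_result`: test name, F statistic and
#'   p value, per-group letters, the pairwise decision table and the
#'   transform applied.
#' @export
anova_posthoc <- function(table, metric,
                          posthoc = c("waller_duncan", "tukey"),
                          alpha = 0.05, transform = c("none", "logit"),
                          k_ratio = 100) {
  posthoc <- match.arg(posthoc)
  transform <- match.arg(transform)
  tb <- check_group_table(table, metric)
  vals <- tb$value
  if (transform == "logit") vals <- logit_transform(vals)
  grp <- factor(tb$group)
  means <- tapply(vals, grp, mean)
  ni <- tapply(vals, grp, length)
  k <- nlevels(grp)

  fit <- aov(vals ~ grp)
  # a perfect fit is flagged as degenerate below; silence the stock warning
  an <- suppressWarnings(anova(fit))
  mse <- an[["Mean Sq"]][2]
  f_value <- an[["F value"]][1]
  p_value <- an[["Pr(>F)"]][1]
  df_treat <- an[["Df"]][1]
  df_error <- an[["Df"]][2]

  degenerate <- !is.finite(mse) || mse <= .Machine$double.eps * max(1, abs(mean(vals)))
  sig <- matrix(FALSE, k, k, dimnames = list(levels(grp), levels(grp)))
  pairwise <- NULL
  if (degenerate) {
    # zero residual variance: identical groups share a letter, any
    # difference in means is taken at face value
    for (i in seq_len(k)) for (j in seq_len(k)) {
      sig[i, j] <- means[i] != means[j]
    }
    f_value <- NA_real_
    p_value <- NA_real_
  } else if (posthoc == "waller_duncan") {
    tcrit <- waller_critical_t(f_value, df_treat, df_error, k_ratio)
    pr <- list()
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      se <- sqrt(mse * (1 / ni[i] + 1 / ni[j]))
      diffm <- abs(means[i] - means[j])
      s <- is.finite(tcrit) && diffm > tcrit * se
      sig[i, j] <- sig[j, i] <- s
      pr[[length(pr) + 1]] <- data.frame(
        comparison = paste(levels(grp)[i], "-", levels(grp)[j]),
        estimate = means[i] - means[j], se = se,
        critical_diff = tcrit * se, significant = s
      )
    }
    pairwise <- do.call(rbind, pr)
  } else {
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$grp
    cmp <- rownames(tk)
    pairwise <- data.frame(
      comparison = gsub("-", " - ", cmp, fixed = TRUE),
      estimate = tk[, "diff"], p_adj = tk[, "p adj"],
      significant = tk[, "p adj"] < alpha, row.names = NULL
    )
    for (r in seq_along(cmp)) {
      gg <- strsplit(cmp[r], "-", fixed = TRUE)[[1]]
      sig[gg[1], gg[2]] <- sig[gg[2], gg[1]] <- tk[r, "p adj"] < alpha
    }
  }
  structure(list(
    test = paste0("one-way ANOVA + ",
                  if (posthoc == "waller_duncan") "Waller-Duncan" else "Tukey HSD"),
    statistic = f_value, p_value = p_value,
    df = c(df_treat, df_error),
    group_means = means, group_n = as.integer(ni),
    letters = cld_letters(means, sig),
    pairwise = pairwise,
    transform = transform, alpha = alpha,
    k_ratio = if (posthoc == "waller_duncan") k_ratio else NA_real_,
    degenerate = degenerate
  ), class = "comparison_result")
}

#' Kruskal-Wallis with Dunn post hoc and Benjamini-Hochberg adjustment
#'
#' Rank-based comparison for non-normally distributed metrics: the global
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]) followed by
#' Dunn z statistics for all pairs, Benjamini-Hochberg adjusted p values,
#' and homogeneous-group letters at `alpha`.
#'
#' @param table tidy group table (`sample_id`, `group`, `metric`, `value`).
#' @param metric metric name to analyse.
#' @param alpha significance level for the letters; 0.05 for PA-style
#'   metrics, 0.005 as used for per-vessel area-ratio comparisons.
#' @return a `comparison_result` with H, its p value, Dunn pairwise z and
#'   adjusted p values, and letters.
#' @export
kruskal_dunn <- function(table, metric, alpha = 0.05) {
  tb <- check_group_table(table, metric)
  grp <- factor(tb$group)
  vals <- tb$value
  k <- nlevels(grp)
  all_tied <- all(vals == vals[1])
  if (all_tied) {
    H <- 0; H_p <- 1; H_df <- k - 1
  } else {
    kw <- kruskal.test(vals, grp)
    H <- unname(kw$statistic); H_p <- kw$p.value; H_df <- unname(kw$parameter)
  }

  r <- rank(vals)
  N <- length(vals)
  rbar <- tapply(r, grp, mean)
  ni <- tapply(r, grp, length)
  ties <- table(vals)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sig <- matrix(FALSE, k, k, dimnames = list(levels(grp), levels(grp)))
  pr <- list()
  if (all_tied) {
    pairwise <- data.frame(comparison = character(0), z = numeric(0),
                           p = numeric(0), p_adj = numeric(0),
                           significant = logical(0))
  } else {
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
      z <- (rbar[i] - rbar[j]) / se
      pr[[length(pr) + 1]] <- data.frame(
        comparison = paste(levels(grp)[i], "-", levels(grp)[j]),
        z = z, p = 2 * pnorm(-abs(z))
      )
    }
    pairwise <- do.call(rbind, pr)
    pairwise$p_adj <- p.adjust(pairwise$p, method = "BH")
    pairwise$significant <- pairwise$p_adj < alpha
    idx <- 0
    for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
      idx <- idx + 1
      sig[i, j] <- sig[j, i] <- pairwise$significant[idx]
    }
  }
  structure(list(
    test = "Kruskal-Wallis + Dunn (Benjamini-Hochberg)",
    statistic = H, p_value = H_p,
    df = H_df,
    group_means = rbar, group_n = as.integer(ni),
    letters = cld_letters(rbar, sig),
    pairwise = pairwise,
    transform = "none", alpha = alpha, k_ratio = NA_real_,
    degenerate = all_tied
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$test, "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g%s\n", x$statistic, x$p_value,
              if (x$degenerate) " (degenerate)" else ""))
  if (x$transform != "none") cat("  transform:", x$transform, "\n")
  lt <- x$letters
  for (g in names(lt)) {
    cat(sprintf("  %-8s %8.3f  %s\n", g, x$group_means[g], lt[g]))
  }
  invisible(x)
}
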