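make_table <- function(values, groups) {
  data.frame(sample_id = paste0("s", seq_along(values)), group = groups,
             metric = "m", value = values, stringsAsFactors = FALSE)
}

test_that("logit transform: symmetry, direct value and boundary adjustment", {
  expect_equal(logit_transform(50), 0)
  expect_equal(logit_transform(73.1), log(0.731 / 0.269))
  expect_equal(logit_transform(0, n_adjust = 10), log(0.05 / 0.95))
  expect_lt(abs(logit_transform(0, n_adjust = 10) - (-2.944)), 1e-3)
  suppressMessages(expect_equal(logit_transform(0), log(1e-6 / (1 - 1e-6))))
  expect_error(logit_transform(101), "\\[0, 100\\]")
  expect_error(logit_transform(-2), "\\[0, 100\\]")
})

test_that("Waller-Duncan critical t matches the known-variance limit", {
  # independent oracle: fine grid search on the closed-form boundary
  # (z E[delta+] / E[delta-] ratio) valid when F and the error df are large
  zs <- seq(0.5, 4, by = 1e-4)
  ratio <- (zs * pnorm(zs) + dnorm(zs)) / (-zs * pnorm(-zs) + dnorm(zs))
  for (K in c(50, 100, 500)) {
    z_oracle <- zs[which.min(abs(ratio - (K - 1)))]
    t_wd <- waller_critical_t(1e7, 4, 10000, k_ratio = K)
    expect_lt(abs(t_wd - z_oracle), 5e-3)
  }
  # monotone: sharper with larger F, stricter with larger K
  ts <- vapply(c(2, 4, 8, 16), function(f) waller_critical_t(f, 4, 20, 100), 0)
  expect_true(all(diff(ts) < 0))
  expect_lt(waller_critical_t(4, 4, 20, 50), waller_critical_t(4, 4, 20, 500))
  # F below 1 carries almost no evidence of between-group variance: the
  # critical value becomes very conservative
  expect_gt(waller_critical_t(0.5, 4, 20, 100), waller_critical_t(2, 4, 20, 100))
  expect_identical(waller_critical_t(0, 4, 20, 100), Inf)
})

test_that("clearly separated group receives its own letter under both post hocs", {
  set.seed(101)
  vals <- c(rnorm(6, 0, 1), rnorm(6, 0, 1), rnorm(6, 5, 1))
  tb <- make_table(vals, rep(c("A", "B", "C"), each = 6))
  for (ph in c("waller_duncan", "tukey")) {
    r <- anova_posthoc(tb, "m", posthoc = ph)
    lt <- r$letters
    expect_equal(lt[["A"]], lt[["B"]])
    expect_false(lt[["C"]] == lt[["A"]])
  }
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(7)
  tb <- make_table(c(rnorm(8, 0), rnorm(8, 1)), rep(c("A", "B"), each = 8))
  r <- anova_posthoc(tb, "m", posthoc = "tukey")
  tt <- t.test(value ~ group, data = tb, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic^2))
})

test_that("degenerate tables are flagged and collapse to one letter", {
  tb <- make_table(rep(5, 12), rep(c("A", "B", "C"), each = 4))
  r <- anova_posthoc(tb, "m")
  expect_true(r$degenerate)
  expect_equal(length(unique(r$letters)), 1)
  rk <- kruskal_dunn(tb, "m")
  expect_true(rk$degenerate)
  expect_equal(rk$statistic, 0)
  expect_equal(length(unique(rk$letters)), 1)
  expect_error(anova_posthoc(make_table(1:4, rep("A", 4)), "m"), "2 groups")
})

test_that("Tukey letters and p-values match the multcomp reference to 4 decimals", {
  skip_if_not_installed("multcomp")
  set.seed(42)
  tb <- make_table(c(rnorm(6, 0), rnorm(6, 0), rnorm(6, 5)),
                   rep(c("G1", "G2", "G3"), each = 6))
  r <- anova_posthoc(tb, "m", posthoc = "tukey")
  tb$groupf <- factor(tb$group)
  fit <- aov(value ~ groupf, data = tb)
  set.seed(1)
  ref <- summary(multcomp::glht(fit, linfct = multcomp::mcp(groupf = "Tukey")))
  expect_true(all(abs(r$pairwise$p_adj - as.numeric(ref$test$pvalues)) < 1e-4))
  expect_equal(unname(r$letters), c("b", "b", "a"))
})

test_that("Dunn z and Benjamini-Hochberg p-values match the frozen reference", {
  # expected values computed independently with scipy/numpy rank arithmetic
  tb <- make_table(
    c(1.2, 3.4, 2.2, 4.0, 2.2, 5.1, 6.3, 5.1, 7.8, 6.0, 2.2, 4.9, 3.4, 5.1, 4.4),
    rep(c("A", "B", "C"), each = 5))
  r <- kruskal_dunn(tb, "m", alpha = 0.05)
  expect_equal(r$statistic, 10.249727767695108, tolerance = 1e-12)
  expect_equal(r$pairwise$z,
               c(-3.172219476412938, -1.211859125820673, 1.9603603505922655),
               tolerance = 1e-10)
  expect_equal(r$pairwise$p_adj,
               c(0.004538358956728621, 0.22556631075580347, 0.07493053006486125),
               tolerance = 1e-10)
  # second independent route: explicit rank sums recomputed here
  rr <- rank(tb$value)
  rbar <- tapply(rr, tb$group, mean)
  N <- 15
  ties <- table(tb$value)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  se <- sqrt((N * (N + 1) / 12 - tie_term) * (2 / 5))
  expect_equal(r$pairwise$z[1], unname((rbar["A"] - rbar["B"]) / se))
  # BH adjustment is monotone in the raw p-values
  o <- order(r$pairwise$p)
  expect_true(all(diff(r$pairwise$p_adj[o]) >= -1e-12))
})

test_that("letters are reproducible and the logit path is a single transform", {
  set.seed(9)
  tb <- make_table(runif(20, 5, 95), rep(c("A", "B", "C", "D"), each = 5))
  r1 <- anova_posthoc(tb, "m", posthoc = "tukey")
  r2 <- anova_posthoc(tb, "m", posthoc = "tukey")
  expect_identical(r1$letters, r2$letters)
  # logit inside equals ANOVA on pre-transformed values
  ra <- anova_posthoc(tb, "m", transform = "logit")
  tb2 <- tb
  tb2$value <- logit_transform(tb2$value)
  rb <- anova_posthoc(tb2, "m", transform = "none")
  expect_equal(ra$statistic, rb$statistic)
  expect_identical(ra$letters, rb$letters)
})

test_that("groups sharing a letter are never significantly different", {
  set.seed(33)
  for (rep in 1:5) {
    tb <- make_table(rnorm(24, rep(sample(0:3, 4), each = 6)),
                     rep(c("A", "B", "C", "D"), each = 6))
    r <- anova_posthoc(tb, "m", posthoc = "tukey")
    sig <- r$pairwise[r$pairwise$significant, "comparison"]
    for (cmp in sig) {
      gg <- strsplit(cmp, " - ", fixed = TRUE)[[1]]
      shared <- intersect(strsplit(r$letters[[gg[1]]], "")[[1]],
                          strsplit(r$letters[[gg[2]]], "")[[1]])
      expect_equal(length(shared), 0)
    }
  }
})
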