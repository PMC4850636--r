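# Independent brute-force oracles, kept deliberately naive: explicit sums over
# groups, no shared code with the package internals.

oracle_anova <- function(values, groups) {
  groups <- as.integer(factor(groups))
  ng <- max(groups)
  grand <- mean(values)
  ssb <- 0
  ssw <- 0
  for (g in seq_len(ng)) {
    x <- values[groups == g]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  df1 <- ng - 1L
  df2 <- length(values) - ng
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

# literal re-implementations of the closed-form phenotype formulas
oracle_weight_change <- function(initial, final) ((final - initial) / initial) * 100
oracle_oih_percent <- function(baseline, post) (1 - post / baseline) * 100
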