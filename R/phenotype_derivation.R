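# Strain-level opioid adaptation phenotypes from raw behavioral records.
#
# Six traits feed the mapping: morphine analgesic tolerance (fold change in
# ED50 from cumulative dose-response curves, pre vs post chronic morphine),
# mechanical / thermal hindpaw / thermal tail-flick opioid-induced
# hyperalgesia (percent decrease of the nociceptive threshold or latency from
# baseline), naloxone-precipitated jumping (physical dependence; a raw count)
# and percent body-weight change.

#' Percent maximal possible effect
#'
#' `%MPE = (measured - baseline) / (cutoff - baseline) x 100`, clamped to
#' \[0, 100\]. The cutoff is the hardware latency ceiling that prevents tissue
#' damage; at cutoff the drug effect is maximal by definition.
#'
#' @param measured,baseline,cutoff latencies in seconds (vectorised over
#'   `measured` and `baseline`).
#' @return %MPE in \[0, 100\].
#' @export
percent_mpe <- function(measured, baseline, cutoff) {
  .assert(all(cutoff > baseline), "cutoff latency must exceed baseline latency")
  .assert(all(baseline > 0), "baseline latency must be positive")
  .assert(all(measured >= 0 & measured <= cutoff),
          "measured latency must lie in [0, cutoff]")
  pmin(pmax((measured - baseline) / (cutoff - baseline) * 100, 0), 100)
}

#' Fit an ED50 from a cumulative dose-response curve
#'
#' Least-squares fit of the two-parameter log-logistic (Hill) model
#' `%MPE(d) = 100 / (1 + (ED50 / d)^h)` over the positive doses; dose 0
#' anchors the lower asymptote and is excluded from the log transform.
#' Starting values come from an exact logit linearisation
#' (`logit(%MPE/100) = h (log d - log ED50)`), refined by Nelder-Mead on the
#' residual sum of squares — chosen over `nls()` because the latter cannot
#' converge on zero-residual (noiseless) curves.
#'
#' @param doses cumulative doses in mg/kg, strictly increasing, non-negative.
#' @param mpe %MPE at each dose, values in \[0, 100\].
#' @return A list of class `ed50_fit`: `ed50` (mg/kg), `hill_slope`, `rss`,
#'   `n` (positive doses used), `fitted`.
#' @export
fit_ed50 <- function(doses, mpe) {
  .assert(length(doses) == length(mpe), "doses and mpe differ in length")
  .assert(length(doses) >= 4L, "need at least 4 dose points")
  .assert(all(doses >= 0) && all(diff(doses) > 0),
          "doses must be non-negative and strictly increasing")
  .assert(all(mpe >= 0 & mpe <= 100), "mpe values must be in [0, 100]")
  pos <- doses > 0
  d <- doses[pos]
  y <- mpe[pos]
  .assert(length(d) >= 3L, "need at least 3 positive doses")
  .assert(stats::sd(y) > 0 && stats::sd(mpe) > 0,
          "mpe values carry no information (all equal)")
  yc <- pmin(pmax(y, 0.5), 99.5)
  lin <- stats::lm(log(yc / (100 - yc)) ~ log(d))
  h0 <- unname(stats::coef(lin)[2])
  .assert(h0 > 0, "dose-response curve is inverted (response decreases with dose)")
  ed0 <- exp(-unname(stats::coef(lin)[1]) / h0)
  obj <- function(par) {
    ed50 <- exp(par[1]); h <- exp(par[2])
    sum((y - 100 / (1 + (ed50 / d)^h))^2)
  }
  opt <- stats::optim(c(log(ed0), log(h0)), obj, method = "Nelder-Mead",
                      control = list(maxit = 5000L, reltol = 1e-12))
  # polish with BFGS; Nelder-Mead reports simplex degeneracy (code 10) when it
  # collapses onto an (often exact) optimum, which is not a failure
  refined <- stats::optim(opt$par, obj, method = "BFGS",
                          control = list(maxit = 1000L, reltol = 1e-14))
  if (refined$value <= opt$value) opt <- refined
  if (!opt$convergence %in% c(0L, 10L)) {
    stop(sprintf("ED50 fit did not converge (code %d, rss %.6g, start ed50 %.4g h %.4g)",
                 opt$convergence, opt$value, ed0, h0), call. = FALSE)
  }
  ed50 <- exp(opt$par[1]); h <- exp(opt$par[2])
  structure(list(ed50 = ed50, hill_slope = h, rss = opt$value,
                 n = length(d), fitted = 100 / (1 + (ed50 / d)^h)),
            class = "ed50_fit")
}

#' @export
print.ed50_fit <- function(x, ...) {
  cat(sprintf("ed50_fit: ED50 = %.4g mg/kg, Hill slope = %.3g, RSS = %.4g (%d doses)\n",
              x$ed50, x$hill_slope, x$rss, x$n))
  invisible(x)
}

#' Tolerance as fold change in ED50
#'
#' @param ed50_post,ed50_pre fitted ED50 values (mg/kg) after and before
#'   chronic morphine; both must be positive.
#' @return `ed50_post / ed50_pre` (dimensionless; 1 = no tolerance).
#' @export
tolerance_fold_change <- function(ed50_post, ed50_pre) {
  .assert(all(ed50_post > 0) && all(ed50_pre > 0), "ED50 values must be positive")
  ed50_post / ed50_pre
}

#' Opioid-induced hyperalgesia from baseline and post-treatment thresholds
#'
#' Returns the post/baseline fraction and the percentage decrease
#' `(1 - fraction) x 100`. Hypoalgesia (post > baseline) passes through as a
#' negative percent decrease — strains vary.
#'
#' @param baseline_threshold,post_threshold withdrawal threshold (grams) or
#'   latency (seconds); baseline must be positive, post non-negative.
#' @return A list of class `oih_record`: `fraction_of_baseline`,
#'   `percent_decrease`.
#' @export
oih_change <- function(baseline_threshold, post_threshold) {
  .assert(all(baseline_threshold > 0), "baseline threshold must be positive")
  .assert(all(post_threshold >= 0), "post threshold must be non-negative")
  fraction <- post_threshold / baseline_threshold
  structure(list(fraction_of_baseline = fraction,
                 percent_decrease = (1 - fraction) * 100),
            class = "oih_record")
}

#' Percent body-weight change
#'
#' `((final - initial) / initial) x 100`.
#'
#' @param initial,final weights in grams; initial must be positive.
#' @return Percent change (negative = weight loss).
#' @export
percent_weight_change <- function(initial, final) {
  .assert(all(initial > 0), "initial weight must be positive")
  (final - initial) / initial * 100
}

#' Derive the six strain-level traits from long-format behavioral records
#'
#' Expects a data.frame with columns `strain`, `assay`, `phase`, `dose`,
#' `value`:
#' \describe{
#'   \item{tail_flick}{latency (s) per cumulative dose (`dose`, mg/kg; dose 0 =
#'     baseline latency), `phase` pre/post chronic morphine. Yields the
#'     tolerance fold change (post/pre ED50) and thermal tail-flick OIH
#'     (percent decrease of the dose-0 latency).}
#'   \item{mech_threshold}{von Frey threshold (g), `phase` baseline/post ->
#'     mechanical OIH as percent decrease.}
#'   \item{thermal_hindpaw}{withdrawal latency (s), `phase` baseline/post ->
#'     thermal hindpaw OIH as percent decrease.}
#'   \item{weight}{body weight (g), `phase` baseline/post -> percent change.}
#'   \item{jumps}{naloxone-precipitated jump count in the 15-min window
#'     (`phase` post); passed through as the dependence trait.}
#' }
#'
#' @param behavior long-format data.frame as above.
#' @param cutoff_latency tail-flick hardware cutoff in seconds (10 by default).
#' @return A [phenotype_table] with traits `tolerance`, `mech_oih`,
#'   `thermal_oih`, `tailflick_oih`, `dependence`, `weight_change`.
#' @export
derive_phenotypes <- function(behavior, cutoff_latency = 10) {
  need <- c("strain", "assay", "phase", "dose", "value")
  .assert(all(need %in% names(behavior)), "behavior table must have columns %s",
          paste(need, collapse = ", "))
  strains <- unique(behavior$strain)
  one <- function(s) {
    b <- behavior[behavior$strain == s, , drop = FALSE]
    grab <- function(assay, phase) {
      v <- b$value[b$assay == assay & b$phase == phase]
      .assert(length(v) == 1L, "strain '%s': expected one %s/%s record, got %d",
              s, assay, phase, length(v))
      v
    }
    ed50_for <- function(phase) {
      tf <- b[b$assay == "tail_flick" & b$phase == phase, , drop = FALSE]
      tf <- tf[order(tf$dose), , drop = FALSE]
      .assert(nrow(tf) >= 4L && tf$dose[1] == 0,
              "strain '%s': tail_flick/%s needs a dose-0 baseline plus >= 3 doses", s, phase)
      baseline <- tf$value[1]
      mpe <- percent_mpe(tf$value, baseline, cutoff_latency)
      fit_ed50(tf$dose, mpe)$ed50
    }
    tol <- tolerance_fold_change(ed50_for("post"), ed50_for("pre"))
    tf0_pre <- b$value[b$assay == "tail_flick" & b$phase == "pre" & b$dose == 0]
    tf0_post <- b$value[b$assay == "tail_flick" & b$phase == "post" & b$dose == 0]
    data.frame(
      strain = s,
      tolerance = tol,
      mech_oih = oih_change(grab("mech_threshold", "baseline"),
                            grab("mech_threshold", "post"))$percent_decrease,
      thermal_oih = oih_change(grab("thermal_hindpaw", "baseline"),
                               grab("thermal_hindpaw", "post"))$percent_decrease,
      tailflick_oih = oih_change(tf0_pre, tf0_post)$percent_decrease,
      dependence = grab("jumps", "post"),
      weight_change = percent_weight_change(grab("weight", "baseline"),
                                            grab("weight", "post")),
      stringsAsFactors = FALSE
    )
  }
  phenotype_table(do.call(rbind, lapply(strains, one)))
}
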