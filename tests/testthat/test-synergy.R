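test_that("fraction affected follows 1 - X_combo/X_ctl", {
  expect_equal(fa_growth(100, 100), 0)
  expect_equal(fa_growth(0, 100), 1)
  expect_equal(fa_growth(30, 100), 0.7)
  expect_error(fa_growth(10, 0), "positive")
  expect_error(fa_growth(10, -5), "positive")
  # inverse identity on (0, 1): X = X_ctl * (1 - fa) recovers fa
  fa <- seq(0.05, 0.95, by = 0.1)
  expect_equal(fa_growth(100 * (1 - fa), 100), fa)
})

test_that("median-effect fits recover exact parameters on noiseless data", {
  # m = 1, Dm = 10: fa = D / (D + 10)
  d <- c(1, 3, 10, 30, 100)
  f <- fit_median_effect(d, d / (d + 10))
  expect_equal(unname(coef(f)), c(1, 10), tolerance = 1e-10)
  expect_equal(f$r_fit, 1, tolerance = 1e-12)

  # m = 2, Dm = 5 via the generator round trip
  sim <- sim_dose_response(m = 2, dm = 5, cv_noise = 0, n_drugs = 1,
                           seed = 1)
  f2 <- fit_median_effect(sim$drug1_dose,
                          fa_growth(sim$effect_value, sim$control_value))
  expect_equal(f2$m, 2, tolerance = 1e-10)
  expect_equal(f2$dm, 5, tolerance = 1e-10)
  expect_equal(predict(f2, 5), 0.5, tolerance = 1e-10)

  expect_error(fit_median_effect(c(2, 2), c(0.4, 0.6)), "distinct doses")
  expect_error(fit_median_effect(3, 0.5), "distinct doses")
  # decreasing response cannot yield a positive slope
  expect_error(fit_median_effect(c(1, 10, 100), c(0.9, 0.5, 0.1)),
               "not positive")
})

test_that("fa values outside the open unit interval are clamped and flagged", {
  d <- c(1, 3, 10, 30)
  fa <- c(-0.05, 0.3, 0.7, 1.02)
  f <- fit_median_effect(d, fa)
  expect_identical(f$n_clamped, 2L)
  expect_equal(range(f$data$fa_fit), c(0.005, 0.995))
  expect_equal(f$data$fa, fa)   # raw values retained for reporting
})

test_that("effective doses invert the median-effect relation", {
  f <- structure(list(m = 2, dm = 5), class = "median_effect")
  expect_equal(dose_for_effect(f, 0.5), 5)
  expect_equal(dose_for_effect(f, 0.9), 5 * 9^(1 / 2))
  f1 <- structure(list(m = 1, dm = 7), class = "median_effect")
  expect_equal(dose_for_effect(f1, 0.75), 21)      # fa/fu = 3
  expect_equal(effective_conc(f1, 50), 7)
  expect_equal(effective_conc(f1, 75), 21)
  expect_error(dose_for_effect(f1, 1), "strictly")
  expect_error(effective_conc(f1, 0), "strictly")

  # printed EC75 pair 13.5 vs 0.84 dose units is a 16-fold reduction
  expect_equal(round(13.5 / 0.84), 16)
})

test_that("combination index reproduces the printed in vivo worked example", {
  # combo doses (3, 0.001) against single-drug equivalents (16, 0.24)
  cp <- combination_index(c(3, 0.001), dx = c(16, 0.24))
  expect_equal(round(cp$ci, 2), 0.19)
  expect_equal(cp$ci, 3 / 16 + 0.001 / 0.24, tolerance = 1e-12)
  expect_equal(unname(cp$dri), c(16 / 3, 0.24 / 0.001), tolerance = 1e-12)
})

test_that("combination index satisfies the Loewe identities", {
  f1 <- structure(list(m = 1.5, dm = 2), class = "median_effect")
  f2 <- structure(list(m = 0.8, dm = 40), class = "median_effect")
  fa <- 0.6
  dx1 <- dose_for_effect(f1, fa)
  dx2 <- dose_for_effect(f2, fa)
  # single drug at its own effective dose
  expect_equal(combination_index(c(dx1, 0), fa, list(f1, f2))$ci, 1)
  # Loewe additivity: half of each equivalent dose
  expect_equal(combination_index(c(dx1 / 2, dx2 / 2), fa, list(f1, f2))$ci, 1)
  # non-exclusive form adds the cross term
  ne <- combination_index(c(dx1 / 2, dx2 / 2), fa, list(f1, f2),
                          exclusive = FALSE)
  expect_equal(ne$ci, 1 + 0.25)
  # scale invariance: rescaling one drug's dose axis and its Dm together
  f1s <- structure(list(m = 1.5, dm = 2 * 1000), class = "median_effect")
  expect_equal(
    combination_index(c(1000 * dx1 / 2, dx2 / 2), fa, list(f1s, f2))$ci,
    combination_index(c(dx1 / 2, dx2 / 2), fa, list(f1, f2))$ci,
    tolerance = 1e-12
  )
  expect_error(combination_index(c(1, 2), fa = 0.5), "supply")
})

test_that("dose reduction index matches the printed in vivo values", {
  expect_equal(dose_reduction_index(34, 10), 3.4)
  expect_equal(dose_reduction_index(0.013, 0.001), 13)
  expect_equal(dose_reduction_index(5, 5), 1)
  expect_error(dose_reduction_index(5, 0), "positive")
  # DRI > 1 iff the combo achieves the effect with less drug
  expect_gt(dose_reduction_index(10, 2), 1)
  expect_lt(dose_reduction_index(2, 10), 1)
})

test_that("combination index round-trips the generator's ground truth", {
  est_ci <- function(alpha, cv, seed, reps = 1) {
    d <- sim_dose_response(m = c(1.5, 2), dm = c(1, 20), cv_noise = cv,
                           alpha = alpha, ratio = 20, n_drugs = 2,
                           replicates = reps, seed = seed)
    fa <- fa_growth(d$effect_value, d$control_value)
    s1 <- d$drug1_dose > 0 & d$drug2_dose == 0
    s2 <- d$drug2_dose > 0 & d$drug1_dose == 0
    # CI is evaluated at the observed fa; points at the assay's floor or
    # ceiling carry no usable effect level and are left out
    co <- which(d$drug1_dose > 0 & d$drug2_dose > 0 & fa > 0.01 & fa < 0.99)
    f1 <- fit_median_effect(d$drug1_dose[s1], fa[s1])
    f2 <- fit_median_effect(d$drug2_dose[s2], fa[s2])
    mean(vapply(co, function(r) {
      combination_index(c(d$drug1_dose[r], d$drug2_dose[r]),
                        fa = fa[r], fits = list(f1, f2))$ci
    }, numeric(1)))
  }
  # noiseless: within 1% of 1/alpha
  expect_lt(abs(est_ci(1, 0, 1) - 1), 0.01)
  expect_lt(abs(est_ci(2, 0, 2) - 0.5) / 0.5, 0.01)
  # cv 5%, 3 replicates: within 10%
  expect_lt(abs(est_ci(2, 0.05, 3, reps = 3) - 0.5) / 0.5, 0.1)
})

test_that("potent synergy needs Fa > 0.7 and CI < 0.7 in every orientation", {
  good <- data.frame(fa = c(0.5, 0.8), ci = c(0.9, 0.6))
  expect_true(classify_potent(list(good, good))$potent)
  low_fa <- data.frame(fa = 0.5, ci = 0.6)
  expect_false(classify_potent(low_fa)$potent)
  high_ci <- data.frame(fa = 0.9, ci = 0.8)
  expect_false(classify_potent(high_ci)$potent)
  # boundary is strict
  expect_false(classify_potent(data.frame(fa = 0.7, ci = 0.6))$potent)
  # one failing orientation blocks the call
  mixed <- classify_potent(list(good, low_fa))
  expect_false(mixed$potent)
  expect_identical(unname(mixed$per_orientation), c(TRUE, FALSE))
  # data frame with an orientation column splits correctly
  df <- rbind(cbind(good, orientation = "varyA"),
              cbind(good, orientation = "varyB"))
  expect_true(classify_potent(df)$potent)
})

test_that("three-drug CI treats the fixed-ratio pair as one entity", {
  # additive triple: CI must come back ~1
  d1 <- sim_dose_response(m = 1.5, dm = c(1, 4, 10), cv_noise = 0,
                          alpha = 1, ratio = 1, n_drugs = 3, seed = 5)
  r1 <- three_drug_ci(d1)
  expect_true(all(abs(r1$points$ci - 1) < 0.01))
  # synergy alpha = 2: CI ~ 0.5
  d2 <- sim_dose_response(m = 1.5, dm = c(1, 4, 10), cv_noise = 0,
                          alpha = 2, ratio = 1, n_drugs = 3, seed = 6)
  r2 <- three_drug_ci(d2)
  expect_true(all(abs(r2$points$ci - 0.5) < 0.005))

  # entity self-consistency: pair alone at its own Dx gives CI = 1
  fa <- 0.6
  dx_pair <- dose_for_effect(r1$pair_fit, fa)
  self <- combination_index(c(dx_pair, 0), fa,
                            list(r1$pair_fit, r1$third_fit))
  expect_equal(self$ci, 1, tolerance = 1e-8)

  # ratio drift beyond 1% is rejected
  drift <- d1
  i <- which(drift$drug1_dose > 0 & drift$drug2_dose > 0)[1]
  drift$drug2_dose[i] <- drift$drug2_dose[i] * 1.05
  expect_error(three_drug_ci(drift), "drift")
})

test_that("growth series are normalised to day 0 then averaged", {
  s <- data.frame(day = c(0, 1, 2), replicate = "r1", value = c(2, 4, 8))
  out <- growth_series_normalize(s)
  expect_equal(out$value, c(1, 2, 4))

  const <- data.frame(day = rep(c(0, 3, 7), 2),
                      replicate = rep(c("a", "b"), each = 3),
                      value = c(5, 5, 5, 9, 9, 9))
  expect_equal(growth_series_normalize(const)$value, c(1, 1, 1))

  # treated grows 2-fold vs vehicle 4-fold at day 7 -> fa = 0.5
  veh <- data.frame(day = c(0, 7), replicate = "v", value = c(10, 40))
  trt <- data.frame(day = c(0, 7), replicate = "t", value = c(10, 20))
  nv <- growth_series_normalize(veh)
  nt <- growth_series_normalize(trt)
  expect_equal(fa_growth(nt$value[nt$day == 7], nv$value[nv$day == 7]), 0.5)

  expect_error(growth_series_normalize(
    data.frame(day = c(1, 2), replicate = "r", value = c(1, 2))
  ), "day-0")
})
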