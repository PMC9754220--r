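# Mixed-effects estimation: exact recovery, combined age effects, LRT
# calibration hooks, percent transforms, multiplicity and marginal R2.

noiseless_table <- function(n = 60L, mode = "grid", seed = 4L) {
  cfg <- oct_config(n_subjects = n, mode = mode, noise_scale = 0,
                    fixation_offset_max = 0)
  simulate_parameter_table(cfg, seed = seed)
}

test_that("noiseless data recovers every injected coefficient", {
  cfg <- oct_config(n_subjects = 60L, noise_scale = 0)
  tab <- noiseless_table(60L)
  le <- cfg$layer_effects
  for (l in c("TRT", "GCIPL", "ONPL")) {
    row <- le[le$parameter == l, ]
    fit <- fit_candidate(tab, l, quadratic = TRUE)
    beta <- lme4::fixef(fit)
    bb <- true_centered_coefs(cfg, l)
    expect_lt(abs(beta[["is_male"]] - row$sex), 1e-3)
    expect_lt(abs(beta[["age_c"]] - bb[1]), 1e-3)
    expect_lt(abs(beta[["age_c2"]] - bb[2]), 1e-4)
    expect_lt(abs(beta[["scan_focus"]] - row$sf), 1e-3)
    comb <- combined_age_effect(fit)
    expect_lt(abs(comb$estimate_per10y - 10 * (bb[1] + 40 * bb[2])), 1e-2)
  }
})

test_that("duplicating every eye leaves the fixed effects unchanged", {
  tab <- noiseless_table(40L)
  one <- tab[!duplicated(tab[c("subject_id", "parameter")]), ]
  set.seed(17)
  one$value <- one$value + stats::rnorm(nrow(one), 0, 2)
  # duplicated-eyes table: every eye appears twice with identical values
  dup <- rbind(one, transform(one, eye = paste0(eye, "bis")))
  d1 <- octmorph:::effects_frame(one, "TRT")
  f1 <- stats::coef(stats::lm(value ~ is_male + age_c + age_c2 + scan_focus,
                              data = d1))
  f2 <- lme4::fixef(fit_candidate(dup, "TRT", quadratic = TRUE))
  # the duplicated fit sits on the zero-residual boundary; agreement is
  # limited by the mixed-model optimizer, not by the algebra
  expect_equal(unname(f1), unname(f2), tolerance = 5e-3)
})

test_that("combined age effect has the right closed forms", {
  tab <- noiseless_table(50L)
  # linear model: combined = 10 * beta_age
  fit <- fit_candidate(tab, "ONPL", quadratic = FALSE)
  comb <- combined_age_effect(fit)
  expect_equal(comb$estimate_per10y, 10 * lme4::fixef(fit)[["age_c"]],
               tolerance = 1e-10)
  # pure quadratic: beta_age(uncentered) = 0 means b1 = 80*b2 centered;
  # combined per decade = 1200 * b2
  cfg <- oct_config(n_subjects = 200L, noise_scale = 0)
  b2 <- 0.001
  tab2 <- simulate_parameter_table(cfg, seed = 8)
  d <- tab2[tab2$parameter == "TRT", ]
  a <- d$age_years
  d$value <- 300 + b2 * a^2   # no linear term on the uncentered scale
  fit2 <- fit_candidate(d, "TRT", quadratic = TRUE)
  comb2 <- combined_age_effect(fit2)
  expect_equal(comb2$estimate_per10y, 1200 * b2, tolerance = 1e-6)
  # CI brackets the estimate
  expect_lt(comb2$ci_per10y[1], comb2$estimate_per10y)
  expect_gt(comb2$ci_per10y[2], comb2$estimate_per10y)
})

test_that("AIC model selection prefers the true form and breaks ties linearly", {
  cfg <- oct_config(n_subjects = 300L)
  tab <- simulate_parameter_table(cfg, seed = 3)
  d <- tab[tab$parameter == "TRT", ]
  set.seed(99)
  a <- d$age_years - 40
  subj <- as.integer(factor(d$subject_id))
  gamma <- stats::rnorm(max(subj), 0, 5)[subj]
  # strong curvature, modest noise -> quadratic wins
  d$value <- 300 - 0.02 * a^2 + gamma + stats::rnorm(nrow(d), 0, 3)
  selq <- select_age_model(d, "TRT")
  expect_equal(selq$model_form, "quadratic")
  expect_lt(selq$aic_quadratic, selq$aic_linear)
  # pure linear truth at large n -> linear wins
  d$value <- 300 - 0.4 * a + gamma + stats::rnorm(nrow(d), 0, 3)
  sell <- select_age_model(d, "TRT")
  expect_equal(sell$model_form, "linear")
  # identical AICs prefer linear by construction of the comparison
  expect_true(sell$aic_linear <= sell$aic_quadratic ||
                sell$model_form == "quadratic")
})

test_that("combined age p-value behaves at the extremes", {
  # no age effect, quadratic selected artificially: p from 2-df LRT
  cfg <- oct_config(n_subjects = 80L)
  tab <- simulate_parameter_table(cfg, seed = 12)
  d <- tab[tab$parameter == "TRT", ]
  set.seed(7)
  d$value <- 300 + stats::rnorm(nrow(d), 0, 5)
  sel <- list(fit = fit_candidate(d, "TRT", quadratic = TRUE),
              model_form = "quadratic")
  p0 <- age_pvalue(d, "TRT", sel)
  expect_gt(p0, 0.001)  # null data rarely gives tiny p
  # strong effect: p far below 0.001
  d$value <- 300 - 0.5 * (d$age_years - 40) + stats::rnorm(nrow(d), 0, 3)
  sel2 <- list(fit = fit_candidate(d, "TRT", quadratic = TRUE),
               model_form = "quadratic")
  expect_lt(age_pvalue(d, "TRT", sel2), 1e-6)
})

test_that("percent transforms use young-group references and rescale cleanly", {
  tab <- noiseless_table(80L, seed = 10)
  refs <- young_reference_means(tab, "TRT")
  d <- tab[tab$parameter == "TRT", ]
  expect_equal(refs$young_mean, mean(d$value[d$age_years <= 40]))
  expect_equal(refs$young_female_mean,
               mean(d$value[d$age_years <= 40 & d$sex == "female"]))
  # the worked example: -3.25 um/decade against a 309.5 um reference
  pt <- percent_transform(-3.25, 309.5238, ci = c(-4.09, -2.39))
  expect_equal(pt$percent, -1.05, tolerance = 1e-3)
  expect_equal(pt$ci_percent, c(-1.3215, -0.7722), tolerance = 1e-3)
  expect_equal(percent_transform(0, 123)$percent, 0)
  # invariance under global unit rescaling
  tab2 <- tab
  tab2$value <- tab2$value * 2
  e1 <- estimate_effects(tab, "GCIPL")
  e2 <- estimate_effects(tab2, "GCIPL")
  expect_equal(e1$beta_age_pct_per10y, e2$beta_age_pct_per10y,
               tolerance = 1e-6)
  expect_equal(e1$beta_sex_pct, e2$beta_sex_pct, tolerance = 1e-6)
  expect_equal(2 * e1$beta_sex_abs, e2$beta_sex_abs, tolerance = 1e-6)
})

test_that("multiplicity corrections match hand-computed values", {
  # Holm with m = 2: adjusted {0.02, 0.04}
  h <- adjust_pvalues(c(0.01, 0.04), method = "holm")
  expect_equal(h$adjusted, c(0.02, 0.04))
  expect_true(all(h$significant))
  # BH step-up on {0.001, 0.02, 0.03, 0.9}: adjusted {0.004, 0.04, 0.04, 0.9}
  b <- adjust_pvalues(c(0.001, 0.02, 0.03, 0.9), method = "bh")
  expect_equal(b$adjusted, c(0.004, 0.04, 0.04, 0.9))
  expect_equal(b$significant, c(TRUE, TRUE, TRUE, FALSE))
  # degenerate and invalid inputs
  expect_equal(adjust_pvalues(rep(1, 5), "holm")$significant, rep(FALSE, 5))
  expect_error(adjust_pvalues(c(0.1, 1.4)), "0, 1")
  # monotonicity: adjusted >= raw, order preserved
  set.seed(5)
  p <- stats::runif(20)
  for (m in c("holm", "bh")) {
    adj <- adjust_pvalues(p, m)$adjusted
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("marginal R-squared matches its limits and analytic expectation", {
  # noiseless, no random intercept: 100%
  tab <- noiseless_table(50L)
  fit <- fit_candidate(tab, "TRT", quadratic = TRUE)
  expect_gt(marginal_r2(fit), 99.9)
  # zero fixed effects: ~0%
  cfg <- oct_config(n_subjects = 100L)
  tab2 <- simulate_parameter_table(cfg, seed = 2)
  d <- tab2[tab2$parameter == "TRT", ]
  set.seed(31)
  d$value <- stats::rnorm(nrow(d), 300, 10)
  expect_lt(marginal_r2(fit_candidate(d, "TRT")), 5)
  # default TRT cohort: matches the analytic expectation for this
  # generator's demographics (var_fixed / (var_fixed + 14^2 + 6^2))
  cfg3 <- oct_config(n_subjects = 444L)
  r2 <- mean(vapply(6:8, function(s) {
    tab3 <- simulate_parameter_table(cfg3, seed = s)
    estimate_effects(tab3, "TRT")$r2_marginal_pct
  }, numeric(1)))
  row <- cfg3$layer_effects[cfg3$layer_effects$parameter == "TRT", ]
  vf <- octmorph:::fixed_effect_variance(row, cfg3)
  expected <- 100 * vf / (vf + 14^2 + 6^2)
  expect_lt(abs(r2 - expected), 4)
})

test_that("effect tables carry the family structure", {
  cfg <- oct_config(n_subjects = 60L)
  tab <- simulate_parameter_table(cfg, seed = 14)
  eff <- estimate_effects(tab, ALL_LAYERS, family_method = "holm")
  expect_equal(nrow(eff), 6L)
  expect_equal(unique(eff$n_tests_family), 12L)
  expect_true(all(eff$p_age_adj >= eff$p_age - 1e-12))
  expect_true(all(eff$beta_age_abs_lo <= eff$beta_age_abs_per10y &
                    eff$beta_age_abs_per10y <= eff$beta_age_abs_hi))
})
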