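test_that("AICc weights: symmetry, closed-form ratios, and input checks", {
  f1 <- fake_fit(rss = 50, n_obs = 200, n_params = 3, scheme = "one_step")
  f2 <- fake_fit(rss = 50, n_obs = 200, n_params = 3, scheme = "two_step")
  cmp <- akaike_compare(list(f1, f2))
  expect_equal(cmp$table$weight, c(0.5, 0.5))
  expect_equal(sum(cmp$table$weight), 1)

  # delta AICc of 10 gives a weight ratio of e^5
  n <- 200
  # choose rss2 so that AICc difference is exactly 10 at equal p
  rss1 <- 50
  rss2 <- rss1 * exp(10 / n)
  g2 <- fake_fit(rss = rss2, n_obs = n, n_params = 3, scheme = "two_step")
  cmp2 <- akaike_compare(list(f1, g2))
  expect_equal(cmp2$table$weight[1] / cmp2$table$weight[2], exp(5),
               tolerance = 1e-10)

  expect_error(akaike_compare(list(f1, fake_fit(50, 100, 3))), "n_obs")
})

test_that("variance-ratio test: hand arithmetic, identity, and clamping", {
  fs <- fake_fit(rss = 110, n_obs = 104, n_params = 2)
  fc <- fake_fit(rss = 100, n_obs = 104, n_params = 4, scheme = "two_step")
  vt <- variance_ratio_test(fs, fc)
  expect_equal(vt$F, 5)
  expect_equal(vt$df1, 2)
  expect_equal(vt$df2, 100)
  expect_equal(vt$p_value, pf(5, 2, 100, lower.tail = FALSE))

  same <- variance_ratio_test(fake_fit(100, 104, 2),
                              fake_fit(100, 104, 4, "two_step"))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  expect_warning(
    worse <- variance_ratio_test(fake_fit(100, 104, 2),
                                 fake_fit(101, 104, 4, "two_step")),
    "clamped")
  expect_equal(worse$F, 0)
  expect_error(variance_ratio_test(fc, fs), "more parameters")
})

test_that("Ki error propagation reproduces the tabulated derived constants", {
  # plasmin / textilinin-1
  ki1 <- ki_with_error(1.72e6, 0.02e6, 7.50e-4, 0.11e-4)
  expect_equal(ki1$K_i * 1e9, 0.436, tolerance = 1e-3)
  expect_lt(abs(ki1$K_i_se * 1e9 - 0.009), 0.001)
  # plasmin / aprotinin
  ki2 <- ki_with_error(2.45e6, 0.04e6, 2.39e-5, 0.25e-5)
  expect_equal(round(ki2$K_i * 1e9, 3), 0.010)
  expect_lt(abs(ki2$K_i_se * 1e9 - 0.001), 5e-4)
  # trypsin / textilinin-1
  ki3 <- ki_with_error(8.60e5, 0.44e5, 3.60e-4, 0.51e-4)
  expect_equal(round(ki3$K_i * 1e9, 3), 0.419)
  expect_lt(abs(ki3$K_i_se * 1e9 - 0.060), 0.005)
  # kallikrein / textilinin-1 lands near 1.9 uM
  ki4 <- ki_with_error(1.26e4, 0.43e4, 2.35e-2, 0.18e-2)
  expect_equal(ki4$K_i * 1e6, 1.9, tolerance = 0.02)

  expect_equal(ki_with_error(1e6, 0, 1e-3, 0)$K_i_se, 0)
  irr <- ki_with_error(4.13e2, 0.06e2, 0, 0)
  expect_true(irr$irreversible)
  expect_identical(irr$K_i, 0)
  expect_error(ki_with_error(0, 0, 1e-3, 0), "k_on")
})

test_that("half-lives at the 1 uM reference reproduce the tabulated values", {
  th <- half_lives(1.26e4, 2.35e-2)
  expect_equal(th$t_half_on_s, 55.0, tolerance = 1e-3)
  expect_equal(th$t_half_off_min, 0.49, tolerance = 0.01)
  expect_equal(half_lives(4.13e2, 1e-9)$t_half_on_s, 1680, tolerance = 2e-3)
  expect_true(is.na(half_lives(1e6, 0)$t_half_off_min))
  expect_error(half_lives(1e6, 1e-3, reference_I = 0), "positive")
})

test_that("selectivity ratios reproduce the fold differences", {
  s <- list(
    tex_plm = inhibition_summary(1.72e6, 0.02e6, 7.50e-4, 0.11e-4),
    apr_plm = inhibition_summary(2.45e6, 0.04e6, 2.39e-5, 0.25e-5),
    tex_kal = inhibition_summary(1.26e4, 0.43e4, 2.35e-2, 0.18e-2),
    apr_kal = inhibition_summary(3.03e4, 0.17e4, 5.76e-4, 0.60e-4))
  m <- selectivity_ratios(s)
  expect_equal(m["tex_plm", "apr_plm"], 44.7, tolerance = 0.01)
  expect_equal(m["tex_kal", "apr_kal"], 98, tolerance = 0.01)
  expect_gt(m["tex_kal", "tex_plm"], 4000)
  # recovery (dissociation half-life) ratio, aprotinin vs textilinin-1
  h <- selectivity_ratios(s, what = "t_half_off_min")
  expect_equal(h["apr_plm", "tex_plm"], 31.4, tolerance = 0.01)
  # and from the printed (rounded) half-lives
  expect_equal(round(483 / 15), 32)

  s$irr <- inhibition_summary(4.13e2, 0.06e2, 0, 0)
  expect_warning(m2 <- selectivity_ratios(s), "irreversible")
  expect_true(is.infinite(m2["tex_plm", "irr"]))
})

test_that("scheme discrimination selects one-step on one-step data and triggers the irreversible refit", {
  des <- small_design("plasmin", dt = 20)
  fam <- generate_family(des, "one_step", rates_for("plasmin"),
                         noise_model(seed = 2))
  sel <- suppressWarnings(discriminate_schemes(fam, n_starts = 1))
  expect_identical(sel$selected, "one_step")
  expect_gt(sel$comparison$table$weight[
    sel$comparison$table$scheme == "one_step"], 0.5)

  # truly irreversible truth: reversible fit leaves k_off undetermined,
  # triggering the k_off = 0 refit and its selection
  famirr <- generate_family(des, "irreversible",
                            rate_parameters(k_on = 1e6, k_off = 0),
                            noise_model(seed = 3))
  selirr <- suppressWarnings(discriminate_schemes(famirr, n_starts = 1))
  expect_false(is.null(selirr$comparison_irreversible))
  expect_identical(selirr$selected, "irreversible")
})

test_that("report table has the expected shape", {
  s <- list(
    `textilinin-1/plasmin` = inhibition_summary(1.72e6, 0.02e6, 7.50e-4,
                                                0.11e-4),
    `aprotinin/plasmin` = inhibition_summary(2.45e6, 0.04e6, 2.39e-5,
                                             0.25e-5))
  rep <- inhibition_report(s)
  expect_equal(dim(rep), c(5, 2))
  expect_setequal(rownames(rep),
                  c("K_i_nM", "k_on", "k_off", "t_half_on_s",
                    "t_half_off_min"))
  expect_equal(rep["K_i_nM", 1], 0.436, tolerance = 1e-3)
})
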