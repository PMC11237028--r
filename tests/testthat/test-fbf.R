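test_that("inference returns consequent centers at grid points and blends midway", {
  fit <- canonical_fit()
  # grid point whose rule consequent is Normal
  expect_equal(predict(fit, data.frame(hgb = 14.1, pao2 = 47.5)), 0.75)
  expect_equal(predict(fit, data.frame(hgb = 8, pao2 = 47.5)), 0.25)
  # midway between a Low and a Normal cell with equal basis weights
  expect_equal(predict(fit, data.frame(hgb = (10.25 + 14.1) / 2,
                                       pao2 = 47.5)), 0.50)
})

test_that("normalized and unnormalized inference coincide under a complete grid base", {
  fit <- canonical_fit()
  set.seed(42)
  z <- data.frame(hgb = runif(300, 8, 16.6), pao2 = runif(300, 30, 90))
  fn <- infer(fit, z, normalize = TRUE)
  fu <- infer(fit, z, normalize = FALSE)
  expect_lt(max(abs(fn - fu)), 1e-12)   # partition of unity
})

test_that("normalized inference equals the brute-force weighted-centroid oracle", {
  for (inputs in list(c("hgb", "pao2"), c("hgb", "ph"), c("pao2", "ph"))) {
    fit <- canonical_fit(inputs)
    set.seed(7)
    lo <- vapply(fit$system$inputs, function(p) min(p$centers), 0)
    hi <- vapply(fit$system$inputs, function(p) max(p$centers), 0)
    z <- cbind(runif(200, lo[1], hi[1]), runif(200, lo[2], hi[2]))
    colnames(z) <- inputs
    got <- infer(fit, z)
    want <- vapply(seq_len(nrow(z)), function(i) {
      oracle_infer(fit, as.list(z[i, ]))
    }, numeric(1))
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("the canonical response is monotone non-decreasing in haemoglobin", {
  fit <- canonical_fit()
  hgb <- seq(8, 16.6, length.out = 400)
  for (pao2 in c(30, 55, 90)) {
    f <- predict(fit, data.frame(hgb = hgb, pao2 = pao2))
    expect_true(all(diff(f) >= -1e-12), label = paste("pao2 =", pao2))
  }
})

test_that("normalized output always stays within the output-center range", {
  fit <- canonical_fit()
  set.seed(11)
  z <- data.frame(hgb = runif(500, 0, 25), pao2 = runif(500, 0, 120))
  f <- infer(fit, z)
  expect_true(all(f >= 0.25 - 1e-12 & f <= 0.75 + 1e-12))
})

test_that("inputs activating no rule raise an uncovered-input error", {
  p <- default_partitions()
  sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
  sys$rules <- learn_rules(sys, data.frame(hgb = 8, pao2 = 30), 0.25)
  expect_error(infer(sys, c(hgb = 16, pao2 = 90)), "uncovered input")
  expect_true(is.na(infer(sys, c(hgb = 16, pao2 = 90), uncovered = "na")))
  bad <- sys; bad$rules <- NULL
  expect_error(infer(bad, c(hgb = 8, pao2 = 30)), "empty")
})

test_that("the fitted model exposes the standard modelling surface", {
  fit <- canonical_fit()
  expect_s3_class(fit, "fbf")
  expect_output(print(fit), "rule space 32")
  expect_length(coef(fit), 16L)
  expect_true(all(coef(fit) %in% c(0.25, 0.75)))
  expect_equal(fitted(fit) + residuals(fit), fit$response)
  s <- summary(fit)
  expect_s3_class(s, "summary.fbf")
  expect_equal(nrow(s$rule_table), 16L)
  expect_output(print(s), "Very Low")
  lab <- predict(fit, data.frame(hgb = c(8, 14.1), pao2 = c(47.5, 47.5)),
                 type = "label")
  expect_equal(lab, c("Low", "Normal"))
  al <- predict(fit, data.frame(hgb = 8, pao2 = 47.5), type = "alarm")
  expect_true(al[[1]]$alarm)
  expect_error(fbf(state ~ nonexistent, data.frame(nonexistent = 1,
                                                   state = 0.25)),
               "no partition")
})

test_that("fitting on simulated days reproduces held-out alarm behaviour sensibly", {
  co <- labeled_cohort(n = 80, horizon = 7, seed = 21)
  d <- data.frame(hgb = co$panel$hgb, pao2 = co$panel$pao2,
                  state = ifelse(co$labels$prbc == 1, 0.25, 0.75))
  fit <- suppressWarnings(fbf(state ~ hgb + pao2, d, complete = TRUE))
  f <- predict(fit, d)
  expect_true(all(f >= 0.25 - 1e-12 & f <= 0.75 + 1e-12))
  # the learned system flags anaemia more than health
  f_low <- predict(fit, data.frame(hgb = 7.5, pao2 = 40))
  f_high <- predict(fit, data.frame(hgb = 14, pao2 = 70))
  expect_lt(f_low, f_high)
})
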