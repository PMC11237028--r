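test_that("cohort sampling is bit-identical under a fixed seed", {
  sch <- build_default_schema()
  a <- sample_cohort(sch, 25, seed = 7)
  b <- sample_cohort(sch, 25, seed = 7)
  expect_identical(a, b)
  c2 <- sample_trajectories(a, 4, 0.6, seed = 9)
  d2 <- sample_trajectories(b, 4, 0.6, seed = 9)
  expect_identical(c2, d2)
  expect_false(identical(a$baseline, sample_cohort(sch, 25, seed = 8)$baseline))
})

test_that("quota sampling reproduces every demographic count exactly at n = 98", {
  sch <- build_default_schema()
  co <- sample_cohort(sch, 98, seed = 3)
  expect_equal(nrow(co$baseline), 98L)
  for (nm in names(sch$category_counts)) {
    got <- table(co$baseline[[nm]])
    want <- sch$category_counts[[nm]]
    expect_equal(as.integer(got[names(want)]), as.integer(want),
                 label = paste("counts for", nm))
  }
})

test_that("continuous marginals recover schema parameters at large n", {
  sch <- build_default_schema()
  co <- sample_cohort(sch, 10000, seed = 5, quota = FALSE)
  cont <- subset(sch$features, kind == "continuous")
  for (i in seq_len(nrow(cont))) {
    fi <- cont[i, ]
    v <- co$baseline[[fi$name]]
    se <- fi$sd / sqrt(length(v))
    expect_lt(abs(mean(v) - fi$mean), 3 * se,
              label = paste("mean of", fi$name))
    # sd of the sample SD ~ sd / sqrt(2 (n - 1)) for a Gaussian
    expect_lt(abs(sd(v) - fi$sd), 3 * fi$sd / sqrt(2 * (length(v) - 1)) +
                0.02 * fi$sd,
              label = paste("sd of", fi$name))
  }
  expect_gt(cor(co$baseline$hgb, co$baseline$hct), 0.85)
})

test_that("sampling rejects invalid arguments", {
  sch <- build_default_schema()
  expect_error(sample_cohort(sch, 0), "invalid n")
  empty <- toy_schema(build_default_schema()$features[0, ],
                      list(x = c(a = 1L)))
  expect_error(sample_cohort(empty, 5), "empty feature list")
  expect_error(sample_cohort(sch, 50, quota = TRUE), "quota")
})

test_that("AR(1) trajectories start at baseline and match the requested autocorrelation", {
  sch <- build_default_schema()
  co <- sample_cohort(sch, 6, seed = 2)
  one <- sample_trajectories(co, horizon = 1, seed = 3)
  d0 <- one$panel[one$panel$day == 0, ]
  expect_equal(d0$hgb, co$baseline$hgb)
  expect_equal(d0$sbp, co$baseline$sbp)

  long <- sample_trajectories(co, horizon = 500, autocorr = 0.8, seed = 4)
  acf1 <- vapply(split(long$panel$sbp, long$panel$id), function(x) {
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(acf1) - 0.8), 0.07)

  iid <- sample_trajectories(co, horizon = 500, autocorr = 0, seed = 4)
  acf0 <- vapply(split(iid$panel$sbp, iid$panel$id), function(x) {
    stats::acf(x, lag.max = 1, plot = FALSE)$acf[2]
  }, numeric(1))
  expect_lt(abs(mean(acf0)), 0.07)
  expect_error(sample_trajectories(co, 5, autocorr = 1), "autocorr")
})

test_that("threshold labelling matches the documented risk extremes", {
  sch <- build_default_schema()
  co <- sample_cohort(sch, 2, seed = 1)
  co <- sample_trajectories(co, horizon = 1, seed = 2)
  # healthy extreme vs anaemic hypoxic acidotic patient; other risk inputs
  # pinned to their population means
  co$panel$hgb <- c(16.0, 7.2)
  co$panel$pao2 <- c(75, 42)
  co$panel$ph <- c(7.40, 7.25)
  co$panel$sbp <- rep(124.64, 2)
  co$panel$platelet <- rep(108.88, 2)
  lab <- assign_daily_labels(co, mode = "threshold")
  expect_equal(lab$labels$prbc, c(0L, 1L))
})

test_that("risk is monotone: lowering haemoglobin never lowers it", {
  sch <- build_default_schema()
  co <- labeled_cohort(n = 10, horizon = 3, seed = 11)
  s1 <- nfabt:::risk_score(co)
  lower <- co
  lower$panel$hgb <- lower$panel$hgb - 1
  s2 <- nfabt:::risk_score(lower)
  expect_true(all(s2 >= s1))
})

test_that("default logistic labels hit about 7% daily prevalence", {
  co <- sample_cohort(build_default_schema(), 2000, seed = 31, quota = FALSE)
  co <- sample_trajectories(co, horizon = 7, seed = 32)
  co <- assign_daily_labels(co, seed = 33)
  expect_lt(abs(mean(co$labels$prbc) - 0.07), 0.02)
})

test_that("trend labels flag haemoglobin drops with day 0 at zero", {
  co <- sample_cohort(build_default_schema(), 3, seed = 41)
  co <- sample_trajectories(co, horizon = 6, seed = 42)
  co <- assign_daily_labels(co, mode = "trend")
  for (pid in unique(co$panel$id)) {
    h <- co$panel$hgb[co$panel$id == pid]
    l <- co$labels$prbc[co$labels$id == pid]
    expect_equal(l, c(0L, as.integer(diff(h) < 0)))
  }
})

test_that("missingness injection is calibrated and respects edge rates", {
  f <- rbind(toy_feature("a", missing_rate = 0),
             toy_feature("b", missing_rate = 1),
             toy_feature("c", missing_rate = 0.95))
  sch <- toy_schema(f)
  n <- 10000
  base <- data.frame(id = sprintf("P%05d", 1:n), a = rnorm(n), b = rnorm(n),
                     c = rnorm(n), stringsAsFactors = FALSE)
  co <- toy_cohort(base, sch)
  out <- inject_missingness(co, seed = 6)
  expect_identical(out$baseline$a, base$a)
  expect_true(all(is.na(out$baseline$b)))
  expect_lt(abs(mean(is.na(out$baseline$c)) - 0.95), 0.01)
})
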