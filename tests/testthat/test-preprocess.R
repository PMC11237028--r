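make_missing_cohort <- function(frac, n = 100) {
  f <- rbind(toy_feature("x"), toy_feature("y"))
  base <- data.frame(id = sprintf("P%03d", 1:n), x = rnorm(n), y = rnorm(n),
                     stringsAsFactors = FALSE)
  base$x[seq_len(round(frac * n))] <- NA
  toy_cohort(base, toy_schema(f))
}

test_that("high-missingness exclusion uses a strict threshold", {
  co <- make_missing_cohort(0.95)
  res <- drop_high_missingness(co, 0.90)
  expect_equal(res$report$dropped_features, "x")
  expect_false("x" %in% names(res$cohort$baseline))
  expect_false("x" %in% res$cohort$schema$features$name)

  ok <- drop_high_missingness(make_missing_cohort(0), 0.90)
  expect_length(ok$report$dropped_features, 0)

  at <- drop_high_missingness(make_missing_cohort(0.90), 0.90)
  expect_length(at$report$dropped_features, 0)  # exactly 90% stays

  expect_error(drop_high_missingness(co, 0), "threshold")
  expect_error(drop_high_missingness(co, 1.2), "threshold")
})

test_that("default synthetic cohort drops exactly the schema's eight flagged features", {
  co <- labeled_cohort(n = 60, horizon = 7, seed = 5)
  co <- inject_missingness(co, seed = 6)
  res <- drop_high_missingness(co)
  flagged <- build_default_schema()
  flagged <- flagged$features$name[flagged$features$missing_rate > 0.9]
  expect_setequal(res$report$dropped_features, flagged)
})

test_that("missingness indicators appear only above the 50% threshold, coded 1 = present", {
  co <- make_missing_cohort(0.60)
  out <- add_missingness_indicators(co)
  expect_true("x_present" %in% names(out$baseline))
  expect_equal(mean(out$baseline$x_present), 0.4)
  expect_false("y_present" %in% names(out$baseline))

  low <- add_missingness_indicators(make_missing_cohort(0.10))
  expect_false("x_present" %in% names(low$baseline))
  full <- make_missing_cohort(0)
  expect_identical(add_missingness_indicators(full)$baseline, full$baseline)
})

test_that("median imputation fills exactly the missing cells", {
  f <- toy_feature("x")
  base <- data.frame(id = c("a", "b", "c", "d"), x = c(1, 2, 4, NA),
                     stringsAsFactors = FALSE)
  co <- toy_cohort(base, toy_schema(f))
  res <- median_impute(co)
  expect_equal(res$cohort$baseline$x, c(1, 2, 4, 2))
  expect_equal(res$report$imputation_values$x, 2)

  clean <- toy_cohort(data.frame(id = "a", x = 1), toy_schema(f))
  expect_identical(median_impute(clean)$cohort$baseline, clean$baseline)

  allna <- toy_cohort(data.frame(id = c("a", "b"), x = c(NA_real_, NA_real_)),
                      toy_schema(f))
  expect_error(median_impute(allna), "x")
})

test_that("categorical encoding follows the documented code tables", {
  f <- rbind(toy_feature("sex", kind = "binary", group = "demographic"),
             toy_feature("cancer_type", kind = "categorical",
                         group = "demographic"),
             toy_feature("sepsis", kind = "binary", group = "demographic"))
  base <- data.frame(id = c("a", "b"), sex = c("Male", "Female"),
                     cancer_type = c("ALL", "CML"), sepsis = c("No", "Yes"),
                     stringsAsFactors = FALSE)
  co <- toy_cohort(base, toy_schema(f))
  enc <- encode_features(co)
  expect_equal(enc$baseline$sex, c(1, 2))
  expect_equal(enc$baseline$cancer_type, c(1, 4))
  expect_equal(enc$baseline$sepsis, c(0, 1))
  # idempotent on already-encoded data
  expect_identical(encode_features(enc)$baseline, enc$baseline)

  bad <- co
  bad$baseline$cancer_type[1] <- "unknown type"
  expect_error(encode_features(bad), "unknown category")
})

test_that("troponin T is binarized at the assay cutoff", {
  f <- toy_feature("troponin_t", time_varying = TRUE)
  panel <- data.frame(id = rep("a", 3), day = 0:2,
                      troponin_t = c(0.005, 0.014, 0.5))
  co <- toy_cohort(data.frame(id = "a"), toy_schema(f), panel = panel)
  enc <- encode_features(co)
  expect_equal(enc$panel$troponin_t, c(0, 0, 1))  # strict > cutoff
})

test_that("first-timepoint anchoring left-aligns each series", {
  f <- toy_feature("heart_rate", time_varying = TRUE)
  panel <- data.frame(id = rep(c("a", "b"), each = 4),
                      day = rep(0:3, 2),
                      heart_rate = c(NA, NA, 80, 82, 70, 71, 72, 73))
  co <- toy_cohort(data.frame(id = c("a", "b")), toy_schema(f), panel = panel)
  out <- anchor_first_timepoint(co, "heart_rate")
  expect_equal(out$panel$heart_rate[out$panel$id == "a"], c(80, 82, NA, NA))
  expect_equal(out$panel$heart_rate[out$panel$id == "b"], c(70, 71, 72, 73))

  allna <- co
  allna$panel$heart_rate[allna$panel$id == "a"] <- NA
  expect_error(anchor_first_timepoint(allna, "heart_rate"),
               "entirely missing")
})

test_that("z-score normalization standardizes and reuses training statistics", {
  f <- rbind(toy_feature("x"), toy_feature("const"))
  base <- data.frame(id = sprintf("p%d", 1:50), x = rnorm(50, 5, 2),
                     const = rep(3, 50), stringsAsFactors = FALSE)
  co <- toy_cohort(base, toy_schema(f))
  expect_warning(res <- normalize_continuous(co), "zero-variance")
  expect_lt(abs(mean(res$cohort$baseline$x)), 1e-9)
  expect_lt(abs(sd(res$cohort$baseline$x) - 1), 1e-9)
  expect_true(all(res$cohort$baseline$const == 0))

  test_base <- data.frame(id = sprintf("q%d", 1:50), x = rnorm(50, 9, 2),
                          const = rep(3, 50), stringsAsFactors = FALSE)
  test_co <- toy_cohort(test_base, toy_schema(f))
  applied <- normalize_continuous(test_co,
                                  stats = res$report$normalization_stats)
  expect_gt(abs(mean(applied$cohort$baseline$x)), 0.5)  # train stats, not own
})

test_that("Pearson matrices have unit diagonal, symmetry and exact toy values", {
  f <- rbind(toy_feature("u", group = "lab1"), toy_feature("v", group = "lab1"),
             toy_feature("w", group = "lab1"))
  base <- data.frame(id = c("a", "b", "c"), u = c(1, 2, 3), v = c(6, 4, 2),
                     w = c(1, 2, 3), stringsAsFactors = FALSE)
  co <- toy_cohort(base, toy_schema(f))
  m <- correlation_matrix(co, "lab1")
  expect_equal(unname(diag(unclass(m))), rep(1, 3))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(m["u", "v"], -1)   # hand-computable anti-correlation
  expect_equal(m["u", "w"], 1)    # duplicated feature
  expect_true(all(eigen(unclass(m), symmetric = TRUE,
                        only.values = TRUE)$values > -1e-10))

  expect_error(correlation_matrix(toy_cohort(base["id"], toy_schema(f[0, ])),
                                  "lab1"), "fewer than 2")
  bad <- co; bad$baseline$u <- 1
  expect_error(correlation_matrix(bad, "lab1"), "zero-variance")
})

test_that("full pipeline is idempotent and never alters observed cells", {
  co <- labeled_cohort(n = 40, horizon = 5, seed = 8)
  co <- inject_missingness(co, seed = 9)
  observed <- !is.na(co$panel$ferritin)
  before <- co$panel$ferritin[observed]

  p1 <- preprocess_cohort(co)
  st <- p1$report$normalization_stats$ferritin
  expect_equal((p1$cohort$panel$ferritin[observed] * st[["scale"]] +
                  st[["center"]]), before)

  p2 <- preprocess_cohort(p1$cohort)
  expect_equal(p2$cohort$panel, p1$cohort$panel, tolerance = 1e-8)
  expect_equal(p2$cohort$baseline, p1$cohort$baseline, tolerance = 1e-8)
  expect_length(p2$report$dropped_features, 0)

  # order contract artefacts: dropped features gone, indicators present
  expect_false(any(p1$report$dropped_features %in%
                     names(p1$cohort$panel)))
  expect_true(all(p1$report$indicator_features %in%
                    c(names(p1$cohort$panel), names(p1$cohort$baseline))))
  expect_false(anyNA(p1$cohort$panel$ferritin))
})
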