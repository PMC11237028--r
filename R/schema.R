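#' Default synthetic cohort schema
#'
#' Builds the generative schema for the synthetic blood-cancer cohort: 61
#' features of demographic, clinical and laboratory data.  Continuous features
#' carry the published cohort mean/SD and a truncation range; demographic
#' (binary/categorical) features carry per-category counts for a 98-patient
#' cohort so that quota sampling reproduces them exactly.  Eight features
#' (BMI, chemotherapy intervals, chloride, anion gap, total iron, iron-binding
#' capacity, lactate, transferrin) are generated with placeholder
#' distributions and a missingness rate above 90%, emulating variables that
#' the preprocessing pipeline excludes.
#'
#' Truncation bounds are mean +/- 4 SD, further clipped to a physiologic hard
#' limit only when that limit lies at least 3 generator SDs from the mean;
#' closer limits would visibly bias the truncated-Gaussian moments away from
#' the published values (see the methods vignette for the consequences for
#' right-skewed analytes).
#'
#' @return An object of class `cohort_schema`: a list with elements
#'   `features` (data frame of per-feature generative metadata: `name`,
#'   `group` in demographic/clinical/lab1/lab2/lab3, `kind`, `mean`, `sd`,
#'   `unit`, `missing_rate`, `lo`, `hi`, `time_varying`), `category_counts`
#'   (named list mapping categorical feature names to category count
#'   vectors), `n_default` (98) and `horizon_default` (7 days).
#' @examples
#' sch <- build_default_schema()
#' nrow(sch$features)                 # 61
#' subset(sch$features, name == "hgb")
#' @export
build_default_schema <- function() {
  cont <- function(name, group, mean, sd, unit, missing_rate = 0,
                   nonneg = TRUE, hard_lo = NA, hard_hi = NA,
                   time_varying = TRUE) {
    if (nonneg && is.na(hard_lo)) hard_lo <- 0
    lo <- mean - 4 * sd
    hi <- mean + 4 * sd
    # hard limits only when >= 3 sd away from the mean
    if (!is.na(hard_lo) && (mean - hard_lo) / sd >= 3) lo <- max(lo, hard_lo)
    if (!is.na(hard_hi) && (hard_hi - mean) / sd >= 3) hi <- min(hi, hard_hi)
    data.frame(name = name, group = group, kind = "continuous",
               mean = mean, sd = sd, unit = unit,
               missing_rate = missing_rate, lo = lo, hi = hi,
               time_varying = time_varying, stringsAsFactors = FALSE)
  }
  cat_ <- function(name, group, kind, unit = "") {
    data.frame(name = name, group = group, kind = kind,
               mean = NA_real_, sd = NA_real_, unit = unit,
               missing_rate = 0, lo = NA_real_, hi = NA_real_,
               time_varying = FALSE, stringsAsFactors = FALSE)
  }

  counts <- list(
    sex                    = c(Male = 55L, Female = 43L),
    age_band               = c(`18-32` = 12L, `32-46` = 23L, `46-60` = 23L,
                               `60-74` = 24L, `74-88` = 14L, `88-90` = 2L),
    cancer_type            = c(ALL = 22L, AML = 27L, CLL = 33L, CML = 16L),
    diabetes               = c(No = 71L, Yes = 27L),
    heart_disease          = c(No = 74L, Yes = 24L),
    respiratory_disease    = c(No = 84L, Yes = 14L),
    chronic_kidney_disease = c(No = 86L, Yes = 12L),
    smoking                = c(No = 65L, Yes = 33L),
    alcohol                = c(No = 82L, Yes = 16L),
    chemotherapy           = c(No = 32L, Yes = 66L),
    sepsis                 = c(No = 88L, Yes = 10L),
    active_infection       = c(No = 75L, Yes = 23L),
    fever                  = c(No = 81L, Yes = 17L),
    antibiotic_injection   = c(No = 34L, Yes = 64L),
    transfusion_history    = c(No = 43L, Yes = 55L),
    active_bleeding        = c(No = 95L, Yes = 3L)
  )

  demo <- do.call(rbind, lapply(names(counts), function(nm) {
    kind <- if (length(counts[[nm]]) == 2L) "binary" else "categorical"
    cat_(nm, "demographic", kind)
  }))

  clinical <- rbind(
    cont("sbp",        "clinical", 124.64, 21.64, "mmHg"),
    cont("dbp",        "clinical",  75.74, 11.76, "mmHg"),
    cont("heart_rate", "clinical",  77.13, 14.46, "bpm"),
    cont("lvef",       "clinical",  50.82,  5.26, "%", missing_rate = 0.55,
         hard_hi = 100)
  )

  lab1 <- rbind(
    cont("base_excess", "lab1",  2.26,  4.69, "mmol/L", missing_rate = 0.05,
         nonneg = FALSE),
    cont("tco2",        "lab1", 39.95,  6.92, "mmol/L", missing_rate = 0.05),
    cont("ph",          "lab1",  7.35,  0.06, "", missing_rate = 0.05,
         hard_lo = 6.8, hard_hi = 7.8),
    cont("pao2",        "lab1", 34.54,  7.25, "mmHg", missing_rate = 0.05),
    cont("spo2",        "lab1", 93.72,  3.14, "%", missing_rate = 0.05,
         hard_hi = 100),
    cont("hgb",         "lab1",  8.93,  2.50, "g/dL"),
    cont("hct",         "lab1", 28.93,  7.58, "%"),
    cont("mch",         "lab1", 29.82,  2.87, "pg"),
    cont("mchc",        "lab1", 33.37,  2.749, "g/dL"),
    cont("mcv",         "lab1", 86.41,  7.159, "fL"),
    cont("rdw",         "lab1", 17.51,  1.61, "%"),
    cont("platelet",    "lab1", 108.88, 67.66, "10^3/uL")
  )

  lab2 <- rbind(
    cont("na",         "lab2", 138.62,  5.82, "mmol/L"),
    cont("k",          "lab2",   4.072, 0.681, "mmol/L"),
    cont("mg",         "lab2",   1.94,  0.26, "mg/dL"),
    cont("phosphate",  "lab2",   4.25,  0.75, "mg/dL"),
    cont("calcium",    "lab2",   8.45,  0.82, "mg/dL"),
    cont("bicarbonate","lab2",  22.23,  4.19, "mmol/L"),
    cont("ferritin",   "lab2", 124.42, 19.08, "ng/mL", missing_rate = 0.60),
    cont("pt",         "lab2",  14.13,  2.06, "s"),
    cont("ptt",        "lab2",  35.03,  9.02, "s"),
    cont("bun",        "lab2",  30.97, 16.09, "mg/dL"),
    cont("creatinine", "lab2",   1.196, 0.58, "mg/dL")
  )

  lab3 <- rbind(
    cont("alt",              "lab3",  60.19,  22.22, "U/L"),
    cont("ast",              "lab3",  59.58,  27.29, "U/L"),
    cont("alp",              "lab3", 466.31, 151.93, "U/L"),
    cont("albumin",          "lab3",   3.262,  0.48, "g/dL"),
    cont("bilirubin_total",  "lab3",   1.134,  0.562, "mg/dL"),
    cont("bilirubin_direct", "lab3",   0.59,   0.29, "mg/dL"),
    cont("ck",               "lab3", 134.23, 132.098, "U/L"),
    cont("ck_mb",            "lab3",  26.63,  17.67, "U/L"),
    cont("ldh",              "lab3", 828.19, 510.078, "U/L"),
    cont("troponin_t",       "lab3",   0.031,  0.171, "ng/mL",
         missing_rate = 0.55)
  )

  # placeholder distributions for the high-missingness variables the
  # preprocessing pipeline excludes (>90% missing)
  excluded <- rbind(
    cont("bmi",                   "clinical", 24.0,  4.0, "kg/m^2",
         missing_rate = 0.95, time_varying = FALSE),
    cont("chemo_interval",        "clinical", 21.0,  7.0, "days",
         missing_rate = 0.95, time_varying = FALSE),
    cont("chloride",              "lab2", 102.0,  5.0, "mmol/L",
         missing_rate = 0.95),
    cont("anion_gap",             "lab2",  12.0,  4.0, "mmol/L",
         missing_rate = 0.95),
    cont("total_iron",            "lab2",  60.0, 30.0, "ug/dL",
         missing_rate = 0.95),
    cont("iron_binding_capacity", "lab2", 300.0, 60.0, "ug/dL",
         missing_rate = 0.95),
    cont("lactate",               "lab1",   2.0,  1.2, "mmol/L",
         missing_rate = 0.95),
    cont("transferrin",           "lab2", 200.0, 50.0, "mg/dL",
         missing_rate = 0.95)
  )

  features <- rbind(demo, clinical, lab1, lab2, lab3, excluded)
  rownames(features) <- NULL
  stopifnot(!anyDuplicated(features$name))

  structure(
    list(features = features, category_counts = counts,
         n_default = 98L, horizon_default = 7L),
    class = "cohort_schema"
  )
}

#' @export
print.cohort_schema <- function(x, ...) {
  f <- x$features
  cat("Synthetic cohort schema:", nrow(f), "features",
      sprintf("(default n = %d, horizon = %d days)\n",
              x$n_default, x$horizon_default))
  tab <- table(f$group, f$kind)
  print(tab)
  hm <- f$name[f$missing_rate > 0.9]
  if (length(hm)) {
    cat("High-missingness (>90%) features:", paste(hm, collapse = ", "), "\n")
  }
  invisible(x)
}

# internal accessors
schema_feature <- function(schema, name) {
  f <- schema$features
  i <- match(name, f$name)
  if (is.na(i)) stop("unknown feature: ", name)
  f[i, , drop = FALSE]
}

schema_continuous <- function(schema) {
  schema$features$name[schema$features$kind == "continuous"]
}

schema_time_varying <- function(schema) {
  schema$features$name[schema$features$time_varying]
}
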