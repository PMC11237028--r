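#' Sample a synthetic patient cohort
#'
#' Draws baseline (admission) values for every schema feature.  Continuous
#' features come from truncated Gaussians with the schema mean/SD and
#' plausible range; haematocrit is coupled to haemoglobin through a
#' marginal-preserving linear relation (correlation 0.9) since the two are
#' physiologically near-proportional.  Demographic features are either
#' quota-sampled — category counts reproduced exactly, rows permuted — or
#' drawn proportionally to the category counts.
#'
#' @param schema A `cohort_schema`, e.g. [build_default_schema()].
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; identical `(schema, n, seed)` give bit-identical
#'   cohorts.
#' @param quota `"auto"` (quota sampling iff `n` equals the schema's category
#'   count total), `TRUE` or `FALSE`.
#' @param hct_rho Correlation between haemoglobin and haematocrit draws.
#' @return An object of class `nfabt_cohort` with elements `schema`,
#'   `baseline` (one row per patient; categorical features as labels),
#'   `panel` (daily series, `NULL` until [sample_trajectories()]), `labels`
#'   (`NULL` until [assign_daily_labels()]) and `seed`.
#' @examples
#' co <- sample_cohort(build_default_schema(), n = 98, seed = 1)
#' table(co$baseline$sex)   # 55 male / 43 female
#' @export
sample_cohort <- function(schema, n, seed = 1L, quota = "auto", hct_rho = 0.9) {
  stopifnot(inherits(schema, "cohort_schema"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("invalid n")
  n <- as.integer(n)
  f <- schema$features
  if (nrow(f) == 0L) stop("schema has an empty feature list")
  quota_total <- sum(schema$category_counts[[1L]])
  if (identical(quota, "auto")) quota <- (n == quota_total)
  if (quota && n != quota_total) {
    stop("quota sampling requires n = ", quota_total)
  }

  baseline <- with_seed(seed, {
    out <- data.frame(id = sprintf("P%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(f))) {
      fi <- f[i, ]
      if (fi$kind == "continuous") {
        out[[fi$name]] <- rtruncnorm(n, fi$mean, fi$sd, fi$lo, fi$hi)
      } else {
        cc <- schema$category_counts[[fi$name]]
        out[[fi$name]] <- if (quota) {
          sample(rep(names(cc), cc))
        } else {
          sample(names(cc), n, replace = TRUE, prob = cc / sum(cc))
        }
      }
    }
    # couple hct to hgb, preserving hct's marginal mean/sd
    if (all(c("hgb", "hct") %in% names(out))) {
      sh <- schema_feature(schema, "hgb")
      sc <- schema_feature(schema, "hct")
      eps <- stats::rnorm(n)
      hct <- sc$mean + hct_rho * sc$sd / sh$sd * (out$hgb - sh$mean) +
        sqrt(1 - hct_rho^2) * sc$sd * eps
      out$hct <- pmin(pmax(hct, sc$lo), sc$hi)
    }
    out
  })

  structure(list(schema = schema, baseline = baseline,
                 panel = NULL, labels = NULL, seed = as.integer(seed)),
            class = "nfabt_cohort")
}

#' Simulate daily trajectories
#'
#' Extends a baseline cohort with daily series for every time-varying
#' feature.  Each series is a stationary AR(1) centred on the patient's
#' baseline value with the feature's schema SD as marginal SD; day 0 equals
#' the baseline draw and values are clamped to the feature's plausible range.
#'
#' @param cohort An `nfabt_cohort` from [sample_cohort()].
#' @param horizon Days per patient, `T >= 1` (default: schema default, 7).
#' @param autocorr Lag-1 autocorrelation `phi` in `[0, 1)`; 0 gives i.i.d.
#'   days.
#' @param seed Integer seed.
#' @return The cohort with a `panel` data frame (`id`, `day` in `0..T-1`, one
#'   column per time-varying feature).
#' @export
sample_trajectories <- function(cohort, horizon = NULL, autocorr = 0.7,
                                seed = 1L) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  horizon <- as.integer(horizon %||% cohort$schema$horizon_default)
  if (horizon < 1L) stop("horizon must be >= 1")
  if (!is.numeric(autocorr) || autocorr < 0 || autocorr >= 1) {
    stop("autocorr must lie in [0, 1)")
  }
  f <- cohort$schema$features
  tv <- f[f$time_varying & f$kind == "continuous", , drop = FALSE]
  n <- nrow(cohort$baseline)

  panel <- data.frame(
    id = rep(cohort$baseline$id, each = horizon),
    day = rep(seq_len(horizon) - 1L, times = n),
    stringsAsFactors = FALSE
  )
  phi <- autocorr
  with_seed(seed, {
    for (i in seq_len(nrow(tv))) {
      fi <- tv[i, ]
      b <- cohort$baseline[[fi$name]]            # per-patient AR(1) mean
      x <- matrix(NA_real_, nrow = n, ncol = horizon)
      x[, 1L] <- b
      if (horizon > 1L) {
        innov_sd <- fi$sd * sqrt(1 - phi^2)
        for (t in 2:horizon) {
          xt <- b + phi * (x[, t - 1L] - b) + stats::rnorm(n, 0, innov_sd)
          x[, t] <- pmin(pmax(xt, fi$lo), fi$hi)
        }
      }
      panel[[fi$name]] <- as.vector(t(x))
    }
  })
  cohort$panel <- panel
  cohort
}

#' Default parameters of the ground-truth daily transfusion-risk model
#'
#' The synthetic daily packed-red-blood-cell label follows a logistic model
#' in the distinguishable variables: standardized haemoglobin and arterial
#' oxygen pressure (negative weights), acidosis distance
#' `max(0, 7.40 - pH) / 0.06` (positive weight), and standardized systolic
#' blood pressure and platelet count (negative weights).  The intercept is
#' calibrated so the default schema yields about 7% daily prevalence.
#'
#' @param intercept Logistic intercept (calibrated default).
#' @param threshold Cut for the deterministic threshold mode, on the linear
#'   score scale.
#' @return A list with `beta`, `intercept`, `threshold`.
#' @export
default_risk_params <- function(intercept = -4.84, threshold = 0) {
  list(beta = c(hgb = -1.2, pao2 = -0.6, acid = 0.8,
                sbp = -0.3, platelet = -0.3),
       intercept = intercept, threshold = threshold)
}

# linear risk score on the day-level panel rows (schema-standardized inputs)
risk_score <- function(cohort, panel = cohort$panel,
                       risk_params = default_risk_params()) {
  need <- c("hgb", "pao2", "ph", "sbp", "platelet")
  miss <- setdiff(need, names(panel))
  if (length(miss)) stop("missing required features: ",
                         paste(miss, collapse = ", "))
  z <- function(nm) {
    s <- schema_feature(cohort$schema, nm)
    (panel[[nm]] - s$mean) / s$sd
  }
  b <- risk_params$beta
  b[["hgb"]] * z("hgb") + b[["pao2"]] * z("pao2") +
    b[["acid"]] * pmax(0, (7.40 - panel$ph) / 0.06) +
    b[["sbp"]] * z("sbp") + b[["platelet"]] * z("platelet")
}

#' Assign daily transfusion labels
#'
#' Adds a daily packed-red-blood-cell requirement label to a cohort with
#' trajectories.  Three ground-truth modes:
#' \describe{
#'   \item{`"logistic"`}{label ~ Bernoulli(plogis(intercept + score)); the
#'     default parameters give about 7% daily prevalence.}
#'   \item{`"threshold"`}{deterministic: label = 1 iff score > threshold;
#'     used for exactly reproducible tests.}
#'   \item{`"trend"`}{label(t) = 1 iff haemoglobin fell since the previous
#'     day (day 0 labelled 0); a purely sequential signal for benchmarking
#'     recurrent against static classifiers.}
#' }
#' The score is monotone: lowering haemoglobin (all else fixed) never lowers
#' the risk.
#'
#' @param cohort Cohort with a `panel` (see [sample_trajectories()]).
#' @param risk_params See [default_risk_params()].
#' @param seed Integer seed (used by the logistic mode only).
#' @param mode One of `"logistic"`, `"threshold"`, `"trend"`.
#' @return The cohort with a `labels` data frame (`id`, `day`, `prbc`).
#' @export
assign_daily_labels <- function(cohort, risk_params = default_risk_params(),
                                seed = 1L,
                                mode = c("logistic", "threshold", "trend")) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  mode <- match.arg(mode)
  if (is.null(cohort$panel)) stop("trajectories not present; run sample_trajectories() first")
  panel <- cohort$panel
  lab <- switch(mode,
    logistic = {
      s <- risk_score(cohort, panel, risk_params)
      p <- stats::plogis(risk_params$intercept + s)
      with_seed(seed, as.integer(stats::runif(length(p)) < p))
    },
    threshold = {
      s <- risk_score(cohort, panel, risk_params)
      as.integer(s > risk_params$threshold)
    },
    trend = {
      if (!"hgb" %in% names(panel)) stop("missing required features: hgb")
      unlist(lapply(split(panel$hgb, panel$id)[unique(panel$id)], function(h) {
        c(0L, as.integer(diff(h) < 0))
      }), use.names = FALSE)
    })
  cohort$labels <- data.frame(id = panel$id, day = panel$day, prbc = lab,
                              stringsAsFactors = FALSE)
  cohort
}

#' Inject missingness
#'
#' Independently masks each observable cell with its feature's schema
#' `missing_rate`.  Masked cells become `NA` (R's explicit missing marker) in
#' the panel (time-varying features) or the baseline table (static features);
#' labels are never masked.
#'
#' @param cohort Cohort (with or without a panel).
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, seed = 1L) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  f <- cohort$schema$features
  with_seed(seed, {
    for (i in seq_len(nrow(f))) {
      fi <- f[i, ]
      if (fi$missing_rate <= 0) next
      if (fi$time_varying && !is.null(cohort$panel)) {
        m <- stats::runif(nrow(cohort$panel)) < fi$missing_rate
        cohort$panel[[fi$name]][m] <- NA
      } else {
        m <- stats::runif(nrow(cohort$baseline)) < fi$missing_rate
        cohort$baseline[[fi$name]][m] <- NA
      }
    }
  })
  cohort
}

#' @export
print.nfabt_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$baseline), "patients,",
      nrow(x$schema$features), "features\n")
  if (!is.null(x$panel)) {
    cat("  daily panel:", max(x$panel$day) + 1L, "days,",
        ncol(x$panel) - 2L, "time-varying features\n")
  }
  if (!is.null(x$labels)) {
    cat(sprintf("  daily PRBC labels: prevalence %.3f\n",
                mean(x$labels$prbc)))
  }
  invisible(x)
}
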