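# Fixture builders shared across the suite; everything is generated in code.

# A hand-built miniature schema for preprocessing unit tests.
toy_schema <- function(features, counts = list(), n_default = 4L,
                       horizon_default = 3L) {
  structure(list(features = features, category_counts = counts,
                 n_default = n_default, horizon_default = horizon_default),
            class = "cohort_schema")
}

toy_feature <- function(name, kind = "continuous", group = "lab1",
                        mean = 0, sd = 1, missing_rate = 0,
                        lo = -10, hi = 10, time_varying = FALSE) {
  data.frame(name = name, group = group, kind = kind, mean = mean, sd = sd,
             unit = "", missing_rate = missing_rate, lo = lo, hi = hi,
             time_varying = time_varying, stringsAsFactors = FALSE)
}

toy_cohort <- function(baseline, schema, panel = NULL, labels = NULL,
                       seed = 1L) {
  structure(list(schema = schema, baseline = baseline, panel = panel,
                 labels = labels, seed = seed),
            class = "nfabt_cohort")
}

# A small fully-simulated labelled cohort for pipeline-level tests.
labeled_cohort <- function(n = 30, horizon = 5, seed = 1,
                           mode = "logistic") {
  co <- sample_cohort(build_default_schema(), n = n, seed = seed)
  co <- sample_trajectories(co, horizon = horizon, seed = seed + 1)
  assign_daily_labels(co, seed = seed + 2, mode = mode)
}

# The canonical two-input rule base: low haemoglobin cells map to the Low
# blood state; used wherever a complete, clinically-shaped rule base is
# needed.
canonical_fit <- function(inputs = c("hgb", "pao2"),
                          parts = default_partitions()) {
  grid <- expand.grid(lapply(parts$inputs[inputs], `[[`, "centers"))
  names(grid) <- inputs
  grid$state <- if ("hgb" %in% inputs) {
    ifelse(grid$hgb <= 10.25, 0.25, 0.75)
  } else {
    ifelse(grid[[1]] <= parts$inputs[[inputs[1]]]$centers[2], 0.25, 0.75)
  }
  fml <- stats::as.formula(paste("state ~", paste(inputs, collapse = "+")))
  fbf(fml, grid, partitions = parts)
}

# Independent inference oracle: explicit loop over every rule, memberships
# evaluated one at a time, weighted-centroid defuzzification.
oracle_infer <- function(fit, z, normalize = TRUE) {
  sys <- fit$system
  rules <- fit$rules
  acols <- paste0("a_", names(sys$inputs))
  num <- 0; den <- 0
  for (i in seq_len(nrow(rules))) {
    d <- 1
    for (j in seq_along(sys$inputs)) {
      d <- d * membership(sys$inputs[[j]], rules[[acols[j]]][i], z[[j]])
    }
    th <- sys$output$centers[rules$consequent[i]]
    num <- num + d * th
    den <- den + d
  }
  if (normalize) num / den else num
}
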