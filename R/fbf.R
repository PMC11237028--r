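#' Fuzzy basis-function system configuration
#'
#' Bundles the input partitions, the output partition and the inference mode.
#' The system output for an input vector `z` is the fuzzy-basis-function
#' expansion `f(z) = sum_i d_i(z) theta_i`, where
#' `d_i(z) = prod_j mu_{A_j^i}(z_j)` is the basis function of rule `i` and
#' `theta_i` the center of its consequent membership function; with
#' `normalize = TRUE` (default) the expansion is divided by `sum_i d_i(z)`,
#' the weighted-centroid form that stays well defined for incomplete learned
#' rule bases.
#'
#' @param inputs Named list of input [fuzzy_partition()]s (order defines the
#'   input vector layout).
#' @param output Output [fuzzy_partition()]; its centers are the `theta_i`.
#' @param normalize Logical; divide by the basis sum (default `TRUE`).
#' @param rules Optional rule base (see [learn_rules()]).
#' @return An object of class `fbf_system`.
#' @export
fbf_system <- function(inputs, output, normalize = TRUE, rules = NULL) {
  if (length(inputs) < 1L) stop("no active inputs")
  stopifnot(all(vapply(inputs, inherits, TRUE, "fuzzy_partition")),
            inherits(output, "fuzzy_partition"))
  if (is.null(names(inputs))) {
    names(inputs) <- vapply(inputs, `[[`, "", "variable")
  }
  structure(list(inputs = inputs, output = output,
                 normalize = isTRUE(normalize), rules = rules),
            class = "fbf_system")
}

as_fbf_system <- function(x) {
  if (inherits(x, "fbf")) {
    s <- x$system
    s$rules <- x$rules
    s
  } else if (inherits(x, "fbf_system")) x
  else stop("expected an 'fbf' fit or an 'fbf_system'")
}

rule_antecedent_cols <- function(system) paste0("a_", names(system$inputs))

#' Enumerate the candidate rule space
#'
#' All combinations of one antecedent membership function per active input
#' with one consequent membership function:
#' `count = prod_j K_j * K_out`.  With the default two four-MF inputs and the
#' two-MF output this gives 4^2 x 2 = 32 candidate rules.
#'
#' @param system An `fbf_system` (or fitted [fbf()] model).
#' @return A list with `rules` (data frame, one antecedent index column per
#'   input plus `consequent`) and `count`.
#' @examples
#' p <- default_partitions()
#' sys <- fbf_system(p$inputs[c("hgb", "pao2")], p$output)
#' enumerate_rule_space(sys)$count   # 32
#' @export
enumerate_rule_space <- function(system) {
  system <- as_fbf_system(system)
  sizes <- c(lapply(system$inputs, function(p) seq_along(p$mfs)),
             list(consequent = seq_along(system$output$mfs)))
  names(sizes) <- c(rule_antecedent_cols(system), "consequent")
  grid <- expand.grid(sizes, KEEP.OUT.ATTRS = FALSE)
  list(rules = grid, count = nrow(grid))
}

#' Fuzzy basis function of one antecedent cell
#'
#' Computes `d_i(z) = prod_j mu_{A_j^i}(z_j)`, the product of the antecedent
#' membership degrees.
#'
#' @param system An `fbf_system`.
#' @param cell Integer vector of membership-function indices, one per active
#'   input.
#' @param z Numeric input vector, one value per active input.
#' @return The basis value in `[0, 1]`.
#' @export
fuzzy_basis <- function(system, cell, z) {
  system <- as_fbf_system(system)
  m <- length(system$inputs)
  if (length(cell) != m || length(z) != m) {
    stop("dimension mismatch: system has ", m, " active inputs")
  }
  prod(vapply(seq_len(m), function(j) {
    membership(system$inputs[[j]], cell[j], z[j])
  }, numeric(1)))
}

# membership matrices for an input matrix Z (n x m), one per input
input_membership <- function(system, Z) {
  lapply(seq_along(system$inputs), function(j) {
    membership_matrix(system$inputs[[j]], Z[, j])
  })
}

# coerce newdata to the system's input matrix (columns in input order)
input_matrix <- function(system, z) {
  nms <- names(system$inputs)
  if (is.data.frame(z)) {
    miss <- setdiff(nms, names(z))
    if (length(miss)) stop("missing input column(s): ",
                           paste(miss, collapse = ", "))
    Z <- as.matrix(z[, nms, drop = FALSE])
  } else if (is.matrix(z)) {
    Z <- if (!is.null(colnames(z)) && all(nms %in% colnames(z))) {
      z[, nms, drop = FALSE]
    } else z
  } else {
    Z <- matrix(z, nrow = 1L)
    if (!is.null(names(z)) && all(nms %in% names(z))) {
      Z <- matrix(z[nms], nrow = 1L)
    }
  }
  if (ncol(Z) != length(nms)) stop("dimension mismatch: expected ",
                                   length(nms), " inputs")
  Z
}

#' Learn a rule base from data (Wang-Mendel table lookup)
#'
#' Each training pair `(z, k)` is assigned to its maximum-membership
#' antecedent cell and consequent membership function; the rule degree is the
#' product of those memberships.  Per antecedent cell only the
#' highest-degree rule survives; degree ties break toward the lower
#' consequent index, then toward the earlier sample, deterministically.
#' Inputs outside the partition's covered range are clipped with a warning.
#'
#' @param system An `fbf_system`.
#' @param z Input data (data frame or matrix, one column per active input).
#' @param k Output values, within the output universe.
#' @return The rule base: a data frame with one antecedent index column per
#'   input, `consequent`, `degree`, and `source = "learned"`.
#' @export
learn_rules <- function(system, z, k) {
  system <- as_fbf_system(system)
  Z <- input_matrix(system, z)
  n <- nrow(Z)
  if (n == 0L) stop("empty training data")
  if (length(k) != n) stop("z and k lengths differ")
  uo <- range(system$output$universe, system$output$centers)
  if (any(k < uo[1] | k > uo[2])) stop("output values outside output universe")

  clipped <- FALSE
  for (j in seq_along(system$inputs)) {
    p <- system$inputs[[j]]
    lo <- min(p$universe[1], p$centers[1])
    hi <- max(p$universe[2], p$centers[length(p$centers)])
    out <- Z[, j] < lo | Z[, j] > hi
    if (any(out)) { clipped <- TRUE; Z[, j] <- pmin(pmax(Z[, j], lo), hi) }
  }
  if (clipped) warning("inputs outside the universe of discourse were clipped")

  M <- input_membership(system, Z)
  idx <- vapply(M, function(m) max.col(m, ties.method = "first"), integer(n))
  idx <- matrix(idx, nrow = n)
  deg <- vapply(seq_along(M), function(j) M[[j]][cbind(seq_len(n), idx[, j])],
                numeric(n))
  deg <- matrix(deg, nrow = n)
  Mo <- membership_matrix(system$output, k)
  oidx <- max.col(Mo, ties.method = "first")
  odeg <- Mo[cbind(seq_len(n), oidx)]
  degree <- apply(deg, 1, prod) * odeg

  cand <- data.frame(idx, consequent = oidx, degree = degree)
  names(cand)[seq_along(system$inputs)] <- rule_antecedent_cols(system)
  cell_key <- apply(idx, 1, paste, collapse = ".")
  ord <- order(cell_key, -cand$degree, cand$consequent, seq_len(n))
  cand <- cand[ord, , drop = FALSE]
  keep <- !duplicated(cell_key[ord])
  rules <- cand[keep, , drop = FALSE]
  rownames(rules) <- NULL
  rules$source <- "learned"
  rules
}

#' Complete a learned rule base over all antecedent cells
#'
#' Wang-Mendel learning only covers cells seen in training.  This fills each
#' uncovered cell with the consequent of the nearest covered cell (Euclidean
#' distance in membership-function index space; ties break toward the lower
#' consequent index), so that normalized inference is defined on the whole
#' universe.
#'
#' @param system An `fbf_system`.
#' @param rules A rule base from [learn_rules()].
#' @return The completed rule base; filled rules carry `degree = 0` and
#'   `source = "completed"`.
#' @export
complete_rule_base <- function(system, rules) {
  system <- as_fbf_system(system)
  acols <- rule_antecedent_cols(system)
  all_cells <- expand.grid(lapply(system$inputs, function(p) {
    seq_along(p$mfs)
  }), KEEP.OUT.ATTRS = FALSE)
  names(all_cells) <- acols
  have <- apply(rules[, acols, drop = FALSE], 1, paste, collapse = ".")
  want <- apply(all_cells, 1, paste, collapse = ".")
  missing <- all_cells[!(want %in% have), , drop = FALSE]
  if (!nrow(missing)) return(rules)
  R <- as.matrix(rules[, acols, drop = FALSE])
  add <- lapply(seq_len(nrow(missing)), function(i) {
    cell <- as.numeric(missing[i, ])
    d2 <- colSums((t(R) - cell)^2)
    near <- which(d2 == min(d2))
    cons <- min(rules$consequent[near])
    cbind(missing[i, , drop = FALSE],
          data.frame(consequent = cons, degree = 0, source = "completed"))
  })
  out <- rbind(rules, do.call(rbind, add))
  rownames(out) <- NULL
  out
}

# vectorized FBF inference over rows of Z
fbf_eval <- function(system, Z, normalize = system$normalize,
                     uncovered = c("error", "na")) {
  uncovered <- match.arg(uncovered)
  rules <- system$rules
  if (is.null(rules) || !nrow(rules)) stop("rule base is empty")
  M <- input_membership(system, Z)
  acols <- rule_antecedent_cols(system)
  D <- matrix(1, nrow = nrow(Z), ncol = nrow(rules))
  for (j in seq_along(M)) D <- D * M[[j]][, rules[[acols[j]]], drop = FALSE]
  theta <- system$output$centers[rules$consequent]
  num <- as.vector(D %*% theta)
  den <- rowSums(D)
  if (normalize) {
    bad <- den <= 0
    if (any(bad)) {
      if (uncovered == "error") {
        stop("uncovered input: no rule has positive basis value")
      }
      num[bad] <- NA_real_; den[bad] <- 1
    }
    num / den
  } else num
}

#' FBF inference
#'
#' Evaluates the fuzzy basis-function expansion at input `z`.  In normalized
#' mode (default) `f(z) = sum_i d_i theta_i / sum_i d_i`, the singleton
#' fuzzifier / product inference / centroid defuzzifier form, bounded by the
#' extreme output centers; with `normalize = FALSE` the literal unnormalized
#' sum is returned (identical under a complete grid rule base, where the
#' basis functions form a partition of unity).
#'
#' @param system An `fbf_system` carrying rules, or a fitted [fbf()] model.
#' @param z Input vector, matrix or data frame (one row per observation).
#' @param normalize Override the system's normalization flag.
#' @param uncovered `"error"` (default) or `"na"` for inputs activating no
#'   rule.
#' @return Numeric vector `f(z)`.
#' @export
infer <- function(system, z, normalize = NULL, uncovered = "error") {
  system <- as_fbf_system(system)
  Z <- input_matrix(system, z)
  fbf_eval(system, Z, normalize %||% system$normalize, uncovered)
}

#' Swarm-distributed FBF inference
#'
#' Distributes the rules over `swarm_size` agents; each agent computes the
#' partial sums `sum d_i theta_i` and `sum d_i` over its own rules, and the
#' aggregation of the partial sums reproduces centralized [infer()] exactly
#' (the expansion is a plain sum, so any partition of the rules gives the
#' same aggregate).
#'
#' @param system An `fbf_system` carrying rules, or a fitted [fbf()] model.
#' @param swarm_size Number of agents (>= 1).
#' @param assignment Optional rule-to-agent map: an integer vector with one
#'   agent id per rule, or a list of rule-index vectors per agent covering
#'   every rule exactly once.  Default: round robin.
#' @param z A single input vector.
#' @param normalize Override the system's normalization flag.
#' @return A list with `value` (the aggregate `f(z)`) and `agents` (data
#'   frame of per-agent partial sums `num = sum d theta`, `den = sum d`,
#'   `n_rules`).
#' @export
swarm_infer <- function(system, swarm_size, assignment = NULL, z,
                        normalize = NULL) {
  system <- as_fbf_system(system)
  rules <- system$rules
  if (is.null(rules) || !nrow(rules)) stop("rule base is empty")
  R <- nrow(rules)
  swarm_size <- as.integer(swarm_size)
  if (swarm_size < 1L) stop("swarm_size must be >= 1")
  if (is.null(assignment)) {
    assignment <- rep_len(seq_len(swarm_size), R)
  } else if (is.list(assignment)) {
    v <- integer(R)
    got <- unlist(assignment, use.names = FALSE)
    if (anyDuplicated(got)) stop("doubly-assigned rule(s)")
    if (!setequal(got, seq_len(R))) stop("assignment does not cover every rule")
    for (a in seq_along(assignment)) v[assignment[[a]]] <- a
    assignment <- v
  }
  if (length(assignment) != R) stop("assignment must map every rule")
  if (any(assignment < 1L | assignment > swarm_size)) {
    stop("agent ids outside 1..swarm_size")
  }

  Z <- input_matrix(system, z)
  if (nrow(Z) != 1L) stop("swarm_infer expects a single input vector")
  M <- input_membership(system, Z)
  acols <- rule_antecedent_cols(system)
  d <- rep(1, R)
  for (j in seq_along(M)) d <- d * M[[j]][1L, rules[[acols[j]]]]
  theta <- system$output$centers[rules$consequent]

  agents <- data.frame(
    agent = seq_len(swarm_size),
    num = vapply(seq_len(swarm_size),
                 function(a) sum(d[assignment == a] * theta[assignment == a]),
                 numeric(1)),
    den = vapply(seq_len(swarm_size),
                 function(a) sum(d[assignment == a]), numeric(1)),
    n_rules = as.integer(tabulate(assignment, swarm_size))
  )
  normalize <- normalize %||% system$normalize
  value <- if (normalize) {
    if (sum(agents$den) <= 0) stop("uncovered input: no rule has positive basis value")
    sum(agents$num) / sum(agents$den)
  } else sum(agents$num)
  list(value = value, agents = agents)
}

#' Alarm decision from the blood-state value
#'
#' Maps the inferred blood state `f(z)` in `[0, 1]` to an alarm: state label
#' `Low` (alarm raised) iff the value is strictly below the threshold; the
#' boundary value itself maps to `Normal` with no alarm.  The message is a
#' structured record ready for gateway delivery.
#'
#' @param state_value Inferred state in `[0, 1]`.
#' @param threshold Decision threshold (default 0.5, the midpoint of the
#'   output centers).
#' @param inputs Optional named input snapshot included in the message.
#' @return An object of class `alarm_decision`: `state_value`, `state_label`,
#'   `alarm`, and `message` (list with `value`, `label`, `alarm`,
#'   `timestamp`, `inputs`).
#' @examples
#' alarm(0.25)   # Low -> alarm
#' alarm(0.75)   # Normal -> no alarm
#' @export
alarm <- function(state_value, threshold = 0.5, inputs = NULL) {
  if (!is.numeric(state_value) || length(state_value) != 1L ||
      is.na(state_value) || state_value < 0 || state_value > 1) {
    stop("state_value must be a single number in [0, 1]")
  }
  label <- if (state_value < threshold) "Low" else "Normal"
  is_alarm <- label == "Low"
  structure(list(
    state_value = state_value, state_label = label, alarm = is_alarm,
    message = list(value = state_value, label = label, alarm = is_alarm,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   inputs = as.list(inputs))
  ), class = "alarm_decision")
}

#' @export
print.alarm_decision <- function(x, ...) {
  cat(sprintf("Blood state %.3f -> %s%s\n", x$state_value, x$state_label,
              if (x$alarm) "  ** TRANSFUSION ALARM **" else ""))
  invisible(x)
}

#' Fit a fuzzy basis-function alarming model
#'
#' Learns a Wang-Mendel rule base over triangular membership partitions and
#' returns a fitted FBF model for the blood-transfusion state.  The
#' right-hand side of `formula` names the active inputs (each must have a
#' partition in `partitions$inputs`); the response is the observed blood
#' state in the output universe, conventionally 0.25 ("Low", transfusion
#' needed) and 0.75 ("Normal").
#'
#' @param formula e.g. `state ~ hgb + pao2`.
#' @param data Data frame holding the response and inputs.
#' @param partitions A list with `inputs` and `output` partitions, as from
#'   [default_partitions()].
#' @param normalize Use normalized (weighted-centroid) inference, the
#'   default.
#' @param complete Complete the learned rule base over all antecedent cells
#'   (see [complete_rule_base()]), guaranteeing coverage of the whole
#'   universe.
#' @return An object of class `fbf` with components `system`, `rules`,
#'   `fitted.values`, `residuals`, `nobs`, `call`; supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `plot()`, `fitted()`,
#'   `residuals()`.
#' @examples
#' p <- default_partitions()
#' d <- data.frame(hgb = c(8, 10.25, 14.1, 16.6), pao2 = rep(47.5, 4),
#'                 state = c(0.25, 0.25, 0.75, 0.75))
#' fit <- fbf(state ~ hgb + pao2, d)
#' predict(fit, data.frame(hgb = 9, pao2 = 47.5))
#' @export
fbf <- function(formula, data, partitions = default_partitions(),
                normalize = TRUE, complete = FALSE) {
  tt <- stats::terms(formula, data = data)
  input_names <- attr(tt, "term.labels")
  mf <- stats::model.frame(tt, data)
  k <- stats::model.response(mf)
  miss <- setdiff(input_names, names(partitions$inputs))
  if (length(miss)) stop("no partition defined for input(s): ",
                         paste(miss, collapse = ", "))
  system <- fbf_system(partitions$inputs[input_names], partitions$output,
                       normalize)
  rules <- learn_rules(system, mf[, input_names, drop = FALSE], k)
  if (complete) rules <- complete_rule_base(system, rules)
  system$rules <- rules
  fitted <- fbf_eval(system, input_matrix(system, mf[, input_names, drop = FALSE]),
                     uncovered = "na")
  structure(list(call = match.call(), formula = formula,
                 input_names = input_names, system = system, rules = rules,
                 fitted.values = fitted, residuals = k - fitted,
                 response = k, nobs = length(k)),
            class = "fbf")
}

#' @export
print.fbf <- function(x, ...) {
  cat("Fuzzy basis-function alarming model\n")
  cat("  inputs:", paste(x$input_names, collapse = ", "),
      sprintf(" (rule space %d, learned %d%s)\n",
              enumerate_rule_space(x$system)$count,
              sum(x$rules$source == "learned"),
              if (any(x$rules$source == "completed")) {
                sprintf(", completed %d", sum(x$rules$source == "completed"))
              } else ""))
  cat(sprintf("  inference: %s; training RMSE %.4f on %d observations\n",
              if (x$system$normalize) "normalized (weighted centroid)"
              else "unnormalized FBF sum",
              sqrt(mean(x$residuals^2, na.rm = TRUE)), x$nobs))
  invisible(x)
}

#' @export
coef.fbf <- function(object, ...) {
  stats::setNames(object$system$output$centers[object$rules$consequent],
                  apply(object$rules[, rule_antecedent_cols(object$system),
                                     drop = FALSE],
                        1, paste, collapse = "."))
}

#' @export
summary.fbf <- function(object, ...) {
  sys <- object$system
  acols <- rule_antecedent_cols(sys)
  tab <- object$rules
  for (j in seq_along(sys$inputs)) {
    tab[[names(sys$inputs)[j]]] <- sys$inputs[[j]]$labels[tab[[acols[j]]]]
  }
  tab$state <- sys$output$labels[tab$consequent]
  tab$theta <- sys$output$centers[tab$consequent]
  tab <- tab[, c(names(sys$inputs), "state", "theta", "degree", "source")]
  structure(list(model = object, rule_table = tab,
                 rmse = sqrt(mean(object$residuals^2, na.rm = TRUE)),
                 coverage = nrow(object$rules) /
                   (enumerate_rule_space(sys)$count /
                      length(sys$output$mfs))),
            class = "summary.fbf")
}

#' @export
print.summary.fbf <- function(x, ...) {
  print(x$model)
  cat(sprintf("  antecedent-cell coverage: %.0f%%\n", 100 * x$coverage))
  cat("\nRule base (IF inputs ... THEN state is ...):\n")
  print(x$rule_table, row.names = FALSE)
  invisible(x)
}

#' @rdname fbf
#' @param object A fitted `fbf` model.
#' @param newdata Data frame of inputs (training inputs if omitted).
#' @param type `"state"` for `f(z)`, `"label"` for the Low/Normal decision,
#'   `"alarm"` for a list of [alarm()] decisions.
#' @param threshold Alarm threshold for `type != "state"`.
#' @param uncovered Passed to [infer()].
#' @param ... Unused.
#' @export
predict.fbf <- function(object, newdata = NULL,
                        type = c("state", "label", "alarm"),
                        threshold = 0.5, uncovered = "error", ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    f <- object$fitted.values
    Z <- NULL
  } else {
    Z <- input_matrix(as_fbf_system(object), newdata)
    f <- infer(object, newdata, uncovered = uncovered)
  }
  switch(type,
    state = f,
    label = ifelse(f < threshold, "Low", "Normal"),
    alarm = lapply(seq_along(f), function(i) {
      alarm(f[i], threshold,
            inputs = if (!is.null(Z)) stats::setNames(as.list(Z[i, ]),
                                                      object$input_names))
    }))
}

#' @rdname fbf
#' @param x A fitted `fbf` model.
#' @export
plot.fbf <- function(x, ...) {
  sys <- x$system
  k <- length(sys$inputs) + 1L
  old <- graphics::par(mfrow = c(k, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in sys$inputs) plot(p)
  plot(sys$output)
  invisible(x)
}

#' @export
fitted.fbf <- function(object, ...) object$fitted.values

#' @export
residuals.fbf <- function(object, ...) object$residuals
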