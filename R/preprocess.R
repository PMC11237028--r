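# Per-feature observed missing fraction: panel cells for time-varying
# features, baseline cells for static ones.
missing_fraction <- function(cohort) {
  f <- cohort$schema$features
  vapply(seq_len(nrow(f)), function(i) {
    fi <- f[i, ]
    col <- if (fi$time_varying && !is.null(cohort$panel) &&
               fi$name %in% names(cohort$panel)) {
      cohort$panel[[fi$name]]
    } else if (fi$name %in% names(cohort$baseline)) {
      cohort$baseline[[fi$name]]
    } else return(NA_real_)
    mean(is.na(col))
  }, numeric(1)) |> stats::setNames(f$name)
}

drop_feature_cols <- function(cohort, names) {
  cohort$schema$features <-
    cohort$schema$features[!cohort$schema$features$name %in% names, ,
                           drop = FALSE]
  cohort$baseline <- cohort$baseline[, !names(cohort$baseline) %in% names,
                                     drop = FALSE]
  if (!is.null(cohort$panel)) {
    cohort$panel <- cohort$panel[, !names(cohort$panel) %in% names,
                                 drop = FALSE]
  }
  cohort
}

#' Exclude features with high missingness
#'
#' Removes every feature whose observed missing fraction is strictly greater
#' than `threshold` (default 90%), mirroring the first preprocessing step of
#' the study pipeline.
#'
#' @param cohort An `nfabt_cohort` (missing cells as `NA`).
#' @param threshold Exclusion threshold in `(0, 1]`; strict inequality.
#' @return A list with `cohort` (features removed from data and schema) and
#'   `report` (fields `dropped_features`, `missing_fraction`).
#' @export
drop_high_missingness <- function(cohort, threshold = 0.90) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  mf <- missing_fraction(cohort)
  dropped <- names(mf)[!is.na(mf) & mf > threshold]
  list(cohort = drop_feature_cols(cohort, dropped),
       report = list(dropped_features = dropped, missing_fraction = mf))
}

#' Add missingness indicator features
#'
#' For each feature whose missing fraction exceeds `threshold` (default 50%),
#' appends a companion indicator feature `<name>_present` coded 0 = missing,
#' 1 = present.  Run after [drop_high_missingness()].
#'
#' @inheritParams drop_high_missingness
#' @param threshold Indicator threshold; strict inequality.
#' @return The cohort with indicator columns (and schema rows) appended.
#' @export
add_missingness_indicators <- function(cohort, threshold = 0.50) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  mf <- missing_fraction(cohort)
  flagged <- names(mf)[!is.na(mf) & mf > threshold]
  for (nm in flagged) {
    ind <- paste0(nm, "_present")
    if (ind %in% cohort$schema$features$name) {
      stop("indicator name collision: ", ind)
    }
    fi <- cohort$schema$features[cohort$schema$features$name == nm, ]
    if (fi$time_varying && !is.null(cohort$panel)) {
      cohort$panel[[ind]] <- as.integer(!is.na(cohort$panel[[nm]]))
    } else {
      cohort$baseline[[ind]] <- as.integer(!is.na(cohort$baseline[[nm]]))
    }
    row <- fi
    row$name <- ind; row$kind <- "binary"; row$mean <- NA; row$sd <- NA
    row$unit <- ""; row$missing_rate <- 0; row$lo <- NA; row$hi <- NA
    cohort$schema$features <- rbind(cohort$schema$features, row)
  }
  attr(cohort, "indicator_features") <- paste0(flagged, "_present")
  cohort
}

#' Median imputation
#'
#' Replaces every missing continuous cell by the feature's median over its
#' observed cells.  Observed cells are never altered; a feature with no
#' observed cells is an error.
#'
#' @inheritParams drop_high_missingness
#' @return A list with `cohort` and `report` (field `imputation_values`, the
#'   name-to-median map of imputed features).
#' @export
median_impute <- function(cohort) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  f <- cohort$schema$features
  meds <- list()
  for (i in seq_len(nrow(f))) {
    fi <- f[i, ]
    if (fi$kind != "continuous") next
    in_panel <- fi$time_varying && !is.null(cohort$panel) &&
      fi$name %in% names(cohort$panel)
    col <- if (in_panel) cohort$panel[[fi$name]]
           else if (fi$name %in% names(cohort$baseline)) cohort$baseline[[fi$name]]
           else next
    if (!anyNA(col)) next
    obs <- col[!is.na(col)]
    if (!length(obs)) stop("cannot impute feature with no observed cells: ",
                           fi$name)
    m <- stats::median(obs)
    col[is.na(col)] <- m
    meds[[fi$name]] <- m
    if (in_panel) cohort$panel[[fi$name]] <- col
    else cohort$baseline[[fi$name]] <- col
  }
  list(cohort = cohort, report = list(imputation_values = meds))
}

#' Encode categorical features numerically
#'
#' Applies the study's coding scheme: sex 1 = male / 2 = female; blood-cancer
#' type ALL/AML/CLL/CML as 1-4; every history or behaviour flag 1 = having /
#' applying, 0 = not; age bands as ordinal 1-6; troponin T binarized at the
#' assay positivity cutoff (0 = negative, 1 = positive).  Columns that are
#' already numeric pass through unchanged, so the operation is idempotent.
#'
#' @inheritParams drop_high_missingness
#' @param troponin_cutoff Positivity cutoff for troponin T (ng/mL).
#' @return The cohort with numeric codes; the code tables are attached as
#'   attribute `encoding_map`.
#' @export
encode_features <- function(cohort, troponin_cutoff = 0.014) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  maps <- list(
    sex = c(Male = 1, Female = 2),
    cancer_type = c(ALL = 1, AML = 2, CLL = 3, CML = 4),
    age_band = c(`18-32` = 1, `32-46` = 2, `46-60` = 3,
                 `60-74` = 4, `74-88` = 5, `88-90` = 6)
  )
  yn <- c(No = 0, Yes = 1)
  f <- cohort$schema$features
  used <- list()
  for (nm in intersect(f$name[f$kind != "continuous"],
                       names(cohort$baseline))) {
    col <- cohort$baseline[[nm]]
    if (is.numeric(col)) next
    map <- maps[[nm]] %||% yn
    bad <- setdiff(unique(col[!is.na(col)]), names(map))
    if (length(bad)) {
      stop("unknown category label(s) for ", nm, ": ",
           paste(bad, collapse = ", "))
    }
    cohort$baseline[[nm]] <- unname(map[col])
    used[[nm]] <- map
  }
  # troponin T: continuous assay value -> positive/negative code
  for (where in c("panel", "baseline")) {
    d <- cohort[[where]]
    if (!is.null(d) && "troponin_t" %in% names(d)) {
      v <- d$troponin_t
      if (!all(v %in% c(0, 1) | is.na(v))) {
        d$troponin_t <- ifelse(is.na(v), NA_real_,
                               as.numeric(v > troponin_cutoff))
        cohort[[where]] <- d
        # now a positivity code: exempt from normalization / re-binarization
        cohort$schema$features$kind[
          cohort$schema$features$name == "troponin_t"] <- "binary"
      }
    }
  }
  used$troponin_t <- c(cutoff = troponin_cutoff)
  attr(cohort, "encoding_map") <- used
  cohort
}

#' Anchor series at the first recording
#'
#' Left-aligns each listed daily series so that day 0 holds the patient's
#' first non-missing recording; leading missing days are removed and the tail
#' padded with `NA` to keep the panel rectangular.  A series with no
#' recording at all is an error.
#'
#' @inheritParams drop_high_missingness
#' @param features Series to anchor (the protocol vitals by default).
#' @return The cohort with shifted series.
#' @export
anchor_first_timepoint <- function(cohort,
                                   features = c("heart_rate", "sbp", "dbp")) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  if (is.null(cohort$panel)) stop("trajectories not present")
  p <- cohort$panel
  ids <- unique(p$id)
  for (nm in intersect(features, names(p))) {
    for (pid in ids) {
      idx <- which(p$id == pid)
      idx <- idx[order(p$day[idx])]
      v <- p[[nm]][idx]
      first <- which(!is.na(v))[1]
      if (is.na(first)) {
        stop("series entirely missing for feature '", nm,
             "', patient ", pid)
      }
      if (first > 1L) {
        p[[nm]][idx] <- c(v[first:length(v)], rep(NA, first - 1L))
      }
    }
  }
  cohort$panel <- p
  cohort
}

#' Normalize continuous features
#'
#' Standardizes every continuous feature (z-score by default, min-max by
#' option) using statistics computed on this cohort, or reuses statistics
#' from a training split via `stats`.  Binary and categorical codes are left
#' untouched; a zero-variance feature is centred and given scale 1 with a
#' warning.
#'
#' @inheritParams drop_high_missingness
#' @param method `"zscore"` or `"minmax"`.
#' @param stats Optional `normalization_stats` from a previous call (training
#'   split), a name -> `c(center, scale)` list.
#' @return A list with `cohort` and `report` (field `normalization_stats`).
#' @export
normalize_continuous <- function(cohort, method = c("zscore", "minmax"),
                                 stats = NULL) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  method <- match.arg(method)
  f <- cohort$schema$features
  out_stats <- list()
  for (i in seq_len(nrow(f))) {
    fi <- f[i, ]
    if (fi$kind != "continuous") next
    in_panel <- fi$time_varying && !is.null(cohort$panel) &&
      fi$name %in% names(cohort$panel)
    col <- if (in_panel) cohort$panel[[fi$name]]
           else if (fi$name %in% names(cohort$baseline)) cohort$baseline[[fi$name]]
           else next
    if (!is.null(stats)) {
      st <- stats[[fi$name]]
      if (is.null(st)) next
    } else if (method == "zscore") {
      ctr <- mean(col, na.rm = TRUE)
      scl <- stats::sd(col, na.rm = TRUE)
      if (!is.finite(scl) || scl == 0) {
        warning("zero-variance feature scaled by 1: ", fi$name)
        scl <- 1
      }
      st <- c(center = ctr, scale = scl)
    } else {
      lo <- min(col, na.rm = TRUE); hi <- max(col, na.rm = TRUE)
      if (hi == lo) {
        warning("zero-variance feature scaled by 1: ", fi$name)
        hi <- lo + 1
      }
      st <- c(center = lo, scale = hi - lo)
    }
    newcol <- (col - st[["center"]]) / st[["scale"]]
    if (in_panel) cohort$panel[[fi$name]] <- newcol
    else cohort$baseline[[fi$name]] <- newcol
    # keep the schema's plausible range on the transformed scale
    r <- which(cohort$schema$features$name == fi$name)
    cohort$schema$features$lo[r] <- (fi$lo - st[["center"]]) / st[["scale"]]
    cohort$schema$features$hi[r] <- (fi$hi - st[["center"]]) / st[["scale"]]
    cohort$schema$features$mean[r] <-
      (fi$mean - st[["center"]]) / st[["scale"]]
    cohort$schema$features$sd[r] <- fi$sd / st[["scale"]]
    # keep baseline copies of daily features on the same scale
    if (in_panel && fi$name %in% names(cohort$baseline)) {
      cohort$baseline[[fi$name]] <-
        (cohort$baseline[[fi$name]] - st[["center"]]) / st[["scale"]]
    }
    out_stats[[fi$name]] <- st
  }
  list(cohort = cohort, report = list(normalization_stats = out_stats,
                                      method = method))
}

#' Pearson correlation matrix of a feature group
#'
#' Patient-level (baseline) Pearson correlations within one schema feature
#' group, used to check that model inputs are relatively uncorrelated.
#'
#' @inheritParams drop_high_missingness
#' @param group One of `demographic`, `clinical`, `lab1`, `lab2`, `lab3`.
#' @return A symmetric correlation matrix (class `nfabt_cor`) with unit
#'   diagonal; plot it with [plot.nfabt_cor()].
#' @export
correlation_matrix <- function(cohort, group) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  f <- cohort$schema$features
  group <- match.arg(group, c("demographic", "clinical", "lab1", "lab2", "lab3"))
  nms <- intersect(f$name[f$group == group], names(cohort$baseline))
  if (length(nms) < 2L) stop("group '", group, "' has fewer than 2 features")
  x <- cohort$baseline[, nms, drop = FALSE]
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("group contains unencoded categorical features; run encode_features()")
  }
  if (anyNA(x)) stop("missing cells present; impute before correlating")
  v <- vapply(x, stats::var, numeric(1))
  if (any(v == 0)) {
    stop("zero-variance feature(s): ", paste(nms[v == 0], collapse = ", "))
  }
  m <- stats::cor(as.matrix(x))
  class(m) <- c("nfabt_cor", class(m))
  m
}

#' @rdname correlation_matrix
#' @param x An `nfabt_cor` matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot.nfabt_cor <- function(x, ...) {
  m <- unclass(x)
  k <- ncol(m)
  graphics::image(seq_len(k), seq_len(k), t(m[k:1, , drop = FALSE]),
                  zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(41, "Blue-Red 2"), ...)
  graphics::axis(1, seq_len(k), colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(k), rev(rownames(m)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Full preprocessing pipeline
#'
#' Applies, in order: high-missingness exclusion, missingness indicators,
#' median imputation, categorical encoding, first-timepoint anchoring and
#' normalization, accumulating a report.  The order is fixed; individual
#' steps are exported for piecewise use.
#'
#' @inheritParams drop_high_missingness
#' @inheritParams add_missingness_indicators
#' @inheritParams normalize_continuous
#' @inheritParams encode_features
#' @inheritParams anchor_first_timepoint
#' @param drop_threshold Exclusion threshold (strict, default 0.90).
#' @param indicator_threshold Indicator threshold (strict, default 0.50).
#' @param anchor_features Series to anchor.
#' @param norm_stats Optional training-split normalization statistics.
#' @return A list with `cohort` and `report` (class `preprocess_report`).
#' @export
preprocess_cohort <- function(cohort, drop_threshold = 0.90,
                              indicator_threshold = 0.50,
                              method = "zscore",
                              troponin_cutoff = 0.014,
                              anchor_features = c("heart_rate", "sbp", "dbp"),
                              norm_stats = NULL) {
  s1 <- drop_high_missingness(cohort, drop_threshold)
  co <- add_missingness_indicators(s1$cohort, indicator_threshold)
  ind <- attr(co, "indicator_features") %||% character(0)
  s3 <- median_impute(co)
  co <- encode_features(s3$cohort, troponin_cutoff)
  enc <- attr(co, "encoding_map")
  if (!is.null(co$panel)) co <- anchor_first_timepoint(co, anchor_features)
  s6 <- normalize_continuous(co, method, stats = norm_stats)
  report <- structure(list(
    dropped_features = s1$report$dropped_features,
    missing_fraction = s1$report$missing_fraction,
    indicator_features = ind,
    imputation_values = s3$report$imputation_values,
    encoding_map = enc,
    normalization_stats = s6$report$normalization_stats
  ), class = "preprocess_report")
  list(cohort = s6$cohort, report = report)
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("Preprocessing report\n")
  cat("  dropped (>90% missing):",
      if (length(x$dropped_features)) paste(x$dropped_features, collapse = ", ")
      else "none", "\n")
  cat("  indicators added:",
      if (length(x$indicator_features)) paste(x$indicator_features, collapse = ", ")
      else "none", "\n")
  cat("  features imputed:", length(x$imputation_values),
      " | features normalized:", length(x$normalization_stats), "\n")
  invisible(x)
}
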