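#' Write / read a cohort as long-format CSV plus a schema sidecar
#'
#' `write_cohort()` serializes a cohort to a long CSV with columns
#' `id, day, feature, value, missing` (static features at empty `day`, daily
#' labels under feature `prbc`) and a JSON sidecar `<path>.schema.json`
#' holding the schema and cohort metadata.  Numeric values are written with
#' 17 significant digits so `read_cohort(write_cohort(x))` reproduces the
#' cohort exactly.
#'
#' `read_cohort()` validates the file: duplicated `(id, day, feature)` rows
#' are an error; observed values outside a feature's plausible range are
#' collected as validation warnings (attached as attribute
#' `validation_log` and raised via `warning()`).
#'
#' @param cohort An `nfabt_cohort`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   the reconstructed `nfabt_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "nfabt_cohort"))
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "", sprintf("%.17g", v))
    else ifelse(is.na(v), "", as.character(v))
  }
  rows <- list()
  f <- cohort$schema$features
  b <- cohort$baseline
  # every baseline column goes out at blank day, daily series at day 0..T-1;
  # the (id, day, feature) key keeps the two apart
  for (nm in setdiff(names(b), "id")) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = b$id, day = NA_integer_, feature = nm,
      value = fmt(b[[nm]]), missing = is.na(b[[nm]]),
      stringsAsFactors = FALSE)
  }
  if (!is.null(cohort$panel)) {
    p <- cohort$panel
    for (nm in setdiff(names(p), c("id", "day"))) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = p$id, day = p$day, feature = nm,
        value = fmt(p[[nm]]), missing = is.na(p[[nm]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cohort$labels)) {
    l <- cohort$labels
    rows[[length(rows) + 1L]] <- data.frame(
      id = l$id, day = l$day, feature = "prbc",
      value = fmt(as.numeric(l$prbc)), missing = FALSE,
      stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  utils::write.csv(long, path, row.names = FALSE, na = "")

  sf_out <- cohort$schema$features
  for (nm in c("mean", "sd", "missing_rate", "lo", "hi")) {
    # %.17g strings survive JSON bit-exactly; bare doubles do not
    sf_out[[nm]] <- ifelse(is.na(sf_out[[nm]]), NA_character_,
                           sprintf("%.17g", sf_out[[nm]]))
  }
  meta <- list(
    schema = list(
      features = sf_out,
      category_counts = lapply(cohort$schema$category_counts, as.list),
      n_default = cohort$schema$n_default,
      horizon_default = cohort$schema$horizon_default
    ),
    seed = cohort$seed,
    has_panel = !is.null(cohort$panel),
    has_labels = !is.null(cohort$labels),
    baseline_features = setdiff(names(b), "id")
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".schema.json")

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar_path(path))) stop("missing schema sidecar for ", path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  sf <- as.data.frame(meta$schema$features, stringsAsFactors = FALSE)
  # JSON has no column types: restore the schema's
  for (nm in c("name", "group", "kind", "unit")) {
    sf[[nm]] <- as.character(sf[[nm]])
    sf[[nm]][is.na(sf[[nm]])] <- ""
  }
  for (nm in c("mean", "sd", "missing_rate", "lo", "hi")) {
    sf[[nm]] <- as.numeric(sf[[nm]])
  }
  sf$time_varying <- as.logical(sf$time_varying)
  sf <- sf[, c("name", "group", "kind", "mean", "sd", "unit",
               "missing_rate", "lo", "hi", "time_varying"), drop = FALSE]
  schema <- structure(
    list(features = sf,
         category_counts = lapply(meta$schema$category_counts, function(x) {
           v <- unlist(x); storage.mode(v) <- "integer"; v
         }),
         n_default = as.integer(meta$schema$n_default),
         horizon_default = as.integer(meta$schema$horizon_default)),
    class = "cohort_schema")

  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(id = "character", day = "integer",
                                         feature = "character",
                                         value = "character",
                                         missing = "logical"))
  key <- paste(long$id, long$day, long$feature, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (id, day, feature) rows in ", path)
  }

  log <- character(0)
  num_value <- function(d, nm) {
    v <- ifelse(d$missing, NA_character_, d$value)
    suppressWarnings(as.numeric(v))
  }
  ids <- unique(long$id)

  # range validation on observed continuous cells
  for (i in seq_len(nrow(sf))) {
    fi <- sf[i, ]
    if (fi$kind != "continuous") next
    d <- long[long$feature == fi$name & !long$missing, , drop = FALSE]
    if (!nrow(d)) next
    v <- suppressWarnings(as.numeric(d$value))
    bad <- which(!is.na(v) & (v < fi$lo | v > fi$hi))
    if (length(bad)) {
      log <- c(log, sprintf(
        "feature '%s': %d observed value(s) outside plausible range [%g, %g]",
        fi$name, length(bad), fi$lo, fi$hi))
    }
  }

  baseline <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (nm in meta$baseline_features) {
    d <- long[long$feature == nm & is.na(long$day), , drop = FALSE]
    if (!nrow(d)) next
    d <- d[match(ids, d$id), , drop = FALSE]
    fi <- sf[sf$name == nm, ]
    baseline[[nm]] <- if (nrow(fi) && fi$kind[1] != "continuous") {
      ifelse(d$missing, NA_character_, d$value)
    } else num_value(d, nm)
  }

  panel <- NULL
  if (isTRUE(meta$has_panel)) {
    dsub <- long[!is.na(long$day) & long$feature != "prbc", , drop = FALSE]
    days <- sort(unique(dsub$day))
    panel <- data.frame(id = rep(ids, each = length(days)),
                        day = rep(days, times = length(ids)),
                        stringsAsFactors = FALSE)
    pkey <- paste(panel$id, panel$day, sep = "\r")
    for (nm in unique(dsub$feature)) {
      d <- dsub[dsub$feature == nm, , drop = FALSE]
      v <- rep(NA_real_, nrow(panel))
      v[match(paste(d$id, d$day, sep = "\r"), pkey)] <- num_value(d, nm)
      panel[[nm]] <- v
    }
  }

  labels <- NULL
  if (isTRUE(meta$has_labels)) {
    d <- long[long$feature == "prbc", , drop = FALSE]
    d <- d[order(match(d$id, ids), d$day), , drop = FALSE]
    labels <- data.frame(id = d$id, day = d$day,
                         prbc = as.integer(as.numeric(d$value)),
                         stringsAsFactors = FALSE)
    rownames(labels) <- NULL
  }

  # keep schema column order in baseline
  baseline <- baseline[, c("id", intersect(sf$name, names(baseline))),
                       drop = FALSE]
  out <- structure(list(schema = schema, baseline = baseline, panel = panel,
                        labels = labels, seed = as.integer(meta$seed)),
                   class = "nfabt_cohort")
  if (length(log)) {
    attr(out, "validation_log") <- log
    warning(paste(log, collapse = "; "))
  }
  out
}
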