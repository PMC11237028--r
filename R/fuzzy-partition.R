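#' Triangular membership function
#'
#' A normal triangular membership function with peak `center` (degree 1) and
#' feet at the adjacent centers; an infinite foot makes a shoulder that stays
#' at degree 1 beyond its extreme center, so partitions remain complete over
#' the whole universe.
#'
#' @param label Linguistic label.
#' @param center Peak location.
#' @param left_foot,right_foot Feet (`-Inf` / `Inf` for shoulders).
#' @return An object of class `triangular_mf`.
#' @export
triangular_mf <- function(label, center, left_foot, right_foot) {
  if (!(left_foot < center && center < right_foot)) {
    stop("membership function requires left_foot < center < right_foot")
  }
  structure(list(label = label, center = center,
                 left_foot = left_foot, right_foot = right_foot),
            class = "triangular_mf")
}

mf_degree <- function(mf, z) {
  out <- numeric(length(z))
  left <- z <= mf$center
  out[left] <- if (is.infinite(mf$left_foot)) 1 else {
    pmax(0, (z[left] - mf$left_foot) / (mf$center - mf$left_foot))
  }
  out[!left] <- if (is.infinite(mf$right_foot)) 1 else {
    pmax(0, (mf$right_foot - z[!left]) / (mf$right_foot - mf$center))
  }
  out
}

#' Fuzzy partition of one variable
#'
#' An ordered, normal, complete and consistent triangular partition: interior
#' membership functions have their feet at the neighbouring centers (which
#' yields the partition-of-unity property between the extreme centers), and
#' the extreme membership functions are shoulders extending to the edges of
#' the universe and beyond, so every point of the universe is covered even
#' when centers lie outside the stated universe.
#'
#' @param variable Variable name.
#' @param universe `c(lo, hi)` stated universe of discourse.
#' @param centers Strictly increasing membership-function centers.
#' @param labels Linguistic labels, one per center.
#' @return An object of class `fuzzy_partition`.
#' @export
fuzzy_partition <- function(variable, universe, centers,
                            labels = paste0("mf", seq_along(centers))) {
  stopifnot(length(universe) == 2L, universe[1] < universe[2],
            length(labels) == length(centers))
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("centers must be strictly increasing")
  }
  K <- length(centers)
  mfs <- lapply(seq_len(K), function(k) {
    triangular_mf(labels[k], centers[k],
                  if (k == 1L) -Inf else centers[k - 1L],
                  if (k == K) Inf else centers[k + 1L])
  })
  structure(list(variable = variable, universe = universe,
                 centers = centers, labels = labels, mfs = mfs),
            class = "fuzzy_partition")
}

#' Evaluate one membership function of a partition
#'
#' Piecewise-linear triangular evaluation; shoulder membership functions
#' return 1 beyond their extreme center.
#'
#' @param partition A `fuzzy_partition`.
#' @param mf_index Membership-function index (or label).
#' @param z Numeric values.
#' @return Degrees in `[0, 1]`, vectorized over `z`.
#' @examples
#' p <- default_partitions()$inputs$hgb
#' membership(p, 1, 8)       # 1 at the peak
#' membership(p, 1, 9.125)   # 0.5 midway to the next center
#' @export
membership <- function(partition, mf_index, z) {
  stopifnot(inherits(partition, "fuzzy_partition"))
  if (is.character(mf_index)) mf_index <- match(mf_index, partition$labels)
  if (is.na(mf_index) || mf_index < 1L || mf_index > length(partition$mfs)) {
    stop("membership-function index out of range")
  }
  mf_degree(partition$mfs[[mf_index]], z)
}

# all K membership degrees at points z: length(z) x K matrix
membership_matrix <- function(partition, z) {
  matrix(vapply(partition$mfs, function(mf) mf_degree(mf, z),
                numeric(length(z))),
         nrow = length(z))
}

#' Check partition normality, completeness and partition of unity
#'
#' Grid-scans the universe: every point must have positive maximum
#' membership (completeness), and between the extreme centers the membership
#' degrees must sum to one.
#'
#' @param partition A `fuzzy_partition`.
#' @param n_grid Number of scan points.
#' @param tol Tolerance for the partition-of-unity check.
#' @return `TRUE` invisibly; errors describe any violated property.
#' @export
check_partition <- function(partition, n_grid = 1000L, tol = 1e-9) {
  lo <- min(partition$universe[1], partition$centers[1])
  hi <- max(partition$universe[2], partition$centers[length(partition$centers)])
  z <- seq(lo, hi, length.out = n_grid)
  m <- membership_matrix(partition, z)
  if (any(apply(m, 1, max) <= 0)) stop("partition is not complete")
  inside <- z >= partition$centers[1] &
    z <= partition$centers[length(partition$centers)]
  s <- rowSums(m[inside, , drop = FALSE])
  if (any(abs(s - 1) > tol)) stop("partition of unity violated")
  peak <- vapply(seq_along(partition$mfs),
                 function(k) membership(partition, k, partition$centers[k]),
                 numeric(1))
  if (any(abs(peak - 1) > tol)) stop("partition is not normal")
  invisible(TRUE)
}

#' Default membership partitions of the alarming system
#'
#' The shipped configuration: haemoglobin on universe \[7, 16.6\] g/dL with
#' four membership functions centred at 8, 10.25, 14.1, 16.6; arterial
#' oxygen pressure on \[40, 80\] mmHg with four centred at 30, 47.5, 65.75,
#' 90 (the extreme centers lie outside the stated universe, so the shoulder
#' construction extends coverage to them); blood pH on \[6.3, 7.8\] with
#' three centred at 7.35, 7.40, 7.45; and the output blood-state variable on
#' \[0, 1\] with two membership functions, Low at 0.25 and Normal at 0.75.
#'
#' @return A list with `inputs` (named list of `fuzzy_partition` for `hgb`,
#'   `pao2`, `ph`) and `output` (the blood-state partition).
#' @export
default_partitions <- function() {
  list(
    inputs = list(
      hgb = fuzzy_partition("hgb", c(7, 16.6), c(8, 10.25, 14.1, 16.6),
                            c("Very Low", "Low", "Normal", "High")),
      pao2 = fuzzy_partition("pao2", c(40, 80), c(30, 47.5, 65.75, 90),
                             c("Normal", "Mild Hypoxemia",
                               "Moderate Hypoxemia", "Severe Hypoxemia")),
      ph = fuzzy_partition("ph", c(6.3, 7.8), c(7.35, 7.40, 7.45),
                           c("Acidosis", "Normal", "Alkalosis"))
    ),
    output = fuzzy_partition("state", c(0, 1), c(0.25, 0.75),
                             c("Low", "Normal"))
  )
}

#' @export
print.fuzzy_partition <- function(x, ...) {
  cat(sprintf("Fuzzy partition '%s' on [%g, %g]: %d triangular MFs\n",
              x$variable, x$universe[1], x$universe[2], length(x$mfs)))
  for (mf in x$mfs) {
    cat(sprintf("  %-20s center %g, feet (%g, %g)\n",
                mf$label, mf$center, mf$left_foot, mf$right_foot))
  }
  invisible(x)
}

#' @rdname fuzzy_partition
#' @param x A `fuzzy_partition`.
#' @param n Curve resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fuzzy_partition <- function(x, n = 400L, ...) {
  lo <- min(x$universe[1], x$centers[1])
  hi <- max(x$universe[2], x$centers[length(x$centers)])
  z <- seq(lo, hi, length.out = n)
  m <- membership_matrix(x, z)
  graphics::matplot(z, m, type = "l", lty = 1, lwd = 2,
                    xlab = x$variable, ylab = "membership degree",
                    ylim = c(0, 1.05), ...)
  graphics::legend("right", legend = x$labels, lty = 1, lwd = 2,
                   col = seq_along(x$labels), bty = "n", cex = 0.8)
  invisible(x)
}

#' Read a fuzzy-system configuration from YAML
#'
#' The YAML file lists partitions (`variable`, `universe`, `centers`,
#' `labels`), the active `inputs`, the `normalize` flag and the
#' `alarm_threshold`; see `system.file("extdata", "partitions.yaml",
#' package = "nfabt")` for the shipped default.
#'
#' @param path YAML file path.
#' @return A list with `partitions` (named list of `fuzzy_partition`),
#'   `output`, `inputs`, `normalize`, `alarm_threshold`.
#' @export
read_fuzzy_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  parts <- lapply(cfg$partitions, function(p) {
    fuzzy_partition(p$variable, as.numeric(p$universe),
                    as.numeric(p$centers), as.character(p$labels))
  })
  names(parts) <- vapply(parts, `[[`, "", "variable")
  out_name <- cfg$output %||% "state"
  list(partitions = parts[setdiff(names(parts), out_name)],
       output = parts[[out_name]],
       inputs = as.character(cfg$inputs %||% setdiff(names(parts), out_name)),
       normalize = isTRUE(cfg$normalize %||% TRUE),
       alarm_threshold = as.numeric(cfg$alarm_threshold %||% 0.5))
}
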