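#' Counting-grid specification
#'
#' A square point lattice overlaid on a micrograph field.  The two set-ups
#' used in practice are a 240-point grid with 77.1 um probe line length and
#' a denser 370-point grid with 65.7 um probe line length; the denser grid
#' avoids under-sampling the smallest previtellogenic oocytes.
#'
#' @param n_points Number of lattice points (>= 1).
#' @param probe_line_length Lattice spacing in um (> 0).
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_b()  # the denser default
grid_spec <- function(n_points = 370, probe_line_length = 65.7) {
  stopifnot(n_points >= 1, probe_line_length > 0)
  structure(list(n_points = as.integer(n_points),
                 probe_line_length = probe_line_length,
                 arrangement = "square"),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @export
grid_a <- function() grid_spec(240, 77.1)

#' @rdname grid_spec
#' @export
grid_b <- function() grid_spec(370, 65.7)

#' Shrinkage-correction model
#'
#' Histological processing shrinks oocytes relative to their stabilized
#' formalin-fixed (whole-mount) dimensions, and the amount of shrinkage
#' depends on the embedding medium (more in paraffin than in resin).  The
#' published account of this pipeline selects between two externally
#' derived correction factors; their numeric values are not part of this
#' package and must be supplied by the user.  The default is the identity
#' model, which warns once when applied so that uncorrected diameters are
#' never mistaken for corrected ones.
#'
#' @param kind `"identity"`, `"multiplicative"` or `"linear"`.
#' @param factor Multiplier for the multiplicative model (corrected =
#'   factor * measured).
#' @param intercept,slope Coefficients for the linear model (corrected =
#'   intercept + slope * measured).
#' @param label Optional label used in model-comparison output.
#' @return An object of class `shrinkage_model`.
#' @export
#' @examples
#' m <- shrinkage_model("multiplicative", factor = 1.25)
#' correct_shrinkage(80, m)  # 100
shrinkage_model <- function(kind = c("identity", "multiplicative", "linear"),
                            factor = NULL, intercept = NULL, slope = NULL,
                            label = NULL) {
  kind <- match.arg(kind)
  if (kind == "multiplicative") {
    stopifnot(is.numeric(factor), length(factor) == 1, factor > 0)
  } else if (kind == "linear") {
    stopifnot(is.numeric(intercept), is.numeric(slope), slope > 0)
  }
  structure(list(kind = kind, factor = factor, intercept = intercept,
                 slope = slope,
                 label = label %||% kind),
            class = "shrinkage_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a shrinkage-correction model to measured diameters
#'
#' @param x Positive diameters (um) as measured on embedded sections.
#' @param model A [shrinkage_model()].
#' @param warn_identity Warn when the identity model is applied (default
#'   `TRUE`: uncorrected diameters bias packing densities cubically).
#' @return Corrected diameters (um), guaranteed positive.
#' @export
correct_shrinkage <- function(x, model = shrinkage_model("identity"),
                              warn_identity = TRUE) {
  stopifnot(inherits(model, "shrinkage_model"), all(x > 0))
  out <- switch(model$kind,
    identity = {
      if (warn_identity) {
        warning("identity shrinkage model: diameters are NOT corrected; ",
                "supply embedding-medium specific coefficients",
                call. = FALSE)
      }
      x
    },
    multiplicative = model$factor * x,
    linear = model$intercept + model$slope * x
  )
  if (any(out <= 0)) {
    stop("shrinkage model produced non-positive corrected diameter",
         call. = FALSE)
  }
  out
}

#' Validate a table of per-field grid counts
#'
#' @param counts A data frame with columns `field_id`, `component`, `hits`
#'   and `n_points` (one row per field x component; components absent from
#'   a field may be omitted and count as zero).
#' @return The validated data frame, invisibly.
#' @export
validate_field_counts <- function(counts) {
  need <- c("field_id", "component", "hits", "n_points")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    stop("grid-count table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(counts$component), section_components())
  if (length(bad)) {
    stop("unknown section component(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$hits < 0)) stop("negative hit counts", call. = FALSE)
  tot <- tapply(counts$hits, counts$field_id, sum)
  npt <- tapply(counts$n_points, counts$field_id, function(x) x[1])
  off <- names(tot)[tot != npt]
  if (length(off)) {
    stop("hits do not sum to n_points in field(s): ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  invisible(counts)
}

#' Delesse volume fraction from pooled grid counts
#'
#' Under the Delesse principle the area fraction of a component on a random
#' section estimates its volume fraction.  The estimate pools hits across
#' fields as a ratio of sums: hits on the component divided by points on
#' sectioned tissue, i.e. total points minus hits on empty space and
#' outside the ovarian wall.  Ratio-of-sums pooling (rather than a mean of
#' per-field ratios) is unbiased when fields have unequal valid-point
#' counts.
#'
#' @param counts Per-field grid counts, see [validate_field_counts()].
#' @param component A component token, e.g. an oocyte stage.
#' @param per_field Return the per-field ratios instead of the pooled one
#'   (used by stabilization diagnostics).
#' @param mode `"tissue"` (default) divides by valid sectioned-tissue
#'   points; `"accounting"` divides by the raw point total so that all
#'   components, including `EMPTY` and `OUTSIDE`, sum to 1.
#' @return The volume fraction in `[0, 1]`, or a per-field numeric vector.
#' @export
#' @examples
#' cnt <- data.frame(field_id = 1,
#'                   component = c("VTO", "OTHER", "EMPTY", "OUTSIDE"),
#'                   hits = c(90, 150, 40, 20), n_points = 300)
#' volume_fraction(cnt, "VTO")  # 90 / 240 = 0.375
volume_fraction <- function(counts, component, per_field = FALSE,
                            mode = c("tissue", "accounting")) {
  mode <- match.arg(mode)
  validate_field_counts(counts)
  assert_component <- component %in% section_components()
  if (!assert_component) stop("unknown component: ", component, call. = FALSE)
  fields <- unique(counts$field_id)
  hit <- vapply(fields, function(f) {
    sum(counts$hits[counts$field_id == f & counts$component == component])
  }, numeric(1))
  valid <- vapply(fields, function(f) {
    rows <- counts$field_id == f
    n <- counts$n_points[rows][1]
    if (mode == "accounting") return(as.numeric(n))
    n - sum(counts$hits[rows &
                          counts$component %in% invalid_point_components()])
  }, numeric(1))
  if (per_field) {
    if (any(valid == 0)) {
      warning("field(s) with zero valid points yield NaN", call. = FALSE)
    }
    return(hit / valid)
  }
  if (sum(valid) == 0) {
    stop("volume fraction undefined: zero valid grid points", call. = FALSE)
  }
  sum(hit) / sum(valid)
}

#' Field-count stabilization diagnostics
#'
#' The pilot question behind grid counting is how many fields per ovary are
#' needed before the running estimate settles.  For a series of per-field
#' values the curve reports, for every n, the normalized absolute deviation
#' of the cumulative mean from the all-field mean,
#' `d_n = |cummean_n - mean_N| / mean_N`, together with the smallest n from
#' which the deviation stays at or below a threshold (0.05 by default,
#' i.e. +/-5 percent of the normalized mean).  The published pilot found
#' stabilization at seven fields under this criterion.
#'
#' @param per_field_values Numeric series of per-field estimates in
#'   counting order.
#' @param threshold Stabilization threshold on the normalized deviation.
#' @return A list with `deviation` (length-N curve), `n_stable` (smallest n
#'   such that all later deviations are within the threshold) and
#'   `threshold`.
#' @export
#' @examples
#' stabilization_curve(c(0, 1))$deviation  # 1, 0
stabilization_curve <- function(per_field_values, threshold = 0.05) {
  x <- as.numeric(per_field_values)
  n <- length(x)
  stopifnot(n >= 1)
  m <- mean(x)
  if (m == 0) stop("stabilization curve undefined: overall mean is zero",
                   call. = FALSE)
  d <- abs(cumsum(x) / seq_len(n) - m) / abs(m)
  ok <- rev(cumprod(rev(d <= threshold))) == 1  # TRUE from n_stable onwards
  list(deviation = d,
       n_stable = if (any(ok)) min(which(ok)) else NA_integer_,
       threshold = threshold)
}

# internal: eligible rows of a measurement table
eligible_measurements <- function(measurements, stage, female_id = NULL) {
  need <- c("stage", "L_um", "S_um", "through_nucleus")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    stop("measurement table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  rows <- measurements$stage == stage & measurements$through_nucleus
  if (!is.null(female_id) && "female_id" %in% names(measurements)) {
    rows <- rows & measurements$female_id == female_id
  }
  m <- measurements[rows, , drop = FALSE]
  if (any(m$S_um <= 0) || any(m$L_um < m$S_um)) {
    stop("invalid axis measurements: need L >= S > 0", call. = FALSE)
  }
  m
}

#' Mean oocyte shape factor
#'
#' The shape factor of one oocyte is the ratio of its long to short axis,
#' k = L / S, under a prolate-spheroid assumption; the stage mean is the
#' arithmetic mean over oocytes sectioned through the nucleus (only those
#' carry the stage's full dimensions).
#'
#' @param measurements Data frame with columns `stage`, `L_um`, `S_um`,
#'   `through_nucleus` and optionally `female_id`.
#' @param stage Stage token.
#' @param female_id Optional female filter.
#' @param min_n Advisory minimum sample size (pilot default 10); fewer
#'   eligible oocytes warn but still compute.
#' @return Mean k (>= 1), or `NA` with a warning when no oocyte qualifies.
#' @export
#' @examples
#' m <- data.frame(stage = "VTO", L_um = 130, S_um = 100,
#'                 through_nucleus = TRUE)
#' shape_factor(m, "VTO")  # 1.3
shape_factor <- function(measurements, stage, female_id = NULL, min_n = 10) {
  m <- eligible_measurements(measurements, stage, female_id)
  if (nrow(m) == 0) {
    warning("no eligible through-nucleus oocytes for stage ", stage,
            call. = FALSE)
    return(NA_real_)
  }
  if (nrow(m) < min_n) {
    warning("only ", nrow(m), " eligible oocytes for stage ", stage,
            " (advisory minimum ", min_n, ")", call. = FALSE)
  }
  mean(m$L_um / m$S_um)
}

#' Volume-based mean oocyte diameter
#'
#' The arithmetic diameter of one oocyte is OD = (L + S) / 2; the
#' volume-based stage mean is the cube root of the mean cubed diameter,
#' `ODv = (mean(OD^3))^(1/3)` - the diameter whose sphere carries the
#' population's mean volume at fixed shape.  By the power-mean inequality
#' ODv is never below the plain mean diameter.
#'
#' @inheritParams shape_factor
#' @return ODv in um, or `NA` with a warning when no oocyte qualifies.
#' @export
#' @examples
#' m <- data.frame(stage = "VTO", L_um = c(80, 100, 120),
#'                 S_um = c(80, 100, 120), through_nucleus = TRUE)
#' volume_based_diameter(m, "VTO")  # 102.5986
volume_based_diameter <- function(measurements, stage, female_id = NULL,
                                  min_n = 10) {
  m <- eligible_measurements(measurements, stage, female_id)
  if (nrow(m) == 0) {
    warning("no eligible through-nucleus oocytes for stage ", stage,
            call. = FALSE)
    return(NA_real_)
  }
  if (nrow(m) < min_n) {
    warning("only ", nrow(m), " eligible oocytes for stage ", stage,
            " (advisory minimum ", min_n, ")", call. = FALSE)
  }
  od <- (m$L_um + m$S_um) / 2
  mean(od^3)^(1 / 3)
}

#' Rank shrinkage-correction models against a whole-mount reference
#'
#' Given several candidate correction models, per-female uncorrected
#' medium-late vitellogenic oocyte numbers, the diameters they were based
#' on, and a per-female reference batch fecundity obtained independently
#' from whole mounts, rank the models by how close the corrected oocyte
#' numbers come to the reference.  Correcting a diameter by a factor f
#' scales the packing density, and hence the oocyte number, by f^-3.
#'
#' @param models List of [shrinkage_model()] objects.
#' @param no_vto Numeric vector of uncorrected stage oocyte numbers per
#'   female.
#' @param odv Numeric vector of the uncorrected volume-based diameters (um)
#'   the numbers were computed from.
#' @param reference_bf Numeric vector of reference batch fecundities.
#' @return Data frame ranked by mean absolute relative deviation, with the
#'   best model first; ties keep input order.
#' @export
compare_correction_models <- function(models, no_vto, odv, reference_bf) {
  stopifnot(length(models) >= 1,
            length(no_vto) == length(reference_bf),
            length(no_vto) == length(odv))
  keep <- is.finite(no_vto) & is.finite(reference_bf) & is.finite(odv) &
    reference_bf > 0
  if (!any(keep)) {
    stop("no females with both corrected numbers and reference values",
         call. = FALSE)
  }
  dev <- vapply(models, function(m) {
    codv <- correct_shrinkage(odv[keep], m, warn_identity = FALSE)
    cno <- no_vto[keep] * (odv[keep] / codv)^3
    mean(abs(cno - reference_bf[keep]) / reference_bf[keep])
  }, numeric(1))
  lab <- vapply(models, function(m) m$label, character(1))
  out <- data.frame(model = lab, mean_abs_rel_dev = dev,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_abs_rel_dev), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "best") <- models[[which.min(dev)]]
  out
}

#' Choose a counting grid from paired pilot estimates
#'
#' Given paired per-field volume-fraction estimates of the same fields
#' under two grids, keep the cheaper (sparser) grid when the two agree to
#' within a stated relative tolerance, and fall back to the conservative
#' denser grid when they differ - the situation that arises when small
#' particles slip between the points of a sparse grid.
#'
#' @param grid1,grid2 Two [grid_spec()] objects.
#' @param estimates1,estimates2 Paired per-field estimates under each grid.
#' @param tolerance Relative tolerance on the difference of means.
#' @return The chosen `grid_spec`, with attribute `reason`.
#' @export
select_grid <- function(grid1, grid2, estimates1, estimates2,
                        tolerance = 0.05) {
  stopifnot(inherits(grid1, "grid_spec"), inherits(grid2, "grid_spec"))
  if (length(estimates1) != length(estimates2)) {
    stop("pilot estimates must be paired (equal length)", call. = FALSE)
  }
  grids <- list(grid1, grid2)
  dense <- grids[[which.max(c(grid1$n_points, grid2$n_points))]]
  sparse <- grids[[which.min(c(grid1$n_points, grid2$n_points))]]
  m1 <- mean(estimates1); m2 <- mean(estimates2)
  rel <- abs(m1 - m2) / max(abs(m1), abs(m2), .Machine$double.eps)
  if (rel > tolerance) {
    structure(dense, reason = sprintf(
      "paired means differ by %.1f%% (> %.1f%%): denser grid retained",
      100 * rel, 100 * tolerance))
  } else {
    structure(sparse, reason = sprintf(
      "paired means agree within %.1f%%: sparser grid suffices", 100 * tolerance))
  }
}
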