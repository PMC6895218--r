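#' Fit the length-weight power law
#'
#' Ordinary least squares of `log10(EW)` on `log10(TL)` gives the
#' allometric fit `EW = a * TL^b`; isometric scaling corresponds to b = 3.
#' For the studied stock the fitted exponent was 3.01 (s.e. 0.07), which
#' justifies using TL^3 as a proxy for eviscerated weight.
#'
#' @param tl Total lengths, cm (> 0).
#' @param ew Eviscerated weights, g (> 0).
#' @return A list of class `allometry_fit` with `a`, `b`, `se_b`, `r2`,
#'   `n` and the underlying `lm` as `fit`.  With exactly two points the
#'   fit interpolates and `se_b` is `NA` (flagged by a warning).
#' @export
#' @examples
#' f <- fit_length_weight_power(c(40, 60, 80), 0.01 * c(40, 60, 80)^3)
#' f$b   # 3
#' f$r2  # 1
fit_length_weight_power <- function(tl, ew) {
  stopifnot(length(tl) == length(ew))
  if (length(tl) < 2) stop("need at least two pairs", call. = FALSE)
  if (any(tl <= 0) || any(ew <= 0)) {
    stop("lengths and weights must be positive", call. = FALSE)
  }
  if (length(tl) == 2) {
    warning("two points: exact interpolation, se_b undefined", call. = FALSE)
  }
  fit <- stats::lm(log10(ew) ~ log10(tl))
  co <- summary(fit)$coefficients
  structure(list(a = 10^co[1, 1], b = co[2, 1],
                 se_b = if (length(tl) > 2) co[2, 2] else NA_real_,
                 r2 = summary(fit)$r.squared, n = length(tl), fit = fit),
            class = "allometry_fit")
}

#' Length-standardized stage oocyte number
#'
#' `NO / TL^3`, in oocytes per cm^3 of cubed body length - usable as a
#' body-size correction because eviscerated weight scales isometrically
#' with length.
#'
#' @param no Stage oocyte number (>= 0).
#' @param tl Total length, cm (> 0).
#' @return Relative oocyte number, oocytes cm^-3.
#' @export
#' @examples
#' tl_based_no(2.376e8, 60)  # 1100
tl_based_no <- function(no, tl) {
  stopifnot(all(tl > 0), all(no >= 0))
  no / tl^3
}

#' Weight-standardized stage oocyte number
#'
#' `NO / EW`, oocytes per gram of eviscerated body weight; retained as a
#' cross-validation of the length-based route on females where EW was
#' recorded.  Missing EW yields a missing result, not an error.
#'
#' @param no Stage oocyte number (>= 0).
#' @param ew Eviscerated weight, g (> 0 or `NA`).
#' @return Relative oocyte number, oocytes g^-1 (NA where EW is missing).
#' @export
ew_based_no <- function(no, ew) {
  stopifnot(all(no >= 0))
  if (any(!is.na(ew) & ew <= 0)) {
    stop("eviscerated weight must be positive", call. = FALSE)
  }
  ifelse(is.na(ew), NA_real_, no / ew)
}

#' Model gonad weight by phase and length
#'
#' Least squares of formalin-fixed gonad weight on ovarian phase
#' (categorical), total length and their interaction:
#' `GWf ~ MAT + TL + MAT:TL`.  With a single phase the model reduces to a
#' simple regression on length.  The interaction F-statistic tests slope
#' homogeneity across phases.
#'
#' @param records Data frame with columns `GWf_g`, `TL_cm`, `MAT`.
#' @param min_per_phase Minimum females per phase (default 3).
#' @return A list of class `gw_model` with `fit`, `coefficients` (per
#'   phase: intercept and slope), `adj_r2`, `interaction_F`,
#'   `interaction_p` (both `NA` for a single phase).
#' @export
fit_gw_model <- function(records, min_per_phase = 3) {
  stopifnot(all(c("GWf_g", "TL_cm", "MAT") %in% names(records)))
  assert_phase(records$MAT)
  tab <- table(records$MAT)
  deficient <- names(tab)[tab < min_per_phase]
  if (length(deficient)) {
    stop("phase(s) with fewer than ", min_per_phase, " females: ",
         paste(deficient, collapse = ", "), call. = FALSE)
  }
  phases <- names(tab)
  if (length(phases) == 1) {
    fit <- stats::lm(GWf_g ~ TL_cm, data = records)
    co <- stats::coef(fit)
    coefs <- data.frame(phase = phases, intercept = co[1], slope = co[2],
                        row.names = NULL)
    return(structure(list(fit = fit, coefficients = coefs,
                          adj_r2 = summary(fit)$adj.r.squared,
                          interaction_F = NA_real_,
                          interaction_p = NA_real_),
                     class = "gw_model"))
  }
  records$MAT <- factor(records$MAT, levels = phases)
  fit <- stats::lm(GWf_g ~ MAT * TL_cm, data = records)
  add <- stats::lm(GWf_g ~ MAT + TL_cm, data = records)
  a <- stats::anova(add, fit)
  co <- stats::coef(fit)
  base_i <- co[["(Intercept)"]]; base_s <- co[["TL_cm"]]
  coefs <- data.frame(
    phase = phases,
    intercept = base_i + c(0, co[paste0("MAT", phases[-1])]),
    slope = base_s + c(0, co[paste0("MAT", phases[-1], ":TL_cm")]),
    row.names = NULL)
  structure(list(fit = fit, coefficients = coefs,
                 adj_r2 = summary(fit)$adj.r.squared,
                 interaction_F = a$F[2], interaction_p = a[["Pr(>F)"]][2]),
            class = "gw_model")
}

#' Predicted stage oocyte number from modelled gonad weight
#'
#' `pNO = OPD * pGWf`, where the predicted gonad weight comes from a
#' fitted [fit_gw_model()] evaluated at the female's phase and length.
#'
#' @param opd Stage packing densities, oocytes g^-1.
#' @param model A `gw_model`.
#' @param mat Ovarian phase token(s).
#' @param tl_cm Total length(s), cm.
#' @return Predicted oocyte numbers.
#' @export
predicted_no <- function(opd, model, mat, tl_cm) {
  stopifnot(inherits(model, "gw_model"), all(opd >= 0))
  n <- max(length(opd), length(mat), length(tl_cm))
  opd <- rep_len(opd, n); mat <- rep_len(mat, n); tl_cm <- rep_len(tl_cm, n)
  idx <- match(mat, model$coefficients$phase)
  if (anyNA(idx)) {
    stop("phase(s) absent from the fitted model: ",
         paste(unique(mat[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  pgwf <- model$coefficients$intercept[idx] +
    model$coefficients$slope[idx] * tl_cm
  opd * pgwf
}

#' Split females into half-open length classes
#'
#' Classes are `[lo, hi)`: a 64.9 cm female belongs to a 45-65 class, a
#' 65.0 cm female to the next one.  Lengths outside the boundary range are
#' flagged, not dropped silently.
#'
#' @param tl_cm Total lengths, cm.
#' @param boundaries Strictly increasing class boundaries, cm.
#' @return A list with `label` (factor of `"lo-hi"` labels, `NA` outside
#'   the range) and `out_of_range` (logical vector).
#' @export
#' @examples
#' length_class_split(c(64.9, 65, 40), c(45, 65, 85))$label
length_class_split <- function(tl_cm, boundaries) {
  stopifnot(length(boundaries) >= 2, all(diff(boundaries) > 0))
  labs <- paste0(boundaries[-length(boundaries)], "-", boundaries[-1])
  label <- cut(tl_cm, breaks = boundaries, labels = labs, right = FALSE)
  list(label = label, out_of_range = is.na(label))
}
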