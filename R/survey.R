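#' Default stage geometry for synthetic survey data
#'
#' Formalin-fixed (whole-mount scale) diameter and shape-factor
#' distributions per oocyte stage.  The real stage-specific size table of
#' any surveyed stock is data, not package constants; these values are
#' synthetic defaults with the right ordering and spacing for a hake-like
#' batch spawner (smallest previtellogenic oocytes a few tens of um,
#' medium-late vitellogenic oocytes a few hundred).
#'
#' @return Data frame: `stage`, `diameter_mean` (um), `diameter_cv`,
#'   `shape_factor_mean`, `shape_factor_cv`.
#' @export
default_stage_geometry <- function() {
  data.frame(
    stage = oocyte_stages(),
    diameter_mean = c(60, 70, 80, 100, 120, 140, 180, 240, 300, 360, 600),
    diameter_cv = 0.12,
    shape_factor_mean = 1.15,
    shape_factor_cv = 0.05,
    stringsAsFactors = FALSE)
}

# expected embedded-scale oocyte volume (um^3) per stage from a geometry
# table; `shrink` is the multiplicative diameter shrinkage applied by
# histological processing (volumes scale with its cube)
stage_expected_volumes <- function(geometry, shrink = 1) {
  vapply(seq_len(nrow(geometry)), function(i) {
    k <- geometry$shape_factor_mean[i]
    (pi / 6) * lnorm_third_moment(geometry$diameter_mean[i] * shrink,
                                  geometry$diameter_cv[i]) *
      8 * k / (1 + k)^3
  }, numeric(1))
}

#' Simulate a full survey data set (fish, grid counts, measurements)
#'
#' Produces the three delimited-text tables the pipeline reads, from a
#' synthetic cohort: per-female grid counts whose hit probabilities equal
#' the female's true stage volume fractions (sections shrink along with
#' the oocytes embedded in them, so section area fractions equal the
#' fixed-scale volume fractions), and axis measurements at the embedded
#' (shrunken) scale.  Grid hits are drawn multinomially per field - the
#' exact sampling model of point counting on a random section - which
#' keeps cohorts of arbitrary packing density cheap; fully geometric
#' rendering of packed spheres is available through
#' [simulate_population()] / [render_fields()] and is exercised by the
#' package tests at small scale.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param geometry Stage geometry table, see [default_stage_geometry()].
#' @param grid A [grid_spec()].
#' @param n_fields Fields counted per female.
#' @param field_cv Between-field lognormal CV on local oocyte density.
#' @param empty_fraction Expected fraction of grid points on empty space.
#' @param shrinkage True diameter shrinkage of histological processing
#'   (a [shrinkage_model()]; the default multiplicative 0.8 emulates
#'   paraffin embedding).  The matching correction model is its inverse.
#' @param n_per_stage Oocytes measured per stage and female.
#' @param seed Integer seed.
#' @return List with data frames `females`, `grid_counts`,
#'   `measurements`, plus `true` (long female x stage truth: `opd`, `vv`,
#'   `no`).
#' @export
simulate_survey_data <- function(cohort,
                                 geometry = default_stage_geometry(),
                                 grid = grid_b(), n_fields = 10,
                                 field_cv = 0.05, empty_fraction = 0.05,
                                 shrinkage = shrinkage_model(
                                   "multiplicative", factor = 0.8),
                                 n_per_stage = 10, seed = 1) {
  opd_long <- attr(cohort, "true_opd")
  if (is.null(opd_long)) stop("cohort carries no true_opd attribute",
                              call. = FALSE)
  ev <- stage_expected_volumes(geometry)
  names(ev) <- geometry$stage
  withr::with_seed(as.integer(seed), {
    gc_parts <- list(); ms_parts <- list(); tr_parts <- list()
    for (i in seq_len(nrow(cohort))) {
      fid <- cohort$female_id[i]
      rho <- suppressWarnings(specific_gravity(cohort$MAO[i]))
      tr <- opd_long[opd_long$female_id == fid, , drop = FALSE]
      # exclude HYO from the countable pool (unmeasurable in practice)
      tr <- tr[tr$stage != "HYO", , drop = FALSE]
      vv <- tr$opd * rho * ev[tr$stage] / UM3_PER_CM3
      if (sum(vv) > 0.85) {
        stop("infeasible female ", fid, ": stage volume fractions sum to ",
             round(sum(vv), 2), call. = FALSE)
      }
      for (f in seq_len(n_fields)) {
        h <- rlnorm_mean_cv(1, 1, field_cv)
        p_stage <- vv * h
        if (sum(p_stage) > 0.9) p_stage <- p_stage * 0.9 / sum(p_stage)
        p <- c(p_stage * (1 - empty_fraction), empty_fraction,
               max(0, 1 - sum(p_stage) * (1 - empty_fraction) -
                     empty_fraction))
        hits <- as.integer(stats::rmultinom(1, grid$n_points, p))
        comp <- c(tr$stage, "EMPTY", "OTHER")
        keep <- hits > 0 | comp == "OTHER"
        gc_parts[[length(gc_parts) + 1]] <- data.frame(
          female_id = fid, field_id = paste0(fid, "_", f),
          component = comp[keep], hits = hits[keep],
          n_points = grid$n_points, stringsAsFactors = FALSE)
      }
      gi <- match(tr$stage, geometry$stage)
      for (s in seq_len(nrow(tr))) {
        g <- geometry[gi[s], ]
        od <- rlnorm_mean_cv(n_per_stage, g$diameter_mean, g$diameter_cv)
        k <- pmax(1, rlnorm_mean_cv(n_per_stage, g$shape_factor_mean,
                                    g$shape_factor_cv))
        s_ax <- correct_shrinkage(2 * od / (1 + k), shrinkage,
                                  warn_identity = FALSE)
        ms_parts[[length(ms_parts) + 1]] <- data.frame(
          female_id = fid, stage = tr$stage[s], L_um = k * s_ax,
          S_um = s_ax, through_nucleus = TRUE, stringsAsFactors = FALSE)
      }
      tr_parts[[length(tr_parts) + 1]] <- data.frame(
        female_id = fid, stage = tr$stage, opd = tr$opd, vv = vv,
        no = tr$opd * cohort$GWf_g[i], stringsAsFactors = FALSE)
    }
    list(females = as.data.frame(cohort),
         grid_counts = do.call(rbind, gc_parts),
         measurements = do.call(rbind, ms_parts),
         true = do.call(rbind, tr_parts))
  })
}
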