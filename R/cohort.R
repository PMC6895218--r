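#' Default phase-dependent gonad-weight model for synthetic cohorts
#'
#' Linear models `GWf = intercept + slope * TL + noise` per ovarian phase,
#' with slopes that differ across phases (ripe ovaries grow much faster
#' with length than resting ones).  Values are synthetic but sized for a
#' medium-bodied gadiform: a 60 cm spawning-capable female carries a
#' gonad of roughly 45 g.
#'
#' @return Data frame with columns `phase`, `intercept`, `slope`, `sd`.
#' @export
default_gw_by_phase <- function() {
  data.frame(
    phase     = c("IM", "DV", "SC", "AS", "RS", "RT"),
    intercept = c(-4, -30, -50, -55, -18, -9),
    slope     = c(0.15, 1.0, 1.6, 1.8, 0.6, 0.3),
    sd        = c(0.5, 5, 8, 9, 3, 1.5),
    stringsAsFactors = FALSE)
}

#' Default monthly phase-frequency table for synthetic cohorts
#'
#' Probabilities of each ovarian phase by capture month, built from a
#' season calendar: spawning-capable and actively-spawning females are
#' enriched within seasons, developing females dominate at season starts,
#' and regressing/regenerating females appear towards and after season
#' ends.  Rows sum to 1.
#'
#' @param calendar A [season_calendar()].
#' @return A 12 x 6 matrix (months x phases).
#' @export
default_phase_frequencies <- function(calendar = default_season_calendar()) {
  phases <- ovarian_phases()
  first_prof <- c(IM = 0.08, DV = 0.35, SC = 0.22, AS = 0.13,
                  RS = 0.10, RT = 0.12)
  mid_prof <- c(IM = 0.08, DV = 0.22, SC = 0.30, AS = 0.25,
                RS = 0.08, RT = 0.07)
  last_prof <- c(IM = 0.08, DV = 0.20, SC = 0.25, AS = 0.22,
                 RS = 0.15, RT = 0.10)
  out <- matrix(NA_real_, 12, length(phases),
                dimnames = list(1:12, phases))
  for (m in 1:12) {
    b <- season_bounds(calendar, m)
    prof <- if (m == b$first) first_prof else
      if (m == b$last) last_prof else mid_prof
    out[m, ] <- prof[phases] / sum(prof)
  }
  out
}

#' Default true packing densities by stage and phase for synthetic cohorts
#'
#' Oocytes per gram of ovary for every stage under every ovarian phase.
#' The relative structure mirrors what packing-density studies find in
#' asynchronous batch spawners - the smallest previtellogenic stages
#' outnumber vitellogenic stages by an order of magnitude, secondary
#' stages peak at spawning capability and collapse after spawning, and
#' early and medium-late vitellogenic densities are comparable (the
#' premise of the batch-fecundity proxy).  Together with the default
#' stage geometry the densities put each detectable stage at a volume
#' fraction of roughly 0.01-0.06, and a spawning-capable 60 cm female
#' near the observed batch-fecundity range.
#'
#' @return A stages x phases matrix of packing densities (oocytes g^-1).
#' @export
default_opd_by_phase <- function() {
  stages <- oocyte_stages()
  phases <- ovarian_phases()
  m <- matrix(0, length(stages), length(phases),
              dimnames = list(stages, phases))
  #               IM      DV     SC     AS     RS     RT
  m["PVO1", ] <- c(65000, 40000, 38000, 38000, 45000, 55000)
  m["PVO2", ] <- c(65000, 40000, 38000, 38000, 45000, 55000)
  m["PVO3", ] <- c(60000, 35000, 33000, 33000, 42000, 50000)
  m["PVO4a", ] <- c(6000, 28000, 25000, 24000, 22000, 17000)
  m["PVO4b", ] <- c(600, 18000, 20000, 18000, 11000, 7500)
  m["PVO4c", ] <- c(0, 9000, 10000, 9500, 4500, 2800)
  m["CAO", ] <- c(0, 5300, 6000, 5700, 1400, 270)
  m["EVTO", ] <- c(0, 3100, 4000, 3700, 440, 90)
  m["VTO", ] <- c(0, 2600, 4000, 3700, 440, 90)
  m["MNO", ] <- c(0, 0, 500, 900, 0, 0)
  m["HYO", ] <- c(0, 0, 0, 700, 0, 0)
  m
}

#' Specification of a synthetic fish cohort
#'
#' World description for [simulate_cohort()]: cohort size, length range,
#' the eviscerated-weight allometry `EW = a * TL^b` with multiplicative
#' lognormal noise (sd on the log10 scale; the default 0.07 yields a
#' log-log r-squared near 0.96 over the default length range), the
#' phase-dependent gonad-weight model, the season calendar, monthly
#' phase frequencies, the stage x phase packing-density schedule with a
#' per-female lognormal CV, and the master seed.
#'
#' @param n_females Cohort size (default 157, the size of the validated
#'   subset in the emulated survey).
#' @param tl_range Total-length interval, cm (default 34-84).
#' @param allometry_a,allometry_b Power-law coefficients (b = 3.01 by
#'   default - isometric scaling as observed for the stock).
#' @param allometry_noise_sd Lognormal noise sd on the log10 scale.
#' @param gw_by_phase See [default_gw_by_phase()].
#' @param season_calendar See [default_season_calendar()].
#' @param phase_frequencies_by_month See [default_phase_frequencies()].
#' @param opd_by_phase See [default_opd_by_phase()].
#' @param opd_female_cv Per-female lognormal CV on true packing densities.
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_females = 157, tl_range = c(34, 84),
                        allometry_a = 0.0065, allometry_b = 3.01,
                        allometry_noise_sd = 0.07,
                        gw_by_phase = default_gw_by_phase(),
                        season_calendar = default_season_calendar(),
                        phase_frequencies_by_month =
                          default_phase_frequencies(season_calendar),
                        opd_by_phase = default_opd_by_phase(),
                        opd_female_cv = 0.25,
                        seed = 1) {
  stopifnot(n_females >= 1, length(tl_range) == 2, diff(tl_range) > 0,
            allometry_a > 0, allometry_b > 0, allometry_noise_sd >= 0,
            opd_female_cv >= 0)
  pf <- phase_frequencies_by_month
  stopifnot(nrow(pf) == 12, all(abs(rowSums(pf) - 1) < 1e-8))
  structure(list(n_females = as.integer(n_females), tl_range = tl_range,
                 allometry_a = allometry_a, allometry_b = allometry_b,
                 allometry_noise_sd = allometry_noise_sd,
                 gw_by_phase = gw_by_phase,
                 season_calendar = season_calendar,
                 phase_frequencies_by_month = pf,
                 opd_by_phase = opd_by_phase,
                 opd_female_cv = opd_female_cv,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# most advanced oocyte stage implied by an ovarian phase (synthetic rule)
mao_for_phase <- function(phase) {
  switch(phase,
         IM = sample(c("PVO3", "PVO4a"), 1),
         DV = sample(c("CAO", "EVTO"), 1),
         SC = "VTO", AS = "MNO", RS = "VTO", RT = "PVO4c")
}

#' Simulate a fish cohort with three spawning seasons
#'
#' Generates one year of female records: capture months uniform over the
#' year, phases drawn from the monthly frequency table, total length
#' uniform on the cohort range, eviscerated weight from the allometric
#' power law with multiplicative lognormal noise, whole weight a fixed
#' offset above it, gonad weight from the phase-dependent linear model,
#' a phase-implied most-advanced-oocyte stage, spawning markers for
#' recently spawning phases, and per-female true stage packing densities
#' from the stage x phase schedule with lognormal female-to-female
#' variation.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of female records (`female_id`, `month`, `TL_cm`,
#'   `WW_g`, `EW_g`, `GW_g`, `GWf_g`, `MAT`, `MAO`, `POF_present`) with
#'   attribute `true_opd`: a long data frame (`female_id`, `stage`,
#'   `opd`) of the per-female true packing densities.
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_spec(n_females = 20, seed = 7))
#' head(coh)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_females
    month <- sample(1:12, n, replace = TRUE)
    phases <- ovarian_phases()
    mat <- vapply(month, function(m) {
      sample(phases, 1, prob = spec$phase_frequencies_by_month[m, phases])
    }, character(1))
    # lengths recorded to 0.1 cm; weights derive from the recorded value
    tl <- round(stats::runif(n, spec$tl_range[1], spec$tl_range[2]), 1)
    ew <- spec$allometry_a * tl^spec$allometry_b *
      10^stats::rnorm(n, 0, spec$allometry_noise_sd)
    ww <- ew * stats::runif(n, 1.08, 1.16)
    gwp <- spec$gw_by_phase
    gi <- match(mat, gwp$phase)
    if (anyNA(gi)) stop("phase missing from gw_by_phase", call. = FALSE)
    gwf <- pmax(0.5, gwp$intercept[gi] + gwp$slope[gi] * tl +
                  stats::rnorm(n, 0, gwp$sd[gi]))
    gw <- gwf * stats::runif(n, 1.00, 1.05)  # fresh vs formalin-fixed
    mao <- vapply(mat, mao_for_phase, character(1))
    pof <- mat == "AS" |
      (mat == "RS" & stats::runif(n) < 0.8) |
      (mat == "RT" & stats::runif(n) < 0.3)
    fem <- data.frame(
      female_id = sprintf("F%03d", seq_len(n)), month = month,
      TL_cm = tl, WW_g = round(ww, 2), EW_g = round(ew, 2),
      GW_g = round(gw, 2), GWf_g = round(gwf, 2), MAT = mat, MAO = mao,
      POF_present = pof, stringsAsFactors = FALSE)
    sched <- spec$opd_by_phase
    longs <- lapply(seq_len(n), function(i) {
      base <- sched[, mat[i]]
      st <- rownames(sched)[base > 0]
      opd <- base[base > 0] *
        rlnorm_mean_cv(length(st), 1, spec$opd_female_cv)
      data.frame(female_id = fem$female_id[i], stage = st, opd = opd,
                 row.names = NULL, stringsAsFactors = FALSE)
    })
    structure(fem, true_opd = do.call(rbind, longs))
  })
}

#' True stage oocyte numbers of a synthetic cohort
#'
#' Multiplies the cohort's true packing densities by the formalin-fixed
#' gonad weights and attaches length, season and phase, producing the
#' long table [build_table1()] consumes.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param calendar A [season_calendar()] used for season assignment
#'   (with the phenology overrides of [assign_spawning_season()]).
#' @return Long data frame: `female_id`, `tl_cm`, `season`, `mat`,
#'   `stage`, `no`.
#' @export
true_stage_numbers <- function(cohort,
                               calendar = default_season_calendar()) {
  opd <- attr(cohort, "true_opd")
  if (is.null(opd)) stop("cohort carries no true_opd attribute",
                         call. = FALSE)
  i <- match(opd$female_id, cohort$female_id)
  data.frame(
    female_id = opd$female_id,
    tl_cm = cohort$TL_cm[i],
    season = assign_spawning_season(cohort$month[i], cohort$MAT[i],
                                    cohort$POF_present[i], calendar),
    mat = cohort$MAT[i],
    stage = opd$stage,
    no = opd$opd * cohort$GWf_g[i],
    stringsAsFactors = FALSE)
}
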