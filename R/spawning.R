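#' Spawning-season calendar
#'
#' Maps every month (1-12) to one of three spawning-season labels.  The
#' three seasons of the studied stock roughly correspond to winter-spring,
#' summer and autumn; exact month boundaries are a configuration choice.
#' Seasons must be contiguous arcs in cyclic month order.
#'
#' @param assignments Character vector of length 12 (month 1 = January)
#'   with values `"SS1"`, `"SS2"`, `"SS3"`.
#' @return An object of class `season_calendar`.
#' @export
#' @examples
#' default_season_calendar()
season_calendar <- function(assignments) {
  stopifnot(length(assignments) == 12)
  labs <- unique(assignments)
  if (!all(labs %in% c("SS1", "SS2", "SS3"))) {
    stop("season labels must be SS1, SS2, SS3", call. = FALSE)
  }
  # contiguity in cyclic order: each season has exactly one cyclic start
  nxt <- c(2:12, 1)
  for (s in labs) {
    starts <- sum(assignments != s & assignments[nxt] == s)
    if (starts != 1) {
      stop("season ", s, " is not a contiguous arc of months", call. = FALSE)
    }
  }
  structure(as.character(assignments), class = "season_calendar")
}

#' @rdname season_calendar
#' @export
default_season_calendar <- function() {
  # winter-spring (Dec-May), summer (Jun-Aug), autumn (Sep-Nov)
  season_calendar(c("SS1", "SS1", "SS1", "SS1", "SS1", "SS2",
                    "SS2", "SS2", "SS3", "SS3", "SS3", "SS1"))
}

# first/last month of the season containing `month`, in cyclic order
season_bounds <- function(calendar, month) {
  s <- calendar[month]
  prv <- c(12, 1:11); nxt <- c(2:12, 1)
  first <- which(calendar == s & calendar[prv] != s)
  last <- which(calendar == s & calendar[nxt] != s)
  list(season = s, first = first, last = last)
}

#' Monthly spawning fraction
#'
#' Proportion of actively spawning females among all sexually mature
#' females (every phase except immature) captured in a month.
#'
#' @param records Data frame with columns `month` and `MAT`.
#' @param month Month(s) to evaluate; default all months present.
#' @return Named numeric vector of spawning fractions in `[0, 1]`; months
#'   without mature females are `NA` with a warning.
#' @export
#' @examples
#' r <- data.frame(month = 3, MAT = c(rep("AS", 3), rep("SC", 7)))
#' spawning_fraction(r)  # 0.3
spawning_fraction <- function(records, month = NULL) {
  stopifnot(all(c("month", "MAT") %in% names(records)))
  assert_phase(records$MAT)
  month <- month %||% sort(unique(records$month))
  sf <- vapply(month, function(m) {
    r <- records[records$month == m, , drop = FALSE]
    mature <- r$MAT != "IM"
    if (!any(mature)) return(NA_real_)
    sum(r$MAT == "AS") / sum(mature)
  }, numeric(1))
  if (anyNA(sf)) {
    warning("month(s) without mature females: ",
            paste(month[is.na(sf)], collapse = ", "), call. = FALSE)
  }
  names(sf) <- month
  sf
}

#' @rdname spawning_fraction
#' @param sf Spawning fractions to band for plotting (bands `<10%`,
#'   `10-30%`, `30-50%`, `>50%`).
#' @export
sf_band <- function(sf) {
  cut(sf, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf),
      labels = c("<10%", "10-30%", "30-50%", ">50%"), right = FALSE)
}

#' Assign females to spawning seasons
#'
#' Default assignment is by capture month through the calendar, with two
#' phenology overrides: a regenerating or regressing female caught in the
#' first month of a season is assumed to have spawned earlier and is
#' assigned to the preceding season; a developing female without spawning
#' markers caught in the last month of a season is assumed to spawn later
#' and is assigned to the next season.  Season succession wraps at the
#' year boundary.
#'
#' @param month Capture month(s), 1-12.
#' @param mat Ovarian phase token(s).
#' @param pof_present Logical: spawning markers (postovulatory follicles)
#'   present.
#' @param calendar A [season_calendar()].
#' @return Character vector of season labels.
#' @export
#' @examples
#' cal <- default_season_calendar()
#' assign_spawning_season(6, "RT", FALSE, cal)  # SS1 (preceding)
#' assign_spawning_season(5, "DV", FALSE, cal)  # SS2 (next)
assign_spawning_season <- function(month, mat, pof_present,
                                   calendar = default_season_calendar()) {
  stopifnot(inherits(calendar, "season_calendar"),
            all(month %in% 1:12))
  assert_phase(mat)
  n <- max(length(month), length(mat), length(pof_present))
  month <- rep_len(month, n); mat <- rep_len(mat, n)
  pof_present <- rep_len(pof_present, n)
  order_ss <- c("SS1", "SS2", "SS3")
  vapply(seq_len(n), function(i) {
    b <- season_bounds(calendar, month[i])
    s <- b$season
    pos <- match(s, order_ss)
    if (mat[i] %in% c("RT", "RS") && month[i] == b$first) {
      return(order_ss[(pos - 2) %% 3 + 1])
    }
    if (mat[i] == "DV" && !isTRUE(pof_present[i]) && month[i] == b$last) {
      return(order_ss[pos %% 3 + 1])
    }
    s
  }, character(1))
}

#' Batch fecundity from vitellogenic oocyte numbers
#'
#' Early and medium-late vitellogenic oocytes each correspond, in
#' principle, to one upcoming batch, so batch fecundity is proxied by
#' their average: `BF = (NO_EVTO + NO_VTO) / 2`.
#'
#' @param no_evto,no_vto Stage oocyte numbers (>= 0, not both 0).
#' @return Batch fecundity in oocytes.
#' @export
#' @examples
#' batch_fecundity(300000, 312000)  # 306000
batch_fecundity <- function(no_evto, no_vto) {
  stopifnot(all(no_evto >= 0), all(no_vto >= 0))
  if (any(no_evto + no_vto == 0)) {
    stop("batch fecundity undefined: both vitellogenic numbers are zero",
         call. = FALSE)
  }
  (no_evto + no_vto) / 2
}

#' Potential number of batches held in one oocyte stage
#'
#' `(NO_i / BF) * 2`, unrounded.  The factor 2 encodes the mid-season
#' sampling assumption: with captures spread over the whole season, the
#' typical female has already released half of her batches, so the
#' standing stock represents half of the season's production.
#'
#' @param no_i Stage oocyte number (>= 0).
#' @param bf Batch fecundity (> 0).
#' @return Unrounded batch count.
#' @export
potential_batches <- function(no_i, bf) {
  if (any(bf <= 0)) stop("batch fecundity must be positive", call. = FALSE)
  stopifnot(all(no_i >= 0))
  2 * no_i / bf
}

#' Cumulative stage labels of the fecundity accounting
#' @return Character vector `VTO, +EVTO, +CA, +PVO4c, +PVO4b, +PVO4a,
#'   +PVO1-3`.
#' @export
cumulative_stage_labels <- function() {
  c("VTO", "+EVTO", "+CA", "+PVO4c", "+PVO4b", "+PVO4a", "+PVO1-3")
}

#' Accumulate stage oocyte numbers into the fecundity ladder
#'
#' Walks the stage order from the batch-ready medium-late vitellogenic
#' pool backwards to the pooled smallest previtellogenic stages,
#' accumulating potential fecundity `PF_m = 2 * sum(NO_i, i <= m)`
#' (unrounded) and the accumulated number of batches
#' `round(PF_m / BF)` (rounded half-up, once, at the cumulative level -
#' per-stage rounding does not reproduce the published worked examples).
#' Nucleus-migration and hydrated oocytes never enter the accumulation.
#'
#' @param stage_nos Named numeric vector of stage oocyte numbers; names
#'   are stage tokens.  `PVO1`, `PVO2`, `PVO3` may be supplied separately
#'   (they are pooled) or pre-pooled as `"PVO1-3"`.  A stage missing from
#'   the ladder is treated as 0 with a warning.
#' @param bf Batch fecundity (> 0).
#' @param interval_days,month_days Passed to [spawning_duration()].
#' @return Data frame with one row per cumulative stage: `stage_label`,
#'   `no`, `pf` (unrounded), `batches` (integer), `duration` (months,
#'   report-rounded), plus unrounded `batches_raw`, `duration_raw`.
#' @export
#' @examples
#' nos <- c(VTO = 100, EVTO = 100, CAO = 150, PVO4c = 200, PVO4b = 300,
#'          PVO4a = 500, `PVO1-3` = 1500)
#' accumulate_batches(nos, bf = 100)
accumulate_batches <- function(stage_nos, bf, interval_days = 4,
                               month_days = 30) {
  if (bf <= 0) stop("batch fecundity must be positive", call. = FALSE)
  nm <- names(stage_nos)
  if (is.null(nm)) stop("stage_nos must be named by stage", call. = FALSE)
  assert_stage(nm, allow_pooled = TRUE)
  x <- tapply(as.numeric(stage_nos), pool_pvo123(nm), sum)
  ladder <- accumulation_order()
  missing <- setdiff(ladder, names(x))
  if (length(missing)) {
    warning("stage(s) missing from accumulation, treated as 0: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  no <- ifelse(ladder %in% names(x), x[ladder], 0)
  pf <- 2 * cumsum(no)
  braw <- pf / bf
  b <- round_half_up(braw)
  data.frame(stage_label = cumulative_stage_labels(),
             no = as.numeric(no), pf = as.numeric(pf),
             batches = as.numeric(b),
             duration = spawning_duration(b, interval_days, month_days),
             batches_raw = as.numeric(braw),
             duration_raw = spawning_duration(braw, interval_days,
                                              month_days, round = FALSE),
             stringsAsFactors = FALSE)
}

#' Spawning-season duration from accumulated batches
#'
#' Duration in months is accumulated batches times the spawning interval
#' (typically one batch every four days) over a 30-day month.  Report
#' rounding follows the published convention: one decimal below ten
#' months, nearest integer from 9.95 upwards.
#'
#' @param batches Accumulated batch count (>= 0).
#' @param interval_days Days between successive batches.
#' @param month_days Days per month used for the conversion.
#' @param round Apply report rounding (default `TRUE`).
#' @return Duration in months.
#' @export
#' @examples
#' spawning_duration(62)  # 8.3
#' spawning_duration(80)  # 11
spawning_duration <- function(batches, interval_days = 4, month_days = 30,
                              round = TRUE) {
  stopifnot(all(batches >= 0), interval_days > 0, month_days > 0)
  m <- batches * interval_days / month_days
  if (!round) return(m)
  ifelse(m < 9.95, round_half_up(m, 1), round_half_up(m, 0))
}

#' Build the class-by-season fecundity report
#'
#' Reproduces the shape of the published spawning-dynamics table: females
#' in the developing, spawning-capable and actively-spawning phases are
#' split into total-length classes and spawning seasons; within each cell
#' the per-stage oocyte numbers are averaged over females, batch fecundity
#' is the average of the early- and medium-late-vitellogenic means, and
#' the cumulative ladder of [accumulate_batches()] is evaluated.  Cells
#' without data are emitted with `NA` entries.
#'
#' @param stage_numbers Long data frame with one row per female x stage:
#'   columns `female_id`, `tl_cm`, `season`, `mat`, `stage`, `no`.
#' @param tl_breaks Strictly increasing class boundaries in cm
#'   (half-open classes `[lo, hi)`); default `c(40, 50, 60, 70, 80)`.
#' @param interval_days,month_days Passed to [accumulate_batches()].
#' @return Data frame with columns `tl_class`, `season`, `bf`,
#'   `stage_label`, `no`, `pf`, `batches`, `duration`, `batches_raw`,
#'   `duration_raw`, `n_females`.
#' @export
build_table1 <- function(stage_numbers, tl_breaks = c(40, 50, 60, 70, 80),
                         interval_days = 4, month_days = 30) {
  need <- c("female_id", "tl_cm", "season", "mat", "stage", "no")
  miss <- setdiff(need, names(stage_numbers))
  if (length(miss)) {
    stop("stage-number table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stage_numbers) == 0) {
    return(data.frame(tl_class = character(0), season = character(0),
                      bf = numeric(0), stage_label = character(0),
                      no = numeric(0), pf = numeric(0), batches = numeric(0),
                      duration = numeric(0), batches_raw = numeric(0),
                      duration_raw = numeric(0), n_females = integer(0)))
  }
  stopifnot(all(diff(tl_breaks) > 0))
  d <- stage_numbers[stage_numbers$mat %in% c("DV", "SC", "AS"), ,
                     drop = FALSE]
  d$stage <- pool_pvo123(d$stage)
  cls <- length_class_split(d$tl_cm, tl_breaks)
  d$tl_class <- cls$label
  d <- d[!is.na(d$tl_class), , drop = FALSE]
  classes <- levels(cls$label)
  seasons <- c("SS1", "SS2", "SS3")
  rows <- list()
  for (cl in classes) {
    for (ss in seasons) {
      cell <- d[d$tl_class == cl & d$season == ss, , drop = FALSE]
      if (nrow(cell) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          tl_class = cl, season = ss, bf = NA_real_,
          stage_label = cumulative_stage_labels(), no = NA_real_,
          pf = NA_real_, batches = NA_real_, duration = NA_real_,
          batches_raw = NA_real_, duration_raw = NA_real_,
          n_females = 0L, stringsAsFactors = FALSE)
        next
      }
      # per-female stage totals (pooled PVOs summed within female), then
      # cell means across females; a stage absent in a female counts as 0
      fem <- unique(cell$female_id)
      mean_no <- vapply(unique(c(accumulation_order(), "EVTO")),
        function(st) {
          per_fem <- vapply(fem, function(f) {
            sum(cell$no[cell$female_id == f & cell$stage == st])
          }, numeric(1))
          mean(per_fem)
        }, numeric(1))
      bf <- batch_fecundity(mean_no[["EVTO"]], mean_no[["VTO"]])
      acc <- accumulate_batches(mean_no[accumulation_order()], bf,
                                interval_days, month_days)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(tl_class = cl, season = ss, bf = bf,
                   stringsAsFactors = FALSE),
        acc, n_females = length(fem))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Size ratio of season-averaged potential fecundity
#'
#' Ratio of the potential fecundity of two length classes at a given
#' cumulative stage, each first averaged over the seasons in which the
#' class has data.
#'
#' @param report A [build_table1()] result (or any data frame with
#'   `tl_class`, `season`, `stage_label`, `pf`).
#' @param class_a,class_b Length-class labels (numerator, denominator).
#' @param cumulative_stage A [cumulative_stage_labels()] entry.
#' @return The ratio (numeric scalar).
#' @export
size_ratio_summary <- function(report, class_a, class_b,
                               cumulative_stage = "+PVO1-3") {
  pick <- function(cl) {
    r <- report[report$tl_class == cl &
                  report$stage_label == cumulative_stage &
                  is.finite(report$pf), , drop = FALSE]
    if (nrow(r) == 0) stop("no data for class ", cl, call. = FALSE)
    r
  }
  a <- pick(class_a); b <- pick(class_b)
  if (!length(intersect(a$season, b$season))) {
    stop("classes share no season with data", call. = FALSE)
  }
  mean(a$pf) / mean(b$pf)
}

#' Regress potential fecundity proxies on body length
#'
#' Least-squares fit of a per-female oocyte-number sum (e.g. the
#' PVO4b-to-VTO pool taken as the potential-fecundity proxy) on total
#' length with spawning season as a factor.  Returns the slope, its
#' p-value, and an F-test of the season factor.
#'
#' @param data Data frame with columns `tl_cm`, `season`, `no`.
#' @return List with `fit` (the `lm`), `slope`, `slope_p`, `season_p`.
#' @export
fecundity_vs_length <- function(data) {
  stopifnot(all(c("tl_cm", "season", "no") %in% names(data)))
  if (length(unique(data$tl_cm)) < 3) {
    stop("need data at three or more lengths", call. = FALSE)
  }
  multi_season <- length(unique(data$season)) > 1
  fit <- if (multi_season) {
    stats::lm(no ~ tl_cm + factor(season), data = data)
  } else {
    stats::lm(no ~ tl_cm, data = data)
  }
  sm <- summary(fit)$coefficients
  season_p <- NA_real_
  if (multi_season) {
    a <- stats::anova(stats::lm(no ~ tl_cm, data = data), fit)
    season_p <- a[["Pr(>F)"]][2]
  }
  list(fit = fit, slope = sm["tl_cm", "Estimate"],
       slope_p = sm["tl_cm", "Pr(>|t|)"], season_p = season_p)
}
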