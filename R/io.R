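#' File schemas
#'
#' All tables are comma-delimited text with a header row, months as
#' integers 1-12, stages and phases as fixed uppercase tokens, and
#' missing values as empty fields.
#'
#' * `females.csv`: `female_id, month, TL_cm, WW_g, EW_g, GW_g, GWf_g,
#'   MAT, MAO, POF_present`
#' * `grid_counts.csv`: `female_id, field_id, component, hits, n_points`
#' * `measurements.csv`: `female_id, stage, L_um, S_um, through_nucleus`
#'
#' @name file-schemas
#' @keywords internal
NULL

female_columns <- function() {
  c("female_id", "month", "TL_cm", "WW_g", "EW_g", "GW_g", "GWf_g",
    "MAT", "MAO", "POF_present")
}

check_header <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

#' Read and validate the pipeline input tables
#'
#' Reads the three delimited tables, checks headers and token
#' vocabularies (unknown stage or phase tokens are a hard error listing
#' the offenders), collects row-level numeric violations with their line
#' numbers, warns about them and returns the valid rows.
#'
#' @param females_path,grid_counts_path,measurements_path File paths;
#'   `grid_counts_path` and `measurements_path` may be `NULL` when only
#'   fish records are needed.
#' @return List with elements `females`, `grid_counts`, `measurements`
#'   (the latter two `NULL` when not requested).
#' @export
read_tables <- function(females_path, grid_counts_path = NULL,
                        measurements_path = NULL) {
  fem <- utils::read.csv(females_path, stringsAsFactors = FALSE)
  check_header(fem, female_columns(), "females")
  assert_phase(fem$MAT)
  assert_stage(fem$MAO, allow_pooled = TRUE)
  bad <- which(!(fem$month %in% 1:12) | !(fem$TL_cm > 0) |
                 !(is.na(fem$GWf_g) | fem$GWf_g > 0))
  if (length(bad)) {
    warning("females: dropped invalid row(s) at line(s) ",
            paste(bad + 1, collapse = ", "),
            " (month outside 1-12, TL <= 0 or GWf <= 0)", call. = FALSE)
    fem <- fem[-bad, , drop = FALSE]
  }
  fem$POF_present <- as.logical(fem$POF_present)
  gc <- NULL
  if (!is.null(grid_counts_path)) {
    gc <- utils::read.csv(grid_counts_path, stringsAsFactors = FALSE)
    check_header(gc, c("female_id", "field_id", "component", "hits",
                       "n_points"), "grid counts")
    bad <- setdiff(unique(gc$component), section_components())
    if (length(bad)) {
      stop("grid counts: unknown component token(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    validate_field_counts(gc)
  }
  ms <- NULL
  if (!is.null(measurements_path)) {
    ms <- utils::read.csv(measurements_path, stringsAsFactors = FALSE)
    check_header(ms, c("female_id", "stage", "L_um", "S_um",
                       "through_nucleus"), "measurements")
    assert_stage(ms$stage, allow_pooled = TRUE)
    ms$through_nucleus <- as.logical(ms$through_nucleus)
    bad <- which(!(ms$S_um > 0) | ms$L_um < ms$S_um)
    if (length(bad)) {
      warning("measurements: dropped invalid row(s) at line(s) ",
              paste(bad + 1, collapse = ", "), " (need L >= S > 0)",
              call. = FALSE)
      ms <- ms[-bad, , drop = FALSE]
    }
  }
  list(females = fem, grid_counts = gc, measurements = ms)
}

# atomic CSV write: temp file in the target directory, then rename
write_table <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE, na = "")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a simulated survey data set to a directory
#'
#' @param survey A [simulate_survey_data()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(survey$females, file.path(dir, "females.csv"))
  write_table(survey$grid_counts, file.path(dir, "grid_counts.csv"))
  write_table(survey$measurements, file.path(dir, "measurements.csv"))
  if (!is.null(survey$true)) {
    write_table(survey$true, file.path(dir, "true_values.csv"))
  }
  invisible(dir)
}

#' Pipeline configuration
#'
#' Gathers every tunable of the pipeline in one validated object.
#'
#' @param grid A [grid_spec()].
#' @param correction Shrinkage-correction model applied to measured
#'   diameters (a [shrinkage_model()]; the identity default warns).
#' @param constant_mode Constant mode of the packing-density formula.
#' @param calendar A [season_calendar()].
#' @param interval_days,month_days Spawning-duration parameters.
#' @param tl_breaks Length-class boundaries for the fecundity report.
#' @param min_fields,min_oocytes Advisory minimum sample sizes from the
#'   pilot trials (7 fields, 10 oocytes per stage).
#' @param seed Master seed for any stochastic step.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid = grid_b(),
                            correction = shrinkage_model("identity"),
                            constant_mode = c("printed", "exact"),
                            calendar = default_season_calendar(),
                            interval_days = 4, month_days = 30,
                            tl_breaks = c(40, 50, 60, 70, 80),
                            min_fields = 7, min_oocytes = 10,
                            seed = 1) {
  constant_mode <- match.arg(constant_mode)
  stopifnot(inherits(grid, "grid_spec"),
            inherits(correction, "shrinkage_model"),
            inherits(calendar, "season_calendar"),
            interval_days > 0, month_days > 0, all(diff(tl_breaks) > 0))
  structure(list(grid = grid, correction = correction,
                 constant_mode = constant_mode, calendar = calendar,
                 interval_days = interval_days, month_days = month_days,
                 tl_breaks = tl_breaks, min_fields = min_fields,
                 min_oocytes = min_oocytes, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Per-female stage density estimation from raw tables
#'
#' For every female and every oocyte stage scored in her grid counts:
#' pooled Delesse volume fraction, mean shape factor and volume-based
#' diameter from through-nucleus measurements, shrinkage correction,
#' specific gravity from the most advanced oocyte stage, packing density
#' and whole-ovary oocyte number.
#'
#' @param females,grid_counts,measurements Validated tables, see
#'   [read_tables()].
#' @param config A [pipeline_config()].
#' @return Long data frame: one row per female x stage with `vv`, `k`,
#'   `codv`, `rho`, `opd`, `no`, `reason`.
#' @export
estimate_stage_densities <- function(females, grid_counts, measurements,
                                     config = pipeline_config()) {
  parts <- lapply(seq_len(nrow(females)), function(i) {
    fid <- females$female_id[i]
    cnt <- grid_counts[grid_counts$female_id == fid, , drop = FALSE]
    if (nrow(cnt) == 0) return(NULL)
    n_fields <- length(unique(cnt$field_id))
    if (n_fields < config$min_fields) {
      warning("female ", fid, ": only ", n_fields,
              " fields (advisory minimum ", config$min_fields, ")",
              call. = FALSE)
    }
    stages <- intersect(unique(cnt$component), oocyte_stages())
    if (length(stages) == 0) return(NULL)
    vv <- vapply(stages, function(st) volume_fraction(cnt, st), numeric(1))
    k <- vapply(stages, function(st) {
      suppressWarnings(shape_factor(measurements, st, fid,
                                    min_n = config$min_oocytes))
    }, numeric(1))
    odv <- vapply(stages, function(st) {
      suppressWarnings(volume_based_diameter(measurements, st, fid,
                                             min_n = config$min_oocytes))
    }, numeric(1))
    codv <- ifelse(is.na(odv), NA_real_,
                   correct_shrinkage(ifelse(is.na(odv), 1, odv),
                                     config$correction,
                                     warn_identity = FALSE))
    st_tab <- stage_table(
      data.frame(stage = stages, vv = vv, k = k, codv = codv,
                 stringsAsFactors = FALSE),
      mao = females$MAO[i], gwf = females$GWf_g[i],
      constant_mode = config$constant_mode)
    cbind(female_id = fid, st_tab, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' Reads (or accepts) the three input tables and produces stage
#' densities, the three standardized oocyte-number variants, spawning
#' phenology, the class-by-season fecundity report, and a run manifest.
#' Deterministic given the configuration seed.
#'
#' @param tables A list as returned by [read_tables()] or
#'   [simulate_survey_data()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all outputs are
#'   written as CSV plus a key-value `manifest.txt`.
#' @return List with `stage_densities`, `standardized`, `allometry`,
#'   `gw_model`, `phenology`, `report`, `manifest`.
#' @export
run_pipeline <- function(tables, config = pipeline_config(),
                         out_dir = NULL) {
  fem <- tables$females
  dens <- estimate_stage_densities(fem, tables$grid_counts,
                                   tables$measurements, config)
  i <- match(dens$female_id, fem$female_id)
  allo <- with(fem[!is.na(fem$EW_g) & !is.na(fem$TL_cm), ],
               fit_length_weight_power(TL_cm, EW_g))
  gwm <- tryCatch(fit_gw_model(fem), error = function(e) NULL)
  std <- data.frame(
    female_id = dens$female_id, stage = dens$stage, no = dens$no,
    no_tl = ifelse(is.na(dens$no), NA_real_,
                   tl_based_no(pmax(dens$no, 0), fem$TL_cm[i])),
    no_ew = ifelse(is.na(dens$no), NA_real_,
                   ew_based_no(pmax(dens$no, 0), fem$EW_g[i])),
    pno = if (is.null(gwm)) NA_real_ else
      ifelse(is.na(dens$opd), NA_real_,
             predicted_no(pmax(dens$opd, 0), gwm, fem$MAT[i],
                          fem$TL_cm[i])),
    stringsAsFactors = FALSE)
  sf <- suppressWarnings(spawning_fraction(fem))
  season <- assign_spawning_season(fem$month, fem$MAT, fem$POF_present,
                                   config$calendar)
  phen <- list(spawning_fraction = data.frame(month = as.integer(names(sf)),
                                              sf = as.numeric(sf)),
               seasons = data.frame(female_id = fem$female_id,
                                    season = season,
                                    stringsAsFactors = FALSE))
  nos <- data.frame(
    female_id = dens$female_id, tl_cm = fem$TL_cm[i],
    season = season[i], mat = fem$MAT[i], stage = dens$stage,
    no = dens$no, stringsAsFactors = FALSE)
  nos <- nos[!is.na(nos$no), , drop = FALSE]
  report <- build_table1(nos, config$tl_breaks, config$interval_days,
                         config$month_days)
  manifest <- c(
    package = as.character(utils::packageVersion("opdensity")),
    seed = config$seed, constant_mode = config$constant_mode,
    grid_points = config$grid$n_points,
    correction = config$correction$label,
    interval_days = config$interval_days, month_days = config$month_days,
    n_females = nrow(fem),
    config_checksum = sum(utf8ToInt(paste(deparse(unclass(config)),
                                          collapse = ""))))
  out <- list(stage_densities = dens, standardized = std, allometry = allo,
              gw_model = gwm, phenology = phen, report = report,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(dens, file.path(out_dir, "stage_densities.csv"))
    write_table(std, file.path(out_dir, "standardized.csv"))
    write_table(phen$spawning_fraction, file.path(out_dir, "phenology.csv"))
    write_table(phen$seasons, file.path(out_dir, "seasons.csv"))
    rep_round <- report[, c("tl_class", "season", "stage_label", "bf",
                            "pf", "batches", "duration", "n_females")]
    write_table(rep_round, file.path(out_dir, "report_table1.csv"))
    write_table(report, file.path(out_dir, "report_unrounded.csv"))
    writeLines(paste(names(manifest), manifest, sep = "="),
               file.path(out_dir, "manifest.txt"))
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: opdensity <subcommand> [options]",
    "",
    "subcommands:",
    "  simulate    --seed INT --out DIR [--n-females INT]",
    "  stereology  --in DIR --out FILE",
    "  opd         --in DIR --out FILE [--correction-factor X]",
    "              [--constant-mode printed|exact]",
    "  standardize --in DIR --out FILE [--correction-factor X]",
    "  dynamics    --in DIR --out FILE",
    "  report      --in DIR --out DIR [--correction-factor X]",
    sep = "\n")
}

cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    if (i == length(args)) stop("missing value for ", a, call. = FALSE)
    out[[substring(a, 3)]] <- args[i + 1]
    i <- i + 2
  }
  out
}

cli_config <- function(opt) {
  correction <- if (!is.null(opt[["correction-factor"]])) {
    shrinkage_model("multiplicative",
                    factor = as.numeric(opt[["correction-factor"]]))
  } else {
    shrinkage_model("identity")
  }
  pipeline_config(
    correction = correction,
    constant_mode = opt[["constant-mode"]] %||% "printed",
    seed = as.integer(opt[["seed"]] %||% 1))
}

#' Command-line entry point
#'
#' Subcommand dispatcher intended to be called from an `Rscript` wrapper
#' (see `inst/exec/opdensity`).  Never quits R itself; returns the exit
#' status so it can be tested in-process.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly (0 on success).
#' @export
opd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (length(args) == 0) {
      message(cli_usage())
      return(invisible(2L))
    }
    sub <- args[1]
    opt <- cli_args(args[-1])
    load_tables <- function() {
      dir <- opt[["in"]]
      if (is.null(dir)) stop("--in DIR is required", call. = FALSE)
      read_tables(file.path(dir, "females.csv"),
                  file.path(dir, "grid_counts.csv"),
                  file.path(dir, "measurements.csv"))
    }
    switch(sub,
      simulate = {
        if (is.null(opt[["out"]])) stop("--out DIR is required",
                                        call. = FALSE)
        seed <- as.integer(opt[["seed"]] %||% 1)
        n <- as.integer(opt[["n-females"]] %||% 40)
        message("simulate: seed=", seed, " n_females=", n)
        coh <- simulate_cohort(cohort_spec(n_females = n, seed = seed))
        sv <- simulate_survey_data(coh, seed = split_seed(seed, 1))
        write_survey(sv, opt[["out"]])
        0L
      },
      stereology = ,
      opd = {
        tb <- load_tables()
        cfg <- cli_config(opt)
        dens <- suppressWarnings(
          estimate_stage_densities(tb$females, tb$grid_counts,
                                   tb$measurements, cfg))
        if (sub == "stereology") dens$opd <- dens$no <- NULL
        if (is.null(opt[["out"]])) stop("--out FILE is required",
                                        call. = FALSE)
        write_table(dens, opt[["out"]])
        0L
      },
      standardize = {
        tb <- load_tables()
        res <- suppressWarnings(run_pipeline(tb, cli_config(opt)))
        write_table(res$standardized, opt[["out"]])
        0L
      },
      dynamics = {
        tb <- load_tables()
        res <- suppressWarnings(run_pipeline(tb, cli_config(opt)))
        write_table(res$phenology$spawning_fraction, opt[["out"]])
        0L
      },
      report = {
        tb <- load_tables()
        suppressWarnings(run_pipeline(tb, cli_config(opt),
                                      out_dir = opt[["out"]]))
        0L
      },
      {
        message("unknown subcommand: ", sub, "\n", cli_usage())
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
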