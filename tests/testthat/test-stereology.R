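test_that("volume fractions pool hits over valid points", {
  cnt <- counts_row(1, c(VTO = 90, OTHER = 150, EMPTY = 40, OUTSIDE = 20))
  expect_equal(volume_fraction(cnt, "VTO"), 90 / 240)
  # saturated component
  full <- counts_row(1, c(CAO = 370))
  expect_equal(volume_fraction(full, "CAO"), 1.0)
  # pooled across unequal fields: ratio of sums, not mean of ratios
  two <- rbind(counts_row(1, c(VTO = 10, OTHER = 10, EMPTY = 280)),
               counts_row(2, c(VTO = 60, OTHER = 240)))
  expect_equal(volume_fraction(two, "VTO"), 70 / 320)
  expect_false(isTRUE(all.equal(volume_fraction(two, "VTO"),
                                mean(c(10 / 20, 60 / 300)))))
  # per-field ratios are available for diagnostics
  expect_equal(volume_fraction(two, "VTO", per_field = TRUE),
               c(10 / 20, 60 / 300))
  # zero valid points is an error
  void <- counts_row(1, c(EMPTY = 370))
  expect_error(volume_fraction(void, "VTO"), "zero valid")
})

test_that("component volume fractions sum to one in both modes", {
  cnt <- rbind(
    counts_row(1, c(VTO = 90, CAO = 30, BLOOD = 10, MISSING = 5,
                    OTHER = 105, EMPTY = 100, OUTSIDE = 30)),
    counts_row(2, c(VTO = 120, CAO = 20, OTHER = 180, EMPTY = 50)))
  tissue <- c("VTO", "CAO", "BLOOD", "MISSING", "OTHER")
  s_tissue <- sum(vapply(tissue, function(cc) volume_fraction(cnt, cc),
                         numeric(1)))
  expect_equal(s_tissue, 1)
  s_all <- sum(vapply(section_components(), function(cc) {
    volume_fraction(cnt, cc, mode = "accounting")
  }, numeric(1)))
  expect_equal(s_all, 1)
})

test_that("pooled grid estimates match the binomial oracle", {
  # 7 fields of 370 points at true Vv = 0.30 with 10% empty points:
  # the estimate is a binomial proportion over the valid points
  set.seed(99)
  reps <- replicate(50, {
    cnt <- do.call(rbind, lapply(1:7, function(f) {
      hits <- as.integer(stats::rmultinom(1, 370,
                                          c(0.27, 0.63, 0.10)))
      counts_row(f, c(VTO = hits[1], OTHER = hits[2], EMPTY = hits[3]))
    }))
    volume_fraction(cnt, "VTO")
  })
  se <- sqrt(0.3 * 0.7 / (370 * 0.9 * 7))
  expect_lt(abs(mean(reps) - 0.30), 3 * se / sqrt(50))
  expect_true(all(abs(reps - 0.30) < 5 * se))
})

test_that("malformed count tables are rejected", {
  bad <- data.frame(field_id = 1, component = "XX", hits = 370,
                    n_points = 370)
  expect_error(validate_field_counts(bad), "unknown section component")
  off <- counts_row(1, c(VTO = 100, OTHER = 100))
  off$n_points <- 370
  expect_error(validate_field_counts(off), "sum to n_points")
})

test_that("stabilization curves behave as defined", {
  # constant series: flat at zero, stable from the first field
  sc <- stabilization_curve(rep(4.2, 8))
  expect_equal(sc$deviation, rep(0, 8))
  expect_identical(sc$n_stable, 1L)
  # hand-computed two-point series
  sc2 <- stabilization_curve(c(0, 1))
  expect_equal(sc2$deviation, c(1, 0))
  # final deviation is exactly zero, always
  set.seed(1)
  x <- runif(10, 1, 2)
  expect_equal(stabilization_curve(x)$deviation[10], 0)
  # invariant to positive rescaling
  expect_equal(stabilization_curve(x)$deviation,
               stabilization_curve(7.3 * x)$deviation)
  # zero mean is undefined
  expect_error(stabilization_curve(c(-1, 1)), "mean is zero")
})

test_that("shape factors average through-nucleus axis ratios", {
  m <- rbind(sphere_measurements("VTO", 100),
             data.frame(female_id = "F1", stage = "VTO", L_um = 130,
                        S_um = 100, through_nucleus = TRUE))
  expect_warning(k <- shape_factor(m, "VTO"), "only 2")
  expect_equal(k, mean(c(1, 1.3)))
  # spheres give exactly 1
  sph <- sphere_measurements("CAO", rep(80, 10))
  expect_equal(shape_factor(sph, "CAO"), 1)
  # non-through-nucleus rows are excluded
  m2 <- rbind(sph, data.frame(female_id = "F1", stage = "CAO",
                              L_um = 200, S_um = 50,
                              through_nucleus = FALSE))
  expect_equal(shape_factor(m2, "CAO"), 1)
  # no eligible oocytes: NA with warning
  expect_warning(k0 <- shape_factor(sph, "VTO"), "no eligible")
  expect_true(is.na(k0))
})

test_that("volume-based diameters are cubic means", {
  expect_equal(volume_based_diameter(
    sphere_measurements("VTO", rep(100, 10)), "VTO"), 100)
  m <- sphere_measurements("VTO", c(80, 100, 120))
  expect_warning(odv <- volume_based_diameter(m, "VTO"), "only 3")
  expect_equal(odv, mean(c(80, 100, 120)^3)^(1 / 3))
  expect_equal(odv, 102.5986, tolerance = 1e-6)
  # single oocyte L = 120, S = 100: OD = ODv = 110
  one <- data.frame(female_id = "F1", stage = "VTO", L_um = 120,
                    S_um = 100, through_nucleus = TRUE)
  expect_warning(expect_equal(volume_based_diameter(one, "VTO"), 110))
  # power-mean inequality and monotonicity over random sets
  set.seed(5)
  for (i in 1:20) {
    od <- runif(10, 50, 400)
    ms <- sphere_measurements("CAO", od)
    v <- suppressWarnings(volume_based_diameter(ms, "CAO"))
    expect_gte(v, mean(od))
    bigger <- od; bigger[3] <- bigger[3] + 25
    v2 <- suppressWarnings(
      volume_based_diameter(sphere_measurements("CAO", bigger), "CAO"))
    expect_gte(v2, v)
  }
})

test_that("shrinkage correction models apply and invert", {
  expect_warning(x <- correct_shrinkage(100, shrinkage_model("identity")),
                 "NOT corrected")
  expect_equal(x, 100)
  m <- shrinkage_model("multiplicative", factor = 1.25)
  expect_equal(correct_shrinkage(80, m), 100)
  lin <- shrinkage_model("linear", intercept = 5, slope = 1.2)
  expect_equal(correct_shrinkage(100, lin), 125)
  expect_equal(
    correct_shrinkage(correct_shrinkage(100, lin),
                      invert_shrinkage_model(lin)), 100)
  # a model that drives diameters non-positive is a domain error
  neg <- shrinkage_model("linear", intercept = -500, slope = 1)
  expect_error(correct_shrinkage(100, neg), "non-positive")
})

test_that("correction models are ranked against whole-mount reference", {
  # truth: diameters shrank by 0.8, so numbers computed from uncorrected
  # diameters overestimate by 1/0.8^3; the true-inverse model must win
  set.seed(8)
  n <- 25
  bf_true <- runif(n, 1e5, 5e5)
  odv_meas <- runif(n, 200, 300)       # embedded scale
  no_unc <- bf_true / 0.8^3            # uncorrected estimate
  models <- list(shrinkage_model("identity"),
                 shrinkage_model("multiplicative", factor = 1.25,
                                 label = "paraffin"),
                 shrinkage_model("multiplicative", factor = 1.05,
                                 label = "resin"))
  rk <- compare_correction_models(models, no_unc, odv_meas, bf_true)
  expect_identical(rk$model[1], "paraffin")
  expect_lt(rk$mean_abs_rel_dev[1], 1e-10)
  expect_identical(attr(rk, "best")$label, "paraffin")
  # single model is trivially best; ties keep input order
  one <- compare_correction_models(models[2], no_unc, odv_meas, bf_true)
  expect_identical(nrow(one), 1L)
  tie <- compare_correction_models(
    list(shrinkage_model("multiplicative", factor = 1.25, label = "a"),
         shrinkage_model("multiplicative", factor = 1.25, label = "b")),
    no_unc, odv_meas, bf_true)
  expect_identical(tie$model, c("a", "b"))
  expect_error(
    compare_correction_models(models, NA_real_, NA_real_, NA_real_),
    "no females")
})

test_that("grid selection is conservative under disagreement", {
  expect_identical(grid_b()$n_points, 370L)
  expect_equal(grid_b()$probe_line_length, 65.7)
  expect_identical(grid_a()$n_points, 240L)
  # identical pilot estimates: the sparser grid suffices
  est <- rep(0.21, 10)
  ch <- select_grid(grid_a(), grid_b(), est, est)
  expect_identical(ch$n_points, 240L)
  expect_error(select_grid(grid_a(), grid_b(), est, est[-1]), "paired")

  # small-particle scenario: emulate the detection loss of a coarse
  # grid/magnification by dropping profiles below half its probe spacing,
  # which biases the sparse-grid estimate low; the denser grid must win
  p <- simulate_population(
    stage_population_spec("PVO2", 6e6, 25, diameter_cv = 0.15),
    ovary_mass = 0.01, seed = 40)
  fs <- section_field_spec(field_width = 900, field_height = 850,
                           n_fields = 10)
  f <- render_fields(p, fs, seed = 41)
  est_a <- vapply(seq_along(f), function(i) {
    fd <- f[[i]]
    kept <- fd[fd$radius_um >= grid_a()$probe_line_length / 2, ,
               drop = FALSE]
    kept <- make_field(kept, 900, 850)
    volume_fraction(count_grid_hits(kept, grid_spec(100, 77.1),
                                    seed = 500 + i), "PVO2")
  }, numeric(1))
  est_b <- vapply(seq_along(f), function(i) {
    volume_fraction(count_grid_hits(f[[i]], grid_spec(140, 65.7),
                                    seed = 600 + i), "PVO2")
  }, numeric(1))
  ch2 <- select_grid(grid_spec(100, 77.1), grid_spec(140, 65.7),
                     est_a, est_b)
  expect_identical(ch2$n_points, 140L)
})
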