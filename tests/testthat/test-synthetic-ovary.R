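test_that("population counts and volume fractions are exact", {
  # one stage: count = round(true_opd * mass)
  p <- simulate_population(
    stage_population_spec("VTO", 1000, 200, diameter_cv = 0),
    ovary_mass = 10, specific_gravity = 1.061, seed = 1)
  expect_identical(nrow(p), 10000L)
  # monodisperse spheres: closed-form Vv = N (pi/6) D^3 rho / (m * 1e12)
  vv_expected <- 10000 * (pi / 6) * 200^3 * 1.061 / (10 * 1e12)
  expect_equal(unname(attr(p, "stage_vv")["VTO"]), vv_expected,
               tolerance = 1e-12)
  expect_equal(vv_expected, 4.444e-3, tolerance = 1e-4)

  # two stages: counts in exact opd ratio
  p2 <- simulate_population(
    list(stage_population_spec("VTO", 1000, 150),
         stage_population_spec("CAO", 500, 100)),
    ovary_mass = 4, seed = 2)
  cnt <- attr(p2, "stage_counts")
  expect_identical(unname(cnt["VTO"] / cnt["CAO"]), 2)

  # determinism under a fixed seed
  p3 <- simulate_population(
    stage_population_spec("VTO", 1000, 150, diameter_cv = 0.1),
    ovary_mass = 1, seed = 7)
  p4 <- simulate_population(
    stage_population_spec("VTO", 1000, 150, diameter_cv = 0.1),
    ovary_mass = 1, seed = 7)
  expect_identical(p3$od_um, p4$od_um)
})

test_that("infeasible packing fractions are rejected", {
  expect_error(
    simulate_population(
      stage_population_spec("VTO", 20000, 400, diameter_cv = 0),
      ovary_mass = 1, specific_gravity = 1),
    "infeasible")
})

test_that("rendered profiles respect section geometry", {
  p <- simulate_population(
    stage_population_spec("VTO", 40000, 150, diameter_cv = 0.1),
    ovary_mass = 1, seed = 3)
  r_max <- max((3 * p$volume_um3 / (4 * pi))^(1 / 3))
  f <- render_fields(p, section_field_spec(n_fields = 3), seed = 4)
  expect_length(f, 3)
  for (fd in f) {
    expect_true(all(fd$radius_um <= r_max + 1e-9))
    expect_true(all(fd$radius_um > 0))
  }
  # determinism
  f2 <- render_fields(p, section_field_spec(n_fields = 3), seed = 4)
  expect_identical(f[[2]]$x_um, f2[[2]]$x_um)

  # an (effectively) empty population renders empty fields
  p0 <- simulate_population(
    stage_population_spec("VTO", 0.01, 150), ovary_mass = 1, seed = 5)
  expect_identical(nrow(p0), 0L)
  f0 <- render_fields(p0, section_field_spec(n_fields = 2), seed = 6)
  expect_identical(nrow(f0[[1]]), 0L)
})

test_that("grid hits classify every point exactly once", {
  # field fully covered by one stage
  full <- make_field(data.frame(x_um = 700, y_um = 650, radius_um = 5000,
                                stage = "CAO"))
  hits <- count_grid_hits(full, grid_b(), seed = 1)
  expect_identical(sum(hits$hits), 370L)
  expect_identical(hits$hits[hits$component == "CAO"], 370L)

  # empty field: everything is background tissue
  empty <- make_field(data.frame(x_um = numeric(0), y_um = numeric(0),
                                 radius_um = numeric(0),
                                 stage = character(0)))
  hits0 <- count_grid_hits(empty, grid_b(), seed = 2)
  expect_identical(hits0$hits[hits0$component == "OTHER"], 370L)

  # overlapping profiles: tie broken by nearest center
  two <- make_field(data.frame(x_um = c(600, 800), y_um = c(650, 650),
                               radius_um = c(5000, 5000),
                               stage = c("VTO", "CAO")))
  h2 <- count_grid_hits(two, grid_b(), seed = 3)
  expect_identical(sum(h2$hits), 370L)
  expect_setequal(h2$component, c("VTO", "CAO"))
})

test_that("grid estimate of a half-covered field is unbiased", {
  # a huge circle whose boundary is a near-vertical line through the
  # field center: true area fraction 0.5; binomial oracle over 200
  # seeded offsets, SE = sqrt(0.25 / 370) per field
  big <- 1e7
  half <- make_field(data.frame(x_um = 700 - big, y_um = 650,
                                radius_um = big, stage = "VTO"))
  est <- vapply(1:200, function(s) {
    h <- count_grid_hits(half, grid_b(), seed = s)
    volume_fraction(h, "VTO")
  }, numeric(1))
  se <- sqrt(0.25 / 370)
  expect_lt(abs(mean(est) - 0.5), 2 * se)
})

test_that("grid area fractions are Delesse-unbiased on packed sections", {
  # 200 small fields, monodisperse spheres at Vv = 0.30; the mean grid
  # estimate must sit within 3 binomial SE (n = points x fields) of truth
  vv_true <- 0.30
  od <- 80
  opd_true <- vv_true * 1e12 / (1.072 * (pi / 6) * od^3)
  p <- simulate_population(
    stage_population_spec("VTO", opd_true, od, diameter_cv = 0),
    ovary_mass = 0.05, specific_gravity = 1.072, seed = 10)
  expect_equal(unname(attr(p, "stage_vv")["VTO"]), vv_true,
               tolerance = 1e-3)
  fs <- section_field_spec(field_width = 700, field_height = 650,
                           n_fields = 200)
  g <- grid_spec(100, 60)
  f <- render_fields(p, fs, seed = 11)
  est <- vapply(seq_along(f), function(i) {
    volume_fraction(count_grid_hits(f[[i]], g, seed = 1000 + i), "VTO")
  }, numeric(1))
  se <- sqrt(vv_true * (1 - vv_true) / (100 * 200))
  expect_lt(abs(mean(est) - unname(attr(p, "stage_vv")["VTO"])), 3 * se)
})

test_that("simulated measurements carry shape and shrinkage exactly", {
  p <- simulate_population(
    stage_population_spec("VTO", 100, 100, diameter_cv = 0,
                          shape_factor_mean = 1, shape_factor_cv = 0),
    ovary_mass = 1, seed = 1)
  # identity shrinkage, spheres: L = S = OD
  m <- simulate_measurements(p, n_per_stage = 10, seed = 2)
  expect_identical(nrow(m), 10L)
  expect_equal(m$L_um, rep(100, 10))
  expect_equal(m$S_um, rep(100, 10))

  # multiplicative shrinkage 0.8: emitted diameter 80
  shr <- shrinkage_model("multiplicative", factor = 0.8)
  m2 <- simulate_measurements(p, n_per_stage = 5, shrinkage = shr, seed = 3)
  expect_equal((m2$L_um + m2$S_um) / 2, rep(80, 5))
  # the inverse model recovers the true dimensions exactly
  back <- correct_shrinkage(m2$S_um, invert_shrinkage_model(shr))
  expect_equal(back, rep(100, 5))

  # requesting an absent stage warns and skips
  expect_warning(
    out <- simulate_measurements(p, n_per_stage = 3, seed = 4,
                                 stages = c("VTO", "CAO")),
    "absent")
  expect_setequal(unique(out$stage), "VTO")

  # k > 1 populations emit L = k * S
  pk <- simulate_population(
    stage_population_spec("CAO", 100, 100, diameter_cv = 0,
                          shape_factor_mean = 1.3, shape_factor_cv = 0),
    ovary_mass = 1, seed = 5)
  mk <- simulate_measurements(pk, n_per_stage = 4, seed = 6)
  expect_equal(mk$L_um / mk$S_um, rep(1.3, 4))
  expect_equal((mk$L_um + mk$S_um) / 2, rep(100, 4))
})

test_that("synthetic cohorts obey their stated allometry", {
  # zero noise: the log-log slope is exactly b
  sp0 <- cohort_spec(n_females = 50, allometry_noise_sd = 0, seed = 21)
  coh0 <- simulate_cohort(sp0)
  f0 <- fit_length_weight_power(coh0$TL_cm, coh0$EW_g)
  # weights are recorded to 0.01 g, so the fit is exact to that precision
  expect_equal(f0$b, 3.01, tolerance = 1e-4)
  expect_equal(f0$r2, 1, tolerance = 1e-6)

  # default noise: b recovered within 2 se, r2 near 0.96
  coh <- simulate_cohort(cohort_spec(seed = 22))
  f <- fit_length_weight_power(coh$TL_cm, coh$EW_g)
  expect_lt(abs(f$b - 3.01), 2 * f$se_b)
  expect_gt(f$r2, 0.9)

  # structure: months cover the year, phases valid, truth attached
  expect_true(all(coh$month %in% 1:12))
  expect_true(all(coh$MAT %in% ovarian_phases()))
  truth <- attr(coh, "true_opd")
  expect_true(all(c("female_id", "stage", "opd") %in% names(truth)))
  expect_true(all(truth$opd > 0))

  # determinism
  coh2 <- simulate_cohort(cohort_spec(seed = 22))
  expect_identical(coh$TL_cm, coh2$TL_cm)
  expect_identical(attr(coh, "true_opd")$opd, attr(coh2, "true_opd")$opd)
})

test_that("the geometric pipeline recovers true packing densities", {
  # two stages at Vv ~ 0.10 and ~ 0.025; 7 fields x 370 points; mean
  # estimate over 12 seeded replicates within 10% of truth (per-replicate
  # noise at the smaller Vv is ~12-14% by binomial arithmetic alone)
  rho <- 1.072
  specs <- list(
    stage_population_spec("VTO", 5.5e5, 70, diameter_cv = 0.05),
    stage_population_spec("CAO", 7.3e5, 50, diameter_cv = 0.05))
  p <- simulate_population(specs, ovary_mass = 0.2,
                           specific_gravity = rho, seed = 30)
  vv_true <- attr(p, "stage_vv")
  expect_gt(min(vv_true), 0.02)
  shr <- shrinkage_model("multiplicative", factor = 0.8)
  corr <- invert_shrinkage_model(shr)
  seeds <- split_seed(31, 24)
  est <- sapply(1:12, function(r) {
    f <- render_fields(p, section_field_spec(n_fields = 7), seeds[r])
    cnt <- do.call(rbind, lapply(seq_along(f), function(i) {
      count_grid_hits(f[[i]], grid_b(),
                      seed = (seeds[12 + r] + i) %% 2147483646,
                      field_id = i)
    }))
    m <- simulate_measurements(p, n_per_stage = 30, shrinkage = shr,
                               seed = seeds[12 + r])
    vapply(c("VTO", "CAO"), function(st) {
      vv <- volume_fraction(cnt, st)
      k <- shape_factor(m, st, min_n = 10)
      codv <- correct_shrinkage(volume_based_diameter(m, st), corr)
      opd(vv, k, codv, rho, constant_mode = "exact")
    }, numeric(1))
  })
  for (st in c("VTO", "CAO")) {
    true_opd <- attr(p, "stage_counts")[st] / 0.2
    rel <- abs(mean(est[st, ]) - true_opd) / true_opd
    expect_lt(rel, 0.10)
  }
})
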