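#' Specification of one synthetic oocyte stage population
#'
#' Holds the ground-truth counterparts of the quantities the stereological
#' pipeline estimates: the true packing density (oocytes per gram of
#' ovary), the distribution of arithmetic diameters and of shape factors.
#' Diameters and shape factors are drawn from lognormal distributions
#' parameterized by mean and coefficient of variation; shape-factor draws
#' are truncated at 1 (prolate assumption).  The stage-specific diameter
#' table of any real species is survey data, not package constants; the
#' defaults used elsewhere in the package are declared synthetic.
#'
#' @param stage Stage token, see [oocyte_stages()].
#' @param true_opd True packing density, oocytes g^-1 (> 0).
#' @param diameter_mean Mean arithmetic diameter OD, um (> 0).
#' @param diameter_cv CV of the diameter distribution (>= 0).
#' @param shape_factor_mean Mean shape factor k = L/S (>= 1).
#' @param shape_factor_cv CV of the shape-factor distribution (>= 0).
#' @return An object of class `stage_population_spec`.
#' @export
stage_population_spec <- function(stage, true_opd, diameter_mean,
                                  diameter_cv = 0.1,
                                  shape_factor_mean = 1,
                                  shape_factor_cv = 0) {
  assert_stage(stage, allow_pooled = TRUE)
  stopifnot(true_opd > 0, diameter_mean > 0, diameter_cv >= 0,
            shape_factor_mean >= 1, shape_factor_cv >= 0)
  structure(list(stage = stage, true_opd = true_opd,
                 diameter_mean = diameter_mean, diameter_cv = diameter_cv,
                 shape_factor_mean = shape_factor_mean,
                 shape_factor_cv = shape_factor_cv),
            class = "stage_population_spec")
}

# expected single-oocyte volume (um^3) under a spec; the shape term is
# evaluated at the mean k (adequate for the small shape-factor CVs used)
expected_oocyte_volume <- function(spec) {
  k <- spec$shape_factor_mean
  (pi / 6) * lnorm_third_moment(spec$diameter_mean, spec$diameter_cv) *
    8 * k / (1 + k)^3
}

#' Generate a synthetic oocyte population for one ovary
#'
#' Materializes every oocyte of every requested stage: the per-stage count
#' is exactly `round(true_opd * ovary_mass)`, diameters and shape factors
#' are drawn per oocyte, and each oocyte's volume is the prolate-spheroid
#' volume `(pi/6) k S^3` expressed through its arithmetic diameter.  The
#' per-stage true volume fraction is the exact ratio of summed oocyte
#' volume to ovary volume (`ovary_mass / specific_gravity`).  Populations
#' whose total packing fraction exceeds `max_packing` (default 0.55) are
#' rejected: non-overlapping geometric placement cannot realize them.
#'
#' @param specs A `stage_population_spec` or list of them.
#' @param ovary_mass Ovary mass, g (> 0).
#' @param specific_gravity Ovary specific gravity, g cm^-3.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @param max_packing Feasibility cap on the total volume fraction.
#' @return An object of class `oocyte_population`: a data frame with one
#'   row per oocyte (`stage`, `od_um`, `k`, `volume_um3`) and attributes
#'   `stage_counts`, `stage_vv`, `ovary_mass`, `specific_gravity`,
#'   `ovary_volume_um3`, `number_density` (oocytes per um^3).
#' @export
#' @examples
#' p <- simulate_population(
#'   stage_population_spec("VTO", 1000, 200, diameter_cv = 0),
#'   ovary_mass = 10, specific_gravity = 1.061, seed = 1)
#' nrow(p)              # exactly 10000
#' attr(p, "stage_vv")  # about 4.44e-3
simulate_population <- function(specs, ovary_mass, specific_gravity = 1.061,
                                seed = NULL, max_packing = 0.55) {
  if (inherits(specs, "stage_population_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1 || is.list(specs),
            ovary_mass > 0, specific_gravity > 0)
  gen <- function() {
    counts <- vapply(specs, function(s) round(s$true_opd * ovary_mass),
                     numeric(1))
    parts <- lapply(seq_along(specs), function(i) {
      s <- specs[[i]]; n <- counts[i]
      if (n == 0) {
        return(data.frame(stage = character(0), od_um = numeric(0),
                          k = numeric(0)))
      }
      od <- rlnorm_mean_cv(n, s$diameter_mean, s$diameter_cv)
      k <- pmax(1, rlnorm_mean_cv(n, s$shape_factor_mean, s$shape_factor_cv))
      data.frame(stage = rep(s$stage, n), od_um = od, k = k)
    })
    oo <- do.call(rbind, parts)
    oo$volume_um3 <- spheroid_volume_od(oo$od_um, oo$k)
    oo
  }
  oo <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  v_ovary <- ovary_mass / specific_gravity * UM3_PER_CM3
  stages <- vapply(specs, function(s) s$stage, character(1))
  vv <- vapply(stages, function(st) {
    sum(oo$volume_um3[oo$stage == st]) / v_ovary
  }, numeric(1))
  names(vv) <- stages
  if (sum(vv) > max_packing) {
    stop(sprintf(
      "infeasible population: total packing fraction %.3f exceeds %.2f",
      sum(vv), max_packing), call. = FALSE)
  }
  counts <- vapply(stages, function(st) sum(oo$stage == st), numeric(1))
  structure(oo,
            stage_counts = counts, stage_vv = vv,
            ovary_mass = ovary_mass, specific_gravity = specific_gravity,
            ovary_volume_um3 = v_ovary,
            number_density = nrow(oo) / v_ovary,
            class = c("oocyte_population", "data.frame"))
}

#' Specification of virtual micrograph fields
#'
#' Geometry of the simulated histological sampling: a rectangular window
#' (one micrograph field), the thickness of the 3D slab oocytes are packed
#' into before sectioning, the number of fields, and an extra between-field
#' lognormal CV on the local oocyte density emulating real within-ovary
#' heterogeneity.  `slab_thickness = NULL` picks a slab three maximal
#' diameters thick, deep enough that the cutting plane sits in the
#' homogeneous interior of the packing.
#'
#' @param field_width,field_height Field window, um (> 0).  The defaults
#'   fit the 370-point, 65.7 um counting grid with room for a random
#'   offset.
#' @param slab_thickness Slab depth for sphere centers, um, or `NULL`.
#' @param n_fields Number of fields per ovary (>= 1; ten in the emulated
#'   protocol).
#' @param field_heterogeneity_cv Between-field CV on local density (>= 0).
#' @return An object of class `section_field_spec`.
#' @export
section_field_spec <- function(field_width = 1400, field_height = 1300,
                               slab_thickness = NULL, n_fields = 10,
                               field_heterogeneity_cv = 0) {
  stopifnot(field_width > 0, field_height > 0, n_fields >= 1,
            field_heterogeneity_cv >= 0,
            is.null(slab_thickness) || slab_thickness > 0)
  structure(list(field_width = field_width, field_height = field_height,
                 slab_thickness = slab_thickness,
                 n_fields = as.integer(n_fields),
                 field_heterogeneity_cv = field_heterogeneity_cv),
            class = "section_field_spec")
}

# random sequential adsorption of spheres in a PERIODIC box; returns
# centers in [0, L) per axis.  Periodic boundaries keep the process
# exactly translation invariant, so each accepted center is marginally
# uniform and planar sections are unbiased (a hard-walled box enriches
# density near the walls and depletes the interior).  Radii are placed
# largest-first; candidates are proposed in vectorized batches and the
# first non-overlapping one is accepted.
rsa_pack <- function(radii, lx, ly, lz, batch = 64, max_batches = 600) {
  n <- length(radii)
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n); ar <- numeric(n)
  ord <- order(radii, decreasing = TRUE)
  pdist2 <- function(c1, a1, l) {
    d <- abs(outer(c1, a1, "-"))
    pmin(d, l - d)^2
  }
  placed <- 0L
  for (i in ord) {
    ri <- radii[i]
    done <- FALSE
    for (b in seq_len(max_batches)) {
      cx <- stats::runif(batch, 0, lx)
      cy <- stats::runif(batch, 0, ly)
      cz <- stats::runif(batch, 0, lz)
      if (placed == 0L) {
        pick <- 1L
      } else {
        j <- seq_len(placed)
        thr2 <- (ri + ar[j])^2
        d2 <- pdist2(cx, ax[j], lx) + pdist2(cy, ay[j], ly) +
          pdist2(cz, az[j], lz)
        ok <- rowSums(sweep(d2, 2, thr2, "<")) == 0
        if (!any(ok)) next
        pick <- which(ok)[1]
      }
      placed <- placed + 1L
      ax[placed] <- cx[pick]; ay[placed] <- cy[pick]
      az[placed] <- cz[pick]; ar[placed] <- ri
      done <- TRUE
      break
    }
    if (!done) {
      stop("infeasible field packing: sphere placement failed after ",
           batch * max_batches, " candidates (local density too high)",
           call. = FALSE)
    }
  }
  list(x = ax, y = ay, z = az, r = ar, index = ord)
}

#' Render virtual histological fields from a population
#'
#' Each field is produced by packing a Poisson number of oocytes (drawn
#' with replacement from the population, at the population's number
#' density, optionally modulated by between-field heterogeneity) into a 3D
#' slab by random sequential adsorption - spheres of volume equal to the
#' oocyte's spheroid volume, no overlaps - and cutting the slab with the
#' plane z = 0.  A sphere of radius R cut at distance d from its center
#' leaves a circular profile of radius `sqrt(R^2 - d^2)`.  The slab is
#' periodic in all three directions (no walls, hence no wall-induced
#' density gradients) and extends one maximal radius beyond the field
#' window laterally, so wrapped periodic images can never reach the
#' window; the expected per-field area fraction of each stage then equals
#' its true volume fraction exactly (Delesse).
#'
#' @param population An [simulate_population()] result.
#' @param field_spec A [section_field_spec()].
#' @param seed Integer seed.
#' @return A list of class `ovary_fields`; each element is a data frame of
#'   profiles (`x_um`, `y_um`, `radius_um`, `stage`) with attributes
#'   `field_width`, `field_height`.
#' @export
render_fields <- function(population, field_spec = section_field_spec(),
                          seed = NULL, max_batches = 600) {
  stopifnot(inherits(population, "oocyte_population"),
            inherits(field_spec, "section_field_spec"))
  W <- field_spec$field_width; H <- field_spec$field_height
  lambda <- attr(population, "number_density")
  radius <- (3 * population$volume_um3 / (4 * pi))^(1 / 3)
  r_max <- if (nrow(population)) max(radius) else 1
  lz <- field_spec$slab_thickness %||% (4 * r_max)
  if (lz <= 2 * r_max) {
    stop("slab_thickness must exceed one maximal oocyte diameter",
         call. = FALSE)
  }
  margin <- r_max * 1.001  # wrapped images stay outside the window
  lx <- W + 2 * margin; ly <- H + 2 * margin
  v_box <- lx * ly * lz
  gen <- function() {
    lapply(seq_len(field_spec$n_fields), function(f) {
      h <- rlnorm_mean_cv(1, 1, field_spec$field_heterogeneity_cv)
      n <- if (nrow(population) == 0) 0L else
        stats::rpois(1, lambda * v_box * h)
      if (n == 0L) {
        prof <- data.frame(x_um = numeric(0), y_um = numeric(0),
                           radius_um = numeric(0), stage = character(0))
      } else {
        idx <- sample.int(nrow(population), n, replace = TRUE)
        rr <- radius[idx]
        pk <- rsa_pack(rr, lx, ly, lz,
                       max_batches = max_batches)
        oidx <- idx[pk$index]
        dz <- pmin(pk$z, lz - pk$z)  # periodic distance to the z = 0 plane
        cut <- dz < pk$r
        pr <- sqrt(pmax(0, pk$r[cut]^2 - dz[cut]^2))
        # window sits at [margin, margin + W] x [margin, margin + H]
        px <- pk$x[cut] - margin; py <- pk$y[cut] - margin
        vis <- px + pr > 0 & px - pr < W & py + pr > 0 & py - pr < H
        prof <- data.frame(x_um = px[vis], y_um = py[vis],
                           radius_um = pr[vis],
                           stage = population$stage[oidx][cut][vis])
      }
      structure(prof, field_width = W, field_height = H, het_factor = h,
                class = c("ovary_field", "data.frame"))
    })
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
  structure(out, class = "ovary_fields")
}

#' Count grid-point hits on a rendered field
#'
#' Lays the square point lattice on the field at a uniformly random offset
#' within one lattice cell and classifies every point as exactly one
#' component: the stage of the profile containing it (overlapping-profile
#' ties - which cannot arise from non-overlapping spheres but can from
#' user-constructed fields - are broken by the nearest profile center), or
#' unclassified tissue (`OTHER`) when no profile covers it.  Hit totals
#' always sum to the grid's point count.
#'
#' @param field One element of a [render_fields()] result.
#' @param grid A [grid_spec()].
#' @param seed Integer seed for the grid offset.
#' @param field_id Identifier copied into the output.
#' @return A data frame of grid counts (`field_id`, `component`, `hits`,
#'   `n_points`) that satisfies [validate_field_counts()].
#' @export
count_grid_hits <- function(field, grid = grid_b(), seed = NULL,
                            field_id = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  W <- attr(field, "field_width"); H <- attr(field, "field_height")
  s <- grid$probe_line_length
  n <- grid$n_points
  nrow_g <- floor(sqrt(n)); ncol_g <- ceiling(n / nrow_g)
  if ((ncol_g - 1) * s + s > W || (nrow_g - 1) * s + s > H) {
    stop("field too small for the requested grid", call. = FALSE)
  }
  off <- if (is.null(seed)) stats::runif(2, 0, s) else
    withr::with_seed(as.integer(seed), stats::runif(2, 0, s))
  px <- off[1] + (seq_len(ncol_g) - 1) * s
  py <- off[2] + (seq_len(nrow_g) - 1) * s
  pts <- expand.grid(x = px, y = py)[seq_len(n), ]
  comp <- rep("OTHER", n)
  if (nrow(field) > 0) {
    d2 <- outer(pts$x, field$x_um, "-")^2 + outer(pts$y, field$y_um, "-")^2
    inside <- sweep(d2, 2, field$radius_um^2, "<=")
    hit_any <- rowSums(inside) > 0
    if (any(hit_any)) {
      d2m <- d2
      d2m[!inside] <- Inf
      comp[hit_any] <- field$stage[max.col(-d2m[hit_any, , drop = FALSE],
                                           ties.method = "first")]
    }
  }
  tab <- table(comp)
  out <- data.frame(field_id = field_id, component = names(tab),
                    hits = as.integer(tab), n_points = n,
                    stringsAsFactors = FALSE)
  validate_field_counts(out)
  out
}

#' Invert a shrinkage model
#'
#' Returns the model that exactly undoes another: the correction model
#' matching a simulated shrinkage, or vice versa.
#'
#' @param model A [shrinkage_model()].
#' @return The inverse `shrinkage_model`.
#' @export
invert_shrinkage_model <- function(model) {
  stopifnot(inherits(model, "shrinkage_model"))
  switch(model$kind,
    identity = model,
    multiplicative = shrinkage_model("multiplicative",
                                     factor = 1 / model$factor,
                                     label = paste0("inv_", model$label)),
    linear = shrinkage_model("linear",
                             intercept = -model$intercept / model$slope,
                             slope = 1 / model$slope,
                             label = paste0("inv_", model$label))
  )
}

#' Simulate whole-mount style axis measurements
#'
#' Draws `n_per_stage` oocytes per stage from the population and emits
#' their long and short axes as they would appear on embedded sections:
#' the true axes (S = 2 OD / (1 + k), L = k S - the "through-nucleus",
#' i.e. equatorial, maximal section) transformed by a shrinkage model.
#' Applying [correct_shrinkage()] with [invert_shrinkage_model()] of the
#' same model recovers the true dimensions exactly.
#'
#' @param population An [simulate_population()] result.
#' @param n_per_stage Oocytes measured per stage (>= 1; ten in the
#'   emulated protocol).
#' @param shrinkage The [shrinkage_model()] applied to emitted axes (maps
#'   true to embedded dimensions, e.g. multiplicative factor 0.8).
#' @param seed Integer seed.
#' @param stages Stages to measure (default: all stages present); a
#'   requested stage absent from the population is skipped with a warning.
#' @param female_id Identifier copied into the output.
#' @return Data frame (`female_id`, `stage`, `L_um`, `S_um`,
#'   `through_nucleus`).
#' @export
simulate_measurements <- function(population, n_per_stage = 10,
                                  shrinkage = shrinkage_model("identity"),
                                  seed = NULL, stages = NULL,
                                  female_id = "SIM") {
  stopifnot(inherits(population, "oocyte_population"), n_per_stage >= 1)
  present <- unique(population$stage)
  stages <- stages %||% present
  absent <- setdiff(stages, present)
  if (length(absent)) {
    warning("stage(s) absent from population, skipped: ",
            paste(absent, collapse = ", "), call. = FALSE)
    stages <- intersect(stages, present)
  }
  gen <- function() {
    parts <- lapply(stages, function(st) {
      rows <- which(population$stage == st)
      idx <- sample(rows, n_per_stage, replace = TRUE)
      s_true <- 2 * population$od_um[idx] / (1 + population$k[idx])
      l_true <- population$k[idx] * s_true
      data.frame(female_id = female_id, stage = st,
                 L_um = correct_shrinkage(l_true, shrinkage,
                                          warn_identity = FALSE),
                 S_um = correct_shrinkage(s_true, shrinkage,
                                          warn_identity = FALSE),
                 through_nucleus = TRUE, stringsAsFactors = FALSE)
    })
    do.call(rbind, parts)
  }
  if (length(stages) == 0) {
    return(data.frame(female_id = character(0), stage = character(0),
                      L_um = numeric(0), S_um = numeric(0),
                      through_nucleus = logical(0)))
  }
  if (is.null(seed)) gen() else withr::with_seed(as.integer(seed), gen())
}
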