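# small shared helpers

#' Fan a master seed out into independent sub-seeds
#'
#' All stochastic operations take an explicit integer seed.  When one master
#' seed drives several operations, sub-seeds are drawn reproducibly from the
#' master: `set.seed(master)` followed by `n` draws from
#' `sample.int(2^31 - 2)`.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' split_seed(1, 3)
split_seed <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1, n >= 1)
  withr::with_seed(as.integer(master), sample.int(2147483646L, n))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# lognormal parameterized by mean and coefficient of variation;
# cv = 0 degenerates to the constant mean
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# E[X^3] for the above lognormal
lnorm_third_moment <- function(mean, cv) {
  mean^3 * (1 + cv^2)^3
}

# microns^3 per cm^3
UM3_PER_CM3 <- 1e12

# volume (um^3) of a prolate spheroid expressed through the arithmetic
# diameter OD = (L + S) / 2 and shape factor k = L / S:
#   S = 2 OD / (1 + k),  v = (pi/6) k S^3 = (pi/6) OD^3 * 8 k / (1 + k)^3
spheroid_volume_od <- function(od, k = 1) {
  (pi / 6) * od^3 * 8 * k / (1 + k)^3
}
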