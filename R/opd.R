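#' Ovary specific gravity by most advanced oocyte stage
#'
#' The gram-to-volume conversion inside the packing-density formula uses a
#' stage-dependent ovary specific gravity: 1.061 g cm^-3 when the most
#' advanced oocyte (MAO) is previtellogenic or in nucleus migration, and
#' 1.072 g cm^-3 when it is at cortical alveoli or in vitellogenesis.  No
#' published value exists for hydrated ovaries (hydrated oocytes are
#' excluded from packing-density estimation altogether); by default they
#' fall back to 1.072 with a warning.
#'
#' @param mao Stage token of the most advanced oocyte in the ovary.
#' @param hyo_value Fallback for hydrated ovaries (set to `NA` to refuse).
#' @return Specific gravity in g cm^-3.
#' @export
#' @examples
#' specific_gravity("PVO4c")  # 1.061
#' specific_gravity("VTO")    # 1.072
specific_gravity <- function(mao, hyo_value = 1.072) {
  assert_stage(mao, allow_pooled = TRUE)
  mao <- as.character(mao)
  vapply(mao, function(s) {
    if (s %in% c(primary_stages(), pooled_pvo_label(), "MNO")) return(1.061)
    if (s %in% c("CAO", "EVTO", "VTO")) return(1.072)
    # HYO: not covered by published values
    warning("specific gravity undefined for hydrated ovaries; using ",
            hyo_value, call. = FALSE)
    as.numeric(hyo_value)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Stage-specific oocyte packing density
#'
#' Number of stage-i oocytes per gram of ovary, from the stereological
#' volume fraction `Vv`, mean shape factor `k`, shrinkage-corrected
#' volume-based diameter `cODv` (um) and ovary specific gravity `rho`
#' (g cm^-3):
#'
#' `log10(OPD) = log10(Vv * (1/rho) * (1+k)^3 / (8k)) + C - 3 log10(cODv)`
#'
#' The constant C converts cm^3 to um^3 for a prolate spheroid:
#' C = 12 + log10(6/pi) = 12.28103, printed as 12.28 in the literature.
#' `constant_mode = "printed"` (default) uses 12.28 for fidelity to the
#' published formula; `"exact"` uses the closed form, under which OPD
#' equals `Vv * 1e12 * (6/pi) * (1+k)^3 / (rho * 8k * cODv^3)` and a
#' monodisperse sphere population is recovered exactly.  The two modes
#' differ by the fixed factor `10^(12.28 - C)` (about 0.9976).
#'
#' @param vv Volume fraction of the stage, in `[0, 1]`.
#' @param k Mean shape factor (>= 1).
#' @param codv Shrinkage-corrected volume-based diameter, um (> 0).
#' @param rho Ovary specific gravity, g cm^-3 (> 0).
#' @param constant_mode `"printed"` or `"exact"`.
#' @return Packing density in oocytes per gram of ovary.  `vv = 0` returns
#'   0 without touching the logarithm.
#' @export
#' @examples
#' opd(pi / 6, k = 1, codv = 100, rho = 1, constant_mode = "exact")  # 1e6
opd <- function(vv, k, codv, rho, constant_mode = c("printed", "exact")) {
  constant_mode <- match.arg(constant_mode)
  stopifnot(all(vv >= 0), all(vv <= 1), all(k >= 1), all(rho > 0))
  if (any(!is.finite(codv)) || any(codv <= 0)) {
    stop("cODv must be positive and finite", call. = FALSE)
  }
  C <- opd_constant(constant_mode)
  n <- max(length(vv), length(k), length(codv), length(rho))
  vv <- rep_len(vv, n); k <- rep_len(k, n)
  codv <- rep_len(codv, n); rho <- rep_len(rho, n)
  out <- numeric(n)
  pos <- vv > 0
  out[pos] <- 10^(log10(vv[pos] * (1 / rho[pos]) *
                          (1 + k[pos])^3 / (8 * k[pos])) +
                    C - 3 * log10(codv[pos]))
  out
}

#' @rdname opd
#' @export
opd_constant <- function(constant_mode = c("printed", "exact")) {
  constant_mode <- match.arg(constant_mode)
  if (constant_mode == "printed") 12.28 else 12 + log10(6 / pi)
}

#' Whole-ovary stage oocyte number
#'
#' The absolute number of stage-i oocytes in an ovary is the packing
#' density times the formalin-fixed gonad weight; no rounding is applied.
#'
#' @param opd Packing density, oocytes g^-1 (>= 0).
#' @param gwf Formalin-fixed gonad weight, g (> 0).
#' @return Oocyte number.
#' @export
#' @examples
#' oocyte_number(1000, 25)  # 25000
oocyte_number <- function(opd, gwf) {
  stopifnot(all(opd >= 0), all(gwf > 0))
  opd * gwf
}

#' Per-female stage table of packing densities and oocyte numbers
#'
#' Computes OPD and NO for every stage of one female from its stage-level
#' inputs.  Hydrated oocytes cannot be measured reliably (extreme
#' shrinkage, irregular shape) and are emitted with missing OPD/NO and a
#' reason code rather than dropped.
#'
#' @param stage_inputs Data frame with columns `stage`, `vv`, `k`, `codv`.
#' @param mao Most advanced oocyte stage of the female (sets rho).
#' @param gwf Formalin-fixed gonad weight, g.
#' @param constant_mode Passed to [opd()].
#' @return Data frame with columns `stage`, `vv`, `k`, `codv`, `rho`,
#'   `opd`, `no`, `reason` (empty string when computed).
#' @export
stage_table <- function(stage_inputs, mao, gwf,
                        constant_mode = c("printed", "exact")) {
  constant_mode <- match.arg(constant_mode)
  cols <- c("stage", "vv", "k", "codv")
  miss <- setdiff(cols, names(stage_inputs))
  if (length(miss)) {
    stop("stage inputs lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(stage_inputs) == 0) {
    out <- stage_inputs
    out$rho <- numeric(0); out$opd <- numeric(0); out$no <- numeric(0)
    out$reason <- character(0)
    return(out)
  }
  assert_stage(stage_inputs$stage, allow_pooled = TRUE)
  rho <- specific_gravity(mao)
  out <- stage_inputs
  out$rho <- rho
  out$opd <- NA_real_
  out$no <- NA_real_
  out$reason <- ""
  hyo <- out$stage == "HYO"
  out$reason[hyo] <- "HYO excluded: unreliable size measurement"
  est <- !hyo & is.finite(out$vv) & is.finite(out$codv) & is.finite(out$k)
  if (any(est)) {
    out$opd[est] <- opd(out$vv[est], out$k[est], out$codv[est], rho,
                        constant_mode)
    out$no[est] <- oocyte_number(out$opd[est], gwf)
  }
  out$reason[!hyo & !est] <- "missing stage inputs"
  attr(out, "constant_mode") <- constant_mode
  out
}
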