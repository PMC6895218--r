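#' Oocyte stage, ovarian phase and section-component vocabularies
#'
#' The package works with a fixed staging scheme for an asynchronous batch
#' spawner: six previtellogenic (primary growth) stages, the PVO4 sub-stages
#' being defined by the circumnuclear ring, followed by secondary growth
#' through cortical alveoli, early and medium-late vitellogenesis, nucleus
#' migration and hydration.  Ovarian phases follow the standard maturity
#' terminology (immature, developing, spawning capable, actively spawning,
#' regressing, regenerating).
#'
#' @name stage-vocabulary
#' @keywords internal
NULL

#' Ordered oocyte developmental stages
#'
#' Stage tokens in developmental order, from the smallest previtellogenic
#' oocytes to hydrated oocytes.
#'
#' @return Character vector of stage tokens.
#' @export
#' @examples
#' oocyte_stages()
oocyte_stages <- function() {
  c("PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b", "PVO4c",
    "CAO", "EVTO", "VTO", "MNO", "HYO")
}

#' @rdname oocyte_stages
#' @export
primary_stages <- function() {
  c("PVO1", "PVO2", "PVO3", "PVO4a", "PVO4b", "PVO4c")
}

#' @rdname oocyte_stages
#' @export
secondary_stages <- function() {
  c("CAO", "EVTO", "VTO", "MNO", "HYO")
}

#' Token used for the pooled PVO1, PVO2 and PVO3 stages
#' @return A length-1 character vector.
#' @export
pooled_pvo_label <- function() "PVO1-3"

#' Fecundity-accumulation stage order
#'
#' Order in which stage-specific oocyte numbers are accumulated into
#' potential fecundity: from the batch-ready medium-late vitellogenic pool
#' backwards to the pooled smallest previtellogenic reservoir.  Migratory
#' nucleus and hydrated oocytes are transient and excluded from accumulation.
#'
#' @return Character vector of cumulative-stage tokens.
#' @export
accumulation_order <- function() {
  c("VTO", "EVTO", "CAO", "PVO4c", "PVO4b", "PVO4a", pooled_pvo_label())
}

#' Ovarian maturity phases
#'
#' IM immature, DV developing, SC spawning capable, AS actively spawning,
#' RS regressing, RT regenerating.
#'
#' @return Character vector of phase tokens.
#' @export
ovarian_phases <- function() {
  c("IM", "DV", "SC", "AS", "RS", "RT")
}

#' Components scored on a sectioned ovary field
#'
#' Everything a grid point can hit: an oocyte stage, one of three atresia
#' classes (early alpha, late alpha, beta), postovulatory follicles, blood
#' capillaries, missing oocytes (tissue torn out during sectioning),
#' unclassified ovarian tissue (stroma etc.), empty space within the
#' section, and area outside the ovarian wall.  `EMPTY` and `OUTSIDE` do
#' not count as sectioned tissue.
#'
#' @return Character vector of component tokens.
#' @export
section_components <- function() {
  c(oocyte_stages(),
    "ATRESIA_EA", "ATRESIA_LA", "ATRESIA_B",
    "POF", "BLOOD", "MISSING", "OTHER", "EMPTY", "OUTSIDE")
}

#' @rdname section_components
#' @export
invalid_point_components <- function() c("EMPTY", "OUTSIDE")

#' Validate stage tokens
#'
#' @param stage Character vector of candidate stage tokens.
#' @param allow_pooled Accept the pooled `"PVO1-3"` token as well.
#' @return The input, invisibly, after validation.
#' @export
assert_stage <- function(stage, allow_pooled = FALSE) {
  valid <- oocyte_stages()
  if (allow_pooled) valid <- c(valid, pooled_pvo_label())
  bad <- setdiff(unique(as.character(stage)), valid)
  if (length(bad)) {
    stop("unknown oocyte stage token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(stage)
}

#' @rdname assert_stage
#' @param phase Character vector of candidate phase tokens.
#' @export
assert_phase <- function(phase) {
  bad <- setdiff(unique(as.character(phase)), ovarian_phases())
  if (length(bad)) {
    stop("unknown ovarian phase token(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(phase)
}

#' Pool the three smallest previtellogenic stages
#'
#' Maps `PVO1`, `PVO2` and `PVO3` to the common `"PVO1-3"` token and leaves
#' every other stage unchanged.  The three stages fluctuate in near lockstep
#' and are pooled throughout the fecundity accounting.
#'
#' @param stage Character vector of stage tokens.
#' @return Character vector with pooled tokens.
#' @export
#' @examples
#' pool_pvo123(c("PVO1", "PVO3", "CAO"))
pool_pvo123 <- function(stage) {
  stage <- as.character(stage)
  stage[stage %in% c("PVO1", "PVO2", "PVO3")] <- pooled_pvo_label()
  stage
}

# internal: developmental rank (pooled token ranks with PVO3)
stage_rank <- function(stage) {
  ord <- c(oocyte_stages(), pooled_pvo_label())
  rank <- c(seq_along(oocyte_stages()), 3L)
  rank[match(as.character(stage), ord)]
}
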