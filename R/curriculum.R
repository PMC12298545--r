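# Curriculum scheduling: a sigmoid difficulty ramp gating monomer
# library tiers (toy analogs of the 50 / 500 / full-library stages).

#' Curriculum schedule
#'
#' Difficulty evolves as
#' `D_t = d_min + (d_max - d_min) * sigmoid(k * (t - t0))` and is cut
#' into stages at `cuts`; a stage unlocks every monomer whose `tier`
#' is at or below the stage index.
#'
#' @param d_min,d_max Difficulty bounds (`d_min <= d_max`).
#' @param k Transition sharpness (> 0).
#' @param t0 Transition midpoint (episode index).
#' @param cuts Increasing difficulty cut points mapping difficulty to
#'   stages 1..(length(cuts) + 1).
#' @return A `curriculum_schedule`.
#' @export
curriculum_schedule <- function(d_min = 0, d_max = 1, k = 0.05, t0 = 150,
                                cuts = c(1 / 3, 2 / 3)) {
  stopifnot(d_min <= d_max, k > 0, !is.unsorted(cuts))
  structure(list(d_min = d_min, d_max = d_max, k = k, t0 = t0, cuts = cuts),
            class = "curriculum_schedule")
}

#' Curriculum difficulty at step t
#'
#' @param t Step (episode) index, vectorized.
#' @param sched A [curriculum_schedule()].
#' @return Difficulty in \[d_min, d_max\], non-decreasing in `t`.
#' @export
curriculum_difficulty <- function(t, sched = curriculum_schedule()) {
  sched$d_min + (sched$d_max - sched$d_min) * sigmoid(sched$k * (t - sched$t0))
}

#' Curriculum stage at step t
#'
#' @param t Step (episode) index.
#' @param sched A [curriculum_schedule()].
#' @return Integer stage (1-based tier index).
#' @export
curriculum_stage <- function(t, sched = curriculum_schedule()) {
  d <- curriculum_difficulty(t, sched)
  1L + findInterval(d, sched$cuts)
}

#' Monomer ids unlocked at a curriculum stage
#'
#' @param library A `monomer_library` whose monomer table carries a
#'   `tier` column (missing tiers default to 1).
#' @param stage Stage index.
#' @return Character vector of allowed monomer ids.
#' @export
stage_monomers <- function(library, stage) {
  tier <- library$monomers[["tier"]] %||% rep(1L, nrow(library$monomers))
  tier[is.na(tier)] <- 1L
  library$monomers$id[tier <= stage]
}
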