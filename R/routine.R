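#' Training-routine specification and duration arithmetic
#'
#' A controller training routine consists of `n_classes` wrist contraction
#' classes, each held for `hold_s` seconds, repeated `reps` times, in
#' `n_limb_positions` limb positions. Its nominal duration is the product of
#' the four fields. The standard position-aware pre-training routine
#' (5 classes x 5 s x 2 reps x 4 positions) lasts 200 s; the shortened
#' transfer-learning recalibration routine (5 x 2 s x 2 x 3) lasts 60 s; a
#' single-position routine (5 x 5 s x 2 x 1) lasts 50 s.
#'
#' @param n_classes Number of wrist contraction classes.
#' @param hold_s Seconds each contraction is held.
#' @param reps Number of repetitions.
#' @param n_limb_positions Number of limb positions.
#' @return Object of class `promet_routine`.
#' @examples
#' routine_duration(routine_spec(5, 5, 2, 4))   # 200
#' routine_reduction(routine_spec(5, 5, 2, 4),
#'                   routine_spec(5, 2, 2, 3))  # 70
#' @export
routine_spec <- function(n_classes, hold_s, reps, n_limb_positions) {
  x <- list(n_classes = n_classes, hold_s = hold_s, reps = reps,
            n_limb_positions = n_limb_positions)
  if (any(!vapply(x, function(v) is.numeric(v) && length(v) == 1L &&
                    is.finite(v) && v > 0, logical(1)))) {
    stop_promet("bad_routine", "all routine fields must be positive scalars")
  }
  structure(x, class = "promet_routine")
}

#' @rdname routine_spec
#' @param spec A [routine_spec()].
#' @return `routine_duration`: duration in seconds.
#' @export
routine_duration <- function(spec) {
  if (!inherits(spec, "promet_routine")) spec <- do.call(routine_spec, as.list(spec))
  spec$n_classes * spec$hold_s * spec$reps * spec$n_limb_positions
}

#' @rdname routine_spec
#' @param long,short [routine_spec()] objects for the full and the reduced
#'   routine.
#' @return `routine_reduction`: percent decrease in duration,
#'   `100 * (duration(long) - duration(short)) / duration(long)`; negative
#'   when the "short" routine is actually longer.
#' @export
routine_reduction <- function(long, short) {
  dl <- routine_duration(long)
  if (dl <= 0) stop_promet("bad_routine", "long routine has zero duration")
  100 * (dl - routine_duration(short)) / dl
}
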