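# Actuation schedules: per-frame records of acquisition time, membrane
# state (relaxed/stretched) and the deformation applied in stretched
# frames. Cyclic experiments image one relaxed and one stretched frame per
# stretch period, so schedules alternate states within each period.

#' Per-frame actuation schedule
#'
#' @param times strictly increasing acquisition times in seconds.
#' @param states character vector, each `"relaxed"` or `"stretched"`.
#' @param modes stretch mode per frame: `"radial"`, `"uniaxial_x"`,
#'   `"uniaxial_y"` or `"biaxial"` (recycled if length 1).
#' @param deformations a single [deformation_spec()] (recycled) or a list
#'   with one spec per frame; the deformation of a stretched frame relative
#'   to the relaxed state of its period.
#' @return A data frame of class `actuation_schedule` with columns `time`,
#'   `state`, `mode` and a list-column `deformation`.
#' @export
actuation_schedule <- function(times, states,
                               modes = "radial",
                               deformations = deformation_spec()) {
  if (length(times) != length(states))
    stop("`times` and `states` must have equal length", call. = FALSE)
  if (length(times) && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (!all(states %in% c("relaxed", "stretched")))
    stop('states must be "relaxed" or "stretched"', call. = FALSE)
  modes_ok <- c("radial", "uniaxial_x", "uniaxial_y", "biaxial")
  modes <- rep_len(modes, length(times))
  if (length(modes) && !all(modes %in% modes_ok))
    stop("unknown stretch mode", call. = FALSE)
  if (inherits(deformations, "deformation_spec"))
    deformations <- rep(list(deformations), length(times))
  if (length(deformations) != length(times))
    deformations <- rep_len(deformations, length(times))
  sched <- data.frame(time = as.numeric(times), state = states,
                      mode = modes, stringsAsFactors = FALSE)
  sched$deformation <- deformations
  class(sched) <- c("actuation_schedule", "data.frame")
  sched
}

#' Build an alternating relaxed/stretched cyclic schedule
#'
#' Convenience constructor for the common acquisition pattern: one relaxed
#' and one stretched frame per stretch period, the relaxed frame first.
#'
#' @param n_periods number of stretch periods.
#' @param period period time in seconds.
#' @param deformation [deformation_spec()] of the stretched state (a single
#'   spec, or a list of one per period to emulate drifting strain).
#' @param mode stretch mode label (or one per period).
#' @param settle_delay imaging delay after each state transition, seconds.
#' @param t0 start time of the first period, seconds.
#' @return An [actuation_schedule()] with `2 * n_periods` frames.
#' @export
cyclic_schedule <- function(n_periods, period = 20,
                            deformation = deformation_spec(kind = "radial",
                                                           radial_strain = 0.08),
                            mode = "radial", settle_delay = 3, t0 = 0) {
  stop_if_not_scalar_num(period, "period", positive = TRUE)
  if (settle_delay < 0 || settle_delay >= period / 2)
    stop("`settle_delay` must be in [0, period/2)", call. = FALSE)
  k <- seq_len(n_periods) - 1L
  times <- as.vector(rbind(t0 + k * period + settle_delay,
                           t0 + k * period + period / 2 + settle_delay))
  states <- rep(c("relaxed", "stretched"), n_periods)
  if (inherits(deformation, "deformation_spec"))
    deformation <- rep(list(deformation), n_periods)
  defs <- rep(deformation, each = 2L)
  modes <- rep(rep_len(mode, n_periods), each = 2L)
  actuation_schedule(times, states, modes, defs)
}
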