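# End-to-end in-silico experiments: strain-vacuum sweep, long-term
# stability, and stretch-mode switching. Each runner synthesizes its
# input imagery with known ground truth, pushes it through the full
# DIC + strain chain, and reports the quantities a bench experiment
# would report. All randomness flows from the single seed in the config,
# so a config reproduces its outputs exactly.

#' Experiment configuration
#'
#' Builds a fully serializable configuration for the experiment runners.
#' Defaults are scaled so each experiment runs in minutes on one CPU
#' (moderate image sizes and a two-pass correlation schedule); the
#' full-scale acquisition protocol (image size, pass windows, duration)
#' can be requested explicitly through the corresponding fields.
#'
#' @param experiment `"strain_vacuum_sweep"`, `"long_term_stability"` or
#'   `"mode_switch"`.
#' @param seed integer seed funnelled to every stochastic stage.
#' @param image_size speckle image size in px.
#' @param particle_density tracer particles per px².
#' @param calibration µm/px.
#' @param dic_windows,dic_steps correlation pass schedule.
#' @param crop_margin strain-field border crop in grid points.
#' @param ... experiment-specific overrides, stored verbatim:
#'   \describe{
#'   \item{sweep}{`vacuum_levels` (percent), `strain_per_vacuum` (slope,
#'     strain fraction per vacuum percent), `mode`, `lateral_ratio`.}
#'   \item{stability}{`duration` (s), `pair_interval` (s), `period` (s),
#'     `radial_strain`, `drift_relative` (total relative strain drift
#'     injected linearly over the run, 0 for none).}
#'   \item{mode switch}{`modes`, `strains` (per-mode `c(exx, eyy)`),
#'     `cycles_per_mode`, `period`, `repeats`, `pairs_per_segment`.}
#'   }
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(experiment = c("strain_vacuum_sweep",
                                             "long_term_stability",
                                             "mode_switch"),
                              seed = 1L,
                              image_size = 512,
                              particle_density = 5e-3,
                              calibration = 2,
                              dic_windows = c(128, 64),
                              dic_steps = dic_windows / 2,
                              crop_margin = 1,
                              ...) {
  experiment <- match.arg(experiment)
  cfg <- c(list(experiment = experiment, seed = as.integer(seed),
                image_size = image_size,
                particle_density = particle_density,
                calibration = calibration,
                dic_windows = dic_windows, dic_steps = dic_steps,
                crop_margin = crop_margin),
           list(...))
  structure(cfg, class = "experiment_config")
}

#' Write / read an experiment configuration as JSON
#'
#' @param config an [experiment_config()].
#' @param path JSON file path.
#' @return `write_config()`: `path` invisibly; `read_config()`: the
#'   configuration.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "experiment_config")
}

# Synthesize a relaxed/stretched pair for a homogeneous deformation and
# run the DIC + strain chain; returns spatially averaged strain.
.strain_of_pair <- function(base_img, dspec, cfg, noise_seed) {
  noise_sd <- 3
  h <- nrow(base_img); w <- ncol(base_img)
  warped <- apply_deformation(base_img, dspec, fill = 10)$warped
  imgs <- with_seed(noise_seed, {
    list(ref = clip_gray(base_img + matrix(stats::rnorm(h * w, sd = noise_sd), h, w), 8),
         def = clip_gray(warped + matrix(stats::rnorm(h * w, sd = noise_sd), h, w), 8))
  })
  fld <- estimate_displacement(
    image_pair(imgs$ref, imgs$def, calibration = cfg$calibration),
    pass_schedule(cfg$dic_windows, cfg$dic_steps))
  st <- green_lagrange(fld, crop_margin = cfg$crop_margin)
  crop_and_average(st)
}

.base_speckle <- function(cfg) {
  generate_speckle(speckle_spec(
    image_size = rep(cfg$image_size, 2)[1:2],
    particle_density = cfg$particle_density,
    noise_sd = 0, seed = cfg$seed))
}

#' Run the strain–vacuum sweep experiment
#'
#' Sweeps the applied vacuum over a range of levels; per level, a speckle
#' pair is synthesized under the configured linear vacuum-to-strain
#' mapping, the DIC + strain chain recovers the average strains, and the
#' strain–vacuum relation is fitted by least squares.
#'
#' @param config an [experiment_config()] (`experiment =
#'   "strain_vacuum_sweep"`).
#' @return List with `table` (vacuum %, avg_Exx, avg_Eyy, ok flag per
#'   level), `fit_xx` / `fit_yy` (slope, intercept, r.squared), and
#'   `generator_slope` (ground-truth strain-per-vacuum slope).
#' @export
run_strain_vacuum_sweep <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  levels <- cfg$vacuum_levels %||% seq(5, 50, by = 5)
  slope <- cfg$strain_per_vacuum %||% 0.0018   # 9% strain at 50% vacuum
  mode <- cfg$mode %||% "radial"
  lateral <- cfg$lateral_ratio %||% (-1 / 3)
  base <- .base_speckle(cfg)

  rows <- list()
  for (i in seq_along(levels)) {
    v <- levels[i]
    eps <- slope * v
    Fm <- if (mode == "radial") diag(c(1 + eps, 1 + eps))
          else diag(c(1 + eps, 1 + lateral * eps))
    res <- tryCatch(
      .strain_of_pair(base, deformation_spec(F = Fm), cfg,
                      noise_seed = cfg$seed + i),
      error = function(e) {
        warning(sprintf("vacuum level %g%%: %s", v, conditionMessage(e)))
        NULL
      })
    rows[[i]] <- data.frame(
      vacuum = v,
      avg_Exx = if (is.null(res)) NA_real_ else res$avg_Exx,
      avg_Eyy = if (is.null(res)) NA_real_ else res$avg_Eyy,
      ok = !is.null(res))
  }
  tab <- do.call(rbind, rows)
  fit <- function(y) {
    m <- stats::lm(y ~ vacuum, data = tab, subset = tab$ok)
    s <- summary(m)
    list(slope = unname(stats::coef(m)[2]),
         intercept = unname(stats::coef(m)[1]),
         r_squared = s$r.squared)
  }
  list(table = tab, fit_xx = fit(tab$avg_Exx), fit_yy = fit(tab$avg_Eyy),
       generator_slope = slope, mode = mode)
}

#' Run the long-term strain-stability experiment
#'
#' Emulates cyclic stretching imaged at regular pair intervals: per
#' acquired pair the relaxed/stretched speckle images are synthesized
#' (with fresh acquisition noise, and optionally a slow linear drift of
#' the applied strain), the DIC + strain chain recovers the averaged
#' strains, and the normalized series and stability metrics are
#' reported. The default run is scaled down (2 h at 10-min pairs); the
#' full bench protocol (18 h) is obtained by setting `duration`.
#'
#' @param config an [experiment_config()] (`experiment =
#'   "long_term_stability"`).
#' @return List with `series` (normalized [strain_series()]),
#'   `stability` ([stability_metrics()]), `n_pairs`, and `cycles` (the
#'   number of stretch cycles in the configured duration).
#' @export
run_long_term_stability <- function(config = experiment_config("long_term_stability")) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  duration <- cfg$duration %||% 7200
  pair_interval <- cfg$pair_interval %||% 600
  period <- cfg$period %||% 20
  eps0 <- cfg$radial_strain %||% 0.08
  drift <- cfg$drift_relative %||% 0

  sched <- acquisition_schedule(period = period, settle_delay = 3,
                                pair_interval = pair_interval,
                                duration = duration)
  base <- .base_speckle(cfg)
  n <- nrow(sched)
  exx <- eyy <- exy <- numeric(n)
  for (i in seq_len(n)) {
    frac <- if (n > 1) (i - 1) / (n - 1) else 0
    eps_i <- eps0 * (1 + drift * frac)
    res <- .strain_of_pair(base,
                           deformation_spec(kind = "radial",
                                            radial_strain = eps_i),
                           cfg, noise_seed = cfg$seed + i)
    exx[i] <- res$avg_Exx; eyy[i] <- res$avg_Eyy; exy[i] <- res$avg_Exy
  }
  ser <- normalize_series(strain_series(sched$stretched_time, exx, eyy, exy))
  list(series = ser, stability = stability_metrics(ser), n_pairs = n,
       cycles = cycles_in_duration(duration, period))
}

#' Run the stretch-mode switching experiment
#'
#' Cycles through four stretch configurations (radial, uniaxial x,
#' uniaxial y, biaxial), each maintained for a fixed number of stretch
#' cycles, the whole pattern repeated; per analyzed pair the DIC + strain
#' chain recovers the averaged strains, which are then summarized per
#' mode. The analysis samples `pairs_per_segment` pairs per mode segment.
#'
#' @param config an [experiment_config()] (`experiment = "mode_switch"`).
#' @return List with `series` (per-pair strains with mode and segment),
#'   `per_mode` (segment-averaged Exx/Eyy per mode), and
#'   `total_scheduled_time` (s) of the full protocol.
#' @export
run_mode_switch <- function(config = experiment_config("mode_switch")) {
  stopifnot(inherits(config, "experiment_config"))
  cfg <- config
  period <- cfg$period %||% 20
  cycles_per_mode <- cfg$cycles_per_mode %||% 20
  repeats <- cfg$repeats %||% 5
  pairs_per_segment <- cfg$pairs_per_segment %||% 1
  modes <- cfg$modes %||% c("radial", "uniaxial_x", "uniaxial_y", "biaxial")
  strains <- cfg$strains %||% list(
    radial = c(0.08, 0.08),
    uniaxial_x = c(0.08, -0.02),
    uniaxial_y = c(-0.01, 0.08),
    biaxial = c(0.08, 0.04))

  proto <- mode_switch_protocol(period = period,
                                cycles_per_mode = cycles_per_mode,
                                repeats = repeats, modes = modes)
  segment_time <- proto$segment_time
  base <- .base_speckle(cfg)

  rows <- list(); k <- 0L
  for (r in seq_len(repeats)) for (m in seq_along(modes)) {
    mode <- modes[m]
    eps <- strains[[mode]]
    Fm <- diag(c(1 + eps[1], 1 + eps[2]))
    seg_start <- ((r - 1) * length(modes) + (m - 1)) * segment_time
    for (j in seq_len(pairs_per_segment)) {
      k <- k + 1L
      res <- .strain_of_pair(base, deformation_spec(F = Fm), cfg,
                             noise_seed = cfg$seed + 1000L * k)
      rows[[k]] <- data.frame(
        time = seg_start + (j - 1) * period + period / 2 + 3,
        repeat_ = r, mode = mode,
        avg_Exx = res$avg_Exx, avg_Eyy = res$avg_Eyy)
    }
  }
  ser <- do.call(rbind, rows)
  per_mode <- do.call(rbind, lapply(modes, function(md) {
    sub <- ser[ser$mode == md, ]
    data.frame(mode = md,
               avg_Exx = mean(sub$avg_Exx), avg_Eyy = mean(sub$avg_Eyy),
               target_Exx = strains[[md]][1] + strains[[md]][1]^2 / 2,
               target_Eyy = strains[[md]][2] + strains[[md]][2]^2 / 2)
  }))
  list(series = ser, per_mode = per_mode,
       total_scheduled_time = proto$total_time)
}

#' Timing of the stretch-mode switching protocol
#'
#' Each stretch mode is maintained for a fixed number of cycles; the full
#' pattern of modes is repeated. The default protocol (four modes, 20
#' cycles of 20 s each, five repeats) schedules 8000 s in total.
#'
#' @param period stretch period, s.
#' @param cycles_per_mode stretch cycles per mode segment.
#' @param repeats repeats of the whole mode pattern.
#' @param modes character vector of mode labels.
#' @return List with `segment_time` (s), `total_time` (s) and `n_segments`.
#' @examples
#' mode_switch_protocol()$total_time  # 8000
#' @export
mode_switch_protocol <- function(period = 20, cycles_per_mode = 20,
                                 repeats = 5,
                                 modes = c("radial", "uniaxial_x",
                                           "uniaxial_y", "biaxial")) {
  segment_time <- cycles_per_mode * period
  list(segment_time = segment_time,
       total_time = length(modes) * segment_time * repeats,
       n_segments = length(modes) * repeats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
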