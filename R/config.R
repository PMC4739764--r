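#' Default run configuration
#'
#' Returns the full nested configuration with every default materialized.
#' Sections: `geometry` (synthetic neuron layout), `simulate` (see
#' [sim_params()]), `detect`, `link`, `filter`, `classify` (polarity
#' thresholds and aggregation), `phenotype` (minus-end read-outs) and
#' `kymograph`.  Every value here is an engineering default, exposed so a
#' run log records exactly what was used.
#'
#' @return nested named list
#' @export
default_config <- function() {
  list(
    geometry = list(n_neurites = 1, neurite_length = 20, curvature = 0,
                    step_length = 1, neurite_width = 1, soma_radius = 2.5,
                    field_size = NULL),
    simulate = list(f_plus_end_out = 0.5, comet_speed = 0.15,
                    comet_lifetime_mean = 15, comet_birth_rate = 0.01,
                    frame_interval = 2, n_frames = 31, pixel_size = 0.1,
                    psf_sigma = 0.15, background_photons = 100,
                    comet_peak_photons = 120, punctum_peak_photons = 250,
                    membrane_photons = 200, read_noise = 2,
                    photon_scale = 1, shot_noise = TRUE,
                    tip_mode = "eb1_like", treatment_frame = NULL,
                    elongation_rate = 0.005, coupling_radius = 1,
                    tip_dwell_fraction = NULL, dwell_mean_frames = 2,
                    punctum_retract_um = 3, n_scattered = 8,
                    n_tip_cluster = 4, clearing_speed = 0.01,
                    tip_start_frac = 0.6, n_cells = 10),
    detect = list(k = 5, min_separation_px = 2),
    link = list(link_radius = NULL, max_gap = 1),
    filter = list(min_length = 3),
    classify = list(out_low = 70, in_low = 110, in_high = 250,
                    out_high = 290, straightness_tol = 30,
                    aggregation = "per_axon"),
    phenotype = list(coloc_radius = 1, tip_zone = 2, mass_threshold = 0.5,
                     min_growth = 1, smooth_window = 3,
                     min_displacement = 2, tip_k = 5, corridor_pad = 2),
    kymograph = list(width_px = 5)
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) document, overlays it on [default_config()],
#' rejects unknown keys, validates ranges, and returns the effective
#' configuration.  An empty file yields the full default configuration.
#'
#' @param path YAML/JSON file path, or NULL for pure defaults
#' @param quiet suppress the effective-config echo
#' @return nested named list (the effective configuration)
#' @export
load_config <- function(path = NULL, quiet = TRUE) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_f("config file '%s' not found", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    cfg <- .merge_config(cfg, user, keypath = character())
  }
  validate_config(cfg)
  if (!quiet) message(format_config(cfg))
  cfg
}

.merge_config <- function(base, user, keypath) {
  for (k in names(user)) {
    full <- paste(c(keypath, k), collapse = ".")
    if (!k %in% names(base))
      stop_f("unknown configuration key '%s'", full)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(user[[k]]))
        stop_f("configuration key '%s' must be a mapping", full)
      base[[k]] <- .merge_config(base[[k]], user[[k]], c(keypath, k))
    } else {
      base[k] <- user[k]   # [k]<- keeps explicit NULLs
    }
  }
  base
}

#' @rdname load_config
#' @param cfg a configuration list
#' @export
validate_config <- function(cfg) {
  in01 <- function(x, key) if (!is.null(x) && (x < 0 || x > 1))
    stop_f("configuration key '%s' must lie in [0, 1] (got %s)", key, format(x))
  pos <- function(x, key) if (!is.null(x) && x <= 0)
    stop_f("configuration key '%s' must be > 0 (got %s)", key, format(x))
  in01(cfg$simulate$f_plus_end_out, "simulate.f_plus_end_out")
  in01(cfg$simulate$tip_dwell_fraction, "simulate.tip_dwell_fraction")
  in01(cfg$simulate$tip_start_frac, "simulate.tip_start_frac")
  pos(cfg$simulate$pixel_size, "simulate.pixel_size")
  pos(cfg$simulate$psf_sigma, "simulate.psf_sigma")
  pos(cfg$simulate$frame_interval, "simulate.frame_interval")
  pos(cfg$simulate$comet_speed, "simulate.comet_speed")
  pos(cfg$geometry$neurite_length, "geometry.neurite_length")
  pos(cfg$geometry$neurite_width, "geometry.neurite_width")
  pos(cfg$detect$k, "detect.k")
  pos(cfg$filter$min_length, "filter.min_length")
  if (!is.null(cfg$link$link_radius)) pos(cfg$link$link_radius, "link.link_radius")
  thr <- cfg$classify
  if (!(0 < thr$out_low && thr$out_low < thr$in_low &&
        thr$in_low < thr$in_high && thr$in_high < thr$out_high &&
        thr$out_high < 360))
    stop_f("configuration keys classify.{out_low,in_low,in_high,out_high} must satisfy 0 < out_low < in_low < in_high < out_high < 360")
  if (!cfg$classify$aggregation %in% c("per_axon", "pooled"))
    stop_f("configuration key 'classify.aggregation' must be 'per_axon' or 'pooled'")
  in01(cfg$phenotype$mass_threshold, "phenotype.mass_threshold")
  invisible(cfg)
}

#' @rdname load_config
#' @export
format_config <- function(cfg) {
  yaml::as.yaml(cfg)
}

#' Build [sim_params()] from a configuration and seed
#'
#' @param cfg configuration list
#' @param seed integer seed
#' @return `mt_sim_params`
#' @export
config_sim_params <- function(cfg, seed = 1) {
  s <- cfg$simulate
  sim_params(f_plus_end_out = s$f_plus_end_out, comet_speed = s$comet_speed,
             comet_lifetime_mean = s$comet_lifetime_mean,
             comet_birth_rate = s$comet_birth_rate,
             frame_interval = s$frame_interval, n_frames = s$n_frames,
             pixel_size = s$pixel_size, psf_sigma = s$psf_sigma,
             background_photons = s$background_photons,
             comet_peak_photons = s$comet_peak_photons,
             punctum_peak_photons = s$punctum_peak_photons,
             membrane_photons = s$membrane_photons,
             read_noise = s$read_noise, photon_scale = s$photon_scale,
             shot_noise = s$shot_noise, tip_mode = s$tip_mode,
             treatment_frame = s$treatment_frame,
             elongation_rate = s$elongation_rate,
             coupling_radius = s$coupling_radius,
             tip_dwell_fraction = s$tip_dwell_fraction,
             dwell_mean_frames = s$dwell_mean_frames,
             punctum_retract_um = s$punctum_retract_um,
             n_scattered = s$n_scattered, n_tip_cluster = s$n_tip_cluster,
             clearing_speed = s$clearing_speed,
             tip_start_frac = s$tip_start_frac, seed = seed)
}

#' Default link radius from expected comet displacement
#'
#' Three times the expected per-frame comet displacement; generous enough
#' for localization noise, tight enough to avoid cross-linking distant
#' comets.
#'
#' @param cfg configuration list
#' @return link radius in micrometres
#' @export
default_link_radius <- function(cfg) {
  if (!is.null(cfg$link$link_radius)) return(cfg$link$link_radius)
  3 * cfg$simulate$comet_speed * cfg$simulate$frame_interval
}
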