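#' Simulate a condition: movies plus ground truth for a set of cells
#'
#' Generates `config$simulate$n_cells` synthetic cells (geometry, ground
#' truth, rendered movie) and writes, per cell: an interleaved calibrated
#' TIFF movie with JSON sidecar, a polyline ROI file, and ground-truth
#' track / tip-series CSVs; plus a run manifest listing every output, the
#' effective configuration and its MD5 hash.  Identical (config, seed)
#' produce byte-identical CSVs.
#'
#' @param config effective configuration ([load_config()] /
#'   [default_config()])
#' @param out_dir run directory (created)
#' @param seed integer master seed; per-cell seeds are drawn from it
#' @param what "comets" simulates EB1 comet movies (particles + membrane);
#'   "tip" simulates punctum/tip-dynamics movies according to
#'   `config$simulate$tip_mode`
#' @return invisible manifest list
#' @export
run_simulate <- function(config, out_dir, seed = 1, what = c("comets", "tip")) {
  what <- match.arg(what)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_cells <- config$simulate$n_cells
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cell_seeds <- sample.int(1e8, n_cells)

  cells <- list()
  for (i in seq_len(n_cells)) {
    g <- config$geometry
    geom <- make_geometry(n_neurites = g$n_neurites,
                          neurite_length = g$neurite_length,
                          curvature = g$curvature,
                          step_length = g$step_length,
                          neurite_width = g$neurite_width,
                          soma_radius = g$soma_radius,
                          field_size = g$field_size, seed = cell_seeds[i])
    params <- config_sim_params(config, seed = cell_seeds[i])
    tag <- sprintf("cell_%03d", i)
    rois <- geometry_to_rois(geom)
    roi_path <- file.path(out_dir, paste0(tag, "_rois.json"))
    write_roi(rois, roi_path)
    movie_path <- file.path(out_dir, paste0(tag, ".tif"))

    if (what == "comets") {
      gt <- simulate_comet_tracks(geom, params)
      movie <- render_movie(geom, gt$tracks, params)
      truth_path <- file.path(out_dir, paste0(tag, "_truth.csv"))
      if (nrow(gt$tracks)) write_tracks(gt$tracks, truth_path)
      else utils::write.csv(gt$tracks, truth_path, row.names = FALSE)
      tip_path <- NULL
    } else {
      tt <- simulate_tip_dynamics(geom, params)
      puncta <- tt$puncta
      if (!is.null(puncta) && nrow(puncta))
        puncta$peak <- params$punctum_peak_photons
      movie <- render_movie(geom, puncta, params, tip_series = tt$tip_series)
      truth_path <- file.path(out_dir, paste0(tag, "_truth.csv"))
      write_tracks(puncta, truth_path)
      tip_path <- file.path(out_dir, paste0(tag, "_tip_truth.csv"))
      write_tip_series(tt$tip_series, tip_path)
    }
    write_movie(movie, movie_path)
    cells[[i]] <- list(tag = tag, movie = basename(movie_path),
                       rois = basename(roi_path),
                       truth = basename(truth_path),
                       tip_truth = if (is.null(tip_path)) NULL else basename(tip_path),
                       soma_center = geom$soma_center, seed = cell_seeds[i])
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  writeLines(format_config(config), cfg_path)
  manifest <- list(run_id = basename(out_dir), what = what, seed = seed,
                   n_cells = n_cells,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   cells = cells,
                   timestamp = format(Sys.time(), tz = "UTC"),
                   package_version = as.character(utils::packageVersion("neuritemt")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.read_manifest <- function(run_dir) {
  p <- file.path(run_dir, "manifest.json")
  if (!file.exists(p)) stop_f("stage 'analyze': manifest '%s' not found", p)
  jsonlite::read_json(p, simplifyVector = FALSE)
}

#' Analyze a simulated (or equivalent) run directory
#'
#' For comet runs: detection, linking, ROI filtering, polarity
#' classification, per-axon summaries and the condition aggregate; with
#' `from_tracks = TRUE` detection and linking are bypassed and the
#' ground-truth track table is classified directly.  For tip runs: tip
#' tracking from the membrane channel, growth events, tip colocalization
#' and phenotype calls.  Every stage's output is persisted as CSV in
#' `run_dir`.
#'
#' @param run_dir directory produced by [run_simulate()]
#' @param config effective configuration (must match the analysis intent;
#'   the simulation's own config is stored in the run directory)
#' @param from_tracks bypass detection/linking and use the ground-truth
#'   track table
#' @param center "estimate" (from the membrane channel) or "manual" (use
#'   the soma centre recorded in the manifest)
#' @return invisible list with `calls`, `summaries`, `aggregate` (comet
#'   runs) or `tip_series`, `events`, `coloc`, `phenotypes` (tip runs)
#' @export
run_analyze <- function(run_dir, config = NULL, from_tracks = FALSE,
                        center = c("estimate", "manual")) {
  center <- match.arg(center)
  man <- .read_manifest(run_dir)
  if (is.null(config)) config <- load_config(file.path(run_dir, "config.yaml"))
  validate_config(config)
  thr <- classifier_thresholds(config$classify$out_low, config$classify$in_low,
                               config$classify$in_high, config$classify$out_high)
  psf <- config$simulate$psf_sigma
  link_radius <- default_link_radius(config)

  if (man$what == "comets") {
    all_calls <- list(); all_sum <- list()
    for (cell in man$cells) {
      rois <- read_roi(file.path(run_dir, cell$rois))
      if (from_tracks) {
        tracks <- read_tracks(file.path(run_dir, cell$truth))
      } else {
        movie <- read_movie(file.path(run_dir, cell$movie))
        spots <- detect_movie_spots(movie, "particles", psf,
                                    k = config$detect$k,
                                    min_separation_px = config$detect$min_separation_px)
        tracks <- link_spots(spots, link_radius, config$link$max_gap)
      }
      tracks <- filter_tracks(tracks, rois, config$filter$min_length)
      if (nrow(tracks) == 0) next
      ctr <- if (center == "manual") unlist(cell$soma_center)
             else estimate_center(read_movie(file.path(run_dir, cell$movie)),
                                  channel = "membrane")
      calls <- classify_tracks(tracks, ctr, thr, config$classify$straightness_tol)
      calls$cell <- cell$tag
      smry <- summarize_polarity(calls)
      smry$cell <- cell$tag
      all_calls[[length(all_calls) + 1L]] <- calls
      all_sum[[length(all_sum) + 1L]] <- smry
    }
    if (!length(all_sum)) stop_f("stage 'classify': no classifiable tracks in run '%s'", run_dir)
    calls <- do.call(rbind, all_calls)
    summaries <- do.call(rbind, all_sum)
    agg <- aggregate_condition(summaries)
    utils::write.csv(calls, file.path(run_dir, "calls.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summaries, file.path(run_dir, "summaries.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(agg, file.path(run_dir, "condition_aggregate.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(calls = calls, summaries = summaries, aggregate = agg))
  } else {
    ph <- config$phenotype
    tips <- list(); evs <- list(); cols <- list(); phen <- list()
    for (cell in man$cells) {
      rois <- read_roi(file.path(run_dir, cell$rois))
      movie <- read_movie(file.path(run_dir, cell$movie))
      if (from_tracks) {
        ptr <- read_tracks(file.path(run_dir, cell$truth))
      } else {
        spots <- detect_movie_spots(movie, "particles", psf,
                                    k = config$detect$k,
                                    min_separation_px = config$detect$min_separation_px)
        ptr <- link_spots(spots, link_radius = 5, max_gap = config$link$max_gap)
      }
      for (roi in rois) {
        tip <- track_tip(movie, roi, k = ph$tip_k, corridor_pad = ph$corridor_pad)
        tip$cell <- cell$tag
        tips[[length(tips) + 1L]] <- tip
        ev <- try(detect_growth_events(tip, ph$min_growth, ph$smooth_window),
                  silent = TRUE)
        if (!inherits(ev, "try-error") && nrow(ev)) {
          ev$cell <- cell$tag
          evs[[length(evs) + 1L]] <- ev
          cf <- tip_colocalization_fraction(ptr, tip, ev, roi, ph$coloc_radius)
          cols[[length(cols) + 1L]] <- data.frame(
            cell = cell$tag, neurite_id = roi$neurite_id, coloc_fraction = cf)
        }
        pc <- phenotype_neurite(ptr, roi, tip, ph$tip_zone, ph$mass_threshold,
                                config$simulate$treatment_frame,
                                ph$min_displacement)
        pc$cell <- cell$tag
        phen[[length(phen) + 1L]] <- pc
      }
    }
    tip_series <- do.call(rbind, tips)
    events <- if (length(evs)) do.call(rbind, evs) else NULL
    coloc <- if (length(cols)) do.call(rbind, cols) else NULL
    phenotypes <- do.call(rbind, phen)
    utils::write.csv(tip_series, file.path(run_dir, "tip_series.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(events))
      utils::write.csv(events, file.path(run_dir, "growth_events.csv"),
                       row.names = FALSE, quote = FALSE)
    if (!is.null(coloc))
      utils::write.csv(coloc, file.path(run_dir, "colocalization.csv"),
                       row.names = FALSE, quote = FALSE)
    utils::write.csv(phenotypes, file.path(run_dir, "phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    invisible(list(tip_series = tip_series, events = events, coloc = coloc,
                   phenotypes = phenotypes))
  }
}

#' Compare two analyzed runs
#'
#' Applies the statistical comparisons between two conditions: Mann-Whitney
#' U on the per-axon plus-end-out fractions (comet runs) and Fisher's exact
#' test on phenotype count tables (tip runs, when phenotype CSVs are
#' present), then assembles the report bundle via [build_report()].
#'
#' @param dir_a,dir_b analyzed run directories
#' @param out_dir report directory
#' @param name_a,name_b condition labels
#' @return invisible list: `stats` (named list of `mt_stat_result`),
#'   `files`
#' @export
run_compare <- function(dir_a, dir_b, out_dir,
                        name_a = basename(dir_a), name_b = basename(dir_b)) {
  cfg_a <- load_config(file.path(dir_a, "config.yaml"))
  cfg_b <- load_config(file.path(dir_b, "config.yaml"))
  if (!identical(cfg_a$classify$aggregation, cfg_b$classify$aggregation))
    stop_f("incompatible aggregation modes: '%s' vs '%s'",
           cfg_a$classify$aggregation, cfg_b$classify$aggregation)
  stats <- list(); summaries <- list(); counts <- NULL

  sa <- file.path(dir_a, "summaries.csv"); sb <- file.path(dir_b, "summaries.csv")
  if (file.exists(sa) && file.exists(sb)) {
    A <- utils::read.csv(sa); B <- utils::read.csv(sb)
    summaries[[name_a]] <- A; summaries[[name_b]] <- B
    stats[[paste0(name_a, "_vs_", name_b, "_f_out")]] <-
      mann_whitney_u(A$f_out[A$defined], B$f_out[B$defined])
  }
  pa <- file.path(dir_a, "phenotypes.csv"); pb <- file.path(dir_b, "phenotypes.csv")
  if (file.exists(pa) && file.exists(pb)) {
    A <- utils::read.csv(pa); B <- utils::read.csv(pb)
    tab <- rbind(
      c(sum(A$distribution_class == "tip_accumulated"),
        sum(A$distribution_class == "scattered")),
      c(sum(B$distribution_class == "tip_accumulated"),
        sum(B$distribution_class == "scattered")))
    stats[[paste0(name_a, "_vs_", name_b, "_tip_accumulation")]] <-
      fisher_exact_2x2(tab)
    counts <- data.frame(condition = c(name_a, name_b),
                         tip_accumulated = tab[, 1], scattered = tab[, 2])
    retro <- rbind(
      c(sum(A$retrograde_clearing == "yes"), sum(A$retrograde_clearing == "no")),
      c(sum(B$retrograde_clearing == "yes"), sum(B$retrograde_clearing == "no")))
    if (all(rowSums(retro) > 0))
      stats[[paste0(name_a, "_vs_", name_b, "_retrograde")]] <-
        fisher_exact_2x2(retro)
  }
  if (!length(stats))
    stop_f("missing upstream output: no summaries.csv or phenotypes.csv in '%s' / '%s'",
           dir_a, dir_b)
  files <- if (length(summaries))
    build_report(summaries, stats, counts, out_dir)
  else {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    st <- do.call(rbind, lapply(names(stats), function(nm) {
      s <- stats[[nm]]
      data.frame(comparison = nm, test = s$test, statistic = s$statistic,
                 p_value = s$p_value, method = s$method,
                 n = paste(s$n, collapse = "|"))
    }))
    f <- file.path(out_dir, "stats.csv")
    utils::write.csv(st, f, row.names = FALSE, quote = FALSE)
    if (!is.null(counts)) {
      fc <- file.path(out_dir, "phenotype_counts.csv")
      utils::write.csv(counts, fc, row.names = FALSE, quote = FALSE)
      f <- c(f, fc)
    }
    f
  }
  invisible(list(stats = stats, files = files))
}
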