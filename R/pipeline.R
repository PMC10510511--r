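# deterministic sub-seed derivation: keeps every stage independently
# reproducible from one recorded global seed (values stay below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Pipeline run configuration
#'
#' Bundles every stage parameter of a dose-response DEL screening run.
#' Defaults describe the standard planted fixture: a full 192 x 288
#' two-cycle library, two planted amino-acid series and one carboxylic-acid
#' series with log-uniform 1-100 uM series potencies, three library
#' equivalents screened per UV intensity at the protease preset
#' (mu - 4.5 sigma dynamic threshold).
#'
#' @param seed global integer seed (mandatory); every stochastic stage
#'   receives a recorded sub-seed derived from it.
#' @param n_aa,n_ca library cycle sizes.
#' @param uv_intensities UV intensities to screen, high dose first.
#' @param equivalents library equivalents of beads per screen.
#' @param n_aa_series,n_ca_series,potency_range,background_rate,series_width
#'   planted-truth parameters, see [plant_actives()].
#' @param lambda,signal_gain,noise_sd,baseline,baseline_drift droplet assay
#'   parameters, see [screen_config()].
#' @param n_sigma sorting threshold depth.
#' @param time_bin threshold bin width, seconds.
#' @param error_rate sequencing per-base substitution rate.
#' @param min_k,noise_k dose-comparison tier thresholds.
#' @param enzyme label recorded on screens.
#' @return list of class `del_run_config`.
#' @export
run_config <- function(seed, n_aa = 192L, n_ca = 288L,
                       uv_intensities = c(1.0, 0.3), equivalents = 3,
                       n_aa_series = 2L, n_ca_series = 1L,
                       potency_range = c(1, 100), background_rate = 1e-4,
                       series_width = NULL,
                       lambda = 0.2, signal_gain = 90, noise_sd = 10,
                       baseline = 20, baseline_drift = 0,
                       n_sigma = 4.5, time_bin = 60, error_rate = 0.005,
                       min_k = 4L, noise_k = 3L, enzyme = "FXa") {
  if (missing(seed) || is.null(seed)) {
    stop("run_config() requires an explicit seed")
  }
  stopifnot(length(uv_intensities) >= 1, equivalents > 0)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "del_run_config"
  cfg
}

#' Simulate, sort and deconvolute one screen at a given UV intensity
#'
#' Convenience wrapper for one arm of the pipeline: simulate the droplet
#' stream for the requested number of library equivalents, bin and
#' threshold it, sort hits, sequence and decode hit beads, and build the
#' k-class table.
#'
#' @param catalog,activity,cal shared library, truth and calibration.
#' @param uv UV intensity for this screen.
#' @param cfg a `del_run_config`.
#' @param seed screen-specific seed.
#' @return list: stream config used, `sort` (`del_sort_result`), `rate`
#'   (`del_hit_rate`), `epsilon`, `kclass` (`del_kclass_table`), `decode`.
#' @export
run_screen <- function(catalog, activity, cal, uv, cfg, seed) {
  n_members <- nrow(catalog$members)
  target_beads <- cfg$equivalents * n_members
  # duration such that rate * duration * 60 * lambda ~ target bead count
  duration <- target_beads / (cfg$lambda * 300 * 60)
  scfg <- screen_config(
    uv_intensity = uv, enzyme = cfg$enzyme, droplet_rate = 300,
    lambda = cfg$lambda, signal_gain = cfg$signal_gain,
    noise_sd = cfg$noise_sd, baseline = cfg$baseline,
    baseline_drift = cfg$baseline_drift, duration = duration,
    seed = derive_seed(seed, 1L))
  stream <- simulate_screen(catalog, activity, cal, scfg)
  stats <- compute_bin_stats(stream, cfg$time_bin)
  thr <- dynamic_threshold(stats, cfg$n_sigma)
  sorted <- sort_events(stream, thr, catalog)
  reads <- reads_from_hits(sorted, catalog, cfg$error_rate,
                           seed = derive_seed(seed, 2L))
  dec <- decode_reads(reads, catalog)
  kc <- k_class_table(dec, catalog,
                      screen_label = sprintf("uv%03d", round(100 * uv)))
  list(config = scfg, bin_stats = stats, thresholds = thr, sort = sorted,
       rate = hit_rate(sorted),
       epsilon = library_equivalents(sorted$beads_screened, n_members),
       decode = dec, kclass = kc)
}

#' Run the full dose-response DEL screening pipeline
#'
#' Executes build-library, plant, simulate/sort/deconvolute per UV
#' intensity, dose comparison and recovery scoring; optionally writes every
#' artifact (TSV/CSV/FASTQ/JSON) into `outdir`. Reruns with the same config
#' are identical; the summary JSON records the seed and per-stage
#' sub-seeds.
#'
#' @param cfg a [run_config()].
#' @param outdir output directory (NULL = keep results in memory only).
#' @param write_streams also write the (large) droplet event CSVs
#'   (default FALSE).
#' @return list of class `del_run`: catalog, activity, calibration,
#'   screens (one per UV intensity), report, recovery, summary.
#' @export
run_pipeline <- function(cfg, outdir = NULL, write_streams = FALSE) {
  stopifnot(inherits(cfg, "del_run_config"))
  catalog <- synthetic_library(cfg$n_aa, cfg$n_ca,
                               seed = derive_seed(cfg$seed, 10L))
  activity <- plant_actives(
    catalog, n_aa_series = cfg$n_aa_series, n_ca_series = cfg$n_ca_series,
    potency_range = cfg$potency_range,
    background_rate = cfg$background_rate, series_width = cfg$series_width,
    seed = derive_seed(cfg$seed, 20L))
  cal <- dose_calibration()
  screens <- lapply(seq_along(cfg$uv_intensities), function(i) {
    run_screen(catalog, activity, cal, cfg$uv_intensities[i], cfg,
               seed = derive_seed(cfg$seed, 30L + i))
  })
  names(screens) <- sprintf("uv%03d", round(100 * cfg$uv_intensities))
  report <- recovery <- NULL
  if (length(screens) >= 2L) {
    report <- dose_compare(screens[[1]]$kclass, screens[[2]]$kclass,
                           min_k = cfg$min_k, noise_k = cfg$noise_k)
    recovery <- score_recovery(report, activity)
  }
  summary <- list(
    seed = cfg$seed,
    library = list(n_aa = cfg$n_aa, n_ca = cfg$n_ca,
                   members = nrow(catalog$members)),
    screens = lapply(screens, function(s) list(
      uv = s$config$uv_intensity,
      droplets = s$sort$droplets,
      beads_screened = s$sort$beads_screened,
      epsilon = s$epsilon,
      hit_beads = s$sort$hit_bead_count,
      hit_rate_percent = s$rate$percent,
      hit_rate_ci = c(s$rate$ci_lo, s$rate$ci_hi),
      n_sigma = s$sort$n_sigma,
      decoded = s$decode$n_decoded,
      discarded = nrow(s$decode$discarded))),
    tiers = if (!is.null(report)) as.list(table(report$bb$tier)),
    recovery = if (!is.null(recovery)) {
      recovery[c("precision", "recall", "spearman")]
    }
  )
  out <- list(catalog = catalog, activity = activity, calibration = cal,
              screens = screens, report = report, recovery = recovery,
              summary = summary, config = cfg)
  class(out) <- "del_run"
  if (!is.null(outdir)) .write_run(out, outdir, write_streams)
  out
}

.write_run <- function(run, outdir, write_streams) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_bb_tsv(run$catalog$aa, file.path(outdir, "bb_aa.tsv"))
  write_bb_tsv(run$catalog$ca, file.path(outdir, "bb_ca.tsv"))
  write_catalog_tsv(run$catalog, file.path(outdir, "catalog.tsv"))
  act <- data.frame(member_id = run$catalog$members$member_id,
                    ic50_uM = run$activity$ic50,
                    delivery = run$activity$delivery)
  utils::write.table(act, file.path(outdir, "activity_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(run$screens)) {
    s <- run$screens[[nm]]
    if (write_streams) {
      # re-simulate for the CSV: streams are not retained in the run object
      stream <- simulate_screen(run$catalog, run$activity,
                                run$calibration, s$config)
      write_events_csv(stream, run$catalog,
                       file.path(outdir, paste0("events_", nm, ".csv")))
    }
    utils::write.table(s$bin_stats,
                       file.path(outdir, paste0("bin_stats_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(s$kclass$bb,
                       file.path(outdir, paste0("kclass_bb_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$report)) {
    write_dose_report(run$report,
                      tsv_path = file.path(outdir, "dose_report.tsv"),
                      json_path = file.path(outdir, "dose_report.json"))
  }
  jsonlite::write_json(run$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.del_run <- function(x, ...) {
  cat(sprintf("DEL dose-response run (seed %d): %d members, %d screens\n",
              x$config$seed, nrow(x$catalog$members), length(x$screens)))
  for (s in x$screens) {
    cat(sprintf("  uv %3d%%: %.2fe screened, hit rate %.3f%%\n",
                round(100 * s$config$uv_intensity), s$epsilon,
                s$rate$percent))
  }
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}
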