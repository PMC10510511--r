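#' Fractional enzyme activity under competitive inhibition
#'
#' Standard single-site inhibition law: a = 1 / (1 + (\[I\]/IC50)^hill).
#' Activity is 1 with no inhibitor and falls to 0.5 at \[I\] = IC50.
#' Vectorized over all arguments; IC50 = Inf denotes an inactive compound.
#'
#' @param conc inhibitor concentration in uM (>= 0).
#' @param ic50 IC50 in uM (> 0, or Inf).
#' @param hill Hill coefficient (> 0, default 1).
#' @return fractional activity in (0, 1].
#' @export
fractional_activity <- function(conc, ic50, hill = 1) {
  if (any(conc < 0)) stop("conc must be >= 0")
  if (any(ic50 <= 0)) stop("ic50 must be > 0 (use Inf for inactive)")
  if (any(hill <= 0)) stop("hill must be > 0")
  # (conc/ic50)^hill with ic50 = Inf -> 0, conc = 0 -> 0
  r <- (conc / ic50)^hill
  r[conc == 0] <- 0
  1 / (1 + r)
}

#' Z-prime assay quality score
#'
#' Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|. Scores above 0.5
#' indicate an assay suitable for screening; at equal variances that
#' boundary corresponds to a 12-standard-deviation separation between the
#' positive and negative control signals.
#'
#' @param pos_signals,neg_signals numeric control measurements (>= 2 each).
#' @return Z' score (<= 1).
#' @examples
#' neg <- c(100, 101, 99, 100)
#' pos <- neg - 12 * sd(neg)
#' zprime(pos, neg)  # 0.5
#' @export
zprime <- function(pos_signals, neg_signals) {
  if (length(pos_signals) < 2L || length(neg_signals) < 2L) {
    stop("each control sample needs >= 2 points")
  }
  dmu <- abs(mean(pos_signals) - mean(neg_signals))
  if (dmu == 0) stop("control means are equal: no separation, Z' undefined")
  1 - 3 * (stats::sd(pos_signals) + stats::sd(neg_signals)) / dmu
}

#' Screen configuration
#'
#' Parameters of one droplet screening run. Defaults describe the
#' fluorogenic endpoint assay regime used throughout: uninhibited droplets
#' fluoresce at baseline + gain RFU; a fully inhibited droplet sits at
#' baseline; detector noise is Gaussian.
#'
#' @param uv_intensity UV photocleavage intensity, fraction of maximum.
#' @param enzyme free-text label (e.g. "FXa", "ATX"); metadata only.
#' @param droplet_rate droplets generated per second.
#' @param lambda mean bead occupancy per droplet (Poisson).
#' @param signal_gain RFU span between zero and full enzyme activity.
#' @param noise_sd detector noise standard deviation, RFU.
#' @param baseline RFU at zero enzyme activity.
#' @param baseline_drift linear baseline drift, RFU per minute.
#' @param duration run length in minutes.
#' @param seed integer seed (mandatory).
#' @return list of class `del_screen_config`.
#' @export
screen_config <- function(uv_intensity, enzyme = "FXa", droplet_rate = 300,
                          lambda = 0.2, signal_gain = 90, noise_sd = 10,
                          baseline = 20, baseline_drift = 0, duration = 10,
                          seed) {
  if (missing(seed)) stop("screen_config() requires an explicit seed")
  stopifnot(uv_intensity >= 0, uv_intensity <= 1, lambda >= 0,
            noise_sd > 0, duration > 0, droplet_rate > 0)
  structure(list(
    uv_intensity = uv_intensity, enzyme = enzyme,
    droplet_rate = droplet_rate, lambda = lambda,
    signal_gain = signal_gain, noise_sd = noise_sd, baseline = baseline,
    baseline_drift = baseline_drift, duration = duration,
    seed = as.integer(seed)
  ), class = "del_screen_config")
}

#' Simulate a droplet screening run
#'
#' Generates the endpoint fluorescence event stream of a bead-based droplet
#' screen. Per droplet: bead count ~ Poisson(lambda); beads are drawn
#' uniformly from the catalog; each bead releases
#' dose_to_concentration(uv) x delivery factor uM of its compound; the
#' droplet's fractional enzyme activity is the product of the per-compound
#' activities (independent inhibition); fluorescence is
#' baseline + drift x t + gain x activity + Gaussian noise. Empty droplets
#' have activity 1. Events are emitted in time order at a fixed droplet
#' rate; the stream is reproducible given the config seed.
#'
#' @param catalog a `del_catalog`.
#' @param activity a `del_activity_map` from [plant_actives()].
#' @param cal a [dose_calibration()].
#' @param cfg a [screen_config()].
#' @return object of class `del_stream`: list with `events`
#'   (data.frame time, rfu, n_beads), `beads` (data.frame event, member —
#'   integer row index into `catalog$members`), and `config`.
#' @export
simulate_screen <- function(catalog, activity, cal, cfg) {
  stopifnot(inherits(catalog, "del_catalog"),
            inherits(activity, "del_activity_map"),
            inherits(cal, "del_dose_cal"),
            inherits(cfg, "del_screen_config"))
  if (activity$n_members != nrow(catalog$members)) {
    stop("activity map and catalog describe different libraries")
  }
  if (cfg$lambda > 0 &&
      stats::qpois(1 - 1e-12, cfg$lambda) > 64) {
    stop("lambda implies > 64 beads/droplet; not a physical droplet regime")
  }
  set.seed(cfg$seed)
  n <- as.integer(round(cfg$droplet_rate * cfg$duration * 60))
  time <- seq_len(n) / cfg$droplet_rate
  n_beads <- stats::rpois(n, cfg$lambda)
  total_beads <- sum(n_beads)
  act <- rep(1, n)
  beads <- data.frame(event = integer(0), member = integer(0))
  if (total_beads > 0) {
    ev <- rep.int(seq_len(n), n_beads)
    member <- sample.int(nrow(catalog$members), total_beads, replace = TRUE)
    beads <- data.frame(event = ev, member = member)
    conc <- dose_to_concentration(cfg$uv_intensity, cal) *
      activity$delivery[member]
    a_bead <- fractional_activity(conc, activity$ic50[member], activity$hill)
    # only droplets holding an inhibiting bead deviate from activity 1
    hot <- a_bead < 1
    if (any(hot)) {
      la <- rowsum(log(a_bead[hot]), group = ev[hot])
      act[as.integer(rownames(la))] <- exp(la[, 1])
    }
  }
  rfu <- cfg$baseline + cfg$baseline_drift * (time / 60) +
    cfg$signal_gain * act + stats::rnorm(n, 0, cfg$noise_sd)
  structure(list(
    events = data.frame(time = time, rfu = rfu, n_beads = n_beads),
    beads = beads, config = cfg
  ), class = "del_stream")
}

#' @export
print.del_stream <- function(x, ...) {
  cat(sprintf(
    "Droplet stream: %d droplets over %.1f min, %d beads (uv = %d%%, %s)\n",
    nrow(x$events), x$config$duration, nrow(x$beads),
    round(100 * x$config$uv_intensity), x$config$enzyme))
  invisible(x)
}

#' Write / read a droplet event stream as CSV
#'
#' Columns: time_s, rfu, n_beads, bead_member_ids (semicolon-joined
#' member_id strings; empty for bead-free droplets).
#'
#' @param stream a `del_stream`.
#' @param catalog the catalog the stream was simulated from (for member ids).
#' @param path output file.
#' @export
write_events_csv <- function(stream, catalog, path) {
  stopifnot(inherits(stream, "del_stream"), inherits(catalog, "del_catalog"))
  ids <- rep("", nrow(stream$events))
  if (nrow(stream$beads)) {
    joined <- tapply(catalog$members$member_id[stream$beads$member],
                     stream$beads$event, paste, collapse = ";")
    ids[as.integer(names(joined))] <- joined
  }
  df <- data.frame(time_s = stream$events$time, rfu = stream$events$rfu,
                   n_beads = stream$events$n_beads, bead_member_ids = ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path, catalog) {
  df <- utils::read.csv(path, colClasses = c(bead_member_ids = "character"))
  has <- nzchar(df$bead_member_ids)
  beads <- data.frame(event = integer(0), member = integer(0))
  if (any(has)) {
    parts <- strsplit(df$bead_member_ids[has], ";", fixed = TRUE)
    ev <- rep.int(which(has), lengths(parts))
    member <- match(unlist(parts), catalog$members$member_id)
    if (anyNA(member)) stop("event CSV references unknown member ids")
    beads <- data.frame(event = ev, member = member)
  }
  structure(list(
    events = data.frame(time = df$time_s, rfu = df$rfu,
                        n_beads = df$n_beads),
    beads = beads, config = NULL
  ), class = "del_stream")
}
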