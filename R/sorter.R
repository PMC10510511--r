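#' Per-time-bin droplet signal statistics
#'
#' Partitions the event stream into disjoint time bins of `time_bin`
#' seconds covering \[k w, (k+1) w) and reports the mean and standard
#' deviation of droplet fluorescence per bin, over all droplets in the bin
#' (hits included — a real-time sorter cannot pre-exclude them; at hit
#' fractions below a quarter percent the moment bias is negligible).
#' Empty bins are kept as records with zero counts and NA moments.
#'
#' @param stream a `del_stream` (or any list with an `events` data.frame
#'   holding `time`, `rfu`, `n_beads`).
#' @param time_bin bin width in seconds (default 60).
#' @return data.frame of class `del_bin_stats`: bin_start, bin_width, mu,
#'   sigma, droplet_count, bead_count.
#' @export
compute_bin_stats <- function(stream, time_bin = 60) {
  ev <- stream$events
  if (is.null(ev) || nrow(ev) == 0L) stop("empty event stream")
  stopifnot(time_bin > 0)
  bin <- floor(ev$time / time_bin)
  bins <- seq.int(min(bin), max(bin))
  idx <- factor(bin, levels = bins)
  cnt <- as.integer(table(idx))
  mu <- as.numeric(tapply(ev$rfu, idx, mean))
  sigma <- as.numeric(tapply(ev$rfu, idx, stats::sd))
  sigma[cnt == 1L] <- 0
  beads <- as.numeric(tapply(ev$n_beads, idx, sum))
  beads[is.na(beads)] <- 0
  out <- data.frame(
    bin_start = bins * time_bin, bin_width = time_bin, mu = mu,
    sigma = sigma, droplet_count = cnt, bead_count = as.integer(beads)
  )
  class(out) <- c("del_bin_stats", "data.frame")
  out
}

#' Dynamic mean-minus-N-sigma sorting thresholds
#'
#' For each time bin the sorting threshold is mu - n_sigma x sigma of that
#' bin's droplet signal, tracking baseline drift. Bins with fewer than
#' `min_events` droplets give unstable moment estimates; their threshold is
#' carried forward from the last well-populated bin and flagged. Leading
#' sparse bins (no previous bin to carry from) fall back to the moments of
#' the whole stream, also flagged.
#'
#' @param stats a `del_bin_stats` from [compute_bin_stats()].
#' @param n_sigma threshold depth in bin standard deviations (> 0); 4.5 is
#'   the protease preset, 6 the more stringent phosphodiesterase preset.
#' @param min_events minimum droplets per bin for a fresh estimate
#'   (default 100).
#' @return data.frame of class `del_thresholds`: bin_start, bin_width,
#'   threshold, carried (logical), plus attribute `n_sigma`.
#' @export
dynamic_threshold <- function(stats, n_sigma = 4.5, min_events = 100L) {
  stopifnot(inherits(stats, "del_bin_stats"), n_sigma > 0)
  k <- nrow(stats)
  thr <- stats$mu - n_sigma * stats$sigma
  ok <- stats$droplet_count >= min_events & !is.na(thr)
  carried <- !ok
  if (!any(ok)) stop("no bin has >= ", min_events, " droplets")
  # global fallback for leading sparse bins
  w <- stats$droplet_count
  gmu <- sum(stats$mu * w, na.rm = TRUE) / sum(w[!is.na(stats$mu)])
  gthr <- NA_real_
  last <- NA_real_
  for (i in seq_len(k)) {
    if (ok[i]) {
      last <- thr[i]
    } else {
      if (is.na(last)) {
        if (is.na(gthr)) {
          # exact pooled moments of the whole stream from per-bin stats
          nz <- w > 0
          ss <- sum((w[nz] - 1) * stats$sigma[nz]^2 +
                      w[nz] * (stats$mu[nz] - gmu)^2)
          gsd <- sqrt(ss / max(sum(w) - 1, 1))
          gthr <- gmu - n_sigma * gsd
        }
        thr[i] <- gthr
      } else {
        thr[i] <- last
      }
    }
  }
  out <- data.frame(bin_start = stats$bin_start,
                    bin_width = stats$bin_width,
                    threshold = thr, carried = carried)
  attr(out, "n_sigma") <- n_sigma
  class(out) <- c("del_thresholds", "data.frame")
  out
}

#' Binary droplet sorting against per-bin thresholds
#'
#' A droplet is sorted as a hit when its fluorescence is strictly below the
#' threshold of its time bin (ties are non-hits). Hit droplets retain the
#' identities of their beads; every bead in a hit droplet is collected.
#'
#' @param stream a `del_stream`.
#' @param thresholds a `del_thresholds` covering the stream's time range.
#' @param catalog optional `del_catalog` to attach member_id strings to hit
#'   beads.
#' @return object of class `del_sort_result`: list with `hits` (data.frame
#'   time, rfu, n_beads), `hit_beads` (data.frame event, member, and
#'   member_id when a catalog is given), `thresholds`, `n_sigma`,
#'   `droplets`, `beads_screened`, `hit_bead_count`.
#' @export
sort_events <- function(stream, thresholds, catalog = NULL) {
  stopifnot(inherits(thresholds, "del_thresholds"))
  ev <- stream$events
  w <- thresholds$bin_width[1]
  bin <- floor(ev$time / w)
  pos <- match(bin * w, thresholds$bin_start)
  if (anyNA(pos)) stop("events fall outside threshold coverage")
  is_hit <- ev$rfu < thresholds$threshold[pos]
  hit_events <- which(is_hit)
  hit_beads <- stream$beads[stream$beads$event %in% hit_events, , drop = FALSE]
  rownames(hit_beads) <- NULL
  if (!is.null(catalog)) {
    hit_beads$member_id <- catalog$members$member_id[hit_beads$member]
  }
  structure(list(
    hits = ev[hit_events, , drop = FALSE],
    hit_beads = hit_beads,
    thresholds = thresholds,
    n_sigma = attr(thresholds, "n_sigma"),
    droplets = nrow(ev),
    beads_screened = sum(ev$n_beads),
    hit_bead_count = nrow(hit_beads)
  ), class = "del_sort_result")
}

#' @export
print.del_sort_result <- function(x, ...) {
  hr <- hit_rate(x)
  cat(sprintf(
    "Sort: %d hit droplets / %d droplets; %d hit beads / %d beads (%.3f%%)\n",
    nrow(x$hits), x$droplets, x$hit_bead_count, x$beads_screened,
    hr$percent))
  invisible(x)
}

#' Hit rate with exact binomial confidence interval
#'
#' Hit beads divided by beads screened, as a percentage, with a 95%
#' Clopper-Pearson interval.
#'
#' @param result a `del_sort_result`, or a count of hit beads.
#' @param beads_screened required when `result` is a count.
#' @param conf confidence level (default 0.95).
#' @return list of class `del_hit_rate`: percent, ci_lo, ci_hi (percent),
#'   hits, beads.
#' @export
hit_rate <- function(result, beads_screened = NULL, conf = 0.95) {
  if (inherits(result, "del_sort_result")) {
    x <- result$hit_bead_count
    n <- result$beads_screened
  } else {
    x <- result
    n <- beads_screened
  }
  if (is.null(n) || n <= 0) stop("beads_screened must be > 0")
  if (x < 0 || x > n) stop("hit count must be within [0, beads_screened]")
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(percent = 100 * x / n, ci_lo = 100 * lo, ci_hi = 100 * hi,
                 hits = x, beads = n),
            class = "del_hit_rate")
}

#' @export
print.del_hit_rate <- function(x, ...) {
  cat(sprintf("Hit rate: %.3f%% (95%% CI %.3f-%.3f%%; %d/%d beads)\n",
              x$percent, x$ci_lo, x$ci_hi, x$hits, x$beads))
  invisible(x)
}

#' Library equivalents screened
#'
#' epsilon = beads screened / library size; one equivalent corresponds to
#' one bead per library member on average.
#'
#' @param beads_screened bead count (>= 0).
#' @param library_size number of library members (> 0).
#' @return numeric epsilon.
#' @examples
#' library_equivalents(497664, 55296)  # 9
#' @export
library_equivalents <- function(beads_screened, library_size) {
  if (library_size <= 0) stop("library_size must be > 0")
  if (beads_screened < 0) stop("beads_screened must be >= 0")
  beads_screened / library_size
}
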