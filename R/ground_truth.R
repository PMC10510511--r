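#' Generate a synthetic two-cycle DEL catalog
#'
#' Stand-in for a real building-block catalog: random DNA encoding tags
#' (pairwise Hamming distance >= 3 within each cycle) and building-block
#' properties drawn so that the assembled library is lead-like — member
#' molecular weights centered near 390 Da (about 98% below 500 Da) and
#' member cLogP centered near 1.2 (about 99.8% below 5).
#'
#' @param n_aa number of cycle-1 amino acids (default 192).
#' @param n_ca number of cycle-2 carboxylic acids (default 288).
#' @param tag_length nucleotides per cycle tag (default 12).
#' @param seed integer seed.
#' @return a `del_catalog` (see [enumerate_library()]).
#' @export
synthetic_library <- function(n_aa = 192L, n_ca = 288L, tag_length = 12L,
                              seed) {
  if (missing(seed)) stop("synthetic_library() requires an explicit seed")
  seed <- as.integer(seed)
  aa_tags <- generate_tags(n_aa, tag_length, 3L, seed = seed)
  ca_tags <- generate_tags(n_ca, tag_length, 3L, seed = seed + 1L)
  set.seed(seed + 2L)
  aa <- building_blocks(
    sprintf("AA%03d", seq_len(n_aa)), 1L, aa_tags,
    mw = stats::rnorm(n_aa, 225, 40),
    clogp = stats::rnorm(n_aa, 0.3, 0.9),
    hbd = stats::rpois(n_aa, 1), hba = stats::rpois(n_aa, 2),
    rotb = stats::rpois(n_aa, 2)
  )
  ca <- building_blocks(
    sprintf("CA%03d", seq_len(n_ca)), 2L, ca_tags,
    mw = stats::rnorm(n_ca, 183, 38),
    clogp = stats::rnorm(n_ca, 0.9, 0.9),
    hbd = stats::rpois(n_ca, 0.5), hba = stats::rpois(n_ca, 1.5),
    rotb = stats::rpois(n_ca, 1.5)
  )
  aa$mw <- pmax(aa$mw, 75); ca$mw <- pmax(ca$mw, 46)
  enumerate_library(aa, ca)
}

#' Plant ground-truth inhibitor activity structured by building-block series
#'
#' Selects `n_aa_series` amino acids and `n_ca_series` carboxylic acids as
#' "warm" building blocks. Every member containing a warm block (or, when
#' `series_width` is given, a fixed-size subset of its partner combinations)
#' is active with a potency correlated within the series:
#' log10(IC50) = series mean + N(0, `jitter_sd`), the series mean drawn
#' log-uniformly over `potency_range`. Isolated background actives are added
#' at `background_rate` with independent log-uniform potencies. All other
#' members are inactive (IC50 = Inf). Series membership is deterministic in
#' count: a full series covers all partner blocks; `series_width` selects
#' exactly that many partners (sampled, but the count is exact).
#'
#' Each member additionally receives a delivery factor modeling
#' failed/truncated synthesis: with probability `truncate_rate` a member's
#' beads deliver no compound (factor 0), otherwise full dose (factor 1).
#'
#' @param catalog a `del_catalog`.
#' @param n_aa_series,n_ca_series number of warm building blocks per cycle.
#' @param potency_range numeric length-2, series-mean IC50 bounds in uM;
#'   must lie in (0, 1000].
#' @param background_rate per-member probability of an isolated background
#'   active, in \[0, 1\].
#' @param series_width number of partner blocks per series (default NULL =
#'   all partners).
#' @param jitter_sd within-series spread of log10(IC50) (default 0.2 dex).
#' @param hill Hill coefficient shared by all actives (default 1).
#' @param truncate_rate per-member probability of failed synthesis
#'   (default 0.1).
#' @param target_id free-text label for the screened target.
#' @param seed integer seed; the map is reproducible given the seed.
#' @return object of class `del_activity_map`: list with `ic50` (numeric,
#'   uM, Inf = inactive), `hill`, `delivery` (0/1 per member), `series`
#'   (data.frame bb_id, cycle, mean_ic50, width), `background_members`,
#'   `target_id`, `seed`.
#' @export
plant_actives <- function(catalog, n_aa_series = 2L, n_ca_series = 1L,
                          potency_range = c(1, 100), background_rate = 1e-4,
                          series_width = NULL, jitter_sd = 0.2, hill = 1,
                          truncate_rate = 0.1, target_id = "target",
                          seed) {
  stopifnot(inherits(catalog, "del_catalog"))
  if (missing(seed)) stop("plant_actives() requires an explicit seed")
  if (length(potency_range) != 2L || any(potency_range <= 0) ||
      any(potency_range > 1000) || diff(potency_range) < 0) {
    stop("potency_range must be increasing and within (0, 1000] uM")
  }
  if (background_rate < 0 || background_rate > 1) {
    stop("background_rate must be in [0, 1]")
  }
  if (truncate_rate < 0 || truncate_rate > 1) {
    stop("truncate_rate must be in [0, 1]")
  }
  if (n_aa_series > catalog$aa_count) {
    stop("n_aa_series exceeds number of amino acids")
  }
  if (n_ca_series > catalog$ca_count) {
    stop("n_ca_series exceeds number of carboxylic acids")
  }
  set.seed(as.integer(seed))
  m <- catalog$members
  n <- nrow(m)
  ic50 <- rep(Inf, n)

  warm_aa <- if (n_aa_series > 0) {
    sample(catalog$aa$bb_id, n_aa_series)
  } else character(0)
  warm_ca <- if (n_ca_series > 0) {
    sample(catalog$ca$bb_id, n_ca_series)
  } else character(0)
  n_series <- length(warm_aa) + length(warm_ca)
  series <- data.frame(
    bb_id = c(warm_aa, warm_ca),
    cycle = c(rep(1L, length(warm_aa)), rep(2L, length(warm_ca))),
    mean_ic50 = rep(NA_real_, n_series),
    width = rep(NA_integer_, n_series),
    stringsAsFactors = FALSE
  )
  lpr <- log10(potency_range)
  for (i in seq_len(nrow(series))) {
    mean_lic50 <- stats::runif(1, lpr[1], lpr[2])
    idx <- if (series$cycle[i] == 1L) {
      which(m$aa_id == series$bb_id[i])
    } else {
      which(m$ca_id == series$bb_id[i])
    }
    if (!is.null(series_width)) {
      if (series_width > length(idx)) {
        stop("series_width exceeds partner count")
      }
      idx <- sample(idx, series_width)
    }
    series$mean_ic50[i] <- 10^mean_lic50
    series$width[i] <- length(idx)
    lic50 <- mean_lic50 + stats::rnorm(length(idx), 0, jitter_sd)
    # a member in two overlapping series keeps its more potent assignment
    ic50[idx] <- pmin(ic50[idx], 10^lic50)
  }

  bg <- which(stats::runif(n) < background_rate & !is.finite(ic50))
  if (length(bg)) {
    ic50[bg] <- 10^stats::runif(length(bg), lpr[1], lpr[2])
  }
  delivery <- as.numeric(stats::runif(n) >= truncate_rate)

  structure(list(
    target_id = target_id, ic50 = ic50, hill = hill, delivery = delivery,
    series = series, background_members = m$member_id[bg],
    n_members = n, seed = as.integer(seed)
  ), class = "del_activity_map")
}

#' Construct an activity map from explicit per-member potencies
#'
#' Lower-level companion to [plant_actives()] for fully specified ground
#' truths (fixtures, single-compound checks).
#'
#' @param catalog a `del_catalog`.
#' @param ic50 per-member IC50 in uM (recycled); Inf = inactive.
#' @param hill Hill coefficient.
#' @param delivery per-member delivered-dose factor in \[0, 1\] (recycled).
#' @param target_id free-text label.
#' @return a `del_activity_map` with an empty series table.
#' @export
activity_map <- function(catalog, ic50, hill = 1, delivery = 1,
                         target_id = "target") {
  stopifnot(inherits(catalog, "del_catalog"))
  n <- nrow(catalog$members)
  ic50 <- rep_len(as.numeric(ic50), n)
  if (any(ic50 <= 0)) stop("ic50 must be > 0 (Inf = inactive)")
  delivery <- rep_len(as.numeric(delivery), n)
  structure(list(
    target_id = target_id, ic50 = ic50, hill = hill, delivery = delivery,
    series = data.frame(bb_id = character(0), cycle = integer(0),
                        mean_ic50 = numeric(0), width = integer(0)),
    background_members = character(0), n_members = n, seed = NA_integer_
  ), class = "del_activity_map")
}

#' @export
print.del_activity_map <- function(x, ...) {
  cat(sprintf(
    "Activity map '%s': %d/%d active members (%d series, %d background)\n",
    x$target_id, sum(is.finite(x$ic50)), x$n_members, nrow(x$series),
    length(x$background_members)))
  invisible(x)
}

#' UV dose to released-compound concentration calibration
#'
#' Anchored on photocleavable-fluorescein measurements: 90, 60 and 50 uM
#' released in droplets at 100%, 30% and 20% of maximum UV intensity, with
#' nothing released at zero dose. The default interpolation is monotone
#' piecewise-linear through the measured anchors; `mode = "linear"` instead
#' uses strict proportionality through (0, 0) and (1, 90).
#'
#' @param anchors data.frame(uv, conc) of calibration points; must include
#'   uv = 0 with conc = 0 (added if absent) and be monotone non-decreasing.
#' @param mode "anchored" (piecewise-linear through anchors, default) or
#'   "linear" (proportional to the maximum-dose anchor).
#' @return object of class `del_dose_cal`.
#' @export
dose_calibration <- function(anchors = data.frame(
                               uv = c(0, 0.2, 0.3, 1.0),
                               conc = c(0, 50, 60, 90)),
                             mode = c("anchored", "linear")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(anchors), all(c("uv", "conc") %in% names(anchors)))
  anchors <- anchors[order(anchors$uv), , drop = FALSE]
  if (!any(anchors$uv == 0)) {
    anchors <- rbind(data.frame(uv = 0, conc = 0), anchors)
  }
  if (anchors$conc[anchors$uv == 0][1] != 0) {
    stop("calibration must release 0 uM at uv = 0")
  }
  if (any(anchors$uv < 0 | anchors$uv > 1)) stop("uv anchors must be in [0,1]")
  if (is.unsorted(anchors$conc)) {
    stop("released concentration must be monotone non-decreasing in uv")
  }
  structure(list(anchors = anchors, mode = mode), class = "del_dose_cal")
}

#' Convert a UV intensity to a released compound concentration
#'
#' @param uv UV intensity as a fraction of maximum, in \[0, 1\] (vectorized).
#' @param cal a [dose_calibration()] object.
#' @return released concentration in uM.
#' @examples
#' cal <- dose_calibration()
#' dose_to_concentration(c(0, 0.2, 1), cal)  # 0, 50, 90
#' @export
dose_to_concentration <- function(uv, cal = dose_calibration()) {
  stopifnot(inherits(cal, "del_dose_cal"))
  if (any(uv < 0 | uv > 1)) stop("uv must be within [0, 1]")
  if (cal$mode == "linear") {
    top <- cal$anchors[nrow(cal$anchors), ]
    return(uv * top$conc / top$uv)
  }
  stats::approx(cal$anchors$uv, cal$anchors$conc, xout = uv,
                method = "linear", rule = 2)$y
}
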