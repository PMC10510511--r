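# Shared fixtures and independent reference implementations.

# deterministic hand-written tag sets (pairwise Hamming distance >= 3)
tiny_aa_tags <- c("AAAAAAAAAAAA", "CCCCAAAAAAAA", "AAAACCCCAAAA")
tiny_ca_tags <- c("GGGGGGGGGGGG", "TTTTGGGGGGGG", "GGGGTTTTGGGG",
                  "GGGGGGGGTTTT")

tiny_catalog <- function() {
  aa <- building_blocks(c("a1", "a2", "a3"), 1, tiny_aa_tags,
                        mw = c(200, 250, 300), clogp = c(0.5, 1, 2),
                        hbd = 1, hba = 2, rotb = 2)
  ca <- building_blocks(c("c1", "c2", "c3", "c4"), 2, tiny_ca_tags,
                        mw = c(120, 150, 180, 210), clogp = c(0, 1, 2, 3),
                        hbd = 0, hba = 1, rotb = 1)
  enumerate_library(aa, ca)
}

# control sample with exactly the requested sample mean and sd
exact_controls <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  mean + sd * (x - base::mean(x)) / stats::sd(x)
}

# independent single-pass reference for bin/threshold/sort: plain loops,
# moments recomputed per bin from raw events
brute_sort_reference <- function(events, time_bin, n_sigma,
                                 min_events = 100) {
  bin_of <- floor(events$time / time_bin)
  bins <- seq(min(bin_of), max(bin_of))
  thr <- numeric(length(bins))
  last <- NA_real_
  for (i in seq_along(bins)) {
    rfu <- events$rfu[bin_of == bins[i]]
    if (length(rfu) >= min_events) {
      last <- base::mean(rfu) - n_sigma * stats::sd(rfu)
    } else if (is.na(last)) {
      last_global <- base::mean(events$rfu) - n_sigma * stats::sd(events$rfu)
      thr[i] <- last_global
      next
    }
    thr[i] <- last
  }
  hit <- logical(nrow(events))
  for (j in seq_len(nrow(events))) {
    hit[j] <- events$rfu[j] < thr[match(bin_of[j], bins)]
  }
  list(thresholds = thr, hits = which(hit))
}
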