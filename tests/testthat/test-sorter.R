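make_stream <- function(time, rfu, n_beads = 0L) {
  structure(list(events = data.frame(time = time, rfu = rfu,
                                     n_beads = n_beads),
                 beads = data.frame(event = integer(0),
                                    member = integer(0)),
                 config = NULL),
            class = "del_stream")
}

test_that("time bins partition the stream and report exact moments", {
  st <- make_stream(time = seq(0.5, 119.5, by = 1), rfu = 100)
  bs <- compute_bin_stats(st, 60)
  expect_equal(nrow(bs), 2L)
  expect_equal(sum(bs$droplet_count), 120L)
  expect_equal(bs$mu, c(100, 100))
  expect_equal(bs$sigma, c(0, 0))

  # drifting stream: per-bin moments equal brute-force recomputation
  set.seed(41)
  tt <- sort(runif(5000, 0, 300))
  rr <- 100 + 0.5 * tt + rnorm(5000, 0, 5)
  st2 <- make_stream(tt, rr)
  bs2 <- compute_bin_stats(st2, 60)
  for (i in seq_len(nrow(bs2))) {
    sel <- tt >= bs2$bin_start[i] & tt < bs2$bin_start[i] + 60
    expect_equal(bs2$mu[i], mean(rr[sel]))
    expect_equal(bs2$sigma[i], sd(rr[sel]))
    expect_equal(bs2$droplet_count[i], sum(sel))
  }
})

test_that("empty interior bins are recorded, never dropped", {
  st <- make_stream(c(seq(1, 59, 1), seq(121, 179, 1)), rfu = 100)
  bs <- compute_bin_stats(st, 60)
  expect_equal(nrow(bs), 3L)
  expect_equal(bs$droplet_count[2], 0L)
  expect_true(is.na(bs$mu[2]))
})

test_that("dynamic thresholds are mu minus n sigma with sparse fallback", {
  st <- make_stream(seq(0.5, 119.5, length.out = 400),
                    rfu = rep(c(90, 110), 200))
  bs <- compute_bin_stats(st, 60)
  bs$mu <- c(100, 100); bs$sigma <- c(10, 10)  # exercise pure arithmetic
  expect_equal(dynamic_threshold(bs, 4.5)$threshold, c(55, 55))
  expect_equal(dynamic_threshold(bs, 6)$threshold, c(40, 40))
  bs$sigma <- c(0, 0)
  expect_equal(dynamic_threshold(bs, 6)$threshold, c(100, 100))

  # a trailing sparse bin carries the previous threshold, flagged
  st2 <- make_stream(c(seq(0.5, 59.5, length.out = 200), 61, 62),
                     rfu = c(rnorm(200, 100, 10), 100, 100))
  bs2 <- compute_bin_stats(st2, 60)
  thr2 <- dynamic_threshold(bs2, 4.5)
  expect_false(thr2$carried[1])
  expect_true(thr2$carried[2])
  expect_equal(thr2$threshold[2], thr2$threshold[1])
})

test_that("sorting is strictly-below with hits retaining bead identity", {
  cat <- tiny_catalog()
  n <- 300
  rfu <- rep(100, n)
  rfu[2:151] <- rep(c(90, 110), 75)  # give the bin spread
  rfu[7] <- 30                       # far below mean - 3 sigma
  st <- make_stream(seq(0.5, 59.5, length.out = n), rfu, n_beads = 1L)
  st$beads <- data.frame(event = seq_len(n),
                         member = rep_len(1:12, n))
  bs <- compute_bin_stats(st, 60)
  thr <- dynamic_threshold(bs, 3)
  res <- sort_events(st, thr, cat)
  expect_equal(nrow(res$hits), 1L)
  expect_equal(res$hit_beads$member, 7L)
  expect_equal(res$hit_beads$member_id, cat$members$member_id[7])
  expect_equal(res$beads_screened, n)

  # all events exactly at the bin mean: zero hits (ties are non-hits)
  flat <- make_stream(seq(0.5, 59.5, length.out = 200), 100)
  bsf <- compute_bin_stats(flat, 60)
  expect_equal(nrow(sort_events(flat, dynamic_threshold(bsf, 4.5))$hits), 0L)

  # events outside threshold coverage are an error
  expect_error(sort_events(make_stream(150, 100), thr), "coverage")
})

test_that("raising n_sigma never increases the hit count", {
  set.seed(13)
  st <- make_stream(sort(runif(5000, 0, 240)), rnorm(5000, 100, 10))
  bs <- compute_bin_stats(st, 60)
  hits <- vapply(c(1, 2, 3, 4, 4.5, 6), function(ns) {
    nrow(sort_events(st, dynamic_threshold(bs, ns))$hits)
  }, numeric(1))
  expect_true(all(diff(hits) <= 0))
})

test_that("bin/threshold/sort pipeline matches the brute-force reference", {
  set.seed(99)
  n <- 10000
  tt <- sort(runif(n, 0, 600))
  rr <- 100 + 0.02 * tt + rnorm(n, 0, 8)
  rr[sample(n, 20)] <- 30  # planted outliers
  st <- make_stream(tt, rr)
  for (ns in c(3, 4.5, 6)) {
    bs <- compute_bin_stats(st, 60)
    thr <- dynamic_threshold(bs, ns)
    res <- sort_events(st, thr)
    ref <- brute_sort_reference(st$events, 60, ns)
    expect_equal(thr$threshold, ref$thresholds, tolerance = 1e-12)
    expect_identical(as.integer(rownames(res$hits)), ref$hits)
  }
})

test_that("null-stream hit fraction matches the Gaussian tail", {
  set.seed(7)
  n <- 1e5
  st <- make_stream(seq_len(n) / (n / 600), rnorm(n, 100, 10))
  bs <- compute_bin_stats(st, 60)
  res <- sort_events(st, dynamic_threshold(bs, 3))
  p <- pnorm(-3)
  frac <- nrow(res$hits) / n
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("hit rate reports percent with an exact binomial interval", {
  hr <- hit_rate(400, 500000)
  expect_equal(hr$percent, 0.08)
  expect_equal(hit_rate(0, 1000)$percent, 0)
  expect_equal(hit_rate(0, 1000)$ci_lo, 0)
  # Clopper-Pearson against the exact-binomial oracle
  for (x in c(0, 1, 5, 17)) {
    bt <- stats::binom.test(x, 120)
    hr <- hit_rate(x, 120)
    expect_equal(hr$ci_lo, 100 * bt$conf.int[1], tolerance = 1e-10)
    expect_equal(hr$ci_hi, 100 * bt$conf.int[2], tolerance = 1e-10)
  }
  expect_error(hit_rate(1, 0), "> 0")
  expect_error(hit_rate(10, 5), "within")
})

test_that("library equivalents reproduce the screening-scale arithmetic", {
  expect_equal(library_equivalents(497664, 55296), 9)
  expect_equal(library_equivalents(55296, 55296), 1)
  expect_equal(library_equivalents(718848, 55296), 13)
  expect_error(library_equivalents(100, 0), "> 0")
})
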