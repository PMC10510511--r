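# Standard planted fixture, shared across the dose-conforming and
# recovery checks: full 192 x 288 catalog, 2 AA + 1 CA planted series,
# 3 library equivalents per screen at uv 1.0 and 0.3, defaults otherwise.
# Computed once per test run (a 20-seed suite) and memoised.

.fixture_env <- new.env(parent = emptyenv())

standard_fixture_runs <- function(n_seeds = 20L) {
  key <- paste0("runs", n_seeds)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  catalog <- synthetic_library(192, 288, seed = 424242)
  cal <- dose_calibration()
  cfg <- run_config(seed = 1)
  runs <- lapply(seq_len(n_seeds), function(s) {
    act <- plant_actives(catalog, seed = 5000 + s)
    hi <- run_screen(catalog, act, cal, 1.0, cfg, seed = 6000 + s)
    lo <- run_screen(catalog, act, cal, 0.3, cfg, seed = 7000 + s)
    rep <- dose_compare(hi$kclass, lo$kclass)
    list(rate_high = hi$rate$percent, rate_low = lo$rate$percent,
         epsilon_high = hi$epsilon,
         recovery = score_recovery(rep, act))
  })
  .fixture_env[[key]] <- runs
  runs
}
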