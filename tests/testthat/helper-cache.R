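# Heavy shared computations (calibration, baseline autoregulated run,
# the default 11-point sweep) are computed once per test session and
# reused across test files.

.willisim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .willisim_cache)) {
    assign(name, force(expr), envir = .willisim_cache)
  }
  get(name, envir = .willisim_cache)
}

cached_calibration <- function() {
  cached("calibration", {
    calibrate_map(build_virtual_patient(age = 70))
  })
}

cached_baseline <- function() {
  cached("baseline", {
    run_autoregulated(cached_calibration()$net)
  })
}

cached_sweep <- function() {
  cached("sweep", {
    run_cea_sweep(cached_calibration()$net, side = "left")
  })
}
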