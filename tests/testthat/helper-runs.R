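# Shared fixtures: protocol runs are expensive, so they are computed once per
# test session and reused across files.

.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache, inherits = FALSE)) {
    assign(key, expr, envir = .run_cache)
  }
  get(key, envir = .run_cache, inherits = FALSE)
}

get_run <- function(name) {
  switch(name,
    classical50 = cached("classical50",
      run_protocol(protocol_config("classical_chemo", 50))),
    classical100 = cached("classical100",
      run_protocol(protocol_config("classical_chemo", 100))),
    classical150 = cached("classical150",
      run_protocol(protocol_config("classical_chemo", 150))),
    thermochemo50 = cached("thermochemo50",
      run_protocol(protocol_config("thermochemo", 50))),
    thermodox50 = cached("thermodox50",
      run_protocol(protocol_config("thermodox", 50))),
    stop("unknown cached run: ", name)
  )
}

# Central-lesion ablation stage and runs: reduced acoustic power so the
# necrotic core sits inside the tumor (the regime of interest for the
# combined protocols); quadrature kept at default for field accuracy.
central_lesion_params <- function() {
  p <- default_params()
  p$hifu$acoustic_power <- 6
  p
}

get_ablation_run <- function() {
  cached("ablation6", {
    p <- central_lesion_params()
    run_protocol(protocol_config("ablation_then_medication", 50, params = p))
  })
}
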