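# small lattice for fast unit tests of the simulator (not the calibrated
# test lattice used for the bifurcation checks)
tiny_params <- function(variant = "control") {
  p <- make_default_params(variant)
  p$lattice$nx <- 6; p$lattice$ny <- 3; p$lattice$nz <- 3
  p
}

quiet_paced <- function(...) suppressWarnings(run_paced(...))
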