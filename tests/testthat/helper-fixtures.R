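# Shared fixtures: a typical mouse-femur geometry and notch, all built in code.

fix_section <- function() cross_section(0.9, 0.7)     # R_m 0.8, t 0.2, ratio 4
fix_notch <- function() notch_geometry(0.55)

fix_record <- function(...) {
  gen_bend_test(fix_section(), fix_notch(), ...)
}

# draw sub-seeds for Monte-Carlo loops from one declared master seed
mc_seeds <- function(n, master = 20181003) {
  set.seed(master)
  sample.int(2^31 - 1, n)
}
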