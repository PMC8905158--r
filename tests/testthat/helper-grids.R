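# Shared parameter grids for property-style tests.
grid_n <- 1:20
grid_c <- seq(0, 0.95, by = 0.05)
grid_xbar <- seq(0.05, 0.95, by = 0.05)
grid_mu <- seq(-0.5, 0.5, by = 0.25)

# tiny desk configurations for fast simulator contract tests
tiny_config <- function(...) {
  defaults <- list(n = 2L, c = 0.2, num_patches = 30L, generations = 40L,
                   burn_in = 10L, seed = 99L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
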