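# Shared fixtures: a small synthetic stand covering the instrumental era,
# regenerated in code at test time.

quick_stand <- function(seed = 1, years = c(1936L, 2016L), n_trees = 6L, ...) {
  cfg <- sim_config(seed = seed, years = years, n_trees = n_trees, ...)
  climate <- simulate_climate(cfg)
  list(cfg = cfg,
       climate = climate,
       trees = simulate_isotope_trees(climate, cfg),
       atm = simulate_atmospheric_co2(cfg))
}

# Corrected, juvenile-excluded chronology for one isotope from a stand.
stand_chronology <- function(stand, isotope = "d13C", juvenile = 30L) {
  ss <- Filter(function(s) attr(s, "isotope") == isotope, stand$trees)
  ss <- lapply(ss, exclude_juvenile, n_rings = juvenile)
  if (isotope == "d13C") {
    ss <- lapply(ss, correct_suess, atm = stand$atm)
  }
  build_chronology(ss)
}

# A noise-free configuration: all stochastic terms off, optional coupling
# overrides, so generated series are exact affine images of climate.
noiseless_config <- function(seed = 1, years = c(1950L, 2016L), n_trees = 2L,
                             d18o_prevsep = 0, d13c_prevsep = 0,
                             suess_total_decline = 0) {
  sim_config(seed = seed, years = years, n_trees = n_trees,
             coupling = list(
               d13c = c(intercept = -21.19, p_july = -0.02,
                        t_prevsep = d13c_prevsep),
               d18o = c(intercept = 20.57, t_july = 0.45,
                        t_prevsep = d18o_prevsep)
             ),
             noise_sd_tree = 0, noise_sd_year = 0, tree_offset_sd = 0,
             juvenile_amp = 0, suess_total_decline = suess_total_decline)
}

year_df <- function(years, values) data.frame(year = years, value = values)
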