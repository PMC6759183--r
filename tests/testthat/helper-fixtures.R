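# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small two-chromosome study used by scan and network tests
small_study <- function() {
  fixture("small_study", function() {
    map <- make_genetic_map(2, 26, 100, seed = 11)
    geno <- simulate_rils(map, 120, seed = 12)
    list(map = map, geno = geno,
         probs = genotype_probabilities(geno, map, step = 2))
  })
}

# modest hierarchical growth fit reused across growth-fit tests
small_growth_fit <- function() {
  fixture("small_growth_fit", function() {
    map <- make_genetic_map(1, 5, 50, seed = 21)
    geno <- simulate_rils(map, 12, seed = 22)
    arch <- growth_architecture(sd_noise = 0.2,
                                sd_rep = c(log_r = 0.03, log_hmax = 0.03, id = 5),
                                sd_block = 0)
    st <- simulate_growth_study(geno, arch, map, treatments = "UN",
                                reps_per_line = 3, seed = 23)
    fit <- fit_hierarchical_growth(st$observations,
                                   mcmc_settings(6000, 3000, 3, seed = 24))
    list(study = st, fit = fit)
  })
}
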