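# shared builders for the suite; everything is generated in code

scalar_op <- function(s) as_operator(function(q) s * q, m_in = 1)

identity_comp <- function(m = 2, ...) {
  make_component(m = m, ensemble = "identity", seed = 1, ...)
}

# a random invertible nonlinear component, deterministic per seed
monotone_comp <- function(m = 4, seed = 1, ...) {
  make_component(m = m, ensemble = "gaussian", nonlinearity = "leaky_softplus",
                 cond_cap = 1e3, seed = seed, ...)
}

two_bump_world <- function() {
  fitloop:::build_world(generate_fixture("two_bump_drive"))
}

two_bump_drive_cfg <- function(...) {
  cfg <- fitloop:::build_drive(generate_fixture("two_bump_drive"))
  mods <- list(...)
  for (k in names(mods)) cfg[[k]] <- mods[[k]]
  cfg
}
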