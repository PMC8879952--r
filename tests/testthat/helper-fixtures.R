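# Shared fixtures: small hand-built curves and standard simulator setups.

# 3-point adsorption curve from the worked reordering example
tiny_forward <- function() {
  work_curve(xi = c(10, 6, 2), work = c(0, -5, -20), direction = "adsorption")
}

tiny_reverse <- function() {
  work_curve(xi = c(2, 6, 10), work = c(0, 15, 20), direction = "desorption")
}

flat_curve <- function(direction = "adsorption", n = 11) {
  xi <- if (direction == "adsorption") seq(10, 2, length.out = n) else seq(2, 10, length.out = n)
  work_curve(xi = xi, work = rep(0, n), direction = direction)
}

# the reference well used throughout the simulator tests
well50 <- function() model_potential("adsorption_well", well_depth = -50)

# a moderately fast protocol that keeps simulation cheap in tests
fast_protocol <- function(velocity = 0.02, ...) {
  pull_protocol(12, 2, velocity = velocity, ...)
}

# n forward pulls with derived seeds
forward_set <- function(potential, protocol, n, seed) {
  set.seed(seed)
  seeds <- sample.int(1e6, n)
  lapply(seq_len(n), function(i) {
    p <- protocol
    p$seed <- seeds[i]
    simulate_pull(potential, p)
  })
}
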