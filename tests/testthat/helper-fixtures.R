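# Shared fixture builders; everything is generated in code at test time.

tiny_fixture <- function(length = 2000, nrl = 190, seed = 42, ...) {
  build_fixture(length, nrl, seed = seed, ...)
}

# A small simulated library + rendered reads, memoised per test run.
.sim_cache <- new.env(parent = emptyenv())

small_library <- function(n_events = 2000, seed = 101) {
  key <- paste0("lib_", n_events, "_", seed)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  fx <- build_fixture(6000, 190, ndrs = rbind(c(2900, 3100)), seed = 1)
  mod <- contact_model(decay_exponent = 1)
  lib <- simulate_ligation_events(fx, mod, n_events, seed = seed)
  rd <- render_sequencing_library(lib, seed = seed + 1L)
  out <- list(fixture = fx, lib = lib, reads = rd)
  .sim_cache[[key]] <- out
  out
}

rzinb <- function(n, mu, size, pi) {
  ifelse(runif(n) < pi, 0, rnbinom(n, size = size, mu = mu))
}

junction_key <- function(j) paste(j$pos_a, j$pos_b, j$dir_a, j$dir_b)
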