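# Shared test fixtures.
#
# default_panel() memoizes full-default simulated panels so the acceptance
# blocks and property tests can share one generation per seed.

.panel_cache <- new.env(parent = emptyenv())

default_panel <- function(seed = 1L) {
  key <- paste0("seed", seed)
  if (is.null(.panel_cache[[key]]))
    .panel_cache[[key]] <- simulate_panel(sim_config(seed = seed))
  .panel_cache[[key]]
}

# small deterministic ternary matrix for toy tests
toy_ternary <- function(nr, nc, seed, na_frac = 0.1,
                        genes = sprintf("g%02d", seq_len(nr)),
                        lines = sprintf("L%02d", seq_len(nc))) {
  set.seed(seed)
  m <- matrix(sample(c(0L, 1L), nr * nc, replace = TRUE), nr, nc,
              dimnames = list(genes, lines))
  m[sample(length(m), round(na_frac * length(m)))] <- NA_integer_
  m
}
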