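# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small inclined-plane DEM with a known outlet, for routing tests.
ramp_grid <- function(nr = 8, nc = 8, slope = 0.1) {
  dom <- grid_domain(nr, nc, cell_size = 2, outlet = c(1L, 1L))
  elev <- outer(seq_len(nr) - 1, seq_len(nc) - 1,
                function(r, c) slope * 2 * (r + c))
  list(domain = dom, elev = elev)
}

# One-year consolidated-gully run at 16 x 16 (ledger identity, analysis).
run_16 <- function() {
  fixture("run_16", function() {
    st <- build_watershed("consolidated", 16, 16, seed = 2)
    list(state0 = st,
         run = run_coevolution(st, run_config(duration_years = 1,
                                              seed = 3)))
  })
}

# Five-year 32 x 32 consolidated run (global closure, climatology, ratio).
run_32_5yr <- function() {
  fixture("run_32_5yr", function() {
    st <- build_watershed("consolidated", 32, 32, seed = 5)
    list(state0 = st,
         run = run_coevolution(st, run_config(duration_years = 5,
                                              seed = 11)))
  })
}

# Exhaustive D8 walk: does every cell's receiver chain hit the outlet?
all_drain_to_outlet <- function(network, n) {
  ok <- logical(n)
  for (i in seq_len(n)) {
    j <- i
    for (s in seq_len(n + 1)) {
      if (network$receiver[j] == 0) { ok[i] <- TRUE; break }
      j <- network$receiver[j]
    }
  }
  ok
}
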