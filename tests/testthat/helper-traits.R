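# Shared fixtures: the default trait table and a few derived helpers.

traits_default <- read_traits()
par_small <- traits_default$small$params
par_large <- traits_default$large$params

# independent bisection of the monotone forward map a*mu^2 + b*mu + c = Q,
# vectorized over cases; the oracle for the closed-form quota inversion
bisect_mu <- function(a, b, c, Q, iters = 90) {
  n <- length(Q)
  lo <- rep(0, n)
  hi <- rep(1, n)
  f <- function(mu) a * mu^2 + b * mu + c - Q
  for (k in 1:60) {
    need <- f(hi) < 0
    if (!any(need)) break
    hi[need] <- hi[need] * 2
  }
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    up <- f(mid) < 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  (lo + hi) / 2
}

# modified copy of an alloc_params object
with_params <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  params
}

# a minimal grid_result for diagnostics unit tests
fake_grid_result <- function(cells, lat = sort(unique(cells$lat)),
                             depth = sort(unique(cells$depth))) {
  structure(list(cells = cells, lat = lat, depth = depth), class = "grid_result")
}
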