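# Shared fixtures: the canonical GAL1pr-like parameter set used
# throughout (maturation half-time ~20 min, turnover ~1/h, weak basal
# activity), its protocol, and cached noiseless/noisy traces.

ref_params <- function() {
  kinetic_params(b = 1e-4, i = 0.001, f = 0.035, d = 0.017,
                 t_on = 10, t_off = 5)
}

ref_protocol <- function() induction_protocol()

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# noiseless full-model trace of the canonical parameters
ref_trace <- function() {
  cached("ref_trace", {
    pr <- ref_protocol()
    tt <- protocol_times(pr)
    data.frame(time_min = tt,
               fluorescence = integrate_model(ref_params(), pr, tt))
  })
}

# trace built from the piecewise second-order (fitting-form) curves:
# the fitters must recover its parameters exactly
taylor_trace <- function(params = ref_params(), protocol = ref_protocol()) {
  tt <- protocol_times(protocol)
  basal <- steady_state(params, FALSE)
  induced <- steady_state(params, TRUE)
  y <- rep(basal, length(tt))
  on <- tt > params$t_on
  y[on] <- basal + (params$i * params$f / 2) * (tt[on] - params$t_on)^2
  fall <- tt >= protocol$t_end
  y[fall] <- induced
  off <- tt > protocol$t_end + params$t_off
  y[off] <- induced - (params$i * params$f / 2) *
    (tt[off] - protocol$t_end - params$t_off)^2
  # deliberately unclamped: the one-sided quadratic goes negative late in
  # the fall window for these rates, and self-consistency needs the raw form
  data.frame(time_min = tt, fluorescence = y)
}

random_params <- function() {
  f <- runif(1, 1e-3, 0.2)
  d <- runif(1, 1e-3, 0.2)
  kinetic_params(b = runif(1, 0, 0.05), i = runif(1, 0, 0.05),
                 f = f, d = d, t_on = runif(1, 0, 30),
                 t_off = runif(1, 0, 30))
}
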