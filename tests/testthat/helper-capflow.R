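# Shared fixture builders (all data generated in code).

# dose_response drawn exactly from a 4PL on log10 concentration; the control
# (0) sits one decade below the smallest nonzero concentration.
make_4pl_dr <- function(conc = c(0, 1, 5, 10, 20, 40, 100),
                        A = 0.22, B = 0.30, xmid = log10(15), scal = 0.35,
                        n = 4, noise_sd = 0, seed = NULL,
                        decreasing = FALSE) {
  x <- ifelse(conc > 0, log10(conc), log10(min(conc[conc > 0])) - 1)
  y <- A + (B - A) / (1 + exp((xmid - x) / scal))
  if (decreasing) y <- rev(y)
  draw <- function() lapply(y, function(v) {
    if (noise_sd > 0) rnorm(n, v, noise_sd) else rep(v, n)
  })
  sig <- if (is.null(seed)) draw() else capflow:::with_seed(seed, draw())
  dose_response(conc, sig)
}

# dose_response with a constant-sd Gaussian signal and a fixed-size mean
# shift injected at every concentration >= c_star (5 sd by default).
make_effect_dr <- function(c_star, conc = c(0, 10, 20, 50, 100, 500),
                           n = 8, mu = 0.25, sdv = 0.01, effect_sd = 5) {
  dose_response(conc, lapply(conc, function(cc) {
    rnorm(n, mu + if (cc >= c_star) effect_sd * sdv else 0, sdv)
  }))
}

paper_k <- function(abp0 = 10, ag0 = 10) {
  kinetic_params(6, 0.1, 1, 0.05, 2, abp0 = abp0, ag0 = ag0)
}

log_grid <- function(lo = 0.01, hi = 1000, n = 40) 10^seq(log10(lo), log10(hi), length.out = n)
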