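# Independent brute-force oracles for the exact small-sample tests.
# These enumerate every assignment of the pooled observations to the two
# groups, so they share no code path with the package implementations.

# Exact two-sample KS p-value: P(D >= observed D) over all C(n+m, n)
# equally likely rank arrangements (distinct values assumed).
ks_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  ord <- order(pooled)
  d_of <- function(idx_a) {
    z <- seq_len(n + m) %in% idx_a
    z <- z[ord]
    max(abs(cumsum(z) / n - cumsum(!z) / m))
  }
  d_obs <- d_of(seq_len(n))
  combos <- utils::combn(n + m, n)
  ds <- apply(combos, 2L, d_of)
  mean(ds >= d_obs - 1e-12)
}

# Exact two-tailed Mann-Whitney p: doubled smaller tail of the enumerated
# U distribution (capped at 1), matching the standard convention.
mw_enum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  u_of <- function(va, vb) sum(outer(va, vb, ">"))
  u_obs <- u_of(a, b)
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2L, function(ia) {
    u_of(pooled[ia], pooled[-ia])
  })
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Analytic leaky integrate-and-fire F-I gain over a current grid: OLS slope
# of the closed-form rate curve (computed here from first principles, not
# via lif_rate()).
lif_gain_oracle <- function(R_in, tau_m, V_rest, V_thresh, t_ref, currents) {
  dv_th <- V_thresh - V_rest
  f <- vapply(currents, function(I) {
    dv_inf <- I * R_in / 1000
    if (dv_inf <= dv_th) return(0)
    1 / (t_ref / 1000 + tau_m / 1000 * log(dv_inf / (dv_inf - dv_th)))
  }, numeric(1))
  unname(stats::coef(stats::lm(f ~ currents))[2])
}
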