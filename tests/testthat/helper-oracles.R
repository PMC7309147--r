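## Independent oracles used across the suite.  These deliberately do not
## share code paths with the package: the nodal oracle solves the two-branch
## network as a complex admittance system, the rank-sum oracle enumerates
## group assignments with a bitmask, and the DF hand evaluations write the
## transfer functions out explicitly.

## nodal analysis of the covered-electrode network: unknowns are the node
## voltage above the two branches (v1) and the voltage behind R_gap (v2),
## unit current injected; Z = R_s + v1.
oracle_cell_impedance <- function(R_s, R_gap, R_ct, C_dl, ff, omega) {
  if (ff == 0) return(R_s + R_ct / (1 + 1i * omega * R_ct * C_dl))
  if (ff == 1) return(R_s + R_gap + R_ct / (1 + 1i * omega * R_ct * C_dl))
  R1 <- R_ct / (1 - ff); C1 <- C_dl * (1 - ff)
  R2 <- R_ct / ff; C2 <- C_dl * ff
  Y1 <- 1 / R1 + 1i * omega * C1
  Y2 <- 1 / R2 + 1i * omega * C2
  A <- matrix(c(Y1 + 1 / R_gap, -1 / R_gap,
                -1 / R_gap, 1 / R_gap + Y2), 2, 2, byrow = TRUE)
  v <- solve(A, c(1, 0))
  R_s + v[1]
}

## exact two-sided rank-sum p by bitmask enumeration of group assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  ws <- numeric(0)
  for (mask in 0:(2^n - 1)) {
    if (sum(bitwAnd(mask, 2^(0:(n - 1))) > 0) == nx)
      ws <- c(ws, sum(r[bitwAnd(mask, 2^(0:(n - 1))) > 0]))
  }
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

## band-pass transfer written out by hand (for loop-transfer checks)
oracle_bandpass <- function(f0, Q, k, omega) {
  w0 <- 2 * pi * f0
  s <- 1i * omega
  k * (w0 / Q) * s / (s^2 + (w0 / Q) * s + w0^2)
}

test_config <- function(...) obt_config(...)
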