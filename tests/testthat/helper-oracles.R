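# Independent oracles used across the suite. These deliberately re-derive
# quantities by a different route than the package code.

# Second, independently coded evaluation of the equilibrium-constant
# formulations (log10/decadic arrangement where the package uses exp/ln
# and vice versa).
oracle_constants <- function(TC, S) {
  TK <- TC + 273.15
  lnK0 <- -60.2409 + 93.4517 * 100 / TK + 23.3585 * (log(TK) - log(100)) +
    S * (0.023517 - 0.023656 * TK / 100 + 0.0047036 * (TK / 100)^2)
  lnK1 <- -2307.1266 / TK + 2.83655 - 1.5529413 * log(TK) -
    (4.0484 / TK + 0.20760841) * sqrt(S) + 0.08468345 * S -
    0.00654208 * S * sqrt(S) + log1p(-0.001005 * S)
  lnK2 <- -3351.6106 / TK - 9.226508 - 0.2005743 * log(TK) -
    (23.9722 / TK + 0.106901773) * sqrt(S) + 0.1130822 * S -
    0.00846934 * S * sqrt(S) + log1p(-0.001005 * S)
  lnKB <- (-8966.90 - 2890.53 * S^0.5 - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK + 148.0248 + 137.1942 * S^0.5 +
    1.62142 * S - (24.4344 + 25.085 * S^0.5 + 0.2474 * S) * log(TK) +
    0.053105 * S^0.5 * TK
  lnKw <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * S^0.5 - 0.01615 * S
  l10c <- -171.9065 - 0.077993 * TK + 2839.319 / TK +
    71.595 * log(TK) / log(10) +
    (-0.77712 + 0.0028426 * TK + 178.34 / TK) * S^0.5 - 0.07711 * S +
    0.0041249 * S^1.5
  l10a <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log(TK) / log(10) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * S^0.5 - 0.10018 * S +
    0.0059415 * S^1.5
  list(K0 = exp(lnK0), K1 = exp(lnK1), K2 = exp(lnK2), KB = exp(lnKB),
       Kw = exp(lnKw), Ksp_calcite = 10^l10c, Ksp_aragonite = 10^l10a,
       BT = 0.0004157 * S / 35, CaT = 0.01028 * S / 35)
}

# total alkalinity (mol kg-1) rebuilt from a speciated state
oracle_alkalinity <- function(state, kc) {
  H <- 10^(-state$ph_total)
  (state$hco3 + 2 * state$co3) * 1e-6 +
    kc$BT * kc$KB / (kc$KB + H) + kc$Kw / H - H
}

# bisection solve of alkalinity for pH at fixed (A_T, C_T); independent of
# the package's uniroot-based solver
oracle_bisect_ph <- function(alk_umol, ct_umol, kc, lo = 4, hi = 11,
                             iter = 200) {
  f <- function(ph) {
    H <- 10^(-ph)
    denom <- 1 + kc$K1 / H + kc$K1 * kc$K2 / H^2
    co2 <- ct_umol * 1e-6 / denom
    hco3 <- co2 * kc$K1 / H
    co3 <- hco3 * kc$K2 / H
    hco3 + 2 * co3 + kc$BT * kc$KB / (kc$KB + H) + kc$Kw / H - H -
      alk_umol * 1e-6
  }
  # f is increasing in pH (at fixed C_T, alkalinity rises with pH)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# direct evaluation of the Platt net curve, written out longhand
oracle_platt <- function(E, ps, a, b, rd) {
  ps * (1 - exp(-(a * E) / ps)) * exp(-(b * E) / ps) - rd
}

# brute-force Type III F statistics for the 2x2 design via explicit
# effects-coded regression (t^2 of each 1-df coefficient in the full model)
oracle_anova_f <- function(value, A, B) {
  a <- ifelse(A == levels(factor(A))[1], 1, -1)
  b <- ifelse(B == levels(factor(B))[1], 1, -1)
  X <- cbind(1, a, b, a * b)
  XtXi <- solve(t(X) %*% X)
  beta <- XtXi %*% t(X) %*% value
  res <- value - X %*% beta
  mse <- sum(res^2) / (length(value) - 4)
  Fs <- (beta[2:4]^2) / (mse * diag(XtXi)[2:4])
  names(Fs) <- c("A", "B", "AB")
  Fs
}
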