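# Independent oracles: solve the component flux balances simultaneously by
# monotone bisection on the net rate, without using the closed-form
# quadratics under test. Scalars only; deliberately plain arithmetic.

oracle_enzyme <- function(Cm, Om, adj) {
  gs <- adj$gamma_star
  Vp <- min(Cm * adj$Vpmax / (Cm + adj$Kp), adj$Vpr)
  g <- function(A) {
    Os <- adj$alpha * A / (adj$ao * adj$gbs) / 1000 + Om
    Cs <- Cm + (Vp - A - adj$Rm) / adj$gbs
    (Cs - gs * Os * 1000) * adj$Vcmax /
      (Cs + adj$Kc * (1 + Os / adj$Ko)) - adj$Rd - A
  }
  lo <- -(adj$Rd + adj$Rm + 5)
  hi <- min(Vp - adj$Rm + adj$gbs * Cm, adj$Vcmax - adj$Rd) - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_light <- function(Cm, Om, J, adj) {
  gs <- adj$gamma_star
  Vpj <- adj$z * adj$x * J / 2
  Jsc <- adj$z * (1 - adj$x) * J / 3
  g <- function(A) {
    Os <- adj$alpha * A / (adj$ao * adj$gbs) / 1000 + Om
    Cs <- Cm + (Vpj - A - adj$Rm) / adj$gbs
    r <- gs * Os * 1000 / Cs
    (1 - r) * Jsc / (1 + 7 * r / 3) - adj$Rd - A
  }
  lo <- -(adj$Rd + adj$Rm + 5)
  hi <- min(Vpj - adj$Rm + adj$gbs * Cm, Jsc - adj$Rd) - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random parameter draw: capacity/kinetic parameters within +/-50% of the
# defaults, stoichiometry held at defaults
draw_params <- function(alpha = 0) {
  jitter <- function(v) v * stats::runif(1, 0.5, 1.5)
  c4_parameters(
    Vcmax25 = jitter(40), Kc25 = jitter(1210), Ko25 = jitter(292),
    Vpmax25 = jitter(200), Vpr = jitter(80), Kp25 = jitter(82),
    gbs = jitter(0.003), Rd25 = jitter(0.4), gm25 = jitter(1),
    Jmax25 = jitter(248), alpha = alpha
  )
}
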