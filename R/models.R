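#' Concentration-response and binding model equations
#'
#' The closed-form mean curves used throughout the package, all with unit
#' (Hill slope = 1) shape:
#'
#' * `eq_saturation()` — specific binding `SB = A * Bmax / (A + KD)`.
#' * `eq_competition()` — percent uninhibited specific binding
#'   `100 * (1 - A / (A + IC50)) + NS`.
#' * `eq_one_site()` — agonist response `Emax * A / (EC50 + A)`.
#' * `eq_two_site()` — sum of two stimulatory components,
#'   `T * [N/100 * A/(A+EC1) + (1-N/100) * A/(A+EC2)]`.
#' * `eq_dip()` — inhibition of a fixed reference-agonist response plus the
#'   compound's own stimulation:
#'   `basal + (control-basal) * (1 - A/(A+IC50)) + Smax * A/(A+EC50)`.
#'
#' @param A concentration (molar), vectorised.
#' @param Bmax maximal specific binding (signal units).
#' @param Kd,ic50,ec50,ec1,ec2 dissociation / half-effect concentrations (molar).
#' @param ns nonspecific floor on the percent scale.
#' @param emax maximal response (percent of the positive control).
#' @param total total span of a two-site curve (percent).
#' @param n_pct percentage of the total occurring via the high-potency site.
#' @param basal,control response without agonist and to the fixed reference
#'   concentration alone (percent).
#' @param smax maximal stimulation of the stimulatory limb (percent).
#' @return numeric vector of model means.
#' @name model-equations
NULL

#' @rdname model-equations
#' @export
eq_saturation <- function(A, Bmax, Kd) A * Bmax / (A + Kd)

#' @rdname model-equations
#' @export
eq_competition <- function(A, ic50, ns = 0) 100 - 100 * A / (A + ic50) + ns

#' @rdname model-equations
#' @export
eq_one_site <- function(A, emax, ec50) emax * A / (ec50 + A)

#' @rdname model-equations
#' @export
eq_two_site <- function(A, total, n_pct, ec1, ec2) {
  f <- n_pct / 100
  total * (f * A / (A + ec1) + (1 - f) * A / (A + ec2))
}

#' @rdname model-equations
#' @export
eq_dip <- function(A, basal, control, ic50, smax, ec50) {
  basal + (control - basal) * (1 - A / (A + ic50)) + smax * A / (A + ec50)
}

# ---------------------------------------------------------------------------
# Occupancy -> response transducer algebra.
#
# The simulator drives every functional curve through a hyperbolic
# transducer: stimulus S = sum over conformations of
# tau_i * occupancy_i, response fraction R = S / (1 + S), where
# tau = intrinsic efficacy x receptor-expression scale.  For a single
# agonist component this is *exactly* the one-site curve with
# Emax = tau/(1+tau) and EC50 = KD/(1+tau); for two components the curve is
# exactly a member of the free-total two-site family.  The two helpers below
# convert between the mechanistic parameters (tau, KD per conformation) and
# the observable two-site parameters via the partial-fraction decomposition
# of the rational (quadratic / quadratic) response function.

# forward: (tau1, K1, tau2, K2) -> observable two-site parameters, response
# fractions in [0, 1].  a1 < a2 (high-potency component first).
.mix_to_two_site <- function(tau1, K1, tau2, K2) {
  c2 <- (1 + tau1 + tau2) / (K1 * K2)
  c1 <- (1 + tau1) / K1 + (1 + tau2) / K2
  disc <- c1 * c1 - 4 * c2
  disc <- max(disc, 0)
  r1 <- (c1 - sqrt(disc)) / (2 * c2)
  r2 <- (c1 + sqrt(disc)) / (2 * c2)
  a1 <- min(r1, r2); a2 <- max(r1, r2)
  total <- (tau1 + tau2) / (1 + tau1 + tau2)
  # numerator N(A) = tau1*(A/K1)(1+A/K2) + tau2*(A/K2)(1+A/K1), residue at -a1
  Nf <- function(A) tau1 * (A / K1) * (1 + A / K2) + tau2 * (A / K2) * (1 + A / K1)
  if (abs(a2 - a1) < 1e-12 * a2) {
    # degenerate equal roots: treat as one site
    m1 <- total; m2 <- 0
  } else {
    m1 <- -Nf(-a1) / (c2 * a1 * (a2 - a1))
    m2 <- total - m1
  }
  list(m1 = m1, a1 = a1, m2 = m2, a2 = a2, total = total)
}

# inverse: observable two-site parameters (fractions) -> mechanistic
# (tau, K) pairs, high-potency component first.
.two_site_to_mix <- function(m1, a1, m2, a2) {
  total <- m1 + m2
  stopifnot(total < 1)
  # S(A) = R/(1-R) = P(A) / Q(A)
  # P(A) = m1*A*(A+a2) + m2*A*(A+a1)
  # Q(A) = (A+a1)(A+a2) - P(A)
  q2 <- 1 - total
  q1 <- a1 + a2 - m1 * a2 - m2 * a1
  q0 <- a1 * a2
  disc <- max(q1 * q1 - 4 * q2 * q0, 0)
  k1 <- (q1 - sqrt(disc)) / (2 * q2)
  k2 <- (q1 + sqrt(disc)) / (2 * q2)
  Pf <- function(A) m1 * A * (A + a2) + m2 * A * (A + a1)
  t1 <- -Pf(-k1) / (q2 * k1 * (k2 - k1))
  t2 <- total / (1 - total) - t1
  list(tau1 = t1, K1 = k1, tau2 = t2, K2 = k2)
}

# single-component observable parameters
.one_site_observable <- function(tau, K) {
  list(emax = tau / (1 + tau), ec50 = K / (1 + tau))
}
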