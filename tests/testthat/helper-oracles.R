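# Shared test utilities: plate builders whose normalised response is exact,
# and brute-force grid minimisers coded independently of the package's
# optimisers, used as fitting oracles.

# A raw plate whose normalised response equals `pct` exactly: basal wells at
# 500 counts, positive controls at 5000, test wells at 500 + 45 * pct.
as_plate <- function(conc, pct, compound = "cmp", cell_line = "lineX",
                     control_pct = NULL, meta = list()) {
  pct <- as.matrix(pct)
  meta$cell_line <- cell_line
  controls <- list(basal = rep(500, 6), positive = rep(5000, 6))
  if (!is.null(control_pct)) controls$reference <- rep(500 + 45 * control_pct, 6)
  conc_series(compound, conc, 500 + 45 * pct, controls = controls, meta = meta)
}

as_curve <- function(...) normalize_plate(as_plate(...))

# exact one_site_fit objects (via noiseless curves) for shift experiments
one_site_at <- function(logEC50, emax = 100, compound = "agonist") {
  grid <- 10^seq(logEC50 - 3, logEC50 + 3, by = 0.5)
  fit_one_site(as_curve(grid, eq_one_site(grid, emax, 10^logEC50),
                        compound = compound))
}

# two-parameter brute-force minimiser: coarse scan then a local fine scan
grid2 <- function(rss, g1, g2) {
  best <- c(NA, NA); brss <- Inf
  for (a in g1) for (b in g2) {
    r <- rss(a, b)
    if (r < brss) { brss <- r; best <- c(a, b) }
  }
  s1 <- g1[2] - g1[1]; s2 <- g2[2] - g2[1]
  for (a in seq(best[1] - s1, best[1] + s1, length.out = 41)) {
    for (b in seq(best[2] - s2, best[2] + s2, length.out = 41)) {
      r <- rss(a, b)
      if (r < brss) { brss <- r; best <- c(a, b) }
    }
  }
  list(par = best, rss = brss)
}

# two-site grid oracle with the total amplitude profiled out analytically
# (the model is linear in the total given the other three parameters)
grid_two_site <- function(x, y, lo, hi) {
  prof <- function(e1, e2, np) {
    base <- np / 100 * x / (x + 10^e1) + (1 - np / 100) * x / (x + 10^e2)
    tot <- sum(base * y) / sum(base * base)
    sum((y - tot * base)^2)
  }
  best <- c(NA, NA, NA); brss <- Inf
  for (e1 in seq(lo, hi, by = 0.15)) for (e2 in seq(lo, hi, by = 0.15)) {
    if (e2 <= e1 + 0.1) next
    for (np in seq(5, 95, by = 5)) {
      r <- prof(e1, e2, np)
      if (r < brss) { brss <- r; best <- c(e1, e2, np) }
    }
  }
  for (e1 in seq(best[1] - 0.15, best[1] + 0.15, by = 0.01)) {
    for (e2 in seq(best[2] - 0.15, best[2] + 0.15, by = 0.01)) {
      if (e2 <= e1 + 0.1) next
      for (np in seq(max(1, best[3] - 5), min(99, best[3] + 5), by = 0.25)) {
        r <- prof(e1, e2, np)
        if (r < brss) { brss <- r; best <- c(e1, e2, np) }
      }
    }
  }
  list(par = best, rss = brss)
}

# dip grid oracle with the stimulatory amplitude profiled out (clamped >= 0)
grid_dip <- function(x, y, basal, control, lo, hi) {
  prof <- function(li, le) {
    inhib <- basal + (control - basal) * (1 - x / (x + 10^li))
    g <- x / (x + 10^le)
    sm <- max(0, sum(g * (y - inhib)) / sum(g * g))
    sum((y - inhib - sm * g)^2)
  }
  grid2(prof, seq(lo, hi, length.out = 100), seq(lo, hi, length.out = 100))
}

# Independent partial-fraction conversion of a two-conformation stimulus
# mixture S(A) = tau1*A/(A+K1) + tau2*A/(A+K2), R = S/(1+S), into the exact
# observable two-site form m1*A/(A+a1) + m2*A/(A+a2).  Derived from the
# roots of the quadratic denominator of R(A) and matching the A->0 slope
# and A->Inf plateau; coded here without reference to the package.
mixture_observables <- function(tau1, K1, tau2, K2) {
  qa <- 1 + tau1 + tau2
  qb <- K1 + K2 + tau1 * K2 + tau2 * K1
  qc <- K1 * K2
  disc <- sqrt(qb^2 - 4 * qa * qc)
  a1 <- (qb - disc) / (2 * qa)
  a2 <- (qb + disc) / (2 * qa)
  total <- (tau1 + tau2) / (1 + tau1 + tau2)
  slope0 <- tau1 / K1 + tau2 / K2        # R(A)/A as A -> 0
  # m1 + m2 = total ; m1/a1 + m2/a2 = slope0
  m1 <- (slope0 - total / a2) / (1 / a1 - 1 / a2)
  m2 <- total - m1
  list(m1 = m1, a1 = a1, m2 = m2, a2 = a2, total = total)
}
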