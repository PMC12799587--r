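# Internal helpers: least-squares machinery shared by all curve fits.
#
# Every concentration-scale parameter is optimised as log10(molar) inside a
# fixed box; this makes the curvature-based standard errors meaningful on the
# scale the results are reported on.

.LOG_LO <- -13
.LOG_HI <- -2

#' @importFrom stats optim pf lm coef vcov qt setNames sd
#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

# Least-squares fit of a mean function over replicate wells.
#
# fn(par, x) -> predicted mean at concentrations x (recycled over replicates
# by the caller); optimisation via Levenberg-Marquardt with an optim() polish
# or fallback.  Returns parameters, their SEs (from the Gauss-Newton
# approximation to the curvature), the residual sum of squares and df.
.ls_fit <- function(fn, start, lower, upper, x, y, starts = NULL) {
  obj <- function(par) {
    r <- y - fn(par, x)
    sum(r * r)
  }
  resid_fun <- function(par) y - fn(par, x)

  run_one <- function(st) {
    st <- pmin(pmax(st, lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = st, fn = resid_fun, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      par <- pmin(pmax(fit$par, lower), upper)
      return(list(par = par, rss = obj(par)))
    }
    opt <- stats::optim(st, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 500))
    list(par = opt$par, rss = opt$value)
  }

  cand <- c(list(start), starts)
  best <- NULL
  for (st in cand) {
    res <- run_one(st)
    if (is.null(best) || res$rss < best$rss - 1e-12) best <- res
  }

  n <- length(y)
  p <- length(best$par)
  dfree <- max(n - p, 1)
  sigma2 <- best$rss / dfree

  # numerical Jacobian for SEs
  J <- .num_jacobian(function(par) fn(par, x), best$par)
  se <- rep(NA_real_, p)
  JtJ <- crossprod(J)
  cv <- tryCatch(solve(JtJ), error = function(e) NULL)
  if (!is.null(cv)) {
    d <- diag(cv) * sigma2
    d[d < 0] <- NA_real_
    se <- sqrt(d)
  }
  names(se) <- names(best$par)
  list(par = best$par, se = se, rss = best$rss, n = n, df = dfree)
}

.num_jacobian <- function(f, par, eps = 1e-6) {
  f0 <- f(par)
  J <- matrix(0, length(f0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - f0) / h
  }
  J
}

# Extra-sum-of-squares F-test between nested least-squares fits.
# Returns list(F, p); if the richer model does not reduce RSS, p = 1.
.ess_f_test <- function(rss_small, df_small, rss_big, df_big) {
  if (df_small <= df_big || df_big <= 0) return(list(statistic = NA_real_, p = 1))
  num <- (rss_small - rss_big) / (df_small - df_big)
  den <- rss_big / df_big
  if (!is.finite(num) || num <= 0 || den <= 0) return(list(statistic = 0, p = 1))
  Fv <- num / den
  list(statistic = Fv,
       p = stats::pf(Fv, df_small - df_big, df_big, lower.tail = FALSE))
}

# Deterministic per-dataset RNG seeding: mixes a base seed with a label so
# that each simulated plate is reproducible independently of call order.
.mix_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) %% 1000000L) * 1009L + (h %% 100003L)
}

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Flatten a concentration grid and a replicate matrix into paired vectors.
.stack_reps <- function(conc, mat) {
  mat <- as.matrix(mat)
  list(x = rep(conc, times = ncol(mat)), y = as.vector(mat))
}
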