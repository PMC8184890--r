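## Independent oracles used across tests.  These deliberately re-derive
## quantities by brute force / enumeration, never by calling the package
## path they check.

## Brute-force Cox partial likelihood (Breslow) by explicit risk-set
## enumeration; works on right-censored data with <= a handful of rows.
oracle_cox_loglik <- function(beta, time, status, X) {
  eta <- drop(as.matrix(X) %*% beta)
  ll <- 0
  for (t_ev in sort(unique(time[status == 1]))) {
    ev <- which(time == t_ev & status == 1)
    risk <- which(time >= t_ev)
    ll <- ll + sum(eta[ev]) - length(ev) * log(sum(exp(eta[risk])))
  }
  ll
}

oracle_cox_mle <- function(time, status, X) {
  X <- as.matrix(X)
  stats::optim(rep(0, ncol(X)),
               function(b) -oracle_cox_loglik(b, time, status, X),
               method = "BFGS", control = list(reltol = 1e-14))$par
}

## HWE exact p-value by direct enumeration with exact log-probabilities,
## implemented independently of the package recurrence arrangement.
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  if (nA == 0 || na == 0) return(1)
  hets <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  logp <- vapply(hets, function(h) {
    naa <- (nA - h) / 2; nbb <- (na - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  }, 1)
  pr <- exp(logp)
  obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

## Tiny LD-blocked panel for fast unit tests.
small_panel <- function(seed = 7, n_hap = 1000, rho = 0.6, n_block = 2,
                        n_var = 8) {
  spec <- rep(list(list(n_variants = n_var, freq_range = c(0.2, 0.4),
                        rho = rho)), n_block)
  simulate_haplotypes(n_hap, spec, seed = seed)
}

## A quick trial cohort with defaults shared across tests.
small_trial <- function(seed = 3, n = 600, prs_hr = 1, os_hr = 1, ...) {
  simulate_trial_cohort(
    n,
    arm_spec = list(
      list(name = "a1", treated = TRUE, frac = 0.4, irae_rate = 8e-4),
      list(name = "a2", treated = TRUE, frac = 0.3, irae_rate = 8e-4),
      list(name = "c1", treated = FALSE, frac = 0.3, irae_rate = 4e-4)),
    prs_log_hr = log(prs_hr), seed = seed,
    os_irae_log_hr = log(os_hr), ...)
}

## shared fixture: planted single causal variant among nulls
lasso_fixture <- function(seed = 1, n = 500, p_var = 10, beta1 = 0.6) {
  set.seed(seed)
  dos <- matrix(rbinom(n * p_var, 2, 0.3), n, p_var)
  X <- dos * 0.3                              # dosage x effect size
  ev <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  Xfull <- cbind(X, ev)
  pen <- c(rep(TRUE, p_var), rep(FALSE, 3))
  lp <- beta1 * X[, 1] + 0.3 * ev[, 1]
  tm <- rexp(n, 5e-4 * exp(lp))
  st <- as.integer(tm <= 700); tm <- pmin(tm, 700)
  list(X = Xfull, pen = pen, time = tm, status = st)
}

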