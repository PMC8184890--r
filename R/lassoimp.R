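## Precomputed sort/grouping structure for the Breslow partial likelihood.
breslow_prep <- function(time, status) {
  n <- length(time)
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]
  new_grp <- c(TRUE, t_s[-1] != t_s[-n])
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  ends <- c(first[-1] - 1L, n)
  csd <- cumsum(d_s)
  d_g <- csd[ends] - c(0, csd[ends[-length(ends)]])
  list(n = n, ord = ord, d_s = d_s, d_s_unord = status, grp = grp,
       first = first, d_g = d_g, ev = d_g > 0, cache = new.env(parent = emptyenv()))
}

## Per-subject gradient g and curvature h of the Breslow log partial
## likelihood with respect to the linear predictor, plus the loglik.
breslow_quantities_prep <- function(pp, eta) {
  e_s <- exp(eta[pp$ord])
  cs <- rev(cumsum(rev(e_s)))
  S_g <- cs[pp$first]
  inc_A <- ifelse(pp$ev, pp$d_g / S_g, 0)
  inc_B <- ifelse(pp$ev, pp$d_g / S_g^2, 0)
  A <- cumsum(inc_A)[pp$grp]
  B <- cumsum(inc_B)[pp$grp]
  g_s <- pp$d_s - e_s * A
  h_s <- pmax(e_s * A - e_s^2 * B, 1e-10)
  loglik <- sum(eta[pp$ord][pp$d_s == 1]) -
    sum(pp$d_g[pp$ev] * log(S_g[pp$ev]))
  g <- h <- numeric(pp$n)
  g[pp$ord] <- g_s; h[pp$ord] <- h_s
  list(g = g, h = h, loglik = loglik)
}

breslow_quantities <- function(time, status, eta) {
  breslow_quantities_prep(breslow_prep(time, status), eta)
}

## reverse cumulative sums down the rows of a matrix, fully vectorized:
## one cumsum over the reversed stacked columns, then per-column offsets
revcumsum_mat <- function(M) {
  n <- nrow(M); k <- ncol(M)
  V <- matrix(cumsum(M[n:1, , drop = FALSE]), n, k)
  if (k > 1) V <- V - rep(c(0, V[n, -k]), each = n)
  V[n:1, , drop = FALSE]
}

## Exact gradient (p-vector) of the Breslow log partial likelihood in
## coefficient space, plus the loglik and the pieces the Hessian needs.
breslow_grad <- function(pp, X, eta) {
  Xs <- X[pp$ord, , drop = FALSE]
  e_s <- exp(eta[pp$ord])
  cs <- rev(cumsum(rev(e_s)))
  S_g <- cs[pp$first][pp$ev]
  d_g <- pp$d_g[pp$ev]
  firsts <- pp$first[pp$ev]
  M1 <- revcumsum_mat(e_s * Xs)[firsts, , drop = FALSE] / S_g
  grad <- drop(crossprod(X, pp$d_s_unord)) - drop(crossprod(M1, d_g))
  loglik <- sum(eta[pp$ord][pp$d_s == 1]) - sum(d_g * log(S_g))
  list(grad = grad, loglik = loglik, Xs = Xs, e_s = e_s, S_g = S_g,
       d_g = d_g, firsts = firsts, M1 = M1)
}

## Exact Hessian of the Breslow log partial likelihood; the pairwise
## column products of the (eta-independent) sorted design are cached on
## the prep object.
breslow_hess <- function(pp, X, gq) {
  p <- ncol(X)
  if (is.null(pp$cache$XX) || !identical(dim(pp$cache$XX), c(pp$n, p * (p + 1L) %/% 2L))) {
    pair_i <- rep(seq_len(p), times = seq(p, 1))
    pair_j <- sequence(seq(p, 1), from = seq_len(p))
    pp$cache$pair_i <- pair_i; pp$cache$pair_j <- pair_j
    pp$cache$XX <- gq$Xs[, pair_i, drop = FALSE] * gq$Xs[, pair_j, drop = FALSE]
  }
  pair_i <- pp$cache$pair_i; pair_j <- pp$cache$pair_j
  M2 <- revcumsum_mat(gq$e_s * pp$cache$XX)[gq$firsts, , drop = FALSE] / gq$S_g
  Hpack <- drop(crossprod(
    M2 - gq$M1[, pair_i, drop = FALSE] * gq$M1[, pair_j, drop = FALSE], gq$d_g))
  H <- matrix(0, p, p)
  H[cbind(pair_i, pair_j)] <- Hpack
  H[cbind(pair_j, pair_i)] <- Hpack
  H
}

breslow_grad_hess <- function(pp, X, eta) {
  gq <- breslow_grad(pp, X, eta)
  list(grad = gq$grad, H = breslow_hess(pp, X, gq), loglik = gq$loglik)
}

#' Non-negative L1-penalized Cox regression
#'
#' Cyclic coordinate descent on the Breslow partial likelihood.
#' Penalized (variant) coefficients are constrained to be >= 0;
#' unpenalized columns (genotype eigenvectors) are unconstrained and
#' excluded from the L1 penalty.  The objective is
#' -(1/n) loglik + lambda * sum(|beta_penalized|).
#'
#' @param X n x p design matrix; for the variant-importance analysis the
#'   entry is risk-allele dosage x conditional effect size.
#' @param time,status right-censored response.
#' @param lambda penalty (>= 0).
#' @param penalized logical vector over columns (TRUE = penalized +
#'   non-negative); default all TRUE.
#' @param beta_init warm start.
#' @param tol convergence threshold on the maximum coefficient change.
#' @param max_sweeps outer (proximal-Newton) iteration cap.
#' @return list of class `nncox_lasso`: beta, loglik, lambda, converged,
#'   n_sweeps.
#' @details The solver is proximal Newton: each outer iteration builds
#'   the exact Breslow gradient and Hessian in coefficient space and
#'   solves the penalized quadratic subproblem by cyclic coordinate
#'   descent with non-negativity clipping, followed by step-halving on
#'   the penalized objective.  With the variant-level designs used here
#'   (tens of columns) this converges quadratically.
#' @export
fit_nonneg_cox_lasso <- function(X, time, status, lambda, penalized = NULL,
                                 beta_init = NULL, tol = 1e-7, max_sweeps = 50L,
                                 prep = NULL, hess_init = NULL) {
  stopifnot(lambda >= 0)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  penalized <- penalized %||% rep(TRUE, p)
  beta <- beta_init %||% numeric(p)
  if (any(beta[penalized] < 0)) beta[penalized] <- pmax(beta[penalized], 0)
  pp <- prep %||% breslow_prep(time, status)
  lam_eff <- if (is.finite(lambda)) lambda else 0
  pen_obj <- function(ll, b) -ll / n +
    (if (is.finite(lambda)) lambda * sum(abs(b[penalized])) else 0)
  eta <- drop(X %*% beta)
  converged <- FALSE
  Hn <- hess_init
  refresh <- is.null(Hn)
  for (sweep in seq_len(max_sweeps)) {
    gq <- breslow_grad(pp, X, eta)
    gn <- gq$grad / n
    ## refresh the Hessian lazily: the gradient is exact every sweep, so
    ## the fixed point (and the KKT conditions) are unaffected by a stale
    ## positive-definite Hessian -- it only shapes the step.
    if (refresh || sweep %% 4L == 0L) {
      Hn <- breslow_hess(pp, X, gq) / n
      diag(Hn) <- pmax(diag(Hn), 1e-10)
      refresh <- FALSE
    }
    f0 <- pen_obj(gq$loglik, beta)
    ## coordinate descent on the exact quadratic model
    b <- beta
    if (!is.finite(lambda)) b[penalized] <- 0
    for (cycle in seq_len(500L)) {
      dmax <- 0
      for (j in seq_len(p)) {
        if (!is.finite(lambda) && penalized[j]) next
        rho <- sum(Hn[j, ] * (b - beta)) - Hn[j, j] * (b[j] - beta[j])
        cj <- gn[j] - rho
        new_b <- if (penalized[j]) max(0, beta[j] + (cj - lam_eff) / Hn[j, j])
                 else beta[j] + cj / Hn[j, j]
        db <- new_b - b[j]
        if (db != 0) { b[j] <- new_b; dmax <- max(dmax, abs(db)) }
      }
      if (dmax < tol / 10) break
    }
    step <- b - beta
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    ## step-halving on the penalized objective
    t_step <- 1
    for (half in 1:30) {
      b_try <- beta + t_step * step
      if (any(penalized & b_try < 0)) b_try[penalized] <- pmax(b_try[penalized], 0)
      eta_try <- drop(X %*% b_try)
      ll_try <- breslow_quantities_prep(pp, eta_try)$loglik
      if (pen_obj(ll_try, b_try) <= f0 + 1e-12) break
      t_step <- t_step / 2
    }
    if (t_step < 1) refresh <- TRUE    # stale Hessian misbehaved
    beta <- b_try; eta <- eta_try
  }
  ## snap numerically-zero boundary coefficients (entry at lambda_max can
  ## leave dust orders of magnitude below the convergence tolerance)
  dust <- penalized & beta > 0 & beta < 1e-8
  if (any(dust)) { beta[dust] <- 0; eta <- drop(X %*% beta) }
  q <- breslow_quantities_prep(pp, eta)
  structure(list(beta = beta, loglik = q$loglik, lambda = lambda,
                 converged = converged, n_sweeps = sweep,
                 penalized = penalized, hess = Hn), class = "nncox_lasso")
}

#' Score vector (gradient of the mean log partial likelihood)
#'
#' Used for the lambda grid and for KKT verification: at a solution,
#' every strictly positive penalized coefficient has score equal to
#' lambda and every zero one has score <= lambda.
#'
#' @inheritParams fit_nonneg_cox_lasso
#' @param beta coefficient vector.
#' @return numeric score vector, one entry per column of `X`.
#' @export
cox_score <- function(X, time, status, beta) {
  q <- breslow_quantities(time, status, drop(as.matrix(X) %*% beta))
  drop(crossprod(as.matrix(X), q$g)) / nrow(X)
}

#' Lambda grid from the score at the null model
#'
#' Unpenalized columns are first fitted alone (penalized coefficients
#' held at zero); lambda_max is the largest positive score among the
#' penalized columns at that null model — the smallest lambda zeroing
#' all penalized coefficients.  The grid is `n_lambda` log-spaced values
#' down to `lambda_min_ratio * lambda_max`.
#'
#' @inheritParams fit_nonneg_cox_lasso
#' @param n_lambda grid size.
#' @param lambda_min_ratio grid floor as a fraction of lambda_max.
#' @return decreasing numeric vector of lambdas.
#' @export
lambda_grid <- function(X, time, status, penalized = NULL,
                        n_lambda = 100L, lambda_min_ratio = 1e-3) {
  X <- as.matrix(X)
  penalized <- penalized %||% rep(TRUE, ncol(X))
  beta0 <- numeric(ncol(X))
  if (any(!penalized)) {
    null_fit <- fit_nonneg_cox_lasso(X, time, status, lambda = Inf,
                                     penalized = penalized)
    beta0 <- null_fit$beta
  }
  s <- cox_score(X, time, status, beta0)
  lmax <- max(s[penalized], 0)
  if (lmax <= 0) lmax <- 1e-3
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

## Verweij & van Houwelingen cross-validated partial-likelihood deviance:
## -2 * (loglik_all(beta_train) - loglik_train(beta_train)).
cv_fold_deviance <- function(X, time, status, train, betas) {
  pp_all <- breslow_prep(time, status)
  pp_tr <- breslow_prep(time[train], status[train])
  Xtr <- X[train, , drop = FALSE]
  eta_all <- X %*% betas
  eta_tr <- Xtr %*% betas
  vapply(seq_len(ncol(betas)), function(k) {
    l_all <- breslow_quantities_prep(pp_all, eta_all[, k])$loglik
    l_tr <- breslow_quantities_prep(pp_tr, eta_tr[, k])$loglik
    -2 * (l_all - l_tr)
  }, 1)
}

## Full regularization path with warm starts; returns p x n_lambda matrix.
lasso_path <- function(X, time, status, lambdas, penalized) {
  p <- ncol(X)
  pp <- breslow_prep(time, status)
  betas <- matrix(0, p, length(lambdas))
  b <- numeric(p)
  H <- NULL
  for (k in seq_along(lambdas)) {
    fit <- fit_nonneg_cox_lasso(X, time, status, lambdas[k],
                                penalized = penalized, beta_init = b,
                                prep = pp, hess_init = H)
    b <- fit$beta
    H <- fit$hess
    betas[, k] <- b
  }
  betas
}

#' Repeated k-fold cross-validation for the L1 penalty
#'
#' Folds are stratified by event status.  Per repeat, the lambda
#' minimizing the summed out-of-fold partial-likelihood deviance
#' (Verweij-van Houwelingen) on a shared log grid is chosen; the
#' returned lambda* is the geometric mean of the per-repeat choices
#' (averaging on the log scale).
#'
#' @inheritParams fit_nonneg_cox_lasso
#' @param k folds.
#' @param repeats CV repetitions.
#' @param seed integer seed.
#' @param lambdas grid (default [lambda_grid()]).
#' @param min_events_per_fold minimum events required per fold.
#' @return list: lambda (geometric mean), per_repeat, lambdas, cv_deviance
#'   (repeats x n_lambda).
#' @export
cv_select_lambda <- function(X, time, status, k = 3L, repeats = 100L, seed = 1,
                             penalized = NULL, lambdas = NULL,
                             min_events_per_fold = 5L) {
  X <- as.matrix(X)
  penalized <- penalized %||% rep(TRUE, ncol(X))
  lambdas <- lambdas %||% lambda_grid(X, time, status, penalized)
  n_ev <- sum(status)
  if (n_ev < k * min_events_per_fold)
    stop("too few events for ", k, "-fold CV (need >= ", k * min_events_per_fold, ")")
  set.seed(substream_seed(seed, "cv_lambda"))
  ev_idx <- which(status == 1); cn_idx <- which(status == 0)
  choices <- numeric(repeats)
  dev_mat <- matrix(NA_real_, repeats, length(lambdas))
  for (rep_i in seq_len(repeats)) {
    for (try_i in 1:10) {   # re-draw folds if any comes out all-censored
      fold <- integer(length(status))
      fold[ev_idx] <- sample(rep_len(seq_len(k), length(ev_idx)))
      fold[cn_idx] <- sample(rep_len(seq_len(k), length(cn_idx)))
      if (all(tapply(status, fold, sum) > 0)) break
    }
    dev <- numeric(length(lambdas))
    for (f in seq_len(k)) {
      train <- fold != f
      betas <- lasso_path(X[train, , drop = FALSE], time[train], status[train],
                          lambdas, penalized)
      dev <- dev + cv_fold_deviance(X, time, status, train, betas)
    }
    dev_mat[rep_i, ] <- dev
    choices[rep_i] <- lambdas[which.min(dev)]
  }
  list(lambda = exp(mean(log(choices))), per_repeat = choices,
       lambdas = lambdas, cv_deviance = dev_mat)
}

#' Re-weighted importance of lasso-retained variants
#'
#' importance_p = |coef_p * beta_p| / sum_q |coef_q * beta_q| over the
#' penalized variants; non-retained variants get importance 0.  An
#' all-zero coefficient vector (the expectation for control-arm data)
#' yields an empty retained set.
#'
#' @param coefficients lasso coefficients for the variant columns.
#' @param effect_sizes conditional effect sizes aligned to the variants.
#' @param ids optional variant ids.
#' @return data.table: id, coefficient, retained, importance.
#' @export
importance <- function(coefficients, effect_sizes, ids = NULL) {
  stopifnot(length(coefficients) == length(effect_sizes))
  ids <- ids %||% sprintf("v%d", seq_along(coefficients))
  w <- abs(coefficients * effect_sizes)
  tot <- sum(w)
  imp <- if (tot > 0) w / tot else rep(0, length(w))
  data.table::data.table(id = ids, coefficient = coefficients,
                         retained = coefficients != 0, importance = imp)
}

#' Build the survival-lasso design matrix
#'
#' Variant columns are risk-allele dosage x conditional effect size (all
#' entries >= 0 given risk-allele orientation); eigenvector columns are
#' appended unpenalized.
#'
#' @param dosages n x m risk-allele dosage matrix (columns named by
#'   variant id, weights order).
#' @param weights `score_weights`.
#' @param eigenvectors n x k matrix or NULL.
#' @return list: X, penalized (logical), variant_ids.
#' @export
lasso_design <- function(dosages, weights, eigenvectors = NULL) {
  idx <- match(weights$id, colnames(dosages))
  if (anyNA(idx)) stop("dosage columns missing for: ",
                       paste(weights$id[is.na(idx)], collapse = ", "))
  Xv <- sweep(dosages[, idx, drop = FALSE], 2, weights$weight, `*`)
  X <- cbind(Xv, eigenvectors)
  penalized <- c(rep(TRUE, ncol(Xv)),
                 rep(FALSE, if (is.null(eigenvectors)) 0 else ncol(eigenvectors)))
  list(X = as.matrix(X), penalized = penalized, variant_ids = weights$id)
}
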