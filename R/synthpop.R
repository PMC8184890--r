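#' Simulate an LD-blocked haplotype panel
#'
#' Haplotypes are generated block by block with a first-order copying
#' process: within a block, the allele at variant j is copied from variant
#' j-1 with probability `rho` and drawn fresh otherwise, giving adjacent
#' pairwise correlation approximately `rho` (exactly `rho` when
#' frequencies are equal) and correlation decaying as `rho^k` with lag k.
#' Fresh-draw probabilities are solved so the marginal alt-allele
#' frequency of every variant hits its target exactly.  Blocks are
#' independent of one another.
#'
#' @param n_haplotypes number of haplotypes (>= 2).
#' @param block_spec list of blocks, each a list with `n_variants`,
#'   `freq_range` (length-2 numeric in (0,1)), and `rho` (within-block
#'   adjacent correlation, in \[0,1)).
#' @param seed integer seed.
#' @param chrom chromosome label for the variant table.
#' @param pos_start 1-based position of the first variant; variants are
#'   spaced `pos_step` bp apart.
#' @param pos_step spacing between adjacent variants in bp.
#' @return an object of class `haplotype_panel`: a list with `variants`
#'   (data.table: id, chrom, pos, ref, alt, freq, block) and `H`
#'   (n_haplotypes x n_variants 0/1 matrix).
#' @export
simulate_haplotypes <- function(n_haplotypes, block_spec, seed,
                                chrom = "chr1", pos_start = 1e6, pos_step = 5e3) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (!length(block_spec)) stop("block_spec must contain at least one block")
  for (b in block_spec) {
    if (is.null(b$n_variants) || b$n_variants < 1) stop("empty block in block_spec")
    rho <- b$rho %||% 0
    if (rho < 0 || rho >= 1) stop("within-block correlation must be in [0, 1)")
    fr <- b$freq_range %||% c(0.05, 0.5)
    if (any(fr <= 0) || any(fr >= 1)) stop("freq_range must lie in (0, 1)")
  }
  set.seed(substream_seed(seed, "haplotypes"))

  alleles <- c("A", "C", "G", "T")
  n_var_total <- sum(vapply(block_spec, function(b) as.integer(b$n_variants), 1L))
  H <- matrix(0L, nrow = n_haplotypes, ncol = n_var_total)
  freq <- numeric(n_var_total)
  block_id <- integer(n_var_total)

  j <- 0L
  for (bi in seq_along(block_spec)) {
    b <- block_spec[[bi]]
    rho <- b$rho %||% 0
    fr <- sort(b$freq_range %||% c(0.05, 0.5))
    f_tgt <- stats::runif(b$n_variants, fr[1], fr[2])
    for (k in seq_len(b$n_variants)) {
      j <- j + 1L
      freq[j] <- f_tgt[k]
      block_id[j] <- bi
      if (k == 1L) {
        H[, j] <- stats::rbinom(n_haplotypes, 1L, f_tgt[k])
      } else {
        ## fresh-draw probability solved so the marginal frequency is exact:
        ## p_j = rho * p_{j-1} + (1 - rho) * f_star
        f_star <- (f_tgt[k] - rho * f_tgt[k - 1]) / (1 - rho)
        f_star <- min(max(f_star, 0), 1)
        copy <- stats::runif(n_haplotypes) < rho
        fresh <- stats::rbinom(n_haplotypes, 1L, f_star)
        H[, j] <- ifelse(copy, H[, j - 1L], fresh)
      }
    }
  }

  ## draw non-complementary ref/alt pairs: strand-ambiguous A/T and C/G
  ## variants would only be removed again during harmonization
  complement <- c(A = "T", C = "G", G = "C", T = "A")
  ra <- t(vapply(seq_len(n_var_total), function(i) {
    ref <- sample(alleles, 1L)
    alt <- sample(setdiff(alleles, c(ref, complement[[ref]])), 1L)
    c(ref, alt)
  }, character(2)))
  variants <- data.table::data.table(
    id = sprintf("rs%06d", seq_len(n_var_total)),
    chrom = chrom,
    pos = as.integer(pos_start + (seq_len(n_var_total) - 1L) * pos_step),
    ref = ra[, 1], alt = ra[, 2],
    freq = freq, block = block_id
  )
  structure(list(variants = variants, H = H), class = "haplotype_panel")
}

#' Draw diploid genotype dosages from a haplotype panel
#'
#' @param panel a `haplotype_panel`.
#' @param n number of individuals.
#' @return n x n_variants integer dosage matrix (0/1/2).
#' @export
draw_genotypes <- function(panel, n) {
  nh <- nrow(panel$H)
  i1 <- sample.int(nh, n, replace = TRUE)
  i2 <- sample.int(nh, n, replace = TRUE)
  panel$H[i1, , drop = FALSE] + panel$H[i2, , drop = FALSE]
}

#' Solve the logistic intercept hitting a target prevalence
#'
#' Monte-Carlo root finding on the expected case probability under the
#' panel's genotype distribution.
#' @keywords internal
solve_intercept <- function(panel, beta, prevalence, n_mc = 20000L) {
  G <- draw_genotypes(panel, n_mc)
  eta <- as.vector(G %*% beta)
  f <- function(a) mean(stats::plogis(a + eta)) - prevalence
  stats::uniroot(f, c(-30, 30), tol = 1e-6)$root
}

#' Simulate a case-control GWAS cohort by quota sampling
#'
#' Phenotypes follow a logistic model on causal dosages; individuals are
#' drawn from the panel and assigned case status until the case and
#' control quotas are both exactly met, mirroring case-control GWAS
#' ascertainment.
#'
#' @param panel a `haplotype_panel`.
#' @param architecture list with `causal_ids` (variant ids), `log_or`
#'   (same length), and `prevalence` (population case probability used to
#'   set the intercept).
#' @param n_cases,n_controls exact quota counts.
#' @param seed integer seed.
#' @param max_draws sampling budget before declaring the prevalence
#'   unattainable.
#' @return list with `G` (dosage matrix), `y` (0/1), `variants`, and
#'   `truth` (causal ids, log ORs, intercept).
#' @export
simulate_gwas_cohort <- function(panel, architecture, n_cases, n_controls, seed,
                                 max_draws = 400L) {
  set.seed(substream_seed(seed, "gwas_cohort"))
  ids <- panel$variants$id
  beta <- numeric(length(ids))
  if (length(architecture$causal_ids)) {
    idx <- match(architecture$causal_ids, ids)
    if (anyNA(idx)) stop("causal variants absent from panel")
    beta[idx] <- architecture$log_or
  }
  prevalence <- architecture$prevalence %||% 0.1
  a <- solve_intercept(panel, beta, prevalence)

  n <- n_cases + n_controls
  G <- matrix(0L, n, length(ids))
  y <- integer(n)
  got_case <- 0L; got_ctrl <- 0L; filled <- 0L
  batch <- max(2L * n, 1000L)
  for (it in seq_len(max_draws)) {
    Gb <- draw_genotypes(panel, batch)
    pb <- stats::plogis(a + as.vector(Gb %*% beta))
    yb <- stats::rbinom(batch, 1L, pb)
    for (cls in c(1L, 0L)) {
      need <- if (cls == 1L) n_cases - got_case else n_controls - got_ctrl
      if (need <= 0L) next
      take <- which(yb == cls)[seq_len(min(need, sum(yb == cls)))]
      if (!length(take)) next
      rows <- filled + seq_along(take)
      G[rows, ] <- Gb[take, , drop = FALSE]
      y[rows] <- cls
      filled <- filled + length(take)
      if (cls == 1L) got_case <- got_case + length(take) else got_ctrl <- got_ctrl + length(take)
    }
    if (got_case >= n_cases && got_ctrl >= n_controls) break
  }
  if (got_case < n_cases || got_ctrl < n_controls)
    stop("case/control quota unattainable at the configured prevalence")
  ord <- sample.int(n)
  list(G = G[ord, , drop = FALSE], y = y[ord], variants = data.table::copy(panel$variants),
       truth = list(causal_ids = architecture$causal_ids,
                    log_or = architecture$log_or, intercept = a))
}

#' Simulate a multi-arm trial cohort with PRS-dependent irAE hazards
#'
#' Event times are drawn from exponential (default) or Weibull hazards
#' h(t) = h0(arm) * exp(beta * PRS + covariate terms).  Overall survival
#' is piecewise exponential: the death hazard is multiplied by
#' `exp(os_irae_log_hr)` from the irAE onset onward, so a protective or
#' harmful irAE-survival coupling can be planted and recovered with a
#' time-dependent covariate.  The PRS effect on irAE can be restricted to
#' active (treated) arms.
#'
#' @param n_patients total cohort size.
#' @param arm_spec list of arms: each a list with `name`, `treated`
#'   (logical), `frac` (fraction of patients; fractions are normalized),
#'   and optional `irae_rate`, `os_rate` per-day baseline hazards.
#' @param prs_log_hr log hazard ratio per unit normalized PRS on irAE
#'   onset (applied in treated arms only unless `active_only = FALSE`).
#' @param covariate_effects named list of log-HRs on the irAE hazard for
#'   `gender`, `tsh`, `ft4`, `ft3` (labs enter on their normalized scale).
#' @param censoring_spec list: `admin_time` (administrative censoring day)
#'   and optional `dropout_rate` (exponential dropout hazard per day).
#' @param seed integer seed.
#' @param weights optional `score_weights` object; when supplied, dosages
#'   for the scored variants are drawn binomially from the weight
#'   frequencies and the raw PRS is computed from them, otherwise the PRS
#'   is drawn standard normal directly.
#' @param os_irae_log_hr log-HR on death after irAE onset (default 0).
#' @param active_only logical; PRS affects irAE hazard in treated arms only.
#' @param shape Weibull shape for event times (1 = exponential).
#' @param hyper_rate baseline hazard for the hyperthyroidism event class.
#' @return data.table of patients (one row each) with arm, treatment flag,
#'   gender (1 = female, 0 = male), normalized PRS, baseline labs,
#'   per-class irAE time/status, OS time/status, and 5 genotype
#'   eigenvector columns `EV1..EV5`; dosage columns `dos_*` when
#'   `weights` is supplied.
#' @export
simulate_trial_cohort <- function(n_patients, arm_spec, prs_log_hr = 0,
                                  covariate_effects = list(), censoring_spec = list(admin_time = 730),
                                  seed = 1, weights = NULL, os_irae_log_hr = 0,
                                  active_only = TRUE, shape = 1,
                                  hyper_rate = 5e-5) {
  set.seed(substream_seed(seed, "trial_cohort"))
  fr <- vapply(arm_spec, function(a) a$frac %||% (1 / length(arm_spec)), 1)
  fr <- fr / sum(fr)
  n_arm <- drop(stats::rmultinom(1, n_patients, fr))
  ## guarantee non-empty arms
  while (any(n_arm == 0)) {
    i <- which.min(n_arm); j <- which.max(n_arm)
    n_arm[i] <- n_arm[i] + 1L; n_arm[j] <- n_arm[j] - 1L
  }
  arm <- rep(vapply(arm_spec, `[[`, "", "name"), n_arm)
  treated <- rep(vapply(arm_spec, function(a) isTRUE(a$treated), TRUE), n_arm)
  irae_rate <- rep(vapply(arm_spec, function(a) a$irae_rate %||% 4e-4, 1), n_arm)
  os_rate <- rep(vapply(arm_spec, function(a) a$os_rate %||% 8e-4, 1), n_arm)
  if (any(irae_rate < 0) || any(os_rate < 0)) stop("negative baseline hazard")

  n <- n_patients
  gender <- stats::rbinom(n, 1L, 0.5)
  tsh <- stats::rlnorm(n, log(1.8), 0.45)
  ft4 <- stats::rlnorm(n, log(15), 0.15)
  ft3 <- stats::rlnorm(n, log(4.5), 0.15)
  ev <- matrix(stats::rnorm(5L * n, 0, 0.02), n, 5L,
               dimnames = list(NULL, paste0("EV", 1:5)))

  dos <- NULL
  if (!is.null(weights)) {
    dos <- vapply(weights$freq, function(f) stats::rbinom(n, 2L, f), numeric(n))
    colnames(dos) <- paste0("dos_", weights$id)
    raw <- drop(dos %*% weights$weight)
    prs <- normal_scores(raw)
  } else {
    prs <- stats::rnorm(n)
  }

  ce <- covariate_effects
  lin <- (ce$gender %||% 0) * gender +
    (ce$tsh %||% 0) * normal_scores(tsh) +
    (ce$ft4 %||% 0) * normal_scores(ft4) +
    (ce$ft3 %||% 0) * normal_scores(ft3)
  prs_term <- prs_log_hr * prs * (if (active_only) as.numeric(treated) else 1)

  draw_time <- function(rate, lp) {
    ## inverse-CDF draw from a Weibull hazard h(t) = rate*shape*t^(shape-1)*exp(lp)
    u <- stats::runif(length(lp))
    (-log(u) / (rate * exp(lp)))^(1 / shape)
  }
  t_hypo <- draw_time(irae_rate, prs_term + lin)
  t_hyper <- draw_time(rep(hyper_rate, n), 0.6 * prs_term)

  ## OS: piecewise exponential around the hypothyroidism irAE onset
  u <- stats::runif(n)
  h0 <- os_rate; h1 <- os_rate * exp(os_irae_log_hr)
  cum_at_onset <- h0 * t_hypo
  t_os <- ifelse(-log(u) <= cum_at_onset,
                 -log(u) / h0,
                 t_hypo + (-log(u) - cum_at_onset) / h1)

  cens <- rep(censoring_spec$admin_time %||% 730, n)
  if (!is.null(censoring_spec$dropout_rate) && censoring_spec$dropout_rate > 0)
    cens <- pmin(cens, stats::rexp(n, censoring_spec$dropout_rate))

  os_time <- pmin(t_os, cens)
  os_status <- as.integer(t_os <= cens)
  hypo_time <- pmin(t_hypo, os_time)
  hypo_status <- as.integer(t_hypo <= os_time)
  hyper_time <- pmin(t_hyper, os_time)
  hyper_status <- as.integer(t_hyper <= os_time)

  out <- data.table::data.table(
    patient_id = sprintf("P%05d", seq_len(n)),
    arm = arm, treated = treated, gender = gender,
    prs = prs, tsh = tsh, ft4 = ft4, ft3 = ft3,
    hypo_time = pmax(hypo_time, 1e-6), hypo_status = hypo_status,
    hyper_time = pmax(hyper_time, 1e-6), hyper_status = hyper_status,
    os_time = pmax(os_time, 1e-6), os_status = os_status
  )
  out <- cbind(out, data.table::as.data.table(ev))
  if (!is.null(dos)) out <- cbind(out, data.table::as.data.table(dos))
  out[]
}

#' Simulate longitudinal TSH lab series with thyroiditis-like ordering
#'
#' For patients carrying both thyroid event classes, hyperthyroidism
#' precedes hypothyroidism with probability `ordering_prob` (default the
#' clinically expected predominance of transient hyperthyroidism before
#' hypothyroidism).  Symptomatic events are placed at most
#' `symptomatic_lag_days` after the first abnormal TSH measurement.
#'
#' @param patients data.table with columns `patient_id`, `followup`
#'   (days), `has_hypo`, `has_hyper` (logical event-class indicators).
#' @param abnormal_threshold TSH abnormality threshold, mU/L (strict >).
#' @param ordering_prob probability that hyper precedes hypo among
#'   dual-event patients; in \[0,1\].
#' @param symptomatic_lag_days maximum lag from first abnormal TSH to the
#'   symptomatic event day.
#' @param seed integer seed.
#' @param visit_step days between scheduled thyroid labs.
#' @return list with `labs` (patient_id, day, tsh), `events` (patient_id,
#'   class, day: symptomatic onsets), and `onsets` (patient_id,
#'   hyper_onset, hypo_onset in biology time).
#' @export
simulate_lab_series <- function(patients, abnormal_threshold = 5,
                                ordering_prob = 0.857, symptomatic_lag_days = 7,
                                seed = 1, visit_step = 28L) {
  if (ordering_prob < 0 || ordering_prob > 1) stop("ordering_prob must be in [0, 1]")
  if (symptomatic_lag_days < 0) stop("symptomatic_lag_days must be >= 0")
  set.seed(substream_seed(seed, "lab_series"))
  labs_list <- list(); ev_list <- list(); on_list <- list()
  for (i in seq_len(nrow(patients))) {
    pid <- patients$patient_id[i]
    fu <- patients$followup[i]
    days <- seq(0L, as.integer(fu), by = visit_step)
    has_hypo <- isTRUE(patients$has_hypo[i]); has_hyper <- isTRUE(patients$has_hyper[i])
    hyper_on <- NA_real_; hypo_on <- NA_real_
    if (has_hypo && has_hyper) {
      two <- sort(stats::runif(2, 0.15 * fu, 0.85 * fu))
      if (stats::runif(1) < ordering_prob) { hyper_on <- two[1]; hypo_on <- two[2] }
      else                                 { hypo_on <- two[1]; hyper_on <- two[2] }
    } else if (has_hypo) {
      hypo_on <- stats::runif(1, 0.15 * fu, 0.85 * fu)
    } else if (has_hyper) {
      hyper_on <- stats::runif(1, 0.15 * fu, 0.85 * fu)
    }
    tsh <- stats::rlnorm(length(days), log(1.8), 0.25)
    if (!is.na(hyper_on)) {
      w <- days >= hyper_on & (is.na(hypo_on) | days < hypo_on)
      tsh[w] <- stats::runif(sum(w), 0.01, 0.2)   # suppressed TSH
    }
    if (!is.na(hypo_on)) {
      w <- days >= hypo_on
      tsh[w] <- abnormal_threshold + stats::rlnorm(sum(w), log(3), 0.4)
    }
    labs_list[[i]] <- data.table::data.table(patient_id = pid, day = days, tsh = tsh)
    mk_ev <- function(cls, onset) {
      first_abn <- if (cls == "hypothyroidism") days[which(tsh > abnormal_threshold)][1]
                   else days[which(tsh < 0.3)][1]
      if (is.na(first_abn)) return(NULL)
      data.table::data.table(patient_id = pid, class = cls,
                             day = first_abn + stats::runif(1, 0, symptomatic_lag_days))
    }
    evs <- list()
    if (!is.na(hypo_on)) evs <- c(evs, list(mk_ev("hypothyroidism", hypo_on)))
    if (!is.na(hyper_on)) evs <- c(evs, list(mk_ev("hyperthyroidism", hyper_on)))
    evs <- Filter(Negate(is.null), evs)
    if (length(evs)) ev_list[[length(ev_list) + 1L]] <- data.table::rbindlist(evs)
    on_list[[i]] <- data.table::data.table(patient_id = pid,
                                           hyper_onset = hyper_on, hypo_onset = hypo_on)
  }
  list(labs = data.table::rbindlist(labs_list),
       events = if (length(ev_list)) data.table::rbindlist(ev_list)
                else data.table::data.table(patient_id = character(), class = character(), day = numeric()),
       onsets = data.table::rbindlist(on_list))
}
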