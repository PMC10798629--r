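#' Specify a simulated observer
#'
#' An observer is defined by a response strategy plus internal (possibly
#' miscalibrated) standard deviations for each prior and likelihood label, and
#' additive Gaussian motor/response noise. The internal values stand for the
#' observer's beliefs about prior and (single-dot) likelihood dispersion; they
#' need not equal the generative design values, which is how systematic
#' likelihood over-weighting is emulated.
#'
#' Strategies:
#' * `"bayes"`: precision-weighted average of prior mean and splash centroid,
#'   with weight `w = sigma_P^2 / (sigma_P^2 + sigma_L^2 / n_dots)` computed
#'   from the internal values.
#' * `"likelihood_only"`: responds at the splash centroid (weight 1).
#' * `"prior_only"`: responds at the prior mean (weight 0).
#' * `"linear_map"`: weight is a linear function of internal precisions,
#'   `w = b0 + b1 / sigma_P^2 + b2 / sigma_L^2`, clipped to `[0, 1]`.
#' * `"exemplar"`: represents the prior as remembered learning-phase coin
#'   positions and responds with a likelihood-weighted resample of them
#'   (see [exemplar_estimate()]).
#' * `"rote"`: behaves like `"bayes"` on trained combinations but, facing a
#'   novel likelihood, keeps the weight it used for the trained combination
#'   sharing the trial's prior (nearest trained likelihood dispersion when
#'   several were trained with that prior) - the zero-transfer baseline.
#'
#' @param strategy One of `"bayes"`, `"likelihood_only"`, `"prior_only"`,
#'   `"linear_map"`, `"exemplar"`, `"rote"`.
#' @param internal_sigma_P Named numeric vector of internal prior standard
#'   deviations, names = prior labels.
#' @param internal_sigma_L Named numeric vector of internal single-dot
#'   likelihood standard deviations, names = likelihood labels.
#' @param motor_sd Standard deviation of additive Gaussian response noise
#'   (screen units), applied identically in the likelihood-only and coin
#'   tasks.
#' @param linear_coeffs Length-3 numeric `c(b0, b1, b2)`; required for
#'   `"linear_map"`.
#' @param exemplar_n Number of exemplars resampled per trial for
#'   `"exemplar"`.
#' @param exemplar_weighting `"single_dot"` weights exemplars by the
#'   likelihood of the splash centroid under the single-dot dispersion (the
#'   default); `"centroid"` uses the centroid dispersion
#'   `sigma_L / sqrt(n_dots)` instead.
#'
#' @return An object of class `coin_observer`.
#' @export
#' @examples
#' d <- coin_task_design("exp1")
#' ideal_observer(d, motor_sd = 0)
observer_spec <- function(strategy = c("bayes", "likelihood_only", "prior_only",
                                       "linear_map", "exemplar", "rote"),
                          internal_sigma_P,
                          internal_sigma_L,
                          motor_sd = 0.005,
                          linear_coeffs = NULL,
                          exemplar_n = 5L,
                          exemplar_weighting = c("single_dot", "centroid")) {
  strategy <- match.arg(strategy)
  exemplar_weighting <- match.arg(exemplar_weighting)
  stopifnot(is.numeric(internal_sigma_P), !is.null(names(internal_sigma_P)),
            is.numeric(internal_sigma_L), !is.null(names(internal_sigma_L)),
            all(internal_sigma_P >= 0), all(internal_sigma_L >= 0),
            motor_sd >= 0)
  if (strategy == "linear_map") {
    if (is.null(linear_coeffs) || length(linear_coeffs) != 3L) {
      stop("`linear_coeffs` (b0, b1, b2) is required for the linear_map strategy",
           call. = FALSE)
    }
  }
  if (strategy == "exemplar" && exemplar_n < 1L) {
    stop("`exemplar_n` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      strategy = strategy,
      internal_sigma_P = internal_sigma_P,
      internal_sigma_L = internal_sigma_L,
      motor_sd = motor_sd,
      linear_coeffs = linear_coeffs,
      exemplar_n = as.integer(exemplar_n),
      exemplar_weighting = exemplar_weighting
    ),
    class = "coin_observer"
  )
}

#' @rdname observer_spec
#' @param design A [coin_task_design()]; internal sigmas are set to the true
#'   generative values.
#' @param ... Passed on to [observer_spec()].
#' @export
ideal_observer <- function(design, strategy = "bayes", motor_sd = 0.005, ...) {
  observer_spec(
    strategy = strategy,
    internal_sigma_P = stats::setNames(design$priors$sigma, design$priors$label),
    internal_sigma_L = stats::setNames(design$likelihoods$sigma, design$likelihoods$label),
    motor_sd = motor_sd,
    ...
  )
}

#' @export
print.coin_observer <- function(x, ...) {
  cat("<coin_observer> strategy:", x$strategy, " motor sd:", x$motor_sd, "\n")
  invisible(x)
}

# Internal weight an observer attaches to the splash centroid for one
# (prior, likelihood) label pair, before any rote/exemplar override.
observer_weight <- function(obs, prior_label, likelihood_label, n_dots) {
  sp <- obs$internal_sigma_P[prior_label]
  sl <- obs$internal_sigma_L[likelihood_label]
  if (anyNA(sp)) stop("observer has no internal prior value for: ",
                      paste(unique(prior_label[is.na(sp)]), collapse = ", "),
                      call. = FALSE)
  if (anyNA(sl)) stop("observer has no internal likelihood value for: ",
                      paste(unique(likelihood_label[is.na(sl)]), collapse = ", "),
                      call. = FALSE)
  w <- switch(obs$strategy,
    likelihood_only = rep(1, length(sp)),
    prior_only = rep(0, length(sp)),
    linear_map = {
      b <- obs$linear_coeffs
      pmin(pmax(b[1] + b[2] / sp^2 + b[3] / sl^2, 0), 1)
    },
    # bayes and (on trained combinations) rote
    sp^2 / (sp^2 + sl^2 / n_dots)
  )
  unname(w)
}

#' Respond to likelihood-only trials
#'
#' Centroid estimation is strategy-independent: every observer responds at the
#' sample mean of the dots plus motor noise.
#'
#' @param obs A [observer_spec()].
#' @param mu_L Numeric vector of splash centroids.
#' @return Numeric vector of responses.
#' @export
respond_likelihood_only <- function(obs, mu_L) {
  stopifnot(inherits(obs, "coin_observer"))
  mu_L + stats::rnorm(length(mu_L), 0, obs$motor_sd)
}

#' Likelihood-weighted exemplar estimate of a hidden location
#'
#' Approximates the posterior-mean location without an explicit prior
#' distribution: `n_samples` exemplars are drawn uniformly with replacement
#' from remembered coin positions, weighted by the Gaussian likelihood of the
#' splash centroid, and averaged (self-normalized importance sampling). As the
#' memory and sample count grow, the estimate converges to the analytic
#' posterior mean with prior variance equal to the memory variance and
#' likelihood variance `weighting_sigma^2`. If all weights underflow to zero
#' (centroid far from every sampled exemplar), the unweighted mean of the
#' drawn exemplars is returned.
#'
#' @param memory Numeric vector of stored coin positions (non-empty).
#' @param mu_L Splash centroid of the current trial (scalar).
#' @param weighting_sigma Standard deviation of the Gaussian weighting kernel.
#' @param n_samples Number of exemplars drawn.
#' @return Scalar location estimate.
#' @export
#' @examples
#' set.seed(1)
#' mem <- rnorm(1e4, 0, 0.085)
#' exemplar_estimate(mem, 0.1, 0.06, 1e4)  # close to 0.667 * 0.1
exemplar_estimate <- function(memory, mu_L, weighting_sigma, n_samples) {
  if (length(memory) == 0L) stop("exemplar memory is empty", call. = FALSE)
  stopifnot(n_samples >= 1, weighting_sigma > 0, length(mu_L) == 1L)
  x <- memory[sample.int(length(memory), n_samples, replace = TRUE)]
  w <- stats::dnorm(x, mean = mu_L, sd = weighting_sigma)
  s <- sum(w)
  if (s == 0) mean(x) else sum(x * w) / s
}

# Vectorized exemplar responses for a block of trials sharing one memory and
# one weighting sigma; `reps` independent simulations are averaged (used by
# the exemplar strategy model, where the prediction is the expected response).
exemplar_estimate_batch <- function(memory, mu_L, weighting_sigma, n_samples,
                                    reps = 1L) {
  m <- length(mu_L) * reps
  x <- matrix(memory[sample.int(length(memory), m * n_samples, replace = TRUE)],
              nrow = m, ncol = n_samples)
  w <- stats::dnorm(x, mean = rep(mu_L, reps), sd = weighting_sigma)
  s <- rowSums(w)
  est <- ifelse(s == 0, rowMeans(x), rowSums(x * w) / s)
  rowMeans(matrix(est, nrow = length(mu_L), ncol = reps))
}

#' Respond to coin-task trials
#'
#' Pre-computes the strategy's location estimate for each trial and adds
#' motor noise. Covers every strategy except `"exemplar"`, whose responses
#' depend on the memory accumulated trial by trial and are produced inside
#' [simulate_participant()]. Rote observers need `trained` to know which
#' combinations they learned; facing a prior they never trained raises an
#' error.
#'
#' @param obs A [observer_spec()].
#' @param trials Coin-task trial rows (see [build_schedule()]).
#' @param design The [coin_task_design()] the trials came from.
#' @param trained Data frame of trained combinations (`prior_label`,
#'   `likelihood_label`); required for the rote strategy.
#' @return Numeric vector of responses.
#' @export
respond_coin <- function(obs, trials, design, trained = NULL) {
  stopifnot(inherits(obs, "coin_observer"), inherits(design, "coin_task_design"))
  if (obs$strategy == "exemplar") {
    stop("exemplar responses are generated by simulate_participant()", call. = FALSE)
  }
  if (obs$strategy == "rote" && is.null(trained)) {
    stop("rote observers need `trained` combinations", call. = FALSE)
  }
  trials <- ensure_mu_L(trials)
  est <- coin_estimates(obs, trials, design, trained)
  est + stats::rnorm(nrow(trials), 0, obs$motor_sd)
}

# Pre-noise coin-task estimates for the vectorizable strategies (everything
# except exemplar, which needs trial-by-trial memory growth).
coin_estimates <- function(obs, trials, design, trained) {
  w <- switch(obs$strategy,
    rote = {
      w <- numeric(nrow(trials))
      trained_key <- paste(trained$prior_label, trained$likelihood_label)
      key <- paste(trials$prior_label, trials$likelihood_label)
      is_trained <- key %in% trained_key
      w[is_trained] <- observer_weight(obs, trials$prior_label[is_trained],
                                       trials$likelihood_label[is_trained],
                                       design$n_dots)
      if (any(!is_trained)) {
        novel <- which(!is_trained)
        for (i in novel) {
          cand <- trained[trained$prior_label == trials$prior_label[i], , drop = FALSE]
          if (nrow(cand) == 0L) {
            stop("rote observer has no trained combination for prior ",
                 trials$prior_label[i], call. = FALSE)
          }
          sl_new <- likelihood_sigma(design, trials$likelihood_label[i])
          sl_tr <- likelihood_sigma(design, cand$likelihood_label)
          pick <- cand$likelihood_label[which.min(abs(sl_tr - sl_new))]
          w[i] <- observer_weight(obs, trials$prior_label[i], pick, design$n_dots)
        }
      }
      w
    },
    observer_weight(obs, trials$prior_label, trials$likelihood_label, design$n_dots)
  )
  mu_P <- design$priors$mu[match(trials$prior_label, design$priors$label)]
  w * trials$mu_L + (1 - w) * mu_P
}

#' Simulate one participant through a full session
#'
#' Runs an observer through the likelihood-only task, the coin-task learning
#' phase, and the transfer phase, in that order. Exemplar observers accumulate
#' memory online from learning-phase coin-position feedback (the current
#' trial's coin is stored after the response; with an empty memory the
#' observer responds at the splash centroid) and their memory is frozen when
#' feedback stops at transfer. Rote observers carry the weights of the trained
#' combinations into the transfer phase as described in [observer_spec()].
#'
#' @param obs A [observer_spec()].
#' @param design A [coin_task_design()].
#' @param group Learning group (see [build_schedule()]).
#' @param counterbalance Experiment 1 counterbalance assignment (1-4).
#' @param participant_id Identifier written into the trial table.
#'
#' @return A trial-table tibble: one row per trial with `participant_id`,
#'   `experiment`, `group`, `phase`, `novelty`, `trial_index`, condition
#'   columns, dot positions, `mu_L`, `response_x`, and `hit`
#'   (`|response_x - coin_x| <= hit_window / 2`; `NA` in the likelihood-only
#'   task, where the target is the splash centroid).
#' @export
simulate_participant <- function(obs, design, group, counterbalance = 1L,
                                 participant_id = "P001") {
  stopifnot(inherits(obs, "coin_observer"), inherits(design, "coin_task_design"))
  lik <- build_likelihood_only_schedule(design)
  lik$response_x <- respond_likelihood_only(obs, lik$mu_L)
  lik$hit <- NA

  coin <- build_schedule(design, group, counterbalance)
  trained <- trained_combos(design, group, counterbalance)

  if (obs$strategy == "exemplar") {
    est <- numeric(nrow(coin))
    memory <- split(numeric(0), character(0))  # per prior label
    wsig <- obs$internal_sigma_L
    if (obs$exemplar_weighting == "centroid") wsig <- wsig / sqrt(design$n_dots)
    for (i in seq_len(nrow(coin))) {
      p <- coin$prior_label[i]
      mem <- memory[[p]]
      est[i] <- if (is.null(mem) || length(mem) == 0L) {
        coin$mu_L[i]
      } else {
        exemplar_estimate(mem, coin$mu_L[i],
                          unname(wsig[coin$likelihood_label[i]]),
                          obs$exemplar_n)
      }
      if (coin$phase[i] == "learning") {
        memory[[p]] <- c(memory[[p]], coin$coin_x[i])
      }
    }
  } else {
    est <- coin_estimates(obs, coin, design, trained)
  }
  coin$response_x <- est + stats::rnorm(nrow(coin), 0, obs$motor_sd)
  coin$hit <- abs(coin$response_x - coin$coin_x) <= design$hit_window / 2

  out <- dplyr::bind_rows(lik, coin)
  out$participant_id <- participant_id
  out$experiment <- design$experiment
  out$group <- group
  dplyr::relocate(out, "participant_id", "experiment", "group")
}

#' Configure a simulated cohort
#'
#' Bundles the design, group, strategy, miscalibration model and noise levels
#' of a cohort of simulated participants. Internal standard deviations are
#' drawn once per participant and class (prior or likelihood) as
#' `true_sigma * bias * exp(rnorm(1, 0, tau))`, a log-normal miscalibration
#' around a multiplicative bias shared by all labels of the class (a subject
#' trait, keeping believed dispersions proportional across conditions):
#' `bias_L < 1` shrinks believed likelihood dispersion and reproduces the
#' over-weighting of sensory evidence seen in human cohorts.
#'
#' @param n_participants Cohort size.
#' @param experiment,group Protocol (see [coin_task_design()],
#'   [build_schedule()]).
#' @param strategy Observer strategy for every participant (see
#'   [observer_spec()]).
#' @param bias_P,bias_L Multiplicative bias on internal prior/likelihood
#'   standard deviations (1 = calibrated).
#' @param tau_P,tau_L Log-scale standard deviations of the per-label
#'   miscalibration draws (0 = deterministic bias).
#' @param motor_sd Motor noise standard deviation shared by all participants.
#' @param linear_coeffs,exemplar_n,exemplar_weighting Passed to
#'   [observer_spec()] for the relevant strategies.
#' @param sigma_Ln_exp2 Narrow-likelihood sigma for experiment 2 designs.
#' @param seed Master seed; fixes the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 50L,
                          experiment = "exp1",
                          group = if (experiment == "exp1") "serial" else "interpolation",
                          strategy = "bayes",
                          bias_P = 1, bias_L = 1,
                          tau_P = 0, tau_L = 0,
                          motor_sd = 0.005,
                          linear_coeffs = NULL,
                          exemplar_n = 5L,
                          exemplar_weighting = "single_dot",
                          sigma_Ln_exp2 = 0.024,
                          seed = 1L) {
  stopifnot(n_participants >= 1, bias_P > 0, bias_L > 0, tau_P >= 0, tau_L >= 0)
  structure(
    list(
      n_participants = as.integer(n_participants),
      experiment = experiment, group = group, strategy = strategy,
      bias_P = bias_P, bias_L = bias_L, tau_P = tau_P, tau_L = tau_L,
      motor_sd = motor_sd, linear_coeffs = linear_coeffs,
      exemplar_n = as.integer(exemplar_n),
      exemplar_weighting = exemplar_weighting,
      sigma_Ln_exp2 = sigma_Ln_exp2,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a cohort of participants
#'
#' Simulates `n_participants` independent sessions under one [cohort_config()].
#' Experiment 1 counterbalance assignments cycle through the four orthogonal
#' combinations. The master seed fixes everything: the same configuration
#' yields an identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A list of class `coin_cohort` with elements `trials` (the stacked
#'   trial table), `participants` (ground-truth sidecar: one row per
#'   participant and distribution label with the drawn internal sigma), and
#'   `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_participants = 2, seed = 42))
#' dplyr::count(cohort$trials, participant_id, phase)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  design <- coin_task_design(config$experiment, sigma_Ln_exp2 = config$sigma_Ln_exp2)
  trials <- vector("list", config$n_participants)
  sidecar <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    id <- sprintf("P%03d", i)
    cb <- if (config$experiment == "exp1") ((i - 1L) %% 4L) + 1L else 1L
    # one multiplier per participant and class: miscalibration is a subject
    # trait, so believed dispersions stay proportional across labels
    sp <- design$priors$sigma * config$bias_P *
      exp(stats::rnorm(1, 0, config$tau_P))
    sl <- design$likelihoods$sigma * config$bias_L *
      exp(stats::rnorm(1, 0, config$tau_L))
    obs <- observer_spec(
      strategy = config$strategy,
      internal_sigma_P = stats::setNames(sp, design$priors$label),
      internal_sigma_L = stats::setNames(sl, design$likelihoods$label),
      motor_sd = config$motor_sd,
      linear_coeffs = config$linear_coeffs,
      exemplar_n = config$exemplar_n,
      exemplar_weighting = config$exemplar_weighting
    )
    trials[[i]] <- simulate_participant(obs, design, config$group, cb, id)
    sidecar[[i]] <- tibble::tibble(
      participant_id = id,
      strategy = config$strategy,
      counterbalance = cb,
      motor_sd = config$motor_sd,
      kind = c(rep("prior", nrow(design$priors)),
               rep("likelihood", nrow(design$likelihoods))),
      label = c(design$priors$label, design$likelihoods$label),
      true_sigma = c(design$priors$sigma, design$likelihoods$sigma),
      internal_sigma = c(sp, sl)
    )
  }
  structure(
    list(
      trials = dplyr::bind_rows(trials),
      participants = dplyr::bind_rows(sidecar),
      config = config
    ),
    class = "coin_cohort"
  )
}

#' @export
print.coin_cohort <- function(x, ...) {
  cat("<coin_cohort> ", x$config$n_participants, " participants, ",
      x$config$experiment, "/", x$config$group,
      ", strategy ", x$config$strategy, "\n", sep = "")
  invisible(x)
}
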