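#' Fit a linear mapping between weighting slopes and precisions
#'
#' The linear-mapping strategy model regresses a participant's learning-phase
#' slopes on the inverse variance proxies:
#' `slope = b0 + b1 / sigma_Pi^2 + b2 / sigma_Li^2`. With `likelihood_only =
#' TRUE` the prior term is dropped (`b1 = 0`), leaving a mapping on likelihood
#' precision alone. When the learning phase provides fewer combinations than
#' free coefficients (two combinations vs three coefficients; or a single
#' prior making the intercept and prior term collinear) the system is
#' rank-deficient and the minimum-norm least-squares solution is returned
#' with a `rank` attribute recording the deficiency.
#'
#' @param slope Learning-phase slopes, one per trained combination.
#' @param inv_sigma_pi_sq Inverse prior variance proxies, same length.
#' @param inv_sigma_li_sq Inverse likelihood variance proxies, same length.
#' @param likelihood_only Drop the prior precision term.
#' @return Named numeric `c(b0, b1, b2)` (with `b1 = 0` for the
#'   likelihood-only variant), attribute `rank` = rank of the design matrix.
#' @export
fit_linear_mapping <- function(slope, inv_sigma_pi_sq, inv_sigma_li_sq,
                               likelihood_only = FALSE) {
  stopifnot(length(slope) == length(inv_sigma_pi_sq),
            length(slope) == length(inv_sigma_li_sq))
  X <- if (likelihood_only) {
    cbind(1, inv_sigma_li_sq)
  } else {
    cbind(1, inv_sigma_pi_sq, inv_sigma_li_sq)
  }
  if (nrow(X) < 2L) stop("need at least 2 learning combinations", call. = FALSE)
  s <- svd(X)
  tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  dinv <- ifelse(s$d > tol, 1 / s$d, 0)
  beta <- drop(s$v %*% (dinv * (t(s$u) %*% slope)))
  out <- if (likelihood_only) c(beta[1], 0, beta[2]) else beta
  names(out) <- c("b0", "b1", "b2")
  structure(out, rank = sum(s$d > tol))
}

# Free-parameter counts for the Gaussian-residual BIC: the Bayesian model has
# none beyond the shared estimation stage; the linear mapping has 3
# coefficients; its likelihood-only restriction 2; the exemplar model one
# (the sample count N).
model_k <- c(bayes = 0L, linear = 3L, likelihood_only = 2L,
             exemplar_N5 = 1L, exemplar_N20 = 1L)

#' Bayesian Information Criterion for least-squares residuals
#'
#' Gaussian-residual form `n * log(RSS / n) + k * log(n)`. A zero residual sum
#' of squares is reported as `-Inf` ("perfect fit") with a warning rather than
#' an error.
#'
#' @param residuals Residual vector (modelled minus measured).
#' @param k Number of free parameters.
#' @return BIC value (smaller is better).
#' @export
#' @examples
#' bic_rss(c(1, 1), k = 1)  # log(2)
bic_rss <- function(residuals, k) {
  n <- length(residuals)
  if (n == 0L) stop("no residuals", call. = FALSE)
  rss <- sum(residuals^2)
  if (rss == 0) {
    warning("perfect fit: RSS = 0", call. = FALSE)
    return(-Inf)
  }
  n * log(rss / n) + k * log(n)
}

# Modelled transfer-new slope per estimates row for one strategy model. All
# models are fitted on learning-phase quantities only.
modelled_new_slopes <- function(model, est_rows, trials, exemplar_reps) {
  pred <- rep(NA_real_, nrow(est_rows))
  if (model == "bayes") {
    return(est_rows$predicted_slope)
  }
  if (model %in% c("linear", "likelihood_only")) {
    if (nrow(est_rows) < 2L) return(pred)
    lo <- model == "likelihood_only"
    beta <- fit_linear_mapping(est_rows$slope_learned,
                               1 / est_rows$sigma_pi_sq,
                               1 / est_rows$sigma_li_sq,
                               likelihood_only = lo)
    use <- !is.na(est_rows$sigma_li_sq_new)
    pred[use] <- beta[1] + beta[2] / est_rows$sigma_pi_sq[use] +
      beta[3] / est_rows$sigma_li_sq_new[use]
    return(pred)
  }
  # exemplar_N5 / exemplar_N20: simulate responses to the participant's own
  # transfer-new trials, resampling their remembered learning-phase coin
  # positions, and refit the slope; reps simulations are averaged so the
  # prediction approximates the expected modelled slope.
  n_samples <- if (model == "exemplar_N5") 5L else 20L
  use <- which(!is.na(est_rows$new_likelihood_label))
  for (i in use) {
    p <- est_rows$prior_label[i]
    nl <- est_rows$new_likelihood_label[i]
    memory <- trials$coin_x[trials$phase == "learning" & trials$prior_label == p]
    tr <- trials[trials$phase == "transfer" & trials$novelty == "new" &
                   trials$prior_label == p & trials$likelihood_label == nl, ]
    if (length(memory) == 0L || nrow(tr) < 2L) next
    slopes <- vapply(seq_len(exemplar_reps), function(r) {
      sim <- exemplar_estimate_batch(memory, tr$mu_L, tr$sigma_L[1], n_samples)
      fit_slope(tr$mu_L, sim)$slope
    }, numeric(1))
    pred[i] <- mean(slopes)
  }
  pred
}

#' Compare strategy models of transfer behaviour by BIC
#'
#' Fits each candidate model on learning-phase estimates, predicts each
#' participant's transfer-new slope, converts it to a modelled transfer score
#' with the participant's own learned slope and Bayes-predicted slope, and
#' scores models by the BIC of the participant-level residuals (modelled
#' minus measured pooled transfer score). The Bayesian model predicts the
#' Bayes slope itself, so its modelled score is 1 by construction. Candidate
#' models: `"bayes"`, `"linear"` (3 coefficients), `"likelihood_only"`
#' (2 coefficients), `"exemplar_N5"` and `"exemplar_N20"` (resampled exemplar
#' memory; 1 parameter).
#'
#' @param trials A cohort trial table.
#' @param models Character vector of model ids to compare.
#' @param exemplar_reps Simulations averaged per exemplar prediction.
#' @param pooling Passed to [transfer_scores()].
#' @param min_n Smallest usable cohort after exclusions.
#' @inheritParams estimate_participants
#' @return A tibble ranked by BIC: `model`, `k`, `n`, `rss`, `bic`,
#'   `delta_bic`; per-participant modelled and measured scores in attribute
#'   `"participants"`.
#' @export
compare_models <- function(trials,
                           models = c("bayes", "linear", "likelihood_only",
                                      "exemplar_N5", "exemplar_N20"),
                           exemplar_reps = 20L,
                           pooling = "mean_ts",
                           min_n = 5L,
                           discard = NULL,
                           slope_cap = 0.99) {
  models <- match.arg(models, names(model_k), several.ok = TRUE)
  est <- estimate_participants(trials, discard = discard, slope_cap = slope_cap)
  est <- est[est$reliable, ]
  measured <- transfer_scores(est, pooling = pooling)
  measured <- measured[!is.na(measured$ts) & measured$n_combos > 0L, ]

  per_pid <- split(est, est$participant_id)
  trial_pid <- split(trials, trials$participant_id)

  modelled <- lapply(models, function(m) {
    vapply(measured$participant_id, function(pid) {
      rows <- per_pid[[pid]]
      pred <- modelled_new_slopes(m, rows, trial_pid[[pid]], exemplar_reps)
      rows$measured_slope_new <- pred
      sc <- transfer_scores(rows, pooling = pooling)
      sc$ts[1]
    }, numeric(1))
  })
  names(modelled) <- models

  complete <- Reduce(`&`, lapply(modelled, function(v) !is.na(v)))
  n <- sum(complete)
  if (n < min_n) {
    stop("only ", n, " participants usable after exclusions (need >= ", min_n, ")",
         call. = FALSE)
  }
  fits <- dplyr::bind_rows(lapply(models, function(m) {
    res <- modelled[[m]][complete] - measured$ts[complete]
    tibble::tibble(model = m, k = model_k[[m]], n = n,
                   rss = sum(res^2), bic = bic_rss(res, model_k[[m]]))
  }))
  fits <- fits[order(fits$bic), ]
  fits$delta_bic <- fits$bic - fits$bic[1]
  part <- tibble::tibble(participant_id = measured$participant_id[complete],
                         measured_ts = measured$ts[complete])
  for (m in models) part[[paste0("ts_", m)]] <- modelled[[m]][complete]
  attr(fits, "participants") <- part
  fits
}
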