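#' Optimal likelihood weight for a prior/likelihood pair
#'
#' The weight an ideal observer puts on the splash centroid when combining it
#' with a Gaussian prior: `sigma_P^2 / (sigma_P^2 + sigma_L^2 / n_dots)`,
#' where `sigma_L^2 / n_dots` is the sampling variance of the centroid of
#' `n_dots` dots. This is also the regression slope of ideal responses on
#' centroids.
#'
#' @param sigma_P Prior standard deviation (> 0).
#' @param sigma_L Single-dot likelihood standard deviation (>= 0).
#' @param n_dots Number of dots averaged into the centroid.
#' @return Weight in `(0, 1]`; vectorized over its arguments.
#' @export
#' @examples
#' optimal_slope(0.085, 0.06)  # 0.9094
#' optimal_slope(0.025, 0.15)  # 0.1220
optimal_slope <- function(sigma_P, sigma_L, n_dots = 5L) {
  if (any(sigma_P <= 0)) stop("`sigma_P` must be positive", call. = FALSE)
  if (any(sigma_L < 0)) stop("`sigma_L` must be non-negative", call. = FALSE)
  sigma_P^2 / (sigma_P^2 + sigma_L^2 / n_dots)
}

#' Fit a sensory-weighting slope for one condition
#'
#' Ordinary least squares of responses on splash centroids over the trials of
#' one prior/likelihood condition, after discarding the first `discard` trials
#' of that condition in presentation order (to exclude initial prior
#' acquisition). A slope of 1 is total reliance on the likelihood; 0 is total
#' reliance on the prior. `zero_intercept = TRUE` forces the regression line
#' through the origin (`beta = sum(x * y) / sum(x^2)`), a robustness variant
#' for the minuscule intercepts observed empirically.
#'
#' @param mu_L Splash centroids, in presentation order.
#' @param response Responses, same length.
#' @param discard Number of initial trials of this condition to drop.
#' @param zero_intercept Force the intercept to zero.
#' @param condition Optional label used in error messages.
#' @return A one-row tibble: `slope`, `intercept`, `n_used`, `discarded`,
#'   `zero_intercept`.
#' @export
fit_slope <- function(mu_L, response, discard = 0L, zero_intercept = FALSE,
                      condition = NULL) {
  stopifnot(length(mu_L) == length(response))
  keep <- seq_along(mu_L) > discard
  x <- mu_L[keep]
  y <- response[keep]
  if (length(x) < 2L) {
    stop("fewer than 2 trials left after discarding",
         if (!is.null(condition)) paste0(" in condition ", condition),
         call. = FALSE)
  }
  if (zero_intercept) {
    slope <- sum(x * y) / sum(x^2)
    intercept <- 0
  } else {
    xc <- x - mean(x)
    slope <- sum(xc * (y - mean(y))) / sum(xc^2)
    intercept <- mean(y) - slope * mean(x)
  }
  tibble::tibble(slope = slope, intercept = intercept,
                 n_used = length(x), discarded = sum(!keep),
                 zero_intercept = zero_intercept)
}

#' Subject-specific likelihood variance proxy
#'
#' Mean squared deviation of a participant's centroid estimates from the
#' generative centres of the dot clouds in the likelihood-only task
#' (population form, divisor `n`). This captures both the sampling dispersion
#' of the centroid (`sigma_L^2 / n_dots`) and the participant's own
#' perception, computation and motor errors, which is what makes it the
#' behaviourally relevant likelihood variance for the weighting model.
#'
#' @param estimates Centroid estimates (responses).
#' @param truths Generative centres of the same trials.
#' @return Scalar variance proxy (screen units squared).
#' @export
sigma_li_sq <- function(estimates, truths) {
  if (length(estimates) == 0L) stop("no trials supplied", call. = FALSE)
  stopifnot(length(estimates) == length(truths))
  if (length(estimates) < 2L) stop("need at least 2 trials", call. = FALSE)
  mean((estimates - truths)^2)
}

#' Subject-specific prior variance proxy
#'
#' Inverts the weighting relation at a fitted slope:
#' `sigma_Pi^2 = sigma_Li^2 * slope / (1 - slope)`. Slopes at or above
#' `slope_cap` (or at or below 0) make the inversion blow up - such values are
#' returned as `NA` so the caller can flag the participant/prior pair as
#' unreliable rather than propagate an arbitrarily large prior variance.
#'
#' @param sigma_li_sq Likelihood variance proxy (> 0), see [sigma_li_sq()].
#' @param slope Fitted sensory-weighting slope.
#' @param slope_cap Largest slope considered invertible.
#' @return Variance proxy, or `NA` where the slope is outside `(0, slope_cap)`.
#'   Vectorized.
#' @export
#' @examples
#' sigma_pi_sq(0.001, 0.5)            # 0.001
#' sigma_pi_sq(7.2e-4, 0.999)         # NA: unreliable
sigma_pi_sq <- function(sigma_li_sq, slope, slope_cap = 0.99) {
  if (any(sigma_li_sq <= 0, na.rm = TRUE)) {
    stop("`sigma_li_sq` must be positive", call. = FALSE)
  }
  ifelse(!is.na(slope) & slope > 0 & slope < slope_cap,
         sigma_li_sq * slope / (1 - slope),
         NA_real_)
}

#' Predicted transfer-phase slope from subject-specific variance proxies
#'
#' Plugs a participant's prior variance proxy and the likelihood variance
#' proxy of the novel likelihood back into the weighting relation:
#' `sigma_Pi^2 / (sigma_Pi^2 + sigma_Li_new^2)`.
#'
#' @param sigma_pi_sq Prior variance proxy (`NA` propagates).
#' @param sigma_li_sq_new Likelihood variance proxy of the novel likelihood.
#' @return Predicted slope in `(0, 1)`; vectorized.
#' @export
predicted_transfer_slope <- function(sigma_pi_sq, sigma_li_sq_new) {
  if (any(sigma_li_sq_new <= 0, na.rm = TRUE)) {
    stop("`sigma_li_sq_new` must be positive", call. = FALSE)
  }
  sigma_pi_sq / (sigma_pi_sq + sigma_li_sq_new)
}

# Recompute mu_L from the dot columns if a read-in table lacks it.
ensure_mu_L <- function(trials) {
  if (!"mu_L" %in% names(trials)) {
    dots <- grep("^dot_x[0-9]+$", names(trials), value = TRUE)
    if (length(dots) == 0L) stop("trial table has neither `mu_L` nor dot columns",
                                 call. = FALSE)
    trials$mu_L <- rowMeans(trials[dots])
  }
  trials
}

#' Per-participant slope and variance-proxy estimates
#'
#' Runs the estimation chain on a trial table: per-likelihood variance proxies
#' from the likelihood-only task, learning-phase slopes per trained
#' prior/likelihood combination (first `discard` trials of each combination
#' dropped), prior variance proxies, and - for each trained combination that
#' shares its prior with a transfer-new condition - the predicted and measured
#' transfer slopes.
#'
#' @param trials A trial table as produced by [simulate_participant()] /
#'   [simulate_cohort()] or read with [read_trial_table()].
#' @param discard Initial learning trials dropped per combination; default 50
#'   for experiment 1 and 25 for experiment 2.
#' @param zero_intercept Fit all slopes through the origin.
#' @param slope_cap Passed to [sigma_pi_sq()].
#' @return A tibble with one row per (participant, trained combination):
#'   identifiers, `slope_learned`, `intercept`, `sigma_li_sq`, `sigma_pi_sq`,
#'   `reliable` (slope within `(0, slope_cap)`), `slope_transfer_old`
#'   (transfer-phase slope of the same combination, `NA` if absent), and -
#'   where the combination's prior meets a novel likelihood in transfer -
#'   `new_likelihood_label`, `sigma_li_sq_new`, `predicted_slope` and
#'   `measured_slope_new` (otherwise `NA`).
#' @export
estimate_participants <- function(trials, discard = NULL, zero_intercept = FALSE,
                                  slope_cap = 0.99) {
  trials <- ensure_mu_L(trials)
  if (is.null(discard)) {
    discard <- if (trials$experiment[1] == "exp1") 50L else 25L
  }
  out <- lapply(split(trials, trials$participant_id), function(tt) {
    tt <- tt[order(tt$trial_index), ]
    lik <- tt[tt$phase == "likelihood_only", ]
    sli <- vapply(split(lik, lik$likelihood_label), function(d) {
      sigma_li_sq(d$response_x, d$coin_x)
    }, numeric(1))

    learn <- tt[tt$phase == "learning", ]
    trans <- tt[tt$phase == "transfer", ]
    new_tr <- trans[trans$novelty == "new", ]
    combos <- unique(learn[c("prior_label", "likelihood_label")])

    transfer_slope <- function(p, l) {
      d <- trans[trans$prior_label == p & trans$likelihood_label == l, ]
      if (nrow(d) < 2L) return(NA_real_)
      fit_slope(d$mu_L, d$response_x, discard = 0L,
                zero_intercept = zero_intercept)$slope
    }

    rows <- lapply(seq_len(nrow(combos)), function(i) {
      p <- combos$prior_label[i]
      l <- combos$likelihood_label[i]
      d <- learn[learn$prior_label == p & learn$likelihood_label == l, ]
      fit <- fit_slope(d$mu_L, d$response_x, discard = discard,
                       zero_intercept = zero_intercept,
                       condition = paste0(p, l))
      spi <- sigma_pi_sq(sli[[l]], fit$slope, slope_cap)
      new_here <- unique(new_tr$likelihood_label[new_tr$prior_label == p])
      if (length(new_here) > 0L) {
        nl <- new_here[1]
        sli_new <- sli[[nl]]
        pred <- predicted_transfer_slope(spi, sli_new)
        meas <- transfer_slope(p, nl)
      } else {
        nl <- NA_character_; sli_new <- NA_real_
        pred <- NA_real_; meas <- NA_real_
      }
      tibble::tibble(
        participant_id = tt$participant_id[1],
        experiment = tt$experiment[1],
        group = tt$group[1],
        prior_label = p,
        likelihood_label = l,
        slope_learned = fit$slope,
        intercept = fit$intercept,
        n_used = fit$n_used,
        sigma_li_sq = sli[[l]],
        sigma_pi_sq = spi,
        reliable = !is.na(spi),
        slope_transfer_old = transfer_slope(p, l),
        new_likelihood_label = nl,
        sigma_li_sq_new = sli_new,
        predicted_slope = pred,
        measured_slope_new = meas
      )
    })
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}
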