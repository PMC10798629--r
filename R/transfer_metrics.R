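#' Transfer score
#'
#' Normalizes a measured slope change on a novel prior/likelihood pairing by
#' the change predicted from the participant's own variance proxies:
#' `ts = (measured_new - learned) / (predicted_new - learned)`. A score of 1
#' is optimal Bayesian transfer; 0 or below is no transfer; values in between
#' are suboptimal transfer. Where the predicted change is smaller than `tol`
#' the score is undefined and `NA` is returned (the exclusion path).
#'
#' @param measured_new Measured slope in the transfer-new condition.
#' @param slope_learned Learning-phase slope of the trained combination
#'   sharing the new condition's prior.
#' @param predicted_new Predicted transfer slope, see
#'   [predicted_transfer_slope()].
#' @param tol Smallest predicted change treated as non-zero.
#' @return Numeric transfer score(s); vectorized.
#' @export
#' @examples
#' transfer_score(0.8, 0.6, 0.9)  # 0.6667
transfer_score <- function(measured_new, slope_learned, predicted_new,
                           tol = 1e-6) {
  change_pred <- predicted_new - slope_learned
  ifelse(!is.na(change_pred) & abs(change_pred) >= tol,
         (measured_new - slope_learned) / change_pred,
         NA_real_)
}

#' Per-participant transfer scores from an estimates table
#'
#' Applies [transfer_score()] to each (participant, trained combination) row
#' of [estimate_participants()] output that faces a novel likelihood, and
#' pools within participant. Experiment 1 contributes one score per
#' participant (only one trained combination shares the transfer prior);
#' experiment 2 contributes two, one per trained combination against the same
#' novel condition, pooled by `pooling`.
#'
#' @param estimates Output of [estimate_participants()].
#' @param pooling `"mean_ts"` averages the per-combination scores (the
#'   default); `"ratio_of_changes"` instead divides the mean measured change
#'   by the mean predicted change.
#' @param tol Passed to [transfer_score()].
#' @return A tibble with one row per participant: `participant_id`,
#'   `experiment`, `group`, `n_combos` (scores pooled), `ts` (`NA` where every
#'   contributing combination was unreliable or undefined).
#' @export
transfer_scores <- function(estimates, pooling = c("mean_ts", "ratio_of_changes"),
                            tol = 1e-6) {
  pooling <- match.arg(pooling)
  rows <- estimates[!is.na(estimates$new_likelihood_label), ]
  rows$ts <- transfer_score(rows$measured_slope_new, rows$slope_learned,
                            rows$predicted_slope, tol = tol)
  pooled <- lapply(split(rows, rows$participant_id), function(d) {
    ok <- !is.na(d$ts)
    ts <- if (!any(ok)) {
      NA_real_
    } else if (pooling == "mean_ts") {
      mean(d$ts[ok])
    } else {
      sum(d$measured_slope_new[ok] - d$slope_learned[ok]) /
        sum(d$predicted_slope[ok] - d$slope_learned[ok])
    }
    tibble::tibble(
      participant_id = d$participant_id[1],
      experiment = d$experiment[1],
      group = d$group[1],
      n_combos = sum(ok),
      ts = ts
    )
  })
  dplyr::bind_rows(pooled)
}

#' Parameters of the true Gaussian posterior for one trial
#'
#' For a centred Gaussian prior and a dot-cloud likelihood, the posterior over
#' the coin position given the splash centroid is Gaussian with variance
#' `(1 / sigma_P^2 + n_dots / sigma_L^2)^-1` and mean
#' `optimal_slope(sigma_P, sigma_L, n_dots) * mu_L`.
#'
#' @param mu_L Splash centroid(s).
#' @param sigma_P Prior standard deviation (> 0).
#' @param sigma_L Single-dot likelihood standard deviation (> 0).
#' @param n_dots Dots per trial.
#' @return A tibble with columns `mean` and `sd`; vectorized over `mu_L`.
#' @export
posterior_params <- function(mu_L, sigma_P, sigma_L, n_dots = 5L) {
  if (any(sigma_P <= 0) || any(sigma_L <= 0)) {
    stop("`sigma_P` and `sigma_L` must be positive", call. = FALSE)
  }
  v <- 1 / (1 / sigma_P^2 + n_dots / sigma_L^2)
  tibble::tibble(mean = optimal_slope(sigma_P, sigma_L, n_dots) * mu_L,
                 sd = sqrt(v))
}

#' Probability of catching the coin at a net position
#'
#' The posterior probability that the coin lands within the net when it is
#' placed at `x`: the Gaussian posterior mass on `[x - width/2, x + width/2]`,
#' where `width` is the net width plus the coin diameter. Maximal when `x`
#' equals the posterior mean.
#'
#' @param x Net position(s).
#' @param mu,sigma Posterior mean and standard deviation (see
#'   [posterior_params()]).
#' @param width Catch window, net width + coin diameter (screen units).
#' @return Probability in `(0, 1)`; vectorized.
#' @export
#' @examples
#' p_hit(0, 0, 0.015, 0.03)  # 2 * pnorm(1) - 1
p_hit <- function(x, mu, sigma, width = 0.03) {
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)
  if (any(width <= 0)) stop("`width` must be positive", call. = FALSE)
  stats::pnorm((x + width / 2 - mu) / sigma) -
    stats::pnorm((x - width / 2 - mu) / sigma)
}

#' Per-trial optimality index
#'
#' The probability of catching the coin at the chosen net position divided by
#' the maximum achievable probability (net at the posterior mean):
#' `p_hit(x) / p_hit(mu)`. Lies in `(0, 1]` and equals 1 only at the
#' posterior mean; used to track performance across phases without
#' conditioning on prior/likelihood combinations.
#'
#' @inheritParams p_hit
#' @return Index in `(0, 1]`; vectorized.
#' @export
optimality_index <- function(x, mu, sigma, width = 0.03) {
  p_hit(x, mu, sigma, width) / p_hit(mu, mu, sigma, width)
}

#' Optimality index for each coin-task trial of a trial table
#'
#' Convenience wrapper computing [optimality_index()] per trial from the
#' design's true prior/likelihood values.
#'
#' @param trials A trial table (coin-task rows; likelihood-only rows are
#'   dropped).
#' @param design The [coin_task_design()] the trials came from.
#' @return The coin-task rows with an `optimality` column appended.
#' @export
trial_optimality <- function(trials, design) {
  trials <- ensure_mu_L(trials)
  coin <- trials[trials$phase %in% c("learning", "transfer"), ]
  post <- posterior_params(coin$mu_L, coin$sigma_P, coin$sigma_L, design$n_dots)
  coin$optimality <- optimality_index(coin$response_x, post$mean, post$sd,
                                      design$hit_window)
  coin
}

#' Robust outlier mask by scaled median absolute deviation
#'
#' Flags values more than `k` scaled MADs from the median
#' (MAD scaled by 1.4826, the normal-consistency constant). When the MAD is
#' zero (degenerate, near-identical samples) only values differing from the
#' median are excluded.
#'
#' @param values Numeric vector (`NA`s are never kept).
#' @param k Exclusion threshold in scaled-MAD units.
#' @return Logical vector, `TRUE` = keep, with attribute `n_excluded`.
#' @export
#' @examples
#' mad_filter(c(1, 1, 1, 100))
mad_filter <- function(values, k = 3) {
  if (sum(!is.na(values)) < 3L) stop("need at least 3 non-missing values",
                                     call. = FALSE)
  med <- stats::median(values, na.rm = TRUE)
  m <- stats::mad(values, na.rm = TRUE)  # 1.4826 scaling
  keep <- if (m == 0) values == med else abs(values - med) <= k * m
  keep[is.na(keep)] <- FALSE
  structure(keep, n_excluded = sum(!keep))
}

# Apply mad_filter within groups; participants owning any flagged value are
# excluded. Returns the excluded participant ids.
stage_exclusions <- function(df, value_col, group_cols, k) {
  bad <- character(0)
  for (g in split(df, df[group_cols], drop = TRUE)) {
    v <- g[[value_col]]
    if (sum(!is.na(v)) < 3L) next
    keep <- mad_filter(v, k)
    bad <- c(bad, g$participant_id[!keep & !is.na(v)])
  }
  unique(bad)
}

#' Full transfer analysis of a cohort trial table
#'
#' Runs the estimation chain ([estimate_participants()]), the staged robust
#' outlier screening, and [transfer_scores()]. Screening applies the `k`-MAD
#' rule in four stages - learning slopes (within condition), prior variance
#' proxies (within prior; unreliable slope inversions are excluded here),
#' predicted transfer slopes (within novel condition), and pooled transfer
#' scores (within group) - removing a participant from all later stages once
#' flagged.
#'
#' @param trials A cohort trial table.
#' @param mad_k MAD threshold for every screening stage.
#' @param pooling Passed to [transfer_scores()].
#' @inheritParams estimate_participants
#' @return A list of class `transfer_analysis`: `estimates`, `scores`
#'   (screened participants carry `excluded = TRUE` and the stage that removed
#'   them), `summary` (per-group n, mean, median, IQR of the surviving
#'   scores), and `exclusions` (tally per stage).
#' @export
transfer_analysis <- function(trials, mad_k = 3, pooling = "mean_ts",
                              discard = NULL, zero_intercept = FALSE,
                              slope_cap = 0.99) {
  est <- estimate_participants(trials, discard = discard,
                               zero_intercept = zero_intercept,
                               slope_cap = slope_cap)
  excluded <- stats::setNames(character(0), character(0))
  note <- function(ids, stage) {
    new <- setdiff(ids, names(excluded))
    stats::setNames(rep(stage, length(new)), new)
  }

  excluded <- c(excluded, note(
    stage_exclusions(est, "slope_learned",
                     c("prior_label", "likelihood_label"), mad_k),
    "slope"))

  est1 <- est[!est$participant_id %in% names(excluded), ]
  excluded <- c(excluded, note(unique(est1$participant_id[!est1$reliable]),
                               "sigma_pi_unreliable"))
  est1 <- est1[!est1$participant_id %in% names(excluded), ]
  excluded <- c(excluded, note(
    stage_exclusions(est1, "sigma_pi_sq", "prior_label", mad_k),
    "sigma_pi"))

  est2 <- est1[!est1$participant_id %in% names(excluded), ]
  pred_rows <- est2[!is.na(est2$predicted_slope), ]
  if (nrow(pred_rows) > 0L) {
    excluded <- c(excluded, note(
      stage_exclusions(pred_rows, "predicted_slope",
                       c("prior_label", "new_likelihood_label"), mad_k),
      "predicted_slope"))
  }

  est3 <- est[!est$participant_id %in% names(excluded), ]
  scores <- transfer_scores(est3, pooling = pooling)
  excluded <- c(excluded, note(scores$participant_id[is.na(scores$ts)],
                               "ts_undefined"))
  ok <- scores[!is.na(scores$ts), ]
  if (nrow(ok) >= 3L) {
    excluded <- c(excluded, note(
      stage_exclusions(ok, "ts", "group", mad_k), "ts"))
  }

  all_scores <- transfer_scores(est, pooling = pooling)
  all_scores$excluded <- all_scores$participant_id %in% names(excluded)
  all_scores$exclusion_stage <- unname(excluded[all_scores$participant_id])

  kept <- all_scores[!all_scores$excluded & !is.na(all_scores$ts), ]
  summary <- dplyr::bind_rows(lapply(
    split(kept, kept[c("experiment", "group")], drop = TRUE),
    function(g) tibble::tibble(
      experiment = g$experiment[1], group = g$group[1], n = nrow(g),
      mean_ts = mean(g$ts), median_ts = stats::median(g$ts),
      iqr_ts = stats::IQR(g$ts)
    )
  ))
  structure(
    list(
      estimates = est,
      scores = all_scores,
      summary = summary,
      exclusions = table(unname(excluded))
    ),
    class = "transfer_analysis"
  )
}

#' @export
print.transfer_analysis <- function(x, ...) {
  cat("<transfer_analysis>\n")
  print(x$summary)
  if (length(x$exclusions)) {
    cat("exclusions:\n")
    print(x$exclusions)
  }
  invisible(x)
}
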