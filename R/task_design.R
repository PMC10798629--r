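#' Define a coin-task experiment design
#'
#' Builds the generative parameters of a coin-task experiment: Gaussian
#' location priors centred on the screen midline, dot-cloud likelihoods, the
#' display geometry, and the per-phase trial counts. All positions are in
#' screen units, where the left and right screen edges sit at -0.5 and +0.5.
#'
#' Two protocols are supported. `"exp1"` uses two priors (narrow `Pn`,
#' sigma = 0.025; wide `Pw`, sigma = 0.085) crossed with two likelihoods
#' (`Ln`, sigma = 0.06; `Lw`, sigma = 0.15): 400 learning trials (200 per
#' trained combination), 180 transfer trials (90 per likelihood, one prior),
#' and an 80-trial likelihood-only task. `"exp2"` uses the single wide prior
#' with three likelihoods (`Ln`, sigma = `sigma_Ln_exp2`; `Lm`, sigma = 0.06;
#' `Lw`, sigma = 0.15): 200 learning trials (100 per trained combination),
#' 225 transfer trials (75 per likelihood), and a 90-trial likelihood-only
#' task.
#'
#' @param experiment `"exp1"` or `"exp2"`.
#' @param sigma_Ln_exp2 Standard deviation of the narrow likelihood in
#'   experiment 2 (screen units). Default 0.024.
#' @param n_dots Number of splash dots per trial.
#' @param net_width Width of the response net, screen units.
#' @param coin_diameter Diameter of the coin, screen units.
#'
#' @return An object of class `coin_task_design`: a list with elements
#'   `experiment`, `priors` (tibble: `label`, `mu`, `sigma`), `likelihoods`
#'   (tibble: `label`, `sigma`), `n_dots`, `net_width`, `coin_diameter`,
#'   `hit_window` (= `net_width + coin_diameter`), `screen_halfwidth`, and
#'   `counts` (per-phase trial counts and the default number of initial
#'   learning trials discarded before slope fitting).
#' @export
#' @examples
#' d <- coin_task_design("exp1")
#' d$likelihoods
coin_task_design <- function(experiment = c("exp1", "exp2"),
                             sigma_Ln_exp2 = 0.024,
                             n_dots = 5L,
                             net_width = 0.02,
                             coin_diameter = 0.01) {
  experiment <- match.arg(experiment)
  stopifnot(n_dots >= 1, net_width > 0, coin_diameter > 0)
  if (experiment == "exp1") {
    priors <- tibble::tibble(label = c("Pn", "Pw"), mu = 0, sigma = c(0.025, 0.085))
    likelihoods <- tibble::tibble(label = c("Ln", "Lw"), sigma = c(0.06, 0.15))
    counts <- list(
      learning_per_combo = 200L, transfer_per_likelihood = 90L,
      likelihood_only_per_likelihood = 40L, discard = 50L
    )
  } else {
    if (sigma_Ln_exp2 <= 0) stop("`sigma_Ln_exp2` must be positive", call. = FALSE)
    priors <- tibble::tibble(label = "Pw", mu = 0, sigma = 0.085)
    likelihoods <- tibble::tibble(label = c("Ln", "Lm", "Lw"),
                                  sigma = c(sigma_Ln_exp2, 0.06, 0.15))
    counts <- list(
      learning_per_combo = 100L, transfer_per_likelihood = 75L,
      likelihood_only_per_likelihood = 30L, discard = 25L
    )
  }
  structure(
    list(
      experiment = experiment,
      priors = priors,
      likelihoods = likelihoods,
      n_dots = as.integer(n_dots),
      net_width = net_width,
      coin_diameter = coin_diameter,
      hit_window = net_width + coin_diameter,
      screen_halfwidth = 0.5,
      counts = counts
    ),
    class = "coin_task_design"
  )
}

#' @export
print.coin_task_design <- function(x, ...) {
  cat("<coin_task_design> ", x$experiment, "\n", sep = "")
  cat("  priors:     ", paste(sprintf("%s (sd %.3g)", x$priors$label, x$priors$sigma),
                              collapse = ", "), "\n", sep = "")
  cat("  likelihoods:", paste(sprintf("%s (sd %.3g)", x$likelihoods$label, x$likelihoods$sigma),
                              collapse = ", "), "\n", sep = "")
  cat("  dots per trial: ", x$n_dots, "; hit window: ", x$hit_window, "\n", sep = "")
  invisible(x)
}

prior_sigma <- function(design, label) {
  i <- match(label, design$priors$label)
  if (anyNA(i)) stop("unknown prior label: ", paste(label[is.na(i)], collapse = ", "),
                     call. = FALSE)
  design$priors$sigma[i]
}

likelihood_sigma <- function(design, label) {
  i <- match(label, design$likelihoods$label)
  if (anyNA(i)) stop("unknown likelihood label: ", paste(label[is.na(i)], collapse = ", "),
                     call. = FALSE)
  design$likelihoods$sigma[i]
}

dot_cols <- function(n_dots) sprintf("dot_x%d", seq_len(n_dots))

#' Sample coin-task trials from the generative model
#'
#' Draws `n` trials of one prior/likelihood combination. The hidden coin
#' position is drawn from the condition's Gaussian prior and the dot cloud
#' i.i.d. Gaussian around the coin. Positions are not truncated at the screen
#' edges: the design sigmas make prior excursions beyond +/-0.5 vanishingly
#' rare, and clipping would distort the Gaussian assumptions underlying the
#' weighting model.
#'
#' Draws come from the R random number stream; call [set.seed()] for
#' reproducibility.
#'
#' @param design A [coin_task_design()].
#' @param prior_label,likelihood_label Condition labels present in the design.
#' @param n Number of trials.
#'
#' @return A tibble with one row per trial: `prior_label`, `likelihood_label`,
#'   `sigma_P`, `sigma_L`, `coin_x`, dot positions `dot_x1..dot_x<n_dots>`,
#'   and the splash centroid `mu_L`.
#' @export
#' @examples
#' set.seed(1)
#' sample_trials(coin_task_design("exp1"), "Pw", "Ln", 3)
sample_trials <- function(design, prior_label, likelihood_label, n) {
  stopifnot(inherits(design, "coin_task_design"), n >= 1)
  sp <- prior_sigma(design, prior_label)
  sl <- likelihood_sigma(design, likelihood_label)
  if (sp <= 0) stop("prior standard deviation must be positive", call. = FALSE)
  if (sl < 0) stop("likelihood standard deviation must be non-negative", call. = FALSE)
  coin_x <- stats::rnorm(n, mean = 0, sd = sp)
  dots <- matrix(stats::rnorm(n * design$n_dots, mean = coin_x, sd = sl),
                 nrow = n, ncol = design$n_dots)
  out <- tibble::tibble(
    prior_label = prior_label,
    likelihood_label = likelihood_label,
    sigma_P = sp,
    sigma_L = sl,
    coin_x = coin_x
  )
  out[dot_cols(design$n_dots)] <- as.data.frame(dots)
  out$mu_L <- rowMeans(dots)
  out
}

# Draw likelihood-only trials: dot clouds around generative centres spread
# uniformly over the central half of the screen (no prior is in play; only the
# deviation of the centroid estimate from the generative centre is analysed).
sample_likelihood_only_trials <- function(design, likelihood_label, n) {
  sl <- likelihood_sigma(design, likelihood_label)
  centre <- stats::runif(n, -0.25, 0.25)
  dots <- matrix(stats::rnorm(n * design$n_dots, mean = centre, sd = sl),
                 nrow = n, ncol = design$n_dots)
  out <- tibble::tibble(
    prior_label = NA_character_,
    likelihood_label = likelihood_label,
    sigma_P = NA_real_,
    sigma_L = sl,
    coin_x = centre
  )
  out[dot_cols(design$n_dots)] <- as.data.frame(dots)
  out$mu_L <- rowMeans(dots)
  out
}

# Pseudorandom interleaving: uniform shuffle of the condition-tagged trial
# list, constrained so no condition runs more than `max_run` consecutive
# trials. Sequentially samples conditions with probability proportional to
# their remaining counts, restarting on the (rare) dead ends.
interleave_labels <- function(labels, counts, max_run = 6L, max_tries = 200L) {
  stopifnot(length(labels) == length(counts), all(counts >= 0))
  total <- sum(counts)
  for (try in seq_len(max_tries)) {
    rem <- counts
    out <- character(total)
    last <- ""
    run <- 0L
    ok <- TRUE
    for (i in seq_len(total)) {
      avail <- which(rem > 0)
      if (run >= max_run) avail <- avail[labels[avail] != last]
      if (length(avail) == 0L) { ok <- FALSE; break }
      pick <- if (length(avail) == 1L) avail else
        sample(avail, 1L, prob = rem[avail])
      out[i] <- labels[pick]
      rem[pick] <- rem[pick] - 1L
      run <- if (identical(labels[pick], last)) run + 1L else 1L
      last <- labels[pick]
    }
    if (ok) return(out)
  }
  stop("could not build an interleaved schedule within ", max_tries, " attempts",
       call. = FALSE)
}

exp1_counterbalance <- function(counterbalance) {
  if (!counterbalance %in% 1:4) {
    stop("`counterbalance` must be 1, 2, 3 or 4 for experiment 1", call. = FALSE)
  }
  trained <- if (counterbalance %in% c(1L, 2L)) {
    data.frame(prior_label = c("Pn", "Pw"), likelihood_label = c("Ln", "Lw"))
  } else {
    data.frame(prior_label = c("Pn", "Pw"), likelihood_label = c("Lw", "Ln"))
  }
  transfer_prior <- if (counterbalance %in% c(1L, 3L)) "Pn" else "Pw"
  list(trained = trained, transfer_prior = transfer_prior)
}

trained_combos <- function(design, group, counterbalance = 1L) {
  if (design$experiment == "exp1") {
    exp1_counterbalance(counterbalance)$trained
  } else {
    liks <- switch(group,
      interpolation = c("Ln", "Lw"),
      extrapolation = c("Ln", "Lm"),
      stop("unknown experiment 2 group: ", group, call. = FALSE)
    )
    data.frame(prior_label = "Pw", likelihood_label = liks)
  }
}

#' Build a learning + transfer schedule for the coin task
#'
#' Assembles the full coin-task trial sequence for one participant: the
#' learning phase (with its serial or interleaved condition ordering) followed
#' by the transfer phase. Experiment 1 groups are `"serial"` (two contiguous
#' 200-trial runs, one per trained combination) and `"parallel"` (the same 400
#' trials interleaved); both then receive 180 interleaved transfer trials of
#' one prior crossed with both likelihoods. Experiment 2 groups are
#' `"interpolation"` (trains `PwLn` and `PwLw`; `PwLm` is novel in transfer)
#' and `"extrapolation"` (trains `PwLn` and `PwLm`; `PwLw` is novel), each with
#' 100 + 100 interleaved learning trials and 225 transfer trials (75 per
#' likelihood). Interleaving never lets one condition run more than 6
#' consecutive trials.
#'
#' @param design A [coin_task_design()].
#' @param group Learning group; `"serial"`/`"parallel"` for experiment 1,
#'   `"interpolation"`/`"extrapolation"` for experiment 2.
#' @param counterbalance For experiment 1, an integer 1-4 choosing which
#'   orthogonal prior/likelihood assignment is trained and which prior carries
#'   into the transfer phase. Ignored for experiment 2.
#'
#' @return A tibble of trials with columns `phase` (`"learning"` or
#'   `"transfer"`), `novelty` (`"old"`/`"new"`, transfer only), `trial_index`
#'   (presentation order within the coin task), the condition columns and dot
#'   positions of [sample_trials()].
#' @export
build_schedule <- function(design, group, counterbalance = 1L) {
  stopifnot(inherits(design, "coin_task_design"))
  groups <- if (design$experiment == "exp1") c("serial", "parallel")
            else c("interpolation", "extrapolation")
  if (!group %in% groups) {
    stop("group must be one of ", paste(groups, collapse = "/"),
         " for ", design$experiment, call. = FALSE)
  }
  trained <- trained_combos(design, group, counterbalance)
  combo_key <- function(p, l) paste(p, l, sep = ":")
  trained_keys <- combo_key(trained$prior_label, trained$likelihood_label)
  n_learn <- design$counts$learning_per_combo

  learn_order <- if (design$experiment == "exp1" && group == "serial") {
    rep(trained_keys, each = n_learn)
  } else {
    interleave_labels(trained_keys, rep(n_learn, length(trained_keys)))
  }
  learn_pool <- lapply(seq_len(nrow(trained)), function(i) {
    sample_trials(design, trained$prior_label[i], trained$likelihood_label[i], n_learn)
  })
  names(learn_pool) <- trained_keys
  learning <- take_in_order(learn_pool, learn_order)
  learning$phase <- "learning"
  learning$novelty <- NA_character_

  if (design$experiment == "exp1") {
    tp <- exp1_counterbalance(counterbalance)$transfer_prior
    transfer_combos <- data.frame(prior_label = tp,
                                  likelihood_label = design$likelihoods$label)
  } else {
    transfer_combos <- data.frame(prior_label = "Pw",
                                  likelihood_label = design$likelihoods$label)
  }
  t_keys <- combo_key(transfer_combos$prior_label, transfer_combos$likelihood_label)
  n_trans <- design$counts$transfer_per_likelihood
  trans_order <- interleave_labels(t_keys, rep(n_trans, length(t_keys)))
  trans_pool <- lapply(seq_len(nrow(transfer_combos)), function(i) {
    sample_trials(design, transfer_combos$prior_label[i],
                  transfer_combos$likelihood_label[i], n_trans)
  })
  names(trans_pool) <- t_keys
  transfer <- take_in_order(trans_pool, trans_order)
  transfer$phase <- "transfer"
  transfer$novelty <- ifelse(
    combo_key(transfer$prior_label, transfer$likelihood_label) %in% trained_keys,
    "old", "new"
  )

  out <- dplyr::bind_rows(learning, transfer)
  out$trial_index <- seq_len(nrow(out))
  dplyr::relocate(out, "phase", "novelty", "trial_index")
}

# Deal trials from per-condition pools following a condition-label order.
take_in_order <- function(pools, order_keys) {
  used <- stats::setNames(integer(length(pools)), names(pools))
  idx <- integer(length(order_keys))
  pool_id <- match(order_keys, names(pools))
  for (i in seq_along(order_keys)) {
    used[pool_id[i]] <- used[pool_id[i]] + 1L
    idx[i] <- used[pool_id[i]]
  }
  dplyr::bind_rows(lapply(seq_along(order_keys), function(i) {
    pools[[pool_id[i]]][idx[i], ]
  }))
}

#' Build the likelihood-only (centroid estimation) schedule
#'
#' The likelihood-only task precedes the coin task and measures how precisely
#' a participant locates the centroid of a dot cloud at each likelihood level,
#' with no prior in play: 80 trials for experiment 1 (40 per likelihood) and
#' 90 for experiment 2 (30 per likelihood). Trials are interleaved with the
#' same maximum-run constraint as the coin task.
#'
#' @inheritParams build_schedule
#' @return A tibble of trials with `phase = "likelihood_only"`; `coin_x` holds
#'   the generative centre of each dot cloud.
#' @export
build_likelihood_only_schedule <- function(design) {
  stopifnot(inherits(design, "coin_task_design"))
  n_per <- design$counts$likelihood_only_per_likelihood
  labs <- design$likelihoods$label
  order_keys <- interleave_labels(labs, rep(n_per, length(labs)))
  pools <- lapply(labs, function(l) sample_likelihood_only_trials(design, l, n_per))
  names(pools) <- labs
  out <- take_in_order(pools, order_keys)
  out$phase <- "likelihood_only"
  out$novelty <- NA_character_
  out$trial_index <- seq_len(nrow(out))
  dplyr::relocate(out, "phase", "novelty", "trial_index")
}
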