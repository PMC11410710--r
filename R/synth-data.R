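#' Configuration for the synthetic paired-intake trial generator
#'
#' Describes a short-term feed-bunk preference experiment: `n_subjects`
#' animals each receive every unordered pair of `items` exactly once (4
#' items give 6 pairs x 12 subjects = 72 offerings over 6 occasions). The
#' defaults emulate the scale of a cattle silage trial: about 2.64 kg DM
#' offered per bin (SD 0.22, truncated to [2.09, 2.99]), right-skewed
#' 30-min per-bin consumption with mean 0.48 kg and SD 0.40 (zeros
#' possible), and an optional 3-h intake correlated about 0.89 with the
#' 30-min intake.
#'
#' The 30-min total eaten at one offering is gamma distributed; the split
#' between the two bins is a beta draw with concentration
#' `share_precision`, calibrated so that the probability of a feed taking
#' the majority of the intake equals its Bradley-Terry selection
#' probability — majority-threshold coding of generated intakes therefore
#' recovers the true abilities. The gamma moments are derived so that the
#' per-bin mean and SD hit `consumption_mean`/`consumption_sd` when the two
#' items are equally palatable.
#'
#' @param items Feed-item labels (default `A0`, `A48`, `B0`, `B48`).
#' @param abilities Named true palatabilities (log-odds); default all zero.
#' @param n_subjects Number of subjects; each gets every pair once.
#' @param offered_mean,offered_sd,offered_min,offered_max Offered kg DM per
#'   bin: truncated-normal parameters.
#' @param consumption_mean,consumption_sd Target per-bin 30-min intake
#'   moments (kg DM) at equal palatabilities.
#' @param share_precision Beta concentration of the intake share around the
#'   Bradley-Terry probability. The default 3 makes roughly 40-50% of
#'   equal-palatability offerings non-decisive at the 70% threshold.
#' @param consumption_mean_3h Target per-bin 3-h intake mean; used only
#'   when `include_3h = TRUE`.
#' @param target_corr_3h Target correlation between 30-min and 3-h per-bin
#'   intakes.
#' @param include_3h Generate `intake_a_3h`/`intake_b_3h` columns? The 3-h
#'   layer only exercises I/O and the correlation property; analysis uses
#'   the 30-min intakes.
#' @return Object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(items = c("A0", "A48", "B0", "B48"),
                             abilities = NULL,
                             n_subjects = 12L,
                             offered_mean = 2.64, offered_sd = 0.22,
                             offered_min = 2.09, offered_max = 2.99,
                             consumption_mean = 0.48, consumption_sd = 0.40,
                             share_precision = 3,
                             consumption_mean_3h = 0.98,
                             target_corr_3h = 0.89,
                             include_3h = FALSE) {
  if (is.null(abilities)) {
    abilities <- stats::setNames(rep(0, length(items)), items)
  }
  stopifnot(length(items) >= 2L, !anyDuplicated(items),
            setequal(names(abilities), items),
            n_subjects >= 1L, offered_sd > 0,
            offered_min < offered_max,
            consumption_sd > 0, share_precision > 0,
            target_corr_3h > 0, target_corr_3h < 1)
  if (consumption_mean <= 0 || consumption_mean >= offered_mean) {
    stop("infeasible config: per-bin consumption mean must be in (0, offered_mean)",
         call. = FALSE)
  }
  structure(list(items = items, abilities = abilities[items],
                 n_subjects = as.integer(n_subjects),
                 offered_mean = offered_mean, offered_sd = offered_sd,
                 offered_min = offered_min, offered_max = offered_max,
                 consumption_mean = consumption_mean,
                 consumption_sd = consumption_sd,
                 share_precision = share_precision,
                 consumption_mean_3h = consumption_mean_3h,
                 target_corr_3h = target_corr_3h,
                 include_3h = include_3h),
            class = "synthetic_config")
}

rtruncnorm_icdf <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Beta mean w such that P(S > 1/2) = p for S ~ Beta(w*phi, (1-w)*phi).
# Calibrates the intake-share layer to the Bradley-Terry selection
# probability: the more palatable feed takes the majority of the intake
# with exactly probability p, so majority-threshold coding of generated
# intakes recovers the true abilities. At p = 0.5 this gives w = 0.5.
beta_share_mean <- function(p, phi) {
  vapply(p, function(pk) {
    if (abs(pk - 0.5) < 1e-12) return(0.5)
    f <- function(w) {
      stats::pbeta(0.5, w * phi, (1 - w) * phi, lower.tail = FALSE) - pk
    }
    stats::uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  }, 0)
}

# Total-intake gamma moments that reproduce the per-bin targets when the
# intake share S ~ Beta(phi/2, phi/2) (equal palatabilities): with
# bin = T*S and S independent of T,
#   E[bin]   = E[T]/2
#   Var[bin] = (Var T + E[T]^2) (Var S + 1/4) - E[T]^2/4.
total_intake_moments <- function(config) {
  mu_t <- 2 * config$consumption_mean
  vs <- 0.25 / (config$share_precision + 1)
  var_t <- (config$consumption_sd^2 + mu_t^2 / 4) / (vs + 0.25) - mu_t^2
  if (var_t <= 0) {
    stop("infeasible config: per-bin consumption SD too small for the share spread",
         call. = FALSE)
  }
  c(mean = mu_t, sd = sqrt(var_t))
}

#' Generate a synthetic paired-intake trial
#'
#' Draws a full trial under a [synthetic_config()]: per subject, the pairs
#' are assigned to occasions in random order and the left/right bin
#' position is randomized; per offering, offered amounts are truncated
#' normal, the 30-min total eaten is gamma (capped at the total offered),
#' and its split between the bins is a beta share whose majority
#' probability is the Bradley-Terry probability of the pair. When
#' `include_3h` is set, 3-h
#' intakes add an independent gamma increment sized to give approximately
#' the target correlation with the 30-min intakes.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed.
#' @return A [trial()]; the true abilities, config and seed are stored in
#'   `metadata`.
#' @export
#' @examples
#' tr <- generate_trial(synthetic_config(), seed = 7)
#' nrow(tr$records)  # 72
generate_trial <- function(config = synthetic_config(), seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(seed)) set.seed(seed)
  items <- config$items
  pr <- utils::combn(items, 2L)
  n_pairs <- ncol(pr)
  tm <- total_intake_moments(config)

  rows <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    day_order <- sample.int(n_pairs)
    flip <- stats::runif(n_pairs) < 0.5
    left <- ifelse(flip, pr[2L, ], pr[1L, ])
    right <- ifelse(flip, pr[1L, ], pr[2L, ])
    offered_l <- rtruncnorm_icdf(n_pairs, config$offered_mean,
                                 config$offered_sd,
                                 config$offered_min, config$offered_max)
    offered_r <- rtruncnorm_icdf(n_pairs, config$offered_mean,
                                 config$offered_sd,
                                 config$offered_min, config$offered_max)
    total <- pmin(rgamma_ms(n_pairs, tm[["mean"]], tm[["sd"]]),
                  offered_l + offered_r)
    p_left <- bt_probability(config$abilities[left],
                             config$abilities[right])
    w_left <- beta_share_mean(p_left, config$share_precision)
    share_l <- stats::rbeta(n_pairs,
                            w_left * config$share_precision,
                            (1 - w_left) * config$share_precision)
    intake_l <- pmin(total * share_l, offered_l)
    intake_r <- pmin(total * (1 - share_l), offered_r)
    d <- data.frame(subject = sprintf("s%02d", s),
                    occasion = sprintf("d%d", day_order),
                    item_a = left, item_b = right,
                    intake_a = intake_l, intake_b = intake_r,
                    offered_a = offered_l, offered_b = offered_r,
                    stringsAsFactors = FALSE)
    if (config$include_3h) {
      inc_mean <- config$consumption_mean_3h - config$consumption_mean
      r <- config$target_corr_3h
      inc_sd <- config$consumption_sd * sqrt(1 / r^2 - 1)
      d$intake_a_3h <- pmin(intake_l + rgamma_ms(n_pairs, inc_mean, inc_sd),
                            offered_l)
      d$intake_b_3h <- pmin(intake_r + rgamma_ms(n_pairs, inc_mean, inc_sd),
                            offered_r)
    }
    rows[[s]] <- d[order(day_order), , drop = FALSE]
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  trial(records, metadata = list(abilities = config$abilities,
                                 config = config, seed = seed))
}

#' Generate a stream of binary Bradley-Terry outcomes
#'
#' Pure win/loss outcomes drawn from the Bradley-Terry probabilities,
#' bypassing the intake layer — the fast path used for estimation tests and
#' for the power engine ([simulate_outcomes()]).
#'
#' @param abilities Named true palatabilities (log-odds).
#' @param pairs Two-column character matrix of unordered pairs.
#' @param replicates Replicate count per pair (scalar or per-pair vector).
#' @return Data frame of outcome records, one per comparison; `subject` is
#'   the replicate index within its pair. Uses the current RNG state.
#' @export
generate_outcome_stream <- function(abilities, pairs, replicates) {
  pairs <- matrix(as.character(pairs), ncol = 2L)
  replicates <- rep_len(as.integer(replicates), nrow(pairs))
  item_a <- rep(pairs[, 1L], replicates)
  item_b <- rep(pairs[, 2L], replicates)
  p_a <- bt_probability(abilities[item_a], abilities[item_b])
  win_a <- stats::runif(length(item_a)) < p_a
  data.frame(
    subject = unlist(lapply(replicates, seq_len)),
    occasion = NA_character_,
    item_a = item_a, item_b = item_b,
    outcome = ifelse(win_a, "win_a", "win_b"),
    stringsAsFactors = FALSE
  )
}
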