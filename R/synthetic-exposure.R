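#' Lognormal parameters matching a target arithmetic mean and SD
#'
#' Moment matching on the log scale: a lognormal with
#' \eqn{\sigma^2 = \ln(1 + sd^2/am^2)} and
#' \eqn{\mu = \ln(am) - \sigma^2/2} has arithmetic mean `am` and
#' standard deviation `sd` exactly.
#'
#' @param am target arithmetic mean (mg/m3), positive.
#' @param sd target standard deviation (mg/m3), positive.
#' @return named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' p <- lognormal_params_from_moments(0.038, 0.048)
#' exp(p["meanlog"] + p["sdlog"]^2 / 2)  # recovers 0.038
#' @export
lognormal_params_from_moments <- function(am, sd) {
  if (!is.numeric(am) || am <= 0) stop("'am' must be positive", call. = FALSE)
  if (!is.numeric(sd) || sd <= 0) stop("'sd' must be positive", call. = FALSE)
  s2 <- log1p(sd^2 / am^2)
  c(meanlog = log(am) - s2 / 2, sdlog = sqrt(s2))
}

#' Generator profile for one workplace
#'
#' Describes the measurement campaign to emulate at one workplace: how many
#' samples, the target arithmetic moments, and the plausible concentration
#' window (the detection limit at the low end and the largest observed
#' value at the high end). Draws are taken from the moment-matched
#' lognormal and rejection-resampled into `[lo, hi]`, so the bounds act as
#' observed extremes rather than censoring points and no probability mass
#' piles up on them.
#'
#' @param workplace_id label.
#' @param n number of samples, at least 2.
#' @param target_am target arithmetic mean, mg/m3, inside `(lo, hi)`.
#' @param target_sd target standard deviation, mg/m3, positive.
#' @param lo truncation floor (detection limit), mg/m3.
#' @param hi truncation ceiling, mg/m3.
#' @return object of class `workplace_profile`.
#' @export
workplace_profile <- function(workplace_id, n, target_am, target_sd, lo, hi) {
  stopifnot(n >= 2, target_sd > 0, lo < hi, is.finite(lo), is.finite(hi))
  if (!(target_am > lo && target_am < hi))
    stop("'target_am' must lie strictly within (lo, hi)", call. = FALSE)
  structure(list(workplace_id = as.character(workplace_id), n = as.integer(n),
                 target_am = target_am, target_sd = target_sd,
                 lo = lo, hi = hi),
            class = "workplace_profile")
}

#' Built-in three-workplace measurement campaign profiles
#'
#' The default profiles emulate a published biphenyl survey of three Korean
#' workplaces (textile and plastic manufacture and lithium-battery
#' electrolyte production) totalling 38 personal and area samples, with
#' per-workplace arithmetic mean, SD and observed range:
#' A (n = 12, AM 0.034, SD 0.048, 0.001-0.145 mg/m3),
#' B (n = 14, AM 0.014, SD 0.022, 0.001-0.057),
#' C (n = 12, AM 0.066, SD 0.075, 0.001-0.240).
#'
#' @return list of [workplace_profile()] objects.
#' @export
biphenyl_survey_profiles <- function() {
  list(workplace_profile("A", 12, 0.034, 0.048, 0.001, 0.145),
       workplace_profile("B", 14, 0.014, 0.022, 0.001, 0.057),
       workplace_profile("C", 12, 0.066, 0.075, 0.001, 0.240))
}

# Stable 31-based polynomial string hash into [0, 2^31 - 2]; used to spawn
# per-workplace substreams so adding a workplace never shifts another
# workplace's draws.
stable_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  h
}

substream_seed <- function(master_seed, workplace_id) {
  (as.numeric(master_seed) %% 2147483647 * 48271 +
     stable_hash(workplace_id)) %% 2147483647
}

#' Generate a synthetic workplace measurement dataset
#'
#' For each profile, draws `n` concentrations from the lognormal matched to
#' the profile's arithmetic moments, rejection-resampled into `[lo, hi]`.
#' Sample kinds alternate personal/area within each workplace. Each
#' workplace uses its own random substream derived from the master seed and
#' a stable hash of the workplace label, so the output is reproducible
#' element-by-element and insensitive to profile order.
#'
#' @param profiles list of [workplace_profile()] objects.
#' @param seed master integer seed.
#' @param detection_limit detection limit recorded on the dataset; defaults
#'   to the smallest profile floor.
#' @return an [exposure_dataset()].
#' @export
generate_workplaces <- function(profiles, seed,
                                detection_limit = min(vapply(profiles, `[[`,
                                                             numeric(1), "lo"))) {
  if (inherits(profiles, "workplace_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, logical(1), "workplace_profile")))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  parts <- lapply(profiles, function(pr) {
    par <- lognormal_params_from_moments(pr$target_am, pr$target_sd)
    accept <- stats::plnorm(pr$hi, par["meanlog"], par["sdlog"]) -
      stats::plnorm(pr$lo, par["meanlog"], par["sdlog"])
    if (accept < 0.01)
      stop(sprintf(paste0("workplace '%s': truncation interval [%g, %g] keeps ",
                          "only %.2f%% of the lognormal mass; refusing to ",
                          "rejection-sample (silent bias)"),
                   pr$workplace_id, pr$lo, pr$hi, 100 * accept), call. = FALSE)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(substream_seed(seed, pr$workplace_id))
    draws <- numeric(0)
    while (length(draws) < pr$n) {
      x <- stats::rlnorm(max(pr$n, 100), par["meanlog"], par["sdlog"])
      draws <- c(draws, x[x >= pr$lo & x <= pr$hi])
    }
    draws <- draws[seq_len(pr$n)]
    data.frame(workplace_id = pr$workplace_id,
               sample_kind = rep_len(c("personal", "area"), pr$n),
               concentration = draws, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  exposure_dataset(all$workplace_id, all$sample_kind, all$concentration,
                   detection_limit = detection_limit)
}
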