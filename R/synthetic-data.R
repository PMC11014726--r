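#' Configuration for the parametric synthetic-data generator
#'
#' Defines a synthetic polymorphism panel with known ground truth. Focal
#' (TE-like) sites are truly neutral with probability `neutral_ratio_r`,
#' otherwise under purifying selection of scaled strength `scaled_S`.
#' Neutral sites emulate synonymous SNPs. Frequencies are drawn from the
#' sample site-frequency spectrum and ages from the Kimura-Ohta mean age at
#' the drawn frequency with Gamma-distributed dispersion; selected sites
#' get down-weighted high frequencies and stochastically shortened ages.
#'
#' @param n_sites_focal,n_sites_neutral numbers of focal and neutral sites.
#' @param neutral_ratio_r fraction of focal sites that are truly neutral.
#' @param scaled_S scaled selection coefficient (`<= 0`) of selected focal
#'   sites.
#' @param Ne effective population size setting the age scale.
#' @param sample_size diploid sample size (frequencies live on a grid of
#'   `1/(2 * sample_size)`); must not exceed `2 * Ne`.
#' @param burst_schedule optional tibble with `start_gen`, `end_gen`,
#'   `rate_multiplier`: transposition-activity bursts, in generations ago,
#'   applied to the focal sites' origin times.
#' @param demography optional tibble with `time_ago` and `Ne` defining a
#'   piecewise-constant population-size history (most recent epoch first,
#'   `time_ago` = start of each older epoch); applied as a monotone time
#'   warp to all ages, focal and neutral alike.
#' @param age_noise_sd standard deviation (log scale) of multiplicative
#'   log-normal age-estimate noise; 0 disables noise.
#' @param n_sites_nonsyn,n_sites_high_effect optional counts of
#'   non-synonymous-like and high-effect-like comparison sites, generated
#'   as selected classes with `S_nonsyn` and `S_high_effect`.
#' @param S_nonsyn,S_high_effect scaled selection strengths of the
#'   comparison classes.
#' @param age_dispersion Gamma shape of the age dispersion around the
#'   Kimura-Ohta mean (mean-1 multiplier; default 2).
#' @param seed integer master seed; every stochastic step derives its seed
#'   from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_sites_focal = 2000, n_sites_neutral = 10000,
                         neutral_ratio_r = 1.0, scaled_S = 0, Ne = 1000,
                         sample_size = 30, burst_schedule = NULL,
                         demography = NULL, age_noise_sd = 0,
                         n_sites_nonsyn = 0, n_sites_high_effect = 0,
                         S_nonsyn = -2, S_high_effect = -4,
                         age_dispersion = 2, seed = 1) {
  if (neutral_ratio_r < 0 || neutral_ratio_r > 1) {
    abort("neutral_ratio_r must lie in [0, 1]")
  }
  if (Ne < 2) abort("Ne must be >= 2")
  if (sample_size > 2 * Ne) abort("infeasible config: sample_size > 2 * Ne")
  if (scaled_S > 0) abort("scaled_S must be <= 0")
  if (age_noise_sd < 0) abort("age_noise_sd must be >= 0")
  if (!is.null(burst_schedule)) {
    burst_schedule <- as_tibble(burst_schedule)
    stopifnot(all(c("start_gen", "end_gen", "rate_multiplier") %in%
                    names(burst_schedule)))
    if (any(burst_schedule$rate_multiplier <= 0)) {
      abort("burst rate multipliers must be > 0")
    }
    check_no_overlap(burst_schedule)
  }
  if (!is.null(demography)) {
    demography <- as_tibble(demography)
    stopifnot(all(c("time_ago", "Ne") %in% names(demography)))
  }
  structure(
    list(n_sites_focal = n_sites_focal, n_sites_neutral = n_sites_neutral,
         neutral_ratio_r = neutral_ratio_r, scaled_S = scaled_S, Ne = Ne,
         sample_size = sample_size, burst_schedule = burst_schedule,
         demography = demography, age_noise_sd = age_noise_sd,
         n_sites_nonsyn = n_sites_nonsyn,
         n_sites_high_effect = n_sites_high_effect,
         S_nonsyn = S_nonsyn, S_high_effect = S_high_effect,
         age_dispersion = age_dispersion, seed = seed),
    class = "synth_config")
}

check_no_overlap <- function(schedule) {
  s <- schedule[order(schedule$start_gen), , drop = FALSE]
  if (any(s$end_gen <= s$start_gen)) abort("burst intervals must have end_gen > start_gen")
  if (nrow(s) > 1 && any(s$start_gen[-1] < s$end_gen[-nrow(s)])) {
    abort("burst intervals must not overlap")
  }
  invisible(TRUE)
}

# draw (frequency, age) pairs for one mutation class; S = 0 means neutral
draw_class <- function(n, S, Ne, sample_size, age_dispersion) {
  if (n == 0) {
    return(tibble(derived_freq = numeric(0), age = numeric(0)))
  }
  n_chr <- 2 * sample_size
  i <- seq_len(n_chr - 1)
  x <- i / n_chr
  # neutral sample SFS ~ 1/i; purifying selection thins high frequencies
  w <- (1 / i) * exp(S * x)
  counts <- sample(i, n, replace = TRUE, prob = w)
  freq <- counts / n_chr
  base_age <- expected_neutral_age(freq, Ne)
  # selection shortens the time a deleterious allele can persist
  shrink <- 1 / (1 + abs(S) / 2)
  disp <- rgamma(n, shape = age_dispersion, rate = age_dispersion)
  tibble(derived_freq = freq, age = base_age * shrink * disp)
}

# piecewise-constant demographic history as a monotone warp of ages:
# one coalescent-time unit in an epoch with size Ne_epoch spans
# Ne_epoch / Ne reference generations
warp_ages <- function(ages, demography, Ne) {
  if (is.null(demography) || nrow(demography) == 0) return(ages)
  d <- demography[order(demography$time_ago), , drop = FALSE]
  starts <- c(0, d$time_ago)
  scales <- c(1, d$Ne / Ne)
  out <- numeric(length(ages))
  # cumulative warped time at each epoch start
  widths <- diff(starts)
  cum_w <- c(0, cumsum(widths * scales[-length(scales)]))
  ep <- findInterval(ages, starts)
  out <- cum_w[ep] + (ages - starts[ep]) * scales[ep]
  out
}

#' Reweight origin times by a transposition-burst schedule
#'
#' Multiplies the density of focal origin times by `rate_multiplier`
#' inside each (non-overlapping) burst interval and renormalizes, by
#' importance-resampling the input times.
#'
#' @param origin_times origin times in generations ago.
#' @param burst_schedule tibble with `start_gen`, `end_gen` (half-open
#'   interval, generations ago) and `rate_multiplier` (> 0).
#' @param seed optional integer seed.
#' @return Resampled origin times of the same length.
#' @export
apply_burst_schedule <- function(origin_times, burst_schedule, seed = NULL) {
  burst_schedule <- as_tibble(burst_schedule)
  if (any(burst_schedule$rate_multiplier <= 0)) {
    abort("burst rate multipliers must be > 0")
  }
  check_no_overlap(burst_schedule)
  w <- burst_weights(origin_times, burst_schedule)
  if (length(unique(w)) <= 1) return(origin_times)  # flat schedule: identity
  if (!is.null(seed)) set.seed(seed)
  idx <- burst_resample_index(origin_times, burst_schedule)
  origin_times[idx]
}

burst_weights <- function(times, schedule) {
  w <- rep(1, length(times))
  for (k in seq_len(nrow(schedule))) {
    inb <- times >= schedule$start_gen[k] & times < schedule$end_gen[k]
    w[inb] <- w[inb] * schedule$rate_multiplier[k]
  }
  w
}

burst_resample_index <- function(times, schedule) {
  w <- burst_weights(times, schedule)
  sample.int(length(times), length(times), replace = TRUE, prob = w)
}

#' Add multiplicative log-normal noise to age estimates
#'
#' Emulates age-estimator error: estimated ages are positive and their
#' error is roughly multiplicative, so noise is log-normal with median 1.
#' `sd = 0` returns the input unchanged.
#'
#' @param ages positive ages in generations.
#' @param age_noise_sd log-scale standard deviation (`>= 0`).
#' @param seed optional integer seed.
#' @return Noisy ages, all positive.
#' @export
add_age_noise <- function(ages, age_noise_sd, seed = NULL) {
  if (age_noise_sd < 0) abort("age_noise_sd must be >= 0")
  if (any(ages <= 0)) abort("ages must be > 0")
  if (age_noise_sd == 0) return(ages)
  if (!is.null(seed)) set.seed(seed)
  ages * exp(rnorm(length(ages), mean = 0, sd = age_noise_sd))
}

#' Generate a synthetic polymorphism dataset with known ground truth
#'
#' Draws focal (TE-like), neutral, and optional comparison (non-synonymous-
#' like, high-effect-like) sites under a [synth_config()]. Truly neutral
#' focal sites are drawn from exactly the same (frequency, age) process as
#' the neutral sites, so under `neutral_ratio_r = 1` the focal and neutral
#' classes are exchangeable and the delta frequency is centred on 0 by
#' construction -- transposition bursts and demographic change only reshape
#' the age distribution, never the frequency-given-age relationship.
#' Deterministic under a fixed `seed`.
#'
#' @param config a [synth_config()].
#' @param sim_sample optional `wf_sample` from [run_wf_simulation()]: when
#'   supplied, selected focal sites are drawn from the simulator's
#'   empirical `focal_selected` output instead of the parametric model.
#' @return A tibble with columns `variant_id`, `class` (`focal`,
#'   `neutral`, `non_synonymous`, `high_effect`), `truly_neutral`,
#'   `derived_freq`, `minor_freq`, `age` (true age), `age_observed` (noisy
#'   when `age_noise_sd > 0`, else equal to `age`), `position`.
#' @export
generate_dataset <- function(config, sim_sample = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 11))
  cfg <- config

  n_f <- cfg$n_sites_focal
  truly_neutral <- runif(n_f) < cfg$neutral_ratio_r
  n_fn <- sum(truly_neutral)
  n_fs <- n_f - n_fn
  if (n_fs > 0 && cfg$scaled_S == 0) {
    abort("scaled_S must be < 0 when some focal sites are selected (neutral_ratio_r < 1)")
  }

  focal_neutral <- draw_class(n_fn, 0, cfg$Ne, cfg$sample_size, cfg$age_dispersion)
  focal_selected <- if (!is.null(sim_sample) && n_fs > 0) {
    src <- sim_sample[sim_sample$mut_class == "focal_selected", , drop = FALSE]
    if (nrow(src) == 0) abort("sim_sample holds no focal_selected mutations")
    pick <- sample.int(nrow(src), n_fs, replace = n_fs > nrow(src))
    tibble(derived_freq = src$sample_frequency[pick], age = src$age[pick])
  } else {
    draw_class(n_fs, cfg$scaled_S, cfg$Ne, cfg$sample_size, cfg$age_dispersion)
  }
  focal <- dplyr::bind_rows(
    dplyr::mutate(focal_neutral, truly_neutral = TRUE),
    dplyr::mutate(focal_selected, truly_neutral = FALSE))
  focal$class <- "focal"

  neutral <- draw_class(cfg$n_sites_neutral, 0, cfg$Ne, cfg$sample_size,
                        cfg$age_dispersion)
  neutral$class <- "neutral"
  neutral$truly_neutral <- TRUE

  nonsyn <- draw_class(cfg$n_sites_nonsyn, cfg$S_nonsyn, cfg$Ne,
                       cfg$sample_size, cfg$age_dispersion)
  if (nrow(nonsyn)) { nonsyn$class <- "non_synonymous"; nonsyn$truly_neutral <- FALSE }
  higheff <- draw_class(cfg$n_sites_high_effect, cfg$S_high_effect, cfg$Ne,
                        cfg$sample_size, cfg$age_dispersion)
  if (nrow(higheff)) { higheff$class <- "high_effect"; higheff$truly_neutral <- FALSE }

  sites <- dplyr::bind_rows(focal, neutral, nonsyn, higheff)

  # demographic change warps all ages identically (focal and neutral alike)
  sites$age <- warp_ages(sites$age, cfg$demography, cfg$Ne)

  # transposition bursts reshape the focal age density; (freq, age) pairs
  # are resampled jointly so frequency-given-age is untouched
  if (!is.null(cfg$burst_schedule)) {
    set.seed(derive_seed(cfg$seed, 13))
    fi <- which(sites$class == "focal")
    ridx <- burst_resample_index(sites$age[fi], cfg$burst_schedule)
    sites[fi, ] <- sites[fi[ridx], ]
  }

  sites$age_observed <- if (cfg$age_noise_sd > 0) {
    add_age_noise(sites$age, cfg$age_noise_sd, seed = derive_seed(cfg$seed, 17))
  } else {
    sites$age
  }

  set.seed(derive_seed(cfg$seed, 19))
  n <- nrow(sites)
  sites$position <- sample.int(1e6, n, replace = TRUE)
  sites$variant_id <- sprintf("syn_%06d", seq_len(n))
  sites$minor_freq <- pmin(sites$derived_freq, 1 - sites$derived_freq)
  dplyr::select(sites, "variant_id", "class", "truly_neutral",
                "derived_freq", "minor_freq", "age", "age_observed",
                "position")
}
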