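# memoised mixture solves (deterministic given the configuration)
.solve_cache <- new.env(parent = emptyenv())

#' Default high-activity population proportions per scenario
#'
#' Fractions of the Belgian MSM population classified as high-activity under
#' the three definitions: PrEP eligibility (34.6%), more than 15 total
#' partners in 12 months (30.41%), more than 15 casual partners (27.90%).
#'
#' @return Named numeric vector.
#' @export
scenario_targets <- function() {
  c(prep_eligibility = 0.346, gt15_total = 0.3041, gt15_casual = 0.2790)
}

# Latent steady-partner count distribution over 0..12 (12-month counts,
# capped at 12). Synthetic stand-in: most respondents report 0 or 1 steady
# partner over a year; the tail is thin.
.steady_pmf_default <- function() {
  p <- c(0.44, 0.46, 0.05, 0.02, 0.01, 0.008, 0.005, 0.003, 0.002,
         0.001, 0.0006, 0.0003, 0.0001)
  p / sum(p)
}

#' Configuration of the synthetic survey generator
#'
#' The generator emulates an EMIS-like behavioural survey: categorical
#' 12-month steady and casual partner counts, ongoing-partnership status,
#' last-encounter type and the fields entering the PrEP eligibility rule.
#' Latent integer counts are drawn from a two-component negative-binomial
#' mixture (a low-activity bulk and a heavy tail). Two mixture quantities --
#' the tail weight and the bulk mean -- are solved at configuration time so
#' that (i) the expected high-activity fraction under the configured scenario
#' equals `target_ha_proportion` as measured on *reconstructed* counts, and
#' (ii) the expected overall reconstructed mean matches the overall target
#' mean. This keeps the synthetic population consistent with the published
#' summary statistics it is meant to stand in for.
#'
#' @param n_respondents Number of respondents (default 2763).
#' @param scenario One of `"prep_eligibility"`, `"gt15_total"`,
#'   `"gt15_casual"`.
#' @param target_ha_proportion Fraction in (0,1); defaults to the scenario's
#'   published proportion (see [scenario_targets()]).
#' @param count_distribution_params List with `k_low`, `k_high`, `mu_high`
#'   (negative-binomial sizes and the tail-component mean); `w` (weight of
#'   the low component) and `mu_low` are solved unless supplied.
#' @param one_off_fraction Fraction of respondents whose last encounter was a
#'   one-off partnership (synthetic stand-in default 0.5).
#' @param hiv_negative_prob,adult_prob Marginal probabilities of the
#'   HIV-negative and over-18 flags.
#' @param ongoing_dependence Gaussian-copula correlation in [-1, 1] between
#'   ongoing steady and casual partnership status (default 0, independent).
#' @param targets [category_targets()] the reconstruction will be run
#'   against; used for the consistency solve.
#' @param cap Upper bound of the ">50" casual category.
#' @param seed Default RNG seed passed to [generate_survey()].
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_respondents = 2763,
                             scenario = c("prep_eligibility", "gt15_total",
                                          "gt15_casual"),
                             target_ha_proportion = NULL,
                             count_distribution_params = list(),
                             one_off_fraction = 0.5,
                             hiv_negative_prob = 0.93,
                             adult_prob = 0.985,
                             ongoing_dependence = 0,
                             targets = category_targets(),
                             cap = 300,
                             seed = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(target_ha_proportion))
    target_ha_proportion <- unname(scenario_targets()[scenario])
  if (!(target_ha_proportion > 0 && target_ha_proportion < 1))
    stop("target_ha_proportion must lie in (0, 1)")
  stopifnot(n_respondents >= 0, one_off_fraction >= 0, one_off_fraction <= 1,
            abs(ongoing_dependence) <= 1)
  cp <- utils::modifyList(
    list(k_low = 1.2, mu_low = NULL, k_high = 1.2, mu_high = NULL, w = NULL),
    count_distribution_params)
  cfg <- list(n_respondents = as.integer(n_respondents), scenario = scenario,
              target_ha_proportion = target_ha_proportion,
              count_distribution_params = cp,
              one_off_fraction = one_off_fraction,
              hiv_negative_prob = hiv_negative_prob, adult_prob = adult_prob,
              ongoing_dependence = ongoing_dependence,
              steady_pmf = .steady_pmf_default(),
              targets = targets, cap = cap, seed = seed)
  if (is.null(cp$w) || is.null(cp$mu_high) || is.null(cp$mu_low)) {
    key <- paste(scenario, target_ha_proportion, cap,
                 paste(unlist(cp), collapse = "_"),
                 paste(unlist(targets$overall), collapse = "_"),
                 paste(unlist(targets$categories[-1]), collapse = "_"),
                 sep = "|")
    cached <- .solve_cache[[key]]
    if (is.null(cached)) {
      cached <- .solve_count_mixture(cfg)
      .solve_cache[[key]] <- cached
    }
    cfg$count_distribution_params <- cached
  }
  class(cfg) <- "generator_config"
  cfg
}

# pmf of the latent casual-count mixture on 0..(cap + 60); mass above is
# negligible for the parameter ranges used and is renormalised away.
.casual_pmf <- function(cp, cap) {
  x <- 0:(cap + 60)
  p <- cp$w * stats::dnbinom(x, size = cp$k_low, mu = cp$mu_low) +
    (1 - cp$w) * stats::dnbinom(x, size = cp$k_high, mu = cp$mu_high)
  p / sum(p)
}

# Expected reconstruction outcomes under a candidate mixture: the overall
# reconstructed mean and the probability that a respondent's reconstructed
# total (or casual) count exceeds 15. Averages over the steady pmf and over
# the overlap-based total-category assignment, using the same truncated
# discrete normal draw distribution the reconstruction uses.
.recon_expectations <- function(cfg, cp) {
  p_c <- .casual_pmf(cp, cfg$cap)
  p_s <- cfg$steady_pmf
  s_vals <- 0:12
  tg <- cfg$targets$categories
  tg_mean <- stats::setNames(tg$mean, tg$label)
  tg_sd <- stats::setNames(tg$sd, tg$label)

  # exact part: casual <= 10
  e_mean <- 0; p_tot15 <- 0; p_le4 <- 0; p_eq5 <- 0
  for (cc in 0:10) {
    pc <- p_c[cc + 1]
    e_mean <- e_mean + pc * (cc + sum(s_vals * p_s))
    p_tot15 <- p_tot15 + pc * sum(p_s[s_vals + cc > 15])
    p_le4 <- p_le4 + pc * sum(p_s[s_vals + cc <= 4])
    p_eq5 <- p_eq5 + pc * sum(p_s[s_vals + cc == 5])
  }
  p_cas15 <- 0
  # interval part
  cb_all <- category_bounds(.interval_levels, cap = cfg$cap)
  for (k in seq_along(.interval_levels)) {
    lab <- .interval_levels[k]
    pcc <- sum(p_c[(cb_all[k, "lo"]:cb_all[k, "hi"]) + 1])
    # drawn totals hit the assigned category's target mean in expectation
    # (narrow-window clamping is compensated within each category)
    if (lab != "11-20") { # reconstructed totals and casuals always > 15
      e_contrib <- 0
      for (si in seq_along(s_vals)) {
        s <- s_vals[si]
        cand <- .total_grid_overlap(c(s + cb_all[k, "lo"],
                                      s + cb_all[k, "hi"]), cap = cfg$cap)
        e_contrib <- e_contrib +
          p_s[si] * sum(cand$prob * tg_mean[cand$label])
      }
      e_mean <- e_mean + pcc * e_contrib
      p_tot15 <- p_tot15 + pcc
      p_cas15 <- p_cas15 + pcc
    } else {
      for (si in seq_along(s_vals)) {
        s <- s_vals[si]
        cand <- .total_grid_overlap(c(s + 11, s + 20), cap = cfg$cap)
        for (ci in seq_len(nrow(cand))) {
          sup <- cand$lo[ci]:cand$hi[ci]
          pmf <- dtnorm_pmf(cand$lo[ci], cand$hi[ci],
                            tg_mean[[cand$label[ci]]], tg_sd[[cand$label[ci]]])
          w_cell <- pcc * p_s[si] * cand$prob[ci]
          e_mean <- e_mean + w_cell * tg_mean[[cand$label[ci]]]
          p_tot15 <- p_tot15 + w_cell * sum(pmf[sup > 15])
          p_cas15 <- p_cas15 + w_cell * sum(pmf[sup - s > 15])
        }
      }
    }
  }
  list(mean = e_mean, p_total_gt15 = p_tot15, p_casual_gt15 = p_cas15,
       p_total_le4 = p_le4, p_total_eq5 = p_eq5)
}

# Solve the bulk weight w, tail-component mean mu_high and bulk mean mu_low
# so that (i) the scenario's expected HA fraction, (ii) the expected overall
# reconstructed mean, and (iii) the probability of a total at or below 4
# (which anchors the overall median at its target of 5) hit their targets.
# For the PrEP scenario (whose HA rule does not involve counts) the casual
# >15 fraction is anchored at the published 27.90% for realism. Supplied
# values are kept fixed; missing ones are solved.
.solve_count_mixture <- function(cfg) {
  cp <- cfg$count_distribution_params
  solve_w <- is.null(cp$w); solve_mh <- is.null(cp$mu_high)
  solve_ml <- is.null(cp$mu_low)
  if (solve_mh) cp$mu_high <- 22
  if (solve_w) cp$w <- 0.55
  if (solve_ml) cp$mu_low <- 3
  tail_target <- switch(cfg$scenario,
                        gt15_total = cfg$target_ha_proportion,
                        gt15_casual = cfg$target_ha_proportion,
                        prep_eligibility = unname(
                          scenario_targets()["gt15_casual"]))
  tail_of <- function(e) switch(cfg$scenario,
                                gt15_total = e$p_total_gt15,
                                e$p_casual_gt15)
  for (pass in 1:8) {
    w_old <- cp$w; mh_old <- cp$mu_high; ml_old <- cp$mu_low
    if (solve_w) {
      f_w <- function(w) {
        cp$w <- w
        tail_of(.recon_expectations(cfg, cp)) - tail_target
      }
      if (f_w(0.02) * f_w(0.98) < 0)
        cp$w <- stats::uniroot(f_w, c(0.02, 0.98), tol = 1e-5)$root
    }
    if (solve_mh) {
      f_m <- function(m) {
        cp$mu_high <- m
        .recon_expectations(cfg, cp)$mean - cfg$targets$overall$mean
      }
      if (f_m(12) * f_m(70) < 0)
        cp$mu_high <- stats::uniroot(f_m, c(12, 70), tol = 1e-5)$root
    }
    if (solve_ml) {
      # centre the overall median at its target: place P(total <= 4) half
      # the mass of {5} below one half, so both median-flip directions are
      # equally unlikely in a finite sample
      m5 <- .recon_expectations(cfg, cp)$p_total_eq5
      f_l <- function(m) {
        cp$mu_low <- m
        .recon_expectations(cfg, cp)$p_total_le4 - (0.5 - m5 / 2)
      }
      if (f_l(0.5) * f_l(6) < 0)
        cp$mu_low <- stats::uniroot(f_l, c(0.5, 6), tol = 1e-5)$root
    }
    if (abs(cp$w - w_old) < 1e-4 && abs(cp$mu_high - mh_old) < 1e-4 &&
        abs(cp$mu_low - ml_old) < 1e-4) break
  }
  cp
}

#' Generate a synthetic EMIS-like survey dataset
#'
#' Draws latent integer steady and casual partner counts, censors them onto
#' the survey category grids, and generates ongoing-partnership status,
#' last-encounter type and PrEP-rule fields. The latent integers are kept as
#' the `latent_counts` attribute (ground truth for reconstruction tests).
#' Under the PrEP scenario, eligibility status is drawn with a probability
#' increasing in total partner count, its intercept solved so the expected
#' eligible fraction equals the configured target; the rule fields are then
#' generated consistently with that status, so rule-based classification
#' recovers it exactly for HIV-negative adults.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; overrides `config$seed`.
#' @return Data frame of class `msm_survey`, one row per respondent, with
#'   attributes `latent_counts` (data frame of latent steady/casual integers)
#'   and `config`.
#' @export
generate_survey <- function(config, seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_respondents
  cp <- config$count_distribution_params

  S <- if (n > 0) sample(0:12, n, replace = TRUE, prob = config$steady_pmf)
       else integer(0)
  low <- stats::runif(n) < cp$w
  C <- integer(n)
  C[low] <- stats::rnbinom(sum(low), size = cp$k_low, mu = cp$mu_low)
  C[!low] <- stats::rnbinom(sum(!low), size = cp$k_high, mu = cp$mu_high)

  # ongoing partnership status, optionally copula-coupled
  rho <- config$ongoing_dependence
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  u1 <- stats::pnorm(z1); u2 <- stats::pnorm(z2)
  v1 <- stats::runif(n); v2 <- stats::runif(n)
  ongoing_steady <- rep("0", n)
  has_s <- S >= 1 & u1 < 0.78
  ongoing_steady[has_s] <- ifelse(S[has_s] >= 2 & v1[has_s] < 0.15, ">1", "1")
  p_any_c <- 1 - exp(-C / 8)
  p_multi <- stats::plogis(-1.5 + 0.08 * pmin(C, 40))
  ongoing_casual <- rep("0", n)
  has_c <- u2 < p_any_c
  ongoing_casual[has_c] <- ifelse(v2[has_c] < p_multi[has_c], ">1", "1")

  hiv_negative <- stats::runif(n) < config$hiv_negative_prob
  age_over_18 <- stats::runif(n) < config$adult_prob
  last_one_off <- stats::runif(n) < config$one_off_fraction

  # PrEP-eligibility latent status and consistent rule fields
  elig <- logical(n)
  if (n > 0) {
    q_target <- config$target_ha_proportion /
      (config$hiv_negative_prob * config$adult_prob)
    if (q_target >= 1)
      stop("target_ha_proportion unreachable given HIV/adult margins")
    lp <- 0.8 * log1p(S + C)
    f <- function(a) mean(stats::plogis(a + lp)) - q_target
    a <- stats::uniroot(f, c(-20, 20), tol = 1e-8)$root
    elig <- stats::runif(n) < stats::plogis(a + lp)
  }
  condomless <- integer(n); sti <- integer(n); pep <- integer(n)
  chemsex <- logical(n)
  if (any(!elig)) {
    k <- sum(!elig)
    condomless[!elig] <- sample(0:1, k, replace = TRUE, prob = c(0.6, 0.4))
    sti[!elig] <- sample(0:1, k, replace = TRUE, prob = c(0.9, 0.1))
    pep[!elig] <- sample(0:1, k, replace = TRUE, prob = c(0.98, 0.02))
  }
  if (any(elig)) {
    k <- sum(elig)
    primary <- sample(c("cond", "sti", "pep", "chem"), k, replace = TRUE,
                      prob = c(0.70, 0.12, 0.05, 0.13))
    condomless[elig] <- ifelse(primary == "cond",
                               2L + stats::rpois(k, pmax(C[elig], 1) / 6),
                               sample(0:1, k, replace = TRUE))
    sti[elig] <- ifelse(primary == "sti", 2L,
                        sample(0:2, k, replace = TRUE,
                               prob = c(0.7, 0.2, 0.1)))
    pep[elig] <- ifelse(primary == "pep", 2L,
                        sample(0:2, k, replace = TRUE,
                               prob = c(0.85, 0.1, 0.05)))
    chemsex[elig] <- primary == "chem" | stats::runif(k) < 0.25
  }

  survey <- data.frame(
    respondent_id = if (n > 0) sprintf("R%05d", seq_len(n)) else character(0),
    hiv_negative = hiv_negative,
    age_over_18 = age_over_18,
    condomless_anal_partners_6mo = condomless,
    sti_count_12mo = sti,
    pep_uses_12mo = pep,
    chemsex = chemsex,
    steady_count_category = steady_category(S),
    casual_count_category = casual_category(C, cap = config$cap),
    ongoing_steady = ongoing_steady,
    ongoing_casual = ongoing_casual,
    last_encounter_one_off = last_one_off,
    stringsAsFactors = FALSE)
  attr(survey, "latent_counts") <- data.frame(steady = S, casual = C)
  attr(survey, "config") <- config
  class(survey) <- c("msm_survey", "data.frame")
  survey
}

#' Classify respondents into activity groups
#'
#' Applies one of three high-activity (HA) definitions. The PrEP-eligibility
#' rule labels a respondent HA iff they are an HIV-negative adult satisfying
#' at least one of: two or more condomless anal partners in 6 months, two or
#' more STIs in 12 months, two or more PEP uses in 12 months, or chemsex.
#' The count-based rules label HA iff the reconstructed total (or casual)
#' 12-month partner count strictly exceeds 15 (a count of exactly 15 is LA).
#'
#' @param survey An `msm_survey` data frame.
#' @param scenario Scenario name; defaults to the survey's configuration.
#' @param counts For the count-based scenarios, a `recon_result` (or its
#'   `counts` data frame) supplying reconstructed `total` and `casual`
#'   columns. When omitted, the survey's latent ground-truth counts are used.
#' @return Character vector of group labels, `"HA"` or `"LA"`.
#' @export
classify_activity <- function(survey, scenario = NULL, counts = NULL) {
  if (is.null(scenario)) {
    cfg <- attr(survey, "config")
    if (is.null(cfg)) stop("scenario not given and survey has no config")
    scenario <- cfg$scenario
  }
  scenario <- match.arg(scenario,
                        c("prep_eligibility", "gt15_total", "gt15_casual"))
  n <- nrow(survey)
  if (scenario == "prep_eligibility") {
    need <- c("hiv_negative", "age_over_18", "condomless_anal_partners_6mo",
              "sti_count_12mo", "pep_uses_12mo", "chemsex")
    miss <- setdiff(need, names(survey))
    if (length(miss) > 0)
      stop("missing required field(s): ", paste(miss, collapse = ", "))
    ha <- survey$age_over_18 & survey$hiv_negative &
      (survey$condomless_anal_partners_6mo >= 2 |
         survey$sti_count_12mo >= 2 |
         survey$pep_uses_12mo >= 2 |
         survey$chemsex)
    return(ifelse(ha, "HA", "LA"))
  }
  if (inherits(counts, "recon_result")) counts <- counts$counts
  if (is.null(counts)) {
    lat <- attr(survey, "latent_counts")
    if (is.null(lat)) stop("count-based scenario needs reconstructed counts")
    counts <- data.frame(total = lat$steady + lat$casual, casual = lat$casual)
  }
  stopifnot(nrow(counts) == n)
  x <- if (scenario == "gt15_total") counts$total else counts$casual
  ifelse(x > 15, "HA", "LA")
}

#' Read and write synthetic surveys
#'
#' The survey is stored as a plain CSV with the documented header; the latent
#' ground-truth integer counts go to a sidecar CSV and the generating
#' configuration to YAML.
#'
#' @param survey An `msm_survey`.
#' @param path CSV path for the survey.
#' @param latent_path Optional CSV path for the latent counts sidecar.
#' @param config_path Optional YAML path for the configuration.
#' @return `write_survey` returns `path` invisibly; `read_survey` returns an
#'   `msm_survey` (with latent counts attached when the sidecar is given).
#' @export
write_survey <- function(survey, path, latent_path = NULL,
                         config_path = NULL) {
  utils::write.csv(as.data.frame(survey), path, row.names = FALSE)
  if (!is.null(latent_path))
    utils::write.csv(attr(survey, "latent_counts"), latent_path,
                     row.names = FALSE)
  if (!is.null(config_path)) {
    cfg <- attr(survey, "config")
    cfg$targets <- NULL # reference targets are reconstructed on load
    yaml::write_yaml(cfg, config_path)
  }
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path, latent_path = NULL) {
  survey <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(steady_count_category = "character",
                                           casual_count_category = "character",
                                           ongoing_steady = "character",
                                           ongoing_casual = "character"))
  if (!is.null(latent_path))
    attr(survey, "latent_counts") <- utils::read.csv(latent_path)
  class(survey) <- c("msm_survey", "data.frame")
  survey
}
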