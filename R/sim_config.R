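#' Configuration for the synthetic claims simulator
#'
#' Bundles every tunable parameter of the synthetic longitudinal claims
#' generator into a validated configuration object. The defaults emulate the
#' statistical structure the downstream analysis assumes: a cohort of tens of
#' thousands of patients served by a few thousand prescribers over three
#' years of quarterly follow-up, a small latent drug-seeker subpopulation
#' (about 2\%) that spreads over a pool of lenient ("lax") low-volume
#' prescribers at the network periphery, right-skewed
#' morphine-milligram-equivalent (MME) totals per
#' prescription, rare overdose events (about 2 per 10,000 patient-quarters at
#' baseline), and censoring by disenrollment.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_providers Number of prescribers on the roster.
#' @param n_quarters Number of calendar quarters of follow-up.
#' @param seeker_fraction Probability that a patient carries the latent
#'   drug-seeker flag (independent Bernoulli draws).
#' @param lax_provider_fraction Probability that a provider belongs to the
#'   lenient high-volume pool.
#' @param mean_rx_per_quarter_seeker Mean opioid prescriptions per enrolled
#'   quarter for seekers (Poisson rate).
#' @param mean_rx_per_quarter_normal Mean prescriptions per enrolled quarter
#'   for non-seekers (Poisson rate).
#' @param mme_log_mean,mme_log_sd Log-scale location and spread of the
#'   log-normal total MME drawn for each prescription.
#' @param lax_mme_multiplier Multiplicative MME inflation for prescriptions
#'   written by lax providers; couples seeker behaviour to high-potency
#'   prescribing. Set to 1 to decouple edge weights from the lax pool.
#' @param seeker_mme_multiplier Multiplicative MME inflation for
#'   prescriptions obtained by seekers, wherever written: drug-seeking
#'   patients extract a larger share of any provider's prescribed quantity,
#'   which is the signal MME edge weights add for the bipartite indices.
#'   Set to 1 to switch the behavioural quantity-seeking channel off.
#' @param lax_popularity Relative mainstream patient throughput of a lax
#'   provider compared to a typical provider. The default is well below 1:
#'   lenient prescribers are low-volume peripheral providers whose practice
#'   is dominated by the seekers who find them, which is what lets
#'   reinforcement-based bipartite indices separate seekers from mainstream
#'   patients of the same degree.
#' @param provider_popularity_sd Log-scale dispersion of the latent provider
#'   throughput. Heavier tails concentrate the many single-provider patients
#'   on a few very-high-degree mainstream providers while seekers spread
#'   over lower-degree prescribers, which is what tips the patient-provider
#'   degree assortativity of the generated network slightly negative.
#' @param seeker_lax_prob Probability that a single seeker prescription is
#'   drawn from the lax pool (by preferential attachment) rather than
#'   uniformly from the full roster.
#' @param baseline_hazard Per patient-quarter event probability scale for a
#'   covariate-free non-seeker.
#' @param gamma_seeker Log-hazard effect of the latent seeker flag.
#' @param beta_covariates Named numeric vector of log-hazard effects for the
#'   six binary comorbidity flags (`hepc`, `hiv`, `cancer`, `psych`,
#'   `palliative`, `mat`).
#' @param comorbidity_prevalence Named numeric vector of marginal prevalences
#'   for the same six flags.
#' @param seeker_comorbidity_or Odds ratio applied to each comorbidity
#'   prevalence among seekers. The default 1 keeps comorbidities independent
#'   of seeker status; values above 1 switch confounding on for sensitivity
#'   runs.
#' @param dropout_prob Per-quarter probability of disenrollment (independent
#'   geometric censoring).
#' @param seed Integer seed; identical configurations produce identical
#'   simulated data.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_claims()] for the end-to-end generator.
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 500, n_providers = 60, n_quarters = 6)
#' cfg
sim_config <- function(n_patients = 20000L,
                       n_providers = 2000L,
                       n_quarters = 12L,
                       seeker_fraction = 0.02,
                       lax_provider_fraction = 0.30,
                       mean_rx_per_quarter_seeker = 1.0,
                       mean_rx_per_quarter_normal = 0.5,
                       mme_log_mean = log(250),
                       mme_log_sd = 1,
                       lax_mme_multiplier = 2,
                       seeker_mme_multiplier = 3,
                       lax_popularity = 0.05,
                       provider_popularity_sd = 1.5,
                       seeker_lax_prob = 0.95,
                       baseline_hazard = 2e-4,
                       gamma_seeker = 4,
                       beta_covariates = c(hepc = 0.75, hiv = 1.0,
                                           cancer = 0.2, psych = 2.0,
                                           palliative = 1.6, mat = 0.9),
                       comorbidity_prevalence = c(hepc = 0.02, hiv = 0.005,
                                                  cancer = 0.05, psych = 0.10,
                                                  palliative = 0.01,
                                                  mat = 0.01),
                       seeker_comorbidity_or = 1,
                       dropout_prob = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_providers = as.integer(n_providers),
    n_quarters = as.integer(n_quarters),
    seeker_fraction = seeker_fraction,
    lax_provider_fraction = lax_provider_fraction,
    mean_rx_per_quarter_seeker = mean_rx_per_quarter_seeker,
    mean_rx_per_quarter_normal = mean_rx_per_quarter_normal,
    mme_log_mean = mme_log_mean,
    mme_log_sd = mme_log_sd,
    lax_mme_multiplier = lax_mme_multiplier,
    seeker_mme_multiplier = seeker_mme_multiplier,
    lax_popularity = lax_popularity,
    provider_popularity_sd = provider_popularity_sd,
    seeker_lax_prob = seeker_lax_prob,
    baseline_hazard = baseline_hazard,
    gamma_seeker = gamma_seeker,
    beta_covariates = beta_covariates,
    comorbidity_prevalence = comorbidity_prevalence,
    seeker_comorbidity_or = seeker_comorbidity_or,
    dropout_prob = dropout_prob,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

comorbidity_names <- function() {
  c("hepc", "hiv", "cancer", "psych", "palliative", "mat")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L)
    stop("n_patients must be a positive integer", call. = FALSE)
  if (is.na(cfg$n_providers) || cfg$n_providers < 1L)
    stop("n_providers must be a positive integer", call. = FALSE)
  if (is.na(cfg$n_quarters) || cfg$n_quarters < 1L)
    stop("n_quarters must be a positive integer", call. = FALSE)
  for (fr in c("seeker_fraction", "lax_provider_fraction", "seeker_lax_prob",
               "dropout_prob")) {
    v <- cfg[[fr]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("%s must lie in [0, 1]", fr), call. = FALSE)
  }
  for (pos in c("mean_rx_per_quarter_seeker", "mean_rx_per_quarter_normal")) {
    v <- cfg[[pos]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop(sprintf("%s must be a nonnegative rate", pos), call. = FALSE)
  }
  if (!is.numeric(cfg$baseline_hazard) || cfg$baseline_hazard < 0)
    stop("baseline_hazard must be nonnegative", call. = FALSE)
  if (cfg$mme_log_sd < 0) stop("mme_log_sd must be nonnegative", call. = FALSE)
  if (cfg$lax_mme_multiplier <= 0 || cfg$seeker_mme_multiplier <= 0 ||
      cfg$lax_popularity <= 0)
    stop("MME multipliers and lax popularity must be strictly positive",
         call. = FALSE)
  if (cfg$provider_popularity_sd < 0)
    stop("provider_popularity_sd must be nonnegative", call. = FALSE)
  nm <- comorbidity_names()
  if (!all(nm %in% names(cfg$beta_covariates)))
    stop("beta_covariates must be named for: ", paste(nm, collapse = ", "),
         call. = FALSE)
  if (!all(nm %in% names(cfg$comorbidity_prevalence)))
    stop("comorbidity_prevalence must be named for: ",
         paste(nm, collapse = ", "), call. = FALSE)
  prev <- cfg$comorbidity_prevalence[nm]
  if (any(prev < 0 | prev > 1))
    stop("comorbidity prevalences must lie in [0, 1]", call. = FALSE)
  if (cfg$seeker_comorbidity_or <= 0)
    stop("seeker_comorbidity_or must be strictly positive", call. = FALSE)
  if (is.na(cfg$seed)) stop("seed must be an integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic claims configuration\n")
  cat(sprintf("  cohort: %d patients, %d providers, %d quarters (seed %d)\n",
              x$n_patients, x$n_providers, x$n_quarters, x$seed))
  cat(sprintf("  seekers: %.1f%% of cohort, %.1f%% lax providers, P(lax visit) = %.2f\n",
              100 * x$seeker_fraction, 100 * x$lax_provider_fraction,
              x$seeker_lax_prob))
  cat(sprintf("  prescriptions/quarter: %.2f (seeker) vs %.2f (other); MME ~ logN(%.2f, %.2f)\n",
              x$mean_rx_per_quarter_seeker, x$mean_rx_per_quarter_normal,
              x$mme_log_mean, x$mme_log_sd))
  cat(sprintf("  hazard: base %.2e, log-HR seeker %.2f; dropout/quarter %.3f\n",
              x$baseline_hazard, x$gamma_seeker, x$dropout_prob))
  invisible(x)
}
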