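#' Draw the synthetic patient and provider rosters
#'
#' Generates the patient-level table (demographics, latent seeker flag,
#' comorbidity indicators, enrollment span) and the provider roster (lax-pool
#' flag and a latent popularity weight governing patient throughput).
#' Overdose outcomes are left unfilled until [simulate_outcomes()] has seen
#' the prescription stream.
#'
#' Enrollment starts at quarter 0 for every patient; disenrollment is an
#' independent per-quarter geometric draw with probability `dropout_prob`,
#' truncated at the end of the study window.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `patients` (one row per patient) and
#'   `providers` (one row per provider).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  m <- config$n_providers

  patients <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    age = pmin(pmax(round(stats::rnorm(n, mean = 50, sd = 15)), 18), 90),
    female = stats::rbinom(n, 1L, 0.55),
    seeker = stats::rbinom(n, 1L, config$seeker_fraction),
    stringsAsFactors = FALSE
  )
  prev <- config$comorbidity_prevalence[comorbidity_names()]
  or <- config$seeker_comorbidity_or
  for (nm in comorbidity_names()) {
    p0 <- prev[[nm]]
    # odds-ratio shift for seekers (default OR = 1 keeps flags independent)
    odds <- p0 / (1 - p0) * ifelse(patients$seeker == 1L, or, 1)
    patients[[nm]] <- stats::rbinom(n, 1L, odds / (1 + odds))
  }
  patients$entry_quarter <- 0L
  if (config$dropout_prob > 0) {
    stay <- stats::rgeom(n, config$dropout_prob)
  } else {
    stay <- rep(config$n_quarters, n)
  }
  patients$exit_quarter <- pmin(patients$entry_quarter + stay,
                                config$n_quarters - 1L)
  patients$overdose_quarter <- NA_integer_

  providers <- data.frame(
    provider_id = sprintf("D%05d", seq_len(m)),
    lax = stats::rbinom(m, 1L, config$lax_provider_fraction),
    stringsAsFactors = FALSE
  )
  # latent throughput: heavy-tailed baseline, inflated for the lax pool
  providers$popularity <- stats::rlnorm(m, meanlog = 0,
                                        sdlog = config$provider_popularity_sd) *
    ifelse(providers$lax == 1L, config$lax_popularity, 1)

  list(patients = patients, providers = providers)
}

#' Simulate the opioid prescription stream
#'
#' Non-seekers are assigned one or two "home" providers, sampled with
#' probability proportional to provider popularity, and draw a Poisson number
#' of prescriptions per enrolled quarter from them. Seekers draw a larger
#' Poisson count each quarter and pick a provider per prescription: with
#' probability `seeker_lax_prob` from the lax pool by preferential attachment
#' (popularity plus the running visit count, so seekers accumulate on shared
#' lenient prescribers), otherwise uniformly from the whole roster. Each
#' prescription carries a log-normal total MME, inflated by
#' `lax_mme_multiplier` when written by a lax provider.
#'
#' @param population Output of [simulate_population()].
#' @param config The same [sim_config()] object.
#' @return A data frame of prescription records with columns `patient_id`,
#'   `provider_id`, `quarter`, `mme`.
#' @export
simulate_prescriptions <- function(population, config) {
  validate_sim_config(config)
  set.seed(config$seed + 1L)
  pats <- population$patients
  provs <- population$providers
  m <- nrow(provs)
  pop_w <- provs$popularity / sum(provs$popularity)

  enrolled <- pats$exit_quarter - pats$entry_quarter + 1L

  ## --- non-seekers: home-provider attachment -------------------------------
  ns <- which(pats$seeker == 0L)
  rec_ns <- NULL
  if (length(ns) > 0 && config$mean_rx_per_quarter_normal > 0) {
    n_home <- sample(1:2, length(ns), replace = TRUE)
    home1 <- sample.int(m, length(ns), replace = TRUE, prob = pop_w)
    home2 <- sample.int(m, length(ns), replace = TRUE, prob = pop_w)
    counts <- stats::rpois(sum(enrolled[ns]),
                           lambda = config$mean_rx_per_quarter_normal)
    pq_pat <- rep(ns, enrolled[ns])
    pq_quarter <- unlist(lapply(ns, function(i)
      seq(pats$entry_quarter[i], pats$exit_quarter[i])), use.names = FALSE)
    keep <- counts > 0L
    if (any(keep)) {
      rx_pat <- rep(pq_pat[keep], counts[keep])
      rx_quarter <- rep(pq_quarter[keep], counts[keep])
      idx <- match(rx_pat, ns)
      pick2 <- stats::runif(length(rx_pat)) < 0.5
      rx_prov <- ifelse(n_home[idx] == 2L & pick2, home2[idx], home1[idx])
      rec_ns <- data.frame(pat = rx_pat, prov = rx_prov, quarter = rx_quarter)
    }
  }

  ## --- seekers: preferential attachment on the lax pool --------------------
  sk <- which(pats$seeker == 1L)
  rec_sk <- NULL
  if (length(sk) > 0 && config$mean_rx_per_quarter_seeker > 0) {
    counts <- stats::rpois(sum(enrolled[sk]),
                           lambda = config$mean_rx_per_quarter_seeker)
    pq_pat <- rep(sk, enrolled[sk])
    pq_quarter <- unlist(lapply(sk, function(i)
      seq(pats$entry_quarter[i], pats$exit_quarter[i])), use.names = FALSE)
    keep <- counts > 0L
    if (any(keep)) {
      rx_pat <- rep(pq_pat[keep], counts[keep])
      rx_quarter <- rep(pq_quarter[keep], counts[keep])
      n_rx <- length(rx_pat)
      lax_pool <- which(provs$lax == 1L)
      use_lax <- stats::runif(n_rx) < config$seeker_lax_prob &
        length(lax_pool) > 0
      rx_prov <- integer(n_rx)
      if (any(!use_lax))
        rx_prov[!use_lax] <- sample.int(m, sum(!use_lax), replace = TRUE)
      if (any(use_lax)) {
        # sequential preferential attachment within the lax pool: weight =
        # 1 + visits so far, so seekers cluster on shared providers
        # irrespective of a provider's mainstream throughput
        w <- rep(1, length(lax_pool))
        ii <- which(use_lax)
        for (k in ii) {
          j <- sample.int(length(lax_pool), 1L, prob = w)
          rx_prov[k] <- lax_pool[j]
          w[j] <- w[j] + 1
        }
      }
      rec_sk <- data.frame(pat = rx_pat, prov = rx_prov, quarter = rx_quarter)
    }
  }

  rec <- rbind(rec_ns, rec_sk)
  if (is.null(rec) || nrow(rec) == 0L) {
    return(data.frame(patient_id = character(), provider_id = character(),
                      quarter = integer(), mme = numeric(),
                      stringsAsFactors = FALSE))
  }
  mme <- stats::rlnorm(nrow(rec), meanlog = config$mme_log_mean,
                       sdlog = config$mme_log_sd)
  mme <- mme * ifelse(provs$lax[rec$prov] == 1L, config$lax_mme_multiplier, 1)
  mme <- mme * ifelse(pats$seeker[rec$pat] == 1L,
                      config$seeker_mme_multiplier, 1)
  out <- data.frame(
    patient_id = pats$patient_id[rec$pat],
    provider_id = provs$provider_id[rec$prov],
    quarter = as.integer(rec$quarter),
    mme = mme,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$patient_id, out$quarter, out$provider_id), ]
  rownames(out) <- NULL
  out
}

#' Simulate overdose outcomes on the patient panel
#'
#' Each at-risk patient-quarter receives event probability
#' `baseline_hazard * exp(gamma_seeker * seeker + beta %*% comorbidities)`,
#' truncated to at most 1 (discrete-time approximation of the continuous
#' hazard; a warning is raised if truncation ever bites). The first event
#' ends follow-up: `exit_quarter` is pulled in to the event quarter and
#' `overdose_quarter` is recorded. Disenrollment censoring drawn in
#' [simulate_population()] is retained for patients without an earlier event.
#'
#' The uniform draws deciding events are indexed by (patient, quarter) and
#' consumed before any parameter-dependent branching, so runs that share a
#' seed but differ in `gamma_seeker` are coupled: raising the log-hazard can
#' only add events (common random numbers).
#'
#' @param population Output of [simulate_population()].
#' @param prescriptions Prescription records from [simulate_prescriptions()];
#'   accepted so the outcome stage sits downstream of the full stream, though
#'   the hazard depends only on latent status and comorbidities.
#' @param config The same [sim_config()] object.
#' @return The `patients` table with `overdose_quarter` and a possibly
#'   shortened `exit_quarter` filled in.
#' @export
simulate_outcomes <- function(population, prescriptions, config) {
  validate_sim_config(config)
  set.seed(config$seed + 2L)
  pats <- population$patients
  n <- nrow(pats)
  nq <- config$n_quarters
  u <- matrix(stats::runif(n * nq), nrow = n, ncol = nq)

  X <- as.matrix(pats[, comorbidity_names()])
  beta <- config$beta_covariates[comorbidity_names()]
  h_raw <- config$baseline_hazard *
    exp(config$gamma_seeker * pats$seeker + drop(X %*% beta))
  if (any(h_raw > 1))
    warning(sprintf("%d patient hazards exceeded 1 and were truncated",
                    sum(h_raw > 1)))
  h <- pmin(h_raw, 1)

  hit <- u < h  # n x nq logical, recycled by column
  for (i in seq_len(n)) {
    span <- seq(pats$entry_quarter[i], pats$exit_quarter[i])
    ev <- span[hit[i, span + 1L]]
    if (length(ev) > 0) {
      pats$overdose_quarter[i] <- ev[1L]
      pats$exit_quarter[i] <- ev[1L]
    }
  }
  pats
}

#' Run the full synthetic claims generator
#'
#' Convenience wrapper chaining [simulate_population()],
#' [simulate_prescriptions()] and [simulate_outcomes()]. Identical
#' configurations (including the seed) give identical output.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `claims_sim`: a list with `patients`,
#'   `providers`, `prescriptions` and the `config` used.
#' @export
#' @examples
#' sim <- simulate_claims(sim_config(n_patients = 300, n_providers = 40,
#'                                   n_quarters = 6, seed = 7))
#' sim
simulate_claims <- function(config) {
  pop <- simulate_population(config)
  rx <- simulate_prescriptions(pop, config)
  pop$patients <- simulate_outcomes(pop, rx, config)
  # an event ends follow-up: drop prescriptions past the shortened exit
  if (nrow(rx) > 0L) {
    exit <- pop$patients$exit_quarter[match(rx$patient_id,
                                            pop$patients$patient_id)]
    rx <- rx[rx$quarter <= exit, , drop = FALSE]
    rownames(rx) <- NULL
  }
  structure(list(patients = pop$patients, providers = pop$providers,
                 prescriptions = rx, config = config),
            class = "claims_sim")
}

#' @export
print.claims_sim <- function(x, ...) {
  cat("Synthetic claims cohort\n")
  cat(sprintf("  %d patients (%d latent seekers), %d providers (%d lax)\n",
              nrow(x$patients), sum(x$patients$seeker),
              nrow(x$providers), sum(x$providers$lax)))
  cat(sprintf("  %d prescriptions over %d quarters; %d overdose events\n",
              nrow(x$prescriptions), x$config$n_quarters,
              sum(!is.na(x$patients$overdose_quarter))))
  invisible(x)
}
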