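# Independent oracles and small fixture builders used across the suite.

# union-find over a bipartite edge list; providers and patients are kept in
# one namespace by prefixing. Returns the number of components and, for the
# patient mode, the fraction covered by the largest component.
uf_components <- function(provider, patient) {
  nodes <- unique(c(paste0("d:", provider), paste0("p:", patient)))
  parent <- stats::setNames(seq_along(nodes), nodes)
  find <- function(i) {
    while (parent[[i]] != i) {
      parent[[i]] <<- parent[[parent[[i]]]]
      i <- parent[[i]]
    }
    i
  }
  for (k in seq_along(provider)) {
    a <- find(which(nodes == paste0("d:", provider[k])))
    b <- find(which(nodes == paste0("p:", patient[k])))
    if (a != b) parent[[b]] <- a
  }
  roots <- vapply(seq_along(nodes), find, numeric(1))
  pat_idx <- startsWith(nodes, "p:")
  pat_roots <- roots[pat_idx]
  list(n_components = length(unique(roots)),
       coverage = max(table(pat_roots)) / length(pat_roots))
}

# hand-written Cox partial likelihood for right-censored data without ties:
# subjects enter at time 0; `time` is event/censoring time, `status` the
# event indicator, `x` a single covariate.
brute_cox_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (i in which(status == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# random small weighted bipartite matrix with no all-zero rows/columns;
# weights on the >= 1 scale (as MME totals are), where every scheme's damped
# iteration is contractive
random_bipartite <- function(nd, np, seed, density = 0.5) {
  set.seed(seed)
  repeat {
    W <- matrix(stats::rbinom(nd * np, 1, density) *
                  stats::runif(nd * np, 1, 3), nd, np)
    if (all(rowSums(W) > 0) && all(colSums(W) > 0)) return(W)
  }
}

# tiny prescription stream fixture
toy_records <- function() {
  data.frame(
    patient_id = c("P1", "P1", "P2", "P3", "P3", "P4"),
    provider_id = c("D1", "D2", "D1", "D2", "D3", "D3"),
    quarter = c(0L, 1L, 1L, 2L, 2L, 2L),
    mme = c(30, 45, 10, 100, 20, 55),
    stringsAsFactors = FALSE
  )
}

# small simulated cohort shared by a few tests (cheap: ~1s)
small_sim <- function(seed = 5, ...) {
  simulate_claims(sim_config(n_patients = 1500, n_providers = 150,
                             n_quarters = 8, seed = seed, ...))
}
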