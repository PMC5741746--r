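# Independent brute-force oracles. These deliberately use different
# factorisations / loop structures from the package implementations so that
# agreement is evidence, not tautology.

# Occupancy likelihood by joint enumeration over all 2^n site-state
# combinations (the package marginalises per site instead).
oracle_occu_nll <- function(psi, p, y) {
  n <- nrow(y)
  total <- 0
  for (code in 0:(2^n - 1)) {
    z <- as.integer(intToBits(code)[1:n])
    prob <- 1
    for (i in 1:n) {
      prob <- prob * (if (z[i] == 1) psi[i] else 1 - psi[i])
      for (t in seq_len(ncol(y))) {
        if (is.na(y[i, t])) next
        pit <- if (z[i] == 1) p[i, t] else 0
        prob <- prob * (if (y[i, t] == 1) pit else 1 - pit)
      }
    }
    total <- total + prob
  }
  -log(total)
}

# N-mixture likelihood by a direct triple loop.
oracle_nmix_nll <- function(lambda, p, y, kmax, pmf = function(n, l) dpois(n, l)) {
  ll <- 0
  for (i in seq_len(nrow(y))) {
    s <- 0
    for (N in 0:kmax) {
      term <- pmf(N, lambda[i])
      for (t in seq_len(ncol(y))) {
        if (is.na(y[i, t])) next
        term <- term * choose(N, y[i, t]) * p[i, t]^y[i, t] *
          (1 - p[i, t])^(N - y[i, t])
      }
      s <- s + term
    }
    ll <- ll + log(s)
  }
  -ll
}

# Hand-normalised Bayes table for one site's posterior abundance.
oracle_posterior <- function(lambda, p, yvec, kmax) {
  g <- dpois(0:kmax, lambda)
  for (yt in yvec) g <- g * dbinom(yt, 0:kmax, p)
  g / sum(g)
}

# Brute-force minimum surveys: scan K upward.
oracle_min_surveys <- function(p, conf) {
  K <- 1L
  while (1 - (1 - p)^K < conf) K <- K + 1L
  K
}

# A small fixed ragged design for reuse.
tiny_design <- function() {
  data.frame(site = c("a", "b", "c"), year = 1,
             habitat = c("scrub", "dune grassland", "scrub"),
             area_ha = c(2, 3, 4), n_visits = c(2, 3, 3),
             acos = c(10, 20, 30), transect_km = c(1, 2.5, 4))
}
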