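# Brute-force likelihood oracles, independent of the glm-based fitting path.

bernoulli_loglik <- function(eta, y) {
  p <- plogis(eta)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# 1-D grid maximizer of the offset log-likelihood logit(p) + c, slope fixed 1
grid_cil_intercept <- function(p, y, lo = -5, hi = 5, step = 1e-4) {
  lp <- qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10))
  cs <- seq(lo, hi, by = step)
  ll <- vapply(cs, function(c) bernoulli_loglik(lp + c, y), numeric(1))
  cs[which.max(ll)]
}

# 2-D grid maximizer of a + b * logit(p): coarse pass, then a refinement pass
# at the requested resolution around the coarse optimum
grid_recalibration <- function(p, y, lo = -5, hi = 5, fine_step = 1e-3) {
  lp <- qlogis(pmin(pmax(p, 1e-10), 1 - 1e-10))
  search <- function(as, bs) {
    best <- c(NA, NA); best_ll <- -Inf
    for (b in bs) {
      ll <- vapply(as, function(a) bernoulli_loglik(a + b * lp, y), numeric(1))
      i <- which.max(ll)
      if (ll[i] > best_ll) { best_ll <- ll[i]; best <- c(as[i], b) }
    }
    best
  }
  coarse <- search(seq(lo, hi, by = 0.05), seq(lo, hi, by = 0.05))
  search(seq(coarse[1] - 0.06, coarse[1] + 0.06, by = fine_step),
         seq(coarse[2] - 0.06, coarse[2] + 0.06, by = fine_step))
}

# small random dataset with both outcome classes present
random_small_ds <- function(n, seed) {
  set.seed(seed)
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  if (sum(y) == 0) y[1] <- 1L
  if (sum(y) == n) y[1] <- 0L
  validation_dataset(p, y)
}

perfect_cohort <- function(n, prevalence = 0.25, auc = 0.71, seed = 1) {
  generate_binormal(generator_config(n, prevalence, auc, seed = seed))
}
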