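# Independent numerical oracle for the bounded walk: evolves the position
# density on a fine grid with absorption at +/-bound (one Gaussian step per
# iteration, drift +1 by symmetry) and returns exact-to-quadrature accuracy,
# mean decision time (forced choice at the step cap), and the renewal-reward
# rate E[coins]/E[steps]. Shares no code with the sampling engine.
fp_oracle <- function(mu, sigma, bound, max_steps = 60,
                      h = min(0.002, bound / 10),
                      coins_correct = 1, coins_error = 0, step_penalty = 0) {
  edges <- seq(-bound, bound, by = h)
  if (edges[length(edges)] < bound) edges <- c(edges, bound)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(centers)
  up_from <- 1 - pnorm(bound, centers + mu, sigma)
  dn_from <- pnorm(-bound, centers + mu, sigma)
  TT <- matrix(0, nb, nb)
  for (j in seq_len(nb))
    TT[, j] <- diff(pnorm(edges, centers[j] + mu, sigma))
  d <- diff(pnorm(edges, mu, sigma))            # survivors after step 1
  up <- numeric(max_steps); dn <- numeric(max_steps)
  up[1] <- 1 - pnorm(bound, mu, sigma)
  dn[1] <- pnorm(-bound, mu, sigma)
  for (k in seq_len(max_steps)[-1]) {
    up[k] <- sum(up_from * d)
    dn[k] <- sum(dn_from * d)
    d <- as.vector(TT %*% d)
  }
  rem <- sum(d)
  acc <- sum(up) + sum(d[centers > 0]) + 0.5 * sum(d[centers == 0])
  mean_dt <- sum(seq_len(max_steps) * (up + dn)) + max_steps * rem
  e_coins <- acc * coins_correct + (1 - acc) * coins_error
  e_cost <- 1 + mean_dt + step_penalty * (1 - acc)
  list(accuracy = acc, mean_dt = mean_dt, rr = e_coins / e_cost)
}
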