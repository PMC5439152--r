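# Brute-force oracles: exhaustive path sums (haploid) and a dense
# O(M |H|^4) transition-matrix implementation (diploid).

brute_haploid <- function(obs, H, theta, eps) {
  nH <- nrow(H)
  M <- ncol(H)
  paths <- as.matrix(expand.grid(rep(list(1:nH), M)))
  em <- function(o, t, e) if (o == 9) 1 else if (o == t) 1 - e else e
  probs <- apply(paths, 1, function(p) {
    pr <- 1 / nH * em(obs[1], H[p[1], 1], eps[1])
    for (i in 2:M) {
      pr <- pr * transition_weight(theta[i - 1], p[i] == p[i - 1], nH) *
        em(obs[i], H[p[i], i], eps[i])
    }
    pr
  })
  lik <- sum(probs)
  post <- matrix(0, M, nH)
  for (i in 1:M) {
    for (h in 1:nH) post[i, h] <- sum(probs[paths[, i] == h]) / lik
  }
  list(post = post, loglik = log(lik))
}

dense_diploid_loglik <- function(obs, H, theta, eps) {
  nH <- nrow(H)
  S <- nH^2
  M <- ncol(H)
  st <- cbind(h = rep(1:nH, each = nH), k = rep(1:nH, nH))
  f <- rep(1 / S, S)
  ll <- 0
  for (i in 1:M) {
    if (i > 1) {
      Tm <- matrix(0, S, S)
      for (s1 in 1:S) {
        for (s2 in 1:S) {
          Tm[s1, s2] <- transition_weight(theta[i - 1], st[s1, 1] == st[s2, 1], nH) *
            transition_weight(theta[i - 1], st[s1, 2] == st[s2, 2], nH)
        }
      }
      f <- as.vector(f %*% Tm)
    }
    e <- vapply(1:S, function(s) {
      emission_diploid(obs[i], c(H[st[s, 1], i], H[st[s, 2], i]), eps[i])
    }, numeric(1))
    f <- f * e
    z <- sum(f)
    f <- f / z
    ll <- ll + log(z)
  }
  ll
}

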