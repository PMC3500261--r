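# Independent brute-force oracles used to check the implementation.

# Exhaustive 10-genotype likelihood enumeration, written independently of
# call_genotype(): explicit per-read loops, natural-log scale, flat prior.
oracle_genotype <- function(bases, quals) {
  bases_all <- c("A", "C", "G", "T")
  gts <- list()
  for (a in 1:4) for (b in a:4)
    gts[[length(gts) + 1]] <- c(bases_all[a], bases_all[b])
  ll <- numeric(length(gts))
  for (g in seq_along(gts)) {
    al <- gts[[g]]
    s <- 0
    for (r in seq_along(bases)) {
      e <- 10^(-quals[r] / 10)
      p1 <- if (bases[r] == al[1]) 1 - e else e / 3
      p2 <- if (bases[r] == al[2]) 1 - e else e / 3
      s <- s + log((p1 + p2) / 2)
    }
    ll[g] <- s
  }
  names(ll) <- vapply(gts, paste, character(1), collapse = "")
  ord <- order(ll, decreasing = TRUE)
  list(genotype = names(ll)[ord[1]], mpg = ll[ord[1]] - ll[ord[2]],
       loglik = ll)
}

# Benjamini-Hochberg step-up by its textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# upper-tail hypergeometric P(X >= x) by direct enumeration
oracle_hyper_tail <- function(N, K, k, x) {
  i <- x:min(K, k)
  sum(choose(K, i) * choose(N - K, k - i)) / choose(N, k)
}

# pyrimidine-anchored class of a substitution via an explicit 12-row table
oracle_spectrum_class <- function(ref, alt) {
  tab <- rbind(
    c("C", "T", "C:G>T:A"), c("G", "A", "C:G>T:A"),
    c("C", "A", "C:G>A:T"), c("G", "T", "C:G>A:T"),
    c("C", "G", "C:G>G:C"), c("G", "C", "C:G>G:C"),
    c("T", "C", "T:A>C:G"), c("A", "G", "T:A>C:G"),
    c("T", "A", "T:A>A:T"), c("A", "T", "T:A>A:T"),
    c("T", "G", "T:A>G:C"), c("A", "C", "T:A>G:C"))
  tab[tab[, 1] == ref & tab[, 2] == alt, 3]
}

# weighted median by direct definition: smallest value whose cumulative
# weight reaches half the total
weighted_median_for_test <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  x[which(cumsum(w) >= sum(w) / 2)[1]]
}

random_pileup <- function() {
  n <- sample(1:50, 1)
  list(ref = sample(c("A", "C", "G", "T"), 1),
       bases = sample(c("A", "C", "G", "T"), n, replace = TRUE,
                      prob = c(0.4, 0.3, 0.2, 0.1)),
       quals = sample(5:40, n, replace = TRUE))
}
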