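# Independent oracles and fixture builders shared across tests.

# Brute-force ERM tail probability: sum the split law over all splits of
# n with larger side >= l.
brute_tail <- function(l, r) {
  n <- l + r
  ks <- seq(ceiling(n / 2), n - 1)
  sum(vapply(ks[ks >= l], function(k)
    if (2 * k == n) 1 / (n - 1) else 2 / (n - 1), 0))
}

# Brute-force 2-state Markov likelihood: enumerate every internal-state
# assignment.
brute_mk_loglik <- function(ct, coding, rates, prior = c(0.5, 0.5)) {
  phy <- ct$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  states <- as.integer(coding[phy$tip.label])
  P <- lapply(seq_len(nrow(phy$edge)), function(i)
    paleoshift:::mk_pmat(rates[1], rates[2], phy$edge.length[i]))
  internal <- (ntip + 1):nn
  tot <- 0
  for (mask in 0:(2^length(internal) - 1)) {
    s <- integer(nn)
    s[seq_len(ntip)] <- states
    s[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1), 1)
    lik <- prior[s[ntip + 1] + 1]
    for (i in seq_len(nrow(phy$edge)))
      lik <- lik * P[[i]][s[phy$edge[i, 1]] + 1, s[phy$edge[i, 2]] + 1]
    tot <- tot + lik
  }
  log(tot)
}

# Brute-force marginal ancestral probabilities by enumeration.
brute_mk_marginals <- function(ct, coding, rates, prior = c(0.5, 0.5)) {
  phy <- ct$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  states <- as.integer(coding[phy$tip.label])
  P <- lapply(seq_len(nrow(phy$edge)), function(i)
    paleoshift:::mk_pmat(rates[1], rates[2], phy$edge.length[i]))
  internal <- (ntip + 1):nn
  acc <- matrix(0, nn, 2)
  for (mask in 0:(2^length(internal) - 1)) {
    s <- integer(nn)
    s[seq_len(ntip)] <- states
    s[internal] <- bitwAnd(bitwShiftR(mask, seq_along(internal) - 1), 1)
    lik <- prior[s[ntip + 1] + 1]
    for (i in seq_len(nrow(phy$edge)))
      lik <- lik * P[[i]][s[phy$edge[i, 1]] + 1, s[phy$edge[i, 2]] + 1]
    acc[cbind(seq_len(nn), s + 1)] <- acc[cbind(seq_len(nn), s + 1)] + lik
  }
  acc / rowSums(acc)
}

# Random calibrated fixture: random topology, fads/lads drawn in a window.
random_calibrated <- function(n, min_branch = 1, window = c(250, 320)) {
  tr <- ape::rtree(n)
  tr$edge.length <- NULL
  fads <- sort(stats::runif(n, window[1], window[2]), decreasing = TRUE)
  rg <- data.frame(taxon = tr$tip.label, fad = fads,
                   lad = fads - stats::runif(n, 0, 20),
                   stringsAsFactors = FALSE)
  rg$lad <- pmax(rg$lad, 0)
  calibrate(tr, rg, min_branch = min_branch)
}

# Larger root-side tip count of a simulated topology, independent of the
# package's subtree-size helpers (reverse sweep over the edge matrix).
root_larger_side_of <- function(tr, n) {
  cnt <- c(rep(1L, n), integer(n - 1L))
  e <- tr$edge
  for (i in rev(seq_len(nrow(e)))) cnt[e[i, 1]] <- cnt[e[i, 1]] + cnt[e[i, 2]]
  kid <- e[e[, 1] == n + 1L, 2]
  max(cnt[kid])
}

# Tip set of a clade key
key_tips <- function(key) strsplit(key, "|", fixed = TRUE)[[1]]

# Graph distance between two nodes on a tree (edges)
node_distance <- function(phy, a, b) {
  p2 <- phy
  p2$edge.length <- rep(1, nrow(phy$edge))
  d <- ape::dist.nodes(p2)
  d[a, b]
}

mrca_of_tips <- function(phy, tips) {
  if (length(tips) == 1) which(phy$tip.label == tips)
  else ape::getMRCA(phy, tips)
}
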