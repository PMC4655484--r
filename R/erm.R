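#' @useDynLib paleoshift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Equal-rates-Markov split probability
#'
#' Probability, under the equal-rates Markov (ERM) model of clade growth,
#' that the root split of a clade of \code{l + r} tips partitions them into
#' unordered sides of sizes \code{l} and \code{r}: \code{2/(n-1)} for unequal
#' sides, \code{1/(n-1)} for an even split (\code{n = l + r}).
#'
#' @param l,r Tip counts on the two sides of the split (order irrelevant).
#' @return Probability of the unordered split \code{(l, r)}.
#' @examples
#' erm_split_probability(1, 4)  # 0.5
#' erm_split_probability(2, 2)  # 1/3
#' @export
erm_split_probability <- function(l, r) {
  stopifnot(length(l) == length(r))
  if (any(l < 1) || any(r < 1)) stop("both sides of a split must have >= 1 tip")
  n <- l + r
  ifelse(l == r, 1 / (n - 1), 2 / (n - 1))
}

#' ERM tail probability of a split at least as asymmetric as observed
#'
#' Sum of \code{\link{erm_split_probability}} over all splits of
#' \code{n = l + r} tips whose larger side has at least \code{l} tips;
#' closed form \code{min(1, 2 (n - l) / (n - 1))} for \code{l >= r}.
#'
#' @inheritParams erm_split_probability
#' @return Tail probability in (0, 1].
#' @export
erm_tail_probability <- function(l, r) {
  if (any(l < 1) || any(r < 1)) stop("both sides of a split must have >= 1 tip")
  if (any(l < r)) stop("l must be the larger side (l >= r)")
  n <- l + r
  pmin(1, 2 * (n - l) / (n - 1))
}

#' Nodal surprise of a diversity partition
#'
#' Negative log ERM tail probability of the observed split; 0 for a
#' maximally balanced partition, growing with asymmetry. This is the
#' building block of the per-node shift statistics.
#'
#' @inheritParams erm_tail_probability
#' @return Non-negative surprise value.
#' @export
nodal_surprise <- function(l, r) {
  -log(erm_tail_probability(l, r))
}

#' Simulate one ERM topology
#'
#' Grows a rooted binary topology by repeatedly splitting a uniformly
#' chosen extant lineage until \code{n} tips exist, so the split sizes at
#' every node follow the ERM split law. Uses R's RNG stream.
#'
#' @param n Number of tips (>= 2).
#' @return An \code{ape} \code{phylo} object (no branch lengths).
#' @export
simulate_erm_topology <- function(n) {
  if (n < 2) stop("n must be >= 2")
  if (n == 2) {
    edge <- matrix(c(3L, 1L, 3L, 2L), ncol = 2, byrow = TRUE)
  } else {
    edge <- erm_topology_edges(as.integer(n))
  }
  phy <- list(edge = edge, tip.label = paste0("t", seq_len(n)),
              Nnode = n - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

# Draw the larger side of an ERM root split of n tips (vectorised).
# P(larger = k) = 2/(n-1) for k in (n/2, n-1]; P(larger = n/2) = 1/(n-1).
erm_draw_larger_side <- function(n, nrep) {
  if (n == 2) return(rep(1L, nrep))
  if (n %% 2 == 0) {
    ks <- seq.int(n / 2, n - 1)
    pr <- c(1, rep(2, length(ks) - 1)) / (n - 1)
  } else {
    ks <- seq.int((n + 1) / 2, n - 1)
    pr <- rep(2 / (n - 1), length(ks))
  }
  if (length(ks) == 1L) rep(ks, nrep) else
    sample(ks, nrep, replace = TRUE, prob = pr)
}

# Null sample of the delta2 statistic at the larger root child of ERM
# trees with n tips. Only the root split and the larger child's own split
# are needed, because conditional on its size a subclade of an ERM tree is
# itself ERM. O(1) per draw.
erm_null_delta2 <- function(n, nrep) {
  if (n < 3) return(numeric(nrep))
  l <- erm_draw_larger_side(n, nrep)
  s_root <- nodal_surprise(l, n - l)
  s_child <- numeric(nrep)
  big <- l >= 3
  for (m in unique(l[big])) {
    idx <- which(l == m)
    l2 <- erm_draw_larger_side(m, length(idx))
    s_child[idx] <- nodal_surprise(l2, m - l2)
  }
  pmax(0, s_root - s_child)
}
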