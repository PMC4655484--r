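#' Per-node shift statistics from tree imbalance
#'
#' For every internal node with at least 3 descendant tips, measures how
#' strongly its diversity partition departs from the equal-rates Markov
#' (ERM) expectation and assigns the statistics to the more speciose child
#' (the branch along which a diversification-rate shift would be
#' inferred): \code{delta1} is the parent split's nodal surprise;
#' \code{delta2} discounts the portion of that surprise explained by
#' imbalance at the scored child itself,
#' \code{max(0, S(parent) - S(child))}, so \code{delta2 <= delta1}.
#'
#' @param phy A binary rooted \code{phylo} with >= 3 tips (or a
#'   \code{calibrated_tree}; only the topology is used).
#' @return A \code{data.frame} with one row per scored node: \code{clade}
#'   (sorted tip labels of the scored child, "|"-separated), \code{node}
#'   (ape node id of the scored child), \code{n} (parent clade size),
#'   \code{l}, \code{r} (parent split sizes), \code{delta1}, \code{delta2}.
#' @export
delta_statistics <- function(phy) {
  if (inherits(phy, "calibrated_tree")) phy <- phy$phy
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("tree must be rooted and binary; resolve polytomies first")
  ntip <- length(phy$tip.label)
  if (ntip < 3) stop("need >= 3 tips to score shifts")
  kids <- children_list(phy)
  tu <- tips_under(phy)
  sizes <- lengths(tu)

  # own-split surprise of every node (0 for tips and cherries)
  surprise <- numeric(ntip + phy$Nnode)
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    ch <- kids[[v]]
    a <- sizes[ch[1]]; b <- sizes[ch[2]]
    surprise[v] <- nodal_surprise(max(a, b), min(a, b))
  }

  rows <- list()
  for (v in (ntip + 1):(ntip + phy$Nnode)) {
    if (sizes[v] < 3) next
    ch <- kids[[v]]
    big <- ch[which.max(sizes[ch])]   # ties: first child, values unaffected
    s_parent <- surprise[v]
    s_child <- if (big > ntip) surprise[big] else 0
    rows[[length(rows) + 1L]] <- data.frame(
      clade = clade_key(phy$tip.label[tu[[big]]]),
      node = big,
      n = sizes[v],
      l = max(sizes[ch]), r = min(sizes[ch]),
      delta1 = s_parent,
      delta2 = max(0, s_parent - s_child),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "tip_labels") <- sort(phy$tip.label)
  out
}

classify_shift <- function(p, alpha = 0.05, alpha_substantial = 0.1) {
  ifelse(p < alpha, "significant",
         ifelse(p < alpha_substantial, "substantial", "none"))
}

#' Monte-Carlo shift p-values under the ERM null
#'
#' For each scored node with parent clade size \code{n}, builds the null
#' distribution of \code{delta2} from \code{n_sims} ERM topologies of
#' \code{n} tips (statistic taken at the larger root child of each) and
#' reports \code{p = (1 + #\{null >= observed\}) / (n_sims + 1)}. Ties
#' count toward the tail, so p-values are conservative and always
#' positive. Null draws exploit the fact that, conditional on its size, a
#' subclade of an ERM tree is itself ERM, so only the two nested splits at
#' the scored node are simulated; null distributions are cached per clade
#' size within one call.
#'
#' @param phy Binary rooted \code{phylo} or \code{calibrated_tree}.
#' @param n_sims Number of null simulations per clade size (>= 100;
#'   default 1e4).
#' @param alpha,alpha_substantial Classification thresholds: p below
#'   \code{alpha} is "significant", p in [alpha, alpha_substantial) is
#'   "substantial", otherwise "none".
#' @param adjust Apply Benjamini-Hochberg correction across scored nodes
#'   before classification (default FALSE: no multiplicity correction).
#' @return The \code{\link{delta_statistics}} table with added columns
#'   \code{p_value} and \code{klass}.
#' @export
shift_pvalues <- function(phy, n_sims = 1e4, alpha = 0.05,
                          alpha_substantial = 0.1, adjust = FALSE) {
  stopifnot(n_sims >= 100)
  ds <- delta_statistics(phy)
  cache <- new.env(parent = emptyenv())
  pv <- numeric(nrow(ds))
  for (i in seq_len(nrow(ds))) {
    key <- as.character(ds$n[i])
    if (is.null(cache[[key]]))
      cache[[key]] <- sort(erm_null_delta2(ds$n[i], n_sims))
    null <- cache[[key]]
    # count null >= observed on the sorted sample
    ge <- n_sims - findInterval(ds$delta2[i] - 1e-12, null)
    pv[i] <- (1 + ge) / (n_sims + 1)
  }
  ds$p_value <- pv
  pk <- if (adjust) stats::p.adjust(pv, "BH") else pv
  ds$klass <- classify_shift(pk, alpha, alpha_substantial)
  attr(ds, "n_sims") <- n_sims
  ds
}

#' Consensus shifts across replicate topologies
#'
#' A shift is retained only if a node subtending the same tip set is
#' significant or substantial in every replicate (e.g. every random
#' polytomy resolution); retained \code{delta1}, \code{delta2} and
#' \code{p_value} are across-replicate means and the class is reassigned
#' from the mean p-value.
#'
#' @param replicate_results List of \code{\link{shift_pvalues}} tables on
#'   identical tip sets.
#' @param alpha,alpha_substantial Classification thresholds.
#' @return A shift table with one row per consensus shift (zero rows when
#'   none survive).
#' @export
consensus_shifts <- function(replicate_results, alpha = 0.05,
                             alpha_substantial = 0.1) {
  stopifnot(length(replicate_results) >= 1)
  tipsets <- lapply(replicate_results, attr, "tip_labels")
  if (length(unique(vapply(tipsets, paste, "", collapse = "|"))) != 1L)
    stop("replicates have different tip sets")
  hit_lists <- lapply(replicate_results,
                      function(r) r[r$klass != "none", , drop = FALSE])
  common <- Reduce(intersect, lapply(hit_lists, `[[`, "clade"))
  if (!length(common)) {
    out <- replicate_results[[1]][0, c("clade", "n", "l", "r",
                                       "delta1", "delta2", "p_value", "klass")]
    return(out)
  }
  rows <- lapply(common, function(cl) {
    recs <- do.call(rbind, lapply(hit_lists,
                                  function(h) h[h$clade == cl, , drop = FALSE]))
    data.frame(clade = cl,
               n = recs$n[1], l = round(mean(recs$l)), r = round(mean(recs$r)),
               delta1 = mean(recs$delta1), delta2 = mean(recs$delta2),
               p_value = mean(recs$p_value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$klass <- classify_shift(out$p_value, alpha, alpha_substantial)
  out[order(out$p_value), , drop = FALSE]
}

#' Write a shift table with a run-metadata header
#'
#' @param shifts A shift table from \code{\link{shift_pvalues}} or
#'   \code{\link{consensus_shifts}}.
#' @param path Output file.
#' @param meta Named character vector recorded as "# key: value" lines.
#' @export
write_shift_table <- function(shifts, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) writeLines(paste0("# ", k, ": ", meta[[k]]), con)
  utils::write.csv(shifts, con, row.names = FALSE)
  invisible(path)
}
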