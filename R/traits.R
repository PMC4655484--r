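#' Read a binary trait coding table
#'
#' Two-column delimited text (\code{taxon}, \code{state}), states 0/1
#' (1 = trait present).
#'
#' @param path Path to the file.
#' @return Named integer vector of states keyed by taxon.
#' @export
read_trait_coding <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (!all(c("taxon", "state") %in% names(tab)))
    stop("trait table needs columns taxon, state")
  if (!all(tab$state %in% c(0, 1)))
    stop("trait states must be binary 0/1")
  if (anyDuplicated(tab$taxon))
    stop("duplicate taxon in trait table")
  stats::setNames(as.integer(tab$state), tab$taxon)
}

# 2-state CTMC transition matrix over duration t (t >= 0).
mk_pmat <- function(q01, q10, t) {
  q <- q01 + q10
  if (q == 0 || t == 0) return(diag(2))
  pi1 <- q01 / q
  pi0 <- 1 - pi1
  e <- exp(-q * t)
  matrix(c(pi0 + pi1 * e, pi1 - pi1 * e,
           pi0 - pi0 * e, pi1 + pi0 * e),
         nrow = 2, byrow = TRUE)
}

mk_root_prior <- function(root_prior, q01, q10) {
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  switch(root_prior,
         uniform = c(0.5, 0.5),
         stationary = if (q01 + q10 == 0) c(0.5, 0.5) else
           c(q10, q01) / (q01 + q10),
         stop("unknown root prior '", root_prior, "'"))
}

# order tip states to tip indices; error on uncoded tips
mk_tip_states <- function(phy, coding) {
  miss <- setdiff(phy$tip.label, names(coding))
  if (length(miss))
    stop("tip(s) lacking a trait coding: ", paste(miss, collapse = ", "))
  states <- coding[phy$tip.label]
  if (!all(states %in% c(0, 1))) stop("trait states must be binary 0/1")
  as.integer(states)
}

# Down (pruning) pass: per-node conditional likelihoods of the data below
# each node given its state, with per-node log scaling factors.
mk_down_pass <- function(phy, durations, states, q01, q10) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  D <- matrix(0, nn, 2)
  logscale <- numeric(nn)
  D[cbind(seq_len(ntip), states + 1L)] <- 1
  kids <- children_list(phy)
  edge_of <- integer(nn)
  edge_of[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  P <- vector("list", nn)
  for (v in phy$edge[, 2]) P[[v]] <- mk_pmat(q01, q10, durations[edge_of[v]])
  for (v in postorder_nodes(phy)) {
    lik <- c(1, 1)
    for (w in kids[[v]]) {
      lik <- lik * as.vector(P[[w]] %*% D[w, ])
      logscale[v] <- logscale[v] + logscale[w]
    }
    m <- max(lik)
    if (m > 0) {
      D[v, ] <- lik / m
      logscale[v] <- logscale[v] + log(m)
    } else {
      D[v, ] <- 0   # data impossible below v for every state
    }
  }
  list(D = D, logscale = logscale, P = P, kids = kids)
}

#' Log-likelihood of binary tip states under a 2-state Markov model
#'
#' Felsenstein pruning over the calibrated tree's branch durations (Ma)
#' with transition rates \code{q01} (gain) and \code{q10} (loss) per Ma.
#' Zero-duration branches use an identity transition matrix; an
#' impossible configuration returns \code{-Inf} rather than erroring.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param coding Named 0/1 vector of tip states.
#' @param rates \code{c(q01, q10)}, both >= 0.
#' @param root_prior \code{"uniform"} (default), \code{"stationary"}, or a
#'   length-2 probability vector.
#' @return Log-likelihood (scalar, possibly \code{-Inf}).
#' @export
mk_loglik <- function(ctree, coding, rates, root_prior = "uniform") {
  stopifnot(inherits(ctree, "calibrated_tree"), length(rates) == 2,
            all(rates >= 0))
  phy <- ctree$phy
  states <- mk_tip_states(phy, coding)
  dp <- mk_down_pass(phy, phy$edge.length, states, rates[1], rates[2])
  root <- length(phy$tip.label) + 1L
  prior <- mk_root_prior(root_prior, rates[1], rates[2])
  lik <- sum(prior * dp$D[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + dp$logscale[root]
}

#' Fit a 2-state Markov model and reconstruct ancestral states
#'
#' Maximises \code{\link{mk_loglik}} over the transition rate(s) by
#' bounded optimisation (equal-rates: 1-D on log scale; all-rates-
#' different: 2-D), then computes marginal ancestral state probabilities
#' at every node by combining the downward conditional likelihoods with
#' an upward pass (equivalent to rerooting at each node).
#'
#' @inheritParams mk_loglik
#' @param model \code{"ER"} (equal rates, default) or \code{"ARD"}.
#' @param upper Upper bound on rates, events per Ma (default 100 over the
#'   tree's root-to-tip span).
#' @return An object of class \code{mk_asr}: list with \code{rates}
#'   (c(q01, q10)), \code{loglik}, \code{model}, \code{root_prior},
#'   \code{anc} (matrix of P(state 0), P(state 1) for all nodes, tips
#'   first) and \code{convergence}.
#' @export
fit_mk <- function(ctree, coding, model = c("ER", "ARD"),
                   root_prior = "uniform", upper = NULL) {
  model <- match.arg(model)
  phy <- ctree$phy
  span <- max(ctree$ages) - min(ctree$ages)
  if (is.null(upper)) upper <- 100 / max(span, 1e-8)
  lo <- log(1e-9)
  hi <- log(upper)
  nll_er <- function(lq) -mk_loglik(ctree, coding, rep(exp(lq), 2), root_prior)
  opt_er <- stats::optimize(nll_er, c(lo, hi), tol = 1e-8)
  if (model == "ER") {
    rates <- rep(exp(opt_er$minimum), 2)
    ll <- -opt_er$objective
    conv <- 0L
  } else {
    nll <- function(lq) -mk_loglik(ctree, coding, exp(lq), root_prior)
    opt <- stats::optim(rep(opt_er$minimum, 2), nll, method = "L-BFGS-B",
                        lower = lo, upper = hi)
    if (opt$convergence != 0)
      warning("ARD optimisation did not converge (code ", opt$convergence,
              "): ", opt$message)
    rates <- exp(opt$par)
    ll <- -opt$value
    conv <- opt$convergence
  }
  anc <- mk_marginals(ctree, coding, rates, root_prior)
  structure(list(rates = rates, loglik = ll, model = model,
                 root_prior = root_prior, anc = anc, convergence = conv),
            class = "mk_asr")
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("mk_asr:", x$model, "model, q01 =", format(x$rates[1], digits = 4),
      ", q10 =", format(x$rates[2], digits = 4),
      ", logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

# Marginal P(state) for every node: up-down algorithm.
mk_marginals <- function(ctree, coding, rates, root_prior = "uniform") {
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  states <- mk_tip_states(phy, coding)
  dp <- mk_down_pass(phy, phy$edge.length, states, rates[1], rates[2])
  prior <- mk_root_prior(root_prior, rates[1], rates[2])
  root <- ntip + 1L
  U <- matrix(0, nn, 2)
  U[root, ] <- prior
  pre <- rev(postorder_nodes(phy))          # parents before children
  edge_of <- integer(nn)
  edge_of[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  for (v in pre) {
    ch <- dp$kids[[v]]
    # M[w, sv] = P(data below w | parent state sv)
    M <- lapply(ch, function(w)
      as.vector(mk_pmat(rates[1], rates[2], phy$edge.length[edge_of[w]]) %*%
                  dp$D[w, ]))
    for (j in seq_along(ch)) {
      w <- ch[j]
      sib <- rep(1, 2)
      for (k in seq_along(ch)) if (k != j) sib <- sib * M[[k]]
      Pw <- mk_pmat(rates[1], rates[2], phy$edge.length[edge_of[w]])
      u <- as.vector(t(Pw) %*% (U[v, ] * sib))
      tot <- sum(u)
      U[w, ] <- if (tot > 0) u / tot else c(0.5, 0.5)
    }
  }
  marg <- U * dp$D
  tot <- rowSums(marg)
  bad <- tot <= 0
  marg[bad, ] <- 0.5
  marg[!bad, ] <- marg[!bad, , drop = FALSE] / tot[!bad]
  dimnames(marg) <- list(c(phy$tip.label, paste0("node", (ntip + 1):nn)),
                         c("p0", "p1"))
  marg
}

#' Partition branches by inferred trait ancestry
#'
#' A branch belongs to the trait group if the node it descends from has
#' marginal P(state 1) above the cutoff, or any of its ancestors does
#' ("descended from" is hereditary by default), or it is the terminal
#' branch of a trait-positive tip. Set \code{hereditary = FALSE} for the
#' strict-state alternative (membership from the parent node's own state
#' only).
#'
#' @param ctree A \code{calibrated_tree}.
#' @param asr An \code{mk_asr} fit on the same tree (or a numeric matrix
#'   of node marginals like its \code{anc} element).
#' @param coding Named 0/1 tip states (used for trait-positive tips).
#' @param cutoff Probability cutoff in (0, 1), default 0.5.
#' @param hereditary Propagate membership to all descendants
#'   (default TRUE).
#' @return List with \code{edge_in_group} (logical per edge of
#'   \code{ctree$phy}) and \code{node_in_group} (logical per node: group
#'   attribution for the cladogenetic event at that node).
#' @export
group_lineages <- function(ctree, asr, coding, cutoff = 0.5,
                           hereditary = TRUE) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must be inside (0, 1)")
  anc <- if (inherits(asr, "mk_asr")) asr$anc else asr
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  if (nrow(anc) != nn) stop("asr does not match the tree")
  pos <- anc[, "p1"] > cutoff
  pos[seq_len(ntip)] <- mk_tip_states(phy, coding) == 1L
  hered <- pos
  if (hereditary) {
    for (v in rev(postorder_nodes(phy))) {
      ch <- phy$edge[phy$edge[, 1] == v, 2]
      hered[ch] <- hered[ch] | hered[v]
    }
  }
  parent_state <- if (hereditary) hered else pos
  edge_in_group <- parent_state[phy$edge[, 1]] |
    (phy$edge[, 2] <= ntip & pos[phy$edge[, 2]])
  node_in_group <- logical(nn)
  node_in_group[phy$edge[, 2]] <- edge_in_group
  node_in_group[ntip + 1L] <- parent_state[ntip + 1L]   # root event
  list(edge_in_group = as.vector(edge_in_group),
       node_in_group = node_in_group)
}

#' Origination-rate series for a trait group and its complement
#'
#' Restricts the per-bin origination accounting to the branches of the
#' trait group (cladogenetic events attributed to the group of the parent
#' branch) and separately to the complement, so that group and complement
#' event and lineage counts sum to the full-tree values in every bin.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param grouping Output of \code{\link{group_lineages}}.
#' @param timescale Timescale \code{data.frame}.
#' @return List of two rate tables, \code{group} and \code{complement},
#'   each with \code{pde}, \code{orig_events} and \code{orig_rate}.
#' @export
group_origination_series <- function(ctree, grouping, timescale) {
  validate_timescale(timescale)
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  li <- lineage_intervals(ctree)           # ordered by origin; has node col
  in_group <- grouping$edge_in_group[match(li$node, phy$edge[, 2])]
  node_ids <- (ntip + 1):(ntip + phy$Nnode)
  node_grp <- grouping$node_in_group[node_ids]
  ob <- event_bin(ctree$ages[node_ids], timescale)
  end_bin <- event_bin(li$end, timescale)
  origin_bin <- event_bin(li$origin, timescale)
  one_side <- function(sel_branch, sel_node) {
    out <- timescale
    out$pde <- vapply(seq_len(nrow(timescale)), function(b) {
      present <- interval_in_bin(li$origin, li$end,
                                 timescale$old_bound[b],
                                 timescale$young_bound[b]) |
        (!is.na(end_bin) & end_bin == b) |
        (!is.na(origin_bin) & origin_bin == b)
      sum(present & sel_branch)
    }, integer(1))
    out$orig_events <- tabulate(ob[sel_node], nbins = nrow(timescale))
    out$orig_rate <- ifelse(out$pde > 0, out$orig_events / out$pde, 0)
    out
  }
  list(group = one_side(in_group, node_grp),
       complement = one_side(!in_group, !node_grp))
}
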