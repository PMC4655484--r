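#' Split geological stages into early/late substage bins
#'
#' Each stage is halved at the midpoint of its duration; substage labels
#' get "-early" / "-late" suffixes. Input stages must be contiguous and
#' ordered old to young.
#'
#' @param stages \code{data.frame} with columns \code{name},
#'   \code{old_bound}, \code{young_bound} (Ma).
#' @return A timescale \code{data.frame} with columns \code{bin},
#'   \code{old_bound}, \code{young_bound}, ordered old to young.
#' @export
make_substage_bins <- function(stages) {
  stopifnot(all(c("name", "old_bound", "young_bound") %in% names(stages)))
  if (any(stages$old_bound <= stages$young_bound))
    stop("every stage must have old_bound > young_bound (zero-duration stage?)")
  if (nrow(stages) > 1) {
    if (any(diff(stages$old_bound) >= 0))
      stop("stages must be ordered old to young")
    gaps <- stages$young_bound[-nrow(stages)] != stages$old_bound[-1]
    if (any(gaps))
      stop("stages have gaps or overlaps at: ",
           paste(stages$name[which(gaps)], collapse = ", "))
  }
  mid <- (stages$old_bound + stages$young_bound) / 2
  out <- data.frame(
    bin = as.vector(rbind(paste0(stages$name, "-early"),
                          paste0(stages$name, "-late"))),
    old_bound = as.vector(rbind(stages$old_bound, mid)),
    young_bound = as.vector(rbind(mid, stages$young_bound)),
    stringsAsFactors = FALSE)
  validate_timescale(out)
  out
}

validate_timescale <- function(ts) {
  stopifnot(all(c("bin", "old_bound", "young_bound") %in% names(ts)))
  if (any(ts$old_bound <= ts$young_bound))
    stop("every bin must have old_bound > young_bound")
  if (nrow(ts) > 1 && any(ts$young_bound[-nrow(ts)] != ts$old_bound[-1]))
    stop("bins must be contiguous and ordered old to young")
  invisible(ts)
}

#' Read a stage table and build substage bins
#'
#' @param path Delimited text file with columns \code{name},
#'   \code{old_bound}, \code{young_bound}.
#' @param substages Halve each stage at its midpoint (default TRUE).
#' @return A timescale \code{data.frame}.
#' @export
read_timescale <- function(path, substages = TRUE) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  if (substages) return(make_substage_bins(tab))
  out <- data.frame(bin = tab$name, old_bound = tab$old_bound,
                    young_bound = tab$young_bound, stringsAsFactors = FALSE)
  validate_timescale(out)
}

# Bin index of point events (ages in Ma). A boundary age belongs to the
# older of the two bins sharing it (young <= age < old); the oldest bin is
# closed at its old bound. Events outside the window get NA.
event_bin <- function(ages, timescale) {
  idx <- rep(NA_integer_, length(ages))
  for (b in seq_len(nrow(timescale))) {
    hit <- ages >= timescale$young_bound[b] & ages < timescale$old_bound[b]
    if (b == 1L) hit <- hit | ages == timescale$old_bound[b]
    hit[is.na(hit)] <- FALSE
    idx[hit & is.na(idx)] <- b
  }
  idx
}

# Positive-duration overlap of age intervals [end, origin] with a bin.
interval_in_bin <- function(origin, end, old_bound, young_bound) {
  pmin(origin, old_bound) - pmax(end, young_bound) > 0
}

#' Prune a calibrated tree to the lineages present in a time bin
#'
#' Retains exactly the tips whose lineage interval (branch origin age down
#' to lad, ghost portion included) intersects the bin with positive
#' duration; unary internal nodes are suppressed and all node ages are
#' kept unchanged. Bins touching a lineage only at a boundary point do not
#' count as presence.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param bin One-row portion of a timescale (or list with
#'   \code{old_bound}, \code{young_bound}).
#' @return A \code{calibrated_tree} for the slice; when fewer than 2
#'   lineages remain, a degenerate object with \code{phy = NULL} and a
#'   \code{tips} element (empty-slice signal, not an error).
#' @export
slice_tree <- function(ctree, bin) {
  stopifnot(inherits(ctree, "calibrated_tree"))
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  parent_of <- integer(ntip)
  parent_of[phy$edge[, 2][phy$edge[, 2] <= ntip]] <-
    phy$edge[, 1][phy$edge[, 2] <= ntip]
  origin <- ctree$ages[parent_of]
  lad <- ctree$ranges$lad
  keep <- interval_in_bin(origin, lad, bin$old_bound, bin$young_bound)
  keep_labels <- phy$tip.label[keep]
  prune_calibrated(ctree, keep_labels)
}

# Prune a calibrated tree to a tip-label subset, preserving node ages.
prune_calibrated <- function(ctree, keep_labels) {
  phy <- ctree$phy
  if (length(keep_labels) < 2) {
    out <- list(phy = NULL, tips = keep_labels,
                ranges = ctree$ranges[ctree$ranges$taxon %in% keep_labels, ,
                                      drop = FALSE])
    class(out) <- c("calibrated_tree")
    return(out)
  }
  sub <- ape::keep.tip(phy, keep_labels)
  ntip_new <- length(sub$tip.label)
  tu_new <- tips_under(sub)
  ages_new <- numeric(ntip_new + sub$Nnode)
  ranges_new <- ctree$ranges[match(sub$tip.label, ctree$ranges$taxon), ,
                             drop = FALSE]
  ages_new[seq_len(ntip_new)] <- ranges_new$lad
  for (v in (ntip_new + 1):(ntip_new + sub$Nnode)) {
    labs <- sub$tip.label[tu_new[[v]]]
    mrca <- if (length(labs) == length(phy$tip.label)) {
      length(phy$tip.label) + 1L
    } else ape::getMRCA(phy, labs)
    ages_new[v] <- ctree$ages[mrca]
  }
  sub$edge.length <- ages_new[sub$edge[, 1]] - ages_new[sub$edge[, 2]]
  out <- list(phy = sub, ages = ages_new, ranges = ranges_new,
              min_branch = ctree$min_branch)
  class(out) <- "calibrated_tree"
  out
}

n_slice_tips <- function(sl) {
  if (is.null(sl$phy)) length(sl$tips) else length(sl$phy$tip.label)
}

#' Mean-delta2 time series from per-bin sliced shift analyses
#'
#' Slices the calibrated tree to every bin of the timescale, runs the
#' shift analysis on each slice, and records the mean \code{delta2} over
#' scored nodes plus the counts of significant and substantial shifts.
#' Bins with fewer than 3 lineages yield mean 0 and zero counts.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param timescale Timescale \code{data.frame}.
#' @param n_sims Null simulations per clade size (see
#'   \code{\link{shift_pvalues}}).
#' @param significant_only Average \code{delta2} over detected shifts only
#'   instead of all scored nodes (default FALSE: all scored nodes, so the
#'   series reflects magnitude and number of shifts jointly).
#' @param ... Passed to \code{\link{shift_pvalues}}.
#' @return \code{data.frame}: \code{bin}, \code{old_bound},
#'   \code{young_bound}, \code{n_tips}, \code{mean_delta2},
#'   \code{n_significant}, \code{n_substantial}.
#' @export
delta2_series <- function(ctree, timescale, n_sims = 1e4,
                          significant_only = FALSE, ...) {
  validate_timescale(timescale)
  out <- timescale
  out$n_tips <- 0L
  out$mean_delta2 <- 0
  out$n_significant <- 0L
  out$n_substantial <- 0L
  for (b in seq_len(nrow(timescale))) {
    sl <- slice_tree(ctree, timescale[b, ])
    nt <- n_slice_tips(sl)
    out$n_tips[b] <- nt
    if (nt < 3) next
    res <- shift_pvalues(sl, n_sims = n_sims, ...)
    out$n_significant[b] <- sum(res$klass == "significant")
    out$n_substantial[b] <- sum(res$klass == "substantial")
    keep <- if (significant_only) res$klass != "none" else
      rep(TRUE, nrow(res))
    out$mean_delta2[b] <- if (any(keep)) mean(res$delta2[keep]) else 0
  }
  out
}
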