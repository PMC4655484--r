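#' Lineage intervals of a calibrated tree
#'
#' One interval per branch, in Ma: origin = parent-node age, end = child
#' age (a tip's lad, or the child node's age for internal branches).
#' Terminal intervals also carry the observed range [fad, lad]; the
#' portion between origin and fad is the ghost lineage.
#'
#' @param ctree A \code{calibrated_tree}.
#' @return \code{data.frame}: \code{node} (child node id), \code{origin},
#'   \code{end}, \code{terminal}, \code{fad}, \code{lad} (NA for internal
#'   branches).
#' @export
lineage_intervals <- function(ctree) {
  stopifnot(inherits(ctree, "calibrated_tree"))
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  child <- phy$edge[, 2]
  terminal <- child <= ntip
  out <- data.frame(
    node = child,
    origin = ctree$ages[phy$edge[, 1]],
    end = ctree$ages[child],
    terminal = terminal,
    fad = ifelse(terminal, ctree$ranges$fad[child], NA_real_),
    lad = ifelse(terminal, ctree$ranges$lad[child], NA_real_))
  out[order(-out$origin), , drop = FALSE]
}

#' Phylogenetic diversity estimate (PDE) per time bin
#'
#' Counts the lineage intervals (ghost lineages and range extensions
#' included) present in each bin: positive-duration intersection, or an
#' origination/termination event assigned to the bin.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param timescale Timescale \code{data.frame}.
#' @return Integer vector of per-bin lineage counts.
#' @export
pde_series <- function(ctree, timescale) {
  validate_timescale(timescale)
  li <- lineage_intervals(ctree)
  end_bin <- event_bin(li$end, timescale)
  origin_bin <- event_bin(li$origin, timescale)
  vapply(seq_len(nrow(timescale)), function(b) {
    present <- interval_in_bin(li$origin, li$end,
                               timescale$old_bound[b],
                               timescale$young_bound[b]) |
      (!is.na(end_bin) & end_bin == b) |
      (!is.na(origin_bin) & origin_bin == b)
    sum(present)
  }, integer(1))
}

#' Raw per-bin origination and extinction rates
#'
#' Origination events are cladogeneses (internal-node ages) assigned to a
#' bin; extinction events are tip lads assigned to a bin, excluding tips
#' whose lad sits at the study window's young edge (extant at window
#' close). Rates divide events by the bin's PDE; bins with PDE 0 get rate
#' 0. Boundary events belong to the older bin.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param timescale Timescale \code{data.frame}.
#' @param window_close Age treated as the study window's young edge
#'   (default: the youngest bin bound).
#' @return \code{data.frame}: \code{bin}, \code{old_bound},
#'   \code{young_bound}, \code{pde}, \code{orig_events},
#'   \code{ext_events}, \code{orig_rate}, \code{ext_rate}.
#' @export
raw_rates <- function(ctree, timescale,
                      window_close = min(timescale$young_bound)) {
  validate_timescale(timescale)
  ntip <- length(ctree$phy$tip.label)
  node_ages <- ctree$ages[(ntip + 1):length(ctree$ages)]
  lads <- ctree$ranges$lad
  extinct <- lads > window_close
  ob <- event_bin(node_ages, timescale)
  eb <- event_bin(lads[extinct], timescale)
  out <- timescale
  out$pde <- pde_series(ctree, timescale)
  out$orig_events <- tabulate(ob, nbins = nrow(timescale))
  out$ext_events <- tabulate(eb, nbins = nrow(timescale))
  out$orig_rate <- ifelse(out$pde > 0, out$orig_events / out$pde, 0)
  out$ext_rate <- ifelse(out$pde > 0, out$ext_events / out$pde, 0)
  out
}

#' Per-bin sampling proportion from ghost lineages
#'
#' For each bin, classifies every lineage crossing it as observed (some
#' tip's [fad, lad] range intersects the bin along that branch) or ghost
#' (ghost segment of a terminal branch, or any internal branch, which
#' carries no observed range by definition) and returns
#' observed / (observed + ghost). Bins with no lineages get 1.
#'
#' @inheritParams pde_series
#' @return Numeric vector of per-bin sampling proportions in [0, 1].
#' @export
sampling_proportion <- function(ctree, timescale) {
  validate_timescale(timescale)
  li <- lineage_intervals(ctree)
  point_bin <- event_bin(ifelse(li$terminal & li$fad == li$lad,
                                li$fad, NA_real_), timescale)
  vapply(seq_len(nrow(timescale)), function(b) {
    old <- timescale$old_bound[b]; young <- timescale$young_bound[b]
    present <- interval_in_bin(li$origin, li$end, old, young)
    if (!any(present)) return(1)
    observed <- li$terminal &
      (interval_in_bin(li$fad, li$lad, old, young) |
         (!is.na(point_bin) & point_bin == b))
    n_obs <- sum(present & observed)
    n_obs / sum(present)
  }, numeric(1))
}

#' Sampling-corrected rate series with mass-extinction flags
#'
#' Applies a pluggable sampling correction to the raw rates. The default
#' damps each bin's rates by its sampling proportion (discounting bins
#' where ghost lineages dominate); \code{"identity"} leaves rates
#' unchanged; a \code{function(rate, s)} may be supplied. Mass-extinction
#' flags are computed from the corrected extinction rate.
#'
#' @param raw Output of \code{\link{raw_rates}}.
#' @param s Per-bin sampling proportions (from
#'   \code{\link{sampling_proportion}}).
#' @param correction \code{"damp"} (default), \code{"identity"}, or a
#'   function of (rate, s).
#' @param threshold Mass-extinction threshold on the corrected extinction
#'   rate (strictly above; default 0.30).
#' @return The rate table with columns \code{sampling},
#'   \code{orig_rate}, \code{ext_rate} (corrected) and \code{mass_ext}.
#' @export
corrected_rates <- function(raw, s, correction = "damp", threshold = 0.30) {
  if (length(s) != nrow(raw)) stop("sampling series length mismatch")
  fn <- if (is.function(correction)) correction
  else switch(correction,
              damp = function(rate, s) rate * s,
              identity = function(rate, s) rate,
              stop("unknown correction '", correction, "'"))
  out <- raw
  out$sampling <- s
  out$orig_rate <- fn(raw$orig_rate, s)
  out$ext_rate <- fn(raw$ext_rate, s)
  out$mass_ext <- mass_extinction_flags(out$ext_rate, threshold)
  out
}

#' Mass-extinction indicator series
#'
#' Flag = 1 for bins whose extinction rate is strictly above the
#' threshold (default 30 percent), else 0.
#'
#' @param ext_rate Numeric vector of per-bin extinction rates.
#' @param threshold Proportion threshold (default 0.30).
#' @return Integer 0/1 vector.
#' @export
mass_extinction_flags <- function(ext_rate, threshold = 0.30) {
  stopifnot(all(ext_rate >= 0))
  as.integer(ext_rate > threshold)
}

#' Full rate series for one calibrated tree
#'
#' Convenience wrapper: raw rates + sampling proportion + correction +
#' mass-extinction flags.
#'
#' @inheritParams raw_rates
#' @inheritParams corrected_rates
#' @return Rate table as in \code{\link{corrected_rates}}.
#' @export
rate_series <- function(ctree, timescale, correction = "damp",
                        threshold = 0.30,
                        window_close = min(timescale$young_bound)) {
  raw <- raw_rates(ctree, timescale, window_close)
  s <- sampling_proportion(ctree, timescale)
  corrected_rates(raw, s, correction, threshold)
}

#' Element-wise mean of rate (or delta2) series across trees
#'
#' @param series_list List of equal-shape \code{data.frame}s on one
#'   timescale (e.g. per polytomy-resolution replicate).
#' @return A single \code{data.frame} with numeric columns averaged;
#'   \code{mass_ext} (if present) is re-flagged from the mean extinction
#'   rate via the attribute \code{threshold} (default 0.30).
#' @param threshold Mass-extinction threshold applied to the mean
#'   extinction rate.
#' @export
mean_over_trees <- function(series_list, threshold = 0.30) {
  stopifnot(length(series_list) >= 1)
  first <- series_list[[1]]
  for (s in series_list[-1]) {
    if (nrow(s) != nrow(first) ||
        any(s$old_bound != first$old_bound) ||
        any(s$young_bound != first$young_bound))
      stop("series are not on the same timescale")
  }
  out <- first
  num <- vapply(first, is.numeric, logical(1)) &
    !names(first) %in% c("old_bound", "young_bound")
  for (col in names(first)[num]) {
    out[[col]] <- rowMeans(vapply(series_list, `[[`, numeric(nrow(first)),
                                  col))
  }
  if ("mass_ext" %in% names(out))
    out$mass_ext <- mass_extinction_flags(out$ext_rate, threshold)
  out
}
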