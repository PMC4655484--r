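#' Read a flat key=value run configuration file
#'
#' Unknown keys are kept; numeric-looking values are converted.
#'
#' @param path Text file of \code{key=value} lines (\code{#} comments
#'   allowed).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  pos <- regexpr("=", lines, fixed = TRUE)
  bad <- pos < 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(substr(lines, 1, pos - 1))
  vals <- trimws(substring(lines, pos + 1))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (is.na(n)) v else n
  })
  names(out) <- keys
  out
}

default_config <- function() {
  list(n_polytomy_replicates = 10, n_sims = 1e4,
       alpha = 0.05, alpha_substantial = 0.1,
       mass_ext_threshold = 0.30, correction = "damp",
       min_branch = 1, seed = 1)
}

#' Run the full shift/rate analysis pipeline
#'
#' Composition of all stages in order: read inputs, resolve polytomies
#' into replicate topologies, time-calibrate, whole-tree shift detection
#' with consensus across replicates, substage time slicing into the
#' mean-delta2 series, origination/extinction/sampling rate series
#' (means across replicates), optional trait ancestral-state
#' reconstruction with per-group origination series, and GLS +
#' random-forest model comparison of the delta2 series against the rate
#' series. All tables are written to \code{out_dir} as CSV with seeds in
#' the log; any stage failure aborts with the stage named, preserving
#' the outputs already written.
#'
#' @param config Named list or path to a key=value config file. Required
#'   keys: \code{tree}, \code{ranges}, \code{timescale} (paths);
#'   optional: \code{traits} (path),
#'   \code{n_polytomy_replicates} (10), \code{n_sims} (1e4),
#'   \code{alpha} (0.05), \code{alpha_substantial} (0.1),
#'   \code{mass_ext_threshold} (0.30), \code{correction} ("damp"),
#'   \code{min_branch} (1), \code{seed} (1), \code{out_dir}.
#' @param out_dir Output directory (overrides config).
#' @return Invisibly, a list with the main result tables.
#' @export
run_full_analysis <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("out_dir must be given")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(..., "\n", file = logf, append = TRUE,
                               sep = "")
  cat("", file = logf)
  logline("paleoshift ", as.character(utils::packageVersion("paleoshift")))
  for (k in names(cfg)) logline("config ", k, "=", paste(cfg[[k]],
                                                         collapse = ","))
  stage <- function(name, expr) {
    logline("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- stage("read-inputs", {
    list(phy = read_tree(cfg$tree),
         ranges = read_taxon_ranges(cfg$ranges),
         timescale = read_timescale(cfg$timescale),
         traits = if (!is.null(cfg$traits)) read_trait_coding(cfg$traits))
  })
  reps <- stage("resolve-polytomies",
                resolve_polytomies(inputs$phy, cfg$n_polytomy_replicates,
                                   seed = cfg$seed))
  ctrees <- stage("calibrate",
                  lapply(reps, calibrate, ranges = inputs$ranges,
                         min_branch = cfg$min_branch))

  shift_tabs <- stage("shifts", {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(cfg$seed + 1)
    lapply(ctrees, function(ct)
      shift_pvalues(ct, n_sims = cfg$n_sims, alpha = cfg$alpha,
                    alpha_substantial = cfg$alpha_substantial))
  })
  consensus <- stage("consensus", consensus_shifts(
    shift_tabs, cfg$alpha, cfg$alpha_substantial))
  write_shift_table(consensus, file.path(cfg$out_dir, "shifts_consensus.csv"),
                    meta = c(seed = cfg$seed, n_sims = cfg$n_sims,
                             n_replicates = length(ctrees)))

  d2 <- stage("time-slices", {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(cfg$seed + 2)
    mean_over_trees(lapply(ctrees, delta2_series,
                           timescale = inputs$timescale,
                           n_sims = cfg$n_sims, alpha = cfg$alpha,
                           alpha_substantial = cfg$alpha_substantial),
                    threshold = cfg$mass_ext_threshold)
  })
  utils::write.csv(d2, file.path(cfg$out_dir, "delta2_series.csv"),
                   row.names = FALSE)

  rates <- stage("rates", mean_over_trees(
    lapply(ctrees, rate_series, timescale = inputs$timescale,
           correction = cfg$correction,
           threshold = cfg$mass_ext_threshold),
    threshold = cfg$mass_ext_threshold))
  utils::write.csv(rates, file.path(cfg$out_dir, "rate_series.csv"),
                   row.names = FALSE)

  groups <- NULL
  if (!is.null(inputs$traits)) {
    groups <- stage("traits", {
      asr <- fit_mk(ctrees[[1]], inputs$traits)
      grp <- group_lineages(ctrees[[1]], asr, inputs$traits)
      gs <- group_origination_series(ctrees[[1]], grp, inputs$timescale)
      utils::write.csv(gs$group,
                       file.path(cfg$out_dir, "group_orig_rates.csv"),
                       row.names = FALSE)
      utils::write.csv(gs$complement,
                       file.path(cfg$out_dir, "complement_orig_rates.csv"),
                       row.names = FALSE)
      list(asr = asr, series = gs)
    })
  }

  comparison <- stage("model-comparison", compare_models(d2, rates))
  utils::write.csv(comparison,
                   file.path(cfg$out_dir, "model_comparison.csv"),
                   row.names = FALSE)
  rf <- stage("random-forest", rf_importance(
    d2$mean_delta2,
    data.frame(origination = rates$orig_rate, extinction = rates$ext_rate,
               mass_extinction = rates$mass_ext),
    seed = cfg$seed + 3))
  utils::write.csv(cbind(rf, variance_explained =
                           attr(rf, "variance_explained")),
                   file.path(cfg$out_dir, "rf_importance.csv"),
                   row.names = FALSE)

  stage("plots", {
    grDevices::pdf(file.path(cfg$out_dir, "summary_plots.pdf"),
                   width = 7, height = 9)
    on.exit(grDevices::dev.off(), add = TRUE)
    mid <- (d2$old_bound + d2$young_bound) / 2
    graphics::par(mfrow = c(3, 1), mar = c(4, 4, 2, 4))
    plot2 <- function(y1, y2, lab1, lab2, main) {
      graphics::plot(mid, y1, type = "l", xlim = rev(range(mid)),
                     xlab = "Age (Ma)", ylab = lab1, main = main)
      graphics::par(new = TRUE)
      graphics::plot(mid, y2, type = "l", lty = 2, axes = FALSE,
                     xlab = "", ylab = "", xlim = rev(range(mid)))
      graphics::axis(4)
      graphics::mtext(lab2, side = 4, line = 2, cex = 0.7)
    }
    plot2(rates$pde, d2$mean_delta2, "PDE", "mean delta2",
          "Diversity vs shift magnitude")
    plot2(rates$ext_rate, d2$mean_delta2, "extinction rate", "mean delta2",
          "Extinction vs shift magnitude")
    if (!is.null(groups)) {
      graphics::plot(mid, groups$series$group$orig_rate, type = "l",
                     xlim = rev(range(mid)), xlab = "Age (Ma)",
                     ylab = "origination rate",
                     main = "Trait group vs complement origination")
      graphics::lines(mid, groups$series$complement$orig_rate, lty = 2)
    }
  })
  logline("done")
  invisible(list(consensus = consensus, delta2 = d2, rates = rates,
                 groups = groups, comparison = comparison,
                 rf = rf, out_dir = cfg$out_dir))
}
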