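#' Specify a synthetic fossil-phylogeny scenario
#'
#' Collects the parameters of the forward birth-death simulation: base
#' speciation/extinction rates (events per lineage per Ma), the study
#' window in Ma (old > young), optional clade rate shifts (at a trigger
#' time one extant lineage and all its descendants switch rates),
#' optional instantaneous extinction pulses with trait-state-dependent
#' survival probabilities, binary-trait transition rates and the fossil
#' sampling rate (samples per lineage per Ma).
#'
#' @param lambda,mu Base speciation and extinction rates (per Ma).
#' @param window \code{c(old, young)} ages in Ma.
#' @param shifts List of \code{list(time =, lambda =, mu =)} entries.
#' @param pulses List of \code{list(time =, survival = c(s0, s1))}
#'   entries; \code{s0}/\code{s1} are survival probabilities for
#'   trait-absent/-present lineages.
#' @param q01,q10 Trait gain/loss rates (per Ma).
#' @param sampling_rate Fossil sampling rate r (per lineage per Ma).
#' @param seed Integer seed.
#' @return A \code{scenario_spec} list.
#' @export
scenario_spec <- function(lambda, mu, window, shifts = list(),
                          pulses = list(), q01 = 0, q10 = 0,
                          sampling_rate = 1, seed = 1) {
  stopifnot(lambda >= 0, mu >= 0, q01 >= 0, q10 >= 0, sampling_rate >= 0,
            length(window) == 2, window[1] > window[2])
  for (s in shifts)
    stopifnot(!is.null(s$time), s$lambda >= 0, s$mu >= 0,
              s$time < window[1], s$time > window[2])
  for (p in pulses)
    stopifnot(!is.null(p$time), length(p$survival) == 2,
              all(p$survival >= 0 & p$survival <= 1),
              p$time < window[1], p$time > window[2])
  structure(list(lambda = lambda, mu = mu, window = window,
                 shifts = shifts, pulses = pulses, q01 = q01, q10 = q10,
                 sampling_rate = sampling_rate, seed = seed),
            class = "scenario_spec")
}

#' Simulate a complete fossil birth-death tree
#'
#' Continuous-time birth-death simulation over the study window starting
#' from an initial split into two lineages at the window's old edge.
#' Binary trait states evolve along lineages (rates \code{q01},
#' \code{q10}); at each extinction pulse every extant lineage survives
#' independently with its trait-state survival probability; at each shift
#' trigger one uniformly chosen extant lineage (and its descendants)
#' switches to the shift's rates. All lineages, extinct included, are
#' returned with their true ages.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param use_seed Seed the RNG from \code{spec$seed} (default TRUE; set
#'   FALSE to draw within an existing RNG stream).
#' @return A \code{calibrated_tree} of the true tree (tip ranges: fad =
#'   branch origin, lad = true end), with extra elements
#'   \code{tip_states}, \code{node_states}, \code{extant} (named logical),
#'   \code{shift_tips} (tip labels of the true shifted clade, if any) and
#'   attribute \code{extinct_before_end}.
#' @export
simulate_bd_tree <- function(spec, use_seed = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (use_seed) {
    old_rng <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old_rng))
    set.seed(spec$seed)
  }
  t_old <- spec$window[1]; t_young <- spec$window[2]
  lam <- c(spec$lambda, vapply(spec$shifts, `[[`, 0, "lambda"))
  mus <- c(spec$mu, vapply(spec$shifts, `[[`, 0, "mu"))
  sched <- data.frame(
    time = c(vapply(spec$shifts, `[[`, 0, "time"),
             vapply(spec$pulses, `[[`, 0, "time")),
    type = rep(c("shift", "pulse"),
               c(length(spec$shifts), length(spec$pulses))),
    idx = c(seq_along(spec$shifts), seq_along(spec$pulses)))
  sched <- sched[order(-sched$time), , drop = FALSE]

  N <- 1024L
  parent <- integer(N); birth <- numeric(N); endage <- numeric(N)
  state <- integer(N); klass <- integer(N); nkid <- integer(N)
  state_end <- integer(N); extant <- logical(N)
  grow <- function(n_used) {
    while (n_used > length(parent)) {
      parent <<- c(parent, integer(N)); birth <<- c(birth, numeric(N))
      endage <<- c(endage, numeric(N)); state <<- c(state, integer(N))
      klass <<- c(klass, integer(N)); nkid <<- c(nkid, integer(N))
      state_end <<- c(state_end, integer(N))
      extant <<- c(extant, logical(N))
      N <<- length(parent)
    }
  }
  root_state <- if (spec$q01 + spec$q10 > 0) {
    stats::rbinom(1, 1, spec$q01 / (spec$q01 + spec$q10))
  } else 0L
  n_lin <- 2L
  parent[1:2] <- 0L; birth[1:2] <- t_old
  state[1:2] <- root_state; klass[1:2] <- 1L
  alive <- c(1L, 2L)
  cur <- t_old
  shift_lineage <- NA_integer_
  si <- 1L

  while (length(alive) && cur > t_young) {
    q_i <- ifelse(state[alive] == 0L, spec$q01, spec$q10)
    haz <- lam[klass[alive]] + mus[klass[alive]] + q_i
    total <- sum(haz)
    t_next <- if (total > 0) cur - stats::rexp(1, total) else -Inf
    next_sched <- if (si <= nrow(sched)) sched$time[si] else -Inf
    if (max(next_sched, t_young) > t_next) {
      if (t_young >= next_sched) { cur <- t_young; break }
      cur <- next_sched
      if (sched$type[si] == "shift") {
        pick <- alive[sample.int(length(alive), 1)]
        klass[pick] <- 1L + sched$idx[si]
        shift_lineage <- pick
      } else {
        surv <- spec$pulses[[sched$idx[si]]]$survival
        p_surv <- surv[state[alive] + 1L]
        died <- stats::runif(length(alive)) > p_surv
        for (v in alive[died]) {
          endage[v] <- cur; state_end[v] <- state[v]
        }
        alive <- alive[!died]
      }
      si <- si + 1L
      next
    }
    cur <- t_next
    pick_j <- sample.int(length(alive), 1, prob = haz)
    v <- alive[pick_j]
    kind <- sample.int(3L, 1, prob = c(lam[klass[v]], mus[klass[v]],
                                       q_i[pick_j]))
    if (kind == 1L) {               # speciation
      grow(n_lin + 2L)
      ch <- n_lin + 1:2
      parent[ch] <- v; birth[ch] <- cur; state[ch] <- state[v]
      klass[ch] <- klass[v]
      n_lin <- n_lin + 2L
      endage[v] <- cur; state_end[v] <- state[v]; nkid[v] <- 2L
      alive <- c(alive[-pick_j], ch)
    } else if (kind == 2L) {        # extinction
      endage[v] <- cur; state_end[v] <- state[v]
      alive <- alive[-pick_j]
    } else {                        # trait flip
      state[v] <- 1L - state[v]
    }
  }
  for (v in alive) {
    endage[v] <- t_young; state_end[v] <- state[v]; extant[v] <- TRUE
  }
  idx <- seq_len(n_lin)
  out <- bd_lineages_to_tree(parent[idx], birth[idx], endage[idx],
                             nkid[idx], state_end[idx], extant[idx],
                             t_old, shift_lineage)
  attr(out, "extinct_before_end") <- length(alive) == 0
  out
}

# Assemble the lineage arrays into a calibrated_tree with true ranges.
bd_lineages_to_tree <- function(parent, birth, endage, nkid, state_end,
                                extant, t_old, shift_lineage) {
  n_lin <- length(parent)
  is_tip <- nkid == 0L
  ntip <- sum(is_tip)
  tip_id <- integer(n_lin); node_id <- integer(n_lin)
  tip_id[is_tip] <- seq_len(ntip)
  node_id[!is_tip] <- ntip + 1L + seq_len(sum(!is_tip))  # root = ntip+1
  endpoint <- ifelse(is_tip, tip_id, node_id)
  startpoint <- ifelse(parent == 0L, ntip + 1L, node_id[pmax(parent, 1L)])
  edge <- cbind(startpoint, endpoint)
  ages <- numeric(ntip + sum(!is_tip) + 1L)
  ages[ntip + 1L] <- t_old
  ages[endpoint] <- endage
  labels <- paste0("t", which(is_tip))
  phy <- list(edge = unname(edge), tip.label = labels,
              Nnode = ntip - 1L,
              edge.length = ages[edge[, 1]] - ages[edge[, 2]])
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  ranges <- data.frame(taxon = labels,
                       fad = birth[is_tip], lad = endage[is_tip],
                       stringsAsFactors = FALSE)
  shift_tips <- character()
  if (!is.na(shift_lineage)) {
    desc <- shift_lineage
    repeat {
      more <- which(parent %in% desc & !(seq_len(n_lin) %in% desc))
      if (!length(more)) break
      desc <- c(desc, more)
    }
    shift_tips <- paste0("t", intersect(which(is_tip), desc))
  }
  out <- list(phy = phy, ages = ages, ranges = ranges, min_branch = 0,
              tip_states = stats::setNames(state_end[is_tip], labels),
              node_states = state_end[!is_tip],
              extant = stats::setNames(extant[is_tip], labels),
              shift_tips = shift_tips)
  class(out) <- "calibrated_tree"
  out
}

#' Simulate a binary trait history along a calibrated tree
#'
#' Forward 2-state Markov simulation: the root state is drawn from the
#' stationary distribution (uniform when both rates are 0) and each
#' node/tip state is drawn from the branch transition probabilities of
#' its parent state.
#'
#' @param ctree A \code{calibrated_tree}.
#' @param q01,q10 Gain/loss rates per Ma.
#' @param seed Optional integer seed.
#' @param root_state Optional fixed root state (0/1) overriding the
#'   stationary draw.
#' @return List with \code{tip_states} (named) and \code{node_states}
#'   (vector over all nodes, tips first).
#' @export
simulate_trait_history <- function(ctree, q01, q10, seed = NULL,
                                   root_state = NULL) {
  stopifnot(q01 >= 0, q10 >= 0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  phy <- ctree$phy
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  states <- integer(nn)
  root <- ntip + 1L
  states[root] <- if (!is.null(root_state)) as.integer(root_state)
  else if (q01 + q10 > 0) stats::rbinom(1, 1, q01 / (q01 + q10))
  else stats::rbinom(1, 1, 0.5)
  edge_of <- integer(nn)
  edge_of[phy$edge[, 2]] <- seq_len(nrow(phy$edge))
  for (v in rev(postorder_nodes(phy))) {
    for (w in phy$edge[phy$edge[, 1] == v, 2]) {
      P <- mk_pmat(q01, q10, phy$edge.length[edge_of[w]])
      states[w] <- stats::rbinom(1, 1, P[states[v] + 1L, 2])
    }
  }
  list(tip_states = stats::setNames(states[seq_len(ntip)], phy$tip.label),
       node_states = states)
}

#' Simulate incomplete fossil sampling of a true tree
#'
#' Each terminal branch accrues Poisson(\code{r} per Ma) sampling events
#' uniformly over its duration; a taxon's observed fad/lad are its
#' extreme sample ages, unsampled tips are dropped and the topology is
#' pruned accordingly. Lineages extant at the window close are
#' additionally recorded there with probability \code{rho} (the standard
#' sampling-at-present convention), so their observed lad equals the
#' window's young edge and the extant-at-window-close rule of
#' \code{\link{raw_rates}} can identify them. The output feeds
#' \code{\link{calibrate}}.
#'
#' @param true_tree A \code{calibrated_tree} from
#'   \code{\link{simulate_bd_tree}}.
#' @param r Sampling rate (per lineage per Ma, >= 0).
#' @param seed Optional integer seed.
#' @param rho Probability that a lineage extant at the window close is
#'   recorded there (default 1).
#' @return List with \code{topology} (pruned \code{phylo}, no branch
#'   lengths), \code{ranges} (observed fad/lad table) and
#'   \code{n_sampled}; fewer than 2 sampled taxa is flagged via
#'   \code{n_sampled}, not an error.
#' @export
simulate_fossil_sampling <- function(true_tree, r, seed = NULL, rho = 1) {
  stopifnot(r >= 0, rho >= 0, rho <= 1)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old))
    set.seed(seed)
  }
  phy <- true_tree$phy
  ntip <- length(phy$tip.label)
  parent_of <- integer(ntip)
  term <- phy$edge[, 2] <= ntip
  parent_of[phy$edge[term, 2]] <- phy$edge[term, 1]
  origin <- true_tree$ages[parent_of]
  lad_true <- true_tree$ranges$lad
  extant <- if (!is.null(true_tree$extant))
    true_tree$extant[phy$tip.label] else rep(FALSE, ntip)
  fads <- lads <- rep(NA_real_, ntip)
  for (i in seq_len(ntip)) {
    dur <- origin[i] - lad_true[i]
    k <- stats::rpois(1, r * dur)
    samp <- if (k > 0) stats::runif(k, lad_true[i], origin[i]) else numeric()
    if (extant[i] && stats::runif(1) <= rho)
      samp <- c(samp, lad_true[i])
    if (length(samp)) {
      fads[i] <- max(samp); lads[i] <- min(samp)
    }
  }
  sampled <- which(!is.na(fads))
  ranges <- data.frame(taxon = phy$tip.label[sampled],
                       fad = fads[sampled], lad = lads[sampled],
                       stringsAsFactors = FALSE)
  topo <- if (length(sampled) >= 2) {
    tp <- ape::keep.tip(phy, phy$tip.label[sampled])
    tp$edge.length <- NULL
    tp
  } else NULL
  list(topology = topo, ranges = ranges, n_sampled = length(sampled))
}

preset_parameters <- function(preset) {
  switch(preset,
    "erm-null" = list(lambda = 0.06, mu = 0.03, q = 0.02, r = 1.0,
                      shifts = list(), pulses = list()),
    "clade-shift" = list(lambda = 0.04, mu = 0.01, q = 0.02, r = 1.5,
                         shifts = list(list(time = 282, lambda = 0.20,
                                            mu = 0.01)),
                         pulses = list()),
    "trait-buffered-pulse" = list(lambda = 0.10, mu = 0.04, q = 0.02,
                                  r = 1.2, shifts = list(),
                                  pulses = list(list(time = 287,
                                                     survival = c(0.2, 0.8)))),
    stop("unknown preset '", preset, "'"))
}

default_stage_table <- function(window = c(320, 260), stage_dur = 10) {
  olds <- seq(window[1], window[2] + stage_dur, by = -stage_dur)
  data.frame(name = paste0("S", seq_along(olds)),
             old_bound = olds, young_bound = olds - stage_dur,
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic dataset bundle from a named preset
#'
#' Presets: \code{"erm-null"} (homogeneous rates), \code{"clade-shift"}
#' (one clade switches to 5x the base speciation rate at 282 Ma) and
#' \code{"trait-buffered-pulse"} (an extinction pulse at 287 Ma that
#' trait-positive lineages survive with probability 0.8 vs 0.2 for
#' trait-negative ones, followed by renewed cladogenesis among
#' survivors). All presets run over a 320-260 Ma window with 10-Ma
#' stages halved into 5-Ma substage bins. Simulations that go totally
#' extinct or leave fewer than \code{min_tips} sampled taxa are redrawn
#' from a derived seed (attempts recorded in the manifest).
#'
#' @param preset Preset name.
#' @param seed Integer seed; the same seed reproduces the bundle
#'   byte-identically.
#' @param dir Optional directory: writes \code{tree.nwk},
#'   \code{ranges.csv}, \code{traits.csv}, \code{timescale.csv} and
#'   \code{manifest.txt}.
#' @param min_tips Minimum sampled taxa for a usable draw (default 20).
#' @return List: \code{true_tree}, \code{topology}, \code{ranges},
#'   \code{traits} (named 0/1 vector for sampled taxa), \code{stages},
#'   \code{timescale}, \code{manifest} (named list), \code{paths} (when
#'   written).
#' @export
scenario_generator <- function(preset, seed = 1, dir = NULL, min_tips = 20) {
  pars <- preset_parameters(preset)
  window <- c(320, 260)
  stages <- default_stage_table(window)
  timescale <- make_substage_bins(stages)
  attempt <- 0L
  repeat {
    attempt <- attempt + 1L
    if (attempt > 100L) stop("no viable simulation in 100 attempts")
    sub_seed <- (seed * 1009L + attempt * 7919L) %% .Machine$integer.max
    spec <- scenario_spec(pars$lambda, pars$mu, window,
                          shifts = pars$shifts, pulses = pars$pulses,
                          q01 = pars$q, q10 = pars$q,
                          sampling_rate = pars$r, seed = sub_seed)
    true_tree <- simulate_bd_tree(spec)
    samp <- simulate_fossil_sampling(true_tree, pars$r,
                                     seed = sub_seed + 1L)
    shift_ok <- !length(pars$shifts) ||
      sum(true_tree$shift_tips %in% samp$ranges$taxon) >= 3
    if (samp$n_sampled >= min_tips && shift_ok) break
  }
  traits <- true_tree$tip_states[samp$ranges$taxon]
  manifest <- list(preset = preset, seed = seed, attempts = attempt,
                   sub_seed = sub_seed,
                   lambda = pars$lambda, mu = pars$mu,
                   q01 = pars$q, q10 = pars$q, sampling_rate = pars$r,
                   window_old = window[1], window_young = window[2],
                   n_true_tips = length(true_tree$phy$tip.label),
                   n_sampled = samp$n_sampled,
                   shift_time = if (length(pars$shifts))
                     pars$shifts[[1]]$time else NA,
                   shift_lambda = if (length(pars$shifts))
                     pars$shifts[[1]]$lambda else NA,
                   pulse_time = if (length(pars$pulses))
                     pars$pulses[[1]]$time else NA,
                   pulse_survival_0 = if (length(pars$pulses))
                     pars$pulses[[1]]$survival[1] else NA,
                   pulse_survival_1 = if (length(pars$pulses))
                     pars$pulses[[1]]$survival[2] else NA,
                   shift_tips = paste(intersect(true_tree$shift_tips,
                                                samp$ranges$taxon),
                                      collapse = "|"))
  bundle <- list(true_tree = true_tree, topology = samp$topology,
                 ranges = samp$ranges, traits = traits, stages = stages,
                 timescale = timescale, manifest = manifest)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(tree = file.path(dir, "tree.nwk"),
                  ranges = file.path(dir, "ranges.csv"),
                  traits = file.path(dir, "traits.csv"),
                  timescale = file.path(dir, "timescale.csv"),
                  manifest = file.path(dir, "manifest.txt"))
    ape::write.tree(samp$topology, paths$tree)
    utils::write.csv(samp$ranges, paths$ranges, row.names = FALSE)
    utils::write.csv(data.frame(taxon = names(traits), state = traits),
                     paths$traits, row.names = FALSE)
    utils::write.csv(stages, paths$timescale, row.names = FALSE)
    writeLines(paste0(names(manifest), "=",
                      vapply(manifest, as.character, "")),
               paths$manifest)
    bundle$paths <- paths
  }
  bundle
}
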