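test_that("scenario specs validate their parameters", {
  expect_s3_class(scenario_spec(0.1, 0.05, c(320, 260)), "scenario_spec")
  expect_error(scenario_spec(-0.1, 0.05, c(320, 260)))
  expect_error(scenario_spec(0.1, 0.05, c(260, 320)))
  expect_error(scenario_spec(0.1, 0.05, c(320, 260),
                             pulses = list(list(time = 280,
                                                survival = c(0.5, 1.2)))))
})

test_that("pure-birth trees have all tips extant at window close", {
  spec <- scenario_spec(0.15, 0, c(300, 280), seed = 3)
  tt <- simulate_bd_tree(spec)
  expect_true(all(tt$extant))
  expect_true(all(tt$ranges$lad == 280))
  expect_false(attr(tt, "extinct_before_end"))
  expect_true(ape::is.binary(tt$phy))
  expect_true(all(tt$phy$edge.length >= 0))
})

test_that("Yule growth matches its expectation", {
  # E[tips] = 2 exp(lambda T); lambda = 0.3, T = 10 from 2 lineages
  set.seed(71)
  sizes <- replicate(500, {
    spec <- scenario_spec(0.3, 0, c(10, 0), seed = sample.int(1e8, 1))
    length(simulate_bd_tree(spec)$phy$tip.label)
  })
  expected <- 2 * exp(0.3 * 10)
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("a 5x speciation clade outgrows its sister lineages", {
  set.seed(72)
  ratio <- replicate(40, {
    spec <- scenario_spec(0.04, 0.01, c(320, 260),
                          shifts = list(list(time = 282, lambda = 0.2,
                                             mu = 0.01)),
                          seed = sample.int(1e8, 1))
    tt <- simulate_bd_tree(spec)
    n_shift <- length(tt$shift_tips)
    n_rest <- length(tt$phy$tip.label) - n_shift
    c(n_shift, n_rest)
  })
  expect_gt(mean(ratio[1, ]), mean(ratio[2, ]))
})

test_that("trait histories respect degenerate and stationary limits", {
  set.seed(73)
  spec <- scenario_spec(0.12, 0.02, c(320, 280), seed = 5)
  tt <- simulate_bd_tree(spec)
  h0 <- simulate_trait_history(tt, 0, 0, seed = 1, root_state = 0)
  expect_true(all(h0$tip_states == 0))
  # very fast evolution: tip frequencies near the stationary distribution
  h <- simulate_trait_history(tt, 3, 1, seed = 2)
  expect_lt(abs(mean(h$tip_states) - 0.75), 0.15)
})

test_that("fossil sampling truncates ranges and prunes unsampled tips", {
  set.seed(74)
  spec <- scenario_spec(0.12, 0.05, c(320, 270), seed = 9)
  tt <- simulate_bd_tree(spec)
  # very dense sampling recovers the true ranges (tips with near-zero
  # terminal durations can still be missed)
  dense <- simulate_fossil_sampling(tt, 200, seed = 1)
  expect_gte(dense$n_sampled, length(tt$phy$tip.label) - 2)
  i <- match(dense$ranges$taxon, tt$ranges$taxon)
  expect_lt(max(abs(dense$ranges$lad - tt$ranges$lad[i])), 0.2)
  # r = 0: extant-at-close lineages are still recorded there (rho = 1)
  none <- simulate_fossil_sampling(tt, 0, seed = 2)
  expect_equal(sort(none$ranges$taxon),
               sort(names(which(tt$extant))))
  expect_true(all(none$ranges$fad == none$ranges$lad))
  # ... and nothing at all without present-day sampling
  empty <- simulate_fossil_sampling(tt, 0, seed = 2, rho = 0)
  expect_equal(empty$n_sampled, 0)
  expect_null(empty$topology)
  # sparser sampling lowers the sampling proportion on average
  ts <- make_substage_bins(paleoshift:::default_stage_table(c(320, 270)))
  mean_s <- function(r, seeds) mean(vapply(seeds, function(s) {
    samp <- simulate_fossil_sampling(tt, r, seed = s)
    if (samp$n_sampled < 3) return(NA_real_)
    ct <- calibrate(samp$topology, samp$ranges, min_branch = 1)
    mean(sampling_proportion(ct, ts))
  }, 0), na.rm = TRUE)
  expect_gt(mean_s(2, 1:15), mean_s(0.3, 1:15))
})

test_that("scenario bundles are deterministic and round-trip the readers", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  b1 <- scenario_generator("erm-null", seed = 4, dir = d1)
  b2 <- scenario_generator("erm-null", seed = 4, dir = d2)
  for (f in c("tree.nwk", "ranges.csv", "traits.csv", "timescale.csv",
              "manifest.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # different seed, different data
  b3 <- scenario_generator("erm-null", seed = 5)
  expect_false(identical(b1$ranges, b3$ranges))

  # round trip through the chrono readers
  phy <- read_tree(file.path(d1, "tree.nwk"))
  expect_setequal(phy$tip.label, b1$ranges$taxon)
  rg <- read_taxon_ranges(file.path(d1, "ranges.csv"))
  expect_equal(rg$fad, b1$ranges$fad, tolerance = 1e-12)
  ts <- read_timescale(file.path(d1, "timescale.csv"))
  expect_equal(ts, b1$timescale)
  tc <- read_trait_coding(file.path(d1, "traits.csv"))
  expect_equal(unname(tc), unname(b1$traits))
  # manifest carries the truth needed for recovery checks
  expect_true(all(c("lambda", "mu", "seed", "n_sampled") %in%
                    names(b1$manifest)))
  expect_error(scenario_generator("no-such-preset", 1), "unknown preset")
})

test_that("generated bundles calibrate cleanly", {
  for (preset in c("erm-null", "clade-shift", "trait-buffered-pulse")) {
    b <- scenario_generator(preset, seed = 8)
    ct <- calibrate(b$topology, b$ranges, min_branch = 1)
    expect_gte(length(ct$phy$tip.label), 20)
    expect_true(all(ct$phy$edge.length >= 0))
    ntip <- length(ct$phy$tip.label)
    term <- ct$phy$edge[, 2] <= ntip
    ghost <- ct$ages[ct$phy$edge[term, 1]] -
      ct$ranges$fad[ct$phy$edge[term, 2]]
    expect_true(all(ghost >= -1e-9))
  }
})
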