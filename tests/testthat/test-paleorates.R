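two_tip_fixture <- function() {
  phy <- ape::read.tree(text = "(A,B);")
  rg <- data.frame(taxon = c("A", "B"), fad = c(300, 300),
                   lad = c(290, 280))
  calibrate(phy, rg, min_branch = 0)
}

test_that("lineage intervals cover every branch with correct spans", {
  ct <- two_tip_fixture()
  li <- lineage_intervals(ct)
  expect_equal(nrow(li), 2)             # 2n - 2 branches
  expect_equal(li$origin, c(300, 300))
  expect_equal(sort(li$end), c(280, 290))
  expect_true(all(li$terminal))

  set.seed(77)
  ct2 <- random_calibrated(12, min_branch = 1)
  li2 <- lineage_intervals(ct2)
  expect_equal(nrow(li2), 2 * 12 - 2)
  expect_true(all(li2$origin >= li2$end))
  # ghost portion: origin >= fad for terminal branches
  expect_true(all(li2$origin[li2$terminal] >= li2$fad[li2$terminal] - 1e-9))
})

test_that("PDE counts lineages per bin, ghost portions included", {
  ct <- two_tip_fixture()
  ts <- data.frame(bin = c("b1", "b2", "b3"),
                   old_bound = c(300, 290, 275),
                   young_bound = c(290, 275, 270))
  expect_equal(pde_series(ct, ts), c(2L, 1L, 0L))
  # PDE >= taxic count (observed ranges only) in every bin
  set.seed(19)
  for (i in 1:8) {
    ct2 <- random_calibrated(sample(5:25, 1))
    span <- range(c(ct2$ages, ct2$ranges$lad))
    bounds <- seq(span[2] + 1, span[1] - 1, length.out = 6)
    ts2 <- data.frame(bin = paste0("b", 1:5), old_bound = bounds[-6],
                      young_bound = bounds[-1])
    pde <- pde_series(ct2, ts2)
    taxic <- vapply(1:5, function(b)
      sum(pmin(ct2$ranges$fad, ts2$old_bound[b]) -
            pmax(ct2$ranges$lad, ts2$young_bound[b]) > 0), 0L)
    expect_true(all(pde >= taxic))
  }
})

test_that("raw rates divide counted events by PDE with edge rules", {
  ct <- two_tip_fixture()
  ts <- data.frame(bin = c("b1", "b2"), old_bound = c(300, 290),
                   young_bound = c(290, 280))
  rr <- raw_rates(ct, ts)
  # root split at 300 is the only origination, in the oldest (closed) bin
  expect_equal(rr$orig_events, c(1L, 0L))
  expect_equal(rr$orig_rate, c(0.5, 0))
  # A dies at 290 (older-bin rule -> b1); B's lad sits at the window edge
  expect_equal(rr$ext_events, c(1L, 0L))
  expect_equal(rr$ext_rate, c(0.5, 0))

  # all tips surviving to window close: no extinctions anywhere
  phy <- ape::read.tree(text = "((A,B),C);")
  rg <- data.frame(taxon = c("A", "B", "C"), fad = c(300, 295, 298),
                   lad = c(280, 280, 280))
  ct2 <- calibrate(phy, rg, min_branch = 0)
  rr2 <- raw_rates(ct2, ts)
  expect_true(all(rr2$ext_events == 0))
  expect_true(all(rr2$ext_rate == 0))
})

test_that("event totals across bins match tree-wide counts", {
  set.seed(53)
  for (i in 1:8) {
    ct <- random_calibrated(sample(6:30, 1), min_branch = 1)
    span <- range(c(ct$ages, ct$ranges$lad))
    bounds <- seq(span[2] + 0.5, span[1] - 0.5, length.out = 9)
    ts <- data.frame(bin = paste0("b", 1:8), old_bound = bounds[-9],
                     young_bound = bounds[-1])
    rr <- raw_rates(ct, ts)
    ntip <- length(ct$phy$tip.label)
    expect_equal(sum(rr$orig_events), ct$phy$Nnode)
    expect_equal(sum(rr$ext_events),
                 sum(ct$ranges$lad > min(ts$young_bound)))
    expect_true(all(rr$ext_rate <= 1 & rr$ext_rate >= 0))
  }
})

test_that("sampling proportion classifies observed vs ghost segments", {
  # complete sampling: fad equals branch origin everywhere
  phy <- ape::read.tree(text = "(A,B);")
  rg <- data.frame(taxon = c("A", "B"), fad = c(300, 300),
                   lad = c(280, 280))
  ct <- calibrate(phy, rg, min_branch = 0)
  ts <- data.frame(bin = c("b1", "b2"), old_bound = c(300, 290),
                   young_bound = c(290, 280))
  expect_equal(sampling_proportion(ct, ts), c(1, 1))

  # 2 observed ranges + 2 pure-ghost terminal crossings -> 0.5
  phy4 <- ape::read.tree(text = "((A,C),(B,D));")
  rg4 <- data.frame(taxon = c("A", "C", "B", "D"),
                    fad = c(300, 285, 300, 285),
                    lad = c(280, 280, 280, 280))
  ct4 <- calibrate(phy4, rg4, min_branch = 0)
  s4 <- sampling_proportion(ct4, data.frame(
    bin = "b", old_bound = 295, young_bound = 290))
  expect_equal(s4, 0.5)
  # empty bin -> 1 by convention
  expect_equal(sampling_proportion(ct4, data.frame(
    bin = "b", old_bound = 260, young_bound = 250)), 1)
})

test_that("corrections damp rates by sampling and flag mass extinctions", {
  raw <- data.frame(bin = c("b1", "b2", "b3"),
                    old_bound = c(30, 20, 10), young_bound = c(20, 10, 0),
                    pde = c(10L, 10L, 10L), orig_events = c(2L, 0L, 1L),
                    ext_events = c(4L, 1L, 0L),
                    orig_rate = c(0.2, 0, 0.1), ext_rate = c(0.4, 0.1, 0))
  out <- corrected_rates(raw, c(0.5, 1, 1))
  expect_equal(out$ext_rate, c(0.2, 0.1, 0))
  expect_equal(out$orig_rate, c(0.1, 0, 0.1))
  expect_equal(out$mass_ext, c(0L, 0L, 0L))
  # identity correction leaves rates alone; flags use the 30% rule
  out2 <- corrected_rates(raw, c(0.5, 1, 1), correction = "identity")
  expect_equal(out2$ext_rate, raw$ext_rate)
  expect_equal(out2$mass_ext, c(1L, 0L, 0L))
  expect_error(corrected_rates(raw, c(1, 1)), "mismatch")

  expect_equal(mass_extinction_flags(c(0.35, 0.30, 0.05)), c(1L, 0L, 0L))
  # corrected never exceeds raw; equality iff s = 1
  s <- c(0.3, 1, 0.8)
  out3 <- corrected_rates(raw, s)
  expect_true(all(out3$ext_rate <= raw$ext_rate + 1e-12))
  expect_equal(out3$ext_rate[2], raw$ext_rate[2])
})

test_that("series means across trees are element-wise", {
  ct <- two_tip_fixture()
  ts <- data.frame(bin = c("b1", "b2"), old_bound = c(300, 290),
                   young_bound = c(290, 280))
  r1 <- rate_series(ct, ts)
  expect_equal(mean_over_trees(list(r1))$ext_rate, r1$ext_rate)
  r2 <- r1
  r2$ext_rate <- r1$ext_rate + 0.2
  m <- mean_over_trees(list(r1, r2))
  expect_equal(m$ext_rate, r1$ext_rate + 0.1)
  expect_equal(mean_over_trees(rep(list(r1), 100))$orig_rate, r1$orig_rate)
  bad <- r1
  bad$old_bound[1] <- 299
  expect_error(mean_over_trees(list(r1, bad)), "timescale")
})
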