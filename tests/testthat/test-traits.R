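test_that("Mk likelihood limits behave", {
  phy <- ape::read.tree(text = "(A,B);")
  rg <- data.frame(taxon = c("A", "B"), fad = c(300, 300),
                   lad = c(280, 280))
  ct <- calibrate(phy, rg, min_branch = 0)
  # rates -> 0 with identical states: only the root prior remains
  expect_equal(mk_loglik(ct, c(A = 0, B = 0), c(1e-12, 1e-12)),
               log(0.5), tolerance = 1e-6)
  # zero rates with conflicting states: impossible, -Inf not an error
  expect_identical(mk_loglik(ct, c(A = 0, B = 1), c(0, 0)), -Inf)
  # saturation: states independent of the tree
  expect_equal(mk_loglik(ct, c(A = 0, B = 1), c(50, 50)),
               2 * log(0.5), tolerance = 1e-6)
  expect_error(mk_loglik(ct, c(A = 0), c(0.1, 0.1)), "lacking")
})

test_that("pruning equals brute-force enumeration over a rate grid", {
  set.seed(5)
  grid <- list(c(0.01, 0.01), c(0.05, 0.2), c(0.3, 0.02))
  for (i in 1:12) {
    ct <- random_calibrated(sample(3:6, 1),
                            min_branch = stats::runif(1, 0.5, 3))
    cod <- stats::setNames(stats::rbinom(length(ct$phy$tip.label), 1, 0.5),
                           ct$phy$tip.label)
    for (q in grid) {
      expect_equal(mk_loglik(ct, cod, q), brute_mk_loglik(ct, cod, q),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant under tip reordering", {
  set.seed(6)
  ct <- random_calibrated(7, min_branch = 1)
  cod <- stats::setNames(c(1, 0, 1, 1, 0, 0, 1), ct$phy$tip.label)
  ll <- mk_loglik(ct, cod, c(0.04, 0.09))
  expect_equal(mk_loglik(ct, cod[sample(names(cod))], c(0.04, 0.09)), ll)
})

test_that("marginal reconstructions match enumeration and fix tips", {
  set.seed(9)
  ct <- random_calibrated(5, min_branch = 1)
  cod <- stats::setNames(c(1, 1, 0, 0, 1), ct$phy$tip.label)
  marg <- paleoshift:::mk_marginals(ct, cod, c(0.05, 0.08))
  oracle <- brute_mk_marginals(ct, cod, c(0.05, 0.08))
  expect_equal(unname(marg), oracle, tolerance = 1e-10)
  expect_true(all(abs(rowSums(marg) - 1) < 1e-12))
  # coded tips are certain
  expect_equal(unname(marg[1:5, "p1"]), c(1, 1, 0, 0, 1))
})

test_that("fitted Mk models behave on degenerate and symmetric data", {
  phy <- ape::read.tree(text = "((A,B),(C,D));")
  rg <- data.frame(taxon = c("A", "B", "C", "D"), fad = rep(300, 4),
                   lad = rep(280, 4))
  ct <- calibrate(phy, rg, min_branch = 1)
  # monomorphic data: rate pinned near zero, ancestors certain
  fit0 <- fit_mk(ct, c(A = 0, B = 0, C = 0, D = 0))
  expect_lt(fit0$rates[1], 1e-4)
  expect_true(all(fit0$anc[5:7, "p0"] > 0.999))
  # symmetric 2-tip case: root marginals are (0.5, 0.5)
  phy2 <- ape::read.tree(text = "(A,B);")
  ct2 <- calibrate(phy2, rg[1:2, ], min_branch = 0)
  fit2 <- fit_mk(ct2, c(A = 0, B = 1))
  expect_equal(unname(fit2$anc[3, ]), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("ER fit agrees with an independent Mk implementation", {
  skip_if_not_installed("phytools")
  set.seed(14)
  spec <- scenario_spec(0.08, 0.02, c(320, 260), q01 = 0.03, q10 = 0.03,
                        seed = 11)
  tt <- simulate_bd_tree(spec)
  fit <- fit_mk(tt, tt$tip_states)
  ref <- phytools::fitMk(tt$phy, factor(tt$tip_states[tt$phy$tip.label]),
                         model = "ER", pi = "equal")
  expect_equal(fit$rates[1], unname(ref$rates), tolerance = 1e-4)
  expect_equal(fit$loglik, ref$logLik, tolerance = 1e-6)
})

test_that("rate recovery from forward-simulated histories", {
  set.seed(21)
  fits <- replicate(20, {
    spec <- scenario_spec(0.12, 0.03, c(320, 240), seed = sample.int(1e7, 1))
    tt <- simulate_bd_tree(spec, use_seed = TRUE)
    if (length(tt$phy$tip.label) < 40) return(NA_real_)
    h <- simulate_trait_history(tt, 0.02, 0.02)
    fit_mk(tt, h$tip_states)$rates[1]
  })
  fits <- fits[!is.na(fits)]
  expect_gt(length(fits), 5)
  expect_lt(abs(log(median(fits) / 0.02)), log(2))  # within a factor of 2
})

test_that("lineage groups are hereditary and partition the events", {
  # hand fixture: trait fixed in one subclade
  phy <- ape::read.tree(text = "(((A,B),C),(D,E));")
  rg <- data.frame(taxon = c("A", "B", "C", "D", "E"),
                   fad = c(300, 298, 296, 299, 297),
                   lad = c(285, 280, 282, 280, 281))
  ct <- calibrate(phy, rg, min_branch = 1)
  cod <- c(A = 1, B = 1, C = 0, D = 0, E = 0)
  # deterministic reconstruction: the trait is certain only at the A+B node
  ntip <- 5
  tu <- paleoshift:::tips_under(ct$phy)
  ab_node <- which(vapply(tu, function(x)
    identical(ct$phy$tip.label[x], c("A", "B")), logical(1)))
  anc <- matrix(c(1, 0), ntip + ct$phy$Nnode, 2, byrow = TRUE,
                dimnames = list(NULL, c("p0", "p1")))
  anc[ab_node, ] <- c(0, 1)
  grp <- group_lineages(ct, anc, cod)
  # the A+B cherry branches are in the group; D/E side is not
  edges_in <- ct$phy$edge[grp$edge_in_group, 2]
  expect_true(all(c(1, 2) %in% edges_in))        # tips A, B
  expect_false(any(c(4, 5) %in% edges_in))       # tips D, E
  # hereditary: all-0 codings give an empty group
  grp0 <- group_lineages(ct, fit_mk(ct, c(A = 0, B = 0, C = 0, D = 0,
                                          E = 0)),
                         c(A = 0, B = 0, C = 0, D = 0, E = 0))
  expect_false(any(grp0$edge_in_group))
  # trait fixed at root: everything in the group
  all1 <- c(A = 1, B = 1, C = 1, D = 1, E = 1)
  grp1 <- group_lineages(ct, fit_mk(ct, all1), all1)
  expect_true(all(grp1$edge_in_group))
  expect_error(group_lineages(ct, anc, cod, cutoff = 1.2), "cutoff")

  ts <- data.frame(bin = c("b1", "b2"), old_bound = c(302, 292),
                   young_bound = c(292, 279))
  gs <- group_origination_series(ct, grp, ts)
  full <- raw_rates(ct, ts)
  expect_equal(gs$group$orig_events + gs$complement$orig_events,
               full$orig_events)
  expect_equal(gs$group$pde + gs$complement$pde, full$pde)
  # empty group: group series all zero, complement equals the full tree
  gs0 <- group_origination_series(ct, grp0, ts)
  expect_true(all(gs0$group$orig_events == 0))
  expect_equal(gs0$complement$orig_events, full$orig_events)
  # whole-tree group: complement all zero
  gs1 <- group_origination_series(ct, grp1, ts)
  expect_true(all(gs1$complement$orig_events == 0))
})

test_that("trait codings read from disk and validate", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("taxon,state", "A,1", "B,0"), f)
  tc <- read_trait_coding(f)
  expect_equal(tc, c(A = 1L, B = 0L))
  writeLines(c("taxon,state", "A,2"), f)
  expect_error(read_trait_coding(f), "binary")
})
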