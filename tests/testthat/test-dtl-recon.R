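test_that("congruent trees reconcile at zero cost with no events", {
  g <- ape::read.tree(text = "((a,b),c);")
  s <- toy_species()
  r <- reconcile_rooted(g, s, toy_map)
  expect_equal(r$cost, 0)
  expect_equal(nrow(enumerate_events(r)), 0)
  expect_equal(unname(r$counts[c("duplication", "transfer", "loss")]),
               c(0L, 0L, 0L))
})

test_that("a single discordant leaf is explained by one transfer", {
  g <- ape::read.tree(text = "((a,c),b);")
  s <- toy_species()
  r <- reconcile_rooted(g, s, toy_map)
  expect_equal(r$cost, 3) # one transfer at default costs
  ev <- enumerate_events(r)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "transfer")
  # donor and recipient species branches must be incomparable
  d <- strsplit(ev$donor, ",")[[1]]
  rcp <- strsplit(ev$recipient, ",")[[1]]
  expect_false(all(d %in% rcp) || all(rcp %in% d))
  expect_equal(brute_force_reconcile(g, s, toy_map)$cost, 3)
})

test_that("same-species cherry needs a duplication; TL mode is infeasible", {
  g <- ape::read.tree(text = "((a1,a2),b);")
  s <- toy_species()
  map <- c(a1 = "A", a2 = "A", b = "B")
  expect_equal(reconcile_rooted(g, s, map)$cost, 2)
  tl <- reconcile_rooted(g, s, map, event_costs(tl_only = TRUE))
  expect_false(tl$feasible)
  expect_identical(tl$cost, Inf)
  expect_error(enumerate_events(tl), "infeasible")
})

test_that("DP agrees with the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:120) {
    inst <- rand_instance(6)
    cs <- rand_costs()
    dp <- reconcile_rooted(inst$gene, inst$species, inst$map, cs)
    bf <- brute_force_reconcile(inst$gene, inst$species, inst$map, cs)
    if (is.finite(dp$cost) || is.finite(bf$cost)) {
      expect_equal(dp$cost, bf$cost, tolerance = 1e-9)
    } else {
      expect_identical(is.finite(dp$cost), is.finite(bf$cost))
    }
  }
})

test_that("unrooted reconciliation equals the minimum over all rootings", {
  set.seed(203)
  for (i in 1:15) {
    inst <- rand_instance(6)
    g <- ape::unroot(inst$gene)
    ru <- reconcile_unrooted(g, inst$species, inst$map)
    per_rooting <- vapply(enumerate_rootings(g), function(tr) {
      reconcile_rooted(tr, inst$species, inst$map)$cost
    }, numeric(1))
    expect_equal(ru$cost, min(per_rooting), tolerance = 1e-9)
    expect_length(ru$rooting_costs, nrow(g$edge))
  }
  # any 3-leaf single-copy family has a congruent rooting
  s <- toy_species()
  g3 <- ape::read.tree(text = "(a,b,c);")
  expect_equal(reconcile_unrooted(g3, s, toy_map)$cost, 0)
})

test_that("optimal cost is monotone in each event cost", {
  set.seed(204)
  for (i in 1:25) {
    inst <- rand_instance(5)
    base <- event_costs(1, 1, 1)
    c0 <- brute_force_reconcile(inst$gene, inst$species, inst$map, base)$cost
    for (bump in list(event_costs(2, 1, 1), event_costs(1, 2, 1),
                      event_costs(1, 1, 2))) {
      c1 <- brute_force_reconcile(inst$gene, inst$species, inst$map,
                                  bump)$cost
      expect_gte(c1, c0 - 1e-12)
    }
  }
})

test_that("TL-mode cost dominates default-cost optimum", {
  set.seed(205)
  for (i in 1:25) {
    inst <- rand_instance(6)
    dtl <- reconcile_rooted(inst$gene, inst$species, inst$map,
                            event_costs())$cost
    tl <- reconcile_rooted(inst$gene, inst$species, inst$map,
                           event_costs(tl_only = TRUE))$cost
    expect_gte(tl, dtl - 1e-12)
  }
})

test_that("event records decompose the total cost on simulated families", {
  set.seed(206)
  for (i in 1:15) {
    sp <- simulate_species_tree(15)
    h <- simulate_gene_tree(sp, dtl_rates("high"))
    r <- reconcile_unrooted(h$gene, sp)
    ev <- enumerate_events(r)
    expect_equal(2 * sum(ev$type == "duplication") +
                   3 * sum(ev$type == "transfer") +
                   sum(ev$type == "loss"), r$cost)
    # transfers connect incomparable species branches
    tr <- ev[ev$type == "transfer", ]
    for (j in seq_len(nrow(tr))) {
      d <- strsplit(tr$donor[j], ",")[[1]]
      rcp <- strsplit(tr$recipient[j], ",")[[1]]
      expect_false(all(d %in% rcp) || all(rcp %in% d))
    }
  }
})

test_that("leaf map plumbing works: rules, files and errors", {
  expect_identical(unname(leaf_map(c("S3_1", "S12_2"))), c("S3", "S12"))
  f <- tempfile()
  writeLines(c("g1\tA", "g2\tB"), f)
  expect_identical(unname(read_leaf_map(f)[c("g1", "g2")]), c("A", "B"))
  g <- ape::read.tree(text = "((a,b),c);")
  expect_error(reconcile_rooted(g, toy_species(), c(a = "A", b = "B")),
               "no species mapping")
  expect_error(reconcile_rooted(g, toy_species(),
                                c(a = "A", b = "B", c = "Z")),
               "absent from species tree")
})

test_that("unrooted reconciliation stays fast at benchmark sizes", {
  # the per-rooting DP is O(m^2 n) overall; this guards against an
  # accidental extra factor and against absolute slowness at the sizes
  # the search uses
  set.seed(207)
  sp <- simulate_species_tree(25)
  timings <- vapply(c(50, 200), function(m) {
    g <- ape::rtree(m)
    g$tip.label <- paste0("S", sample(1:25, m, replace = TRUE), "_",
                          seq_len(m))
    map <- leaf_map(g$tip.label)
    t0 <- Sys.time()
    for (k in 1:5) dtl_cost(g, sp, map)
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }, numeric(1))
  expect_lt(timings[2], 2.5) # 5 unrooted reconciliations of 200 leaves
  # 4x leaves: at most ~16x work plus overhead slack
  expect_lt(timings[2] / max(timings[1], 0.02), 40)
})
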