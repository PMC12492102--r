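cherry <- parse_newick("(A:1,B:1);")

test_that("parsimony reconstruction matches enumerable small cases", {
  m <- matrix(c(3L, 3L), 1, dimnames = list("og1", c("A", "B")))
  rec <- reconstruct_counts(cherry, m)
  expect_equal(rec$cost, 0)
  expect_equal(unname(rec$states[1, 3]), 3) # root node

  m2 <- matrix(c(2L, 4L), 1, dimnames = list("og1", c("A", "B")))
  rec2 <- reconstruct_counts(cherry, m2)
  expect_equal(rec2$cost, 2)
  expect_equal(unname(rec2$states[1, 3]), 2) # smallest minimising root state
  ev2 <- compute_events(cherry, rec2)
  expect_equal(sort(ev2$delta), c(0L, 2L))
  expect_equal(ev2$delta[ev2$branch_id == "B"], 2L)

  bal <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  m3 <- matrix(c(0L, 0L, 5L, 5L), 1,
               dimnames = list("og1", c("A", "B", "C", "D")))
  rec3 <- reconstruct_counts(bal, m3)
  expect_equal(rec3$cost, 5)
  expect_equal(unname(rec3$states[1, 5]), 0) # root ties resolved downward

  expect_error(reconstruct_counts(cherry,
    matrix(1L, 1, 1, dimnames = list("og1", "A"))), "mismatch")
})

test_that("parsimony cost equals the exhaustive assignment minimum on random trees", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    phy <- ape::rtree(n)
    phy$edge.length <- rep(1, nrow(phy$edge))
    tr <- as_time_tree(phy)
    counts <- matrix(sample(0:5, n, replace = TRUE), 1,
                     dimnames = list("og1", phy$tip.label))
    rec <- reconstruct_counts(tr, counts)
    expect_equal(rec$cost, sankoff_oracle(phy, counts[1, phy$tip.label]),
                 info = paste("tree", i))
    # the assignment itself realises the minimal cost
    ev <- compute_events(tr, rec)
    expect_equal(sum(abs(ev$delta)), rec$cost)
  }
})

test_that("gains minus losses telescope to leaf minus root along every path", {
  fix <- demo_fixture()
  sim <- simulate_counts(fix$tree, sim_config(seed = 22, n_families = 120))
  rec <- reconstruct_counts(fix$tree, sim$counts)
  ev <- compute_events(fix$tree, rec)
  phy <- fix$tree$phy
  root <- fix$tree$root
  delta_lookup <- stats::setNames(ev$delta, paste(ev$og_id, ev$branch_id))
  parent <- integer(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  for (og in sample(rownames(sim$counts), 15)) {
    for (tip in seq_along(phy$tip.label)) {
      node <- tip; s <- 0L
      while (node != root) {
        s <- s + delta_lookup[[paste(og, fix$tree$branch_id[node])]]
        node <- parent[node]
      }
      expect_equal(s, sim$counts[og, phy$tip.label[tip]] -
                     unname(rec$states[og, root]))
    }
  }
})

test_that("gain/loss rates divide absolute change by summed branch time", {
  tr <- parse_newick("(A:4,B:2);")
  ev <- data.frame(og_id = c("og1", "og1"), branch_id = c("A", "B"),
                   delta = c(2L, 0L))
  expect_equal(gain_loss_rate(ev, tr, branches = "A"), 0.5)
  expect_equal(gain_loss_rate(ev, tr), 2 / 6)

  tr3 <- parse_newick("((A:4,B:2):2,C:1);")
  ids <- branch_ids(tr3)
  ev3 <- data.frame(
    og_id = "og1",
    branch_id = c("A", "B", setdiff(ids, c("A", "B", "C"))),
    delta = c(2L, 1L, 0L))
  expect_equal(gain_loss_rate(ev3, tr3, branches = ev3$branch_id), 3 / 8)
  expect_error(gain_loss_rate(ev, tr, branches = character(0)), "no usable")
})

test_that("rates are invariant to splitting a branch into collinear segments", {
  t1 <- parse_newick("(A:4,B:2);")
  m <- matrix(c(3L, 1L), 1, dimnames = list("og1", c("A", "B")))
  ev1 <- compute_events(t1, reconstruct_counts(t1, m))
  r1 <- gain_loss_rate(ev1, t1, branches = "A")

  t2 <- parse_newick("((A:3):1,B:2);")
  ev2 <- compute_events(t2, reconstruct_counts(t2, m))
  seg_ids <- setdiff(branch_ids(t2), "B")
  r2 <- gain_loss_rate(ev2, t2, branches = seg_ids)
  expect_equal(r1, r2)
  expect_equal(r1, 0.5)
})

test_that("rapid flags reproduce the Poisson tail probabilities", {
  # constructed so the background rate is 0.5 per family per My:
  # lambda = 1 on branch A (2 My), lambda = 2 on branch B (4 My)
  tr <- parse_newick("(A:2,B:4);")
  ev <- data.frame(
    og_id = rep(c("og1", "og2", "og3"), each = 2),
    branch_id = rep(c("A", "B"), 3),
    delta = c(6L, 0L, 0L, 1L, 2L, 0L))
  fl <- flag_rapid_events(ev, tr, alpha = 0.05)
  p1 <- fl$p_event[fl$og_id == "og1" & fl$branch_id == "A"]
  expect_equal(p1, 5.94e-4, tolerance = 1e-3)
  expect_true(fl$rapid[fl$og_id == "og1" & fl$branch_id == "A"])
  p2 <- fl$p_event[fl$og_id == "og2" & fl$branch_id == "B"]
  expect_equal(p2, 1 - exp(-2), tolerance = 1e-9)
  expect_equal(p2, 0.8647, tolerance = 1e-4)
  expect_false(fl$rapid[fl$og_id == "og2" & fl$branch_id == "B"])
  expect_true(all(fl$p_event[fl$delta == 0] == 1))

  silent <- flag_rapid_events(
    data.frame(og_id = "og1", branch_id = c("A", "B"), delta = c(0L, 0L)), tr)
  expect_true(all(silent$p_event == 1))
  expect_false(any(silent$rapid))
})

test_that("parsimony rate tracks the generator's true net-change rate", {
  # At the documented study conditions the parsimony estimate is a strict
  # undercount of the true net-change rate: parallel losses after
  # extinction collapse onto single ancestral branches. The undercount is
  # bounded (below 50% relative error) and stable.
  fix <- demo_fixture()
  sim <- simulate_counts(fix$tree, sim_config(seed = 23, n_families = 800))
  ev <- compute_events(fix$tree, reconstruct_counts(fix$tree, sim$counts))
  est <- gain_loss_rate(ev, fix$tree)
  truth <- gain_loss_rate(sim$events, fix$tree)
  expect_lte(est, truth)
  expect_lt(abs(est - truth) / truth, 0.5)
  expect_gt(est, 0)
})
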