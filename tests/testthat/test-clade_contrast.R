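# Contrast scans over fabricated clades with abstract branch ids.

make_rapid_events <- function(og_id, clade_a, clade_b, rapid_a, rapid_b) {
  br <- c(clade_a$branches, clade_b$branches)
  rapid <- c(seq_along(clade_a$branches) <= rapid_a,
             seq_along(clade_b$branches) <= rapid_b)
  data.frame(og_id = og_id, branch_id = br,
             delta = as.integer(rapid), rapid = rapid,
             stringsAsFactors = FALSE)
}

test_that("rapid-event enrichment reproduces the 2x2 arithmetic", {
  ca <- fake_clade("P", sprintf("a%02d", 1:40))
  cb <- fake_clade("A", sprintf("b%02d", 1:30))
  ev <- rbind(make_rapid_events("og1", ca, cb, 5, 0),
              make_rapid_events("og2", ca, cb, 4, 3),
              make_rapid_events("og3", ca, cb, 0, 0))
  rep <- rapid_enrichment(ev, ca, cb)
  # og3 has no rapid events anywhere: excluded before BH
  expect_setequal(rep$og_id, c("og1", "og2"))
  r1 <- rep[rep$og_id == "og1", ]
  expect_equal(r1$odds_ratio, (5.5 * 30.5) / (35.5 * 0.5), tolerance = 1e-8)
  r2 <- rep[rep$og_id == "og2", ]
  expect_equal(r2$odds_ratio, 1) # 10% vs 10%
  expect_false(r2$decision)
  expect_equal(r2$direction, "none")

  # swapping the clades inverts the odds ratio, keeps p
  swapped <- rapid_enrichment(ev, cb, ca)
  s1 <- swapped[swapped$og_id == "og1", ]
  expect_equal(s1$odds_ratio, 1 / r1$odds_ratio, tolerance = 1e-10)
  expect_equal(s1$p, r1$p, tolerance = 1e-12)

  expect_error(rapid_enrichment(ev, ca, fake_clade("X", ca$branches[1])),
               "overlap")
})

test_that("rate contrast flags families with faster turnover in clade A", {
  # two clades of three 10-My branches; deltas chosen so per-branch rates
  # are A = (1.0, 0.8, 0.9), B = (0.1, 0, 0.2) for og1
  tr <- parse_newick("((A1:10,A2:10,A3:10):1,(B1:10,B2:10,B3:10):1);")
  ca <- resolve_clade(tr, clade_spec("P", c("A1", "A2", "A3"), "leaf_list"))
  cb <- resolve_clade(tr, clade_spec("A", c("B1", "B2", "B3"), "leaf_list"))
  ev <- data.frame(
    og_id = rep(c("og1", "og2"), each = 6),
    branch_id = rep(c("A1", "A2", "A3", "B1", "B2", "B3"), 2),
    delta = c(10L, 8L, 9L, 1L, 0L, 2L,  3L, 4L, 5L, 3L, 4L, 5L))
  rep <- rate_contrast(ev, tr, ca, cb)
  r1 <- rep[rep$og_id == "og1", ]
  expect_equal(r1$statistic, 9)
  expect_equal(r1$p, 0.05) # exact enumeration, U = 9 of 9
  r2 <- rep[rep$og_id == "og2", ]
  expect_gte(r2$p, 0.5) # identical rate vectors
  expect_false(r2$decision)

  flipped <- rate_contrast(ev, tr, cb, ca, alternative = "less")
  expect_equal(flipped[flipped$og_id == "og1", "p"], r1$p, tolerance = 1e-12)
})

test_that("size contrast compares per-species counts between groups", {
  counts <- rbind(
    og1 = c(10L, 12L, 9L, 1L, 0L, 2L),
    og2 = c(3L, 3L, 3L, 3L, 3L, 3L)
  )
  colnames(counts) <- c("p1", "p2", "p3", "q1", "q2", "q3")
  rep <- size_contrast(counts, c("p1", "p2", "p3"), c("q1", "q2", "q3"),
                       name_a = "P", name_b = "other")
  r1 <- rep[rep$og_id == "og1", ]
  expect_equal(r1$p, 0.05)
  expect_equal(r1$direction, "P")
  r2 <- rep[rep$og_id == "og2", ]
  expect_gte(r2$p, 0.5)
  expect_false(r2$decision)

  # strong separation at n = 10 vs 10 crosses the normal-approximation path
  big <- matrix(c(rep(0L, 10), rep(5L + 0:9, 1)), 1,
                dimnames = list("og1", sprintf("s%02d", 1:20)))
  rep_big <- size_contrast(big, sprintf("s%02d", 11:20), sprintf("s%02d", 1:10))
  expect_lt(rep_big$p_adj, 0.001)

  expect_error(size_contrast(counts, c("p1", "p2"), c("p2", "q1")), "both groups")
})

test_that("presence classes honour the strict 70% boundary", {
  out_sp <- sprintf("o%02d", 1:10)
  test_sp <- sprintf("t%02d", 1:20)
  counts <- matrix(0L, nrow = 3, ncol = 30,
                   dimnames = list(c("miss", "edge", "novel"),
                                   c(out_sp, test_sp)))
  counts["miss", out_sp[1:8]] <- 1L            # 0.8 > 0.7 in outgroup
  counts["edge", out_sp[1:7]] <- 1L            # exactly 0.7: not over
  counts["novel", test_sp[1:15]] <- 2L         # 0.75 > 0.7 in test group
  cls <- presence_classes(counts, test_sp, out_sp)
  expect_equal(cls$missing, "miss")
  expect_equal(cls$novel_core, "novel")

  # invariant to column shuffling and to species in neither group
  shuffled <- counts[, sample(colnames(counts))]
  extra <- cbind(shuffled, zz = 0L)
  cls2 <- presence_classes(extra, test_sp, out_sp)
  expect_identical(cls, cls2)
  expect_error(presence_classes(counts, character(0), out_sp), "non-empty")
})

test_that("differential loss applies strict > 20% and inclusive <= 2% rules", {
  a_sp <- sprintf("a%02d", 1:50)
  o_sp <- sprintf("o%02d", 1:81)
  counts <- matrix(1L, nrow = 3, ncol = 131,
                   dimnames = list(c("hit", "edge_a", "edge_o"),
                                   c(a_sp, o_sp)))
  counts["hit", a_sp[1:12]] <- 0L      # 0.24 > 0.20
  counts["hit", o_sp[1]] <- 0L         # 0.0123 <= 0.02
  counts["edge_a", a_sp[1:10]] <- 0L   # exactly 0.20: excluded
  counts["edge_o", a_sp[1:12]] <- 0L
  counts["edge_o", o_sp[1:2]] <- 0L    # 0.0247 > 0.02: excluded
  hits <- differential_loss(counts, a_sp, o_sp)
  expect_equal(hits, "hit")
})

test_that("scan decisions are reproducible from their own p columns", {
  tr <- parse_newick("((A1:10,A2:10,A3:10):1,(B1:10,B2:10,B3:10):1);")
  ca <- resolve_clade(tr, clade_spec("P", c("A1", "A2", "A3"), "leaf_list"))
  cb <- resolve_clade(tr, clade_spec("A", c("B1", "B2", "B3"), "leaf_list"))
  set.seed(31)
  ev <- data.frame(
    og_id = rep(sprintf("og%02d", 1:20), each = 6),
    branch_id = rep(c("A1", "A2", "A3", "B1", "B2", "B3"), 20),
    delta = sample(0:6, 120, replace = TRUE))
  rep <- rate_contrast(ev, tr, ca, cb)
  expect_equal(rep$p_adj, bh_fdr(rep$p))
  expect_identical(rep$decision, rep$p_adj < 0.05)
})
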