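ec <- function(...) sprintf("1.1.1.%d", c(...))

toy_db <- data.frame(
  pathway_id = c("pw1", "pw2", "pw3"),
  superpathway_id = c("sp1", "sp1", "sp2"),
  name = c("six enzymes", "small", "unreferenced"),
  has_reference = c(TRUE, TRUE, FALSE),
  ecs = c(paste(ec(1:6), collapse = ";"),
          paste(ec(11:16), collapse = ";"),
          paste(ec(21:26), collapse = ";")),
  stringsAsFactors = FALSE
)

test_that("ancestral reconstruction keeps pathways by retained size and reference", {
  outg <- list(sp_out1 = c(ec(1:5), ec(11:14), ec(21:26), "9.9.9.9"))
  anc <- build_ancestral(toy_db, outg)
  # pw1: 5 of 6 ECs retained -> kept at the min_ecs = 5 boundary
  expect_equal(anc$retained$pw1, sort(ec(1:5)))
  # pw2: only 4 retained -> dropped
  expect_false("pw2" %in% names(anc$retained))
  # pw3: no reference species -> dropped despite 6 retained ECs
  expect_false("pw3" %in% names(anc$retained))
  expect_equal(nrow(anc$db), 1L)

  relaxed <- build_ancestral(toy_db, outg, require_reference = FALSE)
  expect_setequal(names(relaxed$retained), c("pw1", "pw3"))

  expect_error(build_ancestral(toy_db, list()), "empty")
  bad <- toy_db; bad$ecs[1] <- "1.2;whoops"
  expect_error(build_ancestral(bad, outg), "invalid EC")
})

test_that("combine modes union, intersection and majority behave as set operations", {
  outg <- list(o1 = ec(1:4), o2 = ec(3:6), o3 = ec(3:4))
  u <- build_ancestral(toy_db, outg, mode = "union", min_ecs = 1,
                       require_reference = FALSE)
  expect_equal(u$retained$pw1, sort(ec(1:6)))
  i <- build_ancestral(toy_db, outg, mode = "intersection", min_ecs = 1,
                       require_reference = FALSE)
  expect_equal(i$retained$pw1, sort(ec(3:4)))
  m <- build_ancestral(toy_db, outg, mode = "majority", min_ecs = 1,
                       require_reference = FALSE)
  expect_equal(m$retained$pw1, sort(ec(3:4))) # present in 2 or 3 of 3
})

test_that("pathway coverage is the annotated fraction of the retained set", {
  outg <- list(sp_out1 = ec(1:5))
  anc <- build_ancestral(toy_db, outg)
  pc <- coverage(list(s1 = ec(1:2), s2 = ec(1:9), s3 = ec(50:60),
                      sp_out1 = ec(1:5)), anc)
  expect_equal(pc["pw1", "s1"], 0.4)
  expect_equal(pc["pw1", "s2"], 1.0)
  expect_equal(pc["pw1", "s3"], 0.0)
  # an outgroup species whose own ECs built the set has full coverage
  expect_equal(pc["pw1", "sp_out1"], 1.0)
  # monotonicity: removing an EC never increases coverage
  pc_small <- coverage(list(s1 = ec(2)), anc)
  expect_lte(pc_small["pw1", "s1"], pc["pw1", "s1"])
})

test_that("coverage contrast separates clades with different enzyme loss", {
  sp_a <- sprintf("a%02d", 1:10)
  sp_b <- sprintf("b%02d", 1:10)
  pc <- matrix(c(rep(0.5, 10), rep(1.0, 10)), nrow = 1,
               dimnames = list("pw1", c(sp_a, sp_b)))
  res <- pc_contrast(pc, sp_a, sp_b, name_a = "P", name_b = "A")
  expect_lt(res$global$p_value, 1e-4)
  expect_true(res$per_pathway$lower_in_P)
  expect_false(res$per_pathway$lower_in_A)

  set.seed(52)
  flat <- matrix(stats::runif(40, 0.7, 0.9), nrow = 2,
                 dimnames = list(c("pw1", "pw2"), c(sp_a, sp_b)))
  res_flat <- pc_contrast(flat, sp_a, sp_b)
  expect_equal(sum(res_flat$per_pathway$lower_in_A,
                   res_flat$per_pathway$lower_in_B), 0)
  expect_error(pc_contrast(pc, sp_a[1], sp_b), ">= 2 species")
})

test_that("synthetic enzyme loss is detected end-to-end", {
  fix <- demo_fixture()
  pw <- sim_pathway_db(n_pathways = 20, seed = 51)
  cfg <- sim_config(seed = 51, ec_loss_prob = c(PAR = 0.3, ACU = 0))
  prof <- simulate_ec_profiles(pw, fix$tree, cfg, fix$clades,
                               fix$clades$OUT$species)
  anc <- build_ancestral(pw, prof[fix$clades$OUT$species])
  expect_equal(length(anc$retained), 20L) # no orphan drops here
  pc <- coverage(prof, anc)
  res <- pc_contrast(pc, fix$clades$PAR$species, fix$clades$ACU$species)
  expect_lt(res$global$p_value, 1e-6)
  expect_gt(mean(res$per_pathway$lower_in_A), 0.8)
})

# coverage matrix with hand-set per-clade CoV per pathway
pc_fixture <- function(anc) {
  pair <- function(m, cv) m * c(1 - cv / sqrt(2), 1 + cv / sqrt(2))
  pw <- names(anc$retained)
  pc <- matrix(0, nrow = length(pw), ncol = 4,
               dimnames = list(pw, c("a1", "a2", "b1", "b2")))
  for (i in seq_along(pw)) {
    pc[i, c("a1", "a2")] <- pair(0.6, 0.3)
    pc[i, c("b1", "b2")] <- pair(0.6, 0.05)
  }
  pc
}

test_that("dropped pathways leave no orphan rows downstream", {
  outg <- list(sp_out1 = ec(1:5))
  anc <- build_ancestral(toy_db, outg) # keeps only pw1
  pc <- coverage(list(s1 = ec(1:3), s2 = ec(2:4)), anc)
  expect_equal(rownames(pc), "pw1")
  db2 <- rbind(toy_db[1, ], toy_db[1, ])
  db2$pathway_id <- c("pw1", "pw1b")
  db2$superpathway_id <- "sp1"
  anc2 <- build_ancestral(db2, outg)
  cvc <- pc_cov_contrast(pc_fixture(anc2), anc2,
                         c("a1", "a2"), c("b1", "b2"))
  expect_setequal(cvc$superpathway_id, "sp1")
})

test_that("coverage-variability contrast works on constructed CoV patterns", {
  # one superpathway, three pathways: clade A CoVs (0.4, 0.5, 0.6),
  # clade B CoVs (0.05, 0.10, 0.15) -> exact one-sided p = 0.05
  pair <- function(m, cv) m * c(1 - cv / sqrt(2), 1 + cv / sqrt(2))
  db <- data.frame(
    pathway_id = c("pw1", "pw2", "pw3", "pw4"),
    superpathway_id = c("spA", "spA", "spA", "lonely"),
    name = "x", has_reference = TRUE,
    ecs = paste(ec(1:5), collapse = ";"),
    stringsAsFactors = FALSE)
  anc <- list(retained = stats::setNames(rep(list(ec(1:5)), 4), db$pathway_id),
              db = db, mode = "union", outgroup_species = "o1")
  class(anc) <- "ancestral_pathways"
  cov_a <- c(0.4, 0.5, 0.6, 0.3)
  cov_b <- c(0.05, 0.10, 0.15, 0.3)
  pc <- matrix(0, nrow = 4, ncol = 4,
               dimnames = list(db$pathway_id, c("a1", "a2", "b1", "b2")))
  for (i in 1:4) {
    pc[i, c("a1", "a2")] <- pair(0.5, cov_a[i])
    pc[i, c("b1", "b2")] <- pair(0.5, cov_b[i])
  }
  res <- pc_cov_contrast(pc, anc, c("a1", "a2"), c("b1", "b2"))
  # the single-pathway superpathway is skipped
  expect_equal(res$superpathway_id, "spA")
  expect_equal(res$p, 0.05, tolerance = 1e-10)
  ct <- attr(res, "cov_table")
  expect_equal(ct$cov_a[ct$pathway_id == "pw3"], 0.6, tolerance = 1e-10)

  # identical coverage within clades: all CoV zero, nothing significant
  pc0 <- matrix(0.8, nrow = 4, ncol = 4,
                dimnames = dimnames(pc))
  res0 <- pc_cov_contrast(pc0, anc, c("a1", "a2"), c("b1", "b2"))
  expect_false(any(res0$decision))
})
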