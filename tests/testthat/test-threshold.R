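test_that("cophenetic distances match brute-force path sums", {
  set.seed(11)
  for (rep in 1:5) {
    tree <- ape::rtree(8)
    dm <- oracle_cophenetic(tree)
    tips <- tree$tip.label
    for (pair in list(c(1, 2), c(3, 8), c(5, 5))) {
      expect_equal(cophenetic_distance(tree, tips[pair[1]], tips[pair[2]]),
                   dm[tips[pair[1]], tips[pair[2]]], tolerance = 1e-10)
    }
  }
  expect_equal(cophenetic_distance(ape::read.tree(text = "(a:0.1,b:0.2);"),
                                   "a", "b"), 0.3)
  expect_error(cophenetic_distance(ape::rtree(4), "t1", "nope"), "unknown")
})

test_that("cut_tree groups are the maximal small-diameter clades", {
  set.seed(23)
  for (rep in 1:20) {
    tree <- ape::rtree(sample(4:12, 1))
    diam <- max(oracle_cophenetic(tree))
    for (t in c(0, runif(3, 0, diam * 1.2), diam * 2)) {
      got <- cut_tree(tree, t)
      got_groups <- lapply(split(got$id, got$group), sort)
      names(got_groups) <- NULL
      want <- oracle_cut(tree, t)
      expect_setequal(got_groups, want)
    }
  }
})

test_that("degenerate thresholds give singletons or one group", {
  tree <- ape::rtree(6)
  all_one <- cut_tree(tree, max(oracle_cophenetic(tree)) + 1)
  expect_equal(length(unique(all_one$group)), 1L)
  singles <- cut_tree(tree, 0)
  expect_equal(length(unique(singles$group)), 6L)
})

test_that("group count is non-increasing in the threshold", {
  set.seed(31)
  tree <- ape::rtree(15)
  ts <- sort(runif(12, 0, max(oracle_cophenetic(tree)) * 1.1))
  counts <- vapply(ts, function(t) length(unique(cut_tree(tree, t)$group)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("over-merge and over-split counts follow the counting rules", {
  # single group {A,A,B,C}: two extra taxa merged in
  tree <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  tax <- labels_as_taxonomy(setNames(c("A", "A", "B", "C"), c("a", "b", "c", "d")))
  part_one <- cut_tree(tree, 1)
  sc <- score_threshold(part_one, tax, "Genus")
  expect_equal(sc$over_merge, 2L)
  expect_equal(sc$over_split, 0L)
  # three groups with majorities {A, A, B}: one duplicated name
  tree2 <- ape::read.tree(
    text = "((a:0.01,b:0.01):0.5,((c:0.01,d:0.01):0.4,(e:0.01,f:0.01):0.4):0.5);")
  tax2 <- labels_as_taxonomy(setNames(c("A", "A", "A", "A", "B", "B"),
                                      letters[1:6]))
  part3 <- cut_tree(tree2, 0.1)
  expect_equal(length(unique(part3$group)), 3L)
  sc2 <- score_threshold(part3, tax2, "Genus")
  expect_equal(sc2$over_merge, 0L)
  expect_equal(sc2$over_split, 1L)
  expect_equal(sc2$error, 1 / 6)
})

test_that("scoring matches a first-principles oracle on random trees", {
  set.seed(47)
  for (rep in 1:20) {
    rl <- random_labeled_tree(sample(5:12, 1), n_taxa = sample(2:4, 1))
    tax <- labels_as_taxonomy(rl$labels)
    t <- runif(1, 0, max(oracle_cophenetic(rl$tree)) * 1.1)
    part <- cut_tree(rl$tree, t)
    got <- score_threshold(part, tax, "Genus")
    want <- oracle_score(lapply(split(part$id, part$group), identity),
                         rl$labels)
    expect_equal(got$over_merge, want$over_merge)
    expect_equal(got$over_split, want$over_split)
    expect_equal(got$error,
                 (want$over_merge + want$over_split) / want$n_labeled)
    expect_gte(got$error, 0)
    expect_lte(got$error, 1)
  }
})

test_that("unlabeled tips are excluded from both error terms", {
  tree <- ape::read.tree(text = "((a:0.01,b:0.01):0.01,(c:0.01,d:0.01):0.01);")
  labs <- setNames(c("A", NA, "B", NA), c("a", "b", "c", "d"))
  sc <- score_threshold(cut_tree(tree, 1), labels_as_taxonomy(labs), "Genus")
  expect_equal(sc$n_labeled, 2L)
  expect_equal(sc$over_merge, 1L)
})

test_that("find_thresholds recovers a separating threshold with zero error", {
  # two genera: within-diameter 0.04, between-distance 0.30
  tree <- ape::read.tree(
    text = "((a:0.02,b:0.02):0.13,(c:0.02,d:0.02):0.13);")
  tax <- labels_as_taxonomy(setNames(c("g1", "g1", "g2", "g2"), letters[1:4]))
  ts <- find_thresholds(tree, tax, ranks = "Genus", mode = "sensitive")
  chosen <- ts$thresholds[["Genus"]]
  expect_gt(chosen, 0.04)
  expect_lte(chosen, 0.30)
  expect_equal(tidy(ts)$error, 0)
})

test_that("single-taxon trees and single-point grids behave as stated", {
  tree <- ape::read.tree(text = "((a:0.1,b:0.1):0.1,c:0.2);")
  tax <- labels_as_taxonomy(setNames(rep("g", 3), c("a", "b", "c")))
  ts <- find_thresholds(tree, tax, ranks = "Genus", mode = "sensitive")
  part <- cut_tree(tree, ts$thresholds[["Genus"]])
  expect_equal(length(unique(part$group)), 1L)
  expect_equal(tidy(ts)$error, 0)
  one <- find_thresholds(tree, tax, ranks = "Genus", grid = 0.123,
                         mode = "sensitive")
  expect_equal(unname(one$thresholds[["Genus"]]), 0.123)
})

test_that("threshold ties break toward the smallest candidate", {
  tree <- ape::read.tree(text = "((a:0.02,b:0.02):0.13,(c:0.02,d:0.02):0.13);")
  tax <- labels_as_taxonomy(setNames(c("g1", "g1", "g2", "g2"), letters[1:4]))
  ts <- find_thresholds(tree, tax, ranks = "Genus", grid = c(0.05, 0.1, 0.2),
                        mode = "sensitive")
  expect_equal(unname(ts$thresholds[["Genus"]]), 0.05)
})

test_that("specificity modes scale only the species threshold", {
  tree <- ape::read.tree(text = "((a:0.01,b:0.01):0.1,(c:0.01,d:0.01):0.1);")
  tax <- parse_taxonomy(tibble::tibble(
    id = letters[1:4],
    lineage = c("B;P;C;O;F;g1;g1 s1", "B;P;C;O;F;g1;g1 s1",
                "B;P;C;O;F;g2;g2 s2", "B;P;C;O;F;g2;g2 s2")))
  ts <- find_thresholds(tree, tax, mode = "sensitive")
  eff_sens <- phylotaxa:::effective_thresholds(ts)
  ts_spec <- specificity_mode(ts, "specific")
  eff_spec <- phylotaxa:::effective_thresholds(ts_spec)
  expect_equal(eff_spec[["Species"]], 0.1 * eff_sens[["Species"]])
  for (r in c("Phylum", "Class", "Order", "Family", "Genus")) {
    expect_equal(eff_spec[[r]], eff_sens[[r]])
  }
  custom <- specificity_mode(ts, multiplier = 0.5)
  expect_equal(phylotaxa:::effective_thresholds(custom)[["Species"]],
               0.5 * eff_sens[["Species"]])
  expect_error(specificity_mode(ts, multiplier = -1), "> 0")
  expect_error(specificity_mode(ts, "bogus"))
})

test_that("threshold sets serialize to JSON and back", {
  tree <- ape::read.tree(text = "((a:0.02,b:0.02):0.13,(c:0.02,d:0.02):0.13);")
  tax <- labels_as_taxonomy(setNames(c("g1", "g1", "g2", "g2"), letters[1:4]))
  ts <- find_thresholds(tree, tax, ranks = "Genus")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_threshold_set(ts, tmp)
  back <- read_threshold_set(tmp)
  expect_equal(back$thresholds, ts$thresholds)
  expect_equal(back$multiplier, ts$multiplier)
  expect_equal(as.data.frame(back$chosen), as.data.frame(ts$chosen))
})
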