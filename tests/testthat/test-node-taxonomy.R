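# threshold_set builder for hand-made trees (bypasses optimization)
manual_thresholds <- function(values, multiplier = 1) {
  structure(list(thresholds = values, multiplier = multiplier,
                 mode = "custom",
                 chosen = tibble::tibble(rank = names(values),
                                         threshold = unname(values),
                                         over_merge = 0L, over_split = 0L,
                                         error = 0),
                 curves = tibble::tibble()),
            class = "threshold_set")
}

full_thresholds <- function(t, species = t, multiplier = 1) {
  manual_thresholds(setNames(c(t, t, t, t, t, species),
                             phylotaxa:::threshold_ranks()),
                    multiplier = multiplier)
}

test_that("dominant label retention follows the exact binomial tail", {
  expect_equal(dominant_labels(c(X = 19, Y = 1)), "X")
  expect_equal(dominant_labels(c(X = 10, Y = 10)), c("X", "Y"))
  # with n = 2 both singleton labels pass (tail 0.0975 <= 0.20)
  expect_equal(dominant_labels(c(X = 1, Y = 1)), c("X", "Y"))
  expect_error(dominant_labels(integer(0)), "empty")
})

test_that("dominant_labels agrees with tail-sum enumeration for n <= 25", {
  for (n in 2:25) {
    for (k in 1:(n - 1)) {
      counts <- c(A = k, B = n - k)
      expect_equal(dominant_labels(counts), oracle_dominant(counts),
                   info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("the alternative tail reading is available and differs", {
  # under "ge", rare labels (large tail prob) are retained instead
  expect_equal(dominant_labels(c(X = 19, Y = 1), tail_rule = "ge"), "Y")
})

test_that("no label passing means all labels are returned", {
  # n = 60, three-way 1/1/58: tails for k=1 are ~0.95 (fail); k=58 passes
  expect_equal(dominant_labels(c(A = 58, B = 1, C = 1)), "A")
  # craft a case where nothing passes: all labels rare relative to n is
  # impossible for two labels (one has k >= n/2), so use the error_prob
  # dial to force it
  expect_equal(dominant_labels(c(A = 3, B = 2), error_prob = 1e-12),
               c("A", "B"))
})

test_that("pure clades propagate their full lineage", {
  tree <- ape::read.tree(
    text = "((a:0.001,b:0.001):0.05,(c:0.001,d:0.001):0.05);")
  tax <- parse_taxonomy(tibble::tibble(
    id = letters[1:4],
    lineage = c("B;P;C;O;F;g1;g1 s1", "B;P;C;O;F;g1;g1 s1",
                "B;P;C;O;F;g2;g2 s2", "B;P;C;O;F;g2;g2 s2")))
  ts <- full_thresholds(0.2, species = 0.01)
  lab <- propagate(tree, tax, ts)
  cherry_ab <- ape::getMRCA(tree, c("a", "b"))
  expect_equal(lab$sets[[cherry_ab]]$Species, "g1 s1")
  expect_equal(lab$sets[[cherry_ab]]$Genus, "g1")
  expect_equal(lab$sets[[cherry_ab]]$Kingdom, "B")
  # root diameter 0.104 exceeds the species threshold but not 0.2:
  root <- ape::getMRCA(tree, letters[1:4])
  expect_equal(lab$sets[[root]]$Species, character(0))
  expect_equal(sort(lab$sets[[root]]$Genus), c("g1", "g2"))
})

test_that("nodes wider than every threshold carry no labels", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tax <- parse_taxonomy(tibble::tibble(
    id = letters[1:4], lineage = rep("B;P;C;O;F;g;g s", 4)))
  lab <- propagate(tree, tax, full_thresholds(0.5))
  root <- ape::getMRCA(tree, letters[1:4])
  expect_true(all(lengths(lab$sets[[root]]) == 0L))
})

test_that("ambiguous ranks descend hierarchically per retained label", {
  # 5+5 tips of two genera interleaved under one node; species differ by genus
  tips <- paste0("t", 1:10)
  newick <- paste0("(", paste(paste0(tips, ":0.001"), collapse = ","), ");")
  tree <- ape::read.tree(text = newick)
  tax <- parse_taxonomy(tibble::tibble(
    id = tips,
    lineage = c(rep("B;P;C;O;F;G1;G1 s1", 5), rep("B;P;C;O;F;G2;G2 s2", 5))))
  lab <- propagate(tree, tax, full_thresholds(1))
  root <- length(tips) + 1L
  expect_equal(lab$sets[[root]]$Genus, c("G1", "G2"))
  # hierarchical: each genus partition resolves its own species
  expect_equal(lab$sets[[root]]$Species, c("G1 s1", "G2 s2"))
})

test_that("pooled descent is available behind the flag", {
  tips <- paste0("t", 1:20)
  newick <- paste0("(", paste(paste0(tips, ":0.001"), collapse = ","), ");")
  tree <- ape::read.tree(text = newick)
  # G1 dominates at 18/20 tips but splits evenly into two species; G2 is
  # rare enough to be absorbed as error at genus level
  tax <- parse_taxonomy(tibble::tibble(
    id = tips,
    lineage = c(rep("B;P;C;O;F;G1;G1 s1", 9), rep("B;P;C;O;F;G1;G1 s2", 9),
                rep("B;P;C;O;F;G2;G2 s3", 2))))
  hier <- propagate(tree, tax, full_thresholds(1), hierarchical = TRUE)
  pooled <- propagate(tree, tax, full_thresholds(1), hierarchical = FALSE)
  root <- length(tips) + 1L
  expect_equal(hier$sets[[root]]$Genus, "G1")
  # genus unambiguous: both modes pool species across all tips,
  # where the two G1 species pass and the rare G2 species is absorbed
  expect_equal(hier$sets[[root]]$Species, c("G1 s1", "G1 s2"))
  expect_equal(pooled$sets[[root]]$Species, c("G1 s1", "G1 s2"))
})

test_that("labels are never invented and renames act equivariantly", {
  fx <- simulate_fixture(fixture_spec(seed = 5))
  ts <- find_thresholds(fx$tree, fx$taxonomy, n_grid = 40, mode = "sensitive")
  lab <- propagate(fx$tree, fx$taxonomy, ts)
  ix <- phylotaxa:::tree_index(fx$tree)
  ranks <- rank_levels()
  for (v in sample(seq_along(lab$sets), 25)) {
    tip_ids <- fx$tree$tip.label[ix$tips[[v]]]
    observed <- fx$taxonomy[fx$taxonomy$id %in% tip_ids, ]
    for (r in ranks) {
      expect_true(all(lab$sets[[v]][[r]] %in% stats::na.omit(observed[[r]])))
    }
  }
  # equivariance under a bijective genus rename
  tax2 <- fx$taxonomy
  tax2$Genus <- paste0("X_", tax2$Genus)
  lab2 <- propagate(fx$tree, tax2, ts)
  for (v in sample(seq_along(lab$sets), 10)) {
    want <- if (length(lab$sets[[v]]$Genus) > 0L) {
      sort(paste0("X_", lab$sets[[v]]$Genus))
    } else {
      character(0)
    }
    expect_equal(lab2$sets[[v]]$Genus, want)
  }
})

test_that("species label sets are monotone under the children union", {
  fx <- simulate_fixture(fixture_spec(seed = 8))
  ts <- find_thresholds(fx$tree, fx$taxonomy, n_grid = 40, mode = "sensitive")
  lab <- propagate(fx$tree, fx$taxonomy, ts)
  ix <- phylotaxa:::tree_index(fx$tree)
  for (v in (ix$n_tip + 1):ix$n_node) {
    mine <- lab$sets[[v]]$Species
    if (length(mine) == 0L) next
    kids <- unlist(lapply(ix$children[[v]], function(c) lab$sets[[c]]$Species))
    if (length(kids) == 0L) next
    expect_true(all(mine %in% kids))
  }
})

test_that("node tables and annotated trees are written", {
  fx <- simulate_fixture(fixture_spec(seed = 3))
  ts <- find_thresholds(fx$tree, fx$taxonomy, n_grid = 30, mode = "sensitive")
  lab <- propagate(fx$tree, fx$taxonomy, ts)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_node_table(lab, tsv)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_true(all(c("node", "rank", "labels", "diameter") %in% names(tab)))
  expect_gt(nrow(tab), 0)
  write_annotated_tree(lab, nwk)
  back <- ape::read.tree(nwk)
  expect_equal(sort(back$tip.label), sort(fx$tree$tip.label))
  expect_true(any(grepl("Species", back$node.label)))
})
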