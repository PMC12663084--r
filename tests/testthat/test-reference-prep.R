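# a tiny aligned database: primer "AAGGTTCC" occupies columns 10..17
# (1-based) in every row, but at different *ungapped* offsets per row
toy_db <- function() {
  tibble::tibble(
    id = c("r1", "r2", "r3"),
    seq = c(
      paste0("ACGTACGT-", "AAGGTTCC", "AAGGCCTTACGT"),
      paste0("ACGTACGTT", "AAGGTTCC", "AAGGCCTTACGT"),
      paste0("--GTACGT-", "AAGGTTCC", "AAGGCCTTACGT")
    )
  )
}

test_that("exact forward primer hits map back to modal alignment columns", {
  db <- toy_db()
  site <- find_primer_site(db, "AAGGTTCC", "forward")
  expect_equal(site, c(9L, 17L))
  chars <- strsplit(db$seq[1], "")[[1]]
  expect_equal(paste(chars[(site[1] + 1):site[2]], collapse = ""), "AAGGTTCC")
  expect_error(find_primer_site(db, "AAAAAAAAAA", "forward"), "not located")
})

test_that("IUPAC degeneracies and reverse primers match correctly", {
  db <- toy_db()
  # Y = C or T: replace one primer base with Y, still an exact-match hit
  site_y <- find_primer_site(db, "AAGGTYCC", "forward")
  site <- find_primer_site(db, "AAGGTTCC", "forward")
  expect_equal(site_y, site)
  # reverse primer given 5'->3' on the reverse strand: revcomp(GGCCTT)=AAGGCC
  site_r <- find_primer_site(db, "GGCCTT", "reverse")
  expect_equal(site_r, c(17L, 23L))
  chars <- strsplit(db$seq[1], "")[[1]]
  expect_equal(paste(chars[(site_r[1] + 1):site_r[2]], collapse = ""),
               "AAGGCC")
})

test_that("region trimming is a pure column slice with primer toggle", {
  db <- tibble::tibble(id = c("a", "b"),
                       seq = c(strrep("ACGT", 25), strrep("TGCA", 25)))
  sl <- trim_to_region(db, c(5L, 25L), c(80L, 100L), keep_primers = FALSE)
  expect_equal(attr(sl, "start"), 25L)
  expect_equal(attr(sl, "end"), 80L)
  expect_equal(nchar(sl$seq[1]), 55L)
  expect_equal(sl$seq[1], substr(db$seq[1], 26, 80))
  sl2 <- trim_to_region(db, c(5L, 25L), c(80L, 100L), keep_primers = TRUE)
  expect_equal(c(attr(sl2, "start"), attr(sl2, "end")), c(5L, 100L))
  expect_error(trim_to_region(db, c(80L, 100L), c(5L, 25L)), "precede")
})

test_that("all-gap sequences are dropped and counted during trimming", {
  db <- tibble::tibble(id = c("a", "b"),
                       seq = c(paste0(strrep("A", 10), strrep("-", 10)),
                               strrep("C", 20)))
  sl <- phylotaxa:::region_slice(db, 12L, 18L)
  expect_equal(sl$id, "b")
  expect_equal(attr(sl, "n_dropped"), 1L)
})

test_that("quality filtering removes N-containing and short sequences", {
  sl <- tibble::tibble(id = c("clean", "withN", "short"),
                       seq = c(strrep("ACGT", 10),
                               paste0("N", substr(strrep("ACGT", 10), 2, 40)),
                               paste0(strrep("-", 30), "ACGTACGTAC")))
  out <- filter_sequences(sl, min_ungapped_len = 20, drop_N = TRUE)
  expect_equal(out$id, "clean")
  expect_equal(attr(out, "n_dropped_N"), 1L)
  expect_equal(attr(out, "n_dropped_short"), 1L)
  out2 <- filter_sequences(sl, min_ungapped_len = 0, drop_N = FALSE)
  expect_equal(nrow(out2), 3L)
  expect_error(filter_sequences(sl, min_ungapped_len = 1000), "no sequences")
})

test_that("trimming then degapping equals substring of the degapped core", {
  seq <- "AC-GT-ACGTAC--GTAA"
  db <- tibble::tibble(id = "x", seq = seq)
  sl <- phylotaxa:::region_slice(db, 3L, 12L)
  chars <- strsplit(seq, "")[[1]]
  manual <- paste(chars[4:12][chars[4:12] != "-"], collapse = "")
  expect_equal(phylotaxa:::degap(sl$seq), manual)
})

test_that("internal NJ recovers an additive topology (four-point oracle)", {
  set.seed(7)
  true <- ape::read.tree(
    text = "((A:0.05,B:0.08):0.06,(C:0.04,D:0.07):0.05,E:0.12);")
  # evolve long sequences so JC distances are near-additive
  spec_len <- 4000L
  bases <- c("A", "C", "G", "T")
  rooted <- phangorn::midpoint(true)
  ixt <- phylotaxa:::tree_index(rooted)
  seqs <- vector("list", ixt$n_node)
  seqs[[ixt$root]] <- sample(bases, spec_len, replace = TRUE)
  for (v in phylotaxa:::preorder_nodes(ixt$children, ixt$root)) {
    if (v == ixt$root) next
    d <- ixt$edge_len_to_parent[v]
    p <- 0.75 * (1 - exp(-4 * d / 3))
    s <- seqs[[ixt$parent[v]]]
    hit <- runif(spec_len) < p
    s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1),
                     character(1))
    seqs[[v]] <- s
  }
  slice <- tibble::tibble(
    id = rooted$tip.label,
    seq = vapply(seq_len(5), function(i) paste(seqs[[i]], collapse = ""),
                 character(1)))
  fit <- build_region_tree(slice, "internal-nj")

  # oracle: least-squares fit of the JC distance matrix over all 15
  # unrooted 5-taxon topologies
  dm <- phylotaxa:::jc_distance_matrix(slice)
  cands <- phangorn::allTrees(5, rooted = FALSE, tip.label = slice$id)
  ssq <- vapply(cands, function(tr) {
    f <- phangorn::nnls.tree(dm, tr, method = "unrooted")
    sum((ape::cophenetic.phylo(f)[slice$id, slice$id] -
           as.matrix(dm)[slice$id, slice$id])^2)
  }, numeric(1))
  best <- cands[[which.min(ssq)]]
  expect_equal(phangorn::RF.dist(ape::unroot(fit), best), 0)
  expect_equal(phangorn::RF.dist(ape::unroot(fit), ape::unroot(true)), 0)
})

test_that("external newick trees are validated against the slice", {
  slice <- tibble::tibble(id = c("A", "B", "C"), seq = rep("ACGT", 3))
  tr <- build_region_tree(slice, "external-newick",
                          newick = "((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_true(ape::is.rooted(tr))
  expect_error(
    build_region_tree(slice, "external-newick",
                      newick = "((A:1,X:1):1,C:2);"),
    "X")
})

test_that("identical sequences give a zero-length star-like NJ tree", {
  slice <- tibble::tibble(id = paste0("s", 1:4), seq = rep(strrep("ACGT", 30), 4))
  tr <- build_region_tree(slice, "internal-nj")
  expect_true(all(tr$edge.length <= 1e-12))
})
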