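test_that("simulated trees are ultrametric, sized 2n-3 and deterministic", {
  tr <- simulate_tree(10, seed = 1)
  expect_equal(nrow(tree_branches(tr)), 17L)
  expect_identical(write_newick(tr), write_newick(simulate_tree(10, seed = 1)))
  expect_false(identical(write_newick(tr), write_newick(simulate_tree(10, seed = 2))))

  rg <- ogdscan:::rooted_geometry(tr)
  tip_depths <- rg$depth[seq_len(tr$n)]
  expect_equal(unname(tip_depths), rep(2, tr$n), tolerance = 1e-9)
  expect_error(simulate_tree(3), "at least 4")
})

test_that("injected transfers respect distance, bookkeeping and coexistence", {
  tr <- simulate_tree(12, seed = 4)
  expect_identical(inject_transfers(tr, 0)$gene_tree, tr)

  inj <- inject_transfers(tr, 2, min_distance = 0.6, seed = 4)
  expect_equal(nrow(inj$truth), 2L)
  expect_true(all(inj$truth$distance >= 0.6))
  expect_true(all(inj$truth$recipient != inj$truth$donor))
  # recipient and donor identify branches of the species tree
  expect_true(all(inj$truth$recipient %in% tr$branches$key))
  expect_true(all(inj$truth$donor %in% tr$branches$key))
  # displacement conserves total tree length (prune + midpoint regraft)
  expect_equal(sum(inj$gene_tree$branches$length),
               sum(tr$branches$length), tolerance = 1e-9)
  # the gene tree actually differs from the species tree
  expect_false(setequal(canonical_splits(inj$gene_tree)$key,
                        canonical_splits(tr)$key))
  # coexistence: donor and recipient depth spans overlap on the clock tree
  rg <- ogdscan:::rooted_geometry(tr)
  span <- function(key) {
    i <- match(key, tr$branches$key)
    hi <- rg$depth[rg$node_of_branch[i]]
    c(max(hi - tr$branches$length[i], 0), hi)
  }
  for (k in seq_len(nrow(inj$truth))) {
    s1 <- span(inj$truth$recipient[k]); s2 <- span(inj$truth$donor[k])
    expect_lte(max(s1[1], s2[1]), min(s1[2], s2[2]) + 1e-12)
  }
  expect_error(inject_transfers(tr, 50, seed = 1), "fewer transfers")
})

test_that("forward simulation follows the substitution model", {
  m <- jtt_model()
  # zero-length tree: all rows equal the root draw
  phy <- ape::unroot(ape::rtree(5))
  phy$edge.length <- rep(0, nrow(phy$edge))
  aln0 <- evolve_alignment(phy, 50, m, seed = 1)
  expect_true(all(apply(aln0, 2, function(col) length(unique(col)) == 1L)))

  # stationarity: residue frequencies approach pi
  tr <- simulate_tree(6, seed = 2)
  aln <- evolve_alignment(tr, 10000, m, seed = 2)
  obs <- table(factor(aln, levels = AA_ALPHABET)) / length(aln)
  expect_lt(max(abs(as.numeric(obs) - m$pi)), 0.02)

  # saturation: at long distances pairwise identity approaches sum(pi^2)
  star <- ape::unroot(ape::read.tree(text = "(A:100,B:100,C:100,D:100);"))
  aln2 <- evolve_alignment(star, 2000, m, seed = 3)
  ident <- mean(aln2["A", ] == aln2["B", ])
  expect_lt(abs(ident - sum(m$pi^2)), 0.03)

  expect_identical(evolve_alignment(tr, 30, m, seed = 9),
                   evolve_alignment(tr, 30, m, seed = 9))
})

test_that("simulated traits are clade-correlated and well-formed", {
  diffs <- vapply(1:20, function(seed) {
    tr <- simulate_tree(10, seed = seed)
    tt <- simulate_traits(tr, seed = seed)
    b <- tree_branches(tr)
    cherries <- b$clade[b$size == 2]
    sister <- mean(vapply(cherries, function(cl)
      abs(diff(tt$gc_percent[match(cl, tt$taxon)])), numeric(1)))
    random <- mean(abs(outer(tt$gc_percent, tt$gc_percent, "-")))
    sister < random
  }, logical(1))
  expect_gte(sum(diffs), 15L)   # sisters are closer in GC than random pairs

  tr <- simulate_tree(10, seed = 3)
  tt <- simulate_traits(tr, seed = 3)
  hab <- as.matrix(tt[, ogdscan:::HABITAT_COLS])
  expect_true(all(hab >= 0))
  expect_true(all(rowSums(hab) >= 1))
  expect_true(all(tt$genome_mb > 0))
  expect_true(all(tt$gc_percent >= 25 & tt$gc_percent <= 75))
})

test_that("fixtures are complete and byte-identical across reruns", {
  fix <- ogd_fixture(n_taxa = 10, n_families = 3, n_transfers = 1,
                     sites = 80, seed = 7)
  expect_equal(length(fix$alignments), 3L)
  expect_equal(nrow(fix$truth), 1L)           # one row per injected event
  expect_equal(dim(fix$alignments$fam01), c(10L, 80L))

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixture(fix, d1)
  write_fixture(ogd_fixture(n_taxa = 10, n_families = 3, n_transfers = 1,
                            sites = 80, seed = 7), d2)
  expect_equal(length(p1), 3L + 1L + 2L + 1L)   # FASTAs + tree + 2 TSV + manifest
  for (f in basename(p1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  # the written tree re-parses to the in-memory tree
  tr2 <- parse_newick(file = file.path(d1, "combined.nwk"))
  expect_equal(canonical_splits(tr2)$length, canonical_splits(fix$tree)$length,
               tolerance = 1e-8)
})

test_that("the true gene tree out-scores the species tree on transfer families", {
  wins <- vapply(1:10, function(seed) {
    fix <- ogd_fixture(n_taxa = 10, n_families = 1, n_transfers = 1,
                       sites = 300, seed = 100 + seed)
    aln <- fix$alignments$fam01
    m <- jtt_model(empirical_frequencies(aln))
    inj <- inject_transfers(fix$tree, 1, min_distance = fix$params$min_distance,
                            seed = fix$params$seed + 1001L)
    sum(site_log_likelihoods(inj$gene_tree, aln, m)) >
      sum(site_log_likelihoods(fix$tree, aln, m))
  }, logical(1))
  expect_gte(sum(wins), 9L)
})
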