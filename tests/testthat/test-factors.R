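toy_rooted <- function() root_between(hand_tree(), "E,F", 0.5)

toy_traits <- function() {
  tibble::tibble(
    taxon = c("A", "B", "C", "D", "E", "F"),
    gc_percent = c(40, 60, 50, 30, 45, 55),
    genome_mb = c(2, 4, 3, 5, 1, 6),
    hab_aquatic = c(2, 0, 1, 0, 1, 0),
    hab_extreme = c(0, 1, 0, 0, 0, 0),
    hab_foodstuff = c(0, 0, 1, 0, 0, 0),
    hab_internal = c(0, 0, 0, 2, 0, 0),
    hab_runoff = c(0, 0, 0, 0, 1, 0),
    hab_terrestrial = c(0, 0, 0, 0, 0, 3)
  )
}

test_that("ancestral trait estimates are clade means", {
  tr <- toy_rooted()
  tt <- toy_traits()
  expect_equal(ancestral_mean(tr, "A,B", tt, "gc_percent"), 50)  # (40+60)/2
  expect_equal(ancestral_mean(tr, "A", tt, "gc_percent"), 40)
  # cross-check by direct summation over the clade
  b <- tree_branches(tr)
  i <- which(b$key == "C,D")
  expect_equal(ancestral_mean(tr, i, tt, "genome_mb"),
               sum(tt$genome_mb[tt$taxon %in% c("C", "D")]) / 2)
  expect_error(ancestral_mean(tr, "A", tt[-1, ], "gc_percent"), "Missing")
})

test_that("habitat profiles normalise and the 6-D distance is bounded", {
  tr <- toy_rooted()
  tt <- toy_traits()
  pA <- habitat_profile(tr, "A", tt)
  expect_equal(unname(pA), c(1, 0, 0, 0, 0, 0))   # single-category taxon
  pAB <- habitat_profile(tr, "A,B", tt)
  expect_equal(sum(pAB), 1)
  expect_equal(unname(pAB[1:2]), c(2 / 3, 1 / 3))

  pF <- habitat_profile(tr, "F", tt)
  expect_equal(habitat_distance(pA, pA), 0)
  expect_equal(habitat_distance(pA, pF), sqrt(2))  # disjoint unit categories
  expect_equal(habitat_distance(pA, pAB), habitat_distance(pAB, pA))
  expect_error(habitat_distance(c(1, 0, 0, 0, 0, 0), rep(0.5, 6)), "normalised")
})

test_that("donor-acceptor distances use branch midpoints on the full tree", {
  tr <- toy_rooted()
  # sister leaves A (0.1) and B (0.2): midpoint-to-midpoint = 0.05 + 0.10
  expect_equal(donor_acceptor_distance(tr, "A", "B"), 0.15)
  expect_equal(donor_acceptor_distance(tr, "A", "C,D"),
               donor_acceptor_distance(tr, "C,D", "A"))
  expect_equal(donor_acceptor_distance(tr, "A", "E"),
               path_length(tr, branch_midpoint_pt(tr, "A"),
                           branch_midpoint_pt(tr, "E")))
})

test_that("the all-pairs null enumerates unordered non-nested pairs", {
  tr <- toy_rooted()
  d <- all_pairs_distances(tr)
  # brute-force oracle over the branch table
  b <- tree_branches(tr)
  oracle <- c()
  for (i in seq_len(nrow(b) - 1)) {
    for (j in (i + 1):nrow(b)) {
      ci <- b$clade[[i]]; cj <- b$clade[[j]]
      if (all(ci %in% cj) || all(cj %in% ci)) next
      oracle <- c(oracle, path_length(tr, branch_midpoint_pt(tr, i),
                                      branch_midpoint_pt(tr, j)))
    }
  }
  expect_equal(sort(d), sort(oracle), tolerance = 1e-12)
  expect_true(all(d >= 0))
})

test_that("the statistical wrappers match hand-computable cases", {
  ks <- ks_two_sample(c(1, 2, 3), c(2, 3, 4))
  expect_equal(ks$statistic, 1 / 3, tolerance = 1e-12)   # ECDF enumeration
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:3, 7:9)$statistic, 1)

  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)        # 2/20 rank splits
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value,
               wilcoxon_rank_sum(c(4, 5, 6), c(1, 2, 3))$p_value)
  expect_gt(wilcoxon_rank_sum(c(1, 2, 9), c(1.5, 2.5, 8))$p_value, 0.6)

  expect_equal(pearson_correlation(1:5, 2 * (1:5))$estimate, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$estimate, -1)
  xy <- withr::with_seed(2, list(x = rnorm(15), y = rnorm(15)))
  pc <- pearson_correlation(xy$x, xy$y)
  r <- sum(scale(xy$x) * scale(xy$y)) / 14                # textbook formula
  expect_equal(pc$estimate, r, tolerance = 1e-12)
  tstat <- r * sqrt(13 / (1 - r^2))
  expect_equal(pc$p_value, 2 * pt(-abs(tstat), 13), tolerance = 1e-12)
  expect_error(pearson_correlation(1:5, rep(1, 5)), "variance")
})

test_that("the runs test matches exhaustive enumeration for small n", {
  x <- c(1, 1, -1, -1, 1, 1, -1, -1)
  rt <- runs_test(x)
  expect_equal(rt$runs, 4L)

  # oracle: enumerate every arrangement of the same sign multiset
  enum_p <- function(s) {
    n1 <- sum(s > 0); n <- length(s)
    pos_sets <- combn(n, n1)
    runs_of <- function(pos) {
      v <- rep(-1, n); v[pos] <- 1
      1L + sum(diff(v) != 0)
    }
    rr <- apply(pos_sets, 2, runs_of)
    obs <- runs_of(which(s > 0))
    lower <- mean(rr <= obs); upper <- mean(rr >= obs)
    min(1, 2 * min(lower, upper))
  }
  expect_equal(rt$p_value, enum_p(x), tolerance = 1e-12)
  for (seed in 1:5) {
    s <- withr::with_seed(seed, sample(c(-1, 1), 10, replace = TRUE))
    if (length(unique(s)) < 2) next
    expect_equal(runs_test(s)$p_value, enum_p(s), tolerance = 1e-12)
  }
  expect_equal(runs_test(c(1, 1, 1))$p_value, 1)   # degenerate
})

test_that("rate points count calls inside clades with brute-force agreement", {
  tr <- toy_rooted()
  calls <- tibble::tibble(
    family = c("f1", "f1", "f2"),
    recipient = c("A", "C,D", "C"),
    donor = c("C", "A,B", "E"),
    elw = 0.9, distance = 1
  )
  rp <- rate_points(tr, calls)
  expect_equal(rp$n_ogds[rp$clade == "A,B"], 1)      # recipient A only
  expect_equal(rp$n_ogds[rp$clade == "C,D"], 2)      # C,D itself and C
  expect_equal(rp$n_ogds[rp$clade == "E"], 0)
  # brute-force membership oracle
  b <- tree_branches(tr)
  for (k in seq_len(nrow(rp))) {
    cl <- b$clade[[match(rp$clade[k], b$key)]]
    cnt <- sum(vapply(calls$recipient, function(r)
      all(strsplit(r, ",")[[1]] %in% cl), logical(1)))
    expect_equal(rp$n_ogds[k], cnt)
  }
  # named independent clades partition their calls additively
  rp2 <- rate_points(tr, calls, clades = list(ab = c("A", "B"),
                                              cd = c("C", "D")))
  expect_equal(sum(rp2$n_ogds), 3)
  expect_true(all(rp2$independent))
  expect_error(rate_points(tr, calls, clades = list(bad = c("A", "C"))),
               "No branch")
})

test_that("rate linearity separates linear from quadratic data", {
  lin <- tibble::tibble(total_length = 1:10,
                        n_ogds = withr::with_seed(1, 2 * (1:10) + rnorm(10, sd = 0.8)))
  f1 <- rate_linearity(lin)
  expect_lt(f1$fit_p, 1e-6)
  expect_gt(f1$linearity_p, 0.05)

  quad <- tibble::tibble(total_length = seq(0, 4, length.out = 20),
                         n_ogds = withr::with_seed(2, seq(0, 4, length.out = 20)^2 +
                                                     rnorm(20, sd = 0.3)))
  f2 <- rate_linearity(quad)
  expect_lt(f2$linearity_p, 0.05)

  col <- tibble::tibble(total_length = 1:6, n_ogds = 3 * (1:6))
  f3 <- rate_linearity(col)
  expect_true(f3$degenerate)
  expect_equal(f3$runs_p, 1)

  expect_error(rate_linearity(lin[1:3, ]), "at least 4")
  expect_error(rate_linearity(tibble::tibble(total_length = rep(1, 5),
                                             n_ogds = 1:5)), "equal")
  expect_s3_class(tidy(f1), "tbl_df")
  expect_equal(glance(f1)$slope, f1$slope)
  expect_s3_class(autoplot(f1), "ggplot")
})

test_that("dating intervals overlap on clock-like trees and not otherwise", {
  # ultrametric synthetic trees: every injected (coexisting-lineage) transfer
  # must have overlapping donor/acceptor intervals in the exact-clock limit
  calls <- dplyr::bind_rows(lapply(1:8, function(seed) {
    tr <- simulate_tree(10, seed = seed)
    inj <- inject_transfers(tr, 1, min_distance = 0.4, seed = seed)
    dplyr::mutate(inj$truth, family = paste0("f", seed), elw = 1)
  }))
  for (seed in 1:8) {
    tr <- simulate_tree(10, seed = seed)
    dt <- dating_intervals(tr, calls[calls$family == paste0("f", seed), ])
    expect_true(all(dt$overlaps))
    expect_true(all(dt$lca_to_donor_mid >= 0))
  }

  # a deliberately non-clock tree: the A branch sits at depths [3.5, 3.55]
  # from the LCA, the C branch at [0.6, 0.65] -- disjoint intervals
  nc <- root_between(
    parse_newick("((A:0.05,B:0.05):3,(C:0.05,D:0.05):0.1,(E:1,F:1):1);"),
    "E,F", 0.5)
  calls2 <- tibble::tibble(family = "f", recipient = "A", donor = "C",
                           elw = 1, distance = 1)
  dt2 <- dating_intervals(nc, calls2)
  expect_false(any(dt2$overlaps))
  expect_error(dating_intervals(nc, tibble::tibble(
    family = "f", recipient = "A", donor = "A,B", elw = 1, distance = 1)),
    "Nested")
})

test_that("the factor report runs all five analyses", {
  tr <- toy_rooted()
  tt <- toy_traits()
  calls <- tibble::tibble(
    family = c("f1", "f1", "f2", "f2"),
    recipient = c("A", "C", "E", "A,B"),
    donor = c("C,D", "A,B", "C", "E"),
    elw = c(0.9, 0.8, 0.7, 1), distance = c(1, 0.5, 0.8, 2)
  )
  rep <- factor_report(tr, calls, tt,
                       interactions = tibble::tibble(
                         family = c("f1", "f2", "f3"),
                         interactions = c(100, 10, 50)))
  expect_setequal(rep$test,
                  c("gc_donor_vs_acceptor", "genome_size_acceptor_vs_donor",
                    "habitat_distance_vs_evolutionary_distance",
                    "evolutionary_distance_vs_null", "interactions_vs_ogds"))
  expect_true(all(rep$p_value >= 0 & rep$p_value <= 1, na.rm = TRUE))
})
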