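# Calling logic, filters and the cutoff grid. A minimal evaluations table is
# assembled by hand against a small named tree so the rules can be checked
# exactly; engine behaviour on data is covered by the simulation tests.

toy_tree <- function() {
  root_between(hand_tree(), "E,F", 0.5)
}

# one evaluated branch: recipient `rec`, best non-original candidate at
# `ins` with the given elw/distance, original takes the remainder
toy_eval <- function(rec, ins, elw, distance, family = "f1") {
  tibble::tibble(
    family = family, recipient = rec,
    candidate = 1:2,
    insertion = c(rec_orig_key(rec), ins),
    is_original = c(TRUE, FALSE),
    log_lik = c(-10, -5),
    elw = c(1 - elw, elw),
    distance = c(0, distance)
  )
}
rec_orig_key <- function(rec) "ORIG"

test_that("calls require both the ELW and the distance cutoff", {
  tr <- toy_tree()
  cfg <- scan_config()
  ev <- dplyr::bind_rows(
    toy_eval("A", "C", 0.64, 1.0),    # below ELW cutoff
    toy_eval("B", "C", 0.90, 0.2),    # phylogenetic-uncertainty guard
    toy_eval("C", "A", 0.90, 0.8),    # both cutoffs met
    toy_eval("D", "B", 0.65, 0.40)    # inclusive boundary
  )
  calls <- call_ogds(ev, tr, cfg)
  expect_setequal(calls$recipient, c("C", "D"))
  expect_equal(calls$donor[calls$recipient == "C"], "A")

  strict <- scan_config(inclusive = FALSE)
  calls2 <- call_ogds(ev, tr, strict)
  expect_equal(calls2$recipient, "C")
})

test_that("reciprocal pairs are removed and the filter is idempotent", {
  calls <- tibble::tibble(
    family = "f1",
    recipient = c("A", "B", "C"),
    donor = c("B", "A", "D"),
    elw = 0.9, distance = 1, original_elw = 0
  )
  kept <- filter_reciprocal(calls)
  expect_equal(kept$recipient, "C")
  expect_identical(filter_reciprocal(kept), kept)
  # the same pair in different families is not reciprocal
  calls2 <- calls
  calls2$family <- c("f1", "f2", "f1")
  expect_equal(nrow(filter_reciprocal(calls2)), 3L)
})

test_that("ancestral donors are removed; sister and descendant donors kept", {
  tr <- toy_tree()
  calls <- tibble::tibble(
    family = "f1",
    recipient = c("A", "A", "A,B"),
    donor = c("A,B", "C,D", "A"),   # parent branch; sister clade; descendant
    elw = 0.9, distance = 1, original_elw = 0
  )
  kept <- filter_ancestral_donor(calls, tr)
  expect_setequal(kept$donor, c("C,D", "A"))
  expect_identical(filter_ancestral_donor(kept, tr), kept)
})

test_that("a family scan is deterministic and unique per branch", {
  fix <- memo("scan_fix", ogd_fixture(n_taxa = 8, n_families = 1,
                                      n_transfers = 1, sites = 150, seed = 5))
  cfg <- scan_config(seed = 5, B = 300)
  s1 <- scan_family(fix$tree, fix$alignments$fam01, cfg, family = "fam01")
  s2 <- scan_family(fix$tree, fix$alignments$fam01, cfg, family = "fam01")
  expect_identical(s1$evaluations, s2$evaluations)
  expect_identical(s1$all_calls, s2$all_calls)

  # candidate count = 2m - 3 per pruned branch; ELW sums to 1 per branch
  per_branch <- dplyr::count(s1$evaluations, recipient)
  b <- fix$tree$branches
  for (k in seq_len(nrow(per_branch))) {
    sz <- b$size[match(per_branch$recipient[k], b$key)]
    m <- fix$tree$n - sz
    expect_equal(per_branch$n[k], 2L * m - 3L)
  }
  sums <- dplyr::summarise(dplyr::group_by(s1$evaluations, recipient),
                           s = sum(elw))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # uniqueness: at most one call per (family, branch)
  expect_lte(max(table(s1$calls$recipient), 0), 1)

  expect_s3_class(tidy(s1), "tbl_df")
  expect_equal(glance(s1)$n_calls, nrow(s1$calls))
  expect_s3_class(autoplot(s1), "ggplot")
})

test_that("an uninformative family yields near-uniform weights and no calls", {
  fix <- memo("scan_fix", ogd_fixture(n_taxa = 8, n_families = 1,
                                      n_transfers = 1, sites = 150, seed = 5))
  const <- matrix("A", nrow = fix$tree$n, ncol = 30,
                  dimnames = list(fix$tree$labels, NULL))
  ev <- evaluate_branch(fix$tree, which(fix$tree$branches$size == 1)[1],
                        const, scan_config(seed = 1, B = 200))
  expect_true(attr(ev, "uninformative"))
  expect_equal(sum(ev$elw), 1, tolerance = 1e-9)
  expect_equal(nrow(call_ogds(dplyr::mutate(ev, family = "f",
                                            recipient = attr(ev, "recipient")),
                              fix$tree, scan_config())), 0L)
})

test_that("the cutoff grid has 100 cells, monotone in both axes", {
  fix <- memo("scan_fix", ogd_fixture(n_taxa = 8, n_families = 1,
                                      n_transfers = 1, sites = 150, seed = 5))
  sc <- memo("scan_fix_scan",
             scan_family(fix$tree, fix$alignments$fam01,
                         scan_config(seed = 5, B = 300), family = "fam01"))
  g <- parameter_grid(sc)
  expect_equal(nrow(g), 100L)
  expect_s3_class(autoplot(g), "ggplot")

  surf <- tidyr::pivot_wider(g, names_from = "distance_cutoff",
                             values_from = "n_ogds")
  mat <- as.matrix(surf[, -1])
  expect_true(all(apply(mat, 1, function(r) all(diff(r) <= 0))))   # distance axis
  expect_true(all(apply(mat, 2, function(c) all(diff(c) <= 0))))   # ELW axis
  expect_lte(g$n_ogds[g$elw_cutoff == 1 & g$distance_cutoff == 1],
             g$n_ogds[g$elw_cutoff == 0.55 & g$distance_cutoff == 0.1])
  expect_error(parameter_grid(sc, elw_grid = c(0.4, 0.6)), "exceed 0.5")
})
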