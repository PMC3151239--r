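# Shared fixtures and independent oracles. Everything is generated in code;
# expensive objects are cached for the duration of the test run.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# The default synthetic fixture: 12 taxa, 5 families (2 with one transfer
# each), 500 sites, seed 42.
default_fixture <- function() memo("fixture", ogd_fixture())

default_scan <- function() memo("scan", {
  fix <- default_fixture()
  scan_families(fix$tree, fix$alignments, scan_config(seed = 42L))
})

sorted_branches <- function(tree) {
  b <- tree_branches(tree)
  b[order(b$key), ]
}

# Canonicalise each branch bipartition to the side NOT containing the
# smallest label, so trees with different (rooted vs unrooted) orientations
# compare equal when their splits and lengths agree.
canonical_splits <- function(tree) {
  b <- tree_branches(tree)
  all_l <- sort(unique(unlist(b$clade)))
  key <- vapply(b$clade, function(cl) {
    side <- if (all_l[1L] %in% cl) setdiff(all_l, cl) else cl
    paste(sort(side), collapse = ",")
  }, character(1))
  out <- data.frame(key = key, length = b$length)
  out[order(out$key), ]
}

has_split <- function(tree, side) {
  b <- tree_branches(tree)
  all_l <- sort(unique(unlist(b$clade)))
  any(vapply(b$clade, function(cl)
    setequal(cl, side) || setequal(setdiff(all_l, cl), side), logical(1)))
}

branch_midpoint_pt <- function(tree, branch) {
  b <- tree_branches(tree)
  i <- if (is.character(branch)) match(branch, b$key) else branch
  new_tree_point(i, b$length[i] / 2)
}

# A small hand tree used across files: 6 leaves, unrooted, all lengths known.
hand_tree <- function() {
  parse_newick("(((A:0.1,B:0.2):0.3,(C:0.4,D:0.5):0.6):0.7,E:0.8,F:0.9);")
}

random_alignment <- function(labels, sites, seed) {
  withr::with_seed(seed, {
    m <- matrix(sample(AA_ALPHABET, length(labels) * sites, replace = TRUE),
                nrow = length(labels))
    rownames(m) <- labels
    m
  })
}

# Independent sitewise log-likelihood oracle: exhaustive summation over all
# internal-node state assignments (feasible for <= 5 leaves).
enum_site_ll <- function(phy, aln, model, rates = NULL) {
  n <- length(phy$tip.label)
  enc <- matrix(match(aln, AA_ALPHABET), nrow(aln), ncol(aln))
  rownames(enc) <- rownames(aln)
  enc <- enc[phy$tip.label, , drop = FALSE]
  internals <- sort(unique(phy$edge[phy$edge[, 1L] > n, 1L]))
  root <- n + 1L
  rs <- if (is.null(rates)) 1 else rates$rates
  grids <- do.call(expand.grid, rep(list(1:20), length(internals)))
  sapply(seq_len(ncol(enc)), function(s) {
    per_cat <- sapply(rs, function(r) {
      P <- lapply(seq_len(nrow(phy$edge)), function(i)
        transition_probabilities(model, phy$edge.length[i], r))
      tot <- 0
      for (g in seq_len(nrow(grids))) {
        state <- integer(max(phy$edge))
        state[internals] <- as.integer(grids[g, ])
        state[seq_len(n)] <- enc[, s]
        pr <- model$pi[state[root]]
        for (i in seq_len(nrow(phy$edge))) {
          u <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
          if (v <= n && is.na(state[v])) next  # missing tip: sums to 1
          pr <- pr * P[[i]][state[u], state[v]]
        }
        tot <- tot + pr
      }
      tot
    })
    log(mean(per_cat))
  })
}
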