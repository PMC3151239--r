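# Synthetic data with known ground truth: ultrametric species trees,
# transfer-perturbed gene trees (SPR of the recipient lineage, i.e.
# displacement semantics: the recipient's gene copy comes to descend from
# the donor), alignments evolved forward under the scan's own model, and
# clade-correlated trait tables. Everything is deterministic per seed.

#' Simulate an ultrametric species tree
#'
#' A pure-birth (Yule) tree with `n` leaves, rescaled so the root-to-tip
#' height equals `height` substitutions/site, returned as an unrooted tree
#' with an explicit root point at the original root position. Labels are
#' `t001`, `t002`, ...
#'
#' @param n Leaf count, `>= 4`.
#' @param birth Birth rate of the Yule process (default 1; affects relative
#'   node depths only, since the tree is rescaled).
#' @param seed Integer seed.
#' @param height Root-to-tip height in substitutions/site (default 2).
#' @return A rooted `ogd_tree`.
#' @export
simulate_tree <- function(n, birth = 1, seed = 1L, height = 2) {
  if (n < 4L) abort("Need at least 4 leaves.")
  phy <- withr::with_seed(as.integer(seed),
                          ape::rphylo(n, birth = birth, death = 0))
  phy$tip.label <- sprintf("t%03d", seq_len(n))
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (height / depth)
  from_rooted_phylo(phy)
}

from_rooted_phylo <- function(phy) {
  n <- length(phy$tip.label)
  rootn <- n + 1L
  kid_edges <- which(phy$edge[, 1L] == rootn)
  stopifnot(length(kid_edges) == 2L)
  kids <- phy$edge[kid_edges, 2L]
  lens <- phy$edge.length[kid_edges]
  side1 <- phy$tip.label[tips_below(phy, kids[1L])]
  anchor <- min(phy$tip.label)
  if (anchor %in% side1) {
    clade <- sort_c(setdiff(phy$tip.label, side1))
    fraction <- if (sum(lens) > 0) lens[1L] / sum(lens) else 0.5
  } else {
    clade <- sort_c(side1)
    fraction <- if (sum(lens) > 0) lens[2L] / sum(lens) else 0.5
  }
  new_ogd_tree(ape::unroot(phy), root = list(clade = clade, fraction = fraction))
}

#' Inject transfer events into a gene tree
#'
#' Applies `k` subtree-prune-regraft moves to a copy of the species tree,
#' each moving a small recipient clade (1 to `max_clade` leaves) to the
#' midpoint of a donor branch at a residual-tree path-length distance of at
#' least `min_distance` from its original attachment. Events are kept
#' independent: recipient and donor leaf neighbourhoods of successive events
#' do not overlap. The returned truth records identify recipient and donor
#' as combined-tree branches and carry the realised distance.
#'
#' When the species tree is rooted (e.g. the ultrametric trees from
#' [simulate_tree()]), donor and recipient branches are additionally required
#' to overlap in depth from the root: a transfer can only happen between
#' lineages that coexist, which is what makes the donor/acceptor dating
#' intervals of true events coincide in the clock limit.
#'
#' @param tree The species `ogd_tree`.
#' @param k Number of transfer events (`>= 0`).
#' @param min_distance Minimum residual-tree distance (default 0.6).
#' @param seed Integer seed.
#' @param max_clade Largest recipient clade size (default 3).
#' @param max_tries Resampling attempts before giving up.
#' @return List with `gene_tree` (an `ogd_tree`) and `truth` (tibble:
#'   `recipient`, `donor`, `distance`, `n_leaves`).
#' @export
inject_transfers <- function(tree, k, min_distance = 0.6, seed = 1L,
                             max_clade = 3L, max_tries = 200L) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (k == 0L) {
    return(list(gene_tree = tree,
                truth = tibble(recipient = character(), donor = character(),
                               distance = numeric(), n_leaves = integer())))
  }
  # depth spans of the species-tree branches (for the coexistence constraint)
  spans <- NULL
  if (!is.null(tree$root)) {
    rg <- rooted_geometry(tree)
    hi <- rg$depth[rg$node_of_branch]
    spans <- cbind(lo = pmax(hi - tree$branches$length, 0), hi = hi)
    rownames(spans) <- tree$branches$key
  }
  coexist <- function(key1, key2) {
    if (is.null(spans)) return(TRUE)
    s1 <- spans[key1, ]; s2 <- spans[key2, ]
    max(s1["lo"], s2["lo"]) <= min(s1["hi"], s2["hi"]) + 1e-12
  }

  withr::with_seed(as.integer(seed), {
    gene <- tree
    used <- character(0)
    truth <- vector("list", k)
    for (ev in seq_len(k)) {
      done <- FALSE
      for (try in seq_len(max_tries)) {
        gb <- gene$branches
        ok <- which(gb$size >= 1L & gb$size <= min(max_clade, gene$n - 4L) &
                      gb$key %in% tree$branches$key &
                      !map_lgl(gb$clade, function(cl) any(cl %in% used)))
        if (!length(ok)) break
        ri <- if (length(ok) == 1L) ok else sample(ok, 1L)
        rec_clade <- gb$clade[[ri]]
        rec_key <- branch_key(rec_clade)
        pruned <- prune_clade(gene, ri)
        pts <- insertion_points(pruned)
        D <- ape::dist.nodes(pruned$residual$phylo)
        p0 <- new_tree_point(pruned$attachment$branch, pruned$attachment$offset)
        d0 <- point_node_distances(pruned$residual, p0, D)
        rb <- pruned$residual$branches
        dist <- pmin(d0[rb$parent] + pts$offset,
                     d0[rb$child] + (rb$length - pts$offset))
        dist[pts$is_original] <- 0
        cand <- which(!pts$is_original & dist >= min_distance &
                        !map_lgl(rb$clade, function(cl) any(cl %in% used)))
        if (!length(cand)) next
        donor_fulls <- vapply(cand, function(ci)
          match_full_branch(tree, rb$clade[[pts$branch[ci]]], rec_clade),
          integer(1))
        admissible <- vapply(seq_along(cand), function(j) {
          if (is.na(donor_fulls[j])) return(FALSE)
          donor_clade <- tree$branches$clade[[donor_fulls[j]]]
          # donors ancestral to the recipient are vertical signal, not HGT
          if (all(rec_clade %in% donor_clade)) return(FALSE)
          coexist(rec_key, tree$branches$key[donor_fulls[j]])
        }, logical(1))
        cand <- cand[admissible]; donor_fulls <- donor_fulls[admissible]
        if (!length(cand)) next
        j <- if (length(cand) == 1L) 1L else sample(length(cand), 1L)
        ci <- cand[j]
        donor_key <- tree$branches$key[donor_fulls[j]]
        gene <- regraft(pruned, pts$branch[ci], pts$offset[ci])
        truth[[ev]] <- tibble(recipient = branch_key(rec_clade),
                              donor = donor_key,
                              distance = dist[ci],
                              n_leaves = length(rec_clade))
        used <- c(used, rec_clade,
                  strsplit(donor_key, ",", fixed = TRUE)[[1L]])
        done <- TRUE
        break
      }
      if (!done) {
        abort(paste0("Could not place transfer ", ev, " of ", k,
                     " under the independence and distance constraints; ",
                     "try fewer transfers or a smaller min_distance."))
      }
    }
    list(gene_tree = gene, truth = bind_rows(truth))
  })
}

#' Evolve an alignment along a tree
#'
#' Forward simulation under the substitution model: root states drawn from
#' the stationary frequencies, states evolved edge by edge via
#' [transition_probabilities()]; with a rate model, each site draws its
#' category uniformly.
#'
#' @param tree An `ogd_tree` or `phylo` (the gene tree).
#' @param length Number of sites.
#' @param model An `ogd_model` (default JTT with model frequencies).
#' @param rates Optional `ogd_rates`.
#' @param seed Integer seed.
#' @return Character matrix (taxa x sites).
#' @export
evolve_alignment <- function(tree, length, model = jtt_model(), rates = NULL,
                             seed = 1L) {
  if (length < 1L) abort("`length` must be >= 1.")
  phy <- if (inherits(tree, "ogd_tree")) tree$phylo else tree
  n <- length(phy$tip.label)
  rs <- category_rates(rates)
  withr::with_seed(as.integer(seed), {
    cat_of_site <- if (length(rs) == 1L) rep(1L, length) else
      sample.int(length(rs), length, replace = TRUE)
    nn <- max(phy$edge)
    states <- matrix(0L, nn, length)
    root <- n + 1L
    states[root, ] <- sample.int(20L, length, replace = TRUE, prob = model$pi)
    pre <- ape::reorder.phylo(phy, "cladewise")
    for (i in seq_len(nrow(pre$edge))) {
      u <- pre$edge[i, 1L]; v <- pre$edge[i, 2L]
      for (ci in seq_along(rs)) {
        sites <- which(cat_of_site == ci)
        if (!length(sites)) next
        P <- transition_probabilities(model, pre$edge.length[i], rs[ci])
        pu <- states[u, sites]
        for (s in unique(pu)) {
          idx <- sites[pu == s]
          states[v, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                       prob = P[s, ])
        }
      }
    }
    m <- matrix(AA_ALPHABET[states[seq_len(n), , drop = FALSE]], nrow = n)
    rownames(m) <- phy$tip.label
    m
  })
}

#' Simulate a clade-correlated trait table
#'
#' GC content follows a Brownian walk along the tree reflected into
#' `gc_range`; genome size is Brownian on the log scale (log-normal across
#' taxa); habitat observation counts are multinomial draws from softmax'd
#' Brownian latent category weights, so related taxa share habitat biases.
#'
#' @param tree An `ogd_tree`.
#' @param seed Integer seed.
#' @param gc_range Reflection bounds for GC% (default 25-75).
#' @param gc_sigma Brownian standard deviation of GC% per unit branch length.
#' @param size_sigma Brownian sd of log genome size per unit branch length.
#' @param hab_sigma Brownian sd of the latent habitat weights.
#' @return Tibble: `taxon`, `gc_percent`, `genome_mb`, six `hab_*` counts.
#' @export
simulate_traits <- function(tree, seed = 1L, gc_range = c(25, 75),
                            gc_sigma = 8, size_sigma = 0.4, hab_sigma = 1.5) {
  stopifnot(inherits(tree, "ogd_tree"))
  phy <- tree$phylo
  n <- length(phy$tip.label)
  withr::with_seed(as.integer(seed), {
    nn <- max(phy$edge)
    gc <- numeric(nn); lsz <- numeric(nn)
    hab <- matrix(0, nn, 6L)
    root <- n + 1L
    gc[root] <- mean(gc_range)
    lsz[root] <- log(4)
    pre <- ape::reorder.phylo(phy, "cladewise")
    reflect <- function(x, lo, hi) {
      span <- hi - lo
      y <- (x - lo) %% (2 * span)
      lo + ifelse(y > span, 2 * span - y, y)
    }
    for (i in seq_len(nrow(pre$edge))) {
      u <- pre$edge[i, 1L]; v <- pre$edge[i, 2L]
      sdl <- sqrt(max(pre$edge.length[i], 1e-8))
      gc[v] <- reflect(gc[u] + rnorm(1, 0, gc_sigma * sdl),
                       gc_range[1L], gc_range[2L])
      lsz[v] <- lsz[u] + rnorm(1, 0, size_sigma * sdl)
      hab[v, ] <- hab[u, ] + rnorm(6L, 0, hab_sigma * sdl)
    }
    counts <- t(vapply(seq_len(n), function(i) {
      p <- exp(hab[i, ] - max(hab[i, ]))
      total <- 1L + rpois(1L, 4)
      as.integer(rmultinom(1L, total, p / sum(p)))
    }, integer(6L)))
    out <- tibble(
      taxon = phy$tip.label,
      gc_percent = gc[seq_len(n)],
      genome_mb = exp(lsz[seq_len(n)])
    )
    out[HABITAT_COLS] <- as.data.frame(counts)
    out
  })
}

#' Build the default synthetic fixture
#'
#' A complete, self-contained test dataset: one species tree, `n_families`
#' gene alignments of which the first `n_transfers` each carry one injected
#' transfer, a trait table, and the truth records. Sub-seeds for every
#' stochastic component are derived from `seed`, so the fixture is fully
#' reproducible.
#'
#' @param n_taxa Leaves in the species tree (default 12).
#' @param n_families Gene families (default 5).
#' @param n_transfers Families carrying one transfer each (default 2).
#' @param sites Alignment length (default 500).
#' @param seed Master seed (default 42).
#' @param height Tree height in substitutions/site (default 2).
#' @param min_distance Minimum residual-tree transfer distance (default 0.6).
#' @return List of class `ogd_fixture`: `tree`, `alignments` (named list),
#'   `truth` (tibble with `family` column), `traits`, `params`.
#' @export
ogd_fixture <- function(n_taxa = 12L, n_families = 5L, n_transfers = 2L,
                        sites = 500L, seed = 42L, height = 2,
                        min_distance = 0.6) {
  if (n_transfers > n_families) abort("`n_transfers` cannot exceed `n_families`.")
  seed <- as.integer(seed)
  tree <- simulate_tree(n_taxa, birth = 1, seed = seed, height = height)
  fams <- sprintf("fam%02d", seq_len(n_families))
  alignments <- vector("list", n_families)
  truth <- vector("list", n_families)
  for (j in seq_len(n_families)) {
    if (j <= n_transfers) {
      inj <- inject_transfers(tree, 1L, min_distance = min_distance,
                              seed = seed + 1000L + j)
      gene <- inj$gene_tree
      truth[[j]] <- mutate(inj$truth, family = fams[j], .before = 1L)
    } else {
      gene <- tree
    }
    alignments[[j]] <- evolve_alignment(gene, sites, jtt_model(),
                                        seed = seed + 2000L + j)
  }
  names(alignments) <- fams
  structure(
    list(tree = tree, alignments = alignments, truth = bind_rows(truth),
         traits = simulate_traits(tree, seed = seed + 3000L),
         params = list(n_taxa = n_taxa, n_families = n_families,
                       n_transfers = n_transfers, sites = sites, seed = seed,
                       height = height, min_distance = min_distance)),
    class = "ogd_fixture"
  )
}

#' @export
print.ogd_fixture <- function(x, ...) {
  p <- x$params
  cat("Synthetic fixture: ", p$n_taxa, " taxa, ", p$n_families, " families (",
      p$n_transfers, " with transfers), ", p$sites, " sites, seed ", p$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write a fixture to disk
#'
#' Emits `combined.nwk` (rooted Newick), one aligned FASTA per family,
#' `traits.tsv`, `truth.tsv` and `manifest.json` recording all parameters
#' and derived seeds. Re-running with the same seed produces byte-identical
#' files.
#'
#' @param fixture An `ogd_fixture`.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "ogd_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "combined.nwk")
  write_newick(fixture$tree, file = p); paths <- c(paths, p)
  for (fam in names(fixture$alignments)) {
    p <- file.path(dir, paste0(fam, ".fasta"))
    write_alignment(fixture$alignments[[fam]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "traits.tsv")
  write_tsv_plain(fixture$traits, p); paths <- c(paths, p)
  p <- file.path(dir, "truth.tsv")
  write_tsv_plain(fixture$truth, p); paths <- c(paths, p)
  p <- file.path(dir, "manifest.json")
  seed <- fixture$params$seed
  manifest <- c(fixture$params, list(
    tree_seed = seed,
    transfer_seeds = seed + 1000L + seq_len(fixture$params$n_transfers),
    alignment_seeds = seed + 2000L + seq_len(fixture$params$n_families),
    trait_seed = seed + 3000L,
    files = basename(paths)
  ))
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated trait table
#'
#' @param path TSV with columns `taxon`, `gc_percent`, `genome_mb` and the
#'   six `hab_*` habitat count columns.
#' @return A tibble.
#' @export
read_traits <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
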