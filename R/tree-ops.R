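# Prune/regraft enumeration and path-length geometry.

#' Prune the clade a branch defines
#'
#' Removes the branch's clade (with the branch itself as the subtree's stem),
#' merging the two branches left dangling at the former attachment node into
#' one branch whose length is their sum. The exact attachment point on the
#' merged branch is recorded so that regrafting there reproduces the original
#' tree.
#'
#' @param tree An `ogd_tree`.
#' @param branch Branch id or key.
#' @return An object of class `ogd_pruned`: list with `residual` (an
#'   `ogd_tree` with `n - k` leaves), `attachment` (branch id + offset of the
#'   original attachment point on the residual tree), `subtree` (the removed
#'   component and its stem length), and `clade` (the pruned leaf labels).
#' @export
prune_clade <- function(tree, branch) {
  stopifnot(inherits(tree, "ogd_tree"))
  i <- resolve_branch(tree, branch)
  br <- tree$branches
  row <- br[i, ]
  k <- row$size
  if (k > tree$n - 3L) {
    abort(paste0("Cannot prune clade of ", k, " leaves from a ", tree$n,
                 "-leaf tree: the residual tree must keep at least 3 leaves ",
                 "(clade size limit ", tree$n - 3L, ")."))
  }
  p <- row$parent; cnode <- row$child

  # branches strictly inside the clade: those whose clade is a proper subset
  inside <- which(br$size < k & vapply(br$clade, function(cl)
    all(cl %in% row$clade[[1L]]), logical(1)))
  if (k == 1L) inside <- integer(0)
  # the two sibling branches at p (other than the pruned branch)
  sib <- which(br$parent == p | br$child == p)
  sib <- setdiff(sib, c(i, inside))
  stopifnot(length(sib) == 2L)
  a <- ifelse(br$parent[sib[1L]] == p, br$child[sib[1L]], br$parent[sib[1L]])
  b <- ifelse(br$parent[sib[2L]] == p, br$child[sib[2L]], br$parent[sib[2L]])
  la <- br$length[sib[1L]]; lb <- br$length[sib[2L]]

  keep <- setdiff(seq_len(nrow(br)), c(i, inside, sib))
  from <- c(as.character(br$parent[keep]), "M1")
  to <- c(as.character(br$child[keep]), "M2")
  len <- c(br$length[keep], la + lb)
  # merged branch M1-M2 spans a..b; reuse original node ids
  from[length(from)] <- as.character(a)
  to[length(to)] <- as.character(b)

  tips_all <- setNames(tree$phylo$tip.label, as.character(seq_len(tree$n)))
  res_tips <- tips_all[!(tips_all %in% row$clade[[1L]])]
  ids_used <- unique(c(from, to))
  base <- ids_used[!(ids_used %in% names(res_tips))][1L]
  if (is.na(base)) base <- from[length(from)]
  rphy <- build_phylo(from, to, len, res_tips, base = base)
  map <- attr(rphy, "node_map")
  residual <- new_ogd_tree(rphy)

  # locate merged branch in the residual table and the attachment offset
  ma <- map[[as.character(a)]]; mb <- map[[as.character(b)]]
  rb <- residual$branches
  mi <- which((rb$parent == ma & rb$child == mb) | (rb$parent == mb & rb$child == ma))
  stopifnot(length(mi) == 1L)
  offset <- if (rb$parent[mi] == ma) la else lb
  attachment <- list(branch = mi, key = rb$key[mi], offset = offset,
                     la = if (rb$parent[mi] == ma) la else lb,
                     lb = if (rb$parent[mi] == ma) lb else la)

  # the removed component, rooted at its former attachment-side node
  if (k == 1L) {
    subtree <- list(kind = "tip", label = row$clade[[1L]], stem = row$length)
  } else {
    sf <- as.character(br$parent[inside]); st <- as.character(br$child[inside])
    sub_tips <- tips_all[tips_all %in% row$clade[[1L]]]
    sphy <- build_phylo(sf, st, br$length[inside], sub_tips,
                        base = as.character(cnode))
    subtree <- list(kind = "clade", phylo = sphy, stem = row$length)
  }
  subtree$clade <- row$clade[[1L]]

  structure(
    list(residual = residual, attachment = attachment, subtree = subtree,
         clade = row$clade[[1L]], source_key = row$key, n_source = tree$n),
    class = "ogd_pruned"
  )
}

#' @export
print.ogd_pruned <- function(x, ...) {
  cat("Pruned tree: clade {", x$source_key, "} (", length(x$clade),
      " leaves) removed; residual ", x$residual$n, " leaves\n", sep = "")
  invisible(x)
}

#' Candidate insertion points after pruning
#'
#' One candidate per residual branch, placed at the branch midpoint, except
#' that on the branch carrying the original attachment the exact original
#' attachment point is used instead of the midpoint (so the original position
#' is always in the candidate set). For a residual tree with m leaves this
#' yields 2m-3 points.
#'
#' @param pruned An `ogd_pruned` from [prune_clade()].
#' @return A tibble with columns `branch`, `key`, `offset`, `is_original`.
#' @export
insertion_points <- function(pruned) {
  stopifnot(inherits(pruned, "ogd_pruned"))
  rb <- pruned$residual$branches
  out <- tibble(
    branch = rb$branch,
    key = rb$key,
    offset = rb$length / 2,
    is_original = rb$branch == pruned$attachment$branch
  )
  out$offset[out$is_original] <- pruned$attachment$offset
  out
}

#' Reattach a pruned subtree at a point
#'
#' Splits the target residual branch at `offset` with a new internal node and
#' attaches the pruned subtree there with its original stem length.
#' Regrafting at the recorded attachment point reproduces the original tree
#' exactly (topology and branch lengths).
#'
#' @param pruned An `ogd_pruned`.
#' @param branch Residual branch id or key of the insertion point.
#' @param offset Distance from the branch's proximal (parent-side) endpoint;
#'   defaults to the recorded original attachment offset when the branch is
#'   the attachment branch, otherwise the branch midpoint.
#' @return An `ogd_tree` with the original leaf count.
#' @export
regraft <- function(pruned, branch, offset = NULL) {
  stopifnot(inherits(pruned, "ogd_pruned"))
  res <- pruned$residual
  i <- resolve_branch(res, branch)
  rb <- res$branches
  len <- rb$length[i]
  att <- pruned$attachment
  if (is.null(offset)) {
    offset <- if (i == att$branch) att$offset else len / 2
  }
  if (offset < -1e-12 || offset > len + 1e-12) {
    abort(paste0("Insertion offset ", format(offset), " lies off the branch ",
                 "(length ", format(len), ")."))
  }
  exact_original <- (i == att$branch) && (abs(offset - att$offset) < 1e-12)
  l1 <- if (exact_original) att$la else offset
  l2 <- if (exact_original) att$lb else len - offset

  keep <- setdiff(seq_len(nrow(rb)), i)
  from <- as.character(rb$parent[keep])
  to <- as.character(rb$child[keep])
  lens <- rb$length[keep]
  from <- c(from, as.character(rb$parent[i]), "X", "X")
  to <- c(to, "X", as.character(rb$child[i]), "SUBROOT")
  lens <- c(lens, l1, l2, pruned$subtree$stem)

  tips <- setNames(res$phylo$tip.label, as.character(seq_len(res$n)))
  if (pruned$subtree$kind == "tip") {
    tips <- c(tips, SUBROOT = pruned$subtree$label)
  } else {
    sphy <- pruned$subtree$phylo
    sn <- length(sphy$tip.label)
    sfrom <- paste0("S", sphy$edge[, 1L])
    sto <- paste0("S", sphy$edge[, 2L])
    # the subtree root node becomes SUBROOT
    rootn <- paste0("S", sn + 1L)
    sfrom[sfrom == rootn] <- "SUBROOT"
    sto[sto == rootn] <- "SUBROOT"
    from <- c(from, sfrom)
    to <- c(to, sto)
    lens <- c(lens, sphy$edge.length)
    tips <- c(tips, setNames(sphy$tip.label, paste0("S", seq_len(sn))))
  }
  phy <- build_phylo(from, to, lens, tips, base = "X")
  new_ogd_tree(phy)
}

# distance from a tree point to every node: offset + nearest endpoint distance
point_node_distances <- function(tree, point, D = NULL) {
  if (is.null(D)) D <- ape::dist.nodes(tree$phylo)
  i <- resolve_branch(tree, point$branch)
  row <- tree$branches[i, ]
  pmin(point$offset + D[row$parent, ], (row$length - point$offset) + D[row$child, ])
}

#' Path-length distance between two points on a tree
#'
#' Sum of branch-length segments along the unique path connecting two tree
#' points (substitutions per site). A tree point is `list(branch =, offset =)`
#' with `offset` measured from the branch's proximal (parent-side) endpoint.
#'
#' @param tree An `ogd_tree`.
#' @param a,b Tree points.
#' @return Nonnegative distance; 0 iff the points coincide.
#' @export
path_length <- function(tree, a, b) {
  stopifnot(inherits(tree, "ogd_tree"))
  ia <- resolve_branch(tree, a$branch)
  ib <- resolve_branch(tree, b$branch)
  if (ia == ib) return(abs(a$offset - b$offset))
  D <- ape::dist.nodes(tree$phylo)
  ra <- tree$branches[ia, ]; rb <- tree$branches[ib, ]
  min(
    a$offset + D[ra$parent, rb$parent] + b$offset,
    a$offset + D[ra$parent, rb$child] + (rb$length - b$offset),
    (ra$length - a$offset) + D[ra$child, rb$parent] + b$offset,
    (ra$length - a$offset) + D[ra$child, rb$child] + (rb$length - b$offset)
  )
}

#' Total branch length within a clade
#'
#' For an internal branch, the sum of the branch lengths strictly inside the
#' clade it defines (the subtending branch's own length is excluded); for a
#' pendant branch, the leaf branch's own length. Used as the evolutionary
#' time/opportunity measure in the rate analysis. Requires a root point.
#'
#' @param tree A rooted `ogd_tree`.
#' @param branch Branch id or key.
#' @return Nonnegative total length (substitutions/site).
#' @export
clade_total_length <- function(tree, branch) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("clade_total_length() requires a root point.")
  i <- resolve_branch(tree, branch)
  br <- tree$branches
  row <- br[i, ]
  if (row$size == 1L) return(row$length)
  inside <- br$size < row$size & vapply(br$clade, function(cl)
    all(cl %in% row$clade[[1L]]), logical(1))
  sum(br$length[inside])
}

#' Last common ancestor of two branches
#'
#' On the rooted tree, the deepest node ancestral to both branch clades.
#' When one branch is ancestral to the other (its clade contains the other's),
#' the nesting is flagged; the ancestral-donor filter consumes this flag.
#'
#' @param tree A rooted `ogd_tree`.
#' @param a,b Branch ids or keys, distinct.
#' @return List with `clade` (leaf set below the LCA), `depth` (distance from
#'   the root point to the LCA), and `nested` (`NA`, `"a"` or `"b"`: which
#'   branch, if either, is ancestral to the other).
#' @export
branch_lca <- function(tree, a, b) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("branch_lca() requires a root point.")
  ia <- resolve_branch(tree, a); ib <- resolve_branch(tree, b)
  if (ia == ib) abort("`a` and `b` must be distinct branches.")
  ca <- tree$branches$clade[[ia]]; cb <- tree$branches$clade[[ib]]
  nested <- if (all(cb %in% ca)) "a" else if (all(ca %in% cb)) "b" else NA_character_
  rg <- rooted_geometry(tree)
  na <- rg$node_of_branch[ia]; nb <- rg$node_of_branch[ib]
  anc_a <- ancestor_chain(rg, na); anc_b <- ancestor_chain(rg, nb)
  common <- intersect(anc_a, anc_b)
  lca <- common[which.max(rg$depth[common])]
  leaves <- rg$phylo$tip.label[tips_below(rg$phylo, lca)]
  list(clade = sort_c(leaves), depth = rg$depth[lca], nested = nested)
}

# rooted phylo + node depths + parent pointers + per-branch child node
rooted_geometry <- function(tree) {
  rp <- rooted_phylo(tree)
  phy <- rp$phylo
  nn <- max(phy$edge)
  parent <- integer(nn)
  for (i in seq_len(nrow(phy$edge))) parent[phy$edge[i, 2L]] <- phy$edge[i, 1L]
  depth <- ape::node.depth.edgelength(phy)
  list(phylo = phy, node_of_branch = rp$node_of_branch,
       root_node = rp$root_node, parent = parent, depth = depth)
}

ancestor_chain <- function(rg, node) {
  out <- node
  while (node != rg$root_node) {
    node <- rg$parent[node]
    out <- c(out, node)
  }
  out
}

# Do two branches of the same tree share an endpoint (or coincide)?
branch_within_one <- function(tree, a, b) {
  ia <- resolve_branch(tree, a); ib <- resolve_branch(tree, b)
  if (ia == ib) return(TRUE)
  ea <- unlist(tree$branches[ia, c("parent", "child")])
  eb <- unlist(tree$branches[ib, c("parent", "child")])
  length(intersect(ea, eb)) > 0L
}

# Map a residual-tree branch (by its clade on the residual tree) back to a
# branch of the full tree: the full branch whose bipartition, restricted to
# the residual taxa, matches. Ties (the two merged branches at the former
# attachment) resolve to the smallest clade.
match_full_branch <- function(tree, residual_clade, pruned_clade) {
  br <- tree$branches
  residual_taxa <- setdiff(tree$labels, pruned_clade)
  target <- branch_key(residual_clade)
  target_c <- branch_key(setdiff(residual_taxa, residual_clade))
  restricted <- vapply(br$clade, function(cl)
    branch_key(setdiff(cl, pruned_clade)), character(1))
  hits <- which(restricted == target | restricted == target_c)
  if (!length(hits)) return(NA_integer_)
  hits[which.min(br$size[hits])]
}
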