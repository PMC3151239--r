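# Tree representation and bookkeeping.
#
# A tree is an ape `phylo` (unrooted, fully bifurcating, branch lengths in
# substitutions per site) wrapped with a stable branch table. Every branch is
# identified by the leaf set ("clade") it defines: the side of its bipartition
# away from a virtual root. The virtual root is the explicit root point when
# one is set, and otherwise a point on the pendant branch of the anchor leaf
# (the lexicographically smallest label), so that every branch has a proper,
# rotation-invariant clade. Branch ordering is a deterministic post-order with
# children visited in order of their smallest descendant label.

sort_c <- function(x) sort(x, method = "radix")

branch_key <- function(leaves) paste(sort_c(leaves), collapse = ",")

#' Construct a tree point
#'
#' A point on a branch, `offset` substitutions/site from the branch's
#' proximal (parent-side) endpoint. Used by [path_length()] and the
#' regrafting machinery.
#'
#' @param branch Branch id or key.
#' @param offset Nonnegative distance from the proximal endpoint.
#' @return A list with elements `branch` and `offset`.
#' @export
new_tree_point <- function(branch, offset) list(branch = branch, offset = offset)

# adjacency list: per node, data frame of (edge row, neighbour, length)
tree_adjacency <- function(phylo) {
  ne <- nrow(phylo$edge)
  nn <- max(phylo$edge)
  adj <- vector("list", nn)
  for (i in seq_len(ne)) {
    a <- phylo$edge[i, 1L]; b <- phylo$edge[i, 2L]
    adj[[a]] <- rbind(adj[[a]], c(i, b))
    adj[[b]] <- rbind(adj[[b]], c(i, a))
  }
  adj
}

# Post-order walk from `node`, entering along edge `in_edge` (0 for none).
# Returns per-edge child node + clade, plus emission order, via environment acc.
walk_orient <- function(node, in_edge, adj, phylo, acc) {
  nb <- adj[[node]]
  nb <- nb[nb[, 1L] != in_edge, , drop = FALSE]
  if (nrow(nb) == 0L) {
    return(list(leaves = phylo$tip.label[node], minlab = phylo$tip.label[node]))
  }
  kids <- vector("list", nrow(nb))
  for (i in seq_len(nrow(nb))) {
    kids[[i]] <- walk_orient(nb[i, 2L], nb[i, 1L], adj, phylo, acc)
    kids[[i]]$edge <- nb[i, 1L]
    kids[[i]]$child <- nb[i, 2L]
  }
  ord <- order(vapply(kids, function(k) k$minlab, character(1)), method = "radix")
  leaves <- character(0)
  for (i in ord) {
    k <- kids[[i]]
    acc$order <- c(acc$order, k$edge)
    acc$parent[k$edge] <- node
    acc$child[k$edge] <- k$child
    acc$clade[[k$edge]] <- sort_c(k$leaves)
    leaves <- c(leaves, k$leaves)
  }
  list(leaves = leaves, minlab = min(vapply(kids, function(k) k$minlab, character(1))))
}

# Locate the edge whose bipartition separates exactly `clade`; returns
# list(edge, side_node) with side_node the endpoint on the clade side.
find_split_edge <- function(phylo, clade) {
  adj <- tree_adjacency(phylo)
  n <- length(phylo$tip.label)
  base <- n + 1L
  acc <- new.env(parent = emptyenv())
  acc$order <- integer(0)
  acc$parent <- integer(nrow(phylo$edge))
  acc$child <- integer(nrow(phylo$edge))
  acc$clade <- vector("list", nrow(phylo$edge))
  walk_orient(base, 0L, adj, phylo, acc)
  key <- branch_key(clade)
  all_labels <- sort_c(phylo$tip.label)
  for (e in seq_len(nrow(phylo$edge))) {
    k <- branch_key(acc$clade[[e]])
    if (k == key) return(list(edge = e, side_node = acc$child[e]))
    if (branch_key(setdiff(all_labels, acc$clade[[e]])) == key) {
      return(list(edge = e, side_node = acc$parent[e]))
    }
  }
  abort("No branch of the tree defines the requested clade.")
}

build_branch_table <- function(phylo, root = NULL) {
  n <- length(phylo$tip.label)
  adj <- tree_adjacency(phylo)
  if (is.null(root)) {
    anchor <- min(phylo$tip.label)
    x <- match(anchor, phylo$tip.label)
    nb <- adj[[x]]
    root_edge <- nb[1L, 1L]
    y <- nb[1L, 2L]
    designated <- anchor
  } else {
    hit <- find_split_edge(phylo, root$clade)
    root_edge <- hit$edge
    x <- hit$side_node
    y <- setdiff(phylo$edge[root_edge, ], x)
    designated <- root$clade
  }

  acc <- new.env(parent = emptyenv())
  acc$order <- integer(0)
  acc$parent <- integer(nrow(phylo$edge))
  acc$child <- integer(nrow(phylo$edge))
  acc$clade <- vector("list", nrow(phylo$edge))
  resx <- walk_orient(x, root_edge, adj, phylo, acc)
  walk_orient(y, root_edge, adj, phylo, acc)
  acc$order <- c(acc$order, root_edge)
  acc$parent[root_edge] <- y
  acc$child[root_edge] <- x
  acc$clade[[root_edge]] <- sort_c(resx$leaves)
  if (!setequal(acc$clade[[root_edge]], designated)) {
    abort("Internal error: designated root clade does not match tree side.")
  }

  lens <- phylo$edge.length[acc$order]
  clades <- acc$clade[acc$order]
  tibble(
    branch = seq_along(acc$order),
    key = vapply(clades, branch_key, character(1)),
    clade = clades,
    length = lens,
    parent = acc$parent[acc$order],
    child = acc$child[acc$order],
    size = lengths(clades),
    is_pendant = acc$parent[acc$order] <= n | acc$child[acc$order] <= n,
    edge = acc$order
  )
}

new_ogd_tree <- function(phylo, root = NULL) {
  n <- length(phylo$tip.label)
  if (n < 3L) abort("Trees must have at least 3 leaves.")
  if (anyDuplicated(phylo$tip.label)) {
    abort(paste0("Duplicate leaf labels: ",
                 paste(unique(phylo$tip.label[duplicated(phylo$tip.label)]),
                       collapse = ", ")))
  }
  if (is.null(phylo$edge.length)) phylo$edge.length <- rep(0, nrow(phylo$edge))
  phylo$edge.length[is.na(phylo$edge.length)] <- 0
  if (any(phylo$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  expected_nnode <- if (n == 3L) 1L else n - 2L
  if (phylo$Nnode != expected_nnode || nrow(phylo$edge) != 2L * n - 3L) {
    abort(paste0("Tree is not an unrooted fully bifurcating topology ",
                 "(polytomies and rooted topologies must be resolved): ",
                 n, " leaves need ", 2L * n - 3L, " branches, found ",
                 nrow(phylo$edge), "."))
  }
  structure(
    list(
      phylo = phylo,
      n = n,
      labels = sort_c(phylo$tip.label),
      anchor = min(phylo$tip.label),
      root = root,
      branches = build_branch_table(phylo, root)
    ),
    class = "ogd_tree"
  )
}

#' @export
print.ogd_tree <- function(x, ...) {
  cat("Unrooted bifurcating tree:", x$n, "leaves,", nrow(x$branches), "branches\n")
  if (!is.null(x$root)) {
    cat("Root point on branch {", branch_key(x$root$clade), "} at fraction ",
        format(x$root$fraction, digits = 4), "\n", sep = "")
  }
  cat("Total branch length:", format(sum(x$branches$length), digits = 6),
      "substitutions/site\n")
  invisible(x)
}

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) abort(paste0("Newick parse error at position ", i,
                                   ": unmatched ')'"))
    }
  }
  if (depth != 0L) {
    abort(paste0("Newick parse error at position ", length(chars),
                 ": ", depth, " unclosed '('"))
  }
  if (!grepl(";\\s*$", text)) {
    abort(paste0("Newick parse error at position ", length(chars),
                 ": missing terminal ';'"))
  }
  invisible(TRUE)
}

#' Parse a Newick string into a tree
#'
#' Accepts unrooted (basal trifurcation) or rooted (binary root) Newick;
#' a rooted input is converted to an unrooted topology with an explicit root
#' point on the branch that the root bisected. Polytomies are rejected:
#' the placement algebra (2n-3 branch counts, unique merge on pruning)
#' requires full bifurcation. Missing branch lengths default to 0.
#'
#' @param text A Newick string.
#' @param file Alternatively, a path to a Newick file.
#' @return An object of class `ogd_tree`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
#' tree_branches(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    stopifnot(!is.null(file))
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) abort(paste0("Newick parse error: ",
                                                   conditionMessage(e))))
  if (is.null(phy)) abort("Newick parse error: ape could not read the string.")
  n <- length(phy$tip.label)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0, nrow(phy$edge))
  phy$edge.length[is.na(phy$edge.length)] <- 0

  if (ape::is.rooted(phy)) {
    if (phy$Nnode != n - 1L) abort("Rooted input contains polytomies.")
    return(from_rooted_phylo(phy))
  }
  new_ogd_tree(phy)
}

# tip/descendant helper (avoids loading phangorn): tips below `node`
tips_below <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) { out <- c(out, v); next }
    stack <- c(stack, phy$edge[phy$edge[, 1L] == v, 2L])
  }
  out
}

#' Write a tree as Newick
#'
#' Emits unrooted Newick, or rooted Newick with the root bisecting the
#' designated branch when a root point is set. The output re-parses to an
#' identical tree (topology and branch lengths).
#'
#' @param tree An `ogd_tree`.
#' @param file Optional path; when `NULL` the string is returned.
#' @param digits Significant digits for branch lengths.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  stopifnot(inherits(tree, "ogd_tree"))
  phy <- if (is.null(tree$root)) tree$phylo else rooted_phylo(tree)$phylo
  s <- ape::write.tree(phy, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' List the branches of a tree
#'
#' Returns the stable branch table: one row per branch (2n-3 rows) in a
#' deterministic post-order, with the clade (leaf set) each branch defines.
#' Clades are root-distal when a root point is set; otherwise they are taken
#' relative to the anchor leaf (smallest label).
#'
#' @param tree An `ogd_tree`.
#' @return A tibble with columns `branch`, `key` (comma-joined sorted clade),
#'   `clade` (list of leaf labels), `length`, `size`, `is_pendant`.
#' @export
tree_branches <- function(tree) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (tree$n < 4L) abort("Branch enumeration requires at least 4 leaves.")
  select(tree$branches, "branch", "key", "clade", "length", "size", "is_pendant")
}

resolve_branch <- function(tree, branch) {
  if (is.character(branch)) {
    i <- match(branch, tree$branches$key)
    if (is.na(i)) abort(paste0("No branch with clade {", branch, "}."))
    return(i)
  }
  branch <- as.integer(branch)
  if (branch < 1L || branch > nrow(tree$branches)) {
    abort(paste0("Branch id ", branch, " out of range."))
  }
  branch
}

#' Place the root point on a branch
#'
#' Sets the root point at `fraction * length` along the branch, measured from
#' its proximal endpoint (the endpoint on the non-clade side), and re-derives
#' every branch's clade root-distally. For the branch carrying the root point
#' itself, the designated clade is the branch's current clade.
#'
#' @param tree An `ogd_tree`.
#' @param branch Branch id or key (see [tree_branches()]).
#' @param fraction Position along the branch in `[0, 1]`.
#' @return A rooted `ogd_tree`.
#' @export
root_between <- function(tree, branch, fraction = 0.5) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
  i <- resolve_branch(tree, branch)
  new_ogd_tree(tree$phylo,
               root = list(clade = tree$branches$clade[[i]], fraction = fraction))
}

# Materialise the rooted binary phylo (explicit root node bisecting the root
# branch). Returns list(phylo, node_of_branch: for each branch id the child
# node id in the rooted phylo, root_node).
rooted_phylo <- function(tree) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("Tree has no root point; call root_between() first.")
  br <- tree$branches
  rooti <- match(branch_key(tree$root$clade), br$key)
  row <- br[rooti, ]
  d <- tree$root$fraction * row$length
  from <- as.character(br$parent)
  to <- as.character(br$child)
  len <- br$length
  from[rooti] <- "ROOT"; len[rooti] <- row$length - d
  from <- c(from, "ROOT"); to <- c(to, as.character(row$parent)); len <- c(len, d)
  tips <- setNames(tree$phylo$tip.label, as.character(seq_len(tree$n)))
  bp <- build_phylo(from, to, len, tips, base = "ROOT")
  map <- attr(bp, "node_map")
  node_of <- map[as.character(br$child)]
  list(phylo = bp, node_of_branch = unname(node_of), root_node = map[["ROOT"]])
}

# Construct a phylo from directed/undirected edges with arbitrary character
# node ids. Tips are the ids named in `tip_labels`; numbering: tips 1..m
# sorted by label, internals in preorder from `base`.
build_phylo <- function(from, to, length, tip_labels, base) {
  from <- as.character(from); to <- as.character(to); base <- as.character(base)
  ids <- unique(c(from, to))
  idx <- setNames(seq_along(ids), ids)
  ne <- length(from)
  adj <- vector("list", length(ids))
  for (i in seq_len(ne)) {
    a <- idx[[from[i]]]; b <- idx[[to[i]]]
    adj[[a]] <- rbind(adj[[a]], c(i, b))
    adj[[b]] <- rbind(adj[[b]], c(i, a))
  }
  tip_ids <- names(tip_labels)[names(tip_labels) %in% ids]
  labs <- tip_labels[tip_ids]
  ord <- order(labs, method = "radix")
  tip_ids <- tip_ids[ord]; labs <- labs[ord]
  m <- length(tip_ids)
  newid <- setNames(rep(NA_integer_, length(ids)), ids)
  newid[tip_ids] <- seq_len(m)

  # orient edges away from base via BFS; internal nodes numbered on first visit
  edge <- matrix(0L, ne, 2L)
  elen <- numeric(ne)
  next_internal <- m + 1L
  if (is.na(newid[[base]])) {
    newid[[base]] <- next_internal
    next_internal <- next_internal + 1L
  }
  visited <- rep(FALSE, length(ids))
  visited[idx[[base]]] <- TRUE
  queue <- idx[[base]]
  eord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]]
    if (is.null(nb)) next
    for (i in seq_len(nrow(nb))) {
      e <- nb[i, 1L]; w <- nb[i, 2L]
      if (visited[w]) next
      visited[w] <- TRUE
      if (is.na(newid[[ids[w]]])) {
        newid[[ids[w]]] <- next_internal
        next_internal <- next_internal + 1L
      }
      edge[e, ] <- c(newid[[ids[v]]], newid[[ids[w]]])
      elen[e] <- length[e]
      eord <- c(eord, e)
      queue <- c(queue, w)
    }
  }
  phy <- list(
    edge = edge[eord, , drop = FALSE],
    edge.length = elen[eord],
    tip.label = unname(labs),
    Nnode = length(ids) - m
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "node_map") <- newid
  phy
}
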