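# Sitewise log-likelihood of an alignment on a fixed tree (Felsenstein
# pruning with per-message scaling), directional partial messages for fast
# evaluation of alternative attachment points, and branch-length
# optimisation by iterative 1-D search.
#
# Messages are (20 x S) conditional-likelihood matrices carried with a
# per-site log-scaling vector; products of messages add their scales.

BL_MIN <- 1e-8
BL_MAX <- 20

tip_partial <- function(enc_row) {
  s <- length(enc_row)
  m <- matrix(0, 20L, s)
  obs <- which(!is.na(enc_row))
  m[cbind(enc_row[obs], obs)] <- 1
  if (length(obs) < s) m[, setdiff(seq_len(s), obs)] <- 1
  m
}

scale_msg <- function(mat) {
  sc <- colSums(mat)
  sc[sc <= 0] <- 1
  list(mat = mat / rep(sc, each = 20L), logsc = log(sc))
}

logsumexp_rows <- function(m) {
  # m: categories x sites; returns log(mean over categories) per site
  mx <- apply(m, 2L, max)
  mx[!is.finite(mx)] <- 0
  log(colMeans(exp(m - rep(mx, each = nrow(m))))) + mx
}

# Full-tree pruning for one rate category. Returns per-site log-likelihood.
pruning_site_ll <- function(phy, tipp, model, rate) {
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  s <- ncol(tipp[[1L]])
  nn <- max(po$edge)
  part <- vector("list", nn)
  logsc <- numeric(s)
  root <- po$edge[nrow(po$edge), 1L]
  for (i in seq_len(nrow(po$edge))) {
    u <- po$edge[i, 1L]; v <- po$edge[i, 2L]
    pv <- if (v <= n) tipp[[v]] else part[[v]]
    msg <- transition_probabilities(model, po$edge.length[i], rate) %*% pv
    sm <- scale_msg(msg)
    logsc <- logsc + sm$logsc
    part[[u]] <- if (is.null(part[[u]])) sm$mat else part[[u]] * sm$mat
  }
  lik <- colSums(model$pi * part[[root]])
  log(lik) + logsc
}

#' Sitewise log-likelihoods of an alignment on a tree
#'
#' Felsenstein pruning under the given substitution model, with optional
#' discrete-gamma rate mixing (site likelihood averaged over equal-probability
#' categories) and per-message scaling against underflow. Gap and ambiguity
#' characters contribute a partial-likelihood vector of ones (standard
#' missing-data treatment); an all-gap column therefore contributes log(1)=0
#' and is flagged in the `all_gap` attribute. The result is independent of
#' where the (reversible) model is rooted.
#'
#' @param tree An `ogd_tree` or ape `phylo`.
#' @param alignment Character matrix (taxa x sites); must cover the tree's
#'   leaf labels.
#' @param model An `ogd_model` from [jtt_model()].
#' @param rates Optional `ogd_rates` from [discrete_gamma()]; `NULL` for a
#'   single rate.
#' @return Numeric vector of per-site log-likelihoods, with attribute
#'   `all_gap` (logical per site).
#' @export
site_log_likelihoods <- function(tree, alignment, model, rates = NULL) {
  phy <- if (inherits(tree, "ogd_tree")) tree$phylo else tree
  enc <- align_to_labels(alignment, phy$tip.label)
  tipp <- lapply(seq_len(nrow(enc)), function(i) tip_partial(enc[i, ]))
  rs <- category_rates(rates)
  ll <- do.call(rbind, lapply(rs, function(r) pruning_site_ll(phy, tipp, model, r)))
  out <- if (length(rs) == 1L) ll[1L, ] else logsumexp_rows(ll)
  attr(out, "all_gap") <- colSums(!is.na(enc)) == 0L
  out
}

#' Total log-likelihood
#'
#' Sum of a sitewise log-likelihood vector.
#'
#' @param site_ll Numeric vector from [site_log_likelihoods()].
#' @return Scalar sum; 0 for an empty site set.
#' @export
total_log_likelihood <- function(site_ll) {
  if (length(site_ll) == 0L) return(0)
  if (any(!is.finite(site_ll))) abort("Non-finite site log-likelihoods.")
  sum(site_ll)
}

# Directional messages and source bundles for every edge of `phy`.
# For edge i with endpoints (u = edge[i,1], v = edge[i,2]):
#   bundle_uv[[cat]][[i]]: product of messages entering u from all edges
#     except i (a 20 x S matrix + logsc) -- the "outside" partial at u;
#   bundle_vu[[cat]][[i]]: same at v excluding i -- the partial below v.
# The site likelihood of the tree factorises across any edge i as
#   sum_x pi_x [P(t_i) %*% bundle_vu]_x * bundle_uv_x.
directional_messages <- function(phy, tipp, model, rates = NULL) {
  n <- length(phy$tip.label)
  po <- ape::reorder.phylo(phy, "postorder")
  ne <- nrow(po$edge)
  nn <- max(po$edge)
  s <- ncol(tipp[[1L]])
  rs <- category_rates(rates)
  root <- po$edge[ne, 1L]

  # per-node incident edges (in po numbering)
  kids <- vector("list", nn)     # edge indices where node is the parent
  up_edge <- integer(nn)         # edge index toward the root, 0 at root
  for (i in seq_len(ne)) {
    u <- po$edge[i, 1L]; v <- po$edge[i, 2L]
    kids[[u]] <- c(kids[[u]], i)
    up_edge[v] <- i
  }

  res <- list(edge = po$edge, edge.length = po$edge.length, root = root,
              ncat = length(rs), nsite = s)
  res$bundle_uv <- res$bundle_vu <- vector("list", length(rs))

  ones <- list(mat = matrix(1, 20L, s), logsc = numeric(s))
  for (ci in seq_along(rs)) {
    P <- lapply(seq_len(ne), function(i)
      transition_probabilities(model, po$edge.length[i], rs[ci]))
    up <- vector("list", ne)      # message child -> parent along edge
    below <- vector("list", nn)   # product of up-messages of child edges
    below_v <- vector("list", nn) # partial below each node (tip or product)
    for (i in seq_len(ne)) {      # postorder guarantees children first
      u <- po$edge[i, 1L]; v <- po$edge[i, 2L]
      bv <- if (v <= n) list(mat = tipp[[v]], logsc = numeric(s)) else below[[v]]
      below_v[[v]] <- bv
      sm <- scale_msg(P[[i]] %*% bv$mat)
      msg <- list(mat = sm$mat, logsc = sm$logsc + bv$logsc)
      up[[i]] <- msg
      below[[u]] <- if (is.null(below[[u]])) msg else
        list(mat = below[[u]]$mat * msg$mat, logsc = below[[u]]$logsc + msg$logsc)
    }
    down <- vector("list", ne)   # message parent -> child along edge
    outside <- vector("list", nn)  # bundle at node excluding its up-edge
    outside[[root]] <- NULL
    for (i in rev(seq_len(ne))) {  # preorder
      u <- po$edge[i, 1L]; v <- po$edge[i, 2L]
      sib <- setdiff(kids[[u]], i)
      bun <- if (u == root) ones else outside[[u]]
      for (j in sib) {
        bun <- list(mat = bun$mat * up[[j]]$mat, logsc = bun$logsc + up[[j]]$logsc)
      }
      outside_uv <- bun                       # bundle at u excluding edge i
      sm <- scale_msg(P[[i]] %*% bun$mat)
      down[[i]] <- list(mat = sm$mat, logsc = sm$logsc + bun$logsc)
      outside[[v]] <- down[[i]]
    }
    res$bundle_uv[[ci]] <- lapply(seq_len(ne), function(i) {
      u <- po$edge[i, 1L]
      sib <- setdiff(kids[[u]], i)
      bun <- if (u == root) ones else outside[[u]]
      for (j in sib) {
        bun <- list(mat = bun$mat * up[[j]]$mat, logsc = bun$logsc + up[[j]]$logsc)
      }
      bun
    })
    res$bundle_vu[[ci]] <- lapply(seq_len(ne), function(i) below_v[[po$edge[i, 2L]]])
  }
  res
}

# Conditional-likelihood partial at the root of a pruned subtree.
subtree_root_partial <- function(subtree, enc, model, rates = NULL) {
  rs <- category_rates(rates)
  s <- ncol(enc)
  if (subtree$kind == "tip") {
    tp <- tip_partial(enc[subtree$label, ])
    return(lapply(seq_along(rs), function(ci) list(mat = tp, logsc = numeric(s))))
  }
  phy <- subtree$phylo
  n <- length(phy$tip.label)
  tipp <- lapply(seq_len(n), function(i) tip_partial(enc[phy$tip.label[i], ]))
  po <- ape::reorder.phylo(phy, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  lapply(seq_along(rs), function(ci) {
    part <- vector("list", max(po$edge))
    logsc_node <- vector("list", max(po$edge))
    for (i in seq_len(nrow(po$edge))) {
      u <- po$edge[i, 1L]; v <- po$edge[i, 2L]
      bv <- if (v <= n) list(mat = tipp[[v]], logsc = numeric(s))
            else list(mat = part[[v]], logsc = logsc_node[[v]])
      sm <- scale_msg(transition_probabilities(model, po$edge.length[i], rs[ci]) %*% bv$mat)
      if (is.null(part[[u]])) {
        part[[u]] <- sm$mat; logsc_node[[u]] <- sm$logsc + bv$logsc
      } else {
        part[[u]] <- part[[u]] * sm$mat
        logsc_node[[u]] <- logsc_node[[u]] + sm$logsc + bv$logsc
      }
    }
    list(mat = part[[root]], logsc = logsc_node[[root]])
  })
}

# Per-site log-likelihood of an attachment configuration: the pruned subtree
# (root partial Z) joins edge i of the residual tree at distances (du, dv)
# from the edge's two endpoints, with stem length `stem`.
attachment_site_ll <- function(msgs, i, Z, model, rates, du, dv, stem) {
  rs <- category_rates(rates)
  ll <- matrix(0, length(rs), msgs$nsite)
  for (ci in seq_along(rs)) {
    A <- transition_probabilities(model, du, rs[ci]) %*% msgs$bundle_uv[[ci]][[i]]$mat
    B <- transition_probabilities(model, dv, rs[ci]) %*% msgs$bundle_vu[[ci]][[i]]$mat
    C <- transition_probabilities(model, stem, rs[ci]) %*% Z[[ci]]$mat
    lik <- colSums(model$pi * A * B * C)
    ll[ci, ] <- log(lik) + msgs$bundle_uv[[ci]][[i]]$logsc +
      msgs$bundle_vu[[ci]][[i]]$logsc + Z[[ci]]$logsc
  }
  if (length(rs) == 1L) ll[1L, ] else logsumexp_rows(ll)
}

# Coordinate-wise optimisation of the three branch lengths created by an
# attachment (two arcs of the split edge + the subtree stem). Derivative-free
# 1-D search per coordinate, sweeps until the log-likelihood improves by
# less than `tol` (log units) or `max_sweeps` is reached.
optimize_attachment <- function(msgs, i, Z, model, rates, init,
                                tol = 1e-4, max_sweeps = 5L) {
  rs <- category_rates(rates)
  pre <- lapply(seq_along(rs), function(ci) {
    list(U = msgs$bundle_uv[[ci]][[i]],
         V = msgs$bundle_vu[[ci]][[i]],
         Z = Z[[ci]])
  })
  lens <- pmax(init, BL_MIN)

  site_ll_at <- function(lens) {
    ll <- matrix(0, length(rs), msgs$nsite)
    for (ci in seq_along(rs)) {
      A <- transition_probabilities(model, lens[1L], rs[ci]) %*% pre[[ci]]$U$mat
      B <- transition_probabilities(model, lens[2L], rs[ci]) %*% pre[[ci]]$V$mat
      C <- transition_probabilities(model, lens[3L], rs[ci]) %*% pre[[ci]]$Z$mat
      ll[ci, ] <- log(colSums(model$pi * A * B * C)) +
        pre[[ci]]$U$logsc + pre[[ci]]$V$logsc + pre[[ci]]$Z$logsc
    }
    if (length(rs) == 1L) ll[1L, ] else logsumexp_rows(ll)
  }

  best <- sum(site_ll_at(lens))
  for (sweep in seq_len(max_sweeps)) {
    prev <- best
    for (coord in c(3L, 1L, 2L)) {  # stem first: it moved the most
      # cache the two fixed factors (incl. pi) per category
      fixed <- lapply(seq_along(rs), function(ci) {
        mats <- list(
          transition_probabilities(model, lens[1L], rs[ci]) %*% pre[[ci]]$U$mat,
          transition_probabilities(model, lens[2L], rs[ci]) %*% pre[[ci]]$V$mat,
          transition_probabilities(model, lens[3L], rs[ci]) %*% pre[[ci]]$Z$mat
        )
        others <- setdiff(1:3, coord)
        list(prod = model$pi * mats[[others[1L]]] * mats[[others[2L]]],
             free = switch(coord, pre[[ci]]$U$mat, pre[[ci]]$V$mat, pre[[ci]]$Z$mat),
             logsc = pre[[ci]]$U$logsc + pre[[ci]]$V$logsc + pre[[ci]]$Z$logsc)
      })
      obj <- function(t) {
        ll <- matrix(0, length(rs), msgs$nsite)
        for (ci in seq_along(rs)) {
          lik <- colSums(fixed[[ci]]$prod *
                           (transition_probabilities(model, t, rs[ci]) %*% fixed[[ci]]$free))
          ll[ci, ] <- log(lik) + fixed[[ci]]$logsc
        }
        sum(if (length(rs) == 1L) ll[1L, ] else logsumexp_rows(ll))
      }
      opt <- optimize(obj, interval = c(BL_MIN, BL_MAX), maximum = TRUE,
                      tol = 1e-3)
      if (opt$objective > best) {
        best <- opt$objective
        lens[coord] <- opt$maximum
      }
    }
    if (best - prev < tol) break
  }
  list(lengths = lens, site_ll = site_ll_at(lens), total = best)
}

#' Optimise branch lengths on a fixed topology
#'
#' Iterative per-branch 1-D optimisation of the log-likelihood,
#' derivative-free, with lengths bounded to `[1e-8, 20]` substitutions/site.
#' `scope = "local"` optimises only the branches named in `branches` (the
#' intended use is the three branches a regraft creates or modifies);
#' `scope = "full"` sweeps all branches. The total log-likelihood is
#' non-decreasing across updates.
#'
#' @param tree An `ogd_tree`.
#' @param alignment Character matrix covering the tree's leaves.
#' @param model An `ogd_model`.
#' @param rates Optional `ogd_rates`.
#' @param scope `"local"` or `"full"`.
#' @param branches Branch ids or keys to optimise when `scope = "local"`.
#' @param tol Convergence tolerance in log units (default 1e-4).
#' @param max_sweeps Maximum sweeps (default 5 local, 20 full).
#' @return The tree with updated branch lengths; attributes `logLik` and
#'   `converged`.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, rates = NULL,
                                    scope = c("local", "full"),
                                    branches = NULL, tol = 1e-4,
                                    max_sweeps = NULL) {
  stopifnot(inherits(tree, "ogd_tree"))
  scope <- match.arg(scope)
  if (is.null(max_sweeps)) max_sweeps <- if (scope == "local") 5L else 20L
  if (scope == "local" && is.null(branches)) {
    abort("`scope = \"local\"` requires `branches`.")
  }
  target_keys <- if (scope == "full") tree$branches$key else
    tree$branches$key[vapply(branches, function(b) resolve_branch(tree, b), 1L)]

  phy <- tree$phylo
  enc <- align_to_labels(alignment, phy$tip.label)
  tipp <- lapply(seq_len(nrow(enc)), function(i) tip_partial(enc[i, ]))
  rs <- category_rates(rates)

  cur <- tree
  best <- sum(site_log_likelihoods(cur, alignment, model, rates))
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    prev <- best
    for (key in target_keys) {
      bi <- match(key, cur$branches$key)
      msgs <- directional_messages(cur$phylo, tipp, model, rates)
      ei <- match_msg_edge(msgs, cur$branches$parent[bi], cur$branches$child[bi])
      obj <- function(t) {
        ll <- matrix(0, length(rs), msgs$nsite)
        for (ci in seq_along(rs)) {
          lik <- colSums(model$pi * msgs$bundle_uv[[ci]][[ei]]$mat *
                           (transition_probabilities(model, t, rs[ci]) %*%
                              msgs$bundle_vu[[ci]][[ei]]$mat))
          ll[ci, ] <- log(lik) + msgs$bundle_uv[[ci]][[ei]]$logsc +
            msgs$bundle_vu[[ci]][[ei]]$logsc
        }
        sum(if (length(rs) == 1L) ll[1L, ] else logsumexp_rows(ll))
      }
      opt <- optimize(obj, interval = c(BL_MIN, BL_MAX), maximum = TRUE,
                      tol = 1e-4)
      if (opt$objective > best) {
        best <- opt$objective
        edge_row <- which(cur$phylo$edge[, 1L] %in%
                            c(cur$branches$parent[bi], cur$branches$child[bi]) &
                          cur$phylo$edge[, 2L] %in%
                            c(cur$branches$parent[bi], cur$branches$child[bi]))
        phy2 <- cur$phylo
        phy2$edge.length[edge_row] <- opt$maximum
        cur <- new_ogd_tree(phy2, root = cur$root)
      }
    }
    if (best - prev < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("Branch-length optimisation did not converge; returning best so far.")
  }
  attr(cur, "logLik") <- best
  attr(cur, "converged") <- converged
  cur
}

match_msg_edge <- function(msgs, u, v) {
  hit <- which((msgs$edge[, 1L] == u & msgs$edge[, 2L] == v) |
               (msgs$edge[, 1L] == v & msgs$edge[, 2L] == u))
  stopifnot(length(hit) == 1L)
  hit
}
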