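# The core displacement scan: for every branch of the combined tree and a
# gene-family alignment, evaluate all alternative placements of the branch,
# score them by expected likelihood weights, and call putative orthologous
# gene displacements by ELW and path-length-distance cutoffs.

#' Scan configuration
#'
#' Cutoffs, grids and model flags for the displacement scan. The defaults are
#' the conservative plateau settings: a best non-original placement needs an
#' expected likelihood weight of at least 0.65 *and* a path-length distance
#' of at least 0.40 substitutions/site from the original position (the
#' distance guard keeps phylogenetic uncertainty from being mistaken for a
#' displacement). The ELW cutoff must exceed 0.5, which guarantees at most
#' one qualifying placement per pruned branch.
#'
#' @param elw_cutoff Minimum ELW of the best non-original placement
#'   (in `(0.5, 1]`, default 0.65).
#' @param distance_cutoff Minimum path-length distance (substitutions/site)
#'   between the original attachment point and the best placement
#'   (default 0.40).
#' @param inclusive Compare cutoffs with `>=` (default) rather than `>`.
#' @param B RELL bootstrap replicates for the ELW (default 1000).
#' @param seed Integer seed; every stochastic step derives from it.
#' @param branch_mode Branch lengths of candidate trees: `"none"` (default;
#'   candidates keep the reference tree's lengths), `"local"` (re-optimise
#'   the three branches the regraft creates — see the methods vignette for
#'   why this is not the default) or `"full"` (re-optimise every branch;
#'   faithful but slow).
#' @param freqs `"empirical"` (default; +F frequencies from the family
#'   alignment) or `"model"` (JTT frequencies).
#' @param gamma_alpha Optional gamma shape for among-site rate variation;
#'   `NULL` (default) evaluates under a single rate.
#' @param gamma_ncat Rate categories when `gamma_alpha` is set (default 4).
#' @param elw_grid,distance_grid Cutoff grids for [parameter_grid()]
#'   (defaults 0.55..1.00 by 0.05 and 0.1..1.0 by 0.1 — 100 combinations).
#' @return A list of class `ogd_config`.
#' @export
scan_config <- function(elw_cutoff = 0.65, distance_cutoff = 0.40,
                        inclusive = TRUE, B = 1000L, seed = 1L,
                        branch_mode = c("none", "local", "full"),
                        freqs = c("empirical", "model"),
                        gamma_alpha = NULL, gamma_ncat = 4L,
                        elw_grid = seq(0.55, 1, by = 0.05),
                        distance_grid = seq(0.1, 1, by = 0.1)) {
  if (elw_cutoff <= 0.5 || elw_cutoff > 1) {
    abort("`elw_cutoff` must be in (0.5, 1]: above 0.5 the best placement is unique.")
  }
  if (distance_cutoff < 0) abort("`distance_cutoff` must be >= 0.")
  if (!length(elw_grid) || !length(distance_grid)) abort("Grids must be nonempty.")
  structure(
    list(elw_cutoff = elw_cutoff, distance_cutoff = distance_cutoff,
         inclusive = inclusive, B = as.integer(B), seed = as.integer(seed),
         branch_mode = match.arg(branch_mode), freqs = match.arg(freqs),
         gamma_alpha = gamma_alpha, gamma_ncat = as.integer(gamma_ncat),
         elw_grid = elw_grid, distance_grid = distance_grid),
    class = "ogd_config"
  )
}

#' @export
print.ogd_config <- function(x, ...) {
  cat("Displacement scan configuration\n")
  cat("  ELW cutoff:", x$elw_cutoff, if (x$inclusive) "(inclusive)" else "(strict)", "\n")
  cat("  distance cutoff:", x$distance_cutoff, "substitutions/site\n")
  cat("  RELL replicates:", x$B, " seed:", x$seed, "\n")
  cat("  branch lengths:", x$branch_mode, " frequencies:", x$freqs, "\n")
  cat("  rates:", if (is.null(x$gamma_alpha)) "single rate" else
    paste0("gamma(alpha=", x$gamma_alpha, "), ", x$gamma_ncat, " categories"), "\n")
  invisible(x)
}

config_model <- function(config, alignment) {
  if (config$freqs == "empirical") {
    jtt_model(empirical_frequencies(alignment))
  } else {
    jtt_model("model")
  }
}

config_rates <- function(config) {
  if (is.null(config$gamma_alpha)) NULL else
    discrete_gamma(config$gamma_alpha, config$gamma_ncat)
}

cutoff_met <- function(x, cutoff, inclusive) {
  if (inclusive) x >= cutoff - 1e-12 else x > cutoff + 1e-12
}

#' Evaluate every placement of one branch
#'
#' Prunes the branch's clade, enumerates all candidate insertion points on
#' the residual tree (one per residual branch, the original position
#' included), computes each candidate's sitewise log-likelihood under the
#' configured model, and converts the candidate set into expected likelihood
#' weights. Each candidate is annotated with its path-length distance from
#' the original attachment point, measured on the residual tree.
#'
#' @param tree The combined reference tree (`ogd_tree`).
#' @param branch Branch id or key (the recipient candidate).
#' @param alignment Gene-family alignment covering all tree taxa.
#' @param config An `ogd_config`.
#' @param model,rates Optional pre-built model objects (defaults follow
#'   `config`).
#' @return A tibble of class `ogd_evaluation`: one row per candidate
#'   insertion point with columns `candidate`, `insertion` (residual-tree
#'   clade key), `is_original`, `log_lik`, `elw`, `distance`. Attributes:
#'   `recipient` (branch key), `uninformative` (no candidate reaches ELW
#'   0.5), `elw_seed`.
#' @export
evaluate_branch <- function(tree, branch, alignment, config = scan_config(),
                            model = NULL, rates = NULL) {
  stopifnot(inherits(tree, "ogd_tree"))
  i <- resolve_branch(tree, branch)
  if (is.null(model)) model <- config_model(config, alignment)
  if (is.null(rates)) rates <- config_rates(config)

  pruned <- prune_clade(tree, i)
  res <- pruned$residual
  pts <- insertion_points(pruned)
  enc <- align_to_labels(alignment, tree$labels)
  tipp_res <- lapply(res$phylo$tip.label, function(lab) tip_partial(enc[lab, ]))
  msgs <- directional_messages(res$phylo, tipp_res, model, rates)
  Z <- subtree_root_partial(pruned$subtree, enc, model, rates)

  # distances from the original attachment point, on the residual tree
  D <- ape::dist.nodes(res$phylo)
  att <- pruned$attachment
  p0 <- new_tree_point(att$branch, att$offset)
  d0 <- point_node_distances(res, p0, D)
  rb <- res$branches
  dist <- pmin(d0[rb$parent] + pts$offset, d0[rb$child] + (rb$length - pts$offset))
  dist[pts$is_original] <- 0
  same <- rb$branch == att$branch & !pts$is_original
  dist[same] <- abs(pts$offset[same] - att$offset)

  ncand <- nrow(pts)
  site_ll <- matrix(0, ncand, ncol(enc))
  lens <- matrix(0, ncand, 3L)
  for (ci in seq_len(ncand)) {
    bi <- pts$branch[ci]
    ei <- match_msg_edge(msgs, rb$parent[bi], rb$child[bi])
    off <- pts$offset[ci]
    if (msgs$edge[ei, 1L] == rb$parent[bi]) {
      init <- c(off, rb$length[bi] - off, pruned$subtree$stem)
    } else {
      init <- c(rb$length[bi] - off, off, pruned$subtree$stem)
    }
    if (config$branch_mode == "local") {
      fit <- optimize_attachment(msgs, ei, Z, model, rates, init)
      site_ll[ci, ] <- fit$site_ll
      lens[ci, ] <- fit$lengths
    } else if (config$branch_mode == "none") {
      site_ll[ci, ] <- attachment_site_ll(msgs, ei, Z, model, rates,
                                          init[1L], init[2L], init[3L])
      lens[ci, ] <- init
    } else {  # full re-optimisation on the regrafted tree
      cand_tree <- regraft(pruned, bi, off)
      opt <- optimize_branch_lengths(cand_tree, alignment, model, rates,
                                     scope = "full")
      site_ll[ci, ] <- site_log_likelihoods(opt, alignment, model, rates)
      lens[ci, ] <- NA_real_
    }
  }

  elw_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
  elw <- expected_likelihood_weights(site_ll, B = config$B, seed = elw_seed)

  out <- tibble(
    candidate = seq_len(ncand),
    insertion = pts$key,
    is_original = pts$is_original,
    log_lik = rowSums(site_ll),
    elw = as.numeric(elw),
    distance = dist
  )
  attr(out, "recipient") <- tree$branches$key[i]
  attr(out, "recipient_branch") <- i
  attr(out, "uninformative") <- max(out$elw) < 0.5
  attr(out, "elw_seed") <- elw_seed
  attr(out, "site_ll") <- site_ll
  class(out) <- c("ogd_evaluation", class(out))
  out
}

# Reduce per-candidate evaluations to one row per (family, recipient):
# the original position's ELW and the best non-original candidate.
summarise_evaluations <- function(evaluations) {
  orig <- evaluations |>
    filter(.data$is_original) |>
    group_by(.data$family, .data$recipient) |>
    summarise(original_elw = sum(.data$elw), .groups = "drop")
  evaluations |>
    filter(!.data$is_original) |>
    group_by(.data$family, .data$recipient) |>
    arrange(desc(.data$elw), .data$candidate, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    ungroup() |>
    select("family", "recipient", donor_insertion = "insertion",
           "elw", "distance") |>
    left_join(orig, by = c("family", "recipient"))
}

#' Call putative displacements from placement evaluations
#'
#' A (family, branch) pair yields a call iff the best non-original placement
#' reaches the ELW cutoff *and* its path-length distance from the original
#' position reaches the distance cutoff. The pruned branch is the recipient;
#' the branch carrying the best placement is the donor. With an ELW cutoff
#' above 0.5 at most one placement can qualify per pruned branch.
#'
#' Donor branches are reported as combined-tree branches: the insertion
#' branch of the residual tree is mapped to the combined-tree branch whose
#' bipartition restricted to the residual taxa matches (ties at the former
#' attachment resolve to the smallest clade).
#'
#' @param evaluations Row-bound [evaluate_branch()] tibbles with `family` and
#'   `recipient` columns (as produced by [scan_family()]).
#' @param tree The combined reference tree.
#' @param config An `ogd_config`.
#' @return A tibble of calls: `family`, `recipient`, `donor`, `elw`,
#'   `distance`, `original_elw`.
#' @export
call_ogds <- function(evaluations, tree, config = scan_config()) {
  smry <- if (identical(attr(evaluations, "summarised"), TRUE)) evaluations
          else summarise_evaluations(evaluations)
  hits <- smry |>
    filter(cutoff_met(.data$elw, config$elw_cutoff, config$inclusive),
           cutoff_met(.data$distance, config$distance_cutoff, config$inclusive))
  if (nrow(hits) == 0L) {
    return(tibble(family = character(), recipient = character(),
                  donor = character(), elw = numeric(), distance = numeric(),
                  original_elw = numeric()))
  }
  donor <- map_chr(seq_len(nrow(hits)), function(k) {
    ri <- resolve_branch(tree, hits$recipient[k])
    full <- match_full_branch(tree,
                              strsplit(hits$donor_insertion[k], ",", fixed = TRUE)[[1L]],
                              tree$branches$clade[[ri]])
    if (is.na(full)) NA_character_ else tree$branches$key[full]
  })
  hits |>
    mutate(donor = donor) |>
    select("family", "recipient", "donor", "elw", "distance", "original_elw")
}

#' Remove reciprocal ("double") transfers
#'
#' If, within one gene family, two branches are each other's donor and
#' recipient, the direction of transfer cannot be identified and both calls
#' are disregarded. Idempotent.
#'
#' @param calls A call tibble from [call_ogds()].
#' @return The calls with reciprocal pairs removed.
#' @export
filter_reciprocal <- function(calls) {
  if (nrow(calls) == 0L) return(calls)
  fwd <- paste(calls$family, calls$recipient, calls$donor, sep = "\r")
  rev <- paste(calls$family, calls$donor, calls$recipient, sep = "\r")
  calls[!(rev %in% fwd), , drop = FALSE]
}

#' Remove transfers from an ancestral donor
#'
#' Calls whose donor branch lies on the root-ward path of the recipient (the
#' donor's root-distal clade properly contains the recipient's) are
#' disregarded: such a placement cannot be distinguished from the signal of
#' shared ancestry. Descendant donors are kept. Idempotent.
#'
#' @param calls A call tibble.
#' @param tree The rooted combined tree.
#' @return The calls without ancestral-donor events.
#' @export
filter_ancestral_donor <- function(calls, tree) {
  if (is.null(tree$root)) abort("filter_ancestral_donor() requires a rooted tree.")
  if (nrow(calls) == 0L) return(calls)
  keep <- map_lgl(seq_len(nrow(calls)), function(k) {
    if (is.na(calls$donor[k])) return(TRUE)
    rc <- tree$branches$clade[[resolve_branch(tree, calls$recipient[k])]]
    dc <- tree$branches$clade[[resolve_branch(tree, calls$donor[k])]]
    !(length(dc) > length(rc) && all(rc %in% dc))
  })
  calls[keep, , drop = FALSE]
}

apply_filters <- function(calls, tree) {
  if (nrow(calls) == 0L) {
    return(mutate(calls, filtered_reason = character(0)))
  }
  after_recip <- filter_reciprocal(calls)
  after_anc <- filter_ancestral_donor(after_recip, tree)
  id <- function(x) paste(x$family, x$recipient, x$donor, sep = "\r")
  calls |>
    mutate(filtered_reason = dplyr::case_when(
      !(id(calls) %in% id(after_recip)) ~ "reciprocal",
      !(id(calls) %in% id(after_anc)) ~ "ancestral_donor",
      TRUE ~ ""
    ))
}

#' Scan one gene family against the combined tree
#'
#' Evaluates every prunable branch of the combined tree with
#' [evaluate_branch()], calls putative displacements and applies the
#' reciprocal-transfer and ancestral-donor filters. Branches whose clade
#' leaves fewer than 3 residual leaves cannot be evaluated and are skipped.
#' Deterministic given the configuration seed.
#'
#' @param tree The rooted combined reference tree.
#' @param alignment Gene-family alignment (one sequence per tree taxon).
#' @param config An `ogd_config`.
#' @param family Family identifier carried through the outputs.
#' @param progress Emit per-branch progress via `message()` (default FALSE).
#' @return An object of class `ogd_scan`: list with `evaluations` (all
#'   candidates, all branches), `calls` (post-filter), `all_calls` (with
#'   `filtered_reason`), `skipped` branch keys, `config`.
#' @export
scan_family <- function(tree, alignment, config = scan_config(),
                        family = "family", progress = FALSE) {
  stopifnot(inherits(tree, "ogd_tree"))
  br <- tree$branches
  prunable <- which(br$size <= tree$n - 3L)
  model <- config_model(config, alignment)
  rates <- config_rates(config)
  evals <- vector("list", length(prunable))
  for (k in seq_along(prunable)) {
    i <- prunable[k]
    if (progress) {
      message("[", family, "] branch ", k, "/", length(prunable),
              " {", br$key[i], "}")
    }
    ev <- evaluate_branch(tree, i, alignment, config, model, rates)
    ev$family <- family
    ev$recipient <- attr(ev, "recipient")
    evals[[k]] <- as_tibble(ev)
  }
  evaluations <- bind_rows(evals)
  all_calls <- apply_filters(call_ogds(evaluations, tree, config), tree)
  structure(
    list(evaluations = evaluations,
         calls = filter(all_calls, .data$filtered_reason == "") |>
           select(-"filtered_reason"),
         all_calls = all_calls,
         skipped = br$key[br$size > tree$n - 3L],
         families = family,
         config = config, tree = tree),
    class = "ogd_scan"
  )
}

#' Scan several gene families
#'
#' @param tree The rooted combined reference tree.
#' @param alignments Named list of family alignments.
#' @param config An `ogd_config`.
#' @param progress Emit progress messages.
#' @return An `ogd_scan` covering all families.
#' @export
scan_families <- function(tree, alignments, config = scan_config(),
                          progress = FALSE) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  scans <- imap(alignments, function(aln, fam)
    scan_family(tree, aln, config, family = fam, progress = progress))
  evaluations <- bind_rows(map(scans, "evaluations"))
  all_calls <- bind_rows(map(scans, "all_calls"))
  structure(
    list(evaluations = evaluations,
         calls = filter(all_calls, .data$filtered_reason == "") |>
           select(-"filtered_reason"),
         all_calls = all_calls,
         skipped = scans[[1L]]$skipped,
         families = names(alignments),
         config = config, tree = tree),
    class = "ogd_scan"
  )
}

#' @export
print.ogd_scan <- function(x, ...) {
  cat("Displacement scan:", length(x$families), "family(ies),",
      length(unique(x$evaluations$recipient)), "branches evaluated\n")
  cat("  calls at ELW >=", x$config$elw_cutoff, "& distance >=",
      x$config$distance_cutoff, ":", nrow(x$calls), "\n")
  if (nrow(x$all_calls) > nrow(x$calls)) {
    cat("  filtered:", nrow(x$all_calls) - nrow(x$calls),
        "(reciprocal / ancestral donor)\n")
  }
  invisible(x)
}

#' Cutoff-grid exploration of the number of displacements
#'
#' Recomputes the call count at every combination of ELW and distance
#' cutoffs (defaults: 10 x 10 = 100 combinations). Counts include the
#' ancestral-donor filter but not the reciprocal-direction rule: the latter
#' removes *pairs* of calls and can therefore revive a call when its partner
#' drops out at a stricter cutoff, which would make the surface non-monotone.
#' With per-call criteria only, counts are monotone non-increasing in both
#' cutoffs.
#'
#' @param scan An `ogd_scan` (or an evaluations tibble plus `tree`).
#' @param tree Combined tree (taken from `scan` when omitted).
#' @param elw_grid,distance_grid Cutoff grids (defaults from the scan config).
#' @return A tibble of class `ogd_grid`: `elw_cutoff`, `distance_cutoff`,
#'   `n_ogds`.
#' @export
parameter_grid <- function(scan, tree = NULL, elw_grid = NULL,
                           distance_grid = NULL) {
  if (inherits(scan, "ogd_scan")) {
    evaluations <- scan$evaluations
    tree <- tree %||% scan$tree
    config <- scan$config
  } else {
    evaluations <- scan
    config <- scan_config()
    if (is.null(tree)) abort("Supply `tree` when passing a raw evaluations table.")
  }
  elw_grid <- elw_grid %||% config$elw_grid
  distance_grid <- distance_grid %||% config$distance_grid
  if (any(elw_grid <= 0.5)) {
    abort("ELW grid values must exceed 0.5 (uniqueness of the best placement).")
  }

  smry <- summarise_evaluations(evaluations)
  attr(smry, "summarised") <- TRUE
  cells <- tidyr::expand_grid(elw_cutoff = elw_grid,
                              distance_cutoff = distance_grid)
  counts <- map_dbl(seq_len(nrow(cells)), function(k) {
    cfg <- config
    cfg$elw_cutoff <- cells$elw_cutoff[k]
    cfg$distance_cutoff <- cells$distance_cutoff[k]
    nrow(filter_ancestral_donor(call_ogds(smry, tree, cfg), tree))
  })
  out <- mutate(cells, n_ogds = counts)
  class(out) <- c("ogd_grid", class(out))
  out
}
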