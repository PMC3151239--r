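# Factor analyses over a set of displacement calls: ancestral trait
# estimates (clade means), habitat profiles and distances, donor-acceptor
# evolutionary distances against the all-pairs null, and the wrapped
# statistical tests. Raw p-values are reported throughout (no
# multiple-testing correction), mirroring single-hypothesis usage.

HABITAT_COLS <- c("hab_aquatic", "hab_extreme", "hab_foodstuff",
                  "hab_internal", "hab_runoff", "hab_terrestrial")

check_traits <- function(traits, needed = character()) {
  if (!is.data.frame(traits) || !"taxon" %in% names(traits)) {
    abort("`traits` must be a data frame with a `taxon` column.")
  }
  missing <- setdiff(needed, names(traits))
  if (length(missing)) {
    abort(paste0("Trait table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  traits
}

#' Ancestral trait estimate for a branch (clade mean)
#'
#' The trait value attributed to the hypothetical ancestor at a branch is the
#' unweighted arithmetic mean of the trait over the extant members of the
#' clade the branch defines; a pendant branch takes its leaf's own value.
#' No model-based ancestral reconstruction is attempted.
#'
#' @param tree A rooted `ogd_tree`.
#' @param branch Branch id or key.
#' @param traits Data frame with columns `taxon` and `column`.
#' @param column Name of the trait column (e.g. `"gc_percent"`).
#' @return Scalar mean.
#' @export
ancestral_mean <- function(tree, branch, traits, column) {
  stopifnot(inherits(tree, "ogd_tree"))
  check_traits(traits, column)
  i <- resolve_branch(tree, branch)
  leaves <- tree$branches$clade[[i]]
  idx <- match(leaves, traits$taxon)
  vals <- traits[[column]][idx]
  bad <- leaves[is.na(idx) | is.na(vals)]
  if (length(bad)) {
    abort(paste0("Missing ", column, " for taxa: ", paste(bad, collapse = ", ")))
  }
  mean(vals)
}

#' Habitat profile of a branch
#'
#' Sums the habitat observation counts of the clade's taxa over the six
#' habitat categories (Aquatic, Extreme, Foodstuff, Internal, Agricultural
#' runoff, Terrestrial) and converts them to proportions of the total
#' observations — the estimate of the ancestor's habitat range.
#'
#' @param tree An `ogd_tree`.
#' @param branch Branch id or key.
#' @param traits Data frame with `taxon` and the six `hab_*` count columns.
#' @return Named numeric 6-vector of proportions summing to 1.
#' @export
habitat_profile <- function(tree, branch, traits) {
  check_traits(traits, HABITAT_COLS)
  i <- resolve_branch(tree, branch)
  leaves <- tree$branches$clade[[i]]
  idx <- match(leaves, traits$taxon)
  if (anyNA(idx)) {
    abort(paste0("Missing habitat counts for taxa: ",
                 paste(leaves[is.na(idx)], collapse = ", ")))
  }
  counts <- colSums(as.matrix(traits[idx, HABITAT_COLS, drop = FALSE]))
  if (any(counts < 0)) abort("Habitat counts must be nonnegative.")
  total <- sum(counts)
  if (total == 0) abort("Clade has zero habitat observations.")
  counts / total
}

#' Euclidean habitat distance between two profiles
#'
#' @param p,q Normalised 6-category habitat profiles.
#' @return Distance in `[0, sqrt(2)]`.
#' @export
habitat_distance <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) abort("Profiles must have equal length.")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("Profiles must be normalised to proportions.")
  }
  sqrt(sum((p - q)^2))
}

branch_midpoint <- function(tree, branch) {
  i <- resolve_branch(tree, branch)
  new_tree_point(i, tree$branches$length[i] / 2)
}

#' Evolutionary distance between the donor and acceptor of a call
#'
#' Path-length distance (substitutions/site) between the midpoints of the
#' donor and acceptor branches, measured on the full combined tree.
#'
#' @param tree The combined `ogd_tree`.
#' @param donor,acceptor Branch ids or keys.
#' @return Nonnegative distance.
#' @export
donor_acceptor_distance <- function(tree, donor, acceptor) {
  path_length(tree, branch_midpoint(tree, donor), branch_midpoint(tree, acceptor))
}

#' Null distribution of donor-acceptor distances
#'
#' Midpoint-to-midpoint path lengths for all unordered pairs of branches,
#' excluding nested pairs (one branch ancestral to the other), mirroring the
#' support of the ancestral-donor filter so observed and null distances are
#' drawn from the same pair universe.
#'
#' @param tree A rooted `ogd_tree`.
#' @return Numeric vector of distances (one per admissible pair).
#' @export
all_pairs_distances <- function(tree) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("all_pairs_distances() requires a rooted tree.")
  br <- tree$branches
  nb <- nrow(br)
  D <- ape::dist.nodes(tree$phylo)
  half <- br$length / 2
  # min over the four endpoint pairings, vectorised over the pair matrix
  dpp <- D[br$parent, br$parent]; dpc <- D[br$parent, br$child]
  dcp <- D[br$child, br$parent]; dcc <- D[br$child, br$child]
  dmat <- pmin(dpp, dpc, dcp, dcc) + outer(half, half, "+")

  memb <- do.call(rbind, lapply(br$clade, function(cl) tree$labels %in% cl))
  inter <- tcrossprod(memb * 1)
  nested <- inter == br$size | inter == rep(br$size, each = nb)
  keep <- upper.tri(dmat) & !nested
  dmat[keep]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|` with the asymptotic p-value.
#'
#' @param x,y Numeric samples.
#' @return One-row tibble: `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both samples must be nonempty.")
  res <- suppressWarnings(ks.test(x, y, exact = FALSE))
  tibble(statistic = unname(res$statistic), p_value = res$p.value,
         n_x = length(x), n_y = length(y))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when `n * m <= 400` and the pooled sample has no ties;
#' otherwise the normal approximation with optional continuity correction.
#'
#' @param x,y Numeric samples.
#' @param continuity Apply the continuity correction in the normal
#'   approximation (default TRUE).
#' @return One-row tibble: `statistic` (W), `p_value`, `exact`.
#' @export
wilcoxon_rank_sum <- function(x, y, continuity = TRUE) {
  if (!length(x) || !length(y)) abort("Both samples must be nonempty.")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) * length(y) <= 400L) && !ties
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = continuity)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value, exact = exact)
}

#' Pearson correlation with t-distribution p-value
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return One-row tibble: `estimate` (r), `statistic` (t), `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("Need at least 3 pairs.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Zero variance: correlation undefined.")
  }
  res <- cor.test(x, y, method = "pearson")
  tibble(estimate = unname(res$estimate), statistic = unname(res$statistic),
         p_value = res$p.value, n = length(x))
}

#' Dating intervals for displacement calls
#'
#' A transfer proves donor and acceptor lineages coexisted. If branch lengths
#' are clock-like, the path-length distances from their last common ancestor
#' to the transfer point must agree; since the event may have occurred
#' anywhere along either branch, each lineage contributes an interval: the
#' LCA-to-branch-midpoint distance plus/minus half the branch length. The
#' `overlaps` flag records whether the two intervals intersect.
#'
#' @param tree The rooted combined `ogd_tree`.
#' @param calls Call tibble with `family`, `recipient` (acceptor), `donor`.
#' @return A tibble with one row per call: LCA-to-midpoint distances, branch
#'   lengths, and `overlaps`.
#' @export
dating_intervals <- function(tree, calls) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("dating_intervals() requires a rooted tree.")
  if (nrow(calls) == 0L) {
    return(tibble(family = character(), donor = character(),
                  acceptor = character(), elw = numeric(), distance = numeric(),
                  lca_to_donor_mid = numeric(), lca_to_acceptor_mid = numeric(),
                  donor_length = numeric(), acceptor_length = numeric(),
                  overlaps = logical()))
  }
  rg <- rooted_geometry(tree)
  rows <- map(seq_len(nrow(calls)), function(k) {
    di <- resolve_branch(tree, calls$donor[k])
    ai <- resolve_branch(tree, calls$recipient[k])
    cd <- tree$branches$clade[[di]]; ca <- tree$branches$clade[[ai]]
    if (all(ca %in% cd) || all(cd %in% ca)) {
      abort("Nested donor/acceptor pair: apply filter_ancestral_donor() first.")
    }
    nd <- rg$node_of_branch[di]; na <- rg$node_of_branch[ai]
    anc <- intersect(ancestor_chain(rg, nd), ancestor_chain(rg, na))
    lca <- anc[which.max(rg$depth[anc])]
    ld <- tree$branches$length[di]; la <- tree$branches$length[ai]
    # abs(): the branch carrying the root point may have its midpoint on the
    # far side of the root, in which case the LCA is the root point and the
    # path to the midpoint crosses it
    md <- abs(rg$depth[nd] - ld / 2 - rg$depth[lca])
    ma <- abs(rg$depth[na] - la / 2 - rg$depth[lca])
    tibble(
      family = calls$family[k], donor = calls$donor[k],
      acceptor = calls$recipient[k],
      elw = if ("elw" %in% names(calls)) calls$elw[k] else NA_real_,
      distance = if ("distance" %in% names(calls)) calls$distance[k] else NA_real_,
      lca_to_donor_mid = md, lca_to_acceptor_mid = ma,
      donor_length = ld, acceptor_length = la,
      overlaps = (md - ld / 2) <= (ma + la / 2) + 1e-12 &
                 (ma - la / 2) <= (md + ld / 2) + 1e-12
    )
  })
  bind_rows(rows)
}

#' Rate points: evolutionary opportunity vs accepted displacements
#'
#' For each branch (or each named clade), the total branch length within the
#' clade it defines (the proxy for evolutionary time/opportunity, see
#' [clade_total_length()]) paired with the number of calls whose recipient
#' lies within the clade.
#'
#' @param tree The rooted combined `ogd_tree`.
#' @param calls Call tibble with a `recipient` column.
#' @param clades Optional named list of leaf-label vectors designating
#'   independent clades; each must correspond to a branch of the tree. When
#'   omitted, every branch contributes a (non-independent) point.
#' @return A tibble of class `ogd_rate_points`: `clade`, `total_length`,
#'   `n_ogds`, `independent`.
#' @export
rate_points <- function(tree, calls, clades = NULL) {
  stopifnot(inherits(tree, "ogd_tree"))
  if (is.null(tree$root)) abort("rate_points() requires a rooted tree.")
  br <- tree$branches
  if (is.null(clades)) {
    keys <- br$key
    sets <- br$clade
    independent <- FALSE
  } else {
    if (is.null(names(clades))) abort("`clades` must be a named list.")
    keys <- names(clades)
    sets <- map(clades, sort_c)
    hit <- match(vapply(sets, branch_key, character(1)), br$key)
    if (anyNA(hit)) {
      abort(paste0("No branch matches clade(s): ",
                   paste(keys[is.na(hit)], collapse = ", ")))
    }
    sets <- br$clade[hit]
    independent <- TRUE
  }
  rec_clades <- map(calls$recipient, function(k)
    strsplit(k, ",", fixed = TRUE)[[1L]])
  counts <- map_dbl(sets, function(cl)
    sum(map_lgl(rec_clades, function(rc) all(rc %in% cl))))
  lens <- map_dbl(seq_along(sets), function(j)
    clade_total_length(tree, branch_key(sets[[j]])))
  out <- tibble(clade = keys, total_length = lens, n_ogds = counts,
                independent = independent)
  class(out) <- c("ogd_rate_points", class(out))
  out
}

#' Wald-Wolfowitz runs test
#'
#' Tests randomness of a sign sequence by its number of runs: exact
#' combinatorial distribution of the run count for up to 30 observations,
#' normal approximation with continuity correction beyond. Two-sided p-value
#' `2 * min(P(R <= r), P(R >= r))` capped at 1. Zeros are dropped.
#'
#' @param x Numeric vector (signs are taken) or logical vector.
#' @return One-row tibble: `runs`, `n_pos`, `n_neg`, `p_value`, `method`.
#' @export
runs_test <- function(x) {
  s <- if (is.logical(x)) ifelse(x, 1, -1) else sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) {
    return(tibble(runs = if (n) 1L else 0L, n_pos = n1, n_neg = n2,
                  p_value = 1, method = "degenerate"))
  }
  r <- 1L + sum(diff(s) != 0)
  if (n <= 30L) {
    rs <- 2:n
    pr <- vapply(rs, function(k) runs_prob(k, n1, n2), numeric(1))
    lower <- sum(pr[rs <= r]); upper <- sum(pr[rs >= r])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- 1 + 2 * n1 * n2 / n
    v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
    z_lo <- (r - mu + 0.5) / sqrt(v)
    z_hi <- (r - mu - 0.5) / sqrt(v)
    p <- min(1, 2 * min(pnorm(z_lo), 1 - pnorm(z_hi)))
    method <- "normal"
  }
  tibble(runs = r, n_pos = n1, n_neg = n2, p_value = p, method = method)
}

# P(R = r) for a random arrangement of n1 positive and n2 negative signs.
runs_prob <- function(r, n1, n2) {
  if (r %% 2 == 0) {
    k <- r / 2
    2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n1 + n2, n1)
  } else {
    k <- (r - 1) / 2
    (choose(n1 - 1, k) * choose(n2 - 1, k - 1) +
     choose(n1 - 1, k - 1) * choose(n2 - 1, k)) / choose(n1 + n2, n1)
  }
}

#' Linearity analysis of the displacement rate
#'
#' Ordinary least squares of the accepted-call count on the clade's total
#' branch length, with three companion tests: the slope t-test (is there a
#' rate at all), a quadratic-term F-test (does curvature improve on the
#' linear model — low p indicates departure from linearity), and a
#' Wald-Wolfowitz runs test on the residual signs (systematic sign patterns
#' also indicate non-linearity; high p is consistent with a constant rate).
#'
#' @param points An [rate_points()] tibble (columns `total_length`,
#'   `n_ogds`), `>= 4` rows with `>= 2` distinct lengths.
#' @return An object of class `ogd_rate_fit`: list with `slope`,
#'   `intercept`, `fit_p` (slope t-test), `linearity_p` (quadratic F-test),
#'   `runs_p`, `degenerate` flag (exactly collinear points), and the fitted
#'   `model`.
#' @export
rate_linearity <- function(points) {
  x <- points$total_length; y <- points$n_ogds
  if (length(x) < 4L) abort("Need at least 4 rate points.")
  if (length(unique(x)) < 2L) abort("All clade lengths are equal; no rate is estimable.")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # collinear input warns on its own
  res <- residuals(fit)
  degenerate <- max(abs(res)) < 1e-10
  fit_p <- sm$coefficients["x", "Pr(>|t|)"]
  if (length(unique(x)) >= 3L && !degenerate) {
    fit2 <- lm(y ~ x + I(x^2))
    linearity_p <- anova(fit, fit2)[2L, "Pr(>F)"]
  } else {
    linearity_p <- NA_real_
  }
  runs_p <- if (degenerate) 1 else runs_test(res)$p_value
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         fit_p = fit_p, linearity_p = linearity_p, runs_p = runs_p,
         degenerate = degenerate, model = fit, points = points),
    class = "ogd_rate_fit"
  )
}

#' @export
print.ogd_rate_fit <- function(x, ...) {
  cat("Displacement rate ~ clade total length (OLS)\n")
  cat("  slope:", format(x$slope, digits = 4),
      "calls per substitution/site; p =", format(x$fit_p, digits = 3), "\n")
  cat("  linearity (quadratic-term F): p =",
      format(x$linearity_p, digits = 3), "\n")
  cat("  runs test on residual signs: p =", format(x$runs_p, digits = 3), "\n")
  if (x$degenerate) cat("  (points exactly collinear)\n")
  invisible(x)
}

#' Factor report over a call set
#'
#' Runs the five factor analyses that apply to a set of displacement calls:
#' GC content (Pearson correlation of donor vs acceptor clade-mean GC),
#' genome size (Wilcoxon rank-sum, acceptor vs donor clade means, continuity
#' correction), habitat (Pearson correlation of donor-acceptor habitat
#' distance with their evolutionary distance), evolutionary distance
#' (Kolmogorov-Smirnov, observed donor-acceptor distances vs the all-pairs
#' null) and, when per-family interaction counts are supplied, interactions
#' (Pearson correlation of interaction count with per-family call count).
#' Raw p-values; no multiple-testing correction.
#'
#' @param tree The rooted combined `ogd_tree`.
#' @param calls Post-filter call tibble.
#' @param traits Per-taxon trait table (`taxon`, `gc_percent`, `genome_mb`,
#'   six `hab_*` columns).
#' @param interactions Optional tibble with `family` and `interactions`
#'   columns (one row per gene family analysed, including zero-call ones).
#' @return A tibble: `test`, `estimate`, `statistic`, `p_value`, `n`.
#' @export
factor_report <- function(tree, calls, traits, interactions = NULL) {
  if (nrow(calls) == 0L) abort("No calls to analyse.")
  don_gc <- map_dbl(calls$donor, ancestral_mean, tree = tree,
                    traits = traits, column = "gc_percent")
  acc_gc <- map_dbl(calls$recipient, ancestral_mean, tree = tree,
                    traits = traits, column = "gc_percent")
  don_sz <- map_dbl(calls$donor, ancestral_mean, tree = tree,
                    traits = traits, column = "genome_mb")
  acc_sz <- map_dbl(calls$recipient, ancestral_mean, tree = tree,
                    traits = traits, column = "genome_mb")
  hd <- map_dbl(seq_len(nrow(calls)), function(k)
    habitat_distance(habitat_profile(tree, calls$donor[k], traits),
                     habitat_profile(tree, calls$recipient[k], traits)))
  ed <- map_dbl(seq_len(nrow(calls)), function(k)
    donor_acceptor_distance(tree, calls$donor[k], calls$recipient[k]))
  null_d <- all_pairs_distances(tree)

  gc <- tryCatch(pearson_correlation(don_gc, acc_gc),
                 error = function(e) tibble(estimate = NA_real_,
                                            statistic = NA_real_,
                                            p_value = NA_real_, n = nrow(calls)))
  gs <- wilcoxon_rank_sum(acc_sz, don_sz, continuity = TRUE)
  hb <- tryCatch(pearson_correlation(hd, ed),
                 error = function(e) tibble(estimate = NA_real_,
                                            statistic = NA_real_,
                                            p_value = NA_real_, n = nrow(calls)))
  ks <- ks_two_sample(ed, null_d)

  out <- bind_rows(
    tibble(test = "gc_donor_vs_acceptor", estimate = gc$estimate,
           statistic = gc$statistic, p_value = gc$p_value, n = nrow(calls)),
    tibble(test = "genome_size_acceptor_vs_donor", estimate = NA_real_,
           statistic = gs$statistic, p_value = gs$p_value, n = nrow(calls)),
    tibble(test = "habitat_distance_vs_evolutionary_distance",
           estimate = hb$estimate, statistic = hb$statistic,
           p_value = hb$p_value, n = nrow(calls)),
    tibble(test = "evolutionary_distance_vs_null", estimate = NA_real_,
           statistic = ks$statistic, p_value = ks$p_value, n = nrow(calls))
  )
  if (!is.null(interactions)) {
    counts <- calls |> dplyr::count(.data$family, name = "n_ogds")
    tab <- left_join(interactions, counts, by = "family") |>
      mutate(n_ogds = dplyr::coalesce(.data$n_ogds, 0))
    ic <- pearson_correlation(tab$interactions, tab$n_ogds)
    out <- bind_rows(out,
      tibble(test = "interactions_vs_ogds", estimate = ic$estimate,
             statistic = ic$statistic, p_value = ic$p_value, n = nrow(tab)))
  }
  out
}
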