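#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and
#' j.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return Symmetric matrix with zero diagonal and tip labels as dimnames.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop_nestevo("tree has no branch lengths", "nestevo_input_error")
  ape::cophenetic.phylo(tree)
}

#' Bray-Curtis dissimilarity between two state sets
#'
#' On presence/absence sets: `1 - 2 |A intersect B| / (|A| + |B|)`; 0 for
#' identical sets, 1 for disjoint ones.
#'
#' @param set_a,set_b Non-empty character vectors of states.
#' @return Dissimilarity in `[0, 1]`.
#' @examples
#' bray_curtis_dissimilarity("cup", c("cup", "simple dome"))
#' @export
bray_curtis_dissimilarity <- function(set_a, set_b) {
  set_a <- unique(set_a[!is.na(set_a)])
  set_b <- unique(set_b[!is.na(set_b)])
  if (!length(set_a) || !length(set_b))
    stop_nestevo("empty state set: family should have been excluded as missing",
                 "nestevo_missing_data")
  1 - 2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}

# Pairwise Bray-Curtis matrix over a named list of non-empty state sets.
bray_curtis_matrix <- function(sets) {
  if (any(lengths(sets) == 0L))
    stop_nestevo("empty state set: drop missing families first",
                 "nestevo_missing_data")
  states <- sort(unique(unlist(sets)))
  M <- vapply(sets, function(s) as.numeric(states %in% s),
              numeric(length(states)))
  M <- matrix(M, nrow = length(states))     # states x families
  inter <- crossprod(M)                     # |A intersect B|
  sizes <- colSums(M)
  D <- 1 - 2 * inter / outer(sizes, sizes, "+")
  dimnames(D) <- list(names(sets), names(sets))
  diag(D) <- 0
  D
}

#' Mantel correlation between two distance matrices
#'
#' Pearson correlation over the strictly-upper-triangle entries of two
#' distance matrices sharing one taxon order.
#'
#' @param D1,D2 Symmetric matrices with identical dimnames order (>= 4 taxa).
#' @return The correlation r in `[-1, 1]`.
#' @export
mantel_statistic <- function(D1, D2) {
  check_paired_matrices(D1, D2)
  ut <- upper.tri(D1)
  x <- D1[ut]
  y <- D2[ut]
  if (var(x) == 0 || var(y) == 0)
    stop_nestevo("zero variance in a distance matrix: Mantel r undefined",
                 "nestevo_undefined_statistic")
  cor(x, y)
}

check_paired_matrices <- function(D1, D2) {
  if (!is.matrix(D1) || !is.matrix(D2) || !identical(dim(D1), dim(D2)))
    stop_nestevo("distance matrices must have identical dimensions",
                 "nestevo_input_error")
  if (nrow(D1) < 4L)
    stop_nestevo("need >= 4 taxa for a Mantel test", "nestevo_input_error")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2)))
    stop_nestevo("distance matrices must share one taxon order",
                 "nestevo_input_error")
  invisible(TRUE)
}

# Two-sided permutation/simulation p-value with add-one correction.
two_sided_p <- function(null_r, emp_r) {
  n <- length(null_r)
  p_up <- (sum(null_r >= emp_r) + 1) / (n + 1)
  p_dn <- (sum(null_r <= emp_r) + 1) / (n + 1)
  list(p_upper = p_up, p_lower = p_dn, p_two = min(1, 2 * min(p_up, p_dn)))
}

mantel_result <- function(empirical_r, null_r, p, method, n_replicates, seed,
                          n_dropped = 0L) {
  structure(list(empirical_r = empirical_r, null_r = null_r,
                 p_upper = p$p_upper, p_lower = p$p_lower, p_two = p$p_two,
                 method = method, n_replicates = n_replicates, seed = seed,
                 n_dropped = n_dropped),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%s Mantel test: r = %.4f, two-sided p = %.4g (%d replicates)\n",
              x$method, x$empirical_r, x$p_two, x$n_replicates))
  if (x$n_dropped > 0)
    cat(sprintf("  %d zero-variance null replicates dropped\n", x$n_dropped))
  invisible(x)
}

#' Conventional Mantel test by taxon-label permutation
#'
#' The null distribution is built by jointly permuting the rows and columns
#' of the trait dissimilarity matrix. P-values carry the add-one correction
#' `(count + 1) / (n_perm + 1)` and the two-sided p doubles the smaller tail
#' (capped at 1), so both significantly positive and significantly negative
#' correlations can be detected.
#'
#' @param D_phylo,D_trait Matched distance matrices (same taxa, same order).
#' @param n_perm Number of permutations (>= 99; 9,999 for a full analysis).
#' @param seed Optional integer seed.
#' @return A `mantel_result` with the empirical r, the permutation null
#'   sample, and one- and two-sided p-values.
#' @export
conventional_mantel <- function(D_phylo, D_trait, n_perm = 9999L, seed = NULL) {
  check_paired_matrices(D_phylo, D_trait)
  if (n_perm < 99L)
    stop_nestevo("n_perm must be >= 99", "nestevo_invalid_parameter")
  emp <- mantel_statistic(D_phylo, D_trait)
  n <- nrow(D_trait)
  ut <- upper.tri(D_phylo)
  x <- D_phylo[ut]
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(x, D_trait[p, p][ut])
  }, numeric(1)))
  mantel_result(emp, null_r, two_sided_p(null_r, emp), "conventional",
                n_perm, seed)
}

#' Evolutionary-model-based (EM-) Mantel test
#'
#' Replaces the permutation null with a neutral-evolution null: each
#' replicate simulates the character on the tree under the fitted Mk model
#' from the estimated root state, converts tips to singleton state sets,
#' and recomputes the Mantel correlation between Bray-Curtis trait
#' dissimilarity and patristic distance. The empirical correlation is then
#' located in this null (two-sided, add-one corrected). Simulated matrices
#' with zero variance (all tips in one state) are dropped with a warning.
#'
#' @param tree The tree (tips = families with data; drop missing families
#'   first).
#' @param tip_state_sets Named list of non-empty state sets for every tip.
#' @param fitted_model An [mk_model()] with rates set, typically at the
#'   posterior mean from [mcmc_sample()].
#' @param root_state Root state for the neutral simulations, typically the
#'   MAP root state from [reconstruct_ancestral_states()].
#' @param n_sim Number of neutral simulations (>= 1; 9,999 for a full
#'   analysis).
#' @param seed Optional integer seed.
#' @return A `mantel_result` with the evolutionary-model null sample.
#' @export
em_mantel <- function(tree, tip_state_sets, fitted_model, root_state,
                      n_sim = 9999L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(fitted_model, "mk_model"))
  if (!is.numeric(n_sim) || n_sim < 1)
    stop_nestevo("n_sim must be >= 1", "nestevo_invalid_parameter")
  rs <- match_state(root_state, fitted_model$states)
  tip_state_sets <- tip_state_sets[tree$tip.label]
  D_phylo <- patristic_distances(tree)
  D_trait <- bray_curtis_matrix(tip_state_sets)[rownames(D_phylo), rownames(D_phylo)]
  emp <- mantel_statistic(D_phylo, D_trait)
  null_r <- with_seed(seed, {
    out <- numeric(n_sim)
    keep <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      tips <- simulate_discrete_trait(tree, fitted_model, rs)
      D_sim <- bray_curtis_matrix(as.list(tips))[rownames(D_phylo), rownames(D_phylo)]
      v <- var(D_sim[upper.tri(D_sim)])
      if (v > 0) {
        out[i] <- mantel_statistic(D_phylo, D_sim)
        keep[i] <- TRUE
      }
    }
    out[keep]
  })
  n_dropped <- n_sim - length(null_r)
  if (n_dropped > 0)
    warning(sprintf("%d of %d neutral replicates had zero trait variance and were dropped",
                    n_dropped, n_sim), call. = FALSE)
  if (!length(null_r))
    stop_nestevo("all neutral replicates degenerate: EM null unavailable",
                 "nestevo_degenerate_null")
  mantel_result(emp, null_r, two_sided_p(null_r, emp), "EM",
                length(null_r), seed, n_dropped)
}

#' Tabular summary of Mantel results per character and subset
#'
#' @param results Named list of `mantel_result` objects (or sub-lists with
#'   elements `conventional` and `em`); names like `"structure.all"` are
#'   split into character and subset columns.
#' @return Data frame with one row per entry: empirical r, permutation and
#'   EM p-values and null means where available.
#' @export
signal_report <- function(results) {
  if (!length(results))
    stop_nestevo("no Mantel results to report", "nestevo_input_error")
  rows <- lapply(names(results), function(nm) {
    x <- results[[nm]]
    if (inherits(x, "mantel_result"))
      x <- setNames(list(x), if (x$method == "EM") "em" else "conventional")
    conv <- x$conventional
    em <- x$em
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    data.frame(character = parts[1],
               subset = if (length(parts) > 1) parts[2] else "all",
               r = (conv %||% em)$empirical_r,
               p_perm = if (!is.null(conv)) conv$p_two else NA_real_,
               null_mean_perm = if (!is.null(conv)) mean(conv$null_r) else NA_real_,
               p_em = if (!is.null(em)) em$p_two else NA_real_,
               null_mean_em = if (!is.null(em)) mean(em$null_r) else NA_real_)
  })
  do.call(rbind, rows)
}
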