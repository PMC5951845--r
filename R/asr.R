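#' Majority-rule consensus tree with least-squares branch lengths
#'
#' Builds the majority-rule consensus topology of a tree set (clades present
#' in more than half of the trees), then fits branch lengths by non-negative
#' least squares to the mean patristic distance matrix of the set. Clade
#' support (the fraction of input trees containing each clade) is stored in
#' `node.label`.
#'
#' @param tree_set A `multiPhylo` (or list) of rooted trees sharing one tip
#'   set.
#' @param method Branch-length model passed to [phangorn::nnls.tree()]:
#'   `"ultrametric"` when every input tree is ultrametric (the default then),
#'   otherwise `"unrooted"`.
#' @return A `phylo` consensus tree with branch lengths and support values in
#'   `node.label`.
#' @export
consensus_tree <- function(tree_set, method = NULL) {
  tree_set <- as_tree_set(tree_set)
  n <- length(tree_set)
  cons <- ape::consensus(tree_set, p = 0.5, rooted = TRUE, check.labels = TRUE)
  labs <- cons$tip.label
  dsum <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  ultra <- TRUE
  for (tr in tree_set) {
    if (is.null(tr$edge.length))
      stop_nestevo("trees must have branch lengths", "nestevo_input_error")
    dsum <- dsum + ape::cophenetic.phylo(tr)[labs, labs]
    if (ultra && !ape::is.ultrametric(tr, tol = 1e-8)) ultra <- FALSE
  }
  if (is.null(method)) method <- if (ultra) "ultrametric" else "unrooted"
  fit <- phangorn::nnls.tree(dsum / n, cons, method = method)
  # clade support from bipartition counts over the tree set
  pp <- ape::prop.part(tree_set)
  plabs <- attr(pp, "labels")
  counts <- attr(pp, "number")
  keys <- vapply(pp, function(ix) paste(sort(plabs[ix]), collapse = "\r"),
                 character(1))
  ntip <- length(labs)
  supp <- vapply(seq_len(fit$Nnode), function(i) {
    tips <- clade_tips(fit, ntip + i)
    hit <- match(paste(sort(tips), collapse = "\r"), keys)
    if (is.na(hit)) 0 else counts[hit] / n
  }, numeric(1))
  fit$node.label <- formatC(supp, digits = 3, format = "g")
  fit
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
}

#' Posterior ancestral states at monitored clades
#'
#' For every retained MCMC sample, computes marginal state probabilities
#' (up-down pass) at the most recent common ancestor of each monitored tip
#' set on that sample's tree, and averages over the samples whose tree
#' contains the clade as a monophyletic group. Clade support is the fraction
#' of sampled trees containing the clade.
#'
#' @param trace An `mcmc_trace` from [mcmc_sample()] on the same inputs.
#' @param tree_set The tree set used for sampling.
#' @param tip_state_sets The character data used for sampling.
#' @param clades Named list of tip-label vectors to monitor. Default: every
#'   clade of the majority-rule consensus tree (the root clade is named
#'   `"root"`).
#' @return An `ancestral_reconstruction`: a data frame with one row per clade
#'   (`clade`, `n_tips`, `support`, and one posterior-probability column per
#'   state), with the monitored tip sets in `attr(, "clades")`.
#' @export
reconstruct_ancestral_states <- function(trace, tree_set, tip_state_sets,
                                         clades = NULL) {
  stopifnot(inherits(trace, "mcmc_trace"))
  if (trace$kind != "mk")
    stop_nestevo("trace was not produced by mcmc_sample()", "nestevo_wrong_model")
  model <- trace$model
  tree_set <- as_tree_set(tree_set)
  preps <- prep_tree_set(tree_set, tip_state_sets, model$states)
  if (is.null(clades)) {
    cons <- consensus_tree(tree_set)
    ntip <- length(cons$tip.label)
    nodes <- ntip + seq_len(cons$Nnode)
    clades <- lapply(nodes, function(nd) clade_tips(cons, nd))
    names(clades) <- ifelse(nodes == ntip + 1L, "root",
                            paste0("node_", nodes))
  }
  if (!length(clades)) stop_nestevo("no clades to monitor", "nestevo_input_error")
  if (is.null(names(clades)) || any(names(clades) == ""))
    names(clades) <- paste0("clade_", seq_along(clades))
  clade_info <- lapply(preps, function(pp) {
    tr <- pp$tree
    lapply(clades, function(tips) {
      idx <- match(tips, tr$tip.label)
      if (anyNA(idx)) return(NULL)
      if (length(idx) == 1L) return(list(node = idx[1], mono = TRUE))
      if (length(idx) == length(tr$tip.label))
        return(list(node = length(tr$tip.label) + 1L, mono = TRUE))
      node <- ape::getMRCA(tr, idx)
      desc <- unlist(phangorn::Descendants(tr, node, "tips"))
      list(node = node, mono = length(desc) == length(idx))
    })
  })
  samples <- trace$samples
  k <- model$k
  er <- model$rate_model == "ER"
  acc <- matrix(0, length(clades), k)
  cnt <- numeric(length(clades))
  for (r in seq_len(nrow(samples))) {
    ti <- samples$tree_index[r]
    pp <- preps[[ti]]
    rates <- as.numeric(samples[r, trace$rate_names])
    Q <- if (er) matrix(0, k, k) else
      mk_generator(mk_model(model$states, "ARD", rates))
    marg <- C_mk_asr(pp$edge, pp$elen, pp$tipL, pp$n_node, Q,
                     model$root_prior, er, if (er) rates[1] else 0)
    ci <- clade_info[[ti]]
    for (ic in seq_along(clades)) {
      info <- ci[[ic]]
      if (!is.null(info) && info$mono) {
        acc[ic, ] <- acc[ic, ] + marg[, info$node]
        cnt[ic] <- cnt[ic] + 1
      }
    }
  }
  if (any(cnt == 0))
    stop_nestevo(paste("clade(s) never present in any sampled tree:",
                       paste(names(clades)[cnt == 0], collapse = ", ")),
                 "nestevo_absent_clade")
  probs <- acc / cnt
  colnames(probs) <- model$states
  out <- data.frame(clade = names(clades),
                    n_tips = lengths(clades),
                    support = cnt / nrow(samples),
                    check.names = FALSE)
  out <- cbind(out, as.data.frame(probs))
  rownames(out) <- NULL
  structure(out, clades = clades, states = model$states,
            class = c("ancestral_reconstruction", "data.frame"))
}

#' Write an ancestral reconstruction to TSV
#'
#' One row per clade: a stable hash of the sorted tip set, the clade size,
#' its support, and the posterior probability of each state.
#'
#' @param asr An `ancestral_reconstruction`.
#' @param path Output file.
#' @export
write_asr_tsv <- function(asr, path) {
  stopifnot(inherits(asr, "ancestral_reconstruction"))
  clades <- attr(asr, "clades")
  df <- cbind(tip_set_hash = vapply(clades, function(tp) config_hash(sort(tp)),
                                    character(1)),
              as.data.frame(asr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Maximum a posteriori root state of a reconstruction
#'
#' @param asr An `ancestral_reconstruction` containing a `"root"` clade.
#' @return The state label with the highest posterior probability at the root.
#' @export
map_root_state <- function(asr) {
  stopifnot(inherits(asr, "ancestral_reconstruction"))
  states <- attr(asr, "states")
  row <- which(asr$clade == "root")
  if (!length(row))
    stop_nestevo("no 'root' clade in the reconstruction", "nestevo_input_error")
  states[which.max(as.numeric(asr[row[1], states]))]
}
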