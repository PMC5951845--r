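# Independent oracles used across the suite. These never call the package's
# own likelihood machinery: transition matrices come from Matrix::expm on a
# hand-built generator, and the likelihood is an exhaustive sum over all
# internal-node state assignments.

oracle_expm <- function(Q, t) as.matrix(Matrix::expm(Q * t))

# Generator of an equal-rates Mk chain, built directly.
oracle_er_generator <- function(k, q) {
  Q <- matrix(q, k, k)
  diag(Q) <- -(k - 1) * q
  Q
}

# All-rates-different generator: off-diagonal rates filled row by row.
oracle_ard_generator <- function(k, rates) {
  Q <- matrix(0, k, k)
  idx <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    Q[i, j] <- rates[idx]
    idx <- idx + 1
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Brute-force likelihood: enumerate every assignment of states to internal
# nodes; tips contribute an indicator over their observed set (all-ones if
# missing).
oracle_enum_loglik <- function(tree, tip_state_sets, k, Q, root_prior = rep(1 / k, k)) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(po$tip.label)
  P <- lapply(seq_len(nrow(po$edge)), function(e) oracle_expm(Q, po$edge.length[e]))
  tipI <- lapply(po$tip.label, function(lb) {
    s <- tip_state_sets[[lb]]
    v <- rep(0, k)
    if (is.null(s) || !length(s)) v[] <- 1 else v[s] <- 1
    v
  })
  grid <- expand.grid(rep(list(seq_len(k)), po$Nnode))
  root <- ntip + 1L
  total <- 0
  for (r in seq_len(nrow(grid))) {
    internal <- as.integer(grid[r, ])
    node_state <- function(nd) internal[nd - ntip]
    pr <- root_prior[node_state(root)]
    for (e in seq_len(nrow(po$edge))) {
      par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
      ps <- node_state(par)
      if (ch <= ntip) pr <- pr * sum(P[[e]][ps, ] * tipI[[ch]])
      else pr <- pr * P[[e]][ps, node_state(ch)]
    }
    total <- total + pr
  }
  log(total)
}

# Random small test tree with uniform branch lengths (independent generator).
oracle_random_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1.5)
  tr
}

# Random tip state sets over k states: mostly singletons, some polymorphic,
# occasionally missing.
oracle_random_tipsets <- function(tree, k, seed, p_poly = 0.2, p_missing = 0.1) {
  set.seed(seed)
  sets <- lapply(tree$tip.label, function(lb) {
    u <- runif(1)
    if (u < p_missing) return(integer(0))
    n_states <- if (u < p_missing + p_poly) 2L else 1L
    sort(sample.int(k, min(n_states, k)))
  })
  names(sets) <- tree$tip.label
  sets
}

# Convert integer state sets to label sets for a given mk_model.
as_label_sets <- function(int_sets, states) {
  lapply(int_sets, function(ix) states[ix])
}

demo_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_demo_dataset(file.path(tempdir(), "nestevo-demo-fixture"),
                                  seed = 101L)
    cache
  }
})
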