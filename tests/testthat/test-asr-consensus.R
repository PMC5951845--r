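test_that("root posteriors behave on cherries", {
  cherry <- ape::read.tree(text = "(A:0.05,B:0.05);")
  cfg <- mcmc_config(n_iter = 2000, burn_in = 500, thin = 10, n_chains = 1,
                     seed = 1)
  same <- mcmc_sample(cherry, list(A = "s1", B = "s1"), mk_model(2, "ER"), cfg)
  asr <- reconstruct_ancestral_states(same, cherry, list(A = "s1", B = "s1"),
                                      clades = list(root = c("A", "B")))
  expect_gt(asr$s1[asr$clade == "root"], 0.99)
  expect_equal(asr$s1 + asr$s2, rep(1, nrow(asr)))
  expect_equal(asr$support, 1)

  sym <- ape::read.tree(text = "(A:0.5,B:0.5);")
  mixed <- mcmc_sample(sym, list(A = "s1", B = "s2"), mk_model(2, "ER"), cfg)
  asr2 <- reconstruct_ancestral_states(mixed, sym, list(A = "s1", B = "s2"),
                                       clades = list(root = c("A", "B")))
  expect_equal(asr2$s1[1], 0.5, tolerance = 0.01)
})

test_that("the simulated root state is recovered on a conserved trait", {
  hits <- 0L
  for (i in 1:5) {
    tr <- simulate_yule_tree(100, 1, seed = 100 + i)
    tips <- simulate_discrete_trait(tr, mk_model(4, "ER", rates = 0.03), 2,
                                    seed = 200 + i)
    cfg <- mcmc_config(n_iter = 3000, burn_in = 1000, thin = 10, n_chains = 1,
                       seed = 300 + i)
    trace <- mcmc_sample(tr, tips, mk_model(4, "ER"), cfg)
    asr <- reconstruct_ancestral_states(trace, tr, tips,
                                        clades = list(root = tr$tip.label))
    hits <- hits + (map_root_state(asr) == "s2")
  }
  expect_gte(hits, 4L)
})

test_that("monitored clades absent from every sampled tree raise an error", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  cfg <- mcmc_config(n_iter = 1000, burn_in = 200, thin = 10, n_chains = 1,
                     seed = 5)
  sets <- list(A = "s1", B = "s1", C = "s2", D = "s2")
  trace <- suppressWarnings(mcmc_sample(tr, sets, mk_model(2, "ER"), cfg))
  expect_error(reconstruct_ancestral_states(trace, tr, sets,
                                            clades = list(x = c("A", "C"))),
               class = "nestevo_absent_clade")
})

test_that("ASR tables export with a stable tip-set hash", {
  cherry <- ape::read.tree(text = "(A:0.1,B:0.1);")
  cfg <- mcmc_config(n_iter = 1000, burn_in = 200, thin = 10, n_chains = 1,
                     seed = 6)
  trace <- suppressWarnings(
    mcmc_sample(cherry, list(A = "s1", B = "s1"), mk_model(2, "ER"), cfg))
  asr <- reconstruct_ancestral_states(trace, cherry, list(A = "s1", B = "s1"),
                                      clades = list(root = c("A", "B")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_asr_tsv(asr, path)
  tab <- read.delim(path)
  expect_identical(names(tab)[1:4], c("tip_set_hash", "clade", "n_tips", "support"))
  expect_equal(tab$s1 + tab$s2, 1)
})

test_that("consensus on identical trees returns them with their branch lengths", {
  base <- simulate_yule_tree(12, 1, seed = 7)
  ts <- perturb_tree_set(base, 5, 0, 0, seed = 8)
  cons <- consensus_tree(ts)
  expect_equal(phangorn::RF.dist(cons, base), 0)
  expect_lt(max(abs(sort(cons$edge.length) - sort(base$edge.length))), 1e-8)
  expect_true(all(as.numeric(cons$node.label) == 1))
})

test_that("majority rule keeps 60% clades and drops 40% clades", {
  t1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  ts <- c(rep(list(t1), 6), rep(list(t2), 4))
  class(ts) <- "multiPhylo"
  cons <- consensus_tree(ts)
  keys <- lapply((length(cons$tip.label) + 1):(length(cons$tip.label) + cons$Nnode),
                 function(nd) sort(nestevo:::clade_tips(cons, nd)))
  has <- function(tips) any(vapply(keys, identical, logical(1), y = tips))
  expect_true(has(c("A", "B")))
  expect_false(has(c("A", "C")))
  ab <- which(vapply(keys, identical, logical(1), y = c("A", "B")))
  expect_equal(as.numeric(cons$node.label[ab]), 0.6)
})

test_that("mixed tip sets are rejected", {
  t1 <- simulate_yule_tree(6, 1, seed = 9)
  t2 <- simulate_yule_tree(7, 1, seed = 10)
  expect_error(consensus_tree(list(t1, t2)), class = "nestevo_input_error")
})
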