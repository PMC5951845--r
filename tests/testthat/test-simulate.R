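test_that("Yule trees are rooted, binary, ultrametric, with positive branches", {
  cherry <- simulate_yule_tree(2, 1.5, seed = 1)
  expect_s3_class(cherry, "phylo")
  expect_length(cherry$tip.label, 2L)
  expect_equal(cherry$edge.length[1], cherry$edge.length[2])

  tr <- simulate_yule_tree(50, 1, seed = 7)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_true(all(tr$edge.length > 0))
  depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
  expect_lt(diff(range(depths)), 1e-9)
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_yule_tree(50, 1, seed = 7)))

  expect_error(simulate_yule_tree(1, 1), class = "nestevo_invalid_parameter")
  expect_error(simulate_yule_tree(10, 0), class = "nestevo_invalid_parameter")
})

test_that("mean Yule tree height matches the closed-form expectation", {
  n_rep <- 500
  heights <- vapply(seq_len(n_rep), function(i)
    max(ape::node.depth.edgelength(simulate_yule_tree(50, 1, seed = 10000 + i))),
    numeric(1))
  expected <- sum(1 / (2:50))
  se <- sd(heights) / sqrt(n_rep)
  expect_lt(abs(mean(heights) - expected), 3 * se)
})

test_that("tree-set perturbation preserves tips and moves topology", {
  base <- simulate_yule_tree(20, 1, seed = 3)
  ident <- perturb_tree_set(base, 10, perturb_strength = 0, bl_jitter = 0, seed = 4)
  expect_length(ident, 10L)
  for (tr in ident) {
    expect_equal(phangorn::RF.dist(tr, base), 0)
    expect_equal(sort(tr$edge.length), sort(base$edge.length))
  }
  moved <- perturb_tree_set(base, 100, perturb_strength = 3, bl_jitter = 0.1, seed = 5)
  expect_true(all(vapply(moved, function(tr)
    setequal(tr$tip.label, base$tip.label), logical(1))))
  rf <- vapply(moved, phangorn::RF.dist, numeric(1), tree2 = base)
  expect_gt(mean(rf), 0)
  expect_true(all(vapply(moved, function(tr) all(tr$edge.length > 0), logical(1))))
})

test_that("trait simulation honours the zero-rate and stationary limits", {
  tr <- simulate_yule_tree(30, 1, seed = 11)
  frozen <- simulate_discrete_trait(tr, mk_model(4, "ER", rates = 0), 3, seed = 12)
  expect_true(all(frozen == "s3"))

  # long star branches reach the uniform stationary distribution
  star <- ape::stree(1000, "star")
  star$edge.length <- rep(100, nrow(star$edge))
  tips <- simulate_discrete_trait(star, mk_model(4, "ER", rates = 0.5), 1, seed = 13)
  expect_gt(chisq.test(table(factor(tips, levels = sprintf("s%d", 1:4))))$p.value,
            0.01)

  expect_error(simulate_discrete_trait(tr, mk_model(3, "ER", rates = 0.1), 5),
               class = "nestevo_invalid_parameter")
})

test_that("equal-rates simulation matches the closed-form transition probability", {
  # cherry with both tip branches t: P(tip = root) = 1/4 + 3/4 exp(-4 q t)
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  m <- mk_model(4, "ER", rates = 0.1)
  n_rep <- 10000
  hits <- 0L
  for (i in seq_len(n_rep)) {
    tips <- simulate_discrete_trait(cherry, m, 1, seed = 20000 + i)
    hits <- hits + (tips[["A"]] == "s1")
  }
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * 0.1 * 1)
  se <- sqrt(p_same * (1 - p_same) / n_rep)
  expect_lt(abs(hits / n_rep - p_same), 3 * se)
  # the closed form itself agrees with the matrix-exponential oracle
  P <- oracle_expm(oracle_er_generator(4, 0.1), 1)
  expect_lt(abs(P[1, 1] - p_same), 1e-12)
})

test_that("polymorphism and missingness are injected at the requested rates", {
  tr <- simulate_yule_tree(1000, 1, seed = 30)
  m <- mk_model(5, "ER", rates = 0.2)
  tips <- simulate_discrete_trait(tr, m, 1, seed = 31)

  ident <- simulate_polymorphic_tipset(tips, m, 0, 0, seed = 32)
  expect_true(all(lengths(ident) == 1L))
  expect_equal(unlist(ident), tips[names(ident)])

  forced <- simulate_polymorphic_tipset(tips, m, 1, 0, seed = 33)
  expect_true(all(lengths(forced) == 2L))
  expect_true(all(vapply(forced, anyDuplicated, numeric(1)) == 0))

  mixed <- simulate_polymorphic_tipset(tips, m, 0.2, 0.05, seed = 34)
  poly_frac <- mean(lengths(mixed) == 2L)
  se <- sqrt(0.2 * 0.8 / 1000)
  expect_lt(abs(poly_frac - 0.2), 3 * se)

  expect_error(simulate_polymorphic_tipset(tips, m, 0.7, 0.4),
               class = "nestevo_invalid_parameter")
})

test_that("correlated-pair simulation collapses to independence with context-free rates", {
  star <- ape::stree(400, "star")
  star$edge.length <- rep(3, nrow(star$edge))
  # context-free: each trait's gain/loss identical in both backgrounds
  cf <- c(q12 = 0.3, q13 = 0.2, q21 = 0.25, q24 = 0.2,
          q31 = 0.15, q34 = 0.3, q42 = 0.15, q43 = 0.25)
  pair <- simulate_correlated_binary_pair(star, cf, "00", seed = 40)
  joint <- table(factor(pair[, 1], 0:1), factor(pair[, 2], 0:1))
  # independent construction with matched rates
  a <- simulate_discrete_trait(star, mk_model(c("0", "1"), "ARD", c(0.2, 0.15)),
                               1, seed = 41)
  b <- simulate_discrete_trait(star, mk_model(c("0", "1"), "ARD", c(0.3, 0.25)),
                               1, seed = 42)
  joint_ind <- table(factor(a, c("0", "1")), factor(b, c("0", "1")))
  tab <- rbind(as.vector(joint), as.vector(joint_ind))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("correlated-pair simulation plants the intended contingency", {
  tr <- simulate_yule_tree(500, 1, seed = 50)
  frozen <- simulate_correlated_binary_pair(tr, rep(0, 8), "01", seed = 51)
  expect_true(all(frozen[, "A"] == 0L & frozen[, "B"] == 1L))

  # B gains only when A = 1
  rates <- c(q12 = 0, q13 = 0.15, q21 = 0.05, q24 = 0.15,
             q31 = 0.05, q34 = 0.6, q42 = 0.05, q43 = 0.05)
  pair <- simulate_correlated_binary_pair(tr, rates, "00", seed = 52)
  tab <- table(factor(pair[, 1], 0:1), factor(pair[, 2], 0:1)) + 0.5
  odds_ratio <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  expect_gt(odds_ratio, 1)

  expect_error(simulate_correlated_binary_pair(tr, c(-1, rep(0.1, 7)), "00"),
               class = "nestevo_invalid_parameter")
})
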