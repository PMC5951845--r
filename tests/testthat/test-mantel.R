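test_that("patristic distances equal hand-computed path sums", {
  cherry <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(patristic_distances(cherry)["A", "B"], 2)
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  D <- patristic_distances(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)
  ultra <- simulate_yule_tree(20, 1, seed = 1)
  h <- max(ape::node.depth.edgelength(ultra))
  expect_equal(max(patristic_distances(ultra)), 2 * h, tolerance = 1e-9)
})

test_that("Bray-Curtis on state sets follows the presence/absence formula", {
  expect_equal(bray_curtis_dissimilarity("cup", "cup"), 0)
  expect_equal(bray_curtis_dissimilarity("cup", "platform"), 1)
  expect_equal(bray_curtis_dissimilarity("cup", c("cup", "simple dome")), 1 / 3)
  expect_error(bray_curtis_dissimilarity(character(0), "cup"),
               class = "nestevo_missing_data")
  # matrix form agrees with vegan on binary data
  skip_if_not_installed("vegan")
  sets <- list(a = c("x", "y"), b = "y", c = c("y", "z"), d = c("x", "z"))
  D <- nestevo:::bray_curtis_matrix(sets)
  M <- t(vapply(sets, function(s) as.numeric(c("x", "y", "z") %in% s), numeric(3)))
  expect_equal(unname(D), unname(as.matrix(vegan::vegdist(M, "bray"))))
  # singleton sets reduce to the 0/1 mismatch metric
  singles <- list(a = "x", b = "x", c = "y", d = "z")
  Ds <- nestevo:::bray_curtis_matrix(singles)
  expect_true(all(Ds %in% c(0, 1)))
  expect_equal(Ds["a", "b"], 0)
  expect_equal(Ds["a", "c"], 1)
})

test_that("the Mantel statistic is an upper-triangle Pearson correlation", {
  set.seed(2)
  D1 <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(D1) <- list(letters[1:4], letters[1:4])
  expect_equal(mantel_statistic(D1, 2 * D1), 1)
  D2 <- as.matrix(dist(matrix(rnorm(8), 4)))
  dimnames(D2) <- dimnames(D1)
  ut <- upper.tri(D1)
  expect_equal(mantel_statistic(D1, D2), cor(D1[ut], D2[ut]))
  skip_if_not_installed("vegan")
  expect_equal(mantel_statistic(D1, D2),
               unname(vegan::mantel(D1, D2, permutations = 0)$statistic))
  Dc <- D1; Dc[] <- 1; diag(Dc) <- 0
  expect_error(mantel_statistic(D1, Dc), class = "nestevo_undefined_statistic")
  expect_error(mantel_statistic(D1[1:3, 1:3], D2[1:3, 1:3]),
               class = "nestevo_input_error")
})

test_that("conventional Mantel detects maximal signal and keeps p positive", {
  tr <- simulate_yule_tree(25, 1, seed = 3)
  D <- patristic_distances(tr)
  res <- conventional_mantel(D, D, n_perm = 999, seed = 4)
  expect_equal(res$empirical_r, 1)
  expect_lte(res$p_two, 0.01)
  expect_gt(res$p_two, 0)
  expect_length(res$null_r, 999L)
  # reproducible under the same seed, invariant to joint relabeling
  res2 <- conventional_mantel(D, D, n_perm = 999, seed = 4)
  expect_identical(res$null_r, res2$null_r)
  expect_error(conventional_mantel(D, D, n_perm = 9),
               class = "nestevo_invalid_parameter")
})

test_that("EM-Mantel guards its inputs and reports dropped null replicates", {
  tr <- simulate_yule_tree(20, 1, seed = 5)
  m <- mk_model(3, "ER", rates = 0.3)
  tips <- simulate_discrete_trait(tr, m, 1, seed = 6)
  sets <- as.list(tips)
  expect_error(em_mantel(tr, sets, m, 1, n_sim = 0),
               class = "nestevo_invalid_parameter")
  expect_error(em_mantel(tr, sets, m, 9, n_sim = 99),
               class = "nestevo_invalid_parameter")
  # a frozen fitted model leaves no usable null replicate
  expect_error(suppressWarnings(
    em_mantel(tr, sets, mk_model(3, "ER", rates = 0), 1, n_sim = 20, seed = 8)),
    class = "nestevo_degenerate_null")
  # a slow model yields some monomorphic replicates, dropped with a warning
  slow <- mk_model(3, "ER", rates = 0.05)
  tips2 <- simulate_discrete_trait(tr, m, 1, seed = 7)
  expect_warning(res <- em_mantel(tr, as.list(tips2), slow, 1, n_sim = 60,
                                  seed = 8), "dropped")
  expect_lt(res$n_replicates, 60)
  expect_gt(res$p_two, 0)
})

test_that("conventional and EM nulls coincide when traits are label-exchangeable", {
  tr <- simulate_yule_tree(50, 1, seed = 9)
  fast <- mk_model(3, "ER", rates = 20)
  tips <- simulate_discrete_trait(tr, fast, 1, seed = 10)
  D <- patristic_distances(tr)
  Dt <- nestevo:::bray_curtis_matrix(as.list(tips))[rownames(D), rownames(D)]
  conv <- conventional_mantel(D, Dt, n_perm = 499, seed = 11)
  em <- suppressWarnings(em_mantel(tr, as.list(tips), fast, 1, n_sim = 499,
                                   seed = 12))
  expect_gt(stats::ks.test(conv$null_r, em$null_r)$p.value, 0.01)
})

test_that("signal reports tabulate one row per character and subset", {
  tr <- simulate_yule_tree(20, 1, seed = 13)
  m <- mk_model(3, "ER", rates = 0.4)
  tips <- simulate_discrete_trait(tr, m, 1, seed = 14)
  D <- patristic_distances(tr)
  Dt <- nestevo:::bray_curtis_matrix(as.list(tips))[rownames(D), rownames(D)]
  conv <- conventional_mantel(D, Dt, n_perm = 99, seed = 15)
  em <- em_mantel(tr, as.list(tips), m, 1, n_sim = 99, seed = 16)
  tab <- signal_report(list(structure.all = list(conventional = conv, em = em),
                            structure.passerines = conv))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$subset, c("all", "passerines"))
  expect_equal(tab$r[1], conv$empirical_r)
  expect_true(is.na(tab$p_em[2]))
  expect_error(signal_report(list()), class = "nestevo_input_error")
})
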