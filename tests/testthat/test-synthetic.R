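test_that("Yule trees have the requested size and are ultrametric", {
  set.seed(41)
  t2 <- simulate_yule(2)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(t2$edge.length[1], t2$edge.length[2])
  for (i in 1:20) {
    n <- sample(3:40, 1)
    tr <- simulate_yule(n)
    expect_equal(length(tr$tip.label), n)
    expect_true(ape::is.ultrametric(tr, tol = 1e-8))
    expect_equal(nrow(tr$edge), 2L * n - 2L)  # binary
  }
  expect_error(simulate_yule(1), "at least 2")
  expect_error(simulate_yule(5, 0), "positive")
})

test_that("Yule depth matches the closed-form expectation", {
  set.seed(42)
  n <- 10; lambda <- 1
  d <- replicate(1500, max(ape::node.depth.edgelength(simulate_yule(n, lambda))))
  expected <- sum(1 / (2:n)) / lambda
  sd_theory <- sqrt(sum(1 / (2:n)^2)) / lambda
  expect_lt(abs(mean(d) - expected), 3 * sd_theory / sqrt(1500))
})

test_that("Mk simulation logs a replayable history", {
  set.seed(43)
  tr <- simulate_yule(10)
  h0 <- simulate_mk_binary(tr, q01 = 0, q10 = 0.5, root_state = "0")
  expect_true(all(h0$tip_states == "0"))
  expect_equal(nrow(h0$events), 0L)
  for (i in 1:20) {
    tr <- simulate_yule(sample(5:25, 1))
    h <- simulate_mk_binary(tr, q01 = 0.6, q10 = 0.4, root_state = sample(c("0", "1"), 1))
    expect_equal(unname(replay_history(tr, h)), unname(h$tip_states))
    expect_equal(h$n_gains, sum(h$events$from == "0" & h$events$to == "1"))
    expect_equal(h$n_losses, sum(h$events$from == "1" & h$events$to == "0"))
  }
  no_len <- parse_newick("((A,B),C);")
  expect_error(simulate_mk_binary(no_len, 0.1, 0.1), "branch lengths")
})

test_that("Mk tip frequencies approach the stationary distribution", {
  set.seed(44)
  q01 <- 3; q10 <- 1
  h <- simulate_mk_binary(star_tree(2000, len = 2), q01, q10, root_state = "0")
  pi1 <- q01 / (q01 + q10)
  se <- sqrt(pi1 * (1 - pi1) / 2000)
  expect_lt(abs(mean(h$tip_states == "1") - pi1), 3 * se)
})

test_that("the exclusive pair never co-occurs and orders loss before gain", {
  set.seed(45)
  for (i in 1:10) {
    tr <- simulate_yule(40)
    ep <- simulate_exclusive_pair(tr, gain_M = 0.3, loss_M = 0.4,
                                  gain_P = 0.3, loss_P = 0.2, root_state = "M")
    m <- ep$muscarine$tip_states; p <- ep$psilocybin$tip_states
    expect_false(any(m == "1" & p == "1"))
    # marginal logs replay to marginal tip states
    expect_equal(unname(replay_history(tr, ep$muscarine)), unname(m))
    expect_equal(unname(replay_history(tr, ep$psilocybin)), unname(p))
    # no logged instant in a both-toxin state: transitions only via N
    expect_true(all(ep$events$from != ep$events$to))
    expect_false(any(ep$events$from == "M" & ep$events$to == "P"))
    expect_false(any(ep$events$from == "P" & ep$events$to == "M"))
  }
})

test_that("psilocybin cannot appear when its gain rate is zero", {
  set.seed(46)
  tr <- simulate_yule(50)
  ep <- simulate_exclusive_pair(tr, gain_M = 0.5, loss_M = 0.5,
                                gain_P = 0, loss_P = 0.5, root_state = "M")
  expect_true(all(ep$psilocybin$tip_states == "0"))
  expect_false(any(ep$events$to == "P"))
})

test_that("every P tip descends from a muscarine loss preceding its gain", {
  set.seed(47)
  found_p <- FALSE
  for (i in 1:20) {
    tr <- simulate_yule(30)
    ep <- simulate_exclusive_pair(tr, gain_M = 0.2, loss_M = 0.5,
                                  gain_P = 0.6, loss_P = 0.05, root_state = "M")
    p_tips <- which(ep$psilocybin$tip_states == "1")
    if (!length(p_tips)) next
    found_p <- TRUE
    parent <- integer(length(tr$tip.label) + tr$Nnode)
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    for (tip in p_tips) {
      path <- tip; v <- tip
      while (parent[v] != 0L) { v <- parent[v]; path <- c(path, v) }
      ev <- ep$events[ep$events$node %in% path, , drop = FALSE]
      ev <- ev[order(ev$time), , drop = FALSE]
      t_loss <- ev$time[ev$from == "M" & ev$to == "N"][1]
      t_gain <- utils::tail(ev$time[ev$from == "N" & ev$to == "P"], 1)
      expect_false(is.na(t_loss))
      expect_lt(t_loss, t_gain)
    }
  }
  expect_true(found_p)
})

test_that("mask_missing masks exactly the requested count, uniformly", {
  set.seed(48)
  tr <- simulate_yule(500)
  h <- simulate_mk_binary(tr, 0.3, 0.3)
  expect_equal(mask_missing(h, 0), h$tip_states)
  expect_true(all(mask_missing(h, 1) == "?"))
  m <- mask_missing(h, 0.8)
  expect_equal(sum(m == "?"), 400L)
  keep <- m != "?"
  expect_equal(m[keep], h$tip_states[keep])  # unmasked states untouched
  expect_error(mask_missing(h, 1.2), "fraction")
})

test_that("NNI perturbation keeps tip sets and ultrametricity, moves topology", {
  skip_if_not_installed("phangorn")
  set.seed(49)
  base <- simulate_yule(25)
  s0 <- perturb_tree_sample(base, 10, n_nni = 0)
  rf0 <- sapply(s0$trees, function(t) phangorn::RF.dist(t, base))
  expect_true(all(rf0 == 0))
  expect_true(all(sapply(s0$trees, ape::is.ultrametric, tol = 1e-8)))

  s1 <- perturb_tree_sample(base, 40, n_nni = 1)
  s5 <- perturb_tree_sample(base, 40, n_nni = 5)
  expect_true(all(sapply(s5$trees, function(t) setequal(t$tip.label, base$tip.label))))
  rf1 <- mean(sapply(s1$trees, function(t) phangorn::RF.dist(t, base)))
  rf5 <- mean(sapply(s5$trees, function(t) phangorn::RF.dist(t, base)))
  expect_gt(rf5, rf1)

  poly <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_error(perturb_tree_sample(poly, 2, 1), "binary")
})

test_that("independent-draw mode gives fresh Yule topologies on the same tips", {
  set.seed(50)
  base <- simulate_yule(15)
  s <- perturb_tree_sample(base, 5, independent = TRUE)
  expect_true(all(sapply(s$trees, function(t) setequal(t$tip.label, base$tip.label))))
  expect_true(all(sapply(s$trees, ape::is.ultrametric, tol = 1e-8)))
})

test_that("noisy assay records recover truth at the binomial rate", {
  set.seed(51)
  tr <- star_tree(300)
  truth <- stats::setNames(sample(c("0", "1"), 300, replace = TRUE), tr$tip.label)
  r0 <- simulate_assay_records(truth, reports_per_species = 1, flip_probability = 0)
  rec0 <- vapply(names(truth), function(s)
    majority_resolve(r0[r0$species == s, , drop = FALSE]), "")
  expect_equal(unname(rec0), unname(truth))

  r <- simulate_assay_records(truth, reports_per_species = 5, flip_probability = 0.1)
  rec <- vapply(names(truth), function(s)
    majority_resolve(r[r$species == s, , drop = FALSE]), "")
  rate <- mean(rec == truth)
  # P(majority of 5 Bernoulli(0.9) correct) = 0.99144
  p_expected <- sum(stats::dbinom(0:2, 5, 0.1))
  expect_lt(abs(rate - p_expected), 3 * sqrt(p_expected * (1 - p_expected) / 300))
  expect_error(simulate_assay_records(truth, 1, 0.5), "flip_probability")
})

test_that("two reports at high error rate can tie, coded ?", {
  set.seed(52)
  tr <- star_tree(200)
  truth <- stats::setNames(rep("1", 200), tr$tip.label)
  r <- simulate_assay_records(truth, reports_per_species = 2, flip_probability = 0.45)
  rec <- vapply(names(truth), function(s)
    majority_resolve(r[r$species == s, , drop = FALSE]), "")
  expect_true(any(rec == "?"))
})

test_that("identical configurations give bit-identical datasets", {
  cfg <- sim_config(n_tips = 25, n_trees = 5, seed = 77)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(sim_config(n_tips = 25, n_trees = 5, seed = 78))
  expect_false(identical(d1$base_tree, d3$base_tree))
  # masked matrix respects the truth where scored
  st <- trait_states(d1$trait_matrix, "muscarine")
  keep <- st != "?"
  expect_equal(st[keep], d1$truth$muscarine$tip_states[keep])
})
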