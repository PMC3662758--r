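## Independent oracles used across the suite.  These deliberately avoid the
## package's own dynamic programmes: parsimony quantities come from
## exhaustive enumeration of internal labelings, tree equality from a
## canonical-form recursion, and trait histories are replayed event by event.

## Exhaustive parsimony: enumerate every assignment of {0,1} to internal
## nodes and to "?" tips, count changes/gains/losses on the rooted edges.
enumerate_asr <- function(tree, trait) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  st <- as.character(trait[tree$tip.label])
  fixed <- integer(n_all)
  fixed[seq_len(n_tip)] <- ifelse(st == "1", 1L, 0L)
  free <- c(which(st == "?"), (n_tip + 1L):n_all)
  n_free <- length(free)
  M <- 2L^n_free
  A <- matrix(rep(fixed, M), n_all, M)
  for (j in seq_len(n_free))
    A[free[j], ] <- rep(rep(0:1, each = 2L^(j - 1L)), length.out = M)
  e <- tree$edge
  gains <- colSums(A[e[, 1L], , drop = FALSE] == 0L & A[e[, 2L], , drop = FALSE] == 1L)
  losses <- colSums(A[e[, 1L], , drop = FALSE] == 1L & A[e[, 2L], , drop = FALSE] == 0L)
  sc <- gains + losses
  best <- min(sc)
  opt <- sc == best
  sets <- lapply(seq_len(n_all), function(v) sort(unique(A[v, opt])))
  names(sets)[seq_len(n_tip)] <- tree$tip.label
  list(score = best,
       sets = sets,
       min_gains = min(gains[opt]), max_gains = max(gains[opt]),
       min_losses = min(losses[opt]), max_losses = max(losses[opt]))
}

## Canonical form: children sorted by their canonical string, lengths
## rounded; equal strings <=> isomorphic rooted trees with equal lengths.
canonical_form <- function(tree, digits = 9) {
  n_tip <- length(tree$tip.label)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]
    kids[[p]] <- c(kids[[p]], tree$edge[i, 2L])
  }
  len <- numeric(n_tip + tree$Nnode)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2L]] <- tree$edge.length
  rec <- function(v) {
    core <- if (v <= n_tip) tree$tip.label[v]
            else paste0("(", paste(sort(vapply(kids[[v]], rec, "")), collapse = ","), ")")
    paste0(core, ":", format(round(len[v], digits)))
  }
  rec(n_tip + 1L)
}

trees_isomorphic <- function(t1, t2) identical(canonical_form(t1), canonical_form(t2))

## Exact permutation p-value by enumerating all placements of the observed
## number of 1s among the scored tips (0s fill the rest, ? fixed).
exact_perm_p <- function(tree, trait) {
  st <- as.character(trait)
  names(st) <- names(trait)
  scored <- names(st)[st != "?"]
  k1 <- sum(st == "1")
  obs <- parsimony_score(tree, st)
  combos <- utils::combn(length(scored), k1)
  null <- apply(combos, 2L, function(ix) {
    s <- st
    s[scored] <- "0"
    s[scored[ix]] <- "1"
    parsimony_score(tree, s)
  })
  mean(null <= obs)
}

## Replay a logged trait history along root-to-tip paths; returns tip states.
replay_history <- function(tree, history) {
  n_tip <- length(tree$tip.label)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  ev <- history$events
  vapply(seq_len(n_tip), function(tip) {
    path <- tip
    v <- tip
    while (parent[v] != 0L) { v <- parent[v]; path <- c(path, v) }
    on_path <- ev[ev$node %in% path, , drop = FALSE]
    on_path <- on_path[order(on_path$time), , drop = FALSE]
    s <- as.character(history$root_state)
    for (i in seq_len(nrow(on_path))) {
      stopifnot(identical(on_path$from[i], s))
      s <- on_path$to[i]
    }
    s
  }, "")
}

## Star tree (one root, n pendant edges of equal length): tips independent
## given the root, used for stationary-distribution checks.
star_tree <- function(n, len = 1) {
  tr <- list(edge = cbind(rep(n + 1L, n), seq_len(n), deparse.level = 0),
             edge.length = rep(len, n),
             tip.label = paste0("t", seq_len(n)),
             Nnode = 1L)
  storage.mode(tr$edge) <- "integer"
  class(tr) <- "phylo"
  tr
}

## Random binary trait over a tree's tips.
random_trait <- function(tree, p1 = 0.4, pq = 0.2) {
  n <- length(tree$tip.label)
  stats::setNames(sample(c("0", "1", "?"), n, replace = TRUE,
                         prob = c(1 - p1 - pq, p1, pq)),
                  tree$tip.label)
}

## A trait with exactly one true gain and no losses: rejection-sample Mk
## histories (root 0, loss rate 0) until exactly one gain occurred and at
## least `min_pos` tips are positive.
single_gain_history <- function(tree, min_pos = 3, q01 = 0.1, max_tries = 500) {
  for (i in seq_len(max_tries)) {
    h <- simulate_mk_binary(tree, q01 = q01, q10 = 0, root_state = "0")
    if (h$n_gains == 1 && sum(h$tip_states == "1") >= min_pos &&
        sum(h$tip_states == "0") >= 2)
      return(h)
  }
  stop("failed to draw a single-gain history")
}

## A history with exactly k gains and no losses (root 0): the positive tips
## are then the union of k disjoint clades, one per logged gain.
k_gain_history <- function(tree, k, q01 = 0.05, max_tries = 2000,
                           max_pos = length(tree$tip.label) / 3) {
  ## rare positives (as for psilocybin in the study system), so that a
  ## root-positive all-losses reconstruction cannot tie the k-gain one
  for (i in seq_len(max_tries)) {
    h <- simulate_mk_binary(tree, q01 = q01, q10 = 0, root_state = "0")
    n_pos <- sum(h$tip_states == "1")
    if (h$n_gains == k && h$n_losses == 0 && n_pos >= k && n_pos <= max_pos &&
        sum(h$tip_states == "0") >= 2)
      return(h)
  }
  stop("failed to draw a ", k, "-gain history")
}

## Single-gain dataset for end-to-end checks: base Yule tree, unperturbed
## branch-length-resampled tree sample, trait masked to `missing` with at
## least 3 scored tips in each state.
single_gain_dataset <- function(n_tips, n_trees, missing, seed,
                                min_pos = 5, q01 = 0.05) {
  set.seed(seed)
  repeat {
    base <- simulate_yule(n_tips)
    h <- try(single_gain_history(base, min_pos = min_pos, q01 = q01), silent = TRUE)
    if (inherits(h, "try-error")) next
    st <- mask_missing(h, missing)
    if (sum(st == "1") >= 3 && sum(st == "0") >= 3) {
      smp <- perturb_tree_sample(base, n_trees, n_nni = 0)
      return(list(base = base, history = h, trait = st, sample = smp))
    }
  }
}
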