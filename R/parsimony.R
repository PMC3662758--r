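## Fitch/Hartigan parsimony on rooted trees with binary states {0,1} and
## ambiguity "?" (= state set {0,1}).  All three user-facing operations share
## one dynamic programme over (node, state); polytomies need no special
## casing because the child contributions are summed per parent state
## (Hartigan's generalization; binary Fitch is the two-child special case).

.as_trait_vector <- function(trait, tips) {
  x <- as.character(trait)
  names(x) <- names(trait)
  if (is.null(names(x))) stop("trait states must be a named vector (names = tip labels)")
  missing <- setdiff(tips, names(x))
  if (length(missing))
    stop(sprintf("tip(s) missing from trait column: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")))
  x <- x[tips]
  bad <- !(x %in% c("0", "1", "?"))
  if (any(bad))
    stop(sprintf("invalid state '%s' for tip '%s' (allowed: 0, 1, ?)",
                 x[bad][1L], tips[bad][1L]))
  x
}

## Postorder edge list reused across permutations of the same tree.
.prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  po <- ape::reorder.phylo(tree, "postorder")
  list(edge = po$edge, n_tip = length(po$tip.label),
       n_all = length(po$tip.label) + po$Nnode,
       root = po$edge[nrow(po$edge), 1L], tip.label = po$tip.label)
}

## Vectorized down-pass over K trait columns at once.
## tip0/tip1: n_tip x K cost matrices (0 if the state is allowed at the tip,
## Inf otherwise).  Returns the K parsimony scores.
.fitch_scores <- function(prep, tip0, tip1) {
  K <- ncol(tip0)
  c0 <- matrix(0, prep$n_all, K)
  c1 <- matrix(0, prep$n_all, K)
  c0[seq_len(prep$n_tip), ] <- tip0
  c1[seq_len(prep$n_tip), ] <- tip1
  e <- prep$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    a <- c0[ch, ]; b <- c1[ch, ]
    c0[p, ] <- c0[p, ] + pmin(a, b + 1)
    c1[p, ] <- c1[p, ] + pmin(b, a + 1)
  }
  pmin(c0[prep$root, ], c1[prep$root, ])
}

.tip_cost <- function(states) {
  list(t0 = ifelse(states == "1", Inf, 0),
       t1 = ifelse(states == "0", Inf, 0))
}

#' Parsimony score of a binary trait on a tree
#'
#' Minimum number of state changes over all assignments of 0/1 to internal
#' nodes, with `?` tips free to take either state.  Hartigan's algorithm,
#' so polytomies are handled exactly.
#'
#' @param tree A rooted `"phylo"` object.
#' @param trait Named character vector of tip states in `{"0","1","?"}`;
#'   every tip of `tree` must be named (a missing tip is an error, distinct
#'   from `?`).
#' @return Nonnegative integer score.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' parsimony_score(tr, c(A = "1", B = "1", C = "0", D = "0"))
#' @export
parsimony_score <- function(tree, trait) {
  prep <- .prep_tree(tree)
  st <- .as_trait_vector(trait, prep$tip.label)
  tc <- .tip_cost(st)
  as.integer(.fitch_scores(prep, matrix(tc$t0), matrix(tc$t1)))
}

## Single-column down-pass returning per-node cost vectors.
.down_pass <- function(prep, st) {
  tc <- .tip_cost(st)
  c0 <- numeric(prep$n_all); c1 <- numeric(prep$n_all)
  c0[seq_len(prep$n_tip)] <- tc$t0
  c1[seq_len(prep$n_tip)] <- tc$t1
  e <- prep$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    a <- c0[ch]; b <- c1[ch]
    c0[p] <- c0[p] + (if (a <= b + 1) a else b + 1)
    c1[p] <- c1[p] + (if (b <= a + 1) b else a + 1)
  }
  list(c0 = c0, c1 = c1, score = min(c0[prep$root], c1[prep$root]))
}

#' Most-parsimonious-reconstruction state sets
#'
#' For every node, the set of states that the node takes in at least one
#' most parsimonious reconstruction (MPR).  Computed by a down-pass
#' (subtree costs per node state) followed by an up-pass that propagates
#' feasibility from the root; tips with observed states return singleton
#' sets, `?` tips the states they can take in an MPR.
#'
#' @inheritParams parsimony_score
#' @return A list of integer vectors (subsets of `c(0L, 1L)`), indexed by
#'   node number (tips `1..n`, then internal nodes), with the parsimony
#'   score in attribute `"score"`.
#' @export
mpr_state_sets <- function(tree, trait) {
  prep <- .prep_tree(tree)
  st <- .as_trait_vector(trait, prep$tip.label)
  dp <- .down_pass(prep, st)
  feas0 <- logical(prep$n_all); feas1 <- logical(prep$n_all)
  feas0[prep$root] <- dp$c0[prep$root] == dp$score
  feas1[prep$root] <- dp$c1[prep$root] == dp$score
  e <- prep$edge
  for (i in rev(seq_len(nrow(e)))) {  # preorder
    p <- e[i, 1L]; ch <- e[i, 2L]
    a <- dp$c0[ch]; b <- dp$c1[ch]
    if (feas0[p]) {  # parent state 0: child 0 costs a, child 1 costs b+1
      best <- min(a, b + 1)
      if (a == best) feas0[ch] <- TRUE
      if (b + 1 == best) feas1[ch] <- TRUE
    }
    if (feas1[p]) {
      best <- min(b, a + 1)
      if (b == best) feas1[ch] <- TRUE
      if (a + 1 == best) feas0[ch] <- TRUE
    }
  }
  sets <- lapply(seq_len(prep$n_all), function(v)
    c(if (feas0[v]) 0L, if (feas1[v]) 1L))
  names(sets)[seq_len(prep$n_tip)] <- prep$tip.label
  structure(sets, score = as.integer(dp$score))
}

#' Minimum and maximum gains and losses over all MPRs
#'
#' Counts 0 -> 1 changes (gains) and 1 -> 0 changes (losses) on the edges of
#' the rooted tree, minimized and maximized over all most parsimonious
#' reconstructions, with the root state free.  Uses a lexicographic
#' dynamic programme over (changes, gains): since every change is a gain or
#' a loss, each MPR satisfies gains + losses = score, so
#' `min_gains + max_losses = score` and `max_gains + min_losses = score`.
#'
#' @inheritParams parsimony_score
#' @return An object of class `"asr_summary"`: a list with integer fields
#'   `score`, `min_gains`, `max_gains`, `min_losses`, `max_losses`.
#' @export
count_gains_losses <- function(tree, trait) {
  prep <- .prep_tree(tree)
  st <- .as_trait_vector(trait, prep$tip.label)
  tc <- .tip_cost(st)
  n <- prep$n_all
  c0 <- numeric(n); c1 <- numeric(n)
  c0[seq_len(prep$n_tip)] <- tc$t0
  c1[seq_len(prep$n_tip)] <- tc$t1
  gmin0 <- numeric(n); gmin1 <- numeric(n)  # min gains | min changes, node state
  gmax0 <- numeric(n); gmax1 <- numeric(n)
  e <- prep$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    a <- c0[ch]; b <- c1[ch]
    ## parent state 0: child 0 -> (a, g(ch,0)); child 1 -> (b+1, g(ch,1)+1) [gain edge]
    if (a < b + 1) { d0 <- a; lo0 <- gmin0[ch]; hi0 <- gmax0[ch] }
    else if (b + 1 < a) { d0 <- b + 1; lo0 <- gmin1[ch] + 1; hi0 <- gmax1[ch] + 1 }
    else { d0 <- a; lo0 <- min(gmin0[ch], gmin1[ch] + 1); hi0 <- max(gmax0[ch], gmax1[ch] + 1) }
    ## parent state 1: child 1 -> (b, g(ch,1)); child 0 -> (a+1, g(ch,0)) [loss edge]
    if (b < a + 1) { d1 <- b; lo1 <- gmin1[ch]; hi1 <- gmax1[ch] }
    else if (a + 1 < b) { d1 <- a + 1; lo1 <- gmin0[ch]; hi1 <- gmax0[ch] }
    else { d1 <- b; lo1 <- min(gmin1[ch], gmin0[ch]); hi1 <- max(gmax1[ch], gmax0[ch]) }
    c0[p] <- c0[p] + d0; gmin0[p] <- gmin0[p] + lo0; gmax0[p] <- gmax0[p] + hi0
    c1[p] <- c1[p] + d1; gmin1[p] <- gmin1[p] + lo1; gmax1[p] <- gmax1[p] + hi1
  }
  r <- prep$root
  score <- min(c0[r], c1[r])
  gmin <- min(if (c0[r] == score) gmin0[r] else Inf,
              if (c1[r] == score) gmin1[r] else Inf)
  gmax <- max(if (c0[r] == score) gmax0[r] else -Inf,
              if (c1[r] == score) gmax1[r] else -Inf)
  structure(list(score = as.integer(score),
                 min_gains = as.integer(gmin),
                 max_gains = as.integer(gmax),
                 min_losses = as.integer(score - gmax),
                 max_losses = as.integer(score - gmin)),
            class = "asr_summary")
}

#' @export
print.asr_summary <- function(x, ...) {
  cat(sprintf("Parsimony ASR: score %d; gains %d-%d; losses %d-%d\n",
              x$score, x$min_gains, x$max_gains, x$min_losses, x$max_losses))
  invisible(x)
}

#' Ancestral-state reconstruction over a posterior tree sample
#'
#' Runs [count_gains_losses()] on every tree of a sample and aggregates
#' the across-sample ranges, the way an ASR is repeated for each tree in a
#' Bayesian posterior distribution.
#'
#' @param sample A [tree_sample()].
#' @param trait Named character vector of tip states in `{"0","1","?"}`
#'   covering the shared tip set.
#' @return An object of class `"asr_sample_summary"`: list with `per_tree`
#'   (data frame: tree, score, min_gains, max_gains, min_losses,
#'   max_losses) and `range` (named list of across-tree `c(min, max)` for
#'   score, gains and losses).
#' @export
asr_over_sample <- function(sample, trait) {
  stopifnot(inherits(sample, "tree_sample"))
  rows <- lapply(seq_along(sample$trees), function(i) {
    s <- count_gains_losses(sample$trees[[i]], trait)
    data.frame(tree = i, score = s$score,
               min_gains = s$min_gains, max_gains = s$max_gains,
               min_losses = s$min_losses, max_losses = s$max_losses)
  })
  per_tree <- do.call(rbind, rows)
  structure(list(
    per_tree = per_tree,
    range = list(score = range(per_tree$score),
                 gains = c(min(per_tree$min_gains), max(per_tree$max_gains)),
                 losses = c(min(per_tree$min_losses), max(per_tree$max_losses)))
  ), class = "asr_sample_summary")
}

#' @export
print.asr_sample_summary <- function(x, ...) {
  cat(sprintf("ASR over %d trees: score %d-%d; gains %d-%d; losses %d-%d\n",
              nrow(x$per_tree),
              x$range$score[1], x$range$score[2],
              x$range$gains[1], x$range$gains[2],
              x$range$losses[1], x$range$losses[2]))
  invisible(x)
}
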