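## Tip-label randomization test of phylogenetic conservatism: shuffle the
## observed 0/1 states among the scored tips (tips with no data stay "?"),
## rescore by parsimony, and ask how often a random arrangement is at least
## as parsimonious as the observed one.  Low p = fewer changes than chance =
## conserved.

#' Permute trait states among scored tips
#'
#' Uniformly shuffles the 0/1 states among the tips that have data; `?`
#' tips are untouched, so the multiset of scored states is preserved.
#' Uses the session RNG (call `set.seed()` for reproducibility).
#'
#' @param trait Named character vector of states in `{"0","1","?"}`.
#' @return A permuted copy of `trait`.
#' @export
permute_scored_states <- function(trait) {
  x <- as.character(trait)
  names(x) <- names(trait)
  sc <- which(x != "?")
  if (length(sc) < 2L)
    stop("fewer than 2 scored tips: nothing to permute")
  x[sc] <- x[sc][sample.int(length(sc))]
  x
}

#' Randomization test of phylogenetic conservatism for one tree
#'
#' Compares the observed parsimony score with the scores of `n_perm`
#' uniform permutations of the scored tip states.  The p-value is the
#' plain proportion of null scores less than or equal to the observed
#' score (ties count as extreme; the estimate can be 0).  Set
#' `add_one = TRUE` for the (obs+1)/(n+1) variant that cannot be 0.
#'
#' @param tree A rooted `"phylo"` object.
#' @param trait Named character vector of tip states in `{"0","1","?"}`.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Optional integer seed for this test.
#' @param add_one Use the add-one p estimator.
#' @return An object of class `"permutation_test"`: list with `observed`,
#'   `null` (integer vector of length `n_perm`), `p_value`, `n_perm`,
#'   `seed`, `estimator`.
#' @examples
#' tr <- parse_newick("(((A,B),(C,D)),((E,F),(G,H)));")
#' trait <- c(A="1",B="1",C="1",D="1",E="0",F="0",G="0",H="0")
#' conservatism_test(tr, trait, n_perm = 99, seed = 1)
#' @export
conservatism_test <- function(tree, trait, n_perm = 100, seed = NULL,
                              add_one = FALSE) {
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  prep <- .prep_tree(tree)
  st <- .as_trait_vector(trait, prep$tip.label)
  sc <- which(st != "?")
  if (length(sc) < 2L)
    stop("fewer than 2 scored tips: conservatism test undefined")
  observed <- as.integer(.down_pass(prep, st)$score)
  ## all permutations scored in one vectorized down-pass
  vals <- st[sc]
  P <- vapply(seq_len(n_perm), function(j) vals[sample.int(length(vals))],
              character(length(vals)))
  tip0 <- matrix(0, prep$n_tip, n_perm)
  tip1 <- matrix(0, prep$n_tip, n_perm)
  tip0[sc, ] <- ifelse(P == "1", Inf, 0)
  tip1[sc, ] <- ifelse(P == "0", Inf, 0)
  null_scores <- as.integer(.fitch_scores(prep, tip0, tip1))
  p <- if (add_one) (sum(null_scores <= observed) + 1) / (n_perm + 1)
       else mean(null_scores <= observed)
  structure(list(observed = observed, null = null_scores, p_value = p,
                 n_perm = as.integer(n_perm),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 estimator = if (add_one) "add_one" else "proportion"),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Conservatism randomization test: observed score %d, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$n_perm))
  invisible(x)
}

#' Conservatism test averaged over a posterior tree sample
#'
#' Runs [conservatism_test()] on every tree of a sample and reports the
#' arithmetic mean of the per-tree p-values.  Per-tree seeds are derived
#' deterministically from `seed`, so the full analysis is reproducible.
#'
#' @param sample A [tree_sample()].
#' @param trait Named character vector of tip states.
#' @param n_perm Permutations per tree.
#' @param seed Master seed.
#' @param add_one Use the add-one p estimator per tree.
#' @return An object of class `"conservatism_sample"`: list with
#'   `per_tree` (data frame: tree, observed, p_value), `average_p`,
#'   `n_perm`, `seed`.
#' @export
conservatism_over_sample <- function(sample, trait, n_perm = 100, seed = 1,
                                     add_one = FALSE) {
  stopifnot(inherits(sample, "tree_sample"))
  n <- length(sample$trees)
  if (!n) stop("empty tree sample")
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, n)
  rows <- lapply(seq_len(n), function(i) {
    r <- conservatism_test(sample$trees[[i]], trait, n_perm = n_perm,
                           seed = tree_seeds[i], add_one = add_one)
    data.frame(tree = i, observed = r$observed, p_value = r$p_value)
  })
  per_tree <- do.call(rbind, rows)
  structure(list(per_tree = per_tree,
                 average_p = mean(per_tree$p_value),
                 n_perm = as.integer(n_perm),
                 seed = as.integer(seed)),
            class = "conservatism_sample")
}

#' @export
print.conservatism_sample <- function(x, ...) {
  cat(sprintf("Conservatism over %d trees: average p = %.4g (%d permutations/tree)\n",
              nrow(x$per_tree), x$average_p, x$n_perm))
  invisible(x)
}
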