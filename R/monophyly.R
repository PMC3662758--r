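## Posterior-odds monophyly test: in each posterior tree, drop the tips with
## unknown trait state, ask whether the trait-positive tips form a clade,
## and report the proportion of trees in which they do.

#' Test whether a set of tips is monophyletic
#'
#' True iff the tip set of the most recent common ancestor of `tips`
#' equals `tips`.  A singleton set is monophyletic by convention.  The
#' check is a single postorder count pass (a node whose descendant tips
#' are exactly the marked tips exists iff the set is a clade), so no
#' explicit MRCA lookup is needed.
#'
#' @param tree A rooted `"phylo"` object.
#' @param tips Nonempty character vector of tip labels.
#' @return Logical scalar.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' is_monophyletic(tr, c("A", "B"))  # TRUE
#' is_monophyletic(tr, c("A", "C"))  # FALSE
#' @export
is_monophyletic <- function(tree, tips) {
  stopifnot(inherits(tree, "phylo"))
  tips <- unique(as.character(tips))
  if (!length(tips)) stop("'tips' must not be empty")
  unknown <- setdiff(tips, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown tip label(s): %s", paste(unknown, collapse = ", ")))
  k <- length(tips)
  if (k == 1L || k == length(tree$tip.label)) return(TRUE)
  prep <- .prep_tree(tree)
  n_desc <- integer(prep$n_all)    # tips below each node
  n_mark <- integer(prep$n_all)    # marked tips below each node
  n_desc[seq_len(prep$n_tip)] <- 1L
  n_mark[match(tips, prep$tip.label)] <- 1L
  e <- prep$edge
  for (i in seq_len(nrow(e))) {
    p <- e[i, 1L]; ch <- e[i, 2L]
    n_desc[p] <- n_desc[p] + n_desc[ch]
    n_mark[p] <- n_mark[p] + n_mark[ch]
  }
  any(n_mark == k & n_desc == k)
}

#' Posterior proportion of trees in which trait-positive taxa are a clade
#'
#' For every tree in the sample: prune to the tips with known trait state
#' (non-`?`), then test whether the state-1 tips are monophyletic on the
#' pruned tree.  The proportion of trees passing is the posterior support
#' for monophyly of the trait-positive group; a proportion of 0 means no
#' sampled tree is consistent with the group being a clade.
#'
#' @param sample A [tree_sample()].
#' @param trait Named character vector of tip states in `{"0","1","?"}`.
#' @return An object of class `"monophyly_result"`: list with `n_trees`,
#'   `n_monophyletic`, `proportion`, `n_positive`, `n_scored`,
#'   `degenerate` (TRUE when the positive group is a singleton or the
#'   whole scored set, which is monophyletic by convention).
#' @export
monophyly_over_sample <- function(sample, trait) {
  stopifnot(inherits(sample, "tree_sample"))
  st <- .as_trait_vector(trait, sample$trees[[1L]]$tip.label)
  scored <- names(st)[st != "?"]
  positive <- names(st)[st == "1"]
  if (!length(positive))
    stop("no tips scored 1: monophyly of the positive group is undefined")
  degenerate <- length(positive) == 1L || length(positive) == length(scored)
  if (degenerate)
    warning("positive group is a singleton or the full scored set; monophyletic by convention")
  hits <- vapply(sample$trees, function(tr) {
    pruned <- if (length(scored) >= 2L) prune_to(tr, scored) else tr
    is_monophyletic(pruned, positive)
  }, logical(1L))
  structure(list(n_trees = length(hits),
                 n_monophyletic = sum(hits),
                 proportion = mean(hits),
                 n_positive = length(positive),
                 n_scored = length(scored),
                 degenerate = degenerate),
            class = "monophyly_result")
}

#' @export
print.monophyly_result <- function(x, ...) {
  cat(sprintf("Monophyly over %d trees: %d monophyletic (proportion %.4g); %d positive of %d scored tips\n",
              x$n_trees, x$n_monophyletic, x$proportion, x$n_positive, x$n_scored))
  if (isTRUE(x$degenerate))
    cat("  (degenerate positive group: monophyletic by convention)\n")
  invisible(x)
}
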