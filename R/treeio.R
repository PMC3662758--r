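## Trees are plain ape "phylo" objects throughout; a tree_sample wraps an
## ordered multiPhylo with per-tree MCMC provenance (run, generation).

# ---------------------------------------------------------------------------
# Newick parsing / writing
#
# Hand-written so that the dialect contract holds bit-exactly: labels with
# spaces or punctuation are single-quoted ('' escapes a quote) and round-trip
# unchanged; underscores in unquoted labels are verbatim (never turned into
# spaces); negative branch lengths and duplicate tip labels are rejected with
# the offending token position.
# ---------------------------------------------------------------------------

.newick_tokens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  type <- character(0); value <- character(0); pos <- integer(0)
  push <- function(t, v, p) {
    type[length(type) + 1L] <<- t
    value[length(value) + 1L] <<- v
    pos[length(pos) + 1L] <<- p
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t", "\n", "\r")) {
      i <- i + 1L
    } else if (ch %in% c("(", ")", ",", ":", ";")) {
      push(ch, ch, i)
      i <- i + 1L
    } else if (ch == "'") {
      start <- i
      i <- i + 1L
      buf <- character(0)
      repeat {
        if (i > n)
          stop(sprintf("newick parse error at position %d: unterminated quoted label", start))
        if (chars[i] == "'") {
          if (i + 1L <= n && chars[i + 1L] == "'") {  # '' escapes a quote
            buf <- c(buf, "'"); i <- i + 2L
          } else {
            i <- i + 1L
            break
          }
        } else {
          buf <- c(buf, chars[i]); i <- i + 1L
        }
      }
      push("quoted", paste(buf, collapse = ""), start)
    } else {
      start <- i
      while (i <= n && !(chars[i] %in% c("(", ")", ",", ":", ";", "'", " ", "\t", "\n", "\r")))
        i <- i + 1L
      push("word", paste(chars[start:(i - 1L)], collapse = ""), start)
    }
  }
  list(type = type, value = value, pos = pos)
}

#' Parse a Newick string into a phylogenetic tree
#'
#' Parses one rooted tree in Newick format into an [ape::phylo] object.
#' Labels may be single-quoted (with `''` escaping an embedded quote);
#' underscores in unquoted labels are kept verbatim.  Polytomies are legal.
#' Branch lengths are optional; when present they must be nonnegative.
#'
#' @param text A single character string ending in `";"`.
#' @return An object of class `"phylo"`.  Child order is preserved as
#'   written.  If the string carries no branch lengths at all the returned
#'   tree has no `edge.length` component.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' @seealso [write_newick()], [parse_nexus_trees()]
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L)
    stop("'text' must be a single character string")
  tk <- .newick_tokens(text)
  if (length(tk$type) == 0L || tk$type[length(tk$type)] != ";")
    stop("newick parse error: string must end in ';'")
  idx <- 1L
  peek <- function() if (idx <= length(tk$type)) tk$type[idx] else "eof"
  take <- function() { idx <<- idx + 1L; idx - 1L }
  expect <- function(t) {
    if (peek() != t)
      stop(sprintf("newick parse error at position %d: expected '%s', found '%s'",
                   if (idx <= length(tk$pos)) tk$pos[idx] else nchar(text), t,
                   if (idx <= length(tk$type)) tk$value[idx] else "end of input"))
    take()
  }
  parse_len <- function() {
    j <- expect("word")  # the token after ':'
    len <- suppressWarnings(as.numeric(tk$value[j]))
    if (is.na(len))
      stop(sprintf("newick parse error at position %d: invalid branch length '%s'",
                   tk$pos[j], tk$value[j]))
    if (len < 0)
      stop(sprintf("newick parse error at position %d: negative branch length %s",
                   tk$pos[j], tk$value[j]))
    len
  }
  parse_clade <- function() {
    if (peek() == "(") {
      take()
      children <- list(parse_clade())
      while (peek() == ",") {
        take()
        children[[length(children) + 1L]] <- parse_clade()
      }
      expect(")")
      lab <- NA_character_
      if (peek() %in% c("word", "quoted")) lab <- tk$value[take()]
      len <- if (peek() == ":") { take(); parse_len() } else NA_real_
      list(children = children, label = lab, len = len)
    } else if (peek() %in% c("word", "quoted")) {
      lab <- tk$value[take()]
      len <- if (peek() == ":") { take(); parse_len() } else NA_real_
      list(children = NULL, label = lab, len = len)
    } else {
      stop(sprintf("newick parse error at position %d: unexpected '%s'",
                   if (idx <= length(tk$pos)) tk$pos[idx] else nchar(text),
                   if (idx <= length(tk$type)) tk$value[idx] else "end of input"))
    }
  }
  root <- parse_clade()
  expect(";")
  if (peek() != "eof")
    stop(sprintf("newick parse error at position %d: trailing content after ';'", tk$pos[idx]))
  if (is.null(root$children))
    stop("newick parse error: a tree needs at least two tips")
  .clade_to_phylo(root)
}

.clade_to_phylo <- function(root) {
  n_tip <- 0L; n_int <- 0L
  count <- function(nd) {
    if (is.null(nd$children)) n_tip <<- n_tip + 1L
    else { n_int <<- n_int + 1L; for (ch in nd$children) count(ch) }
  }
  count(root)
  n_edge <- n_tip + n_int - 1L
  edge <- matrix(0L, n_edge, 2L)
  edge_len <- rep(NA_real_, n_edge)
  tip_label <- character(n_tip)
  node_label <- character(n_int)
  ti <- 0L; ni <- 0L; ei <- 0L
  walk <- function(nd, parent) {
    if (is.null(nd$children)) {
      ti <<- ti + 1L; id <- ti; tip_label[ti] <<- nd$label
    } else {
      ni <<- ni + 1L; id <- n_tip + ni
      node_label[ni] <<- if (is.na(nd$label)) "" else nd$label
    }
    if (!is.na(parent)) {
      ei <<- ei + 1L
      edge[ei, ] <<- c(parent, id)
      edge_len[ei] <<- nd$len
    }
    if (!is.null(nd$children)) for (ch in nd$children) walk(ch, id)
    id
  }
  walk(root, NA_integer_)
  dup <- tip_label[duplicated(tip_label)]
  if (length(dup))
    stop(sprintf("newick parse error: duplicate tip label '%s'", dup[1L]))
  tr <- list(edge = edge, tip.label = tip_label, Nnode = n_int)
  if (any(!is.na(edge_len))) tr$edge.length <- edge_len
  if (any(nzchar(node_label))) tr$node.label <- node_label
  if (!is.na(root$len)) tr$root.edge <- root$len
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

.quote_label <- function(lab) {
  need <- grepl("[](),:;'\\[ \t]", lab)
  ifelse(need, paste0("'", gsub("'", "''", lab, fixed = TRUE), "'"), lab)
}

#' Write a phylogenetic tree as a Newick string
#'
#' Inverse of [parse_newick()]: labels containing spaces or punctuation are
#' single-quoted, branch lengths are printed with enough significant digits
#' to round-trip, and child order is preserved.
#'
#' @param tree A `"phylo"` object.
#' @param digits Significant digits for branch lengths.
#' @return A single character string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  kids <- .child_list(tree)
  has_len <- !is.null(tree$edge.length)
  len_of <- numeric(n_tip + tree$Nnode)
  if (has_len) len_of[tree$edge[, 2L]] <- tree$edge.length
  fmt <- function(x) sprintf("%.*g", digits, x)
  lab_of <- function(id) {
    if (id <= n_tip) .quote_label(tree$tip.label[id])
    else if (!is.null(tree$node.label) && nzchar(tree$node.label[id - n_tip]))
      .quote_label(tree$node.label[id - n_tip])
    else ""
  }
  rec <- function(id, is_root) {
    core <- if (id <= n_tip) lab_of(id)
            else paste0("(", paste(vapply(kids[[id]], rec, "", is_root = FALSE),
                                   collapse = ","), ")", lab_of(id))
    if (!is_root && has_len) paste0(core, ":", fmt(len_of[id])) else core
  }
  root <- n_tip + 1L
  out <- rec(root, TRUE)
  if (!is.null(tree$root.edge)) out <- paste0(out, ":", fmt(tree$root.edge))
  paste0(out, ";")
}

.child_list <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  kids <- vector("list", n_all)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  kids
}

# ---------------------------------------------------------------------------
# Tree samples (posterior distributions)
# ---------------------------------------------------------------------------

#' Construct a tree sample (posterior distribution stand-in)
#'
#' Bundles an ordered collection of trees with per-tree MCMC provenance
#' (run identifier and generation index) and sampling metadata, the way a
#' post-burn-in Bayesian posterior sample is handled.
#'
#' @param trees A list of `"phylo"` objects (or a `multiPhylo`).  All trees
#'   must share one tip-label set.
#' @param run Integer run identifier(s), recycled over trees.
#' @param generation Integer generation index per tree (`NA` if unknown).
#'   Within a run, known generations must be strictly increasing.
#' @param chain_length,sample_interval,n_runs Optional sampler metadata
#'   (generations).
#' @return An object of class `"tree_sample"` with elements `trees`,
#'   `provenance` (data frame with columns `run`, `generation`) and
#'   `metadata`.
#' @export
tree_sample <- function(trees, run = 1L, generation = NULL,
                        chain_length = NA_real_, sample_interval = NA_real_,
                        n_runs = NA_integer_) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (!length(trees)) stop("'trees' must contain at least one tree")
  ok <- vapply(trees, inherits, TRUE, what = "phylo")
  if (!all(ok)) stop("all elements of 'trees' must be \"phylo\" objects")
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees))
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop(sprintf("tree %d does not share the tip-label set of tree 1", i))
  n <- length(trees)
  run <- rep_len(as.integer(run), n)
  generation <- if (is.null(generation)) rep(NA_integer_, n)
                else rep_len(as.integer(generation), n)
  for (r in unique(run)) {
    g <- generation[run == r]
    g <- g[!is.na(g)]
    if (length(g) > 1L && any(diff(g) <= 0))
      stop(sprintf("generation indices within run %d must be strictly increasing", r))
    if (!is.na(sample_interval) && length(g) && any(g %% sample_interval != 0))
      stop("generation indices must be multiples of the sampling interval")
  }
  structure(list(
    trees = structure(trees, class = "multiPhylo"),
    provenance = data.frame(run = run, generation = generation),
    metadata = list(chain_length = chain_length,
                    sample_interval = sample_interval,
                    n_runs = if (is.na(n_runs)) length(unique(run)) else as.integer(n_runs))
  ), class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
`[.tree_sample` <- function(x, i) {
  ## direct rebuild: a slice (in any order) of a valid sample is valid,
  ## so the constructor's generation-monotonicity check is not re-run
  structure(list(
    trees = structure(unclass(x$trees)[i], class = "multiPhylo"),
    provenance = x$provenance[i, , drop = FALSE],
    metadata = x$metadata
  ), class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat(sprintf("Tree sample: %d trees, %d tips, %d run(s)\n",
              length(x$trees), length(x$trees[[1L]]$tip.label),
              length(unique(x$provenance$run))))
  invisible(x)
}

#' Parse a NEXUS trees block into a tree sample
#'
#' Reads the `trees` block of a NEXUS document (the dialect written by
#' Bayesian MCMC samplers), applying the optional `translate` table so that
#' every returned tree carries full-text tip labels.  Square-bracket
#' comments (e.g. `[&R]`) are ignored.  Generation indices are taken from
#' trailing integers in tree names (e.g. `STATE_500000`).
#'
#' @param x Path to a NEXUS file, or the document itself as a string.
#' @param run Integer run identifier stored in the sample's provenance.
#' @param chain_length,sample_interval Optional sampler metadata.
#' @return A [tree_sample()].
#' @export
parse_nexus_trees <- function(x, run = 1L, chain_length = NA_real_,
                              sample_interval = NA_real_) {
  text <- if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "\n") else paste(x, collapse = "\n")
  block <- regmatches(text, regexpr("(?is)begin\\s+trees\\s*;.*?\\bend\\s*;", text, perl = TRUE))
  if (!length(block)) stop("NEXUS format error: no trees block found")
  block <- block[[1L]]

  translate <- NULL
  tr_m <- regmatches(block, regexpr("(?is)translate\\b(.*?);", block, perl = TRUE))
  if (length(tr_m)) {
    body <- sub("(?is)^translate\\b", "", tr_m[[1L]], perl = TRUE)
    body <- sub(";\\s*$", "", body)
    entries <- strsplit(body, ",")[[1L]]
    entries <- trimws(entries)
    entries <- entries[nzchar(entries)]
    toks <- sub("^(\\S+)\\s+.*$", "\\1", entries)
    labs <- sub("^\\S+\\s+", "", entries)
    quoted <- grepl("^'.*'$", labs)
    labs[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", labs[quoted]))
    translate <- stats::setNames(labs, toks)
    block <- sub("(?is)translate\\b.*?;", "", block, perl = TRUE)
  }

  stmts <- regmatches(block, gregexpr("(?is)\\btree\\s+\\S+\\s*=[^;]*;", block, perl = TRUE))[[1L]]
  if (!length(stmts)) stop("NEXUS format error: trees block contains no tree statements")
  trees <- vector("list", length(stmts))
  gens <- rep(NA_integer_, length(stmts))
  for (i in seq_along(stmts)) {
    name <- sub("(?is)^\\s*tree\\s+(\\S+)\\s*=.*$", "\\1", stmts[i], perl = TRUE)
    nwk <- sub("(?is)^\\s*tree\\s+\\S+\\s*=\\s*", "", stmts[i], perl = TRUE)
    nwk <- gsub("\\[[^]]*\\]", "", nwk)  # strip [&R] and figtree-style comments
    tr <- parse_newick(trimws(nwk))
    if (!is.null(translate)) {
      hit <- match(tr$tip.label, names(translate))
      if (anyNA(hit))
        stop(sprintf("NEXUS format error: translate token '%s' has no mapping",
                     tr$tip.label[which(is.na(hit))[1L]]))
      tr$tip.label <- unname(translate[hit])
    }
    g <- regmatches(name, regexpr("[0-9]+$", name))
    if (length(g)) gens[i] <- as.integer(g)
    trees[[i]] <- tr
  }
  tree_sample(trees, run = run, generation = gens,
              chain_length = chain_length, sample_interval = sample_interval)
}

#' Write a tree sample as a NEXUS trees block
#'
#' @param sample A [tree_sample()].
#' @param file Optional path; when `NULL` the document is returned as a
#'   character string.
#' @param digits Significant digits for branch lengths.
#' @return The NEXUS document, invisibly when written to `file`.
#' @export
write_nexus_trees <- function(sample, file = NULL, digits = 15) {
  stopifnot(inherits(sample, "tree_sample"))
  labs <- sort(sample$trees[[1L]]$tip.label)
  tok <- stats::setNames(as.character(seq_along(labs)), labs)
  lines <- c("#NEXUS", "BEGIN TREES;", "\tTRANSLATE")
  tr_lines <- paste0("\t\t", seq_along(labs), " ", .quote_label(labs))
  tr_lines <- paste0(tr_lines, c(rep(",", length(labs) - 1L), ";"))
  lines <- c(lines, tr_lines)
  for (i in seq_along(sample$trees)) {
    tr <- sample$trees[[i]]
    tr$tip.label <- unname(tok[tr$tip.label])
    g <- sample$provenance$generation[i]
    nm <- if (is.na(g)) sprintf("TREE_%d", i) else sprintf("STATE_%d", g)
    lines <- c(lines, sprintf("\tTREE %s = [&R] %s", nm, write_newick(tr, digits = digits)))
  }
  lines <- c(lines, "END;")
  doc <- paste(lines, collapse = "\n")
  if (is.null(file)) return(doc)
  writeLines(doc, file)
  invisible(doc)
}

# ---------------------------------------------------------------------------
# Burn-in arithmetic and pruning
# ---------------------------------------------------------------------------

#' Number of posterior trees retained after burn-in
#'
#' Computes how many trees a set of MCMC runs contributes to the combined
#' post-burn-in posterior: `n_runs * (chain_length - burnin) /
#' sample_interval`.  The generation-0 sample is excluded by convention,
#' so a full chain of length C sampled every i generations yields C/i trees
#' per run, not C/i + 1.
#'
#' @param n_runs Number of independent runs.
#' @param chain_length Chain length in generations.
#' @param sample_interval Sampling interval in generations; must divide both
#'   `chain_length` and `burnin`.
#' @param burnin Generations discarded from the start of each run.
#' @return Integer-valued count of retained trees.
#' @examples
#' posterior_sample_count(5, 5e7, 5000, 3e7)  # 20000
#' @export
posterior_sample_count <- function(n_runs, chain_length, sample_interval, burnin) {
  if (n_runs < 1) stop("'n_runs' must be at least 1")
  if (sample_interval <= 0) stop("'sample_interval' must be positive")
  if (burnin < 0 || burnin > chain_length)
    stop("'burnin' must lie in [0, chain_length]")
  divides <- function(x) abs(x / sample_interval - round(x / sample_interval)) < 1e-9
  if (!divides(chain_length) || !divides(burnin))
    stop("'sample_interval' must divide both 'chain_length' and 'burnin'")
  n_runs * round((chain_length - burnin) / sample_interval)
}

#' Discard burn-in trees from a sample
#'
#' Retains, within each run, exactly the trees whose generation index
#' exceeds `burnin`.
#'
#' @param sample A [tree_sample()] with generation provenance.
#' @param burnin Generations to discard.
#' @return A [tree_sample()].
#' @export
discard_burnin <- function(sample, burnin) {
  stopifnot(inherits(sample, "tree_sample"))
  g <- sample$provenance$generation
  if (anyNA(g))
    stop("cannot discard burn-in: sample lacks generation provenance")
  sample[g > burnin]
}

#' Prune a tree to a set of tips
#'
#' Drops all tips outside `keep`, suppressing the resulting unifurcations
#' with branch lengths summed so that tip-to-root path lengths of retained
#' tips are preserved.
#'
#' @param tree A `"phylo"` object.
#' @param keep Character vector of tip labels to retain (a nonempty subset
#'   of the tree's tips, at least two).
#' @return A `"phylo"` object with exactly the tips in `keep`.  When all
#'   retained tips fall inside one subtree, the distance from the original
#'   root down to that subtree is kept in `root.edge`, so the path length
#'   from the (original) root to every retained tip is preserved.
#' @export
prune_to <- function(tree, keep) {
  stopifnot(inherits(tree, "phylo"))
  keep <- unique(as.character(keep))
  if (!length(keep)) stop("'keep' must not be empty")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown))
    stop(sprintf("unknown tip label(s): %s", paste(unknown, collapse = ", ")))
  if (length(keep) < 2L)
    stop("'keep' must retain at least two tips")
  if (setequal(keep, tree$tip.label)) return(tree)
  pruned <- ape::keep.tip(tree, keep)
  if (!is.null(tree$edge.length)) {
    ## stem lost above the retained tips' MRCA, recoverable from any tip
    d_full <- ape::node.depth.edgelength(tree)[match(keep[1L], tree$tip.label)]
    d_sub <- ape::node.depth.edgelength(pruned)[match(keep[1L], pruned$tip.label)]
    stem <- d_full - d_sub
    if (stem > 1e-12)
      pruned$root.edge <- stem + (if (is.null(tree$root.edge)) 0 else tree$root.edge)
  }
  pruned
}

## Internal: path length from root to every node (requires branch lengths).
.node_depths <- function(tree) {
  if (is.null(tree$edge.length))
    stop("operation requires branch lengths, but the tree has none")
  ape::node.depth.edgelength(tree)
}
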