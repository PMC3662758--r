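## End-to-end orchestration: code assay records (if given) into a trait
## matrix, then for each toxin run ASR, the conservatism randomization test
## and the posterior monophyly test, collecting everything into one
## machine-readable report.

.stage <- function(stage, toxin, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s:%s] %s", stage, toxin, conditionMessage(e)), call. = FALSE))
}

#' Run the full coding / ASR / conservatism / monophyly analysis
#'
#' For each requested toxin: summarise the coding, reconstruct ancestral
#' states with gain/loss extremes on every tree ([asr_over_sample()]),
#' run the tip-randomization conservatism test averaged over the sample
#' ([conservatism_over_sample()]), and compute the posterior proportion
#' of trees in which the toxin-positive taxa are monophyletic
#' ([monophyly_over_sample()]).  Any stage error is re-raised with the
#' stage and toxin named.  All randomness is governed by `seed` via
#' per-toxin substreams, so reports are reproducible bit for bit.
#'
#' @param sample A [tree_sample()].
#' @param traits A `"trait_matrix"`, or an `"assay_records"` data frame
#'   (in which case `tips` must be given and coding runs first).
#' @param toxins Toxin columns to analyse.
#' @param n_perm Permutations per tree for the conservatism test.
#' @param seed Master seed.
#' @param tips,proximity,synonyms,regions Passed to [build_trait_matrix()]
#'   when `traits` is an assay-record table.
#' @return An object of class `"analysis_report"`: list with `metadata`
#'   and a per-toxin list `toxins`, each holding `coding` (n_scored,
#'   n_positive, n_ambiguous), `asr` (per-tree table and ranges),
#'   `conservatism` (per-tree table, average p) and `monophyly`.
#' @export
run_full_analysis <- function(sample, traits, toxins = TOXINS,
                              n_perm = 100, seed = 1,
                              tips = NULL, proximity = NULL,
                              synonyms = NULL, regions = NULL) {
  stopifnot(inherits(sample, "tree_sample"))
  if (inherits(traits, "assay_records")) {
    if (is.null(tips))
      stop("[traitcode:all] 'tips' table required when coding from assay records")
    traits <- .stage("traitcode", "all",
                     build_trait_matrix(tips, traits, toxins = toxins,
                                        proximity = proximity,
                                        synonyms = synonyms, regions = regions))
  }
  if (!inherits(traits, "trait_matrix"))
    stop("'traits' must be a trait_matrix or assay_records")
  set.seed(seed)
  toxin_seeds <- stats::setNames(sample.int(.Machine$integer.max, length(toxins)),
                                 toxins)
  res <- list()
  for (tox in toxins) {
    st <- trait_states(traits, tox)
    coding <- list(n_scored = sum(st != "?"),
                   n_positive = sum(st == "1"),
                   n_ambiguous = sum(st == "?"))
    asr <- .stage("parsimony", tox, asr_over_sample(sample, st))
    cons <- .stage("conservatism", tox,
                   conservatism_over_sample(sample, st, n_perm = n_perm,
                                            seed = toxin_seeds[[tox]]))
    mono <- if (coding$n_positive == 0L) {
      ## monophyly of an empty positive group is undefined, not an error
      structure(list(n_trees = length(sample$trees), n_monophyletic = NA_integer_,
                     proportion = NA_real_, n_positive = 0L,
                     n_scored = coding$n_scored, degenerate = NA),
                class = "monophyly_result")
    } else {
      .stage("monophyly", tox, suppressWarnings(monophyly_over_sample(sample, st)))
    }
    res[[tox]] <- list(coding = coding,
                       asr = asr,
                       conservatism = cons,
                       monophyly = mono)
  }
  structure(list(
    metadata = list(n_trees = length(sample$trees),
                    n_tips = length(sample$trees[[1L]]$tip.label),
                    n_perm = as.integer(n_perm),
                    seed = as.integer(seed),
                    toxins = toxins,
                    package_version = as.character(utils::packageVersion("toxitrait"))),
    toxins = res
  ), class = "analysis_report")
}

#' Minimum number of independent origins defensible from a report
#'
#' The across-sample minimum of the per-tree minimum gain counts: no tree
#' in the posterior admits a most-parsimonious reconstruction with fewer
#' independent origins of the trait than this.
#'
#' @param report An `"analysis_report"`.
#' @param toxin Toxin name present in the report.
#' @return Integer.
#' @export
minimum_transitions_claim <- function(report, toxin) {
  stopifnot(inherits(report, "analysis_report"))
  if (!toxin %in% names(report$toxins))
    stop("toxin not present in report: ", toxin)
  as.integer(min(report$toxins[[toxin]]$asr$per_tree$min_gains))
}

#' Serialise a report to JSON (plus per-tree TSV side tables)
#'
#' The JSON holds the summary quantities (coding counts, across-sample
#' ranges, average p, monophyly proportion); the per-tree tables go to
#' `<dir>/<toxin>_asr.tsv` and `<dir>/<toxin>_conservatism.tsv`.
#'
#' @param report An `"analysis_report"`.
#' @param dir Output directory (created if needed).
#' @return Path of the JSON file, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- list(metadata = report$metadata)
  for (tox in names(report$toxins)) {
    r <- report$toxins[[tox]]
    js$toxins[[tox]] <- list(
      coding = r$coding,
      asr = list(score_range = r$asr$range$score,
                 gain_range = r$asr$range$gains,
                 loss_range = r$asr$range$losses),
      conservatism = list(average_p = r$conservatism$average_p,
                          n_perm = r$conservatism$n_perm),
      monophyly = list(n_trees = r$monophyly$n_trees,
                       n_monophyletic = r$monophyly$n_monophyletic,
                       proportion = r$monophyly$proportion))
    utils::write.table(r$asr$per_tree,
                       file.path(dir, paste0(tox, "_asr.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$conservatism$per_tree,
                       file.path(dir, paste0(tox, "_conservatism.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report: %d trees, %d tips, seed %d\n",
              x$metadata$n_trees, x$metadata$n_tips, x$metadata$seed))
  for (tox in names(x$toxins)) {
    r <- x$toxins[[tox]]
    cat(sprintf("  %s: %d scored (%d positive); gains %d-%d, losses %d-%d; avg p %.4g; monophyly %.3f\n",
                tox, r$coding$n_scored, r$coding$n_positive,
                r$asr$range$gains[1], r$asr$range$gains[2],
                r$asr$range$losses[1], r$asr$range$losses[2],
                r$conservatism$average_p, r$monophyly$proportion))
  }
  invisible(x)
}
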