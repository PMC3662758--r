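## Coding of heterogeneous literature assay reports into per-toxin tip
## states {0, 1, ?}: simple-majority resolution of conflicting reports,
## geographic-proximity scoring when sequenced material and assayed material
## come from different regions, and the mutual-exclusivity constraint
## (no species carries both toxins).

TOXINS <- c("muscarine", "psilocybin")

#' Construct a table of assay records
#'
#' One row per published (or simulated) assay report: which species was
#' assayed, where the material came from, which toxin, and the outcome.
#' `reliable = FALSE` flags reports from methods prone to false positives;
#' such records are dropped before any majority vote.
#'
#' @param species,region Character vectors (non-empty strings).
#' @param toxin `"muscarine"` or `"psilocybin"`.
#' @param result `"present"` or `"absent"`.
#' @param source Citation key or assay batch identifier.
#' @param reliable Logical, default `TRUE`.
#' @return A data frame of class `"assay_records"`.
#' @export
assay_records <- function(species, region, toxin, result, source,
                          reliable = TRUE) {
  df <- data.frame(species = as.character(species),
                   region = as.character(region),
                   toxin = as.character(toxin),
                   result = as.character(result),
                   source = as.character(source),
                   reliable = rep_len(as.logical(reliable), length(species)))
  if (any(!nzchar(df$species)) || any(!nzchar(df$region)))
    stop("species and region must be non-empty")
  if (any(!df$toxin %in% TOXINS))
    stop(sprintf("toxin must be one of: %s", paste(TOXINS, collapse = ", ")))
  if (any(!df$result %in% c("present", "absent")))
    stop("result must be 'present' or 'absent'")
  class(df) <- c("assay_records", "data.frame")
  df
}

#' Read assay records from delimited text
#'
#' Expects columns `species`, `region`, `toxin`, `result`, `source` and
#' optionally `reliable`.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return An `"assay_records"` data frame.
#' @export
read_assay_records <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"")
  rel <- if ("reliable" %in% names(df)) df$reliable else TRUE
  assay_records(df$species, df$region, df$toxin, df$result, df$source, rel)
}

#' Apply a synonym table to species names
#'
#' Replaces every name listed in `synonyms$name` by `synonyms$canonical`,
#' so that taxonomically redundant reports (e.g. one species published
#' under three names) are counted once.  No fuzzy matching.
#'
#' @param x Character vector of species names.
#' @param synonyms Data frame with columns `name` and `canonical`, or
#'   `NULL` for no mapping.
#' @return Character vector of canonical names.
#' @export
apply_synonyms <- function(x, synonyms = NULL) {
  if (is.null(synonyms)) return(x)
  stopifnot(all(c("name", "canonical") %in% names(synonyms)))
  hit <- match(x, synonyms$name)
  x[!is.na(hit)] <- synonyms$canonical[hit[!is.na(hit)]]
  x
}

#' Resolve conflicting assay reports by simple majority
#'
#' All records must concern one species, one region and one toxin.
#' Records flagged unreliable are dropped first.  A strict majority of
#' "present" codes 1, a strict majority of "absent" codes 0, and an exact
#' tie codes `?` (ambiguous) -- the conservative choice when no further
#' reports can break the tie.
#'
#' @param records An `"assay_records"` data frame (rows for one
#'   species/region/toxin).
#' @return `"1"`, `"0"` or `"?"`.
#' @export
majority_resolve <- function(records) {
  if (!nrow(records)) stop("no assay records to resolve")
  if (length(unique(records$species)) > 1L)
    stop("majority_resolve: records mix more than one species")
  if (length(unique(records$toxin)) > 1L)
    stop("majority_resolve: records mix more than one toxin")
  rec <- records[records$reliable, , drop = FALSE]
  if (!nrow(rec)) return("?")
  n_pos <- sum(rec$result == "present")
  n_neg <- sum(rec$result == "absent")
  if (n_pos > n_neg) "1" else if (n_neg > n_pos) "0" else "?"
}

.proximate_regions <- function(region, proximity = NULL) {
  out <- region
  if (!is.null(proximity)) {
    stopifnot(all(c("region_a", "region_b") %in% names(proximity)))
    out <- c(out,
             proximity$region_b[proximity$region_a == region],
             proximity$region_a[proximity$region_b == region])
  }
  unique(out)
}

#' Code one tip from the assay record table
#'
#' Looks up all (reliable) records for the tip's species and the requested
#' toxin.  Records from the tip's own region -- or a region declared
#' proximate in the `proximity` table -- are resolved by
#' [majority_resolve()].  If the species has been assayed only in
#' non-proximate regions, or not at all, the tip is coded `?`: missing
#' data are never fabricated from far-away material.
#'
#' @param species,region The tip's species name and sampling region.
#' @param records An `"assay_records"` data frame.
#' @param toxin `"muscarine"` or `"psilocybin"`.
#' @param proximity Optional data frame with columns `region_a`,
#'   `region_b` declaring a symmetric proximity relation; by default only
#'   the identical region counts as proximate.
#' @param regions Optional controlled vocabulary of region tokens; when
#'   given, an unknown tip region is an error.
#' @return A list with `state` (`"1"`, `"0"` or `"?"`) and `note` (the
#'   rule that produced the state).
#' @export
assign_tip_state <- function(species, region, records, toxin,
                             proximity = NULL, regions = NULL) {
  if (!toxin %in% TOXINS) stop("unknown toxin: ", toxin)
  if (!is.null(regions) && !region %in% regions)
    stop(sprintf("unknown region token '%s'", region))
  rec <- records[records$species == species & records$toxin == toxin &
                   records$reliable, , drop = FALSE]
  if (!nrow(rec))
    return(list(state = "?", note = "no assay records"))
  prox <- .proximate_regions(region, proximity)
  near <- rec[rec$region %in% prox, , drop = FALSE]
  if (!nrow(near))
    return(list(state = "?", note = "records only from non-proximate regions"))
  list(state = majority_resolve(near),
       note = sprintf("majority of %d record(s) in proximate region(s)", nrow(near)))
}

#' Build a per-toxin tip-state matrix from assay records
#'
#' Applies [assign_tip_state()] to every tip for each toxin, then (by
#' default) [enforce_mutual_exclusivity()].
#'
#' @param tips Data frame with columns `tip` (tree tip label), `species`
#'   and `region`; `species` defaults to `tip` when absent.
#' @param records An `"assay_records"` data frame.
#' @param toxins Toxins to code (columns of the output).
#' @param proximity,regions See [assign_tip_state()].
#' @param synonyms Optional synonym table applied to both records and tip
#'   species before matching (see [apply_synonyms()]).
#' @param exclusivity Apply the mutual-exclusivity rule (default `TRUE`).
#' @return A `"trait_matrix"` data frame: one row per tip, one state
#'   column per toxin plus a `<toxin>_note` provenance column.
#' @export
build_trait_matrix <- function(tips, records, toxins = TOXINS,
                               proximity = NULL, regions = NULL,
                               synonyms = NULL, exclusivity = TRUE) {
  if (!"tip" %in% names(tips)) stop("'tips' needs a 'tip' column")
  if (!"species" %in% names(tips)) tips$species <- tips$tip
  if (!"region" %in% names(tips)) stop("'tips' needs a 'region' column")
  records$species <- apply_synonyms(records$species, synonyms)
  tips$species <- apply_synonyms(tips$species, synonyms)
  out <- data.frame(tip = as.character(tips$tip))
  for (tox in toxins) {
    res <- lapply(seq_len(nrow(tips)), function(i)
      assign_tip_state(tips$species[i], tips$region[i], records, tox,
                       proximity = proximity, regions = regions))
    out[[tox]] <- vapply(res, `[[`, "", "state")
    out[[paste0(tox, "_note")]] <- vapply(res, `[[`, "", "note")
  }
  class(out) <- c("trait_matrix", "data.frame")
  if (exclusivity && all(TOXINS %in% toxins)) out <- enforce_mutual_exclusivity(out)
  out
}

#' Construct a trait matrix directly from state vectors
#'
#' @param tip Character vector of tip labels.
#' @param ... Named state vectors (one per toxin) in `{"0","1","?"}`.
#' @return A `"trait_matrix"` data frame.
#' @export
trait_matrix <- function(tip, ...) {
  cols <- list(...)
  out <- data.frame(tip = as.character(tip))
  for (nm in names(cols)) {
    v <- as.character(cols[[nm]])
    if (any(!v %in% c("0", "1", "?")))
      stop(sprintf("states in '%s' must be 0, 1 or ?", nm))
    out[[nm]] <- v
  }
  class(out) <- c("trait_matrix", "data.frame")
  out
}

#' Extract one toxin's states as a named vector
#'
#' @param matrix A `"trait_matrix"`.
#' @param toxin Column name.
#' @return Named character vector (names = tip labels).
#' @export
trait_states <- function(matrix, toxin) {
  if (!toxin %in% names(matrix)) stop("no such toxin column: ", toxin)
  stats::setNames(as.character(matrix[[toxin]]), matrix$tip)
}

#' Enforce mutual exclusivity of the two toxins
#'
#' Taxa confirmed positive for one toxin are coded negative for the other;
#' `(?,?)` rows are untouched.  A tip already coded positive for both is a
#' contradiction and raises an error naming the tip.
#'
#' @param matrix A `"trait_matrix"` with `muscarine` and `psilocybin`
#'   columns.
#' @return The corrected `"trait_matrix"`; on output no tip is `(1,1)`.
#' @export
enforce_mutual_exclusivity <- function(matrix) {
  stopifnot(all(TOXINS %in% names(matrix)))
  both <- matrix$muscarine == "1" & matrix$psilocybin == "1"
  if (any(both))
    stop(sprintf("tip '%s' is coded positive for both toxins: contradictory input",
                 matrix$tip[which(both)[1L]]))
  fix_p <- matrix$muscarine == "1" & matrix$psilocybin == "?"
  fix_m <- matrix$psilocybin == "1" & matrix$muscarine == "?"
  matrix$psilocybin[fix_p] <- "0"
  matrix$muscarine[fix_m] <- "0"
  if ("psilocybin_note" %in% names(matrix))
    matrix$psilocybin_note[fix_p] <- "0 by mutual exclusivity (muscarine-positive)"
  if ("muscarine_note" %in% names(matrix))
    matrix$muscarine_note[fix_m] <- "0 by mutual exclusivity (psilocybin-positive)"
  matrix
}

#' Write / read a trait matrix as TSV
#'
#' @param matrix A `"trait_matrix"`.
#' @param path File path.
#' @return `read_trait_matrix()` returns a `"trait_matrix"`.
#' @export
write_trait_matrix <- function(matrix, path) {
  utils::write.table(matrix, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trait_matrix
#' @export
read_trait_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  class(df) <- c("trait_matrix", "data.frame")
  df
}

#' Summary counts over an assay record table
#'
#' Counts, per toxin, the number of species assayed and the number coded
#' positive by pooled simple majority, after synonym deduplication; also
#' a per-genus breakdown (genus = first word of the species name).
#'
#' @param records An `"assay_records"` data frame.
#' @param synonyms Optional synonym table (see [apply_synonyms()]).
#' @return An object of class `"assay_summary"`: per-toxin list with
#'   `n_assayed`, `n_positive`, `by_genus` (data frame).
#' @export
summarize_assays <- function(records, synonyms = NULL) {
  records$species <- apply_synonyms(records$species, synonyms)
  out <- list()
  for (tox in unique(records$toxin)) {
    rec <- records[records$toxin == tox & records$reliable, , drop = FALSE]
    sp <- unique(rec$species)
    state <- vapply(sp, function(s)
      majority_resolve(rec[rec$species == s, , drop = FALSE]), "")
    genus <- sub("^(\\S+).*$", "\\1", sp)
    by_genus <- stats::aggregate(list(n_assayed = sp), list(genus = genus), length)
    by_genus$n_positive <- stats::aggregate(list(x = state == "1"),
                                            list(genus = genus), sum)$x
    out[[tox]] <- list(n_assayed = length(sp),
                       n_positive = sum(state == "1"),
                       by_genus = by_genus)
  }
  class(out) <- "assay_summary"
  out
}

#' Percentage of accepted species that have been assayed
#'
#' @param assayed Number of species assayed.
#' @param accepted Number of accepted species in the group (> 0).
#' @return A list with `percent` (exact, `100 * assayed / accepted`) and
#'   `rounded` (nearest integer).
#' @examples
#' percent_assayed(98, 507)$rounded  # 19
#' @export
percent_assayed <- function(assayed, accepted) {
  if (accepted <= 0) stop("'accepted' must be positive")
  if (assayed < 0) stop("'assayed' must be nonnegative")
  pct <- 100 * assayed / accepted
  list(percent = pct, rounded = as.integer(round(pct)))
}
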