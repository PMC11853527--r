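#' Merge somatic-mutation records across databases
#'
#' Combines a primary database with one or more secondary databases at the
#' protein level. All primary records are kept, including recurrent entries
#' (the same amino-acid change reported in several patients). A secondary
#' record is added only when its protein-level key `(position, ref_aa,
#' alt_aa)` is absent from the primary set, so recurrences already
#' represented in the primary database are not double-counted. Provenance
#' (`source_db`) is preserved. Conflicting reference residues at the same
#' position across sources trigger a warning; the primary annotation wins
#' (conflicting secondary records are still admitted under their own key,
#' flagged in the warning).
#'
#' @param primary data frame of mutation records (columns `position`,
#'   `ref_aa`, `alt_aa`, and optionally `source_db`, `tissue`, `sample_id`).
#' @param secondaries a list of data frames with the same columns.
#' @return The merged data frame.
#' @export
merge_databases <- function(primary, secondaries = list()) {
  validate_mutations(primary)
  if (is.data.frame(secondaries)) secondaries <- list(secondaries)
  key <- function(d) paste(d$position, d$ref_aa, d$alt_aa, sep = "|")
  merged <- primary
  for (sec in secondaries) {
    validate_mutations(sec)
    conflict <- merge(unique(primary[, c("position", "ref_aa")]),
                      unique(sec[, c("position", "ref_aa")]),
                      by = "position", suffixes = c("_primary", "_secondary"))
    bad <- conflict$ref_aa_primary != conflict$ref_aa_secondary
    if (any(bad)) {
      warning("reference residue conflict at position(s) ",
              paste(unique(conflict$position[bad]), collapse = ", "),
              "; primary annotation wins")
    }
    new <- sec[!(key(sec) %in% key(merged)), , drop = FALSE]
    ## within a secondary batch keep one record per new key
    new <- new[!duplicated(key(new)), , drop = FALSE]
    merged <- rbind(merged, new)
  }
  rownames(merged) <- NULL
  merged
}

validate_mutations <- function(d, protein_length = NULL) {
  stopifnot(is.data.frame(d),
            all(c("position", "ref_aa", "alt_aa") %in% names(d)))
  if (nrow(d) == 0) return(invisible(d))
  if (any(d$position < 1)) stop("positions must be >= 1")
  if (!is.null(protein_length) && any(d$position > protein_length)) {
    stop("positions exceed the protein length")
  }
  if (!all(d$ref_aa %in% .AA1)) stop("invalid reference amino-acid code(s)")
  invisible(d)
}

#' Classify a mutation record
#'
#' `"*"` denotes a stop-introducing change, `"="` (or an alternate residue
#' equal to the reference) a silent change, any other valid residue a
#' missense change.
#'
#' @param ref_aa,alt_aa one-letter codes (`alt_aa` may be `"*"` or `"="`).
#'   Vectorized.
#' @return Character vector: `"missense"`, `"silent"` or `"stop"`.
#' @export
classify_mutation <- function(ref_aa, alt_aa) {
  ok <- alt_aa %in% c(.AA1, "*", "=")
  if (!all(ok)) stop("invalid alternate code(s): ",
                     paste(unique(alt_aa[!ok]), collapse = ", "))
  ifelse(alt_aa == "*", "stop",
         ifelse(alt_aa == "=" | alt_aa == ref_aa, "silent", "missense"))
}

#' Sliding-window mutation profile along the protein
#'
#' Counts mutation records per residue and sums them over a centered
#' window of `window` residues (default 7: the residue plus three up- and
#' downstream neighbours). Windows overlapping the protein termini are
#' clipped, not wrapped and not renormalized, so the profile reports counts,
#' not densities.
#'
#' @param records mutation data frame (see [merge_databases()]).
#' @param protein_length protein length (residues).
#' @param window odd window size >= 1 (1 returns the raw counts).
#' @param classes mutation classes included (default missense only).
#' @return An object of class `"window_profile"`: data frame columns
#'   `position`, `raw` (records at the residue), `count` (windowed sum);
#'   the window size is kept as an attribute.
#' @export
window_scan <- function(records, protein_length, window = 7,
                        classes = "missense") {
  if (window %% 2 != 1 || window < 1) stop("window must be an odd positive integer")
  validate_mutations(records, protein_length)
  cls <- classify_mutation(records$ref_aa, records$alt_aa)
  pos <- records$position[cls %in% classes]
  raw <- tabulate(pos, nbins = protein_length)
  half <- (window - 1) / 2
  counts <- vapply(seq_len(protein_length), function(i) {
    sum(raw[max(1, i - half):min(protein_length, i + half)])
  }, numeric(1))
  structure(data.frame(position = seq_len(protein_length),
                       raw = raw, count = counts),
            class = c("window_profile", "data.frame"),
            window = window, classes = classes)
}

#' Flag candidate hotspot regions on a window profile
#'
#' Marks residues whose windowed count reaches `threshold_factor` times the
#' protein-wide mean windowed count, and returns the contiguous runs as
#' candidate regions. The factor is an adjustable screening default, not a
#' calibrated significance rule.
#'
#' @param profile a `"window_profile"`.
#' @param threshold_factor multiple of the mean windowed count (default 2).
#' @return Data frame with columns `start`, `end`, `peak_count`.
#' @export
hotspot_calls <- function(profile, threshold_factor = 2) {
  thr <- threshold_factor * mean(profile$count)
  hot <- profile$count >= thr & profile$count > 0
  if (!any(hot)) {
    return(data.frame(start = integer(0), end = integer(0),
                      peak_count = numeric(0)))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             peak_count = vapply(which(keep), function(j) {
               max(profile$count[starts[j]:ends[j]])
             }, numeric(1)))
}

#' Per-region mutation statistics
#'
#' For each region, reports the percentage of residues carrying at least one
#' mutation record and the mean number of records per residue.
#'
#' @param records mutation data frame.
#' @param regions data frame with columns `name`, `start`, `end`
#'   (1-based inclusive).
#' @param classes mutation classes counted (default: all).
#' @return Data frame with columns `name`, `start`, `end`, `n_residues`,
#'   `n_mutations`, `affected_fraction` (percent), `mutations_per_residue`.
#' @export
region_statistics <- function(records, regions,
                              classes = c("missense", "silent", "stop")) {
  validate_mutations(records)
  regions <- as.data.frame(regions)
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end)) stop("inverted region bounds")
  cls <- classify_mutation(records$ref_aa, records$alt_aa)
  pos <- records$position[cls %in% classes]
  out <- lapply(seq_len(nrow(regions)), function(j) {
    s <- regions$start[j]; e <- regions$end[j]
    in_reg <- pos[pos >= s & pos <= e]
    n_res <- e - s + 1
    data.frame(name = regions$name[j], start = s, end = e,
               n_residues = n_res, n_mutations = length(in_reg),
               affected_fraction = 100 * length(unique(in_reg)) / n_res,
               mutations_per_residue = length(in_reg) / n_res)
  })
  do.call(rbind, out)
}
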