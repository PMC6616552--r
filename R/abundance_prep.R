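# QC filtering, contaminant removal, normalization, core/resident rules -------

#' Drop OTUs with insufficient support
#'
#' Retains exactly the OTUs that reach at least `min_reads` reads in at least
#' `min_samples` samples (the default 4-sample/4-read rule). The sample set
#' is unchanged; the operation is idempotent.
#'
#' @param x an [otu_table()].
#' @param min_samples,min_reads support thresholds.
#' @return filtered [otu_table()].
#' @export
filter_low_support_otus <- function(x, min_samples = 4, min_reads = 4) {
  keep <- rowSums(x$counts >= min_reads) >= min_samples
  if (!any(keep)) warning("no OTUs pass the support filter")
  subset_otu_table(x, otus = which(keep))
}

#' Remove control-supported contaminant OTUs
#'
#' Drops every OTU with `min_reads` (default 5) or more reads in ANY single
#' negative-control sample (PCR or extraction-kit control) - the rule is
#' per-control-sample, not summed across controls. Control columns are then
#' removed from the analysis table.
#'
#' @param x an [otu_table()].
#' @param control_sample_ids character vector of control sample ids; must be
#'   nonempty unless `allow_no_controls = TRUE`.
#' @param min_reads contaminant support threshold per control sample.
#' @param allow_no_controls explicit opt-out when the study has no controls.
#' @return list with `table` (controls and contaminants dropped) and
#'   `removed` (character vector of contaminant OTU ids).
#' @export
remove_contaminants <- function(x, control_sample_ids, min_reads = 5,
                                allow_no_controls = FALSE) {
  if (length(control_sample_ids) == 0) {
    if (!allow_no_controls)
      stop("no control samples given; pass allow_no_controls = TRUE to skip")
    return(list(table = x, removed = character(0)))
  }
  missing <- setdiff(control_sample_ids, colnames(x$counts))
  if (length(missing))
    stop("control sample(s) not in table: ", paste(missing, collapse = ", "))
  ctrl <- x$counts[, control_sample_ids, drop = FALSE]
  removed <- rownames(x$counts)[apply(ctrl >= min_reads, 1, any)]
  keep_otus <- setdiff(rownames(x$counts), removed)
  keep_samples <- setdiff(colnames(x$counts), control_sample_ids)
  list(table = subset_otu_table(x, keep_otus, keep_samples), removed = removed)
}

#' Convert counts to relative abundance
#'
#' Total-sum scaling: each sample column divided by its read depth, the
#' standard correction for variable depth before distance and association
#' analyses.
#'
#' @param x an [otu_table()].
#' @return object of class `rel_abundance`: list with `values` (proportions,
#'   columns summing to 1) and `taxonomy`.
#' @export
to_relative_abundance <- function(x) {
  tot <- colSums(x$counts)
  zero <- colnames(x$counts)[tot == 0]
  if (length(zero))
    stop("zero-sum sample(s): ", paste(zero, collapse = ", "))
  structure(list(values = sweep(x$counts, 2, tot, "/"),
                 taxonomy = x$taxonomy),
            class = "rel_abundance")
}

#' Aggregate a count matrix to genus level
#'
#' Counts of OTUs sharing a genus label are summed. Unclassified genera are
#' keyed by their family plus an `(uncl.)` suffix so that unrelated
#' unclassified OTUs are not pooled.
#'
#' @param x an [otu_table()] with taxonomy.
#' @return an [otu_table()] whose rows are genera.
#' @export
aggregate_genus <- function(x) {
  if (is.null(x$taxonomy) || !"genus" %in% names(x$taxonomy))
    stop("genus aggregation requires a taxonomy with a genus column")
  g <- x$taxonomy$genus
  uncl <- is.na(g) | g == "unclassified"
  if (any(uncl)) {
    fam <- if ("family" %in% names(x$taxonomy)) x$taxonomy$family[uncl]
           else "unknown_family"
    g[uncl] <- paste0(fam, " (uncl.)")
  }
  agg <- rowsum(x$counts, group = g)
  structure(list(counts = agg, taxonomy = NULL), class = "otu_table")
}

#' Preflight core microbiome of a body site
#'
#' Members are the taxa (OTU or genus level) present with at least
#' `min_reads` reads in at least `prevalence` of the site's preflight
#' samples (default: >= 4 reads in >= 75%).
#'
#' @param x an [otu_table()].
#' @param metadata sample metadata (see [read_metadata()]).
#' @param site body site to evaluate.
#' @param prevalence required fraction of preflight samples, in (0, 1].
#' @param min_reads detection threshold per sample.
#' @param level `"otu"` or `"genus"` (counts summed within genus first).
#' @return data.frame (member, prevalence, n_preflight_samples) with one row
#'   per core member.
#' @export
core_microbiome <- function(x, metadata, site, prevalence = 0.75,
                            min_reads = 4, level = c("otu", "genus")) {
  level <- match.arg(level)
  stopifnot(prevalence > 0, prevalence <= 1)
  if (!site %in% metadata$site) stop("unknown site: ", site)
  pre <- metadata$sample_id[metadata$site == site &
                            !is.na(metadata$stage) &
                            metadata$stage == "preflight"]
  pre <- intersect(pre, colnames(x$counts))
  if (length(pre) == 0) stop("no preflight samples at site ", site)
  tab <- subset_otu_table(x, samples = pre)
  if (level == "genus") tab <- aggregate_genus(tab)
  prev <- rowMeans(tab$counts >= min_reads)
  keep <- prev >= prevalence
  data.frame(member = rownames(tab$counts)[keep],
             prevalence = unname(prev[keep]),
             n_preflight_samples = length(pre),
             stringsAsFactors = FALSE)[order(-prev[keep]), ]
}

#' Resident OTUs of an ISS surface
#'
#' A surface OTU qualifies under the strict rule when it is detected
#' (count > 0) at every relative timepoint surveyed, and under the relaxed
#' rule when its detection vector has no run of two or more consecutive
#' zero timepoints. Strict residents are always a subset of relaxed
#' residents; both flags are reported and the default reporting rule is
#' strict.
#'
#' @param x an [otu_table()].
#' @param metadata sample metadata; ISS samples must carry `relative_time`.
#' @param surface an ISS surface site id.
#' @param rule which flag the `qualifies` column mirrors.
#' @return data.frame (otu, detections as `+`/`0` string, qualifies_strict,
#'   qualifies_relaxed, qualifies).
#' @export
resident_otus <- function(x, metadata, surface, rule = c("strict", "relaxed")) {
  rule <- match.arg(rule)
  sel <- metadata[metadata$site == surface, , drop = FALSE]
  if (nrow(sel) == 0) stop("unknown or unsampled surface: ", surface)
  times <- sort(unique(sel$relative_time))
  if (length(times) < 2)
    stop("surface ", surface, " has fewer than 2 relative timepoints")
  # pool samples within a relative timepoint: detected if seen in any of them
  det <- sapply(times, function(tt) {
    ids <- intersect(sel$sample_id[sel$relative_time == tt], colnames(x$counts))
    rowSums(x$counts[, ids, drop = FALSE]) > 0
  })
  strict <- apply(det, 1, all)
  relaxed <- apply(det, 1, function(v) {
    r <- rle(!v)
    !any(r$values & r$lengths >= 2)
  })
  data.frame(otu = rownames(x$counts),
             detections = apply(det, 1, function(v)
               paste(ifelse(v, "+", "0"), collapse = "")),
             qualifies_strict = unname(strict),
             qualifies_relaxed = unname(relaxed),
             qualifies = unname(if (rule == "strict") strict else relaxed),
             stringsAsFactors = FALSE)
}
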