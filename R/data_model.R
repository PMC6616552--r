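# Domain vocabulary -----------------------------------------------------------

#' Timepoint and site vocabularies
#'
#' The mission design uses a closed set of collection timepoints: four
#' preflight sessions (`L-240` to `L-60`, days before launch), up to four
#' flight-day sessions (`FD7` to `FD360`), and four return sessions (`R+0` to
#' `R+180`). `R+180` occurs only for blood/saliva panels; free-form day
#' offsets are rejected so that downstream pairing logic can key on labels.
#'
#' @format Character vectors of valid tokens.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
mission_timepoints <- function() {
  c("L-240", "L-150", "L-90", "L-60",
    "FD7", "FD90", "FD180", "FD360",
    "R+0", "R+30", "R+60", "R+180")
}

#' @rdname vocabularies
#' @export
body_sites <- function() c("forehead", "forearm", "nares", "tongue", "stool")

#' @rdname vocabularies
#' @export
iss_sites <- function() paste0("iss_ss", LETTERS[1:6])

#' @rdname vocabularies
#' @export
control_sites <- function() c("control_pcr", "control_kit")

#' @rdname vocabularies
#' @export
cytokine_sessions <- function() c("L-60", "FD7", "FD180", "R+0", "R+180")

#' Derive mission stage from a timepoint label
#'
#' `L-*` timepoints map to `preflight`, `FD*` to `inflight` and `R+*` to
#' `postflight`. The derivation is total over the closed timepoint vocabulary;
#' any other token is an error.
#'
#' @param timepoint character vector of timepoint labels.
#' @return character vector of stages (`preflight`, `inflight`, `postflight`).
#' @examples
#' mission_stage(c("L-240", "FD90", "R+30"))
#' @export
mission_stage <- function(timepoint) {
  bad <- setdiff(unique(timepoint), mission_timepoints())
  if (length(bad))
    stop("unknown timepoint token(s): ", paste(bad, collapse = ", "))
  out <- rep(NA_character_, length(timepoint))
  out[startsWith(timepoint, "L-")] <- "preflight"
  out[startsWith(timepoint, "FD")] <- "inflight"
  out[startsWith(timepoint, "R+")] <- "postflight"
  out
}

# OtuTable ---------------------------------------------------------------------

#' Construct an OTU count table
#'
#' The unit consumed by every analysis stage: an integer count matrix with
#' OTUs as rows and samples as columns, plus an optional 6-rank taxonomy
#' (phylum to genus; `"unclassified"` allowed at any rank).
#'
#' @param counts numeric matrix of nonnegative integer counts, OTUs in rows
#'   (rownames) and samples in columns (colnames).
#' @param taxonomy optional data.frame with rownames (or an `otu_id` column)
#'   matching `rownames(counts)` and columns among
#'   `phylum, class, order, family, genus` (a `species`/extra rank is kept
#'   as-is).
#' @return an object of class `otu_table`: a list with elements `counts` and
#'   `taxonomy`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have OTU rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate otu_ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample_ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be nonnegative and non-missing")
  nonint <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
  if (nrow(nonint) > 0)
    stop(sprintf("non-integer count at otu '%s', sample '%s'",
                 rownames(counts)[nonint[1, 1]],
                 colnames(counts)[nonint[1, 2]]))
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if ("otu_id" %in% names(taxonomy)) {
      rownames(taxonomy) <- taxonomy$otu_id
      taxonomy$otu_id <- NULL
    }
    missing <- setdiff(rownames(counts), rownames(taxonomy))
    if (length(missing))
      stop("taxonomy missing for otus: ", paste(missing, collapse = ", "))
    taxonomy <- taxonomy[rownames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (%s taxonomy)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$taxonomy)) "no" else "with"))
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

# keep taxonomy aligned when subsetting rows/columns
subset_otu_table <- function(x, otus = NULL, samples = NULL) {
  counts <- x$counts
  if (!is.null(otus)) counts <- counts[otus, , drop = FALSE]
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  tax <- x$taxonomy
  if (!is.null(tax)) tax <- tax[rownames(counts), , drop = FALSE]
  structure(list(counts = counts, taxonomy = tax), class = "otu_table")
}

# Readers ----------------------------------------------------------------------

read_tsv_raw <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Read an OTU count table
#'
#' Supports three dialects: plain TSV (taxa as rows, first column the OTU id),
#' the mothur `.shared` format (samples as rows with `label`, `Group`,
#' `numOtus` lead columns; transposed on read so the in-memory orientation is
#' always OTU x sample), and dense BIOM-JSON (read through the biomformat
#' package). `#` comment lines are ignored in the TSV dialects.
#'
#' @param path file path.
#' @param dialect one of `"tsv"`, `"mothur_shared"`, `"biom_json"`.
#' @param taxonomy optional taxonomy data.frame passed to [otu_table()].
#' @return an [otu_table()].
#' @export
read_count_table <- function(path, dialect = c("tsv", "mothur_shared", "biom_json"),
                             taxonomy = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "biom_json") {
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(otu_table(m, taxonomy))
  }
  df <- read_tsv_raw(path)
  if (dialect == "mothur_shared") {
    need <- c("label", "Group", "numOtus")
    if (!all(need %in% names(df)))
      stop("not a mothur shared file: missing ",
           paste(setdiff(need, names(df)), collapse = ", "))
    groups <- as.character(df$Group)
    m <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
    check_integral_cells(m, row_ids = groups)
    m <- t(m)                       # samples-as-rows on disk -> otu x sample
    colnames(m) <- groups
    return(otu_table(m, taxonomy))
  }
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  check_integral_cells(m, row_ids = ids)
  otu_table(m, taxonomy)
}

check_integral_cells <- function(m, row_ids) {
  if (!is.numeric(m))
    stop("non-numeric count column(s): ",
         paste(colnames(m)[!apply(m, 2, is.numeric)], collapse = ", "))
  bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer count at row '%s', column '%s'",
                 row_ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  invisible(TRUE)
}

#' Write an OTU count table
#'
#' Inverse of [read_count_table()]; all three dialects round-trip losslessly.
#'
#' @param x an [otu_table()].
#' @param path output file path.
#' @param dialect output dialect, as in [read_count_table()].
#' @export
write_count_table <- function(x, path,
                              dialect = c("tsv", "mothur_shared", "biom_json")) {
  dialect <- match.arg(dialect)
  counts <- x$counts
  if (dialect == "biom_json") {
    b <- biomformat::make_biom(counts)
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  if (dialect == "mothur_shared") {
    df <- data.frame(label = "0.03", Group = colnames(counts),
                     numOtus = nrow(counts),
                     t(counts), check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  df <- data.frame(otu_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 6-rank taxonomy table
#'
#' TSV with an `otu_id` column and lineage ranks (phylum..genus);
#' `unclassified` is allowed at any rank.
#'
#' @param path file path.
#' @return data.frame keyed by `otu_id` rownames.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_raw(path)
  if (!"otu_id" %in% names(df)) stop("taxonomy requires an otu_id column")
  if (anyDuplicated(df$otu_id)) stop("duplicate otu_id in taxonomy")
  rownames(df) <- df$otu_id
  df$otu_id <- NULL
  df
}

#' Read sample metadata
#'
#' Expects a TSV with columns `sample_id`, `subject_id`, `site`, `timepoint`
#' and optionally `relative_time` (months since study start, used for ISS
#' temporal analyses). Mission stage is derived from the timepoint label for
#' every non-control sample; control samples (`site` in
#' `control_pcr`/`control_kit`) carry no subject or timepoint.
#'
#' @param path file path.
#' @param counts optional [otu_table()]; every sample in the count table must
#'   be present in the metadata, otherwise an error lists the missing ids.
#' @return data.frame with one row per sample and a derived `stage` column.
#' @export
read_metadata <- function(path, counts = NULL) {
  df <- read_tsv_raw(path)
  need <- c("sample_id", "subject_id", "site", "timepoint")
  if (!all(need %in% names(df)))
    stop("metadata missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  validate_metadata(df, counts)
}

#' Validate a metadata data.frame and derive mission stage
#'
#' @param df data.frame with `sample_id`, `subject_id`, `site`, `timepoint`.
#' @param counts optional [otu_table()] checked for metadata coverage.
#' @return the validated data.frame with a `stage` column.
#' @export
validate_metadata <- function(df, counts = NULL) {
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  ok_sites <- c(body_sites(), iss_sites(), "water", control_sites())
  bad <- setdiff(unique(df$site), ok_sites)
  if (length(bad)) stop("unknown site(s): ", paste(bad, collapse = ", "))
  is_ctrl <- df$site %in% control_sites()
  df$subject_id[is_ctrl] <- NA_character_
  df$stage <- NA_character_
  df$stage[!is_ctrl] <- mission_stage(df$timepoint[!is_ctrl])
  iss <- df$site %in% iss_sites()
  if (any(iss & !startsWith(df$timepoint, "FD")))
    stop("ISS-surface samples must be at FD timepoints")
  if (!"relative_time" %in% names(df)) df$relative_time <- NA_real_
  if (any(!is.na(df$relative_time) & df$relative_time < 0))
    stop("relative_time must be nonnegative")
  if (!is.null(counts)) {
    missing <- setdiff(colnames(counts$counts), df$sample_id)
    if (length(missing))
      stop("samples present in counts but absent in metadata: ",
           paste(missing, collapse = ", "))
    zero <- colnames(counts$counts)[colSums(counts$counts) == 0]
    if (length(zero))
      stop("samples with zero total reads (normalization undefined): ",
           paste(zero, collapse = ", "))
  }
  df
}

# Result tables ----------------------------------------------------------------

#' Write a result table as TSV
#'
#' Deterministic column order (as supplied), header row, tab-separated; the
#' written file round-trips losslessly through [read_result_table()]. An
#' empty record set yields a header-only file.
#'
#' @param records data.frame of homogeneous records.
#' @param path output path.
#' @param comments optional character vector written as leading `#` lines
#'   (seeds and parameters are echoed here by the pipeline stages).
#' @export
write_result_table <- function(records, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  read_tsv_raw(path)
}
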