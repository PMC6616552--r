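# Within-subject Somers' D association between discretized OTU abundance ------
# and cytokine expression.
#
# Relative abundance is discretized to dyadic levels (multiples of log 2) so
# that only changes of at least twofold register; pairs of test sessions are
# formed within subject only; Somers' D conditions on pairs untied in the
# abundance level; the standard error is a delete-one-subject jackknife.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Discretize stool relative abundance to dyadic levels
#'
#' For RA > 0, Y is the nearest integer to log2(RA) (exact half-levels round
#' away from zero); for RA = 0, Y is one level below the minimum positive
#' level observed for that OTU across the analysis set, so any zero-to-
#' positive transition registers as at least a twofold change. OTUs with
#' zero abundance everywhere in the set have no defined level and are
#' reported as excluded.
#'
#' @param ra a `rel_abundance` (see [to_relative_abundance()]).
#' @param metadata sample metadata; stool samples are matched to blood
#'   sessions by exact timepoint label.
#' @param otus OTUs to discretize (default all rows).
#' @param subjects subjects to include (default all stool subjects present).
#' @param sessions session labels (default the five blood sessions).
#' @return data.frame (subject, session, otu, ra, Y, zero_flag), with
#'   attribute `excluded_otus` (all-zero OTUs).
#' @export
discretize_abundance <- function(ra, metadata, otus = NULL, subjects = NULL,
                                 sessions = cytokine_sessions()) {
  meta <- metadata[metadata$site == "stool" &
                   metadata$timepoint %in% sessions &
                   metadata$sample_id %in% colnames(ra$values), , drop = FALSE]
  if (!is.null(subjects))
    meta <- meta[meta$subject_id %in% subjects, , drop = FALSE]
  if (nrow(meta) == 0) stop("no stool samples match the requested sessions")
  vals <- ra$values[, meta$sample_id, drop = FALSE]
  if (!is.null(otus)) vals <- vals[otus, , drop = FALSE]

  lv <- matrix(NA_real_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  pospart <- vals > 0
  lv[pospart] <- round_half_away(log2(vals[pospart]))
  excluded <- rownames(vals)[rowSums(pospart) == 0]
  for (i in seq_len(nrow(vals))) {
    if (rownames(vals)[i] %in% excluded) next
    zmin <- min(lv[i, pospart[i, ]])
    lv[i, !pospart[i, ]] <- zmin - 1
  }
  out <- data.frame(
    subject = rep(meta$subject_id, each = nrow(vals)),
    session = rep(meta$timepoint, each = nrow(vals)),
    otu = rep(rownames(vals), times = ncol(vals)),
    ra = as.vector(vals), Y = as.vector(lv),
    zero_flag = as.vector(!pospart),
    stringsAsFactors = FALSE)
  out <- out[!out$otu %in% excluded, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_otus") <- excluded
  out
}

#' Enumerate within-subject session pairs for one cytokine-OTU combination
#'
#' Pairs are formed over each subject's sessions where both the discretized
#' abundance level and an uncensored cytokine measurement exist; pairs never
#' cross subjects. The number of valid comparisons counts, per the
#' configured unit, either the subject-sessions with RA > 0 and uncensored
#' cytokine (`"observations"`, the default reading) or the session pairs in
#' which both ends are valid (`"pairs"`).
#'
#' @param disc output of [discretize_abundance()].
#' @param panel cytokine panel data.frame (subject_id, session, analyte,
#'   concentration, censored).
#' @param analyte,otu the combination.
#' @param comparison_unit `"observations"` or `"pairs"`.
#' @return list with `pairs` (subject, session_a, session_b, dY, dX) and
#'   `n_valid`.
#' @export
build_within_subject_pairs <- function(disc, panel, analyte, otu,
                                       comparison_unit = c("observations", "pairs")) {
  comparison_unit <- match.arg(comparison_unit)
  da <- disc[disc$otu == otu, , drop = FALSE]
  pa <- panel[panel$analyte == analyte, , drop = FALSE]
  mrg <- merge(da, pa, by.x = c("subject", "session"),
               by.y = c("subject_id", "session"))
  mrg <- mrg[!mrg$censored, , drop = FALSE]   # censored X: level unknown
  mrg$X <- log(mrg$concentration)
  n_valid_obs <- sum(!mrg$zero_flag)          # RA > 0 and uncensored cytokine

  pair_rows <- list()
  for (s in unique(mrg$subject)) {
    ms <- mrg[mrg$subject == s, , drop = FALSE]
    if (nrow(ms) < 2) next
    cmb <- utils::combn(seq_len(nrow(ms)), 2)
    pair_rows[[s]] <- data.frame(
      subject = s,
      session_a = ms$session[cmb[1, ]], session_b = ms$session[cmb[2, ]],
      dY = ms$Y[cmb[2, ]] - ms$Y[cmb[1, ]],
      dX = ms$X[cmb[2, ]] - ms$X[cmb[1, ]],
      valid_a = !ms$zero_flag[cmb[1, ]], valid_b = !ms$zero_flag[cmb[2, ]],
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(pair_rows)) do.call(rbind, pair_rows) else
    data.frame(subject = character(0), session_a = character(0),
               session_b = character(0), dY = numeric(0), dX = numeric(0),
               valid_a = logical(0), valid_b = logical(0))
  rownames(pairs) <- NULL
  n_valid <- if (comparison_unit == "observations") n_valid_obs
             else sum(pairs$valid_a & pairs$valid_b)
  list(pairs = pairs, n_valid = n_valid)
}

#' Pooled within-subject Somers' D
#'
#' Over all pairs pooled across subjects: D = (C - Q) / T, where C and Q are
#' the concordant and discordant pair counts and T is the number of pairs
#' untied on the abundance level. Pairs tied on the cytokine but untied on
#' the level count in the denominator only; pairs tied on the level are
#' excluded entirely (the probabilities are conditional on a level change,
#' i.e. on at least a twofold abundance change). D = +1 is perfect
#' concordance, D = -1 perfect discordance.
#'
#' @param pairs data.frame with `dY` and `dX` columns (see
#'   [build_within_subject_pairs()]).
#' @return list (D, n_untied, concordant, discordant, x_ties).
#' @export
somers_d_pooled <- function(pairs) {
  dY <- pairs$dY; dX <- pairs$dX
  untied <- dY != 0
  n_untied <- sum(untied)
  if (n_untied == 0) stop("all pairs tied on the abundance level; D undefined")
  conc <- sum(dY * dX > 0)
  disc <- sum(dY * dX < 0)
  list(D = (conc - disc) / n_untied, n_untied = n_untied,
       concordant = conc, discordant = disc,
       x_ties = sum(untied & dX == 0))
}

#' Delete-one-subject jackknife standard error of pooled Somers' D
#'
#' D is recomputed with each contributing subject's pairs removed;
#' SE = sqrt((g - 1)/g * sum_i (D_(i) - mean(D_(.)))^2) over the g subjects
#' contributing untied pairs. The p-value is a two-sided normal test of
#' D/SE. When all leave-one-out replicates coincide the SE is zero and the
#' combination is flagged degenerate (p suppressed).
#'
#' @param pairs data.frame with `subject`, `dY`, `dX` columns.
#' @return list (se, p, g, D, degenerate).
#' @export
jackknife_se <- function(pairs) {
  full <- somers_d_pooled(pairs)
  contrib <- unique(pairs$subject[pairs$dY != 0])
  g <- length(contrib)
  if (g < 2)
    return(list(se = NA_real_, p = NA_real_, g = g, D = full$D,
                degenerate = TRUE))
  d_i <- vapply(contrib, function(s) {
    somers_d_pooled(pairs[pairs$subject != s, , drop = FALSE])$D
  }, numeric(1))
  se <- sqrt((g - 1) / g * sum((d_i - mean(d_i))^2))
  if (se < 1e-12)
    return(list(se = se, p = NA_real_, g = g, D = full$D, degenerate = TRUE))
  # floor the normal tail so downstream FDR machinery sees p in (0, 1]
  p <- max(2 * stats::pnorm(-abs(full$D / se)), 1e-300)
  list(se = se, p = p, g = g, D = full$D, degenerate = FALSE)
}

#' Screen all candidate-OTU x cytokine combinations
#'
#' Evaluates the full grid of candidate OTUs (e.g. those flagged by
#' [da_screen()] or an externally supplied list) against the analyte panel.
#' Combinations failing to support at least `min_comparisons` valid
#' comparisons are excluded before any p-value is computed; Benjamini-
#' Hochberg control at `fdr` is applied across the computed p-values only.
#' D < 0 is a negative association between cytokine concentration and OTU
#' abundance.
#'
#' @param ra stool `rel_abundance`.
#' @param panel cytokine panel data.frame.
#' @param metadata sample metadata.
#' @param candidates candidate OTU ids (nonempty).
#' @param analytes analytes to screen (default: all in the panel).
#' @param fdr BH level.
#' @param min_comparisons exclusion threshold (default 10).
#' @param comparison_unit see [build_within_subject_pairs()].
#' @return data.frame with one row per combination: analyte, otu, D, se,
#'   n_valid, n_pairs_untied, p, q, significant, excluded, reason,
#'   direction (sign of D).
#' @export
screen_combinations <- function(ra, panel, metadata, candidates,
                                analytes = NULL, fdr = 0.01,
                                min_comparisons = 10,
                                comparison_unit = c("observations", "pairs")) {
  comparison_unit <- match.arg(comparison_unit)
  if (length(candidates) == 0) stop("candidate OTU list is empty")
  if (is.null(analytes)) analytes <- unique(panel$analyte)
  keep <- intersect(candidates, rownames(ra$values))
  if (length(bad <- setdiff(candidates, keep)))
    warning("candidate OTU(s) not in table: ", paste(bad, collapse = ", "))
  disc <- discretize_abundance(ra, metadata, otus = keep)
  all_zero <- attr(disc, "excluded_otus")

  rows <- list()
  for (a in analytes) {
    for (o in keep) {
      row <- data.frame(analyte = a, otu = o, D = NA_real_, se = NA_real_,
                        n_valid = NA_integer_, n_pairs_untied = NA_integer_,
                        p = NA_real_, q = NA_real_, significant = FALSE,
                        excluded = TRUE, reason = "", direction = NA_integer_,
                        stringsAsFactors = FALSE)
      if (o %in% all_zero) {
        row$reason <- "otu has zero abundance across the analysis set"
        rows[[paste(a, o)]] <- row; next
      }
      bp <- build_within_subject_pairs(disc, panel, a, o,
                                       comparison_unit = comparison_unit)
      row$n_valid <- bp$n_valid
      if (bp$n_valid < min_comparisons) {
        row$reason <- sprintf("only %d valid comparisons (< %d)",
                              bp$n_valid, min_comparisons)
        rows[[paste(a, o)]] <- row; next
      }
      if (all(bp$pairs$dY == 0)) {
        row$reason <- "all pairs tied on the abundance level"
        rows[[paste(a, o)]] <- row; next
      }
      jk <- jackknife_se(bp$pairs)
      row$D <- jk$D; row$se <- jk$se
      row$n_pairs_untied <- somers_d_pooled(bp$pairs)$n_untied
      row$direction <- sign(jk$D)
      if (jk$degenerate) {
        row$reason <- if (jk$g < 2) "fewer than 2 contributing subjects"
                      else "degenerate jackknife (all replicates equal)"
        rows[[paste(a, o)]] <- row; next
      }
      row$p <- jk$p
      row$excluded <- FALSE
      rows[[paste(a, o)]] <- row
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  comp <- !res$excluded
  if (any(comp)) {
    bh <- bh_fdr(res$p[comp], fdr)
    res$q[comp] <- bh$q
    res$significant[comp] <- bh$flag
  }
  attr(res, "n_evaluated") <- nrow(res)
  attr(res, "n_computed") <- sum(comp)
  res
}
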