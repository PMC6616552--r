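# Mission-stage inference machinery --------------------------------------------

#' Random-intercept mixed-model contrasts against a baseline level
#'
#' Fits `value ~ level + (1 | subject)` by REML (lme4) and reports one record
#' per non-baseline level with a Wald normal test. When the fit is singular
#' (zero between-subject variance) or fails, the model falls back to
#' fixed-effects OLS and the record is flagged.
#'
#' @param observations data.frame with columns `subject`, `level`, `value`.
#' @param baseline the reference level.
#' @return data.frame (term, estimate, se, p, method) with one row per
#'   non-baseline level; `method` is `"lmm_wald"` or `"ols_fallback"`.
#' @export
mixed_contrast <- function(observations, baseline) {
  obs <- observations
  stopifnot(all(c("subject", "level", "value") %in% names(obs)))
  if (length(unique(obs$subject)) < 2) stop("need >= 2 subjects")
  levs <- unique(as.character(obs$level))
  if (length(levs) < 2) stop("need >= 2 levels")
  if (!baseline %in% levs) stop("baseline level absent: ", baseline)
  obs$level <- stats::relevel(factor(obs$level), ref = baseline)

  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(value ~ level + (1 | subject), data = obs, REML = TRUE))),
    error = function(e) NULL)
  use_ols <- is.null(fit) || lme4::isSingular(fit, tol = 1e-5)
  if (use_ols) {
    ols <- stats::lm(value ~ level, data = obs)
    cf <- summary(ols)$coefficients
    method <- "ols_fallback"
  } else {
    cf <- summary(fit)$coefficients
    method <- "lmm_wald"
  }
  rows <- grepl("^level", rownames(cf))
  data.frame(term = sub("^level", "", rownames(cf)[rows]),
             estimate = cf[rows, 1], se = cf[rows, 2],
             p = 2 * stats::pnorm(-abs(cf[rows, 1] / cf[rows, 2])),
             method = method, row.names = NULL, stringsAsFactors = FALSE)
}

#' Within-astronaut distance observations for a stage comparison
#'
#' Enumerates all unordered sample pairs within each astronaut among samples
#' of the two compared stages and labels each pair within-stage or
#' between-stage. Pairs crossing astronauts are never emitted (they are
#' eliminated from the design). The output feeds [mixed_contrast()] with
#' `category` as the fixed-effect level.
#'
#' @param dm a `dist_matrix` (see [distance_matrix()]).
#' @param metadata sample metadata with `stage` and `subject_id`.
#' @param comparison `"pre_in"` (preflight vs inflight) or `"pre_post"`.
#' @return data.frame (astronaut, category, distance, sample_a, sample_b);
#'   categories are `within_<comparison>` / `between_<comparison>`.
#' @export
stage_distance_table <- function(dm, metadata, comparison = c("pre_in", "pre_post")) {
  comparison <- match.arg(comparison)
  stages <- c("preflight", if (comparison == "pre_in") "inflight" else "postflight")
  d <- as_dist_input(dm)
  meta <- metadata[metadata$sample_id %in% rownames(d) &
                   !is.na(metadata$subject_id) &
                   !is.na(metadata$stage) & metadata$stage %in% stages, ,
                   drop = FALSE]
  out <- list()
  for (subj in unique(meta$subject_id)) {
    ids <- meta$sample_id[meta$subject_id == subj]
    if (length(ids) < 2) next
    st <- meta$stage[match(ids, meta$sample_id)]
    cmb <- utils::combn(seq_along(ids), 2)
    cat_lab <- ifelse(st[cmb[1, ]] == st[cmb[2, ]],
                      paste0("within_", comparison),
                      paste0("between_", comparison))
    out[[subj]] <- data.frame(astronaut = subj, category = cat_lab,
                              distance = d[cbind(ids[cmb[1, ]], ids[cmb[2, ]])],
                              sample_a = ids[cmb[1, ]], sample_b = ids[cmb[2, ]],
                              stringsAsFactors = FALSE)
  }
  if (length(out) == 0) stop("no astronaut has >= 2 samples in the compared stages")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-astronaut mean distance to the preflight baseline
#'
#' For every inflight/postflight timepoint of each astronaut, the mean
#' distance between that timepoint's sample(s) and all of the astronaut's
#' preflight samples; the preflight baseline value is the mean over all
#' within-preflight pairs. Only within-astronaut distances are used.
#' Astronauts without preflight samples are excluded with a warning.
#'
#' @param dm a `dist_matrix`.
#' @param metadata sample metadata.
#' @return data.frame (astronaut, timepoint, mean_distance, n_pairs);
#'   the baseline row carries timepoint `"preflight"`.
#' @export
baseline_distance_trajectory <- function(dm, metadata) {
  d <- as_dist_input(dm)
  meta <- metadata[metadata$sample_id %in% rownames(d) &
                   !is.na(metadata$subject_id) & !is.na(metadata$stage), ,
                   drop = FALSE]
  out <- list()
  for (subj in unique(meta$subject_id)) {
    sm <- meta[meta$subject_id == subj, , drop = FALSE]
    pre <- sm$sample_id[sm$stage == "preflight"]
    if (length(pre) == 0) {
      warning("astronaut ", subj, " has no preflight samples; excluded")
      next
    }
    rows <- list()
    if (length(pre) >= 2) {
      cmb <- utils::combn(pre, 2)
      rows[["baseline"]] <- data.frame(
        astronaut = subj, timepoint = "preflight",
        mean_distance = mean(d[cbind(cmb[1, ], cmb[2, ])]),
        n_pairs = ncol(cmb), stringsAsFactors = FALSE)
    }
    post <- sm[sm$stage != "preflight", , drop = FALSE]
    for (tp in unique(post$timepoint)) {
      ids <- post$sample_id[post$timepoint == tp]
      pairs <- expand.grid(a = ids, b = pre, stringsAsFactors = FALSE)
      rows[[tp]] <- data.frame(
        astronaut = subj, timepoint = tp,
        mean_distance = mean(d[cbind(pairs$a, pairs$b)]),
        n_pairs = nrow(pairs), stringsAsFactors = FALSE)
    }
    out[[subj]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-factor PERMANOVA, optionally stratified
#'
#' Distance-based pseudo-F via `vegan::adonis2`. The permutation p-value is
#' count-exact: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm), so the minimum
#' attainable p is 1/(n_perm + 1). When `strata` is given, labels are
#' permuted within strata only (the conventional reading of stratifying by
#' body site).
#'
#' @param dm a `dist_matrix` (or square symmetric matrix).
#' @param grouping factor of group labels, one per sample (in `dm` order).
#' @param n_perm number of permutations (>= 99).
#' @param strata optional factor restricting permutations.
#' @param seed RNG seed for the permutations.
#' @return list (f, r_squared, p, n_perm).
#' @export
permanova <- function(dm, grouping, n_perm = 999, strata = NULL, seed = 1) {
  d <- as_dist_input(dm)
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stop("need >= 2 groups")
  if (any(table(grouping) < 2)) stop("each group needs >= 2 samples")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(strata)) {
    strata <- factor(strata)
    mono <- tapply(grouping, strata, function(g) length(unique(g)) == 1)
    if (any(mono))
      warning("stratum entirely in one group contributes no permutation ",
              "variability: ", paste(names(mono)[mono], collapse = ", "))
    perm <- permute::how(nperm = n_perm, blocks = strata)
  } else {
    perm <- n_perm
  }
  df <- data.frame(group = grouping)
  set.seed(seed)
  res <- vegan::adonis2(stats::as.dist(d) ~ group, data = df,
                        permutations = perm)
  list(f = res$F[1], r_squared = res$R2[1], p = res$`Pr(>F)`[1],
       n_perm = n_perm)
}

#' Welch test of inter-astronaut distances between two stages
#'
#' Compares the cross-subject (inter-astronaut) distances among samples of
#' one stage against those of another with an unequal-variance two-sample
#' t-test; a drop in the inflight mean indicates inter-subject convergence.
#'
#' @param dm a `dist_matrix`.
#' @param metadata sample metadata.
#' @param stage_a,stage_b the compared stages.
#' @return list (t, df, p, mean_a, mean_b, n_a, n_b).
#' @export
convergence_welch <- function(dm, metadata, stage_a = "preflight",
                              stage_b = "inflight") {
  d <- as_dist_input(dm)
  inter_stage <- function(stage) {
    sel <- metadata[metadata$sample_id %in% rownames(d) &
                    !is.na(metadata$subject_id) &
                    !is.na(metadata$stage) & metadata$stage == stage, ,
                    drop = FALSE]
    if (length(unique(sel$subject_id)) < 2)
      stop("stage ", stage, " has fewer than 2 astronauts")
    cmb <- utils::combn(seq_len(nrow(sel)), 2)
    cross <- sel$subject_id[cmb[1, ]] != sel$subject_id[cmb[2, ]]
    d[cbind(sel$sample_id[cmb[1, cross]], sel$sample_id[cmb[2, cross]])]
  }
  a <- inter_stage(stage_a)
  b <- inter_stage(stage_b)
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 inter-astronaut pairs per stage")
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean_a = mean(a), mean_b = mean(b), n_a = length(a), n_b = length(b))
}

#' Rank taxa by inter-subject CV reduction from preflight to inflight
#'
#' For each genus (or OTU), the coefficient of variation of relative
#' abundance across subjects is computed separately for preflight and
#' inflight, using each subject's mean abundance over its samples in the
#' stage (pooling replicates first avoids conflating within-subject with
#' inter-subject variance). Reductions (CV_pre - CV_in) are ranked
#' descending and the cumulative fraction of the total positive reduction is
#' reported, mirroring the attribution of inflight convergence to a few
#' genera.
#'
#' @param ra a `rel_abundance` (see [to_relative_abundance()]); typically the
#'   stool subset.
#' @param metadata sample metadata.
#' @param subjects subjects to include (default: all with stool samples in
#'   both stages).
#' @param level `"genus"` (requires taxonomy) or `"otu"`.
#' @return data.frame (taxon, cv_pre, cv_in, reduction, undefined flag,
#'   cumulative_fraction) ordered by decreasing reduction;
#'   `cumulative_fraction` is filled for positive reductions and is
#'   nondecreasing, ending at 1.
#' @export
cv_reduction_ranking <- function(ra, metadata, subjects = NULL,
                                 level = c("genus", "otu")) {
  level <- match.arg(level)
  vals <- ra$values
  if (level == "genus") {
    if (is.null(ra$taxonomy)) stop("genus level requires taxonomy")
    g <- ra$taxonomy[rownames(vals), "genus"]
    vals <- rowsum(vals, group = g)
  }
  meta <- metadata[metadata$sample_id %in% colnames(vals) &
                   !is.na(metadata$subject_id) &
                   metadata$stage %in% c("preflight", "inflight"), , drop = FALSE]
  if (is.null(subjects)) {
    both <- tapply(meta$stage, meta$subject_id,
                   function(s) all(c("preflight", "inflight") %in% s))
    subjects <- names(both)[both]
  }
  meta <- meta[meta$subject_id %in% subjects, , drop = FALSE]
  if (length(unique(meta$subject_id)) < 2) stop("need >= 2 subjects")

  stage_cv <- function(stage) {
    sm <- meta[meta$stage == stage, , drop = FALSE]
    subj_mean <- sapply(subjects, function(s) {
      ids <- sm$sample_id[sm$subject_id == s]
      rowMeans(vals[, ids, drop = FALSE])
    })
    mu <- rowMeans(subj_mean)
    cv <- apply(subj_mean, 1, stats::sd) / mu
    cv[mu == 0] <- NA_real_
    cv
  }
  cv_pre <- stage_cv("preflight")
  cv_in <- stage_cv("inflight")
  red <- cv_pre - cv_in
  res <- data.frame(taxon = rownames(vals), cv_pre = unname(cv_pre),
                    cv_in = unname(cv_in), reduction = unname(red),
                    undefined = is.na(red), stringsAsFactors = FALSE)
  res <- res[order(ifelse(is.na(res$reduction), -Inf, res$reduction),
                   decreasing = TRUE), ]
  pos <- !is.na(res$reduction) & res$reduction > 0
  res$cumulative_fraction <- NA_real_
  if (any(pos))
    res$cumulative_fraction[pos] <-
      cumsum(res$reduction[pos]) / sum(res$reduction[pos])
  rownames(res) <- NULL
  res
}

#' Pearson correlation between two aligned diversity series
#'
#' @param series_a,series_b numeric vectors aligned by relative timepoint.
#' @return list (r, r_squared, p, n).
#' @export
paired_alpha_correlation <- function(series_a, series_b) {
  ok <- stats::complete.cases(series_a, series_b)
  a <- series_a[ok]; b <- series_b[ok]
  if (length(a) < 3) stop("need >= 3 aligned pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("zero variance in a series")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(a))
}

#' Permutation screen for stage-associated OTUs
#'
#' A plumbing-level stand-in for external differential-abundance callers:
#' subject-centered log relative abundance (floored at half the minimum
#' nonzero value per OTU), with the stage effect tested by permuting stage
#' labels within subject and BH control at the configured FDR. An externally
#' supplied candidate list bypasses the screen and is passed through
#' verbatim.
#'
#' @param x an [otu_table()] (typically one body site).
#' @param metadata sample metadata.
#' @param fdr BH threshold for candidacy.
#' @param n_perm within-subject label permutations.
#' @param seed RNG seed.
#' @param candidates optional externally produced candidate OTU ids; when
#'   given, returned unchanged.
#' @param stage_a,stage_b compared stages (baseline first).
#' @return list with `records` (otu, estimate, p, q, candidate), `candidates`
#'   (character vector) and `bypass` flag.
#' @export
da_screen <- function(x, metadata, fdr = 0.10, n_perm = 999, seed = 1,
                      candidates = NULL, stage_a = "preflight",
                      stage_b = "inflight") {
  if (!is.null(candidates))
    return(list(records = NULL, candidates = candidates, bypass = TRUE))
  meta <- metadata[metadata$sample_id %in% colnames(x$counts) &
                   !is.na(metadata$subject_id) &
                   metadata$stage %in% c(stage_a, stage_b), , drop = FALSE]
  has_both <- tapply(meta$stage, meta$subject_id,
                     function(s) all(c(stage_a, stage_b) %in% s))
  meta <- meta[meta$subject_id %in% names(has_both)[has_both], , drop = FALSE]
  if (nrow(meta) == 0) stop("no subject has samples in both stages")
  m <- x$counts[, meta$sample_id, drop = FALSE]
  ra <- sweep(m, 2, colSums(m), "/")
  allzero <- rowSums(ra) == 0
  if (any(allzero)) {
    warning(sum(allzero), " OTU(s) absent from all compared samples; dropped")
    ra <- ra[!allzero, , drop = FALSE]
  }
  floorv <- apply(ra, 1, function(v) min(v[v > 0]) / 2)
  y <- log(pmax(ra, floorv))
  # center within subject
  for (s in unique(meta$subject_id)) {
    idx <- which(meta$subject_id == s)
    y[, idx] <- y[, idx, drop = FALSE] - rowMeans(y[, idx, drop = FALSE])
  }
  is_b <- meta$stage == stage_b
  w_of <- function(lab_b) ifelse(lab_b, 1 / sum(lab_b), -1 / sum(!lab_b))
  t_obs <- drop(y %*% w_of(is_b))
  set.seed(seed)
  subj_idx <- split(seq_len(nrow(meta)), meta$subject_id)
  W <- sapply(seq_len(n_perm), function(i) {
    lab <- is_b
    for (idx in subj_idx) lab[idx] <- sample(lab[idx])
    w_of(lab)
  })
  t_perm <- y %*% W
  p <- (1 + rowSums(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  q <- stats::p.adjust(p, method = "BH")
  rec <- data.frame(otu = rownames(ra), estimate = t_obs, p = p, q = q,
                    candidate = q <= fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(records = rec, candidates = rec$otu[rec$candidate], bypass = FALSE)
}
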