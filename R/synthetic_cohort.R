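# Synthetic longitudinal cohort generator -------------------------------------
#
# Emulates the mission sampling design: 9 crew members followed over
# preflight (L-240..L-60), inflight (FD7..FD180/FD360) and postflight
# (R+0..R+60) sessions at five body sites, six ISS surface sites swabbed at
# flight-day sessions, negative controls carrying planted reagent
# contaminants, and a left-censored plasma cytokine panel at five blood
# sessions. Counts are Dirichlet-multinomial so taxon-wise variance is
# inflated relative to multinomial sampling.

default_analytes <- function() {
  c("IL-1a", "IL-1b", "IL-1ra", "IL-2", "IL-4", "IL-5", "IL-6", "IL-8",
    "IL-10", "IL-12", "IL-13", "IL-17", "TNFa", "IFNg", "MCP-1", "MIP-1a",
    "MIP-1b", "GM-CSF", "G-CSF", "VEGF", "EGF", "Eotaxin")
}

#' Specification of a synthetic mission cohort
#'
#' Defaults mirror the study design: 9 subjects of whom 5 collect stool,
#' 10 sampling sessions from L-240 to R+60, 5 body sites plus 6 ISS surface
#' sites, lognormal library sizes with median ~20k reads, subject-specific
#' log-abundance intercepts, and day-to-day (session-level) taxon
#' fluctuations. Planted structure is controlled by `stage_effects`
#' (taxon/stage log2 fold changes), `convergence_taxa`/`convergence_factor`
#' (inter-subject dispersion of designated gut taxa multiplied by a factor
#' < 1 on inflight samples), `coupling` (cytokine means driven by stool taxon
#' log abundance) and `contaminant_taxa` (seeded into negative controls).
#'
#' @param n_taxa number of (non-contaminant) OTUs per cohort.
#' @param subjects,stool_subjects subject ids; stool is generated only for
#'   `stool_subjects`.
#' @param sites body sites to generate; `surfaces` the ISS sites
#'   (`character(0)` to skip).
#' @param timepoints sampling sessions for body sites (ISS surfaces use the
#'   FD subset).
#' @param lib_meanlog,lib_sdlog lognormal library-size parameters (reads).
#' @param concentration Dirichlet concentration; smaller = more overdispersed.
#' @param base_shape gamma shape of the per-site baseline composition
#'   weights; small values (default 0.4) give the heavy-tailed rank-abundance
#'   curves typical of 16S surveys, large values a more even community.
#' @param subject_effect_sd SD (natural log) of per-subject, per-taxon
#'   abundance intercepts.
#' @param subject_sd_overrides optional named numeric vector (taxon -> SD)
#'   giving selected taxa a different intercept SD; gut taxa with strong
#'   personal signatures (inter-individual ranges of several orders of
#'   magnitude) are emulated this way.
#' @param temporal_sd SD (log2 units) of per-sample taxon fluctuations.
#' @param stage_effects data.frame(taxon, stage, log2fc) applied
#'   multiplicatively on samples of that stage.
#' @param convergence_taxa,convergence_factor taxa whose subject intercepts
#'   are multiplied by `convergence_factor` on inflight samples (factor in
#'   (0, 1]; 1 = no convergence).
#' @param surface_skin_weight mixture weight of the concurrent crew's mean
#'   skin composition in ISS-surface profiles (the remainder is the
#'   surface-resident profile).
#' @param coupling data.frame(analyte, taxon, strength): cytokine
#'   log-concentration gains `strength` x (centered generative log RA of the
#'   taxon in that subject's stool at that session).
#' @param cytokine_stage_effects data.frame(analyte, session, delta) planted
#'   log-scale session effects relative to L-60.
#' @param analytes analyte names for the plasma panel.
#' @param cytokine_noise_sd,cytokine_subject_sd residual and between-subject
#'   SD of log concentration.
#' @param censor_limit named numeric (pg/mL) or scalar detection limit; values
#'   below it are reported at the limit and flagged censored.
#' @param contaminant_taxa names of reagent-contaminant OTUs planted into
#'   control samples (>= 5 reads) and sprinkled at trace level elsewhere.
#' @param seed integer RNG seed; identical specs and seeds give identical
#'   cohorts.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_taxa = 120,
                        subjects = paste0("Ast", LETTERS[1:9]),
                        stool_subjects = paste0("Ast", c("B", "C", "D", "F", "G")),
                        sites = body_sites(),
                        surfaces = iss_sites(),
                        timepoints = c("L-240", "L-150", "L-90", "L-60",
                                       "FD7", "FD90", "FD180",
                                       "R+0", "R+30", "R+60"),
                        lib_meanlog = log(20000), lib_sdlog = 0.5,
                        concentration = 50,
                        base_shape = 0.4,
                        subject_effect_sd = 1,
                        subject_sd_overrides = NULL,
                        temporal_sd = 0.5,
                        stage_effects = NULL,
                        convergence_taxa = character(0),
                        convergence_factor = 1,
                        surface_skin_weight = 0.3,
                        coupling = NULL,
                        cytokine_stage_effects = NULL,
                        analytes = default_analytes(),
                        cytokine_noise_sd = 0.2,
                        cytokine_subject_sd = 0.3,
                        censor_limit = 5,
                        contaminant_taxa = paste0("Contam_", 1:4),
                        seed = 1) {
  stopifnot(n_taxa >= 2, length(subjects) >= 1,
            all(stool_subjects %in% subjects),
            all(timepoints %in% mission_timepoints()))
  if (convergence_factor <= 0 || convergence_factor > 1)
    stop("convergence_factor must be in (0, 1]")
  if (length(censor_limit) == 1 && is.null(names(censor_limit)))
    censor_limit <- stats::setNames(rep(censor_limit, length(analytes)), analytes)
  spec <- list(n_taxa = n_taxa, subjects = subjects,
               stool_subjects = stool_subjects, sites = sites,
               surfaces = surfaces, timepoints = timepoints,
               lib_meanlog = lib_meanlog, lib_sdlog = lib_sdlog,
               concentration = concentration,
               base_shape = base_shape,
               subject_effect_sd = subject_effect_sd,
               subject_sd_overrides = subject_sd_overrides,
               temporal_sd = temporal_sd,
               stage_effects = stage_effects,
               convergence_taxa = convergence_taxa,
               convergence_factor = convergence_factor,
               surface_skin_weight = surface_skin_weight,
               coupling = coupling,
               cytokine_stage_effects = cytokine_stage_effects,
               analytes = analytes,
               cytokine_noise_sd = cytokine_noise_sd,
               cytokine_subject_sd = cytokine_subject_sd,
               censor_limit = censor_limit,
               contaminant_taxa = contaminant_taxa,
               seed = seed)
  class(spec) <- "cohort_spec"
  spec
}

taxon_names <- function(spec) sprintf("Otu%04d", seq_len(spec$n_taxa))

# nominal month of each session label, used for ISS relative_time
session_month <- function(tp) {
  m <- c("L-240" = 0, "L-150" = 3, "L-90" = 5, "L-60" = 6,
         "FD7" = 8, "FD90" = 11, "FD180" = 14, "FD360" = 20,
         "R+0" = 14, "R+30" = 15, "R+60" = 16, "R+180" = 20)
  unname(m[tp])
}

softmax_rows <- function(lp) {
  e <- exp(lp - max(lp))
  e / sum(e)
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws every biological sample Dirichlet-multinomial: the per-site baseline
#' log composition is shifted by the subject's random intercepts, the
#' session-level fluctuation, and any planted stage fold changes, then
#' renormalized. ISS surfaces are a mixture of a surface-resident profile and
#' the concurrent crew's mean generative skin composition. Controls carry the
#' planted contaminant taxa (always >= 5 reads) plus sparse (< 5 read) noise.
#'
#' @param spec a [cohort_spec()].
#' @return list with `table` (an [otu_table()] including control columns and
#'   contaminant rows), `metadata` (validated data.frame) and `truth` (planted
#'   effects plus the generative proportion matrix `p_expected` for biological
#'   samples, used by [generate_cytokine_panel()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  taxa <- taxon_names(spec)
  known <- c(taxa, spec$contaminant_taxa)
  for (nm in c("stage_effects")) {
    ef <- spec[[nm]]
    if (!is.null(ef) && length(bad <- setdiff(ef$taxon, taxa)))
      stop("fold change on unknown taxon: ", paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(spec$convergence_taxa, taxa)))
    stop("convergence on unknown taxon: ", paste(bad, collapse = ", "))

  set.seed(spec$seed)
  n <- spec$n_taxa
  ns <- length(spec$subjects)

  # per-site baseline composition: heavy-tailed, site-specific
  all_sites <- c(spec$sites, spec$surfaces)
  base <- sapply(all_sites, function(s) {
    w <- stats::rgamma(n, shape = spec$base_shape) * seq(2, 0.2, length.out = n)
    w / sum(w)
  })
  rownames(base) <- taxa

  # subject x taxon random intercepts (natural log), shared across sites
  taxon_sd <- rep(spec$subject_effect_sd, n)
  names(taxon_sd) <- taxa
  if (!is.null(spec$subject_sd_overrides)) {
    if (length(bad <- setdiff(names(spec$subject_sd_overrides), taxa)))
      stop("subject_sd_overrides for unknown taxon: ",
           paste(bad, collapse = ", "))
    taxon_sd[names(spec$subject_sd_overrides)] <- spec$subject_sd_overrides
  }
  # winsorized at +/- 2 SD: personal signatures are strong but bounded, so a
  # single subject cannot swallow the composition through one taxon
  zint <- pmin(pmax(stats::rnorm(ns * n), -2), 2)
  intercepts <- matrix(zint * rep(taxon_sd, each = ns),
                       nrow = ns, dimnames = list(spec$subjects, taxa))

  # planted stage log2 fold changes as a (stage x taxon) log-scale matrix
  stage_lfc <- matrix(0, nrow = 3, ncol = n,
                      dimnames = list(c("preflight", "inflight", "postflight"), taxa))
  if (!is.null(spec$stage_effects))
    for (i in seq_len(nrow(spec$stage_effects))) {
      ef <- spec$stage_effects[i, ]
      stage_lfc[ef$stage, ef$taxon] <-
        stage_lfc[ef$stage, ef$taxon] + log(2) * ef$log2fc
    }

  conv_idx <- match(spec$convergence_taxa, taxa)

  rows <- list()
  p_cols <- list()
  counts_cols <- list()
  lib_sizes <- list()
  month0 <- 3 * (seq_len(ns) - 1)           # staggered launches, months
  names(month0) <- spec$subjects

  draw_sample <- function(p_gen, sid) {
    libsize <- max(100L, as.integer(round(stats::rlnorm(1, spec$lib_meanlog,
                                                        spec$lib_sdlog))))
    p_real <- rdirichlet1(spec$concentration * p_gen)
    ct <- stats::rmultinom(1, libsize, p_real)[, 1]
    counts_cols[[sid]] <<- ct
    p_cols[[sid]] <<- p_gen
    lib_sizes[[sid]] <<- libsize
  }

  # body-site samples
  skin_mean <- list()   # per timepoint: mean generative skin composition
  for (tp in spec$timepoints) {
    stage <- mission_stage(tp)
    skin_acc <- NULL
    for (subj in spec$subjects) {
      for (site in spec$sites) {
        if (site == "stool" && !(subj %in% spec$stool_subjects)) next
        shrink <- rep(1, n)
        if (stage == "inflight" && length(conv_idx))
          shrink[conv_idx] <- spec$convergence_factor
        lp <- log(base[, site]) + intercepts[subj, ] * shrink +
          stage_lfc[stage, ] +
          log(2) * stats::rnorm(n, 0, spec$temporal_sd)
        p_gen <- softmax_rows(lp)
        sid <- paste(subj, site, tp, sep = ".")
        draw_sample(p_gen, sid)
        rows[[sid]] <- data.frame(sample_id = sid, subject_id = subj,
                                  site = site, timepoint = tp,
                                  relative_time = month0[subj] + session_month(tp),
                                  stringsAsFactors = FALSE)
        if (site %in% c("forehead", "forearm"))
          skin_acc <- if (is.null(skin_acc)) p_gen else skin_acc + p_gen
      }
    }
    if (!is.null(skin_acc)) skin_mean[[tp]] <- skin_acc / sum(skin_acc)
  }

  # ISS surface samples at FD sessions, mixture of residents and crew skin
  fd_tp <- spec$timepoints[startsWith(spec$timepoints, "FD")]
  for (surf in spec$surfaces) {
    for (tp in fd_tp) {
      p_mix <- (1 - spec$surface_skin_weight) * base[, surf] +
        spec$surface_skin_weight * skin_mean[[tp]]
      lp <- log(p_mix) + log(2) * stats::rnorm(n, 0, spec$temporal_sd)
      p_gen <- softmax_rows(lp)
      sid <- paste("ISS", surf, tp, sep = ".")
      draw_sample(p_gen, sid)
      rows[[sid]] <- data.frame(sample_id = sid, subject_id = NA_character_,
                                site = surf, timepoint = tp,
                                relative_time = session_month(tp),
                                stringsAsFactors = FALSE)
    }
  }

  bio_counts <- do.call(cbind, counts_cols)
  rownames(bio_counts) <- taxa
  p_expected <- do.call(cbind, p_cols)
  rownames(p_expected) <- taxa

  # trace-level contaminant reads in biological samples
  ncont <- length(spec$contaminant_taxa)
  cont_bio <- matrix(stats::rpois(ncont * ncol(bio_counts), 0.5),
                     nrow = ncont,
                     dimnames = list(spec$contaminant_taxa, colnames(bio_counts)))
  full <- rbind(bio_counts, cont_bio)

  # negative controls: contaminants at >= 5 reads, other taxa < 5 reads
  ctrl_ids <- c("NegCtrl.pcr", "NegCtrl.kit")
  ctrl_sites <- control_sites()
  ctrl <- sapply(ctrl_ids, function(cid) {
    v <- c(pmin(stats::rpois(n, 0.2), 4L),
           5L + stats::rpois(ncont, 40))
    v
  })
  rownames(ctrl) <- c(taxa, spec$contaminant_taxa)
  full <- cbind(full, ctrl)
  ctrl_meta <- data.frame(sample_id = ctrl_ids, subject_id = NA_character_,
                          site = ctrl_sites, timepoint = "L-240",
                          relative_time = NA_real_, stringsAsFactors = FALSE)

  meta <- rbind(do.call(rbind, rows), ctrl_meta)
  rownames(meta) <- NULL
  genus <- paste0("Genus", sprintf("%03d", ceiling(seq_len(n) / 2)))
  tax <- data.frame(
    phylum = rep(c("Firmicutes", "Bacteroidetes", "Proteobacteria",
                   "Actinobacteria"), length.out = n + ncont),
    family = paste0("Family", sprintf("%03d", ceiling(seq_len(n + ncont) / 6))),
    genus = c(genus, paste0("ContamGenus", seq_len(ncont))),
    row.names = c(taxa, spec$contaminant_taxa), stringsAsFactors = FALSE)

  tab <- otu_table(full, taxonomy = tax)
  meta <- validate_metadata(meta, tab)
  list(table = tab, metadata = meta,
       truth = list(contaminants = spec$contaminant_taxa,
                    stage_effects = spec$stage_effects,
                    convergence_taxa = spec$convergence_taxa,
                    convergence_factor = spec$convergence_factor,
                    p_expected = p_expected,
                    lib_sizes = unlist(lib_sizes),
                    intercepts = intercepts))
}

#' Generate a synthetic plasma cytokine panel
#'
#' Log concentration of each analyte = analyte baseline + subject intercept +
#' coupling terms + planted session effects + noise. A coupling term is
#' `strength` x the centered generative log relative abundance of the coupled
#' taxon in that subject's stool at that session (sessions without a stool
#' sample, i.e. R+180, contribute no coupling term). Acting on the generative
#' abundance rather than realized counts avoids circularity while keeping the
#' concordance recoverable. Values below the detection limit are clamped to
#' the limit and flagged censored.
#'
#' @param spec a [cohort_spec()].
#' @param cohort the result of [generate_cohort()] for the same spec.
#' @return data.frame (subject_id, session, analyte, concentration, censored,
#'   detection_limit).
#' @export
generate_cytokine_panel <- function(spec, cohort) {
  stopifnot(inherits(spec, "cohort_spec"))
  taxa <- taxon_names(spec)
  if (!is.null(spec$coupling) &&
      length(bad <- setdiff(spec$coupling$taxon, taxa)))
    stop("coupling to taxon absent from table: ", paste(bad, collapse = ", "))

  set.seed(spec$seed + 104729L)    # independent stream from the count draw
  sessions <- cytokine_sessions()
  subjects <- spec$stool_subjects
  pexp <- cohort$truth$p_expected

  # log generative stool RA per (subject, session, taxon), NA when no stool
  stool_lra <- function(subj, sess, taxon) {
    sid <- paste(subj, "stool", sess, sep = ".")
    if (!sid %in% colnames(pexp)) return(NA_real_)
    log(pexp[taxon, sid])
  }

  base_mu <- stats::setNames(
    log(20) + stats::rnorm(length(spec$analytes), 0, 0.5), spec$analytes)
  subj_int <- matrix(stats::rnorm(length(subjects) * length(spec$analytes),
                                  0, spec$cytokine_subject_sd),
                     nrow = length(subjects),
                     dimnames = list(subjects, spec$analytes))

  sess_eff <- matrix(0, nrow = length(sessions), ncol = length(spec$analytes),
                     dimnames = list(sessions, spec$analytes))
  if (!is.null(spec$cytokine_stage_effects))
    for (i in seq_len(nrow(spec$cytokine_stage_effects))) {
      ef <- spec$cytokine_stage_effects[i, ]
      sess_eff[ef$session, ef$analyte] <- sess_eff[ef$session, ef$analyte] + ef$delta
    }

  # pre-center coupling regressors per (analyte, taxon) across subject-sessions
  records <- expand.grid(subject_id = subjects, session = sessions,
                         analyte = spec$analytes, stringsAsFactors = FALSE)
  coup_term <- numeric(nrow(records))
  if (!is.null(spec$coupling)) {
    for (i in seq_len(nrow(spec$coupling))) {
      cp <- spec$coupling[i, ]
      z <- mapply(stool_lra, records$subject_id, records$session,
                  MoreArgs = list(taxon = cp$taxon))
      sel <- records$analyte == cp$analyte
      zc <- z - mean(z[!is.na(z)])
      zc[is.na(zc)] <- 0
      coup_term[sel] <- coup_term[sel] + cp$strength * zc[sel]
    }
  }

  logc <- base_mu[records$analyte] +
    subj_int[cbind(records$subject_id, records$analyte)] +
    sess_eff[cbind(records$session, records$analyte)] +
    coup_term +
    stats::rnorm(nrow(records), 0, spec$cytokine_noise_sd)
  conc <- exp(logc)
  lim <- spec$censor_limit[records$analyte]
  censored <- conc < lim
  conc[censored] <- lim[censored]
  data.frame(subject_id = records$subject_id, session = records$session,
             analyte = records$analyte, concentration = unname(conc),
             censored = unname(censored), detection_limit = unname(lim),
             stringsAsFactors = FALSE)
}
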