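# Cytokine transforms, censored regression, stage contrasts, BH FDR -----------

#' Build a per-analyte transform registry
#'
#' Each analyte maps to one of `identity`, `log`, or `reciprocal_censored`.
#' The reciprocal transform converts a left-censoring bound (values below
#' the detection limit L) into right-censoring at 1/L, which a right-censored
#' lognormal regression can then absorb. Analytes without an entry default to
#' `log`.
#'
#' @param reciprocal_censored analytes to analyse on the reciprocal scale.
#' @param identity analytes left untransformed.
#' @param log_transform analytes analysed on the log scale (the default for
#'   everything unlisted).
#' @return named character vector keyed by analyte (class `transform_spec`).
#' @export
transform_spec <- function(reciprocal_censored = character(0),
                           identity = character(0),
                           log_transform = character(0)) {
  spec <- c(stats::setNames(rep("reciprocal_censored",
                                length(reciprocal_censored)), reciprocal_censored),
            stats::setNames(rep("identity", length(identity)), identity),
            stats::setNames(rep("log", length(log_transform)), log_transform))
  if (anyDuplicated(names(spec)))
    stop("analyte listed under more than one transform")
  class(spec) <- "transform_spec"
  spec
}

transform_of <- function(spec, analyte) {
  if (!is.null(spec) && analyte %in% names(spec)) unname(spec[[analyte]])
  else "log"
}

#' Apply the per-analyte transform to a cytokine panel
#'
#' `identity` and `log` act directly on concentration and preserve censoring
#' flags; `reciprocal_censored` maps concentration c to 1/c, so a record
#' left-censored at limit L becomes right-censored at 1/L.
#'
#' @param panel data.frame (subject_id, session, analyte, concentration,
#'   censored, detection_limit).
#' @param spec a [transform_spec()] (or NULL: everything log).
#' @return the panel with added columns `value`, `right_censored`,
#'   `transform`.
#' @export
transform_cytokine <- function(panel, spec = NULL) {
  tr <- vapply(panel$analyte, transform_of, "", spec = spec)
  if (any(panel$concentration <= 0 & tr != "identity"))
    stop("nonpositive concentration under log/reciprocal transform")
  value <- panel$concentration
  value[tr == "log"] <- log(panel$concentration[tr == "log"])
  value[tr == "reciprocal_censored"] <-
    1 / panel$concentration[tr == "reciprocal_censored"]
  panel$value <- value
  panel$right_censored <- panel$censored & tr == "reciprocal_censored"
  panel$transform <- tr
  panel
}

#' Right-censored lognormal regression of session contrasts
#'
#' Maximum likelihood with normal errors on the log scale; right-censored
#' observations contribute upper-tail survival terms. The design is additive
#' in subject and session, with each session tested against the `L-60`
#' baseline by a Wald test. With no censored observations the ML solution
#' coincides with OLS on the log values (within numerical tolerance).
#'
#' @param values positive response values (e.g. reciprocal concentrations).
#' @param censored logical; TRUE = right-censored at the recorded value.
#' @param session factor of session labels.
#' @param subject factor of subject ids.
#' @param baseline baseline session.
#' @return data.frame (term, estimate, se, p, method); method is
#'   `"censored_mle"` or flagged `"non_convergence"`.
#' @export
censored_lognormal_regression <- function(values, censored, session, subject,
                                          baseline = "L-60") {
  if (all(censored)) stop("all observations censored")
  session <- stats::relevel(factor(session), ref = baseline)
  fully <- tapply(!censored, session, sum)
  if (any(fully == 0))
    stop("session(s) with all observations censored: ",
         paste(names(fully)[fully == 0], collapse = ", "))
  subject <- factor(subject)
  fit <- survival::survreg(
    survival::Surv(values, !censored) ~ subject + session,
    dist = "lognormal",
    control = survival::survreg.control(maxiter = 100, rel.tolerance = 1e-10))
  converged <- is.null(fit$fail)
  cf <- summary(fit)$table
  rows <- grepl("^session", rownames(cf))
  data.frame(term = sub("^session", "", rownames(cf)[rows]),
             estimate = cf[rows, "Value"], se = cf[rows, "Std. Error"],
             p = cf[rows, "p"],
             method = if (converged) "censored_mle" else "non_convergence",
             row.names = NULL, stringsAsFactors = FALSE)
}

# log-likelihood of the right-censored lognormal model at given parameters;
# used to verify that the MLE dominates the naive OLS solution
censored_lognormal_loglik <- function(values, censored, mu, sigma) {
  z <- (log(values) - mu) / sigma
  sum(ifelse(censored,
             stats::pnorm(z, lower.tail = FALSE, log.p = TRUE),
             stats::dnorm(z, log = TRUE) - log(sigma) - log(values)))
}

#' Stage contrasts for every analyte in a cytokine panel
#'
#' Four comparisons per analyte (FD7, FD180, R+0, R+180 against the L-60
#' baseline). Analytes whose transform is `reciprocal_censored` go through
#' [censored_lognormal_regression()]; all others are transformed and fitted
#' with the random-intercept [mixed_contrast()]. Analytes with more than
#' `max_censored_fraction` censored records are excluded with a reason
#' (mirroring panels with too many censored observations to analyse).
#' Benjamini-Hochberg correction is applied once across the full
#' analyte x session grid and the realized p-value threshold is reported.
#'
#' @param panel data.frame (subject_id, session, analyte, concentration,
#'   censored, detection_limit).
#' @param spec a [transform_spec()].
#' @param fdr FDR level for the joint BH correction.
#' @param max_censored_fraction exclusion threshold on the per-analyte
#'   censored fraction.
#' @return list with `contrasts` (analyte, term, estimate, se, p, q,
#'   significant, method), `excluded` (analyte, reason), `threshold` (the
#'   realized BH p threshold), `n_tests`.
#' @export
cytokine_stage_contrasts <- function(panel, spec = NULL, fdr = 0.05,
                                     max_censored_fraction = 0.5) {
  stopifnot(length(unique(panel$subject_id)) >= 2)
  panel <- transform_cytokine(panel, spec)
  out <- list(); excluded <- list()
  for (a in unique(panel$analyte)) {
    pa <- panel[panel$analyte == a, , drop = FALSE]
    cens_frac <- mean(pa$censored)
    if (cens_frac > max_censored_fraction) {
      excluded[[a]] <- data.frame(analyte = a,
                                  reason = sprintf("censored fraction %.2f > %.2f",
                                                   cens_frac, max_censored_fraction),
                                  stringsAsFactors = FALSE)
      next
    }
    rec <- if (pa$transform[1] == "reciprocal_censored" && any(pa$censored)) {
      censored_lognormal_regression(pa$value, pa$right_censored,
                                    pa$session, pa$subject_id)
    } else {
      obs <- data.frame(subject = pa$subject_id, level = pa$session,
                        value = pa$value)
      mixed_contrast(obs, baseline = "L-60")
    }
    rec$analyte <- a
    out[[a]] <- rec
  }
  contrasts <- do.call(rbind, out)
  rownames(contrasts) <- NULL
  # Wald tails can underflow to an exact 0 for extreme z; BH needs p > 0
  contrasts$p <- pmax(contrasts$p, 1e-300)
  bh <- bh_fdr(contrasts$p, fdr)
  contrasts$q <- bh$q
  contrasts$significant <- bh$flag
  contrasts <- contrasts[, c("analyte", "term", "estimate", "se", "p", "q",
                             "significant", "method")]
  list(contrasts = contrasts,
       excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
       threshold = bh$threshold, n_tests = nrow(contrasts))
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Flags all p-values at or below p_(k*), where k* is the largest k with
#' p_(k) <= k q / m, and reports the realized threshold p_(k*) along with
#' monotone-adjusted q-values.
#'
#' @param p vector of p-values in (0, 1].
#' @param q target FDR level.
#' @return list (q = adjusted q-values, flag = logical, threshold = realized
#'   p threshold, 0 when nothing is flagged).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) stop("p-values must be in (0, 1]")
  qv <- stats::p.adjust(p, method = "BH")
  m <- length(p)
  ord <- order(p)
  ok <- p[ord] <= seq_len(m) * q / m
  if (any(ok)) {
    kstar <- max(which(ok))
    threshold <- p[ord][kstar]
    flag <- p <= threshold
  } else {
    threshold <- 0
    flag <- rep(FALSE, m)
  }
  list(q = qv, flag = flag, threshold = threshold)
}
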