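# Shared fixtures and independent oracles, built in code at test time.

toy_counts <- function() {
  m <- matrix(c(5, 0,
                1, 2,
                0, 7), nrow = 3, byrow = TRUE,
              dimnames = list(c("OtuA", "OtuB", "OtuC"), c("s1", "s2")))
  otu_table(m)
}

random_otu_table <- function(seed, n_otu = 8, n_samp = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_otu * n_samp, 15) + 1L, nrow = n_otu,
              dimnames = list(sprintf("Otu%03d", seq_len(n_otu)),
                              sprintf("S%02d", seq_len(n_samp))))
  otu_table(m)
}

# metadata for a hand-built longitudinal design
toy_metadata <- function(subjects, timepoints, site = "stool") {
  grid <- expand.grid(subject_id = subjects, timepoint = timepoints,
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$subject_id, site, grid$timepoint, sep = ".")
  grid$site <- site
  validate_metadata(grid)
}

# Brute-force Somers' D: enumerate all within-subject session pairs directly
# from per-session (subject, Y, X) observations.
somers_brute <- function(obs) {
  conc <- 0; disc <- 0; untied <- 0
  for (s in unique(obs$subject)) {
    o <- obs[obs$subject == s, , drop = FALSE]
    n <- nrow(o)
    if (n < 2) next
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dy <- o$Y[j] - o$Y[i]; dx <- o$X[j] - o$X[i]
      if (dy == 0) next
      untied <- untied + 1
      if (dy * dx > 0) conc <- conc + 1
      if (dy * dx < 0) disc <- disc + 1
    }
  }
  if (untied == 0) return(NA_real_)
  (conc - disc) / untied
}

# Brute-force BH step-up by definition.
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- which(ps <= seq_len(m) * q / m)
  flag <- rep(FALSE, m)
  if (length(k)) flag[p <= ps[max(k)]] <- TRUE
  flag
}

# observations -> pairs table matching build_within_subject_pairs output
pairs_from_obs <- function(obs) {
  rows <- list()
  for (s in unique(obs$subject)) {
    o <- obs[obs$subject == s, , drop = FALSE]
    if (nrow(o) < 2) next
    cmb <- utils::combn(seq_len(nrow(o)), 2)
    rows[[s]] <- data.frame(subject = s,
                            dY = o$Y[cmb[2, ]] - o$Y[cmb[1, ]],
                            dX = o$X[cmb[2, ]] - o$X[cmb[1, ]])
  }
  do.call(rbind, rows)
}

# tiny rel_abundance + matched stool/blood metadata builders
make_ra <- function(vals, otus, samples) {
  m <- matrix(vals, nrow = length(otus), dimnames = list(otus, samples))
  structure(list(values = m, taxonomy = NULL), class = "rel_abundance")
}

disc_meta <- function(subjects, sessions) {
  grid <- expand.grid(subject_id = subjects, timepoint = sessions,
                      stringsAsFactors = FALSE)
  grid$sample_id <- paste(grid$subject_id, "stool", grid$timepoint, sep = ".")
  grid$site <- "stool"
  validate_metadata(grid)
}

# small cohort spec used by several tests (stool only, no surfaces)
small_stool_spec <- function(seed, ...) {
  cohort_spec(n_taxa = 50, sites = "stool", surfaces = character(0),
              subjects = paste0("Ast", LETTERS[1:5]),
              stool_subjects = paste0("Ast", LETTERS[1:5]),
              seed = seed, ...)
}
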