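test_that("abundance discretization maps RA to the nearest dyadic level", {
  md <- disc_meta("A", c("L-60", "FD7", "FD180"))
  ra <- make_ra(c(1.0, 0.3, 0.0,
                  0.5, 0.5, 0.03125), otus = c("o1", "o2"),
                samples = md$sample_id)
  # matrix fill is by column: o1 = (1.0, 0.0, 0.5); o2 = (0.3, 0.5, 0.03125)
  d <- discretize_abundance(ra, md)
  y <- function(o, s) d$Y[d$otu == o & d$session == s]
  expect_equal(y("o1", "L-60"), 0)              # log2(1) = 0
  expect_equal(y("o2", "L-60"), -2)             # log2(0.3) = -1.737 -> -2
  expect_equal(y("o2", "FD7"), -1)              # log2(0.5) = -1
  expect_equal(y("o2", "FD180"), -5)            # exact level
  # zero maps one level below the per-OTU minimum positive level (-1 here)
  expect_equal(y("o1", "FD7"), -2)
  expect_true(d$zero_flag[d$otu == "o1" & d$session == "FD7"])
})

test_that("an all-zero OTU is excluded with a reason", {
  md <- disc_meta("A", c("L-60", "FD7"))
  ra <- make_ra(c(0.5, 0, 0.5, 0), otus = c("live", "dead"),
                samples = md$sample_id)
  d <- discretize_abundance(ra, md)
  expect_equal(attr(d, "excluded_otus"), "dead")
  expect_false("dead" %in% d$otu)
})

test_that("discretization separates >= 2-fold changes and merges < sqrt(2)-fold ones", {
  set.seed(42)
  n <- 5000
  round_dyadic <- function(x) sign(log2(x)) * floor(abs(log2(x)) + 0.5)
  a <- runif(n, 1e-6, 1)
  b <- a * runif(n, 2, 100)          # ratio >= 2 implies a level change
  expect_true(all(abs(round_dyadic(b) - round_dyadic(a)) >= 1))
  # within (1/sqrt(2), sqrt(2)) of the same dyadic level -> same Y
  lev <- sample(-12:-1, n, replace = TRUE)
  r1 <- 2^lev * runif(n, 1 / sqrt(2) + 1e-9, sqrt(2) - 1e-9)
  expect_equal(round_dyadic(r1), lev)
})

test_that("within-subject pairs follow session combinatorics and never cross subjects", {
  md <- disc_meta(c("A", "B"), cytokine_sessions())
  ra <- make_ra(rep(0.1, 10), otus = "o1", samples = md$sample_id)
  d <- discretize_abundance(ra, md)
  panel <- data.frame(subject_id = md$subject_id, session = md$timepoint,
                      analyte = "IL-6", concentration = exp(rnorm(10)),
                      censored = FALSE, stringsAsFactors = FALSE)
  bp <- build_within_subject_pairs(d, panel, "IL-6", "o1")
  expect_equal(nrow(bp$pairs), 2 * choose(5, 2))     # 10 per subject
  expect_true(all(bp$pairs$subject %in% c("A", "B")))
  # drop two of B's sessions: 10 + C(3,2) = 13 pairs
  panel2 <- panel[!(panel$subject_id == "B" &
                    panel$session %in% c("R+0", "R+180")), ]
  bp2 <- build_within_subject_pairs(d, panel2, "IL-6", "o1")
  expect_equal(nrow(bp2$pairs), 10 + 3)
  expect_equal(bp$n_valid, 10)
})

test_that("pooled Somers' D matches exhaustive enumeration on hand examples", {
  # Y=(0,1,2), X=(1,3,2): C=2, Disc=1, D=1/3
  p <- pairs_from_obs(data.frame(subject = "A", Y = c(0, 1, 2), X = c(1, 3, 2)))
  res <- somers_d_pooled(p)
  expect_equal(res$D, 1 / 3)
  expect_equal(res$concordant, 2)
  expect_equal(res$discordant, 1)
  # perfect concordance / discordance
  inc <- data.frame(subject = rep(c("A", "B"), each = 5),
                    Y = rep(1:5, 2), X = rep(1:5, 2))
  expect_equal(somers_d_pooled(pairs_from_obs(inc))$D, 1)
  dec <- transform(inc, X = -X)
  expect_equal(somers_d_pooled(pairs_from_obs(dec))$D, -1)
  # all tied on Y is undefined
  tied <- data.frame(subject = "A", Y = c(1, 1, 1), X = 1:3)
  expect_error(somers_d_pooled(pairs_from_obs(tied)), "tied")
})

test_that("pooled Somers' D equals the brute-force oracle on random cohorts", {
  set.seed(7)
  agree <- vapply(1:300, function(i) {
    g <- sample(2:6, 1)
    obs <- do.call(rbind, lapply(seq_len(g), function(s) {
      n <- sample(3:5, 1)
      data.frame(subject = paste0("S", s),
                 Y = sample(-3:3, n, replace = TRUE),
                 X = round(rnorm(n), 2))
    }))
    expected <- somers_brute(obs)
    pr <- pairs_from_obs(obs)
    if (is.na(expected))
      inherits(tryCatch(somers_d_pooled(pr), error = identity), "error")
    else
      identical(somers_d_pooled(pr)$D, expected)
  }, logical(1))
  expect_true(all(agree))
})

test_that("D is antisymmetric under X -> -X", {
  set.seed(11)
  for (i in 1:50) {
    obs <- data.frame(subject = rep(c("A", "B"), each = 4),
                      Y = sample(-2:2, 8, replace = TRUE),
                      X = rnorm(8))
    pr <- pairs_from_obs(obs)
    if (all(pr$dY == 0)) next
    d1 <- somers_d_pooled(pr)$D
    pr$dX <- -pr$dX
    expect_equal(somers_d_pooled(pr)$D, -d1)
  }
})

test_that("jackknife SE matches the closed two-subject formula and flags degeneracy", {
  obs <- data.frame(subject = rep(c("A", "B"), each = 3),
                    Y = c(0, 1, 2, 0, 1, 2),
                    X = c(1, 2, 3, 1, 3, 2))
  pr <- pairs_from_obs(obs)
  d_a <- somers_brute(obs[obs$subject == "B", ])  # leave A out
  d_b <- somers_brute(obs[obs$subject == "A", ])  # leave B out
  jk <- jackknife_se(pr)
  dbar <- mean(c(d_a, d_b))
  expect_equal(jk$se, sqrt(1 / 2 * ((d_a - dbar)^2 + (d_b - dbar)^2)))
  expect_false(jk$degenerate)
  # identical pair patterns -> SE 0, degenerate, p suppressed
  same <- data.frame(subject = rep(c("A", "B", "C"), each = 3),
                     Y = rep(0:2, 3), X = rep(c(1, 2, 3), 3))
  jk0 <- jackknife_se(pairs_from_obs(same))
  expect_true(jk0$degenerate)
  expect_equal(jk0$se, 0)
  expect_true(is.na(jk0$p))
  # single contributing subject: SE undefined
  one <- data.frame(subject = "A", Y = 0:2, X = c(1, 2, 3))
  jk1 <- jackknife_se(pairs_from_obs(one))
  expect_true(jk1$degenerate)
  expect_true(is.na(jk1$se))
})

test_that("the valid-comparison exclusion boundary sits exactly at 10", {
  md <- disc_meta(c("A", "B"), cytokine_sessions())
  set.seed(3)
  ra <- make_ra(2^runif(10, -8, -1), otus = "o1", samples = md$sample_id)
  d <- discretize_abundance(ra, md)
  panel <- data.frame(subject_id = md$subject_id, session = md$timepoint,
                      analyte = "IL-6", concentration = exp(rnorm(10) * 2),
                      censored = FALSE, stringsAsFactors = FALSE)
  scr10 <- screen_combinations(ra, panel, md, candidates = "o1",
                               analytes = "IL-6")
  expect_equal(scr10$n_valid, 10)
  expect_false(scr10$excluded)
  # censor one observation: 9 valid comparisons -> excluded, no p
  panel$censored[1] <- TRUE
  scr9 <- screen_combinations(ra, panel, md, candidates = "o1",
                              analytes = "IL-6")
  expect_equal(scr9$n_valid, 9)
  expect_true(scr9$excluded)
  expect_true(is.na(scr9$p))
})

test_that("screen evaluates the full candidate x analyte grid", {
  md <- disc_meta(c("A", "B", "C"), cytokine_sessions())
  set.seed(5)
  otus <- sprintf("o%02d", 1:4)
  ra <- make_ra(2^runif(4 * 15, -8, -1), otus = otus, samples = md$sample_id)
  analytes <- c("IL-6", "TNFa", "MCP-1")
  panel <- expand.grid(subject_id = c("A", "B", "C"),
                       session = cytokine_sessions(),
                       analyte = analytes, stringsAsFactors = FALSE)
  panel$concentration <- exp(rnorm(nrow(panel)))
  panel$censored <- FALSE
  scr <- screen_combinations(ra, panel, md, candidates = otus,
                             analytes = analytes)
  expect_equal(nrow(scr), 4 * 3)
  expect_equal(attr(scr, "n_evaluated"), 12)
  expect_true(all(scr$D[!scr$excluded] >= -1 & scr$D[!scr$excluded] <= 1))
  # BH q-values only where computed
  expect_true(all(is.na(scr$q[scr$excluded])))
})
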