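test_that("mixed contrast reduces to OLS group differences with no subject variance", {
  set.seed(1)
  obs <- expand.grid(subject = paste0("S", 1:6),
                     level = c("preflight", "inflight", "postflight"),
                     stringsAsFactors = FALSE)
  obs$value <- ifelse(obs$level == "inflight", 2, 0) + rnorm(nrow(obs), 0, 0.5)
  res <- mixed_contrast(obs, baseline = "preflight")
  fit <- lm(value ~ relevel(factor(level), "preflight"), data = obs)
  ols <- coef(fit)[-1]
  got <- res$estimate[match(c("inflight", "postflight"), res$term)]
  expect_equal(unname(got), unname(ols[c(1, 2)]), tolerance = 1e-6)
})

test_that("mixed contrast recovers a planted stage effect", {
  set.seed(2)
  est <- vapply(1:40, function(i) {
    obs <- expand.grid(subject = paste0("S", 1:9), rep = 1:3,
                       level = c("preflight", "inflight"),
                       stringsAsFactors = FALSE)
    b <- rnorm(9, 0, 1)
    obs$value <- b[as.integer(factor(obs$subject))] +
      2 * (obs$level == "inflight") + rnorm(nrow(obs), 0, 0.5)
    res <- mixed_contrast(obs, "preflight")
    res$estimate[res$term == "inflight"]
  }, numeric(1))
  expect_equal(mean(est), 2, tolerance = 0.1)
})

test_that("stage distance observations follow within-astronaut combinatorics", {
  md <- rbind(toy_metadata("AstA", c("L-240", "L-150", "FD7", "FD90")),
              toy_metadata("AstB", c("L-240", "FD7")))
  n <- nrow(md)
  set.seed(4)
  pts <- matrix(rnorm(2 * n), ncol = 2)
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- md$sample_id
  obs <- stage_distance_table(d, md, "pre_in")
  # AstA: C(4,2) = 6 pairs (1 within-pre, 1 within-in, 4 between);
  # AstB: 1 between pair
  expect_equal(nrow(obs), 7)
  expect_equal(sum(obs$astronaut == "AstA"), choose(4, 2))
  expect_equal(sum(obs$category == "between_pre_in" & obs$astronaut == "AstA"), 4)
  expect_equal(sum(obs$category == "within_pre_in" & obs$astronaut == "AstA"), 2)
  # cross-astronaut pairs never appear: total equals sum of per-astronaut C(n,2)
  expect_equal(nrow(obs), choose(4, 2) + choose(2, 2 - 1) * 0 + 1)
  for (i in seq_len(nrow(obs)))
    expect_equal(md$subject_id[md$sample_id == obs$sample_a[i]],
                 md$subject_id[md$sample_id == obs$sample_b[i]])
})

test_that("baseline distance trajectory reproduces hand arithmetic", {
  md <- toy_metadata("AstA", c("L-240", "L-150", "FD7"))
  d <- matrix(0, 3, 3, dimnames = list(md$sample_id, md$sample_id))
  d[1, 2] <- d[2, 1] <- 0.2
  d[1, 3] <- d[3, 1] <- 0.5
  d[2, 3] <- d[3, 2] <- 0.5
  tr <- baseline_distance_trajectory(d, md)
  expect_equal(tr$mean_distance[tr$timepoint == "preflight"], 0.2)
  expect_equal(tr$mean_distance[tr$timepoint == "FD7"], 0.5)
  expect_equal(tr$n_pairs[tr$timepoint == "FD7"], 2)
  # identical compositions give a zero trajectory
  z <- matrix(0, 3, 3, dimnames = dimnames(d))
  tz <- baseline_distance_trajectory(z, md)
  expect_true(all(tz$mean_distance == 0))
})

test_that("permanova p-values are count-exact and reject separated clusters", {
  set.seed(9)
  pts <- rbind(matrix(rnorm(12, 0), ncol = 2), matrix(rnorm(12, 8), ncol = 2))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:12)
  g <- rep(c("a", "b"), each = 6)
  res <- permanova(d, g, n_perm = 199, seed = 5)
  expect_equal(res$p, 1 / 200)
  expect_gt(res$f, 1)
  expect_error(permanova(d, rep("a", 12)), "2 groups")
  # stratified call runs and warns when a stratum is single-group
  strata <- rep(c("x", "y"), 6)
  res2 <- permanova(d, g, n_perm = 199, strata = strata, seed = 5)
  expect_true(res2$p <= 1)
  expect_warning(permanova(d, g, n_perm = 199, strata = g, seed = 5),
                 "no permutation variability")
})

test_that("Welch convergence test matches the textbook statistic on hand data", {
  md <- rbind(toy_metadata(c("AstA", "AstB"), c("L-240", "FD7")))
  ids <- md$sample_id
  d <- matrix(0, 4, 4, dimnames = list(ids, ids))
  # inter-astronaut preflight pair and inflight pair
  pre_a <- md$sample_id[md$timepoint == "L-240"]
  in_a <- md$sample_id[md$timepoint == "FD7"]
  d[pre_a[1], pre_a[2]] <- d[pre_a[2], pre_a[1]] <- 0.4
  d[in_a[1], in_a[2]] <- d[in_a[2], in_a[1]] <- 0.3
  # need >= 2 pairs per stage: extend with a third astronaut
  md3 <- rbind(md, toy_metadata("AstC", c("L-240", "FD7")))
  ids3 <- md3$sample_id
  set.seed(6)
  dd <- matrix(runif(36, 0.2, 0.6), 6, 6, dimnames = list(ids3, ids3))
  dd <- (dd + t(dd)) / 2; diag(dd) <- 0
  res <- convergence_welch(dd, md3)
  # oracle: collect the distances by hand and run t.test
  pre <- md3$sample_id[md3$stage == "preflight"]
  inf <- md3$sample_id[md3$stage == "inflight"]
  a <- dd[t(combn(pre, 2))]
  b <- dd[t(combn(inf, 2))]
  tt <- t.test(a, b)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-9)
})

test_that("Welch test on two fixed samples matches the closed formula", {
  a <- c(0.2, 0.4); b <- c(0.3, 0.5)
  tt <- t.test(a, b)
  se <- sqrt(var(a) / 2 + var(b) / 2)
  expect_equal(unname(tt$statistic), (mean(a) - mean(b)) / se, tolerance = 1e-12)
})

test_that("CV reduction ranking matches hand arithmetic and orders correctly", {
  md <- rbind(toy_metadata(c("S1", "S2", "S3"), c("L-60", "FD7")))
  vals <- matrix(0, 2, 6, dimnames = list(c("g1", "g2"), md$sample_id))
  # per-subject means preflight (0.1, 0.2, 0.3), inflight (0.2, 0.2, 0.2)
  pre_ids <- md$sample_id[md$stage == "preflight"]
  in_ids <- md$sample_id[md$stage == "inflight"]
  vals["g1", pre_ids] <- c(0.1, 0.2, 0.3)
  vals["g1", in_ids] <- 0.2
  vals["g2", ] <- 0.5
  ra <- structure(list(values = vals, taxonomy = NULL), class = "rel_abundance")
  cv <- cv_reduction_ranking(ra, md, level = "otu")
  g1 <- cv[cv$taxon == "g1", ]
  expect_equal(g1$cv_in, 0)
  expect_equal(g1$reduction, sd(c(0.1, 0.2, 0.3)) / 0.2)
  expect_equal(g1$cumulative_fraction, 1)
  g2 <- cv[cv$taxon == "g2", ]
  expect_equal(g2$reduction, 0)
  # cumulative fraction is nondecreasing and ends at 1 over positives
  sp <- small_stool_spec(seed = 13)
  ch <- generate_cohort(sp)
  raf <- to_relative_abundance(ch$table)
  cc <- cv_reduction_ranking(raf, ch$metadata, level = "genus")
  cf <- cc$cumulative_fraction[!is.na(cc$cumulative_fraction)]
  expect_true(all(diff(cf) >= -1e-12))
  expect_equal(cf[length(cf)], 1)
})

test_that("paired Pearson correlation matches hand arithmetic", {
  expect_equal(paired_alpha_correlation(1:4, 1:4)$r, 1)
  expect_equal(paired_alpha_correlation(1:4, -(1:4))$r, -1)
  res <- paired_alpha_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$r_squared, 0.64)
  expect_error(paired_alpha_correlation(c(1, 1, 1), 1:3), "zero variance")
})

test_that("da_screen passes an external candidate list through verbatim", {
  tab <- random_otu_table(1)
  res <- da_screen(tab, data.frame(), candidates = c("OtuX", "OtuY"))
  expect_true(res$bypass)
  expect_identical(res$candidates, c("OtuX", "OtuY"))
})

test_that("da_screen flags planted four-fold changes with high probability", {
  det <- vapply(1:15, function(seed) {
    sp0 <- small_stool_spec(seed = seed + 300, temporal_sd = 0.5)
    ab <- rowMeans(generate_cohort(sp0)$truth$p_expected)
    taxa <- names(sort(ab, decreasing = TRUE))[c(3, 5, 8, 10)]
    sp <- small_stool_spec(seed = seed + 300, temporal_sd = 0.5,
                           stage_effects = data.frame(taxon = taxa,
                                                      stage = "inflight",
                                                      log2fc = c(-2, 2, -2, 2)))
    ch <- generate_cohort(sp)
    ctl <- ch$metadata$sample_id[ch$metadata$site %in% control_sites()]
    ft <- filter_low_support_otus(remove_contaminants(ch$table, ctl)$table)
    # with ~45 OTUs at FDR 0.1 the BH cut sits near 0.002-0.009, so the
    # permutation count must make such p-values attainable
    ds <- suppressWarnings(da_screen(ft, ch$metadata, seed = seed, n_perm = 999))
    mean(taxa %in% ds$candidates)
  }, numeric(1))
  expect_gte(mean(det), 0.8)
})
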