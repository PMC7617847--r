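test_that("PMA regression recovers exact and null relationships", {
  pma <- runif(50, 26, 42)
  exact <- tibble::tibble(
    id = as.character(1:50), group = "g", pma = pma, adult = FALSE,
    age_bin = assign_age_bin(pma, rep(FALSE, 50)), scope = "all",
    n_nonmissing = 66L, n_present = 33L,
    proportion_present = 0.02 * pma + 0.1,
    mean_log_strength = -1 + 0.05 * pma)
  # summary.lm warns about the exact fit; that is the point of the fixture
  fit <- suppressWarnings(fit_pma_regression(exact, "proportion"))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 0.02)
  fit_s <- suppressWarnings(fit_pma_regression(exact, "strength"))
  expect_equal(fit_s$r_squared, 1)
  # constant metric: slope and R^2 are zero by convention
  const <- exact; const$proportion_present <- 0.5
  fc <- fit_pma_regression(const, "proportion")
  expect_equal(fc$r_squared, 0)
  expect_equal(fc$slope, 0)
})

test_that("a metric independent of PMA gives near-zero R-squared", {
  set.seed(21)
  hits <- 0
  for (i in 1:10) {
    pma <- runif(200, 26, 42)
    tab <- tibble::tibble(
      id = as.character(1:200), group = "g", pma = pma, adult = FALSE,
      age_bin = assign_age_bin(pma, rep(FALSE, 200)), scope = "all",
      n_nonmissing = 66L, n_present = 33L,
      proportion_present = runif(200), mean_log_strength = rnorm(200))
    if (fit_pma_regression(tab, "proportion")$r_squared < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a designed R-squared of 0.5 is recovered within 0.1", {
  # noise sd chosen analytically: R^2 = var(signal) / (var(signal) + sd^2)
  set.seed(22)
  r2 <- numeric(20)
  for (i in 1:20) {
    pma <- runif(200, 26, 42)
    signal <- 0.05 * pma
    noise_sd <- sqrt(var(signal))  # equal variances -> R^2 ~ 0.5
    tab <- tibble::tibble(
      id = as.character(1:200), group = "g", pma = pma, adult = FALSE,
      age_bin = assign_age_bin(pma, rep(FALSE, 200)), scope = "all",
      n_nonmissing = 66L, n_present = 33L,
      proportion_present = signal + rnorm(200, 0, noise_sd),
      mean_log_strength = 0)
    r2[i] <- fit_pma_regression(tab, "proportion")$r_squared
  }
  expect_lt(abs(mean(r2) - 0.5), 0.1)
})

test_that("Dunnett comparisons give zero estimates for copied groups", {
  set.seed(23)
  ad <- rnorm(50, 0.8, 0.05)
  gv <- list("adult" = ad, "34-36" = ad,  # identical to adult
             "36-38" = rnorm(50, 0.5, 0.05), "38-40" = rnorm(50, 0.6, 0.05))
  dn <- groups_vs_adult(make_summaries(gv), "proportion", seed = 1)
  est <- dn$estimate[dn$comparison == "34-36 - adult"]
  expect_equal(est, 0, tolerance = 1e-12)
  expect_equal(nrow(dn), 3)
})

test_that("Dunnett-corrected p-values dominate their unadjusted counterparts", {
  set.seed(24)
  gv <- list("adult" = rnorm(40, 0.7, 0.1), "<32" = rnorm(20, 0.55, 0.1),
             "34-36" = rnorm(25, 0.65, 0.1), "36-38" = rnorm(25, 0.68, 0.1),
             "40-42" = rnorm(30, 0.72, 0.1))
  sm <- make_summaries(gv)
  dn <- groups_vs_adult(sm, "proportion", seed = 1)
  # unadjusted reference: same model, no multiplicity adjustment
  df <- sm[!is.na(sm$proportion_present), ]
  df$grp <- droplevels(df$age_bin)
  fit <- aov(proportion_present ~ grp, data = df)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  p_raw <- summary(gl, test = multcomp::adjusted("none"))$test$pvalues
  expect_true(all(dn$p_adj >= as.vector(p_raw) - 1e-10))
})

test_that("a group shifted by three SDs is reliably detected", {
  set.seed(33)
  hits <- 0
  for (i in 1:50) {
    gv <- list("adult" = rnorm(50), "34-36" = rnorm(50),
               "36-38" = rnorm(50), "40-42" = rnorm(50, mean = 3))
    dn <- groups_vs_adult(make_summaries(gv), "proportion", seed = i)
    if (dn$p_adj[dn$comparison == "40-42 - adult"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("groups with fewer than 2 subjects are excluded with a warning", {
  set.seed(25)
  gv <- list("adult" = rnorm(20, 0.7, 0.1), "<32" = 0.4,
             "36-38" = rnorm(10, 0.6, 0.1), "40-42" = rnorm(10, 0.7, 0.1))
  expect_warning(dn <- groups_vs_adult(make_summaries(gv), "proportion"),
                 "<32")
  expect_false("<32 - adult" %in% dn$comparison)
})

test_that("ANOVA error degrees of freedom match the factorial layout", {
  # 470 subjects (8, 8, 34, 40, 100, 182 infants + 98 adults) x 3
  # subnetworks: residual df = 1410 - 21 = 1389
  set.seed(26)
  sizes <- c("<32" = 8, "32-34" = 8, "34-36" = 34, "36-38" = 40,
             "38-40" = 100, "40-42" = 182, "adult" = 98)
  sub <- dplyr::bind_rows(lapply(subnetwork_names(), function(sn) {
    make_summaries(lapply(as.list(sizes), function(n) runif(n)), scope = sn)
  }))
  res <- subnetwork_anova(sub, "proportion")
  expect_equal(res$error_df, 1389)
  expect_true(all(res$anova$p >= 0 & res$anova$p <= 1, na.rm = TRUE))
})

test_that("null interaction p-values are uniform", {
  set.seed(27)
  ks_p <- local({
    pvals <- vapply(1:500, function(i) {
      sub <- dplyr::bind_rows(lapply(subnetwork_names(), function(sn) {
        make_summaries(list("<32" = rnorm(10), "34-36" = rnorm(10),
                            "38-40" = rnorm(10), "adult" = rnorm(10)),
                       scope = sn)
      }))
      res <- subnetwork_anova(sub, "proportion")
      res$anova$p[res$anova$term == "age_group:subnetwork"]
    }, numeric(1))
    stats::ks.test(pvals, "punif")$p.value
  })
  expect_gt(ks_p, 0.01)
})

test_that("a designed age-by-subnetwork interaction is detected", {
  set.seed(28)
  slopes <- c(sensory = 0.08, affective = 0.04, cognitive = 0.01)
  hits <- 0
  for (rep in 1:30) {
    sub <- dplyr::bind_rows(lapply(subnetwork_names(), function(sn) {
      vals <- lapply(c("<32" = 29, "34-36" = 35, "38-40" = 39),
                     function(p) slopes[[sn]] * p + rnorm(50, 0, 0.3))
      vals$adult <- rnorm(50, 3, 0.3)
      make_summaries(vals, scope = sn)
    }))
    res <- subnetwork_anova(sub, "proportion")
    p_int <- res$anova$p[res$anova$term == "age_group:subnetwork"]
    if (p_int < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 28)
})

test_that("Tukey-corrected p-values dominate unadjusted pairwise p-values", {
  set.seed(29)
  sub <- dplyr::bind_rows(lapply(subnetwork_names(), function(sn) {
    make_summaries(list("<32" = rnorm(15, 0.3, 0.1),
                        "38-40" = rnorm(20, 0.5, 0.1),
                        "adult" = rnorm(20, 0.6, 0.1)), scope = sn)
  }))
  res <- subnetwork_anova(sub, "proportion")
  df <- sub
  df$subnetwork <- factor(df$scope, levels = subnetwork_names())
  df$age_group <- droplevels(df$age_bin)
  df$value <- df$proportion_present
  fit <- lm(value ~ age_group * subnetwork, data = df)
  raw <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ subnetwork | age_group),
    method = "pairwise", adjust = "none"))
  adj <- res$tukey_subnetwork_within_age
  key <- paste(adj$contrast, adj$age_group)
  raw_key <- paste(raw$contrast, raw$age_group)
  expect_true(all(adj$p.value >= raw$p.value[match(key, raw_key)] - 1e-10))
})

test_that("identical term and adult groups produce empty tallies", {
  idx <- connection_index()
  set.seed(30)
  vals <- runif(66, 0.5, 1.5)
  tabs <- lapply(1:8, function(i) {
    dplyr::bind_rows(
      hand_norm_table(vals, id = paste0("i", i), pma = 41),
      hand_norm_table(vals, id = paste0("a", i), adult = TRUE))
  })
  tab <- dplyr::bind_rows(tabs)
  # add tiny per-subject noise so variances are nonzero but groups identical
  set.seed(31)
  eps <- rnorm(nrow(tab) / 2, 0, 1e-4)
  tab$r_norm[!tab$adult] <- tab$r_norm[!tab$adult] + eps
  tab$r_norm[tab$adult] <- tab$r_norm[tab$adult] + eps
  ct <- connection_level_tests(tab)
  expect_equal(ct$tallies$pct_stronger, rep(0, 3))
  expect_equal(ct$tallies$pct_weaker, rep(0, 3))
})

test_that("FDR families follow the subnetwork connection counts", {
  pc <- processed_small_cohort()
  ct <- connection_level_tests(pc$pres$table)
  expect_equal(ct$tallies$n_connections[ct$tallies$family == "sensory"], 10L)
  expect_equal(ct$tallies$n_connections[ct$tallies$family == "affective"], 10L)
  expect_equal(ct$tallies$n_connections[ct$tallies$family == "cognitive"], 15L)
  ct_all <- connection_level_tests(pc$pres$table, family = "all")
  expect_equal(ct_all$tallies$n_connections, 66L)
})

test_that("FDR-adjusted p-values are monotone in raw-p rank within families", {
  pc <- processed_small_cohort()
  for (fam in c("subnetwork", "all")) {
    ct <- connection_level_tests(pc$pres$table, family = fam)
    tested <- ct$tests[!ct$tests$skipped, ]
    for (f in unique(tested$family)) {
      sub <- tested[tested$family == f, ]
      ord <- order(sub$p_raw)
      expect_true(all(diff(sub$p_adj[ord]) >= -1e-15))
      expect_true(all(sub$p_adj >= sub$p_raw - 1e-15))
    }
  }
})
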