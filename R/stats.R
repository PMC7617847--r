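#' Linear regression of a summary metric on PMA
#'
#' Ordinary least squares of the per-subject metric (proportion of present
#' connections or mean log10 strength) on postmenstrual age, infants only.
#'
#' @param summaries A [subject_summary()] tibble.
#' @param metric `"proportion"` or `"strength"`.
#' @return Tibble: `metric`, `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`. A constant metric yields slope 0 and R-squared 0.
#' @export
fit_pma_regression <- function(summaries, metric = c("proportion", "strength")) {
  metric <- match.arg(metric)
  col <- if (metric == "proportion") "proportion_present" else "mean_log_strength"
  df <- summaries[!summaries$adult & !is.na(summaries$pma) &
                    !is.na(summaries[[col]]), ]
  if (nrow(df) < 3) stop("need at least 3 infants with a non-missing metric")
  y <- df[[col]]
  x <- df$pma
  if (var(y) == 0) {
    return(tibble(metric = metric, slope = 0, intercept = mean(y),
                  r_squared = 0, p_value = NA_real_, n = nrow(df)))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(metric = metric,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         p_value = sm$coefficients[2, 4],
         n = nrow(df))
}

#' Dunnett-corrected comparisons of infant age bins against adults
#'
#' Many-to-one comparisons of each infant PMA bin against the adult control
#' group, with single-step Dunnett correction via the multivariate-t
#' distribution (as implemented in \pkg{multcomp}). Groups with fewer than
#' 2 subjects are excluded with a warning. The multivariate-t integration
#' is quasi-random; `seed` fixes it for reproducibility.
#'
#' @param summaries A [subject_summary()] tibble (all scopes mixed is an
#'   error; pass one scope).
#' @param metric `"proportion"` or `"strength"`.
#' @param seed Integer seed for the correction's numerical integration.
#' @return Tibble: `comparison`, `estimate`, `lwr`, `upr`, `p_adj`, `n`.
#' @export
groups_vs_adult <- function(summaries, metric = c("proportion", "strength"),
                            seed = 1L) {
  metric <- match.arg(metric)
  if (length(unique(summaries$scope)) > 1) {
    stop("summaries mix several scopes; filter to one before comparing")
  }
  col <- if (metric == "proportion") "proportion_present" else "mean_log_strength"
  df <- summaries[!is.na(summaries[[col]]) & !is.na(summaries$age_bin), ]
  sizes <- table(df$age_bin)
  small <- names(sizes)[sizes > 0 & sizes < 2]
  if (length(small) > 0) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    df <- df[!(as.character(df$age_bin) %in% small), ]
    sizes <- table(df$age_bin)
  }
  if (!"adult" %in% names(sizes) || sizes["adult"] == 0) {
    stop("adult group is empty")
  }
  if (sum(sizes[names(sizes) != "adult"] > 0) < 2) {
    stop("need at least 2 non-empty infant groups")
  }
  df$grp <- droplevels(df$age_bin)
  y <- df[[col]]
  fit <- aov(y ~ grp, data = df)
  set.seed(seed)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  sm <- summary(gl)
  ci <- stats::confint(gl)$confint
  tibble(
    comparison = names(sm$test$coefficients),
    estimate = unname(sm$test$coefficients),
    lwr = unname(ci[, "lwr"]),
    upr = unname(ci[, "upr"]),
    p_adj = unname(as.vector(sm$test$pvalues)),
    n = as.integer(sizes[sub(" - adult$", "", names(sm$test$coefficients))])
  )
}

#' Two-way age-by-subnetwork ANOVA with Tukey pairwise comparisons
#'
#' Fixed-effects two-way ANOVA with interaction on the unbalanced
#' subject-by-subnetwork layout (each subject contributes one value per
#' subnetwork; rows are treated as independent). Sums of squares are Type
#' II (\pkg{car}); the interaction's explained-variance share is its SS
#' divided by the total SS. Tukey-adjusted pairwise comparisons
#' (\pkg{emmeans}) are returned for subnetworks within each age group and
#' for age groups within each subnetwork.
#'
#' @param subnet_summaries Output of [subject_subnetwork_summaries()].
#' @param metric `"proportion"` or `"strength"`.
#' @return A list: `anova` (tibble of term, sum_sq, df, f, p),
#'   `interaction_variance_share`, `error_df`,
#'   `tukey_subnetwork_within_age`, `tukey_age_within_subnetwork`
#'   (tibbles with Tukey-adjusted p-values).
#' @export
subnetwork_anova <- function(subnet_summaries,
                             metric = c("proportion", "strength")) {
  metric <- match.arg(metric)
  col <- if (metric == "proportion") "proportion_present" else "mean_log_strength"
  df <- subnet_summaries[!is.na(subnet_summaries[[col]]) &
                           !is.na(subnet_summaries$age_bin), ]
  df$subnetwork <- factor(df$scope, levels = subnetwork_names())
  df$age_group <- droplevels(df$age_bin)
  df$value <- df[[col]]
  cells <- table(df$age_group, df$subnetwork)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop("empty age-by-subnetwork cell(s): ",
         paste(sprintf("%s x %s", rownames(cells)[bad[, 1]],
                       colnames(cells)[bad[, 2]]), collapse = ", "))
  }
  fit <- lm(value ~ age_group * subnetwork, data = df)
  an <- car::Anova(fit, type = 2)
  tab <- tibble(
    term = rownames(an),
    sum_sq = an[["Sum Sq"]],
    df = an[["Df"]],
    f = an[["F value"]],
    p = an[["Pr(>F)"]]
  )
  ss_total <- sum((df$value - mean(df$value))^2)
  ss_int <- tab$sum_sq[tab$term == "age_group:subnetwork"]
  em_sub <- emmeans::emmeans(fit, ~ subnetwork | age_group)
  em_age <- emmeans::emmeans(fit, ~ age_group | subnetwork)
  pair_tbl <- function(em) {
    as_tibble(as.data.frame(
      emmeans::contrast(em, method = "pairwise", adjust = "tukey")))
  }
  list(
    anova = tab,
    interaction_variance_share = ss_int / ss_total,
    error_df = tab$df[tab$term == "Residuals"],
    tukey_subnetwork_within_age = pair_tbl(em_sub),
    tukey_age_within_subnetwork = pair_tbl(em_age)
  )
}

#' Per-connection term-infant versus adult t-tests with FDR correction
#'
#' Within each subnetwork's connection family, compares the normalised
#' strength of every connection between late-term infants (40-42 weeks
#' PMA bin by default) and adults with Welch two-sample t-tests,
#' Benjamini-Hochberg-adjusts the p-values within the family, and tallies
#' the share of connections significantly stronger or weaker in term
#' infants. With `family = "all"` a single 66-connection family is used
#' and every connection is tested once.
#'
#' @param norm Presence-called table (`table` element of
#'   [presence_threshold()]).
#' @param term_bin Age-bin label of the infant group (default `"40-42"`).
#' @param family `"subnetwork"` (default) or `"all"`.
#' @param use_log Test `log10(r_norm)` of present connections instead of
#'   raw `r_norm` (default `FALSE`).
#' @param alpha FDR level for the tallies (default 0.05).
#' @return A list: `tests` (tibble: `family`, `connection_id`, `t`,
#'   `p_raw`, `p_adj`, `direction`, `mean_term`, `mean_adult`, `skipped`)
#'   and `tallies` (tibble: `family`, `n_connections`, `pct_stronger`,
#'   `pct_weaker`).
#' @export
connection_level_tests <- function(norm, term_bin = "40-42",
                                   family = c("subnetwork", "all"),
                                   use_log = FALSE, alpha = 0.05) {
  family <- match.arg(family)
  norm$age_bin <- assign_age_bin(norm$pma, norm$adult)
  fams <- if (family == "subnetwork") {
    lapply(subnetwork_names(), function(nm) {
      list(name = nm, conns = subnetwork_definition(nm)$connections)
    })
  } else {
    list(list(name = "all", conns = connection_index()$connection_id))
  }
  tests <- dplyr::bind_rows(lapply(fams, function(fm) {
    rows <- lapply(fm$conns, function(cid) {
      term <- norm$r_norm[norm$age_bin %in% term_bin &
                            norm$connection_id == cid]
      ad <- norm$r_norm[norm$adult & norm$connection_id == cid]
      term <- term[!is.na(term)]
      ad <- ad[!is.na(ad)]
      if (use_log) {
        term <- log10(term[term > 0])
        ad <- log10(ad[ad > 0])
      }
      if (length(term) < 2 || length(ad) < 2) {
        stop("connection ", cid, " has fewer than 2 values in a group")
      }
      if (var(term) == 0 && var(ad) == 0) {
        return(tibble(family = fm$name, connection_id = cid,
                      t = NA_real_, p_raw = NA_real_,
                      direction = 0,
                      mean_term = mean(term), mean_adult = mean(ad),
                      skipped = TRUE))
      }
      tt <- t.test(term, ad)
      tibble(family = fm$name, connection_id = cid,
             t = unname(tt$statistic), p_raw = tt$p.value,
             direction = sign(mean(term) - mean(ad)),
             mean_term = mean(term), mean_adult = mean(ad),
             skipped = FALSE)
    })
    out <- dplyr::bind_rows(rows)
    out$p_adj <- NA_real_
    tested <- !out$skipped
    out$p_adj[tested] <- p.adjust(out$p_raw[tested], method = "BH")
    out
  }))
  tallies <- dplyr::summarise(
    dplyr::group_by(tests, .data$family),
    n_connections = dplyr::n(),
    pct_stronger = 100 * sum(.data$p_adj < alpha & .data$direction > 0,
                             na.rm = TRUE) / .data$n_connections,
    pct_weaker = 100 * sum(.data$p_adj < alpha & .data$direction < 0,
                           na.rm = TRUE) / .data$n_connections,
    .groups = "drop"
  )
  list(tests = tests, tallies = tallies)
}
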