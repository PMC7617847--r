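#' Default cohort group table
#'
#' Mirrors the age-group structure of the source cohorts: six infant bins
#' between 26 and 42 weeks PMA with sizes 8, 8, 34, 40, 100 and 182, plus
#' 98 adults, for 470 subjects in total.
#'
#' @return Tibble with columns `label`, `pma_min`, `pma_max`, `n`, `adult`.
#' @export
default_cohort_groups <- function() {
  tibble(
    label   = c("<32", "32-34", "34-36", "36-38", "38-40", "40-42", "adult"),
    pma_min = c(26, 32, 34, 36, 38, 40, NA),
    pma_max = c(32, 34, 36, 38, 40, 42, NA),
    n       = c(8L, 8L, 34L, 40L, 100L, 182L, 98L),
    adult   = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles everything the generator needs: the group table, per-group series
#' lengths (2300 volumes for infants, 1200 for adults, matching the source
#' acquisitions), one growth model per connection, the hemispheric jitter,
#' an optional AR(1) coefficient for the latent series, and the master seed.
#'
#' @param groups Tibble like [default_cohort_groups()]; non-adult rows need
#'   `pma_min < pma_max`, all rows `n >= 1`.
#' @param series_length Named vector `c(infant = , adult = )`, each `>= 50`.
#' @param growth_models Named list of [growth_model()]s covering every
#'   connection id exactly once.
#' @param hemispheric_asymmetry_sd SD of the Gaussian jitter applied
#'   independently to the left and right generating target of each
#'   connection (clipped to `[0, 0.9]`); default 0.02 so hemisphere
#'   averaging is exercised nontrivially.
#' @param ar1 AR(1) coefficient of the latent series in `[0, 0.95]`;
#'   default 0 (temporally white). The stationary cross-sectional
#'   covariance is preserved for any value.
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(groups = default_cohort_groups(),
                        series_length = c(infant = 2300L, adult = 1200L),
                        growth_models = default_growth_models(),
                        hemispheric_asymmetry_sd = 0.02,
                        ar1 = 0,
                        seed = 1L) {
  groups <- as_tibble(groups)
  req <- c("label", "pma_min", "pma_max", "n", "adult")
  if (!all(req %in% names(groups))) {
    stop("groups must have columns ", paste(req, collapse = ", "))
  }
  if (nrow(groups) == 0L) stop("groups must contain at least one row")
  if (any(groups$n < 1L)) stop("every group needs n >= 1")
  inf <- !groups$adult
  if (any(inf & (is.na(groups$pma_min) | is.na(groups$pma_max) |
                   groups$pma_min >= groups$pma_max))) {
    stop("infant groups need pma_min < pma_max")
  }
  if (!all(c("infant", "adult") %in% names(series_length)) ||
      any(series_length < 50)) {
    stop("series_length must be named c(infant=, adult=) with values >= 50")
  }
  ids <- connection_index()$connection_id
  if (!setequal(names(growth_models), ids) ||
      length(growth_models) != length(ids)) {
    stop("growth_models must contain exactly one model per connection")
  }
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)")
  structure(
    list(groups = groups,
         series_length = vapply(series_length, as.integer, integer(1)),
         growth_models = growth_models[ids],
         hemispheric_asymmetry_sd = hemispheric_asymmetry_sd,
         ar1 = ar1,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Deterministic per-subject seed: a fixed multiplicative counter scheme on
# the master seed, kept inside the 32-bit integer range.
.subject_seed <- function(master, counter) {
  as.integer((as.double(master) * 1000003 + counter * 7919) %% 2147483647) + 1L
}

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate one subject's bilateral ROI time series
#'
#' Draws a `T x 24` zero-mean Gaussian series (left block then right block
#' of the 12 ROI types) whose per-hemisphere precision matrix realises the
#' growth-model targets at this subject's PMA (or the asymptotic adult
#' targets). Left and right targets are independently jittered by
#' `hemispheric_asymmetry_sd`; the two hemisphere blocks are generated
#' independently (block-diagonal precision), matching an analysis that only
#' uses within-hemisphere pairs. With `ar1 > 0` the series is an AR(1)
#' process with the same stationary cross-sectional covariance.
#'
#' RNG draw order under the subject seed is fixed (left jitter, right
#' jitter, postnatal age, sex, series innovations), so identical inputs are
#' bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @param pma Weeks PMA (ignored for adults).
#' @param seed Integer seed for this subject.
#' @param adult Logical; adults are generated at the asymptotic targets.
#' @param id Subject identifier.
#' @param group Group label carried into the record.
#' @return A list of class `subject_record` with fields `id`, `group`,
#'   `pma`, `pna`, `sex`, `adult`, `timeseries` (matrix with
#'   [ts_column_names()] columns) and `targets` (tibble of realised
#'   generating values: `connection_id`, `target_left`, `target_right`,
#'   `target`).
#' @export
simulate_subject <- function(spec, pma, seed, adult = FALSE,
                             id = "s1", group = NA_character_) {
  stopifnot(inherits(spec, "cohort_spec"))
  T_len <- unname(spec$series_length[if (adult) "adult" else "infant"])
  idx <- connection_index()
  base <- vapply(spec$growth_models, function(m) {
    if (adult) m$adult_target else growth_target(m, pma)
  }, numeric(1))

  set.seed(seed)
  jit_l <- rnorm(length(base), 0, spec$hemispheric_asymmetry_sd)
  jit_r <- rnorm(length(base), 0, spec$hemispheric_asymmetry_sd)
  t_l <- .clip(base + jit_l, 0, 0.9)
  t_r <- .clip(base + jit_r, 0, 0.9)
  pna <- if (adult) NA_real_ else round(runif(1, 0, 14), 1)
  sex <- sample(c("female", "male"), 1)

  S <- connection_sign_matrix()
  make_block <- function(tv) {
    M <- matrix(0, 12, 12, dimnames = list(roi_types(), roi_types()))
    for (i in seq_len(nrow(idx))) {
      M[idx$roi_a[i], idx$roi_b[i]] <- tv[i]
      M[idx$roi_b[i], idx$roi_a[i]] <- tv[i]
    }
    pb <- build_precision_matrix(M, signs = S)
    emin <- min(eigen(pb$precision, symmetric = TRUE,
                      only.values = TRUE)$values)
    if (emin <= 0) {
      stop("internal error: precision matrix not positive definite after ",
           "loading (min eigenvalue ", signif(emin, 3), ")")
    }
    pb
  }
  pb_l <- make_block(t_l)
  pb_r <- make_block(t_r)
  realized <- function(pb) {
    vapply(seq_len(nrow(idx)), function(i) {
      pb$realized_targets[idx$roi_a[i], idx$roi_b[i]]
    }, numeric(1))
  }
  r_l <- realized(pb_l)
  r_r <- realized(pb_r)

  draw_block <- function(pb) {
    Sigma <- chol2inv(chol(pb$precision))
    L <- chol(Sigma)
    Z <- matrix(rnorm(T_len * 12L), T_len, 12L)
    if (spec$ar1 > 0) {
      phi <- spec$ar1
      for (t in 2:T_len) {
        Z[t, ] <- phi * Z[t - 1L, ] + sqrt(1 - phi^2) * Z[t, ]
      }
    }
    Z %*% L
  }
  X <- cbind(draw_block(pb_l), draw_block(pb_r))
  colnames(X) <- ts_column_names()

  structure(
    list(id = id, group = group, pma = if (adult) NA_real_ else pma,
         pna = pna, sex = sex, adult = adult,
         timeseries = X,
         targets = tibble(connection_id = idx$connection_id,
                          target_left = r_l, target_right = r_r,
                          target = (r_l + r_r) / 2)),
    class = "subject_record"
  )
}

#' Simulate a full cohort
#'
#' Draws `n` subjects per group with PMA uniform within the group range
#' (adults at the asymptotic targets) and returns the subject records
#' together with their metadata and the per-subject generating targets.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort` with elements `subjects` (list of
#'   [simulate_subject()] records), `meta` (tibble: `id`, `group`, `pma`,
#'   `pna`, `sex`, `adult`) and `ground_truth` (tibble with one row per
#'   subject x connection: realised `target_left`, `target_right`,
#'   `target`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  grp <- spec$groups
  pma_list <- lapply(seq_len(nrow(grp)), function(g) {
    if (grp$adult[g]) rep(NA_real_, grp$n[g])
    else sort(runif(grp$n[g], grp$pma_min[g], grp$pma_max[g]))
  })
  counter <- 0L
  subjects <- list()
  for (g in seq_len(nrow(grp))) {
    for (k in seq_len(grp$n[g])) {
      counter <- counter + 1L
      id <- sprintf("sub-%04d", counter)
      subjects[[counter]] <- simulate_subject(
        spec, pma = pma_list[[g]][k],
        seed = .subject_seed(spec$seed, counter),
        adult = grp$adult[g], id = id, group = grp$label[g]
      )
    }
  }
  meta <- dplyr::bind_rows(lapply(subjects, function(s) {
    tibble(id = s$id, group = s$group, pma = s$pma, pna = s$pna,
           sex = s$sex, adult = s$adult)
  }))
  gt <- dplyr::bind_rows(lapply(subjects, function(s) {
    dplyr::mutate(s$targets, id = s$id, .before = 1)
  }))
  structure(list(subjects = subjects, meta = meta, ground_truth = gt),
            class = "cohort")
}

#' Write cohort tables to CSV
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param timeseries Also write one `T x 24` CSV per subject.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, timeseries = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(dir, "subjects.csv")
  gt_path <- file.path(dir, "ground_truth.csv")
  write.csv(cohort$meta, meta_path, row.names = FALSE)
  write.csv(cohort$ground_truth, gt_path, row.names = FALSE)
  paths <- c(meta_path, gt_path)
  if (timeseries) {
    ts_dir <- file.path(dir, "timeseries")
    dir.create(ts_dir, showWarnings = FALSE)
    for (s in cohort$subjects) {
      p <- file.path(ts_dir, paste0(s$id, ".csv"))
      write.csv(as.data.frame(s$timeseries), p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
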