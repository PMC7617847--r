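# Scaled-down cohort fixtures: same study conditions (PMA bins, full series
# lengths of 2300/1200 volumes) with smaller group sizes for test runtime.

scaled_groups <- function(n_infant = c(8L, 8L, 12L, 12L, 12L, 12L),
                          n_adult = 16L) {
  tibble::tibble(
    label = c("<32", "32-34", "34-36", "36-38", "38-40", "40-42", "adult"),
    pma_min = c(26, 32, 34, 36, 38, 40, NA),
    pma_max = c(32, 34, 36, 38, 40, 42, NA),
    n = c(n_infant, n_adult),
    adult = c(rep(FALSE, 6), TRUE)
  )
}

# A fully processed small cohort, memoised across tests in one session.
.cohort_cache <- new.env(parent = emptyenv())

processed_small_cohort <- function(seed = 42) {
  key <- paste0("seed", seed)
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  spec <- cohort_spec(groups = scaled_groups(), seed = seed)
  cohort <- simulate_cohort(spec)
  conn <- connection_table(cohort)
  qc <- apply_outlier_qc(conn)
  ref <- adult_reference_means(qc$table)
  normed <- normalize_connectome(qc$table, ref)
  pres <- presence_threshold(normed)
  res <- list(cohort = cohort, conn = conn, qc = qc, ref = ref,
              pres = pres)
  .cohort_cache[[key]] <- res
  res
}

# Hand-built per-subject summary tables (no simulation) for the
# statistical battery: one entry per group label, values become both
# metrics.
make_summaries <- function(group_values, scope = "all") {
  dplyr::bind_rows(lapply(names(group_values), function(g) {
    v <- group_values[[g]]
    adult <- g == "adult"
    pma <- if (adult) rep(NA_real_, length(v)) else
      rep(mean(switch(g, "<32" = c(26, 32), "32-34" = c(32, 34),
                      "34-36" = c(34, 36), "36-38" = c(36, 38),
                      "38-40" = c(38, 40), "40-42" = c(40, 42))),
          length(v))
    adult_vec <- rep(adult, length(v))
    tibble::tibble(
      id = paste0(g, "_", seq_along(v)), group = g, pma = pma,
      adult = adult_vec, age_bin = assign_age_bin(pma, adult_vec),
      scope = scope, n_nonmissing = 66L,
      n_present = round(v * 66), proportion_present = v,
      mean_log_strength = v
    )
  }))
}

# Minimal valid normalized table built by hand (no simulation), for unit
# tests of the summary and presence logic.
hand_norm_table <- function(r_norm, present = r_norm > 0,
                            id = "s1", pma = 40, adult = FALSE) {
  idx <- connection_index()
  stopifnot(length(r_norm) == 66)
  tibble::tibble(
    id = id, group = ifelse(adult, "adult", "40-42"),
    pma = ifelse(adult, NA_real_, pma), adult = adult,
    connection_id = idx$connection_id,
    r = abs(r_norm), qc_keep = !is.na(r_norm),
    r_norm = r_norm, present = ifelse(is.na(r_norm), NA, present)
  )
}
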