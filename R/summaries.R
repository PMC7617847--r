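#' Assign PMA age bins
#'
#' Bins infants at <32, [32,34), [34,36), [36,38), [38,40) and [40,42]
#' weeks PMA (half-open on the left, last bin closed at 42) and labels
#' adults `"adult"`. The returned factor puts `"adult"` first so it is the
#' reference level in many-to-one comparisons.
#'
#' @param pma Numeric PMA vector (NA for adults).
#' @param adult Logical vector.
#' @return Factor with levels `adult, <32, 32-34, ..., 40-42`.
#' @export
assign_age_bin <- function(pma, adult) {
  if (length(pma) != length(adult)) {
    stop("pma and adult must have the same length")
  }
  labs <- c("<32", "32-34", "34-36", "36-38", "38-40", "40-42")
  bin <- rep(NA_character_, length(pma))
  bin[adult] <- "adult"
  inf <- !adult & !is.na(pma)
  br <- c(-Inf, 32, 34, 36, 38, 40, 42)
  ix <- findInterval(pma[inf], br, left.open = FALSE, rightmost.closed = TRUE)
  ix[pma[inf] >= 42] <- pmin(ix[pma[inf] >= 42], 6L)
  bin[inf] <- labs[ix]
  factor(bin, levels = c("adult", labs))
}

#' Per-subject connectome summary metrics
#'
#' For each subject, within the chosen scope (all 66 connections or one
#' subnetwork's connection list), computes the proportion of present
#' connections (present / non-missing) and the mean log10 normalised
#' strength over present connections only (absent connections would make
#' the log diverge; restricting the average to present connections matches
#' a strength-of-present-connections reading). Subjects with zero
#' non-missing connections in scope get missing metrics; zero present
#' connections gives a missing strength.
#'
#' @param norm Presence-called table (`table` element of
#'   [presence_threshold()]).
#' @param scope `"all"` or a subnetwork name.
#' @return Tibble: `id`, `group`, `pma`, `adult`, `age_bin`, `scope`,
#'   `n_nonmissing`, `n_present`, `proportion_present`,
#'   `mean_log_strength`.
#' @export
subject_summary <- function(norm, scope = "all") {
  if (!"present" %in% names(norm)) {
    stop("presence has not been called; run presence_threshold() first")
  }
  if (!identical(scope, "all")) {
    def <- subnetwork_definition(scope)
    norm <- dplyr::filter(norm, .data$connection_id %in% def$connections)
  }
  out <- dplyr::summarise(
    dplyr::group_by(norm, .data$id, .data$group, .data$pma, .data$adult),
    n_nonmissing = sum(!is.na(.data$r_norm)),
    n_present = sum(.data$present %in% TRUE),
    proportion_present = ifelse(.data$n_nonmissing > 0,
                                .data$n_present / .data$n_nonmissing,
                                NA_real_),
    mean_log_strength = ifelse(
      .data$n_present > 0,
      mean(log10(.data$r_norm[.data$present %in% TRUE])),
      NA_real_),
    .groups = "drop"
  )
  out$age_bin <- assign_age_bin(out$pma, out$adult)
  out$scope <- scope
  dplyr::relocate(out, "age_bin", "scope", .after = "adult")
}

#' Per-subject summaries for every subnetwork
#'
#' One row per subject per subnetwork (three rows per subject), the layout
#' consumed by [subnetwork_anova()].
#'
#' @param norm Presence-called table.
#' @return Tibble like [subject_summary()] with `scope` in
#'   `sensory`/`affective`/`cognitive`.
#' @export
subject_subnetwork_summaries <- function(norm) {
  dplyr::bind_rows(lapply(subnetwork_names(), function(nm) {
    subject_summary(norm, scope = nm)
  }))
}

#' Per-connection group maps
#'
#' For each age bin and connection: the share of subjects in which the
#' connection is present, and the mean normalised strength over subjects
#' in which it is present.
#'
#' @param norm Presence-called table.
#' @return Tibble: `age_bin`, `connection_id`, `n_subjects`,
#'   `share_present`, `mean_strength`.
#' @export
connection_maps <- function(norm) {
  norm$age_bin <- assign_age_bin(norm$pma, norm$adult)
  dplyr::summarise(
    dplyr::group_by(norm, .data$age_bin, .data$connection_id),
    n_subjects = sum(!is.na(.data$r_norm)),
    share_present = ifelse(.data$n_subjects > 0,
                           sum(.data$present %in% TRUE) / .data$n_subjects,
                           NA_real_),
    mean_strength = ifelse(sum(.data$present %in% TRUE) > 0,
                           mean(.data$r_norm[.data$present %in% TRUE]),
                           NA_real_),
    .groups = "drop"
  )
}
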