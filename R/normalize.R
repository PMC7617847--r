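#' Cook's-distance screen for infant connectivity values
#'
#' Fits ordinary least squares `value ~ intercept + PMA` for one connection
#' across infants and flags points whose Cook's distance exceeds 3 times
#' the average Cook's distance (strict inequality; ties survive). Because
#' connectivity rises steeply with PMA over this period, an age-blind
#' z-screen would flag legitimate young or old subjects; screening against
#' the age trend targets genuinely spurious values.
#'
#' @param values Numeric vector of absolute partial correlations (may
#'   contain `NA`).
#' @param pma Matching PMA vector (weeks).
#' @return A list with `keep` (logical, `NA` positions stay `NA`),
#'   `cooks` (distances, `NA` where the value was missing) and
#'   `threshold` (`3 * mean(D)`). With fewer than 4 complete pairs no
#'   discarding is done and a warning is raised.
#' @export
infant_outlier_mask <- function(values, pma) {
  if (length(values) != length(pma)) stop("values and pma lengths differ")
  ok <- !is.na(values) & !is.na(pma)
  keep <- rep(NA, length(values))
  cooks <- rep(NA_real_, length(values))
  if (sum(ok) < 4L) {
    warning("fewer than 4 complete points; no outlier screening applied")
    keep[ok] <- TRUE
    return(list(keep = keep, cooks = cooks, threshold = NA_real_))
  }
  fit <- lm(values[ok] ~ pma[ok])
  if (sum(residuals(fit)^2) <= 1e-18 * max(sum(values[ok]^2), 1)) {
    # degenerate perfect fit: every distance is zero, everything is kept
    cooks[ok] <- 0
    keep[ok] <- TRUE
    return(list(keep = keep, cooks = cooks, threshold = 0))
  }
  D <- cooks.distance(fit)
  thr <- 3 * mean(D)
  cooks[ok] <- D
  keep[ok] <- D <= thr
  list(keep = keep, cooks = cooks, threshold = thr)
}

#' 3-SD screen for adult connectivity values
#'
#' Flags values deviating from the connection mean by more than 3 sample
#' standard deviations (single pass, strict inequality; values at exactly
#' mean +- 3 SD survive). Zero variance keeps everything.
#'
#' @param values Numeric vector (may contain `NA`).
#' @return Logical keep-mask (`NA` positions stay `NA`).
#' @export
adult_outlier_mask <- function(values) {
  ok <- !is.na(values)
  keep <- rep(NA, length(values))
  if (sum(ok) < 3L) {
    warning("fewer than 3 values; no outlier screening applied")
    keep[ok] <- TRUE
    return(keep)
  }
  m <- mean(values[ok])
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) {
    keep[ok] <- TRUE
  } else {
    keep[ok] <- abs(values[ok] - m) <= 3 * s
  }
  keep
}

#' Apply both outlier screens across a cohort connection table
#'
#' Per connection: infants are screened with the Cook's-distance rule
#' against the PMA trend ([infant_outlier_mask()]), adults with the 3-SD
#' rule ([adult_outlier_mask()]). Discarded values are marked missing for
#' every downstream stage — never imputed, never zeroed.
#'
#' @param conn Long tibble from [connection_table()].
#' @return A list with `table` (input plus logical `qc_keep` and numeric
#'   `qc_stat`) and `report` (an outlier report: overall infant/adult
#'   discard fractions, per-connection counts, and one record per discard).
#' @export
apply_outlier_qc <- function(conn) {
  req <- c("id", "adult", "pma", "connection_id", "r")
  if (!all(req %in% names(conn))) {
    stop("connection table needs columns ", paste(req, collapse = ", "))
  }
  conn <- dplyr::arrange(conn, .data$connection_id, .data$adult, .data$id)
  out <- dplyr::group_modify(
    dplyr::group_by(conn, .data$connection_id),
    function(df, key) {
      df$qc_keep <- NA
      df$qc_stat <- NA_real_
      inf <- !df$adult
      if (any(inf)) {
        m <- infant_outlier_mask(df$r[inf], df$pma[inf])
        df$qc_keep[inf] <- m$keep
        df$qc_stat[inf] <- m$cooks
      }
      if (any(df$adult)) {
        va <- df$r[df$adult]
        df$qc_keep[df$adult] <- adult_outlier_mask(va)
        ma <- mean(va, na.rm = TRUE); sa <- sd(va, na.rm = TRUE)
        df$qc_stat[df$adult] <- if (is.finite(sa) && sa > 0) abs(va - ma) / sa else 0
      }
      df
    }
  ) |> dplyr::ungroup()

  disc <- dplyr::filter(out, !is.na(.data$qc_keep) & !.data$qc_keep)
  frac <- function(adult_flag) {
    pool <- dplyr::filter(out, .data$adult == adult_flag, !is.na(.data$r))
    if (nrow(pool) == 0) return(NA_real_)
    sum(!pool$qc_keep, na.rm = TRUE) / nrow(pool)
  }
  per_conn <- dplyr::summarise(
    dplyr::group_by(out, .data$connection_id),
    n_infant_discarded = sum(!.data$qc_keep & !.data$adult, na.rm = TRUE),
    n_adult_discarded = sum(!.data$qc_keep & .data$adult, na.rm = TRUE),
    .groups = "drop"
  )
  report <- list(
    infant_discard_fraction = frac(FALSE),
    adult_discard_fraction = frac(TRUE),
    per_connection = per_conn,
    records = disc[, c("id", "connection_id", "r", "qc_stat", "adult")]
  )
  list(table = out, report = report)
}

#' Adult reference means per connection
#'
#' Arithmetic mean of the surviving (post-QC) adult absolute partial
#' correlations for each connection; the denominator of the adult-likeness
#' normalisation.
#'
#' @param conn_qc QC'd connection table (output `table` of
#'   [apply_outlier_qc()], or any table with `adult`, `connection_id`, `r`
#'   and optionally `qc_keep`).
#' @return A tibble of class `adult_reference`: `connection_id`, `r_ca`
#'   (mean), `n_adult` (survivors used).
#' @export
adult_reference_means <- function(conn_qc) {
  if (!"qc_keep" %in% names(conn_qc)) conn_qc$qc_keep <- TRUE
  ad <- dplyr::filter(conn_qc, .data$adult,
                      !is.na(.data$r), .data$qc_keep %in% TRUE)
  ref <- dplyr::summarise(
    dplyr::group_by(ad, .data$connection_id),
    r_ca = mean(.data$r), n_adult = dplyr::n(), .groups = "drop"
  )
  all_ids <- connection_index()$connection_id
  missing <- setdiff(all_ids, ref$connection_id)
  if (length(missing) > 0) {
    stop("no surviving adult values for connection(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(ref$r_ca <= 0)) {
    stop("adult reference mean must be positive for every connection")
  }
  ref <- ref[match(all_ids, ref$connection_id), ]
  class(ref) <- c("adult_reference", class(ref))
  ref
}

#' Normalise connection strengths by the adult reference
#'
#' Divides each (subject, connection) absolute partial correlation by the
#' adult mean for that connection, yielding the degree of adult-like
#' connectivity (`r_norm`, 1 = adult-like). QC-discarded values propagate
#' as missing.
#'
#' @param conn_qc QC'd connection table.
#' @param ref An [adult_reference_means()] table.
#' @return The table with columns `r_norm` (NA where QC-discarded) added.
#' @export
normalize_connectome <- function(conn_qc, ref) {
  stopifnot(inherits(ref, "adult_reference"))
  if (!"qc_keep" %in% names(conn_qc)) conn_qc$qc_keep <- TRUE
  out <- dplyr::left_join(conn_qc,
                          ref[, c("connection_id", "r_ca")],
                          by = "connection_id")
  out$r_norm <- ifelse(!is.na(out$r) & out$qc_keep %in% TRUE,
                       out$r / out$r_ca, NA_real_)
  out
}

#' Call connection presence against the thalamus-SI reference
#'
#' The presence threshold is the mean normalised strength of the
#' thalamus-SI connection across the reference group (infants below
#' `reference_max_pma` weeks PMA), a connection known to be functional
#' already at that age. Every `r_norm` strictly below the threshold is set
#' to 0 and marked absent — in every subject of every group, adults
#' included; values at exactly the threshold stay present.
#'
#' @param norm Normalised connection table from [normalize_connectome()].
#' @param reference_connection Connection id (default `"thalamus-SI"`).
#' @param reference_max_pma Upper PMA bound of the reference group
#'   (default 32 weeks, strict).
#' @return A list with `threshold` (scalar) and `table` (input with
#'   `r_norm` zeroed where absent and logical `present` added; `present`
#'   is `NA` where the value is missing).
#' @export
presence_threshold <- function(norm, reference_connection = "thalamus-SI",
                               reference_max_pma = 32) {
  ref_vals <- norm$r_norm[!norm$adult & !is.na(norm$pma) &
                            norm$pma < reference_max_pma &
                            norm$connection_id == reference_connection]
  ref_vals <- ref_vals[!is.na(ref_vals)]
  if (length(ref_vals) == 0) {
    stop("reference group (infants < ", reference_max_pma,
         " weeks PMA) has no non-missing ", reference_connection, " value")
  }
  thr <- mean(ref_vals)
  absent <- !is.na(norm$r_norm) & norm$r_norm < thr
  norm$r_norm[absent] <- 0
  norm$present <- ifelse(is.na(norm$r_norm), NA, norm$r_norm > 0)
  list(threshold = thr, table = norm)
}
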