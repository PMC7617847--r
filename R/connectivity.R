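#' Pearson partial correlation matrix
#'
#' Entry (i, j) is the correlation between the residuals of columns i and j
#' after linear regression on all remaining columns; computed here through
#' the inverse of the column correlation matrix,
#' `-P_ij / sqrt(P_ii P_jj)`. No regularisation is applied: an
#' ill-conditioned correlation matrix is an error, not a silent ridge fit.
#'
#' @param ts Numeric `T x k` matrix with `T > k + 2`.
#' @param max_condition Condition-number guard on the correlation matrix
#'   (default `1e12`).
#' @return Symmetric `k x k` matrix with unit diagonal.
#' @export
partial_correlation_matrix <- function(ts, max_condition = 1e12) {
  ts <- as.matrix(ts)
  k <- ncol(ts)
  if (nrow(ts) <= k + 2) stop("need T > k + 2 time points")
  if (anyNA(ts)) stop("time series contains missing values")
  v <- apply(ts, 2, var)
  if (any(v == 0)) {
    bad <- colnames(ts)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  C <- cor(ts)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
    stop("correlation matrix is singular or ill-conditioned ",
         "(condition number > ", format(max_condition), ")")
  }
  P <- chol2inv(chol(C))
  d <- sqrt(diag(P))
  pc <- -P / outer(d, d)
  diag(pc) <- 1
  dimnames(pc) <- list(colnames(ts), colnames(ts))
  (pc + t(pc)) / 2
}

#' Hemisphere-averaged absolute partial correlations for one subject
#'
#' Computes the 66-entry connection vector: absolute Pearson partial
#' correlations between the 12 ROI types, with the absolute value taken
#' before the two homologous hemisphere values are averaged. Under the
#' default `per_hemisphere` conditioning, a 12 x 12 partial-correlation
#' matrix is computed separately within each hemisphere's 12 columns; under
#' `joint`, one 24 x 24 matrix conditions each pair on all other 22 regions
#' before homologous averaging. Cross-hemisphere pairs are never emitted.
#'
#' @param ts `T x 24` matrix with [ts_column_names()] columns, a
#'   `roi_timeseries`, or a `subject_record`.
#' @param conditioning `"per_hemisphere"` (default) or `"joint"`.
#' @param subject_id Identifier attached to the rows (taken from the input
#'   object when available).
#' @return Tibble with one row per connection: `id`, `connection_id`,
#'   `left`, `right` (absolute values) and `r` (their mean, in `[0, 1]`).
#' @export
connection_vector <- function(ts,
                              conditioning = c("per_hemisphere", "joint"),
                              subject_id = NULL) {
  conditioning <- match.arg(conditioning)
  if (inherits(ts, "subject_record")) {
    if (is.null(subject_id)) subject_id <- ts$id
    ts <- ts$timeseries
  } else if (inherits(ts, "roi_timeseries")) {
    if (is.null(subject_id)) subject_id <- ts$id
    ts <- ts$matrix
  }
  if (is.null(subject_id)) subject_id <- "s1"
  ts <- as.matrix(ts)
  cols <- ts_column_names()
  if (!all(cols %in% colnames(ts))) {
    stop("time-series matrix must have all 24 columns ",
         "(<roi>_L, <roi>_R in canonical order)")
  }
  ts <- ts[, cols]
  rois <- roi_types()
  idx <- connection_index()

  if (conditioning == "per_hemisphere") {
    pc_l <- partial_correlation_matrix(ts[, paste0(rois, "_L")])
    pc_r <- partial_correlation_matrix(ts[, paste0(rois, "_R")])
    colnames(pc_l) <- rownames(pc_l) <- rois
    colnames(pc_r) <- rownames(pc_r) <- rois
  } else {
    pc <- partial_correlation_matrix(ts)
    pc_l <- pc[paste0(rois, "_L"), paste0(rois, "_L")]
    pc_r <- pc[paste0(rois, "_R"), paste0(rois, "_R")]
    colnames(pc_l) <- rownames(pc_l) <- rois
    colnames(pc_r) <- rownames(pc_r) <- rois
  }
  left <- abs(pc_l[cbind(idx$roi_a, idx$roi_b)])
  right <- abs(pc_r[cbind(idx$roi_a, idx$roi_b)])
  tibble(id = subject_id,
         connection_id = idx$connection_id,
         left = left, right = right,
         r = (left + right) / 2)
}

#' Connection table for a whole cohort
#'
#' Applies [connection_vector()] to every subject and binds the results
#' with the subject metadata.
#'
#' @param cohort A [simulate_cohort()] result, or a list of
#'   `subject_record`/`roi_timeseries` objects plus a `meta` tibble.
#' @param conditioning Passed to [connection_vector()].
#' @return Long tibble: `id`, `group`, `pma`, `adult`, `connection_id`,
#'   `left`, `right`, `r`.
#' @export
connection_table <- function(cohort,
                             conditioning = c("per_hemisphere", "joint")) {
  conditioning <- match.arg(conditioning)
  stopifnot(inherits(cohort, "cohort"))
  if (anyDuplicated(cohort$meta$id)) {
    stop("duplicate subject ids in cohort: ",
         paste(unique(cohort$meta$id[duplicated(cohort$meta$id)]),
               collapse = ", "))
  }
  vecs <- dplyr::bind_rows(lapply(cohort$subjects, connection_vector,
                                  conditioning = conditioning))
  dplyr::left_join(vecs,
                   cohort$meta[, c("id", "group", "pma", "adult")],
                   by = "id") |>
    dplyr::relocate("group", "pma", "adult", .after = "id")
}
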