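.known_config_keys <- c(
  "mode", "seed", "out_dir", "conditioning", "fdr_family",
  "use_log_strength", "presence", "groups", "series_length",
  "hemispheric_asymmetry_sd", "ar1", "term_bin",
  "bold_dir", "atlas_image", "atlas_table", "gm_mask", "subject_table",
  "min_voxels", "gm_threshold"
)
.known_presence_keys <- c("reference_connection", "reference_max_pma")

#' Build a validated run configuration
#'
#' A single configuration drives the whole pipeline; unknown keys are
#' rejected before any computation. In `synthetic` mode the cohort is
#' generated; in `real` mode per-subject NIfTI images are extracted using
#' a shared atlas and gray-matter mask.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param seed Master seed.
#' @param out_dir Output directory for all artifacts.
#' @param ... Optional keys: `conditioning` (`"per_hemisphere"`/`"joint"`),
#'   `fdr_family` (`"subnetwork"`/`"all"`), `use_log_strength` (logical),
#'   `presence` (list with `reference_connection`, `reference_max_pma`),
#'   `term_bin`, and, per mode: synthetic — `groups` (data frame like
#'   [default_cohort_groups()]), `series_length`,
#'   `hemispheric_asymmetry_sd`, `ar1`; real — `bold_dir`, `atlas_image`,
#'   `atlas_table`, `gm_mask`, `subject_table`, `min_voxels`,
#'   `gm_threshold`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), seed = 1L,
                       out_dir = tempfile("painconn_run_"), ...) {
  mode <- match.arg(mode)
  extra <- list(...)
  unknown <- setdiff(names(extra), .known_config_keys)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- list(
    mode = mode, seed = as.integer(seed), out_dir = out_dir,
    conditioning = "per_hemisphere", fdr_family = "subnetwork",
    use_log_strength = FALSE, term_bin = "40-42",
    presence = list(reference_connection = "thalamus-SI",
                    reference_max_pma = 32),
    groups = NULL, series_length = c(infant = 2300L, adult = 1200L),
    hemispheric_asymmetry_sd = 0.02, ar1 = 0,
    bold_dir = NULL, atlas_image = NULL, atlas_table = NULL,
    gm_mask = NULL, subject_table = NULL,
    min_voxels = 1L, gm_threshold = 0.5
  )
  if ("presence" %in% names(extra)) {
    unknown_p <- setdiff(names(extra$presence), .known_presence_keys)
    if (length(unknown_p) > 0) {
      stop("unknown presence key(s): ", paste(unknown_p, collapse = ", "))
    }
    cfg$presence[names(extra$presence)] <- extra$presence
    extra$presence <- NULL
  }
  cfg[names(extra)] <- extra
  cfg$conditioning <- match.arg(cfg$conditioning,
                                c("per_hemisphere", "joint"))
  cfg$fdr_family <- match.arg(cfg$fdr_family, c("subnetwork", "all"))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File ending in `.yaml`/`.yml` or `.json`.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("config must be .yaml/.yml or .json")
  }
  if (!is.null(raw$groups)) raw$groups <- as_tibble(raw$groups)
  if (!is.null(raw$series_length)) {
    raw$series_length <- unlist(raw$series_length)
  }
  do.call(run_config, raw)
}

#' Validate configuration inputs without running anything
#'
#' Checks file existence (real mode), subject-table schema and infant PMA
#' ranges (26-42 weeks), and group-table sanity (synthetic mode). All
#' problems are reported at once; nothing is thrown.
#'
#' @param config A [run_config()].
#' @return Character vector of problems (length 0 when fully valid).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- character()
  if (config$mode == "real") {
    for (key in c("atlas_image", "atlas_table", "gm_mask", "subject_table")) {
      p <- config[[key]]
      if (is.null(p)) {
        problems <- c(problems, paste0("real mode requires ", key))
      } else if (!file.exists(p)) {
        problems <- c(problems, paste0(key, " not found: ", p))
      }
    }
    st <- config$subject_table
    if (!is.null(st) && file.exists(st)) {
      tab <- read.csv(st, stringsAsFactors = FALSE)
      req <- c("id", "group", "pma", "pna", "sex", "adult", "bold_path")
      miss <- setdiff(req, names(tab))
      if (length(miss) > 0) {
        problems <- c(problems, paste0("subject table missing column(s): ",
                                       paste(miss, collapse = ", ")))
      }
      if (all(c("pma", "adult") %in% names(tab))) {
        inf <- tab[!tab$adult, ]
        bad <- inf$id[!is.na(inf$pma) & (inf$pma < 26 | inf$pma > 42)]
        if (length(bad) > 0) {
          problems <- c(problems,
                        paste0("infant PMA out of 26-42 week range: ",
                               paste(bad, collapse = ", ")))
        }
      }
      if (!is.null(config$bold_dir) && "bold_path" %in% names(tab)) {
        paths <- file.path(config$bold_dir, tab$bold_path)
        gone <- paths[!file.exists(paths)]
        if (length(gone) > 0) {
          problems <- c(problems, paste0("BOLD image not found: ",
                                         paste(gone, collapse = ", ")))
        }
      }
    }
  } else {
    groups <- if (is.null(config$groups)) default_cohort_groups() else config$groups
    ok <- tryCatch({
      cohort_spec(groups = groups, series_length = config$series_length,
                  hemispheric_asymmetry_sd = config$hemispheric_asymmetry_sd,
                  ar1 = config$ar1, seed = config$seed)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) problems <- c(problems, paste0("cohort spec: ", ok))
    inf <- groups[!groups$adult, ]
    bad <- inf$label[!is.na(inf$pma_min) &
                       (inf$pma_min < 26 | inf$pma_max > 42)]
    if (length(bad) > 0) {
      problems <- c(problems, paste0("infant group outside 26-42 weeks PMA: ",
                                     paste(bad, collapse = ", ")))
    }
  }
  problems
}

.write_table <- function(x, dir, name) {
  p <- file.path(dir, name)
  write.csv(as.data.frame(x), p, row.names = FALSE)
  p
}

#' Run the full pipeline
#'
#' Executes simulate/extract, connect, QC, normalise, presence and the
#' statistics battery in order, writing every intermediate table plus a
#' manifest recording the configuration, the seed, the stage decisions and
#' MD5 hashes of all outputs. Identical configuration and seed give
#' byte-identical primary tables.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results (`cohort` or
#'   `extracted`, `connections`, `qc`, `reference`, `threshold`,
#'   `normalized`, `summaries`, `stats`) and `paths` of written files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_inputs(config)
  if (length(problems) > 0) {
    stop("invalid inputs:\n  ", paste(problems, collapse = "\n  "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  counts <- list()

  if (config$mode == "synthetic") {
    groups <- if (is.null(config$groups)) default_cohort_groups() else config$groups
    spec <- cohort_spec(groups = groups,
                        series_length = config$series_length,
                        hemispheric_asymmetry_sd = config$hemispheric_asymmetry_sd,
                        ar1 = config$ar1, seed = config$seed)
    cohort <- simulate_cohort(spec)
    paths <- c(paths, .write_table(cohort$meta, config$out_dir, "subjects.csv"))
    paths <- c(paths, .write_table(cohort$ground_truth, config$out_dir,
                                   "ground_truth.csv"))
    message("stage simulate: ", nrow(cohort$meta), " subjects")
  } else {
    cohort <- .extract_real_cohort(config)
    paths <- c(paths, .write_table(cohort$meta, config$out_dir, "subjects.csv"))
    message("stage extract: ", nrow(cohort$meta), " subjects")
  }
  counts$n_subjects <- nrow(cohort$meta)

  conn <- connection_table(cohort, conditioning = config$conditioning)
  paths <- c(paths, .write_table(conn, config$out_dir, "connections.csv"))
  message("stage connect: ", nrow(conn), " connection values")

  qc <- apply_outlier_qc(conn)
  counts$infant_discard_fraction <- qc$report$infant_discard_fraction
  counts$adult_discard_fraction <- qc$report$adult_discard_fraction
  jsonlite::write_json(
    list(infant_discard_fraction = qc$report$infant_discard_fraction,
         adult_discard_fraction = qc$report$adult_discard_fraction,
         per_connection = qc$report$per_connection,
         records = qc$report$records),
    file.path(config$out_dir, "qc_report.json"),
    auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, file.path(config$out_dir, "qc_report.json"))
  message("stage qc: infant discard ",
          sprintf("%.2f%%", 100 * qc$report$infant_discard_fraction),
          ", adult discard ",
          sprintf("%.2f%%", 100 * qc$report$adult_discard_fraction))

  ref <- adult_reference_means(qc$table)
  normed <- normalize_connectome(qc$table, ref)
  pres <- presence_threshold(
    normed,
    reference_connection = config$presence$reference_connection,
    reference_max_pma = config$presence$reference_max_pma)
  counts$presence_threshold <- pres$threshold
  jsonlite::write_json(
    list(presence_threshold = pres$threshold, adult_reference = ref),
    file.path(config$out_dir, "reference.json"),
    auto_unbox = TRUE, digits = NA)
  paths <- c(paths, file.path(config$out_dir, "reference.json"))
  paths <- c(paths, .write_table(pres$table, config$out_dir, "normalized.csv"))
  message("stage normalize: presence threshold ",
          signif(pres$threshold, 4))

  summaries <- subject_summary(pres$table, scope = "all")
  subnet <- subject_subnetwork_summaries(pres$table)
  paths <- c(paths, .write_table(summaries, config$out_dir,
                                 "subject_summaries.csv"))
  paths <- c(paths, .write_table(subnet, config$out_dir,
                                 "subnetwork_summaries.csv"))

  reg <- dplyr::bind_rows(fit_pma_regression(summaries, "proportion"),
                          fit_pma_regression(summaries, "strength"))
  dun <- dplyr::bind_rows(
    dplyr::mutate(groups_vs_adult(summaries, "proportion",
                                  seed = config$seed),
                  metric = "proportion", .before = 1),
    dplyr::mutate(groups_vs_adult(summaries, "strength",
                                  seed = config$seed),
                  metric = "strength", .before = 1))
  anv_p <- subnetwork_anova(subnet, "proportion")
  anv_s <- subnetwork_anova(subnet, "strength")
  ct <- connection_level_tests(pres$table, term_bin = config$term_bin,
                               family = config$fdr_family,
                               use_log = config$use_log_strength)
  maps <- connection_maps(pres$table)

  paths <- c(paths, .write_table(reg, config$out_dir, "regression.csv"))
  paths <- c(paths, .write_table(dun, config$out_dir, "dunnett.csv"))
  anova_tbl <- dplyr::bind_rows(
    dplyr::mutate(anv_p$anova, metric = "proportion", .before = 1),
    dplyr::mutate(anv_s$anova, metric = "strength", .before = 1))
  paths <- c(paths, .write_table(anova_tbl, config$out_dir, "anova.csv"))
  tukey_tbl <- dplyr::bind_rows(
    dplyr::mutate(anv_p$tukey_subnetwork_within_age,
                  metric = "proportion", slice = "subnetwork_within_age",
                  .before = 1),
    dplyr::mutate(anv_p$tukey_age_within_subnetwork,
                  metric = "proportion", slice = "age_within_subnetwork",
                  .before = 1),
    dplyr::mutate(anv_s$tukey_subnetwork_within_age,
                  metric = "strength", slice = "subnetwork_within_age",
                  .before = 1),
    dplyr::mutate(anv_s$tukey_age_within_subnetwork,
                  metric = "strength", slice = "age_within_subnetwork",
                  .before = 1))
  paths <- c(paths, .write_table(tukey_tbl, config$out_dir, "tukey.csv"))
  paths <- c(paths, .write_table(ct$tests, config$out_dir,
                                 "connection_tests.csv"))
  paths <- c(paths, .write_table(ct$tallies, config$out_dir, "tallies.csv"))
  paths <- c(paths, .write_table(maps, config$out_dir, "connection_maps.csv"))
  message("stage stats: written")

  cfg_for_hash <- unclass(config)
  cfg_for_hash$groups <- if (is.null(config$groups)) "default" else
    as.data.frame(config$groups)
  manifest <- list(
    config = cfg_for_hash,
    seed = config$seed,
    decisions = list(conditioning = config$conditioning,
                     fdr_family = config$fdr_family,
                     use_log_strength = config$use_log_strength,
                     presence = config$presence,
                     qc = "infant Cook>3*mean vs PMA trend; adult |dev|>3*SD",
                     boundary = "strict inequalities; ties survive"),
    counts = counts,
    outputs = as.list(tools::md5sum(sort(paths)))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)

  invisible(list(
    cohort = cohort, connections = conn, qc = qc, reference = ref,
    threshold = pres$threshold, normalized = pres$table,
    summaries = summaries, subnetwork_summaries = subnet,
    stats = list(regression = reg, dunnett = dun,
                 anova_proportion = anv_p, anova_strength = anv_s,
                 connection_tests = ct, maps = maps),
    paths = c(paths, manifest_path)
  ))
}

# Real-data mode: read the subject table, extract each subject's ROI series
# from its 4D image with the shared atlas and gray-matter mask, and shape
# the result like a simulated cohort.
.extract_real_cohort <- function(config) {
  tab <- read.csv(config$subject_table, stringsAsFactors = FALSE)
  atlas <- load_atlas(config$atlas_image, config$atlas_table)
  gm <- as.array(RNifti::readNifti(config$gm_mask))
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    bold <- file.path(config$bold_dir, tab$bold_path[i])
    ts <- extract_roi_timeseries(bold, atlas, gm,
                                 min_voxels = config$min_voxels,
                                 gm_threshold = config$gm_threshold,
                                 subject_id = tab$id[i])
    structure(list(id = tab$id[i], group = tab$group[i],
                   pma = if (tab$adult[i]) NA_real_ else tab$pma[i],
                   pna = tab$pna[i], sex = tab$sex[i],
                   adult = tab$adult[i], timeseries = ts$matrix,
                   voxel_counts = ts$voxel_counts),
              class = "subject_record")
  })
  meta <- tibble(id = tab$id, group = tab$group,
                 pma = ifelse(tab$adult, NA_real_, tab$pma),
                 pna = tab$pna, sex = tab$sex, adult = tab$adult)
  structure(list(subjects = subjects, meta = meta, ground_truth = NULL),
            class = "cohort")
}
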