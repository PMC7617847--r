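#' The 12 pain-connectome region types
#'
#' Ordered list of the bilateral regions of interest making up the pain
#' connectome: thalamus, primary and secondary somatosensory cortices (SI,
#' SII), anterior and posterior insula (aI, pI), anterior and mid-cingulate
#' cortices (ACC, MCC), amygdala, basal ganglia (BG), orbitofrontal cortex
#' (OFC), and ventrolateral and dorsolateral prefrontal cortices (vlPFC,
#' dlPFC). This ordering is canonical throughout the package: connection
#' identifiers and time-series columns follow it.
#'
#' @return Character vector of length 12.
#' @export
roi_types <- function() {
  c("thalamus", "SI", "SII", "aI", "pI", "ACC", "MCC",
    "amygdala", "BG", "OFC", "vlPFC", "dlPFC")
}

#' Hemisphere labels
#'
#' @return Character vector `c("L", "R")`.
#' @export
hemispheres <- function() c("L", "R")

#' Time-series column names for a 24-region bilateral matrix
#'
#' Columns are ordered left-hemisphere block first (the 12 ROI types in
#' [roi_types()] order, suffixed `_L`), then the right-hemisphere block
#' (`_R`).
#'
#' @return Character vector of length 24.
#' @export
ts_column_names <- function() {
  c(paste0(roi_types(), "_L"), paste0(roi_types(), "_R"))
}

#' Canonical connection identifier for an ROI pair
#'
#' Pairs are unordered; the identifier always lists the ROI that comes first
#' in [roi_types()] order first, joined by `-` (e.g. `"thalamus-SI"`).
#'
#' @param a,b Character vectors of ROI type names.
#' @return Character vector of connection identifiers.
#' @export
connection_id <- function(a, b) {
  ord <- roi_types()
  ia <- match(a, ord)
  ib <- match(b, ord)
  if (anyNA(ia) || anyNA(ib)) {
    stop("Unknown ROI type: ",
         paste(unique(c(a[is.na(ia)], b[is.na(ib)])), collapse = ", "))
  }
  if (any(ia == ib)) stop("Self-pairs are not connections")
  ifelse(ia < ib, paste(a, b, sep = "-"), paste(b, a, sep = "-"))
}

#' Index of the 66 pain-connectome connections
#'
#' All unordered pairs of the 12 ROI types, in lexicographic order of the
#' canonical ROI ordering. This is the fixed row index used by every
#' connection-keyed table in the package.
#'
#' @return A tibble with columns `connection_id`, `roi_a`, `roi_b`
#'   (66 rows; `roi_a` precedes `roi_b` in [roi_types()] order).
#' @export
connection_index <- function() {
  pr <- combn(roi_types(), 2)
  tibble(
    connection_id = paste(pr[1, ], pr[2, ], sep = "-"),
    roi_a = pr[1, ],
    roi_b = pr[2, ]
  )
}

.subnetwork_rois <- list(
  sensory   = c("SI", "SII", "thalamus", "BG", "pI"),
  affective = c("aI", "ACC", "thalamus", "amygdala", "BG"),
  cognitive = c("dlPFC", "vlPFC", "OFC", "MCC", "BG", "aI")
)

#' Subnetwork definitions of the pain connectome
#'
#' The three functional subdivisions of the pain connectome and their
#' within-set connections: sensory-discriminative (SI, SII, thalamus, BG,
#' posterior insula; 10 connections), affective-motivational (aI, ACC,
#' thalamus, amygdala, BG; 10 connections) and cognitive-evaluative (dlPFC,
#' vlPFC, OFC, MCC, BG, aI; 15 connections). Connections between two ROIs
#' shared by several subnetworks (e.g. thalamus-BG) legitimately belong to
#' each of them.
#'
#' @param name One of `"sensory"`, `"affective"`, `"cognitive"`.
#' @return A list with elements `name`, `roi_set` and `connections`
#'   (character vector of connection ids).
#' @export
subnetwork_definition <- function(name = c("sensory", "affective", "cognitive")) {
  name <- match.arg(name)
  rois <- .subnetwork_rois[[name]]
  pr <- combn(rois, 2)
  list(
    name = name,
    roi_set = rois,
    connections = connection_id(pr[1, ], pr[2, ])
  )
}

#' Names of the three subnetworks
#' @return `c("sensory", "affective", "cognitive")`
#' @export
subnetwork_names <- function() names(.subnetwork_rois)

#' Long table of subnetwork membership
#'
#' @return A tibble with columns `subnetwork`, `connection_id`; a connection
#'   appears once per subnetwork that contains it.
#' @export
subnetwork_membership <- function() {
  dplyr::bind_rows(lapply(subnetwork_names(), function(nm) {
    def <- subnetwork_definition(nm)
    tibble(subnetwork = nm, connection_id = def$connections)
  }))
}
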