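#' The six functional subnetworks of the Dosenbach parcellation
#'
#' Vocabulary of subnetwork names used throughout the package. Every atlas
#' row must carry one of these names.
#'
#' @return Character vector of the six subnetwork names.
#' @export
flex_subnetworks <- function() {
  c("default mode", "occipital", "cingulo-opercular",
    "fronto-parietal", "sensorimotor", "cerebellar")
}

new_atlas <- function(labels, coords, subnetwork) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("atlas format error: duplicate ROI labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) != length(labels))
    stop("atlas format error: coordinates must be N x 3")
  if (any(!is.finite(coords)))
    stop("atlas format error: non-finite MNI coordinate")
  subnetwork <- as.character(subnetwork)
  bad <- setdiff(unique(subnetwork), flex_subnetworks())
  if (length(bad))
    stop("atlas format error: unknown subnetwork name(s): ",
         paste(bad, collapse = ", "))
  if (length(subnetwork) != length(labels))
    stop("atlas format error: one subnetwork per ROI required")
  dimnames(coords) <- list(labels, c("x", "y", "z"))
  structure(
    list(labels = labels, coords = coords,
         subnetwork = factor(subnetwork,
                             levels = intersect(flex_subnetworks(),
                                                unique(subnetwork)))),
    class = "flex_atlas")
}

#' Read a parcellation atlas from CSV
#'
#' The file must have columns `label`, `x`, `y`, `z`, `subnetwork` (header
#' required). Row order defines the node index order used by every matrix in
#' the package.
#'
#' @param path Path to the atlas CSV.
#' @return A `flex_atlas` object with fields `labels`, `coords` (N x 3 MNI
#'   mm), and `subnetwork` (factor over [flex_subnetworks()]).
#' @seealso [dosenbach_atlas()] for the packaged 160-ROI atlas.
#' @export
load_atlas <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "subnetwork")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas format error: missing column(s): ", paste(miss, collapse = ", "))
  new_atlas(df$label, df[, c("x", "y", "z")], df$subnetwork)
}

#' Write an atlas back to CSV
#'
#' Inverse of [load_atlas()]; a load/save/load round trip preserves values.
#'
#' @param atlas A `flex_atlas`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "flex_atlas"))
  df <- data.frame(label = atlas$labels,
                   x = atlas$coords[, "x"], y = atlas$coords[, "y"],
                   z = atlas$coords[, "z"],
                   subnetwork = as.character(atlas$subnetwork))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The Dosenbach 160-ROI functional atlas
#'
#' Loads the packaged transcription of the published Dosenbach et al. (2010)
#' 160-ROI coordinate table, with each ROI assigned to one of six functional
#' subnetworks (default mode, occipital, cingulo-opercular, fronto-parietal,
#' sensorimotor, cerebellar).
#'
#' @return A `flex_atlas` with 160 ROIs.
#' @export
dosenbach_atlas <- function() {
  atlas <- load_atlas(system.file("extdata", "dosenbach160.csv",
                                  package = "dynflex", mustWork = TRUE))
  stopifnot(length(atlas$labels) == 160L,
            nlevels(atlas$subnetwork) == 6L)
  atlas
}

#' @export
print.flex_atlas <- function(x, ...) {
  cat("<flex_atlas> ", length(x$labels), " ROIs, ",
      nlevels(x$subnetwork), " subnetworks\n", sep = "")
  print(table(x$subnetwork))
  invisible(x)
}

#' Number of nodes in an atlas
#' @param atlas A `flex_atlas`.
#' @return Integer node count.
#' @export
n_nodes <- function(atlas) length(atlas$labels)
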