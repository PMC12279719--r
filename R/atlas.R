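#' Node atlas for the 84-region connectome
#'
#' The bundled atlas follows the Desikan cortical parcellation (34 regions
#' per hemisphere) plus seven subcortical structures per hemisphere and the
#' two cerebellar hemispheres, for 84 nodes in total. Each node carries a
#' seven-way lobe grouping (frontal, parietal, temporal, occipital,
#' insula-cingulate, subcortical, cerebellum) following the Klein-Tourville
#' assignment of Desikan regions.
#'
#' @param path Optional path to a user atlas CSV with columns
#'   \code{label}, \code{hemisphere} (left/right/midline) and \code{group}.
#'   When \code{NULL} the bundled 84-node atlas is used.
#' @return A data.frame of class \code{node_atlas} with columns
#'   \code{label}, \code{hemisphere}, \code{group}.
#' @examples
#' atlas <- default_atlas()
#' table(atlas$group)
#' @export
default_atlas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "atlas_desikan84.csv",
                        package = "efmediate", mustWork = TRUE)
  }
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_atlas(at)
}

#' Validate a node atlas
#'
#' @param atlas A data.frame with columns \code{label}, \code{hemisphere},
#'   \code{group}.
#' @return The atlas, invisibly classed as \code{node_atlas}.
#' @export
validate_atlas <- function(atlas) {
  req <- c("label", "hemisphere", "group")
  if (!all(req %in% names(atlas))) {
    stop("atlas must have columns: ", paste(req, collapse = ", "))
  }
  bad_h <- setdiff(unique(atlas$hemisphere), c("left", "right", "midline"))
  if (length(bad_h)) stop("unknown hemisphere value(s): ",
                          paste(bad_h, collapse = ", "))
  bad_g <- setdiff(unique(atlas$group), atlas_groups())
  if (length(bad_g)) stop("unknown group label(s): ",
                          paste(bad_g, collapse = ", "))
  key <- paste(atlas$hemisphere, atlas$label)
  if (anyDuplicated(key)) stop("atlas labels must be unique within hemisphere")
  class(atlas) <- c("node_atlas", "data.frame")
  atlas
}

#' The seven lobe groups, in canonical reporting order
#' @return Character vector of group names.
#' @export
atlas_groups <- function() {
  c("frontal", "parietal", "temporal", "occipital",
    "insula-cingulate", "subcortical", "cerebellum")
}

#' Partition atlas nodes into the seven lobe groups
#'
#' @param atlas A \code{node_atlas}.
#' @return Named list mapping group name to integer node indices (1-based,
#'   in atlas order). The lists partition \code{1:nrow(atlas)}.
#' @examples
#' g <- group_nodes(default_atlas())
#' lengths(g)
#' @export
group_nodes <- function(atlas) {
  atlas <- validate_atlas(atlas)
  out <- lapply(atlas_groups(), function(g) which(atlas$group == g))
  names(out) <- atlas_groups()
  out[lengths(out) > 0 | TRUE]
}

#' Full display name for a node (label plus hemisphere)
#' @param atlas A \code{node_atlas}.
#' @return Character vector like \code{"Precuneus (left)"}.
#' @export
node_names <- function(atlas) {
  paste0(atlas$label, " (", atlas$hemisphere, ")")
}

# Normalize a region name for matching across sources: lower-case, strip
# punctuation and filler words ("gyrus", "cortex", "of", "the").
normalize_region <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z ]", " ", x)
  x <- gsub("\\b(gyrus|cortex|of|the)\\b", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}
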