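#' Component atlas: assignment of components to functional networks
#'
#' Loads a two-column CSV (`component_id`, `network`) describing which
#' functional network each independent component belongs to. The package
#' bundles the NeuroMark fMRI 1.0 labeling of 53 components into seven
#' networks: subcortical (SCN), auditory (AUD), sensorimotor (SMN), visual
#' (VSN), cognitive control (CCN), default mode (DMN) and cerebellar (CBN).
#' Membership is data, not a constant: any atlas with the same two columns is
#' accepted, which is how reduced synthetic cohorts are labeled in tests.
#'
#' @param path Path to an atlas CSV; the bundled NeuroMark atlas when `NULL`.
#' @return A data frame of class `component_atlas` with columns
#'   `component_id` and `network` (factor, levels in order of appearance).
#' @export
#' @examples
#' atlas <- component_atlas()
#' table(atlas$network)
component_atlas <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "neuromark_fmri_1p0_atlas.csv",
                        package = "connage", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  make_atlas(df$component_id, df$network)
}

#' Build an atlas from label vectors
#'
#' @param component_ids Character vector of unique component labels.
#' @param networks Character vector, one network label per component.
#' @return A `component_atlas` data frame.
#' @export
make_atlas <- function(component_ids, networks) {
  if (is.null(component_ids) || is.null(networks))
    stop("atlas requires 'component_id' and 'network' columns")
  if (length(component_ids) != length(networks))
    stop("component_ids and networks must have equal length")
  if (anyDuplicated(component_ids))
    stop("every component must be assigned exactly one network; duplicated: ",
         paste(unique(component_ids[duplicated(component_ids)]), collapse = ", "))
  df <- data.frame(component_id = as.character(component_ids),
                   network = factor(networks, levels = unique(networks)),
                   stringsAsFactors = FALSE)
  class(df) <- c("component_atlas", "data.frame")
  df
}

#' Networks defined by an atlas
#' @param atlas A `component_atlas`.
#' @return Character vector of network labels.
#' @export
atlas_networks <- function(atlas) levels(atlas$network)

#' Components belonging to one network
#' @param atlas A `component_atlas`.
#' @param network A single network label present in the atlas.
#' @return Character vector of component ids, in atlas order.
#' @export
network_components <- function(atlas, network) {
  if (!network %in% atlas_networks(atlas))
    stop("unknown network '", network, "'; valid labels: ",
         paste(atlas_networks(atlas), collapse = ", "))
  atlas$component_id[atlas$network == network]
}
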