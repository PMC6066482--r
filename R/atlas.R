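#' The 24-node reward-circuit atlas
#'
#' Twelve reward-related regions per hemisphere: dorsolateral prefrontal cortex
#' (dlPFC), anterior cingulate (ACC), ventral tegmental area (VTA),
#' orbitofrontal cortex (OFC), insula (INS), ventral striatum (VStr), caudate,
#' amygdala (AMY), hippocampus (HIP), thalamus (THA), putamen and pallidum.
#' The reward-control subnetwork comprises dlPFC, ACC, OFC and INS (8 nodes);
#' the remaining subcortical nodes form the reward-driving subnetwork (16
#' nodes).
#'
#' @return A data frame with columns \code{node} (e.g. \code{"L_VTA"}),
#'   \code{region}, \code{hemisphere} (\code{"L"}/\code{"R"}) and
#'   \code{subnetwork} (\code{"control"}/\code{"driving"}).
#' @examples
#' atlas <- reward_atlas()
#' table(atlas$subnetwork)
#' @export
reward_atlas <- function() {
  regions <- c("dlPFC", "ACC", "VTA", "OFC", "INS", "VStr",
               "caudate", "AMY", "HIP", "THA", "putamen", "pallidum")
  control <- c("dlPFC", "ACC", "OFC", "INS")
  out <- data.frame(
    node = c(paste0("L_", regions), paste0("R_", regions)),
    region = rep(regions, 2),
    hemisphere = rep(c("L", "R"), each = length(regions)),
    stringsAsFactors = FALSE
  )
  out$subnetwork <- ifelse(out$region %in% control, "control", "driving")
  out
}

#' Canonical edge identifier for an unordered node pair
#'
#' @param a,b node names (vectorised).
#' @return Character vector like \code{"L_ACC--L_VTA"}; the two node names are
#'   sorted so the id does not depend on argument order.
#' @export
edge_id <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Enumerate all edges of an atlas with their subnetwork class
#'
#' For \code{n} nodes there are \code{n(n-1)/2} unordered edges; for the
#' default 24-node atlas that is 276, partitioned into Control (28 =
#' choose(8,2)), Driving (120 = choose(16,2)) and BTN (128 = 8*16, edges
#' linking a control node to a driving node).
#'
#' @param atlas an atlas data frame, as from [reward_atlas()].
#' @return Data frame with columns \code{edge}, \code{node1}, \code{node2},
#'   \code{class} in \code{c("Control","Driving","BTN")}, ordered by edge id.
#' @examples
#' nrow(atlas_edges(reward_atlas()))  # 276
#' @export
atlas_edges <- function(atlas = reward_atlas()) {
  stopifnot(is.data.frame(atlas), !anyDuplicated(atlas$node))
  idx <- utils::combn(nrow(atlas), 2)
  n1 <- atlas$node[idx[1, ]]
  n2 <- atlas$node[idx[2, ]]
  s1 <- atlas$subnetwork[idx[1, ]]
  s2 <- atlas$subnetwork[idx[2, ]]
  cls <- ifelse(s1 == "control" & s2 == "control", "Control",
         ifelse(s1 == "driving" & s2 == "driving", "Driving", "BTN"))
  out <- data.frame(edge = edge_id(n1, n2), node1 = pmin(n1, n2),
                    node2 = pmax(n1, n2), class = cls,
                    stringsAsFactors = FALSE)
  out[order(out$edge), , drop = FALSE]
}
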