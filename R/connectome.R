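#' Per-edge voxel data container
#'
#' Holds, for one network edge, the per-subject streamline (connective value)
#' maps on a shared 3-D voxel grid. Maps are stored sparsely: only voxels in
#' \code{voxels} may carry non-zero streamline values; every other grid voxel
#' is implicitly zero for all subjects.
#'
#' @param edge canonical edge id (see [edge_id()]).
#' @param values numeric matrix, subjects x length(voxels), of non-negative
#'   streamline values; rownames are subject ids.
#' @param voxels integer vector of 1-based linear voxel indices into the grid.
#' @param grid_shape integer vector of length 3.
#' @return An object of class \code{"edge_voxel_data"}.
#' @export
edge_voxel_data <- function(edge, values, voxels, grid_shape) {
  values <- as.matrix(values)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1),
            ncol(values) == length(voxels),
            all(voxels >= 1), all(voxels <= prod(grid_shape)),
            !anyDuplicated(voxels), !is.null(rownames(values)))
  if (any(values < 0)) stop("streamline values must be non-negative")
  structure(list(edge = edge, values = values, voxels = as.integer(voxels),
                 grid_shape = as.integer(grid_shape)),
            class = "edge_voxel_data")
}

#' Convert a dense subjects-x-voxels streamline matrix to edge voxel data
#'
#' Voxels that are zero for every subject are dropped from the sparse support
#' (they can never enter a streamline region).
#'
#' @inheritParams edge_voxel_data
#' @param dense subjects x prod(grid_shape) matrix with subject-id rownames.
#' @export
as_edge_voxel_data <- function(edge, dense, grid_shape) {
  dense <- as.matrix(dense)
  stopifnot(ncol(dense) == prod(grid_shape))
  keep <- which(colSums(dense != 0) > 0)
  edge_voxel_data(edge, dense[, keep, drop = FALSE], keep, grid_shape)
}

#' Define the streamline region of an edge from one group's maps
#'
#' A voxel enters the region when its streamline values across the group's
#' subjects are significantly greater than zero by a one-sample t-test
#' (one-sided, since streamline values are non-negative) at level
#' \code{alpha}. Degenerate voxels are handled by the limiting behaviour of
#' the t statistic: a constant positive value across subjects is included
#' (t -> +Inf), a constant zero is excluded. No voxel-level multiplicity
#' correction is applied.
#'
#' @param edge_data an [edge_voxel_data()] object, already restricted to the
#'   subjects of one group (use \code{subset_subjects}).
#' @param alpha per-voxel significance level (default 0.05).
#' @param subjects optional character vector of subject ids to restrict to.
#' @param group optional label recording which group the region was estimated
#'   from.
#' @return An object of class \code{"streamline_region"}: list with
#'   \code{edge}, \code{group}, \code{mask} (sorted linear voxel indices,
#'   possibly empty) and \code{grid_shape}.
#' @export
define_streamline_region <- function(edge_data, alpha = 0.05,
                                     subjects = NULL, group = NA_character_) {
  stopifnot(inherits(edge_data, "edge_voxel_data"),
            is.numeric(alpha), alpha > 0, alpha < 1)
  v <- edge_data$values
  if (!is.null(subjects)) {
    miss <- setdiff(subjects, rownames(v))
    if (length(miss))
      stop("no streamline map for subject(s) ", paste(miss, collapse = ", "),
           " on edge ", edge_data$edge)
    v <- v[subjects, , drop = FALSE]
  }
  n <- nrow(v)
  if (n < 2) stop("need at least 2 subjects to define a streamline region")
  mu <- colMeans(v)
  sdv <- apply(v, 2, stats::sd)
  keep <- logical(ncol(v))
  zv <- sdv == 0
  keep[zv] <- mu[zv] > 0                      # constant positive -> in
  if (any(!zv)) {
    tt <- mu[!zv] / (sdv[!zv] / sqrt(n))
    keep[!zv] <- stats::pt(tt, df = n - 1, lower.tail = FALSE) < alpha
  }
  structure(list(edge = edge_data$edge, group = group,
                 mask = sort(edge_data$voxels[keep]),
                 grid_shape = edge_data$grid_shape),
            class = "streamline_region")
}

#' Edge strength: mean FA over a streamline region
#'
#' The connective strength of an edge for one subject is the arithmetic mean
#' of the subject's fractional anisotropy over the voxels of the edge's
#' streamline region.
#'
#' @param fa_map numeric vector of per-voxel FA values (length
#'   \code{prod(grid_shape)}), values in \[0, 1\].
#' @param region a \code{"streamline_region"}.
#' @return Mean FA, in \[0, 1\]. An empty region yields \code{NA} carrying
#'   attribute \code{undefined = TRUE} (an explicit flag, never a silent
#'   zero).
#' @export
edge_strength <- function(fa_map, region) {
  stopifnot(inherits(region, "streamline_region"),
            length(fa_map) == prod(region$grid_shape))
  if (length(region$mask) == 0)
    return(structure(NA_real_, undefined = TRUE))
  mean(fa_map[region$mask])
}

#' Build per-subject FA-weighted connectivity
#'
#' Estimates a streamline region per edge (per group by default), then scores
#' every subject's mean FA over the relevant region, assembling a
#' subjects-x-edges strength matrix from which symmetric 24 x 24 matrices are
#' derived.
#'
#' @param voxel_data named list of [edge_voxel_data()] objects, one per edge.
#' @param fa subjects x voxels FA matrix (subject ids as rownames), shared
#'   grid.
#' @param subjects data frame with columns \code{id} and \code{group}.
#' @param alpha voxel-level significance level for region definition.
#' @param region_mode \code{"group"}: each group gets its own region and each
#'   subject is scored against their own group's region (the default);
#'   \code{"union"}: one region from the union of both groups' significant
#'   voxels, used for everyone.
#' @return Object of class \code{"connectivity"}: \code{strengths}
#'   (subjects x edges), \code{subjects}, \code{regions}, \code{flagged}
#'   (edges with an empty region for some scoring group), \code{region_mode}.
#' @export
build_connectivity <- function(voxel_data, fa, subjects, alpha = 0.05,
                               region_mode = c("group", "union")) {
  region_mode <- match.arg(region_mode)
  stopifnot(is.list(voxel_data), length(voxel_data) >= 1,
            is.data.frame(subjects), all(c("id", "group") %in% names(subjects)))
  fa <- as.matrix(fa)
  miss <- setdiff(subjects$id, rownames(fa))
  if (length(miss)) stop("no FA map for subject(s) ", paste(miss, collapse = ", "))
  edges <- unname(vapply(voxel_data, `[[`, character(1), "edge"))
  if (anyDuplicated(edges)) stop("duplicate edge ids in voxel data")
  names(voxel_data) <- edges
  groups <- unique(subjects$group)
  strengths <- matrix(NA_real_, nrow(subjects), length(edges),
                      dimnames = list(subjects$id, edges))
  regions <- list()
  flagged <- character(0)
  for (e in edges) {
    ed <- voxel_data[[e]]
    miss <- setdiff(subjects$id, rownames(ed$values))
    if (length(miss))
      stop("no streamline map for subject(s) ", paste(miss, collapse = ", "),
           " on edge ", e)
    if (region_mode == "group") {
      regs <- lapply(groups, function(g)
        define_streamline_region(ed, alpha,
                                 subjects = subjects$id[subjects$group == g],
                                 group = g))
      names(regs) <- groups
      for (g in groups) {
        ids <- subjects$id[subjects$group == g]
        if (length(regs[[g]]$mask) == 0) {
          flagged <- c(flagged, e)
        } else {
          strengths[ids, e] <- rowMeans(fa[ids, regs[[g]]$mask, drop = FALSE])
        }
      }
      regions[[e]] <- regs
    } else {
      regs <- lapply(groups, function(g)
        define_streamline_region(ed, alpha,
                                 subjects = subjects$id[subjects$group == g],
                                 group = g))
      mask <- sort(unique(unlist(lapply(regs, `[[`, "mask"))))
      reg <- structure(list(edge = e, group = "union", mask = mask,
                            grid_shape = ed$grid_shape),
                       class = "streamline_region")
      if (length(mask) == 0) flagged <- c(flagged, e)
      else strengths[, e] <- rowMeans(fa[subjects$id, mask, drop = FALSE])
      regions[[e]] <- reg
    }
  }
  structure(list(strengths = strengths, subjects = subjects,
                 regions = regions, flagged = unique(flagged),
                 region_mode = region_mode),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("FA-weighted connectivity:", nrow(x$strengths), "subjects x",
      ncol(x$strengths), "edges (region mode:", x$region_mode, ")\n")
  if (length(x$flagged))
    cat("  ", length(x$flagged), "edge(s) with empty streamline region\n")
  invisible(x)
}

#' Symmetric node-by-node strength matrix for one subject
#'
#' @param conn a \code{"connectivity"} object.
#' @param subject subject id.
#' @param atlas atlas data frame; defaults to [reward_atlas()].
#' @return Symmetric matrix (diagonal zero) over the atlas nodes.
#' @export
conn_matrix <- function(conn, subject, atlas = reward_atlas()) {
  stopifnot(inherits(conn, "connectivity"), subject %in% rownames(conn$strengths))
  nodes <- atlas$node
  m <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  s <- conn$strengths[subject, ]
  parts <- strsplit(names(s), "--", fixed = TRUE)
  for (k in seq_along(s)) {
    i <- parts[[k]][1]; j <- parts[[k]][2]
    m[i, j] <- m[j, i] <- s[k]
  }
  m
}

#' Per-subject subnetwork mean strengths
#'
#' Averages edge strengths over the Control, Driving and BTN edge classes and
#' over a supplied set of Diff-connections (edges previously found
#' group-different). The Diff mean is \code{NA} when \code{diff_edges} is
#' empty.
#'
#' @param conn a \code{"connectivity"} object.
#' @param atlas atlas data frame used to classify edges.
#' @param diff_edges character vector of edge ids (may be empty).
#' @return Data frame: one row per subject, columns \code{id}, \code{group},
#'   \code{Control}, \code{Driving}, \code{BTN}, \code{Diff}.
#' @export
subnetwork_means <- function(conn, atlas = reward_atlas(),
                             diff_edges = character(0)) {
  stopifnot(inherits(conn, "connectivity"))
  et <- atlas_edges(atlas)
  have <- colnames(conn$strengths)
  unknown <- setdiff(diff_edges, et$edge)
  if (length(unknown)) stop("unknown edge id(s): ", paste(unknown, collapse = ", "))
  cls <- et$class[match(have, et$edge)]
  mean_over <- function(set) {
    if (!length(set)) return(rep(NA_real_, nrow(conn$strengths)))
    rowMeans(conn$strengths[, set, drop = FALSE])
  }
  out <- data.frame(
    id = rownames(conn$strengths),
    group = conn$subjects$group[match(rownames(conn$strengths), conn$subjects$id)],
    Control = mean_over(have[cls == "Control"]),
    Driving = mean_over(have[cls == "Driving"]),
    BTN = mean_over(have[cls == "BTN"]),
    Diff = mean_over(intersect(have, diff_edges)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
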