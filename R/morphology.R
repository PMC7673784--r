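#' @useDynLib retinasim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Morphology container
# ---------------------------------------------------------------------------

#' Construct a neuron morphology
#'
#' A morphology is a rooted tree of skeleton nodes, each carrying a 3-D
#' position (micrometres), a radius (micrometres) and an integer structure
#' label following the SWC convention (1 = soma, 2 = axon, 3 = dendrite).
#'
#' @param nodes data frame with columns `id`, `parent` (`-1` for the root),
#'   `x`, `y`, `z`, `radius` (all micrometres) and `type` (integer SWC
#'   structure label).
#' @param source character tag recording where the morphology came from.
#' @param metadata optional list of extra annotations (e.g. per-node shapes
#'   for idealized morphologies, or condensed edge geometry).
#' @return an object of class `retina_morphology`.
#' @export
morphology <- function(nodes, source = "unknown", metadata = list()) {
  req <- c("id", "parent", "x", "y", "z", "radius", "type")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, req]
  if (anyDuplicated(nodes$id)) stop("node ids must be unique")
  if (any(nodes$radius <= 0)) stop("all radii must be > 0")
  roots <- which(nodes$parent < 0)
  if (length(roots) != 1L) {
    stop("morphology must have exactly one root, found ", length(roots))
  }
  idx <- match(nodes$parent, nodes$id)
  bad <- which(nodes$parent >= 0 & is.na(idx))
  if (length(bad)) stop("parent id not found for node id ", nodes$id[bad[1]])
  .check_tree(nodes)
  structure(list(nodes = nodes, source = source, metadata = metadata),
            class = "retina_morphology")
}

# verify the parent links form a tree (no cycles, all reachable from root)
.check_tree <- function(nodes) {
  n <- nrow(nodes)
  pidx <- match(nodes$parent, nodes$id)
  for (i in seq_len(n)) {
    seen <- 0L
    j <- i
    while (!is.na(pidx[j])) {
      j <- pidx[j]
      seen <- seen + 1L
      if (seen > n) stop("cyclic parent links detected at node id ", nodes$id[i])
    }
  }
  invisible(TRUE)
}

#' @export
print.retina_morphology <- function(x, ...) {
  cat(sprintf("<retina_morphology> %d nodes, source: %s\n",
              nrow(x$nodes), x$source))
  invisible(x)
}

#' Number of nodes in a morphology
#' @param m a `retina_morphology`.
#' @return integer node count.
#' @export
n_nodes <- function(m) nrow(m$nodes)

# ---------------------------------------------------------------------------
# SWC I/O
# ---------------------------------------------------------------------------

#' Read an SWC morphology file
#'
#' Parses the standard 7-column whitespace-separated SWC dialect
#' (`id type x y z radius parent`). Lines starting with `#` are ignored.
#'
#' @param path path to an SWC file.
#' @return a [morphology()] object.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!length(keep)) stop("no data rows in SWC file: ", path)
  rows <- strsplit(trimws(raw[keep]), "\\s+")
  nc <- lengths(rows)
  if (any(nc != 7L)) {
    stop(sprintf("malformed SWC row at line %d of %s: expected 7 columns, got %d",
                 keep[which(nc != 7L)[1]], path, nc[nc != 7L][1]))
  }
  vals <- suppressWarnings(matrix(as.numeric(unlist(rows)), ncol = 7, byrow = TRUE))
  if (anyNA(vals)) {
    bad <- keep[which(rowSums(is.na(vals)) > 0)[1]]
    stop(sprintf("malformed SWC row at line %d of %s: non-numeric field", bad, path))
  }
  nodes <- data.frame(id = vals[, 1], type = vals[, 2],
                      x = vals[, 3], y = vals[, 4], z = vals[, 5],
                      radius = vals[, 6], parent = vals[, 7])
  morphology(nodes[, c("id", "parent", "x", "y", "z", "radius", "type")],
             source = basename(path))
}

#' Write a morphology to an SWC file
#'
#' Note that annotations stored in `metadata` (per-node shapes, condensed
#' edge geometry) are not representable in SWC and are dropped.
#'
#' @param m a `retina_morphology`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  nd <- m$nodes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by retinasim", con)
  writeLines(sprintf("%g %g %.6g %.6g %.6g %.6g %g",
                     nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent), con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Idealized cone morphology
# ---------------------------------------------------------------------------

#' Idealized four-compartment cone morphology
#'
#' Builds the simplified mouse cone used throughout the package: a conical
#' outer segment (length 14.4 um), a spherical inner-segment/soma
#' (diameter 5.13 um), a cylindrical axon (diameter 1.3 um, length 15 um)
#' and a spherical axon terminal (diameter 6 um). The light-collecting area
#' of the outer segment (0.2 um^2) is recorded as metadata.
#'
#' @param os_diameter base diameter of the conical outer segment in um.
#'   The outer-segment length is fixed; its diameter is not separately
#'   constrained by the compartment geometry and defaults to 2 um.
#' @return a [morphology()] with per-node shape annotations in `metadata`.
#' @export
cone_morphology <- function(os_diameter = 2) {
  l_os <- 14.4; d_s <- 5.13; d_a <- 1.3; l_a <- 15; d_at <- 6
  # nodes placed along the z axis, outer segment on top
  z_s  <- 0
  z_os <- z_s + d_s / 2 + l_os / 2
  z_a  <- z_s - d_s / 2 - l_a / 2
  z_at <- z_a - l_a / 2 - d_at / 2
  nodes <- data.frame(
    id = 1:4, parent = c(2, -1, 2, 3),
    x = 0, y = 0, z = c(z_os, z_s, z_a, z_at),
    radius = c(os_diameter / 2, d_s / 2, d_a / 2, d_at / 2),
    type = c(2, 1, 2, 2))
  shapes <- data.frame(
    id = 1:4,
    shape = c("cone", "sphere", "cylinder", "sphere"),
    length_um = c(l_os, 0, l_a, 0),
    diam_um = c(os_diameter, d_s, d_a, d_at),
    region = c("OS", "IS/S", "A", "AT"))
  morphology(nodes, source = "idealized cone",
             metadata = list(shapes = shapes, light_collecting_area_um2 = 0.2))
}

# ---------------------------------------------------------------------------
# Region mapping
# ---------------------------------------------------------------------------

#' Default SWC-type to region mapping rules for bipolar cells
#'
#' Bipolar-cell compartments are grouped into six regions: distal dendrite
#' (DD), proximal dendrite (PD), soma (S), proximal axon (PA), distal axon
#' (DA) and axon terminal (AT). SWC type 1 maps to S; type 3 (dendrite)
#' splits into PD/DD at a path-distance threshold from the soma; type 2
#' (axon) splits into PA/DA by path distance with branched tips labelled AT.
#'
#' @param dendrite_split_um path distance (um) separating PD from DD.
#' @param axon_split_um path distance (um) separating PA from DA.
#' @return a list of rule parameters consumed by [map_regions()].
#' @export
bc_region_rules <- function(dendrite_split_um = 15, axon_split_um = 30) {
  list(dendrite_split_um = dendrite_split_um, axon_split_um = axon_split_um)
}

#' Assign region labels to morphology nodes
#'
#' @param m a `retina_morphology`.
#' @param rules rule parameters from [bc_region_rules()].
#' @return `m` with a `region` column added to `m$nodes`.
#' @export
map_regions <- function(m, rules = bc_region_rules()) {
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  # path distance from root along edges
  dist <- numeric(nrow(nd))
  ord <- .topo_order(nd)
  for (i in ord) {
    if (!is.na(pidx[i])) {
      seg <- sqrt((nd$x[i] - nd$x[pidx[i]])^2 + (nd$y[i] - nd$y[pidx[i]])^2 +
                    (nd$z[i] - nd$z[pidx[i]])^2)
      dist[i] <- dist[pidx[i]] + seg
    }
  }
  nkids <- tabulate(pidx[!is.na(pidx)], nbins = nrow(nd))
  region <- character(nrow(nd))
  for (i in seq_len(nrow(nd))) {
    region[i] <- switch(as.character(nd$type[i]),
      "1" = "S",
      "3" = if (dist[i] <= rules$dendrite_split_um) "PD" else "DD",
      "2" = {
        if (nkids[i] == 0L) "AT"
        else if (dist[i] <= rules$axon_split_um) "PA" else "DA"
      },
      "S")
  }
  m$nodes$region <- region
  m
}

# children count helper and a parent-before-child ordering
.topo_order <- function(nd) {
  pidx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  depth <- integer(n)
  for (i in seq_len(n)) {
    j <- i; d <- 0L
    while (!is.na(pidx[j])) { j <- pidx[j]; d <- d + 1L }
    depth[i] <- d
  }
  order(depth)
}

# ---------------------------------------------------------------------------
# Compartmentalization (Eq. for rm, cm, ri on per-compartment areas)
# ---------------------------------------------------------------------------

#' Passive membrane specification
#'
#' @param Rm specific membrane resistance, Ohm cm^2.
#' @param Cm specific membrane capacitance, uF/cm^2.
#' @param Ri axial resistivity, Ohm cm (132 Ohm cm for all retinal cell
#'   types modelled here).
#' @param Vr leak reversal (resting) potential, mV.
#' @return a `membrane_spec` list.
#' @export
membrane_spec <- function(Rm = 1e4, Cm = 1, Ri = 132, Vr = -60) {
  if (Rm <= 0 || Cm <= 0 || Ri <= 0) stop("Rm, Cm and Ri must be > 0")
  structure(list(Rm = Rm, Cm = Cm, Ri = Ri, Vr = Vr), class = "membrane_spec")
}

# geometric surface areas in um^2 and effective lengths in um per node
.node_geometry <- function(m, sphere_coupling = c("radius", "diameter")) {
  sphere_coupling <- match.arg(sphere_coupling)
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  n <- nrow(nd)
  shape <- rep("cylinder", n)
  len <- numeric(n); diam <- 2 * nd$radius; area <- numeric(n)
  lc <- numeric(n)       # length entering the axial-resistance formula
  region <- if (!is.null(nd$region)) nd$region else rep(NA_character_, n)

  shp <- m$metadata$shapes
  eg <- m$metadata$edge_geom   # condensed geometry overrides (length, area)
  for (i in seq_len(n)) {
    if (!is.null(shp)) {
      k <- match(nd$id[i], shp$id)
      shape[i] <- shp$shape[k]; len[i] <- shp$length_um[k]
      diam[i] <- shp$diam_um[k]
      if (!is.null(shp$region)) region[i] <- shp$region[k]
    } else if (is.na(pidx[i])) {
      shape[i] <- "sphere"; len[i] <- 0
    } else {
      len[i] <- sqrt((nd$x[i] - nd$x[pidx[i]])^2 + (nd$y[i] - nd$y[pidx[i]])^2 +
                       (nd$z[i] - nd$z[pidx[i]])^2)
      if (len[i] <= 0) len[i] <- diam[i]  # coincident points: fall back
    }
    r <- diam[i] / 2
    area[i] <- switch(shape[i],
      sphere = 4 * pi * r^2,
      cylinder = pi * diam[i] * len[i],
      cone = pi * r * sqrt(r^2 + len[i]^2))
    lc[i] <- switch(shape[i],
      sphere = if (sphere_coupling == "radius") r else diam[i],
      cylinder = len[i],
      cone = len[i])
    if (!is.null(eg)) {
      k <- match(nd$id[i], eg$id)
      if (!is.na(k)) { area[i] <- eg$area_um2[k]; lc[i] <- eg$lc_um[k]; len[i] <- eg$lc_um[k] }
    }
  }
  data.frame(id = nd$id, parent = nd$parent, shape = shape,
             length_um = ifelse(shape == "sphere", 0, len),
             lc_um = lc, diam_um = diam, area_um2 = area,
             x = nd$x, y = nd$y, z = nd$z, region = region)
}

#' Turn a morphology into electrical compartments
#'
#' Each node becomes one compartment. Surface area `Am` comes from the node
#' shape (sphere `pi d^2`, cylinder lateral `pi d l`, cone lateral
#' `pi r sqrt(r^2 + l^2)`). The passive elements follow
#' `rm = Rm / Am`, `cm = Cm * Am`, `ri = Ri * lc / Am`,
#' converted to Ohm, Farad and Ohm (areas um^2 -> cm^2, lengths um -> cm).
#' Spherical compartments have zero cable length; their axial coupling uses
#' the sphere radius (configurable to the diameter) as coupling length.
#'
#' @param m a `retina_morphology` (optionally with regions mapped).
#' @param spec a [membrane_spec()].
#' @param sphere_coupling coupling length rule for spheres: `"radius"`
#'   (default) or `"diameter"`.
#' @return a `compartments` data frame with geometry plus `rm` (Ohm),
#'   `cm` (F) and `ri` (Ohm) columns; attribute `Vr` carries the resting
#'   potential in mV.
#' @export
compartmentalize <- function(m, spec, sphere_coupling = "radius") {
  stopifnot(inherits(m, "retina_morphology"), inherits(spec, "membrane_spec"))
  g <- .node_geometry(m, sphere_coupling)
  if (any(g$area_um2 <= 0)) {
    stop("zero-area compartment: node id ", g$id[which(g$area_um2 <= 0)[1]])
  }
  A_cm2 <- g$area_um2 * 1e-8
  l_cm <- g$lc_um * 1e-4
  g$rm <- spec$Rm / A_cm2
  g$cm <- spec$Cm * 1e-6 * A_cm2
  g$ri <- spec$Ri * l_cm / A_cm2
  attr(g, "Vr") <- spec$Vr
  attr(g, "membrane_spec") <- spec
  class(g) <- c("compartments", "data.frame")
  g
}

# ---------------------------------------------------------------------------
# Condensation
# ---------------------------------------------------------------------------

#' Reduce the number of compartments of a morphology
#'
#' Iteratively merges unbranched (degree-2) interior nodes into their
#' parent edge, always taking the electrically closest pair first (the node
#' whose two adjacent edges have the smallest summed axial resistance).
#' Merging conserves total membrane surface area exactly and conserves the
#' series axial resistance of the merged chain exactly: a merged edge stores
#' surface area `A = A1 + A2` and an effective length
#' `l = A * (l1/A1 + l2/A2)` so that `l/A` equals the summed `l/A` of its
#' parts. Branch points, tips, the root and region boundaries are never
#' merged away, so region labels are never mixed.
#'
#' @param m a `retina_morphology`; region labels (if present) constrain
#'   merging.
#' @param target_n requested maximum number of nodes.
#' @return a condensed `retina_morphology` whose `metadata$edge_geom`
#'   carries the conserved per-edge (`lc_um`, `area_um2`) geometry.
#' @export
condense <- function(m, target_n) {
  nd <- m$nodes
  n <- nrow(nd)
  if (target_n >= n) return(m)
  g <- .node_geometry(m)
  pidx <- match(nd$parent, nd$id)
  region <- if (!is.null(nd$region)) nd$region else rep("", n)
  alive <- rep(TRUE, n)

  mergeable <- function(i) {
    # a node can be folded into its child's edge if it is a pass-through
    # point: exactly one child, has a parent, same region as parent & child
    if (!alive[i] || is.na(pidx[i])) return(FALSE)
    kids <- which(pidx == i & alive)
    if (length(kids) != 1L) return(FALSE)
    region[i] == region[pidx[i]] && region[i] == region[kids]
  }
  n_min <- sum(!vapply(seq_len(n), mergeable, logical(1)))
  if (target_n < n_min) {
    stop("target_n below topological minimum of ", n_min, " compartments")
  }

  lc <- g$lc_um; area <- g$area_um2
  count <- n
  while (count > target_n) {
    cand <- which(vapply(seq_len(n), mergeable, logical(1)))
    if (!length(cand)) break
    # axial resistance score l/A of own edge plus the single child's edge
    score <- vapply(cand, function(i) {
      child <- which(pidx == i & alive)
      lc[i] / area[i] + lc[child] / area[child]
    }, numeric(1))
    i <- cand[which.min(score)]
    child <- which(pidx == i & alive)
    # fold node i into the child's edge: child now connects to i's parent
    area_new <- area[i] + area[child]
    lc_new <- area_new * (lc[i] / area[i] + lc[child] / area[child])
    area[child] <- area_new; lc[child] <- lc_new
    pidx[child] <- pidx[i]
    alive[i] <- FALSE
    count <- count - 1L
  }
  keep <- which(alive)
  nd2 <- nd[keep, , drop = FALSE]
  nd2$parent <- ifelse(is.na(pidx[keep]), -1, nd$id[pidx[keep]])
  eg <- data.frame(id = nd$id[keep], lc_um = lc[keep], area_um2 = area[keep])
  md <- m$metadata
  md$edge_geom <- eg
  out <- morphology(nd2, source = paste0(m$source, " (condensed)"), metadata = md)
  if (!is.null(nd$region)) out$nodes$region <- region[keep]
  out
}

#' Total membrane surface area of a morphology
#' @param m a `retina_morphology`.
#' @return total area in um^2.
#' @export
total_area <- function(m) sum(.node_geometry(m)$area_um2)

#' Axial resistance along the path between two nodes
#'
#' Sums the per-edge `Ri * lc / Am` contributions along the unique tree path
#' between two node ids (in the units of [compartmentalize()], Ohm).
#'
#' @param m a `retina_morphology`.
#' @param from,to node ids.
#' @param Ri axial resistivity in Ohm cm.
#' @return path resistance in Ohm.
#' @export
path_resistance <- function(m, from, to, Ri = 132) {
  g <- .node_geometry(m)
  nd <- m$nodes
  pidx <- match(nd$parent, nd$id)
  anc <- function(i) { out <- i; while (!is.na(pidx[i])) { i <- pidx[i]; out <- c(out, i) }; out }
  ia <- anc(match(from, nd$id)); ib <- anc(match(to, nd$id))
  common <- intersect(ia, ib)[1]
  path <- c(setdiff(ia, anc(common)), setdiff(ib, anc(common)))
  sum(Ri * (g$lc_um[path] * 1e-4) / (g$area_um2[path] * 1e-8))
}
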