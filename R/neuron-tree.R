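#' Neuron reconstruction trees
#'
#' A `neuron_tree` is a tibble of SWC-style records — one row per node with
#' columns `id`, `type`, `x`, `y`, `z`, `radius`, `parent` — plus a coordinate
#' unit tag and a per-axis voxel size so positions can be moved between voxel
#' indices and micrometers. Structure type codes follow the SWC convention
#' (1 = soma, 2 = axon, 3 = basal dendrite, 4 = apical dendrite); other codes
#' pass through untouched. A root node has `parent == -1`.
#'
#' Reconstructions follow the quasi-binary convention: after finalisation a
#' tree has a single root (the soma), no cycles, and every non-soma node has
#' at most two children; only the soma may have more. [validate_tree()] checks
#' these invariants and reports violations instead of erroring, so fragment
#' files remain representable.
#'
#' @param nodes A data frame with at least the seven SWC columns. Extra
#'   columns (e.g. the ESWC `seg_id`, `level`, `mode`, `timestamp`) are kept.
#' @param unit Coordinate unit, `"micron"` or `"voxel"`.
#' @param voxel_size Numeric length-3, micrometers per voxel along x, y, z.
#' @param metadata Free-form named list carried along with the tree.
#'
#' @return A `neuron_tree` (a tibble subclass).
#' @examples
#' tr <- neuron_tree(data.frame(
#'   id = 1:3, type = c(1, 2, 2), x = c(0, 1, 2), y = 0, z = 0,
#'   radius = c(5, 1, 1), parent = c(-1, 1, 2)
#' ))
#' validate_tree(tr)
#' @export
neuron_tree <- function(nodes = NULL, unit = c("micron", "voxel"),
                        voxel_size = c(1, 1, 1), metadata = list()) {
  unit <- match.arg(unit)
  if (is.null(nodes)) {
    nodes <- tibble::tibble(
      id = integer(), type = integer(), x = double(), y = double(),
      z = double(), radius = double(), parent = integer()
    )
  }
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  missing_cols <- setdiff(req, names(nodes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "`nodes` is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  nodes <- tibble::as_tibble(nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$type <- as.integer(nodes$type)
  nodes$parent <- as.integer(nodes$parent)
  for (col in c("x", "y", "z", "radius")) nodes[[col]] <- as.double(nodes[[col]])
  nodes <- nodes[, c(req, setdiff(names(nodes), req))]
  if (anyDuplicated(nodes$id) > 0) {
    rlang::abort(paste0(
      "duplicate node id(s): ",
      paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")
    ), class = "neuronkit_structural_error")
  }
  if (nrow(nodes) > 0 && any(!is.finite(c(nodes$x, nodes$y, nodes$z)))) {
    rlang::abort("node positions must be finite")
  }
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(
    nodes,
    unit = unit,
    voxel_size = as.double(voxel_size),
    metadata = metadata,
    class = c("neuron_tree", class(tibble::tibble()))
  )
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat(sprintf(
    "# A neuron_tree: %d nodes, unit = %s, voxel size = (%g, %g, %g) um\n",
    nrow(x), attr(x, "unit"),
    attr(x, "voxel_size")[1], attr(x, "voxel_size")[2], attr(x, "voxel_size")[3]
  ))
  NextMethod()
}

# Rebuild a neuron_tree from a plain node table, carrying attributes over.
tree_like <- function(template, nodes) {
  neuron_tree(nodes,
    unit = attr(template, "unit"),
    voxel_size = attr(template, "voxel_size"),
    metadata = attr(template, "metadata")
  )
}

#' @rdname neuron_tree
#' @param x An object.
#' @export
is_neuron_tree <- function(x) inherits(x, "neuron_tree")

#' @rdname neuron_tree
#' @param tree A `neuron_tree`.
#' @export
tree_unit <- function(tree) attr(tree, "unit")

#' @rdname neuron_tree
#' @export
tree_voxel_size <- function(tree) attr(tree, "voxel_size")

#' Convert a tree between voxel and micrometer coordinates
#'
#' Voxel coordinates are 0-based indices; conversion multiplies (or divides)
#' each axis by the tree's voxel size. Radii are scaled by the mean voxel
#' size so they stay a scalar.
#'
#' @param tree A `neuron_tree`.
#' @param to Target unit.
#' @return A `neuron_tree` in the requested unit.
#' @export
convert_units <- function(tree, to = c("micron", "voxel")) {
  to <- match.arg(to)
  from <- tree_unit(tree)
  if (from == to) return(tree)
  vs <- tree_voxel_size(tree)
  nodes <- tibble::as_tibble(tree)
  if (to == "micron") {
    nodes$x <- nodes$x * vs[1]
    nodes$y <- nodes$y * vs[2]
    nodes$z <- nodes$z * vs[3]
    nodes$radius <- nodes$radius * mean(vs)
  } else {
    nodes$x <- nodes$x / vs[1]
    nodes$y <- nodes$y / vs[2]
    nodes$z <- nodes$z / vs[3]
    nodes$radius <- nodes$radius / mean(vs)
  }
  neuron_tree(nodes, unit = to, voxel_size = vs, metadata = attr(tree, "metadata"))
}

# ---- internal tree helpers -------------------------------------------------

# number of children per node, aligned with row order
n_children <- function(tree) {
  if (nrow(tree) == 0) return(integer(0))
  tab <- table(factor(tree$parent[tree$parent != -1], levels = tree$id))
  as.integer(tab)
}

# list of child row indices per node row
children_index <- function(tree) {
  kids <- vector("list", nrow(tree))
  prow <- match(tree$parent, tree$id)
  for (i in seq_len(nrow(tree))) {
    p <- prow[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

root_rows <- function(tree) which(tree$parent == -1L)

# Euclidean length of the edge from each node to its parent (0 for roots /
# orphan parents), in the tree's coordinate units.
edge_lengths <- function(tree) {
  if (nrow(tree) == 0) return(double(0))
  prow <- match(tree$parent, tree$id)
  len <- rep(0, nrow(tree))
  has <- !is.na(prow) & tree$parent != -1L
  if (any(has)) {
    len[has] <- sqrt(
      (tree$x[has] - tree$x[prow[has]])^2 +
        (tree$y[has] - tree$y[prow[has]])^2 +
        (tree$z[has] - tree$z[prow[has]])^2
    )
  }
  len
}

#' Validate the quasi-binary tree invariants
#'
#' Checks a reconstruction against the conventions expected of a finalised
#' neuron tree and reports every violation rather than stopping at the first:
#' multiple roots, orphan parent references, cycles, non-soma nodes with more
#' than two children, and negative radii. The soma (type 1) is allowed any
#' number of children.
#'
#' @param tree A `neuron_tree`.
#' @return A tibble with columns `node_id`, `rule`, `message`; zero rows for a
#'   valid tree.
#' @export
validate_tree <- function(tree) {
  viol <- list()
  add <- function(node_id, rule, message) {
    viol[[length(viol) + 1]] <<- tibble::tibble(
      node_id = as.integer(node_id), rule = rule, message = message
    )
  }
  roots <- root_rows(tree)
  if (nrow(tree) > 0 && length(roots) == 0) {
    add(NA, "no_root", "tree has no root node (parent == -1)")
  }
  if (length(roots) > 1) {
    for (r in roots[-1]) {
      add(tree$id[r], "multiple_roots", sprintf("extra root node %d", tree$id[r]))
    }
  }
  prow <- match(tree$parent, tree$id)
  orphan <- which(is.na(prow) & tree$parent != -1L)
  for (i in orphan) {
    add(tree$id[i], "orphan_parent",
        sprintf("node %d references missing parent %d", tree$id[i], tree$parent[i]))
  }
  neg <- which(tree$radius < 0)
  for (i in neg) {
    add(tree$id[i], "negative_radius",
        sprintf("node %d has negative radius %g", tree$id[i], tree$radius[i]))
  }
  nk <- n_children(tree)
  over <- which(nk > 2 & tree$type != 1L)
  for (i in over) {
    add(tree$id[i], "quasi_binary",
        sprintf("non-soma node %d has %d children", tree$id[i], nk[i]))
  }
  # cycle / reachability: follow parents; any node that never reaches a root
  # or an orphan reference is on a cycle
  if (nrow(tree) > 0) {
    state <- integer(nrow(tree)) # 0 unknown, 1 ok, 2 cycle
    for (i in seq_len(nrow(tree))) {
      if (state[i] != 0) next
      path <- integer(0)
      j <- i
      repeat {
        if (j %in% path) {
          for (p in path[which(path == j)[1]:length(path)]) state[p] <- 2L
          for (p in setdiff(path, path[which(path == j)[1]:length(path)])) {
            state[p] <- 2L # upstream of a cycle is also unreachable from root
          }
          break
        }
        path <- c(path, j)
        if (tree$parent[j] == -1L || is.na(prow[j])) {
          for (p in path) state[p] <- 1L
          break
        }
        j <- prow[j]
        if (state[j] != 0) {
          for (p in path) state[p] <- state[j]
          break
        }
      }
    }
    for (i in which(state == 2L)) {
      add(tree$id[i], "cycle", sprintf("node %d lies on or above a cycle", tree$id[i]))
    }
  }
  if (length(viol) == 0) {
    tibble::tibble(node_id = integer(), rule = character(), message = character())
  } else {
    dplyr::bind_rows(viol)
  }
}

#' Total cable length of a tree
#'
#' Sum of Euclidean parent-child edge lengths in the tree's coordinate units.
#'
#' @param tree A `neuron_tree`.
#' @return A scalar length.
#' @export
total_length <- function(tree) sum(edge_lengths(tree))

# Decompose a tree into unbranched paths between topological nodes (root,
# branching points, tips). Returns a list of integer row-index vectors, each
# ordered from the upstream topological node to the downstream one.
branch_paths <- function(tree) {
  n <- nrow(tree)
  if (n == 0) return(list())
  kids <- children_index(tree)
  nk <- lengths(kids)
  roots <- root_rows(tree)
  topo <- nk >= 2
  topo[roots] <- TRUE
  paths <- list()
  for (start in which(topo)) {
    for (child in kids[[start]]) {
      path <- c(start, child)
      j <- child
      while (nk[j] == 1 && !topo[j]) {
        j <- kids[[j]][1]
        path <- c(path, j)
      }
      paths[[length(paths) + 1]] <- path
    }
  }
  # isolated root with a single chain: covered above since root is topo
  paths
}
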