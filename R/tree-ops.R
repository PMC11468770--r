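#' Prune short terminal branches
#'
#' Removes every terminal branch carrying fewer than `min_nodes` SWC records,
#' where a terminal branch is the path from a tip up to — but excluding — the
#' nearest branching point. A "unit" is a node record: the branching point
#' belongs to the retained structure, so it is never counted or removed.
#' Pruning repeats until a fixed point, because removing a branch can turn a
#' bifurcation into a pass-through node and expose a new short terminal
#' branch. Branches attached directly to the root are exempt, which prevents
#' a small unbranched tree from deleting itself; the soma is never removed.
#'
#' @param tree A [neuron_tree()].
#' @param min_nodes Minimum node count for a terminal branch to survive
#'   (default 6: branches with fewer than six records are pruned).
#' @return The pruned `neuron_tree`.
#' @export
prune_short_terminal_branches <- function(tree, min_nodes = 6) {
  repeat {
    n <- nrow(tree)
    if (n == 0) return(tree)
    kids <- children_index(tree)
    nk <- lengths(kids)
    prow <- match(tree$parent, tree$id)
    roots <- root_rows(tree)
    is_root <- logical(n)
    is_root[roots] <- TRUE
    tips <- which(nk == 0 & !is_root)
    drop <- logical(n)
    for (tip in tips) {
      path <- tip
      j <- tip
      repeat {
        p <- prow[j]
        if (is.na(p)) { # orphan attachment: treat like a root attachment
          p <- NA_integer_
          break
        }
        if (is_root[p] || nk[p] >= 2) break
        path <- c(path, p)
        j <- p
      }
      if (is.na(p) || is_root[p]) next # exempt: attached directly to root
      if (length(path) < min_nodes) drop[path] <- TRUE
    }
    if (!any(drop)) return(tree)
    tree <- tree_like(tree, tibble::as_tibble(tree)[!drop, , drop = FALSE])
  }
}

#' Resample a tree to uniform node spacing
#'
#' Linearly interpolates positions and radii along every unbranched path so
#' consecutive nodes are approximately `step` apart. Branching points, tips
#' and the root are preserved exactly, so the topology (tip and bifurcation
#' counts) never changes.
#'
#' @param tree A [neuron_tree()].
#' @param step Target spacing in the tree's coordinate units; must be > 0.
#' @return The resampled `neuron_tree` (node ids are renumbered from 1).
#' @export
resample_tree <- function(tree, step) {
  if (!is.numeric(step) || length(step) != 1 || !is.finite(step) || step <= 0) {
    rlang::abort("`step` must be a single positive number")
  }
  n <- nrow(tree)
  if (n == 0) return(tree)
  kids <- children_index(tree)
  nk <- lengths(kids)
  paths <- branch_paths(tree)
  roots <- root_rows(tree)

  paths_by_start <- split(seq_along(paths), vapply(paths, `[`, integer(1), 1))

  new_id <- 0L
  out <- list()
  emit <- function(type, x, y, z, radius, parent) {
    new_id <<- new_id + 1L
    out[[length(out) + 1]] <<- tibble::tibble(
      id = new_id, type = as.integer(type), x = x, y = y, z = z,
      radius = radius, parent = as.integer(parent)
    )
    new_id
  }

  topo_new <- rep(NA_integer_, n)
  queue <- integer(0)
  for (r in roots) {
    topo_new[r] <- emit(tree$type[r], tree$x[r], tree$y[r], tree$z[r],
                        tree$radius[r], -1L)
    queue <- c(queue, r)
  }
  # orphan-parent fragment heads behave as extra roots
  prow <- match(tree$parent, tree$id)
  for (r in which(is.na(prow) & tree$parent != -1L)) {
    topo_new[r] <- emit(tree$type[r], tree$x[r], tree$y[r], tree$z[r],
                        tree$radius[r], -1L)
    queue <- c(queue, r)
  }

  while (length(queue) > 0) {
    t0 <- queue[1]
    queue <- queue[-1]
    for (pi in paths_by_start[[as.character(t0)]]) {
      path <- paths[[pi]]
      px <- tree$x[path]; py <- tree$y[path]; pz <- tree$z[path]
      pr <- tree$radius[path]
      seg <- sqrt(diff(px)^2 + diff(py)^2 + diff(pz)^2)
      s <- c(0, cumsum(seg))
      L <- s[length(s)]
      n_seg <- max(1L, as.integer(round(L / step)))
      ts <- seq(0, L, length.out = n_seg + 1L)
      if (L == 0) ts <- c(0, 0)
      ss <- if (anyDuplicated(s) > 0) s + seq_along(s) * 1e-12 else s
      xi <- stats::approx(ss, px, xout = ts, rule = 2)$y
      yi <- stats::approx(ss, py, xout = ts, rule = 2)$y
      zi <- stats::approx(ss, pz, xout = ts, rule = 2)$y
      ri <- stats::approx(ss, pr, xout = ts, rule = 2)$y
      end <- path[length(path)]
      btype <- tree$type[path[min(2, length(path))]]
      m <- length(ts)
      n_new <- m - 1L # interior samples plus the path endpoint
      ids <- new_id + seq_len(n_new)
      new_id <- new_id + n_new
      inner <- seq_len(n_new - 1L) + 1L
      out[[length(out) + 1]] <- tibble::tibble(
        id = as.integer(ids),
        type = as.integer(c(rep(btype, n_new - 1L), tree$type[end])),
        x = c(xi[inner], tree$x[end]),
        y = c(yi[inner], tree$y[end]),
        z = c(zi[inner], tree$z[end]),
        radius = c(ri[inner], tree$radius[end]),
        parent = as.integer(c(topo_new[t0], ids[-n_new]))
      )
      topo_new[end] <- ids[n_new]
      if (nk[end] >= 1) queue <- c(queue, end)
    }
  }
  tree_like(tree, dplyr::bind_rows(out))
}

#' Global morphological features of a reconstruction
#'
#' L-Measure-style whole-tree summaries: total cable length, number of
#' bifurcations (non-root nodes with two children, plus the root once if it
#' has two or more), number of tips, topological depth (maximum number of
#' bifurcations on any root-to-tip path, plus one) and volume as the sum of
#' conical-frustum volumes over edges,
#' \eqn{\sum \pi h (r_1^2 + r_1 r_2 + r_2^2)/3}.
#'
#' @param tree A [neuron_tree()]; convert to micrometers first for features
#'   in physical units.
#' @return A one-row tibble with columns `total_length`, `n_bifurcations`,
#'   `n_tips`, `topological_depth`, `volume`.
#' @export
global_features <- function(tree) {
  n <- nrow(tree)
  if (n == 0) {
    return(tibble::tibble(
      total_length = 0, n_bifurcations = 0L, n_tips = 0L,
      topological_depth = 0L, volume = 0
    ))
  }
  kids <- children_index(tree)
  nk <- lengths(kids)
  roots <- root_rows(tree)
  is_root <- logical(n)
  is_root[roots] <- TRUE
  n_bif <- sum(nk >= 2 & !is_root) + sum(nk[roots] >= 2)
  n_tip <- sum(nk == 0 & !is_root)

  # edge-wise length and frustum volume
  prow <- match(tree$parent, tree$id)
  has <- !is.na(prow) & tree$parent != -1L
  h <- edge_lengths(tree)
  r1 <- tree$radius
  r2 <- ifelse(has, tree$radius[prow], 0)
  vol <- sum(pi * h[has] * (r1[has]^2 + r1[has] * r2[has] + r2[has]^2) / 3)

  # topological depth: DFS accumulating the branching-node count on the path
  depth <- 1L
  for (s in c(roots, which(is.na(prow) & tree$parent != -1L))) {
    stack_i <- s
    stack_d <- if (nk[s] >= 2) 1L else 0L
    while (length(stack_i) > 0) {
      i <- stack_i[length(stack_i)]
      d <- stack_d[length(stack_d)]
      stack_i <- stack_i[-length(stack_i)]
      stack_d <- stack_d[-length(stack_d)]
      if (nk[i] == 0) {
        depth <- max(depth, d + 1L)
      } else {
        for (k in kids[[i]]) {
          stack_i <- c(stack_i, k)
          stack_d <- c(stack_d, d + if (nk[k] >= 2) 1L else 0L)
        }
      }
    }
  }
  tibble::tibble(
    total_length = sum(h),
    n_bifurcations = as.integer(n_bif),
    n_tips = as.integer(n_tip),
    topological_depth = as.integer(depth),
    volume = vol
  )
}
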