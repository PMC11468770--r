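#' Read a neuron reconstruction from SWC or ESWC
#'
#' Parses the standard 7-column SWC table (`id type x y z radius parent`,
#' whitespace separated, `#` comments). ESWC files carry four extra columns
#' (`seg_id`, `level`, `mode`, `timestamp`) which are preserved; any further
#' trailing columns are kept as `extra_1`, `extra_2`, ... Reading does not
#' enforce the single-root convention — multi-root fragment files stay
#' representable and [validate_tree()] reports on them.
#'
#' @param path Path to an SWC/ESWC file.
#' @inheritParams neuron_tree
#' @return A [neuron_tree()].
#' @export
read_swc <- function(path, unit = c("micron", "voxel"), voxel_size = c(1, 1, 1)) {
  unit <- match.arg(unit)
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_lines <- lines[keep]
  line_no <- which(keep)
  if (length(data_lines) == 0) {
    return(neuron_tree(unit = unit, voxel_size = voxel_size,
                       metadata = list(source = path)))
  }
  fields <- strsplit(trimws(data_lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 7)) {
    bad <- which(nf < 7)[1]
    rlang::abort(
      sprintf("malformed SWC line %d in %s: expected >= 7 fields, got %d",
              line_no[bad], path, nf[bad]),
      class = "neuronkit_parse_error"
    )
  }
  ncol_extra <- max(nf) - 7L
  mat <- matrix(NA_real_, nrow = length(fields), ncol = 7L + ncol_extra)
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v[1:7])) {
      rlang::abort(
        sprintf("malformed SWC line %d in %s: non-numeric field", line_no[i], path),
        class = "neuronkit_parse_error"
      )
    }
    mat[i, seq_along(v)] <- v
  }
  nodes <- tibble::tibble(
    id = as.integer(mat[, 1]), type = as.integer(mat[, 2]),
    x = mat[, 3], y = mat[, 4], z = mat[, 5],
    radius = mat[, 6], parent = as.integer(mat[, 7])
  )
  if (ncol_extra > 0) {
    extra_names <- c("seg_id", "level", "mode", "timestamp")
    if (ncol_extra > 4) {
      extra_names <- c(extra_names, paste0("extra_", seq_len(ncol_extra - 4)))
    } else {
      extra_names <- extra_names[seq_len(ncol_extra)]
    }
    for (k in seq_len(ncol_extra)) nodes[[extra_names[k]]] <- mat[, 7L + k]
  }
  if (anyDuplicated(nodes$id) > 0) {
    rlang::abort(
      sprintf("duplicate node id(s) in %s: %s", path,
              paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")),
      class = "neuronkit_structural_error"
    )
  }
  neuron_tree(nodes, unit = unit, voxel_size = voxel_size,
              metadata = list(source = path))
}

#' Write a neuron reconstruction to SWC or ESWC
#'
#' Nodes are written in topological order (parents before children) with
#' coordinates and radii formatted to 3 decimal places — sub-nanometer
#' precision is meaningless at light-microscope resolution. ESWC columns
#' present on the tree are appended after the standard seven.
#'
#' @param tree A [neuron_tree()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  prow <- match(tree$parent, tree$id)
  if (any(is.na(prow) & tree$parent != -1L)) {
    rlang::abort("tree has orphan parent references; fix before writing")
  }
  ord <- topological_order(tree)
  extra_cols <- setdiff(names(tree), c("id", "type", "x", "y", "z", "radius", "parent"))
  fmt_num <- function(v) {
    out <- formatC(v, digits = 3, format = "f")
    out <- sub("0+$", "", out) # 3 decimals max, trailing zeros dropped
    sub("\\.$", "", out)
  }
  header <- c(
    "# SWC written by neuronkit",
    paste0("# columns: id type x y z radius parent",
           if (length(extra_cols)) paste0(" ", paste(extra_cols, collapse = " ")) else "")
  )
  if (nrow(tree) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  tr <- tree[ord, , drop = FALSE]
  cols <- list(
    as.character(tr$id), as.character(tr$type),
    fmt_num(tr$x), fmt_num(tr$y), fmt_num(tr$z),
    fmt_num(tr$radius), as.character(tr$parent)
  )
  for (col in extra_cols) cols[[length(cols) + 1]] <- fmt_num(tr[[col]])
  lines <- do.call(paste, cols)
  writeLines(c(header, lines), path)
  invisible(path)
}

# Row order with every parent before its children (roots and orphan-parent
# nodes first, in file order).
topological_order <- function(tree) {
  n <- nrow(tree)
  if (n == 0) return(integer(0))
  prow <- match(tree$parent, tree$id)
  kids <- children_index(tree)
  seeds <- which(tree$parent == -1L | is.na(prow))
  ord <- integer(0)
  visited <- logical(n)
  for (s in seeds) {
    if (visited[s]) next
    stack <- s
    while (length(stack) > 0) {
      i <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (visited[i]) next
      visited[i] <- TRUE
      ord <- c(ord, i)
      ks <- kids[[i]]
      if (length(ks) > 0) stack <- c(stack, rev(ks))
    }
  }
  c(ord, which(!visited)) # nodes on cycles appended as-is
}
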