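# Fixture builders and independent oracle implementations used across tests.
# Oracles are deliberately naive (O(n^2) searches, direct recursion) and
# never share code with the package internals they check.

mk_tree <- function(df, unit = "micron", voxel_size = c(1, 1, 1)) {
  neuron_tree(df, unit = unit, voxel_size = voxel_size)
}

# plain node table with the tree attributes stripped (for exact comparisons)
node_df <- function(tree) {
  df <- as.data.frame(tree)
  attributes(df) <- attributes(df)[c("names", "class", "row.names")]
  rownames(df) <- NULL
  df
}

# simple fixed shapes
chain_tree <- function(n = 11, spacing = 10, type = 2) {
  mk_tree(data.frame(
    id = seq_len(n), type = c(1, rep(type, n - 1)),
    x = (seq_len(n) - 1) * spacing, y = 0, z = 0, radius = 1,
    parent = c(-1, seq_len(n - 1))
  ))
}

y_tree <- function() {
  mk_tree(data.frame(
    id = 1:4, type = c(1, 2, 2, 2),
    x = c(0, 10, 20, 20), y = c(0, 0, 10, -10), z = 0, radius = 1,
    parent = c(-1, 1, 2, 2)
  ))
}

# random tree with coordinates on a 3-decimal grid (SWC round-trip safe);
# quasi-binary by construction, soma may take several children
random_tree <- function(seed, n = 30, extra_cols = FALSE) {
  set.seed(seed)
  id <- seq_len(n)
  parent <- c(-1L, integer(n - 1))
  nkids <- integer(n)
  type <- c(1L, rep(2L, n - 1))
  for (i in 2:n) {
    cap <- ifelse(type[seq_len(i - 1)] == 1L, 12L, 2L)
    open <- which(nkids[seq_len(i - 1)] < cap)
    p <- open[sample.int(length(open), 1)]
    parent[i] <- p
    nkids[p] <- nkids[p] + 1L
  }
  df <- data.frame(
    id = id, type = type,
    x = round(stats::runif(n, 0, 100), 3),
    y = round(stats::runif(n, 0, 100), 3),
    z = round(stats::runif(n, 0, 100), 3),
    radius = round(stats::runif(n, 0.1, 3), 3),
    parent = parent
  )
  if (extra_cols) {
    df$seg_id <- round(stats::runif(n, 0, 50))
    df$level <- round(stats::runif(n, 1, 5))
    df$mode <- rep(0, n)
    df$timestamp <- round(stats::runif(n, 0, 1000), 3)
  }
  mk_tree(df)
}

# render Gaussian tubes for a tree into a fresh volume (independent of the
# package's phantom renderer where a simple fixture is enough)
render_tubes <- function(tree, shape, amplitude = 300, sigma = NULL,
                         background = 50, noise_sd = 0, seed = 1,
                         bit_depth = 16) {
  set.seed(seed)
  vol <- array(0, dim = shape)
  prow <- match(tree$parent, tree$id)
  for (i in which(!is.na(prow) & tree$parent != -1L)) {
    a <- c(tree$x[i], tree$y[i], tree$z[i])
    b <- c(tree$x[prow[i]], tree$y[prow[i]], tree$z[prow[i]])
    s <- if (is.null(sigma)) max(tree$radius[i], 0.8) / 2 else sigma
    pad <- ceiling(3 * s + 1)
    lo <- pmax(floor(pmin(a, b) - pad), 0)
    hi <- pmin(ceiling(pmax(a, b) + pad), shape - 1)
    if (any(lo > hi)) next
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    gm <- as.matrix(g)
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, nrow(gm)) else
      pmin(pmax(((gm[, 1] - a[1]) * ab[1] + (gm[, 2] - a[2]) * ab[2] +
                   (gm[, 3] - a[3]) * ab[3]) / len2, 0), 1)
    d <- sqrt((gm[, 1] - (a[1] + t * ab[1]))^2 +
                (gm[, 2] - (a[2] + t * ab[2]))^2 +
                (gm[, 3] - (a[3] + t * ab[3]))^2)
    idx <- gm + 1
    vol[idx] <- pmax(vol[idx], amplitude * exp(-d^2 / (2 * s^2)))
  }
  vol <- vol + background
  if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(shape), sd = noise_sd), dim = shape)
  image_volume(round(pmax(vol, 0)), bit_depth = bit_depth)
}

# ---- oracles ---------------------------------------------------------------

# exhaustive nearest-neighbour distances from each row of a to rows of b,
# via the full pairwise distance matrix
oracle_nn_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))])
}

# exhaustive match-length recomputation mirroring the published definition:
# resample both trees, midpoint-test every edge against all points of the
# other side
oracle_match <- function(test, ref, thr) {
  step <- min(1, thr / 2)
  ts <- resample_tree(test, step)
  rs <- resample_tree(ref, step)
  side <- function(a, b) {
    prow <- match(a$parent, a$id)
    has <- which(!is.na(prow) & a$parent != -1L)
    mid <- cbind((a$x[has] + a$x[prow[has]]) / 2,
                 (a$y[has] + a$y[prow[has]]) / 2,
                 (a$z[has] + a$z[prow[has]]) / 2)
    len <- sqrt((a$x[has] - a$x[prow[has]])^2 +
                  (a$y[has] - a$y[prow[has]])^2 +
                  (a$z[has] - a$z[prow[has]])^2)
    d <- oracle_nn_dist(mid, cbind(b$x, b$y, b$z))
    c(matched = sum(len[d <= thr]), total = sum(len))
  }
  t <- side(ts, rs)
  r <- side(rs, ts)
  Rc <- t["matched"] / t["total"]
  Rm <- r["matched"] / r["total"]
  list(Rc = unname(Rc), Rm = unname(Rm),
       accuracy = unname(2 * Rc * Rm / (Rc + Rm)))
}

# quadratic greedy non-maximum suppression
oracle_nms <- function(cand, radius) {
  ord <- order(-cand$score, cand$x, cand$y, cand$z)
  cand <- cand[ord, , drop = FALSE]
  kept <- cand[0, ]
  for (i in seq_len(nrow(cand))) {
    if (nrow(kept) > 0) {
      d <- sqrt((kept$x - cand$x[i])^2 + (kept$y - cand$y[i])^2 +
                  (kept$z - cand$z[i])^2)
      if (any(d <= radius)) next
    }
    kept <- rbind(kept, cand[i, ])
  }
  kept
}

# direct recursive topological height (tips 1, branch points 1 + max child)
oracle_th <- function(tree) {
  kids <- split(seq_len(nrow(tree)), factor(tree$parent, levels = tree$id))
  rec <- function(i) {
    ks <- kids[[as.character(tree$id[i])]]
    if (length(ks) == 0) return(1L)
    sub <- vapply(ks, rec, integer(1))
    if (length(ks) == 1) max(sub) else 1L + max(sub)
  }
  vapply(seq_len(nrow(tree)), rec, integer(1))
}

# Drive n random (mostly illegal) events through try_event, checking the
# state invariants at regular checkpoints. Returns the number of invariant
# violations observed and the number of accepted events. Kept as a function
# so the hot loop is byte-compiled.
fuzz_protocol <- function(n_events, seed = 77, n_ids = 300) {
  set.seed(seed)
  users <- c("A", "B", "C", "D")
  st <- protocol_state(c(0, 0, 0, 5))
  accepted <- 0L
  bad <- 0L
  check <- max(1L, n_events %/% 5L)
  for (i in seq_len(n_events)) {
    act <- c("add", "confirm", "delete")[sample.int(3, 1)]
    ev <- list(
      timestamp = i, user = users[sample.int(4, 1)], action = act,
      segment_id = paste0("s", sample.int(n_ids, 1)),
      parent_id = if (act == "add") {
        if (stats::runif(1) < 0.3) "SOMA" else paste0("s", sample.int(n_ids, 1))
      } else NA_character_,
      parent_node = NA_integer_, replaces = NA_character_,
      geometry = list(if (act == "add") {
        tibble::tibble(x = stats::runif(2, 0, 50), y = stats::runif(2, 0, 50),
                       z = stats::runif(2, 0, 50), radius = 1)
      } else NULL)
    )
    res <- try_event(st, ev)
    st <- res$state
    accepted <- accepted + res$accepted
    if (i %% check == 0) {
      for (s in Filter(function(s) !s$deleted, st$segments)) {
        if (s$status == "confirmed" && identical(s$confirmer, s$author)) {
          bad <- bad + 1L
        }
        parent_ok <- identical(s$parent_id, "SOMA") ||
          (!is.null(st$segments[[s$parent_id]]) &&
             !st$segments[[s$parent_id]]$deleted)
        if (!parent_ok) bad <- bad + 1L
      }
    }
  }
  list(violations = bad, accepted = accepted)
}

# Run seeded multi-annotator simulations and collect per-stage accuracy,
# completion, final agreement, and final-stage unmatched length split by NTH.
run_collab_sessions <- function(n_runs, error_rate = 0.1, diligence = 0.9,
                                n_annotators = 3, n_stages = 8,
                                tree_seed0 = 3000, sim_seed0 = 4000) {
  ann <- tibble::tibble(error_rate = rep(error_rate, n_annotators),
                        confirm_diligence = diligence)
  acc <- matrix(NA_real_, n_runs, n_stages)
  complete <- logical(n_runs)
  agr <- double(n_runs)
  unm_high <- 0
  unm_all <- 0
  for (r in seq_len(n_runs)) {
    spec <- phantom_spec(volume_shape = c(96, 96, 96), n_branches = 10,
                         branch_length_range = c(15, 30), soma_radius = 6,
                         seed = tree_seed0 + r)
    truth <- neuron_tree(as.data.frame(make_tree(spec)), unit = "micron")
    log <- simulate_collaboration(truth, ann, seed = sim_seed0 + r)
    st <- replay_state(log)
    complete[r] <- is_complete(st)
    agr[r] <- agreement(st)
    ser <- stage_snapshots(log, n_stages)
    for (s in seq_len(n_stages)) {
      acc[r, s] <- match_length(ser$stages[[s]], truth, dist_threshold = 2)$accuracy
    }
    tab <- matched_unmatched_by_nth(ser, truth, bins = 10, dist_threshold = 2)
    fin <- tab[tab$stage == max(tab$stage), ]
    unm_all <- unm_all + sum(fin$unmatched_length)
    unm_high <- unm_high + sum(fin$unmatched_length[fin$nth_lo >= 0.5])
  }
  list(acc = acc, complete = complete, agreement = agr,
       unmatched_high_nth = unm_high, unmatched_total = unm_all)
}

# standalone classic Sholl count at one centre
oracle_sholl <- function(tree, center, radii) {
  prow <- match(tree$parent, tree$id)
  has <- which(!is.na(prow) & tree$parent != -1L)
  d <- sqrt((tree$x - center[1])^2 + (tree$y - center[2])^2 +
              (tree$z - center[3])^2)
  vapply(radii, function(r) {
    sum(xor(d[has] > r, d[prow[has]] > r))
  }, numeric(1))
}
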