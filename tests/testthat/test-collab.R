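ev_row <- function(timestamp, user, action, segment_id,
                   parent_id = NA_character_, geometry = NULL) {
  tibble::tibble(
    timestamp = timestamp, user = user, action = action,
    segment_id = segment_id, parent_id = parent_id,
    parent_node = NA_integer_, replaces = NA_character_,
    geometry = list(geometry)
  )
}
seg_geom <- function(x0) tibble::tibble(x = x0 + c(5, 10), y = 0, z = 0, radius = 1)

test_that("protocol rules accept and reject the canonical cases", {
  st <- protocol_state(c(0, 0, 0, 5))
  st <- apply_event(st, ev_row(1, "A", "add", "s1", "SOMA", seg_geom(0)))

  # A confirms own segment: rejected
  expect_error(apply_event(st, ev_row(2, "A", "confirm", "s1")),
               class = "protocol_self_confirm")
  # B extends A's unconfirmed segment: rejected
  expect_error(apply_event(st, ev_row(2, "B", "add", "s2", "s1", seg_geom(10))),
               class = "protocol_unconfirmed_parent")
  # B adds from the soma, then extends B's own unvalidated segment: accepted
  st <- apply_event(st, ev_row(2, "B", "add", "s2", "SOMA", seg_geom(0)))
  st <- apply_event(st, ev_row(3, "B", "add", "s3", "s2", seg_geom(10)))
  expect_equal(length(Filter(function(s) !s$deleted, st$segments)), 3)
  # referencing a segment that does not exist
  expect_error(apply_event(st, ev_row(4, "A", "confirm", "nope")),
               class = "protocol_unknown_segment")
  # B confirms A's soma-anchored segment: accepted; then A may extend it
  st <- apply_event(st, ev_row(5, "B", "confirm", "s1"))
  expect_equal(st$segments[["s1"]]$status, "confirmed")
  expect_equal(st$segments[["s1"]]$confirmer, "B")
  st <- apply_event(st, ev_row(6, "A", "add", "s4", "s1", seg_geom(10)))
  # confirm of a segment whose parent is unconfirmed: rejected
  expect_error(apply_event(st, ev_row(7, "A", "confirm", "s3")),
               class = "protocol_unconfirmed_parent")
  # try_event leaves the state unchanged on violation
  res <- try_event(st, ev_row(8, "A", "confirm", "s4"))
  expect_false(res$accepted)
  expect_equal(res$reason, "protocol_self_confirm")
  expect_identical(res$state, st)
})

test_that("completion requires every live segment confirmed", {
  st <- protocol_state(c(0, 0, 0, 5))
  expect_true(is_complete(st)) # vacuous
  st <- apply_event(st, ev_row(1, "A", "add", "s1", "SOMA", seg_geom(0)))
  expect_false(is_complete(st))
  st <- apply_event(st, ev_row(2, "B", "confirm", "s1"))
  expect_true(is_complete(st))
})

test_that("agreement is the confirmed share of live cable length", {
  st <- protocol_state(c(0, 0, 0, 5))
  st <- apply_event(st, ev_row(1, "A", "add", "s1", "SOMA",
                               tibble::tibble(x = c(0, 30), y = 0, z = 0, radius = 1)))
  st <- apply_event(st, ev_row(2, "B", "add", "s2", "SOMA",
                               tibble::tibble(x = 0, y = c(0, 10), z = 0, radius = 1)))
  st <- apply_event(st, ev_row(3, "B", "confirm", "s1"))
  expect_equal(agreement(st), 0.75) # 30 um of 40 um confirmed
  expect_error(agreement(protocol_state()), "empty")
})

test_that("fuzzing random events never corrupts the protocol invariants", {
  fz <- fuzz_protocol(4000, seed = 99, n_ids = 80)
  expect_equal(fz$violations, 0L)
  expect_gt(fz$accepted, 100) # the fuzz actually exercised accepted paths
})

sim_truth <- function(seed = 11, n_branches = 10) {
  spec <- phantom_spec(volume_shape = c(96, 96, 96), n_branches = n_branches,
                       branch_length_range = c(15, 30), soma_radius = 6,
                       seed = seed)
  neuron_tree(as.data.frame(make_tree(spec)), unit = "micron")
}

test_that("perfect annotators complete with accuracy 1 and one annotator errors", {
  truth <- sim_truth(3)
  log <- simulate_collaboration(
    truth, tibble::tibble(error_rate = c(0, 0), confirm_diligence = 1), seed = 1
  )
  st <- replay_state(log)
  expect_true(is_complete(st))
  expect_equal(agreement(st), 1)
  expect_equal(match_length(state_to_tree(st), truth, 2)$accuracy, 1)

  expect_error(
    simulate_collaboration(truth, tibble::tibble(error_rate = 0,
                                                 confirm_diligence = 1), 1),
    "2 annotators"
  )
})

test_that("simulation is a pure function of the seed", {
  truth <- sim_truth(5)
  ann <- tibble::tibble(error_rate = 0.1, confirm_diligence = 0.9)[c(1, 1, 1), ]
  l1 <- simulate_collaboration(truth, ann, seed = 7)
  l2 <- simulate_collaboration(truth, ann, seed = 7)
  expect_identical(log_events(l1), log_events(l2))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_edit_log(l1, f1)
  write_edit_log(l2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("agreement never decreases under a confirm-only suffix", {
  truth <- sim_truth(8)
  log <- simulate_collaboration(
    truth, tibble::tibble(error_rate = c(0.1, 0.1), confirm_diligence = 0.9),
    seed = 3
  )
  ev <- log_events(log)
  st <- protocol_state(log$soma)
  agr <- c()
  for (i in seq_len(nrow(ev))) {
    st <- try_event(st, ev[i, ])$state
    if (length(Filter(function(s) !s$deleted, st$segments)) > 0) {
      agr <- c(agr, agreement(st))
    }
  }
  conf_only <- ev$action == "confirm"
  # after the last non-confirm event, agreement is non-decreasing
  tail_start <- max(which(!conf_only))
  if (tail_start < nrow(ev)) {
    expect_true(all(diff(agr[tail_start:length(agr)]) >= -1e-12))
  }
})

test_that("revoking cross edits resurrects peer-deleted spurious branches", {
  st_truth <- sim_truth(13)
  # force errors so deletes occur
  log <- simulate_collaboration(
    st_truth, tibble::tibble(error_rate = c(0.35, 0.35), confirm_diligence = 1),
    seed = 21
  )
  ev <- log_events(log)
  cross_del <- any(ev$action == "delete")
  collab <- replay_log(log)
  noncollab <- revoke_cross_edits(log)
  if (cross_del) {
    expect_gt(total_length(noncollab), total_length(collab) - 1e-9)
    # bookkeeping: length difference equals the revoked deletions' lengths
    # (each segment's cable includes the edge from its attachment point)
    authors <- list()
    geoms <- list()
    parents <- list()
    for (i in seq_len(nrow(ev))) {
      if (ev$action[i] == "add") {
        authors[[ev$segment_id[i]]] <- ev$user[i]
        geoms[[ev$segment_id[i]]] <- ev$geometry[[i]]
        parents[[ev$segment_id[i]]] <- ev$parent_id[i]
      }
    }
    revoked <- 0
    for (i in which(ev$action == "delete")) {
      sid <- ev$segment_id[i]
      if (authors[[sid]] != ev$user[i]) {
        g <- geoms[[sid]]
        att <- if (identical(parents[[sid]], "SOMA")) {
          log$soma[1:3]
        } else {
          pg <- geoms[[parents[[sid]]]]
          c(pg$x[nrow(pg)], pg$y[nrow(pg)], pg$z[nrow(pg)])
        }
        revoked <- revoked +
          sqrt(sum((c(g$x[1], g$y[1], g$z[1]) - att)^2)) +
          sum(sqrt(diff(g$x)^2 + diff(g$y)^2 + diff(g$z)^2))
      }
    }
    expect_equal(total_length(noncollab) - total_length(collab), revoked,
                 tolerance = 1e-6)
  } else {
    expect_equal(total_length(noncollab), total_length(collab))
  }
  # log without cross edits: identical replay
  clean <- simulate_collaboration(
    st_truth, tibble::tibble(error_rate = c(0, 0), confirm_diligence = 1),
    seed = 2
  )
  expect_equal(as.data.frame(revoke_cross_edits(clean)),
               as.data.frame(replay_log(clean)))
})

test_that("edit logs round-trip through JSONL and import from CSV", {
  truth <- sim_truth(2, n_branches = 6)
  log <- simulate_collaboration(
    truth, tibble::tibble(error_rate = c(0.2, 0.2), confirm_diligence = 0.9),
    seed = 5
  )
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_edit_log(log, f)
  back <- read_edit_log(f)
  expect_equal(back$soma, log$soma)
  expect_equal(log_events(back)$segment_id, log_events(log)$segment_id)
  expect_equal(as.data.frame(replay_log(back)), as.data.frame(replay_log(log)))

  csv <- withr::local_tempfile(fileext = ".csv")
  ev <- log_events(log)
  gstr <- vapply(ev$geometry, function(g) {
    if (is.null(g)) "" else paste(apply(g[, c("x", "y", "z", "radius")], 1,
                                        paste, collapse = ":"), collapse = ";")
  }, character(1))
  utils::write.csv(
    data.frame(timestamp = ev$timestamp, user = ev$user, action = ev$action,
               segment_id = ev$segment_id, parent_id = ev$parent_id,
               parent_node = ev$parent_node, geometry = gstr),
    csv, row.names = FALSE, na = ""
  )
  back2 <- read_edit_log_csv(csv, soma = log$soma)
  expect_equal(as.data.frame(replay_log(back2)), as.data.frame(replay_log(log)))
})

test_that("stage replay equals the final tree and cross-module snapshots agree", {
  truth <- sim_truth(4)
  log <- simulate_collaboration(
    truth, tibble::tibble(error_rate = c(0.1, 0.1, 0.1), confirm_diligence = 0.9),
    seed = 6
  )
  ser <- stage_snapshots(log, 8)
  expect_equal(as.data.frame(ser$stages[[8]]), as.data.frame(replay_log(log)))
})

test_that("contrast maps localise collaborative additions by region", {
  collab <- mk_tree(data.frame(
    id = 1:3, type = c(1, 2, 2), x = c(4, 27, 27), y = c(4, 4, 27), z = 4,
    radius = 1, parent = c(-1, 1, 2)
  ), unit = "voxel")
  noncollab <- mk_tree(as.data.frame(collab)[1:2, ], unit = "voxel")
  # two regions split at y = 16
  lab <- array(1L, dim = c(32, 32, 8))
  lab[, 17:32, ] <- 2L
  regions <- image_volume(lab, bit_depth = 8)
  tab <- contrast_projection_map(collab, noncollab, regions, dist_threshold = 2)
  expect_equal(tab$symbol[tab$region == 2], "+")
  expect_equal(tab$added_length[tab$region == 1] +
                 tab$added_length[tab$region == 2],
               sum(tab$added_length), tolerance = 1e-9)
  # identical trees: everything 'o'
  tab0 <- contrast_projection_map(collab, collab, regions)
  expect_true(all(tab0$symbol == "o"))
  # conservation: per-region added sums to the whole-volume added length
  one_region <- image_volume(array(1L, dim = c(32, 32, 8)), bit_depth = 8)
  tab1 <- contrast_projection_map(collab, noncollab, one_region)
  expect_equal(sum(tab$added_length), sum(tab1$added_length), tolerance = 0.01)
})
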