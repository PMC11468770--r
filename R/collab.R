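#' Annotation events and edit logs
#'
#' An edit log is the time-ordered record of segment-level annotation events
#' that produced a reconstruction: `add` events carry the new segment's
#' polyline geometry and its attachment (the parent segment and node index,
#' or `"SOMA"`), while `delete` and `confirm` reference an existing segment.
#' Replaying the log reproduces the reconstruction at any moment, which is
#' what makes stage recovery ([stage_snapshots()]) and the
#' collaborative-vs-noncollaborative contrast ([revoke_cross_edits()])
#' possible.
#'
#' @param events A tibble with columns `timestamp` (non-decreasing), `user`,
#'   `action` (`add`/`delete`/`confirm`), `segment_id`, `parent_id`,
#'   `parent_node`, `replaces` and a `geometry` list-column of tibbles with
#'   `x`, `y`, `z`, `radius` (for `add` events).
#' @param soma Numeric length-4 `(x, y, z, radius)` soma position.
#' @param ground_truth Optional [neuron_tree()] the log was generated from.
#' @return An `edit_log`.
#' @export
edit_log <- function(events, soma, ground_truth = NULL) {
  events <- tibble::as_tibble(events)
  req <- c("timestamp", "user", "action", "segment_id")
  stopifnot(all(req %in% names(events)))
  if (!"parent_id" %in% names(events)) events$parent_id <- NA_character_
  if (!"parent_node" %in% names(events)) events$parent_node <- NA_integer_
  if (!"replaces" %in% names(events)) events$replaces <- NA_character_
  if (!"geometry" %in% names(events)) events$geometry <- vector("list", nrow(events))
  if (is.unsorted(events$timestamp)) {
    rlang::abort("event timestamps must be non-decreasing")
  }
  structure(
    list(events = events, soma = as.double(soma), ground_truth = ground_truth),
    class = "edit_log"
  )
}

#' @rdname edit_log
#' @param log An `edit_log`.
#' @export
log_events <- function(log) log$events

#' @export
print.edit_log <- function(x, ...) {
  ev <- x$events
  cat(sprintf(
    "# edit_log: %d events (%d add / %d delete / %d confirm), %d user(s)\n",
    nrow(ev), sum(ev$action == "add"), sum(ev$action == "delete"),
    sum(ev$action == "confirm"), length(unique(ev$user))
  ))
  invisible(x)
}

#' Protocol state of a collaborative reconstruction
#'
#' The collaborative protocol is a set of rules over segment-level
#' annotations: (1) a user may add a neurite only where it originates from
#' the soma, from a neurite the same user reconstructed, or from a confirmed
#' neurite; (2) a user may confirm, delete or modify another user's neurite
#' only if it originates from the soma or extends a confirmed neurite;
#' (3) nobody confirms their own reconstruction; (4) the reconstruction is
#' complete only when every remaining neurite has been confirmed.
#'
#' @param soma Numeric length-4 `(x, y, z, radius)`.
#' @return A `protocol_state`.
#' @export
protocol_state <- function(soma = c(0, 0, 0, 5)) {
  structure(
    list(soma = as.double(soma), segments = list()),
    class = "protocol_state"
  )
}

#' @export
print.protocol_state <- function(x, ...) {
  segs <- x$segments
  del <- vapply(segs, function(s) s$deleted, logical(1))
  conf <- vapply(segs, function(s) s$status == "confirmed", logical(1))
  cat(sprintf(
    "# protocol_state: %d live segment(s) (%d confirmed), %d deleted\n",
    sum(!del), sum(conf & !del), sum(del)
  ))
  invisible(x)
}

# base conditions: this sits on the replay/fuzz hot path where the cost of
# building an rlang backtrace per rejected event is prohibitive
protocol_abort <- function(type, msg) {
  stop(errorCondition(msg,
                      class = c(paste0("protocol_", type), "protocol_violation")))
}

#' Apply one annotation event to a protocol state
#'
#' Enforces the collaboration rules; a violating event raises a classed
#' `protocol_violation` condition (`protocol_self_confirm`,
#' `protocol_unanchored_add`, `protocol_unconfirmed_parent`,
#' `protocol_unknown_segment`) and leaves the state unchanged. Deleting a
#' segment cascades to everything attached to it.
#'
#' @param state A [protocol_state()].
#' @param event A one-row event tibble, or an equivalent named list (see
#'   [edit_log()]).
#' @return The updated `protocol_state`.
#' @export
apply_event <- function(state, event) {
  res <- apply_event_impl(state, event)
  if (!is.null(res$violation)) {
    protocol_abort(res$violation, res$message)
  }
  res$state
}

# Non-signalling rule engine shared by apply_event() and try_event():
# returns list(state, violation = NULL | type, message). Kept condition-free
# because replay and fuzzing reject thousands of events per run.
apply_event_impl <- function(state, event) {
  reject <- function(type, msg) list(state = state, violation = type, message = msg)
  action <- event$action
  user <- event$user
  sid <- event$segment_id
  segs <- state$segments
  if (action == "add") {
    pid <- event$parent_id
    if (is.na(pid)) return(reject("unanchored_add", "add event lacks an attachment"))
    if (!identical(pid, "SOMA")) {
      par <- segs[[pid]]
      if (is.null(par) || par$deleted) {
        return(reject("unanchored_add",
                      sprintf("attachment segment %s does not exist", pid)))
      }
      if (par$author != user && par$status != "confirmed") {
        return(reject("unconfirmed_parent", sprintf(
          "user %s cannot extend %s's unconfirmed segment %s",
          user, par$author, pid
        )))
      }
    }
    if (!is.null(segs[[sid]])) {
      return(reject("unknown_segment", sprintf("segment id %s already used", sid)))
    }
    geom <- event$geometry[[1]]
    if (is.null(geom) || nrow(geom) == 0) {
      return(reject("unanchored_add", "add event carries no geometry"))
    }
    segs[[sid]] <- list(
      id = sid, author = user, status = "unvalidated", confirmer = NA_character_,
      parent_id = pid,
      parent_node = if (is.na(event$parent_node)) NA_integer_ else event$parent_node,
      geometry = tibble::as_tibble(geom), deleted = FALSE
    )
  } else if (action %in% c("confirm", "delete")) {
    seg <- segs[[sid]]
    if (is.null(seg) || seg$deleted) {
      return(reject("unknown_segment", sprintf("segment %s does not exist", sid)))
    }
    rule2_ok <- identical(seg$parent_id, "SOMA") ||
      (!is.null(segs[[seg$parent_id]]) &&
         segs[[seg$parent_id]]$status == "confirmed" &&
         !segs[[seg$parent_id]]$deleted)
    if (action == "confirm") {
      if (seg$author == user) {
        return(reject("self_confirm",
                      sprintf("user %s cannot confirm their own segment %s",
                              user, sid)))
      }
      if (!rule2_ok) {
        return(reject("unconfirmed_parent", sprintf(
          "segment %s does not originate from the soma or a confirmed segment",
          sid
        )))
      }
      segs[[sid]]$status <- "confirmed"
      segs[[sid]]$confirmer <- user
    } else {
      if (seg$author != user && !rule2_ok) {
        return(reject("unconfirmed_parent", sprintf(
          "user %s cannot delete segment %s under an unconfirmed parent",
          user, sid
        )))
      }
      # cascade: the whole attached subtree goes
      to_del <- sid
      repeat {
        more <- names(segs)[vapply(segs, function(s) {
          !s$deleted && !(s$id %in% to_del) && s$parent_id %in% to_del
        }, logical(1))]
        if (length(more) == 0) break
        to_del <- c(to_del, more)
      }
      for (d in to_del) segs[[d]]$deleted <- TRUE
    }
  } else {
    rlang::abort(sprintf("unknown action '%s'", action))
  }
  state$segments <- segs
  list(state = state, violation = NULL, message = NULL)
}

#' @rdname apply_event
#' @return `try_event()` returns `list(state, accepted, reason)` instead of
#'   signalling.
#' @export
try_event <- function(state, event) {
  res <- apply_event_impl(state, event)
  if (is.null(res$violation)) {
    list(state = res$state, accepted = TRUE, reason = NA_character_)
  } else {
    list(state = state, accepted = FALSE,
         reason = paste0("protocol_", res$violation))
  }
}

#' Is the collaborative reconstruction complete?
#'
#' True when every non-deleted segment has been confirmed (vacuously true
#' for a soma-only state).
#'
#' @param state A [protocol_state()].
#' @return Logical.
#' @export
is_complete <- function(state) {
  live <- Filter(function(s) !s$deleted, state$segments)
  all(vapply(live, function(s) s$status == "confirmed", logical(1)))
}

segment_cable_length <- function(seg) {
  g <- seg$geometry
  if (nrow(g) < 2) return(0)
  sum(sqrt(diff(g$x)^2 + diff(g$y)^2 + diff(g$z)^2))
}

#' Agreement ratio of a reconstruction state
#'
#' The fraction of reconstructed cable length that has been mutually agreed
#' upon — confirmed by a collaborator other than its author (the protocol
#' guarantees at least two distinct users touched every confirmed segment).
#'
#' @param state A [protocol_state()] with at least one live segment.
#' @return Ratio in \[0, 1\].
#' @export
agreement <- function(state) {
  live <- Filter(function(s) !s$deleted, state$segments)
  if (length(live) == 0) rlang::abort("agreement is undefined for an empty state")
  len <- vapply(live, segment_cable_length, double(1))
  conf <- vapply(live, function(s) s$status == "confirmed", logical(1))
  sum(len[conf]) / sum(len)
}

#' Assemble the current reconstruction tree from a protocol state
#'
#' @param state A [protocol_state()].
#' @param unit,voxel_size Coordinate metadata for the resulting tree.
#' @return A [neuron_tree()] rooted at the soma.
#' @export
state_to_tree <- function(state, unit = "micron", voxel_size = c(1, 1, 1)) {
  soma <- state$soma
  rows <- list(tibble::tibble(
    id = 1L, type = 1L, x = soma[1], y = soma[2], z = soma[3],
    radius = soma[4], parent = -1L
  ))
  next_id <- 2L
  node_ids <- list() # segment_id -> node ids of its geometry
  for (seg in state$segments) {
    if (seg$deleted) next
    g <- seg$geometry
    att <- if (identical(seg$parent_id, "SOMA")) {
      1L
    } else {
      ids <- node_ids[[seg$parent_id]]
      if (is.null(ids)) 1L else {
        k <- seg$parent_node
        if (is.na(k) || k < 1 || k > length(ids)) ids[length(ids)] else ids[k]
      }
    }
    ids <- next_id:(next_id + nrow(g) - 1L)
    next_id <- next_id + nrow(g)
    rows[[length(rows) + 1]] <- tibble::tibble(
      id = as.integer(ids), type = 2L, x = g$x, y = g$y, z = g$z,
      radius = g$radius, parent = as.integer(c(att, ids[-length(ids)]))
    )
    node_ids[[seg$id]] <- ids
  }
  neuron_tree(dplyr::bind_rows(rows), unit = unit, voxel_size = voxel_size)
}

#' Replay an edit log
#'
#' `replay_state()` reconstructs the protocol state after all events up to
#' `upto`; `replay_log()` returns the corresponding tree. With
#' `revoke = TRUE`, every delete whose actor is not the segment's author —
#' and every add that replaces another user's segment — is skipped,
#' producing the noncollaborative reconstruction in which cross-user edits
#' never happened.
#'
#' @param log An [edit_log()].
#' @param upto Replay events with `timestamp <= upto` (default all).
#' @param revoke Skip cross-user edits (default `FALSE`).
#' @return `replay_state()`: a `protocol_state`; `replay_log()`: a
#'   [neuron_tree()].
#' @export
replay_state <- function(log, upto = Inf, revoke = FALSE) {
  state <- protocol_state(log$soma)
  ev <- log$events
  authors <- list()
  for (i in seq_len(nrow(ev))) {
    if (ev$timestamp[i] > upto) break
    # plain-list event view: tibble row slicing is too slow for replay loops
    e <- list(
      timestamp = ev$timestamp[i], user = ev$user[i], action = ev$action[i],
      segment_id = ev$segment_id[i], parent_id = ev$parent_id[i],
      parent_node = ev$parent_node[i], replaces = ev$replaces[i],
      geometry = ev$geometry[i]
    )
    if (e$action == "add") authors[[e$segment_id]] <- e$user
    if (revoke) {
      if (e$action == "delete") {
        a <- authors[[e$segment_id]]
        if (!is.null(a) && a != e$user) next
      }
      if (e$action == "add" && !is.na(e$replaces)) {
        a <- authors[[e$replaces]]
        if (!is.null(a) && a != e$user) next
      }
    }
    res <- try_event(state, e)
    state <- res$state
  }
  state
}

#' @rdname replay_state
#' @inheritParams state_to_tree
#' @export
replay_log <- function(log, upto = Inf, revoke = FALSE, unit = "micron",
                       voxel_size = c(1, 1, 1)) {
  state_to_tree(replay_state(log, upto = upto, revoke = revoke),
                unit = unit, voxel_size = voxel_size)
}

#' @rdname replay_state
#' @export
revoke_cross_edits <- function(log, unit = "micron", voxel_size = c(1, 1, 1)) {
  replay_log(log, revoke = TRUE, unit = unit, voxel_size = voxel_size)
}

# ---- simulator -------------------------------------------------------------

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate a collaborative reconstruction session
#'
#' Round-robin agents reconstruct a known ground-truth tree under the
#' collaboration protocol. Each turn an agent first reviews an eligible peer
#' segment if one exists — confirming a correct segment, deleting a spurious
#' one with probability `confirm_diligence` (and wrongly confirming it
#' otherwise) — and otherwise traces an untraced true branch it is allowed
#' to extend; with probability `error_rate` it instead attaches a spurious
#' branch there. Every event passes [apply_event()], timestamps are turn
#' indices, and the whole run is a pure function of `seed`.
#'
#' @param truth A [neuron_tree()] ground truth (single root).
#' @param annotators A data frame with one row per annotator and columns
#'   `error_rate` and `confirm_diligence` (optionally `user`); at least two
#'   annotators, since nobody may confirm their own work.
#' @param seed Integer seed.
#' @param turn_cap Maximum number of turns (default 50 times the number of
#'   true branches).
#' @return An [edit_log()] with the truth attached.
#' @export
simulate_collaboration <- function(truth, annotators, seed = 1,
                                   turn_cap = NULL) {
  annotators <- tibble::as_tibble(annotators)
  stopifnot(all(c("error_rate", "confirm_diligence") %in% names(annotators)))
  if (nrow(annotators) < 2) {
    rlang::abort("at least 2 annotators are required: nobody may confirm their own work")
  }
  if (!"user" %in% names(annotators)) {
    annotators$user <- paste0("user", seq_len(nrow(annotators)))
  }
  roots <- root_rows(truth)
  if (length(roots) != 1) rlang::abort("`truth` must have exactly one root")

  # decompose the truth into branch segments with parent links
  paths <- branch_paths(truth)
  starts <- vapply(paths, `[`, integer(1), 1)
  ends <- vapply(paths, function(p) p[length(p)], integer(1))
  parent_seg <- vapply(seq_along(paths), function(k) {
    if (starts[k] == roots) 0L else match(starts[k], ends)
  }, integer(1))
  geom_of <- function(k) {
    p <- paths[[k]][-1]
    tibble::tibble(x = truth$x[p], y = truth$y[p], z = truth$z[p],
                   radius = truth$radius[p])
  }
  nseg <- length(paths)
  if (is.null(turn_cap)) turn_cap <- 50L * max(nseg, 1L)
  soma <- c(truth$x[roots], truth$y[roots], truth$z[roots], truth$radius[roots])

  with_preserved_seed(seed, {
    state <- protocol_state(soma)
    events <- list()
    seg_counter <- 0L
    # bookkeeping: per truth segment, the live state segment id (or NA)
    live_id <- rep(NA_character_, nseg)
    is_false <- character(0) # state segment ids that are spurious
    emit <- function(turn, user, action, segment_id, parent_id = NA_character_,
                     parent_node = NA_integer_, geometry = NULL) {
      tibble::tibble(
        timestamp = as.double(turn), user = user, action = action,
        segment_id = segment_id, parent_id = parent_id,
        parent_node = parent_node, replaces = NA_character_,
        geometry = list(geometry)
      )
    }
    parent_state_id <- function(k) {
      if (parent_seg[k] == 0L) "SOMA" else live_id[parent_seg[k]]
    }
    done <- function() {
      all(!is.na(live_id)) && is_complete(state)
    }
    spurious_geometry <- function(at) {
      dir <- stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
      n <- sample(4:7, 1)
      step <- stats::runif(1, 1.5, 2.5)
      jig <- matrix(stats::rnorm(3 * n, sd = 0.4), ncol = 3)
      pos <- matrix(at, n, 3, byrow = TRUE) +
        outer(seq_len(n) * step, dir) + jig
      tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                     radius = rep(1, n))
    }
    for (turn in seq_len(turn_cap)) {
      ag <- annotators[(turn - 1L) %% nrow(annotators) + 1L, ]
      user <- ag$user
      # 1) review an eligible peer segment
      segs <- state$segments
      reviewable <- names(segs)[vapply(segs, function(s) {
        !s$deleted && s$status == "unvalidated" && s$author != user &&
          (identical(s$parent_id, "SOMA") ||
             (!is.null(segs[[s$parent_id]]) &&
                segs[[s$parent_id]]$status == "confirmed" &&
                !segs[[s$parent_id]]$deleted))
      }, logical(1))]
      if (length(reviewable) > 0) {
        sid <- reviewable[sample.int(length(reviewable), 1)]
        false_seg <- sid %in% is_false
        act <- if (false_seg && stats::runif(1) < ag$confirm_diligence) {
          "delete"
        } else {
          "confirm"
        }
        e <- emit(turn, user, act, sid)
        state <- apply_event(state, e[1, ])
        events[[length(events) + 1]] <- e
        if (act == "delete") {
          idx <- match(sid, live_id)
          if (!is.na(idx)) live_id[idx] <- NA_character_
        }
        if (done()) break
        next
      }
      # 2) trace an untraced true branch this user may extend
      eligible <- which(vapply(seq_len(nseg), function(k) {
        if (!is.na(live_id[k])) return(FALSE)
        pid <- parent_state_id(k)
        if (is.na(pid)) return(FALSE)
        if (identical(pid, "SOMA")) return(TRUE)
        par <- state$segments[[pid]]
        !is.null(par) && !par$deleted &&
          (par$author == user || par$status == "confirmed")
      }, logical(1)))
      if (length(eligible) == 0) next
      k <- eligible[sample.int(length(eligible), 1)]
      pid <- parent_state_id(k)
      seg_counter <- seg_counter + 1L
      sid <- sprintf("s%04d", seg_counter)
      if (stats::runif(1) < ag$error_rate) {
        at <- if (identical(pid, "SOMA")) {
          soma[1:3]
        } else {
          g <- state$segments[[pid]]$geometry
          c(g$x[nrow(g)], g$y[nrow(g)], g$z[nrow(g)])
        }
        e <- emit(turn, user, "add", sid, parent_id = pid,
                  geometry = spurious_geometry(at))
        state <- apply_event(state, e[1, ])
        events[[length(events) + 1]] <- e
        is_false <- c(is_false, sid)
      } else {
        e <- emit(turn, user, "add", sid, parent_id = pid,
                  geometry = geom_of(k))
        state <- apply_event(state, e[1, ])
        events[[length(events) + 1]] <- e
        live_id[k] <- sid
      }
      if (done()) break
    }
    edit_log(dplyr::bind_rows(events), soma = soma, ground_truth = truth)
  })
}

#' Contrast map between collaborative and noncollaborative reconstructions
#'
#' Per region of a label volume, the cable length present only in the
#' collaborative reconstruction (`added_length`), the length present only in
#' the noncollaborative one (`subtracted_length`), and the dominant symbol:
#' `"+"` where collaborative addition dominates, `"-"` where subtraction
#' dominates, `"o"` where no collaborative editing took place.
#'
#' @param collab,noncollab [neuron_tree()]s in the label volume's voxel
#'   frame.
#' @param regions An [image_volume()] of integer region labels.
#' @param dist_threshold Match distance (default two voxels).
#' @param tol Lengths below `tol` count as zero.
#' @return A tibble with columns `region`, `added_length`,
#'   `subtracted_length`, `symbol`.
#' @export
contrast_projection_map <- function(collab, noncollab, regions,
                                    dist_threshold = 2, tol = 1e-9) {
  if (!is_image_volume(regions)) rlang::abort("`regions` must be an image_volume")
  d <- dim(regions$data)
  step <- min(1, dist_threshold / 2)
  rc <- resample_tree(collab, step)
  rn <- resample_tree(noncollab, step)
  side <- function(a, b) {
    prow <- match(a$parent, a$id)
    has <- !is.na(prow) & a$parent != -1L
    if (!any(has)) {
      return(tibble::tibble(region = integer(), len = double()))
    }
    mid <- cbind(
      (a$x[has] + a$x[prow[has]]) / 2,
      (a$y[has] + a$y[prow[has]]) / 2,
      (a$z[has] + a$z[prow[has]]) / 2
    )
    len <- edge_lengths(a)[has]
    if (nrow(b) > 0) {
      nn <- nearest_points(mid, cbind(b$x, b$y, b$z))
      un <- nn$distance > dist_threshold
    } else {
      un <- rep(TRUE, nrow(mid))
    }
    if (!any(un)) return(tibble::tibble(region = integer(), len = double()))
    vox <- pmin(pmax(round(mid[un, , drop = FALSE] -
                             matrix(regions$origin, sum(un), 3, byrow = TRUE)),
                     0), matrix(d - 1, sum(un), 3, byrow = TRUE))
    lab <- regions$data[vox + 1]
    tibble::tibble(region = as.integer(lab), len = len[un])
  }
  added <- side(rc, rn)
  subtracted <- side(rn, rc)
  all_regions <- sort(unique(as.integer(regions$data)))
  agg <- function(df) {
    out <- stats::setNames(rep(0, length(all_regions)), all_regions)
    if (nrow(df) > 0) {
      s <- tapply(df$len, factor(df$region, levels = all_regions), sum)
      out[!is.na(s)] <- s[!is.na(s)]
    }
    out
  }
  a <- agg(added)
  s <- agg(subtracted)
  symbol <- ifelse(a < tol & s < tol, "o", ifelse(a > s, "+", ifelse(s > a, "-", "o")))
  tibble::tibble(
    region = all_regions, added_length = unname(a),
    subtracted_length = unname(s), symbol = unname(symbol)
  )
}

# ---- edit-log serialisation ------------------------------------------------

#' Read and write edit logs
#'
#' Logs are serialised as JSON lines: a schema header line followed by one
#' event object per line. A simple CSV import is also provided, with
#' geometry encoded as semicolon-separated `x:y:z:radius` quadruples.
#'
#' @param log An [edit_log()].
#' @param path File path.
#' @return `write_edit_log()` returns `path` invisibly; the readers return
#'   an `edit_log`.
#' @export
write_edit_log <- function(log, path) {
  header <- jsonlite::toJSON(
    list(schema = "neuronkit-editlog-1", soma = log$soma),
    auto_unbox = TRUE, digits = NA
  )
  ev <- log$events
  lines <- vapply(seq_len(nrow(ev)), function(i) {
    g <- ev$geometry[[i]]
    obj <- list(
      timestamp = ev$timestamp[i], user = ev$user[i], action = ev$action[i],
      segment_id = ev$segment_id[i]
    )
    if (!is.na(ev$parent_id[i])) obj$parent_id <- ev$parent_id[i]
    if (!is.na(ev$parent_node[i])) obj$parent_node <- ev$parent_node[i]
    if (!is.na(ev$replaces[i])) obj$replaces <- ev$replaces[i]
    if (!is.null(g)) obj$geometry <- unname(as.matrix(g[, c("x", "y", "z", "radius")]))
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}

#' @rdname write_edit_log
#' @export
read_edit_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) rlang::abort("empty edit-log file")
  header <- jsonlite::fromJSON(lines[1])
  if (!identical(header$schema, "neuronkit-editlog-1")) {
    rlang::abort("unrecognised edit-log schema")
  }
  rows <- lapply(lines[-1], function(l) {
    o <- jsonlite::fromJSON(l)
    geom <- NULL
    if (!is.null(o$geometry)) {
      m <- matrix(unlist(o$geometry), ncol = 4,
                  byrow = !is.matrix(o$geometry))
      if (is.matrix(o$geometry)) m <- o$geometry
      geom <- tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], radius = m[, 4])
    }
    tibble::tibble(
      timestamp = as.double(o$timestamp), user = o$user, action = o$action,
      segment_id = o$segment_id,
      parent_id = if (is.null(o$parent_id)) NA_character_ else o$parent_id,
      parent_node = if (is.null(o$parent_node)) NA_integer_ else as.integer(o$parent_node),
      replaces = if (is.null(o$replaces)) NA_character_ else o$replaces,
      geometry = list(geom)
    )
  })
  edit_log(dplyr::bind_rows(rows), soma = as.double(header$soma))
}

#' @rdname write_edit_log
#' @param soma Soma position for the CSV import (the CSV has no header line
#'   carrying it).
#' @export
read_edit_log_csv <- function(path, soma = c(0, 0, 0, 5)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  geom <- lapply(df$geometry, function(s) {
    if (is.na(s) || s == "") return(NULL)
    quads <- strsplit(strsplit(s, ";")[[1]], ":")
    m <- do.call(rbind, lapply(quads, as.numeric))
    tibble::tibble(x = m[, 1], y = m[, 2], z = m[, 3], radius = m[, 4])
  })
  ev <- tibble::tibble(
    timestamp = as.double(df$timestamp), user = as.character(df$user),
    action = as.character(df$action), segment_id = as.character(df$segment_id),
    parent_id = if ("parent_id" %in% names(df)) as.character(df$parent_id) else NA_character_,
    parent_node = if ("parent_node" %in% names(df)) as.integer(df$parent_node) else NA_integer_,
    replaces = NA_character_,
    geometry = geom
  )
  edit_log(ev, soma = soma)
}
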