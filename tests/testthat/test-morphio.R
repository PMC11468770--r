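test_that("read_swc parses minimal files and degenerate input", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 5 -1", "2 2 1 0 0 1 1", "3 2 2 0 0 1 2"), f)
  tr <- read_swc(f)
  expect_equal(nrow(tr), 3)
  expect_equal(tr$id[tr$parent == -1], 1)
  expect_equal(tr$radius[1], 5)

  writeLines(c("# header only", "# nothing else"), f)
  expect_equal(nrow(read_swc(f)), 0)
})

test_that("read_swc rejects malformed lines with the line number", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# c", "1 1 0 0 0 5 -1", "2 2 1 0"), f)
  expect_error(read_swc(f), "line 3", class = "neuronkit_parse_error")
  writeLines(c("1 1 0 0 0 5 -1", "1 2 1 0 0 1 1"), f)
  expect_error(read_swc(f), class = "neuronkit_structural_error")
})

test_that("write_swc emits a single data line for a one-node soma and a header for empty trees", {
  f <- withr::local_tempfile(fileext = ".swc")
  soma <- mk_tree(data.frame(id = 1, type = 1, x = 1.5, y = 2, z = 3,
                             radius = 4.25, parent = -1))
  write_swc(soma, f)
  lines <- readLines(f)
  data <- lines[!grepl("^#", lines)]
  expect_equal(data, "1 1 1.5 2 3 4.25 -1")

  write_swc(mk_tree(NULL), f)
  expect_true(all(grepl("^#", readLines(f))))
})

test_that("SWC round-trip is exact on random trees, with ESWC columns preserved", {
  f <- withr::local_tempfile(fileext = ".swc")
  for (seed in 1:100) {
    tr <- random_tree(seed, n = sample(5:40, 1), extra_cols = seed %% 3 == 0)
    write_swc(tr, f)
    back <- read_swc(f)
    a <- node_df(tr)[order(tr$id), ]
    b <- node_df(back)[order(back$id), ]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a[, names(b)])
  }
  # 11-column ESWC output keeps the extra columns
  tr <- random_tree(3, n = 12, extra_cols = TRUE)
  write_swc(tr, f)
  fields <- strsplit(grep("^#", readLines(f), invert = TRUE, value = TRUE)[1],
                     "\\s+")[[1]]
  expect_length(fields, 11)
})

test_that("validate_tree reports each violation kind", {
  expect_equal(nrow(validate_tree(y_tree())), 0)

  three_kids <- mk_tree(data.frame(
    id = 1:6, type = c(1, 2, 2, 2, 2, 2),
    x = c(0, 5, 10, 10, 10, 10), y = c(0, 0, 3, -3, 0, 6), z = 0, radius = 1,
    parent = c(-1, 1, 2, 2, 2, 3)
  ))
  v <- validate_tree(three_kids)
  expect_true("quasi_binary" %in% v$rule)
  expect_equal(v$node_id[v$rule == "quasi_binary"], 2)

  two_roots <- mk_tree(data.frame(
    id = 1:3, type = c(1, 2, 1), x = 0:2, y = 0, z = 0, radius = 1,
    parent = c(-1, 1, -1)
  ))
  expect_true("multiple_roots" %in% validate_tree(two_roots)$rule)

  orphan <- mk_tree(data.frame(id = 1:2, type = c(1, 2), x = 0:1, y = 0, z = 0,
                               radius = 1, parent = c(-1, 99)))
  expect_true("orphan_parent" %in% validate_tree(orphan)$rule)

  neg <- mk_tree(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                            radius = -1, parent = -1))
  expect_true("negative_radius" %in% validate_tree(neg)$rule)
})

test_that("soma with many children is allowed but a cycle is reported", {
  soma_multi <- mk_tree(data.frame(
    id = 1:5, type = c(1, 2, 2, 2, 2), x = c(0, 1, -1, 0, 0),
    y = c(0, 0, 0, 1, -1), z = 0, radius = 1, parent = c(-1, 1, 1, 1, 1)
  ))
  expect_equal(nrow(validate_tree(soma_multi)), 0)

  cyc <- mk_tree(data.frame(id = 1:3, type = 2, x = 0:2, y = 0, z = 0,
                            radius = 1, parent = c(3, 1, 2)))
  expect_true("cycle" %in% validate_tree(cyc)$rule)
})

test_that("terminal branches below six nodes are pruned, six-node branches kept", {
  # stem of 3, bifurcation at node 3, one long arm (7 nodes) + short arm
  build <- function(short_n) {
    long <- data.frame(
      id = 4:10, type = 2, x = 3:9, y = 1, z = 0, radius = 1,
      parent = c(3, 4:9)
    )
    short <- data.frame(
      id = 11:(10 + short_n), type = 2, x = 3:(2 + short_n), y = -1, z = 0,
      radius = 1, parent = c(3, if (short_n > 1) 11:(9 + short_n))
    )
    mk_tree(rbind(
      data.frame(id = 1:3, type = c(1, 2, 2), x = 0:2, y = 0, z = 0,
                 radius = 1, parent = c(-1, 1, 2)),
      long, short
    ))
  }
  pruned5 <- prune_short_terminal_branches(build(5))
  expect_equal(nrow(pruned5), 10) # 5-node branch removed
  expect_false(any(pruned5$id %in% 11:15))

  pruned6 <- prune_short_terminal_branches(build(6))
  expect_equal(nrow(pruned6), 16) # exactly six units retained
})

test_that("pruning is iterative, root-exempt and idempotent", {
  # straight tree: single terminal branch hangs off the root -> exempt
  ch <- chain_tree(20, spacing = 1)
  expect_equal(nrow(prune_short_terminal_branches(ch)), 20)

  for (seed in 1:100) {
    tr <- random_tree(seed, n = sample(10:60, 1))
    once <- prune_short_terminal_branches(tr)
    twice <- prune_short_terminal_branches(once)
    expect_equal(as.data.frame(twice), as.data.frame(once))
  }
})

test_that("resampling spaces nodes evenly and preserves topology and length", {
  ch <- chain_tree(11, spacing = 10) # 100 um straight segment
  rs <- resample_tree(ch, 10)
  expect_equal(nrow(rs), 11)
  d <- sqrt(diff(rs$x)^2 + diff(rs$y)^2 + diff(rs$z)^2)
  expect_true(all(abs(d - 10) < 1e-9))

  soma_only <- mk_tree(data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                                  radius = 5, parent = -1))
  expect_equal(nrow(resample_tree(soma_only, 3)), 1)

  expect_error(resample_tree(ch, 0), "positive")

  for (seed in 1:50) {
    tr <- random_tree(seed, n = sample(10:50, 1))
    f0 <- global_features(tr)
    f1 <- global_features(resample_tree(tr, 2))
    expect_lt(abs(f1$total_length - f0$total_length) / max(f0$total_length, 1e-9), 0.01)
    expect_equal(f1$n_tips, f0$n_tips)
    expect_equal(f1$n_bifurcations, f0$n_bifurcations)
  }
})

test_that("global features match closed forms", {
  y <- y_tree() # 10 um stem + two sqrt(200) arms? no: arms are 10*sqrt(2)
  f <- global_features(y)
  expect_equal(f$n_bifurcations, 1L)
  expect_equal(f$n_tips, 2L)
  expect_equal(f$total_length, 10 + 2 * sqrt(100 + 100))
  expect_equal(f$topological_depth, 2L)

  # cylinder of radius 1, height 10: frustum volume = 10 * pi
  cyl <- mk_tree(data.frame(id = 1:2, type = c(1, 2), x = c(0, 10), y = 0,
                            z = 0, radius = 1, parent = c(-1, 1)))
  expect_equal(global_features(cyl)$volume, 10 * pi)

  expect_equal(global_features(mk_tree(NULL))$total_length, 0)

  # full binary trees hanging off a 1-child soma: tips = bifurcations + 1
  for (seed in 1:20) {
    tr <- random_tree(seed + 500, n = 41)
    f <- global_features(tr)
    kids <- table(factor(tr$parent, levels = tr$id))
    if (kids[1] == 1 && all(kids %in% c(0, 1, 2))) {
      expect_equal(f$n_tips, f$n_bifurcations + 1L)
    }
  }
})

test_that("unit conversion is an involution and scales positions per axis", {
  tr <- neuron_tree(as.data.frame(random_tree(1)), unit = "voxel",
                    voxel_size = c(0.5, 0.5, 2))
  um <- convert_units(tr, "micron")
  expect_equal(um$z, tr$z * 2)
  expect_equal(um$x, tr$x * 0.5)
  back <- convert_units(um, "voxel")
  expect_equal(as.data.frame(back), as.data.frame(tr))
})
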