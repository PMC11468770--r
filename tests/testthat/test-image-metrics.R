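test_that("signal complexity divides foreground by background mean per cube", {
  # one 16^3 cube volume: half foreground at 200, half background at 50
  vol <- array(50, dim = c(16, 16, 16))
  tr <- mk_tree(data.frame(id = 1:2, type = c(1, 2), x = c(0, 15), y = 8,
                           z = 8, radius = 2, parent = c(-1, 1)), unit = "voxel")
  mask <- neuronkit:::rasterize_tree_mask(tr, c(0, 0, 0), c(16, 16, 16))
  vol[mask] <- 200
  cm <- signal_complexity_map(image_volume(vol), tr, cube = 16)
  expect_equal(as.vector(attr(cm, "raw")), 4)

  # all-background cube scores zero; rescaled max is 255 for non-constant maps
  tr2 <- mk_tree(data.frame(id = 1:2, type = c(1, 2), x = c(0, 12), y = 8,
                            z = 8, radius = 2, parent = c(-1, 1)), unit = "voxel")
  mask2 <- neuronkit:::rasterize_tree_mask(tr2, c(0, 0, 0), c(32, 16, 16))
  vol2 <- array(50, dim = c(32, 16, 16))
  vol2[mask2] <- 200
  cm2 <- signal_complexity_map(image_volume(vol2), tr2, cube = 16)
  expect_equal(dim(cm2$data), c(2, 1, 1))
  expect_equal(attr(cm2, "raw")[2, 1, 1], 0)
  expect_equal(max(cm2$data), 255)

  expect_warning(
    signal_complexity_map(image_volume(array(50, dim = c(16, 16, 16))),
                          mk_tree(NULL), cube = 16),
    "zero"
  )
})

test_that("local structural complexity reduces to classic Sholl at the root", {
  ch <- chain_tree(21, spacing = 5)
  sc <- local_structural_complexity(ch, radii = c(12, 23))
  mid <- sc$score[sc$id == 11]
  expect_equal(mid, 4L) # 2 crossings per radius on a straight chain

  for (seed in 1:10) {
    tr <- resample_tree(random_tree(seed, n = 25), 2)
    radii <- c(5, 15, 30)
    got <- local_structural_complexity(tr, radii, per_radius = TRUE)
    root <- tr$id[tr$parent == -1][1]
    want <- oracle_sholl(tr, c(tr$x[tr$id == root], tr$y[tr$id == root],
                               tr$z[tr$id == root]), radii)
    expect_equal(got$crossings[got$id == root], as.integer(want))
  }

  # radii beyond the bounding sphere give zero
  far <- local_structural_complexity(ch, radii = 1e5)
  expect_true(all(far$score == 0))
  expect_true(all(local_structural_complexity(ch, radii = c(3, 8))$score >= 0))
})

test_that("user attention counts distinct users in the node box", {
  tr <- chain_tree(3, spacing = 50)
  geom_near <- tibble::tibble(x = 2, y = 1, z = 0, radius = 1)
  ev <- tibble::tibble(
    timestamp = c(1, 2, 3, 4),
    user = c("u1", "u1", "u1", "u2"),
    action = c("add", "confirm", "confirm", "add"),
    segment_id = c("s1", "s1", "s1", "s2"),
    parent_id = c("SOMA", NA, NA, "SOMA"),
    parent_node = NA_integer_, replaces = NA_character_,
    geometry = list(geom_near, NULL, NULL,
                    tibble::tibble(x = 3, y = -2, z = 1, radius = 1))
  )
  log <- edit_log(ev, soma = c(0, 0, 0, 3))
  att <- user_attention(tr, log, box = 20)
  expect_equal(att$attention[att$id == 1], 2L) # two distinct users
  expect_equal(att$attention[att$id == 2], 0L) # nothing near x = 50
  # three events by one user still count once
  att1 <- user_attention(tr, edit_log(ev[1:3, ], soma = c(0, 0, 0, 3)), box = 20)
  expect_equal(att1$attention[att1$id == 1], 1L)
  # order of events is irrelevant
  att_rev <- user_attention(tr, edit_log(ev[c(1, 4, 2, 3), ] |>
                                           dplyr::mutate(timestamp = 1:4),
                                         soma = c(0, 0, 0, 3)), box = 20)
  expect_equal(att_rev$attention, att$attention)
})

test_that("attention box is closed below and open above", {
  tr <- chain_tree(2, spacing = 100)
  mk_log <- function(x) {
    edit_log(tibble::tibble(
      timestamp = 1, user = "u1", action = "add", segment_id = "s1",
      parent_id = "SOMA", parent_node = NA_integer_, replaces = NA_character_,
      geometry = list(tibble::tibble(x = x, y = 0, z = 0, radius = 1))
    ), soma = c(0, 0, 0, 3))
  }
  expect_equal(user_attention(tr, mk_log(-10), box = 20)$attention[1], 1L)
  expect_equal(user_attention(tr, mk_log(10), box = 20)$attention[1], 0L)
})

test_that("NMF quality separates sparse bright tubes from uniform background", {
  spec <- phantom_spec(volume_shape = c(64, 64, 64), n_branches = 4,
                       branch_length_range = c(15, 30), soma_radius = 6,
                       intensity = list(noise_sd = 20), seed = 2)
  rend <- render_volume(make_tree(spec), spec)
  q <- nmf_image_quality(rend$volume, slab = 10, rank = 3)
  expect_gt(q$signal_median, 0)
  expect_gt(q$signal_rsd, 0)
  expect_true(is.finite(q$contrast))
  expect_equal(q$n_components, 3L)

  expect_error(nmf_image_quality(image_volume(array(7, dim = c(16, 16, 30)))),
               "degenerate|constant")
  expect_error(nmf_image_quality(image_volume(array(7, dim = c(16, 16, 5)))),
               "slab")
})

test_that("NMF quality is monotone in the phantom noise level", {
  rsd <- vapply(c(10, 40, 80), function(ns) {
    sp <- phantom_spec(volume_shape = c(64, 64, 64), n_branches = 4,
                       branch_length_range = c(15, 30), soma_radius = 6,
                       intensity = list(noise_sd = ns), seed = 2)
    nmf_image_quality(render_volume(make_tree(sp), sp)$volume)$signal_rsd
  }, double(1))
  # ranking by signal_rsd (descending) puts the cleanest phantom first
  expect_true(all(diff(rsd) < 0))
})

test_that("NMF quality is stable under z-slab permutation of a homogeneous phantom", {
  set.seed(6)
  vol <- array(round(pmax(rnorm(32 * 32 * 40, 80, 10), 0)), dim = c(32, 32, 40))
  vol[10:20, 10:20, ] <- vol[10:20, 10:20, ] + 150 # z-homogeneous structure
  q1 <- nmf_image_quality(image_volume(vol), slab = 10)
  perm <- c(2, 4, 1, 3)
  vol2 <- vol
  for (s in 1:4) {
    vol2[, , ((s - 1) * 10 + 1):(s * 10)] <-
      vol[, , ((perm[s] - 1) * 10 + 1):(perm[s] * 10)]
  }
  q2 <- nmf_image_quality(image_volume(vol2), slab = 10)
  expect_equal(q1$signal_median, q2$signal_median, tolerance = 0.05)
  expect_equal(q1$signal_rsd, q2$signal_rsd, tolerance = 0.05)
})
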