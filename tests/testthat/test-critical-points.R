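test_that("extract_candidates prunes first, then emits branch points and tips", {
  # spread-out Y: stem 1-4, arm A nodes 5..10 off node 4, arm B nodes 11..16
  yy <- mk_tree(data.frame(
    id = 1:16, type = c(1, rep(2, 15)),
    x = c(0:3, 4:9, 4:9), y = c(rep(0, 4), 1:6, -(1:6)), z = 0, radius = 1,
    parent = c(-1, 1:3, 4, 5:9, 4, 11:15)
  ))
  cand <- extract_candidates(yy)
  expect_equal(sum(cand$kind == "branching"), 1)
  expect_equal(sum(cand$kind == "terminal"), 2)
  expect_equal(cand$x[cand$kind == "branching"], 3)

  # a 4-node terminal branch is pruned away and emits nothing
  with_short <- mk_tree(rbind(
    as.data.frame(yy),
    data.frame(id = 17:20, type = 2, x = 4:7, y = 0.5, z = 0, radius = 1,
               parent = c(10, 17:19))
  ))
  cand2 <- extract_candidates(with_short)
  expect_equal(nrow(cand2), nrow(cand))

  # identity scale keeps positions; anisotropic scale multiplies per axis
  sc <- extract_candidates(yy, resolution_scale = c(2, 1, 1))
  expect_equal(sc$x, cand$x * 2)
  expect_equal(sc$y, cand$y)
})

test_that("patch pairs are always size^3 with masks following the tubes", {
  vol <- image_volume(array(100, dim = c(64, 64, 64)))
  straight <- mk_tree(data.frame(
    id = 1:2, type = c(1, 2), x = c(0, 63), y = 32, z = 32, radius = 1,
    parent = c(-1, 1)
  ), unit = "voxel")
  pp <- make_patch_pair(vol, straight, c(32, 32, 32))
  expect_equal(dim(pp$image_patch), c(32, 32, 32))
  expect_equal(dim(pp$mask_patch), c(32, 32, 32))
  # tube of radius 1 through a 32-long patch: compare with cylinder volume
  expect_equal(sum(pp$mask_patch), pi * 1^2 * 32, tolerance = 0.3 * pi * 32)

  far <- make_patch_pair(vol, straight, c(32, 5, 5))
  expect_equal(sum(far$mask_patch), 0)

  corner <- make_patch_pair(vol, straight, c(0, 0, 0))
  expect_equal(dim(corner$image_patch), c(32, 32, 32)) # zero-padded
  expect_equal(sum(corner$image_patch == 0) > 0, TRUE)
})

test_that("patch extraction is translation-equivariant", {
  set.seed(8)
  base <- array(round(runif(40^3, 0, 500)), dim = c(40, 40, 40))
  big <- array(0, dim = c(48, 48, 48))
  big[5:44, 5:44, 5:44] <- base
  tr <- chain_tree(4)
  p1 <- make_patch_pair(image_volume(base), tr, c(20, 20, 20), size = 16)
  p2 <- make_patch_pair(image_volume(big), tr, c(24, 24, 24), size = 16)
  expect_equal(p1$image_patch, p2$image_patch)
})

test_that("the heuristic verifier separates junctions, terminals and continuations", {
  set.seed(4)
  shape <- c(64, 64, 64)
  junction <- mk_tree(data.frame(
    id = 1:4, type = c(1, 2, 2, 2), x = c(0, 32, 63, 63),
    y = c(32, 32, 52, 12), z = 32, radius = 1.5, parent = c(-1, 1, 2, 2)
  ), unit = "voxel")
  vj <- render_tubes(junction, shape, amplitude = 300, noise_sd = 12, seed = 4)
  tube <- mk_tree(data.frame(
    id = 1:2, type = c(1, 2), x = c(0, 63), y = 20, z = 20, radius = 1.5,
    parent = c(-1, 1)
  ), unit = "voxel")
  vt <- render_tubes(tube, shape, amplitude = 300, noise_sd = 12, seed = 5)
  ended <- mk_tree(data.frame(
    id = 1:2, type = c(1, 2), x = c(0, 32), y = 20, z = 20, radius = 1.5,
    parent = c(-1, 1)
  ), unit = "voxel")
  ve <- render_tubes(ended, shape, amplitude = 300, noise_sd = 12, seed = 6)

  pj <- make_patch_pair(vj, junction, c(32, 32, 32))
  expect_equal(heuristic_classifier(pj, "branching"), 1)
  # straight tube with a false bifurcation claimed at its middle
  pm <- make_patch_pair(vt, tube, c(32, 20, 20))
  expect_equal(heuristic_classifier(pm, "branching"), 0)
  expect_equal(heuristic_classifier(pm, "terminal"), 0) # continues both ways
  # genuine end of a neurite
  pe <- make_patch_pair(ve, ended, c(32, 20, 20))
  expect_equal(heuristic_classifier(pe, "terminal"), 1)
})

test_that("verify_candidates enforces the classifier contract", {
  vol <- image_volume(array(100, dim = c(40, 40, 40)))
  pp <- make_patch_pair(vol, chain_tree(3), c(20, 20, 20))
  out <- verify_candidates(list(pp, pp), c("branching", "terminal"),
                           classifier = function(pair, kind) 1)
  expect_equal(out$label, c(TRUE, TRUE))
  expect_error(
    verify_candidates(list(pp), "branching", classifier = function(p, k) 1.7),
    "contract"
  )
})

test_that("evaluate_verifier scores against the expert tree and recounts exactly", {
  expert <- mk_tree(data.frame(
    id = 1:16, type = c(1, rep(2, 15)),
    x = c(0:3, 4:9, 4:9), y = c(rep(0, 4), 1:6, -(1:6)), z = 0, radius = 1,
    parent = c(-1, 1:3, 4, 5:9, 4, 11:15)
  ))
  cand <- extract_candidates(expert, min_nodes = 1)
  # oracle-true predictions: everything positive at its own location
  perfect <- evaluate_verifier(cand, rep(TRUE, nrow(cand)), expert)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$accuracy, 1)

  # balanced truth, all-positive classifier: recall 1, accuracy 0.5
  off <- cand
  off$x <- off$x + 50 # displaced duplicates are negatives
  both <- rbind(cand, off)
  ev <- evaluate_verifier(both, rep(TRUE, nrow(both)), expert)
  expect_equal(ev$recall, 1)
  expect_equal(ev$accuracy, 0.5)
  # brute recount from raw labels
  truth <- c(rep(TRUE, nrow(cand)), rep(FALSE, nrow(off)))
  pred <- rep(TRUE, nrow(both))
  expect_equal(ev$tp, sum(pred & truth))
  expect_equal(ev$fp, sum(pred & !truth))
})

test_that("the heuristic beats the sanity floor on injected errors", {
  set.seed(10)
  shape <- c(96, 96, 64)
  truth <- mk_tree(data.frame(
    id = 1:6, type = c(1, 2, 2, 2, 2, 2),
    x = c(4, 48, 92, 92, 70, 92), y = c(32, 32, 52, 12, 42, 42), z = 32,
    radius = 1.5, parent = c(-1, 1, 2, 2, 3, 5)
  ), unit = "voxel")
  vol <- render_tubes(truth, shape, amplitude = 300, noise_sd = 12, seed = 10)
  # candidates: one true junction, one false junction (mid-shaft), one true
  # terminal, one false terminal (mid-shaft break claim)
  cand <- tibble::tibble(
    x = c(48, 26, 92, 70),
    y = c(32, 32, 12, 32),
    z = c(32, 32, 32, 32),
    kind = c("branching", "branching", "terminal", "terminal")
  )
  pairs <- lapply(seq_len(nrow(cand)), function(i) {
    make_patch_pair(vol, truth, c(cand$x[i], cand$y[i], cand$z[i]))
  })
  verdicts <- verify_candidates(pairs, cand$kind)
  truth_lab <- c(TRUE, FALSE, TRUE, FALSE)
  expect_gte(mean(verdicts$label == truth_lab), 0.8)
})
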