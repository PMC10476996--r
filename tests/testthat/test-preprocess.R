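# Preprocessing chain: normalization, AddMap, eligibility, windowing,
# padding, sample assembly.

test_that("z-score statistics come from voxels above the air threshold", {
  v <- image_volume(array(c(-1000, 0, 100, -1000), c(1, 2, 2)), c(3, 2, 2))
  out <- zscore_normalize(v)
  st <- attr(out, "norm_stats")
  expect_equal(unname(st), c(50, 50))                 # population sd
  expect_equal(sort(unique(as.vector(out$voxels))), c(-21, -1, 1))
  # already standardized above threshold -> unchanged there
  x <- array(c(-1000, -1, 1, -1000, -1, 1), c(1, 2, 3))
  v2 <- zscore_normalize(image_volume(x, c(3, 2, 2)))
  expect_equal(v2$voxels[x > -1000], x[x > -1000])
  # degenerate inputs
  expect_error(zscore_normalize(image_volume(array(-1000, c(2, 2, 2)),
                                             c(1, 1, 1))), "fewer than 2")
  expect_error(zscore_normalize(image_volume(array(7, c(2, 2, 2)),
                                             c(1, 1, 1))), "degenerate")
})

test_that("AddMap encodes overlap 1, body-only 0.5, background 0", {
  body <- array(0L, c(3, 4, 4)); body[, 2:3, 2:3] <- 1L
  s <- array(0L, c(3, 4, 4)); s[2, 2, 2] <- 1L
  am <- make_addmap(body, s)
  expect_equal(am[2, 2, 2], 1)
  expect_equal(am[1, 2, 2], 0.5)
  expect_equal(am[1, 1, 1], 0)
  expect_setequal(unique(as.vector(am)), c(0, 0.5, 1))
  outside <- s; outside[1, 1, 1] <- 1L
  expect_warning(am2 <- make_addmap(body, outside), "outside the body")
  expect_equal(am2[1, 1, 1], 0.5)
  expect_error(make_addmap(body * 2L, s), "binary")
})

test_that("masking outside the body zeroes the tabletop region", {
  ct <- image_volume(array(200, c(2, 3, 3)), c(3, 2, 2))
  body <- array(0L, c(2, 3, 3)); body[, 1:2, ] <- 1L
  out <- mask_outside_body(ct, body)
  expect_true(all(out$voxels[, 3, ] == 0))
  expect_true(all(out$voxels[, 1:2, ] == 200))
  expect_identical(mask_outside_body(ct, array(1L, c(2, 3, 3)))$voxels,
                   ct$voxels)
  expect_error(mask_outside_body(ct, array(0L, c(2, 3, 3))), "empty")
})

test_that("crop_to_body spans the tight bounding box and is idempotent", {
  a <- array(rnorm(6 * 8 * 8), c(6, 8, 8))
  body <- array(0L, c(6, 8, 8)); body[2:5, 3:6, 2:7] <- 1L
  out <- crop_to_body(a, body)
  expect_identical(dim(out), c(4L, 4L, 6L))
  body_c <- crop_to_body(body, body)
  expect_identical(dim(crop_to_body(body_c, body_c)), dim(body_c))
  expect_identical(crop_to_body(a, array(1L, dim(a))), a,
                   ignore_attr = TRUE)
})

test_that("slice eligibility flips strictly between cap and cap + 1", {
  mk <- function(n_slices) {
    m <- array(0L, c(100, 2, 2)); m[seq_len(n_slices), 1, 1] <- 1L
    m
  }
  expect_true(slice_eligibility(mk(96), 96))
  expect_false(slice_eligibility(mk(97), 96))
  # the count is nonzero slices, not extent
  gap <- array(0L, c(100, 2, 2)); gap[c(1, 100), 1, 1] <- 1L
  expect_true(slice_eligibility(gap, 96))
})

test_that("center window follows the floor-midpoint rule and keeps all nonzero slices", {
  m <- array(0L, c(200, 2, 2)); m[41:61, 1, 1] <- 1L   # 0-based 40..60
  expect_identical(center_window(m, 96L), c(3L, 98L))  # 0-based [2, 98)
  # symmetric structure -> symmetric window
  m2 <- array(0L, c(50, 2, 2)); m2[21:30, 1, 1] <- 1L
  w <- center_window(m2, 10L)
  expect_identical(w[2] - w[1] + 1L, 10L)
  expect_true(w[1] <= 21 && w[2] >= 30)
  # structure near the inferior edge: window clipped + zero-padded
  m3 <- array(0L, c(30, 2, 2)); m3[1:5, 1, 1] <- 1L
  w3 <- center_window(m3, 20L)
  expect_lt(w3[1], 1L)
  win <- extract_window(m3, w3)
  expect_identical(dim(win)[1], 20L)
  expect_equal(sum(win), sum(m3))                      # containment
  expect_true(all(win[seq_len(1L - w3[1]), , ] == 0))  # zero-filled part
})

test_that("pad_or_downscale pads symmetrically and downscales only at inference", {
  ch <- array(1, c(96, 150, 250))
  out <- pad_or_downscale(ch, c(184L, 280L, 96L))
  expect_identical(dim(out), c(96L, 184L, 280L))
  expect_true(all(out[, 1:17, ] == 0) && all(out[, 168:184, ] == 0))
  expect_true(all(out[, , 1:15] == 0) && all(out[, , 266:280] == 0))
  expect_true(all(out[, 18:167, 16:265] == 1))
  # odd remainder goes to the high-index side
  odd <- pad_or_downscale(array(1, c(2, 3, 3)), c(4L, 4L, 2L))
  expect_identical(dim(odd), c(2L, 4L, 4L))
  expect_true(all(odd[, 4, ] == 0) && all(odd[, , 4] == 0))
  expect_true(all(odd[, 1:3, 1:3] == 1))
  # already at target size -> identity
  same <- array(rnorm(4 * 4 * 2), c(2, 4, 4))
  expect_identical(pad_or_downscale(same, c(4L, 4L, 2L)), same)
  # oversize: fatal in training, in-plane downscale at inference
  big <- array(0.5, c(96, 220, 340))
  expect_error(pad_or_downscale(big, c(200L, 328L, 96L)), "downscal")
  shrunk <- pad_or_downscale(big, c(200L, 328L, 96L),
                             allow_downscale = TRUE)
  expect_identical(dim(shrunk), c(96L, 200L, 328L))
  expect_setequal(unique(as.vector(shrunk)), 0.5)      # NN keeps codomain
})

test_that("sample assembly composes the chain deterministically", {
  p <- generate_phantom(phantom_spec("desk"), 11, "p01")
  cfg <- preprocess_config("desk")
  s1 <- suppressMessages(
    preprocess_patient(p$volume, p$structures, cfg, labels = p$labels))
  s2 <- suppressMessages(
    preprocess_patient(p$volume, p$structures, cfg, labels = p$labels))
  expect_gt(length(s1), 0)
  expect_identical(s1, s2)                             # determinism
  tg <- cfg$target_grid
  for (s in s1) {
    expect_identical(dim(s$ct), c(tg[3], tg[1], tg[2]))
    expect_true(all(s$addmap %in% c(0, 0.5, 1)))
  }
  # different structures get different slice windows when centers differ
  nms <- vapply(s1, function(s) s$name, character(1))
  am_bl <- s1[[which(nms == "Bladder")]]$addmap
  am_bw <- s1[[which(nms == "Bowel_Dev")]]$addmap
  expect_false(identical(am_bl, am_bw))
  ct_bl <- s1[[which(nms == "Bladder")]]$ct
  ct_bw <- s1[[which(nms == "Bowel_Dev")]]$ct
  expect_false(identical(ct_bl, ct_bw))                # per-structure CT
})

test_that("oversize structures are skipped with a message", {
  p <- generate_phantom(phantom_spec("desk"), 11, "p01")
  cfg <- preprocess_config("desk")
  tall <- array(0L, dim(p$volume$voxels))
  tall[1:(cfg$slice_cap + 1L), 20:24, 20:24] <- 1L
  body <- p$structures$structures[[1]]$mask
  tall <- tall * body
  expect_gt(length(nonzero_slices(tall)), cfg$slice_cap)
  ss <- structure_set("p01", c(p$structures$structures,
                               list(named_structure("TallOne", tall))),
                      body_index = 1L)
  msgs <- capture_messages(
    out <- preprocess_patient(p$volume, ss, cfg))
  expect_match(paste(msgs, collapse = "\n"), "TallOne")
  expect_true("TallOne" %in% attr(out, "skipped"))
  expect_false("TallOne" %in% vapply(out, function(s) s$name,
                                     character(1)))
})

test_that("profile configs carry the clinical-scale values", {
  bowel <- preprocess_config("bowel")
  pelvis <- preprocess_config("pelvis")
  expect_equal(bowel$target_spacing, c(3, 2, 2))
  expect_equal(bowel$target_grid, c(184L, 280L, 96L))
  expect_equal(pelvis$target_grid, c(200L, 328L, 96L))
  expect_equal(bowel$slice_cap, 96L)
  expect_equal(bowel$air_threshold, -1000)
  expect_error(preprocess_config("bowel", target_grid = c(10L, 10L, 5L)),
               "slice cap")
})
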