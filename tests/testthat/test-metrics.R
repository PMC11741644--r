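test_that("Dice matches hand-evaluated overlaps and conventions", {
  # |S| = 8, |T| = 8, |S intersect T| = 6 on a 4x4 toy grid
  a <- array(0L, c(4, 4)); a[1:2, 1:4] <- 1L
  b <- array(0L, c(4, 4)); b[1:2, 2:4] <- 1L; b[3, 1:2] <- 1L
  expect_equal(dice_score(a, b, 1), 0.75)

  # identity is perfect
  set.seed(5)
  v <- array(sample(0:3, 6^3, TRUE), c(6, 6, 6))
  for (l in 1:3) expect_equal(dice_score(v, v, l), 1)

  # disjoint masks
  d1 <- array(0L, c(5, 4)); d1[1:2, ] <- 1L
  d2 <- array(0L, c(5, 4)); d2[4:5, ] <- 1L
  expect_equal(dice_score(d1, d2, 1), 0)

  # absent from both: 1 by convention; grid mismatch errors
  expect_equal(dice_score(a, b, 7), 1)
  expect_error(dice_score(a, array(0L, c(5, 5)), 1), "grids differ")
})

test_that("Dice equals brute-force counting on random masks", {
  set.seed(21)
  for (rep in 1:60) {
    d <- if (rep %% 2 == 0) c(6, 6, 6) else c(5, 7)
    p <- array(sample(0:2, prod(d), TRUE), d)
    t <- array(sample(0:2, prod(d), TRUE), d)
    l <- sample(1:2, 1)
    expect_equal(dice_score(p, t, l), dice_bruteforce(p, t, l),
                 tolerance = 1e-12)
    expect_equal(dice_score(p, t, l), dice_score(t, p, l))
  }
})

test_that("surface extraction follows the face-connectivity convention", {
  # single voxel is its own surface
  m <- array(0L, c(3, 3, 3)); m[2, 2, 2] <- 1L
  s <- extract_surface(m, 1)
  expect_identical(nrow(s), 1L)
  expect_equal(as.vector(s), c(2, 2, 2))

  # filled 5^3 cube: 5^3 - 3^3 = 98 surface voxels
  cube <- array(0L, c(7, 7, 7)); cube[2:6, 2:6, 2:6] <- 1L
  expect_identical(nrow(extract_surface(cube, 1)), 98L)

  # 1-voxel-thick sheet: every voxel is surface
  sheet <- array(0L, c(6, 6, 6)); sheet[3, , ] <- 1L
  expect_identical(nrow(extract_surface(sheet, 1)), 36L)

  # grid edges count as outside: only the centre of a full 3x3 grid has all
  # of its face neighbours inside the mask
  full <- array(1L, c(3, 3))
  expect_identical(nrow(extract_surface(full, 1)), 8L)

  expect_error(extract_surface(array(0L, c(4, 4)), 1), "empty")

  # agreement with the brute-force neighbour check
  set.seed(31)
  for (rep in 1:20) {
    mask <- random_mask(c(5, 5, 5))
    got <- extract_surface(mask, TRUE)
    want <- surface_bruteforce(mask)
    expect_identical(nrow(got), nrow(want))
    expect_identical(got[order(got[, 1], got[, 2], got[, 3]), , drop = FALSE],
                     matrix(as.numeric(want[order(want[, 1], want[, 2],
                                                  want[, 3]), , drop = FALSE]),
                            ncol = 3))
  }
})

test_that("ASD matches hand geometry and scales with spacing", {
  # identical volumes: 0
  set.seed(6)
  v <- array(sample(0:1, 5^3, TRUE), c(5, 5, 5))
  expect_equal(asd(v, v, 1), 0)

  # two parallel unit-spaced sheets offset by 2 voxels: every nearest
  # distance is exactly 2
  s1 <- array(0L, c(8, 8, 8)); s1[3, , ] <- 1L
  s2 <- array(0L, c(8, 8, 8)); s2[5, , ] <- 1L
  expect_equal(asd(s1, s2, 1), 2)
  expect_equal(asd(s1, s2, 1, spacing = c(2, 2, 2)), 4)

  # spacing must agree between volumes unless overridden
  lv1 <- label_volume(s1, spacing = c(1, 1, 1))
  lv2 <- label_volume(s2, spacing = c(2, 1, 1))
  expect_error(asd(lv1, lv2, 1), "spacing")
  expect_equal(asd(lv1, lv2, 1, spacing = c(1, 1, 1)), 2)

  # undefined for empty masks
  empty <- array(0L, c(8, 8, 8))
  expect_error(asd(s1, empty, 1), "undefined")
})

test_that("ASD equals the brute-force double loop and is symmetric", {
  set.seed(41)
  for (rep in 1:25) {
    d <- c(6, 6, 6)
    p <- random_mask(d, 0.35)
    t <- random_mask(d, 0.35)
    sp <- sample(c(1, 0.5, 2), 3, replace = TRUE)
    got <- asd(p, t, TRUE, spacing = sp)
    want <- asd_bruteforce(p, t, TRUE, spacing = sp)
    expect_equal(got, want, tolerance = 1e-9)
    expect_equal(asd(p, t, TRUE, spacing = sp), asd(t, p, TRUE, spacing = sp),
                 tolerance = 1e-12)
  }
})

test_that("mean quality averages per-label Dice (environment response)", {
  set.seed(8)
  p <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
  t <- array(sample(0:3, 8^3, TRUE), c(8, 8, 8))
  per <- vapply(1:3, function(l) dice_score(p, t, l), numeric(1))
  expect_equal(mean_quality(p, t, 1:3), mean(per))
  expect_equal(mean_quality(p, t, 2), per[2])
  expect_equal(mean_quality(t, t, 1:3), 1)
  expect_error(mean_quality(p, t, integer(0)), "at least one")
})

test_that("label volumes validate their contents", {
  expect_error(label_volume(array(c(0.5, 1), c(1, 2))), "integers")
  expect_error(label_volume(array(-1L, c(2, 2))), "integers")
  expect_error(label_volume(array(0L, c(2, 2)), spacing = c(1, 0)),
               "spacing")
  lv <- label_volume(array(0:3, c(2, 2)), spacing = c(0.5, 2))
  expect_identical(lv$labels[2, 2], 3L)
})
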