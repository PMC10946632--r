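test_that("overlap metrics match their printed formulas", {
  g <- array(0L, c(10, 10, 1))
  a <- g; a[1:5, 1, 1] <- 1L
  cc <- confusion_counts(a, a)
  expect_identical(unlist(cc), c(tp = 5L, fp = 0L, fn = 0L, tn = 95L))
  expect_equal(dice_score(cc), 1)
  cc2 <- confusion_counts(g, a)
  expect_identical(cc2$fn, 5L)
  expect_equal(dice_score(list(tp = 2, fp = 1, fn = 1, tn = 0)), 4 / 6)
  expect_equal(sensitivity(list(tp = 3, fn = 1, fp = 0, tn = 0)), 0.75)
  expect_equal(specificity(list(tn = 99, fp = 1, tp = 0, fn = 0)), 0.99)
  expect_equal(specificity(list(tn = 10, fp = 0, tp = 0, fn = 0)), 1)
  # empty-mask conventions
  expect_equal(dice_score(list(tp = 0, fp = 0, fn = 0, tn = 27)), 1)
  expect_true(is.na(sensitivity(list(tp = 0, fn = 0, fp = 0, tn = 27))))
})

test_that("counts agree with an exhaustive per-voxel tally on random masks", {
  set.seed(42)
  for (rep in 1:20) {
    a <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    b <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
    tp <- fp <- fn <- tn <- 0
    for (i in 1:64) {
      if (a[i] == 1 && b[i] == 1) tp <- tp + 1
      else if (a[i] == 1) fp <- fp + 1
      else if (b[i] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    cc <- confusion_counts(a, b)
    expect_equal(unlist(cc), c(tp = tp, fp = fp, fn = fn, tn = tn),
                 ignore_attr = FALSE, tolerance = 0)
  }
})

test_that("surface extraction marks exactly the face-exposed voxels", {
  m <- array(0L, c(7, 7, 7))
  m[2:6, 2:6, 2:6] <- 1L
  sp <- surface_points(m)
  expect_identical(nrow(sp), 125L - 27L)     # 5^3 minus the 3^3 interior
  # single voxel is its own boundary
  s1 <- array(0L, c(3, 3, 3)); s1[2, 2, 2] <- 1L
  expect_identical(nrow(surface_points(s1)), 1L)
  # spacing scales coordinates
  sp2 <- surface_points(m, spacing = c(2, 1, 1))
  expect_equal(max(sp2[, 1]) / max(sp[, 1]), 2)
})

test_that("surface distances match brute-force all-pairs oracles", {
  set.seed(7)
  x <- matrix(runif(300, 0, 20), 100, 3)
  y <- matrix(runif(300, 0, 20), 100, 3)
  D <- sqrt(outer(rowSums(x^2), rowSums(y^2), "+") - 2 * x %*% t(y))
  dxy <- apply(D, 1, min)
  dyx <- apply(D, 2, min)
  h_oracle <- max(quantile(dxy, 0.95, type = 7),
                  quantile(dyx, 0.95, type = 7))
  expect_equal(hausdorff95(x, y), as.numeric(h_oracle), tolerance = 1e-9)
  abd_oracle <- (sum(dxy) + sum(dyx)) / 200
  expect_equal(average_boundary_distance(x, y), abd_oracle,
               tolerance = 1e-9)
  # symmetry
  expect_equal(hausdorff95(x, y), hausdorff95(y, x))
  expect_equal(average_boundary_distance(x, y),
               average_boundary_distance(y, x))
  # two single points distance d apart
  p1 <- matrix(c(0, 0, 0), 1)
  p2 <- matrix(c(3, 0, 0), 1)
  expect_equal(hausdorff95(p1, p2), 3)
  expect_equal(average_boundary_distance(p1, p2), 3)
  expect_true(is.na(hausdorff95(matrix(numeric(0), 0, 3), p1)))
})

test_that("case evaluation is exact on identity and shifts, and scales", {
  case <- std_phantom()
  r <- encode_regions(case$labels)
  m <- evaluate_case(r, r)
  expect_equal(m$dice, rep(1, 3))
  expect_equal(m$haus95_mm, rep(0, 3))
  expect_equal(m$abd_mm, rep(0, 3))
  # one-voxel shift of a large cube: haus95 = 1 mm at unit spacing
  a <- array(0L, c(30, 30, 30)); a[5:25, 5:25, 5:25] <- 1L
  b <- array(0L, c(30, 30, 30)); b[6:26, 5:25, 5:25] <- 1L
  h1 <- hausdorff95(surface_points(a), surface_points(b))
  expect_equal(h1, 1)
  # doubling spacing doubles distances, leaves rates unchanged
  ra <- structure(list(wt = a, tc = a, et = a), class = "region_channels")
  rb <- structure(list(wt = b, tc = b, et = b), class = "region_channels")
  m1 <- evaluate_case(ra, rb, spacing = c(1, 1, 1))
  m2 <- evaluate_case(ra, rb, spacing = c(2, 2, 2))
  expect_equal(m2$haus95_mm, 2 * m1$haus95_mm)
  expect_equal(m2$abd_mm, 2 * m1$abd_mm, tolerance = 1e-12)
  expect_equal(m2$dice, m1$dice)
  # empty prediction: dice 0, distances undefined
  empty <- structure(list(wt = a * 0L, tc = a * 0L, et = a * 0L),
                     class = "region_channels")
  m3 <- evaluate_case(empty, ra)
  expect_equal(m3$dice, rep(0, 3))
  expect_true(all(is.na(m3$haus95_mm)))
})

test_that("dice from counts equals the overlap form on binary masks", {
  set.seed(11)
  for (rep in 1:10) {
    a <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    b <- array(rbinom(27, 1, 0.5), c(3, 3, 3))
    cc <- confusion_counts(a, b)
    lhs <- dice_score(cc)
    rhs <- if (sum(a) + sum(b) == 0) 1 else
      2 * sum(a & b) / (sum(a) + sum(b))
    expect_equal(lhs, rhs)
  }
})
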