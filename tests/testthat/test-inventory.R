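test_that("multi-stem DBH combination follows the root-sum-of-squares rule", {
  expect_equal(combine_multistem_dbh(c(3, 4)), 5)
  expect_equal(combine_multistem_dbh(10), 10)
  expect_equal(combine_multistem_dbh(c(1, 1, 1)), sqrt(3))
  expect_error(combine_multistem_dbh(numeric()), "non-empty")
  expect_error(combine_multistem_dbh(c(3, -1)), "positive")
})

test_that("multi-stem DBH is permutation-invariant and superadditive", {
  set.seed(7)
  for (i in 1:20) {
    d <- runif(sample(2:5, 1), 0.5, 20)
    expect_equal(combine_multistem_dbh(d), combine_multistem_dbh(sample(d)))
    expect_gt(combine_multistem_dbh(c(d, 0.3)), combine_multistem_dbh(d))
  }
})

test_that("per-tree geometry formulas and their contracts hold", {
  expect_equal(tree_basal_area(2), pi)
  expect_equal(tree_basal_area(0), 0)
  expect_equal(tree_basal_area(10), 0.25 * pi * 100)
  expect_error(tree_basal_area(-1), "non-negative")

  expect_equal(tree_crown_area(2, 2), pi)
  expect_equal(tree_crown_area(0, 5), 0)
  expect_equal(tree_crown_area(3, 4), 3 * pi)
  expect_error(tree_crown_area(-1, 2), "non-negative")

  expect_equal(tree_crown_length(20, 12), 8)
  expect_equal(tree_crown_length(10, 10), 0)
  expect_equal(tree_crown_length(15.5, 3.25), 12.25)
  expect_error(tree_crown_length(10, 11), "tree top")
})

test_that("stand totals sum per-tree values and honour the DBH rule", {
  inv <- toy_inventory()
  tot <- stand_totals(inv)
  expect_equal(tot$tree_count, 6)
  expect_equal(tot$total_basal_area, sum(0.25 * pi * toy_trees()$dbh^2))
  expect_equal(tot$total_crown_area,
               sum(0.25 * pi * toy_trees()$crown_d1 * toy_trees()$crown_d2))
  expect_equal(tot$total_crown_length,
               sum(toy_trees()$height - toy_trees()$crown_base))
  expect_equal(tot$max_height, 20)

  # sub-threshold trees are excluded on the *effective* DBH
  tr <- toy_trees()
  tr$dbh[1] <- 0.9
  expect_equal(stand_totals(stand_inventory(tr, "X", 10))$tree_count, 5)

  empty <- stand_inventory(toy_trees()[0, ], "E", 10)
  expect_equal(stand_totals(empty)$total_basal_area, 0)
  expect_equal(stand_totals(empty)$tree_count, 0)
})

test_that("stand totals match an independent per-tree accumulation", {
  set.seed(11)
  inv <- random_inventory(100)
  tot <- stand_totals(inv)
  acc <- c(ba = 0, ca = 0, cl = 0)
  for (i in seq_len(nrow(inv))) {   # naive second route
    acc["ba"] <- acc["ba"] + 0.25 * pi * inv$dbh[i]^2
    acc["ca"] <- acc["ca"] + 0.25 * pi * inv$crown_d1[i] * inv$crown_d2[i]
    acc["cl"] <- acc["cl"] + (inv$height[i] - inv$crown_base[i])
  }
  expect_equal(tot$total_basal_area, unname(acc["ba"]))
  expect_equal(tot$total_crown_area, unname(acc["ca"]))
  expect_equal(tot$total_crown_length, unname(acc["cl"]))
})

test_that("trees rooted outside the plot are excluded with a warning", {
  tr <- toy_trees()
  tr$x[2] <- 41
  expect_warning(inv <- stand_inventory(tr, "X", 10), "outside")
  expect_equal(nrow(inv), 5)
})

test_that("subplot indexing uses half-open 5 m cells", {
  expect_equal(subplot_index(0, 0), 0L)
  expect_equal(subplot_index(4.999, 4.999), 0L)
  expect_equal(subplot_index(5, 0), 1L)
  expect_equal(subplot_index(0, 5), 8L)
  expect_equal(subplot_index(39.9, 9.9), 15L)
  expect_true(is.na(subplot_index(40, 5)))
})

test_that("structural CV over subplot sums matches hand and two-pass values", {
  # all trees in distinct cells with equal attribute -> every cell equal?
  # easier: equal subplot sums -> CV 0
  tr <- data.frame(x = 2.5 + 5 * (0:7), y = 2.5,
                   dbh = rep(10, 8), height = 10, crown_base = 5,
                   crown_d1 = 2, crown_d2 = 2)
  tr <- rbind(tr, transform(tr, y = 7.5))
  inv <- stand_inventory(tr, "X", 10)
  expect_equal(structural_cv(inv, "basal_area"), 0)

  # single occupied cell: sums (s, 0 x 15); CV = 100 * sd/mean = 400
  one <- stand_inventory(data.frame(x = 1, y = 1, dbh = 10, height = 10,
                                    crown_base = 5, crown_d1 = 2,
                                    crown_d2 = 2), "X", 10)
  expect_equal(structural_cv(one, "basal_area"), 400)

  set.seed(5)
  inv <- random_inventory(80)
  sums <- numeric(16)
  for (i in seq_len(nrow(inv)))   # brute-force two-pass oracle
    sums[inv$subplot[i] + 1] <- sums[inv$subplot[i] + 1] + inv$crown_area[i]
  m <- mean(sums)
  s <- sqrt(sum((sums - m)^2) / 15)
  expect_equal(structural_cv(inv, "crown_area"), 100 * s / m)
  expect_error(structural_cv(stand_inventory(toy_trees()[0, ], "E", 1),
                             "basal_area"), "zero")
})

test_that("cumulative profiles rank by height and normalize to 100", {
  tr <- data.frame(x = c(1, 2, 3), y = c(1, 2, 3),
                   dbh = sqrt(c(1, 1, 2) / pi) * 2,  # basal areas 1, 1, 2
                   height = c(10, 5, 15), crown_base = c(1, 1, 1),
                   crown_d1 = 1, crown_d2 = 1)
  inv <- stand_inventory(tr, "X", 10)
  cp <- cumulative_profile(inv, "basal_area")
  expect_equal(cp$height, c(5, 10, 15))
  expect_equal(cp$cumulative_percent, c(25, 50, 100))

  single <- stand_inventory(tr[1, ], "X", 10)
  cp1 <- cumulative_profile(single, "height")
  expect_equal(cp1$cumulative_percent, 100)

  # height ties keep input order
  tr2 <- tr; tr2$height <- c(7, 7, 7); tr2$tree_id <- c("a", "b", "c")
  cp2 <- cumulative_profile(stand_inventory(tr2, "X", 10), "basal_area")
  expect_equal(cp2$cumulative_percent, c(25, 50, 100))
})

test_that("cumulative profiles are non-decreasing and end at 100 (property)", {
  set.seed(13)
  for (i in 1:15) {
    inv <- random_inventory(sample(5:80, 1))
    for (at in c("basal_area", "height", "crown_area", "crown_length")) {
      cp <- cumulative_profile(inv, at)
      expect_true(all(diff(cp$cumulative_percent) >= -1e-12))
      expect_equal(cp$cumulative_percent[nrow(cp)], 100)
      expect_false(is.unsorted(cp$height))
    }
  }
})

test_that("structure sigmoid fits recover parameters of exact curves", {
  set.seed(17)
  h <- sort(runif(40, 1, 25))
  y <- 100 / (1 + exp(-0.8 * (h - 12)))
  # build a profile object directly
  cp <- structure(data.frame(height = h, cumulative_percent = y),
                  attribute = "basal_area",
                  class = c("cumulative_profile", "data.frame"))
  fit <- fit_structure_sigmoid(cp)
  expect_true(fit$converged)
  expect_equal(fit$a, 0.8, tolerance = 1e-6)
  expect_equal(fit$b, 12, tolerance = 1e-6)
  expect_error(
    fit_structure_sigmoid(structure(
      data.frame(height = c(1, 1, 2, 2), cumulative_percent = c(10, 20, 80, 100)),
      attribute = "height", class = c("cumulative_profile", "data.frame"))),
    "4 distinct")
})

test_that("stand totals are additive under inventory concatenation", {
  set.seed(19)
  a <- random_inventory(30, plot_id = "A")
  b <- random_inventory(40, plot_id = "A")
  both <- stand_inventory(rbind(as.data.frame(a)[names(toy_trees())],
                                as.data.frame(b)[names(toy_trees())]),
                          "A", 20)
  ta <- stand_totals(a); tb <- stand_totals(b); tt <- stand_totals(both)
  expect_equal(tt$total_basal_area, ta$total_basal_area + tb$total_basal_area)
  expect_equal(tt$tree_count, ta$tree_count + tb$tree_count)
})
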