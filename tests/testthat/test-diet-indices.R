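test_that("vacuity index is the percentage of empty stomachs", {
  expect_equal(vacuity_index(2, 10), 20)
  expect_equal(vacuity_index(0, 7), 0)
  expect_equal(vacuity_index(7, 7), 100)
  expect_error(vacuity_index(1, 0), "positive")
  expect_error(vacuity_index(5, 3), "n_empty")
})

test_that("composition normalises group totals to percentages", {
  dm <- dm_from_matrices(rbind(c(3, 1), c(0, 0)),
                         rbind(c(30, 1), c(0, 0)))
  expect_equal(unname(composition(dm, "weight")), c(75, 25))
  expect_equal(sum(composition(dm, "count")), 100)
  single <- dm_from_matrices(matrix(c(2, 1), 2, 1))
  expect_equal(unname(composition(single, "weight")), 100)
  empty <- dm_from_matrices(matrix(0, 2, 2))
  expect_error(composition(empty, "weight"), "empty")
})

test_that("frequency of occurrence counts stomachs containing each group", {
  W <- rbind(c(1, 0), c(1, 0), c(1, 1), c(0, 0))
  dm <- dm_from_matrices(W)
  fo <- frequency_of_occurrence(dm)
  expect_equal(unname(fo), c(75, 25))
  expect_equal(unname(frequency_of_occurrence(dm, include_empty = FALSE)),
               c(100, 100 / 3))
  all_in <- dm_from_matrices(matrix(1, 3, 1))
  expect_equal(unname(frequency_of_occurrence(all_in)), 100)
})

test_that("prey-specific ratios restrict to stomachs containing the group", {
  # stomach 1: group A 1 g of 2 g total; stomach 2: A 3 g of 4 g total
  W <- rbind(c(1, 1), c(3, 1))
  dm <- dm_from_matrices(W)
  # pooled-sums convention: 100 * (1 + 3) / (2 + 4)
  expect_equal(unname(prey_specific_ratios(dm, method = "pooled")$PW[1]),
               100 * 4 / 6)
  # mean-of-ratios convention (PSIRI's): (50 + 75) / 2
  expect_equal(unname(prey_specific_ratios(dm)$PW[1]), 62.5)
  # appending a stomach without the group leaves PW unchanged (both forms)
  W2 <- rbind(W, c(0, 5))
  dm2 <- dm_from_matrices(W2)
  expect_equal(unname(prey_specific_ratios(dm2, method = "pooled")$PW[1]),
               100 * 4 / 6)
  expect_equal(unname(prey_specific_ratios(dm2)$PW[1]), 62.5)
  # a group alone in its stomachs scores 100 either way
  alone <- dm_from_matrices(rbind(c(2, 0), c(0, 1)))
  expect_equal(unname(prey_specific_ratios(alone)$PW), c(100, 100))
  expect_equal(unname(prey_specific_ratios(alone, method = "pooled")$PW),
               c(100, 100))
  # never-observed group is missing, not zero
  miss <- dm_from_matrices(rbind(c(1, 0), c(2, 0)))
  expect_true(is.na(prey_specific_ratios(miss)$PW[2]))
})

test_that("only the mean-of-ratios convention preserves the PSIRI sum", {
  # counterexample matrix where the pooled form breaks the sum-to-100
  dm <- dm_from_matrices(rbind(c(1, 0), c(1, 3)))
  expect_equal(sum(index_table(dm)$PSIRI), 100, tolerance = 1e-12)
  expect_equal(sum(index_table(dm, method = "pooled")$PSIRI), 77.5,
               tolerance = 1e-12)
})

test_that("PSIRI follows FO (PW + PN) / 200 and is bounded by FO", {
  expect_equal(psiri(100, 100, 100), 100)
  expect_equal(psiri(0, 40, 60), 0)
  expect_error(psiri(120, 10, 10), "0, 100")
  set.seed(41)
  for (k in 1:20) {
    dm <- random_diet_matrix()
    it <- index_table(dm)
    expect_equal(it$PSIRI, it$FO * (it$PW + it$PN) / 200, tolerance = 1e-12)
    expect_true(all(it$PSIRI <= it$FO + 1e-12))
  }
})

test_that("Pi equals PW by construction on arbitrary matrices", {
  set.seed(42)
  for (k in 1:20) {
    dm <- random_diet_matrix()
    Pi <- prey_specific_abundance(dm)
    PW <- prey_specific_ratios(dm)$PW
    expect_equal(Pi, PW, tolerance = 1e-12)
  }
})

test_that("%N and %W are invariant to row order and to item splitting", {
  set.seed(43)
  dm <- random_diet_matrix(n = 6, g = 3)
  perm <- sample(6)
  dm_p <- dm_from_matrices(dm$weight[perm, ], dm$count[perm, ])
  expect_equal(composition(dm, "weight"), composition(dm_p, "weight"))
  expect_equal(composition(dm, "count"), composition(dm_p, "count"))
  # splitting one stomach's group-1 weight across two stomach rows of the
  # pooled table changes nothing at the population level
  W <- dm$weight; W[1, 1] <- W[1, 1] / 2
  W <- rbind(W, c(dm$weight[1, 1] / 2, rep(0, 2)))
  N <- rbind(dm$count, 0)
  expect_equal(unname(composition(dm_from_matrices(W, N), "weight")),
               unname(composition(dm, "weight")))
})

test_that("vacuity and percent-with-food are complementary", {
  W <- rbind(c(1, 0), c(0, 0), c(0, 2), c(0, 0))
  dm <- dm_from_matrices(W)
  it <- index_table(dm)
  vac <- attr(it, "vacuity")
  pct_food <- 100 * mean(rowSums(W) > 0)
  expect_equal(vac + pct_food, 100)
})

test_that("index_table lists only observed groups and errors on all-empty", {
  W <- cbind(c(1, 2), c(0, 0), c(3, 0))
  colnames(W) <- c("copepods", "fish", "euphausiids")
  dm <- dm_from_matrices(W)
  it <- index_table(dm)
  expect_setequal(it$prey_group, c("copepods", "euphausiids"))
  expect_error(index_table(dm_from_matrices(matrix(0, 3, 2))), "empty")
})

test_that("Amundsen coordinates and quadrants follow the 50/50 midlines", {
  # engineered matrix: group 1 common and dominant, group 2 rare and minor
  W <- rbind(c(10, 0), c(8, 0), c(9, 0), c(5, 0.5), c(6, 0), c(7, 0),
             c(9, 0), c(8, 0), c(9, 0), c(10, 0.2))
  dm <- dm_from_matrices(W)
  sp <- amundsen_points(dm)
  g1 <- sp[1, ]
  expect_equal(g1$quadrant, "dominant/specialised")
  g2 <- sp[2, ]
  expect_lt(g2$FO, 50)
  expect_equal(g2$quadrant, "rare/generalised")
  # boundary point: exactly 50/50 falls in the dominant quadrant
  Wb <- rbind(c(1, 1), c(0, 1))   # group 1: FO 50, Pi 50
  spb <- amundsen_points(dm_from_matrices(Wb))
  expect_equal(spb$quadrant[1], "dominant/specialised")
})

test_that("strategy plot renders without error", {
  dm <- random_diet_matrix()
  sp <- amundsen_points(dm)
  png_file <- withr::local_tempfile(fileext = ".png")
  grDevices::png(png_file)
  expect_no_error(plot(sp))
  grDevices::dev.off()
  expect_true(file.exists(png_file))
})
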