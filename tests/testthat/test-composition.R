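test_that("closure rescales to the day total and preserves zeros", {
  expect_equal(unname(close_composition(c(480, 480, 480, 0))),
               c(480, 480, 480, 0))
  expect_equal(unname(close_composition(c(1, 1, 1, 1))),
               rep(360, 4))
  # arithmetic-mean day of the emulated study as a smoke input
  smoke <- close_composition(c(sleep = 476, sb = 630.6, lpa = 236.4, mvpa = 81))
  expect_equal(sum(smoke), 1440)
  expect_error(close_composition(c(0, 0, 0, 0)), "all-zero")
  expect_error(close_composition(c(-1, 10, 10, 10)), "non-negative")
})

test_that("pivot ilr matches hand-derived closed forms", {
  # equal parts map to the origin under every rotation
  for (ord in names(ilr_orderings)) {
    expect_all_close(ilr_transform(rep(360, 4), ord), c(0, 0, 0), 1e-12)
  }
  # SB twice pivoted against three equal parts: ilr1 = sqrt(3/4) ln 3
  z <- ilr_transform(c(sleep = 240, sb = 720, lpa = 240, mvpa = 240), "H1")
  expect_equal(unname(z[1]), sqrt(3 / 4) * log(3), tolerance = 1e-9)
  expect_equal(unname(z[1]), 0.951426, tolerance = 1e-5)
  expect_all_close(z[2:3], c(0, 0), 1e-12)
  # sleep-to-SB balance at ratio 1:2: ilr3 of H4 = sqrt(1/2) ln(1/2)
  z4 <- ilr_transform(c(sleep = 480, sb = 960, lpa = 100, mvpa = 100), "H4")
  expect_equal(unname(z4[3]), sqrt(0.5) * log(0.5), tolerance = 1e-9)
  expect_equal(unname(z4[3]), -0.490129, tolerance = 1e-5)
  expect_error(ilr_transform(c(0, 1, 1, 1)), "positive")
})

test_that("ilr is scale invariant and inverts exactly", {
  comps <- random_compositions(1000, seed = 3)
  for (ord in names(ilr_orderings)) {
    z <- ilr_transform(comps, ord)
    expect_all_close(ilr_transform(comps * 7.3, ord), z, 1e-9)
    back <- ilr_inverse(z, ord)
    expect_all_close(back, comps, 1e-9)
    expect_all_close(ilr_transform(back, ord), z, 1e-9)
  }
  # neutral element
  expect_all_close(ilr_inverse(c(0, 0, 0)), rep(360, 4), 1e-9)
  # rotation consistency: the recovered composition does not depend on
  # which rotation carried the coordinates
  c1 <- ilr_inverse(ilr_transform(comps, "H1"), "H1")
  c4 <- ilr_inverse(ilr_transform(comps, "H4"), "H4")
  expect_all_close(c1, c4, 1e-9)
})

test_that("the four rotations are isometries of the same geometry", {
  comps <- random_compositions(200, seed = 9)
  tv <- vapply(names(ilr_orderings), function(ord) {
    sum(apply(ilr_transform(comps, ord), 2, stats::var))
  }, numeric(1))
  expect_all_close(tv, tv[1], 1e-9)
})

test_that("geometric-mean composition is idempotent and matches hand values", {
  one <- c(sleep = 500, sb = 600, lpa = 240, mvpa = 100)
  rows <- rbind(one, one, one)
  colnames(rows) <- behavior_parts
  expect_all_close(geometric_mean_composition(rows), one, 1e-9)
  two <- rbind(c(720, 360, 240, 120), c(360, 720, 240, 120))
  colnames(two) <- behavior_parts
  gm <- geometric_mean_composition(two)
  expect_all_close(gm, c(531.93, 531.93, 250.76, 125.38), 0.011)
  expect_error(geometric_mean_composition(rbind(c(0, 1, 1, 1))), "positive")
})

test_that("within-person centering removes person means exactly", {
  d <- data.frame(pid = rep(c("a", "b"), each = 2),
                  ilr1 = c(1, 1, -1, 1), ilr2 = c(0, 2, 0, 0),
                  ilr3 = c(-1, 1, 3, 3))
  cw <- center_within_person(d)
  expect_equal(cw$data$ilr1_c, c(0, 0, -1, 1))
  expect_equal(cw$data$ilr3_c[1:2], c(-1, 1))
  expect_equal(cw$data$ilr3_c[3:4], c(0, 0))
  # property: person means of centered values vanish on a generated table
  comps <- random_compositions(300, seed = 5)
  tab <- data.frame(pid = rep(sprintf("p%02d", 1:30), each = 10),
                    ilr_transform(comps, "H2"))
  cw2 <- center_within_person(tab)
  for (cl in c("ilr1_c", "ilr2_c", "ilr3_c")) {
    expect_lt(max(abs(tapply(cw2$data[[cl]], cw2$data$pid, mean))), 1e-12)
  }
})

test_that("centering equals perturbation by the inverse person geometric mean", {
  comps <- random_compositions(60, seed = 8)
  pid <- rep(sprintf("p%d", 1:6), each = 10)
  z <- ilr_transform(comps, "H3")
  cw <- center_within_person(data.frame(pid = pid, z))
  for (p in unique(pid)) {
    rows <- pid == p
    gm <- geometric_mean_composition(comps[rows, , drop = FALSE])
    pert <- close_composition(sweep(comps[rows, , drop = FALSE], 2, gm, "/"))
    expect_all_close(as.matrix(cw$data[rows, c("ilr1_c", "ilr2_c", "ilr3_c")]),
                     ilr_transform(pert, "H3"), 1e-9)
  }
})
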