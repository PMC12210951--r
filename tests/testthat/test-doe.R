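test_that("L9 skeleton has the published level pattern and is orthogonal", {
  m <- l9_design()
  expect_equal(unname(m[5, ]), c(2L, 2L, 3L))
  for (j in 1:3) expect_equal(unname(tabulate(m[, j], 3)), rep(3L, 3))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(anyDuplicated(paste(m[, i], m[, j])), 0L)
})

test_that("main-effects ANOVA reproduces the published buffer-salt table", {
  an <- main_effects_anova(load_builtin("table1"))
  f <- function(src, col) an[[col]][an$source == src]
  expect_equal(f("ammonium_citrate", "f"), 20.256, tolerance = 1e-4)
  expect_equal(f("dipotassium_phosphate", "f"), 15.651, tolerance = 1e-4)
  expect_equal(f("sodium_acetate", "f"), 5.047, tolerance = 1e-4)
  expect_equal(f("intercept", "ss"), 795.428, tolerance = 1e-5)
  expect_equal(f("ammonium_citrate", "eta_squared"), 0.483, tolerance = 1e-3)
  expect_equal(f("dipotassium_phosphate", "eta_squared"), 0.373, tolerance = 1e-3)
  expect_equal(f("sodium_acetate", "eta_squared"), 0.120, tolerance = 1e-2)
  expect_equal(attr(an, "r_squared"), 0.976, tolerance = 1e-3)
  expect_equal(f("ammonium_citrate", "p"), 0.047, tolerance = 1e-2)
})

test_that("ANOVA sums of squares match a definitional oracle and add up", {
  set.seed(3)
  for (rep in 1:5) {
    tab <- orthogonal_table(l9_design(), rnorm(9, 9.4, 0.1))
    an <- main_effects_anova(tab)
    y <- tab$response
    # oracle: SS_factor = 3 * sum over levels of (level mean - grand mean)^2
    for (f in names(tab)[2:4]) {
      ss_oracle <- 3 * sum((tapply(y, tab[[f]], mean) - mean(y))^2)
      expect_lt(abs(an$ss[an$source == f] - ss_oracle), 1e-10)
    }
    ss <- an$ss
    expect_lt(abs(sum(ss[2:4]) + ss[an$source == "residual"] -
                    ss[an$source == "total"]), 1e-10)
    # eta-squared values of the factors sum to the model R-squared
    expect_equal(sum(an$eta_squared[2:4]), attr(an, "r_squared"),
                 tolerance = 1e-12)
  }
})

test_that("ANOVA agrees with the stats::aov cross-check on the study table", {
  tab <- load_builtin("table1")
  an <- main_effects_anova(tab)
  ref <- summary(stats::aov(
    response ~ factor(sodium_acetate) + factor(ammonium_citrate) +
      factor(dipotassium_phosphate), data = as.data.frame(tab)))[[1]]
  expect_equal(an$ss[2:4], unname(ref[1:3, "Sum Sq"]), tolerance = 1e-10)
  expect_equal(an$f[2:4], unname(ref[1:3, "F value"]), tolerance = 1e-8)
  expect_equal(an$p[2:4], unname(ref[1:3, "Pr(>F)"]), tolerance = 1e-8)
})

test_that("constant responses give zero factor SS and tie-rule best levels", {
  tab <- orthogonal_table(l9_design(), rep(9.4, 9))
  an <- suppressWarnings(main_effects_anova(tab))
  expect_equal(an$ss[2:4], rep(0, 3))
  bl <- best_levels(tab)
  expect_equal(bl$best_level, rep(1L, 3))
  expect_true(all(bl$tie))
})

test_that("best level of the dominant buffer salt is its middle level", {
  bl <- best_levels(load_builtin("table1"))
  expect_equal(bl$best_level[bl$factor == "ammonium_citrate"], 2L)
  expect_equal(bl$level_mean[bl$factor == "ammonium_citrate"], 9.46,
               tolerance = 1e-12)
})

test_that("Tukey comparisons flag the ammonium citrate levels and are symmetric", {
  tab <- load_builtin("table1")
  tk <- tukey_hsd(tab, "ammonium_citrate")
  expect_true(any(tk$significant))
  expect_equal(nrow(tk), 3)
  # agreement with the stats::TukeyHSD cross-check
  ref <- stats::TukeyHSD(stats::aov(
    response ~ factor(sodium_acetate) + factor(ammonium_citrate) +
      factor(dipotassium_phosphate), data = as.data.frame(tab)))
  ref_ac <- ref[["factor(ammonium_citrate)"]]
  expect_equal(sort(tk$p_adj), sort(unname(ref_ac[, "p adj"])),
               tolerance = 1e-8)
  # identical level means: nothing significant
  tk0 <- suppressWarnings(tukey_hsd(orthogonal_table(l9_design(), rep(1, 9)),
                                    "factor1"))
  expect_false(any(tk0$significant))
})

test_that("Box-Behnken designs decode correctly", {
  d <- box_behnken(list(glucose = c(10, 20, 30), peptone = c(20, 40, 60),
                        corn_juice = c(4, 8, 12)), center_runs = 3)
  expect_equal(nrow(d), 15)
  coded <- as.matrix(d[, grep("_coded$", names(d))])
  # every edge run has exactly one coded zero
  expect_true(all(rowSums(coded[1:12, ] == 0) == 1))
  # coded (-1,-1,0) decodes to (10, 20, 8)
  hit <- which(coded[, 1] == -1 & coded[, 2] == -1 & coded[, 3] == 0)
  expect_equal(unname(unlist(d[hit, c("glucose", "peptone", "corn_juice")])),
               c(10, 20, 8))
  # center runs decode to the center point
  expect_equal(unname(unlist(d[13, c("glucose", "peptone", "corn_juice")])),
               c(20, 40, 8))
  expect_error(box_behnken(list(a = c(1, 2), b = c(1, 2, 3), c = c(1, 2, 3))),
               "3 strictly increasing")
})
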