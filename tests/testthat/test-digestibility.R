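test_that("air-dry to DM conversion scales by the DM fraction", {
  expect_equal(to_dm_basis(17.71, 90.85), 17.71 / 0.9085, tolerance = 1e-12)
  expect_equal(to_dm_basis(17.71, 90.85), 19.494, tolerance = 1e-4)
  expect_equal(to_dm_basis(5, 100), 5)
  expect_equal(to_dm_basis(0.89, 90.85) * 10, 9.797, tolerance = 1e-3)
  expect_error(to_dm_basis(5, 0), "dm_pct")
  expect_error(to_dm_basis(5, -10), "dm_pct")
})

test_that("AID follows the marker-ratio equation", {
  expect_equal(compute_aid(0, 5, 20, 10), 100)
  expect_equal(compute_aid(10, 5, 20, 10), 0)   # digesta ratio equals diet ratio
  expect_equal(compute_aid(120, 6.0, 150, 3.0), 60.0)
  # negative values are not clamped
  expect_lt(compute_aid(50, 5, 20, 10), 0)
  expect_error(compute_aid(1, 0, 1, 1), "undefined")
  expect_error(compute_aid(1, 1, 0, 1), "undefined")
})

test_that("AID is invariant to common rescaling of all concentrations", {
  set.seed(42)
  for (i in 1:25) {
    x <- runif(4, 0.5, 50)
    k <- runif(1, 0.01, 100)
    expect_equal(compute_aid(x[1], x[2], x[3], x[4]),
                 compute_aid(k * x[1], k * x[2], k * x[3], k * x[4]),
                 tolerance = 1e-9)
  }
})

test_that("endogenous loss is the marker-corrected N-free digesta flow", {
  expect_equal(compute_endogenous(10, 3, 6), 5.0)
  expect_equal(compute_endogenous(7.3, 4, 4), 7.3)  # marker unconcentrated
  expect_equal(compute_endogenous(0, 3, 6), 0)
  expect_error(compute_endogenous(1, 1, 0), "undefined")
})

test_that("SID correction reproduces the published crude-protein values", {
  expect_near(compute_sid(70.29, 21.24, to_dm_basis(17.71, 90.85) * 10),
              81.19, 0.005)
  expect_near(compute_sid(46.54, 21.24, to_dm_basis(12.82, 92.89) * 10),
              61.92, 0.05)
  expect_equal(compute_sid(70.29, 0, 194.93), 70.29)
  expect_error(compute_sid(70, 21, 0), "diet_conc_dm")
  expect_error(compute_sid(70, -1, 100), "iaa_end")
})

test_that("the whole published CP row reconstructs from AID, diets and endogenous", {
  sid <- compute_sid(row_values(fx$aid, "CP"), fx$endogenous[["CP"]],
                     diet_conc_dm("cp"))
  expect_near(sid, row_values(fx$sid, "CP"), 0.05)
})

test_that("SID >= AID for every component and lot in the published tables", {
  for (comp in fx$aid$component) {
    expect_true(all(row_values(fx$sid, comp) >= row_values(fx$aid, comp)),
                label = comp)
  }
})

test_that("treatment summaries: ANOVA, pooled SEM, Tukey letters", {
  # identical groups: no separation, shared letter
  s <- summarize_treatments(rep(1, 6), rep(c("g1", "g2"), each = 3))
  expect_equal(s$table$letters, c("a", "a"))
  expect_equal(s$p_value, 1)

  # clearly separated groups with tiny jitter
  set.seed(1)
  v <- c(rnorm(3, 0, 0.01), rnorm(3, 10, 0.01))
  s <- summarize_treatments(v, rep(c("lo", "hi"), each = 3))
  expect_lt(s$p_value, 1e-6)
  tab <- s$table[order(-s$table$mean), ]
  expect_equal(tab$letters, c("a", "b"))

  # pooled SEM convention: sqrt(MSE / n per group)
  set.seed(2)
  v <- rnorm(12)
  g <- rep(c("a", "b", "c"), each = 4)
  s <- summarize_treatments(v, g, z_cutoff = Inf)
  expect_equal(s$sem, sqrt(s$mse / 4))

  expect_error(summarize_treatments(c(1, 2, 3), c("a", "a", "b")),
               "degrees-of-freedom")
})

test_that("Z-score screen drops wild replicates before summarization", {
  set.seed(3)
  v <- c(rnorm(20, 50, 1), rnorm(19, 50, 1), 500)  # one gross assay error
  g <- rep(c("a", "b"), each = 20)
  s3 <- summarize_treatments(v, g, z_cutoff = 3)
  expect_equal(s3$n_excluded, 1)
  sInf <- summarize_treatments(v, g, z_cutoff = Inf)
  expect_equal(sInf$n_excluded, 0)
  expect_lt(abs(s3$table$mean[s3$table$group == "b"] - 50), 2)
  expect_gt(sInf$table$mean[sInf$table$group == "b"], 70)  # (19*50 + 500)/20
})

test_that("letter groups cover graded means correctly", {
  # three groups, outer two separated, middle overlapping both
  set.seed(4)
  v <- c(rnorm(6, 0, 1), rnorm(6, 1.6, 1), rnorm(6, 4, 1))
  g <- rep(c("lo", "mid", "hi"), each = 6)
  s <- summarize_treatments(v, g)
  lets <- setNames(s$table$letters, s$table$group)
  expect_true(all(nchar(lets) >= 1))
  # the separated extremes share no letter
  expect_length(intersect(strsplit(lets[["lo"]], "")[[1]],
                          strsplit(lets[["hi"]], "")[[1]]), 0)
})
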