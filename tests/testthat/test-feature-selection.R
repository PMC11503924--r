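test_that("a detail sub-series correlates perfectly with itself", {
  m <- dwt_mra(wiggle(1024, seed = 4), "db4", 8)
  r <- subseries_correlations(m, m$details[, "D6"])
  expect_equal(unname(r["D6"]), 1.0, tolerance = 1e-10)
})

test_that("independent white noise correlates with no sub-series", {
  hits <- 0
  for (s in 1:10) {
    set.seed(300 + s)
    m <- dwt_mra(rnorm(2048), "db4", 8)
    r <- subseries_correlations(m, rnorm(2048))
    if (all(abs(r) < 0.1)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("a target built from one level is found at that level", {
  set.seed(8)
  m <- dwt_mra(rnorm(2048), "db4", 8)
  target <- m$details[, "D5"] + rnorm(2048, sd = 0.1 * sd(m$details[, "D5"]))
  r <- subseries_correlations(m, target)
  expect_equal(unname(which.max(abs(r))), 5L)
})

test_that("degenerate series are handled by the documented conventions", {
  m <- dwt_mra(rep(1, 64), "haar", 2)
  r <- suppressWarnings(subseries_correlations(m, wiggle(64)))
  expect_equal(unname(r), c(0, 0))
  m1 <- dwt_mra(rep(1, 64), "haar", 1)
  expect_warning(subseries_correlations(m1, wiggle(64)), "zero-variance")
  m2 <- dwt_mra(wiggle(64), "haar", 2)
  expect_error(subseries_correlations(m2, rep(2, 64)), "zero variance")
  expect_error(subseries_correlations(m2, rnorm(32)), "length")
})

test_that("the sign-consistency rule reproduces the reference level sets", {
  ref <- reference_subseries_correlations()
  rownames(ref) <- ref$variable
  lev <- function(vn) {
    select_components(as.numeric(ref[vn, paste0("D", 1:10)]),
                      ref[vn, "overall"], threshold = 0.08)
  }
  expect_equal(lev("lmc"), 1:10)
  expect_equal(lev("lph"), 3:10)
  expect_equal(lev("lt"), 3:9)
  expect_equal(lev("rh"), c(3, 4, 5, 6, 8, 9, 10))
  # documented inconsistencies in the reference study: the temperature row
  # is sign-inconsistent with its positive overall correlation (auto rule
  # selects nothing), and one velocity level is omitted without explanation
  expect_equal(lev("t"), integer(0))
  expect_equal(lev("v"), c(3, 4, 5, 6, 7, 8))
  ov <- reference_component_selections()
  expect_equal(ov$t, list(rule = "explicit", levels = 2:10))
  expect_equal(ov$v, list(rule = "explicit", levels = c(3L, 4L, 5L, 6L, 8L)))
  expect_equal(ov$lmc$rule, "auto")
  expect_equal(select_components(rep(0, 10), 0.5), integer(0))
})

test_that("feature reconstruction obeys the MRA identity and exact level sums", {
  x <- wiggle(512, seed = 13)
  m <- dwt_mra(x, "db4", 6)
  expect_equal(reconstruct_feature(m, 1:6, include_approximation = TRUE), x,
               tolerance = 1e-8)
  expect_equal(reconstruct_feature(m, 4), unname(m$details[, "D4"]))
  expect_error(reconstruct_feature(m, integer(0)), "degenerate")
  expect_silent(reconstruct_feature(m, integer(0), include_approximation = TRUE))
  expect_error(reconstruct_feature(m, 7), "selected_levels")
})

test_that("Pearson correlation is invariant to the near-constant approximation", {
  d <- generate_dataset(generator_config(seed = 17))
  m <- dwt_mra(d$lmc, "db4", 10)
  # with the approximation included the feature is exactly the raw series
  r_exact <- pearson_r(reconstruct_feature(m, 1:10, TRUE), d$nh3)
  r_raw <- pearson_r(d$lmc, d$nh3)
  expect_equal(r_exact, r_raw, tolerance = 1e-12)
  # without it, the near-constant A10 shifts the correlation only marginally
  r_all <- pearson_r(reconstruct_feature(m, 1:10), d$nh3)
  expect_lt(abs(r_all - r_raw), 5e-3)
  # adding any constant shift leaves correlation untouched
  expect_lt(abs(pearson_r(d$lmc + 5, d$nh3) - r_raw), 1e-10)
})

test_that("deselecting exactly the injected noise levels never hurts", {
  for (s in c(31, 32, 33)) {
    d <- generate_dataset(generator_config(seed = s))
    noise_levels <- attr(d, "config")$noise_levels
    for (vn in c("lt", "rh", "v")) {
      m <- dwt_mra(d[[vn]], "db4", 10)
      keep <- setdiff(1:10, noise_levels[[vn]])
      den <- reconstruct_feature(m, keep)
      expect_gte(abs(cor(den, d$nh3)), abs(cor(d[[vn]], d$nh3)))
    }
  }
})

test_that("component selections carry their provenance and print cleanly", {
  sel <- component_selection("lt", c(-0.1, -0.2, 0.3), -0.4, rule = "auto",
                             threshold = 0.08)
  expect_equal(sel$selected_levels, c(1L, 2L))
  expect_output(print(sel), "selected levels: D1 \\+ D2")
  sel2 <- component_selection("v", c(-0.1, -0.2, 0.3), -0.4,
                              rule = "explicit", levels = c(3, 1))
  expect_equal(sel2$selected_levels, c(1L, 3L))
})
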