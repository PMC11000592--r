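# Sweep machinery: consistency, window recovery on a known predicate,
# derived-symbol sweeps and determinism.

test_that("a length-1 sweep equals a direct simulate-and-extract call", {
  m <- reference_model("mixed")
  sw <- sweep_param(m, "pNT", 22.4, species = "A")
  f <- simulate_features(m, species = "A")
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$class, f$dynamic_class)
  expect_equal(sw$amplitude, f$amplitude)
  expect_equal(sw$period, f$period)
})

test_that("sweeps reject bad grids and record per-point failures non-fatally", {
  m <- reference_model("mixed")
  expect_error(sweep_param(m, "pNT", c(2, 1)), "increasing")
  expect_error(sweep_param(m, "nope", 1), "unknown symbol")
  # a grid value that violates an invariant is recorded as an error row
  sw <- sweep_param(reference_model("activator_repressor"), "alpha1",
                    c(0.5, 300), horizon = 10)
  expect_equal(sw$class[1], "error")
  expect_false(sw$class[2] == "error")
})

test_that("window detection recovers the edges of a known step predicate", {
  w <- oscillation_window(NULL, "x", c(0, 10), edge_tolerance = 1e-3,
                          log_spaced = FALSE,
                          predicate = function(v) v > 2.5 && v < 7.5)
  expect_length(w, 1)
  expect_equal(w[[1]]$lower, 2.5, tolerance = 1e-3)
  expect_equal(w[[1]]$upper, 7.5, tolerance = 1e-3)
  # predicate true on the whole bracket: window = bracket
  w2 <- oscillation_window(NULL, "x", c(1, 4), predicate = function(v) TRUE)
  expect_equal(c(w2[[1]]$lower, w2[[1]]$upper), c(1, 4))
  # no sustained point: empty result, not an error
  expect_length(oscillation_window(NULL, "x", c(1, 4),
                                   predicate = function(v) FALSE), 0)
  # two disjoint windows are both returned
  w3 <- oscillation_window(NULL, "x", c(0, 10), edge_tolerance = 1e-3,
                           log_spaced = FALSE, n_coarse = 64,
                           predicate = function(v)
                             (v > 1 && v < 3) || (v > 6 && v < 8))
  expect_length(w3, 2)
  expect_equal(w3[[1]]$upper, 3, tolerance = 1e-3)
  expect_equal(w3[[2]]$lower, 6, tolerance = 1e-3)
})

test_that("critical_parameter needs a class change across the bracket", {
  expect_error(critical_parameter(lo = 0, hi = 1,
                                  predicate = function(v) "same"),
               "no class boundary")
  r <- critical_parameter(lo = 0, hi = 1, edge_tolerance = 1e-4,
                          predicate = function(v) v > 0.3183)
  expect_equal(r$value, 0.3183, tolerance = 1e-4)
})

test_that("a kon/koff scaling sweep leaves the dissociation constant invariant", {
  m <- reference_model("activator_repressor")
  kd0 <- nanodeg_kd(m$params$nanodeg)
  expect_equal(kd0, 4.41)
  for (v in c(1, 3, 10)) {
    mv <- set_param(m, "v", v)
    expect_equal(nanodeg_kd(mv$params$nanodeg), 4.41, tolerance = 1e-12)
    expect_equal(mv$params$nanodeg$kon, v * m$params$nanodeg$kon)
  }
})

test_that("repeated sweeps with identical settings are bit-identical", {
  m <- reference_model("mixed")
  g <- c(10, 22.4, 50)
  s1 <- sweep_param(m, "dna_dose", g, species = "A")
  s2 <- sweep_param(m, "dna_dose", g, species = "A")
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})
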