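make_qy <- function(n = 201) {
  lambda <- seq(600, 800, length.out = n)
  spectrum(lambda, gaussian_curve(lambda, 670, 20), axis_unit = "nm")
}

test_that("spectrum files round-trip through read/write to full precision", {
  s <- make_qy()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(s, path)
  r <- read_spectrum(path)
  expect_equal(nrow(r), 201)
  expect_equal(r$axis, s$axis, tolerance = 1e-12)
  expect_equal(r$intensity, s$intensity, tolerance = 1e-12)
  expect_identical(axis_unit(r), "nm")
})

test_that("reader handles dialects, headers, comments and descending axes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# a comment", "axis,intensity",
               sprintf("%g,%g", seq(800, 600, by = -10), 1:21)), path)
  r <- read_spectrum(path)
  expect_false(is.unsorted(r$axis))
  expect_equal(r$intensity[1], 21)  # reordered with the axis

  ws <- withr::local_tempfile()
  writeLines(sprintf("%g  %g", 1:10, (1:10)^2), ws)
  expect_equal(nrow(read_spectrum(ws)), 10)
})

test_that("reader rejects malformed input with line numbers", {
  one_col <- withr::local_tempfile()
  writeLines(as.character(1:10), one_col)
  expect_error(read_spectrum(one_col), "fewer than 2 columns")

  bad <- withr::local_tempfile()
  writeLines(c("1\t2", "2\t3", "3\toops", sprintf("%d\t1", 4:10)), bad)
  expect_error(read_spectrum(bad), "line 3")

  short <- withr::local_tempfile()
  writeLines(sprintf("%d\t1", 1:5), short)
  expect_error(read_spectrum(short), "at least 8")
})

test_that("wavelength <-> wavenumber conversion is the 1e7/x involution", {
  s <- make_qy()
  w <- to_wavenumber(s)
  expect_identical(axis_unit(w), "wavenumber")
  expect_equal(max(w$axis), 1e7 / 600, tolerance = 1e-12)
  expect_equal(min(w$axis), 1e7 / 800, tolerance = 1e-12)
  # bracket values: 830 nm and 800 nm
  expect_equal(1e7 / 830, 12048.19, tolerance = 1e-6)
  expect_equal(1e7 / 800, 12500)
  back <- to_wavelength(w)
  expect_equal(back$axis, s$axis, tolerance = 1e-9)
  expect_equal(back$intensity, s$intensity, tolerance = 1e-12)
  neg <- spectrum(c(-1, seq(2, 8)), rep(1, 8), axis_unit = "nm")
  expect_error(to_wavenumber(neg), "positive")
})

test_that("regrid produces 2^k uniform points and is exact on matching grids", {
  s <- make_qy(257)
  g <- regrid(s, k = 12, window = c(620, 780))
  expect_equal(nrow(g), 4096)
  expect_lt(diff(range(diff(g$axis))), 1e-9)

  # identity: input already uniform on the requested grid
  u <- spectrum(seq(0, 1, length.out = 16), sin(seq(0, 1, length.out = 16)))
  expect_equal(regrid(u, k = 4)$intensity, u$intensity, tolerance = 1e-12)

  # cubic interpolation reproduces a linear ramp exactly
  ramp <- spectrum(seq(0, 10, length.out = 33), seq(5, 8, length.out = 33))
  r8 <- regrid(ramp, k = 3)
  expect_equal(r8$intensity, 5 + 0.3 * r8$axis, tolerance = 1e-12)

  expect_error(regrid(s, k = 10, window = c(100, 900)), "outside")
  expect_error(regrid(s, k = 2), "between 3 and 16")
})

test_that("center_peak moves the maximum to the middle sample, reversibly", {
  n <- 4096
  ax <- seq_len(n)
  y <- gaussian_curve(ax, 100, 30)
  s <- spectrum(ax, y)
  cs <- center_peak(s)
  expect_equal(which.max(cs$intensity), n %/% 2 + 1)
  # intensity values preserved away from the padded margin
  expect_equal(sort(cs$intensity, decreasing = TRUE)[1:200],
               sort(y, decreasing = TRUE)[1:200])
  back <- uncenter_peak(cs)
  expect_equal(which.max(back$intensity), 100)

  already <- spectrum(ax, gaussian_curve(ax, n %/% 2 + 1, 30))
  expect_equal(center_peak(already)$intensity, already$intensity)

  expect_error(center_peak(spectrum(ax, rep(1, n))), "no distinct maximum")
  two <- spectrum(1:64, c(rep(0, 10), 5, rep(0, 20), 5, rep(0, 32)))
  expect_warning(centered <- center_peak(two), "equal maxima")
  expect_equal(which.max(centered$intensity), 33)  # lowest-axis peak used
})

test_that("normalize_peak scales to exactly unit maximum, preserving shape", {
  s <- make_qy()
  scaled <- spectrum(s$axis, 0.73 * s$intensity, axis_unit = "nm")
  norm <- normalize_peak(scaled)
  expect_identical(max(norm$intensity), 1)
  expect_equal(norm$intensity, s$intensity / max(s$intensity), tolerance = 1e-15)
  expect_equal(normalize_peak(norm)$intensity, norm$intensity)
  expect_error(normalize_peak(spectrum(1:8, rep(0, 8))), "positive")
})

test_that("spectrum invariants are enforced at construction", {
  expect_error(spectrum(1:7, 1:7), "at least 8")
  expect_error(spectrum(c(1, 1, 2:7), 1:8), "strictly increasing")
  expect_error(spectrum(1:8, c(1:7, NaN)), "finite")
})
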