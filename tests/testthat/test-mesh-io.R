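test_that("PLY round-trips geometry, rim flags, and scalar channels", {
  s <- make_initial_colony(0.06, 0, 0.006)
  s$channels <- list(flux = seq_len(nrow(s$vertices)) / nrow(s$vertices),
                     conc = rev(seq_len(nrow(s$vertices))) * 0.001)
  for (binary in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".ply")
    write_ply(s, path, binary = binary)
    r <- read_ply(path)
    expect_equal(r$vertices, s$vertices, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_identical(r$faces, s$faces)
    expect_identical(r$boundary, s$boundary)
    expect_equal(r$channels$flux, s$channels$flux, tolerance = 1e-12)
    expect_equal(r$channels$conc, s$channels$conc, tolerance = 1e-12)
  }
})

test_that("OFF round-trips geometry", {
  s <- make_icosphere(2, radius = 0.03)
  path <- tempfile(fileext = ".off")
  write_off(s, path)
  r <- read_off(path)
  expect_equal(r$vertices, s$vertices, tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(r$faces, s$faces)
})

test_that("STL export writes one facet per triangle", {
  s <- make_icosphere(1)
  path <- tempfile(fileext = ".stl")
  write_stl(s, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^facet normal", txt)), nrow(s$faces))
})

test_that("NRRD round-trips binary volumes and scalar fields", {
  mask <- array(runif(4 * 5 * 6) > 0.5, c(4, 5, 6))
  vol <- voxel_volume(mask, c(3.5e-4, 3.5e-4, 3e-4), origin = c(1, 2, 3))
  for (enc in c("raw", "ascii")) {
    path <- tempfile(fileext = ".nrrd")
    write_nrrd(vol, path, encoding = enc)
    r <- read_nrrd(path)
    expect_identical(r$mask, vol$mask)
    expect_equal(r$pitch, vol$pitch)
    expect_equal(r$origin, vol$origin)
  }
  field <- array(rnorm(60), c(4, 5, 3))
  path <- tempfile(fileext = ".nrrd")
  write_nrrd(field, path, pitch = rep(1e-3, 3))
  r <- read_nrrd(path)
  expect_equal(r$values, field, tolerance = 1e-15)
})

test_that("VTK field export is well-formed", {
  f <- array(seq_len(24) / 24, c(2, 3, 4))
  path <- tempfile(fileext = ".vtk")
  write_vtk_field(f, path, pitch = rep(0.01, 3), name = "conc")
  txt <- readLines(path)
  expect_true(any(grepl("DIMENSIONS 2 3 4", txt)))
  expect_true(any(grepl("SCALARS conc double", txt)))
  vals <- as.numeric(strsplit(trimws(txt[length(txt)]), " +")[[1]])
  expect_equal(vals, as.vector(f), tolerance = 1e-7)
})

test_that("flux CSV export carries vertex positions and values", {
  s <- make_icosphere(1)
  path <- tempfile(fileext = ".csv")
  write_flux_csv(s, runif(nrow(s$vertices)), path)
  d <- read.csv(path)
  expect_equal(nrow(d), nrow(s$vertices))
  expect_named(d, c("vertex", "x", "y", "z", "flux"))
})
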