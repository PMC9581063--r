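# MRC volume I/O and preprocessing for the network.

test_that("density_map validates inputs and maps voxel indices to world", {
  m <- density_map(array(0, c(3, 4, 5)), origin = c(1, -2, 0.5),
                   voxel_size = c(1, 2, 0.5))
  expect_equal(dim(m), c(3L, 4L, 5L))
  ijk <- rbind(c(0, 0, 0), c(2, 3, 4))
  w <- voxel_to_world(m, ijk)
  expect_equal(w[1, ], c(1, -2, 0.5))
  expect_equal(w[2, ], c(1 + 2, -2 + 6, 0.5 + 2))
  expect_equal(world_to_voxel(m, w), ijk, ignore_attr = TRUE)
  expect_error(density_map(matrix(0, 2, 2)), "3D")
  expect_error(density_map(array(0, c(0, 2, 2))), ">= 1")
})

test_that("write_mrc / read_mrc round trip preserves grid, origin, voxel size", {
  m <- density_map(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                   origin = c(1.5, -2.25, 3), voxel_size = c(1, 1, 1))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, path)
  r <- read_mrc(path)
  expect_equal(r$data, m$data, tolerance = 1e-6)  # float32 precision
  expect_equal(r$origin, m$origin, tolerance = 1e-6)
  expect_equal(r$voxel_size, m$voxel_size, tolerance = 1e-6)

  # constant map: header min = max = constant
  mc <- density_map(array(2.5, c(3, 3, 3)))
  write_mrc(mc, path)
  con <- file(path, "rb"); hdr <- readBin(con, "raw", 1024); close(con)
  flt <- function(w) readBin(hdr[(4 * (w - 1) + 1):(4 * w)], "numeric", size = 4)
  expect_equal(flt(20), 2.5, tolerance = 1e-6)  # DMIN
  expect_equal(flt(21), 2.5, tolerance = 1e-6)  # DMAX
  # cell length = n voxels x 1 A
  expect_equal(flt(11), 3)
})

test_that("read_mrc honors axis permutations (world-coordinate oracle)", {
  set.seed(7)
  dims <- c(4L, 3L, 5L)
  a <- array(rnorm(prod(dims)), dims)
  origin <- c(2, -1, 0)
  canon <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(density_map(a, origin = origin), canon)

  # hand-write a permuted file: file axes (columns, rows, sections) carry
  # world axes (y, z, x), i.e. MAPC/MAPR/MAPS = 2, 3, 1
  perm_path <- withr::local_tempfile(fileext = ".mrc")
  p <- c(2L, 3L, 1L)
  afile <- aperm(a, p)  # dims (ny, nz, nx)
  con <- file(perm_path, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dim(afile)); wi(2L); wi(c(0L, 0L, 0L)); wi(dims)
  wf(dims); wf(c(90, 90, 90)); wi(p)
  wf(c(min(a), max(a), mean(a))); wi(c(0L, 0L)); wi(rep(0L, 2L))
  writeBin(charToRaw("MRCO"), con); wi(20140L); wi(rep(0L, 21L))
  wf(origin); writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con); wf(0); wi(0L)
  writeBin(raw(800), con)
  writeBin(as.numeric(afile), con, size = 4L, endian = "little")
  close(con)

  r1 <- read_mrc(canon)
  r2 <- read_mrc(perm_path)
  # brute-force lookup: same value at identical world coordinates
  expect_equal(r2$origin, r1$origin, tolerance = 1e-6)
  expect_equal(dim(r2$data), dim(r1$data))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_equal(r2$data[i, j, k], r1$data[i, j, k], tolerance = 1e-6)
  expect_equal(r2$data, r1$data, tolerance = 1e-6)
})

test_that("read_mrc rejects malformed and unsupported files", {
  junk <- withr::local_tempfile()
  writeBin(as.raw(sample(0:255, 10, TRUE)), junk)
  expect_error(read_mrc(junk), "malformed")
  expect_error(read_mrc(file.path(tempdir(), "nope.mrc")), "not found")

  # unsupported mode (4 = complex)
  m <- density_map(array(0, c(2, 2, 2)))
  path <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(m, path)
  con <- file(path, "r+b")
  seek(con, 12, rw = "write")
  writeBin(4L, con, size = 4L, endian = "little")
  close(con)
  expect_error(read_mrc(path), "unsupported MRC mode")
})

test_that("resample_to_unit is exact on trilinear functions and identities", {
  # already at 1 A: bitwise identity
  m <- density_map(array(rnorm(27), c(3, 3, 3)))
  expect_identical(resample_to_unit(m), m)

  # constant map at 0.5 A stays constant
  mc <- density_map(array(3.7, c(5, 5, 5)), voxel_size = c(0.5, 0.5, 0.5))
  rc <- resample_to_unit(mc)
  expect_equal(rc$voxel_size, c(1, 1, 1))
  expect_true(all(abs(rc$data - 3.7) < 1e-12))

  # linear ramp f(world x) sampled at 0.5 A: resampled values equal the ramp
  # at integer Angstrom positions (closed-form trilinear result)
  dims <- c(9L, 4L, 4L)
  origin <- c(2, 0, 0)
  wx <- origin[1] + (seq_len(dims[1]) - 1L) * 0.5
  ramp <- array(rep(wx, times = prod(dims[2:3])), dim = dims)
  mr <- resample_to_unit(density_map(ramp, origin = origin,
                                     voxel_size = c(0.5, 0.5, 0.5)))
  new_wx <- origin[1] + seq_len(dim(mr$data)[1]) - 1L
  expect_equal(dim(mr$data)[1], 5L)  # world extent preserved within a voxel
  for (i in seq_along(new_wx))
    expect_equal(mr$data[i, 1, 1], new_wx[i], tolerance = 1e-12)

  expect_error(resample_to_unit(density_map(array(0, c(2, 2, 2)),
                                            voxel_size = c(0, 1, 1))),
               "positive")
})

test_that("extract_component keeps exactly the in-radius voxels and crops", {
  m <- density_map(array(1, c(21, 21, 21)))
  out <- extract_component(m, matrix(c(10, 10, 10), 1), radius = 5)
  expect_equal(sum(out$data != 0), 515L)  # lattice points with |d| <= 5
  expect_equal(dim(out$data), c(11L, 11L, 11L))
  expect_equal(out$origin, c(5, 5, 5))

  # radius covering the whole grid: identity after trivial crop
  big <- extract_component(m, matrix(c(10, 10, 10), 1), radius = 100)
  expect_equal(big$data, m$data)
  expect_equal(big$origin, m$origin)

  expect_error(extract_component(m, matrix(c(200, 0, 0), 1), radius = 5),
               "empty component")
})

test_that("extract_component matches a brute-force distance scan", {
  set.seed(11)
  for (rep in 1:5) {
    dims <- sample(6:14, 3, replace = TRUE)
    m <- density_map(array(rnorm(prod(dims)), dims), origin = runif(3, -5, 5))
    atoms <- cbind(runif(3, m$origin[1], m$origin[1] + dims[1] - 1),
                   runif(3, m$origin[2], m$origin[2] + dims[2] - 1),
                   runif(3, m$origin[3], m$origin[3] + dims[3] - 1))
    radius <- runif(1, 1.5, 4)
    keep <- array(FALSE, dims)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2]))
      for (k in seq_len(dims[3])) {
        ctr <- m$origin + c(i, j, k) - 1
        for (a in seq_len(nrow(atoms)))
          if (sqrt(sum((ctr - atoms[a, ])^2)) <= radius) keep[i, j, k] <- TRUE
      }
    if (!any(keep)) next
    out <- extract_component(m, atoms, radius)
    expected <- m$data * keep
    idx <- which(keep, arr.ind = TRUE)
    lo <- unname(apply(idx, 2, min)); hi <- unname(apply(idx, 2, max))
    expect_equal(out$data,
                 expected[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
    expect_equal(out$origin, m$origin + lo - 1)
  }
})

test_that("normalize_density min-max scales to [0, 1]", {
  m <- density_map(array(c(2, 4, 6, 2, 4, 6, 2, 4), c(2, 2, 2)))
  n <- normalize_density(m)
  expect_equal(sort(unique(as.numeric(n$data))), c(0, 0.5, 1))
  # degenerate range: all zeros
  expect_true(all(normalize_density(density_map(array(5, c(3, 3, 3))))$data == 0))
  # already [0, 1] with min 0, max 1: unchanged
  v <- array(seq(0, 1, length.out = 8), c(2, 2, 2))
  expect_equal(normalize_density(density_map(v))$data, v)
})

test_that("pad_for_network pads to multiples and unpad inverts exactly", {
  m <- density_map(array(rnorm(57 * 47 * 42), c(57, 47, 42)),
                   origin = c(3, 4, 5))
  r <- pad_for_network(m, 4L)
  expect_equal(dim(r$map$data), c(60L, 48L, 44L))
  expect_identical(unpad_map(r$map, r$pad), m)
  # world coordinates of original voxels unchanged
  expect_equal(r$map$origin + r$pad$before * m$voxel_size, m$origin)

  # dims already multiples: zero padding
  m4 <- density_map(array(rnorm(4 * 8 * 12), c(4, 8, 12)))
  r4 <- pad_for_network(m4, 4L)
  expect_equal(r4$pad$before, c(0L, 0L, 0L))
  expect_equal(r4$pad$after, c(0L, 0L, 0L))
  expect_identical(r4$map$data, m4$data)

  # boundary at the 100-voxel design limit: 99 -> 100 allowed, beyond errors
  m99 <- density_map(array(0, c(99, 99, 99)))
  expect_equal(dim(pad_for_network(m99, 4L)$map$data), c(100L, 100L, 100L))
  m98 <- density_map(array(0, c(98, 98, 98)))
  expect_error(pad_for_network(m98, 8L), "100-voxel")
})
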