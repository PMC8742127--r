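test_that("plexus labeling reproduces the 30 um vessel diameter", {
  vol <- buildTissueVolume(skinGeometry())
  expect_equal(plexusDiameter(vol), 30)
  # desk-scale geometry keeps the physical plexus size
  expect_equal(plexusDiameter(buildTissueVolume(deskGeometry())), 30)
})

test_that("zero capillary diameter reduces to a plain layered volume", {
  vol <- buildTissueVolume(skinGeometry(capDiameter = 0,
                                        plexusX = numeric()))
  zs <- c(0, 100, 150, 200, 299, 300, 500, 1999)
  labs <- voxelLabels(vol, zIndices = zs)
  expect_true(all(labs <= 7L))
  # layer boundaries are planes of constant z
  for (k in seq_along(zs))
    expect_equal(length(unique(as.vector(labs[, , k]))), 1L)
})

test_that("blood voxel count matches the analytic cylinder volume", {
  # single vertical limb: radius 5 um, 150 voxel planes
  g <- skinGeometry(capDiameter = 10,
                    loops = data.frame(x = 550, y1 = 250, y2 = 250),
                    plexusX = numeric(), loopZ = c(150, 299))
  cnt <- countLabelVoxels(buildTissueVolume(g), zIndices = 140:310)
  expect_lt(abs(cnt - pi * 25 * 150) / (pi * 25 * 150), 0.10)
})

test_that("labeling is idempotent and order-independent for disjoint vessels", {
  gA <- skinGeometry(capDiameter = 8,
                     loops = data.frame(x = c(550, 700), y1 = c(250, 450),
                                        y2 = c(295, 495)))
  gB <- skinGeometry(capDiameter = 8,
                     loops = data.frame(x = c(700, 550), y1 = c(450, 250),
                                        y2 = c(495, 295)))
  zs <- c(150, 200, 300)
  expect_identical(voxelLabels(buildTissueVolume(gA), zIndices = zs),
                   voxelLabels(buildTissueVolume(gB), zIndices = zs))
})

test_that("halved voxel size converges to the same blood volume fraction", {
  base <- skinGeometry(capDiameter = 10, dims = c(60L, 60L, 40L),
                       voxelSize = 1,
                       loops = data.frame(x = 30, y1 = 30, y2 = 30),
                       plexusX = numeric(), loopZ = c(0, 39),
                       sourcePositions = rbind(c(10, 10), c(10, 20)),
                       crossSectionX = 30)
  fine <- skinGeometry(capDiameter = 10, dims = c(120L, 120L, 80L),
                       voxelSize = 0.5,
                       loops = data.frame(x = 60, y1 = 60, y2 = 60),
                       plexusX = numeric(), loopZ = c(0, 79),
                       sourcePositions = rbind(c(20, 20), c(20, 40)),
                       crossSectionX = 60)
  layers <- data.frame(name = "one", thickness_um = 1000)
  media <- defaultMediaProperties()[c(1, 8), ]
  fBase <- countLabelVoxels(buildTissueVolume(base, layers, media)) /
    prod(base@dims)
  fFine <- countLabelVoxels(buildTissueVolume(fine, layers, media)) /
    prod(fine@dims)
  expect_lt(abs(fFine - fBase) / fBase, 0.05)
})

test_that("default geometry instantiates 6 loops and 2 plexus legs", {
  g <- skinGeometry()
  expect_equal(nrow(g@loops), 6L)
  expect_equal(length(g@plexusX), 2L)
  # Table-verbatim lateral positions
  expect_equal(g@loops$x, c(550, 550, 550, 700, 700, 700))
  expect_equal(g@loops$y1, c(250, 450, 650, 250, 450, 650))
})

test_that("out-of-bounds and overlapping vessels are rejected", {
  expect_error(skinGeometry(loops = data.frame(x = 949, y1 = 250,
                                               y2 = 295)),
               "bounds")
  expect_error(skinGeometry(capDiameter = 10,
                            loops = data.frame(x = c(550, 552),
                                               y1 = c(250, 250),
                                               y2 = c(295, 295))),
               "overlap")
})

test_that("layer stack must cover the volume depth", {
  shallow <- data.frame(name = letters[1:7],
                        thickness_um = rep(10, 7))
  expect_error(buildTissueVolume(skinGeometry(), layers = shallow),
               "depth")
})

test_that("label stacks export to TIFF", {
  vol <- buildTissueVolume(deskGeometry())
  path <- tempfile(fileext = ".tif")
  writeLabelTIFF(vol, path, zIndices = 74:76)
  expect_true(file.exists(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  expect_equal(length(pages), 3L)
  expect_equal(dim(pages[[1]]), c(240, 240))
})
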