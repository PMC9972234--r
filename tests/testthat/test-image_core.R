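# volume data model, NIfTI round trips, connected components, morphology,
# resampling and the Jacobian determinant

test_that("volume constructors enforce their invariants", {
  expect_error(scalar_volume(array(NA_real_, c(3, 3, 3))), "finite")
  expect_error(scalar_volume(array(0, c(3, 3))), "3-D")
  expect_error(scalar_volume(array(0, c(3, 3, 3)), spacing = c(1, -1, 1)),
               "positive")
  expect_error(label_volume(array(0.5, c(3, 3, 3))), "integer")
  expect_error(label_volume(array(-1L, c(3, 3, 3))), "non-negative")
  expect_error(displacement_field(array(0, c(3, 3, 3, 2))), "last axis 3")
  v <- scalar_volume(array(0, c(4, 4, 4)), spacing = c(1, 1.2, 3))
  expect_equal(voxel_volume(v), 1 * 1.2 * 3)
})

test_that("NIfTI round trip preserves data, spacing and affine", {
  withr::local_seed(42)
  for (ext in c(".nii", ".nii.gz")) {
    v <- scalar_volume(array(rnorm(4 * 5 * 6), c(4, 5, 6)),
                       spacing = c(0.49, 0.49, 3))
    tf <- withr::local_tempfile(fileext = ext)
    write_volume(v, tf)
    v2 <- read_volume(tf, "scalar")
    expect_equal(v2$data, v$data)                        # float64 payload
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)  # float32 header
    expect_equal(v2$affine, v$affine, tolerance = 1e-6)
  }
  # zero scalar volume identity
  z <- scalar_volume(array(0, c(4, 4, 4)))
  tf <- withr::local_tempfile(fileext = ".nii")
  write_volume(z, tf)
  expect_true(all(read_volume(tf, "scalar")$data == 0))
  # labels {0,1,2} survive and the label set is right
  lv <- label_volume(array(sample(0:2, 4^3, TRUE), c(4, 4, 4)))
  tf2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(lv, tf2)
  lv2 <- read_volume(tf2, "label")
  expect_identical(label_set(lv2), sort(unique(as.vector(lv$labels)))[-1])
  expect_identical(lv2$labels, lv$labels)
  # displacement field round trip
  f <- displacement_field(array(rnorm(3 * 4 * 5 * 3), c(3, 4, 5, 3)),
                          spacing = c(1, 1, 1.2))
  tf3 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(f, tf3)
  expect_equal(read_volume(tf3, "field")$vectors, f$vectors)
})

test_that("NIfTI reader matches nibabel on a shared fixture", {
  # independent oracle: write with the package, decode with Python nibabel
  v <- scalar_volume(array(seq(0, 1, length.out = 60), c(3, 4, 5)),
                     spacing = c(0.65, 0.65, 3))
  tf <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, tf)
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  expect_true(nzchar(py))  # python ships in the runtime image
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", tf, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(d.shape, float(d.sum()), ",
    "' '.join('%g' % z for z in img.header.get_zooms()))"))),
    stdout = TRUE)
  expect_match(out, "^\\(3, 4, 5\\)")
  parts <- strsplit(sub("^\\(3, 4, 5\\) ", "", out), " ")[[1]]
  expect_equal(as.numeric(parts[1]), sum(v$data), tolerance = 1e-12)
  expect_equal(as.numeric(parts[2:4]), v$spacing, tolerance = 1e-6)
})

test_that("read_volume rejects garbage and non-integer labels", {
  tf <- withr::local_tempfile(fileext = ".nii")
  writeBin(as.raw(1:100), tf)
  expect_error(read_volume(tf, "scalar"), "NIfTI")
  expect_error(read_volume(file.path(tempdir(), "missing.nii"), "scalar"),
               "no such file")
  v <- scalar_volume(array(0.5, c(3, 3, 3)))
  tf2 <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, tf2)
  expect_error(read_volume(tf2, "label"), "non-integer")
})

test_that("connected components: blocks, corner voxel, empty mask", {
  m <- array(FALSE, c(6, 6, 6))
  m[1:2, 1:2, 1:2] <- TRUE
  m[5:6, 5:6, 5:6] <- TRUE
  cc <- connected_components(m)
  expect_identical(label_set(cc), c(1L, 2L))
  expect_equal(unname(tabulate(cc$labels)), c(8, 8))
  single <- array(FALSE, c(4, 4, 4)); single[1, 1, 1] <- TRUE
  cc1 <- connected_components(single)
  expect_identical(label_set(cc1), 1L)
  expect_equal(sum(cc1$labels == 1L), 1)
  expect_identical(label_set(connected_components(array(FALSE, c(3, 3, 3)))),
                   integer(0))
})

test_that("connected components partition random grids like the BFS oracle", {
  withr::local_seed(7)
  for (rep in 1:3) {
    m <- array(runif(10^3) < 0.35, c(10, 10, 10))
    got <- connected_components(m)$labels
    want <- oracle_cc26(m)
    # identical partitions: same voxel sets per label (size ties may swap
    # ids, so compare the induced partitions)
    expect_identical(got > 0L, want > 0L)
    split_got <- split(which(got > 0L), got[got > 0L])
    split_want <- split(which(want > 0L), want[want > 0L])
    expect_true(setequal(lapply(split_got, sort), lapply(split_want, sort)))
    # and size ordering is decreasing
    sizes <- tabulate(got)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("shell_masks does cube arithmetic and flags empty cores", {
  labs <- cube_labels(c(9, 9, 9), 3, 7)   # 5^3 cube
  sm <- shell_masks(labs, 1L, core_erosion = 1L, ring_dilation = 2L)
  expect_equal(sum(sm$core), 27)          # 3^3
  expect_equal(sum(sm$shell), 125 - 27)
  expect_false(sm$core_empty)
  expect_equal(sum(sm$core & sm$shell), 0)
  expect_equal(sum(sm$shell & sm$ring), 0)
  expect_equal(sum(sm$core & sm$ring), 0)
  single <- array(0L, c(5, 5, 5)); single[3, 3, 3] <- 1L
  sm1 <- shell_masks(label_volume(single), 1L)
  expect_true(sm1$core_empty)
  expect_equal(sum(sm1$shell), 1)         # shell = whole lesion
  expect_error(shell_masks(labs, 99L), "not present")
})

test_that("shell masks of a random blob match the voxelwise morphology oracle", {
  withr::local_seed(21)
  m <- array(FALSE, c(10, 10, 10))
  seed_pts <- cbind(sample(4:7, 6, TRUE), sample(4:7, 6, TRUE), sample(4:7, 6, TRUE))
  m[seed_pts] <- TRUE
  m <- oracle_morph6(m, 1, erode = FALSE)  # grow a blob
  labs <- label_volume(array(as.integer(m), dim(m)))
  sm <- shell_masks(labs, 1L, core_erosion = 1L, ring_dilation = 2L)
  core_o <- oracle_morph6(m, 1, erode = TRUE)
  ring_o <- oracle_morph6(m, 2, erode = FALSE) & !m
  expect_identical(sm$core, core_o)
  expect_identical(sm$shell, m & !core_o)
  expect_identical(sm$ring, ring_o)
})

test_that("label resampling: identity, upsampling, oracle equality", {
  labs <- cube_labels(c(6, 6, 6), 2, 4)
  same <- resample_labels_nn(labs, scalar_volume(array(0, c(6, 6, 6))))
  expect_identical(same$labels, labs$labels)
  # idempotence on identical lattices
  expect_identical(resample_labels_nn(same, scalar_volume(array(0, c(6, 6, 6))))$labels,
                   labs$labels)
  # 2x upsampling of one labelled voxel -> an 8-voxel block (the target
  # lattice is offset half a voxel so no target centre is equidistant
  # between two source centres)
  one <- array(0L, c(4, 4, 4)); one[2, 2, 2] <- 1L
  src <- label_volume(one, spacing = c(2, 2, 2))
  taff <- diag(c(1, 1, 1, 1)); taff[1:3, 4] <- -0.5
  tgt <- scalar_volume(array(0, c(8, 8, 8)), spacing = c(1, 1, 1),
                       affine = taff)
  up <- resample_labels_nn(src, tgt)
  expect_equal(sum(up$labels == 1L), 8)
  expect_true(all(sort(unique(as.vector(up$labels))) %in% c(0L, 1L)))
  # arbitrary (rotated + offset, tie-free) affine pair vs exhaustive oracle
  withr::local_seed(5)
  lab <- label_volume(array(sample(0:3, 6^3, TRUE), c(6, 6, 6)),
                      spacing = c(1.013, 1.207, 1.993))
  th <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
              byrow = TRUE)
  aff2 <- rbind(cbind(R %*% diag(c(1.013, 1.207, 1.993)), c(0.2, 0.1, -0.3)),
                c(0, 0, 0, 1))
  lab_rot <- label_volume(lab$labels, c(1.013, 1.207, 1.993), affine = aff2)
  taff <- diag(c(0.711, 1.409, 1.913, 1)); taff[1:3, 4] <- c(0.123, -0.345, 0.217)
  tgt2 <- scalar_volume(array(0, c(7, 6, 5)), c(0.711, 1.409, 1.913),
                        affine = taff)
  for (src2 in list(lab, lab_rot)) {
    got <- resample_labels_nn(src2, tgt2)$labels
    expect_identical(got, oracle_nn_resample(src2, c(7L, 6L, 5L), taff))
    expect_true(all(unique(as.vector(got)) %in% c(0L, label_set(src2))))
  }
  # singular affine errors
  bad <- labs; bad$affine[1, 1] <- 0
  expect_error(resample_labels_nn(bad, tgt), "singular")
})

test_that("Jacobian: zero field, uniform scaling, affine fields, oracle", {
  z <- displacement_field(array(0, c(5, 5, 5, 3)))
  expect_equal(jacobian_determinant(z)$data, array(1, c(5, 5, 5)))
  # u(x) = (s - 1) x with s = 1.1 -> J = 1.331 at interior voxels
  s <- 1.1
  f <- affine_field(diag(rep(s, 3)), c(6, 6, 6), c(1, 1, 1))
  J <- jacobian_determinant(f)$data
  expect_equal(J[2:5, 2:5, 2:5], array(s^3, c(4, 4, 4)), tolerance = 1e-12)
  # general affine, anisotropic spacing: J = det(A) interior to < 1e-10
  A <- matrix(c(1.1, 0.02, 0, 0.01, 0.95, 0.03, 0, 0.02, 1.05), 3, byrow = TRUE)
  sp <- c(1, 1.5, 2)
  J2 <- jacobian_determinant(affine_field(A, c(7, 7, 7), sp))$data
  expect_lt(max(abs(J2[2:6, 2:6, 2:6] - det(A))), 1e-10)
  # smooth random field vs entry-by-entry oracle
  withr::local_seed(3)
  vec <- array(0, c(5, 5, 5, 3))
  for (c_ in 1:3) {
    vec[, , , c_] <- 0.05 * array(sin(seq(0, c_, length.out = 125)), c(5, 5, 5))
  }
  sp3 <- c(0.8, 1, 1.3)
  got <- jacobian_determinant(displacement_field(vec, sp3))$data
  expect_equal(got, oracle_jacobian(vec, sp3), tolerance = 1e-12)
  # preconditions
  expect_error(jacobian_determinant(displacement_field(array(0, c(2, 5, 5, 3)))),
               ">= 3 voxels")
})

test_that("Jacobian integral over an expanding lesion matches the volume change", {
  # generator-style radial field: integral of J over the lesion approximates
  # (deformed volume) / (original volume) = s^3
  cfg <- sim_config(seed = 6, n_patients = 1)
  b <- generate_patient(cfg, 1)
  J <- jacobian_determinant(b$field)
  sel_ids <- b$lesions$lesion_id[b$lesions$true_sel]
  expect_gt(length(sel_ids), 0)
  for (id in sel_ids[seq_len(min(3, length(sel_ids)))]) {
    les <- b$lesions[b$lesions$lesion_id == id, ]
    mean_J <- mean(J$data[b$labels$labels == id])
    expect_equal(mean_J, les$total_scale^3, tolerance = 0.02)
  }
})
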