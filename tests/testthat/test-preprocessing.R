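test_that("lobule atlas exclusion yields the analysis parcellation", {
  atlas <- cerebellum_atlas()
  expect_length(atlas, 28L)
  kept <- exclude_rois(atlas, "Vermis Crus I")
  expect_length(kept, 27L)
  expect_false("Vermis Crus I" %in% kept$labels)
  # relative order preserved
  expect_identical(kept$labels, setdiff(atlas$labels, "Vermis Crus I"))
  expect_error(exclude_rois(atlas, "Nucleus Dentatus"), "unknown ROI")
})

test_that("exclude_rois is an order-preserving filter", {
  atlas <- roi_atlas(c("a", "b", "c", "d", "e"), ids = c(3L, 9L, 1L, 7L, 5L))
  expect_identical(exclude_rois(atlas, character(0)), atlas)
  kept <- exclude_rois(atlas, c("b", "d"))
  expect_identical(kept$labels, c("a", "c", "e"))
  expect_identical(kept$ids, c(3L, 1L, 5L))
})

test_that("ROI mean extraction averages labelled voxels per frame", {
  atlas <- roi_atlas(c("one", "two"), ids = c(1L, 2L))
  lab <- array(0L, dim = c(2, 2, 1))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L   # two-voxel ROI
  lab[1, 2, 1] <- 2L                        # single-voxel ROI
  vol <- array(0, dim = c(2, 2, 1, 3))
  vol[1, 1, 1, ] <- 4; vol[2, 1, 1, ] <- 6
  vol[1, 2, 1, ] <- c(1, 2, 3)
  ts <- extract_roi_means(vol, lab, atlas)
  expect_equal(unname(ts[, "one"]), rep(5, 3))
  expect_equal(unname(ts[, "two"]), c(1, 2, 3))
})

test_that("ROI mean extraction matches an explicit voxel loop on a random phantom", {
  set.seed(42)
  dims <- c(4, 3, 2)
  lab <- array(sample(0:3, prod(dims), replace = TRUE), dim = dims)
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 2L; lab[3, 1, 1] <- 3L  # all ids present
  n_frames <- 5L
  vol <- array(rnorm(prod(dims) * n_frames), dim = c(dims, n_frames))
  atlas <- roi_atlas(c("A", "B", "C"), ids = 1:3)
  ts <- extract_roi_means(vol, lab, atlas)
  for (k in 1:3) {
    for (f in seq_len(n_frames)) {
      acc <- c()
      for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
        if (lab[x, y, z] == k) acc <- c(acc, vol[x, y, z, f])
      }
      expect_equal(unname(ts[f, k]), mean(acc))
    }
  }
})

test_that("ROI mean extraction validates atlas ids and grids", {
  atlas <- roi_atlas(c("A", "Bmissing"), ids = c(1L, 9L))
  lab <- array(1L, dim = c(2, 2, 2))
  vol <- array(0, dim = c(2, 2, 2, 4))
  expect_error(extract_roi_means(vol, lab, atlas), "Bmissing")
  lab2 <- array(1L, dim = c(3, 2, 2))
  expect_error(extract_roi_means(vol, lab2, roi_atlas("A", 1L)), "grid mismatch")
})

test_that("NIfTI volumes round-trip through mean extraction", {
  dims <- c(3, 3, 2)
  lab <- array(0L, dim = dims)
  lab[1:2, 1, 1] <- 1L
  vol <- array(rnorm(prod(dims) * 4), dim = c(dims, 4))
  labf <- file.path(tempdir(), "lab.nii.gz")
  volf <- file.path(tempdir(), "vol.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(lab + 0), labf)
  RNifti::writeNifti(RNifti::asNifti(vol), volf)
  atlas <- roi_atlas("A", 1L)
  ts <- extract_roi_means(volf, labf, atlas)
  expect_equal(unname(ts[, 1]), colMeans(rbind(vol[1, 1, 1, ], vol[2, 1, 1, ])),
               tolerance = 1e-6)
})

test_that("IQ group assignment follows the interval rule", {
  rec <- data.frame(subject_id = sprintf("S%d", 1:6),
                    iq_score = c(3, 4, 10, 16, 22, 24))
  out <- form_iq_groups(rec)
  expect_identical(out$group, c("excluded", "low", "low", "mid", "high", "high"))
  counts <- attr(out, "counts")
  expect_equal(unname(counts[c("low", "mid", "high", "excluded")]), c(2L, 1L, 2L, 1L),
               ignore_attr = TRUE)
  # empty input is vacuous
  empty <- form_iq_groups(rec[0, , drop = FALSE])
  expect_equal(nrow(empty), 0L)
  # overlapping intervals are a configuration error
  expect_error(form_iq_groups(rec, low_interval = c(4, 22), high_interval = c(20, 24)),
               "disjoint")
})

test_that("connectivity is nonnegative Pearson correlation with zero diagonal", {
  x <- rnorm(30)
  ts <- roi_timeseries(cbind(a = x, b = x, c = -x + rnorm(30, sd = 1e-8)),
                       sampling_interval = 1)
  conn <- build_connectivity(ts)
  expect_equal(conn["a", "b"], 1)
  expect_equal(conn["a", "c"], 0)   # negative correlation discarded
  expect_equal(diag(as.matrix(conn)), rep(0, 3), ignore_attr = TRUE)
})

test_that("connectivity matches the Pearson formula evaluated by explicit sums", {
  set.seed(7)
  m <- matrix(rnorm(15), nrow = 5, ncol = 3,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  conn <- build_connectivity(roi_timeseries(m, sampling_interval = 1))
  hand_pearson <- function(x, y) {
    n <- length(x)
    num <- sum(x * y) - n * mean(x) * mean(y)
    den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    num / den
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(unname(as.matrix(conn)[i, j]),
                   max(0, hand_pearson(m[, i], m[, j])))
    }
  }
})

test_that("zero-variance signals are rejected with the ROI named", {
  m <- cbind(flat = rep(1, 10), ok = rnorm(10))
  expect_error(build_connectivity(roi_timeseries(m, sampling_interval = 1)),
               "flat")
})

test_that("connectivity invariants hold on random inputs and permutation is equivariant", {
  set.seed(11)
  for (rep in 1:10) {
    m <- matrix(rnorm(40 * 6), 40, 6,
                dimnames = list(NULL, paste0("R", 1:6)))
    conn <- as.matrix(build_connectivity(roi_timeseries(m, sampling_interval = 1)))
    expect_true(isSymmetric(conn))
    expect_true(all(diag(conn) == 0))
    expect_true(all(conn >= 0 & conn <= 1))
    perm <- sample(6)
    conn_p <- as.matrix(build_connectivity(
      roi_timeseries(m[, perm], sampling_interval = 1)))
    expect_equal(conn_p, conn[perm, perm], ignore_attr = TRUE)
  }
})

test_that("time-series and connectivity TSVs round-trip", {
  ts <- roi_timeseries(matrix(rnorm(30), 10, 3,
                              dimnames = list(NULL, c("Left VI", "Right VI", "Vermis VI"))))
  f <- file.path(tempdir(), "ts.tsv")
  write_roi_timeseries(ts, f)
  back <- read_roi_timeseries(f)
  expect_equal(unclass(back), unclass(ts), tolerance = 1e-12, ignore_attr = TRUE)
  conn <- build_connectivity(ts)
  g <- file.path(tempdir(), "conn.tsv")
  write_connectivity(conn, g)
  expect_equal(as.matrix(read_connectivity(g)), as.matrix(conn), tolerance = 1e-12)
})
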