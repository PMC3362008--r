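short_sequence <- function(n = 3) {
  rs <- clean_phantom()
  s <- rs$sequence
  s$frames <- lapply(s$frames[seq_len(n)], round)
  s$meta <- list()
  s
}

test_that("TIFF round trip is bit-identical with metadata intact", {
  s <- short_sequence()
  path <- file.path(tempdir(), "seq.tif")
  write_sequence(s, path, format = "tiff")
  r <- read_sequence(path)
  expect_identical(lapply(r$frames, function(f) round(f)), s$frames)
  expect_equal(r$frame_rate, s$frame_rate)
  expect_equal(r$pixel_spacing, s$pixel_spacing)
  expect_identical(r$bit_depth, s$bit_depth)
  unlink(c(path, sub("\\.tif$", ".json", path)))
})

test_that("PNG frame directories are read in numeric order", {
  s <- short_sequence()
  dir <- file.path(tempdir(), "framedir")
  dir.create(dir, showWarnings = FALSE)
  # deliberately shuffled names whose lexicographic order is wrong
  names <- c("frame_10.png", "frame_2.png", "frame_1.png")
  for (i in 1:3) {
    png::writePNG(s$frames[[i]] / 255, file.path(dir, names[i]))
  }
  jsonlite::write_json(list(frame_rate = 12.5, bit_depth = 8),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  r <- read_sequence(dir)
  # numeric order 1, 2, 10 corresponds to frames 3, 2, 1 as written
  expect_equal(round(r$frames[[1]]), s$frames[[3]])
  expect_equal(round(r$frames[[2]]), s$frames[[2]])
  expect_equal(round(r$frames[[3]]), s$frames[[1]])
  unlink(dir, recursive = TRUE)
})

test_that("a missing frame rate warns and is flagged unknown", {
  s <- short_sequence()
  dir <- file.path(tempdir(), "framedir2")
  dir.create(dir, showWarnings = FALSE)
  for (i in 1:3) {
    png::writePNG(s$frames[[i]] / 255, file.path(dir, sprintf("f_%d.png", i)))
  }
  expect_warning(r <- read_sequence(dir), "frame rate unknown")
  expect_true(is.na(r$frame_rate))
  unlink(dir, recursive = TRUE)
})

test_that("landmark files round-trip and are validated", {
  rs <- clean_phantom()
  lmk <- phantom_landmarks(rs$truth, rs$sequence, n_markings = 2,
                           jitter_sd = 0.5, seed = 2)
  path <- file.path(tempdir(), "landmarks.csv")
  write_landmarks(lmk, path)
  back <- read_landmarks(path)
  expect_equal(as.data.frame(back), as.data.frame(lmk), tolerance = 1e-12)
  # a marking listed with mirrored winding (superior and inferior roles
  # exchanged wholesale) is reordered to canonical order with a warning
  bad <- lmk
  swap <- function(df, v, m, r1, r2) {
    i1 <- which(df$vertebra == v & df$marking_id == m & df$point_role == r1)
    i2 <- which(df$vertebra == v & df$marking_id == m & df$point_role == r2)
    tmp <- df[i1, c("x_px", "y_px")]
    df[i1, c("x_px", "y_px")] <- df[i2, c("x_px", "y_px")]
    df[i2, c("x_px", "y_px")] <- tmp
    df
  }
  bad <- swap(bad, "L4", 1, "corner_as", "corner_ai")
  bad <- swap(bad, "L4", 1, "corner_ps", "corner_pi")
  write_landmarks(bad, path)
  expect_warning(fixed <- read_landmarks(path), "reordered")
  cc0 <- lmk[lmk$vertebra == "L4" & lmk$marking_id == 1 &
               grepl("corner", lmk$point_role), ]
  cc1 <- fixed[fixed$vertebra == "L4" & fixed$marking_id == 1 &
                 grepl("corner", fixed$point_role), ]
  expect_equal(as.data.frame(cc1), as.data.frame(cc0), tolerance = 1e-9)
  # an adjacent-corner swap gives a bow-tie: rejected with the vertebra named
  bad2 <- swap(lmk, "L5", 2, "corner_ps", "corner_pi")
  write_landmarks(bad2, path)
  expect_error(read_landmarks(path), "L5.*self-intersecting")
  unlink(path)
})

# Craft a minimal explicit-VR little-endian DICOM file in code.
write_test_dicom <- function(path, frames, bits_stored = 12,
                             spacing = "0.5\\0.5", frame_time_ms = "66.6667") {
  rows <- nrow(frames[[1]]); cols <- ncol(frames[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  el_short <- function(group, element, vr, bytes) {
    writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    writeBin(length(bytes), con, size = 2, endian = "little")
    writeBin(bytes, con)
  }
  el_long <- function(group, element, vr, bytes) {
    writeBin(as.integer(c(group, element)), con, size = 2, endian = "little")
    writeChar(vr, con, eos = NULL)
    writeBin(as.integer(0), con, size = 2, endian = "little")
    writeBin(length(bytes), con, size = 4, endian = "little")
    writeBin(bytes, con)
  }
  us <- function(v) writeBin(as.integer(v), raw(), size = 2, endian = "little")
  str_even <- function(s) {
    b <- charToRaw(s)
    if (length(b) %% 2 == 1) b <- c(b, charToRaw(" "))
    b
  }
  el_short(0x0002, 0x0010, "UI", str_even("1.2.840.10008.1.2.1"))
  el_short(0x0018, 0x1063, "DS", str_even(frame_time_ms))
  el_short(0x0028, 0x0008, "IS", str_even(as.character(length(frames))))
  el_short(0x0028, 0x0010, "US", us(rows))
  el_short(0x0028, 0x0011, "US", us(cols))
  el_short(0x0028, 0x0030, "DS", str_even(spacing))
  el_short(0x0028, 0x0100, "US", us(16))
  el_short(0x0028, 0x0101, "US", us(bits_stored))
  px <- unlist(lapply(frames, function(f) as.integer(t(f))))
  el_long(0x7FE0, 0x0010, "OW",
          writeBin(px, raw(), size = 2, endian = "little"))
  invisible(path)
}

test_that("minimal DICOM reading: stored bits, spacing, timing, pixels", {
  set.seed(8)
  frames <- lapply(1:3, function(i) {
    matrix(sample(0:4095, 24 * 16, replace = TRUE), 24, 16)
  })
  path <- file.path(tempdir(), "test.dcm")
  write_test_dicom(path, frames, bits_stored = 12)
  r <- read_sequence(path)
  # bit depth reported as stored bits, not allocated bits
  expect_identical(r$bit_depth, 12L)
  expect_equal(r$frame_rate, 1000 / 66.6667, tolerance = 1e-4)
  expect_equal(r$pixel_spacing, 0.5)
  expect_identical(length(r$frames), 3L)
  for (i in 1:3) expect_equal(r$frames[[i]], frames[[i]])
  unlink(path)
})

test_that("kinematic results are written as curves plus an index summary", {
  tp <- tracked_phantom()
  stem <- file.path(tempdir(), "results")
  files <- write_results(tp$kin, stem)
  curves <- read.csv(paste0(stem, "_curves.csv"))
  expect_true(all(c("level", "frame", "trunk_angle_deg", "iv_rotation_deg",
                    "iv_translation_pct", "disc_height_pct") %in% names(curves)))
  idx <- read.csv(paste0(stem, "_indices.csv"))
  expect_identical(nrow(idx), 3L)
  expect_true(all(c("max_rotation_range_deg", "laxity_ratio", "coherence",
                    "motion_share", "phase_lag_deg") %in% names(idx)))
  unlink(paste0(stem, c("_curves.csv", "_indices.csv")))
})

test_that("mixed frame dimensions are a format error", {
  dir <- file.path(tempdir(), "mixdir")
  dir.create(dir, showWarnings = FALSE)
  png::writePNG(matrix(0.5, 32, 32), file.path(dir, "f_1.png"))
  png::writePNG(matrix(0.5, 16, 32), file.path(dir, "f_2.png"))
  expect_error(suppressWarnings(read_sequence(dir)), "mixed dimensions")
  unlink(dir, recursive = TRUE)
})
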