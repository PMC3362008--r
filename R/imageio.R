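#' Read an image sequence from disk
#'
#' Reads a multi-page TIFF, a directory of PNG/TIFF frames (ordered by the
#' number embedded in each file name), a single (possibly multi-frame)
#' uncompressed DICOM file, or a directory of single-frame DICOM files.
#' Metadata come from the DICOM headers where present, otherwise from a
#' JSON sidecar (`<stem>.json` next to the file, or `meta.json` inside a
#' frame directory); anything still missing is flagged unknown, and
#' time-based operations downstream will refuse to run without a frame
#' rate.
#'
#' @param path file or directory path.
#' @param format_hint optional `"tiff"`, `"png"` or `"dicom"` override.
#' @return A [qf_sequence()].
#' @export
read_sequence <- function(path, format_hint = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, full.names = TRUE,
                        pattern = "\\.(png|tif|tiff|dcm)$", ignore.case = TRUE)
    if (length(files) == 0) stop("no image frames found in ", path, call. = FALSE)
    num <- as.numeric(gsub("\\D", "", basename(files)))
    files <- files[order(num)]
    ext <- tolower(tools::file_ext(files[1]))
    fmt <- format_hint %||% ifelse(ext == "dcm", "dicom",
                                   ifelse(ext == "png", "png", "tiff"))
    if (fmt == "dicom") {
      parsed <- lapply(files, read_dicom_minimal)
      frames <- lapply(parsed, function(p) p$frames[[1]])
      meta <- parsed[[1]]
      return(sequence_from_frames(frames, meta, path))
    }
    frames <- lapply(files, function(f) {
      raw <- if (fmt == "png") png::readPNG(f) else tiff::readTIFF(f)
      raster_to_matrix(raw)
    })
    return(sequence_from_frames(frames, NULL, path))
  }
  ext <- tolower(tools::file_ext(path))
  fmt <- format_hint %||% switch(ext, dcm = "dicom", png = "png", "tiff")
  if (fmt == "dicom") {
    p <- read_dicom_minimal(path)
    return(sequence_from_frames(p$frames, p, path))
  }
  if (fmt == "png") {
    frames <- list(raster_to_matrix(png::readPNG(path)))
    return(sequence_from_frames(frames, NULL, path))
  }
  raw <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(raw)) raw <- list(raw)
  frames <- lapply(raw, raster_to_matrix)
  sequence_from_frames(frames, NULL, path)
}

# readTIFF/readPNG return [0,1] floats (possibly with extra channels).
raster_to_matrix <- function(x) {
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}

sequence_from_frames <- function(frames, dicom_meta, path) {
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("format error: frames have mixed dimensions", call. = FALSE)
  }
  sidecar <- read_sidecar(path)
  bit_depth <- dicom_meta$bits_stored %||% sidecar$bit_depth %||% 8L
  # stored as [0,1] floats by the PNG/TIFF readers; rescale to grey levels
  if (is.null(dicom_meta)) {
    frames <- lapply(frames, function(f) f * (2^bit_depth - 1))
  }
  fr <- dicom_meta$frame_rate %||% sidecar$frame_rate
  if (is.null(fr)) {
    warning("frame rate unknown; time-based operations will refuse to run")
    fr <- NA_real_
  }
  qf_sequence(
    frames,
    frame_rate = fr,
    bit_depth = as.integer(bit_depth),
    pixel_spacing = dicom_meta$pixel_spacing %||% sidecar$pixel_spacing %||% NA_real_,
    plane = sidecar$plane %||% "sagittal",
    orientation_config = sidecar$orientation_config %||% "recumbent_passive",
    direction = sidecar$direction %||% "flexion",
    meta = c(list(source = path),
             sidecar[setdiff(names(sidecar),
                             c("frame_rate", "bit_depth", "pixel_spacing",
                               "plane", "orientation_config", "direction"))]))
}

read_sidecar <- function(path) {
  cand <- if (dir.exists(path)) file.path(path, "meta.json")
  else paste0(tools::file_path_sans_ext(path), ".json")
  if (file.exists(cand)) jsonlite::read_json(cand, simplifyVector = TRUE)
  else list()
}

#' Write an image sequence to disk
#'
#' Writes a multi-page TIFF (or a directory of numbered PNG frames) plus a
#' JSON metadata sidecar.  Grey levels are stored losslessly at the
#' sequence's bit depth (8-bit frames round-trip bit-identically; higher
#' depths are stored as 16-bit).
#'
#' @param seq a [qf_sequence()].
#' @param path output file (`.tif`) or directory (PNG frames).
#' @param format `"tiff"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_sequence <- function(seq, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  top <- 2^seq$bit_depth - 1
  store_bits <- if (seq$bit_depth <= 8) 8L else 16L
  store_top <- 2^store_bits - 1
  norm <- lapply(seq$frames, function(f) round(f) / top)
  sidecar <- list(frame_rate = seq$frame_rate, bit_depth = seq$bit_depth,
                  pixel_spacing = seq$pixel_spacing, plane = seq$plane,
                  orientation_config = seq$orientation_config,
                  direction = seq$direction)
  if (format == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = store_bits)
    jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(norm)) {
      png::writePNG(norm[[i]], file.path(path, sprintf("frame_%05d.png", i - 1)))
    }
    jsonlite::write_json(sidecar, file.path(path, "meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}

canonical_roles <- c("corner_as", "corner_ps", "corner_pi", "corner_ai")

#' Read a landmark file
#'
#' Reads the delimited-text landmark schema (columns `vertebra`,
#' `marking_id`, `point_role`, `region_id`, `point_index`, `x_px`, `y_px`).
#' Corner rows are checked to form a simple quadrilateral in canonical role
#' order (anterior-superior, posterior-superior, posterior-inferior,
#' anterior-inferior); corners listed with inconsistent winding are
#' reordered to canonical order with a warning.
#'
#' @param path CSV file path.
#' @return A landmark tibble.
#' @export
read_landmarks <- function(path) {
  lm <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  required <- c("vertebra", "marking_id", "point_role", "x_px", "y_px")
  if (!all(required %in% names(lm))) {
    stop("landmark file lacks required columns: ",
         paste(setdiff(required, names(lm)), collapse = ", "), call. = FALSE)
  }
  if (!"region_id" %in% names(lm)) lm$region_id <- 1L
  if (!"point_index" %in% names(lm)) lm$point_index <- 1L
  if (any(!lm$marking_id %in% 1:5)) {
    stop("marking_id must be within 1..5", call. = FALSE)
  }
  keys <- dplyr::distinct(lm, .data$vertebra, .data$marking_id)
  out <- lm
  # bow-ties are errors; a simple quadrilateral whose winding disagrees with
  # the file majority has its superior/inferior roles mirrored: reverse to
  # canonical order with a warning (orientation test via signed area)
  get_cc <- function(sel) {
    as.matrix(out[sel, c("x_px", "y_px")][
      match(canonical_roles, out$point_role[sel]), ])
  }
  sels <- list(); areas <- numeric(0)
  for (ki in seq_len(nrow(keys))) {
    sel <- out$vertebra == keys$vertebra[ki] &
      out$marking_id == keys$marking_id[ki] &
      out$point_role %in% canonical_roles
    if (sum(sel) != 4) { sels[[ki]] <- NULL; next }
    cc <- get_cc(sel)
    if (polygon_self_intersects(cc)) {
      stop("validation error: corners of ", keys$vertebra[ki], " marking ",
           keys$marking_id[ki], " form a self-intersecting quadrilateral",
           call. = FALSE)
    }
    a <- polygon_area(cc)
    if (abs(a) < 1e-9) {
      stop("validation error: corners of ", keys$vertebra[ki], " marking ",
           keys$marking_id[ki], " are degenerate (zero area)", call. = FALSE)
    }
    sels[[ki]] <- sel
    areas[ki] <- a
  }
  ref_sign <- sign(sum(sign(areas)))
  if (ref_sign == 0) ref_sign <- sign(areas[1])
  for (ki in seq_len(nrow(keys))) {
    sel <- sels[[ki]]
    if (is.null(sel) || sign(areas[ki]) == ref_sign) next
    warning("corners of ", keys$vertebra[ki], " marking ",
            keys$marking_id[ki],
            " reordered to canonical role order (winding was inconsistent)")
    cc <- get_cc(sel)
    fixed <- cc[c(4, 3, 2, 1), ]
    rows <- which(sel)[match(canonical_roles, out$point_role[sel])]
    for (ri in 1:4) {
      out[rows[ri], c("x_px", "y_px")] <- as.list(fixed[ri, ])
    }
  }
  out
}

#' Write a landmark file
#'
#' @param lm landmark tibble (see [read_landmarks()] for the schema).
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  write.csv(lm[, c("vertebra", "marking_id", "point_role", "region_id",
                   "point_index", "x_px", "y_px")],
            path, row.names = FALSE)
  invisible(path)
}

#' Write kinematic results to disk
#'
#' Writes the continuous curves as long-format delimited text (level, frame,
#' trunk angle, intervertebral rotation, translation, disc height) and the
#' per-level summary of the consensus indices as a second table.
#'
#' @param kin a `qf_kinematics` with indices computed (see
#'   [motion_indices()]).
#' @param path output stem; `<path>_curves.csv` and `<path>_indices.csv`
#'   are written.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(kin, path) {
  stopifnot(inherits(kin, "qf_kinematics"))
  curves <- dplyr::left_join(kin$rotation, kin$translation,
                             by = c("level", "frame"))
  if (!is.null(kin$trunk)) {
    curves$trunk_angle_deg <- kin$trunk[curves$frame + 1]
  }
  long <- curves[, c("level", "frame",
                     intersect("trunk_angle_deg", names(curves)),
                     "median", "trans_median_pct", "disc_median_pct")]
  names(long)[names(long) == "median"] <- "iv_rotation_deg"
  names(long)[names(long) == "trans_median_pct"] <- "iv_translation_pct"
  names(long)[names(long) == "disc_median_pct"] <- "disc_height_pct"
  f1 <- paste0(path, "_curves.csv")
  write.csv(long, f1, row.names = FALSE)
  files <- f1
  if (!is.null(kin$indices)) {
    f2 <- paste0(path, "_indices.csv")
    write.csv(kin$indices, f2, row.names = FALSE)
    files <- c(files, f2)
  }
  invisible(files)
}

# --- minimal DICOM support -------------------------------------------------
# A deliberately small reader for uncompressed little-endian DICOM
# (explicit or implicit VR): enough to obtain the pixel grid, stored bit
# depth, pixel spacing and frame timing of fluoroscopic exports.  No
# installed package provides DICOM parsing; compressed transfer syntaxes
# are out of scope and rejected.

dcm_tag <- function(group, element) bitwShiftL(group, 16) + element

read_dicom_minimal <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) > 132 && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
  } else {
    pos <- 1L
  }
  u16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1])
  u32 <- function(at) as.numeric(u16(at)) + 65536 * as.numeric(u16(at + 2))
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  fields <- list()
  pixel <- NULL; pixel_len <- 0
  while (pos + 8 <= length(raw)) {
    group <- u16(pos); element <- u16(pos + 2)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    explicit <- grepl("^[A-Z]{2}$", vr)
    if (explicit && vr %in% long_vrs) {
      len <- u32(pos + 8); data_at <- pos + 12
    } else if (explicit) {
      len <- u16(pos + 6); data_at <- pos + 8
    } else {
      vr <- "UN"; len <- u32(pos + 4); data_at <- pos + 8
    }
    if (len < 0 || data_at + len - 1 > length(raw)) break
    tag <- dcm_tag(group, element)
    bytes <- if (len > 0) raw[data_at:(data_at + len - 1)] else raw(0)
    if (tag == dcm_tag(0x7FE0, 0x0010)) {
      pixel <- bytes; pixel_len <- len
    } else {
      fields[[as.character(tag)]] <- bytes
    }
    pos <- data_at + len
  }
  getf <- function(g, e) fields[[as.character(dcm_tag(g, e))]]
  as_us <- function(b) if (is.null(b)) NULL else
    as.integer(b[1]) + 256L * as.integer(b[2])
  as_str <- function(b) if (is.null(b)) NULL else trimws(rawToChar(b))
  rows <- as_us(getf(0x0028, 0x0010))
  cols <- as_us(getf(0x0028, 0x0011))
  bits_alloc <- as_us(getf(0x0028, 0x0100)) %||% 16L
  bits_stored <- as_us(getf(0x0028, 0x0101)) %||% bits_alloc
  ts <- as_str(getf(0x0002, 0x0010))
  if (!is.null(ts) && !ts %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")) {
    stop("unsupported DICOM transfer syntax ", ts,
         " (only uncompressed little endian is read)", call. = FALSE)
  }
  if (is.null(rows) || is.null(cols) || is.null(pixel)) {
    stop("not a readable DICOM image file: ", path, call. = FALSE)
  }
  nfr_s <- as_str(getf(0x0028, 0x0008))
  nfr <- if (is.null(nfr_s)) NA_integer_ else
    suppressWarnings(as.integer(nfr_s))
  spacing <- as_str(getf(0x0028, 0x0030))
  spacing <- if (!is.null(spacing)) {
    as.numeric(strsplit(spacing, "\\\\")[[1]][1])
  } else NULL
  frame_time_ms <- as_str(getf(0x0018, 0x1063))
  cine_rate <- as_str(getf(0x0018, 0x0040))
  frame_rate <- if (!is.null(frame_time_ms)) 1000 / as.numeric(frame_time_ms)
  else if (!is.null(cine_rate)) as.numeric(cine_rate)
  else NULL
  bpp <- bits_alloc / 8
  n_px <- pixel_len / bpp
  vals <- if (bpp == 1) as.integer(pixel)
  else readBin(pixel, "integer", n = n_px, size = 2, signed = FALSE,
               endian = "little")
  if (is.na(nfr)) nfr <- max(1L, floor(n_px / (rows * cols)))
  frames <- lapply(seq_len(nfr), function(k) {
    off <- (k - 1) * rows * cols
    # DICOM stores row-major; R matrices are column-major
    matrix(vals[(off + 1):(off + rows * cols)], nrow = rows, ncol = cols,
           byrow = TRUE)
  })
  list(frames = frames, bits_stored = as.integer(bits_stored),
       pixel_spacing = spacing, frame_rate = frame_rate)
}
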