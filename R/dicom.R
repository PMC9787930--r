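# Minimal DICOM part-10 I/O: explicit VR little endian, uncompressed,
# single-frame secondary-capture-style MR slices carrying the four geometry
# tags the pipeline needs (Slice Location, Pixel Spacing, Spacing Between
# Slices, Image Orientation) plus pixel data stored as unsigned 16-bit.
# Full DICOM conformance is out of scope.

#' A single DICOM-style MR slice
#'
#' @param pixel_grid 2D numeric matrix of finite intensities (rows x columns).
#' @param slice_location position in mm along the stack normal.
#' @param pixel_spacing length-2 positive numeric, row/column spacing in mm.
#' @param spacing_between_slices positive scalar, mm between slice centers.
#' @param image_orientation length-6 numeric: direction cosines of the first
#'   row and first column in LPS patient space (two unit 3-vectors).
#' @param series_modality one of `"FLAIR"`, `"T1w"`, `"T1wCE"`, `"T2w"`.
#' @param patient_id opaque identifier.
#' @return object of class `slice_record`.
#' @export
slice_record <- function(pixel_grid, slice_location, pixel_spacing,
                         spacing_between_slices,
                         image_orientation = c(0, 1, 0, 0, 0, -1),
                         series_modality = "FLAIR", patient_id = "anon") {
  if (!is.matrix(pixel_grid) || any(!is.finite(pixel_grid)))
    stop("pixel_grid must be a finite numeric matrix")
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("pixel_spacing must be two positive values")
  if (spacing_between_slices <= 0)
    stop("spacing_between_slices must be positive")
  io <- as.numeric(image_orientation)
  if (length(io) != 6L ||
      abs(sqrt(sum(io[1:3]^2)) - 1) > 1e-4 ||
      abs(sqrt(sum(io[4:6]^2)) - 1) > 1e-4)
    stop("image_orientation must hold two unit direction-cosine vectors")
  structure(
    list(pixel_grid = pixel_grid, slice_location = as.numeric(slice_location),
         pixel_spacing = as.numeric(pixel_spacing),
         spacing_between_slices = as.numeric(spacing_between_slices),
         image_orientation = io, series_modality = series_modality,
         patient_id = patient_id),
    class = "slice_record")
}

#' Stack DICOM slices into a 3D volume
#'
#' Slices are ordered by the Slice Location tag alone, ascending, and stacked
#' along the third grid axis. All slices must agree on patient, modality,
#' grid shape, pixel spacing, slice spacing and orientation.
#'
#' @param slices list of [slice_record] objects.
#' @return a [brain_volume] with spacing `(row, column, between-slices)` mm.
#' @export
assemble_volume <- function(slices) {
  if (length(slices) < 1L) stop("need at least one slice")
  stopifnot(all(vapply(slices, inherits, TRUE, "slice_record")))
  ref <- slices[[1L]]
  same <- function(f, tol = 1e-9) {
    all(vapply(slices, function(s) {
      a <- s[[f]]; b <- ref[[f]]
      if (is.numeric(a)) length(a) == length(b) && all(abs(a - b) <= tol)
      else identical(a, b)
    }, TRUE))
  }
  shapes <- vapply(slices, function(s) dim(s$pixel_grid), integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]) ||
      !same("pixel_spacing") || !same("spacing_between_slices") ||
      !same("image_orientation") || !same("series_modality") ||
      !same("patient_id"))
    stop("inconsistent series: slices disagree on shape, spacing, ",
         "orientation, modality or patient")
  locs <- vapply(slices, `[[`, numeric(1), "slice_location")
  if (anyDuplicated(locs))
    stop("ambiguous ordering: duplicate Slice Location values")
  ord <- order(locs)
  d <- dim(ref$pixel_grid)
  grid <- array(0, dim = c(d[1], d[2], length(slices)))
  for (i in seq_along(ord)) grid[, , i] <- slices[[ord[i]]]$pixel_grid
  r <- ref$image_orientation[1:3]
  cc <- ref$image_orientation[4:6]
  normal <- c(r[2] * cc[3] - r[3] * cc[2],
              r[3] * cc[1] - r[1] * cc[3],
              r[1] * cc[2] - r[2] * cc[1])
  brain_volume(grid,
               spacing = c(ref$pixel_spacing, ref$spacing_between_slices),
               orientation = cbind(r, cc, normal, deparse.level = 0),
               modality = ref$series_modality, patient_id = ref$patient_id)
}

# ---- part-10 writer ---------------------------------------------------------

dcm_u16_raw <- function(values) {
  v <- as.integer(round(values))
  writeBin(as.integer(ifelse(v > 32767L, v - 65536L, v)), raw(),
           size = 2L, endian = "little")
}

dcm_text_raw <- function(s, pad_null = FALSE) {
  b <- charToRaw(s)
  if (length(b) %% 2L == 1L)
    b <- c(b, if (pad_null) as.raw(0L) else charToRaw(" "))
  b
}

dcm_ds <- function(x) paste(sprintf("%.10g", x), collapse = "\\")

dcm_element <- function(group, elem, vr, value_raw) {
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2L,
                  endian = "little")
  long_form <- vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")
  if (long_form) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(value_raw), raw(), size = 4L, endian = "little"),
      value_raw)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2L,
               endian = "little"),
      value_raw)
  }
}

#' Write a volume as a DICOM series
#'
#' Emits one part-10 file per slice along the third grid axis (explicit VR
#' little endian, unsigned 16-bit pixels) with Slice Location, Pixel Spacing,
#' Spacing Between Slices and Image Orientation tags, so that
#' `assemble_volume(read_dicom_series(dir))` reproduces the volume exactly
#' for integer-valued grids.
#'
#' @param vol a [brain_volume] with values in `[0, 65535]`.
#' @param out_dir output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
write_dicom_series <- function(vol, out_dir) {
  validate_volume(vol)
  if (any(vol$grid < 0 | vol$grid > 65535))
    stop("pixel values outside the unsigned 16-bit range")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(vol$grid)
  iop <- c(vol$orientation[, 1], vol$orientation[, 2])
  ts <- dcm_text_raw("1.2.840.10008.1.2.1", pad_null = TRUE)
  meta_body <- dcm_element(0x0002, 0x0010, "UI", ts)
  meta <- c(dcm_element(0x0002, 0x0000, "UL",
                        writeBin(length(meta_body), raw(), size = 4L,
                                 endian = "little")),
            meta_body)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    sl <- vol$grid[, , k]
    body <- c(
      dcm_element(0x0008, 0x0060, "CS", dcm_text_raw("MR")),
      dcm_element(0x0008, 0x103E, "LO", dcm_text_raw(vol$modality)),
      dcm_element(0x0010, 0x0020, "LO", dcm_text_raw(vol$patient_id)),
      dcm_element(0x0018, 0x0088, "DS",
                  dcm_text_raw(dcm_ds(vol$spacing[3]))),
      dcm_element(0x0020, 0x0037, "DS", dcm_text_raw(dcm_ds(iop))),
      dcm_element(0x0020, 0x1041, "DS",
                  dcm_text_raw(dcm_ds((k - 1) * vol$spacing[3]))),
      dcm_element(0x0028, 0x0010, "US", dcm_u16_raw(d[1])),
      dcm_element(0x0028, 0x0011, "US", dcm_u16_raw(d[2])),
      dcm_element(0x0028, 0x0030, "DS",
                  dcm_text_raw(dcm_ds(vol$spacing[1:2]))),
      dcm_element(0x0028, 0x0100, "US", dcm_u16_raw(16)),
      dcm_element(0x0028, 0x0103, "US", dcm_u16_raw(0)),
      dcm_element(0x7FE0, 0x0010, "OW", dcm_u16_raw(as.vector(t(sl))))
    )
    path <- file.path(out_dir, sprintf("%s_%s_%04d.dcm", vol$patient_id,
                                       vol$modality, k))
    con <- file(path, "wb")
    writeBin(c(raw(128L), charToRaw("DICM"), meta, body), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

# ---- part-10 reader ---------------------------------------------------------

dcm_parse_file <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  pos <- 133L
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    grp <- readBin(bytes[pos:(pos + 1L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    ele <- readBin(bytes[(pos + 2L):(pos + 3L)], "integer", size = 2L,
                   signed = FALSE, endian = "little")
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- readBin(bytes[(pos + 8L):(pos + 11L)], "integer", size = 4L,
                     endian = "little")
      val_start <- pos + 12L
    } else {
      len <- readBin(bytes[(pos + 6L):(pos + 7L)], "integer", size = 2L,
                     signed = FALSE, endian = "little")
      val_start <- pos + 8L
    }
    val <- if (len > 0L) bytes[val_start:(val_start + len - 1L)] else raw(0)
    key <- sprintf("%04X%04X", grp, ele)
    out[[key]] <- list(vr = vr, raw = val)
    pos <- val_start + len
  }
  out
}

dcm_value <- function(el) {
  switch(el$vr,
    DS = as.numeric(strsplit(trimws(rawToChar(el$raw)), "\\\\")[[1]]),
    US = readBin(el$raw, "integer", n = length(el$raw) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    OW = readBin(el$raw, "integer", n = length(el$raw) / 2L, size = 2L,
                 signed = FALSE, endian = "little"),
    trimws(rawToChar(el$raw))
  )
}

#' Read a DICOM series into slice records
#'
#' @param dir_or_paths a directory containing `.dcm` files, or an explicit
#'   character vector of file paths.
#' @return list of [slice_record] objects (file order, not spatial order;
#'   ordering is [assemble_volume]'s job).
#' @export
read_dicom_series <- function(dir_or_paths) {
  paths <- if (length(dir_or_paths) == 1L && dir.exists(dir_or_paths))
    list.files(dir_or_paths, pattern = "\\.dcm$", full.names = TRUE)
  else dir_or_paths
  if (length(paths) == 0L) stop("no DICOM files found")
  lapply(paths, function(p) {
    els <- dcm_parse_file(p)
    need <- c("00180088", "00201041", "00280010", "00280011", "00280030",
              "00200037", "7FE00010")
    if (!all(need %in% names(els)))
      stop("missing required DICOM tags in ", p)
    nr <- dcm_value(els[["00280010"]])
    nc <- dcm_value(els[["00280011"]])
    px <- dcm_value(els[["7FE00010"]])
    grid <- t(matrix(as.numeric(px), nrow = nc, ncol = nr))
    slice_record(
      pixel_grid = grid,
      slice_location = dcm_value(els[["00201041"]]),
      pixel_spacing = dcm_value(els[["00280030"]]),
      spacing_between_slices = dcm_value(els[["00180088"]]),
      image_orientation = dcm_value(els[["00200037"]]),
      series_modality = if ("0008103E" %in% names(els))
        dcm_value(els[["0008103E"]]) else "FLAIR",
      patient_id = if ("00100020" %in% names(els))
        dcm_value(els[["00100020"]]) else "anon")
  })
}
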