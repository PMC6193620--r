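# Frame and tabular I/O: 8-bit grayscale PNG, minimal uncompressed DICOM
# (explicit/implicit VR little endian, single-frame monochrome), and cohort
# manifest CSVs.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_SC_STORAGE <- "1.2.840.10008.5.1.4.1.1.7"  # secondary capture

# ---- DICOM writing ---------------------------------------------------------

uint_le <- function(x, size) {
  out <- raw(size)
  for (k in seq_len(size)) {
    out[k] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

dcm_tag <- function(group, elem) c(uint_le(group, 2), uint_le(elem, 2))

# One explicit-VR little-endian data element.
dcm_elem <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, as.raw(if (vr == "UI") 0L else 0x20))
  if (vr %in% c("OB", "OW", "UT", "UN", "SQ")) {
    c(dcm_tag(group, elem), charToRaw(vr), raw(2), uint_le(length(value_raw), 4), value_raw)
  } else {
    c(dcm_tag(group, elem), charToRaw(vr), uint_le(length(value_raw), 2), value_raw)
  }
}

dcm_str <- function(group, elem, vr, s) dcm_elem(group, elem, vr, charToRaw(s))
dcm_us <- function(group, elem, x) dcm_elem(group, elem, "US", uint_le(x, 2))

neolus_uid <- function() {
  # Deterministic-ish private UID; uniqueness is irrelevant for analysis use.
  paste0("1.2.826.0.1.3680043.9.9999.", format(as.numeric(Sys.time()) * 1000, scientific = FALSE, trim = TRUE),
         ".", sample.int(1e6, 1))
}

#' Write a grayscale image as minimal uncompressed DICOM
#'
#' Emits a single-frame MONOCHROME2 secondary-capture object with explicit
#' VR little endian transfer syntax. Bit depths above 8 are supported so
#' deeper-than-8-bit fixtures can be produced; pixel values must fit in
#' `bits_stored` bits.
#'
#' @param pixels integer matrix of non-negative pixel values
#' @param path output file path
#' @param bits_stored stored bit depth (8, 12 or 16)
#' @return `path`, invisibly
#' @export
write_dicom_gray <- function(pixels, path, bits_stored = 8) {
  stop_if_not(is.matrix(pixels) && all(pixels >= 0), "pixels must be a non-negative matrix")
  stop_if_not(bits_stored %in% c(8, 12, 16), "bits_stored must be 8, 12 or 16")
  stop_if_not(all(pixels < 2^bits_stored), "pixel values exceed bits_stored")
  bits_alloc <- if (bits_stored > 8) 16L else 8L
  vals <- as.integer(t(pixels))  # DICOM pixel order is row-major

  pix_raw <- if (bits_alloc == 8) as.raw(vals)
  else as.raw(rbind(vals %% 256L, vals %/% 256L))
  uid <- neolus_uid()

  meta <- c(
    dcm_elem(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    dcm_str(0x0002, 0x0002, "UI", UID_SC_STORAGE),
    dcm_str(0x0002, 0x0003, "UI", uid),
    dcm_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE)
  )
  dataset <- c(
    dcm_str(0x0008, 0x0016, "UI", UID_SC_STORAGE),
    dcm_str(0x0008, 0x0018, "UI", uid),
    dcm_us(0x0028, 0x0002, 1),
    dcm_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_us(0x0028, 0x0010, nrow(pixels)),
    dcm_us(0x0028, 0x0011, ncol(pixels)),
    dcm_us(0x0028, 0x0100, bits_alloc),
    dcm_us(0x0028, 0x0101, bits_stored),
    dcm_us(0x0028, 0x0102, bits_stored - 1),
    dcm_us(0x0028, 0x0103, 0),
    dcm_elem(0x7FE0, 0x0010, if (bits_alloc == 8) "OB" else "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(dcm_elem(0x0002, 0x0000, "UL", uint_le(length(meta), 4)), con)
  writeBin(meta, con)
  writeBin(dataset, con)
  invisible(path)
}

# ---- DICOM reading ---------------------------------------------------------

raw_uint_le <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))

# Parse a stream of little-endian data elements starting at offset `pos`
# (1-based) in `bytes`; returns a named list tag -> raw value. Stops after
# PixelData. `explicit` selects the VR encoding.
parse_dcm_elements <- function(bytes, pos, explicit, end = length(bytes)) {
  out <- list()
  n <- end
  long_vrs <- c("OB", "OW", "OF", "UT", "UN", "SQ")
  while (pos + 7 <= n) {
    group <- raw_uint_le(bytes[pos:(pos + 1)])
    elem <- raw_uint_le(bytes[(pos + 2):(pos + 3)])
    pos <- pos + 4
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1)])
      if (vr %in% long_vrs) {
        len <- raw_uint_le(bytes[(pos + 4):(pos + 7)])
        pos <- pos + 8
      } else {
        len <- raw_uint_le(bytes[(pos + 2):(pos + 3)])
        pos <- pos + 4
      }
    } else {
      len <- raw_uint_le(bytes[pos:(pos + 3)])
      pos <- pos + 4
    }
    if (len == 4294967295) stop("undefined-length DICOM element: unsupported (compressed?)")
    if (pos + len - 1 > n) stop("truncated DICOM element")
    key <- sprintf("%04X,%04X", group, elem)
    out[[key]] <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    if (key == "7FE0,0010") break
  }
  out
}

dcm_get_str <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  v <- v[v != as.raw(0)]  # strip UI nul padding before conversion
  sub(" +$", "", rawToChar(v))
}

dcm_get_us <- function(elems, key) {
  v <- elems[[key]]
  if (is.null(v)) return(NULL)
  raw_uint_le(v[1:2])
}

read_dicom_gray <- function(path) {
  bytes <- readBin(path, "raw", file.info(path)$size)
  stop_if_not(length(bytes) > 132 && identical(bytes[129:132], charToRaw("DICM")),
              "not a DICOM part-10 file: ", path)
  # First meta element is the group length: tag(4) + "UL"(2) + len(2) + value(4).
  stop_if_not(rawToChar(bytes[137:138]) == "UL", "malformed DICOM meta header")
  meta_len <- raw_uint_le(bytes[141:144])
  meta_end <- 132 + 12 + meta_len
  meta <- parse_dcm_elements(bytes, 145, explicit = TRUE, end = meta_end)
  ts <- dcm_get_str(meta, "0002,0010")
  if (is.null(ts)) ts <- UID_EXPLICIT_LE
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    stop("unsupported DICOM transfer syntax (only uncompressed little endian): ", ts)

  el <- parse_dcm_elements(bytes, meta_end + 1, explicit = ts == UID_EXPLICIT_LE)
  rows <- dcm_get_us(el, "0028,0010"); cols <- dcm_get_us(el, "0028,0011")
  ba <- dcm_get_us(el, "0028,0100"); bs <- dcm_get_us(el, "0028,0101")
  spp <- dcm_get_us(el, "0028,0002")
  photo <- dcm_get_str(el, "0028,0004")
  pix <- el[["7FE0,0010"]]
  stop_if_not(!is.null(rows) && !is.null(cols) && !is.null(ba) && !is.null(pix),
              "DICOM file lacks image elements: ", path)
  if (!is.null(spp) && spp != 1)
    stop("color DICOM (SamplesPerPixel = ", spp, ") not supported; grayscale input required")
  if (!is.null(photo) && photo != "MONOCHROME2")
    stop("unsupported photometric interpretation: ", photo)
  if (is.null(bs)) bs <- ba

  vals <- if (ba <= 8) as.integer(pix[seq_len(rows * cols)])
  else {
    stop_if_not(length(pix) >= 2 * rows * cols, "pixel data shorter than Rows x Columns")
    m <- matrix(as.integer(pix[seq_len(2 * rows * cols)]), nrow = 2)
    m[1, ] + 256L * m[2, ]
  }
  px <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  if (bs > 8) px <- round(px * 255 / (2^bs - 1))  # linear rescale to 8 bit
  px
}

# ---- Frame-level API -------------------------------------------------------

#' Read a grayscale frame from PNG or DICOM
#'
#' DICOM input must be uncompressed little endian, single-sample
#' MONOCHROME2; bit depths above 8 are linearly rescaled to \code{[0, 255]}
#' by `round(v * 255 / (2^bits_stored - 1))`. Color input (RGB PNG or
#' multi-sample DICOM) is rejected.
#'
#' @param path file path; format detected from content (DICOM magic) with
#'   PNG fallback
#' @param patient_id,view metadata attached to the returned frame
#' @return an [lus_frame()]
#' @export
read_frame <- function(path, patient_id = NA_character_, view = NA_character_) {
  stop_if_not(file.exists(path), "no such file: ", path)
  head <- readBin(path, "raw", 132)
  px <- if (length(head) >= 132 && identical(head[129:132], charToRaw("DICM"))) {
    read_dicom_gray(path)
  } else {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3)
      stop("color or alpha-channel PNG not supported; grayscale input required: ", path)
    round(img * 255)
  }
  lus_frame(px, patient_id = patient_id, view = view, source_path = path)
}

#' Write a frame to PNG or DICOM
#'
#' @param frame an [lus_frame()] or pixel matrix
#' @param path output path; format chosen from the extension (`.png` or
#'   `.dcm`) unless `format` is given
#' @param format `"png"` or `"dicom"`
#' @return `path`, invisibly
#' @export
write_frame <- function(frame, path, format = NULL) {
  px <- frame_pixels(frame)
  if (is.null(format)) {
    format <- if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom" else "png"
  }
  if (format == "png") png::writePNG(px / 255, path)
  else if (format == "dicom") write_dicom_gray(px, path, bits_stored = 8)
  else stop("unknown format: ", format)
  invisible(path)
}

# ---- Cohort manifests ------------------------------------------------------

#' Tabulate a cohort as a per-frame manifest
#'
#' @param cohort an `lus_cohort`
#' @param frame_paths optional character vector of per-frame file paths (in
#'   cohort order) to record
#' @return data frame with one row per frame: patient_id, view, frame_path,
#'   true_grade, rater1, rater2, fio2, pao2, paco2, seed
#' @export
cohort_manifest <- function(cohort, frame_paths = NULL) {
  rows <- lapply(cohort, function(p) {
    nv <- length(p$frames)
    data.frame(
      patient_id = p$patient_id,
      view = vapply(p$frames, function(f) f$view, character(1)),
      frame_path = NA_character_,
      true_grade = p$true_grades,
      rater1 = p$rater_grades$rater1, rater2 = p$rater_grades$rater2,
      fio2 = p$fio2, pao2 = p$pao2, paco2 = p$paco2, seed = p$seed,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(frame_paths)) out$frame_path <- frame_paths
  out
}

#' Write a cohort to disk (frames + manifest CSV)
#'
#' @param cohort an `lus_cohort`
#' @param dir output directory (created if needed)
#' @param format frame format, `"png"` or `"dicom"`
#' @return path of the written manifest CSV, invisibly
#' @export
write_cohort <- function(cohort, dir, format = c("png", "dicom")) {
  format <- match.arg(format)
  ext <- if (format == "png") "png" else "dcm"
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  paths <- unlist(lapply(cohort, function(p) {
    vapply(p$frames, function(f) {
      rel <- file.path("frames", sprintf("%s_%s.%s", p$patient_id, f$view, ext))
      write_frame(f, file.path(dir, rel), format = format)
      rel
    }, character(1))
  }))
  man <- cohort_manifest(cohort, frame_paths = paths)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Read a cohort manifest CSV
#'
#' Groups rows by patient, validates the schema (every patient has exactly
#' `views_per_patient` rows, grades within 0..3) and returns patient records.
#' Frames are loaded lazily: each record carries `frame_paths` (resolved
#' against the manifest's directory) and `frames` is `NULL` until
#' [load_patient_frames()] is called, unless `load_frames = TRUE`.
#'
#' @param path manifest CSV path
#' @param views_per_patient required number of rows (views) per patient
#' @param load_frames read pixel data immediately?
#' @return list of patient records, class `lus_cohort`
#' @export
read_cohort_manifest <- function(path, views_per_patient = 8, load_frames = FALSE) {
  stop_if_not(file.exists(path), "no such file: ", path)
  man <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot parse manifest: ", conditionMessage(e), call. = FALSE))
  needed <- c("patient_id", "view", "frame_path", "true_grade", "rater1",
              "rater2", "fio2", "pao2", "paco2")
  stop_if_not(nrow(man) > 0, "manifest is empty: ", path)
  missing_cols <- setdiff(needed, names(man))
  stop_if_not(length(missing_cols) == 0,
              "manifest lacks columns: ", paste(missing_cols, collapse = ", "))
  grades <- c(man$true_grade, man$rater1, man$rater2)
  bad <- !(grades %in% 0:3 | is.na(grades))
  stop_if_not(!any(bad), "manifest contains grades outside 0..3")
  counts <- table(man$patient_id)
  short <- names(counts)[counts != views_per_patient]
  stop_if_not(length(short) == 0,
              "patients without exactly ", views_per_patient, " views: ",
              paste(short, collapse = ", "))
  base <- dirname(path)
  recs <- lapply(split(man, man$patient_id), function(g) {
    rec <- structure(list(
      patient_id = g$patient_id[1], severity = NA_real_, frames = NULL,
      frame_paths = file.path(base, g$frame_path),
      views = g$view,
      true_grades = as.integer(g$true_grade),
      rater_grades = list(rater1 = as.integer(g$rater1),
                          rater2 = as.integer(g$rater2)),
      fio2 = g$fio2[1], pao2 = g$pao2[1], paco2 = g$paco2[1],
      seed = if ("seed" %in% names(g)) g$seed[1] else NA_integer_
    ), class = "lus_patient")
    if (load_frames) rec <- load_patient_frames(rec)
    rec
  })
  recs <- recs[order(names(recs))]
  structure(unname(recs), class = "lus_cohort")
}

#' Load the pixel data of a lazily-read patient record
#'
#' @param record an `lus_patient` from [read_cohort_manifest()]
#' @return the record with `frames` populated
#' @export
load_patient_frames <- function(record) {
  if (!is.null(record$frames)) return(record)
  missing <- record$frame_paths[!file.exists(record$frame_paths)]
  stop_if_not(length(missing) == 0,
              "missing frame file(s) for patient ", record$patient_id, ": ",
              paste(missing, collapse = ", "))
  record$frames <- Map(function(pth, v) read_frame(pth, record$patient_id, v),
                       record$frame_paths, record$views)
  record$frames <- unname(record$frames)
  record
}
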