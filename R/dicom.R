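# Minimal single-frame CT DICOM interchange: Explicit VR Little Endian
# only, 16-bit signed stored pixels with Rescale Slope/Intercept mapping to
# HU. Covers round-tripping phantoms and reading files written by standard
# tooling in the same transfer syntax; it is deliberately not a general
# DICOM implementation.

UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
UID_CT_IMAGE_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

raw_u16 <- function(x) as.raw(c(x %% 256, x %/% 256))
raw_u32 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256,
                                (x %/% 65536) %% 256, (x %/% 16777216) %% 256))

dcm_string <- function(s, ui = FALSE) {
  v <- charToRaw(s)
  if (length(v) %% 2 == 1) v <- c(v, if (ui) as.raw(0) else charToRaw(" "))
  v
}

dcm_element <- function(group, elem, vr, value) {
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(raw_u16(group), raw_u16(elem), charToRaw(vr), as.raw(c(0, 0)),
      raw_u32(length(value)), value)
  else
    c(raw_u16(group), raw_u16(elem), charToRaw(vr), raw_u16(length(value)),
      value)
}

instance_uid <- function(id) {
  h <- 0
  for (c in utf8ToInt(id)) h <- (h * 131 + c) %% 1e9
  sprintf("1.2.826.0.1.3680043.9.7432.%d.%d", h, 1)
}

#' Write a CT image as a single-frame DICOM file
#'
#' Explicit VR Little Endian; stored values are `round(HU) + 1024` with
#' Rescale Slope 1 and Intercept -1024, so HU round-trip within 0.5 HU
#' (the integer quantisation step).
#'
#' @param img A [ct_image()].
#' @param path Output file path.
#' @param instance_number Instance Number tag value (series ordering).
#' @return `path`, invisibly.
#' @export
write_dicom <- function(img, path, instance_number = 1) {
  if (!inherits(img, "ct_image"))
    stop("`img` must be a ct_image", call. = FALSE)
  px <- img$pixels
  stored <- matrix(as.integer(round(px)) + 1024L, nrow(px), ncol(px))
  # row-major pixel order
  pix_raw <- writeBin(as.vector(t(stored)), raw(), size = 2,
                      endian = "little")

  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", dcm_string(UID_CT_IMAGE_STORAGE, ui = TRUE)),
    dcm_element(0x0002, 0x0003, "UI", dcm_string(instance_uid(img$id), ui = TRUE)),
    dcm_element(0x0002, 0x0010, "UI", dcm_string(UID_EXPLICIT_VR_LE, ui = TRUE)))
  meta <- c(dcm_element(0x0002, 0x0000, "UL", raw_u32(length(meta_body))),
            meta_body)

  spacing <- sprintf("%.10g\\%.10g", img$spacing_mm, img$spacing_mm)
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", dcm_string(UID_CT_IMAGE_STORAGE, ui = TRUE)),
    dcm_element(0x0008, 0x0018, "UI", dcm_string(instance_uid(img$id), ui = TRUE)),
    dcm_element(0x0008, 0x0060, "CS", dcm_string("CT")),
    dcm_element(0x0020, 0x0013, "IS",
                dcm_string(sprintf("%d", as.integer(instance_number)))),
    dcm_element(0x0028, 0x0002, "US", raw_u16(1)),
    dcm_element(0x0028, 0x0004, "CS", dcm_string("MONOCHROME2")),
    dcm_element(0x0028, 0x0010, "US", raw_u16(nrow(px))),
    dcm_element(0x0028, 0x0011, "US", raw_u16(ncol(px))),
    dcm_element(0x0028, 0x0030, "DS", dcm_string(spacing)),
    dcm_element(0x0028, 0x0100, "US", raw_u16(16)),
    dcm_element(0x0028, 0x0101, "US", raw_u16(16)),
    dcm_element(0x0028, 0x0102, "US", raw_u16(15)),
    dcm_element(0x0028, 0x0103, "US", raw_u16(1)),
    dcm_element(0x0028, 0x1052, "DS", dcm_string("-1024")),
    dcm_element(0x0028, 0x1053, "DS", dcm_string("1")),
    dcm_element(0x7FE0, 0x0010, "OW", pix_raw))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, dataset), con)
  invisible(path)
}

read_u16 <- function(bytes, at)
  as.integer(bytes[at]) + 256L * as.integer(bytes[at + 1])
read_u32 <- function(bytes, at)
  as.integer(bytes[at]) + 256 * as.integer(bytes[at + 1]) +
  65536 * as.integer(bytes[at + 2]) + 16777216 * as.integer(bytes[at + 3])

#' Read a single-frame CT DICOM file
#'
#' Supports Explicit VR Little Endian with Rescale Slope/Intercept present;
#' HU = stored * slope + intercept. Non-CT modality raises a warning;
#' files that are not parseable raise a format error.
#'
#' @param path DICOM file path.
#' @return A [ct_image()], with attribute `"instance_number"`.
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 200 ||
      !identical(rawToChar(bytes[129:132]), "DICM"))
    ctaudit_error(paste0("not a DICOM file: ", path),
                  "ctaudit_error_dicom_format")
  pos <- 133
  tags <- list()
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  while (pos + 8 <= length(bytes)) {
    group <- read_u16(bytes, pos)
    elem <- read_u16(bytes, pos + 2)
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      ctaudit_error("unsupported transfer syntax (expected Explicit VR LE)",
                    "ctaudit_error_dicom_format")
    if (vr %in% long_vrs) {
      len <- read_u32(bytes, pos + 8)
      data_at <- pos + 12
    } else {
      len <- read_u16(bytes, pos + 6)
      data_at <- pos + 8
    }
    if (data_at + len - 1 > length(bytes))
      ctaudit_error(paste0("truncated DICOM element in ", path),
                    "ctaudit_error_dicom_format")
    key <- sprintf("%04X,%04X", group, elem)
    tags[[key]] <- list(vr = vr,
                        value = bytes[seq(data_at, length.out = len)])
    pos <- data_at + len
  }
  need <- c("0028,0010", "0028,0011", "0028,0030", "7FE0,0010")
  if (!all(need %in% names(tags)))
    ctaudit_error("missing required image tags", "ctaudit_error_dicom_format")
  if (!all(c("0028,1052", "0028,1053") %in% names(tags)))
    ctaudit_error("missing Rescale Slope/Intercept tags",
                  "ctaudit_error_dicom_format")
  str_of <- function(key) {
    v <- tags[[key]]$value
    trimws(rawToChar(v[v != as.raw(0)]))
  }
  modality <- if ("0008,0060" %in% names(tags)) str_of("0008,0060") else ""
  if (!identical(modality, "CT"))
    warning("DICOM modality is not CT: '", modality, "'", call. = FALSE)
  rows <- read_u16(tags[["0028,0010"]]$value, 1)
  cols <- read_u16(tags[["0028,0011"]]$value, 1)
  spacing <- as.numeric(strsplit(str_of("0028,0030"), "\\\\")[[1]][1])
  intercept <- as.numeric(str_of("0028,1052"))
  slope <- as.numeric(str_of("0028,1053"))
  signed <- !("0028,0103" %in% names(tags)) ||
    read_u16(tags[["0028,0103"]]$value, 1) == 1
  stored <- readBin(tags[["7FE0,0010"]]$value, "integer",
                    n = rows * cols, size = 2, signed = signed,
                    endian = "little")
  hu <- matrix(stored * slope + intercept, rows, cols, byrow = TRUE)
  inst <- if ("0020,0013" %in% names(tags))
    as.integer(str_of("0020,0013")) else NA_integer_
  out <- ct_image(clamp_hu(hu), spacing, dose_fraction = 1,
                  id = tools::file_path_sans_ext(basename(path)))
  attr(out, "instance_number") <- inst
  out
}

#' Read a directory of DICOM files as an ordered series
#'
#' Slices are ordered by Instance Number (not filename).
#'
#' @param path Directory containing `.dcm` files.
#' @return List of [ct_image()] objects.
#' @export
read_dicom_series <- function(path) {
  files <- list.files(path, pattern = "\\.dcm$", full.names = TRUE)
  if (length(files) == 0)
    ctaudit_error(paste0("no DICOM files in ", path),
                  "ctaudit_error_dicom_format")
  imgs <- lapply(files, read_dicom)
  inst <- vapply(imgs, function(x) {
    v <- attr(x, "instance_number")
    if (is.na(v)) .Machine$integer.max else v
  }, 0L)
  imgs[order(inst)]
}
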