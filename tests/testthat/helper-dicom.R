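# Synthetic DICOM fixture writer (explicit-VR little-endian, single-frame CT
# slices). Writes only the tags the reader consumes; files are generated at
# test time, never stored.

dcm_raw_uint16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                       endian = "little")
dcm_raw_uint32 <- function(x) writeBin(as.integer(x), raw(), size = 4,
                                       endian = "little")

dcm_element <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2 == 1) value_raw <- c(value_raw, as.raw(0))
  head <- c(dcm_raw_uint16(group), dcm_raw_uint16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN"))
    c(head, as.raw(c(0, 0)), dcm_raw_uint32(length(value_raw)), value_raw)
  else
    c(head, dcm_raw_uint16(length(value_raw)), value_raw)
}

dcm_str_element <- function(group, element, vr, s)
  dcm_element(group, element, vr, charToRaw(s))

# pixels: integer matrix (rows x cols) of stored values (unsigned 16-bit).
write_test_dicom <- function(path, pixels, z = 0, series = "1.2.3.4",
                             pixel_spacing = c(1, 1), thickness = 6,
                             slope = 1, intercept = -1024, instance = 1,
                             patient = "PHANTOM", omit_rescale = FALSE) {
  stored <- as.integer(round(t(pixels)))   # row-major order
  body <- c(
    dcm_str_element(0x0010, 0x0020, "LO", patient),
    dcm_str_element(0x0018, 0x0050, "DS", format(thickness)),
    dcm_str_element(0x0020, 0x000E, "UI", series),
    dcm_str_element(0x0020, 0x0013, "IS", format(instance)),
    dcm_str_element(0x0020, 0x0032, "DS",
                    paste(0, 0, format(z), sep = "\\")),
    dcm_element(0x0028, 0x0010, "US", dcm_raw_uint16(nrow(pixels))),
    dcm_element(0x0028, 0x0011, "US", dcm_raw_uint16(ncol(pixels))),
    dcm_str_element(0x0028, 0x0030, "DS",
                    paste(format(pixel_spacing[1]), format(pixel_spacing[2]),
                          sep = "\\")),
    dcm_element(0x0028, 0x0100, "US", dcm_raw_uint16(16)),
    dcm_element(0x0028, 0x0103, "US", dcm_raw_uint16(0))
  )
  if (!omit_rescale)
    body <- c(body,
              dcm_str_element(0x0028, 0x1052, "DS", format(intercept)),
              dcm_str_element(0x0028, 0x1053, "DS", format(slope)))
  body <- c(body,
            dcm_element(0x7FE0, 0x0010, "OW",
                        writeBin(stored, raw(), size = 2, endian = "little")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}

# Write a consistent n-slice series of HU volumes (HU = stored + intercept).
write_test_series <- function(dir, hu_slices, spacing = c(0.5, 0.5, 6),
                              series = "1.2.3.4", shuffle = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(hu_slices)
  idx <- if (shuffle) rev(seq_len(n)) else seq_len(n)
  for (j in seq_len(n)) {
    k <- idx[j]
    write_test_dicom(file.path(dir, sprintf("slice%02d.dcm", j)),
                     pixels = hu_slices[[k]] + 1024, z = (k - 1) * spacing[3],
                     series = series, pixel_spacing = spacing[1:2],
                     thickness = spacing[3], instance = k)
  }
  invisible(dir)
}
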