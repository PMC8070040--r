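# Minimal single-frame CT DICOM reader/writer (little endian, explicit or
# implicit VR on read; Part-10 explicit VR on write). Covers the tags the
# pipeline needs: geometry, rescale slope/intercept and the pixel data.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
UID_CT_STORAGE <- "1.2.840.10008.5.1.4.1.1.2"

LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

dcm_uid <- function(suffix) {
  # org-root style UID under a generic prefix; uniqueness within a run only
  paste0("1.2.826.0.1.3680043.8.498.", suffix)
}

pad_even <- function(x) {
  if (length(x) %% 2L == 1L) c(x, as.raw(0)) else x
}

dcm_element <- function(group, elem, vr, value) {
  bytes <- switch(vr,
    UI = , CS = , LO = , IS = , DS = , SH = , PN =
      pad_even(charToRaw(as.character(value))),
    US = writeBin(as.integer(value), raw(), size = 2L, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4L, endian = "little"),
    OW = value,
    stop("unsupported VR ", vr)
  )
  head <- c(
    writeBin(as.integer(group), raw(), size = 2L, endian = "little"),
    writeBin(as.integer(elem), raw(), size = 2L, endian = "little"),
    charToRaw(vr)
  )
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(bytes), raw(), size = 4L, endian = "little"), bytes)
  } else {
    c(head, writeBin(length(bytes), raw(), size = 2L, endian = "little"), bytes)
  }
}

# Write one axial CT slice. `hu` is a rows x cols integer matrix of HU
# values; stored values use slope 1 / intercept -1024, signed 16-bit.
dcm_write_slice <- function(hu, path, instance = 1L, z = 0, subject = "phantom",
                            series_uid = dcm_uid("1.1"), spacing = c(1, 1),
                            thickness = 2.5, intercept = -1024, slope = 1) {
  stored <- as.integer(round((as.vector(t(hu)) - intercept) / slope))
  if (any(stored < -32768L | stored > 32767L)) {
    stop("stored pixel values exceed int16 range", call. = FALSE)
  }
  pix <- writeBin(stored, raw(), size = 2L, endian = "little")
  sop_uid <- dcm_uid(paste0("1.2.", instance))
  ds <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_CT_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", sop_uid),
    dcm_element(0x0008, 0x0060, "CS", "CT"),
    dcm_element(0x0010, 0x0020, "LO", subject),
    dcm_element(0x0020, 0x000E, "UI", series_uid),
    dcm_element(0x0020, 0x0013, "IS", as.character(instance)),
    dcm_element(0x0020, 0x0032, "DS",
                sprintf("0\\0\\%s", format(z, trim = TRUE))),
    dcm_element(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_element(0x0028, 0x0002, "US", 1L),
    dcm_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dcm_element(0x0028, 0x0010, "US", nrow(hu)),
    dcm_element(0x0028, 0x0011, "US", ncol(hu)),
    dcm_element(0x0028, 0x0030, "DS",
                sprintf("%s\\%s", format(spacing[1]), format(spacing[2]))),
    dcm_element(0x0018, 0x0050, "DS", format(thickness)),
    dcm_element(0x0028, 0x0100, "US", 16L),
    dcm_element(0x0028, 0x0101, "US", 16L),
    dcm_element(0x0028, 0x0102, "US", 15L),
    dcm_element(0x0028, 0x0103, "US", 1L),
    dcm_element(0x0028, 0x1052, "DS", format(intercept)),
    dcm_element(0x0028, 0x1053, "DS", format(slope)),
    dcm_element(0x7FE0, 0x0010, "OW", pix)
  )
  meta_body <- c(
    dcm_element(0x0002, 0x0002, "UI", UID_CT_STORAGE),
    dcm_element(0x0002, 0x0003, "UI", sop_uid),
    dcm_element(0x0002, 0x0010, "UI", UID_EXPLICIT_LE)
  )
  meta <- c(dcm_element(0x0002, 0x0000, "UL", length(meta_body)), meta_body)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128L), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}

# --- reading -----------------------------------------------------------------

read_u16 <- function(bytes, at) {
  sum(as.integer(bytes[at:(at + 1L)]) * c(1L, 256L))
}

read_u32 <- function(bytes, at) {
  sum(as.numeric(bytes[at:(at + 3L)]) * c(1, 256, 65536, 16777216))
}

# Parse one element at offset `at` (1-based); returns fields + next offset.
dcm_parse_element <- function(bytes, at, explicit) {
  group <- read_u16(bytes, at)
  elem <- read_u16(bytes, at + 2L)
  if (explicit) {
    vr <- rawToChar(bytes[(at + 4L):(at + 5L)])
    if (vr %in% LONG_VRS) {
      len <- read_u32(bytes, at + 8L)
      data_at <- at + 12L
    } else {
      len <- read_u16(bytes, at + 6L)
      data_at <- at + 8L
    }
  } else {
    vr <- NA_character_
    len <- read_u32(bytes, at + 4L)
    data_at <- at + 8L
  }
  list(group = group, elem = elem, vr = vr, len = len,
       data_at = data_at, next_at = data_at + len)
}

dcm_element_string <- function(bytes, el) {
  if (el$len == 0) return("")
  b <- bytes[el$data_at:(el$data_at + el$len - 1L)]
  trimws(rawToChar(b[b != as.raw(0)]))  # strip padding nulls and spaces
}

# Read a single-frame CT DICOM file into a list (hu matrix + metadata).
dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  at <- 1L
  explicit <- TRUE
  if (length(bytes) > 132L && rawToChar(bytes[129:132]) == "DICM") {
    at <- 133L
    ts <- UID_EXPLICIT_LE
    # file meta group is always explicit VR little endian
    while (at + 7L <= length(bytes)) {
      el <- dcm_parse_element(bytes, at, explicit = TRUE)
      if (el$group != 0x0002) break
      if (el$elem == 0x0010) ts <- dcm_element_string(bytes, el)
      at <- el$next_at
    }
    if (ts == UID_IMPLICIT_LE) {
      explicit <- FALSE
    } else if (ts != UID_EXPLICIT_LE) {
      stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
    }
  } else {
    # raw dataset without preamble: sniff explicit VR from the first element
    vr_guess <- rawToChar(bytes[5:6])
    explicit <- grepl("^[A-Z]{2}$", vr_guess)
  }
  meta <- list(slope = 1, intercept = 0, instance = NA_integer_,
               z = NA_real_, rows = NA_integer_, cols = NA_integer_,
               signed = TRUE, subject = NA_character_,
               spacing = c(NA_real_, NA_real_), thickness = NA_real_)
  pixel <- NULL
  while (at + 7L <= length(bytes)) {
    el <- dcm_parse_element(bytes, at, explicit)
    val <- function() dcm_element_string(bytes, el)
    key <- sprintf("%04X,%04X", el$group, el$elem)
    if (key == "7FE0,0010") {
      pixel <- bytes[el$data_at:(el$data_at + el$len - 1L)]
    } else if (key == "0028,0010") {
      meta$rows <- read_u16(bytes, el$data_at)
    } else if (key == "0028,0011") {
      meta$cols <- read_u16(bytes, el$data_at)
    } else if (key == "0028,0103") {
      meta$signed <- read_u16(bytes, el$data_at) == 1L
    } else if (key == "0028,1052") {
      meta$intercept <- as.numeric(val())
    } else if (key == "0028,1053") {
      meta$slope <- as.numeric(val())
    } else if (key == "0020,0013") {
      meta$instance <- suppressWarnings(as.integer(val()))
    } else if (key == "0020,0032") {
      pos <- as.numeric(strsplit(val(), "\\", fixed = TRUE)[[1]])
      if (length(pos) == 3L) meta$z <- pos[3]
    } else if (key == "0010,0020") {
      meta$subject <- val()
    } else if (key == "0028,0030") {
      meta$spacing <- as.numeric(strsplit(val(), "\\", fixed = TRUE)[[1]])
    } else if (key == "0018,0050") {
      meta$thickness <- as.numeric(val())
    }
    at <- el$next_at
  }
  if (is.null(pixel)) stop("no PixelData in ", path, call. = FALSE)
  if (is.na(meta$rows) || is.na(meta$cols)) {
    stop("missing Rows/Columns in ", path, call. = FALSE)
  }
  stored <- readBin(pixel, "integer", n = meta$rows * meta$cols,
                    size = 2L, signed = meta$signed, endian = "little")
  hu <- meta$slope * stored + meta$intercept
  meta$hu <- matrix(hu, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
  meta
}
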