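## Minimal DICOM codec: explicit-VR little-endian only, the tag set needed for
## CT image series, RT Dose and RT Structure Set fixtures. Files written here
## carry the standard 128-byte preamble, "DICM" magic and a file-meta group,
## and are readable by mainstream DICOM toolkits.

.UID_CT      <- "1.2.840.10008.5.1.4.1.1.2"
.UID_RTDOSE  <- "1.2.840.10008.5.1.4.1.1.481.2"
.UID_RTSTRUCT <- "1.2.840.10008.5.1.4.1.1.481.3"
.UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.UID_ROOT <- "1.2.826.0.1.3680043.9.7435"   # synthetic fixture UID root

.vr32 <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.uint16raw <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")
.uint32raw <- function(v) writeBin(as.integer(v), raw(), size = 4L, endian = "little")

.dcmElement <- function(group, elem, vr, payload) {
  if (length(payload) %% 2L == 1L) {
    pad <- if (vr %in% c("UI", "OB")) as.raw(0L) else charToRaw(" ")
    payload <- c(payload, pad)
  }
  hdr <- c(.uint16raw(group), .uint16raw(elem), charToRaw(vr))
  if (vr %in% .vr32) {
    c(hdr, as.raw(c(0L, 0L)), .uint32raw(length(payload)), payload)
  } else {
    if (length(payload) > 65534L) stop("payload too long for short-form VR ", vr)
    c(hdr, .uint16raw(length(payload)), payload)
  }
}

.dcmStr <- function(group, elem, vr, values) {
  .dcmElement(group, elem, vr, charToRaw(paste(values, collapse = "\\")))
}

.dcmDS <- function(group, elem, values) {
  s <- vapply(values, function(v) formatC(v, format = "g", digits = 10, width = 1),
              character(1))
  .dcmStr(group, elem, "DS", s)
}

.dcmUS <- function(group, elem, values) .dcmElement(group, elem, "US", .uint16raw(values))

.dcmItem <- function(payload) c(.uint16raw(0xFFFE), .uint16raw(0xE000),
                                .uint32raw(length(payload)), payload)

.dcmSQ <- function(group, elem, items) {
  payload <- do.call(c, c(lapply(items, .dcmItem), list(raw(0))))
  .dcmElement(group, elem, "SQ", payload)
}

.dcmUid <- function(...) paste(.UID_ROOT, ..., sep = ".")

## File assembly: preamble + DICM + meta group + dataset
.dcmFile <- function(sopClass, sopInstance, dataset) {
  meta <- c(.dcmStr(0x0002, 0x0002, "UI", sopClass),
            .dcmStr(0x0002, 0x0003, "UI", sopInstance),
            .dcmStr(0x0002, 0x0010, "UI", .UID_EXPLICIT_LE))
  metaLen <- .dcmElement(0x0002, 0x0000, "UL", .uint32raw(length(meta)))
  c(raw(128), charToRaw("DICM"), metaLen, meta, dataset)
}

## ---------------------------------------------------------------------------
## Parser

.dcmParse <- function(bytes, pos, end) {
  out <- list()
  while (pos < end) {
    group <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE,
                     endian = "little")
    elem <- readBin(bytes[pos + 3:4], "integer", size = 2L, signed = FALSE,
                    endian = "little")
    if (group == 0xFFFE) {  # item / delimiter inside an undefined-length region
      len <- readBin(bytes[pos + 5:8], "integer", size = 4L, endian = "little")
      pos <- pos + 8L
      if (elem == 0xE00D || elem == 0xE0DD) next
      stop("unexpected item tag outside sequence parsing")
    }
    vr <- rawToChar(bytes[pos + 5:6])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("not explicit-VR little-endian DICOM (implicit VR unsupported)")
    if (vr %in% .vr32) {
      len <- readBin(bytes[pos + 9:12], "integer", size = 4L, endian = "little")
      pos <- pos + 12L
    } else {
      len <- readBin(bytes[pos + 7:8], "integer", size = 2L, signed = FALSE,
                     endian = "little")
      pos <- pos + 8L
    }
    key <- sprintf("%04x,%04x", group, elem)
    if (vr == "SQ") {
      r <- .dcmParseSQ(bytes, pos, len)
      out[[key]] <- structure(r$items, vr = "SQ")
      pos <- r$pos
    } else {
      if (len == -1L) stop("undefined length only supported for SQ")
      payload <- if (len > 0L) bytes[pos + seq_len(len)] else raw(0)
      out[[key]] <- structure(payload, vr = vr)
      pos <- pos + len
    }
  }
  list(elements = out, pos = pos)
}

.dcmParseSQ <- function(bytes, pos, len) {
  undefined <- len == -1L
  end <- if (undefined) length(bytes) else pos + len
  items <- list()
  while (pos < end) {
    group <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE,
                     endian = "little")
    elem <- readBin(bytes[pos + 3:4], "integer", size = 2L, signed = FALSE,
                    endian = "little")
    ilen <- readBin(bytes[pos + 5:8], "integer", size = 4L, endian = "little")
    pos <- pos + 8L
    if (group == 0xFFFE && elem == 0xE0DD) break        # sequence delimiter
    if (!(group == 0xFFFE && elem == 0xE000))
      stop("malformed sequence: expected item tag")
    if (ilen == -1L) {  # undefined-length item: parse until item delimiter
      r <- .dcmParseUndefItem(bytes, pos)
    } else {
      r <- .dcmParse(bytes, pos, pos + ilen)
    }
    items[[length(items) + 1L]] <- r$elements
    pos <- r$pos
  }
  list(items = items, pos = pos)
}

.dcmParseUndefItem <- function(bytes, pos) {
  out <- list()
  repeat {
    group <- readBin(bytes[pos + 1:2], "integer", size = 2L, signed = FALSE,
                     endian = "little")
    elem <- readBin(bytes[pos + 3:4], "integer", size = 2L, signed = FALSE,
                    endian = "little")
    if (group == 0xFFFE && elem == 0xE00D) { pos <- pos + 8L; break }
    r <- .dcmParse(bytes, pos, pos + 1L)  # parse exactly one element
    out <- c(out, r$elements)
    pos <- r$pos
  }
  list(elements = out, pos = pos)
}

.dcmRead <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 132L || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)
  pos <- 132L
  ## file meta group is always explicit LE; group length bounds it
  meta0 <- .dcmParse(bytes, pos, pos + 12L)
  metaLen <- readBin(meta0$elements[[1]], "integer", size = 4L, endian = "little")
  meta <- .dcmParse(bytes, meta0$pos, meta0$pos + metaLen)
  ts <- .dcmAsString(meta$elements[["0002,0010"]])
  if (!identical(ts, .UID_EXPLICIT_LE))
    stop("unsupported transfer syntax: ", ts, call. = FALSE)
  .dcmParse(bytes, meta$pos, length(bytes))$elements
}

.dcmAsString <- function(el) {
  if (is.null(el)) return(NULL)
  s <- rawToChar(el[el != as.raw(0)])
  sub("\\s+$", "", s)
}
.dcmAsStrings <- function(el) strsplit(.dcmAsString(el), "\\", fixed = TRUE)[[1]]
.dcmAsNumeric <- function(el) as.numeric(.dcmAsStrings(el))
.dcmAsInt <- function(el) as.integer(.dcmAsNumeric(el))
.dcmAsUS <- function(el) readBin(el, "integer", n = length(el) / 2L, size = 2L,
                                 signed = FALSE, endian = "little")

.dcmRequire <- function(ds, key, what, path) {
  el <- ds[[key]]
  if (is.null(el))
    stop(sprintf("missing DICOM tag (%s) %s in %s", key, what, path), call. = FALSE)
  el
}

## ---------------------------------------------------------------------------
## CT series

#' Write a CT volume as a DICOM series (one file per slice)
#'
#' Fixture writer: explicit-VR little-endian, 16-bit signed pixels, rescale
#' slope 1 / intercept -1024. HU values are rounded to integers (CT HU are
#' integer-valued), so a write/read round trip reproduces integer HU exactly.
#'
#' @param ct a [CtVolume-class].
#' @param dir output directory (created if needed).
#' @param seriesUid optional series instance UID.
#' @return character vector of file paths, in slice order, invisibly.
#' @export
writeCtSeries <- function(ct, dir, seriesUid = .dcmUid("1", format(1L))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- geometry(ct)
  d <- geom@dims; sp <- geom@spacing; R <- geom@orientation
  intercept <- -1024
  stored <- round(ct@voxels) - intercept
  studyUid <- .dcmUid("2", "1")
  paths <- character(d[3])
  iop <- c(R[, 1], R[, 2])
  for (k in seq_len(d[3])) {
    ipp <- geom@origin + R %*% c(0, 0, (k - 1) * sp[3])
    sopUid <- .dcmUid("3", format(k))
    px <- as.integer(stored[, , k])  # column (axis 1) fastest = DICOM row order
    dataset <- c(
      .dcmStr(0x0008, 0x0016, "UI", .UID_CT),
      .dcmStr(0x0008, 0x0018, "UI", sopUid),
      .dcmStr(0x0008, 0x0060, "CS", "CT"),
      .dcmStr(0x0020, 0x000D, "UI", studyUid),
      .dcmStr(0x0020, 0x000E, "UI", seriesUid),
      .dcmStr(0x0020, 0x0013, "IS", format(k)),
      .dcmDS(0x0020, 0x0032, as.numeric(ipp)),
      .dcmDS(0x0020, 0x0037, iop),
      .dcmUS(0x0028, 0x0002, 1L),
      .dcmStr(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmUS(0x0028, 0x0010, d[2]),            # Rows
      .dcmUS(0x0028, 0x0011, d[1]),            # Columns
      .dcmDS(0x0028, 0x0030, c(sp[2], sp[1])), # row spacing, column spacing
      .dcmUS(0x0028, 0x0100, 16L), .dcmUS(0x0028, 0x0101, 16L),
      .dcmUS(0x0028, 0x0102, 15L), .dcmUS(0x0028, 0x0103, 1L),
      .dcmDS(0x0028, 0x1052, intercept),
      .dcmDS(0x0028, 0x1053, 1),
      .dcmElement(0x7FE0, 0x0010, "OW",
                  writeBin(px, raw(), size = 2L, endian = "little")))
    paths[k] <- file.path(dir, sprintf("ct_%03d.dcm", k))
    writeBin(.dcmFile(.UID_CT, sopUid, dataset), paths[k])
  }
  invisible(paths)
}

#' Read a DICOM CT series
#'
#' Reads every `.dcm` file in `path` (or the given file vector), sorts slices
#' by position along the slice normal, checks that the series is single and
#' geometrically consistent (uniform slice gap within 1%), and applies the
#' rescale slope/intercept to recover HU.
#'
#' @param path directory containing one CT series, or a character vector of
#'   file paths.
#' @param breathingPhase phase tag for the returned volume.
#' @return a [CtVolume-class].
#' @export
readCtSeries <- function(path, breathingPhase = "free_breathing") {
  files <- if (length(path) == 1L && dir.exists(path))
    list.files(path, pattern = "\\.dcm$", full.names = TRUE) else path
  if (!length(files)) stop("no DICOM files found in ", path, call. = FALSE)
  slices <- lapply(files, .dcmRead)

  seriesUids <- vapply(slices, function(s)
    .dcmAsString(s[["0020,000e"]]) %||% "", character(1))
  if (length(unique(seriesUids)) > 1L)
    stop("mixed series: multiple SeriesInstanceUIDs in ", path, call. = FALSE)

  first <- slices[[1]]
  iop <- .dcmAsNumeric(.dcmRequire(first, "0020,0037", "ImageOrientationPatient", path))
  rowDir <- iop[1:3]; colDir <- iop[4:6]
  normal <- c(rowDir[2] * colDir[3] - rowDir[3] * colDir[2],
              rowDir[3] * colDir[1] - rowDir[1] * colDir[3],
              rowDir[1] * colDir[2] - rowDir[2] * colDir[1])
  for (s in slices) {
    iop2 <- .dcmAsNumeric(.dcmRequire(s, "0020,0037", "ImageOrientationPatient", path))
    if (max(abs(iop2 - iop)) > 1e-6)
      stop("mixed series: inconsistent orientation across slices", call. = FALSE)
  }
  ipp <- t(vapply(slices, function(s)
    .dcmAsNumeric(.dcmRequire(s, "0020,0032", "ImagePositionPatient", path)),
    numeric(3)))
  zpos <- as.numeric(ipp %*% normal)
  ord <- order(zpos)
  slices <- slices[ord]; ipp <- ipp[ord, , drop = FALSE]; zpos <- zpos[ord]

  nz <- length(slices)
  if (nz > 1L) {
    gaps <- diff(zpos)
    if (any(gaps <= 0))
      stop("duplicate slice positions in series", call. = FALSE)
    if ((max(gaps) - min(gaps)) / mean(gaps) > 0.01)
      stop(sprintf("non-uniform slice spacing (gaps %.4g..%.4g mm)",
                   min(gaps), max(gaps)), call. = FALSE)
    dz <- mean(gaps)
  } else dz <- 1

  rows <- .dcmAsUS(.dcmRequire(first, "0028,0010", "Rows", path))
  cols <- .dcmAsUS(.dcmRequire(first, "0028,0011", "Columns", path))
  psp <- .dcmAsNumeric(.dcmRequire(first, "0028,0030", "PixelSpacing", path))
  if (any(psp <= 0)) stop("non-positive pixel spacing", call. = FALSE)
  hu <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    slope <- .dcmAsNumeric(.dcmRequire(s, "0028,1053", "RescaleSlope", path))
    icept <- .dcmAsNumeric(.dcmRequire(s, "0028,1052", "RescaleIntercept", path))
    signed <- .dcmAsUS(.dcmRequire(s, "0028,0103", "PixelRepresentation", path)) == 1L
    px <- .dcmRequire(s, "7fe0,0010", "PixelData", path)
    v <- readBin(px, "integer", n = length(px) / 2L, size = 2L,
                 signed = TRUE, endian = "little")
    if (!signed) v <- ifelse(v < 0, v + 65536, v)
    hu[, , k] <- v * slope + icept
  }
  geom <- volumeGeometry(c(cols, rows, nz), spacing = c(psp[2], psp[1], dz),
                         origin = ipp[1, ], orientation = cbind(rowDir, colDir, normal))
  ctVolume(hu, geom, breathingPhase = breathingPhase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---------------------------------------------------------------------------
## RT Dose

#' Write / read an RT Dose object
#'
#' `writeRtDose()` stores the grid as 32-bit unsigned integers with a dose-grid
#' scaling factor; `readRtDose()` reconstructs Gy as stored value x scaling.
#' Doses quantized to a multiple of `scaling` round-trip exactly.
#'
#' @param dose a [DoseVolume-class].
#' @param path output / input file path.
#' @param scaling dose-grid scaling factor in Gy per stored unit.
#' @return `writeRtDose()` returns `path` invisibly; `readRtDose()` a
#'   [DoseVolume-class].
#' @export
writeRtDose <- function(dose, path, scaling = 1e-3) {
  geom <- geometry(dose)
  d <- geom@dims; sp <- geom@spacing; R <- geom@orientation
  stored <- as.integer(round(dose@voxels / scaling))
  sopUid <- .dcmUid("4", "1")
  dataset <- c(
    .dcmStr(0x0008, 0x0016, "UI", .UID_RTDOSE),
    .dcmStr(0x0008, 0x0018, "UI", sopUid),
    .dcmStr(0x0008, 0x0060, "CS", "RTDOSE"),
    .dcmDS(0x0020, 0x0032, geom@origin),
    .dcmDS(0x0020, 0x0037, c(R[, 1], R[, 2])),
    .dcmStr(0x0028, 0x0008, "IS", format(d[3])),
    .dcmUS(0x0028, 0x0010, d[2]),
    .dcmUS(0x0028, 0x0011, d[1]),
    .dcmDS(0x0028, 0x0030, c(sp[2], sp[1])),
    .dcmUS(0x0028, 0x0100, 32L), .dcmUS(0x0028, 0x0101, 32L),
    .dcmUS(0x0028, 0x0102, 31L), .dcmUS(0x0028, 0x0103, 0L),
    .dcmStr(0x3004, 0x0002, "CS", "GY"),
    .dcmStr(0x3004, 0x000A, "CS", "PLAN"),
    .dcmDS(0x3004, 0x000C, (seq_len(d[3]) - 1) * sp[3]),
    .dcmDS(0x3004, 0x000E, scaling),
    .dcmElement(0x7FE0, 0x0010, "OW",
                writeBin(stored, raw(), size = 4L, endian = "little")))
  writeBin(.dcmFile(.UID_RTDOSE, sopUid, dataset), path)
  invisible(path)
}

#' @rdname writeRtDose
#' @export
readRtDose <- function(path) {
  ds <- .dcmRead(path)
  scaling <- .dcmAsNumeric(.dcmRequire(ds, "3004,000e", "DoseGridScaling", path))
  rows <- .dcmAsUS(.dcmRequire(ds, "0028,0010", "Rows", path))
  cols <- .dcmAsUS(.dcmRequire(ds, "0028,0011", "Columns", path))
  nframes <- .dcmAsInt(.dcmRequire(ds, "0028,0008", "NumberOfFrames", path))
  psp <- .dcmAsNumeric(.dcmRequire(ds, "0028,0030", "PixelSpacing", path))
  offsets <- .dcmAsNumeric(.dcmRequire(ds, "3004,000c", "GridFrameOffsetVector", path))
  ipp <- .dcmAsNumeric(.dcmRequire(ds, "0020,0032", "ImagePositionPatient", path))
  iop <- .dcmAsNumeric(.dcmRequire(ds, "0020,0037", "ImageOrientationPatient", path))
  if (any(psp <= 0)) stop("non-positive pixel spacing in RT Dose", call. = FALSE)
  dz <- if (nframes > 1L) {
    gaps <- diff(offsets)
    if (any(gaps <= 0)) stop("non-increasing grid frame offsets", call. = FALSE)
    mean(gaps)
  } else 1
  px <- .dcmRequire(ds, "7fe0,0010", "PixelData", path)
  v <- readBin(px, "integer", n = length(px) / 4L, size = 4L, endian = "little")
  if (any(v < 0)) stop("stored dose values overflow 31 bits", call. = FALSE)
  rowDir <- iop[1:3]; colDir <- iop[4:6]
  normal <- c(rowDir[2] * colDir[3] - rowDir[3] * colDir[2],
              rowDir[3] * colDir[1] - rowDir[1] * colDir[3],
              rowDir[1] * colDir[2] - rowDir[2] * colDir[1])
  geom <- volumeGeometry(c(cols, rows, nframes),
                         spacing = c(psp[2], psp[1], dz), origin = ipp,
                         orientation = cbind(rowDir, colDir, normal))
  doseVolume(array(v * scaling, dim = geom@dims), geom)
}

## ---------------------------------------------------------------------------
## RT Structure Set

#' Write / read an RT Structure Set
#'
#' Stores each structure's closed planar contours (ContourData triplets in mm)
#' in StructureSetROISequence / ROIContourSequence.
#'
#' @param ss a [StructureSet-class].
#' @param path file path.
#' @return `writeRtStruct()` returns `path` invisibly; `readRtStruct()` a
#'   [StructureSet-class].
#' @export
writeRtStruct <- function(ss, path) {
  validObject(ss)
  nms <- names(ss@structures)
  roiItems <- lapply(seq_along(nms), function(i)
    c(.dcmStr(0x3006, 0x0022, "IS", format(i)),
      .dcmStr(0x3006, 0x0026, "LO", nms[i])))
  contourItems <- lapply(seq_along(nms), function(i) {
    polys <- ss@structures[[i]]
    cs <- lapply(polys, function(p) {
      xyz <- as.numeric(rbind(p$x, p$y, rep(p$z, length(p$x))))
      c(.dcmStr(0x3006, 0x0042, "CS", "CLOSED_PLANAR"),
        .dcmStr(0x3006, 0x0046, "IS", format(length(p$x))),
        .dcmDS(0x3006, 0x0050, xyz))
    })
    c(.dcmSQ(0x3006, 0x0040, cs),
      .dcmStr(0x3006, 0x0084, "IS", format(i)))
  })
  sopUid <- .dcmUid("5", "1")
  dataset <- c(
    .dcmStr(0x0008, 0x0016, "UI", .UID_RTSTRUCT),
    .dcmStr(0x0008, 0x0018, "UI", sopUid),
    .dcmStr(0x0008, 0x0060, "CS", "RTSTRUCT"),
    .dcmSQ(0x3006, 0x0020, roiItems),
    .dcmSQ(0x3006, 0x0039, contourItems))
  writeBin(.dcmFile(.UID_RTSTRUCT, sopUid, dataset), path)
  invisible(path)
}

#' @rdname writeRtStruct
#' @export
readRtStruct <- function(path) {
  ds <- .dcmRead(path)
  roiSeq <- .dcmRequire(ds, "3006,0020", "StructureSetROISequence", path)
  names <- character(); numbers <- integer()
  for (item in roiSeq) {
    numbers <- c(numbers, .dcmAsInt(item[["3006,0022"]]))
    names <- c(names, .dcmAsString(item[["3006,0026"]]))
  }
  contourSeq <- .dcmRequire(ds, "3006,0039", "ROIContourSequence", path)
  structures <- stats::setNames(rep(list(list()), length(names)), names)
  for (item in contourSeq) {
    ref <- .dcmAsInt(item[["3006,0084"]])
    nm <- names[match(ref, numbers)]
    polys <- list()
    for (c_item in item[["3006,0040"]] %||% list()) {
      xyz <- .dcmAsNumeric(c_item[["3006,0050"]])
      m <- matrix(xyz, nrow = 3)
      polys[[length(polys) + 1L]] <-
        list(x = m[1, ], y = m[2, ], z = m[3, 1])
    }
    structures[[nm]] <- polys
  }
  structureSet(structures)
}
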