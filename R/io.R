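#' Read a 3D volume or mask from disk
#'
#' Reads NRRD (the package's canonical intermediate format) or NIfTI-1
#' volumes, preserving grid geometry (spacing and origin in mm). Integer-typed
#' inputs are preserved losslessly. The format is inferred from the file
#' extension when `format = "auto"`.
#'
#' A DICOM series is not supported by this implementation; requesting
#' `format = "dicom"` raises an informative error.
#'
#' @param path path to an existing `.nrrd`, `.nii` or `.nii.gz` file.
#' @param format one of `"auto"`, `"nrrd"`, `"nifti"`, `"dicom"`.
#' @param as_mask if `TRUE`, return a [binary_mask()] (voxels > 0 are true).
#' @return A [voxel_volume()] (or [binary_mask()] when `as_mask = TRUE`).
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = c("auto", "nrrd", "nifti", "dicom"),
                        as_mask = FALSE) {
  format <- match.arg(format)
  if (format == "dicom")
    stop("DICOM series input is not supported by this implementation; ",
         "convert the series to NRRD or NIfTI first", call. = FALSE)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  vol <- switch(format,
    nrrd  = read_nrrd(path),
    nifti = read_nifti_volume(path)
  )
  if (as_mask) binary_mask(vol$data > 0, vol$spacing, vol$origin) else vol
}

#' Write a 3D volume or mask to disk
#'
#' Writes NRRD (gzip-encoded by default) or NIfTI-1 with full geometry
#' headers, so that [read_volume()] recovers an equal object (geometry within
#' 1e-6 mm). Masks are written as 8-bit 0/1 volumes.
#'
#' @param volume a [voxel_volume()] or [binary_mask()].
#' @param path output path; the parent directory must exist.
#' @param format one of `"auto"`, `"nrrd"`, `"nifti"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, format = c("auto", "nrrd", "nifti")) {
  format <- match.arg(format)
  if (!is_cv_volume(volume) && !is_cv_mask(volume))
    stop("`volume` must be a cv_volume or cv_mask", call. = FALSE)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nrrd  = write_nrrd(volume, path),
    nifti = write_nifti_volume(volume, path)
  )
  invisible(path)
}

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  stop("cannot infer volume format from extension of '", basename(path),
       "'; pass `format` explicitly (nrrd or nifti)", call. = FALSE)
}

# ---- NRRD ------------------------------------------------------------------
# Minimal NRRD reader/writer for 3D axis-aligned scalar grids. No installed R
# package handles NRRD, so the subset used by this pipeline (raw/gzip
# encodings, little-endian, diagonal space directions) is implemented here.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "ushort" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "uint" = list(what = "integer", size = 4, signed = FALSE),
  "uint32" = list(what = "integer", size = 4, signed = FALSE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8 || rawToChar(raw_all[1:4]) != "NRRD")
    stop("NRRD format error: missing 'NRRD' magic in ", path, call. = FALSE)
  # header ends at the first blank line (\n\n)
  sep <- which(raw_all[-length(raw_all)] == as.raw(10L) &
               raw_all[-1] == as.raw(10L))
  if (length(sep) == 0)
    stop("NRRD format error: no blank line terminating the header", call. = FALSE)
  hdr_end <- sep[1]
  header <- strsplit(rawToChar(raw_all[seq_len(hdr_end - 1)]), "\n", fixed = TRUE)[[1]]
  header <- header[-1]  # drop magic
  header <- header[!grepl("^#", header) & nzchar(header)]
  kv <- regmatches(header, regexec("^([^:]+):=?\\s*(.*)$", header))
  fields <- stats::setNames(
    vapply(kv, function(m) trimws(m[3]), ""),
    tolower(vapply(kv, function(m) trimws(m[2]), ""))
  )
  need <- function(name) {
    if (is.na(fields[name]) || !nzchar(fields[name]))
      stop("NRRD format error: missing required field '", name, "'", call. = FALSE)
    fields[[name]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("NRRD format error: field 'dimension' must be 3", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  if (length(sizes) != 3L || any(is.na(sizes)) || any(sizes < 1))
    stop("NRRD format error: field 'sizes' is not 3 positive integers", call. = FALSE)
  type <- nrrd_types[[need("type")]]
  if (is.null(type))
    stop("NRRD format error: unsupported field 'type: ", fields[["type"]], "'",
         call. = FALSE)
  encoding <- need("encoding")
  if (!encoding %in% c("raw", "gzip", "gz"))
    stop("NRRD format error: unsupported field 'encoding: ", encoding, "'",
         call. = FALSE)
  endian <- if (!is.na(fields["endian"])) fields[["endian"]] else "little"

  spacing <- NULL
  if (!is.na(fields["space directions"])) {
    vecs <- parse_nrrd_vectors(fields[["space directions"]], "space directions")
    offdiag <- vecs; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-9))
      warning("NRRD 'space directions' is not axis-aligned; ",
              "using per-axis norms as spacing", call. = FALSE)
    spacing <- sqrt(rowSums(vecs^2))
  } else if (!is.na(fields["spacings"])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    spacing <- c(1, 1, 1)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NRRD format error: field 'space directions'/'spacings' yields ",
         "non-positive spacing", call. = FALSE)
  origin <- c(0, 0, 0)
  if (!is.na(fields["space origin"]))
    origin <- parse_nrrd_point(fields[["space origin"]], "space origin")

  payload <- raw_all[(hdr_end + 2):length(raw_all)]
  if (encoding %in% c("gzip", "gz"))
    payload <- memDecompress(payload, type = "gzip")
  n <- prod(sizes)
  if (length(payload) < n * type$size)
    stop("NRRD format error: payload shorter than 'sizes' imply", call. = FALSE)
  values <- readBin(payload, what = type$what, n = n, size = type$size,
                    signed = type$signed, endian = endian)
  voxel_volume(array(values, dim = sizes), spacing, origin)
}

parse_nrrd_vectors <- function(txt, field) {
  m <- regmatches(txt, gregexpr("\\(([^)]*)\\)", txt))[[1]]
  if (length(m) != 3L)
    stop("NRRD format error: field '", field, "' must hold 3 vectors", call. = FALSE)
  t(vapply(m, function(s) {
    as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]])
  }, numeric(3)))
}

parse_nrrd_point <- function(txt, field) {
  v <- as.numeric(strsplit(gsub("[()]", "", txt), ",")[[1]])
  if (length(v) != 3L || any(!is.finite(v)))
    stop("NRRD format error: field '", field, "' is not a 3-vector", call. = FALSE)
  v
}

write_nrrd <- function(volume, path, compress = TRUE) {
  d <- volume$data
  if (is_cv_mask(volume)) {
    type <- "uint8"; size <- 1; what <- as.integer(d)
  } else if (all(d == round(d)) && max(abs(d)) <= .Machine$integer.max) {
    type <- "int"; size <- 4; what <- as.integer(d)
  } else {
    type <- "double"; size <- 8; what <- as.numeric(d)
  }
  sp <- volume$spacing
  header <- c(
    "NRRD0004",
    "# written by condylovol",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(dim(d), collapse = " ")),
    sprintf("space directions: (%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
            sp[1], sp[2], sp[3]),
    "kinds: domain domain domain",
    "endian: little",
    paste0("encoding: ", if (compress) "gzip" else "raw"),
    sprintf("space origin: (%.9g,%.9g,%.9g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    ""
  )
  payload <- writeBin(what, raw(), size = size, endian = "little")
  if (compress) payload <- memCompress(payload, type = "gzip")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(paste(header, collapse = "\n"), "\n")), con)
  writeBin(payload, con)
  invisible(path)
}

# ---- NIfTI (via RNifti) ----------------------------------------------------

read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stop("NIfTI format error: expected a 3D volume, got ", length(d),
         " dimensions (field 'dim')", call. = FALSE)
  xf <- RNifti::xform(im)
  rot <- xf[1:3, 1:3]
  offdiag <- rot; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-6 * max(abs(diag(rot)))))
    warning("NIfTI xform is not axis-aligned; geometry passed through as ",
            "per-axis spacing plus offset", call. = FALSE)
  spacing <- RNifti::pixdim(im)[1:3]
  origin <- as.numeric(xf[1:3, 4])
  voxel_volume(array(as.numeric(im), dim = d), spacing, origin)
}

write_nifti_volume <- function(volume, path) {
  d <- volume$data
  if (is_cv_mask(volume)) storage.mode(d) <- "integer"
  im <- RNifti::asNifti(d)
  RNifti::pixdim(im) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  im <- RNifti::`sform<-`(im, structure(m, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}
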