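# MetaImage (mhd + raw) input/output.
#
# The header is plain "Key = Value" text; DimSize, ElementSpacing and
# Offset are in the format's native (x, y, z) order and are transposed to
# the package-wide (z, y, x) convention at this boundary.  The raw payload
# is x-fastest, which matches an R array of dim (nx, ny, nz); we aperm.

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

#' Read a MetaImage volume
#'
#' Reads an `.mhd` header and its raw payload into a [volume()] (or, on
#' request, a [label_volume()]).  Little- and big-endian payloads and
#' zlib/gzip-compressed raw files (`CompressedData = True`) are handled.
#'
#' @param path path to the `.mhd` header file.
#' @param as_labels interpret an integer-typed file as a label volume.
#' @return A `spine_volume` or `spine_label_volume`.
#' @export
read_mhd <- function(path, as_labels = FALSE) {
  if (!file.exists(path)) stop("MetaImage header not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3L) kv[[m[2]]] <- m[3]
  }
  need <- function(key) {
    if (is.null(kv[[key]])) stop("corrupt MetaImage header (missing ", key, "): ", path)
    kv[[key]]
  }
  ndims <- as.integer(need("NDims"))
  if (ndims != 3L) stop("only 3D MetaImage volumes are supported: ", path)
  dim_xyz <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
  sp_xyz <- if (!is.null(kv[["ElementSpacing"]]))
    as.numeric(strsplit(kv[["ElementSpacing"]], "\\s+")[[1]]) else c(1, 1, 1)
  org_xyz <- if (!is.null(kv[["Offset"]]))
    as.numeric(strsplit(kv[["Offset"]], "\\s+")[[1]])
  else if (!is.null(kv[["Origin"]]))
    as.numeric(strsplit(kv[["Origin"]], "\\s+")[[1]]) else c(0, 0, 0)
  type <- need("ElementType")
  tinfo <- .met_types[[type]]
  if (is.null(tinfo)) stop("unsupported ElementType ", type, " in ", path)
  datafile <- need("ElementDataFile")
  if (identical(datafile, "LOCAL"))
    stop("inline (LOCAL) MetaImage payloads are not supported: ", path)
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path))
    stop("MetaImage raw data file not found: ", raw_path)
  msb <- isTRUE(tolower(kv[["BinaryDataByteOrderMSB"]]) == "true") ||
    isTRUE(tolower(kv[["ElementByteOrderMSB"]]) == "true")
  n <- prod(dim_xyz)
  compressed <- isTRUE(tolower(kv[["CompressedData"]]) == "true")
  if (compressed) {
    payload <- readBin(raw_path, "raw", n = file.size(raw_path))
    payload <- memDecompress(payload, type = "gzip")
    vals <- readBin(payload, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = if (msb) "big" else "little")
  } else {
    vals <- readBin(raw_path, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = if (msb) "big" else "little")
  }
  if (length(vals) < n)
    stop("MetaImage raw data file truncated: ", raw_path)
  arr <- aperm(array(vals, dim = dim_xyz), c(3, 2, 1))  # (x,y,z) -> (z,y,x)
  spacing <- rev(sp_xyz)
  origin <- rev(org_xyz)
  integral <- tinfo$what == "integer"
  if (as_labels) {
    if (!integral) stop("cannot interpret ", type, " data as labels: ", path)
    label_volume(arr, spacing, origin)
  } else {
    volume(arr, spacing, origin)
  }
}

#' Write a MetaImage volume
#'
#' Writes `path` (`.mhd` header) plus a sibling raw payload.  Label
#' volumes default to `MET_USHORT`, scalar volumes to `MET_FLOAT`; pass
#' `element_type = "MET_SHORT"` for CT in Hounsfield units or
#' `"MET_DOUBLE"` for lossless round trips of non-integer data.
#'
#' @param v a `spine_volume` or `spine_label_volume`.
#' @param path output header path (`.mhd`).
#' @param element_type MetaImage element type; see Details.
#' @param compress write a zlib/gzip-compressed payload
#'   (`CompressedData = True`).
#' @return `path`, invisibly.
#' @export
write_mhd <- function(v, path, element_type = NULL, compress = FALSE) {
  stopifnot(inherits(v, "spine_volume"))
  if (is.null(element_type))
    element_type <- if (is_label_volume(v)) "MET_USHORT" else "MET_FLOAT"
  tinfo <- .met_types[[element_type]]
  if (is.null(tinfo)) stop("unsupported ElementType ", element_type)
  d <- dim(v$data)
  raw_name <- paste0(sub("\\.mhd$", "", basename(path)),
                     if (compress) ".zraw" else ".raw")
  vals <- as.vector(aperm(v$data, c(3, 2, 1)))  # back to x-fastest
  if (tinfo$what == "integer") {
    vals <- as.integer(round(vals))
  } else {
    vals <- as.numeric(vals)
  }
  payload <- writeBin(vals, raw(), size = tinfo$size, endian = "little")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    paste("CompressedData =", if (compress) "True" else "False"),
    paste("Offset =", paste(format(rev(v$origin), trim = TRUE), collapse = " ")),
    paste("ElementSpacing =", paste(format(rev(v$spacing), trim = TRUE), collapse = " ")),
    paste("DimSize =", paste(rev(d), collapse = " ")),
    paste("ElementType =", element_type),
    paste("ElementDataFile =", raw_name)
  )
  if (compress) payload <- memCompress(payload, type = "gzip")
  writeLines(header, path)
  writeBin(payload, file.path(dirname(path), raw_name))
  invisible(path)
}
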