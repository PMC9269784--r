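# Minimal NRRD0004 support for 3D scalar volumes. Covers what ROI-mask
# exchange needs: raw and text encodings, the common scalar types, and
# spacing via either `spacings` or diagonal `space directions`. Written
# in-package because no installed R package reads NRRD.

nrrd_types <- list(
  "signed char" = list(what = "integer", size = 1, signed = TRUE),
  "int8" = list(what = "integer", size = 1, signed = TRUE),
  "uchar" = list(what = "integer", size = 1, signed = FALSE),
  "unsigned char" = list(what = "integer", size = 1, signed = FALSE),
  "uint8" = list(what = "integer", size = 1, signed = FALSE),
  "short" = list(what = "integer", size = 2, signed = TRUE),
  "int16" = list(what = "integer", size = 2, signed = TRUE),
  "unsigned short" = list(what = "integer", size = 2, signed = FALSE),
  "uint16" = list(what = "integer", size = 2, signed = FALSE),
  "int" = list(what = "integer", size = 4, signed = TRUE),
  "int32" = list(what = "integer", size = 4, signed = TRUE),
  "float" = list(what = "double", size = 4, signed = TRUE),
  "double" = list(what = "double", size = 8, signed = TRUE)
)

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[0-9]$", magic))
    stop("not an NRRD file (bad magic line): ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "[[:space:]]+")[[1]])
  ndim <- as.integer(fields[["dimension"]])
  if (length(dims) != ndim) stop("inconsistent NRRD sizes/dimension in ", path)
  type <- nrrd_types[[tolower(fields[["type"]])]]
  if (is.null(type)) stop("unsupported NRRD type: ", fields[["type"]])
  encoding <- tolower(fields[["encoding"]])
  n <- prod(dims)
  if (encoding == "raw") {
    endian <- if (identical(fields[["endian"]], "big")) "big" else "little"
    data <- readBin(con, what = type$what, n = n, size = type$size,
                    signed = if (type$size >= 4) TRUE else type$signed,
                    endian = endian)
  } else if (encoding %in% c("text", "txt", "ascii")) {
    data <- scan(con, what = double(), n = n, quiet = TRUE)
  } else {
    stop("unsupported NRRD encoding: ", encoding)
  }
  if (length(data) != n) stop("truncated NRRD data in ", path)
  spacing <- NULL
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "[[:space:]]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    spacing <- sqrt(colSums(mat^2))  # row-major direction vectors -> norms
  }
  list(data = array(data, dim = dims), spacing = spacing)
}

write_nrrd <- function(grid, path, spacing, encoding = c("raw", "text")) {
  encoding <- match.arg(encoding)
  dims <- dim(grid)
  header <- c(
    "NRRD0004",
    "# binary ROI mask",
    "type: int",
    sprintf("dimension: %d", length(dims)),
    sprintf("sizes: %s", paste(dims, collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, digits = 17), collapse = " ")),
    sprintf("encoding: %s", encoding),
    if (encoding == "raw") "endian: little",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (encoding == "raw") {
    writeBin(as.integer(grid), con, size = 4, endian = "little")
  } else {
    writeLines(paste(as.integer(grid), collapse = " "), con)
  }
  invisible(path)
}
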