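## Minimal ENVI dialect: ASCII header + raw binary payload.
## Supported: interleaves bil/bip/bsq, data types 4 (float32) and
## 12 (uint16), byte order 0 (little endian), header offset 0.

ENVI_TYPE_FLOAT32 <- 4L
ENVI_TYPE_UINT16 <- 12L

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1L]))
    stop("not an ENVI header (missing 'ENVI' magic): ", header_path)
  body <- paste(txt[-1L], collapse = "\n")
  fields <- list()
  # join {...} blocks (may span lines), then split on newlines outside braces
  pos <- 1L
  lines <- character()
  chars <- strsplit(body, "")[[1L]]
  depth <- 0L; buf <- character()
  for (ch in chars) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) {
      lines <- c(lines, paste(buf, collapse = "")); buf <- character()
    } else buf <- c(buf, ch)
  }
  lines <- c(lines, paste(buf, collapse = ""))
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    fields[[key]] <- val
  }
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(fields))
  if (length(miss))
    stop("ENVI header missing required field(s): ", paste(miss, collapse = ", "))
  parse_num_list <- function(v) {
    v <- gsub("[{}]", "", v)
    as.numeric(trimws(strsplit(v, ",")[[1L]]))
  }
  if (is.null(fields[["wavelength"]]))
    stop("ENVI header has no wavelength list; cannot build a spectral cube")
  list(samples = as.integer(fields$samples),
       lines = as.integer(fields$lines),
       bands = as.integer(fields$bands),
       interleave = tolower(fields$interleave),
       data_type = as.integer(fields[["data type"]]),
       byte_order = if (is.null(fields[["byte order"]])) 0L
                    else as.integer(fields[["byte order"]]),
       wavelength = parse_num_list(fields$wavelength),
       wavelength_units = fields[["wavelength units"]])
}

#' Read a hyperspectral cube from an ENVI image/header pair
#'
#' Reads band-interleaved ENVI files (interleaves `bil`, `bip`, `bsq`;
#' data types float32 and uint16, little endian) into a
#' [spectral_cube()] in `rows x cols x bands` order, independent of the
#' on-disk interleave. Wavelengths (assumed nm unless the header states
#' another unit) are taken from the header's `wavelength` list.
#'
#' @param image_path path to the binary image file.
#' @param header_path path to the ASCII header; default
#'   `paste0(image_path, ".hdr")`.
#' @return a [spectral_cube()].
#' @export
read_envi_cube <- function(image_path, header_path = paste0(image_path, ".hdr")) {
  h <- parse_envi_header(header_path)
  if (length(h$wavelength) != h$bands)
    stop("corrupt ENVI pair: header declares ", h$bands, " bands but ",
         length(h$wavelength), " wavelengths")
  if (!h$interleave %in% c("bil", "bip", "bsq"))
    stop("unsupported interleave: ", h$interleave)
  n <- h$samples * h$lines * h$bands
  endian <- if (h$byte_order == 0L) "little" else "big"
  con <- file(image_path, "rb"); on.exit(close(con))
  raw_vals <- switch(as.character(h$data_type),
    "4" = readBin(con, what = numeric(), n = n + 1L, size = 4L, endian = endian),
    "12" = readBin(con, what = integer(), n = n + 1L, size = 2L, signed = FALSE,
                   endian = endian),
    stop("unsupported ENVI data type: ", h$data_type))
  if (length(raw_vals) != n)
    stop("corrupt ENVI pair: payload holds ", length(raw_vals),
         " values but header implies ", n)
  a <- switch(h$interleave,
    # on-disk fastest-to-slowest axes:
    bsq = aperm(array(raw_vals, c(h$samples, h$lines, h$bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw_vals, c(h$samples, h$bands, h$lines)), c(3L, 1L, 2L)),
    bip = aperm(array(raw_vals, c(h$bands, h$samples, h$lines)), c(3L, 2L, 1L)))
  spectral_cube(a, h$wavelength,
                meta = list(source = image_path, interleave = h$interleave,
                            data_type = h$data_type,
                            wavelength_units = h$wavelength_units))
}

#' Write a hyperspectral cube as an ENVI image/header pair
#'
#' Lossless for the chosen numeric type: float32 payloads round-trip
#' bit-exactly, uint16 requires integral values in \[0, 65535\].
#'
#' @param cube a valid [spectral_cube()] (all values finite).
#' @param image_path output binary path.
#' @param header_path output header path; default `image_path + ".hdr"`.
#' @param interleave one of "bsq", "bil", "bip".
#' @param data_type 4 (float32, default) or 12 (uint16).
#' @return invisibly, `image_path`.
#' @export
write_envi_cube <- function(cube, image_path,
                            header_path = paste0(image_path, ".hdr"),
                            interleave = c("bsq", "bil", "bip"),
                            data_type = ENVI_TYPE_FLOAT32) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  stopifnot_finite_cube(cube, "cube to write")
  d <- dim(cube$values)
  a <- switch(interleave,
    bsq = aperm(cube$values, c(2L, 1L, 3L)),
    bil = aperm(cube$values, c(2L, 3L, 1L)),
    bip = aperm(cube$values, c(3L, 2L, 1L)))
  vals <- as.vector(a)
  con <- file(image_path, "wb")
  if (data_type == ENVI_TYPE_FLOAT32) {
    writeBin(as.numeric(vals), con, size = 4L, endian = "little")
  } else if (data_type == ENVI_TYPE_UINT16) {
    if (any(vals < 0 | vals > 65535 | vals != round(vals))) {
      close(con)
      stop("uint16 payload requires integral values in [0, 65535]")
    }
    writeBin(as.integer(vals), con, size = 2L, endian = "little")
  } else {
    close(con)
    stop("unsupported ENVI data type: ", data_type)
  }
  close(con)
  hdr <- c("ENVI",
           "description = { xhclust spectral cube }",
           paste0("samples = ", d[2L]),
           paste0("lines = ", d[1L]),
           paste0("bands = ", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           paste0("interleave = ", interleave),
           "byte order = 0",
           "wavelength units = Nanometers",
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE, digits = 15),
                        collapse = ", "), " }"))
  writeLines(hdr, header_path)
  invisible(image_path)
}

#' Write a label image (cluster map) as a single-band ENVI pair
#'
#' Unlabelled pixels are written as 0, cluster ids as 1..k (uint16).
#'
#' @param map a `cluster_map`.
#' @param image_path,header_path output paths.
#' @return invisibly, `image_path`.
#' @export
write_label_map <- function(map, image_path,
                            header_path = paste0(image_path, ".hdr")) {
  stopifnot(inherits(map, "cluster_map"))
  lab <- map$labels
  lab[is.na(lab)] <- 0L
  cube <- spectral_cube(array(lab, c(dim(lab), 1L)), wavelengths = 0,
                        meta = list(kind = "label_map", k = map$k))
  write_envi_cube(cube, image_path, header_path, interleave = "bsq",
                  data_type = ENVI_TYPE_UINT16)
}

#' Read a single-band label image written by [write_label_map()]
#'
#' @param image_path,header_path input paths.
#' @param k number of clusters to record (default: max label found).
#' @return a `cluster_map` (0 pixels become `NA`/unlabelled).
#' @export
read_label_map <- function(image_path, header_path = paste0(image_path, ".hdr"),
                           k = NULL) {
  cube <- read_envi_cube(image_path, header_path)
  lab <- cube$values[, , 1L]
  lab[lab == 0] <- NA
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  if (is.null(k)) k <- max(lab, na.rm = TRUE)
  structure(list(labels = lab, k = as.integer(k), image = image_path),
            class = "cluster_map")
}
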