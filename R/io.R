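#' Write an imaging area as an ENVI cube
#'
#' Band-sequential (BSQ) layout, 64-bit floating point (data type 5),
#' little endian, with the band wavelengths recorded in the `.hdr` header.
#' Per-row metadata (sample/area/class/tissue and the set's mode) goes to
#' a JSON sidecar `<prefix>.json`. Pixels are stored row-major: row i of
#' the set is line `(i-1) %/% samples + 1`, column `(i-1) %% samples + 1`.
#'
#' @param set A `spectrum_set` whose row count is `lines * samples`.
#' @param prefix Path prefix; writes `<prefix>.dat`, `<prefix>.hdr`,
#'   `<prefix>.json`.
#' @param lines,samples Spatial dimensions (default square).
#' @return `prefix`, invisibly.
#' @export
write_envi_cube <- function(set, prefix, lines = NULL, samples = NULL) {
  n <- n_spectra(set)
  if (is.null(lines)) lines <- as.integer(round(sqrt(n)))
  if (is.null(samples)) samples <- as.integer(ceiling(n / lines))
  if (lines * samples != n) stop("lines * samples must equal row count", call. = FALSE)
  nb <- length(set$wavenumbers)
  hdr <- c(
    "ENVI",
    "description = {synthetic FTIR imaging area}",
    paste0("samples = ", samples),
    paste0("lines = ", lines),
    paste0("bands = ", nb),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    "wavelength units = cm-1",
    paste0("wavelength = {", paste(format(set$wavenumbers, digits = 17,
                                          trim = TRUE, scientific = FALSE),
                                   collapse = ", "), "}"))
  writeLines(hdr, paste0(prefix, ".hdr"))
  con <- file(paste0(prefix, ".dat"), "wb")
  on.exit(close(con))
  # BSQ: all pixels of band 1, then band 2, ... = column-major over x
  writeBin(as.vector(set$x), con, size = 8, endian = "little")
  jsonlite::write_json(list(mode = set$mode, meta = set$meta),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

parse_envi_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(txt, regexpr(paste0("(?mi)^", name,
                                        "\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"),
                                 txt, perl = TRUE))
    if (!length(m)) return(NULL)
    v <- sub(paste0("(?i)^", name, "\\s*=\\s*"), "", m, perl = TRUE)
    gsub("[{}]", "", v)
  }
  num <- function(name) {
    v <- get_field(name)
    if (is.null(v)) NULL else as.numeric(trimws(v))
  }
  list(samples = num("samples"), lines = num("lines"), bands = num("bands"),
       data_type = num("data type"), interleave = trimws(get_field("interleave")),
       byte_order = num("byte order"),
       wavelength = if (is.null(get_field("wavelength"))) NULL else
         as.numeric(trimws(strsplit(get_field("wavelength"), ",")[[1]])))
}

#' Read an ENVI cube into a spectrum set
#'
#' Accepts BSQ interleave with data type 4 (float32) or 5 (float64). The
#' header must declare band wavelengths; a non-square pixel grid is
#' accepted with a warning. If a `<prefix>.json` sidecar exists its
#' metadata and mode are restored; otherwise rows get pixel indices as
#' area ids and mode defaults to `"transmission"`.
#'
#' @param prefix Path prefix (as in [write_envi_cube()]) or a `.hdr` path.
#' @return A `spectrum_set` with one row per pixel.
#' @export
read_envi_cube <- function(prefix) {
  prefix <- sub("\\.(hdr|dat)$", "", prefix)
  h <- parse_envi_header(paste0(prefix, ".hdr"))
  if (is.null(h$wavelength)) {
    stop("ENVI header has no wavelength field: ", prefix, ".hdr", call. = FALSE)
  }
  if (length(h$wavelength) != h$bands) {
    stop("wavelength count does not match bands in ", prefix, ".hdr", call. = FALSE)
  }
  if (!identical(tolower(h$interleave), "bsq")) {
    stop("only BSQ interleave is supported (got ", h$interleave, ")", call. = FALSE)
  }
  if (h$samples != h$lines) warning("non-square pixel grid (", h$lines, " x ",
                                    h$samples, "), accepted")
  n <- h$samples * h$lines
  size <- if (h$data_type == 5) 8L else if (h$data_type == 4) 4L else
    stop("unsupported ENVI data type ", h$data_type, call. = FALSE)
  con <- file(paste0(prefix, ".dat"), "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n * h$bands, size = size,
                  endian = if (h$byte_order %in% 1) "big" else "little")
  x <- matrix(vals, nrow = n, ncol = h$bands)  # BSQ: band-major columns
  meta <- NULL; mode <- "transmission"
  side <- paste0(prefix, ".json")
  if (file.exists(side)) {
    j <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta <- as.data.frame(j$meta, stringsAsFactors = FALSE)
    mode <- j$mode
  }
  spectrum_set(h$wavelength, x, meta, mode)
}

#' Write spectra as CSV
#'
#' Metadata columns first (`sample_id`, `area_id`, `class`, `role`,
#'  `tissue`, `mode`), then one column per wavenumber whose header is the
#' wavenumber itself. Full double precision; round trips are lossless to
#' well below 1e-12 relative tolerance.
#'
#' @param set A `spectrum_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csv_spectra <- function(set, path) {
  xs <- as.data.frame(lapply(as.data.frame(set$x), function(col)
    format(col, digits = 17, trim = TRUE, scientific = FALSE)),
    check.names = FALSE, stringsAsFactors = FALSE)
  names(xs) <- format(set$wavenumbers, digits = 17, trim = TRUE,
                      scientific = FALSE)
  df <- cbind(set$meta[c("sample_id", "area_id", "class", "role", "tissue")],
              mode = set$mode, xs)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from CSV written by [write_csv_spectra()]
#'
#' @param path CSV file: first columns metadata, remaining column headers
#'   are wavenumbers.
#' @return A `spectrum_set`.
#' @export
read_csv_spectra <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing CSV file: ", path, call. = FALSE)
  }
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged CSV: row ", bad, " has ", nf[bad], " fields, expected ",
         nf[1], call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("CSV contains no spectra: ", path, call. = FALSE)
  meta_cols <- c("sample_id", "area_id", "class", "role", "tissue", "mode")
  wn_cols <- setdiff(names(df), meta_cols)
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wn))) stop("non-numeric wavenumber column headers", call. = FALSE)
  x <- as.matrix(df[wn_cols])
  meta <- df[intersect(meta_cols[meta_cols != "mode"], names(df))]
  mode <- if ("mode" %in% names(df)) df$mode[1] else "absorbance"
  spectrum_set(wn, x, meta, mode)
}
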