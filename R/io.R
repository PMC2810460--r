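# Image and annotation I/O. PGM (P2/P5) is parsed directly -- the mini-MIAS
# distribution format; PNG goes through the png package. All intensities are
# carried in [0, 255] regardless of the on-disk bit depth.

.pgmTokens <- function(raw, n = 4L) {
  # return the first n header tokens and the byte offset just past the last
  toks <- character(0); i <- 1L; nb <- length(raw)
  while (length(toks) < n && i <= nb) {
    b <- raw[i]
    if (b == charToRaw("#")) {                       # comment to end of line
      while (i <= nb && raw[i] != as.raw(10L)) i <- i + 1L
      i <- i + 1L
    } else if (b %in% as.raw(c(9L, 10L, 13L, 32L))) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= nb && !(raw[j] %in% as.raw(c(9L, 10L, 13L, 32L, 35L))))
        j <- j + 1L
      toks <- c(toks, rawToChar(raw[i:(j - 1L)]))
      i <- j
    }
  }
  if (length(toks) < n) stop("truncated PGM header")
  list(tokens = toks, offset = i)
}

.readPgm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P5")) stop("not a P2/P5 PGM file: ", path)
  hd <- .pgmTokens(raw, 4L)
  w <- as.integer(hd$tokens[2]); h <- as.integer(hd$tokens[3])
  maxval <- as.integer(hd$tokens[4])
  if (is.na(w) || is.na(h) || is.na(maxval) || w < 1L || h < 1L || maxval < 1L)
    stop("malformed PGM header in ", path)
  if (magic == "P2") {
    vals <- scan(text = rawToChar(raw[hd$offset:length(raw)]),
                 what = integer(), quiet = TRUE)
  } else {
    i <- hd$offset + 1L                              # single whitespace after maxval
    if (maxval > 255L) {
      vals <- readBin(raw[i:length(raw)], "integer", n = w * h, size = 2L,
                      signed = FALSE, endian = "big")
    } else {
      vals <- as.integer(raw[i:(i + w * h - 1L)])
    }
  }
  if (length(vals) < w * h) stop("PGM pixel data truncated in ", path)
  m <- matrix(as.numeric(vals[seq_len(w * h)]), nrow = h, byrow = TRUE)
  if (maxval != 255L) m <- m * (255 / maxval)
  m
}

#' Read a grayscale image (PGM or PNG)
#'
#' Reads P2/P5 PGM or grayscale PNG into a \linkS4class{GrayImage} with
#' values in \[0, 255\]. Inputs with higher bit depth (e.g. 16-bit PGM) are
#' linearly rescaled so that maxval maps to 255. Color PNGs are accepted only
#' when all channels are identical.
#'
#' @param path file path.
#' @param pixelPitchUm microns per pixel to attach (default 200).
#' @return A \linkS4class{GrayImage}.
#' @seealso \code{\link{writeGray}}
#' @export
readGray <- function(path, pixelPitchUm = 200) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  magic <- readBin(path, "raw", 8L)
  if (length(magic) >= 2 && rawToChar(magic[1:2]) %in% c("P2", "P5")) {
    m <- .readPgm(path)
  } else if (length(magic) >= 8 &&
             identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a,
                                       0x1a, 0x0a)))) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      nc <- dim(a)[3]
      rgb <- a[, , seq_len(min(3L, nc)), drop = FALSE]
      if (dim(rgb)[3] > 1L) {
        spread <- max(abs(sweep(rgb, c(1, 2), rgb[, , 1])))
        if (spread > 1e-9)
          stop("color PNG without a single-channel representation: ", path)
      }
      a <- rgb[, , 1]
    }
    m <- a * 255
  } else {
    stop("unsupported image format (expected PGM or PNG): ", path)
  }
  GrayImage(m, pixelPitchUm = pixelPitchUm)
}

#' Write a grayscale image (PGM or PNG)
#'
#' Values are clipped to \[0, 255\] and rounded to integers; the written file
#' round-trips bit-exactly through \code{\link{readGray}} for 8-bit content.
#' Format is chosen from the file extension (.pgm or .png); PGM is written as
#' binary P5 unless \code{ascii = TRUE} (P2).
#'
#' @param image a \linkS4class{GrayImage} (or numeric matrix).
#' @param path output path ending in .pgm or .png.
#' @param ascii write ASCII P2 instead of binary P5 (PGM only).
#' @return Invisibly, \code{path}.
#' @export
writeGray <- function(image, path, ascii = FALSE) {
  m <- if (is(image, "GrayImage")) pixels(image) else image
  if (!all(is.finite(m))) stop("cannot write non-finite pixel values")
  v <- round(pmin(pmax(m, 0), 255))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(v / 255, path)
  } else if (ext == "pgm") {
    if (ascii) {
      con <- file(path, "wb")
      on.exit(close(con))
      writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
      writeLines(apply(v, 1, paste, collapse = " "), con)
    } else {
      con <- file(path, "wb")
      on.exit(close(con))
      writeChar(paste0("P5\n", ncol(v), " ", nrow(v), "\n255\n"), con,
                eos = NULL)
      writeBin(as.raw(as.integer(t(v))), con)
    }
  } else {
    stop("unsupported output extension '", ext, "' (use .pgm or .png)")
  }
  invisible(path)
}

.miasTissue <- c(F = "fatty", G = "fatty-glandular", D = "dense-glandular")

#' Parse MIAS-style annotation records
#'
#' Records are whitespace-separated lines: reference id, tissue code
#' (F/G/D), abnormality class (e.g. CALC, NORM), and for abnormal cases a
#' severity code (B/M) plus x, y, approximate radius in pixels. MIAS
#' measures x from the left and y from the *bottom* edge; coordinates are
#' converted here to this package's top-left 1-based (row, col) convention
#' via \code{center_row = image_height - y}.
#'
#' @param text annotation text (one record per line) or a file path.
#' @param imageHeight image height in pixels (1024 for mini-MIAS).
#' @return data.frame with columns ref_id, tissue, abnormality, severity,
#'   center_row, center_col, radius_px (location columns are NA for records
#'   without a locus, e.g. normals).
#' @examples
#' parseMiasAnnotations("mdb001 G CALC B 500 500 10", imageHeight = 1024)
#' @export
parseMiasAnnotations <- function(text, imageHeight) {
  if (length(text) == 1L && !grepl("[\n ]", text) && file.exists(text))
    text <- readLines(text)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    tk <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (!length(tk) %in% c(3L, 7L))
      stop("malformed annotation on line ", i, ": expected 3 or 7 fields, got ",
           length(tk))
    tissue <- .miasTissue[tk[2]]
    if (is.na(tissue)) stop("unknown tissue code '", tk[2], "' on line ", i)
    if (length(tk) == 3L) {
      data.frame(ref_id = tk[1], tissue = tissue, abnormality = tk[3],
                 severity = "none", center_row = NA_real_,
                 center_col = NA_real_, radius_px = NA_real_)
    } else {
      sev <- switch(tk[4], B = "benign", M = "malignant",
                    stop("unknown severity code '", tk[4], "' on line ", i))
      x <- as.numeric(tk[5]); y <- as.numeric(tk[6]); r <- as.numeric(tk[7])
      if (anyNA(c(x, y, r))) stop("non-numeric location on line ", i)
      if (r < 0) stop("negative radius on line ", i)
      cr <- imageHeight - y
      if (cr < 1 || cr > imageHeight || x + 1 < 1)
        stop("location outside image on line ", i)
      data.frame(ref_id = tk[1], tissue = tissue, abnormality = tk[3],
                 severity = sev, center_row = cr, center_col = x + 1,
                 radius_px = r)
    }
  })
  do.call(rbind, out)
}

#' Write annotations in MIAS record format
#'
#' Inverse of \code{\link{parseMiasAnnotations}}; used by the phantom
#' generator so that phantoms and real mammograms share one loader.
#'
#' @param ann annotation data.frame (as from \code{parseMiasAnnotations}).
#' @param imageHeight image height in pixels.
#' @param path optional output file; when NULL the lines are returned.
#' @return Character vector of record lines (invisibly when written).
#' @export
writeMiasAnnotations <- function(ann, imageHeight, path = NULL) {
  code <- function(t) names(.miasTissue)[match(t, .miasTissue)]
  lines <- vapply(seq_len(nrow(ann)), function(i) {
    a <- ann[i, ]
    if (is.na(a$center_row)) {
      paste(a$ref_id, code(a$tissue), a$abnormality)
    } else {
      paste(a$ref_id, code(a$tissue), a$abnormality,
            switch(a$severity, benign = "B", malignant = "M", "B"),
            round(a$center_col - 1), round(imageHeight - a$center_row),
            round(a$radius_px))
    }
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
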