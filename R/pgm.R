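#' Read and write portable graymap / pixmap images
#'
#' Minimal PGM (grayscale) and PPM (RGB) codecs covering the binary (P5/P6)
#' and ASCII (P2/P3) variants at 8-bit depth. Used for cohort image files
#' and rendered overlays; no external imaging library is required.
#'
#' @param px integer matrix of intensities in \[0, 255\] (rows = image rows).
#' @param path file destination.
#' @param ascii write the ASCII (P2) variant instead of binary (P5).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(px, path, ascii = FALSE) {
  px <- round(pmin(pmax(px, 0), 255))
  h <- nrow(px); w <- ncol(px)
  vals <- as.integer(t(px))  # raster order: rows top-to-bottom
  if (ascii) {
    con <- file(path, "w")
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(paste(vals, collapse = " "), con)
    close(con)
  } else {
    con <- file(path, "wb")
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
    close(con)
  }
  invisible(path)
}

#' @rdname write_pgm
#' @return for `read_pgm`, an integer matrix.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- read_token(con)
  if (!magic %in% c("P2", "P5")) {
    rit_stop("ritmap_data_error", "not a PGM file: magic '%s'", magic)
  }
  w <- as.integer(read_token(con)); h <- as.integer(read_token(con))
  maxval <- as.integer(read_token(con))
  if (is.na(w) || is.na(h) || maxval > 255) {
    rit_stop("ritmap_data_error", "unsupported PGM header in %s", path)
  }
  vals <- if (magic == "P5") {
    as.integer(readBin(con, "raw", n = w * h))
  } else {
    scan(con, what = integer(), n = w * h, quiet = TRUE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

# next whitespace-delimited token, skipping '#' comments
read_token <- function(con) {
  tok <- character(0)
  repeat {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) break
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(tok)) break else next
    }
    tok <- c(tok, ch)
  }
  paste(tok, collapse = "")
}

#' @rdname write_pgm
#' @param rgb numeric array `H x W x 3` with values in \[0, 1\].
#' @export
write_ppm <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  vals <- round(pmin(pmax(rgb, 0), 1) * 255)
  # interleave channels in raster order
  inter <- integer(h * w * 3)
  for (ch in 1:3) inter[seq(ch, by = 3, length.out = h * w)] <-
    as.integer(t(vals[, , ch]))
  con <- file(path, "wb")
  writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
  writeBin(as.raw(inter), con)
  close(con)
  invisible(path)
}
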