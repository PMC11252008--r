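## Minimal baseline TIFF 6.0 codec (little-endian, uncompressed, one sample
## per pixel, multi-page; z = page order). No TIFF-reading package exists in
## this stack, so the few features the pipeline needs are implemented here:
## uint/int/float samples, strip reading, and ImageJ-style spacing metadata
## (X/YResolution in pixels-per-cm plus a "spacing=<um>" description line for
## the axial step).

.tiff_write <- function(arr, path, voxelNm = c(50, 50, 50)) {
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (is.logical(arr)) arr <- array(as.integer(arr), d)
  is_int <- is.integer(arr)
  bytes_px <- 4L
  fmt <- if (is_int) 2L else 3L  # SampleFormat: 2 = signed int, 3 = float
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  ## ImageJ-style description (axial spacing in um)
  desc <- sprintf("ImageJ=1.53\nimages=%d\nslices=%d\nunit=micron\nspacing=%.6f\n",
                  nz, nz, voxelNm[1] / 1000)
  desc_raw <- c(charToRaw(desc), as.raw(0))
  if (length(desc_raw) %% 2) desc_raw <- c(desc_raw, as.raw(0))
  ## offsets: header(8) | desc | xres(8) | yres(8) | page data | IFDs
  off_desc <- 8L
  off_xres <- off_desc + length(desc_raw)
  off_yres <- off_xres + 8L
  off_data <- off_yres + 8L
  page_bytes <- nx * ny * bytes_px
  off_pages <- off_data + (seq_len(nz) - 1L) * page_bytes
  n_tags <- 13L
  ifd_bytes <- 2L + n_tags * 12L + 4L
  off_ifd <- off_data + nz * page_bytes + (seq_len(nz) - 1L) * ifd_bytes
  ## header
  writeBin(charToRaw("II"), con)
  w2(42L); w4(off_ifd[1])
  writeBin(desc_raw, con)
  ## resolutions: pixels per cm as RATIONAL (1e7 / voxel_nm)
  rat <- function(nm) { w4(round(1e9)); w4(round(nm * 100)) }  # 1e9/(nm*100) px/cm
  rat(voxelNm[3]); rat(voxelNm[2])
  ## pixel data, page-major, row-major within page
  for (z in seq_len(nz)) {
    page <- t(arr[z, , ])           # -> nx x ny, columns = rows of the image
    if (is_int) writeBin(as.integer(page), con, size = 4, endian = "little")
    else writeBin(as.numeric(page), con, size = 4, endian = "little")
  }
  ## IFDs
  tag <- function(id, type, count, value, raw4 = NULL) {
    w2(id); w2(type); w4(count)
    if (!is.null(raw4)) { writeBin(raw4, con) }
    else if (type == 3L && count == 1L) { w2(value); w2(0L) }
    else w4(value)
  }
  for (z in seq_len(nz)) {
    w2(n_tags)
    tag(256L, 4L, 1L, nx)                 # ImageWidth
    tag(257L, 4L, 1L, ny)                 # ImageLength
    tag(258L, 3L, 1L, 8L * bytes_px)      # BitsPerSample
    tag(259L, 3L, 1L, 1L)                 # Compression: none
    tag(262L, 3L, 1L, 1L)                 # Photometric: BlackIsZero
    tag(270L, 2L, length(desc_raw), off_desc)  # ImageDescription
    tag(273L, 4L, 1L, off_pages[z])       # StripOffsets
    tag(277L, 3L, 1L, 1L)                 # SamplesPerPixel
    tag(278L, 4L, 1L, ny)                 # RowsPerStrip
    tag(279L, 4L, 1L, page_bytes)         # StripByteCounts
    tag(282L, 5L, 1L, off_xres)           # XResolution
    tag(283L, 5L, 1L, off_yres)           # YResolution
    tag(339L, 3L, 1L, fmt)                # SampleFormat
    w4(if (z < nz) off_ifd[z + 1L] else 0L)
  }
  invisible(path)
}

.tiff_read <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_le <- rawToChar(raw[1:2]) == "II"
  if (!order_le && rawToChar(raw[1:2]) != "MM")
    stop("not a TIFF file: ", path)
  endian <- if (order_le) "little" else "big"
  rd <- function(off, size, what = "integer", n = 1L, signed = TRUE)
    readBin(raw[(off + 1L):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  if (rd(2, 2, signed = FALSE) != 42L) stop("not a TIFF file: ", path)
  off <- rd(4, 4)
  pages <- list()
  desc <- NULL; xres <- NA_real_; yres <- NA_real_
  while (off > 0) {
    ntag <- rd(off, 2, signed = FALSE)
    tags <- list()
    for (i in seq_len(ntag)) {
      base <- off + 2L + (i - 1L) * 12L
      id <- rd(base, 2, signed = FALSE)
      type <- rd(base + 2L, 2, signed = FALSE)
      count <- rd(base + 4L, 4)
      val <- switch(as.character(type),
        `3` = rd(base + 8L, 2, signed = FALSE),
        `4` = rd(base + 8L, 4),
        `2` = { p <- rd(base + 8L, 4)
                rawToChar(raw[(p + 1L):(p + count - 1L)]) },
        `5` = { p <- rd(base + 8L, 4)
                num <- rd(p, 4); den <- rd(p + 4L, 4); num / den },
        rd(base + 8L, 4))
      tags[[as.character(id)]] <- val
    }
    gt <- function(id, default = NULL)
      if (!is.null(tags[[as.character(id)]])) tags[[as.character(id)]]
      else default
    if ((cmp <- gt(259, 1L)) != 1L) stop("compressed TIFF not supported")
    nx <- gt(256); ny <- gt(257)
    bits <- gt(258, 8L); fmt <- gt(339, 1L)
    sOff <- gt(273); sCnt <- gt(279)
    if (is.null(nx) || is.null(ny) || is.null(sOff))
      stop("malformed TIFF IFD")
    if (is.null(desc)) desc <- gt(270)
    if (is.na(xres)) xres <- gt(282, NA_real_)
    if (is.na(yres)) yres <- gt(283, NA_real_)
    npx <- nx * ny
    size <- bits %/% 8L
    what <- if (fmt == 3L) "numeric" else "integer"
    vals <- rd(sOff, size, what = what, n = npx,
               signed = !(fmt == 1L && bits < 32L))
    page <- matrix(vals, nrow = nx, ncol = ny)  # row-major storage
    pages[[length(pages) + 1L]] <- t(page)      # -> ny x nx
    off <- rd(off + 2L + ntag * 12L, 4)
  }
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  arr <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  ## spacing: lateral from XResolution (pixels per cm), axial from the
  ## ImageJ "spacing=<um>" line
  vox <- c(NA_real_, NA_real_, NA_real_)
  if (!is.na(xres) && xres > 0) vox[3] <- 1e7 / xres
  if (!is.na(yres) && yres > 0) vox[2] <- 1e7 / yres
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1]]
    if (length(m) == 2) vox[1] <- as.numeric(m[2]) * 1000
  }
  if (any(is.na(vox))) {
    warning("TIFF lacks spacing metadata; assuming 50 nm isotropic voxels")
    vox[is.na(vox)] <- 50
  }
  list(data = arr, voxelNm = vox)
}
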