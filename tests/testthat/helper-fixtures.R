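# Fixture builders shared across the test files. Everything is generated in
# code at test time; nothing binary ships with the package.

# --- ImageJ .roi binary records -------------------------------------------

# rectangle ROI record (type 1); bounds as big-endian shorts
imagej_rect_roi_bytes <- function(top, left, bottom, right) {
  raw <- raw(64)
  raw[1:4] <- charToRaw("Iout")
  raw[5:6] <- writeBin(228L, raw(), size = 2, endian = "big")  # version
  raw[7] <- as.raw(1L)                                         # type: rect
  raw[9:10] <- writeBin(as.integer(top), raw(), size = 2, endian = "big")
  raw[11:12] <- writeBin(as.integer(left), raw(), size = 2, endian = "big")
  raw[13:14] <- writeBin(as.integer(bottom), raw(), size = 2, endian = "big")
  raw[15:16] <- writeBin(as.integer(right), raw(), size = 2, endian = "big")
  raw
}

# straight-line ROI record (type 3); endpoints as big-endian floats (x=col,
# y=row in ImageJ convention)
imagej_line_roi_bytes <- function(x1, y1, x2, y2) {
  raw <- raw(64)
  raw[1:4] <- charToRaw("Iout")
  raw[5:6] <- writeBin(228L, raw(), size = 2, endian = "big")
  raw[7] <- as.raw(3L)                                         # type: line
  raw[19:22] <- writeBin(x1, raw(), size = 4, endian = "big")
  raw[23:26] <- writeBin(y1, raw(), size = 4, endian = "big")
  raw[27:30] <- writeBin(x2, raw(), size = 4, endian = "big")
  raw[31:34] <- writeBin(y2, raw(), size = 4, endian = "big")
  raw
}

# --- minimal STORED zip writer (for ImageJ .zip archives) ------------------

crc32_r <- function(data) {
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1L), -306674912L) else bitwShiftR(c, 1L)
    tab[n + 1L] <- c
  }
  crc <- -1L
  for (b in as.integer(data))
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  bitwXor(crc, -1L)
}

write_stored_zip <- function(files, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  offs <- integer(0); crcs <- integer(0); pos <- 0
  for (nm in names(files)) {
    data <- files[[nm]]; n <- length(data); name_raw <- charToRaw(nm)
    crc <- crc32_r(data); crcs <- c(crcs, crc)
    writeBin(as.integer(c(0x50, 0x4b, 0x03, 0x04)), con, size = 1)
    writeBin(c(20L, 0L, 0L, 0L, 33L), con, size = 2, endian = "little")
    writeBin(crc, con, size = 4, endian = "little")
    writeBin(as.integer(c(n, n)), con, size = 4, endian = "little")
    writeBin(c(length(name_raw), 0L), con, size = 2, endian = "little")
    writeBin(name_raw, con)
    writeBin(data, con)
    offs <- c(offs, pos)
    pos <- pos + 30 + length(name_raw) + n
  }
  cd0 <- pos
  for (i in seq_along(files)) {
    nm <- names(files)[i]; data <- files[[nm]]
    n <- length(data); name_raw <- charToRaw(nm)
    writeBin(as.integer(c(0x50, 0x4b, 0x01, 0x02)), con, size = 1)
    writeBin(c(20L, 20L, 0L, 0L, 0L, 33L), con, size = 2, endian = "little")
    writeBin(crcs[i], con, size = 4, endian = "little")
    writeBin(as.integer(c(n, n)), con, size = 4, endian = "little")
    writeBin(c(length(name_raw), 0L, 0L, 0L, 0L), con, size = 2,
             endian = "little")
    writeBin(0L, con, size = 4, endian = "little")
    writeBin(as.integer(offs[i]), con, size = 4, endian = "little")
    writeBin(name_raw, con)
    pos <- pos + 46 + length(name_raw)
  }
  writeBin(as.integer(c(0x50, 0x4b, 0x05, 0x06)), con, size = 1)
  writeBin(as.integer(c(0L, 0L, length(files), length(files))), con, size = 2,
           endian = "little")
  writeBin(as.integer(c(pos - cd0, cd0)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")
  invisible(path)
}

# --- small image-stack builders -------------------------------------------

# textured patch stack: a reproducible random patch on a flat background,
# shifted by (dr, dc) pixels per frame (integer shifts only)
translated_patch_stack <- function(n_frames, h = 64, w = 64, patch_h = 12,
                                   patch_w = 12, at = c(26, 26), shifts_r = 0,
                                   shifts_c = 0, seed = 42) {
  patch <- withr::with_seed(seed, matrix(stats::runif(patch_h * patch_w),
                                         patch_h, patch_w))
  shifts_r <- rep_len(shifts_r, n_frames)
  shifts_c <- rep_len(shifts_c, n_frames)
  px <- array(0.1, dim = c(n_frames, h, w))
  for (k in seq_len(n_frames)) {
    r0 <- at[1] + shifts_r[k]; c0 <- at[2] + shifts_c[k]
    px[k, (r0 + 1):(r0 + patch_h), (c0 + 1):(c0 + patch_w)] <- patch
  }
  frame_stack(px, frame_interval = 0.025, origin_label = "test patch stack")
}

# smooth analytic scene sampled at sub-pixel column shifts per frame
subpixel_shift_stack <- function(shifts_c, h = 48, w = 96,
                                 frame_interval = 0.025) {
  scene <- function(cc) {
    0.3 + 0.25 * sin(2 * pi * cc / 11.3) + 0.2 * cos(2 * pi * cc / 23.7) +
      0.15 * sin(2 * pi * cc / 5.1 + 1)
  }
  cols <- seq_len(w) - 1
  px <- array(0, dim = c(length(shifts_c), h, w))
  for (k in seq_along(shifts_c)) {
    row_vals <- scene(cols - shifts_c[k])
    taper <- 0.5 + 0.5 * sin(2 * pi * (seq_len(h) - 1) / (2 * (h - 1)))
    px[k, , ] <- outer(taper, row_vals)
  }
  frame_stack(px, frame_interval, origin_label = "subpixel test stack")
}

# displacement trace tibble without going through the tracker
make_displacement_trace <- function(time_s, displacement_px) {
  out <- tibble::tibble(time_s = time_s, displacement_px = displacement_px,
                        correlation_peak = rep(1, length(time_s)))
  class(out) <- c("displacement_trace", class(out))
  out
}

# fluorescence trace tibble from raw values
make_fluorescence_trace <- function(time_s, values) {
  out <- tibble::tibble(time_s = time_s, f_over_f0 = values)
  attr(out, "f0_value") <- 1
  class(out) <- c("fluorescence_trace", class(out))
  out
}
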