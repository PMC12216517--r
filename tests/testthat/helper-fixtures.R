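# Shared fixtures, generated in code. Small grids keep unit tests fast;
# acceptance tests use the full default geometry.

# small tube phantom: 64 x 64 x 12 voxels, in-plane 1.2 mm
small_spec <- function(...) {
  tube_phantom_spec(shape = c(64, 64, 12), spacing = c(1.2, 1.2, 4), ...)
}

# fast registration settings for small grids (named arguments override)
fast_control <- function(...) {
  defaults <- list(metric = "ssd", stages = c("rigid", "bspline"),
                   levels = c(2), grid_spacing_mm = 12,
                   steps_mm = list(c(4, 2, 1)), passes = 2, sync_passes = 20,
                   bending_lambda = 0.01, axes = c(TRUE, TRUE, FALSE),
                   rotations = FALSE)
  do.call(reg_control, utils::modifyList(defaults, list(...)))
}

# a small healthy atlas, built once per test session
cached <- new.env()
small_atlas <- function() {
  if (is.null(cached$atlas)) {
    healthy <- lapply(1:3, function(i) {
      tube <- make_tube(small_spec(seed = 500L + i, noise_sd = 0.02))
      list(volume = tube$volume, mask = tube$mask)
    })
    cached$atlas <- build_atlas(healthy, max_iters = 1,
                                control = fast_control())
  }
  cached$atlas
}

# synthetic feature table with a planted separable signal
separable_table <- function(n = 48, p_noise = 15, delta = 3, seed = 11) {
  set.seed(seed)
  label <- rep(c("responder", "non-responder"), length.out = n)
  x1 <- rnorm(n) + ifelse(label == "responder", delta, 0)
  x2 <- rnorm(n) + ifelse(label == "responder", delta / 2, 0)
  noise <- matrix(rnorm(n * p_noise), n)
  colnames(noise) <- paste0("noise", seq_len(p_noise))
  data.frame(id = sprintf("P%03d", seq_len(n)), label = label,
             sig1 = x1, sig2 = x2, noise, check.names = FALSE,
             stringsAsFactors = FALSE)
}

# minimal explicit-VR little-endian DICOM writer (fixture generation only)
write_dicom_slice <- function(path, pixels, spacing_xy = c(1, 1),
                              position = c(0, 0, 0), thickness = 1) {
  stopifnot(is.matrix(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  put_us <- function(grp, ele, val) {
    writeBin(as.integer(c(grp, ele)), con, 2, endian = "little")
    writeBin(charToRaw("US"), con)
    writeBin(2L, con, 2, endian = "little")
    writeBin(as.integer(val), con, 2, endian = "little")
  }
  put_ds <- function(grp, ele, vals) {
    s <- paste(format(vals, trim = TRUE), collapse = "\\")
    if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
    writeBin(as.integer(c(grp, ele)), con, 2, endian = "little")
    writeBin(charToRaw("DS"), con)
    writeBin(nchar(s), con, 2, endian = "little")
    writeBin(charToRaw(s), con)
  }
  put_ds(0x0018, 0x0050, thickness)
  put_ds(0x0020, 0x0032, position)
  put_us(0x0028, 0x0010, nrow(t(pixels)))          # Rows (y)
  put_us(0x0028, 0x0011, ncol(t(pixels)))          # Columns (x)
  put_ds(0x0028, 0x0030, rev(spacing_xy))          # row spacing, col spacing
  px <- as.integer(round(as.vector(pixels)))       # x fastest = row-major
  writeBin(as.integer(c(0x7fe0, 0x0010)), con, 2, endian = "little")
  writeBin(charToRaw("OW"), con)
  writeBin(raw(2), con)
  writeBin(length(px) * 2L, con, 4, endian = "little")
  writeBin(px, con, 2, endian = "little")
  invisible(path)
}
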