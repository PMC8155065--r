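# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdirs.

# Small constant-color patch.
solid_patch <- function(h = 4, w = 4, rgb = c(255, 255, 255)) {
  rgb_patch(array(rep(as.integer(rgb), each = h * w), dim = c(h, w, 3)))
}

# Mask from a 0/1 matrix literal.
mk_mask <- function(m, role = "other") binary_mask(m == 1, role = role)

# Independent scalar RGB->HSV reference (textbook max/min formulation),
# deliberately separate from the vectorized implementation under test.
scalar_rgb_to_hsv <- function(r, g, b, convention = "hue179") {
  mx <- max(r, g, b) / 255
  mn <- min(r, g, b) / 255
  d <- mx - mn
  h_deg <- if (d == 0) 0
  else if (mx == r / 255) 60 * (((g - b) / 255 / d) %% 6)
  else if (mx == g / 255) 60 * ((b - r) / 255 / d + 2)
  else 60 * ((r - g) / 255 / d + 4)
  s <- if (mx == 0) 0 else d / mx
  if (convention == "hue179") {
    c(h = round(h_deg / 2) %% 180, s = round(s * 255), v = round(mx * 255))
  } else {
    c(h = round(h_deg / 360 * 255), s = round(s * 255), v = round(mx * 255))
  }
}

# Brute-force binary dilation with an arbitrary 0/1 kernel and
# outside-as-unset border handling; the independent morphology oracle.
brute_dilate <- function(bits, kern) {
  r <- (nrow(kern) - 1) %/% 2
  h <- nrow(bits); w <- ncol(bits)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!bits[i, j]) next
    for (di in -r:r) for (dj in -r:r) {
      if (kern[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) out[ii, jj] <- TRUE
    }
  }
  out
}

brute_erode <- function(bits, kern) {
  r <- (nrow(kern) - 1) %/% 2
  h <- nrow(bits); w <- ncol(bits)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    keep <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (kern[di + r + 1, dj + r + 1] == 0) next
      ii <- i + di; jj <- j + dj
      inside <- ii >= 1 && ii <= h && jj >= 1 && jj <= w && bits[ii, jj]
      if (!inside) { keep <- FALSE; break }
    }
    out[i, j] <- keep
  }
  out
}

# Desk-scale segmenter recipe used across tests (small MLP head wants a
# larger step size than the full-scale default schedule).
desk_segmenter_config <- function(epochs = 25, seed = 42) {
  segmenter_config(epochs = epochs, initial_lr = 2, final_lr = 0.1, seed = seed)
}

# Training pairs from the synthetic generator.
segmenter_examples <- function(seeds, role = "epithelium", side = 96) {
  lapply(seeds, function(s) {
    b <- generate_patch(synthetic_patch_spec(height = side, width = side, seed = s))
    list(patch = b$patch,
         mask = if (role == "epithelium") b$truth_epithelium else b$truth_necrotic,
         bundle = b)
  })
}

random_mask <- function(h, w, p = 0.3, role = "other") {
  binary_mask(matrix(runif(h * w) < p, h, w), role = role)
}
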