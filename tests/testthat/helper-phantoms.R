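# Small in-code fixtures shared across test files.

# Uniform-background image with optional painted boxes.
mk_image <- function(dim3 = c(10, 10, 10), background = 1,
                     spacing = c(2, 2, 2), frame_id = "t") {
  suv_image(array(background, dim = dim3), spacing = spacing,
            frame_id = frame_id)
}

# Paint an axis-aligned box [x0:x1, y0:y1, z0:z1] with a value.
paint_box <- function(image, x, y, z, value) {
  image$values[x, y, z] <- value
  image
}

# Brute-force 3-D connected-component labelling by BFS flood fill,
# independent of the package implementation. Small grids only.
flood_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(off))
  off <- off[switch(as.character(connectivity),
                    "6" = ord == 1, "18" = ord >= 1 & ord <= 2,
                    "26" = ord >= 1), , drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (lin in which(mask)) {
    if (lab[lin] != 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(lin, d)[1L, ])
    lab[lin] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (r in seq_len(nrow(off))) {
        nb <- v + off[r, ]
        if (any(nb < 1L) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- cur
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  lab
}

# A one-lesion spherical phantom spec of a requested volume (mL).
sphere_spec <- function(volume_ml = 20, suv = 8, spacing = c(2, 2, 2),
                        shape = c(40, 40, 40), noise_sd = 0, seed = 1L,
                        center_mm = (shape - 1) * spacing / 2) {
  r <- (3 * volume_ml * 1000 / (4 * pi))^(1 / 3)
  phantom_spec(shape = shape, spacing = spacing, background_suv = 1,
               lesions = list(list(center_mm = center_mm,
                                   radii_mm = rep(r, 3), suv = suv)),
               noise_sd = noise_sd, seed = seed)
}
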