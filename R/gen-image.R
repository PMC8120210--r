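#' Synthetic three-channel tissue image with exact ground truth
#'
#' Renders a 2D field of elongated, non-overlapping cells into DAPI, WGA and
#' alpha-actinin channels at the stated pixel size, together with a label map
#' and a per-cell ground-truth table. Cells are ellipses placed on a jittered
#' anisotropic lattice sized so that every cell fits its own lattice tile,
#' which guarantees a non-overlapping packing; per-cell axial orientations
#' are `orientation_mean` plus wrapped-normal noise on doubled angles. The
#' WGA channel carries the membrane ring of each cell, DAPI one nuclear
#' ellipse per cell, and the actinin channel sinusoidal striations of period
#' `sarcomere_period` running perpendicular to the cell axis (intensity
#' varies along the axis), present only in myocyte cells. Gaussian optical
#' blur and additive noise are applied last.
#'
#' @param params an [image_params()] object
#' @param canvas_size optional integer c(width, height) in pixels; by default
#'   the canvas is sized to hold `n_cells` lattice tiles. If given and too
#'   small for the requested cells an error names the packing constraint.
#' @return list with `channels` (named list of numeric matrices `dapi`,
#'   `wga`, `actinin`, x-by-y), `labels` (integer matrix, 0 = background),
#'   `truth` (data frame, one row per cell) and `params`
#' @examples
#' img <- generate_tissue_image(image_params(n_cells = 4, rng_seed = 7))
#' table(img$truth$is_myocyte)
#' @export
generate_tissue_image <- function(params, canvas_size = NULL) {
  stopifnot(inherits(params, "image_params"))
  p <- params
  px <- p$pixel_size

  with_rng(p$rng_seed, {
    n <- p$n_cells
    # per-cell geometry (half-axes in px), orientation in degrees
    len <- p$mean_cell_length * pmin(pmax(1 + p$length_cv * stats::rnorm(n), 0.6), 1.4)
    wid <- p$mean_cell_width * pmin(pmax(1 + p$width_cv * stats::rnorm(n), 0.6), 1.4)
    eps <- if (p$orientation_sd > 0) {
      dev_cap <- min(88, 3 * p$orientation_sd)
      pmin(pmax(stats::rnorm(n, 0, p$orientation_sd), -dev_cap), dev_cap)
    } else rep(0, n)
    theta <- p$orientation_mean + eps          # degrees, canvas frame
    a <- len / (2 * px); b <- wid / (2 * px)   # half axes, px
    th <- theta * pi / 180
    ex <- sqrt((a * cos(th))^2 + (b * sin(th))^2)  # bbox half-extents, px
    ey <- sqrt((a * sin(th))^2 + (b * cos(th))^2)

    gap <- max(2, ceiling(p$membrane_thickness / px))
    tile_w <- ceiling(2 * max(ex)) + gap
    tile_h <- ceiling(2 * max(ey)) + gap
    if (is.null(canvas_size)) {
      nx <- max(1L, ceiling(sqrt(n * tile_h / tile_w)))
      ny <- ceiling(n / nx)
      canvas_size <- c(nx * tile_w, ny * tile_h) + 2L * p$margin_px
    } else {
      nx <- (canvas_size[1] - 2L * p$margin_px) %/% tile_w
      ny <- (canvas_size[2] - 2L * p$margin_px) %/% tile_h
      if (nx * ny < n)
        stop_eht(paste0("cannot place %d cells: canvas %d x %d px holds only ",
                        "%d tiles of %d x %d px (cell bounding boxes + gap)"),
                 n, canvas_size[1], canvas_size[2], nx * ny, tile_w, tile_h)
    }
    W <- as.integer(canvas_size[1]); H <- as.integer(canvas_size[2])

    # jittered tile centers, row-major over the lattice
    tiles <- which(matrix(TRUE, nx, ny), arr.ind = TRUE)[seq_len(n), , drop = FALSE]
    jf <- p$jitter_frac %||% 0.5
    cx <- p$margin_px + (tiles[, 1] - 0.5) * tile_w +
      jf * stats::runif(n, -1, 1) * (tile_w / 2 - ex - gap / 2)
    cy <- p$margin_px + (tiles[, 2] - 0.5) * tile_h +
      jf * stats::runif(n, -1, 1) * (tile_h / 2 - ey - gap / 2)

    is_myo <- stats::runif(n) < p$myocyte_fraction
    nuc_area <- pmax(p$nucleus_area_mean / 2,
                     stats::rnorm(n, p$nucleus_area_mean, 0.15 * p$nucleus_area_mean))

    labels <- matrix(0L, W, H)
    dapi <- matrix(0, W, H); wga <- matrix(0, W, H); act <- matrix(0, W, H)
    mem_px <- p$membrane_thickness / px
    period_px <- p$sarcomere_period / px
    area_px <- numeric(n); nuc_px <- numeric(n)

    for (i in seq_len(n)) {
      x0 <- max(1L, floor(cx[i] - ex[i] - 1)); x1 <- min(W, ceiling(cx[i] + ex[i] + 1))
      y0 <- max(1L, floor(cy[i] - ey[i] - 1)); y1 <- min(H, ceiling(cy[i] + ey[i] + 1))
      xs <- x0:x1; ys <- y0:y1
      dx <- outer(xs - cx[i], rep(1, length(ys)))
      dy <- outer(rep(1, length(xs)), ys - cy[i])
      ct <- cos(th[i]); st <- sin(th[i])
      u <- dx * ct + dy * st       # along cell axis, px
      w <- -dx * st + dy * ct
      rho <- sqrt((u / a[i])^2 + (w / b[i])^2)
      inside <- rho <= 1
      area_px[i] <- sum(inside)

      sub <- labels[xs, ys]; sub[inside] <- i; labels[xs, ys] <- sub

      # membrane: pixels whose radial distance to the boundary <= thickness
      r_pix <- sqrt(u^2 + w^2)
      dist_b <- ifelse(rho > 1e-9, (1 - rho) * r_pix / rho, Inf)
      memb <- inside & dist_b <= mem_px
      sub <- wga[xs, ys]; sub[memb] <- sub[memb] + 1; wga[xs, ys] <- sub

      # nucleus: aligned ellipse, aspect 1.6, clipped to stay inside the cell
      an <- sqrt(nuc_area[i] / px^2 * 1.6 / pi); bn <- an / 1.6
      an <- min(an, 0.85 * a[i]); bn <- min(bn, 0.85 * b[i])
      nmask <- (u / an)^2 + (w / bn)^2 <= 1
      nuc_px[i] <- sum(nmask)
      sub <- dapi[xs, ys]; sub[nmask] <- sub[nmask] + 1; dapi[xs, ys] <- sub

      if (is_myo[i]) {
        stripes <- 0.5 * (1 + cos(2 * pi * u / period_px))
        core <- inside & dist_b > mem_px
        sub <- act[xs, ys]; sub[core] <- sub[core] + stripes[core]; act[xs, ys] <- sub
      }
    }

    blur_px <- p$blur_sd / px
    render <- function(m, amp) {
      img <- p$background_level + amp * m
      if (blur_px > 0)
        img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_px))
      if (p$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, p$noise_sd)
      pmax(img, 0)
    }
    channels <- list(dapi = render(dapi, p$dapi_amp),
                     wga = render(wga, p$wga_amp),
                     actinin = render(act, p$actinin_amp))

    truth <- data.frame(
      cell = seq_len(n),
      center_x_px = cx, center_y_px = cy,
      orientation_deg = wrap_axial(theta),
      length_um = 2 * a * px, width_um = 2 * b * px,
      area_um2 = area_px * px^2,
      nucleus_area_um2 = nuc_px * px^2,
      is_myocyte = is_myo,
      sarcomere_period_um = ifelse(is_myo, p$sarcomere_period, NA_real_))

    list(channels = channels, labels = labels, truth = truth, params = p)
  })
}
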