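#' Segment nuclei from a DAPI channel
#'
#' Automatic histogram-based (Otsu) threshold, morphological closing with a
#' disc, connected-component labelling, and removal of components smaller
#' than `min_area_um2` (the bound is inclusive: a component of exactly the
#' minimum area is retained).
#'
#' @param dapi numeric matrix of DAPI intensities (x-by-y)
#' @param pixel_size um per pixel
#' @param closing_radius_um disc radius for morphological closing, um
#' @param min_area_um2 minimum nucleus area, um^2 (default 5, inclusive)
#' @return integer label matrix (0 = background); a uniform input yields
#'   zero nuclei with a warning
#' @export
segment_nuclei <- function(dapi, pixel_size = 0.1, closing_radius_um = 0.3,
                           min_area_um2 = 5) {
  if (!length(dapi)) stop_eht("empty image")
  rng <- range(dapi)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("uniform DAPI image: no nuclei segmented", call. = FALSE)
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  th <- EBImage::otsu(EBImage::Image(dapi), range = rng, levels = 256)
  mask <- dapi > th
  r_px <- max(1L, round(closing_radius_um / pixel_size))
  brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  mask <- EBImage::closing(EBImage::Image(mask * 1), brush) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- as.matrix(lab)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas * pixel_size^2 >= min_area_um2)
  if (!length(keep)) {
    warning("no nucleus at or above the minimum area", call. = FALSE)
    return(matrix(0L, nrow(dapi), ncol(dapi)))
  }
  remap <- integer(length(areas)); remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  nz <- lab > 0
  out[nz] <- remap[lab[nz]]
  out
}

#' Nucleus-seeded watershed cell segmentation on WGA intensity
#'
#' Floods the WGA (membrane) intensity from the nucleus seeds so that region
#' boundaries settle on the bright membrane ridges; each output segment
#' contains exactly one seed. The flooding is restricted to a foreground
#' mask, by default derived from the WGA and DAPI support (thresholded,
#' closed and hole-filled) so that empty background is excluded. Set
#' `use_gradient = TRUE` to flood the gradient magnitude of the WGA channel
#' instead of the raw intensity.
#'
#' @param wga numeric matrix of WGA intensities
#' @param nuclei integer nucleus label matrix from [segment_nuclei()]
#' @param pixel_size um per pixel
#' @param mask optional logical foreground matrix; `NULL` derives one
#' @param close_radius_um radius used when deriving the foreground mask, so
#'   that near-touching cells form a connected tissue region
#' @param lambda regularization of the intensity-weighted flooding (see
#'   `EBImage::propagate`)
#' @param use_gradient flood the gradient magnitude instead of intensity
#' @return integer cell label matrix; labels match the seed labels
#' @export
watershed_cells <- function(wga, nuclei, pixel_size = 0.1, mask = NULL,
                            close_radius_um = 0.5, lambda = 1e-4,
                            use_gradient = FALSE) {
  if (!any(nuclei > 0)) stop_eht("no seeds: nucleus label map is empty")
  relief <- wga
  if (use_gradient) {
    gx <- relief * 0; gy <- relief * 0
    gx[2:(nrow(relief) - 1), ] <- (relief[-(1:2), ] - relief[1:(nrow(relief) - 2), ]) / 2
    gy[, 2:(ncol(relief) - 1)] <- (relief[, -(1:2)] - relief[, 1:(ncol(relief) - 2)]) / 2
    relief <- sqrt(gx^2 + gy^2)
  }
  if (is.null(mask)) {
    th <- EBImage::otsu(EBImage::Image(wga), range = range(wga), levels = 256)
    fg <- wga > th | nuclei > 0
    r_px <- max(1L, round(close_radius_um / pixel_size))
    brush <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
    fg <- EBImage::closing(EBImage::Image(fg * 1), brush) > 0.5
    fg <- EBImage::fillHull(EBImage::Image(fg * 1)) > 0.5
    mask <- as.matrix(fg)
  }
  labs <- EBImage::propagate(EBImage::Image(relief),
                             seeds = EBImage::Image(nuclei),
                             mask = mask, lambda = lambda)
  matrix(as.integer(as.matrix(labs)), nrow(wga), ncol(wga))
}

#' Threshold the sarcomeric alpha-actinin channel (mode + 1 SD)
#'
#' The threshold is the intensity-histogram mode (bin width `bin_width`)
#' plus one whole-image standard deviation; with `sd_from = "background"`
#' the SD is instead computed from pixels at or below the mode.
#'
#' @param actinin numeric matrix of actinin intensities
#' @param bin_width histogram bin width in intensity units (default 1)
#' @param sd_from "image" (default) or "background"
#' @return list with `mask` (logical matrix, intensity strictly above the
#'   threshold), `threshold`, `mode`, `sd`; a constant image yields an empty
#'   mask with a warning
#' @export
segment_actinin <- function(actinin, bin_width = 1,
                            sd_from = c("image", "background")) {
  sd_from <- match.arg(sd_from)
  if (!length(actinin)) stop_eht("empty image")
  rng <- range(actinin)
  if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("constant actinin image: empty mask", call. = FALSE)
    return(list(mask = matrix(FALSE, nrow(actinin), ncol(actinin)),
                threshold = rng[1], mode = rng[1], sd = 0))
  }
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                ceiling(rng[2] / bin_width) * bin_width + bin_width,
                by = bin_width)
  h <- hist(as.vector(actinin), breaks = breaks, plot = FALSE)
  mode_val <- h$mids[which.max(h$counts)]
  s <- if (sd_from == "image") stats::sd(as.vector(actinin))
       else stats::sd(actinin[actinin <= mode_val])
  th <- mode_val + s
  list(mask = actinin > th, threshold = th, mode = mode_val, sd = s)
}

#' Principal-axis geometry of labelled cells
#'
#' For every label: area (pixel count times pixel area), the axial
#' orientation of the first principal axis of the pixel coordinates (degrees
#' in [0, 180)), and the extents of the pixel projections on the first and
#' second principal axes (length and width). Labels with fewer than 3 pixels
#' are skipped; collinear pixel sets get zero width. Cells whose principal
#' axes are nearly degenerate (eigenvalue ratio below `iso_ratio`) are
#' flagged `isotropic`, their orientation being unstable.
#'
#' @param labels integer label matrix
#' @param pixel_size um per pixel
#' @param iso_ratio eigenvalue ratio below which a cell is flagged isotropic
#' @return data frame: `cell`, `centroid_x_px`, `centroid_y_px`, `area_um2`,
#'   `length_um`, `width_um`, `orientation_deg`, `isotropic`
#' @export
cell_morphology <- function(labels, pixel_size = 0.1, iso_ratio = 1.2) {
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(ids, function(i) {
    xy <- which(labels == i, arr.ind = TRUE)
    if (nrow(xy) < 3) return(NULL)
    mu <- colMeans(xy)
    cv <- stats::cov(xy)
    eg <- eigen(cv, symmetric = TRUE)
    v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
    ang <- wrap_axial(atan2(v1[2], v1[1]) * 180 / pi)
    ctr <- sweep(xy, 2, mu)
    p1 <- ctr %*% v1; p2 <- ctr %*% v2
    len <- (max(p1) - min(p1) + 1) * pixel_size
    wid <- if (eg$values[2] > 1e-12) (max(p2) - min(p2) + 1) * pixel_size else 0
    iso <- eg$values[2] > 1e-12 && eg$values[1] / eg$values[2] < iso_ratio
    data.frame(cell = i, centroid_x_px = mu[1], centroid_y_px = mu[2],
               area_um2 = nrow(xy) * pixel_size^2,
               length_um = len, width_um = wid,
               orientation_deg = ang, isotropic = iso)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(cell = integer(), centroid_x_px = numeric(),
                                      centroid_y_px = numeric(), area_um2 = numeric(),
                                      length_um = numeric(), width_um = numeric(),
                                      orientation_deg = numeric(), isotropic = logical())
  rownames(out) <- NULL
  out
}

#' First- and second-degree neighbors of labelled cells
#'
#' Two cells are first-degree neighbors iff their labels touch across a
#' 4-connected pixel boundary; second-degree neighbors are neighbors of
#' neighbors, excluding the cell itself and its first-degree neighbors.
#'
#' @param labels integer label matrix
#' @return list with `first` and `second`: lists of integer neighbor-id
#'   vectors, indexed by cell label
#' @export
neighbor_graph <- function(labels) {
  n <- max(labels, 0L)
  first <- vector("list", n); second <- vector("list", n)
  if (n == 0) return(list(first = first, second = second))
  pairs <- rbind(
    cbind(as.vector(labels[-nrow(labels), ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -ncol(labels)]), as.vector(labels[, -1])))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  pairs <- unique(rbind(pairs, pairs[, 2:1, drop = FALSE]))
  for (i in seq_len(n))
    first[[i]] <- as.integer(sort(unique(pairs[pairs[, 1] == i, 2])))
  for (i in seq_len(n)) {
    nn <- unique(unlist(first[first[[i]]]))
    second[[i]] <- as.integer(sort(setdiff(nn, c(i, first[[i]]))))
  }
  list(first = first, second = second)
}

#' Local axial orientation dispersion over the neighborhood of each cell
#'
#' For each cell, takes the axial orientations of the cell together with its
#' first- and second-degree neighbors, doubles the angles, computes the
#' circular mean, wraps each doubled-angle residual to (-180, 180] and halves
#' it (giving axial deviations in (-90, 90]), and returns their standard
#' deviation in degrees. Low dispersion indicates locally aligned cells.
#'
#' @param orientation_deg named or plain numeric vector of axial orientations
#'   indexed by cell label
#' @param graph neighbor structure from [neighbor_graph()]
#' @param min_set minimum neighborhood size (self included); smaller sets
#'   give `NA`
#' @param population use the population (divide by n) rather than sample SD
#' @return numeric vector of dispersions, degrees, one per cell
#' @export
local_dispersion <- function(orientation_deg, graph, min_set = 3,
                             population = FALSE) {
  n <- length(graph$first)
  vapply(seq_len(n), function(i) {
    set <- c(i, graph$first[[i]], graph$second[[i]])
    set <- set[set <= length(orientation_deg)]
    th <- orientation_deg[set]
    th <- th[!is.na(th)]
    if (length(th) < min_set) return(NA_real_)
    axial_sd(th, population = population)
  }, 0)
}

#' Axial circular standard deviation of orientations
#'
#' @param theta_deg axial angles in degrees
#' @param population divide by n instead of n - 1
#' @return SD in degrees on the axial scale
#' @export
axial_sd <- function(theta_deg, population = FALSE) {
  d2 <- 2 * theta_deg * pi / 180
  mu2 <- atan2(mean(sin(d2)), mean(cos(d2))) * 180 / pi
  dev <- wrap_pm180(2 * theta_deg - mu2) / 2
  if (population) sqrt(mean((dev - mean(dev))^2)) else stats::sd(dev)
}

#' Keep only cardiomyocyte segments
#'
#' Retains cells with an alpha-actinin area fraction of at least
#' `min_actinin_fraction` and a nucleus area of at least
#' `min_nucleus_area_um2`; both bounds are inclusive. The pre- and
#' post-filter counts are attached as attributes.
#'
#' @param cells data frame with columns `actinin_area_fraction` and
#'   `nucleus_area_um2`
#' @param min_actinin_fraction default 0.07
#' @param min_nucleus_area_um2 default 5
#' @return the retained subset, with attributes `n_pre` and `n_post`
#' @export
filter_myocytes <- function(cells, min_actinin_fraction = 0.07,
                            min_nucleus_area_um2 = 5) {
  stopifnot(all(c("actinin_area_fraction", "nucleus_area_um2") %in% names(cells)))
  keep <- cells$actinin_area_fraction >= min_actinin_fraction &
    cells$nucleus_area_um2 >= min_nucleus_area_um2
  out <- cells[keep, , drop = FALSE]
  attr(out, "n_pre") <- nrow(cells)
  attr(out, "n_post") <- nrow(out)
  out
}

#' Sarcomere length of one cell from striation periodicity
#'
#' Samples the actinin intensity along parallel lines that follow the cell's
#' principal axis, estimates each line's dominant period from the first
#' autocorrelation peak within `period_range` (with sub-pixel parabolic
#' refinement), and averages the line periods. A cell qualifies only if it is
#' at least three minimal periods long, at least `min_valid` lines show a
#' clear striation (normalized autocorrelation peak at or above
#' `prominence`), and the detected period fits at least three times into the
#' cell length.
#'
#' @param actinin numeric actinin intensity matrix
#' @param labels integer cell label matrix
#' @param cell one row of a [cell_morphology()] data frame (or a list with
#'   `cell`, `centroid_x_px`, `centroid_y_px`, `orientation_deg`,
#'   `length_um`, `width_um`)
#' @param pixel_size um per pixel
#' @param n_lines number of parallel sampling lines
#' @param min_valid minimum number of lines with a clear period
#' @param period_range admissible sarcomere periods, um
#' @param prominence minimum normalized autocorrelation peak height
#' @return list with `sarcomere_um` (NA if missing) and `reason`
#' @export
sarcomere_length <- function(actinin, labels, cell, pixel_size = 0.1,
                             n_lines = 7, min_valid = 5,
                             period_range = c(1.2, 3.0), prominence = 0.1) {
  L_px <- cell$length_um / pixel_size
  W_px <- cell$width_um / pixel_size
  if (cell$length_um < 3 * period_range[1])
    return(list(sarcomere_um = NA_real_, reason = "cell shorter than 3 periods"))
  th <- cell$orientation_deg * pi / 180
  u <- c(cos(th), sin(th)); v <- c(-sin(th), cos(th))
  ctr <- c(cell$centroid_x_px, cell$centroid_y_px)
  offs <- seq(-0.3, 0.3, length.out = n_lines) * W_px
  lag_min <- max(2L, floor(period_range[1] / pixel_size))
  lag_max <- ceiling(period_range[2] / pixel_size)
  W <- nrow(actinin); H <- ncol(actinin)

  line_period <- function(off) {
    s <- seq(-L_px / 2, L_px / 2, by = 1)
    px <- ctr[1] + s * u[1] + off * v[1]
    py <- ctr[2] + s * u[2] + off * v[2]
    ok <- px >= 1 & px <= W - 1 & py >= 1 & py <= H - 1
    px <- px[ok]; py <- py[ok]
    if (length(px) < 3 * lag_min) return(NA_real_)
    inlab <- labels[cbind(pmin(pmax(round(px), 1), W),
                          pmin(pmax(round(py), 1), H))] == cell$cell
    if (mean(inlab) < 0.7) return(NA_real_)
    x0 <- floor(px); y0 <- floor(py)
    fx <- px - x0; fy <- py - y0
    val <- actinin[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
      actinin[cbind(x0 + 1, y0)] * fx * (1 - fy) +
      actinin[cbind(x0, y0 + 1)] * (1 - fx) * fy +
      actinin[cbind(x0 + 1, y0 + 1)] * fx * fy
    val <- val[inlab]
    ny <- length(val)
    if (ny < 2 * lag_max) return(NA_real_)
    if (stats::sd(val) < 1e-6 * (abs(mean(val)) + 1e-12)) return(NA_real_)
    y <- val - mean(val)
    denom <- sum(y^2) / ny
    if (denom <= 0) return(NA_real_)
    lags <- 0:min(lag_max + 2L, ny - 2L)
    ac <- vapply(lags, function(l)
      sum(y[1:(ny - l)] * y[(1 + l):ny]) / (ny - l), 0) / denom
    lo <- lag_min + 1L; hi <- min(lag_max + 1L, length(ac) - 1L)
    if (hi <= lo) return(NA_real_)
    win <- lo:hi
    locmax <- win[ac[win] >= ac[win - 1L] & ac[win] >= ac[win + 1L]]
    if (!length(locmax)) return(NA_real_)
    pk <- locmax[which.max(ac[locmax])]
    if (ac[pk] < prominence) return(NA_real_)
    a <- ac[pk - 1L]; b <- ac[pk]; cc <- ac[pk + 1L]
    shift <- if (a - 2 * b + cc < 0) 0.5 * (a - cc) / (a - 2 * b + cc) else 0
    (pk - 1L + shift) * pixel_size
  }

  periods <- vapply(offs, line_period, 0)
  periods <- periods[!is.na(periods)]
  if (length(periods) < min_valid)
    return(list(sarcomere_um = NA_real_, reason = "no striation"))
  p <- mean(periods)
  if (cell$length_um < 3 * p)
    return(list(sarcomere_um = NA_real_, reason = "cell shorter than 3 periods"))
  list(sarcomere_um = p, reason = NA_character_)
}

#' Actinin-positive area of a tissue section
#'
#' @param mask logical actinin-positive mask
#' @param pixel_size um per pixel
#' @param section_area_um2 reference section area; defaults to the full image
#' @return list with `actinin_area_um2`, `actinin_area_mm2`, `fraction`,
#'   `section_area_um2`
#' @export
cross_section_stats <- function(mask, pixel_size = 0.1,
                                section_area_um2 = NULL) {
  area <- sum(mask) * pixel_size^2
  section_area_um2 <- section_area_um2 %||% (length(mask) * pixel_size^2)
  check_positive(section_area_um2, "section_area_um2")
  list(actinin_area_um2 = area, actinin_area_mm2 = area / 1e6,
       fraction = area / section_area_um2,
       section_area_um2 = section_area_um2)
}

#' Full confocal morphometry pipeline
#'
#' Runs the complete per-image analysis: nucleus segmentation (DAPI),
#' nucleus-seeded watershed on the WGA membrane channel, actinin
#' thresholding (mode + 1 SD), per-cell principal-axis geometry, per-cell
#' actinin area fraction and nucleus area, myocyte filtering, neighbor-graph
#' orientation dispersion, and sarcomere length for the retained myocytes.
#'
#' Cell geometry is measured on a tight segmentation (foreground closely
#' hugging the stained cells); for the neighbor graph the segments are then
#' grown into a gap-closed tissue mask (closing radius
#' `adjacency_close_um`), so that cells separated by narrow unstained
#' clefts still count as adjacent while their measured shapes stay
#' undistorted.
#'
#' @param dapi,wga,actinin numeric channel matrices of equal size
#' @param pixel_size um per pixel
#' @param min_actinin_fraction,min_nucleus_area_um2 myocyte filter bounds
#' @param adjacency_close_um closing radius used to bridge inter-cell gaps
#'   when establishing adjacency, um
#' @param sarcomere_args list of extra arguments for [sarcomere_length()]
#' @return list with `cells` (per-cell data frame including `is_myocyte`,
#'   `dispersion_deg`, `sarcomere_um`), `labels`, `nuclei`, `actinin_mask`,
#'   `actinin_threshold`, `section` (from [cross_section_stats()]), and the
#'   pre/post filter counts `n_pre`/`n_post`
#' @export
eht_morphometry <- function(dapi, wga, actinin, pixel_size = 0.1,
                            min_actinin_fraction = 0.07,
                            min_nucleus_area_um2 = 5,
                            adjacency_close_um = 4,
                            sarcomere_args = list()) {
  nuclei <- segment_nuclei(dapi, pixel_size)
  labels <- watershed_cells(wga, nuclei, pixel_size)
  seg_act <- segment_actinin(actinin)
  cells <- cell_morphology(labels, pixel_size)
  if (!nrow(cells))
    return(list(cells = cells, labels = labels, nuclei = nuclei,
                actinin_mask = seg_act$mask,
                actinin_threshold = seg_act$threshold,
                section = cross_section_stats(seg_act$mask, pixel_size),
                n_pre = 0L, n_post = 0L))

  lab_v <- as.vector(labels)
  nmax <- max(lab_v)
  tot <- tabulate(lab_v, nbins = nmax)
  act_px <- tabulate(lab_v[as.vector(seg_act$mask)], nbins = nmax)
  nuc_px <- tabulate(lab_v[as.vector(nuclei) > 0], nbins = nmax)
  cells$actinin_area_fraction <- (act_px / pmax(tot, 1))[cells$cell]
  cells$nucleus_area_um2 <- (nuc_px * pixel_size^2)[cells$cell]
  cells$is_myocyte <- cells$actinin_area_fraction >= min_actinin_fraction &
    cells$nucleus_area_um2 >= min_nucleus_area_um2

  # adjacency from segments grown into the gap-closed tissue mask
  r_px <- max(1L, round(adjacency_close_um / pixel_size))
  wide <- EBImage::closing(EBImage::Image((labels > 0) * 1),
                           EBImage::makeBrush(2L * r_px + 1L, "disc")) > 0.5
  adj_labels <- matrix(as.integer(as.matrix(
    EBImage::propagate(EBImage::Image(wga), seeds = EBImage::Image(labels),
                       mask = as.matrix(wide)))), nrow(wga), ncol(wga))
  graph <- neighbor_graph(adj_labels)
  ori <- rep(NA_real_, nmax)
  ori[cells$cell] <- cells$orientation_deg
  disp <- local_dispersion(ori, graph)
  cells$dispersion_deg <- disp[cells$cell]

  cells$sarcomere_um <- NA_real_
  cells$sarcomere_missing_reason <- NA_character_
  for (r in which(cells$is_myocyte)) {
    sl <- do.call(sarcomere_length,
                  c(list(actinin = actinin, labels = labels,
                         cell = cells[r, ], pixel_size = pixel_size),
                    sarcomere_args))
    cells$sarcomere_um[r] <- sl$sarcomere_um
    cells$sarcomere_missing_reason[r] <- sl$reason
  }

  list(cells = cells, labels = labels, nuclei = nuclei,
       actinin_mask = seg_act$mask, actinin_threshold = seg_act$threshold,
       section = cross_section_stats(seg_act$mask, pixel_size),
       n_pre = nrow(cells), n_post = sum(cells$is_myocyte))
}
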