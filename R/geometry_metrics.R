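# Resolution, field-of-view and radial-distortion metrics from bar-target and
# checkerboard images.

#' USAF-1951 spatial frequency and line width
#'
#' The chart indexes resolution by (group, element): spatial frequency is
#' 2^(group + (element - 1) / 6) line pairs per mm, so the bar (line) width is
#' half the line-pair period, 500 / f micrometres.
#'
#' @param group integer group.
#' @param element integer element in \[1, 6\].
#' @return `usaf_frequency()`: line pairs per mm; `usaf_line_width_um()`:
#'   bar width in micrometres.
#' @export
usaf_frequency <- function(group, element) {
  if (any(!element %in% 1:6)) stop("element must be in [1, 6]")
  2^(group + (element - 1) / 6)
}

#' @rdname usaf_frequency
#' @export
usaf_line_width_um <- function(group, element) {
  500 / usaf_frequency(group, element)
}

#' Michelson contrast of an image region
#'
#' (max - min) / (max + min) of the Rec.601 luma. Used as the objective
#' stand-in for the human two-observer "resolvable" judgment: a bar element
#' counts as resolved when its rendered contrast is at least `threshold`
#' (default 10%).
#'
#' @param image a [raster_image()].
#' @param roi optional `c(x0, y0, x1, y1)` region, 0-based inclusive.
#' @return Contrast in \[0, 1\] (0 for a uniform black region).
#' @export
michelson_contrast <- function(image, roi = NULL) {
  stopifnot(inherits(image, "raster_image"))
  y <- luma8(image)
  if (!is.null(roi)) {
    roi <- as.integer(roi)
    y <- y[(roi[2] + 1):(roi[4] + 1), (roi[1] + 1):(roi[3] + 1)]
  }
  if (max(y) + min(y) == 0) return(0)
  (max(y) - min(y)) / (max(y) + min(y))
}

#' Grid observation: an ordered checkerboard corner lattice
#'
#' @param x,y R x C matrices of sub-pixel corner coordinates (0-based pixel
#'   coordinates; x increases along rows of the matrix's columns, y down its
#'   rows).
#' @param square_mm physical square size, if known.
#' @return An object of class `grid_observation`.
#' @export
grid_observation <- function(x, y, square_mm = NULL) {
  if (!is.matrix(x) || !is.matrix(y) || !identical(dim(x), dim(y)))
    stop("x and y must be matrices of identical dimension")
  if (nrow(x) < 3L || ncol(x) < 3L)
    stop("corner grid must be at least 3 x 3")
  if (any(apply(x, 1, diff) <= 0))
    stop("corner grid is not topologically ordered in x")
  if (any(apply(y, 2, diff) <= 0))
    stop("corner grid is not topologically ordered in y")
  structure(list(x = x, y = y, rows = nrow(x), cols = ncol(x),
                 square_mm = square_mm),
            class = "grid_observation")
}

#' @export
print.grid_observation <- function(x, ...) {
  cat(sprintf("<grid_observation> %d x %d corners%s\n", x$rows, x$cols,
              if (is.null(x$square_mm)) ""
              else sprintf(", %g mm squares", x$square_mm)))
  invisible(x)
}

# separable Gaussian blur via banded-kernel matrix products
gauss_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  band <- function(n) {
    K <- matrix(0, n, n)
    for (j in -r:r) {
      idx <- seq_len(n)
      tgt <- idx + j
      okk <- tgt >= 1 & tgt <= n
      K[cbind(idx[okk], tgt[okk])] <- K[cbind(idx[okk], tgt[okk])] +
        k[j + r + 1]
    }
    K / rowSums(K)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

# gradient-orthogonality sub-pixel refinement (saddle-point solver): the
# corner q minimizes sum_w [grad I(p) . (p - q)]^2 over a window around q.
refine_corner <- function(Ix, Iy, x0, y0, win, iters = 6L) {
  H <- nrow(Ix); W <- ncol(Ix)
  q <- c(x0, y0)
  for (it in seq_len(iters)) {
    cxr <- round(q[1]); cyr <- round(q[2])
    xs <- max(1, cxr - win):min(W - 2, cxr + win)   # 0-based coords
    ys <- max(1, cyr - win):min(H - 2, cyr + win)
    gx <- Ix[ys + 1, xs + 1, drop = FALSE]
    gy <- Iy[ys + 1, xs + 1, drop = FALSE]
    px <- outer(rep(1, length(ys)), xs)
    py <- outer(ys, rep(1, length(xs)))
    w <- exp(-((px - q[1])^2 + (py - q[2])^2) / (2 * (win / 1.5)^2))
    a <- sum(w * gx * gx); b <- sum(w * gx * gy); cc <- sum(w * gy * gy)
    bx <- sum(w * (gx * gx * px + gx * gy * py))
    by <- sum(w * (gx * gy * px + gy * gy * py))
    det <- a * cc - b * b
    if (!is.finite(det) || det < 1e-9) break
    qn <- c((cc * bx - b * by) / det, (a * by - b * bx) / det)
    if (sum((qn - q)^2) > win^2) break      # diverged; keep previous
    moved <- sum((qn - q)^2)
    q <- qn
    if (moved < 1e-10) break
  }
  q
}

#' Detect an ordered checkerboard corner grid
#'
#' Saddle-point corner detection (Hessian response on a Gaussian-smoothed
#' luma image) with gradient-orthogonality sub-pixel refinement. Detected
#' corners are clustered into grid rows and columns; when the image contains
#' more corners than requested, the most central fully-populated
#' `rows` x `cols` block is returned, in canonical row-major order (x
#' increasing along rows, y increasing down columns).
#'
#' @param image a [raster_image()] containing a checkerboard with squares of
#'   at least ~8 px.
#' @param rows,cols expected corner grid dimensions (>= 3 each).
#' @param square_mm physical square size to attach to the observation.
#' @return A [grid_observation()].
#' @export
detect_grid <- function(image, rows, cols, square_mm = NULL) {
  stopifnot(inherits(image, "raster_image"))
  if (rows < 3L || cols < 3L) stop("rows and cols must be >= 3")
  d <- dim(image$pixels); H <- d[1]; W <- d[2]
  y <- luma8(image) / 255
  g <- gauss_blur(y, sigma = 2)

  # Hessian saddle response: corners of a checkerboard are strong saddles
  Ixx <- cbind(0, g[, -c(1, W)] * -2 + g[, -(W - 1):-W] + g[, -(1:2)], 0)
  Iyy <- rbind(0, g[-c(1, H), ] * -2 + g[-(H - 1):-H, ] + g[-(1:2), ], 0)
  shift <- function(m, dr, dc) {
    out <- matrix(0, H, W)
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    okr <- rs >= 1 & rs <= H; okc <- cs >= 1 & cs <= W
    out[which(okr), which(okc)] <- m[rs[okr], cs[okc]]
    out
  }
  Ixy <- (shift(g, 1, 1) - shift(g, 1, -1) - shift(g, -1, 1) +
            shift(g, -1, -1)) / 4
  resp <- Ixy^2 - Ixx * Iyy
  resp[resp < 0] <- 0
  # finite-difference padding makes the outermost rows/columns spurious
  resp[c(1, 2, H - 1, H), ] <- 0
  resp[, c(1, 2, W - 1, W)] <- 0

  if (max(resp) < 1e-6)
    stop("grid detection error: found 0 corner candidates (need ",
         rows * cols, ")")

  # non-maximum suppression on a coarse threshold, then greedy min-distance
  thr <- 0.1 * max(resp)
  dmin <- 0.5 * min(H / (rows + 1), W / (cols + 1))
  cand <- which(resp >= thr &
                  resp >= shift(resp, 1, 0) & resp >= shift(resp, -1, 0) &
                  resp >= shift(resp, 0, 1) & resp >= shift(resp, 0, -1) &
                  resp >= shift(resp, 1, 1) & resp >= shift(resp, -1, -1) &
                  resp >= shift(resp, 1, -1) & resp >= shift(resp, -1, 1),
                arr.ind = TRUE)
  border <- 3
  keep <- cand[, 1] > border & cand[, 1] <= H - border &
    cand[, 2] > border & cand[, 2] <= W - border
  cand <- cand[keep, , drop = FALSE]
  o <- order(resp[cand], decreasing = TRUE)
  cand <- cand[o, , drop = FALSE]
  acc <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (nrow(acc) == 0 ||
        min((acc[, 1] - p[1])^2 + (acc[, 2] - p[2])^2) >= dmin^2)
      acc <- rbind(acc, p)
  }
  if (nrow(acc) < rows * cols)
    stop("grid detection error: found ", nrow(acc), " corner candidates, ",
         "need ", rows * cols)

  cx0 <- acc[, 2] - 1; cy0 <- acc[, 1] - 1          # 0-based (x, y)

  # assemble the lattice by walking right/down neighbor links: robust to the
  # row curvature a radial warp introduces, unlike 1-D coordinate clustering
  n <- nrow(acc)
  neighbor <- function(i, axis, lo, hi, shear) {
    # nearest point roughly one step along +x (axis 1) or +y (axis 2)
    du <- if (axis == 1) cx0 - cx0[i] else cy0 - cy0[i]
    dv <- if (axis == 1) cy0 - cy0[i] else cx0 - cx0[i]
    okn <- du > lo & du < hi & abs(dv) < shear * du
    if (!any(okn)) return(NA_integer_)
    cand2 <- which(okn)
    cand2[which.min(du[cand2]^2 + dv[cand2]^2)]
  }
  # pass 1: crude nearest-rightward links give a robust pitch estimate
  right <- vapply(seq_len(n), neighbor, integer(1), axis = 1,
                  lo = 0.4 * dmin, hi = Inf, shear = 0.5)
  pitch <- stats::median(cx0[right] - cx0, na.rm = TRUE)
  # pass 2: only accept single-step links, so lattice holes never alias
  right <- vapply(seq_len(n), neighbor, integer(1), axis = 1,
                  lo = 0.6 * pitch, hi = 1.45 * pitch, shear = 0.35)
  down <- vapply(seq_len(n), neighbor, integer(1), axis = 2,
                 lo = 0.6 * pitch, hi = 1.45 * pitch, shear = 0.35)
  ij <- matrix(NA_integer_, n, 2)
  start <- which.min((cx0 - mean(cx0))^2 + (cy0 - mean(cy0))^2)
  ij[start, ] <- c(0L, 0L)
  queue <- start
  while (length(queue)) {
    k <- queue[1]; queue <- queue[-1]
    for (lnk in list(c(right[k], 1L, 0L), c(down[k], 0L, 1L))) {
      m <- lnk[1]
      if (!is.na(m) && is.na(ij[m, 1])) {
        ij[m, ] <- ij[k, ] + lnk[2:3]
        queue <- c(queue, m)
      }
    }
    # backward links via reverse lookup
    for (m in which(right == k)) if (is.na(ij[m, 1]) && !is.na(ij[k, 1])) {
      ij[m, ] <- ij[k, ] - c(1L, 0L); queue <- c(queue, m)
    }
    for (m in which(down == k)) if (is.na(ij[m, 1]) && !is.na(ij[k, 1])) {
      ij[m, ] <- ij[k, ] - c(0L, 1L); queue <- c(queue, m)
    }
  }
  linked <- !is.na(ij[, 1])
  if (sum(linked) < rows * cols)
    stop("grid detection error: only ", sum(linked), " of ", n,
         " corners form a connected lattice, need ", rows * cols)
  ci <- ij[linked, 1] - min(ij[linked, 1]) + 1L
  ri <- ij[linked, 2] - min(ij[linked, 2]) + 1L
  nr <- max(ri); nc <- max(ci)
  if (nr < rows || nc < cols)
    stop("grid detection error: found ", nr, " x ", nc,
         " corner grid, need ", rows, " x ", cols)
  present <- matrix(FALSE, nr, nc)
  xm <- matrix(NA_real_, nr, nc); ym <- matrix(NA_real_, nr, nc)
  present[cbind(ri, ci)] <- TRUE
  xm[cbind(ri, ci)] <- cx0[linked]; ym[cbind(ri, ci)] <- cy0[linked]

  # rows x cols block centered on the lattice node nearest the frame center
  # (falls back to the most central fully-populated block)
  d2c <- (xm - (W - 1) / 2)^2 + (ym - (H - 1) / 2)^2
  d2c[!present] <- Inf
  ctr <- arrayInd(which.min(d2c), dim(d2c))
  r0 <- min(max(1L, ctr[1] - (rows - 1L) %/% 2L), nr - rows + 1L)
  c0 <- min(max(1L, ctr[2] - (cols - 1L) %/% 2L), nc - cols + 1L)
  best <- NULL
  if (all(present[r0:(r0 + rows - 1), c0:(c0 + cols - 1)]))
    best <- list(rr = r0:(r0 + rows - 1), cc = c0:(c0 + cols - 1))
  if (is.null(best)) {
    bestd <- Inf
    for (r0 in seq_len(nr - rows + 1)) for (c0 in seq_len(nc - cols + 1)) {
      rr <- r0:(r0 + rows - 1); cc <- c0:(c0 + cols - 1)
      if (all(present[rr, cc])) {
        cen <- c(mean(xm[rr, cc]), mean(ym[rr, cc]))
        dd <- (cen[1] - (W - 1) / 2)^2 + (cen[2] - (H - 1) / 2)^2
        if (dd < bestd) { bestd <- dd; best <- list(rr = rr, cc = cc) }
      }
    }
  }
  if (is.null(best))
    stop("grid detection error: no complete ", rows, " x ", cols,
         " corner block among ", sum(present), " detected corners")
  X <- xm[best$rr, best$cc]; Y <- ym[best$rr, best$cc]

  # sub-pixel refinement on the lightly smoothed image gradients
  gs <- gauss_blur(y, sigma = 1)
  Ixg <- cbind(0, (gs[, -(1:2)] - gs[, -(W - 1):-W]) / 2, 0)
  Iyg <- rbind(0, (gs[-(1:2), ] - gs[-(H - 1):-H, ]) / 2, 0)
  spacing <- stats::median(c(abs(diff(t(X))), abs(diff(Y))))
  win <- max(3L, min(10L, floor(0.35 * spacing)))
  for (i in seq_len(length(X))) {
    q <- refine_corner(Ixg, Iyg, X[i], Y[i], win = win)
    X[i] <- q[1]; Y[i] <- q[2]
  }
  grid_observation(X, Y, square_mm = square_mm)
}

#' SMIA TV distortion of a corner grid
#'
#' The SMIA 1.0 television-distortion convention: with A1 and A2 the vertical
#' extents of the leftmost and rightmost corner columns and B the vertical
#' extent of the central column, distortion is 100 (A - B) / B with
#' A = (A1 + A2) / 2. Negative values are barrel (outer columns shorter),
#' positive pincushion; |percent| <= 0.05 (the corner-detection noise floor)
#' is labelled `none`.
#'
#' @param g a [grid_observation()].
#' @return An object of class `distortion_report`: list with `percent`,
#'   `label`, and the intermediate `A1`, `A2`, `B`.
#' @export
smia_tv_distortion <- function(g) {
  stopifnot(inherits(g, "grid_observation"))
  A1 <- max(g$y[, 1]) - min(g$y[, 1])
  A2 <- max(g$y[, g$cols]) - min(g$y[, g$cols])
  mid <- (g$cols + 1) / 2
  B <- if (mid == floor(mid)) {
    max(g$y[, mid]) - min(g$y[, mid])
  } else {
    ((max(g$y[, floor(mid)]) - min(g$y[, floor(mid)])) +
       (max(g$y[, ceiling(mid)]) - min(g$y[, ceiling(mid)]))) / 2
  }
  if (B <= 0) stop("degenerate grid: central column has zero vertical extent")
  A <- (A1 + A2) / 2
  percent <- 100 * (A - B) / B
  label <- if (percent < -0.05) "barrel"
           else if (percent > 0.05) "pincushion" else "none"
  structure(list(percent = percent, label = label, A1 = A1, A2 = A2, B = B),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("<distortion_report> %+.3f%% (%s)\n", x$percent, x$label))
  invisible(x)
}

#' Diagonal field of view from a calibrated grid
#'
#' The physical scale is estimated as `square_mm` divided by the median
#' corner spacing; the field of view is the image diagonal in pixels times
#' that scale. Row/column spacing disagreement above 5% raises a calibration
#' warning and the mean of the two estimates is used.
#'
#' @param g a [grid_observation()] with known `square_mm`.
#' @param image the [raster_image()] the grid was detected in (for the
#'   frame diagonal).
#' @return Field of view in mm, with attribute `mm_per_px`.
#' @export
diagonal_fov <- function(g, image) {
  stopifnot(inherits(g, "grid_observation"), inherits(image, "raster_image"))
  if (is.null(g$square_mm)) stop("grid observation has no square_mm")
  sx <- stats::median(abs(t(apply(g$x, 1, diff))))
  sy <- stats::median(abs(apply(g$y, 2, diff)))
  if (abs(sx - sy) / mean(c(sx, sy)) > 0.05)
    warning(sprintf(paste0("anisotropic corner spacing (x %.2f px vs y %.2f ",
                           "px); using the mean"), sx, sy))
  mm_per_px <- g$square_mm / mean(c(sx, sy))
  d <- dim(image$pixels)
  fov <- sqrt(d[1]^2 + d[2]^2) * mm_per_px
  attr(fov, "mm_per_px") <- mm_per_px
  fov
}

#' Magnification relative to a declared reference field
#'
#' For fixed-lens digital systems magnification has no unique optical
#' definition; this package uses the ratio of a declared reference field of
#' view to the measured one.
#'
#' @param fov_diag_mm measured diagonal field of view, mm.
#' @param reference_fov_mm declared reference field, mm.
#' @return Dimensionless magnification.
#' @export
magnification <- function(fov_diag_mm, reference_fov_mm) {
  if (fov_diag_mm <= 0 || reference_fov_mm <= 0)
    stop("fields of view must be positive")
  reference_fov_mm / fov_diag_mm
}
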