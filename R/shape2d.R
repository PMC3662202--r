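# --- boundary tracing -------------------------------------------------------

# Moore-neighbour contour tracing (8-neighbourhood, clockwise, Jacob's
# stopping criterion) of a single connected component given as a logical
# matrix. Returns the ordered closed contour as an n x 2 matrix of (row,
# col) pixel coordinates; a single-pixel component returns one row.
trace_contour <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  start <- which(m)[1]
  s <- c((start - 1) %% nr + 1, (start - 1) %/% nr + 1)
  # clockwise Moore neighbourhood starting north
  offs <- matrix(c(-1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1),
                 ncol = 2, byrow = TRUE)
  inside <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  fg <- function(p) inside(p) && m[p[1], p[2]]
  # we found `s` scanning column-major, so the pixel before it (north) is
  # background or off-grid: a valid backtrack
  contour <- matrix(s, 1, 2)
  p <- s; bdir <- 1L  # start searching from the north offset
  first_move <- NULL
  max_steps <- 4L * (nr * nc + 4L)
  for (step in seq_len(max_steps)) {
    q <- NULL
    for (k in seq_len(8L)) {
      dir <- ((bdir - 1L + k - 1L) %% 8L) + 1L
      cand <- p + offs[dir, ]
      if (fg(cand)) {
        q <- cand
        # new backtrack: the neighbour examined just before q, expressed
        # as a direction from q (consecutive ring cells are adjacent)
        prevdir <- ((dir - 2L) %% 8L) + 1L
        bprev <- p + offs[prevdir, ]
        diffb <- bprev - q
        newb <- which(offs[, 1] == diffb[1] & offs[, 2] == diffb[2])
        break
      }
    }
    if (is.null(q)) return(contour)  # isolated pixel
    # closed: the start pixel is about to repeat its first move
    if (!is.null(first_move) && all(p == s) && all(q == first_move)) break
    if (is.null(first_move)) first_move <- q
    bdir <- newb
    p <- q
    contour <- rbind(contour, p)
  }
  contour
}

# All closed contours of a binary slice (one per 4-connected component),
# traced on each component in isolation.
slice_contours <- function(sl) {
  d <- dim(sl)
  lab <- array(.label_components6(as.logical(sl != 0), c(d, 1L)), d)
  lapply(seq_len(max(lab, 0L)), function(id) trace_contour(lab == id))
}

contour_length <- function(contour) {
  if (nrow(contour) < 2L) return(0)
  steps <- sqrt(rowSums(diff(contour)^2))
  sum(steps)  # 1 for axial steps, sqrt(2) for diagonal steps
}

# --- descriptor computation -------------------------------------------------

shape2d_names <- c("Area", "Area_PR", "Area_PL", "Area_FR", "Area_FL",
                   "Perimeter", "Circularity", "Elongation", "Rectangularity",
                   "d_AG", "d_BG", "d_CG", "d_DG", "d_AC", "d_BD",
                   "MinThickness", "MeanSig")

#' Datum slice: the axial slice of maximum ventricular area
#'
#' @param mask a [vm_mask].
#' @return The 1-based index of the axial (third-axis) slice with the most
#'   mask pixels; ties resolve to the lowest index.
#' @export
datum_slice <- function(mask) {
  m <- if (inherits(mask, "vm_mask")) mask$mask else mask
  counts <- apply(m != 0, 3, sum)
  if (all(counts == 0)) vm_stop("empty_mask", "mask is empty")
  which.max(counts)
}

#' Two-dimensional shape descriptors of a ventricle slice
#'
#' Computes the 17 descriptors of the datum-plane shape analysis on a
#' binary slice. Conventions (fixed for reproducibility):
#' * the first matrix index runs left to right, the second anterior (frontal,
#'   low index) to posterior (high index);
#' * `Area` is the pixel count times the squared pixel size; the four
#'   sub-areas split the region at the centroid G along both image axes
#'   (P/F = posterior/frontal, R/L = right/left) and sum to `Area`;
#' * `Perimeter` is the summed length of the traced outer contour of every
#'   connected component, diagonal steps weighted sqrt(2);
#' * `Circularity` = 100 * 4 * pi * Area / Perimeter^2 (percent of a perfect
#'   circle; 100 by convention when the perimeter is zero);
#' * `Elongation` is the major/minor axis ratio of the second-moment
#'   (inertia-equivalent) ellipse, with the 1/12 per-pixel term so a solid
#'   a x b rectangle gives exactly a/b;
#' * `Rectangularity` = Area / area of the minimum-area oriented bounding
#'   rectangle (1 degree orientation steps over pixel corners);
#' * landmarks: G = centroid; A/B/C/D = anterior-, right-, posterior- and
#'   left-most boundary pixels (ties resolved toward the preceding
#'   clockwise extreme), with Euclidean in-plane distances in mm;
#' * `MinThickness` = minimum caliper width over 180 orientations;
#' * `MeanSig` = mean centroid-to-boundary distance (centroid-distance
#'   shape signature).
#'
#' Multiple connected components (the ventricles are bilateral) are
#' measured as their union. A single-pixel region returns distances 0,
#' elongation 1 and circularity 100 by convention.
#'
#' @param slice binary matrix (a datum slice of a ventricle mask).
#' @param pixel_size in-plane pixel size in mm (isotropic).
#' @return A named list of class `vm_shape2d` with the 17 descriptors.
#' @export
shape2d <- function(slice, pixel_size = 1) {
  if (is.array(slice) && length(dim(slice)) == 3L && dim(slice)[3] == 1L)
    slice <- slice[, , 1]
  if (!is.matrix(slice)) vm_stop("parameter", "slice must be a binary matrix")
  sl <- slice != 0
  if (!any(sl)) vm_stop("empty_mask", "slice contains no region")
  p <- check_number(pixel_size, "pixel_size", min = 0, strict = TRUE)

  pix <- which(sl, arr.ind = TRUE)
  x <- pix[, 1]; y <- pix[, 2]
  n <- length(x)
  G <- c(mean(x), mean(y))
  area <- n * p^2
  post <- y >= G[2]; right <- x >= G[1]
  area_pr <- sum(post & right) * p^2
  area_pl <- sum(post & !right) * p^2
  area_fr <- sum(!post & right) * p^2
  area_fl <- sum(!post & !right) * p^2

  contours <- slice_contours(sl)
  perimeter <- sum(vapply(contours, contour_length, numeric(1))) * p
  circularity <- if (perimeter > 0) 100 * 4 * pi * area / perimeter^2 else 100

  # second-moment ellipse with the per-pixel (unit square) inertia term
  mxx <- mean((x - G[1])^2) + 1 / 12
  myy <- mean((y - G[2])^2) + 1 / 12
  mxy <- mean((x - G[1]) * (y - G[2]))
  tr <- (mxx + myy) / 2
  det <- sqrt(((mxx - myy) / 2)^2 + mxy^2)
  elongation <- sqrt((tr + det) / max(tr - det, .Machine$double.eps))

  bnd <- unique(do.call(rbind, contours))
  bx <- bnd[, 1]; by <- bnd[, 2]
  pick <- function(primary, secondary) bnd[order(primary, secondary)[1], ]
  A <- pick(by, bx)    # anterior-most, tie: left-most
  B <- pick(-bx, by)   # right-most, tie: anterior-most
  C <- pick(-by, -bx)  # posterior-most, tie: right-most
  D <- pick(bx, -by)   # left-most, tie: posterior-most
  dd <- function(u, v) sqrt(sum((u - v)^2)) * p

  # caliper widths and minimum-area oriented bounding rectangle over the
  # pixel-corner set (pixels are unit squares)
  corners <- rbind(cbind(bx - 0.5, by - 0.5), cbind(bx + 0.5, by - 0.5),
                   cbind(bx - 0.5, by + 0.5), cbind(bx + 0.5, by + 0.5))
  hull <- corners[grDevices::chull(corners), , drop = FALSE]
  th <- (0:89) * pi / 180
  cu <- outer(hull[, 1], cos(th)) + outer(hull[, 2], sin(th))
  cv <- -outer(hull[, 1], sin(th)) + outer(hull[, 2], cos(th))
  wu <- apply(cu, 2, max) - apply(cu, 2, min)
  wv <- apply(cv, 2, max) - apply(cv, 2, min)
  min_rect <- min(wu * wv)
  rectangularity <- n / min_rect
  min_thickness <- min(c(wu, wv)) * p

  mean_sig <- mean(sqrt((bx - G[1])^2 + (by - G[2])^2)) * p

  structure(list(area = area, area_pr = area_pr, area_pl = area_pl,
                 area_fr = area_fr, area_fl = area_fl,
                 perimeter = perimeter, circularity = circularity,
                 elongation = elongation, rectangularity = rectangularity,
                 d_ag = dd(A, G), d_bg = dd(B, G), d_cg = dd(C, G),
                 d_dg = dd(D, G), d_ac = dd(A, C), d_bd = dd(B, D),
                 min_thickness = min_thickness, mean_signature = mean_sig,
                 centroid = G, landmarks = rbind(A = A, B = B, C = C, D = D),
                 pixel_size = p),
            class = "vm_shape2d")
}

#' @export
print.vm_shape2d <- function(x, ...) {
  v <- as_feature_row(x)
  cat("<vm_shape2d>\n")
  print(round(v, 2))
  invisible(x)
}

#' Flatten shape descriptors to a named feature vector
#'
#' @param x a [shape2d] result.
#' @return Named numeric vector with the 17 canonical column names
#'   (`Area`, `Area_PR`, ..., `MeanSig`).
#' @export
as_feature_row <- function(x) {
  stopifnot(inherits(x, "vm_shape2d"))
  stats::setNames(
    c(x$area, x$area_pr, x$area_pl, x$area_fr, x$area_fl, x$perimeter,
      x$circularity, x$elongation, x$rectangularity, x$d_ag, x$d_bg,
      x$d_cg, x$d_dg, x$d_ac, x$d_bd, x$min_thickness, x$mean_signature),
    shape2d_names)
}
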