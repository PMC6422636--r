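# Charge maps: per-site evoked charge over a stimulation grid, annotated with
# laminar boundaries and soma position; binarization against baseline charge,
# rotation/translation/cropping/averaging across cells, and the laminar
# charge-proportion statistic.

#' Construct a charge map
#'
#' A charge map holds the evoked charge (pC) at every site of a rectangular
#' stimulation grid, with rows running down the cortical depth axis and
#' columns along the horizontal axis, plus the annotations needed for
#' cross-cell alignment: the four laminar boundaries (depths delimiting
#' L2/3, L4, L5 and L6), the soma position of the recorded cell, and the
#' home-column x position.
#'
#' @param charge numeric matrix of site charges (rows = depths, columns = x).
#' @param col_x,row_depths site coordinates, um; both strictly increasing.
#' @param boundaries numeric length 5, strictly increasing depths: top of
#'   L2/3, L2/3|L4, L4|L5, L5|L6, bottom of L6.
#' @param soma_xy numeric length 2, \code{c(x, depth)} of the recorded soma.
#' @param home_x x position of the home column.
#' @param l45_points optional \code{data.frame(x, depth)} of annotated points
#'   on the L4-L5 boundary, used to estimate map rotation; defaults to the
#'   horizontal line at \code{boundaries[3]}.
#' @return Object of class \code{"charge_map"}.
#' @export
charge_map <- function(charge, col_x, row_depths, boundaries, soma_xy = NULL,
                       home_x = NULL, l45_points = NULL) {
  charge <- as.matrix(charge)
  if (nrow(charge) != length(row_depths) || ncol(charge) != length(col_x))
    stop_config("charge matrix dimensions must match coordinate vectors")
  if (length(boundaries) != 5L || any(diff(boundaries) <= 0))
    stop_config("'boundaries' must be 5 strictly increasing depths")
  if (is.unsorted(col_x, strictly = TRUE) || is.unsorted(row_depths, strictly = TRUE))
    stop_config("coordinates must be strictly increasing")
  if (is.null(l45_points))
    l45_points <- data.frame(x = range(col_x), depth = boundaries[3])
  structure(list(charge = charge, col_x = as.numeric(col_x),
                 row_depths = as.numeric(row_depths),
                 boundaries = as.numeric(boundaries),
                 soma_xy = soma_xy, home_x = home_x,
                 l45_points = l45_points, rotation_deg = 0),
            class = "charge_map")
}

#' @export
print.charge_map <- function(x, ...) {
  cat(sprintf("Charge map: %d x %d sites, L4-L5 boundary at %g um\n",
              nrow(x$charge), ncol(x$charge), x$boundaries[3]))
  invisible(x)
}

#' Binarize a charge map against baseline charge
#'
#' Per-site one-sided Monte Carlo resampling test of the evoked charge
#' against charges measured during baseline periods: each permutation draws a
#' surrogate "evoked" charge from the baseline samples, and
#' \code{p = (1 + #\{perm >= observed\}) / (1 + n_perm)}, so a site charge
#' exceeding every baseline value attains the minimal p of
#' \code{1 / (n_perm + 1)}. A site is flagged iff \code{p <= alpha / n_sites}
#' (Bonferroni over the sites of the map).
#'
#' @param map a \code{\link{charge_map}}.
#' @param baseline_samples numeric vector of baseline charges (>= 2 values).
#' @param n_perm number of permutations (>= 1000).
#' @param alpha familywise error level before Bonferroni division.
#' @param seed integer seed.
#' @return Logical matrix of the map's shape; attribute \code{"p"} carries
#'   the per-site permutation p-values.
#' @export
binarize_charge_map <- function(map, baseline_samples, n_perm = 10000, alpha = 0.05,
                                seed = NULL) {
  if (!inherits(map, "charge_map")) stop_config("'map' must be a charge_map")
  if (length(baseline_samples) < 2L)
    stop_config("need at least 2 baseline samples")
  n_perm <- check_count(n_perm, "n_perm", min = 1000L)
  seed_rng(seed)
  n_sites <- length(map$charge)
  if (n_sites == 0L) {
    out <- matrix(logical(), nrow(map$charge), ncol(map$charge))
    attr(out, "p") <- matrix(numeric(), nrow(map$charge), ncol(map$charge))
    return(out)
  }
  p <- vapply(as.numeric(map$charge), function(obs) {
    perm <- baseline_samples[sample.int(length(baseline_samples), n_perm,
                                        replace = TRUE)]
    (1 + sum(perm >= obs)) / (1 + n_perm)
  }, numeric(1))
  flags <- matrix(p <= alpha / n_sites, nrow(map$charge), ncol(map$charge))
  attr(flags, "p") <- matrix(p, nrow(map$charge), ncol(map$charge))
  flags
}

# bilinear interpolation of map charge at query points; NA outside support
map_interp <- function(map, xq, dq) {
  xs <- map$col_x
  ds <- map$row_depths
  z <- map$charge
  ix <- findInterval(xq, xs)
  id <- findInterval(dq, ds)
  out <- rep(NA_real_, length(xq))
  ok <- ix >= 1L & ix < length(xs) & id >= 1L & id < length(ds)
  # allow exact upper-edge queries
  edge_x <- abs(xq - xs[length(xs)]) < 1e-9
  edge_d <- abs(dq - ds[length(ds)]) < 1e-9
  ix[edge_x] <- length(xs) - 1L
  id[edge_d] <- length(ds) - 1L
  ok <- ok | (edge_x & id >= 1L & (id < length(ds) | edge_d)) |
        (edge_d & ix >= 1L & (ix < length(xs) | edge_x))
  ok[!is.finite(xq) | !is.finite(dq)] <- FALSE
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- id[ok]
  wx <- (xq[ok] - xs[i]) / (xs[i + 1L] - xs[i])
  wd <- (dq[ok] - ds[j]) / (ds[j + 1L] - ds[j])
  out[ok] <- (1 - wd) * ((1 - wx) * z[cbind(j, i)] + wx * z[cbind(j, i + 1L)]) +
             wd * ((1 - wx) * z[cbind(j + 1L, i)] + wx * z[cbind(j + 1L, i + 1L)])
  out
}

#' Align charge maps and average them
#'
#' Each map is (1) rotated so that its laminar boundaries run horizontally
#' (the rotation angle is a least-squares line fit to the annotated L4-L5
#' boundary points, rotation about the map centre), (2) translated vertically
#' so the L4-L5 boundary sits at depth 0, (3) translated horizontally to
#' align either the home column or the soma of the recorded cell at x = 0,
#' (4) horizontally cropped to +/- \code{crop_um} of that centre, and
#' (5) averaged element-wise with the other maps over their overlapping
#' support (sites with no contributing map are NA).
#'
#' @param maps list of \code{\link{charge_map}} objects.
#' @param align_mode \code{"home_column"} or \code{"soma"}.
#' @param crop_um horizontal crop half-width, um (default 300).
#' @return A \code{\link{charge_map}} on the aligned coordinate frame (L4-L5
#'   boundary at depth 0); boundaries are averaged across maps.
#' @export
align_and_average_maps <- function(maps, align_mode = c("home_column", "soma"),
                                   crop_um = 300) {
  align_mode <- match.arg(align_mode)
  if (!length(maps)) stop_config("'maps' must contain at least one charge_map")
  if (!all(vapply(maps, inherits, logical(1), "charge_map")))
    stop_config("'maps' must be a list of charge_map objects")

  aligned <- lapply(maps, function(m) {
    if (is.null(m$l45_points) || nrow(m$l45_points) < 2L)
      stop_config("map lacks L4-L5 boundary annotation")
    if (align_mode == "home_column" && is.null(m$home_x))
      stop_config("map lacks home-column annotation")
    if (align_mode == "soma" && is.null(m$soma_xy))
      stop_config("map lacks soma annotation")
    fit <- lm(depth ~ x, data = m$l45_points)
    theta <- atan(unname(coef(fit)[2]))          # boundary tilt, radians
    cx <- mean(range(m$col_x))
    cd <- mean(range(m$row_depths))
    rot_fwd <- function(x, d) {                  # map-frame -> aligned frame
      list(x = cx + cos(theta) * (x - cx) + sin(theta) * (d - cd),
           d = cd - sin(theta) * (x - cx) + cos(theta) * (d - cd))
    }
    bp <- rot_fwd(m$l45_points$x, m$l45_points$depth)
    l45_depth <- mean(bp$d)
    x0 <- if (align_mode == "home_column") m$home_x else m$soma_xy[1]
    x0 <- rot_fwd(x0, l45_depth)$x
    list(map = m, theta = theta, cx = cx, cd = cd,
         l45_depth = l45_depth, x0 = x0,
         spacing = min(diff(m$col_x)),
         depth_lo = min(m$row_depths) - l45_depth,
         depth_hi = max(m$row_depths) - l45_depth)
  })

  spacing <- min(vapply(aligned, `[[`, numeric(1), "spacing"))
  d_lo <- min(vapply(aligned, `[[`, numeric(1), "depth_lo"))
  d_hi <- max(vapply(aligned, `[[`, numeric(1), "depth_hi"))
  gx <- seq(-crop_um, crop_um, by = spacing)
  gd <- seq(spacing * floor(d_lo / spacing), spacing * ceiling(d_hi / spacing),
            by = spacing)
  qq <- expand.grid(x = gx, d = gd)

  acc <- matrix(0, length(gd), length(gx))
  cnt <- matrix(0L, length(gd), length(gx))
  for (a in aligned) {
    # invert the alignment: aligned (x', d') -> original map frame
    xg <- qq$x + a$x0
    dg <- qq$d + a$l45_depth
    xo <- a$cx + cos(a$theta) * (xg - a$cx) - sin(a$theta) * (dg - a$cd)
    do <- a$cd + sin(a$theta) * (xg - a$cx) + cos(a$theta) * (dg - a$cd)
    v <- matrix(map_interp(a$map, xo, do), length(gx), length(gd))
    v <- t(v)
    hit <- !is.na(v)
    acc[hit] <- acc[hit] + v[hit]
    cnt <- cnt + hit
  }
  avg <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)

  bmat <- vapply(seq_along(maps), function(i)
    maps[[i]]$boundaries - aligned[[i]]$l45_depth, numeric(5))
  charge_map(avg, col_x = gx, row_depths = gd,
             boundaries = rowMeans(bmat), soma_xy = c(0, NA), home_x = 0)
}

#' Proportion of evoked charge arising from L4 and L6
#'
#' Fraction of the total evoked charge in a map that originates from sites in
#' L4 or L6: \code{[L4 + L6] / [L2/3 + L4 + L5 + L6]}. Rows are assigned to
#' layers by the map's boundary depths (half-open intervals). Non-Martinotti
#' cells receive most of their input from L4/L6, Martinotti cells from
#' L2/3/L5, so this proportion separates the two populations.
#'
#' @param map a \code{\link{charge_map}}.
#' @param na_rm drop NA site charges before summing (default TRUE).
#' @return Proportion in [0, 1] for non-negative charges; NA (with a warning)
#'   when the four-layer total is zero.
#' @export
layer_charge_proportion <- function(map, na_rm = TRUE) {
  if (!inherits(map, "charge_map")) stop_config("'map' must be a charge_map")
  b <- map$boundaries
  layer <- cut(map$row_depths, breaks = b, labels = c("L2/3", "L4", "L5", "L6"),
               right = FALSE)
  tot <- function(layers) {
    rows <- which(layer %in% layers)
    if (!length(rows)) return(0)
    sum(map$charge[rows, , drop = FALSE], na.rm = na_rm)
  }
  num <- tot(c("L4", "L6"))
  den <- tot(c("L2/3", "L4", "L5", "L6"))
  if (den == 0) {
    warning("total evoked charge is zero; proportion undefined")
    return(NA_real_)
  }
  num / den
}
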