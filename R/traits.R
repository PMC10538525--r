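# Skeleton-based root trait measurement. The cleaned binary mask is
# thinned to a one-pixel medial skeleton; the Euclidean distance
# transform of the mask supplies a local radius at every skeleton pixel,
# from which length, diameter, surface-area and volume traits follow
# under a cylinder model. Architectural traits come from the mask pixels
# themselves (extent, convex hull, centroid).

as_mask_matrix <- function(mask) {
  m <- if (inherits(mask, "binary_mask")) mask$mask else mask
  if (!is.logical(m) || !is.matrix(m)) stopf("mask must be a logical matrix")
  m
}

# 8-neighbour count of every true pixel (matrix of same shape).
neighbor_counts <- function(S) {
  H <- nrow(S); W <- ncol(S)
  P <- matrix(0L, H + 2, W + 2)
  P[2:(H + 1), 2:(W + 1)] <- S
  n <- matrix(0L, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    n <- n + P[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  n
}

#' Skeletonize a root mask
#'
#' Topology-preserving (Zhang-Suen) thinning to a 1-px skeleton,
#' followed by pruning of spurs -- branch-to-endpoint side paths shorter
#' than `min_spur_px` pixels, which are thinning artifacts at this
#' scale, not real laterals. Each skeleton pixel carries the Euclidean
#' distance-transform radius of the mask at that location.
#'
#' @param mask A `binary_mask` or logical matrix (non-empty).
#' @param min_spur_px Minimum spur length kept, in pixels.
#' @return An object of class `root_skeleton`: `skel` (logical matrix),
#'   `coords` (n x 2 row/col), `radius_px`, `degree` (8-neighbour
#'   counts), `endpoints` and `branchpoints` (index vectors into
#'   `coords`).
#' @export
skeletonize <- function(mask, min_spur_px = 5) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("no foreground")
  sk <- thin_cpp(m)
  sk <- prune_spurs_cpp(sk, as.integer(min_spur_px))
  deg <- neighbor_counts(sk)
  runs <- nbr_runs_cpp(sk)
  idx <- which(sk)
  coords <- cbind(row = ((idx - 1L) %% nrow(m)) + 1L,
                  col = ((idx - 1L) %/% nrow(m)) + 1L)
  # the distance-transform value runs centre-to-background-centre and
  # alternates between over- and under-shooting the true half width by
  # half a pixel with stroke parity; -0.25 centres the estimator
  radius <- pmax(sqrt(edt_sq_cpp(m))[idx] - 0.25, 0.5)
  dg <- deg[idx]
  rn <- runs[idx]
  sk_obj <- structure(list(skel = sk, coords = coords, radius_px = radius,
                           degree = dg,
                           endpoints = which(rn == 1L & dg >= 1L),
                           isolated = which(dg == 0L),
                           branchpoints = which(rn >= 3L)),
                      class = "root_skeleton")
  sk_obj$step_px <- skeleton_step_lengths(sk_obj, idx)
  sk_obj
}

#' @export
print.root_skeleton <- function(x, ...) {
  cat(sprintf("<root_skeleton> %d px, %d endpoints, %d branch points\n",
              nrow(x$coords), length(x$endpoints), length(x$branchpoints)))
  invisible(x)
}

#' Locate the root/shoot junction
#'
#' The junction is the topmost root pixel (pouches hang root-down, so
#' depth increases with row index). Ties in the top row are broken by
#' the column closest to the mask centroid column, then by the smaller
#' column.
#'
#' @param mask A `binary_mask` or logical matrix (non-empty).
#' @return c(row, col).
#' @export
detect_junction <- function(mask) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("no foreground")
  rmin <- which(rowSums(m) > 0)[1]
  cand <- which(m[rmin, ])
  ccol <- mean(col(m)[m])
  d <- abs(cand - ccol)
  cand <- cand[d == min(d)]
  c(row = rmin, col = min(cand))
}

#' Count root tips
#'
#' A tip is a skeleton endpoint; the endpoint nearest the root/shoot
#' junction is the collar, not a tip, and is excluded. Endpoints of
#' every connected skeleton component are counted (debris surviving the
#' cleaning stage will inflate the count -- intentionally, since
#' removing it is the cleaning stage's job). A component reduced to a
#' single isolated skeleton pixel counts as one tip.
#'
#' @param skel A `root_skeleton`.
#' @param junction c(row, col) from [detect_junction()].
#' @return Integer tip count (TRT).
#' @export
count_tips <- function(skel, junction) {
  stopifnot(inherits(skel, "root_skeleton"))
  eps <- c(skel$endpoints, skel$isolated)
  if (length(eps) == 0) return(0L)
  length(eps) - 1L  # exclude the collar (endpoint nearest the junction)
}

# Running mean with a window that shrinks toward the ends (so the first
# and last samples -- root tips -- stay fixed).
smooth_adaptive <- function(v, h) {
  n <- length(v)
  if (n < 3 || h < 1) return(v)
  cs <- cumsum(v)
  i <- seq_len(n)
  hi <- pmin(h, i - 1, n - i)
  lo <- i - hi
  up <- i + hi
  (cs[up] - c(0, cs)[lo]) / (up - lo + 1)
}

# Per-pixel step lengths (px) from ordered skeleton paths. Raw pixel
# chains overestimate curve length by up to ~8% (staircase effect), so
# each path's coordinates are smoothed with a short running mean before
# summing Euclidean segments; straight axis-aligned paths are unchanged
# (1 px per axial step). Each pixel receives half of each incident
# segment; node pixels accumulate over all their paths.
skeleton_step_lengths <- function(skel, idx, smooth_h = 3L) {
  paths <- skeleton_paths_cpp(skel$skel)
  step <- numeric(length(idx))
  for (p in paths) {
    if (length(p) < 2) next
    k <- match(p, idx)
    rs <- smooth_adaptive(as.numeric(skel$coords[k, 1]), smooth_h)
    cs <- smooth_adaptive(as.numeric(skel$coords[k, 2]), smooth_h)
    seg <- sqrt(diff(rs)^2 + diff(cs)^2)
    half <- 0.5 * seg
    n <- length(p)
    step[k[-n]] <- step[k[-n]] + half
    step[k[-1]] <- step[k[-1]] + half
  }
  # round-cap allowance: the medial axis stops at the cap centre, but
  # the root continues ~radius further; thinning retreats a little more
  ep <- skel$endpoints
  step[ep] <- step[ep] + pmax(skel$radius_px[ep] - 0.5, 0)
  step
}

#' Measure morphological traits from a skeleton
#'
#' Per skeleton pixel i: step length `l_i` (1/scale cm for axial
#' adjacency, sqrt(2)/scale for diagonal, half of each incident step)
#' and local diameter `d_i = 2 * radius_px / scale * 10` mm. Then
#' TRL = sum(l), DIM = sum(d l)/sum(l), TSA = pi sum((d/10) l),
#' TRV = pi/4 sum((d/10)^2 l), and TSA1/TSA3 restrict TSA to the
#' diameter classes [0, 0.5) and [1.0, 1.5) mm.
#'
#' @param skel A `root_skeleton`.
#' @param scale Pixels per cm (> 0).
#' @return Named list: TRL, DIM, TSA, TRV, TSA1, TSA3.
#' @export
measure_morphology <- function(skel, scale) {
  stopifnot(inherits(skel, "root_skeleton"))
  if (!is.numeric(scale) || scale <= 0) stopf("scale must be > 0")
  ell <- skel$step_px / scale               # cm
  d <- 2 * skel$radius_px / scale * 10      # mm
  TRL <- sum(ell)
  if (TRL == 0) stopf("skeleton carries no length")
  DIM <- sum(d * ell) / TRL
  TSA <- pi * sum(d / 10 * ell)
  TRV <- pi / 4 * sum((d / 10)^2 * ell)
  in1 <- d < 0.5
  in3 <- d >= 1.0 & d < 1.5
  list(TRL = TRL, DIM = DIM, TSA = TSA, TRV = TRV,
       TSA1 = pi * sum((d / 10 * ell)[in1]),
       TSA3 = pi * sum((d / 10 * ell)[in3]))
}

#' Surface area decomposed into 0.5-mm diameter classes
#'
#' @param skel A `root_skeleton`.
#' @param scale Pixels per cm.
#' @param class_width_mm Diameter class width (half-open on the right).
#' @return Data frame with class bounds and class surface areas; the
#'   areas sum to TSA.
#' @export
tsa_by_class <- function(skel, scale, class_width_mm = 0.5) {
  ell <- skel$step_px / scale
  d <- 2 * skel$radius_px / scale * 10
  k <- floor(d / class_width_mm)
  sa <- pi * d / 10 * ell
  agg <- rowsum(sa, k)
  data.frame(d_min = as.numeric(rownames(agg)) * class_width_mm,
             d_max = (as.numeric(rownames(agg)) + 1) * class_width_mm,
             TSA = as.vector(agg))
}

#' Measure architectural traits
#'
#' TRW is the horizontal pixel extent in cm; TCA the convex-hull area of
#' the root pixels (hull taken over pixel corners so a solid rectangle
#' has solidity exactly 1); SOL the root pixel area divided by TCA; COPM
#' the vertical distance of the root-pixel centroid from the junction;
#' RDI the fraction of skeleton surface area lying strictly below
#' one-third of the rooting depth (junction to deepest pixel).
#'
#' @param mask A `binary_mask` or logical matrix.
#' @param skel A `root_skeleton` of the same mask.
#' @param junction c(row, col) from [detect_junction()].
#' @param scale Pixels per cm.
#' @return Named list: TRW, TCA, SOL, COPM, RDI.
#' @export
measure_architecture <- function(mask, skel, junction, scale) {
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("no foreground")
  junction <- unname(junction)
  idx <- which(m)
  rows <- ((idx - 1L) %% nrow(m)) + 1L
  cols <- ((idx - 1L) %/% nrow(m)) + 1L

  TRW <- (max(cols) - min(cols) + 1) / scale

  h1 <- chull(cols, rows)
  if (length(h1) < 3) stopf("degenerate hull")
  hx <- cols[h1]; hy <- rows[h1]
  cx <- rep(hx, each = 4) + c(-0.5, -0.5, 0.5, 0.5)
  cy <- rep(hy, each = 4) + c(-0.5, 0.5, -0.5, 0.5)
  h2 <- chull(cx, cy)
  TCA <- poly_area(cx[h2], cy[h2]) / scale^2
  if (TCA <= 0) stopf("degenerate hull")

  SOL <- (length(idx) / scale^2) / TCA
  COPM <- (mean(rows) - junction[1]) / scale

  ell <- skel$step_px / scale
  d <- 2 * skel$radius_px / scale * 10
  sa <- pi * d / 10 * ell
  D <- max(rows) - junction[1]
  below <- skel$coords[, 1] > junction[1] + D / 3
  RDI <- if (sum(sa) > 0) sum(sa[below]) / sum(sa) else 0

  list(TRW = TRW, TCA = TCA, SOL = SOL, COPM = COPM, RDI = RDI)
}

#' Measure all 12 root traits
#'
#' Given a raw [pouch_image], runs the cleaning pipeline first; given a
#' mask, measures it as-is. All connected fragments of the mask are
#' measured -- rejecting non-root objects is the cleaning stage's
#' responsibility.
#'
#' @param x A [pouch_image], `binary_mask`, or logical matrix.
#' @param pixels_per_cm Image scale; taken from the image when `x` is a
#'   [pouch_image].
#' @param cleaning A [cleaning_config()]; defaults to
#'   [default_cleaning_config()] at the image scale.
#' @param min_spur_px Spur-pruning length for [skeletonize()].
#' @return A [trait_record] with the cleaning stage recorded in the
#'   `"stage"` attribute.
#' @export
measure_all <- function(x, pixels_per_cm = NULL, cleaning = NULL,
                        min_spur_px = 5) {
  if (inherits(x, "pouch_image")) {
    scale <- x$pixels_per_cm
    if (is.null(cleaning)) cleaning <- default_cleaning_config(scale)
    cl <- clean_image(x, cleaning)
    mask <- cl$cleaned_mask
    stage <- "cleaned"
  } else {
    if (is.null(pixels_per_cm)) stopf("pixels_per_cm required for a mask")
    scale <- pixels_per_cm
    mask <- x
    stage <- if (inherits(x, "binary_mask")) x$stage else "mask"
  }
  m <- as_mask_matrix(mask)
  if (!any(m)) stopf("no foreground")
  skel <- skeletonize(m, min_spur_px)
  junction <- detect_junction(m)
  mor <- measure_morphology(skel, scale)
  arc <- measure_architecture(m, skel, junction, scale)
  TRT <- count_tips(skel, junction)
  rec <- trait_record(TRL = mor$TRL, TSA = mor$TSA, DIM = mor$DIM,
                      TRV = mor$TRV, TRT = TRT, TSA1 = mor$TSA1,
                      TSA3 = mor$TSA3, TRW = arc$TRW, TCA = arc$TCA,
                      RDI = arc$RDI, SOL = arc$SOL, COPM = arc$COPM)
  attr(rec, "stage") <- stage
  attr(rec, "pixels_per_cm") <- scale
  rec
}
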