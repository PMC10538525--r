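# Parametric synthetic root systems with analytic ground truth, rendered
# as growth-pouch style images (bright roots on a dark background, with
# optional debris particles and meniscus halo artifacts).
#
# Units follow field convention: lengths in cm, root widths/diameters in
# mm (factor 10 applied once at the render/measure boundary). Model
# coordinates put the root/shoot junction at (0, 0) with y increasing
# downward, matching image row order for pouches hung root-down.

#' Parameters of a synthetic root system model
#'
#' Defines a tap root with first-order laterals. Laterals emerge at
#' alternating sides of the tap at roughly even spacing, with stochastic
#' insertion angles, lengths and curvature. Defaults emulate a 10-day-old
#' pouch-grown soybean seedling: total root length on the order of
#' 100-200 cm, 50-100 root tips, tap diameter ~1.2 mm and lateral
#' diameters ~0.55 mm.
#'
#' @param tap_length_cm Tap root length in cm (> 0).
#' @param n_laterals Number of lateral roots requested (>= 0). The
#'   realized number can be lower when crowding makes a collision-free
#'   placement impossible; the ground-truth traits always describe the
#'   realized geometry.
#' @param lateral_length_cm List with `mean`, `sd`, `min` (cm) of the
#'   truncated-normal lateral length distribution. `sd = 0` gives
#'   constant lengths. Upper laterals are longer (acropetal scaling).
#' @param root_width_mm Numeric of length 2: basal diameter of the tap
#'   root and of laterals, in mm. Both taper toward the tip.
#' @param insertion_angle_deg List with `mean`, `sd`: lateral insertion
#'   angle from the vertical, in degrees (clamped to 20-85).
#' @param wiggle Heading-noise standard deviation in degrees per 2 mm
#'   growth step; 0 gives straight roots.
#' @param seed Integer seed; the model is a deterministic function of
#'   the parameters and this seed.
#' @return An object of class `root_model_params`.
#' @export
root_model_params <- function(tap_length_cm = 20,
                              n_laterals = 60,
                              lateral_length_cm = list(mean = 1.4, sd = 1.0, min = 0.5),
                              root_width_mm = c(tap = 1.2, lateral = 0.55),
                              insertion_angle_deg = list(mean = 55, sd = 10),
                              wiggle = 6,
                              seed = 1L) {
  if (!is.numeric(tap_length_cm) || tap_length_cm <= 0)
    stopf("tap_length_cm must be a positive number")
  if (n_laterals < 0 || n_laterals != round(n_laterals))
    stopf("n_laterals must be a non-negative integer")
  for (nm in c("mean", "sd", "min"))
    if (is.null(lateral_length_cm[[nm]]))
      stopf("lateral_length_cm must provide '%s'", nm)
  if (lateral_length_cm$sd < 0)
    stopf("lateral_length_cm$sd must be >= 0 (0 means constant length)")
  if (lateral_length_cm$min <= 0 || lateral_length_cm$mean <= 0)
    stopf("lateral lengths must be positive")
  if (length(root_width_mm) != 2 || any(root_width_mm <= 0))
    stopf("root_width_mm must be two positive widths (tap, lateral)")
  if (is.null(insertion_angle_deg$mean) || is.null(insertion_angle_deg$sd) ||
      insertion_angle_deg$sd < 0)
    stopf("insertion_angle_deg must provide mean and sd >= 0")
  if (wiggle < 0) stopf("wiggle must be >= 0")
  structure(list(
    tap_length_cm = as.numeric(tap_length_cm),
    n_laterals = as.integer(n_laterals),
    lateral_length_cm = lateral_length_cm,
    root_width_mm = unname(as.numeric(root_width_mm)),
    insertion_angle_deg = insertion_angle_deg,
    wiggle = as.numeric(wiggle),
    seed = as.integer(seed)
  ), class = "root_model_params")
}

# --- polyline helpers --------------------------------------------------

# Resample a polyline (n x 2 matrix, cm) with per-vertex widths (mm) at
# arclength spacing `step`. Returns x, y, w at sample points plus the
# cumulative arclength.
resample_polyline <- function(xy, w, step) {
  seg <- sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stopf("degenerate (zero-length) polyline")
  t <- unique(c(seq(0, total, by = step), total))
  list(
    x = stats::approx(s, xy[, 1], t, ties = "ordered")$y,
    y = stats::approx(s, xy[, 2], t, ties = "ordered")$y,
    w = stats::approx(s, w, t, ties = "ordered")$y,
    s = t, total = total
  )
}

polyline_length <- function(xy) sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))

# Shoelace area of a polygon given as x/y vectors (unclosed).
poly_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Grow a curved root strand from `origin`, heading measured from the
# vertical (degrees, signed; positive = +x). The heading relaxes toward
# vertical (gravitropism) with e-folding scale `droop_cm` and receives
# AR(1) wiggle noise.
grow_strand <- function(origin, length_cm, angle0_deg, wiggle, droop_cm = 6,
                        step = 0.2) {
  n <- max(2L, ceiling(length_cm / step) + 1L)
  t <- seq(0, length_cm, length.out = n)
  base <- angle0_deg * exp(-t / droop_cm)
  noise <- numeric(n)
  if (wiggle > 0) {
    e <- rnorm(n, 0, wiggle)
    for (k in 2:n) noise[k] <- 0.85 * noise[k - 1] + e[k]
  }
  ang <- pmin(88, pmax(-88, base + noise)) * pi / 180
  dt <- diff(t)
  x <- origin[1] + cumsum(c(0, dt * sin(ang[-n])))
  y <- origin[2] + cumsum(c(0, dt * cos(ang[-n])))
  cbind(x, y)
}

# Minimum clearance violation check: returns index of the first candidate
# sample that comes closer than (r_cand + r_occ + gap) to any occupied
# sample, or 0 when clear.
first_violation <- function(cx, cy, cr, ox, oy, or_, gap) {
  if (length(ox) == 0 || length(cx) == 0) return(0L)
  bb <- c(min(cx), max(cx), min(cy), max(cy))
  keep <- ox >= bb[1] - 0.5 & ox <= bb[2] + 0.5 &
          oy >= bb[3] - 0.5 & oy <= bb[4] + 0.5
  if (!any(keep)) return(0L)
  ox <- ox[keep]; oy <- oy[keep]; or_ <- or_[keep]
  for (i in seq_along(cx)) {
    d <- sqrt((ox - cx[i])^2 + (oy - cy[i])^2) - or_ - cr[i] - gap
    if (any(d < 0)) return(i)
  }
  0L
}

#' Generate a synthetic root system
#'
#' Builds the tap root polyline, then places laterals top-down at
#' alternating sides. Each lateral is rejection-sampled (up to 100
#' retries) so that no two strands cross or come within a clearance
#' margin of each other; this keeps the ground-truth tip count
#' unambiguous once rendered. A lateral that cannot be placed is
#' truncated before the collision or, if too short, dropped.
#'
#' @param params A [root_model_params()] object.
#' @return An object of class `root_model` with elements `segments`
#'   (list of polylines with per-vertex widths and an order tag),
#'   `junction` (always c(0, 0)), `params`, and `truth`, the analytic
#'   [trait_record] of the realized geometry.
#' @export
generate_model <- function(params) {
  if (!inherits(params, "root_model_params"))
    params <- do.call(root_model_params, params)
  with_seed(params$seed, generate_model_impl(params))
}

generate_model_impl <- function(params) {
  step <- 0.2
  w_tap <- params$root_width_mm[1]
  w_lat <- params$root_width_mm[2]

  tap_xy <- grow_strand(c(0, 0), params$tap_length_cm, 0,
                        wiggle = params$wiggle * 0.5, droop_cm = 3,
                        step = step)
  n_tap <- nrow(tap_xy)
  tap_w <- seq(w_tap, 0.35 * w_tap, length.out = n_tap)
  segments <- list(list(xy = tap_xy, w = tap_w, order = "tap"))

  nl <- params$n_laterals
  if (nl > 0) {
    tap_fine <- resample_polyline(tap_xy, tap_w, 0.05)
    occ <- list(x = tap_fine$x, y = tap_fine$y, r = tap_fine$w / 20)

    # free endpoints need a wider berth than strand bodies: anything
    # overrunning a tip erases it from the rendered mask; the tap tip
    # counts too
    ttz <- tap_fine$s > tap_fine$total - 0.25
    occ_tips <- list(x = tap_fine$x[ttz], y = tap_fine$y[ttz],
                     r = tap_fine$w[ttz] / 20)

    z0 <- 0.4
    z1 <- max(z0 + 0.1, params$tap_length_cm - 0.4)
    spacing <- (z1 - z0) / nl
    pos <- z0 + (seq_len(nl) - 0.5) * spacing +
      rnorm(nl, 0, 0.15 * spacing)
    pos <- sort(pmin(z1, pmax(z0, pos)))
    sides <- rep(c(-1, 1), length.out = nl)

    ang_par <- params$insertion_angle_deg
    len_par <- params$lateral_length_cm
    # neighbouring laterals on a side share a developmental angle
    # gradient; correlated angles also keep dense systems placeable
    ang_state <- c(ang_par$mean, ang_par$mean)

    for (i in seq_len(nl)) {
      s_i <- pos[i]
      origin <- c(stats::approx(tap_fine$s, tap_fine$x, s_i)$y,
                  stats::approx(tap_fine$s, tap_fine$y, s_i)$y)
      tap_r_here <- stats::approx(tap_fine$s, tap_fine$w, s_i)$y / 20
      depth_scale <- 1.5 - s_i / params$tap_length_cm  # acropetal: upper longer
      placed <- NULL
      side_ix <- if (sides[i] < 0) 1L else 2L
      for (try in seq_len(100)) {
        ang_draw <- 0.6 * ang_state[side_ix] +
          0.4 * rnorm(1, ang_par$mean, ang_par$sd) +
          rnorm(1, 0, 0.4 * ang_par$sd)
        ang <- sides[i] * min(85, max(20, ang_draw))
        len <- max(len_par$min,
                   rnorm(1, len_par$mean * depth_scale, len_par$sd))
        xy <- grow_strand(origin, len, ang, wiggle = params$wiggle,
                          droop_cm = 5, step = step)
        fine <- resample_polyline(xy, rep(w_lat, nrow(xy)), 0.05)
        excl <- (tap_r_here + w_lat / 20 + 0.06) /
          max(abs(sin(ang * pi / 180)), 0.25) + 0.05
        chk <- fine$s > excl
        # 0.03 cm edge-to-edge clearance keeps strands separable at
        # 50 px/cm while letting ~200 laterals fit on a 20 cm tap
        viol <- first_violation(fine$x[chk], fine$y[chk],
                                rep(w_lat / 20, sum(chk)),
                                occ$x, occ$y, occ$r, gap = 0.03)
        tip_hit <- first_violation(fine$x, fine$y,
                                   rep(w_lat / 20, length(fine$x)),
                                   occ_tips$x, occ_tips$y, occ_tips$r,
                                   gap = 0.05)
        if (viol == 0L && tip_hit == 0L) {
          placed <- list(xy = xy, fine = fine, excl = excl)
          break
        }
        if (viol == 0L) viol <- max(1L, sum(chk))
        if (try == 100L) {
          # truncate before the collision, then keep cutting until the
          # whole remaining path (tip included) clears with an extra
          # margin -- converging strands can stay near-touching long
          # before the formal violation point
          s_cut <- fine$s[chk][viol] - 0.25
          for (cut_try in 1:10) {
            if (s_cut < max(excl, 0.4)) break
            keep <- fine$s <= s_cut
            xy2 <- cbind(fine$x[keep], fine$y[keep])
            f2 <- resample_polyline(xy2, rep(w_lat, nrow(xy2)), 0.05)
            # body up to the first violation already cleared the normal
            # gap; the free tip needs a wider berth so it stays a
            # distinct endpoint after rasterisation
            tipz <- f2$s > max(excl, s_cut - 0.3)
            v2 <- first_violation(f2$x[tipz], f2$y[tipz],
                                  rep(w_lat / 20, sum(tipz)),
                                  occ$x, occ$y, occ$r, gap = 0.08)
            v3 <- first_violation(f2$x, f2$y,
                                  rep(w_lat / 20, length(f2$x)),
                                  occ_tips$x, occ_tips$y, occ_tips$r,
                                  gap = 0.05)
            if (v2 == 0L && v3 == 0L) {
              placed <- list(xy = xy2, fine = f2, excl = excl)
              break
            }
            if (v3 > 0L && f2$s[v3] <= max(excl, s_cut - 0.3)) break # unfixable
            s_cut <- min(if (v2 > 0L) f2$s[tipz][v2] else Inf,
                         if (v3 > 0L) f2$s[v3] else Inf) - 0.25
          }
        }
      }
      if (is.null(placed)) next
      ang_state[side_ix] <- abs(ang)
      n_v <- nrow(placed$xy)
      w_v <- seq(w_lat, 0.5 * w_lat, length.out = n_v)
      segments[[length(segments) + 1L]] <-
        list(xy = placed$xy, w = w_v, order = "lateral")
      keep <- placed$fine$s > placed$excl
      occ$x <- c(occ$x, placed$fine$x[keep])
      occ$y <- c(occ$y, placed$fine$y[keep])
      occ$r <- c(occ$r, rep(w_lat / 20, sum(keep)))
      tz <- placed$fine$s > placed$fine$total - 0.25
      occ_tips$x <- c(occ_tips$x, placed$fine$x[tz])
      occ_tips$y <- c(occ_tips$y, placed$fine$y[tz])
      occ_tips$r <- c(occ_tips$r, rep(w_lat / 20, sum(tz)))
    }
  }

  model <- structure(list(segments = segments, junction = c(0, 0),
                          params = params, truth = NULL),
                     class = "root_model")
  model$truth <- truth_traits(model)
  model
}

#' @export
print.root_model <- function(x, ...) {
  nlat <- sum(vapply(x$segments, function(s) s$order == "lateral", TRUE))
  cat(sprintf("<root_model> tap %.1f cm, %d laterals (seed %d)\n",
              x$params$tap_length_cm, nlat, x$params$seed))
  cat("truth: "); print(x$truth)
  invisible(x)
}

# --- analytic ground-truth traits -------------------------------------

#' Analytic trait record of a synthetic root model
#'
#' Computes the 12 root traits directly from the model geometry,
#' independently of any rendering or image analysis. Length-derived
#' traits use a cylinder model over finely resampled polylines
#' (TSA = pi * sum(d * l), TRV = pi/4 * sum(d^2 * l), DIM the
#' length-weighted mean diameter). Projected-area traits (SOL, COPM) use
#' a high-resolution rasterization of the strands so that overlap at
#' branch points is counted once, as in a real image; the raster
#' resolution is independent of, and much finer than, the measurement
#' pipeline's.
#'
#' @param model A `root_model`.
#' @param raster_ppcm Resolution of the area rasterization (pixels/cm).
#' @return A [trait_record].
#' @export
truth_traits <- function(model, raster_ppcm = 120) {
  segs <- model$segments
  if (length(segs) == 0) stopf("model has no segments")

  fine <- lapply(segs, function(s) resample_polyline(s$xy, s$w, 0.02))
  # per sub-segment midpoint quantities
  ell <- unlist(lapply(fine, function(f) diff(f$s)))
  dmm <- unlist(lapply(fine, function(f) (f$w[-1] + f$w[-length(f$w)]) / 2))
  ym  <- unlist(lapply(fine, function(f) (f$y[-1] + f$y[-length(f$y)]) / 2))

  TRL <- sum(ell)
  TSA <- pi * sum(dmm / 10 * ell)
  TRV <- pi / 4 * sum((dmm / 10)^2 * ell)
  DIM <- sum(dmm * ell) / TRL
  TSA1 <- pi * sum((dmm / 10 * ell)[dmm < 0.5])
  TSA3 <- pi * sum((dmm / 10 * ell)[dmm >= 1.0 & dmm < 1.5])
  TRT <- sum(vapply(segs, function(s) s$order == "lateral", TRUE)) + 1

  # width and convex hull from edge-offset points
  px <- unlist(lapply(fine, function(f) f$x))
  py <- unlist(lapply(fine, function(f) f$y))
  pr <- unlist(lapply(fine, function(f) f$w / 20))
  offs <- lapply(fine, function(f) {
    n <- length(f$x)
    dx <- diff(f$x); dy <- diff(f$y)
    h <- sqrt(dx^2 + dy^2); h[h == 0] <- 1
    nx <- c(-dy / h, -dy[n - 1] / h[n - 1])
    ny <- c(dx / h, dx[n - 1] / h[n - 1])
    r <- f$w / 20
    list(x = c(f$x + nx * r, f$x - nx * r),
         y = c(f$y + ny * r, f$y - ny * r))
  })
  hx <- c(unlist(lapply(offs, `[[`, "x")))
  hy <- c(unlist(lapply(offs, `[[`, "y")))
  TRW <- max(hx) - min(hx)
  hull <- chull(hx, hy)
  TCA <- poly_area(hx[hull], hy[hull])

  jy <- model$junction[2]
  depth <- max(py + pr) - jy
  below <- ym > jy + depth / 3
  RDI <- sum((dmm / 10 * ell)[below]) / sum(dmm / 10 * ell)

  # rasterized projected area and centre of mass; sample spacing must be
  # well below one raster pixel or the stroke edges scallop
  ppcm <- raster_ppcm
  rfine <- lapply(segs, function(s) resample_polyline(s$xy, s$w, 0.2 / ppcm))
  rx <- unlist(lapply(rfine, function(f) f$x))
  ry <- unlist(lapply(rfine, function(f) f$y))
  rr <- unlist(lapply(rfine, function(f) f$w / 20))
  x0 <- min(px - pr) - 2 / ppcm; y0 <- min(py - pr) - 2 / ppcm
  W <- ceiling((max(px + pr) - x0) * ppcm) + 4L
  H <- ceiling((max(py + pr) - y0) * ppcm) + 4L
  cov <- stamp_disks_cpp(matrix(0, H, W),
                         (rx - x0) * ppcm, (ry - y0) * ppcm, rr * ppcm)
  m <- cov >= 0.5
  area_cm2 <- sum(m) / ppcm^2
  rows <- row(m)[m]
  COPM <- mean(rows) / ppcm + y0 - jy
  SOL <- area_cm2 / TCA

  trait_record(TRL = TRL, TSA = TSA, DIM = DIM, TRV = TRV, TRT = TRT,
               TSA1 = TSA1, TSA3 = TSA3, TRW = TRW, TCA = TCA,
               RDI = RDI, SOL = SOL, COPM = COPM)
}

# --- scene rendering ---------------------------------------------------

#' Parameters of a rendered pouch scene
#'
#' Controls the rasterization of a root model into an 8-bit RGB pouch
#' image: geometry scale, brightness levels, sensor noise, the number and
#' size of bright debris particles ("root debris and dust") scattered on
#' the background, and an optional meniscus halo along root edges that
#' emulates imaging in air rather than submerged in water.
#'
#' @param image_size_px Integer c(height, width) of the image.
#' @param pixels_per_cm Image scale (> 0). 50 px/cm resolves a 0.55 mm
#'   lateral as a ~3 px stroke.
#' @param background_level,root_brightness 8-bit grey levels of the dark
#'   filter-paper background and of root strokes; brightness must exceed
#'   background.
#' @param noise_sd Gaussian pixel noise standard deviation (grey levels).
#' @param debris_count Number of debris particles to scatter.
#' @param debris_area_px c(min, max) particle area in pixels. Particles
#'   are placed disjoint from the root system so that, if not filtered,
#'   each one contributes exactly one false root tip.
#' @param meniscus_halo Logical; add the in-air meniscus artifact: a
#'   half-bright rim of `halo_width_px` around every root plus small
#'   bright protrusions sprouting from root edges.
#' @param halo_width_px Width of the halo rim in pixels.
#' @param margin_top_cm Depth of the root/shoot junction below the top
#'   image edge.
#' @param seed Integer seed for noise, debris and halo placement.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size_px = c(1250L, 1000L),
                         pixels_per_cm = 50,
                         background_level = 25,
                         root_brightness = 215,
                         noise_sd = 5,
                         debris_count = 30L,
                         debris_area_px = c(4, 40),
                         meniscus_halo = FALSE,
                         halo_width_px = 2L,
                         margin_top_cm = 1,
                         seed = 1L) {
  if (pixels_per_cm <= 0) stopf("pixels_per_cm must be > 0")
  if (root_brightness <= background_level)
    stopf("root_brightness must exceed background_level")
  if (noise_sd < 0 || debris_count < 0) stopf("negative noise/debris")
  if (length(debris_area_px) != 2 || any(debris_area_px <= 0) ||
      debris_area_px[2] < debris_area_px[1])
    stopf("debris_area_px must be an increasing positive range")
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixels_per_cm = as.numeric(pixels_per_cm),
    background_level = background_level,
    root_brightness = root_brightness,
    noise_sd = noise_sd,
    debris_count = as.integer(debris_count),
    debris_area_px = debris_area_px,
    meniscus_halo = isTRUE(meniscus_halo),
    halo_width_px = as.integer(halo_width_px),
    margin_top_cm = margin_top_cm,
    seed = as.integer(seed)
  ), class = "scene_params")
}

#' Render a root model as a pouch image
#'
#' Roots are drawn as anti-aliased bright strokes of width
#' `diameter_mm / 10 * pixels_per_cm`; debris as bright blobs disjoint
#' from the root mask; optional meniscus halo along root edges; then
#' Gaussian noise is added and the image clipped to 0-255. Deterministic
#' for a given model and scene seed.
#'
#' @param model A `root_model`.
#' @param scene A [scene_params()] object.
#' @return A list of class `pouch_scene`: `image` (a [pouch_image]),
#'   `debris` (manifest data.frame with centroid and area of every
#'   particle), `root_mask` (the true, artifact-free root pixel mask)
#'   and `junction_px` (c(row, col) of the root/shoot junction).
#' @export
render_scene <- function(model, scene = scene_params()) {
  if (!inherits(scene, "scene_params")) scene <- do.call(scene_params, scene)
  with_seed(scene$seed, render_scene_impl(model, scene))
}

render_scene_impl <- function(model, scene) {
  H <- scene$image_size_px[1]; W <- scene$image_size_px[2]
  ppcm <- scene$pixels_per_cm
  jrow <- scene$margin_top_cm * ppcm
  jcol <- W / 2

  fine <- lapply(model$segments, function(s)
    resample_polyline(s$xy, s$w, 0.25 / ppcm))
  x_px <- unlist(lapply(fine, function(f) jcol + f$x * ppcm))
  y_px <- unlist(lapply(fine, function(f) jrow + f$y * ppcm))
  r_px <- unlist(lapply(fine, function(f) f$w / 20 * ppcm))

  if (any(x_px - r_px < 1) || any(x_px + r_px > W) ||
      any(y_px - r_px < 1) || any(y_px + r_px > H))
    warnf("model extends beyond the image and will be clipped")

  cov <- stamp_disks_cpp(matrix(0, H, W), x_px, y_px, r_px)
  root_mask <- cov >= 0.5

  halo <- NULL
  if (scene$meniscus_halo) {
    droot <- sqrt(edt_sq_cpp(!root_mask))
    ring <- droot > 0 & droot <= scene$halo_width_px
    # bright protrusions sprouting from the root edge
    bidx <- which(droot > 0 & droot <= 1.5)
    npro <- min(length(bidx), max(10L, round(length(bidx) / 120)))
    prot <- matrix(0, H, W)
    if (npro > 0) {
      pick <- sample(bidx, npro)
      pr_ <- ((pick - 1) %% H) + 1
      pc_ <- ((pick - 1) %/% H) + 1
      th <- runif(npro, 0, 2 * pi)
      len <- runif(npro, 7, 12)
      sx <- c(); sy <- c(); sr <- c()
      for (k in seq_len(npro)) {
        t <- seq(0, len[k], by = 0.5)
        sx <- c(sx, pc_[k] + t * cos(th[k]))
        sy <- c(sy, pr_[k] + t * sin(th[k]))
        sr <- c(sr, rep(1.1, length(t)))
      }
      prot <- stamp_disks_cpp(prot, sx, sy, sr)
    }
    halo <- list(ring = ring, prot = prot)
  }

  # debris disjoint from the root system (and from the halo, if any)
  manifest <- data.frame(row = numeric(0), col = numeric(0),
                         radius_px = numeric(0), area_px = numeric(0))
  dcov <- matrix(0, H, W)
  if (scene$debris_count > 0) {
    avoid <- root_mask
    if (!is.null(halo)) avoid <- avoid | halo$ring | (halo$prot >= 0.5)
    dclear <- sqrt(edt_sq_cpp(!avoid))   # distance to nearest root pixel
    for (k in seq_len(scene$debris_count)) {
      area <- runif(1, scene$debris_area_px[1], scene$debris_area_px[2])
      rd <- sqrt(area / pi)
      ok <- FALSE
      for (try in 1:200) {
        rr <- runif(1, rd + 2, H - rd - 2)
        cc <- runif(1, rd + 2, W - rd - 2)
        if (dclear[round(rr), round(cc)] <= rd + 4) next
        if (nrow(manifest) > 0 &&
            any(sqrt((manifest$row - rr)^2 + (manifest$col - cc)^2) <
                rd + manifest$radius_px + 3)) next
        ok <- TRUE
        break
      }
      if (!ok) next
      dcov <- stamp_disks_cpp(dcov, cc, rr, rd)
      manifest <- rbind(manifest, data.frame(row = rr, col = cc,
                                             radius_px = rd,
                                             area_px = pi * rd^2))
    }
  }

  bg <- scene$background_level
  fg <- scene$root_brightness
  val <- bg + (fg - bg) * pmax(cov, dcov)
  if (!is.null(halo)) {
    val <- pmax(val, bg + (fg - bg) * halo$prot)
    val[halo$ring] <- pmax(val[halo$ring], bg + 0.55 * (fg - bg))
  }
  if (scene$noise_sd > 0)
    val <- val + rnorm(length(val), 0, scene$noise_sd)
  val <- round(pmin(255, pmax(0, val)))

  px <- array(0L, dim = c(H, W, 3))
  px[, , 1] <- val; px[, , 2] <- val; px[, , 3] <- val
  img <- pouch_image(px, pixels_per_cm = ppcm,
                     id = sprintf("synth-seed%d", scene$seed))
  structure(list(image = img, debris = manifest, root_mask = root_mask,
                 junction_px = c(row = jrow, col = jcol),
                 model = model, scene = scene),
            class = "pouch_scene")
}
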