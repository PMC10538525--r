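test_that("skeletonization of simple shapes has the expected topology", {
  # 5-px-wide horizontal bar -> a single path with 2 endpoints
  m <- matrix(FALSE, 30, 120)
  m[13:17, 10:109] <- TRUE
  sk <- skeletonize(m, min_spur_px = 5)
  expect_length(sk$endpoints, 2)
  expect_length(sk$branchpoints, 0)
  expect_length(rootpouch:::skeleton_paths_cpp(sk$skel), 1)
  # plus sign -> 4 endpoints around 1 branch point
  p <- matrix(FALSE, 61, 61)
  p[29:33, 11:51] <- TRUE
  p[11:51, 29:33] <- TRUE
  skp <- skeletonize(p, min_spur_px = 5)
  expect_length(skp$endpoints, 4)
  expect_gte(length(skp$branchpoints), 1)
  expect_error(skeletonize(matrix(FALSE, 5, 5)), "no foreground")
})

test_that("skeleton radius tracks the half width of a bar", {
  m <- matrix(FALSE, 30, 200)
  m[11:19, 20:180] <- TRUE            # 9 px wide
  sk <- skeletonize(m, 5)
  interior <- sk$coords[, 2] > 40 & sk$coords[, 2] < 160
  expect_true(all(abs(sk$radius_px[interior] - 4.5) <= 0.5))
})

test_that("spur pruning removes short side-spurs, keeps real branches", {
  m <- matrix(FALSE, 40, 120)
  m[20, 10:110] <- TRUE
  m[17:19, 60] <- TRUE                # 3-px spur off the path
  sk <- skeletonize(m, min_spur_px = 5)
  expect_length(sk$endpoints, 2)
  m[5:19, 80] <- TRUE                 # 15-px genuine branch
  sk2 <- skeletonize(m, min_spur_px = 5)
  expect_length(sk2$endpoints, 3)
})

test_that("junction detection: topmost pixel with deterministic ties", {
  m <- matrix(FALSE, 50, 50)
  m[10:40, 25] <- TRUE
  expect_equal(unname(detect_junction(m)), c(10, 25))
  # two top pixels equidistant from the centroid column -> smaller col
  m2 <- matrix(FALSE, 20, 20)
  m2[5, c(8, 12)] <- TRUE
  m2[6:15, 10] <- TRUE
  expect_equal(unname(detect_junction(m2)), c(5, 8))
  expect_error(detect_junction(matrix(FALSE, 3, 3)), "no foreground")
})

test_that("tip counting excludes the collar", {
  m <- matrix(FALSE, 100, 30)
  m[10:90, 15] <- TRUE
  sk <- skeletonize(m, 5)
  expect_equal(count_tips(sk, detect_junction(m)), 1)
  mod <- generate_model(tiny_model(n_laterals = 5, seed = 13))
  sc <- render_scene(mod, tiny_scene(seed = 13, debris_count = 0,
                                     noise_sd = 0))
  sk2 <- skeletonize(sc$root_mask, 5)
  expect_equal(count_tips(sk2, detect_junction(sc$root_mask)), 6)
})

test_that("debris inflates raw tip counts; cleaning restores truth", {
  mod <- generate_model(tiny_model(n_laterals = 5, seed = 14))
  sc <- render_scene(mod, tiny_scene(seed = 14, debris_count = 10,
                                     noise_sd = 0))
  cl <- clean_image(sc$image, cleaning_config(min_area_px = 50))
  tips_raw <- count_tips(skeletonize(cl$raw_mask, 5),
                         detect_junction(cl$raw_mask))
  tips_cln <- count_tips(skeletonize(cl$cleaned_mask, 5),
                         detect_junction(cl$cleaned_mask))
  truth <- unname(mod$truth["TRT"])
  expect_equal(tips_cln, truth)
  # each particle contributes one or two false tips (disks can thin to a
  # short two-endpoint path), never fewer
  expect_gte(tips_raw, truth + 10)
  expect_lte(tips_raw, truth + 20)
})

test_that("morphology on calibration bars matches closed forms", {
  # 101 axial skeleton px at 100 px/cm -> 1.00 cm
  m <- matrix(FALSE, 20, 140)
  m[10, 10:110] <- TRUE
  sk <- skeletonize(m, 0)
  mor <- measure_morphology(sk, 100)
  expect_equal(mor$TRL, 1.00, tolerance = 0.01)
  expect_error(measure_morphology(sk, -1), "scale")
  # uniform bar of true diameter 1.2 mm at 50 px/cm: single class 3
  b <- matrix(FALSE, 40, 300)
  b[15:20, 20:280] <- TRUE
  mb <- measure_morphology(skeletonize(b, 5), 50)
  expect_gt(mb$TSA3 / mb$TSA, 0.95)
  expect_lt(mb$TSA1 / mb$TSA, 0.05)
  expect_equal(mb$DIM, 1.2, tolerance = 0.15)
})

test_that("diameter classes partition TSA", {
  mod <- generate_model(tiny_model(n_laterals = 6, seed = 15))
  sc <- render_scene(mod, tiny_scene(seed = 15, debris_count = 0))
  sk <- skeletonize(sc$root_mask, 5)
  mor <- measure_morphology(sk, 50)
  classes <- tsa_by_class(sk, 50)
  expect_equal(sum(classes$TSA), mor$TSA, tolerance = 1e-9)
  expect_equal(classes$TSA[classes$d_min == 0], mor$TSA1, tolerance = 1e-9)
})

test_that("architecture on reference shapes", {
  # solid rectangle: hull equals region, solidity exactly 1
  m <- matrix(FALSE, 60, 60)
  m[20:39, 15:44] <- TRUE
  sk <- skeletonize(m, 5)
  arc <- measure_architecture(m, sk, detect_junction(m), 50)
  expect_equal(arc$SOL, 1.0, tolerance = 1e-9)
  expect_equal(arc$TRW, 30 / 50)
  # uniform vertical bar, 10 cm from the junction
  b <- matrix(FALSE, 600, 40)
  b[51:550, 18:22] <- TRUE
  skb <- skeletonize(b, 5)
  arcb <- measure_architecture(b, skb, detect_junction(b), 50)
  expect_equal(arcb$COPM, 5.0, tolerance = 0.02)
  expect_equal(arcb$RDI, 2 / 3, tolerance = 0.03)
  # single-pixel mask: degenerate hull
  s <- matrix(FALSE, 10, 10); s[5, 5] <- TRUE
  expect_error(measure_architecture(s, skeletonize(s, 0), c(5, 5), 50),
               "degenerate hull")
})

test_that("RDI is 1 when all root length lies below the one-third line", {
  m <- matrix(FALSE, 400, 60)
  m[10, 30] <- TRUE                   # junction speck, zero length
  m[300:390, 28:32] <- TRUE           # all mass deep down
  sk <- skeletonize(m, 5)
  arc <- measure_architecture(m, sk, detect_junction(m), 50)
  expect_equal(arc$RDI, 1)
})

test_that("convex area matches the gift-wrapping + shoelace oracle", {
  set.seed(31)
  for (i in 1:5) {
    cov <- matrix(0, 80, 80)
    cov <- rootpouch:::stamp_disks_cpp(cov, runif(6, 15, 65),
                                       runif(6, 15, 65), runif(6, 3, 10))
    m <- cov >= 0.5
    sk <- skeletonize(m, 5)
    arc <- measure_architecture(m, sk, detect_junction(m), 1)
    idx <- which(m)
    rows <- ((idx - 1) %% nrow(m)) + 1
    cols <- ((idx - 1) %/% nrow(m)) + 1
    cx <- rep(cols, each = 4) + c(-0.5, -0.5, 0.5, 0.5)
    cy <- rep(rows, each = 4) + c(-0.5, 0.5, -0.5, 0.5)
    h <- giftwrap_hull(cx, cy)
    expect_equal(arc$TCA, shoelace(cx[h], cy[h]), tolerance = 1e-9)
  }
})

test_that("solidity drops when the same root area spreads wider", {
  narrow <- matrix(FALSE, 100, 100)
  narrow[10:90, c(40, 50, 60)] <- TRUE
  wide <- matrix(FALSE, 100, 100)
  wide[10:90, c(10, 50, 90)] <- TRUE
  skn <- skeletonize(narrow, 5); skw <- skeletonize(wide, 5)
  sn <- measure_architecture(narrow, skn, detect_junction(narrow), 50)$SOL
  sw <- measure_architecture(wide, skw, detect_junction(wide), 50)$SOL
  expect_gt(sn, sw)
})

test_that("measure_all is deterministic and validates input", {
  mod <- generate_model(tiny_model(seed = 16))
  sc <- render_scene(mod, tiny_scene(seed = 16, debris_count = 5))
  r1 <- measure_all(sc$image)
  r2 <- measure_all(sc$image)
  expect_equal(unclass(r1), unclass(r2))
  expect_equal(attr(r1, "stage"), "cleaned")
  expect_error(measure_all(matrix(FALSE, 10, 10), pixels_per_cm = 50),
               "no foreground")
  expect_error(measure_all(matrix(TRUE, 4, 4)), "pixels_per_cm")
  expect_true(r1["RDI"] >= 0 && r1["RDI"] <= 1)
  expect_true(r1["SOL"] > 0 && r1["SOL"] <= 1)
})

test_that("adding a disjoint component never decreases TRT, TRL, TCA", {
  mod <- generate_model(tiny_model(seed = 17))
  sc <- render_scene(mod, tiny_scene(seed = 17, debris_count = 0))
  m <- sc$root_mask
  m2 <- m
  m2[420:440, 320:340] <- TRUE
  r <- measure_all(m, pixels_per_cm = 50)
  r2 <- measure_all(m2, pixels_per_cm = 50)
  expect_gte(r2["TRT"], r["TRT"])
  expect_gte(r2["TRL"], r["TRL"])
  expect_gte(r2["TCA"], r["TCA"])
})

test_that("scale-robust traits change little when resolution doubles", {
  mod <- generate_model(tiny_model(n_laterals = 4, seed = 18))
  sc50 <- render_scene(mod, tiny_scene(seed = 18, debris_count = 0,
                                       noise_sd = 0))
  sc100 <- render_scene(mod, scene_params(
    image_size_px = c(900L, 700L), pixels_per_cm = 100,
    margin_top_cm = 0.6, seed = 18, debris_count = 0, noise_sd = 0))
  r50 <- measure_all(clean_image(sc50$image,
                                 default_cleaning_config(50))$cleaned_mask,
                     pixels_per_cm = 50)
  r100 <- measure_all(clean_image(sc100$image,
                                  default_cleaning_config(100))$cleaned_mask,
                      pixels_per_cm = 100)
  for (k in c("TRL", "TRT", "COPM", "RDI", "TCA", "TRW")) {
    expect_lt(abs(r100[k] - r50[k]) / max(abs(r50[k]), 1e-9), 0.02,
              label = sprintf("trait %s at double resolution", k))
  }
})
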