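test_that("the clinical schema reproduces the published partition", {
  sch <- landmark_schema()
  expect_identical(nrow(sch), 46L)
  expect_identical(sum(sch$laterality == "left"), 16L)
  expect_identical(sum(sch$laterality == "right"), 16L)
  expect_identical(sum(sch$laterality == "midline"), 14L)
  expect_identical(as.integer(table(sch$group)[c("dental", "facial-surgery",
                                                 "skeletal")]),
                   c(12L, 9L, 25L))
  expect_identical(sch$mirror_id[sch$id == "PoL"], "PoR")
  expect_identical(sch$mirror_id[sch$id == "UIAR"], "UIAL")
  expect_true(is.na(sch$mirror_id[sch$id == "S"]))
  expect_false(anyDuplicated(sch$id) > 0)
  # toy subset
  expect_identical(nrow(landmark_schema("toy8")), 8L)
})

test_that("TLS plane fitting is exact on coplanar points", {
  pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), rep(5, 4))
  fit <- fit_plane_tls(pts)
  expect_equal(abs(fit$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit$centroid, c(0.5, 0.5, 5))
  # three points define their plane exactly
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1))
  f3 <- fit_plane_tls(tri)
  expect_lt(max(abs((tri - rep(1, 3) %o% f3$centroid) %*% f3$normal)), 1e-12)
  expect_error(fit_plane_tls(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
  expect_error(fit_plane_tls(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))),
               "collinear")
})

test_that("TLS plane normals agree with an SVD oracle on noisy point sets", {
  set.seed(11)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    base <- random_rotation()
    pts <- cbind(rnorm(n, sd = 20), rnorm(n, sd = 15),
                 rnorm(n, sd = 0.05)) %*% t(base) +
      rep(1, n) %o% rnorm(3, sd = 30)
    fit <- fit_plane_tls(pts)
    sv <- svd(sweep(pts, 2, colMeans(pts)))
    oracle <- sv$v[, 3]
    expect_lt(min(sqrt(sum((fit$normal - oracle)^2)),
                  sqrt(sum((fit$normal + oracle)^2))), 1e-9)
  }
})

test_that("the Frankfort frame matches a constructed planar configuration", {
  lms <- landmark_set(list(PoL = c(40, -60, 0), PoR = c(-40, -60, 0),
                           OrL = c(30, 10, 0), OrR = c(-30, 10, 0),
                           N = c(0, 20, 30)), schema = "clinical46")
  fr <- frankfort_frame(lms)
  expect_equal(fr$superior, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$anterior, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$lateral, c(-1, 0, 0), tolerance = 1e-12)
  # translation invariance of the axes
  up <- transform_landmarks(lms, translation = c(0, 0, 7))
  fr2 <- frankfort_frame(up)
  expect_equal(fr2$superior, fr$superior, tolerance = 1e-12)
  expect_equal(fr2$anterior, fr$anterior, tolerance = 1e-12)
  expect_equal(fr2$fh_point, fr$fh_point + c(0, 0, 7), tolerance = 1e-12)
  # orthonormal triad
  M <- cbind(fr$superior, fr$anterior, fr$lateral)
  expect_lt(max(abs(crossprod(M) - diag(3))), 1e-9)
})

test_that("the Frankfort frame is equivariant under rotation", {
  lms <- full46_landmarks()
  fr <- frankfort_frame(lms)
  set.seed(12)
  for (rep in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 25)
    moved <- transform_landmarks(lms, R, t)
    fr2 <- frankfort_frame(moved)
    expect_equal(fr2$superior, as.numeric(R %*% fr$superior),
                 tolerance = 1e-9)
    expect_equal(fr2$anterior, as.numeric(R %*% fr$anterior),
                 tolerance = 1e-9)
    expect_equal(fr2$lateral, as.numeric(R %*% fr$lateral),
                 tolerance = 1e-9)
  }
})

test_that("frame preconditions: visible-point minimum and orientation", {
  lms <- full46_landmarks()
  drop1 <- lms
  drop1$coords["PoL", ] <- NA # 3 points remain: still a frame
  expect_s3_class(frankfort_frame(drop1), "anatomical_frame")
  drop2 <- drop1
  drop2$coords["OrL", ] <- NA # 2 points: degenerate
  expect_error(frankfort_frame(drop2), "fewer than 3")
  noN <- lms
  noN$coords["N", ] <- NA
  expect_error(frankfort_frame(noN), "Nasion")
})

test_that("three-point and plane angles evaluate classical cases", {
  expect_equal(three_point_angle(c(0, 10, 0), c(0, 0, 0), c(10, 0, 0)), 90)
  expect_equal(three_point_angle(c(-3, 0, 0), c(0, 0, 0), c(5, 0, 0)), 180)
  expect_equal(three_point_angle(c(1, 0, 0), c(0, 0, 0), c(1, 1, 0)), 45,
               tolerance = 1e-9)
  expect_error(three_point_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
  expect_equal(plane_angle(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(plane_angle(c(0, 0, 1), c(0, 0, -1)), 0)
  a <- 10 * pi / 180
  expect_equal(plane_angle(c(0, 0, 1), c(0, sin(a), cos(a))), 10,
               tolerance = 1e-9)
  expect_error(plane_angle(c(0, 0, 2), c(0, 0, 1)), "unit")
})

test_that("point-to-point measures follow their endpoint definitions", {
  lms <- landmark_set(list(CoL = c(0, 0, 0), Gn = c(3, 4, 0),
                           PoL = c(40, -60, 0), PoR = c(-40, -60, 0),
                           OrL = c(30, 10, 0), OrR = c(-30, 10, 0),
                           N = c(0, 20, 30)), "clinical46")
  rep <- measure_all(lms)
  row <- rep[rep$id == "left_effective_mandibular_length", ]
  expect_true(row$available)
  expect_equal(row$value, 5.0)
  expect_false(rep$available[rep$id == "anterior_facial_height"])
})

test_that("a horizontal mandible gives a zero mandibular plane angle", {
  lms <- landmark_set(list(PoL = c(40, -60, 0), PoR = c(-40, -60, 0),
                           OrL = c(30, 10, 0), OrR = c(-30, 10, 0),
                           N = c(0, 20, 30), Me = c(0, -80, -40),
                           GoL = c(-40, -50, -40), GoR = c(40, -50, -40)),
                      "clinical46")
  rep <- measure_all(lms)
  expect_equal(rep$value[rep$id == "mandibular_plane_angle"], 0,
               tolerance = 1e-9)
  expect_equal(rep$value[rep$id == "frankfort_horizontal_angle"], 0,
               tolerance = 1e-9)
})

test_that("vector components equal hand-computed projections on the template", {
  lms <- full46_landmarks()
  rep <- measure_all(lms)
  expect_true(all(rep$available))
  fr <- frankfort_frame(lms)
  co <- lms$coords
  expect_equal(rep$value[rep$id == "nasion_perpendicular_to_A"],
               sum((co["A", ] - co["N", ]) * fr$anterior), tolerance = 1e-9)
  expect_equal(rep$value[rep$id == "pogonion_to_nasion_perpendicular"],
               sum((co["Pog", ] - co["N", ]) * fr$anterior),
               tolerance = 1e-9)
  expect_equal(rep$value[rep$id == "left_upper_incisor_A_vertical"],
               sum((co["UIEL", ] - co["A", ]) * fr$anterior),
               tolerance = 1e-9)
  # lower-incisor offset: hand-computed point-line distance with sign
  dvec <- co["Pog", ] - co["A", ]
  dvec <- dvec / sqrt(sum(dvec^2))
  v <- co["LIER", ] - co["A", ]
  perp <- v - sum(v * dvec) * dvec
  expected <- sign(sum(perp * fr$anterior)) * sqrt(sum(perp^2))
  expect_equal(rep$value[rep$id == "right_lower_incisor_to_A_pogonion"],
               expected, tolerance = 1e-9)
  # SNA / SNB / difference
  expect_equal(rep$value[rep$id == "SNA"],
               three_point_angle(co["S", ], co["N", ], co["A", ]))
  expect_equal(rep$value[rep$id == "SNA_minus_SNB"],
               rep$value[rep$id == "SNA"] - rep$value[rep$id == "SNB"])
})

test_that("all measures except the true-horizontal angle are rigid-motion invariant", {
  lms <- full46_landmarks()
  base <- measure_all(lms)
  set.seed(13)
  for (rep_i in 1:20) {
    R <- random_rotation()
    moved <- transform_landmarks(lms, R, rnorm(3, sd = 30))
    rep2 <- measure_all(moved)
    keep <- base$id != "frankfort_horizontal_angle"
    expect_equal(rep2$value[keep], base$value[keep], tolerance = 1e-6)
  }
})

test_that("mirroring swaps left/right measures and fixes midline ones", {
  lms <- full46_landmarks()
  m <- lms$coords
  m[, 1] <- 120 - m[, 1] # reflect through the midsagittal plane x = 60
  sch <- landmark_schema()
  mirrored <- m
  for (i in seq_len(nrow(sch)))
    if (!is.na(sch$mirror_id[i]))
      mirrored[sch$id[i], ] <- m[sch$mirror_id[i], ]
  ml <- landmark_set(mirrored, "clinical46")
  a <- measure_all(lms)
  b <- measure_all(ml)
  swap <- function(id) sub("^left_", "right_",
                           sub("^right_", "left_", id))
  for (i in seq_len(nrow(a))) {
    j <- match(swap(a$id[i]), b$id)
    expect_equal(b$value[j], a$value[i], tolerance = 1e-9,
                 label = paste("measure", a$id[i]))
  }
})

test_that("absence propagates to measures without failing the report", {
  lms <- full46_landmarks()
  lms$coords[c("PoL", "OrL"), ] <- NA # frame impossible
  rep <- measure_all(lms)
  expect_false(any(rep$available[rep$type == "vector-component"]))
  expect_false(rep$available[rep$id == "frankfort_horizontal_angle"])
  # point-to-point and SNA-type measures survive
  expect_true(rep$available[rep$id == "anterior_facial_height"])
  expect_true(rep$available[rep$id == "SNA"])
  expect_identical(nrow(rep), 16L)
})
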