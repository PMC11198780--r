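#' Total-least-squares plane fit
#'
#' Fits the plane minimizing the sum of squared orthogonal distances to the
#' points: the plane passes through the centroid and its unit normal is the
#' eigenvector of the centered second-moment matrix with the smallest
#' eigenvalue.
#'
#' @param points n x 3 matrix (n >= 3) of world coordinates.
#' @return `list(centroid =, normal =)` with a unit-length normal (sign
#'   arbitrary).
#' @examples
#' pts <- cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), rep(5, 4))
#' fit_plane_tls(pts)$normal # (0, 0, +/-1)
#' @export
fit_plane_tls <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L)
    stop("degenerate geometry: need at least 3 points for a plane fit",
         call. = FALSE)
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  e <- eigen(crossprod(x), symmetric = TRUE)
  # collinear points leave two near-zero eigenvalues
  scale2 <- max(e$values[1], .Machine$double.eps)
  if (e$values[2] / scale2 < 1e-12)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  n <- e$vectors[, 3]
  list(centroid = unname(ctr), normal = unname(n / sqrt(sum(n^2))))
}

#' Anatomical reference frame from the Frankfort horizontal plane
#'
#' The Frankfort horizontal (FH) plane is the total-least-squares fit
#' through the *visible* Porions and Orbitales (at least three of PoL, PoR,
#' OrL, OrR). The frame axes are: `superior`, the FH normal signed so that
#' Nasion lies on the positive side; `anterior`, the unit in-plane
#' component of the vector from the Porion midpoint to the Orbitale
#' midpoint (ear toward orbit); and `lateral = superior x anterior`,
#' completing a right-handed triad.
#'
#' @param landmarks a [landmark_set()] containing at least three of
#'   PoL/PoR/OrL/OrR plus N.
#' @return An object of class `anatomical_frame` with fields `fh_point`
#'   (plane centroid), `superior`, `anterior`, `lateral`.
#' @export
frankfort_frame <- function(landmarks) {
  po <- intersect(c("PoL", "PoR"), present_ids(landmarks))
  or <- intersect(c("OrL", "OrR"), present_ids(landmarks))
  pts_ids <- c(po, or)
  if (length(pts_ids) < 3L)
    stop("frame error: fewer than 3 of PoL/PoR/OrL/OrR are present",
         call. = FALSE)
  if (!lm_has(landmarks, "N"))
    stop("frame error: Nasion required to orient the frame", call. = FALSE)
  pts <- landmarks$coords[pts_ids, , drop = FALSE]
  fit <- fit_plane_tls(pts)
  sup <- fit$normal
  if (sum((lm_coord(landmarks, "N") - fit$centroid) * sup) < 0) sup <- -sup
  mid_po <- colMeans(landmarks$coords[po, , drop = FALSE])
  mid_or <- colMeans(landmarks$coords[or, , drop = FALSE])
  a <- mid_or - mid_po
  a <- a - sum(a * sup) * sup
  na <- sqrt(sum(a^2))
  if (na < 1e-9)
    stop("frame error: anterior axis degenerate (Orbitale midpoint ",
         "coincides with Porion midpoint in the FH plane)", call. = FALSE)
  ant <- a / na
  lat <- c(sup[2] * ant[3] - sup[3] * ant[2],
           sup[3] * ant[1] - sup[1] * ant[3],
           sup[1] * ant[2] - sup[2] * ant[1])
  structure(list(fh_point = unname(fit$centroid), superior = unname(sup),
                 anterior = unname(ant), lateral = unname(lat)),
            class = "anatomical_frame")
}

#' Angle at a vertex between two rays
#'
#' Classical three-point cephalometric angle (e.g. SNA is the angle at
#' Nasion between the rays toward Sella and toward the A point), in
#' degrees, in `[0, 180]`.
#'
#' @param p,q,r world coordinates; the angle is measured at `q`.
#' @return Angle in degrees.
#' @examples
#' three_point_angle(c(0, 10, 0), c(0, 0, 0), c(10, 0, 0)) # 90
#' @export
three_point_angle <- function(p, q, r) {
  u <- p - q
  v <- r - q
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: zero-length ray in three-point angle",
         call. = FALSE)
  acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1)) * 180 / pi
}

#' Unsigned angle between two planes
#'
#' `acos(|n1 . n2|)` in degrees, in `[0, 90]`; antiparallel normals give 0.
#' Inputs within 1e-6 of unit length are normalized silently.
#'
#' @param n1,n2 plane normals.
#' @return Angle in degrees.
#' @export
plane_angle <- function(n1, n2) {
  norm1 <- sqrt(sum(n1^2)); norm2 <- sqrt(sum(n2^2))
  if (abs(norm1 - 1) > 1e-6 || abs(norm2 - 1) > 1e-6)
    stop("plane_angle expects unit normals (within 1e-6)", call. = FALSE)
  acos(pmin(abs(sum((n1 / norm1) * (n2 / norm2))), 1)) * 180 / pi
}

MEASURE_TABLE <- data.frame(
  id = c("anterior_facial_height",
         "left_effective_mandibular_length",
         "left_effective_midfacial_length",
         "right_effective_mandibular_length",
         "right_effective_midfacial_length",
         "nasion_perpendicular_to_A",
         "pogonion_to_nasion_perpendicular",
         "right_upper_incisor_A_vertical",
         "left_upper_incisor_A_vertical",
         "right_lower_incisor_to_A_pogonion",
         "left_lower_incisor_to_A_pogonion",
         "frankfort_horizontal_angle",
         "mandibular_plane_angle",
         "SNA", "SNB", "SNA_minus_SNB"),
  name = c("Anterior facial height",
           "Left effective mandibular length",
           "Left effective midfacial length",
           "Right effective mandibular length",
           "Right effective midfacial length",
           "Nasion perpendicular to point A",
           "Pogonion to Nasion perpendicular",
           "Right Upper Incisor point A vertical",
           "Left Upper Incisor point A vertical",
           "Right Lower Incisor to point A-pogonion line",
           "Left Lower Incisor to point A-pogonion line",
           "Frankfort horizontal plane",
           "Mandibular plane angle",
           "SNA", "SNB", "SNA - SNB"),
  type = c(rep("point-to-point", 5), rep("vector-component", 6),
           rep("plane-angle", 5)),
  units = c(rep("mm", 11), rep("degrees", 5)),
  stringsAsFactors = FALSE)

#' The 16 cephalometric characteristic measures
#'
#' Computes all 16 measures from a landmark set, flagging a measure
#' unavailable (value NA) whenever a required landmark — or the Frankfort
#' frame it depends on — is missing. Three families:
#'
#' * point-to-point distances (mm): anterior facial height `|ANS - Me|`,
#'   left/right effective mandibular length `|Co - Gn|`, left/right
#'   effective midfacial length `|Co - A|`;
#' * vector components (mm), projections on the Frankfort-frame anterior
#'   axis: `(A - N) . anterior`, `(Pog - N) . anterior`, upper-incisor
#'   offsets `(UIE - A) . anterior`, and the signed perpendicular offset of
#'   each lower incisor edge from the A-Pogonion line (sign taken along
#'   the anterior axis);
#' * plane angles (degrees): SNA, SNB, their signed difference, the
#'   mandibular plane angle (plane through Menton and both Gonions versus
#'   the FH plane), and the angle between the FH plane and the true
#'   horizontal.
#'
#' All measures are invariant under rigid motion of the landmark set except
#' the Frankfort-horizontal angle, which references the scanner's axial
#' plane through `true_horizontal`.
#'
#' @param landmarks a [landmark_set()] (clinical schema, or any schema
#'   containing the needed ids).
#' @param true_horizontal unit normal of the scanner axial plane in world
#'   coordinates (default `c(0, 0, 1)`).
#' @return A `ceph_report`: data frame with one row per measure (`id`,
#'   `name`, `type`, `units`, `value`, `available`, `inputs`).
#' @export
measure_all <- function(landmarks, true_horizontal = c(0, 0, 1)) {
  frame <- tryCatch(frankfort_frame(landmarks), error = function(e) NULL)
  res <- MEASURE_TABLE
  res$value <- NA_real_
  res$available <- FALSE
  res$inputs <- ""
  co <- landmarks$coords
  setm <- function(id, value, inputs) {
    i <- match(id, res$id)
    res$value[i] <<- value
    res$available[i] <<- TRUE
    res$inputs[i] <<- paste(inputs, collapse = "+")
  }
  p2p <- function(id, a, b) {
    if (lm_has(landmarks, c(a, b)))
      setm(id, sqrt(sum((co[a, ] - co[b, ])^2)), c(a, b))
  }
  p2p("anterior_facial_height", "ANS", "Me")
  p2p("left_effective_mandibular_length", "CoL", "Gn")
  p2p("right_effective_mandibular_length", "CoR", "Gn")
  p2p("left_effective_midfacial_length", "CoL", "A")
  p2p("right_effective_midfacial_length", "CoR", "A")

  if (!is.null(frame)) {
    ant <- frame$anterior
    vc <- function(id, from, to) {
      if (lm_has(landmarks, c(from, to)))
        setm(id, sum((co[to, ] - co[from, ]) * ant), c(from, to))
    }
    vc("nasion_perpendicular_to_A", "N", "A")
    vc("pogonion_to_nasion_perpendicular", "N", "Pog")
    vc("right_upper_incisor_A_vertical", "A", "UIER")
    vc("left_upper_incisor_A_vertical", "A", "UIEL")
    li <- function(id, lie) {
      if (lm_has(landmarks, c("A", "Pog", lie))) {
        dvec <- co["Pog", ] - co["A", ]
        dvec <- dvec / sqrt(sum(dvec^2))
        v <- co[lie, ] - co["A", ]
        perp <- v - sum(v * dvec) * dvec
        val <- sqrt(sum(perp^2))
        sgn <- sum(perp * ant)
        setm(id, if (sgn < 0) -val else val, c(lie, "A", "Pog"))
      }
    }
    li("right_lower_incisor_to_A_pogonion", "LIER")
    li("left_lower_incisor_to_A_pogonion", "LIEL")

    setm("frankfort_horizontal_angle",
         plane_angle(frame$superior,
                     true_horizontal / sqrt(sum(true_horizontal^2))),
         c("PoL", "PoR", "OrL", "OrR"))
    if (lm_has(landmarks, c("Me", "GoL", "GoR"))) {
      mp <- tryCatch(fit_plane_tls(co[c("Me", "GoL", "GoR"), ]),
                     error = function(e) NULL)
      if (!is.null(mp))
        setm("mandibular_plane_angle", plane_angle(mp$normal, frame$superior),
             c("Me", "GoL", "GoR"))
    }
  }

  sna <- snb <- NULL
  if (lm_has(landmarks, c("S", "N", "A"))) {
    sna <- three_point_angle(co["S", ], co["N", ], co["A", ])
    setm("SNA", sna, c("S", "N", "A"))
  }
  if (lm_has(landmarks, c("S", "N", "B"))) {
    snb <- three_point_angle(co["S", ], co["N", ], co["B", ])
    setm("SNB", snb, c("S", "N", "B"))
  }
  if (!is.null(sna) && !is.null(snb))
    setm("SNA_minus_SNB", sna - snb, c("S", "N", "A", "B"))

  structure(res, class = c("ceph_report", "data.frame"),
            frame_available = !is.null(frame), schema_version = "1")
}

#' @export
print.ceph_report <- function(x, ...) {
  cat("<ceph_report> 16 cephalometric characteristic measures\n")
  df <- as.data.frame(x)
  df$value <- round(df$value, 2)
  print(df[, c("name", "type", "value", "units", "available")],
        row.names = FALSE)
  invisible(x)
}

#' Write a cephalometric report to CSV or JSON
#'
#' @param report a [measure_all()] result.
#' @param path output path (`.csv` or `.json`).
#' @export
write_report <- function(report, path) {
  df <- as.data.frame(report)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
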