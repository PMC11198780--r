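#' The clinical 46-landmark cephalometric schema
#'
#' Sixteen bilaterally symmetric landmark pairs (32 points, ids suffixed `L`
#' and `R`) plus fourteen midline landmarks. Each definition carries the
#' anatomical name, laterality, the clinical group used for reporting
#' (dental, facial-surgery, or skeletal), and the contralateral mirror id
#' where one exists.
#'
#' @param name schema name: `"clinical46"` (default) or `"toy8"`, an
#'   8-landmark midline/mandible subset used by the phantom benchmark.
#' @return A data frame with columns `id`, `name`, `laterality`, `group`,
#'   `mirror_id` (NA for midline landmarks).
#' @examples
#' nrow(landmark_schema())            # 46
#' table(landmark_schema()$group)
#' @export
landmark_schema <- function(name = "clinical46") {
  switch(name,
         clinical46 = schema_clinical46(),
         toy8 = schema_clinical46()[match(TOY8_IDS, schema_clinical46()$id), ],
         stop("unknown schema: ", name, call. = FALSE))
}

TOY8_IDS <- c("N", "S", "A", "B", "Pog", "Me", "GoL", "GoR")

# Bilateral base codes with full names; expanded to <code>L / <code>R.
# Groups follow the clinical reporting partition: 12 dental, 9
# facial-surgery, 25 skeletal entries.
schema_clinical46 <- function() {
  bil <- data.frame(
    code = c("Co", "FInf", "FMan", "FMen", "FPal", "Go", "J", "LIA",
             "LIE", "LMol", "Or", "PcmU", "Po", "UIA", "UIE", "UMol"),
    name = c("Condylion", "Foramen Infraorbitale", "Foramen Mandibulae",
             "Foramen Mentale", "Foramen Palatinum major", "Gonion",
             "Jugale", "Lower Incisor Apex", "Lower Incisor Edge",
             "Lower Molar", "Orbitale", "Crestal point between molars, upper",
             "Porion", "Upper Incisor Apex", "Upper Incisor Edge",
             "Upper Molar"),
    group = c("skeletal", "facial-surgery", "facial-surgery",
              "facial-surgery", "facial-surgery", "skeletal", "skeletal",
              "dental", "dental", "dental", "skeletal", "dental",
              "skeletal", "dental", "skeletal", "skeletal"),
    stringsAsFactors = FALSE)
  mid <- data.frame(
    id = c("A", "ANS", "B", "Ba", "CLI", "CUI", "FI", "Gn", "Me", "N",
           "PNS", "Pog", "S", "SM"),
    name = c("Subspinale", "Anterior Nasal Spine", "Supramentale", "Basion",
             "Center of lower incisors", "Center of upper incisors",
             "Foramen Incisivum", "Gnathion", "Menton", "Nasion",
             "Posterior Nasal Spine", "Pogonion", "Sella Turcica",
             "Spina Mentalis"),
    group = c("skeletal", "skeletal", "skeletal", "skeletal", "dental",
              "dental", "facial-surgery", "skeletal", "skeletal", "skeletal",
              "skeletal", "skeletal", "skeletal", "skeletal"),
    stringsAsFactors = FALSE)
  left <- data.frame(id = paste0(bil$code, "L"),
                     name = paste(bil$name, "Left"),
                     laterality = "left", group = bil$group,
                     mirror_id = paste0(bil$code, "R"),
                     stringsAsFactors = FALSE)
  right <- data.frame(id = paste0(bil$code, "R"),
                      name = paste(bil$name, "Right"),
                      laterality = "right", group = bil$group,
                      mirror_id = paste0(bil$code, "L"),
                      stringsAsFactors = FALSE)
  midline <- data.frame(id = mid$id, name = mid$name, laterality = "midline",
                        group = mid$group, mirror_id = NA_character_,
                        stringsAsFactors = FALSE)
  out <- rbind(left, right, midline)
  rownames(out) <- NULL
  out
}

schema_ids <- function(schema) {
  if (is.character(schema) && length(schema) == 1L &&
      schema %in% c("clinical46", "toy8"))
    landmark_schema(schema)$id
  else
    as.character(schema)
}

#' Landmark coordinate sets
#'
#' A `landmark_set` maps every landmark id of a schema to a world coordinate
#' in mm or marks it absent (NA row). Both ground-truth annotations and
#' model predictions use this container.
#'
#' @param coords named n x 3 numeric matrix of world mm coordinates (rows may
#'   be all-NA for absent landmarks), or a named list of length-3 vectors /
#'   NULLs. Ids not in the schema are rejected.
#' @param schema schema name (`"clinical46"`, `"toy8"`) or a character vector
#'   of ids defining a custom schema.
#' @param confidence optional named numeric vector of per-landmark decoder
#'   confidences.
#' @return An object of class `landmark_set` with fields `coords` (full
#'   schema-ordered matrix, NA rows for absent) and `schema`.
#' @examples
#' lms <- landmark_set(list(N = c(0, 85, 30), S = c(0, 55, 40)),
#'                     schema = "toy8")
#' present_ids(lms)
#' @export
landmark_set <- function(coords, schema = "clinical46", confidence = NULL) {
  ids <- schema_ids(schema)
  if (is.list(coords)) {
    m <- matrix(NA_real_, length(ids), 3, dimnames = list(ids, c("x", "y", "z")))
    for (id in names(coords)) {
      if (!id %in% ids)
        stop("unknown landmark id for this schema: ", id, call. = FALSE)
      if (!is.null(coords[[id]])) m[id, ] <- as.numeric(coords[[id]])
    }
    coords <- m
  } else {
    coords <- as.matrix(coords)
    if (is.null(rownames(coords)))
      stop("coords matrix must have landmark ids as rownames", call. = FALSE)
    bad <- setdiff(rownames(coords), ids)
    if (length(bad))
      stop("unknown landmark id(s) for this schema: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(rownames(coords)))
      stop("duplicate landmark id(s) in coords", call. = FALSE)
    m <- matrix(NA_real_, length(ids), 3, dimnames = list(ids, c("x", "y", "z")))
    m[rownames(coords), ] <- coords
    coords <- m
  }
  pres <- stats::complete.cases(coords)
  if (any(!is.finite(coords[pres, ])))
    stop("present landmark coordinates must be finite", call. = FALSE)
  partial <- rowSums(is.na(coords)) %in% c(1L, 2L)
  if (any(partial))
    stop("landmark(s) with partially missing coordinates: ",
         paste(rownames(coords)[partial], collapse = ", "), call. = FALSE)
  structure(list(coords = coords,
                 schema = if (is.character(schema) && length(schema) == 1L)
                   schema else as.character(schema),
                 confidence = confidence),
            class = "landmark_set")
}

#' @rdname landmark_set
#' @param x a `landmark_set`.
#' @export
present_ids <- function(x) {
  rownames(x$coords)[stats::complete.cases(x$coords)]
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d/%d landmarks present (schema %s)\n",
              length(present_ids(x)), nrow(x$coords),
              if (length(x$schema) == 1L) x$schema else "custom"))
  invisible(x)
}

lm_coord <- function(set, id) {
  v <- set$coords[id, ]
  if (any(is.na(v))) NULL else v
}

lm_has <- function(set, ids) {
  all(ids %in% rownames(set$coords)) &&
    all(stats::complete.cases(set$coords[ids, , drop = FALSE]))
}

#' Apply a rigid (or general affine) motion to all landmarks
#'
#' Utility used by augmentation, the phantom generator, and invariance
#' tests: `x -> R x + t` applied to every present landmark.
#'
#' @param set a [landmark_set()].
#' @param rotation 3x3 matrix.
#' @param translation length-3 vector (mm).
#' @param center optional rotation center (mm); default origin.
#' @return The transformed `landmark_set`.
#' @export
transform_landmarks <- function(set, rotation = diag(3),
                                translation = c(0, 0, 0),
                                center = c(0, 0, 0)) {
  m <- set$coords
  pres <- stats::complete.cases(m)
  if (any(pres)) {
    p <- t(m[pres, , drop = FALSE]) - center
    m[pres, ] <- t(rotation %*% p + center + translation)
  }
  out <- set
  out$coords <- m
  out
}
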