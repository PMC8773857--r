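# Image normalization, despeckling, and the ten annotation-aware
# augmentation scenarios (A1-A10) with their eight dataset assemblies
# (D1-D8). Geometric scenarios transform the ground-truth mask through the
# same map as the pixels and return the axis-aligned hull of the warped
# mask; filter scenarios leave the annotation untouched.

#' Normalize and center-crop a frame
#'
#' Center-crops to the target size, then min-max normalizes to `[0, 255]`
#' (a constant image maps to 0 by the package-wide degenerate-range
#' convention).
#'
#' @param image Numeric matrix with both dimensions >= the target unless
#'   `pad = TRUE`.
#' @param target `c(height, width)`, default 600 x 700.
#' @param pad If `TRUE`, smaller inputs are symmetric-reflection padded up
#'   to the target instead of erroring.
#' @return 8-bit matrix of size `target`.
#' @export
normalize_crop <- function(image, target = c(600L, 700L), pad = FALSE) {
  nr <- nrow(image); nc <- ncol(image)
  if ((nr < target[1] || nc < target[2]) && !pad) {
    abort(sprintf(
      "input %d x %d is smaller than the %d x %d target; set pad = TRUE to reflect-pad",
      nr, nc, target[1], target[2]))
  }
  if (nr < target[1] || nc < target[2]) {
    ridx <- reflect_index(seq_len(max(nr, target[1])) -
                            floor((max(0, target[1] - nr)) / 2), nr)
    cidx <- reflect_index(seq_len(max(nc, target[2])) -
                            floor((max(0, target[2] - nc)) / 2), nc)
    image <- image[ridx, cidx, drop = FALSE]
    nr <- nrow(image); nc <- ncol(image)
  }
  r0 <- floor((nr - target[1]) / 2)
  c0 <- floor((nc - target[2]) / 2)
  out <- image[(r0 + 1):(r0 + target[1]), (c0 + 1):(c0 + target[2]), drop = FALSE]
  rescale_8bit(out)
}

#' The augmentation scenario table
#'
#' @return Tibble with scenario `id`, a short `description`, whether the
#'   scenario is `spatial` (geometric) and the exact number of images
#'   `n_images` it produces from one input.
#' @export
aug_scenarios <- function() {
  tibble(
    id = paste0("A", 1:10),
    description = c(
      "flips about the origin, x-axis and y-axis",
      "rotations by 45, 90, 135 degrees, both directions",
      "original + 3 flips sheared by 5..30 degrees, both axes, both signs",
      "diagonal translations by 10% of width and height",
      "single-level UDWT (coif2), all four subbands",
      "exponential derivative", "Laplacian-of-Gaussian derivative",
      "logarithmic derivative", "squared derivative", "square-root derivative"
    ),
    spatial = c(TRUE, TRUE, TRUE, TRUE, rep(FALSE, 6)),
    n_images = c(3L, 6L, 96L, 4L, 4L, 1L, 1L, 1L, 1L, 1L)
  )
}

#' The dataset assembly table
#'
#' @return Tibble with dataset `id`, the scenario ids it includes, and the
#'   per-input-image multiplier (the sum of its scenarios' counts).
#' @export
dataset_specs <- function() {
  spatial <- paste0("A", 1:4)
  specs <- list(
    D1 = paste0("A", 1:10),
    D2 = c(spatial, "A5"), D3 = c(spatial, "A6"), D4 = c(spatial, "A8"),
    D5 = c(spatial, "A7"), D6 = spatial, D7 = c(spatial, "A10"),
    D8 = c(spatial, "A9")
  )
  counts <- setNames(aug_scenarios()$n_images, aug_scenarios()$id)
  tibble(
    id = names(specs),
    scenarios = unname(specs),
    multiplier = vapply(specs, function(s) sum(counts[s]), integer(1),
                        USE.NAMES = FALSE)
  )
}

# ---- geometric primitives ---------------------------------------------------

flip_image <- function(img, about = c("origin", "x", "y")) {
  about <- match.arg(about)
  switch(about,
    origin = img[rev(seq_len(nrow(img))), rev(seq_len(ncol(img))), drop = FALSE],
    x = img[rev(seq_len(nrow(img))), , drop = FALSE],
    y = img[, rev(seq_len(ncol(img))), drop = FALSE]
  )
}

rotation_matrix <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

shear_matrix <- function(deg, axis = c("x", "y")) {
  axis <- match.arg(axis)
  s <- tan(deg * pi / 180)
  if (axis == "x") matrix(c(1, 0, s, 1), 2, 2) else matrix(c(1, s, 0, 1), 2, 2)
}

# Warp an image (reflection fill) and its mask (zero fill) through the same
# linear map; the inverse-mapped source coordinates are computed once and
# shared. Returns list(image, mask).
warp_pair <- function(img, mask, A, t = c(0, 0)) {
  nr <- nrow(img); nc <- ncol(img)
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  Ai <- solve(A)
  xs <- rep(seq_len(nc), each = nr)  # column-major destination grid
  ys <- rep.int(seq_len(nr), nc)
  dx <- xs - cx - t[1]; dy <- ys - cy - t[2]
  sx <- Ai[1, 1] * dx + Ai[1, 2] * dy + cx
  sy <- Ai[2, 1] * dx + Ai[2, 2] * dy + cy
  wi <- matrix(interp_points(img, sy, sx), nr, nc)
  # image pixels outside the source frame come from symmetric reflection;
  # the mask instead is zero-filled there so no phantom lesion copies arise
  inside <- sx >= 0.5 & sx <= nc + 0.5 & sy >= 0.5 & sy <= nr + 0.5
  wm_vals <- mask[cbind(reflect_index(as.integer(round(sy)), nr),
                        reflect_index(as.integer(round(sx)), nc))]
  wm <- matrix(wm_vals & inside, nr, nc)
  list(image = round(pmin(pmax(wi, 0), 255)), mask = wm)
}

# ---- filtered derivatives ---------------------------------------------------

#' Pointwise and multiresolution filter derivatives of an image
#'
#' Intensities are rescaled to `[0, 1]` before any pointwise nonlinearity
#' and the result is min-max mapped back to 8-bit, keeping every derivative
#' in a common display range. `UDWT-coif2` returns all four single-level
#' undecimated subbands.
#'
#' @param image 8-bit matrix.
#' @param kind One of `"EXP"`, `"LN"`, `"LoG"`, `"SQUARED"`, `"SQRT"`,
#'   `"UDWT-coif2"`.
#' @param log_sigma Gaussian scale for the `LoG` kind, pixels.
#' @return List of one 8-bit matrix (four for `UDWT-coif2`).
#' @export
derive_filtered <- function(image, kind, log_sigma = 2) {
  kind <- match.arg(kind, c("EXP", "LN", "LoG", "SQUARED", "SQRT", "UDWT-coif2"))
  x <- rescale01(image)
  out <- switch(kind,
    EXP = list((exp(x) - 1) / (exp(1) - 1)),
    LN = list(log1p(x)),
    SQUARED = list(x^2),
    SQRT = list(sqrt(x)),
    LoG = list(log_response(image, log_sigma)),
    `UDWT-coif2` = unname(udwt2(image, "coif2"))
  )
  lapply(out, rescale_8bit)
}

# ---- scenarios --------------------------------------------------------------

#' Apply one augmentation scenario to an annotated image
#'
#' @param annotated An `annotated_image`, or a list with at least `image`
#'   (8-bit matrix) and either `gt_mask` or `gt_box`.
#' @param scenario Scenario id `"A1"` .. `"A10"`.
#' @return Tibble with one row per output: `scenario`, `variant` (a short
#'   tag), `image` (list-column of 8-bit matrices) and the transformed
#'   ground-truth box columns `x`, `y`, `w`, `h` (the axis-aligned hull of
#'   the transformed mask for geometric scenarios; the input box unchanged
#'   for filter scenarios; `NA` if the lesion left the frame entirely).
#' @export
apply_scenario <- function(annotated, scenario) {
  scenario <- match.arg(scenario, paste0("A", 1:10))
  img <- annotated$image
  mask <- annotated$gt_mask
  if (is.null(mask)) {
    if (is.null(annotated$gt_box)) abort("annotated input needs gt_mask or gt_box")
    mask <- box_to_mask(annotated$gt_box, dim(img))
  }
  box0 <- bbox_from_mask(mask)

  emit <- function(tag, image, mask = NULL, box = NULL) {
    if (is.null(box)) {
      box <- if (!is.null(mask) && any(mask)) bbox_from_mask(mask) else NULL
    }
    tibble(
      scenario = scenario, variant = tag, image = list(image),
      x = box$x %||% NA_real_, y = box$y %||% NA_real_,
      w = box$w %||% NA_real_, h = box$h %||% NA_real_
    )
  }

  if (scenario == "A1") {
    return(purrr::map_dfr(c("origin", "x", "y"), function(ab) {
      emit(paste0("flip_", ab), flip_image(img, ab), flip_image(mask, ab))
    }))
  }
  if (scenario == "A2") {
    angs <- c(45, 90, 135)
    return(purrr::map_dfr(c(angs, -angs), function(a) {
      wp <- warp_pair(img, mask, rotation_matrix(a))
      emit(sprintf("rot_%+d", a), wp$image, wp$mask)
    }))
  }
  if (scenario == "A3") {
    bases <- list(none = list(i = img, m = mask),
                  origin = list(i = flip_image(img, "origin"),
                                m = flip_image(mask, "origin")),
                  x = list(i = flip_image(img, "x"), m = flip_image(mask, "x")),
                  y = list(i = flip_image(img, "y"), m = flip_image(mask, "y")))
    grid <- expand.grid(base = names(bases), ang = c(5, 10, 15, 20, 25, 30),
                        axis = c("x", "y"), sign = c(1, -1),
                        stringsAsFactors = FALSE)
    return(purrr::pmap_dfr(grid, function(base, ang, axis, sign) {
      b <- bases[[base]]
      wp <- warp_pair(b$i, b$m, shear_matrix(sign * ang, axis))
      emit(sprintf("shear_%s_%s%+d", base, axis, sign * ang), wp$image, wp$mask)
    }))
  }
  if (scenario == "A4") {
    dx <- round(0.1 * ncol(img)); dy <- round(0.1 * nrow(img))
    moves <- list(rd = c(dx, dy), ru = c(dx, -dy), lu = c(-dx, -dy),
                  ld = c(-dx, dy))
    return(purrr::imap_dfr(moves, function(mv, tag) {
      ti <- translate_reflect(img, mv[1], mv[2])
      # zero-fill translation for the mask
      tm <- matrix(FALSE, nrow(mask), ncol(mask))
      src_r <- seq_len(nrow(mask)) - mv[2]
      src_c <- seq_len(ncol(mask)) - mv[1]
      okr <- src_r >= 1 & src_r <= nrow(mask)
      okc <- src_c >= 1 & src_c <= ncol(mask)
      tm[okr, okc] <- mask[src_r[okr], src_c[okc]]
      emit(paste0("trans_", tag), ti, tm)
    }))
  }
  # filter scenarios: annotation unchanged
  kind <- switch(scenario, A5 = "UDWT-coif2", A6 = "EXP", A7 = "LoG",
                 A8 = "LN", A9 = "SQUARED", A10 = "SQRT")
  outs <- derive_filtered(img, kind)
  tags <- if (scenario == "A5") paste0("udwt_", c("LL", "LH", "HL", "HH")) else
    tolower(kind)
  purrr::map2_dfr(outs, tags, function(im, tag) emit(tag, im, box = box0))
}

#' Assemble an augmented training set from a dataset spec
#'
#' Applies every scenario of the chosen assembly to every input image. The
#' output size is exactly `length(images) * multiplier` for the spec's
#' multiplier (see [dataset_specs()]).
#'
#' @param images List of `annotated_image` objects (or compatible lists).
#' @param spec Dataset id `"D1"` .. `"D8"`, or a character vector of
#'   scenario ids.
#' @param dir Optional output directory; when given, each augmented image
#'   is written as `<id>__<scenario>__<k>.png` with a matching VOC XML.
#' @param ids Optional image identifiers (default `img_001` ...).
#' @return Tibble with columns `image_id`, `scenario`, `variant`, `image`
#'   (list-column, dropped when `dir` is given to keep memory flat), `x`,
#'   `y`, `w`, `h` and (if written) `path`.
#' @export
assemble_dataset <- function(images, spec, dir = NULL, ids = NULL) {
  scen <- if (length(spec) == 1 && grepl("^D[1-8]$", spec)) {
    specs <- dataset_specs()
    specs$scenarios[[match(spec, specs$id)]]
  } else {
    match.arg(spec, paste0("A", 1:10), several.ok = TRUE)
  }
  ids <- ids %||% sprintf("img_%03d", seq_along(images))
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  purrr::map2_dfr(images, ids, function(im, id) {
    rows <- purrr::map_dfr(scen, function(s) apply_scenario(im, s))
    rows <- dplyr::mutate(rows, image_id = id,
                          k = dplyr::row_number(), .before = 1)
    if (!is.null(dir)) {
      rows$path <- purrr::pmap_chr(
        list(rows$image, rows$scenario, rows$k, rows$x, rows$y, rows$w, rows$h),
        function(imx, s, k, x, y, w, h) {
          base <- sprintf("%s__%s__%03d", id, s, k)
          p <- file.path(dir, paste0(base, ".png"))
          png::writePNG(imx / 255, p)
          bx <- if (is.na(x)) list() else list(bbox(x, y, w, h))
          voc_write(file.path(dir, paste0(base, ".xml")), base, dim(imx), bx)
          p
        })
      rows$image <- NULL
    }
    rows
  })
}
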