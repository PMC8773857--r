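# Synthetic B-mode-like speckle phantoms with ground truth. The generator
# emulates the kind of single-lesion ultrasound frames the pipeline is
# designed for: multiplicative Rayleigh speckle over a piecewise-constant
# echogenicity map, smooth elliptical iso/hyperechoic benign lesions vs
# spiculated hypoechoic heterogeneous malignant ones, and a small panel of
# simulated annotators drawing slightly jittered ground-truth boxes.

#' Parameters of one synthetic lesion phantom
#'
#' @param label `"benign"` or `"malignant"`.
#' @param seed Integer seed; the phantom is a pure function of its params.
#' @param height,width Frame size in pixels (default 600 x 700).
#' @param lesion_center `(row, col)` center in pixels, or `NULL` to draw it.
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels, or `NULL` to draw.
#' @param spiculation_amplitude Margin perturbation as a fraction of the
#'   local radius; 0 for benign (smooth margin), default 0.25 for malignant.
#' @param echo_contrast Lesion-minus-background intensity offset in gray
#'   levels; default +20 (benign, iso/hyperechoic) or -40 (malignant,
#'   hypoechoic).
#' @param heterogeneity_sd Within-lesion echotexture standard deviation in
#'   gray levels; default 5 (benign) or 20 (malignant).
#' @param speckle_scale Fraction of full Rayleigh speckle modulation in
#'   `[0, 1]`; 1 gives the full multiplicative Rayleigh field, 0 disables
#'   speckle.
#' @return A `phantom_params` list, validated.
#' @export
phantom_params <- function(label,
                           seed,
                           height = 600L,
                           width = 700L,
                           lesion_center = NULL,
                           semi_axes = NULL,
                           spiculation_amplitude = if (label == "malignant") 0.25 else 0,
                           echo_contrast = if (label == "malignant") -40 else 20,
                           heterogeneity_sd = if (label == "malignant") 20 else 5,
                           speckle_scale = 1) {
  label <- match.arg(label, c("benign", "malignant"))
  if (label == "benign" && spiculation_amplitude != 0) {
    abort("benign lesions must have spiculation_amplitude = 0")
  }
  if (label == "malignant" && spiculation_amplitude <= 0) {
    abort("malignant lesions must have spiculation_amplitude > 0")
  }
  p <- list(
    height = as.integer(height), width = as.integer(width), label = label,
    lesion_center = lesion_center, semi_axes = semi_axes,
    spiculation_amplitude = spiculation_amplitude,
    echo_contrast = echo_contrast, heterogeneity_sd = heterogeneity_sd,
    speckle_scale = speckle_scale, seed = as.integer(seed)
  )
  class(p) <- "phantom_params"
  p
}

# Draw any unset geometry from the phantom's own seed, then check margins.
resolve_geometry <- function(p) {
  withr::with_seed(child_seed(p$seed, 1L), {
    if (is.null(p$semi_axes)) {
      lo <- 0.08 * min(p$height, p$width)
      hi <- 0.16 * min(p$height, p$width)
      p$semi_axes <- runif(2, lo, hi)
    }
    maxr <- max(p$semi_axes) * (1 + p$spiculation_amplitude)
    if (is.null(p$lesion_center)) {
      p$lesion_center <- c(
        runif(1, maxr + 6, p$height - maxr - 6),
        runif(1, maxr + 6, p$width - maxr - 6)
      )
    }
  })
  maxr <- max(p$semi_axes) * (1 + p$spiculation_amplitude)
  ctr <- p$lesion_center
  if (ctr[1] - maxr < 5 || ctr[1] + maxr > p$height - 5 ||
      ctr[2] - maxr < 5 || ctr[2] + maxr > p$width - 5) {
    abort(sprintf(
      "lesion does not fit in the frame: center (%.0f, %.0f), max radius %.0f needs a 5-pixel margin in a %d x %d frame",
      ctr[1], ctr[2], maxr, p$height, p$width))
  }
  p
}

#' Generate one annotated speckle phantom
#'
#' Deterministic for fixed parameters: the same `phantom_params` always
#' yields bit-identical pixels, mask and boxes. The lesion margin is a
#' radially perturbed ellipse `r(theta) = r0(theta) * (1 + A sin(k theta +
#' phi))` with the lobe count `k` drawn from 5..9, giving benign phantoms a
#' smooth margin (`A = 0`) and malignant ones a spiculated margin.
#'
#' @param params A [phantom_params()] object.
#' @param n_annotators Number of simulated readers drawing a ground-truth
#'   box (default 3).
#' @param annotator_jitter_sd Annotator box jitter in normalized units
#'   (default 0.02).
#' @return An `annotated_image`: list with `image` (8-bit matrix), `gt_mask`
#'   (logical matrix), `gt_box` (`bbox`, the tight box of the mask), `label`,
#'   `annotator_boxes` (list of `bbox`) and `params`.
#' @export
generate_phantom <- function(params, n_annotators = 3L,
                             annotator_jitter_sd = 0.02) {
  stopifnot(inherits(params, "phantom_params"))
  p <- resolve_geometry(params)
  h <- p$height; w <- p$width
  a <- p$semi_axes[1]; b <- p$semi_axes[2]
  ctr <- p$lesion_center

  img <- withr::with_seed(p$seed, {
    k_lobes <- sample(5:9, 1)
    phi <- runif(1, 0, 2 * pi)

    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    dy <- rows - ctr[1]; dx <- cols - ctr[2]
    r <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    # polar radius of the ellipse with semi-axes (a along rows, b along cols)
    r0 <- (a * b) / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
    rim <- r0 * (1 + p$spiculation_amplitude * sin(k_lobes * theta + phi))
    mask <- r <= rim

    echo <- matrix(110, h, w)
    echo[mask] <- 110 + p$echo_contrast
    if (p$heterogeneity_sd > 0) {
      tex <- gaussian_blur(matrix(rnorm(h * w), h, w), 3)
      tex <- tex / sd(tex) * p$heterogeneity_sd
      echo[mask] <- echo[mask] + tex[mask]
    }

    # multiplicative Rayleigh speckle, unit mean, blended by speckle_scale
    u <- matrix(runif(h * w), h, w)
    ray <- sqrt(-2 * log(pmax(u, .Machine$double.eps)))
    mult <- (1 - p$speckle_scale) + p$speckle_scale * ray / sqrt(pi / 2)
    smoothed <- gaussian_blur(echo * mult, 1.5)
    list(img = rescale_8bit(smoothed), mask = mask)
  })

  gt_box <- bbox_from_mask(img$mask)
  ann <- emulate_annotators(gt_box, n_users = n_annotators,
                            jitter_sd = annotator_jitter_sd,
                            seed = child_seed(p$seed, 2L), dims = c(h, w))
  structure(
    list(image = img$img, gt_mask = img$mask, gt_box = gt_box,
         label = p$label, annotator_boxes = ann, params = p),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("<annotated_image %dx%d %s gt_box=%s annotators=%d>\n",
              nrow(x$image), ncol(x$image), x$label, format(x$gt_box),
              length(x$annotator_boxes)))
  invisible(x)
}

#' Simulate annotators drawing a ground-truth box
#'
#' Each simulated reader perturbs the center and size of the true box with
#' independent zero-mean Gaussian noise of standard deviation `jitter_sd` in
#' normalized coordinates (so the jitter severity is image-size invariant),
#' then the box is clipped to the frame. `jitter_sd = 0` returns exact
#' copies.
#'
#' @param gt_box The true `bbox`.
#' @param n_users Number of annotators.
#' @param jitter_sd Noise sd in normalized units (>= 0).
#' @param seed Integer seed.
#' @param dims `c(height, width)` of the frame.
#' @return List of `n_users` `bbox` objects.
#' @export
emulate_annotators <- function(gt_box, n_users = 3L, jitter_sd = 0.02,
                               seed = 1L, dims) {
  if (jitter_sd < 0) abort("jitter_sd must be >= 0")
  if (jitter_sd == 0) return(replicate(n_users, gt_box, simplify = FALSE))
  nb <- bbox_normalize(gt_box, dims)
  withr::with_seed(seed, {
    purrr::map(seq_len(n_users), function(i) {
      eps <- rnorm(4, 0, jitter_sd)
      # the jittered center is clamped into the frame so that even extreme
      # draws keep some overlap before the box is clipped
      xc <- min(max(nb$xc + eps[1], 0), 1)
      yc <- min(max(nb$yc + eps[2], 0), 1)
      ww <- max(nb$w + eps[3], 1 / dims[2])
      hh <- max(nb$h + eps[4], 1 / dims[1])
      box <- bbox(
        x = (xc - ww / 2) * dims[2], y = (yc - hh / 2) * dims[1],
        w = ww * dims[2], h = hh * dims[1]
      )
      bbox_clip(box, dims)
    })
  })
}

#' Generate a labeled phantom cohort
#'
#' Per-phantom seeds are derived deterministically from the master seed, so
#' the cohort is reproducible as a whole while every phantom differs.
#'
#' @param n_benign,n_malignant Class counts (>= 0).
#' @param seed Master integer seed.
#' @param height,width Frame size passed to every phantom.
#' @param ... Further arguments forwarded to [phantom_params()] (e.g.
#'   `speckle_scale`) applied to all phantoms.
#' @return List with `images` (list of `annotated_image`) and `manifest`
#'   (tibble: id, label, seed, x, y, w, h).
#' @export
generate_cohort <- function(n_benign, n_malignant, seed,
                            height = 600L, width = 700L, ...) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  images <- purrr::imap(labels, function(lab, i) {
    generate_phantom(phantom_params(
      label = lab, seed = child_seed(seed, i),
      height = height, width = width, ...
    ))
  })
  manifest <- purrr::imap_dfr(images, function(im, i) {
    tibble(
      id = sprintf("phantom_%03d", i), label = im$label,
      seed = im$params$seed,
      x = im$gt_box$x, y = im$gt_box$y, w = im$gt_box$w, h = im$gt_box$h
    )
  })
  if (length(images) == 0) {
    manifest <- tibble(id = character(), label = character(), seed = integer(),
                       x = numeric(), y = numeric(), w = numeric(), h = numeric())
  }
  list(images = images, manifest = manifest)
}

#' Write a cohort to disk (PNG images, PNG masks, VOC XML, CSV manifest)
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble augmented with file paths, invisibly; also
#'   written as `manifest.csv` with columns id, path, label, xmin, ymin,
#'   xmax, ymax.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  paths <- character(nrow(man))
  for (i in seq_along(cohort$images)) {
    im <- cohort$images[[i]]
    id <- man$id[i]
    paths[i] <- file.path(dir, paste0(id, ".png"))
    png::writePNG(im$image / 255, paths[i])
    png::writePNG(im$gt_mask * 1, file.path(dir, paste0(id, "_mask.png")))
    voc_write(file.path(dir, paste0(id, ".xml")), id,
              dim(im$image), c(list(im$gt_box), im$annotator_boxes),
              label = c("lesion", paste0("annotator_", seq_along(im$annotator_boxes))))
  }
  out <- tibble(
    id = man$id, path = paths, label = man$label,
    xmin = man$x, ymin = man$y, xmax = man$x + man$w, ymax = man$y + man$h
  )
  utils::write.csv(out, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(out)
}

#' Display a phantom with its ground-truth and annotator boxes
#'
#' @param image An `annotated_image`.
#' @param show_boxes Draw the ground-truth (solid) and annotator (dashed)
#'   boxes.
#' @return A ggplot object.
#' @export
plot_phantom <- function(image, show_boxes = TRUE) {
  stopifnot(inherits(image, "annotated_image"))
  df <- tidyr::expand_grid(
    row = seq_len(nrow(image$image)), col = seq_len(ncol(image$image))
  )
  df$value <- as.vector(t(image$image))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s phantom", image$label),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
  if (show_boxes) {
    gb <- bbox_tbl(image$gt_box)
    ab <- bbox_tbl(image$annotator_boxes)
    p <- p +
      ggplot2::geom_rect(
        data = gb, inherit.aes = FALSE, fill = NA, colour = "cyan",
        ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                     ymin = .data$y, ymax = .data$y + .data$h)) +
      ggplot2::geom_rect(
        data = ab, inherit.aes = FALSE, fill = NA, colour = "yellow",
        linetype = "dashed",
        ggplot2::aes(xmin = .data$x, xmax = .data$x + .data$w,
                     ymin = .data$y, ymax = .data$y + .data$h))
  }
  p
}
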