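# Synthetic pupa-image generator.
#
# Real pupa image sets of the kind used for species/sex sorting are rarely
# deposited, so every downstream stage here is exercised against generated
# images with known ground truth: an elongated super-ellipse body with a
# blunt head and a tapered tail (so head/tail disambiguation is testable),
# species-dependent size/aspect/color/texture, sex-dependent tail taper and
# size, a per-pupa weight covariate for weight-stratified partitioning, and
# optional molt-debris clutter for segmentation testing.

#' Define a species appearance profile
#'
#' @param name species label.
#' @param body_length_px numeric length-2 vector c(mean, sd) of body length in
#'   pixels; mean must be positive.
#' @param aspect_ratio c(mean, sd) of the body major/minor axis ratio; the
#'   mean must exceed 1 (pupae are elongated).
#' @param base_color_hsv length-3 HSV triple in [0,1] for the cuticle color.
#' @param texture_grain nonnegative scalar controlling multiplicative
#'   brightness grain on the body surface.
#' @param weight_g mean pupa weight in grams (lognormal location).
#' @return an object of class `species_profile`.
#' @export
species_profile <- function(name, body_length_px = c(220, 10),
                            aspect_ratio = c(2.4, 0.12),
                            base_color_hsv = c(0.08, 0.55, 0.45),
                            texture_grain = 0.05, weight_g = 1.1) {
  stopifnot(length(body_length_px) == 2, length(aspect_ratio) == 2,
            length(base_color_hsv) == 3)
  if (body_length_px[1] <= 0) stop("body_length_px mean must be > 0")
  if (aspect_ratio[1] <= 1) stop("aspect_ratio mean must be > 1")
  if (any(c(body_length_px[2], aspect_ratio[2]) < 0)) stop("sd values must be >= 0")
  if (texture_grain < 0) stop("texture_grain must be >= 0")
  structure(list(name = as.character(name), body_length_px = body_length_px,
                 aspect_ratio = aspect_ratio, base_color_hsv = base_color_hsv,
                 texture_grain = texture_grain, weight_g = weight_g),
            class = "species_profile")
}

#' Sex-dependent morphological effect
#'
#' Males are modeled relative to females: a stronger posterior taper,
#' a (usually negative) relative size change, and an additive weight shift.
#'
#' @param tail_taper_delta extra posterior half-width taper for males
#'   (fraction of the local half-width lost at the tail tip).
#' @param size_delta relative body-length change for males.
#' @param weight_shift additive weight change for males, grams.
#' @return an object of class `sex_effect`.
#' @export
sex_effect <- function(tail_taper_delta = 0.25, size_delta = -0.05,
                       weight_shift = -0.22) {
  structure(list(tail_taper_delta = tail_taper_delta, size_delta = size_delta,
                 weight_shift = weight_shift), class = "sex_effect")
}

#' Default five-species profile sets
#'
#' Three presets controlling class separability. `"realistic"` uses moderate
#' within-species variation; `"high"` shrinks the sd parameters to near zero
#' and widens between-class differences (used for end-to-end recovery
#' checks); `"none"` makes all five species identical, so any classifier
#' should fall to chance.
#'
#' @param separation one of "realistic", "high", "none".
#' @return a named list of five [species_profile()] objects.
#' @export
default_species_profiles <- function(separation = c("realistic", "high", "none")) {
  separation <- match.arg(separation)
  nm <- c("7532", "872", "871", "FuRong", "HaoYue")
  len  <- c(200, 220, 240, 255, 185)
  ar   <- c(2.1, 2.4, 2.7, 3.0, 1.9)
  hue  <- c(0.06, 0.09, 0.12, 0.05, 0.10)
  sat  <- c(0.60, 0.50, 0.40, 0.68, 0.35)
  val  <- c(0.42, 0.50, 0.38, 0.55, 0.30)
  grain <- c(0.04, 0.06, 0.05, 0.08, 0.03)
  wt   <- c(1.00, 1.15, 1.25, 1.35, 0.90)
  sds <- switch(separation, realistic = c(8, 0.10), high = c(0.5, 0.005),
                none = c(8, 0.10))
  if (separation == "none") {
    len[] <- 220; ar[] <- 2.4; hue[] <- 0.08; sat[] <- 0.5; val[] <- 0.45
    grain[] <- 0.05; wt[] <- 1.1
  }
  stats::setNames(lapply(seq_along(nm), function(i) {
    species_profile(nm[i], body_length_px = c(len[i], sds[1]),
                    aspect_ratio = c(ar[i], sds[2]),
                    base_color_hsv = c(hue[i], sat[i], val[i]),
                    texture_grain = grain[i], weight_g = wt[i])
  }), nm)
}

# Per-pupa body draw (shared by the three posture images of one pupa).
.pupa_body <- function(profile, sex, fx, seed) {
  withr::with_seed(seed, {
    len <- max(40, rnorm(1, profile$body_length_px[1], profile$body_length_px[2]))
    ar <- max(1.1, rnorm(1, profile$aspect_ratio[1], profile$aspect_ratio[2]))
    if (sex == "male") len <- len * (1 + fx$size_delta)
    taper <- 0.30 + if (sex == "male") fx$tail_taper_delta else 0
    weight <- rlnorm(1, meanlog = log(profile$weight_g), sdlog = 0.08) +
      if (sex == "male") fx$weight_shift else 0
    list(length = len, aspect = ar, taper = min(taper, 0.9),
         weight = max(weight, 0.05))
  })
}

#' Generate one synthetic pupa image
#'
#' Renders a single elongated super-ellipse pupa body on a light background.
#' The head end is blunt and the tail end tapers (more strongly for males),
#' the posture modulates silhouette width and dorsal-bulge asymmetry, the
#' body lies at a random orientation, and the rasterized ground-truth body
#' contour plus a weight covariate are recorded. Bit-identical output for
#' identical arguments.
#'
#' @param profile a [species_profile()].
#' @param sex "female" or "male".
#' @param posture one of "back", "abdomen", "side".
#' @param seed integer seed; body shape and weight depend on the seed only,
#'   pose and pixel noise additionally on the posture.
#' @param fx a [sex_effect()].
#' @param canvas integer c(height, width) of the output image; the default
#'   480 x 480 leaves margin so a centered 320 x 320 crop never clips the body.
#' @return an object of class `pupa_image` with fields `pixels` (H x W x 3
#'   array in [0,1]), `species`, `sex`, `posture`, `pupa_id`, `weight` and
#'   `truth_contour` (a `pupa_contour`).
#' @export
generate_pupa <- function(profile, sex, posture, seed, fx = sex_effect(),
                          canvas = c(480, 480)) {
  if (!inherits(profile, "species_profile")) stop("profile must be a species_profile")
  if (!sex %in% c("female", "male")) stop("invalid sex label: ", sex)
  if (!posture %in% c("back", "abdomen", "side")) stop("invalid posture label: ", posture)
  body <- .pupa_body(profile, sex, fx, derive_seed(seed, 0L))
  H <- canvas[1]; W <- canvas[2]
  pose_seed <- derive_seed(seed, match(posture, c("back", "abdomen", "side")))
  withr::with_seed(pose_seed, {
    a <- body$length / 2
    b <- a / body$aspect
    width_scale <- switch(posture, back = 1.0, abdomen = 0.96, side = 0.84)
    bulge <- switch(posture, back = 0.14, abdomen = -0.10, side = 0.04)
    b <- b * width_scale
    phi <- runif(1, 0, 2 * pi)
    cy <- H / 2 + runif(1, -12, 12)
    cx <- W / 2 + runif(1, -12, 12)
    # background: light gray with faint noise
    bg_v <- 0.93 + matrix(rnorm(H * W, 0, 0.008), H, W)
    pix <- array(pmin(pmax(bg_v, 0), 1), dim = c(H, W, 3))
    # body-frame membership test over the bounding disc of the body
    rad <- ceiling(a + b + 2)
    rows <- max(1, floor(cy - rad)):min(H, ceiling(cy + rad))
    cols <- max(1, floor(cx - rad)):min(W, ceiling(cx + rad))
    yy <- matrix(rows - 1, length(rows), length(cols))
    xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
    u <- ((xx - cx) * cos(phi) + (yy - cy) * sin(phi)) / a       # along body
    v <- (-(xx - cx) * sin(phi) + (yy - cy) * cos(phi))          # across body
    p <- 2.5                                  # super-ellipse exponent: blunt ends
    hw <- b * (1 - pmin(abs(u), 1)^p)^(1 / p) *
      (1 - body$taper * pmax(u, 0))           # posterior taper (tail at u = +1)
    off <- bulge * b * (1 - pmin(abs(u), 1)^2) # posture-dependent dorsal bulge
    inside <- abs(u) < 1 & abs(v - off) < hw
    # body coloring: species HSV with grain noise and mild segmental banding
    hsv <- profile$base_color_hsv
    nin <- sum(inside)
    if (nin < 25) stop("degenerate body raster; increase canvas or body size")
    grain <- 1 + profile$texture_grain * rnorm(nin) +
      0.04 * sin(9 * pi * u[inside])
    col <- hsv_to_rgb(rep(hsv[1], nin), rep(hsv[2], nin),
                      pmin(pmax(hsv[3] * grain, 0), 1))
    mask <- matrix(FALSE, H, W)
    mask[rows, cols] <- inside
    idx <- which(mask)
    pix[idx] <- col$r
    pix[idx + H * W] <- col$g
    pix[idx + 2L * H * W] <- col$b
    truth <- contour_from_mask(mask)
  })
  structure(list(pixels = pix, species = profile$name, sex = sex,
                 posture = posture,
                 pupa_id = sprintf("%s_%s_s%d", profile$name, sex, seed),
                 weight = body$weight, truth_contour = truth),
            class = "pupa_image")
}

#' Add molt-debris fragments to a pupa image
#'
#' Scatters small dark elliptical fragments that never touch the body, so an
#' area-thresholded segmentation can filter them by design. The ground-truth
#' contour is unchanged.
#'
#' @param image a `pupa_image`.
#' @param n_fragments number of fragments; 0 returns the image unchanged.
#' @param max_area_frac maximum fragment area as a fraction of the image
#'   area; keep this below the segmentation area threshold.
#' @param seed integer seed.
#' @param max_retries placement attempts per fragment before erroring.
#' @return the modified `pupa_image`.
#' @export
add_debris <- function(image, n_fragments, max_area_frac = 0.005, seed = 1,
                       max_retries = 200) {
  stopifnot(inherits(image, "pupa_image"))
  if (n_fragments == 0) return(image)
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  body <- polygon_mask(image$truth_contour$points, H, W)
  body <- EBImage::dilate(body * 1, EBImage::makeBrush(7, "disc")) > 0
  occupied <- body
  pix <- image$pixels
  withr::with_seed(derive_seed(seed, 17L), {
    for (f in seq_len(n_fragments)) {
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        area_cap <- max_area_frac * H * W
        ae <- runif(1, sqrt(area_cap / pi) * 0.4, sqrt(area_cap / pi) * 0.9)
        be <- ae * runif(1, 0.3, 0.8)
        ang <- runif(1, 0, pi)
        fy <- runif(1, ae + 2, H - ae - 2)
        fx <- runif(1, ae + 2, W - ae - 2)
        rows <- max(1, floor(fy - ae)):min(H, ceiling(fy + ae))
        cols <- max(1, floor(fx - ae)):min(W, ceiling(fx + ae))
        yy <- matrix(rows - 1, length(rows), length(cols))
        xx <- matrix(cols - 1, length(rows), length(cols), byrow = TRUE)
        uu <- ((xx - fx) * cos(ang) + (yy - fy) * sin(ang)) / ae
        vv <- (-(xx - fx) * sin(ang) + (yy - fy) * cos(ang)) / be
        inside <- uu^2 + vv^2 < 1
        if (sum(inside) >= area_cap || sum(inside) < 4) next
        sub <- occupied[rows, cols]
        if (any(sub & inside)) next
        occupied[rows, cols] <- sub | inside
        shade <- 0.18 + 0.1 * runif(1)
        nin <- sum(inside)
        frag <- matrix(FALSE, H, W); frag[rows, cols] <- inside
        idx <- which(frag)
        jitter <- pmin(pmax(shade * (1 + 0.1 * rnorm(nin)), 0), 1)
        pix[idx] <- jitter * 1.1
        pix[idx + H * W] <- jitter * 0.9
        pix[idx + 2L * H * W] <- jitter * 0.7
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place debris fragment ", f,
                        " without overlap after ", max_retries, " retries")
    }
  })
  image$pixels <- pix
  image
}

#' Generate a labeled multi-class pupa dataset
#'
#' Emits `pupae_per_class` pupae for every (species, sex) class, each imaged
#' in all three postures, mirroring the study design in which 120 pupae per
#' class photographed in 3 postures yield 3600 images (360 per class).
#'
#' @param profiles named list of exactly five [species_profile()] objects
#'   (or more generally >= 5).
#' @param pupae_per_class pupae per (species, sex) class, > 0.
#' @param seed integer master seed; the full dataset is a deterministic
#'   function of it.
#' @param fx a [sex_effect()].
#' @param render if TRUE, rendered `pupa_image` objects are kept in `$images`
#'   (named by `<pupa_id>_<posture>`); if FALSE only the manifest is built,
#'   which is cheap even at the full 3600-image scale.
#' @param out_dir optional directory; when given, images are rendered and
#'   written as `<species>_<sex>/<pupa_id>_<posture>.png` plus `manifest.csv`.
#' @return an object of class `pupa_dataset`: list(manifest, images). The
#'   manifest has one row per image: pupa_id, species, sex, posture, weight,
#'   class, seed, path.
#' @export
generate_dataset <- function(profiles, pupae_per_class, seed = 1,
                             fx = sex_effect(), render = is.null(out_dir),
                             out_dir = NULL) {
  if (length(profiles) < 5) stop("at least 5 species profiles are required")
  if (pupae_per_class <= 0) stop("pupae_per_class must be > 0")
  postures <- c("back", "abdomen", "side")
  sexes <- c("female", "male")
  rows <- list(); images <- list()
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  k <- 0L
  for (sp in profiles) for (sx in sexes) for (i in seq_len(pupae_per_class)) {
    k <- k + 1L
    pupa_seed <- derive_seed(seed, k)
    pupa_id <- sprintf("%s_%s_%03d", sp$name, sx, i)
    weight <- .pupa_body(sp, sx, fx, derive_seed(pupa_seed, 0L))$weight
    for (po in postures) {
      path <- if (!is.null(out_dir))
        file.path(out_dir, sprintf("%s_%s", sp$name, sx),
                  sprintf("%s_%s.png", pupa_id, po)) else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        pupa_id = pupa_id, species = sp$name, sex = sx, posture = po,
        weight = weight, class = paste(sp$name, sx, sep = "_"),
        seed = pupa_seed, path = path, stringsAsFactors = FALSE)
      if (render || !is.null(out_dir)) {
        img <- generate_pupa(sp, sx, po, pupa_seed, fx = fx)
        img$pupa_id <- pupa_id
        if (!is.null(out_dir)) {
          dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
          EBImage::writeImage(EBImage::Image(aperm(img$pixels, c(2, 1, 3)),
                                             colormode = "Color"), path)
        }
        if (render) images[[sprintf("%s_%s", pupa_id, po)]] <- img
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(manifest = manifest, images = images), class = "pupa_dataset")
}

#' @export
print.pupa_dataset <- function(x, ...) {
  cat(sprintf("pupa_dataset: %d images, %d classes, %d pupae (%srendered)\n",
              nrow(x$manifest), length(unique(x$manifest$class)),
              length(unique(x$manifest$pupa_id)),
              if (length(x$images)) "" else "not "))
  invisible(x)
}
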