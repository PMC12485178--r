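# Synthetic fundus-image generator.
#
# Emulates the gross structure of a color fundus photograph: a bright circular
# retina on a black frame with green-dominant coloration, one elliptical
# optic-disc highlight, a random-walk vessel tree darker than the surrounding
# retina, and grade-dependent lesions (dark dots ~ hemorrhages / microaneurysms,
# bright blobs ~ exudates) whose count is Poisson with a per-grade rate.
# Severity is ordinal on 5 grades (0 = no disease ... 4 = proliferative).

#' Configuration for the synthetic fundus generator
#'
#' @param image_size square image side in pixels (>= 64).
#' @param retina_radius_frac retina radius as a fraction of the half-width,
#'   in (0, 1].
#' @param lesion_rate_per_grade expected lesion counts for grades 0..4; must
#'   be strictly increasing. The defaults give an effect size a lesion-count
#'   oracle can separate.
#' @param dual_view if `TRUE`, each synthetic eye is rendered as a
#'   left/right pair sharing retina layout up to mirroring, with
#'   independently drawn vessel noise.
#' @param seed integer seed used when no explicit stream is passed.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(image_size = 224,
                             retina_radius_frac = 0.92,
                             lesion_rate_per_grade = c(0, 2, 5, 10, 20),
                             dual_view = FALSE,
                             seed = 1) {
  if (image_size < 64) stop("image_size must be >= 64")
  if (retina_radius_frac <= 0 || retina_radius_frac > 1)
    stop("retina_radius_frac must be in (0, 1]")
  if (length(lesion_rate_per_grade) != 5 || any(lesion_rate_per_grade < 0))
    stop("lesion_rate_per_grade must be 5 non-negative rates")
  if (any(diff(lesion_rate_per_grade) <= 0))
    stop("lesion_rate_per_grade must be strictly increasing in grade")
  structure(list(image_size = as.integer(image_size),
                 retina_radius_frac = retina_radius_frac,
                 lesion_rate_per_grade = lesion_rate_per_grade,
                 dual_view = isTRUE(dual_view),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Fundus image container
#'
#' @param pixels H x W x 3 integer array with values in 0..255.
#' @param id image identifier.
#' @param grade optional ordinal severity grade in 0..4.
#' @param view one of `"single"`, `"left"`, `"right"`.
#' @return an object of class `fundus_image`.
#' @export
fundus_image <- function(pixels, id, grade = NULL, view = "single") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (any(pixels < 0 | pixels > 255)) stop("pixel values must be in [0, 255]")
  if (!is.null(grade) && !(grade %in% 0:4)) stop("grade must be in 0..4")
  if (!view %in% c("single", "left", "right")) stop("invalid view tag")
  structure(list(pixels = pixels, id = as.character(id),
                 grade = if (is.null(grade)) NULL else as.integer(grade),
                 view = view),
            class = "fundus_image")
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %s  %dx%d  grade=%s  view=%s>\n", x$id,
              d[1], d[2], if (is.null(x$grade)) "NA" else x$grade, x$view))
  invisible(x)
}

# Sample the geometry of one synthetic eye (shared between dual views).
sample_eye_layout <- function(cfg, grade) {
  S <- cfg$image_size
  R <- cfg$retina_radius_frac * S / 2
  n_lesions <- stats::rpois(1, cfg$lesion_rate_per_grade[grade + 1])
  disc_ang <- stats::runif(1, -0.5, 0.5)
  disc_rad <- stats::runif(1, 0.45, 0.62) * R
  lesions <- if (n_lesions > 0) {
    ang <- stats::runif(n_lesions, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_lesions)) * 0.82 * R
    data.frame(
      dy = rad * sin(ang), dx = rad * cos(ang),
      r = stats::runif(n_lesions, 1.2, 2.6),
      bright = stats::runif(n_lesions) < 0.5
    )
  } else NULL
  list(S = S, R = R, grade = grade, n_lesions = n_lesions,
       disc_dy = disc_rad * sin(disc_ang), disc_dx = disc_rad * cos(disc_ang),
       disc_a = stats::runif(1, 0.14, 0.18) * R,
       disc_b = stats::runif(1, 0.10, 0.13) * R,
       shade = stats::runif(1, 0.25, 0.4),
       lesions = lesions)
}

# Render one view of a layout; vessels are drawn with the supplied stream so
# paired views share everything except vessel noise.
render_eye <- function(layout, mirror = FALSE) {
  S <- layout$S; R <- layout$R
  cy <- (S + 1) / 2; cx <- (S + 1) / 2
  yy <- matrix(seq_len(S), S, S)
  xx <- matrix(seq_len(S), S, S, byrow = TRUE)
  dist <- sqrt((yy - cy)^2 + (xx - cx)^2)
  cov <- clamp(R + 0.5 - dist, 0, 1) # anti-alias band <= 1 px
  shade <- 1 - layout$shade * (dist / R)^2
  mir <- function(dx) if (mirror) -dx else dx

  red <- 96 * shade
  grn <- 152 * shade
  blu <- 52 * shade

  # optic disc: bright ellipse
  ddx <- mir(layout$disc_dx)
  ey <- yy - (cy + layout$disc_dy)
  ex <- xx - (cx + ddx)
  inside <- (ey / layout$disc_b)^2 + (ex / layout$disc_a)^2
  disc_w <- clamp(1.4 - inside, 0, 1)
  red <- red + (210 - red) * disc_w
  grn <- grn + (228 - grn) * disc_w
  blu <- blu + (150 - blu) * disc_w

  # vessel tree: random walks from the optic disc, darker than the retina
  vmask <- matrix(0, S, S)
  n_walk <- sample(6:9, 1)
  for (v in seq_len(n_walk)) {
    py <- cy + layout$disc_dy
    px <- cx + ddx
    ang <- stats::runif(1, 0, 2 * pi)
    thick <- sample(0:1, 1)
    for (s in seq_len(round(2.2 * R))) {
      ang <- ang + stats::rnorm(1, 0, 0.25)
      py <- py + sin(ang)
      px <- px + cos(ang)
      if (sqrt((py - cy)^2 + (px - cx)^2) > 0.95 * R) break
      iy <- round(py); ix <- round(px)
      y0 <- max(1, iy - thick); y1 <- min(S, iy + thick)
      x0 <- max(1, ix - thick); x1 <- min(S, ix + thick)
      vmask[y0:y1, x0:x1] <- 1
    }
  }
  vfac <- 1 - 0.55 * vmask
  red <- red * vfac; grn <- grn * vfac; blu <- blu * vfac

  # lesions inside the retina disc
  if (!is.null(layout$lesions)) {
    for (i in seq_len(nrow(layout$lesions))) {
      L <- layout$lesions[i, ]
      ly <- cy + L$dy
      lx <- cx + mir(L$dx)
      w <- clamp(L$r + 0.5 - sqrt((yy - ly)^2 + (xx - lx)^2), 0, 1)
      if (L$bright) {
        red <- red + (238 - red) * w
        grn <- grn + (225 - grn) * w
        blu <- blu + (140 - blu) * w
      } else {
        red <- red + (55 - red) * w
        grn <- grn + (22 - grn) * w
        blu <- blu + (16 - blu) * w
      }
    }
  }

  px <- array(0, c(S, S, 3))
  px[, , 1] <- red * cov
  px[, , 2] <- grn * cov
  px[, , 3] <- blu * cov
  round(clamp(px, 0, 255))
}

#' Generate one synthetic fundus image
#'
#' @param cfg a [synthetic_config()].
#' @param grade ordinal severity grade in 0..4; the lesion count is drawn
#'   from Poisson(`cfg$lesion_rate_per_grade[grade + 1]`).
#' @param rng optional [msssl_rng()] stream; defaults to a fresh stream from
#'   `cfg$seed`. Byte-identical output for identical stream states.
#' @param id image identifier.
#' @param view view tag.
#' @return a [fundus_image()] with attribute `lesion_count`.
#' @export
generate_fundus <- function(cfg, grade, rng = NULL, id = "synthetic",
                            view = "single") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(grade) != 1 || !(grade %in% 0:4)) stop("grade must be in 0..4")
  rng <- rng %||% msssl_rng(cfg$seed)
  with_rng(rng, {
    layout <- sample_eye_layout(cfg, grade)
    px <- render_eye(layout, mirror = (view == "right"))
    img <- fundus_image(px, id, grade, view)
    attr(img, "lesion_count") <- layout$n_lesions
    img
  })
}

#' Generate a labeled synthetic dataset with a CSV manifest
#'
#' Writes `5 * n_per_grade` PNG images (twice that when `cfg$dual_view`:
#' left/right renderings of the same eye, sharing lesion layout up to
#' mirroring with independent vessel noise) plus a manifest
#' `manifest.csv` with header `id,grade,view,file`.
#'
#' @param cfg a [synthetic_config()].
#' @param n_per_grade images (or eyes, in dual view) per grade, >= 1.
#' @param dir output directory, created if needed.
#' @return the manifest as a data frame, invisibly also written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
generate_dataset <- function(cfg, n_per_grade, dir) {
  stopifnot(inherits(cfg, "synthetic_config"), n_per_grade >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  rng <- msssl_rng(cfg$seed)
  rows <- list()
  for (g in 0:4) {
    for (i in seq_len(n_per_grade)) {
      id <- sprintf("g%d_%03d", g, i)
      with_rng(rng, {
        layout <- sample_eye_layout(cfg, g)
        if (cfg$dual_view) {
          for (vw in c("left", "right")) {
            px <- render_eye(layout, mirror = (vw == "right"))
            f <- file.path(dir, sprintf("%s_%s.png", id, vw))
            png::writePNG(px / 255, f)
            rows[[length(rows) + 1]] <- data.frame(
              id = id, grade = g, view = vw, file = f,
              stringsAsFactors = FALSE)
          }
        } else {
          px <- render_eye(layout, mirror = FALSE)
          f <- file.path(dir, sprintf("%s.png", id))
          png::writePNG(px / 255, f)
          rows[[length(rows) + 1]] <- data.frame(
            id = id, grade = g, view = "single", file = f,
            stringsAsFactors = FALSE)
        }
      })
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Read a fundus image from a PNG file
#'
#' @param path PNG file path.
#' @param id,grade,view metadata attached to the result.
#' @return a [fundus_image()].
#' @export
load_fundus <- function(path, id = basename(path), grade = NULL,
                        view = "single") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  fundus_image(round(px * 255), id, grade, view)
}
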