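# Seeded synthetic slides with known ground truth.
#
# A slide is a bright field holding several darker, textured section
# ellipses. Each section contains planted "primordial follicle" objects —
# a pale oocyte disc with a single dark nucleolus dot and a surrounding
# ring of small elongated dark nuclei (flattened granulosa cells) — plus
# distractor blobs that never complete the full follicle template.

#' Synthetic slide specification
#'
#' Parameters of the synthetic-slide generator. Intensities are on an
#' 8-bit scale (background ~230, section stroma ~150, nuclei ~60, oocyte
#' ~200), mirroring a hematoxylin-eosin scan after grayscale conversion:
#' detectability is contrast-driven, not colour-driven.
#'
#' @param slide_w,slide_h Slide size in pixels.
#' @param n_sections Number of section ellipses per slide.
#' @param follicles_per_section Length-2 integer range (min, max).
#' @param follicle_diameter Length-2 range of oocyte diameters in px.
#' @param distractors_per_section Length-2 integer range (min, max).
#' @param noise_sd Additive Gaussian noise SD, 8-bit intensity units.
#' @param seed Master seed; a fixed seed makes the output bit-identical.
#' @param allow_pairs Plant a few follicle pairs closer than half a
#'   detection frame, to exercise the two-follicles-in-one-frame
#'   evaluation rule.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(slide_w = 1024, slide_h = 1024, n_sections = 4,
                           follicles_per_section = c(5, 15),
                           follicle_diameter = c(18, 30),
                           distractors_per_section = c(10, 30),
                           noise_sd = 8, seed = 1, allow_pairs = FALSE) {
  spec <- list(slide_w = slide_w, slide_h = slide_h, n_sections = n_sections,
               follicles_per_section = follicles_per_section,
               follicle_diameter = follicle_diameter,
               distractors_per_section = distractors_per_section,
               noise_sd = noise_sd, seed = seed, allow_pairs = allow_pairs)
  stopifnot(slide_w >= 64, slide_h >= 64, n_sections >= 1,
            length(follicles_per_section) == 2,
            diff(follicles_per_section) >= 0, follicles_per_section[1] >= 0,
            length(follicle_diameter) == 2, follicle_diameter[1] >= 6,
            diff(follicle_diameter) >= 0,
            length(distractors_per_section) == 2,
            distractors_per_section[1] >= 0, noise_sd >= 0)
  structure(spec, class = "synthetic_spec")
}

# --- raster primitives (0-based centre coordinates) -----------------------

draw_disc <- function(canvas, cx, cy, r, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  r0 <- max(1, floor(cy - r) + 1); r1 <- min(h, ceiling(cy + r) + 1)
  c0 <- max(1, floor(cx - r) + 1); c1 <- min(w, ceiling(cx + r) + 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  yy <- (r0:r1) - 1 - cy
  xx <- (c0:c1) - 1 - cx
  m <- outer(yy^2, xx^2, "+") <= r^2
  sub <- canvas[r0:r1, c0:c1, drop = FALSE]
  sub[m] <- value
  canvas[r0:r1, c0:c1] <- sub
  canvas
}

draw_rot_ellipse <- function(canvas, cx, cy, a, b, theta, value) {
  h <- nrow(canvas); w <- ncol(canvas)
  rr <- max(a, b)
  r0 <- max(1, floor(cy - rr) + 1); r1 <- min(h, ceiling(cy + rr) + 1)
  c0 <- max(1, floor(cx - rr) + 1); c1 <- min(w, ceiling(cx + rr) + 1)
  if (r0 > r1 || c0 > c1) return(canvas)
  yy <- (r0:r1) - 1 - cy
  xx <- (c0:c1) - 1 - cx
  ct <- cos(theta); st <- sin(theta)
  X <- matrix(xx, length(yy), length(xx), byrow = TRUE)
  Y <- matrix(yy, length(yy), length(xx))
  u <- ct * X + st * Y
  v <- -st * X + ct * Y
  m <- (u / a)^2 + (v / b)^2 <= 1
  sub <- canvas[r0:r1, c0:c1, drop = FALSE]
  sub[m] <- value
  canvas[r0:r1, c0:c1] <- sub
  canvas
}

# Ring of small elongated dark nuclei around (cx, cy) at radius ring_r.
# arc_frac < 1 draws only a partial ring (a distractor pattern).
draw_granulosa_ring <- function(canvas, cx, cy, ring_r, value,
                                arc_frac = 1, phase = 0) {
  n <- max(6, round(2 * pi * ring_r / 5))
  n_drawn <- max(2, round(n * arc_frac))
  angles <- phase + 2 * pi * (seq_len(n_drawn) - 1) / n
  for (ang in angles) {
    gx <- cx + ring_r * cos(ang)
    gy <- cy + ring_r * sin(ang)
    canvas <- draw_rot_ellipse(canvas, gx, gy, 2.6, 1.3, ang + pi / 2, value)
  }
  canvas
}

# Render one primordial follicle; returns the canvas.
draw_follicle <- function(canvas, cx, cy, diameter, jitter) {
  r_o <- diameter / 2
  oocyte <- (200 + jitter(8)) / 255
  nucleus <- (60 + jitter(8)) / 255
  canvas <- draw_granulosa_ring(canvas, cx, cy, r_o + 1.8, nucleus,
                                phase = runif(1, 0, 2 * pi))
  canvas <- draw_disc(canvas, cx, cy, r_o, oocyte)
  canvas <- draw_disc(canvas, cx, cy, max(1.6, diameter / 10), nucleus)
  canvas
}

# Candidate follicle centres inside a rotated ellipse: jittered hexagonal
# grid with guaranteed pairwise separation (jitter is diagonal, so two
# points can approach by at most 2*jit*sqrt(2) + sqrt(2) after rounding;
# the spacing absorbs that, keeping any two candidates >= separation
# apart within one pixel).
follicle_center_candidates <- function(cx, cy, a, b, theta, separation,
                                       edge_margin) {
  jit <- 2
  spacing <- separation + 8
  a_in <- a - edge_margin
  b_in <- b - edge_margin
  if (a_in <= 0 || b_in <= 0) return(matrix(numeric(0), ncol = 2))
  rr <- max(a_in, b_in)
  row_step <- spacing * sqrt(3) / 2
  vs <- seq(-rr, rr, by = row_step)
  vs <- vs - mean(vs)
  us <- seq(-rr - spacing, rr + spacing, by = spacing)
  us <- us - mean(us)
  pts <- do.call(rbind, lapply(seq_along(vs), function(r) {
    cbind(u = us + (r %% 2) * spacing / 2, v = vs[r])
  }))
  pts <- as.data.frame(pts)
  pts$u <- pts$u + runif(nrow(pts), -jit, jit)
  pts$v <- pts$v + runif(nrow(pts), -jit, jit)
  keep <- (pts$u / a_in)^2 + (pts$v / b_in)^2 <= 1
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0) return(matrix(numeric(0), ncol = 2))
  ct <- cos(theta); st <- sin(theta)
  cbind(x = cx + ct * pts$u - st * pts$v,
        y = cy + st * pts$u + ct * pts$v)
}

# Uniform random point inside a (rotated) ellipse shrunk by edge_margin.
random_point_in_ellipse <- function(cx, cy, a, b, theta, edge_margin) {
  a_in <- max(1, a - edge_margin); b_in <- max(1, b - edge_margin)
  repeat {
    u <- runif(1, -1, 1); v <- runif(1, -1, 1)
    if (u^2 + v^2 <= 1) break
  }
  ct <- cos(theta); st <- sin(theta)
  c(x = cx + ct * a_in * u - st * b_in * v,
    y = cy + st * a_in * u + ct * b_in * v)
}

#' Generate one synthetic slide with ground truth
#'
#' @param spec A [synthetic_spec].
#' @param slide_id Identifier written into the annotations.
#' @return A list with `slide` (a [slide_image]) and `annotations`
#'   (tibble `slide_id, x, y, follicle_class`, one row per planted
#'   primordial follicle, coordinates at the oocyte centre).
#' @export
generate_slide <- function(spec, slide_id = "synthetic_slide") {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, generate_slide_impl(spec, slide_id))
}

generate_slide_impl <- function(spec, slide_id) {
  w <- spec$slide_w; h <- spec$slide_h
  jitter <- function(amp) runif(1, -amp, amp)
  canvas <- matrix(230 / 255, h, w) +
    matrix(runif(h * w, -3, 3) / 255, h, w)   # mild background mottle

  # lay sections out on a jittered grid of cells so they never overlap
  gx <- ceiling(sqrt(spec$n_sections))
  gy <- ceiling(spec$n_sections / gx)
  cell_w <- w / gx; cell_h <- h / gy
  max_semi <- 0.45 * min(cell_w, cell_h)
  min_semi <- 0.32 * min(cell_w, cell_h)
  if (max_semi < 1.5 * spec$follicle_diameter[2]) {
    abort("sections too small to host follicles; enlarge the slide or reduce n_sections")
  }
  cells <- expand.grid(ix = seq_len(gx) - 1, iy = seq_len(gy) - 1)
  cells <- cells[seq_len(spec$n_sections), , drop = FALSE]

  sections <- list()
  for (i in seq_len(spec$n_sections)) {
    a <- runif(1, min_semi, max_semi)
    b <- runif(1, min_semi, max_semi)
    theta <- runif(1, 0, pi)
    margin <- max_semi - max(a, b)
    cx <- (cells$ix[i] + 0.5) * cell_w + runif(1, -margin, margin)
    cy <- (cells$iy[i] + 0.5) * cell_h + runif(1, -margin, margin)
    sections[[i]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
  }

  max_diam <- spec$follicle_diameter[2]
  separation <- 1.5 * max_diam
  edge_margin <- max_diam / 2 + 8
  ann_x <- numeric(0); ann_y <- numeric(0)

  for (sec in sections) {
    # draw everything belonging to this section on a local sub-canvas to
    # avoid repeated full-slide copies
    rr <- max(sec$a, sec$b) + 3
    x0 <- max(0, floor(sec$cx - rr)); y0 <- max(0, floor(sec$cy - rr))
    x1 <- min(w - 1, ceiling(sec$cx + rr)); y1 <- min(h - 1, ceiling(sec$cy + rr))
    local <- canvas[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
    lx <- function(gx) gx - x0
    ly <- function(gy) gy - y0

    stroma <- (150 + jitter(10)) / 255
    local <- draw_rot_ellipse(local, lx(sec$cx), ly(sec$cy), sec$a, sec$b,
                              sec$theta, stroma)

    # stromal texture: scattered small dark nuclei
    area <- pi * sec$a * sec$b
    n_dots <- round(area / 1400)
    for (k in seq_len(n_dots)) {
      p <- random_point_in_ellipse(sec$cx, sec$cy, sec$a, sec$b, sec$theta, 4)
      local <- draw_rot_ellipse(local, lx(p[1]), ly(p[2]),
                                runif(1, 1.2, 2.2), runif(1, 0.8, 1.4),
                                runif(1, 0, pi), (75 + jitter(15)) / 255)
    }

    k_fol <- if (spec$follicles_per_section[2] == 0) 0L else
      sample(spec$follicles_per_section[1]:spec$follicles_per_section[2], 1)
    cand <- follicle_center_candidates(sec$cx, sec$cy, sec$a, sec$b,
                                       sec$theta, separation, edge_margin)
    if (k_fol > nrow(cand)) {
      abort(sprintf(
        "cannot place %d follicles in a section with %d feasible sites",
        k_fol, nrow(cand)))
    }
    centers <- if (k_fol > 0) {
      cand[sample(nrow(cand), k_fol), , drop = FALSE]
    } else matrix(numeric(0), ncol = 2)

    if (isTRUE(spec$allow_pairs) && k_fol >= 2) {
      # plant close partners next to up to two follicles
      ct <- cos(sec$theta); st <- sin(sec$theta)
      a_in <- sec$a - edge_margin; b_in <- sec$b - edge_margin
      inside <- function(p) {
        u <- ct * (p[1] - sec$cx) + st * (p[2] - sec$cy)
        v <- -st * (p[1] - sec$cx) + ct * (p[2] - sec$cy)
        (u / a_in)^2 + (v / b_in)^2 <= 1
      }
      for (idx in utils::head(sample(k_fol), 2)) {
        base <- centers[idx, ]
        d_pair <- runif(1, 0.6, 0.9) * max_diam
        for (try in 1:20) {
          ang <- runif(1, 0, 2 * pi)
          p <- c(base[1] + d_pair * cos(ang), base[2] + d_pair * sin(ang))
          if (inside(p)) { centers <- rbind(centers, p); break }
        }
      }
    }

    for (j in seq_len(nrow(centers))) {
      d <- runif(1, spec$follicle_diameter[1], spec$follicle_diameter[2])
      cxy <- round(centers[j, ])
      local <- draw_follicle(local, lx(cxy[1]), ly(cxy[2]), d, jitter)
      ann_x <- c(ann_x, cxy[1]); ann_y <- c(ann_y, cxy[2])
    }

    # distractors: dark blobs, partial rings, ring-less pale discs
    k_dis <- sample(spec$distractors_per_section[1]:
                      spec$distractors_per_section[2], 1)
    placed <- centers
    got <- 0; tries <- 0
    while (got < k_dis && tries < 60 * k_dis) {
      tries <- tries + 1
      p <- random_point_in_ellipse(sec$cx, sec$cy, sec$a, sec$b, sec$theta,
                                   edge_margin)
      if (nrow(placed) > 0) {
        dmin <- min(sqrt((placed[, 1] - p[1])^2 + (placed[, 2] - p[2])^2))
        if (dmin < 1.2 * max_diam) next
      }
      kind <- sample(3, 1)
      if (kind == 1) {                   # solid dark blob
        local <- draw_rot_ellipse(local, lx(p[1]), ly(p[2]), runif(1, 4, 11),
                                  runif(1, 3, 9), runif(1, 0, pi),
                                  (85 + jitter(20)) / 255)
      } else if (kind == 2) {            # partial granulosa arc, no oocyte
        local <- draw_granulosa_ring(local, lx(p[1]), ly(p[2]),
                                     runif(1, 8, 14), (60 + jitter(8)) / 255,
                                     arc_frac = runif(1, 0.2, 0.45),
                                     phase = runif(1, 0, 2 * pi))
      } else {                           # pale disc without ring or dot
        local <- draw_disc(local, lx(p[1]), ly(p[2]), runif(1, 6, 12),
                           (200 + jitter(8)) / 255)
      }
      placed <- rbind(placed, p)
      got <- got + 1
    }
    canvas[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1)] <- local
  }

  if (spec$noise_sd > 0) {
    canvas <- canvas + matrix(rnorm(h * w, 0, spec$noise_sd / 255), h, w)
  }
  canvas <- pmin(pmax(canvas, 0), 1)

  annotations <- tibble(
    slide_id = rep(slide_id, length(ann_x)),
    x = as.numeric(ann_x), y = as.numeric(ann_y),
    follicle_class = rep("primordial", length(ann_x))
  )
  list(
    slide = slide_image(canvas, microns_per_pixel = 1, slide_id = slide_id,
                        scale_factor = 1),
    annotations = annotations,
    sections = sections
  )
}

#' Generate a corpus of synthetic slides on disk
#'
#' Writes `n_slides` LZW-compressed TIFF slides, one combined annotations
#' CSV, and a JSON manifest with per-slide follicle counts. Per-slide seeds
#' are derived deterministically from the spec's master seed, so
#' regeneration with the same spec reproduces the corpus exactly.
#'
#' @param spec A [synthetic_spec]; its `seed` is the master seed.
#' @param n_slides Number of slides.
#' @param out_dir Output directory (created if needed).
#' @param prefix Slide id / file-name prefix.
#' @return Tibble manifest: `slide_id, path, seed, n_follicles`.
#' @export
generate_corpus <- function(spec, n_slides, out_dir, prefix = "slide") {
  stopifnot(inherits(spec, "synthetic_spec"), n_slides >= 0)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create directory %s", out_dir))
  rows <- vector("list", n_slides)
  all_ann <- vector("list", n_slides)
  for (i in seq_len(n_slides)) {
    sid <- sprintf("%s%03d", prefix, i)
    sspec <- spec
    sspec$seed <- derive_seed(spec$seed, sid)
    gen <- generate_slide(sspec, slide_id = sid)
    path <- file.path(out_dir, paste0(sid, ".tif"))
    write_slide(gen$slide, path, compression = "LZW")
    all_ann[[i]] <- gen$annotations
    rows[[i]] <- tibble(slide_id = sid, path = path, seed = sspec$seed,
                        n_follicles = nrow(gen$annotations))
  }
  manifest <- dplyr::bind_rows(rows)
  if (nrow(manifest) == 0) {
    manifest <- tibble(slide_id = character(), path = character(),
                       seed = integer(), n_follicles = integer())
  }
  ann <- dplyr::bind_rows(all_ann)
  if (nrow(manifest) > 0 || n_slides == 0) {
    if (nrow(ann) == 0) {
      ann <- tibble(slide_id = character(), x = numeric(), y = numeric(),
                    follicle_class = character())
    }
    readr::write_csv(ann, file.path(out_dir, "annotations.csv"))
    jsonlite::write_json(
      list(master_seed = spec$seed, n_slides = n_slides,
           slides = manifest[, c("slide_id", "seed", "n_follicles")]),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  manifest
}
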