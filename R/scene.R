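# Deterministic per-stage seed derived from one global seed, so adding a
# stage never shifts another stage's random draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) + 1000003 * (h %% 1009)) %% 2147483647)
}

# Distance from pixel grid points to a line segment, vectorized.
segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  tt <- ((px - x1) * vx + (py - y1) * vy) / (vx^2 + vy^2)
  tt <- pmin(pmax(tt, 0), 1)
  sqrt((px - (x1 + tt * vx))^2 + (py - (y1 + tt * vy))^2)
}

# Smooth random field: uniform draws on a coarse grid (one node every
# `scale` pixels), bilinearly upsampled.  Values stay inside [lo, hi].
# Polarimetric tissue parameters vary on scales well above the pixel pitch;
# pixel-scale i.i.d. texture would defeat any mosaic-based reconstruction.
smooth_field <- function(H, W, lo, hi, scale = 8) {
  nh <- ceiling(H / scale) + 1L
  nw <- ceiling(W / scale) + 1L
  coarse <- matrix(stats::runif(nh * nw, lo, hi), nh, nw)
  rows <- round(seq(1, H, length.out = nh))
  cols <- round(seq(1, W, length.out = nw))
  interp_operator(rows, H) %*% coarse %*% t(interp_operator(cols, W))
}

# Logical H x W mask of an axis-aligned ellipse in unit coordinates.
ellipse_mask <- function(H, W, cx, cy, rx, ry) {
  px <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)
  py <- matrix(rep((seq_len(H) - 0.5) / H, times = W), H, W)
  ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1
}

#' Ground-truth polarimetric scene container
#'
#' Per-pixel optical parameters from which every imaging path is derived:
#' linear retardance `delta` (radians, in `[0, pi]`) with fast axis `theta`,
#' diagonal depolarizer factors `a`, `b`, `c` (1 = polarization preserved),
#' a brightness scale, and integer region labels.
#'
#' @param delta,theta,a,b,c,brightness H x W numeric matrices.
#' @param labels H x W integer matrix indexing `label_levels`.
#' @param label_levels character vector of region names.
#' @return list of class `"ground_truth"`.
#' @export
ground_truth <- function(delta, theta, a, b, c, brightness, labels,
                         label_levels) {
  stopifnot(all(delta >= 0 & delta <= pi),
            all(a >= 0 & a <= 1), all(b >= 0 & b <= 1),
            all(c >= 0 & c <= 1))
  structure(list(delta = delta, theta = theta, a = a, b = b, c = c,
                 brightness = brightness, labels = labels,
                 label_levels = label_levels),
            class = "ground_truth")
}

new_scene_spec <- function(kind, shape, illumination, seed, params, truth) {
  counts <- tabulate(truth$labels, nbins = length(truth$label_levels))
  structure(list(kind = kind, shape = shape,
                 illumination = as.numeric(illumination), seed = seed,
                 params = params,
                 regions = data.frame(label = truth$label_levels,
                                      pixels = counts,
                                      fraction = counts / prod(shape))),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %s> %dx%d, seed=%d\n", x$kind,
              x$shape[1], x$shape[2], x$seed))
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Synthetic M-shaped retardance phantom
#'
#' Emulates a two-layer bench phantom: an M-shaped, spatially uniform
#' birefringent target over a purely depolarizing, non-retarding scattering
#' background.  Brightness is matched between target and background so the
#' glyph is nearly invisible in the intensity reference and in colour, but
#' shows full contrast in the retardance map (`A_delta = sin(delta_target)`
#' inside the glyph, about 0 outside).
#'
#' @param shape `c(H, W)`, even, at least 64x64.
#' @param delta_target retardance phase of the film, radians in `(0, pi)`.
#' @param background_dep circular depolarization of the scattering
#'   background (its depolarizer factors are `1 - background_dep`).
#' @param theta_axis fast-axis angle of the film (radians); spatially
#'   uniform, as for a real birefringent film.
#' @param seed integer seed.
#' @param stroke stroke width of the glyph as a fraction of image size.
#' @return list with `spec` ([print.scene_spec()]) and `truth`
#'   ([ground_truth()]).
#' @export
make_m_phantom <- function(shape = c(256L, 256L), delta_target = pi / 3,
                           background_dep = 0.9, theta_axis = pi / 6,
                           seed = 1L, stroke = 0.07) {
  H <- shape[1]; W <- shape[2]
  if (H < 64 || W < 64) stop("shape too small for the M glyph")
  if (delta_target <= 0 || delta_target >= pi)
    stop("delta_target must lie in (0, pi)")
  set.seed(substream_seed(seed, "m_phantom"))

  px <- matrix(rep((seq_len(W) - 0.5) / W, each = H), H, W)
  py <- matrix(rep((seq_len(H) - 0.5) / H, times = W), H, W)
  segs <- rbind(c(0.18, 0.78, 0.18, 0.22),
                c(0.18, 0.22, 0.50, 0.62),
                c(0.50, 0.62, 0.82, 0.22),
                c(0.82, 0.22, 0.82, 0.78))
  dmin <- Reduce(pmin, lapply(seq_len(nrow(segs)), function(i) {
    segment_distance(px, py, segs[i, 1], segs[i, 2], segs[i, 3], segs[i, 4])
  }))
  glyph <- dmin <= stroke / 2

  one <- matrix(1, H, W); zero <- matrix(0, H, W)
  delta <- zero; delta[glyph] <- delta_target
  theta <- matrix(theta_axis, H, W)
  dep <- one * (1 - background_dep)
  a <- b <- c_ <- dep
  a[glyph] <- b[glyph] <- c_[glyph] <- 1     # clear film: no depolarization
  labels <- matrix(1L, H, W); labels[glyph] <- 2L

  truth <- ground_truth(delta, theta, a, b, c_, brightness = one * 0.7,
                        labels = labels,
                        label_levels = c("background", "retarder_target"))
  params <- list(delta_target = delta_target, background_dep = background_dep,
                 stroke = stroke,
                 palette = list(background      = c(0.720, 0.700, 0.660),
                                retarder_target = c(0.720, 0.698, 0.662)))
  list(spec = new_scene_spec("m_phantom", c(H, W), spe_illumination(),
                             seed, params, truth),
       truth = truth)
}

#' Synthetic laryngeal tissue scene
#'
#' A phenomenological two-class larynx scene: normal mucosa (strongly
#' retarding from the collagen of the lamina propria, strongly
#' depolarizing from multiple scattering) with embedded cancerous lesions
#' (low retardance and low depolarization, reflecting collagen disruption),
#' plus blood patches dark enough to underexpose and specular patches bright
#' enough to saturate.  Per-pixel parameters are smooth random fields
#' (coarse per-class uniform draws, bilinearly upsampled): tissue optical
#' properties vary on scales well above the pixel pitch, and the
#' mosaic-based reconstruction assumes as much.
#'
#' @param shape `c(H, W)`, even.
#' @param seed integer seed.
#' @param params per-class parameter ranges; see Details.  Defaults: normal
#'   `delta ~ U(50, 80)` degrees, circular depolarizer factor
#'   `c ~ U(0.1, 0.4)`; cancer `delta ~ U(0, 15)` degrees,
#'   `c ~ U(0.5, 0.8)`; linear factors `a = b = 1`; texture correlation
#'   lengths `texture_px = 16` for retardance/depolarization and
#'   `axis_texture_px = 32` for the fast axis (roughly the 0.5 mm scale on
#'   which laryngeal tissue structure varies).
#' @param n_lesions,n_blood,n_specular number of elliptical patches of each
#'   kind.
#' @return list with `spec` and `truth`, as [make_m_phantom()].
#' @export
make_larynx_scene <- function(shape = c(256L, 256L), seed = 1L,
                              params = list(), n_lesions = 3L,
                              n_blood = 2L, n_specular = 2L) {
  H <- shape[1]; W <- shape[2]
  p <- utils::modifyList(list(
    normal_delta_deg = c(50, 80), normal_c = c(0.1, 0.4),
    cancer_delta_deg = c(0, 15),  cancer_c = c(0.5, 0.8),
    blood_brightness = 0.03, specular_brightness = 3.0,
    base_brightness = 0.7, min_class_px = 64L,
    texture_px = 16, axis_texture_px = 32
  ), params)
  set.seed(substream_seed(seed, "larynx_scene"))

  labels <- matrix(1L, H, W)
  draw_patches <- function(n, lab, r_range) {
    for (i in seq_len(n)) {
      m <- ellipse_mask(H, W, stats::runif(1, 0.15, 0.85),
                        stats::runif(1, 0.15, 0.85),
                        stats::runif(1, r_range[1], r_range[2]),
                        stats::runif(1, r_range[1], r_range[2]))
      labels[m] <<- lab
    }
  }
  draw_patches(n_lesions, 2L, c(0.08, 0.18))
  draw_patches(n_blood, 3L, c(0.03, 0.06))
  draw_patches(n_specular, 4L, c(0.02, 0.05))

  lev <- c("normal", "cancer", "blood", "specular")
  n_class <- tabulate(labels, 4L)
  if (any(n_class[1:2] < p$min_class_px))
    stop("a tissue class has too few pixels; enlarge the scene")

  field <- function(rng) smooth_field(H, W, rng[1], rng[2], p$texture_px)
  delta <- field(p$normal_delta_deg * pi / 180)
  dc <- field(p$cancer_delta_deg * pi / 180)
  delta[labels == 2L] <- dc[labels == 2L]
  delta[labels >= 3L] <- 0
  theta <- smooth_field(H, W, 0, pi, p$axis_texture_px)
  c_ <- field(p$normal_c)
  cc <- field(p$cancer_c)
  c_[labels == 2L] <- cc[labels == 2L]
  c_[labels == 3L] <- 0.2
  c_[labels == 4L] <- 1
  a <- b <- matrix(1, H, W)

  brightness <- matrix(p$base_brightness, H, W)
  brightness[labels == 3L] <- p$blood_brightness
  brightness[labels == 4L] <- p$specular_brightness

  truth <- ground_truth(delta, theta, a, b, c_, brightness, labels, lev)
  p$palette <- list(normal   = c(0.78, 0.56, 0.54),
                    cancer   = c(0.80, 0.52, 0.52),
                    blood    = c(0.30, 0.05, 0.05),
                    specular = c(1.00, 1.00, 1.00))
  list(spec = new_scene_spec("larynx", c(H, W), spe_illumination(),
                             seed, p, truth),
       truth = truth)
}

#' Emergent Stokes image of a ground-truth scene
#'
#' Applies, per pixel, the depolarizer-after-retarder model
#' `S = brightness * M_delta(a,b,c) %*% M_R(delta,theta) %*% S_illum`.
#'
#' @param truth a [ground_truth()].
#' @param illumination length-4 Stokes vector of the illumination;
#'   default ideal right-circular (see [spe_illumination()]).
#' @return a full [stokes_image()].
#' @export
scene_to_stokes <- function(truth, illumination = spe_illumination()) {
  s <- as.numeric(illumination)
  c2 <- cos(2 * truth$theta); s2 <- sin(2 * truth$theta)
  cd <- cos(truth$delta); sd <- sin(truth$delta)
  # rows 2-4 of the rotated-retarder matrix applied to the constant input
  S1 <- (c2^2 + s2^2 * cd) * s[2] + c2 * s2 * (1 - cd) * s[3] - s2 * sd * s[4]
  S2 <- c2 * s2 * (1 - cd) * s[2] + (s2^2 + c2^2 * cd) * s[3] + c2 * sd * s[4]
  S3 <- s2 * sd * s[2] - c2 * sd * s[3] + cd * s[4]
  bB <- truth$brightness
  stokes_image(S0 = bB * s[1], S1 = bB * truth$a * S1,
               S2 = bB * truth$b * S2, S3 = bB * truth$c * S3,
               mode = "full")
}

#' Per-pixel Mueller image of a ground-truth scene
#'
#' Builds `M = brightness * M_delta(a,b,c) %*% M_R(delta,theta)` for every
#' pixel, consistent with [scene_to_stokes()] by construction.
#'
#' @inheritParams scene_to_stokes
#' @return a [mueller_image()].
#' @export
scene_to_mueller <- function(truth) {
  H <- nrow(truth$delta); W <- ncol(truth$delta)
  c2 <- cos(2 * truth$theta); s2 <- sin(2 * truth$theta)
  cd <- cos(truth$delta); sd <- sin(truth$delta)
  bB <- truth$brightness
  M <- array(0, c(H, W, 4, 4))
  M[, , 1, 1] <- bB
  M[, , 2, 2] <- bB * truth$a * (c2^2 + s2^2 * cd)
  M[, , 2, 3] <- bB * truth$a * (c2 * s2 * (1 - cd))
  M[, , 2, 4] <- bB * truth$a * (-s2 * sd)
  M[, , 3, 2] <- bB * truth$b * (c2 * s2 * (1 - cd))
  M[, , 3, 3] <- bB * truth$b * (s2^2 + c2^2 * cd)
  M[, , 3, 4] <- bB * truth$b * (c2 * sd)
  M[, , 4, 2] <- bB * truth$c * (s2 * sd)
  M[, , 4, 3] <- bB * truth$c * (-c2 * sd)
  M[, , 4, 4] <- bB * truth$c * cd
  mueller_image(M)
}

#' Synthetic colour photograph of a scene
#'
#' Renders each labelled region with its base colour from the scene palette,
#' scaled by brightness (relative to the scene's typical level) and with a
#' little sensor noise.  For the phantom the two region colours are nearly
#' identical, emulating a target that is barely perceptible in colour.
#'
#' @param scene a `make_*` result (list with `spec` and `truth`).
#' @param noise_sd per-channel Gaussian noise standard deviation.
#' @param seed integer seed (defaults to the scene seed).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
scene_to_rgb <- function(scene, noise_sd = 0.005, seed = NULL) {
  truth <- scene$truth
  pal <- scene$spec$params$palette
  H <- nrow(truth$labels); W <- ncol(truth$labels)
  if (is.null(seed)) seed <- scene$spec$seed
  set.seed(substream_seed(seed, "scene_rgb"))
  shade <- pmin(truth$brightness / stats::median(truth$brightness), 1.4)
  out <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    base <- matrix(0, H, W)
    for (k in seq_along(truth$label_levels)) {
      base[truth$labels == k] <- pal[[truth$label_levels[k]]][ch]
    }
    out[, , ch] <- pmin(pmax(base * shade +
                               stats::rnorm(H * W, 0, noise_sd), 0), 1)
  }
  out
}
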