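#' Synthetic angiographic phantom frames
#'
#' Generates synthetic X-ray angiographic frames paired with gold-standard
#' masks that emulate the statistical structure of intra-procedural TAVI
#' imaging: a transcatheter heart valve (THV) appears as a dark ("radiopaque")
#' reticular lattice of thin threads on a brighter, smoothly varying noisy
#' background, and its annotation occupies well under 1% of the pixels.
#'
#' The device is modelled as a cylindrical mesh of crossing helical struts,
#' orthographically projected onto the image plane with a seed-dependent
#' viewing direction (in-plane rotation plus out-of-plane tilt), so both the
#' near and the far wall of the stent project into the frame and produce the
#' characteristic diamond pattern.  Four frame types are supported:
#'
#' * `"expanded"` — fully deployed device;
#' * `"deploying"` — only the distal `deployment_fraction` of the lattice is
#'   expanded, the rest tapers into a narrow funnel;
#' * `"contrast"` — an injected-contrast blob obscures part of the device;
#'   the gold mask covers only the visible part (a *partial pattern*);
#' * `"no_device"` — background only, empty mask.
#'
#' Geometry defaults are calibrated constants chosen so that the mean
#' foreground count of expanded-stage masks at 512x512 matches the
#' gold-standard statistic of the clinical regime this generator emulates
#' (about 2350 pixels, i.e. <1% of the image).
#'
#' @param image_size Pixels per side (square frames), >= 64.
#' @param stent_radius,stent_height Device size in pixels; `NULL` (default)
#'   samples them from the calibrated prior using `seed`.
#' @param n_struts Number of helical threads per winding direction.
#' @param thread_width Rendered thread width in pixels (mask support).
#' @param thread_contrast Intensity drop of a thread below the background,
#'   on the 0-255 scale.
#' @param background_noise_scale Standard deviation of per-pixel Gaussian
#'   intensity noise (0-255 scale).
#' @param stage Frame type, one of `"expanded"`, `"deploying"`, `"contrast"`,
#'   `"no_device"`.
#' @param deployment_fraction For `"deploying"` frames, fraction (in `[0,1]`)
#'   of the lattice height that is fully expanded.
#' @param contrast_region For `"contrast"` frames, optional list with
#'   elements `center` (x, y in pixels), `semi_axes` (pixels) and `angle`
#'   (radians) describing the elliptical contrast blob; `NULL` samples one.
#' @param projection_angle,tilt,center Optional viewing parameters (radians,
#'   radians, pixel coordinates); `NULL` samples them from `seed`.
#' @param seed Integer seed; identical seed and parameters give bit-identical
#'   frame and mask.
#'
#' @return `phantom_params()` returns a validated parameter list of class
#'   `"phantom_params"`.
#' @export
phantom_params <- function(image_size = 512L,
                           stent_radius = NULL,
                           stent_height = NULL,
                           n_struts = 6L,
                           thread_width = 1.1,
                           thread_contrast = 70,
                           background_noise_scale = 4,
                           stage = c("expanded", "deploying", "contrast",
                                     "no_device"),
                           deployment_fraction = 1,
                           contrast_region = NULL,
                           projection_angle = NULL,
                           tilt = NULL,
                           center = NULL,
                           seed = 1L) {
  if (length(stage) == 1L && !stage %in%
        c("expanded", "deploying", "contrast", "no_device")) {
    stop_thinseg(
      "invalid stage '", stage,
      "'; allowed stages are: expanded, deploying, contrast, no_device"
    )
  }
  stage <- match.arg(stage)
  if (image_size < 64) stop_thinseg("image_size must be >= 64")
  if (thread_width < 1) stop_thinseg("thread_width must be >= 1")
  if (deployment_fraction < 0 || deployment_fraction > 1) {
    stop_thinseg("deployment_fraction must be in [0, 1]")
  }
  if (n_struts < 1) stop_thinseg("n_struts must be >= 1")
  structure(
    list(
      image_size = as.integer(image_size),
      stent_radius = stent_radius,
      stent_height = stent_height,
      n_struts = as.integer(n_struts),
      thread_width = thread_width,
      thread_contrast = thread_contrast,
      background_noise_scale = background_noise_scale,
      stage = stage,
      deployment_fraction = deployment_fraction,
      contrast_region = contrast_region,
      projection_angle = projection_angle,
      tilt = tilt,
      center = center,
      seed = as.integer(seed)
    ),
    class = "phantom_params"
  )
}

# Calibrated geometry priors, expressed at the reference 512-px frame and
# scaled linearly with image size.  Stored constants (not a runtime fit):
# with these values the mean expanded-mask foreground count at 512x512 sits
# near 2350 pixels and every mask stays below 1% foreground.
.phantom_cal <- list(
  radius = 44,          # mean stent radius [px at 512]
  height = 134,         # mean stent height [px at 512]
  turns = 0.55,         # helix turns over the device height
  size_jitter = 0.04,   # relative sd-like half-range of radius/height
  tilt_range = c(5, 25) * pi / 180,
  bg_level = 175,       # mean background intensity
  bg_amp = 14,          # low-frequency background modulation amplitude
  funnel_min = 0.22     # undeployed funnel radius, as fraction of radius
)

#' Render one phantom frame and its gold-standard mask
#'
#' @param params A [phantom_params()] object.
#' @return A list of class `"thv_frame"` with elements `frame` (integer
#'   matrix, intensities 0-255), `mask` (integer matrix with values 0/1,
#'   foreground = THV threads), `stage`, and `geometry` (the sampled or
#'   supplied geometry/view parameters actually used).
#' @examples
#' fm <- generate_frame(phantom_params(image_size = 128, seed = 3))
#' mean(fm$mask)   # foreground fraction
#' @export
generate_frame <- function(params) {
  if (!inherits(params, "phantom_params")) {
    stop_thinseg("params must be created with phantom_params()")
  }
  local_seed(params$seed, render_phantom(params))
}

# actual renderer; assumes the RNG is already seeded
render_phantom <- function(params) {
  n <- params$image_size
  sc <- n / 512
  cal <- .phantom_cal

  # geometry and view: supplied values win, otherwise sample from the prior
  jit <- function(mu) mu * (1 + runif(1, -cal$size_jitter, cal$size_jitter))
  R <- params$stent_radius %||% (jit(cal$radius) * sc)
  Hs <- params$stent_height %||% (jit(cal$height) * sc)
  phi <- params$projection_angle %||% runif(1, 0, 2 * pi)
  tau <- params$tilt %||% runif(1, cal$tilt_range[1], cal$tilt_range[2])
  ctr <- params$center %||% (n / 2 + runif(2, -0.05 * n, 0.05 * n))

  geometry <- list(
    stent_radius = R, stent_height = Hs, projection_angle = phi,
    tilt = tau, center = ctr, n_struts = params$n_struts,
    turns = cal$turns, thread_width = params$thread_width
  )

  # smooth background field + device + pixel noise
  bg <- phantom_background(n, cal$bg_level, cal$bg_amp)

  opacity <- matrix(0, n, n)
  mask <- matrix(0L, n, n)
  if (params$stage != "no_device") {
    frac <- if (params$stage == "deploying") params$deployment_fraction else 1
    pts <- strut_points(R, Hs, params$n_struts, cal$turns, frac,
                        cal$funnel_min, phi, tau, ctr)
    hit <- matrix(0, n, n)
    keep <- pts$row >= 1 & pts$row <= n & pts$col >= 1 & pts$col <= n
    hit[cbind(pts$row[keep], pts$col[keep])] <- 1
    dist <- edt(hit)
    w2 <- params$thread_width / 2
    opacity <- pmin(1, pmax(0, w2 + 0.5 - dist))
    mask <- matrix(as.integer(dist <= w2), n, n)
  }

  frame <- bg - params$thread_contrast * opacity

  if (params$stage == "contrast") {
    blob <- params$contrast_region %||% sample_contrast_region(ctr, R, Hs)
    q <- ellipse_q(n, blob)
    inside <- q <= 1
    # contrast agent is strongly radiopaque: darken and hide the threads
    frame <- frame - 110 * pmin(1, pmax(0, 1.25 * (1 - q)))
    mask[inside] <- 0L
    geometry$contrast_region <- blob
  }

  frame <- frame + rnorm(n * n, sd = params$background_noise_scale)
  frame <- matrix(as.integer(round(pmin(255, pmax(0, frame)))), n, n)

  structure(
    list(frame = frame, mask = mask, stage = params$stage,
         geometry = geometry),
    class = "thv_frame"
  )
}

# low-frequency Perlin-style field: coarse Gaussian grid, bilinearly
# upsampled, plus a gentle radial vignette
phantom_background <- function(n, level, amp) {
  coarse <- matrix(rnorm(81), 9, 9)
  smooth <- EBImage::resize(coarse, w = n, h = n)
  rr <- ((seq_len(n) - n / 2) / n)
  vig <- outer(rr^2, rr^2, `+`)
  level + amp * smooth - 20 * vig
}

# sampled points (pixel row/col) along the projected helical struts
strut_points <- function(R, Hs, n_struts, turns, deploy_frac, funnel_min,
                         phi, tau, ctr) {
  # arc-length-ish sampling: enough points that consecutive samples are
  # closer than ~0.35 px after projection
  npts <- max(400L, as.integer(4 * (Hs + 2 * pi * R * turns)))
  z <- seq(-Hs / 2, Hs / 2, length.out = npts)
  # radius profile: fully expanded above z0, tapering funnel below
  z0 <- Hs / 2 - deploy_frac * Hs
  r <- ifelse(z >= z0, R,
              R * (funnel_min + (1 - funnel_min) *
                     (z - (-Hs / 2)) / max(z0 - (-Hs / 2), 1e-9)))
  rows <- cols <- integer(0)
  for (k in seq_len(n_struts)) {
    for (dir in c(1, -1)) {
      a0 <- 2 * pi * (k - 1) / n_struts + (dir == -1) * pi / n_struts
      a <- a0 + dir * 2 * pi * turns * (z / Hs + 0.5)
      x3 <- r * cos(a)
      y3 <- r * sin(a)
      u <- x3
      v <- z * cos(tau) - y3 * sin(tau)
      xi <- u * cos(phi) - v * sin(phi) + ctr[1]
      yi <- u * sin(phi) + v * cos(phi) + ctr[2]
      cols <- c(cols, as.integer(round(xi)))
      rows <- c(rows, as.integer(round(yi)))
    }
  }
  list(row = rows, col = cols)
}

sample_contrast_region <- function(ctr, R, Hs) {
  list(
    center = ctr + runif(2, -0.3, 0.3) * c(R, Hs / 2),
    semi_axes = c(runif(1, 0.9, 1.4) * R, runif(1, 0.35, 0.55) * Hs),
    angle = runif(1, 0, pi)
  )
}

# normalized squared elliptical radius for every pixel (<= 1 inside)
ellipse_q <- function(n, blob) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  dx <- xs - blob$center[1]
  dy <- ys - blob$center[2]
  ca <- cos(blob$angle); sa <- sin(blob$angle)
  u <- dx * ca + dy * sa
  v <- -dx * sa + dy * ca
  sqrt((u / blob$semi_axes[1])^2 + (v / blob$semi_axes[2])^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic dataset on disk
#'
#' Writes frames and gold-standard masks as 8-bit grayscale PNG files
#' (masks use values 0/255) plus a CSV manifest, organised by patient and
#' sequence.  Per-patient device geometry (stent size) is sampled once and
#' shared across that patient's sequences; each sequence gets its own
#' projection, and each frame its own noise realisation and a small view
#' drift, mimicking how angiographic runs of the same patient differ.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_patients,sequences_per_patient Counts (>= 1).
#' @param frames_per_sequence Either a single count or a length-2 range from
#'   which each sequence's length is sampled uniformly (default 25-100,
#'   matching typical angiographic run lengths).
#' @param stage_mix Named proportions over frame types (must sum to 1);
#'   the default emulates a peri-procedural archive dominated by
#'   fully-expanded frames with a minority of aortic-root frames without
#'   the device.
#' @param base_seed Integer; the whole dataset is a deterministic function
#'   of it.
#' @param image_size Pixels per side.
#' @return The manifest as a tibble with columns `frame_path`, `mask_path`,
#'   `patient_id`, `sequence_id`, `frame_index`, `stage` (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(out_dir,
                             n_patients = 15L,
                             sequences_per_patient = 3L,
                             frames_per_sequence = c(25L, 100L),
                             stage_mix = c(expanded = 0.88, no_device = 0.12),
                             base_seed = 1L,
                             image_size = 512L) {
  if (n_patients < 1 || sequences_per_patient < 1) {
    stop_thinseg("n_patients and sequences_per_patient must be >= 1")
  }
  if (any(frames_per_sequence < 1)) {
    stop_thinseg("frames_per_sequence must be >= 1")
  }
  if (abs(sum(stage_mix) - 1) > 1e-8) {
    stop_thinseg("stage_mix proportions must sum to 1")
  }
  bad <- setdiff(names(stage_mix),
                 c("expanded", "deploying", "contrast", "no_device"))
  if (length(bad)) {
    stop_thinseg("unknown stage(s) in stage_mix: ",
                 paste(bad, collapse = ", "),
                 "; allowed stages are: expanded, deploying, contrast, ",
                 "no_device")
  }
  dir.create(file.path(out_dir, "frames"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_thinseg("cannot create ", out_dir)

  sc <- image_size / 512
  cal <- .phantom_cal
  rows <- local_seed(base_seed, {
    out <- list()
    frame_counter <- 0L
    for (p in seq_len(n_patients)) {
      pid <- sprintf("P%02d", p)
      # per-patient device geometry, shared across the patient's sequences
      R_p <- cal$radius * sc *
        (1 + runif(1, -cal$size_jitter, cal$size_jitter))
      H_p <- cal$height * sc *
        (1 + runif(1, -cal$size_jitter, cal$size_jitter))
      for (s in seq_len(sequences_per_patient)) {
        sid <- sprintf("S%02d", s)
        nf <- if (length(frames_per_sequence) == 2L) {
          sample(frames_per_sequence[1]:frames_per_sequence[2], 1L)
        } else as.integer(frames_per_sequence)
        phi_s <- runif(1, 0, 2 * pi)
        tau_s <- runif(1, cal$tilt_range[1], cal$tilt_range[2])
        ctr_s <- image_size / 2 + runif(2, -0.05, 0.05) * image_size
        stages <- sample(names(stage_mix), nf, replace = TRUE,
                         prob = stage_mix)
        for (f in seq_len(nf)) {
          frame_counter <- frame_counter + 1L
          drift <- runif(2, -0.01, 0.01) * image_size
          prm <- phantom_params(
            image_size = image_size,
            stent_radius = R_p, stent_height = H_p,
            stage = stages[f],
            deployment_fraction = if (stages[f] == "deploying") {
              runif(1, 0.2, 0.9)
            } else 1,
            projection_angle = phi_s, tilt = tau_s, center = ctr_s + drift,
            seed = base_seed + frame_counter
          )
          fm <- render_phantom(prm)
          stem <- sprintf("%s_%s_%04d", pid, sid, f)
          fp <- file.path(out_dir, "frames", paste0(stem, ".png"))
          mp <- file.path(out_dir, "masks", paste0(stem, ".png"))
          write_frame(fm$frame, fp)
          write_mask(fm$mask, mp)
          out[[frame_counter]] <- tibble::tibble(
            frame_path = fp, mask_path = mp, patient_id = pid,
            sequence_id = sid, frame_index = f, stage = stages[f]
          )
        }
      }
    }
    out
  })
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
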