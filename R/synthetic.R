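# Synthetic chest-radiograph generator: square-ish grayscale images with a
# dark trachea band bifurcating at a carina landmark, an optional bright
# ETT line ending at a distal tip landmark, per-exam pixel spacing, and a
# paired report sentence consistent with the rendered geometry. Exact
# ground truth for every stage of the cascade.

#' Synthetic-cohort parameters
#'
#' Defaults emulate the study population this generator stands in for:
#' ~50% ETT prevalence and a tip-carina distance distribution that is
#' lognormal with median 4.10 cm and log-sd 0.3807 (quartiles ~3.2/5.3 cm,
#' mean ~4.4 cm), truncated to `dist_bounds` by resampling.
#'
#' `spacing_range` is defined at a `spacing_ref`-pixel reference grid and is
#' rescaled by `spacing_ref / image_h`, so a smaller image matrix images the
#' same physical chest at coarser resolution (constant field of view).
#'
#' @param image_h,image_w Image size in pixels (default 512).
#' @param spacing_range Pixel spacing range in mm/px at the reference grid
#'   (default `c(0.6, 0.8)`, isotropic).
#' @param spacing_ref Reference grid for `spacing_range` (default 512).
#' @param anisotropy Extra multiplicative factor range applied to the column
#'   spacing (default `c(1, 1)`: isotropic).
#' @param ett_prevalence Probability an exam carries an ETT (default 0.5).
#' @param dist_median,dist_sdlog Lognormal parameters of the tip-carina
#'   distance in cm (defaults 4.10 and 0.3807).
#' @param dist_bounds Truncation bounds in cm (default `c(0.5, 9)`).
#' @param noise_sd Gaussian intensity noise, on the unit intensity scale
#'   (default 0.04).
#' @param distractor_prob Probability of an off-axis non-ETT tube line that
#'   does not end near the carina (default 0.3).
#' @return A `synth_params` object.
#' @export
synth_params <- function(image_h = 512, image_w = 512,
                         spacing_range = c(0.6, 0.8), spacing_ref = 512,
                         anisotropy = c(1, 1),
                         ett_prevalence = 0.5,
                         dist_median = 4.10, dist_sdlog = 0.3807,
                         dist_bounds = c(0.5, 9.0),
                         noise_sd = 0.04, distractor_prob = 0.3) {
  stopifnot(image_h >= 32, image_w >= 32,
            all(spacing_range > 0), diff(spacing_range) >= 0,
            ett_prevalence >= 0, ett_prevalence <= 1,
            dist_median > 0, dist_sdlog > 0,
            all(dist_bounds > 0), diff(dist_bounds) > 0,
            noise_sd >= 0, distractor_prob >= 0, distractor_prob <= 1)
  structure(as.list(environment()), class = "synth_params")
}

#' Sample the tip-carina distance distribution
#'
#' Truncated lognormal draw (median `dist_median`, log-sd `dist_sdlog`,
#' resampled into `dist_bounds`). Consumes the R RNG stream.
#'
#' @param n Number of draws.
#' @param params A `synth_params`.
#' @return Numeric vector of distances in cm.
#' @export
sample_tip_distance <- function(n, params = synth_params()) {
  lo <- params$dist_bounds[1]; hi <- params$dist_bounds[2]
  d <- rlnorm(n, meanlog = log(params$dist_median), sdlog = params$dist_sdlog)
  bad <- which(d < lo | d > hi)
  while (length(bad) > 0) {
    d[bad] <- rlnorm(length(bad), log(params$dist_median), params$dist_sdlog)
    bad <- bad[d[bad] < lo | d[bad] > hi]
  }
  d
}

#' Sample patient anatomy: trachea centerline and carina landmark
#'
#' The carina falls uniformly in the central region (rows 45-65%, columns
#' 45-55% of the image); the trachea is a slightly curved dark band (width
#' 8-14 px at the 512 reference, scaled with image size) from the top margin
#' to the carina; two bronchial branches leave the carina at 25-40 degrees
#' from vertical. Consumes the R RNG stream.
#'
#' @param params A `synth_params`.
#' @return An `anatomy` list: `carina` (ORIGINAL-frame `landmark`), shape
#'   coefficients, band widths and branch angles (degrees).
#' @export
sample_anatomy <- function(params = synth_params()) {
  h <- params$image_h; w <- params$image_w
  sfac <- h / 512
  cy <- runif(1, 0.45, 0.65) * h
  cx <- runif(1, 0.45, 0.55) * w
  top_off <- runif(1, -0.10, 0.10) * w   # centerline offset at the top margin
  bulge <- runif(1, -0.03, 0.03) * w     # mid-course curvature
  structure(list(
    carina = landmark(cy, cx, "ORIGINAL"),
    top_off = top_off, bulge = bulge,
    trachea_w = runif(1, 8, 14) * sfac,
    tube_w = runif(1, 3, 5) * sfac,
    branch_angle = runif(2, 25, 40),
    branch_len = runif(1, 0.15, 0.22) * h),
    class = "anatomy")
}

# trachea centerline column position at (possibly fractional) rows y <= carina
centerline_x <- function(anat, y) {
  cy <- anat$carina$y; cx <- anat$carina$x
  u <- (cy - y) / cy                     # 0 at carina, 1 at top margin
  cx + anat$top_off * u^2 + anat$bulge * 4 * u * (1 - u)
}

# smooth band profile: ~flat core with soft ~1 px edge
band_profile <- function(d, half_width) {
  exp(-(d / pmax(half_width, 0.5))^4)
}

# band field of one segment p0 -> p1 (profile in [0, 1])
segment_field <- function(p0, p1, width, Y, X) {
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  L2 <- sum(v^2)
  if (L2 < 1e-9) return(band_profile(sqrt((Y - p0[1])^2 + (X - p0[2])^2), width / 2))
  t <- ((Y - p0[1]) * v[1] + (X - p0[2]) * v[2]) / L2
  t[t < 0] <- 0; t[t > 1] <- 1
  d <- sqrt((Y - (p0[1] + t * v[1]))^2 + (X - (p0[2] + t * v[2]))^2)
  band_profile(d, width / 2)
}

# band field of a polyline given as (n x 2) [y, x] vertices: max over segments
polyline_field <- function(pts, width, Y, X) {
  f <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    f <- pmax(f, segment_field(pts[i, ], pts[i + 1, ], width, Y, X))
  }
  f
}

# walk up the trachea centerline to the point whose straight-line distance
# from the carina is `d_mm` millimeters — the chord a radiologist would
# measure (returns NULL when the walk leaves the image top margin)
point_above_carina <- function(anat, d_mm, spacing, margin_px = 4) {
  ys <- seq(anat$carina$y, 0, by = -0.25)
  xs <- centerline_x(anat, ys)
  chord <- sqrt(((ys - anat$carina$y) * spacing$row_mm_per_px)^2 +
                ((xs - anat$carina$x) * spacing$col_mm_per_px)^2)
  if (d_mm > chord[length(chord)]) return(NULL)
  i <- which(chord >= d_mm)[1]
  if (i == 1) i <- 2
  f <- (d_mm - chord[i - 1]) / (chord[i] - chord[i - 1])
  y <- ys[i - 1] + f * (ys[i] - ys[i - 1])
  x <- xs[i - 1] + f * (xs[i] - xs[i - 1])
  if (y < margin_px) return(NULL)
  landmark(y, x, "ORIGINAL")
}

#' Render one synthetic exam
#'
#' Background = low-frequency blob field + Gaussian noise; dark trachea band
#' with bronchial branches; with probability `ett_prevalence` a bright ETT
#' line runs from the top margin along the trachea centerline and terminates
#' at a tip `d` cm above the carina (`d` drawn from the distance
#' distribution and resampled whenever the walk leaves the image); with
#' probability `distractor_prob` an off-axis tube-like line that does NOT
#' end near the carina. The paired report sentence states the rounded
#' distance. Consumes the R RNG stream.
#'
#' @param params A `synth_params`.
#' @param patient_id,exam_id Identifier strings.
#' @param anatomy Optional pre-sampled `anatomy` (repeat exams of one
#'   patient share it); default samples fresh.
#' @param ett_present Optional logical override of the prevalence draw.
#' @return A `synth_exam`: `image` (h x w matrix, unit intensity scale),
#'   `spacing`, ids, `ett_present`, `carina`, `ett_tip` (or `NULL`),
#'   `distance_cm` (geometric, or `NA`), `report_text`, `has_distractor`.
#' @export
render_exam <- function(params = synth_params(), patient_id = "P1",
                        exam_id = "E1", anatomy = NULL, ett_present = NULL) {
  h <- params$image_h; w <- params$image_w
  sp_scale <- params$spacing_ref / h
  row_mm <- runif(1, params$spacing_range[1], params$spacing_range[2]) * sp_scale
  col_mm <- row_mm * runif(1, params$anisotropy[1], params$anisotropy[2])
  spacing <- pixel_spacing(row_mm, col_mm)
  if (is.null(anatomy)) anatomy <- sample_anatomy(params)
  if (is.null(ett_present)) ett_present <- runif(1) < params$ett_prevalence

  Y <- matrix(seq_len(h) - 1, h, w)
  X <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)

  # low-frequency background blob field
  img <- matrix(0.55, h, w)
  for (b in seq_len(4)) {
    by <- runif(1, 0, h); bx <- runif(1, 0, w)
    amp <- runif(1, -0.12, 0.12); sig <- runif(1, 0.2, 0.5) * h
    img <- img + amp * exp(-((Y - by)^2 + (X - bx)^2) / (2 * sig^2))
  }

  # trachea: dark band from top margin to the carina, then two branches
  cy <- anatomy$carina$y; cx <- anatomy$carina$x
  ys <- seq(0, cy, length.out = 8)
  img <- img - 0.30 * polyline_field(cbind(ys, centerline_x(anatomy, ys)),
                                     anatomy$trachea_w, Y, X)
  for (sgn in c(-1, 1)) {
    ang <- anatomy$branch_angle[if (sgn < 0) 1 else 2] * pi / 180
    p1 <- c(cy + anatomy$branch_len * cos(ang),
            cx + sgn * anatomy$branch_len * sin(ang))
    img <- img - 0.22 * polyline_field(rbind(c(cy, cx), p1),
                                       anatomy$trachea_w * 0.8, Y, X)
  }

  tip <- NULL; d_cm <- NA_real_
  if (ett_present) {
    for (try in seq_len(100)) {
      d_cm <- sample_tip_distance(1, params)
      tip <- point_above_carina(anatomy, d_cm * 10, spacing)
      if (!is.null(tip)) break
    }
    if (is.null(tip)) {  # extreme geometry: place the tip halfway up
      d_cm <- NA_real_
      tip <- landmark(cy / 2, centerline_x(anatomy, cy / 2), "ORIGINAL")
    }
    ys <- seq(0, tip$y, length.out = 6)
    xs <- centerline_x(anatomy, ys)
    xs[length(xs)] <- tip$x
    img <- img + 0.35 * polyline_field(cbind(ys, xs), anatomy$tube_w, Y, X)
  }

  has_distractor <- runif(1) < params$distractor_prob
  if (has_distractor) {
    # an off-axis tube (e.g. nasogastric) well lateral to the carina
    side <- sample(c(-1, 1), 1)
    x0 <- cx + side * runif(1, 0.18, 0.30) * w
    x1 <- x0 + side * runif(1, 0.02, 0.08) * w
    y1 <- runif(1, 0.75, 0.95) * h
    img <- img + 0.30 * polyline_field(rbind(c(0, x0), c(y1, x1)),
                                       anatomy$tube_w, Y, X)
  }

  if (params$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, sd = params$noise_sd), h, w)
  }

  report <- if (ett_present && is.finite(d_cm)) {
    sprintf("Endotracheal tube tip terminates %.1f cm above the carina.", d_cm)
  } else if (ett_present) {
    "Endotracheal tube is present."
  } else {
    "No endotracheal tube is seen."
  }
  if (has_distractor) {
    report <- paste(report, "A nasogastric tube is noted.")
  }

  structure(list(image = img, spacing = spacing,
                 patient_id = patient_id, exam_id = exam_id,
                 ett_present = ett_present, carina = anatomy$carina,
                 ett_tip = tip, distance_cm = d_cm,
                 report_text = report, has_distractor = has_distractor,
                 anatomy = anatomy),
            class = "synth_exam")
}

#' Generate a synthetic cohort
#'
#' Samples patients (each with its own anatomy), renders 1 or more exams per
#' patient (repeat exams share patient anatomy with a small carina
#' translation) and assembles the manifest shared with the training harness.
#' ETT status is assigned at the patient level. With `out_dir` set, each
#' exam is written as a 16-bit PGM plus JSON sidecar (see
#' [write_synth_exam()]); otherwise (or additionally) a per-exam `transform`
#' can consume exams in memory.
#'
#' @param n_patients Number of patients.
#' @param exams_per_patient Inclusive integer range, default `c(1, 2)`.
#' @param params A `synth_params`.
#' @param seed Optional seed (sets the R RNG locally).
#' @param out_dir Optional output directory for PGM + sidecar files.
#' @param transform Optional `function(exam)`; its results are returned as
#'   the `exams` attribute in place of the raw exams (use to keep memory
#'   bounded on large cohorts).
#' @param keep_exams Keep exams (or transformed exams) in the `exams`
#'   attribute (default TRUE when `out_dir` is NULL).
#' @return The manifest data frame (`exam_id`, `patient_id`, `path`,
#'   `label`, `carina_y`, `carina_x`, `tip_y`, `tip_x`, `spacing_row_mm`,
#'   `spacing_col_mm`, `report_text`), with attribute `exams` when kept.
#' @export
generate_dataset <- function(n_patients, exams_per_patient = c(1, 2),
                             params = synth_params(), seed = NULL,
                             out_dir = NULL, transform = NULL,
                             keep_exams = is.null(out_dir)) {
  if (!is.null(seed)) {
    return(withr_seed(seed, generate_dataset(n_patients, exams_per_patient,
                                             params, NULL, out_dir,
                                             transform, keep_exams)))
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
      ettc_error(sprintf("cannot create output directory %s", out_dir),
                 "ettc_io_error")
    }
  }
  rows <- list(); kept <- list(); k <- 0
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%05d", p)
    anat <- sample_anatomy(params)
    status <- runif(1) < params$ett_prevalence
    n_ex <- sample(seq(exams_per_patient[1], exams_per_patient[2]), 1)
    for (e in seq_len(n_ex)) {
      k <- k + 1
      eid <- sprintf("%s_E%d", pid, e)
      a <- anat
      if (e > 1) {  # repeat exam: same anatomy, small translation
        a$carina <- landmark(a$carina$y + runif(1, -6, 6) * params$image_h / 512,
                             a$carina$x + runif(1, -6, 6) * params$image_w / 512,
                             "ORIGINAL")
      }
      ex <- render_exam(params, pid, eid, anatomy = a, ett_present = status)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(eid, ".pgm"))
        write_synth_exam(ex, out_dir)
      }
      rows[[k]] <- data.frame(
        exam_id = eid, patient_id = pid, path = path,
        label = as.integer(ex$ett_present),
        carina_y = ex$carina$y, carina_x = ex$carina$x,
        tip_y = if (is.null(ex$ett_tip)) NA_real_ else ex$ett_tip$y,
        tip_x = if (is.null(ex$ett_tip)) NA_real_ else ex$ett_tip$x,
        spacing_row_mm = ex$spacing$row_mm_per_px,
        spacing_col_mm = ex$spacing$col_mm_per_px,
        report_text = ex$report_text,
        stringsAsFactors = FALSE)
      if (keep_exams) {
        kept[[k]] <- if (is.null(transform)) ex else transform(ex)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (keep_exams) attr(manifest, "exams") <- kept
  manifest
}
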