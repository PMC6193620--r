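# Synthetic cohort generator: ultrasound-like frames in the four standard
# severity grades, with severity-linked blood gases and two simulated raters.
# Everything downstream (ROI, texture, regression, clinical statistics) is
# testable against these cohorts without any clinical images.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All generator randomness flows through this.
with_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of one synthetic ultrasound frame
#'
#' @param grade integer severity class in 0..3: 0 = normal aerated pattern
#'   (horizontal A-line reverberations), 1 = more than three well-spaced
#'   vertical B lines, 2 = coalescent B lines raising the subpleural mean,
#'   3 = irregular pleural line with a near-uniformly bright subpleural field
#'   and darker consolidation blobs.
#' @param width,height frame size in pixels. The defaults (512 wide, 384
#'   deep) leave room for a 100,000-pixel region of interest below the
#'   pleural line.
#' @param pleural_depth row of the pleural line (pixels from the skin
#'   surface); must be shallower than a quarter of the frame height.
#' @param seed integer seed making the frame reproducible in isolation
#' @return an object of class `frame_spec`
#' @export
frame_spec <- function(grade, width = 512, height = 384, pleural_depth = 48,
                       seed = 1L) {
  stop_if_not(length(grade) == 1 && is.finite(grade) && grade == round(grade) &&
                grade >= 0 && grade <= 3,
              "grade must be an integer in 0..3")
  stop_if_not(is_count(width) && is_count(height), "width/height must be positive integers")
  stop_if_not(pleural_depth >= 1 && pleural_depth < height / 4,
              "pleural_depth must be positive and < height/4")
  structure(list(width = as.integer(width), height = as.integer(height),
                 pleural_depth = as.integer(pleural_depth),
                 grade = as.integer(grade), seed = as.integer(seed)),
            class = "frame_spec")
}

# Draw a vertical hyperechoic streak (B line) from just below the pleura to
# the bottom of the frame.
draw_streak <- function(img, top, center, half_width, value) {
  cols <- max(1, center - half_width):min(ncol(img), center + half_width)
  img[top:nrow(img), cols] <- value
  img
}

#' Generate one synthetic B-mode frame
#'
#' Renders a noiseless scene for the requested severity grade — bright
#' pleural band, grade-dependent subpleural content — then applies
#' multiplicative Rayleigh speckle and quantizes to 8 bits. The expected
#' subpleural mean intensity is strictly increasing in grade by
#' construction: grade 0 is dark background with a few A-line echoes,
#' grade 1 adds sparse bright streaks, grade 2 overlapping wide streaks on a
#' raised background, grade 3 a bright field with darker consolidations.
#'
#' @param spec a [frame_spec()]
#' @param speckle_sigma speckle strength in (0, 1]; the multiplier applied to
#'   each pixel is `1 + speckle_sigma * (X - 1)` where `X` is a
#'   Rayleigh-distributed amplitude normalized to unit mean, so the expected
#'   image is the noiseless scene and `speckle_sigma = 0` is exactly
#'   noise-free.
#' @param dark_level background gray level of non-aerated dark regions
#' @param patient_id,view optional metadata carried on the frame
#' @return an [lus_frame()]
#' @export
generate_frame <- function(spec, speckle_sigma = 0.3, dark_level = 20,
                           patient_id = NA_character_, view = NA_character_) {
  stop_if_not(inherits(spec, "frame_spec"), "spec must be a frame_spec")
  h <- spec$height; w <- spec$width; pd <- spec$pleural_depth
  sub_top <- pd + 4  # first row clearly below the pleural band

  px <- with_rng(spec$seed, {
    img <- matrix(as.numeric(dark_level), h, w)

    if (spec$grade == 0L) {
      # A lines: reverberations of the pleura at integer multiples of its
      # depth, fading with depth.
      k <- 2
      while (k * pd + 1 <= h) {
        val <- dark_level + 75 * 0.8^(k - 2)
        img[(k * pd):min(h, k * pd + 1), ] <- val
        k <- k + 1
      }
    } else if (spec$grade == 1L) {
      nb <- sample(4:8, 1)
      slot <- w / nb
      centers <- round((seq_len(nb) - 0.5) * slot + stats::runif(nb, -slot / 4, slot / 4))
      for (b in seq_len(nb)) {
        img <- draw_streak(img, sub_top, centers[b], sample(1:2, 1),
                           150 + stats::rnorm(1, 0, 8))
      }
    } else if (spec$grade == 2L) {
      img[sub_top:h, ] <- dark_level + 25  # partial loss of aeration
      nb <- sample(9:14, 1)
      centers <- sort(sample.int(w, nb))
      for (b in seq_len(nb)) {
        img <- draw_streak(img, sub_top, centers[b], sample(7:13, 1),
                           165 + stats::rnorm(1, 0, 8))
      }
    } else {
      # Near-complete loss of aeration: bright field + darker consolidations.
      img[sub_top:h, ] <- 170
      nb <- sample(3:6, 1)
      for (b in seq_len(nb)) {
        cr <- sample(seq(min(sub_top + 30, h - 1), h - 10), 1)
        cc <- sample.int(w, 1)
        rr <- sample(8:20, 1); rc <- sample(15:40, 1)
        rows <- max(sub_top, cr - rr):min(h, cr + rr)
        cols <- max(1, cc - rc):min(w, cc + rc)
        ell <- outer((rows - cr) / rr, (cols - cc) / rc,
                     function(a, b) a^2 + b^2) <= 1
        blk <- img[rows, cols, drop = FALSE]
        blk[ell] <- 60
        img[rows, cols] <- blk
      }
    }

    # Pleural band; irregular and jittered at grade 3.
    if (spec$grade == 3L) {
      jit <- round(stats::runmed(stats::rnorm(w, 0, 4), 21))
      bright <- 200 + round(stats::runmed(stats::rnorm(w, 0, 25), 11))
      for (cc in seq_len(w)) {
        r0 <- clip(pd + jit[cc], 1, h - 4)
        img[r0:(r0 + 3), cc] <- clip(bright[cc], 150, 245)
      }
    } else {
      img[pd:(pd + 3), ] <- 230
    }

    if (speckle_sigma > 0) {
      u <- pmax(stats::runif(h * w), 1e-12)
      x <- sqrt(-2 * log(u)) / sqrt(pi / 2)  # Rayleigh amplitude, unit mean
      img <- img * (1 + speckle_sigma * (x - 1))
    }
    matrix(clip(round(img), 0, 255), h, w)
  })

  lus_frame(px, patient_id = patient_id, view = view)
}

#' Synthetic cohort configuration
#'
#' Bundles every constant of the severity law linking the latent severity
#' `s` in \code{[0, 1]} to frame grades and blood gases:
#' per-view grade `clip(round(3 s + eps), 0, 3)` with
#' `eps ~ Normal(0, grade_noise_sd)`; `FiO2 = fio2_base + fio2_slope * s`;
#' `PaO2/FiO2 = clip(ratio_intercept - ratio_slope * s + Normal(0, ratio_sd),
#' ratio_range)`; `PaO2 = ratio * FiO2`; `PaCO2 ~ clip(Normal(paco2_mean,
#' paco2_sd), paco2_range)`. Each rater reports the true grade with
#' probability `1 - rater_error_rate`, otherwise an adjacent grade.
#'
#' @param n_patients number of patients (>= 2)
#' @param views_per_patient frames per patient; default 8 (four standard
#'   views per side)
#' @param rater_error_rate per-frame probability that a rater misgrades by
#'   one level
#' @param seed global integer seed driving the hierarchical seed stream
#' @param width,height,pleural_depth,speckle_sigma,dark_level frame
#'   rendering parameters, see [frame_spec()] and [generate_frame()]
#' @param grade_noise_sd SD of the grade jitter around `3 s`
#' @param ratio_intercept,ratio_slope,ratio_sd,ratio_range PaO2/FiO2 law
#'   (mmHg): value at `s = 0`, drop to `s = 1`, Gaussian noise SD, clip range
#' @param fio2_base,fio2_slope inspired oxygen fraction law
#' @param paco2_mean,paco2_sd,paco2_range arterial CO2 law (mmHg)
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_patients = 75, views_per_patient = 8,
                          rater_error_rate = 0.05, seed = 1L,
                          width = 512, height = 384, pleural_depth = 48,
                          speckle_sigma = 0.3, dark_level = 20,
                          grade_noise_sd = 0.5,
                          ratio_intercept = 400, ratio_slope = 280,
                          ratio_sd = 40, ratio_range = c(50, 500),
                          fio2_base = 0.21, fio2_slope = 0.59,
                          paco2_mean = 45, paco2_sd = 7,
                          paco2_range = c(25, 80)) {
  stop_if_not(is_count(n_patients) && n_patients >= 2, "n_patients must be >= 2")
  stop_if_not(is_count(views_per_patient), "views_per_patient must be a positive integer")
  stop_if_not(rater_error_rate >= 0 && rater_error_rate <= 1,
              "rater_error_rate must be a probability")
  stop_if_not(fio2_base + fio2_slope <= 1 && fio2_base >= 0.21,
              "FiO2 law must stay within [0.21, 1]")
  structure(list(
    n_patients = as.integer(n_patients),
    views_per_patient = as.integer(views_per_patient),
    rater_error_rate = rater_error_rate, seed = as.integer(seed),
    width = width, height = height, pleural_depth = pleural_depth,
    speckle_sigma = speckle_sigma, dark_level = dark_level,
    grade_noise_sd = grade_noise_sd,
    ratio_intercept = ratio_intercept, ratio_slope = ratio_slope,
    ratio_sd = ratio_sd, ratio_range = ratio_range,
    fio2_base = fio2_base, fio2_slope = fio2_slope,
    paco2_mean = paco2_mean, paco2_sd = paco2_sd, paco2_range = paco2_range
  ), class = "cohort_config")
}

# The eight standard scan positions: four views per side.
standard_views <- function(n = 8) {
  base <- c("emiclavear", "ant_axillary", "mid_axillary", "post_axillary")
  if (n == 8) paste(rep(c("R", "L"), each = 4), base, sep = "_")
  else paste0("view", seq_len(n))
}

#' Generate one synthetic patient record
#'
#' @param severity latent severity `s` in \code{[0, 1]}
#' @param config a [cohort_config()]
#' @param seed integer seed for this patient (frames derive per-view child
#'   seeds from it)
#' @param patient_id identifier
#' @return an object of class `lus_patient` with fields `frames` (list of
#'   [lus_frame()]), `true_grades`, `rater_grades` (two integer vectors),
#'   `fio2`, `pao2`, `paco2`
#' @export
generate_patient <- function(severity, config = cohort_config(), seed = 1L,
                             patient_id = "P001") {
  stop_if_not(length(severity) == 1 && is.finite(severity) &&
                severity >= 0 && severity <= 1,
              "severity must lie in [0, 1]")
  nv <- config$views_per_patient
  views <- standard_views(nv)

  st <- with_rng(seed, {
    eps <- stats::rnorm(nv, 0, config$grade_noise_sd)
    grades <- as.integer(clip(round(3 * severity + eps), 0, 3))
    ratio <- clip(config$ratio_intercept - config$ratio_slope * severity +
                    stats::rnorm(1, 0, config$ratio_sd),
                  config$ratio_range[1], config$ratio_range[2])
    paco2 <- clip(stats::rnorm(1, config$paco2_mean, config$paco2_sd),
                  config$paco2_range[1], config$paco2_range[2])
    raters <- lapply(1:2, function(r) {
      err <- stats::runif(nv) < config$rater_error_rate
      step <- sample(c(-1L, 1L), nv, replace = TRUE)
      as.integer(clip(grades + ifelse(err, step, 0L), 0, 3))
    })
    list(grades = grades, ratio = ratio, paco2 = paco2, raters = raters)
  })

  fio2 <- config$fio2_base + config$fio2_slope * severity
  frames <- lapply(seq_len(nv), function(v) {
    generate_frame(
      frame_spec(grade = st$grades[v], width = config$width,
                 height = config$height, pleural_depth = config$pleural_depth,
                 seed = derive_seed(seed, 100 + v)),
      speckle_sigma = config$speckle_sigma, dark_level = config$dark_level,
      patient_id = patient_id, view = views[v]
    )
  })

  structure(list(
    patient_id = patient_id, severity = severity, frames = frames,
    true_grades = st$grades,
    rater_grades = list(rater1 = st$raters[[1]], rater2 = st$raters[[2]]),
    fio2 = fio2, pao2 = st$ratio * fio2, paco2 = st$paco2, seed = seed
  ), class = "lus_patient")
}

#' Generate a full synthetic cohort
#'
#' Latent severities are drawn uniformly on \code{[0, 1]}; each patient then
#' gets `views_per_patient` frames, two raters' grades and blood gases from
#' the severity law in [cohort_config()]. Fully reproducible: the same
#' config (including seed) yields a bit-identical cohort.
#'
#' @param config a [cohort_config()]
#' @return a list of [generate_patient()] records, class `lus_cohort`
#' @export
generate_cohort <- function(config = cohort_config()) {
  stop_if_not(inherits(config, "cohort_config"), "config must be a cohort_config")
  n <- config$n_patients
  severities <- with_rng(derive_seed(config$seed, 0), stats::runif(n))
  ids <- sprintf("P%03d", seq_len(n))
  cohort <- lapply(seq_len(n), function(i) {
    generate_patient(severities[i], config, seed = derive_seed(config$seed, i),
                     patient_id = ids[i])
  })
  structure(cohort, class = "lus_cohort", config = config)
}

#' @export
print.lus_cohort <- function(x, ...) {
  nf <- sum(vapply(x, function(p) length(p$frames), integer(1)))
  cat(sprintf("<lus_cohort> %d patients, %d frames\n", length(x), nf))
  invisible(x)
}
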