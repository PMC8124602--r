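# Parametric pig phenotypes.
#
# A phenotype is a small set of morphometric traits (body length BL,
# shoulder width SW, shoulder height SH, hip width HW, hip height HH, all
# cm), a body weight (kg), and posture parameters (yaw, lateral offset,
# vertical head displacement, spine bend).  The body solid is a loft of
# half-elliptical cross-sections along the spine whose half-width w(s) and
# apex height a(s) profiles are piecewise linear through six stations:
# snout tip, ear root, shoulder, hip, tail root, tail tip.  Head and tail
# are rendered as tapered appendages beyond the ear-root/tail-root extent,
# so BL keeps its "ear root to tail root" meaning.

# Trunk proportions at latent size 1 (a mid-sized finishing pig), cm.
PIG_BASE <- c(BL = 100, SW = 26, SH = 56, HW = 24, HH = 54)

# Station geometry relative to BL and to the section traits.
PIG_PROFILE <- list(
  head_frac = 0.15,   # head appendage length / BL, forward of the ear root
  tail_frac = 0.05,   # tail appendage length / BL, behind the tail root
  shoulder_frac = 0.20,  # shoulder station position / BL
  hip_frac = 0.85,       # hip station position / BL
  neck_w = 0.60, neck_a = 0.85,   # ear-root width/height as fraction of SW/2, SH
  rump_w = 0.55, rump_a = 0.70)   # tail-root width/height as fraction of HW/2, HH

#' Construct a pig phenotype
#'
#' Low-level constructor with full validation; see [sample_phenotype()] for
#' the population sampler.
#'
#' @param body_length_cm,shoulder_width_cm,shoulder_height_cm,hip_width_cm,hip_height_cm
#'   trunk morphometry in cm (BL: ear root to tail root; SW/HW: widest
#'   transverse extent at shoulder/hip; SH/HH: highest point at the
#'   shoulder/hip section).
#' @param body_weight_kg body weight in kg.
#' @param yaw_deg orientation of the spine relative to the platform long
#'   axis, degrees.
#' @param lateral_offset_cm sideways displacement of the body centre from
#'   the platform centre line, cm.
#' @param head_pitch_cm vertical displacement of the shoulder apex caused by
#'   head movement, cm (range about +/- 4).
#' @param bend_deg spine curvature: angle between the front and rear spine
#'   direction, degrees (0 = straight pig).
#' @return an object of class `pig_phenotype`.
#' @export
pig_phenotype <- function(body_length_cm, shoulder_width_cm, shoulder_height_cm,
                          hip_width_cm, hip_height_cm, body_weight_kg,
                          yaw_deg = 0, lateral_offset_cm = 0,
                          head_pitch_cm = 0, bend_deg = 0) {
  p <- list(body_length_cm = body_length_cm,
            shoulder_width_cm = shoulder_width_cm,
            shoulder_height_cm = shoulder_height_cm,
            hip_width_cm = hip_width_cm,
            hip_height_cm = hip_height_cm,
            body_weight_kg = body_weight_kg,
            yaw_deg = yaw_deg, lateral_offset_cm = lateral_offset_cm,
            head_pitch_cm = head_pitch_cm, bend_deg = bend_deg)
  for (f in names(p)) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("field '", f, "' must be a single finite number")
  }
  lengths <- p[1:6]
  bad <- names(lengths)[unlist(lengths) <= 0]
  if (length(bad)) stop("field '", bad[1], "' must be > 0")
  if (abs(p$head_pitch_cm) > 8)
    stop("field 'head_pitch_cm' outside the plausible +/- 8 cm range")
  class(p) <- "pig_phenotype"
  p
}

#' @export
print.pig_phenotype <- function(x, ...) {
  cat(sprintf(
    "<pig_phenotype> BW %.1f kg | BL %.1f SW %.1f SH %.1f HW %.1f HH %.1f cm | yaw %.1f deg, offset %.1f cm, head pitch %+.1f cm, bend %.1f deg\n",
    x$body_weight_kg, x$body_length_cm, x$shoulder_width_cm, x$shoulder_height_cm,
    x$hip_width_cm, x$hip_height_cm, x$yaw_deg, x$lateral_offset_cm,
    x$head_pitch_cm, x$bend_deg))
  invisible(x)
}

# Piecewise-linear (s, half-width, apex-height) profile of the loft, cm.
# `as_imaged` raises the shoulder apex by the head pitch, as the camera
# sees it; the at-rest profile is what the weight model integrates.
body_profile <- function(phen, as_imaged = FALSE) {
  pr <- PIG_PROFILE
  bl <- phen$body_length_cm
  sh <- phen$shoulder_height_cm + if (as_imaged) phen$head_pitch_cm else 0
  s <- c(-pr$head_frac * bl, 0, pr$shoulder_frac * bl, pr$hip_frac * bl,
         bl, bl + pr$tail_frac * bl)
  w <- c(0, pr$neck_w * phen$shoulder_width_cm / 2, phen$shoulder_width_cm / 2,
         phen$hip_width_cm / 2, pr$rump_w * phen$hip_width_cm / 2, 0)
  a <- c(0, pr$neck_a * sh, sh, phen$hip_height_cm, pr$rump_a * phen$hip_height_cm, 0)
  list(s = s, w = w, a = a)
}

#' Analytic body volume of the lofted solid
#'
#' The cross-section at axial position `s` is the upper half of an ellipse
#' with half-width `w(s)` and height `a(s)`, giving section area
#' `(pi/2) w(s) a(s)`.  With piecewise-linear profiles the integrand is
#' quadratic on each segment, so Simpson's rule per segment is exact.
#'
#' @param phen a [pig_phenotype()].
#' @param as_imaged if `TRUE`, use the shoulder apex as displaced by head
#'   pitch (what the camera integrates); if `FALSE` (default), the at-rest
#'   body that the scale weighs.
#' @return volume in cm^3.
#' @export
body_volume_cm3 <- function(phen, as_imaged = FALSE) {
  pr <- body_profile(phen, as_imaged = as_imaged)
  area <- function(w, a) (pi / 2) * w * a
  v <- 0
  for (i in seq_len(length(pr$s) - 1)) {
    h <- pr$s[i + 1] - pr$s[i]
    mid_w <- (pr$w[i] + pr$w[i + 1]) / 2
    mid_a <- (pr$a[i] + pr$a[i + 1]) / 2
    v <- v + h / 6 * (area(pr$w[i], pr$a[i]) + 4 * area(mid_w, mid_a) +
                        area(pr$w[i + 1], pr$a[i + 1]))
  }
  v
}

#' Phenotype from a latent size scalar
#'
#' Deterministic allometric core of the sampler: every linear trait scales
#' with `size`, so volume (and therefore noise-free weight) scales with
#' `size^3`.
#'
#' @param size latent size scalar (1 = mid-sized pig, BL 100 cm).
#' @param shape_mult named or positional multipliers for (BL, SW, SH, HW,
#'   HH); defaults to 1 (no shape noise).
#' @param density_g_cm3 tissue density; default 1.0.
#' @param weight_mult multiplicative weight noise term (1 = none).
#' @param yaw_deg,lateral_offset_cm,head_pitch_cm,bend_deg posture, passed
#'   through.
#' @return a [pig_phenotype()].
#' @export
phenotype_from_latent <- function(size, shape_mult = rep(1, 5), density_g_cm3 = 1,
                                  weight_mult = 1, yaw_deg = 0, lateral_offset_cm = 0,
                                  head_pitch_cm = 0, bend_deg = 0) {
  if (!is.finite(density_g_cm3) || density_g_cm3 <= 0)
    stop("field 'density_g_cm3' must be a finite positive number")
  stopifnot(length(shape_mult) == 5, all(is.finite(shape_mult)), all(shape_mult > 0))
  dims <- PIG_BASE * size * shape_mult
  # SW is by definition the widest transverse extent: keep HW strictly below
  if (dims["HW"] >= dims["SW"]) dims["HW"] <- 0.97 * dims["SW"]
  phen <- pig_phenotype(dims[["BL"]], dims[["SW"]], dims[["SH"]], dims[["HW"]],
                        dims[["HH"]], body_weight_kg = 1,
                        yaw_deg = yaw_deg, lateral_offset_cm = lateral_offset_cm,
                        head_pitch_cm = head_pitch_cm, bend_deg = bend_deg)
  phen$body_weight_kg <- density_g_cm3 / 1000 * body_volume_cm3(phen) * weight_mult
  phen
}

#' Sample a pig phenotype from the population
#'
#' Draws a body weight uniformly over `weight_range_kg`, a multiplicative
#' lognormal weight-noise term, and per-trait shape multipliers (lognormal,
#' truncated to +/- 5 percent), then solves for the latent size that makes
#' `BW = density * volume * noise` hold exactly.  Posture (yaw, offset,
#' head pitch, bend) is drawn from ranges typical of a pig drinking at a
#' trough, truncated so the body stays on the platform.
#'
#' @param weight_range_kg length-2 numeric, the population weight range.
#' @param seed optional integer; when given, seeds the RNG so repeated calls
#'   are identical.  When `NULL`, draws from the current RNG stream.
#' @param density_g_cm3 tissue density (g/cm^3).
#' @param weight_noise_sd sd of the log weight-noise term.
#' @param shape_noise_sd sd of the log shape multipliers (truncated at 5%).
#' @param posture if `FALSE`, the pig is straight, centred and level.
#' @param platform_length_m,platform_width_m platform extent used to
#'   truncate posture draws.
#' @return a [pig_phenotype()].
#' @export
sample_phenotype <- function(weight_range_kg = c(16.5, 117), seed = NULL,
                             density_g_cm3 = 1, weight_noise_sd = 0.03,
                             shape_noise_sd = 0.02, posture = TRUE,
                             platform_length_m = 1.5, platform_width_m = 0.5) {
  if (!is.numeric(weight_range_kg) || length(weight_range_kg) != 2 ||
      any(!is.finite(weight_range_kg)) || weight_range_kg[1] <= 0 ||
      weight_range_kg[2] <= weight_range_kg[1] || weight_range_kg[2] > 200)
    stop("field 'weight_range_kg' must be an increasing pair within (0, 200)")
  if (!is.numeric(density_g_cm3) || !is.finite(density_g_cm3) || density_g_cm3 <= 0)
    stop("field 'density_g_cm3' must be a finite positive number")
  if (!is.null(seed)) set.seed(as.integer(seed))

  bw <- runif(1, weight_range_kg[1], weight_range_kg[2])
  noise <- exp(rnorm(1, 0, weight_noise_sd))
  mult <- exp(pmin(pmax(rnorm(5, 0, shape_noise_sd), log(0.95)), log(1.05)))

  # volume the loft must enclose so that BW = density * V * noise
  v_target <- bw / (density_g_cm3 / 1000 * noise)
  unit <- phenotype_from_latent(1, shape_mult = mult, density_g_cm3 = density_g_cm3)
  size <- (v_target / body_volume_cm3(unit))^(1 / 3)

  yaw <- 0; offset <- 0; pitch <- 0; bend <- 0
  if (posture) {
    base <- phenotype_from_latent(size, shape_mult = mult,
                                  density_g_cm3 = density_g_cm3)
    pitch <- runif(1, -4, 4)
    bend <- pmin(pmax(rnorm(1, 0, 5), -12), 12)
    # feasible yaw/offset from the platform slack for the actual body
    pr <- PIG_PROFILE
    total_len <- base$body_length_cm * (1 + pr$head_frac + pr$tail_frac)
    half_w <- base$shoulder_width_cm / 2 +
      abs(bend_offset_cm(total_len / 2, bend, total_len))
    max_yaw <- feasible_yaw_deg(total_len, half_w,
                                platform_length_m * 100, platform_width_m * 100)
    yaw <- pmin(pmax(rnorm(1, 0, 4), -max_yaw), max_yaw)
    th <- yaw * pi / 180
    slack <- platform_width_m * 100 / 2 -
      (total_len / 2 * abs(sin(th)) + half_w * cos(th))
    if (slack > 0) offset <- pmin(pmax(rnorm(1, 0, 3), -0.9 * slack), 0.9 * slack)
  }
  phen <- phenotype_from_latent(size, shape_mult = mult, density_g_cm3 = density_g_cm3,
                                weight_mult = noise, yaw_deg = yaw,
                                lateral_offset_cm = offset, head_pitch_cm = pitch,
                                bend_deg = bend)
  phen
}

# Largest |yaw| (deg, with a 2% safety margin) at which a body of given
# total length and half-width still fits the platform when centred.
feasible_yaw_deg <- function(total_len_cm, half_w_cm, platform_l_cm, platform_w_cm) {
  fits <- function(yaw) {
    th <- yaw * pi / 180
    total_len_cm / 2 * abs(sin(th)) + half_w_cm * cos(th) <= 0.98 * platform_w_cm / 2 &&
      total_len_cm / 2 * cos(th) + half_w_cm * abs(sin(th)) <= 0.98 * platform_l_cm / 2
  }
  if (!fits(0)) return(0)
  lo <- 0; hi <- 45
  if (fits(hi)) return(hi)
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (fits(mid)) lo <- mid else hi <- mid
  }
  lo
}

#' Label vector of a phenotype
#'
#' @param phen a [pig_phenotype()].
#' @param sh_label `"as_imaged"` labels SH as the camera sees the shoulder
#'   apex (at-rest SH plus head pitch); `"at_rest"` labels the measured
#'   standing SH.
#' @return named numeric of length 6, order BW, SW, SH, HW, HH, BL.
#' @export
phenotype_labels <- function(phen, sh_label = c("as_imaged", "at_rest")) {
  sh_label <- match.arg(sh_label)
  sh <- phen$shoulder_height_cm + if (sh_label == "as_imaged") phen$head_pitch_cm else 0
  setNames(c(phen$body_weight_kg, phen$shoulder_width_cm, sh,
             phen$hip_width_cm, phen$hip_height_cm, phen$body_length_cm),
           TARGET_NAMES)
}
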