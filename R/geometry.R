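#' Squeeze-channel geometry
#'
#' Describes the microfluidic constriction the cells transit. The default
#' matches the device used throughout the package: a 5.2 µm gap (smaller than
#' either cell population's mean diameter, which is what forces deformation)
#' with a 20 µm front-to-back depth.
#'
#' @param gap_height Constriction gap from top to bottom wall, µm.
#' @param depth Front-to-back channel depth, µm (metadata only; the rendered
#'   images and the simulator are two-dimensional).
#' @param constriction_length Axial length of the narrow segment, µm.
#' @param channel_length Total rendered channel length, µm.
#' @param pixel_scale Image scale, µm per pixel.
#' @param wide_gap Channel gap outside the constriction, µm. Drives the
#'   velocity peak inside the narrow segment through mass conservation.
#'
#' @return A `channel_geometry` list.
#' @examples
#' channel_geometry()
#' @export
channel_geometry <- function(gap_height = 5.2, depth = 20,
                             constriction_length = 20, channel_length = 100,
                             pixel_scale = 0.5, wide_gap = 30) {
  check_number(gap_height, "gap_height", lower = 1e-6)
  check_number(constriction_length, "constriction_length", lower = 1e-6)
  check_number(channel_length, "channel_length", lower = constriction_length)
  check_number(pixel_scale, "pixel_scale", lower = 1e-6)
  check_number(wide_gap, "wide_gap", lower = gap_height)
  if (constriction_length >= channel_length) {
    abort("`constriction_length` must be smaller than `channel_length`")
  }
  structure(
    list(gap_height = gap_height, depth = depth,
         constriction_length = constriction_length,
         channel_length = channel_length, pixel_scale = pixel_scale,
         wide_gap = wide_gap),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf(
    "<channel_geometry> gap %.1f um x depth %.0f um, constriction %.0f/%.0f um, %.2f um/px\n",
    x$gap_height, x$depth, x$constriction_length, x$channel_length,
    x$pixel_scale))
  invisible(x)
}

# entry/exit plane x-positions (µm) of the constriction
constriction_planes <- function(geometry) {
  mid <- geometry$channel_length / 2
  c(entry = mid - geometry$constriction_length / 2,
    exit = mid + geometry$constriction_length / 2)
}

#' Class-conditional population profile
#'
#' Holds the distributional parameters one synthetic cell class is drawn
#' from: diameter, deformation index (DI), normalized maximum velocity, the
#' velocity/transition-time coupling, and the optional deformation-index
#' rate (DIR).
#'
#' @param name Class label.
#' @param diameter_mean,diameter_sd Cell diameter distribution, µm.
#' @param di_mean,di_sd Deformation-index distribution (dimensionless;
#'   samples are truncated to \[0, 1\]).
#' @param vmax_mean,vmax_sd Maximum-velocity distribution in flow-normalized
#'   units.
#' @param vtt_correlation Target standardized regression coefficient between
#'   vmax and transition time; must lie in \[-1, 0\] (faster cells transit
#'   sooner).
#' @param dir_mean,dir_sd Deformation-index-rate distribution, 1/s (samples
#'   truncated to positive values).
#'
#' @return A `class_profile` list.
#' @seealso [hct116_profile()], [wbc_profile()] for the calibrated defaults.
#' @export
class_profile <- function(name, diameter_mean, diameter_sd, di_mean, di_sd,
                          vmax_mean, vmax_sd, vtt_correlation = -0.96,
                          dir_mean = 100, dir_sd = 20) {
  stopifnot(is.character(name), nchar(name) > 0)
  check_number(di_mean, "di_mean", lower = 1e-9, upper = 1 - 1e-9)
  check_number(di_sd, "di_sd", lower = 1e-9)
  check_number(diameter_mean, "diameter_mean", lower = 1e-6)
  check_number(vmax_mean, "vmax_mean", lower = 1e-9)
  check_number(vtt_correlation, "vtt_correlation", lower = -1, upper = 0)
  structure(
    list(name = name, diameter_mean = diameter_mean, diameter_sd = diameter_sd,
         di_mean = di_mean, di_sd = di_sd, vmax_mean = vmax_mean,
         vmax_sd = vmax_sd, vtt_correlation = vtt_correlation,
         dir_mean = dir_mean, dir_sd = dir_sd),
    class = "class_profile"
  )
}

#' Calibrated default class profiles
#'
#' Two overlapping populations as characterized on the reference device:
#' a colorectal tumor line (softer, more deformable, faster through the
#' constriction) and white blood cells (stiffer, slower). DI statistics are
#' the published population values; velocity means are in flow-normalized
#' units with the tumor line faster, and the DIR scale follows from DI
#' excursions of ~0.7 over millisecond-scale transits.
#'
#' @return A `class_profile`.
#' @export
hct116_profile <- function() {
  class_profile("HCT116", diameter_mean = 14.2, diameter_sd = 4.4,
                di_mean = 0.722, di_sd = 0.085,
                vmax_mean = 0.65, vmax_sd = 0.08,
                vtt_correlation = -0.96, dir_mean = 110, dir_sd = 20)
}

#' @rdname hct116_profile
#' @export
wbc_profile <- function() {
  class_profile("WBC", diameter_mean = 13.5, diameter_sd = 1.5,
                di_mean = 0.660, di_sd = 0.091,
                vmax_mean = 0.55, vmax_sd = 0.08,
                vtt_correlation = -0.96, dir_mean = 90, dir_sd = 20)
}

#' @rdname hct116_profile
#' @param di_mean Mean deformation index of the chemically stiffened
#'   variant. Fixation (e.g. paraformaldehyde) crosslinks the cytoskeleton,
#'   so the stiffened cells deform far less and transit more slowly than
#'   the untreated line while keeping the same size distribution.
#' @export
hct_stiffened_profile <- function(di_mean = 0.48) {
  class_profile("HCT-Stiffened", diameter_mean = 14.2, diameter_sd = 4.4,
                di_mean = di_mean, di_sd = 0.085,
                vmax_mean = 0.48, vmax_sd = 0.08,
                vtt_correlation = -0.96, dir_mean = 60, dir_sd = 15)
}

#' Synthetic-dataset generator configuration
#'
#' Bundles everything [make_dataset()] needs: the class profiles, per-class
#' counts, channel geometry, rendering parameters, and the split-wise
#' illumination shift that emulates recordings taken on different days.
#' The default reproduces the reference benchmark: 1156 WBC-like and 1365
#' tumor-like cells (2521 cells, 5042 images).
#'
#' @param class_profiles List of [class_profile()]s (at least one; two or
#'   more for classification use).
#' @param n_per_class Named integer vector of cells per class; names must
#'   match profile names.
#' @param geometry A [channel_geometry()].
#' @param n_frames Frames per rendered transit (for [render_transit()]).
#' @param noise_sd Additive Gaussian pixel noise, 8-bit intensity units.
#' @param illumination_shift_range Half-width of the uniform additive
#'   intensity shift applied (once per split) to the validation and test
#'   splits only.
#' @param crop_size Square crop side, pixels.
#' @param background,cell_intensity Background and cell intensities (8-bit).
#' @param tt_scale Transition-time scale `c` in the inverse law
#'   `TT = c / vmax`, seconds.
#' @param test_fraction Fraction of cells held out as the test split
#'   (`floor(test_fraction * N)` cells; the remainder is the train+val pool).
#' @param n_folds Cross-validation folds assigned round-robin over the
#'   train+val pool.
#' @param seed Integer seed; identical configs generate bit-identical data.
#'
#' @return A `generator_config` list.
#' @export
generator_config <- function(class_profiles = list(wbc_profile(), hct116_profile()),
                             n_per_class = c(WBC = 1156, HCT116 = 1365),
                             geometry = channel_geometry(),
                             n_frames = 25, noise_sd = 8,
                             illumination_shift_range = 20,
                             crop_size = 64, background = 200,
                             cell_intensity = 80, tt_scale = 0.008,
                             test_fraction = 0.2, n_folds = 5L,
                             seed = 42L) {
  if (inherits(class_profiles, "class_profile")) class_profiles <- list(class_profiles)
  names(class_profiles) <- vapply(class_profiles, `[[`, "", "name")
  if (!all(names(n_per_class) %in% names(class_profiles))) {
    abort("every name in `n_per_class` must match a class profile")
  }
  if (any(n_per_class < 0)) abort("`n_per_class` must be non-negative")
  if (n_frames < 3) abort("`n_frames` must be at least 3")
  structure(
    list(class_profiles = class_profiles, n_per_class = n_per_class,
         geometry = geometry, n_frames = as.integer(n_frames),
         noise_sd = noise_sd,
         illumination_shift_range = illumination_shift_range,
         crop_size = as.integer(crop_size), background = background,
         cell_intensity = cell_intensity, tt_scale = tt_scale,
         test_fraction = test_fraction, n_folds = as.integer(n_folds),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Generator preset with controlled modality separability
#'
#' A benchmark configuration in which the image and feature modalities carry
#' partially independent class signal: images separate the classes mainly
#' through cell diameter (distributions chosen for roughly 70% Bayes-optimal
#' accuracy), while the mechanical features separate them more strongly
#' (roughly 85% from DI and vmax combined). Because diameters and features
#' are sampled independently, the single-modality errors are independent,
#' which is the regime where multimodal fusion should beat either branch.
#'
#' @param n_per_class Cells per class.
#' @param crop_size Square crop side, pixels.
#' @param seed Integer seed.
#' @return A `generator_config`.
#' @export
complementarity_config <- function(n_per_class = c(A = 300, B = 300),
                                   crop_size = 32, seed = 42L) {
  a <- class_profile("A", diameter_mean = 13.5, diameter_sd = 1.5,
                     di_mean = 0.660, di_sd = 0.091,
                     vmax_mean = 0.53, vmax_sd = 0.08)
  b <- class_profile("B", diameter_mean = 15.1, diameter_sd = 1.5,
                     di_mean = 0.722, di_sd = 0.085,
                     vmax_mean = 0.68, vmax_sd = 0.08)
  names(n_per_class) <- c("A", "B")
  generator_config(class_profiles = list(a, b), n_per_class = n_per_class,
                   crop_size = crop_size, seed = seed)
}
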