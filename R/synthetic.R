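#' Perturbation model for simulated spectra
#'
#' Describes how a reference peak list is perturbed into one replicate
#' of a batch, time-point or stress-treatment arm: per-peak random
#' chemical-shift displacements, independent peak disappearance, and
#' multiplicative intensity jitter.
#'
#' In `"gaussian"` mode the \eqn{^1}H and \eqn{^{13}}C displacements are
#' drawn from centered normals with standard deviations `shift_sd_h` and
#' `shift_sd_c` (ppm). In `"fixed_magnitude_random_sign"` mode every peak
#' is displaced by exactly `shift_sd_h` (resp. `shift_sd_c`) ppm with a
#' random sign, which gives every matched pair the same CCSD — useful as
#' a closed-form ground truth.
#'
#' @param shift_sd_h,shift_sd_c displacement scale in ppm (>= 0);
#'   standard deviation in gaussian mode, exact magnitude in
#'   fixed-magnitude mode.
#' @param shift_magnitude_mode `"gaussian"` or
#'   `"fixed_magnitude_random_sign"`.
#' @param p_disappear probability in `[0, 1]` that a peak disappears.
#' @param intensity_jitter_cv coefficient of variation of the
#'   multiplicative (log-normal, mean 1) intensity jitter; 0 disables it.
#' @param seed integer RNG seed.
#' @return An object of class `perturbation_model`.
#' @export
perturbation_model <- function(shift_sd_h = 0, shift_sd_c = 0,
                               shift_magnitude_mode = c("gaussian",
                                 "fixed_magnitude_random_sign"),
                               p_disappear = 0,
                               intensity_jitter_cv = 0,
                               seed = 1L) {
  shift_magnitude_mode <- match.arg(shift_magnitude_mode)
  if (shift_sd_h < 0 || shift_sd_c < 0)
    stop("perturbation_model: shift scales must be >= 0")
  if (p_disappear < 0 || p_disappear > 1)
    stop("perturbation_model: p_disappear must be in [0, 1]")
  if (intensity_jitter_cv < 0)
    stop("perturbation_model: intensity_jitter_cv must be >= 0")
  structure(list(shift_sd_h = shift_sd_h, shift_sd_c = shift_sd_c,
                 shift_magnitude_mode = shift_magnitude_mode,
                 p_disappear = p_disappear,
                 intensity_jitter_cv = intensity_jitter_cv,
                 seed = as.integer(seed)),
            class = "perturbation_model")
}

#' Lineshape parameters for spectrum rendering
#'
#' @param fwhm_h,fwhm_c full width at half maximum in ppm (> 0). The
#'   defaults (0.02 ppm \eqn{^1}H, 0.2 ppm \eqn{^{13}}C) are typical of
#'   methyl cross-peaks of a large protein after processing.
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param voigt_eta Lorentzian fraction in `[0, 1]` for the pseudo-Voigt
#'   profile.
#' @return An object of class `lineshape_params`.
#' @export
lineshape_params <- function(fwhm_h = 0.02, fwhm_c = 0.2,
                             shape = c("gaussian", "lorentzian",
                                       "pseudo_voigt"),
                             voigt_eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm_h <= 0 || fwhm_c <= 0)
    stop("lineshape_params: FWHM must be > 0")
  if (voigt_eta < 0 || voigt_eta > 1)
    stop("lineshape_params: voigt_eta must be in [0, 1]")
  structure(list(fwhm_h = fwhm_h, fwhm_c = fwhm_c, shape = shape,
                 voigt_eta = voigt_eta),
            class = "lineshape_params")
}

#' One arm of a simulated comparability study
#'
#' @param label arm label (e.g. `"T7"`, `"h2o2_24h"`).
#' @param model a [perturbation_model()].
#' @param n_replicates number of replicate spectra (>= 1).
#' @return A list of class `scenario_arm`.
#' @export
scenario_arm <- function(label, model, n_replicates = 1L) {
  stopifnot(inherits(model, "perturbation_model"))
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) stop("scenario_arm: n_replicates must be >= 1")
  structure(list(label = as.character(label), model = model,
                 n_replicates = n_replicates),
            class = "scenario_arm")
}

#' Simulation scenario: reference plus perturbed arms
#'
#' Encodes a full study design (e.g. four time points of two batches, or
#' control / pH-stress / oxidative-stress arms) with a single master seed
#' from which all per-stage seeds are derived, so the whole study is
#' reproducible and each arm independently regenerable.
#'
#' @param name scenario name.
#' @param arms list of [scenario_arm()] with unique labels.
#' @param reference_batch label of the reference spectrum (matching the
#'   workflow where one batch's peak list is reused for all spectra).
#' @param region a [spectral_region()].
#' @param lineshape a [lineshape_params()].
#' @param noise_sd standard deviation of additive grid noise (intensity
#'   units).
#' @param grid integer `c(n_h, n_c)` rendering grid for the arm spectra.
#' @param replicate_model a [perturbation_model()] applied independently
#'   to every replicate on top of its arm's (systematic) perturbation;
#'   the default is a small measurement-repeatability jitter
#'   (0.0005 ppm \eqn{^1}H / 0.002 ppm \eqn{^{13}}C, 2\% intensity CV,
#'   no drops).
#' @param n_peaks number of reference cross-peaks.
#' @param seed master seed; expanded into child seeds for the reference
#'   list, each perturbation and each noise draw via a seeded stream
#'   (see [simulate_study()]).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, arms, reference_batch = "reference",
                     region = spectral_region(),
                     lineshape = lineshape_params(),
                     noise_sd = 0.01, grid = c(512L, 256L),
                     replicate_model = perturbation_model(
                       shift_sd_h = 5e-4, shift_sd_c = 2e-3,
                       intensity_jitter_cv = 0.02),
                     n_peaks = 110L, seed = 1L) {
  if (!length(arms) || !all(vapply(arms, inherits, logical(1), "scenario_arm")))
    stop("scenario: arms must be a non-empty list of scenario_arm objects")
  labels <- vapply(arms, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("scenario: arm labels must be unique")
  stopifnot(inherits(region, "spectral_region"),
            inherits(lineshape, "lineshape_params"))
  if (noise_sd < 0) stop("scenario: noise_sd must be >= 0")
  stopifnot(inherits(replicate_model, "perturbation_model"))
  structure(list(name = as.character(name), arms = arms,
                 replicate_model = replicate_model,
                 reference_batch = as.character(reference_batch),
                 region = region, lineshape = lineshape,
                 noise_sd = noise_sd, grid = as.integer(grid),
                 n_peaks = as.integer(n_peaks),
                 seed = as.integer(seed)),
            class = "scenario")
}

# internal: deterministic expansion of one master seed into n child seeds.
# Splitting rule: seed a Mersenne-Twister stream with the master seed and
# draw n integers in [1, 2^31 - 2]. Documented so arms can be regenerated.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Generate a reference methyl peak list
#'
#' Places `n_peaks` labelled cross-peaks inside a methyl sub-box of the
#' analysis region by rejection sampling under a minimum-separation
#' constraint, emulating a manually curated, unambiguous peak list of
#' roughly 110 methyl cross-peaks. Two peaks conflict when they are
#' closer than `min_sep_h` in \eqn{^1}H *and* closer than `min_sep_c` in
#' \eqn{^{13}}C; separation along either axis suffices. Intensities are
#' log-normal (median 1).
#'
#' @param n_peaks number of peaks (>= 1).
#' @param region a [spectral_region()]; peaks are placed inside the
#'   sub-box and the sub-box must lie inside the region.
#' @param seed integer RNG seed.
#' @param h_box,c_box placement sub-box (ppm); defaults \eqn{^1}H
#'   `c(-0.5, 1.5)`, \eqn{^{13}}C `c(10, 25)`, inside the default region
#'   so binning edges are exercised without clipping.
#' @param min_sep_h,min_sep_c minimum separations in ppm; the defaults
#'   (0.02 / 0.2) equal the default matching tolerances so matching is
#'   unambiguous.
#' @param intensity_sdlog log-scale sd of peak intensities.
#' @param max_tries rejection-sampling attempts per peak before a packing
#'   failure is signalled.
#' @return A [peaklist()] with labels `ss001`, `ss002`, ...
#' @examples
#' pl <- generate_reference_peaklist(110, seed = 7)
#' nrow(pl)
#' @export
generate_reference_peaklist <- function(n_peaks = 110L,
                                        region = spectral_region(),
                                        seed = 1L,
                                        h_box = c(-0.5, 1.5),
                                        c_box = c(10, 25),
                                        min_sep_h = 0.02,
                                        min_sep_c = 0.2,
                                        intensity_sdlog = 0.5,
                                        max_tries = 2000L) {
  n_peaks <- as.integer(n_peaks)
  if (n_peaks < 1L) stop("generate_reference_peaklist: n_peaks must be >= 1")
  stopifnot(inherits(region, "spectral_region"))
  if (h_box[1] < region$h_min || h_box[2] > region$h_max ||
      c_box[1] < region$c_min || c_box[2] > region$c_max)
    stop("generate_reference_peaklist: placement sub-box must lie inside the region")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  dh <- numeric(n_peaks); dc <- numeric(n_peaks)
  placed <- 0L
  while (placed < n_peaks) {
    tries <- 0L
    repeat {
      ch <- stats::runif(1, h_box[1], h_box[2])
      cc <- stats::runif(1, c_box[1], c_box[2])
      ok <- placed == 0L ||
        all(abs(dh[seq_len(placed)] - ch) >= min_sep_h |
            abs(dc[seq_len(placed)] - cc) >= min_sep_c)
      if (ok) break
      tries <- tries + 1L
      if (tries >= max_tries)
        stop(sprintf(paste0(
          "generate_reference_peaklist: packing failure after %d peaks -- ",
          "n_peaks = %d is too large for the separation constraint ",
          "(%g ppm 1H / %g ppm 13C) in the given sub-box"),
          placed, n_peaks, min_sep_h, min_sep_c))
    }
    placed <- placed + 1L
    dh[placed] <- ch; dc[placed] <- cc
  }
  width <- max(3L, nchar(as.character(n_peaks)))
  labels <- sprintf(paste0("ss%0", width, "d"), seq_len(n_peaks))
  intensity <- stats::rlnorm(n_peaks, meanlog = 0, sdlog = intensity_sdlog)
  peaklist(labels, dh, dc, intensity, spectrum_id = "reference",
           metadata = list(seed = seed))
}

#' Perturb a peak list with known ground truth
#'
#' Applies a [perturbation_model()] to a reference list: every peak is
#' displaced in both dimensions, dropped independently with probability
#' `p_disappear`, and its intensity multiplied by a positive log-normal
#' jitter with unit mean. Surviving peaks keep their labels.
#'
#' @param ref a [peaklist()].
#' @param model a [perturbation_model()]; its `seed` makes the output a
#'   pure function of `(ref, model)`.
#' @param spectrum_id id for the perturbed list.
#' @return A list with elements `peaks` (the perturbed [peaklist()]) and
#'   `truth` (a data.frame of per-peak true displacements `dh`, `dc` in
#'   ppm, the intensity factor, and a `dropped` flag).
#' @export
perturb_peaklist <- function(ref, model, spectrum_id = "perturbed") {
  stopifnot(is_peaklist(ref), inherits(model, "perturbation_model"))
  n <- nrow(ref)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(model$seed)
  if (model$shift_magnitude_mode == "gaussian") {
    dh <- stats::rnorm(n, 0, model$shift_sd_h)
    dc <- stats::rnorm(n, 0, model$shift_sd_c)
  } else {
    dh <- model$shift_sd_h * sample(c(-1, 1), n, replace = TRUE)
    dc <- model$shift_sd_c * sample(c(-1, 1), n, replace = TRUE)
    if (model$shift_sd_h == 0) dh <- rep(0, n)
    if (model$shift_sd_c == 0) dc <- rep(0, n)
  }
  dropped <- stats::runif(n) < model$p_disappear
  if (model$intensity_jitter_cv > 0) {
    sdlog <- sqrt(log(1 + model$intensity_jitter_cv^2))
    jitter <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    jitter <- rep(1, n)
  }
  truth <- data.frame(label = ref$label, dh = dh, dc = dc,
                      intensity_factor = jitter, dropped = dropped,
                      stringsAsFactors = FALSE)
  keep <- !dropped
  if (!any(keep))
    stop("perturb_peaklist: all peaks dropped; p_disappear too high for this seed")
  out <- peaklist(ref$label[keep],
                  ref$delta_h[keep] + dh[keep],
                  ref$delta_c[keep] + dc[keep],
                  ref$intensity[keep] * jitter[keep],
                  spectrum_id = spectrum_id,
                  metadata = attr(ref, "metadata"))
  list(peaks = out, truth = truth)
}

# internal: unit-amplitude 1D lineshape evaluated on axis x, centered at x0
lineshape_1d <- function(x, x0, fwhm, shape, eta) {
  g <- exp(-4 * log(2) * ((x - x0) / fwhm)^2)
  if (shape == "gaussian") return(g)
  l <- 1 / (1 + (2 * (x - x0) / fwhm)^2)
  if (shape == "lorentzian") return(l)
  eta * l + (1 - eta) * g
}

#' Render a peak list as a gridded 2D spectrum
#'
#' Sums separable 2D lineshapes (unit amplitude at the peak center,
#' scaled by peak intensity) over a rectangular ppm grid and adds i.i.d.
#' Gaussian noise. This stands in for a processed frequency-domain
#' spectrum; no time-domain synthesis is performed.
#'
#' @param peaks a [peaklist()] (may be empty of rows only via subsetting;
#'   zero peaks give a pure-noise spectrum).
#' @param region a [spectral_region()]; the grid spans it exactly.
#' @param grid integer vector `c(n_h, n_c)` of grid sizes (>= 2 each).
#' @param lineshape a [lineshape_params()].
#' @param noise_sd standard deviation of additive Gaussian grid noise.
#' @param seed RNG seed for the noise.
#' @param on_outside what to do with a peak outside the region:
#'   `"clip"` warns and clips the center to the boundary, `"error"` fails.
#' @return A [spectrum2d()] with ascending ppm axes.
#' @export
render_spectrum <- function(peaks, region = spectral_region(),
                            grid = c(512L, 256L),
                            lineshape = lineshape_params(),
                            noise_sd = 0, seed = 1L,
                            on_outside = c("clip", "error")) {
  on_outside <- match.arg(on_outside)
  stopifnot(inherits(region, "spectral_region"),
            inherits(lineshape, "lineshape_params"))
  if (length(grid) != 2L || any(grid < 2L))
    stop("render_spectrum: grid must be c(n_h, n_c) with both >= 2")
  n_h <- as.integer(grid[1]); n_c <- as.integer(grid[2])
  axis_h <- seq(region$h_min, region$h_max, length.out = n_h)
  axis_c <- seq(region$c_min, region$c_max, length.out = n_c)
  mat <- matrix(0, nrow = n_c, ncol = n_h)
  if (!is.null(peaks) && nrow(peaks) > 0L) {
    ph <- peaks$delta_h; pc <- peaks$delta_c
    out <- !in_region(region, ph, pc)
    if (any(out)) {
      if (on_outside == "error")
        stop("render_spectrum: ", sum(out), " peak(s) outside the region: ",
             paste(peaks$label[out], collapse = ", "))
      warning("render_spectrum: clipping ", sum(out),
              " peak(s) to the region boundary")
      ph <- pmin(pmax(ph, region$h_min), region$h_max)
      pc <- pmin(pmax(pc, region$c_min), region$c_max)
    }
    for (k in seq_len(nrow(peaks))) {
      gh <- lineshape_1d(axis_h, ph[k], lineshape$fwhm_h,
                         lineshape$shape, lineshape$voigt_eta)
      gc_ <- lineshape_1d(axis_c, pc[k], lineshape$fwhm_c,
                          lineshape$shape, lineshape$voigt_eta)
      mat <- mat + peaks$intensity[k] * (gc_ %o% gh)
    }
  }
  if (noise_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    mat <- mat + matrix(stats::rnorm(n_c * n_h, 0, noise_sd),
                        nrow = n_c, ncol = n_h)
  }
  spectrum2d(axis_h, axis_c, mat,
             metadata = list(noise_sd = noise_sd, seed = seed))
}

#' Simulate a full comparability study
#'
#' Expands a [scenario()] into a reference peak list plus, per arm and
#' replicate, a perturbed peak list, a rendered spectrum and the ground
#' truth of the perturbation. Each arm's [perturbation_model()] is
#' applied *once* — it is the systematic structural effect of that batch,
#' time point or treatment, shared by all its replicates — and the
#' scenario's `replicate_model` then adds small independent
#' measurement-level jitter to every replicate. This is what makes
#' replicates of one arm cluster together in chemometric analyses while
#' arms separate. Child seeds are drawn deterministically from the
#' scenario's master seed (see `child_seeds` rule in [scenario()]), so
#' two runs with the same scenario are identical.
#'
#' @param sc a [scenario()].
#' @param out_dir optional directory; when given, peak lists (TSV),
#'   spectra (`csv_grid`) and a `manifest.tsv` (columns `file`, `arm`,
#'   `replicate`, `kind`) are written there.
#' @return A list of class `study_bundle` with elements `reference`
#'   (the reference [peaklist()]), `peaklists` / `spectra` / `truths`
#'   (named lists keyed `<arm>_r<replicate>`; each truth records the
#'   total per-peak displacement vs. the reference and the dropped
#'   labels), and `manifest` (data.frame).
#' @export
simulate_study <- function(sc, out_dir = NULL) {
  stopifnot(inherits(sc, "scenario"))
  n_runs <- sum(vapply(sc$arms, `[[`, integer(1), "n_replicates"))
  # seed layout: [1] reference; per arm 1 seed (systematic perturbation);
  # per replicate 2 seeds (replicate jitter, render noise)
  seeds <- child_seeds(sc$seed, 1L + length(sc$arms) + 2L * n_runs)
  ref <- generate_reference_peaklist(sc$n_peaks, sc$region,
                                     seed = seeds[1L])
  attr(ref, "spectrum_id") <- sc$reference_batch
  peaklists <- list(); spectra <- list(); truths <- list()
  manifest <- data.frame(file = character(), arm = character(),
                         replicate = integer(), kind = character(),
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  s_at <- 1L
  k <- 1L
  for (arm in sc$arms) {
    s_at <- s_at + 1L
    arm_model <- arm$model
    arm_model$seed <- seeds[s_at]
    arm_pert <- perturb_peaklist(ref, arm_model,
                                 spectrum_id = paste0(arm$label, "_arm"))
    for (r in seq_len(arm$n_replicates)) {
      id <- sprintf("%s_r%d", arm$label, r)
      rep_model <- sc$replicate_model
      rep_model$seed <- seeds[1L + length(sc$arms) + 2L * k - 1L]
      pert <- perturb_peaklist(arm_pert$peaks, rep_model, spectrum_id = id)
      # total ground truth vs the reference list
      at <- arm_pert$truth
      rt <- pert$truth[match(at$label, pert$truth$label), ]
      truth <- data.frame(
        label = at$label,
        dh = at$dh + ifelse(is.na(rt$dh), 0, rt$dh),
        dc = at$dc + ifelse(is.na(rt$dc), 0, rt$dc),
        intensity_factor = at$intensity_factor *
          ifelse(is.na(rt$intensity_factor), 1, rt$intensity_factor),
        dropped = at$dropped | (!is.na(rt$dropped) & rt$dropped),
        stringsAsFactors = FALSE)
      spec <- render_spectrum(pert$peaks, sc$region, grid = sc$grid,
                              lineshape = sc$lineshape,
                              noise_sd = sc$noise_sd,
                              seed = seeds[1L + length(sc$arms) + 2L * k])
      peaklists[[id]] <- pert$peaks
      truths[[id]] <- truth
      spectra[[id]] <- spec
      if (!is.null(out_dir)) {
        pf <- file.path(out_dir, paste0(id, ".peaks.tsv"))
        sf <- file.path(out_dir, paste0(id, ".grid.csv"))
        write_peaklist(pert$peaks, pf)
        write_spectrum(spec, sf)
        manifest <- rbind(manifest,
          data.frame(file = basename(c(pf, sf)), arm = arm$label,
                     replicate = r, kind = c("peaklist", "spectrum"),
                     stringsAsFactors = FALSE))
      } else {
        manifest <- rbind(manifest,
          data.frame(file = id, arm = arm$label, replicate = r,
                     kind = "simulated", stringsAsFactors = FALSE))
      }
      k <- k + 1L
    }
  }
  if (!is.null(out_dir)) {
    rf <- file.path(out_dir, "reference.peaks.tsv")
    write_peaklist(ref, rf)
    manifest <- rbind(manifest,
      data.frame(file = basename(rf), arm = sc$reference_batch,
                 replicate = 0L, kind = "reference",
                 stringsAsFactors = FALSE))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(reference = ref, peaklists = peaklists,
                 spectra = spectra, truths = truths,
                 manifest = manifest, scenario = sc),
            class = "study_bundle")
}
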