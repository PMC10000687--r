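# Synthetic-data module: calibration image sets, polarized cell fields
# with ground truth, and hierarchical cell cohorts.
#
# Noise model: Poisson photon noise on the pre-quantization intensity,
# additive Gaussian read noise, then clip-and-round to the detector bit
# depth. With every noise source off the images are ideal real-valued
# radiometric fields (no quantization), so noiseless round-trips are
# exact.

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Instrument profile for the polarization-imaging simulator
#'
#' Describes the simulated confocal polarization microscope: its
#' polarization transmission bias (the true G-factor), field of view,
#' detector geometry and noise. Defaults follow the imaging configuration
#' the package emulates: a 205 um square field recorded as 512 x 512
#' 8-bit images with an instrument bias of 0.75.
#'
#' @param g_true true polarization transmission bias (> 0) injected into
#'   the cross-polarized detection path.
#' @param field_of_view_um square field of view side length, micrometers.
#' @param image_size_px image side length in pixels.
#' @param bit_depth detector bit depth (8 gives the 0..255 range).
#' @param photon_noise logical; apply Poisson photon noise.
#' @param read_noise_sd Gaussian read noise SD in intensity units
#'   (applied only when `photon_noise` is `TRUE` or it is > 0).
#' @param background_level uniform background intensity added to both
#'   detection channels.
#' @param frames_per_acquisition number of independent noise realizations
#'   recorded per acquisition.
#' @param quantize `NULL` (default) quantizes to the bit depth whenever
#'   any noise source is on and otherwise returns the ideal continuous
#'   field; set `TRUE`/`FALSE` to force either behavior (e.g. `TRUE`
#'   with noise off isolates pure quantization error).
#' @return An object of class `"instrument_profile"`.
#' @export
instrument_profile <- function(g_true = 0.75, field_of_view_um = 205,
                               image_size_px = 512, bit_depth = 8,
                               photon_noise = TRUE, read_noise_sd = 1,
                               background_level = 5,
                               frames_per_acquisition = 1,
                               quantize = NULL) {
  stopifnot(g_true > 0, field_of_view_um > 0, image_size_px >= 1,
            bit_depth >= 1, read_noise_sd >= 0, background_level >= 0,
            frames_per_acquisition >= 1)
  structure(
    list(g_true = g_true, field_of_view_um = field_of_view_um,
         image_size_px = as.integer(image_size_px),
         bit_depth = as.integer(bit_depth),
         photon_noise = isTRUE(photon_noise),
         read_noise_sd = read_noise_sd,
         background_level = background_level,
         frames_per_acquisition = as.integer(frames_per_acquisition),
         quantize = quantize),
    class = "instrument_profile")
}

#' @rdname instrument_profile
#' @param x an `"instrument_profile"`.
#' @export
pixel_size_um <- function(x) x$field_of_view_um / x$image_size_px

#' Load the bundled instrument profile
#'
#' Reads `fixtures/instrument.json` shipped with the package (bias 0.75,
#' 205 um field, 512 px, 8 bit).
#'
#' @param path optional path to an instrument JSON file.
#' @return An [instrument_profile()].
#' @export
instrument_fixture <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "fixtures", "instrument.json",
                        package = "fpolcyto", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  instrument_profile(
    g_true = j$g_true, field_of_view_um = j$field_of_view_um,
    image_size_px = j$image_size_px, bit_depth = j$bit_depth,
    photon_noise = j$photon_noise, read_noise_sd = j$read_noise_sd,
    background_level = j$background_level,
    frames_per_acquisition = j$frames_per_acquisition)
}

#' Calibration solution specification
#'
#' A uniform dye solution with a known true polarization, used to
#' simulate the four-configuration calibration acquisition. The package
#' ships two conventional defaults: an aqueous solution where the dye
#' rotates freely (low Fpol) and a glycerol solution where rotation is
#' hindered (high Fpol).
#'
#' @param true_fpol true solution polarization, raw scale in `[0, 1)`.
#' @param emission_level total emission intensity of the solution.
#' @param label text label.
#' @return An object of class `"solution_spec"`.
#' @export
solution_spec <- function(true_fpol = 0.05, emission_level = 160,
                          label = "MB-PBS") {
  p <- fpol_raw(true_fpol)
  stopifnot(p >= 0, p < 1, emission_level > 0)
  structure(list(true_fpol = p, emission_level = emission_level,
                 label = label),
            class = "solution_spec")
}

#' @rdname solution_spec
#' @export
solution_mb_pbs <- function() solution_spec(0.05, 160, "MB-PBS")

#' @rdname solution_spec
#' @export
solution_mb_glycerol <- function() solution_spec(0.35, 160, "MB-glycerol")

# detector: Poisson photon noise + Gaussian read noise + quantization.
# Noiseless path returns the ideal real-valued field untouched.
.detect <- function(ideal, instrument) {
  noisy <- instrument$photon_noise || instrument$read_noise_sd > 0
  quantize <- if (is.null(instrument$quantize)) noisy
              else isTRUE(instrument$quantize)
  x <- ideal
  if (instrument$photon_noise) {
    x[] <- rpois(length(x), lambda = pmax(x, 0))
  }
  if (instrument$read_noise_sd > 0) {
    x <- x + rnorm(length(x), sd = instrument$read_noise_sd)
  }
  if (quantize) {
    qmax <- 2^instrument$bit_depth - 1
    x <- round(pmin(pmax(x, 0), qmax))
  }
  x
}

#' Simulate a four-configuration calibration image set
#'
#' Renders the four uniform-field acquisitions (vertical/horizontal
#' excitation x vertical/horizontal detection) of a dye solution under an
#' instrument with polarization bias `g_true`. Under vertical excitation
#' the co-polarized channel receives \eqn{E(1+p)/2} and the
#' cross-polarized channel \eqn{E(1-p)/(2G)}; under horizontal excitation
#' the analyzer roles swap so the vertical detector receives
#' \eqn{G\,E(1-p)/2}. On the noiseless set [solve_g_factor()] recovers
#' `g_true` exactly.
#'
#' @param solution a [solution_spec()].
#' @param instrument an [instrument_profile()].
#' @param seed integer seed for the noise realization.
#' @return A [calibration_set()] whose intensities are the image means
#'   and whose `images` field holds the four rendered images.
#' @export
simulate_calibration_set <- function(solution, instrument = instrument_profile(),
                                     seed = 0) {
  stopifnot(inherits(solution, "solution_spec"),
            inherits(instrument, "instrument_profile"))
  p <- solution$true_fpol
  E <- solution$emission_level
  b <- instrument$g_true
  npx <- instrument$image_size_px
  means <- c(vv = E * (1 + p) / 2,
             vh = E * (1 - p) / (2 * b),
             hh = E * (1 + p) / 2,
             hv = b * E * (1 - p) / 2)
  imgs <- with_seed(seed, lapply(means, function(m) {
    .detect(matrix(m, npx, npx), instrument)
  }))
  qmax <- 2^instrument$bit_depth - 1
  sat <- vapply(imgs, function(im) mean(im >= qmax), 1)
  if (any(sat > 0.01)) {
    warning(sprintf(
      "calibration saturation: %.1f%% of pixels at the detector maximum; lower the emission level",
      100 * max(sat)), call. = FALSE)
  }
  calibration_set(mean(imgs$vv), mean(imgs$vh), mean(imgs$hh), mean(imgs$hv),
                  solution_label = solution$label, images = imgs)
}

#' Cell-field specification for the image simulator
#'
#' Describes a synthetic monolayer field: non-overlapping circular cells
#' with per-cell true Fpol drawn from a normal distribution and per-cell
#' emission drawn uniformly from a range.
#'
#' @param n_cells number of cells to place.
#' @param radius_um_range min/max cell radius, micrometers.
#' @param fpol_mean,fpol_sd per-cell true Fpol distribution (raw scale).
#' @param emission_range min/max per-cell total emission intensity.
#' @return An object of class `"cell_field_spec"`.
#' @export
cell_field_spec <- function(n_cells = 30, radius_um_range = c(4, 10),
                            fpol_mean = 0.22, fpol_sd = 0.02,
                            emission_range = c(120, 220)) {
  stopifnot(n_cells >= 0, length(radius_um_range) == 2,
            radius_um_range[1] > 0,
            radius_um_range[1] <= radius_um_range[2],
            fpol_sd >= 0, fpol_mean >= -1, fpol_mean <= 1,
            length(emission_range) == 2, emission_range[1] > 0,
            emission_range[1] <= emission_range[2])
  structure(list(n_cells = as.integer(n_cells),
                 radius_um_range = radius_um_range,
                 fpol_mean = fpol_mean, fpol_sd = fpol_sd,
                 emission_range = emission_range),
            class = "cell_field_spec")
}

# rejection-sample non-overlapping disk centers; 200 attempts per cell
.place_disks <- function(n, rmin, rmax, fov) {
  radius <- if (n > 0) runif(n, rmin, rmax) else numeric(0)
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(200)) {
      x <- runif(1, radius[i], fov - radius[i])
      y <- runif(1, radius[i], fov - radius[i])
      if (i == 1L ||
          all(sqrt((cx[seq_len(i - 1)] - x)^2 + (cy[seq_len(i - 1)] - y)^2) >
              radius[seq_len(i - 1)] + radius[i] + 0.5)) {
        cx[i] <- x; cy[i] <- y; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(structure(class = c("fpol_placement_error", "error", "condition"),
                     list(message = sprintf(
                       "could not place cell %d of %d without overlap in 200 attempts; reduce n_cells or radii",
                       i, n), call = NULL)))
    }
  }
  data.frame(cell_id = seq_len(n), centroid_x_um = cx, centroid_y_um = cy,
             radius_um = radius)
}

#' Simulate a polarized image pair of a synthetic cell field
#'
#' Places non-overlapping circular cells in the field of view, assigns
#' each a true Fpol and emission, renders co-/cross-polarized detected
#' intensities through the forward model with the instrument bias, adds
#' background and detector noise, and returns the frames together with
#' the ground-truth label mask and per-cell table.
#'
#' @param spec a [cell_field_spec()].
#' @param instrument an [instrument_profile()].
#' @param seed integer seed governing placement, per-cell draws, and noise.
#' @return A list with `frames` (list of [fpol_pair()] of length
#'   `frames_per_acquisition`) and `truth` (list with `label_mask`, an
#'   integer matrix with 0 background and labels `1..n_cells`, and
#'   `cells`, a data frame of true per-cell parameters).
#' @export
simulate_cell_field <- function(spec = cell_field_spec(),
                                instrument = instrument_profile(),
                                seed = 0) {
  stopifnot(inherits(spec, "cell_field_spec"),
            inherits(instrument, "instrument_profile"))
  npx <- instrument$image_size_px
  px <- pixel_size_um(instrument)
  fov <- instrument$field_of_view_um
  with_seed(seed, {
    cells <- .place_disks(spec$n_cells, spec$radius_um_range[1],
                          spec$radius_um_range[2], fov)
    n <- nrow(cells)
    cells$true_fpol <- pmin(pmax(
      rnorm(n, spec$fpol_mean, spec$fpol_sd), 0), 0.999)
    cells$true_emission <- runif(n, spec$emission_range[1],
                                 spec$emission_range[2])

    # pixel-center coordinates (0-based row-major grid, um units)
    xc <- (seq_len(npx) - 0.5) * px
    label <- matrix(0L, npx, npx)
    emission <- matrix(0, npx, npx)
    pmap <- matrix(0, npx, npx)
    for (i in seq_len(n)) {
      rows <- which(abs(xc - cells$centroid_y_um[i]) <= cells$radius_um[i])
      cols <- which(abs(xc - cells$centroid_x_um[i]) <= cells$radius_um[i])
      for (r in rows) {
        dx2 <- (xc[cols] - cells$centroid_x_um[i])^2
        dy2 <- (xc[r] - cells$centroid_y_um[i])^2
        inside <- cols[dx2 + dy2 <= cells$radius_um[i]^2]
        label[r, inside] <- i
        emission[r, inside] <- cells$true_emission[i]
        pmap[r, inside] <- cells$true_fpol[i]
      }
    }
    cells$area_px <- as.integer(tabulate(label[label > 0], nbins = max(n, 1))[seq_len(n)])
    fwd <- forward_intensities(emission, pmap, instrument$g_true)
    co_ideal <- matrix(fwd$i_par, npx, npx) + instrument$background_level
    cross_ideal <- matrix(fwd$i_perp, npx, npx) + instrument$background_level

    frames <- lapply(seq_len(instrument$frames_per_acquisition), function(f) {
      fpol_pair(co = .detect(co_ideal, instrument),
                cross = .detect(cross_ideal, instrument),
                pixel_size_um = px, bit_depth = instrument$bit_depth)
    })
    list(frames = frames,
         truth = list(label_mask = label, cells = cells))
  })
}

#' Cohort specification for the hierarchical cell simulator
#'
#' A cohort is a fixed table of specimens (with subject, diagnostic
#' group, histology, grade, cell count, and a generative mean Fpol on the
#' display scale) plus dispersion parameters. Cells are generated with a
#' specimen-level random intercept (between-specimen SD) and within-
#' specimen cell scatter, matching the random-intercept structure the
#' group model fits. In `"mixture"` mode a fraction of cells in each
#' malignant specimen is drawn from a contamination (noncancerous-like)
#' distribution instead, emulating tumor heterogeneity.
#'
#' @param specimens data frame with columns `specimen_id`, `subject_id`,
#'   `group`, `histology`, `grade` (NA allowed), `n_cells`,
#'   `mean_fpol_display`.
#' @param within_specimen_sd_display cell-to-cell SD within a specimen
#'   (display scale, x10^-2).
#' @param between_specimen_sd_display SD of specimen-level intercepts
#'   about the group mean (display scale).
#' @param mode `"group-mean"` (homogeneous specimens) or `"mixture"`.
#' @param contamination_fraction fraction of cells in malignant specimens
#'   drawn from the contamination distribution (mixture mode only).
#' @param contamination_mean_fpol_display mean of the contamination
#'   distribution, display scale.
#' @param cell_size_meanlog,cell_size_sdlog log-normal parameters for
#'   projected cell area (um^2).
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(specimens,
                        within_specimen_sd_display = 1.4,
                        between_specimen_sd_display = 0.5,
                        mode = c("group-mean", "mixture"),
                        contamination_fraction = 0.27,
                        contamination_mean_fpol_display = 19.1,
                        cell_size_meanlog = 5.0, cell_size_sdlog = 0.4) {
  mode <- match.arg(mode)
  specimens <- as.data.frame(specimens)
  need <- c("specimen_id", "subject_id", "group", "histology", "grade",
            "n_cells", "mean_fpol_display")
  missing_cols <- setdiff(need, names(specimens))
  if (length(missing_cols))
    stop("specimens table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stopifnot(all(specimens$n_cells > 0),
            within_specimen_sd_display >= 0,
            between_specimen_sd_display >= 0,
            contamination_fraction >= 0, contamination_fraction < 1)
  structure(
    list(specimens = specimens,
         within_specimen_sd_display = within_specimen_sd_display,
         between_specimen_sd_display = between_specimen_sd_display,
         mode = mode,
         contamination_fraction = contamination_fraction,
         contamination_mean_fpol_display = contamination_mean_fpol_display,
         cell_size_meanlog = cell_size_meanlog,
         cell_size_sdlog = cell_size_sdlog),
    class = "cohort_spec")
}

#' Load the bundled study-structure cohort fixture
#'
#' Reads `fixtures/cohort_table1.json`: 44 specimens (3808 cells) from 28
#' subjects with the published diagnostic/histologic/grade structure.
#' Each specimen carries generative means at three granularities —
#' diagnostic group, histology, and (for malignant specimens) tumor
#' grade — so that each recovery experiment can be keyed by the grouping
#' whose parameters it recovers.
#'
#' @param means which generative mean to assign to each specimen:
#'   `"diagnostic"` (default; 24.40/19.49/19.14 for
#'   malignant/benign/normal), `"histology"`, or `"grade"`. With
#'   `"grade"` the cohort is restricted to the 19 malignant specimens.
#' @param mode,path passed through; see [cohort_spec()].
#' @return A [cohort_spec()].
#' @export
cohort_table1 <- function(means = c("diagnostic", "histology", "grade"),
                          mode = "group-mean", path = NULL) {
  means <- match.arg(means)
  if (is.null(path))
    path <- system.file("extdata", "fixtures", "cohort_table1.json",
                        package = "fpolcyto", mustWork = TRUE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- j$specimens
  sp$grade <- suppressWarnings(as.integer(sp$grade))
  if (means == "grade") {
    sp <- sp[!is.na(sp$grade), , drop = FALSE]
    sp$mean_fpol_display <- sp$grade_mean_fpol_display
  } else if (means == "histology") {
    sp$mean_fpol_display <- sp$histology_mean_fpol_display
  } else {
    sp$mean_fpol_display <- sp$group_mean_fpol_display
  }
  sp$grade_mean_fpol_display <- NULL
  sp$histology_mean_fpol_display <- NULL
  sp$group_mean_fpol_display <- NULL
  cohort_spec(
    specimens = sp,
    within_specimen_sd_display = j$within_specimen_sd_display,
    between_specimen_sd_display = j$between_specimen_sd_display,
    mode = mode,
    contamination_fraction = j$contamination$fraction,
    contamination_mean_fpol_display = j$contamination$mean_fpol_display,
    cell_size_meanlog = j$cell_size_lognormal$meanlog,
    cell_size_sdlog = j$cell_size_lognormal$sdlog)
}

#' Simulate a per-cell cohort table
#'
#' For each specimen, draws a specimen-level intercept
#' `Normal(mean_fpol_display, between_specimen_sd_display)`, then per-cell
#' Fpol `Normal(intercept, within_specimen_sd_display)` (display scale).
#' In mixture mode, a `contamination_fraction` of cells in each malignant
#' specimen is instead drawn around the contamination mean, and the
#' cancer-cell component mean is raised by inverting the mixture
#' (`(mean - f * contamination_mean) / (1 - f)`), so the specimen's
#' all-cells expectation stays at its configured mean while the
#' at-or-below-cutoff fraction tracks the injected contamination
#' fraction. Values are clipped to the physical display range
#' (-100, 100); cell sizes are log-normal.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return A data frame of cell records with columns `specimen_id`,
#'   `subject_id`, `cell_id`, `group`, `histology`, `grade`,
#'   `cell_size_um2`, `fpol_display`.
#' @export
simulate_cohort <- function(spec, seed = 0) {
  stopifnot(inherits(spec, "cohort_spec"))
  sp <- spec$specimens
  with_seed(seed, {
    out <- lapply(seq_len(nrow(sp)), function(i) {
      n <- sp$n_cells[i]
      mixed <- spec$mode == "mixture" && sp$group[i] == "malignant" &&
        spec$contamination_fraction > 0
      centre <- sp$mean_fpol_display[i]
      if (mixed) {
        # cancer-cell component mean such that the all-cells mixture
        # expectation equals the configured specimen mean
        centre <- (centre - spec$contamination_fraction *
                     spec$contamination_mean_fpol_display) /
          (1 - spec$contamination_fraction)
      }
      intercept <- rnorm(1, centre, spec$between_specimen_sd_display)
      fp <- rnorm(n, intercept, spec$within_specimen_sd_display)
      contaminated <- rep(FALSE, n)
      if (mixed) {
        n_cont <- round(spec$contamination_fraction * n)
        idx <- sample.int(n, n_cont)
        fp[idx] <- rnorm(n_cont, spec$contamination_mean_fpol_display,
                         spec$within_specimen_sd_display)
        contaminated[idx] <- TRUE
      }
      data.frame(
        specimen_id = sp$specimen_id[i], subject_id = sp$subject_id[i],
        cell_id = sprintf("%s_c%04d", sp$specimen_id[i], seq_len(n)),
        group = sp$group[i], histology = sp$histology[i],
        grade = sp$grade[i],
        cell_size_um2 = rlnorm(n, spec$cell_size_meanlog,
                               spec$cell_size_sdlog),
        fpol_display = pmin(pmax(fp, -100), 100),
        contaminated = contaminated)
    })
    records <- do.call(rbind, out)
    if (spec$mode != "mixture") records$contaminated <- NULL
    rownames(records) <- NULL
    records
  })
}
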