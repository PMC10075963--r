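#' Word-similarity predictors
#'
#' \code{predictor_enfr()} returns the 14-condition linear predictor
#' \code{[1 2 2 3 4 5 5 6 7 8 8 9 10 10] / 10}: activity assumed to rise
#' with component frequency within each level and with word similarity
#' across levels (letters < bigrams < quadrigrams < words), with no
#' language difference. \code{predictor_five()} returns the five-step
#' predictor \code{[1 2 3 4 5] / 5} used when only five ordered conditions
#' per language are fitted. Both are normalized to a maximum of 1.
#'
#' @return named numeric vector of weights in [0, 1].
#' @export
predictor_enfr <- function() {
  stats::setNames(c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8, 8, 9, 10, 10) / 10,
                  condition_labels("enfr"))
}

#' @rdname predictor_enfr
#' @param labels optional names for the five conditions.
#' @export
predictor_five <- function(labels = NULL) {
  w <- (1:5) / 5
  if (!is.null(labels)) {
    stopifnot(length(labels) == 5L)
    names(w) <- labels
  }
  w
}

#' Plant an exact sample correlation
#'
#' Orthogonalize-and-rescale construction: given a fixed vector \code{x}
#' and a helper vector, returns \code{y} whose sample Pearson correlation
#' with \code{x} equals \code{target_r} exactly (to floating point). The
#' helper is residualized against \code{x}, both parts are standardized,
#' and combined as \code{r * zx + sqrt(1 - r^2) * ze}.
#'
#' @param x numeric vector (nonconstant).
#' @param target_r desired correlation in [-1, 1].
#' @param helper optional helper vector (defaults to a deterministic
#'   alternating ramp); must not be collinear with \code{x}.
#' @param scale_sd,center sd and mean of the returned vector.
#' @return numeric vector \code{y} with \code{cor(x, y) == target_r}.
#' @export
plant_correlation <- function(x, target_r, helper = NULL, scale_sd = 1,
                              center = 0) {
  n <- length(x)
  if (stats::sd(x) == 0) stop("x must not be constant")
  if (abs(target_r) > 1) stop("target_r must be in [-1, 1]")
  if (is.null(helper))
    helper <- rep_len(c(1, -1), n) * seq_len(n)
  zx <- as.numeric(scale(x))
  e <- stats::lm.fit(cbind(1, zx), helper)$residuals
  if (stats::sd(e) == 0) stop("helper is collinear with x")
  ze <- as.numeric(scale(e))
  y <- target_r * zx + sqrt(1 - target_r^2) * ze
  center + scale_sd * y
}

#' Simulate a synthetic ROI cohort
#'
#' Generates a cohort of participants with ROIs in three broad regions
#' (ventral occipitotemporal, lateral temporal, lateral frontal). Each ROI
#' has a Talairach centroid and a voxel-by-condition beta matrix generated
#' from the planted model: \code{beta = baseline + slope(Y) * predictor +
#' language/face terms + Gaussian noise}, where the word-similarity slope
#' increases linearly along the posterior-to-anterior (TAL Y) axis at
#' \code{gradient_coef} slope units per mm. Localizer betas (9 visual
#' categories) carry a word-selective profile tied to the same slope. In
#' the \code{"logographic-split"} scenario a fraction of VOTC ROIs are
#' language patches: an additive offset on all conditions of the preferred
#' language, a response profile flat over the alphabetic conditions and
#' rising over the logographic hierarchy, and an elevated localizer face
#' beta. All planted parameters are stored in \code{ground_truth}.
#'
#' @param n_participants number of participants (study cohorts: 21).
#' @param rois_per_region named integer vector: ROIs per participant in
#'   each region.
#' @param voxels_per_roi voxels per ROI.
#' @param labels main-run condition labels (14).
#' @param predictor named weights over \code{labels}; defaults to
#'   \code{\link{predictor_enfr}} for the alphabetic design and the
#'   five-step predictor structure otherwise.
#' @param gradient_coef planted gradient: slope units per mm of TAL Y.
#' @param baseline baseline beta (percent signal change).
#' @param noise_sd voxel noise standard deviation.
#' @param y_ranges named list of TAL Y ranges per region (mm).
#' @param prop_right probability that an ROI is right-hemispheric.
#' @param slope_jitter_sd optional sd of voxel-level jitter around the ROI
#'   slope.
#' @param scenario "shared-alphabet" or "logographic-split".
#' @param patch_fraction fraction of VOTC ROIs that are language patches
#'   (logographic-split only).
#' @param patch_effect additive preferred-language offset (beta units).
#' @param face_amplitude localizer face-beta elevation in language patches.
#' @param loc_categories localizer category labels.
#' @param reading_mean,reading_sd distribution of one-minute reading counts.
#' @param seed integer seed.
#' @return object of class \code{cohort_data}: \code{participants} (each
#'   with reading counts, dominance score and a list of ROI records),
#'   \code{labels}, \code{loc_categories}, \code{ground_truth}.
#' @export
simulate_cohort <- function(n_participants = 21L,
                            rois_per_region = c(VOTC = 10L,
                                                lateral_temporal = 4L,
                                                lateral_frontal = 4L),
                            voxels_per_roi = 50L,
                            labels = condition_labels("enfr"),
                            predictor = NULL,
                            gradient_coef = 0.0443,
                            baseline = 0.5,
                            noise_sd = 0.1,
                            y_ranges = list(VOTC = c(-75, -25),
                                            lateral_temporal = c(-60, -10),
                                            lateral_frontal = c(0, 40)),
                            prop_right = 0.3,
                            slope_jitter_sd = 0,
                            scenario = c("shared-alphabet",
                                         "logographic-split"),
                            patch_fraction = 0.2,
                            patch_effect = 0.5,
                            face_amplitude = 1,
                            loc_categories = c("words_en", "words_fr",
                                               "numbers", "false_fonts",
                                               "faces", "bodies", "houses",
                                               "tools", "checkerboard"),
                            reading_mean = 110, reading_sd = 25,
                            seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_participants < 2L) stop("need at least 2 participants")
  if (voxels_per_roi < 1L) stop("need at least 1 voxel per ROI")
  if (patch_fraction < 0 || patch_fraction > 1)
    stop("patch_fraction must be in [0, 1]")
  if (is.null(predictor)) {
    predictor <- if (identical(labels, condition_labels("enfr")))
      predictor_enfr()
    else if (identical(labels, condition_labels("encn")))
      stats::setNames(c((1:7) / 7, (1:7) / 7), labels)
    else stop("supply a predictor for non-standard labels")
  }
  stopifnot(all(labels %in% names(predictor)))
  pred <- predictor[labels]
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  regions <- names(rois_per_region)
  # localizer category profile multipliers on the word-similarity slope,
  # plus baseline shares: words full, symbols intermediate, non-script low
  loc_slope_w <- stats::setNames(
    c(1, 1, 0.5, 0.5, 0, 0, 0, 0, 0)[seq_along(loc_categories)],
    loc_categories)
  loc_base_w <- stats::setNames(
    c(1, 1, 0.9, 0.9, 0.6, 0.6, 0.6, 0.6, 0.5)[seq_along(loc_categories)],
    loc_categories)
  participants <- vector("list", n_participants)
  gt_rois <- list()
  for (p in seq_len(n_participants)) {
    rois <- list()
    ridx <- 0L
    for (reg in regions) {
      yr <- y_ranges[[reg]]
      for (k in seq_len(rois_per_region[[reg]])) {
        ridx <- ridx + 1L
        hemi <- if (stats::runif(1) < prop_right) "right" else "left"
        y <- stats::runif(1, yr[1L], yr[2L])
        x <- (if (hemi == "left") -1 else 1) * stats::runif(1, 25, 45)
        z <- if (reg == "lateral_frontal") stats::runif(1, 0, 50) else
          stats::runif(1, -25, -5)
        slope <- gradient_coef * (y - yr[1L])
        vox_slope <- rep(slope, voxels_per_roi) + if (slope_jitter_sd > 0)
          stats::rnorm(voxels_per_roi, 0, slope_jitter_sd) else 0
        betas <- baseline +
          outer(vox_slope, pred) +
          matrix(stats::rnorm(voxels_per_roi * length(labels), 0, noise_sd),
                 voxels_per_roi, length(labels))
        colnames(betas) <- labels
        patch <- FALSE
        pref_lang <- NA_character_
        if (scenario == "logographic-split" && reg == "VOTC" &&
            stats::runif(1) < patch_fraction) {
          patch <- TRUE
          pref_lang <- "second"
          second <- grepl("F$|^S$|^SG$|^RI$|^RP$|^CP$|^WL$|^WH$", labels)
          if (!any(second)) second <- grepl("F$", labels)
          betas[, second] <- betas[, second] + patch_effect
          # rising profile over the logographic hierarchy, flat elsewhere
          hier <- intersect(c("S", "SG", "RI", "RP", "CP", "WL", "WH"),
                            labels)
          if (length(hier))
            betas[, hier] <- betas[, hier] +
              matrix(patch_effect * seq(0, 1, length.out = length(hier)),
                     voxels_per_roi, length(hier), byrow = TRUE)
        }
        loc <- baseline * matrix(loc_base_w, voxels_per_roi,
                                 length(loc_categories), byrow = TRUE) +
          slope * matrix(loc_slope_w, voxels_per_roi,
                         length(loc_categories), byrow = TRUE) +
          matrix(stats::rnorm(voxels_per_roi * length(loc_categories), 0,
                              noise_sd),
                 voxels_per_roi, length(loc_categories))
        colnames(loc) <- loc_categories
        if (patch && "faces" %in% loc_categories)
          loc[, "faces"] <- loc[, "faces"] + face_amplitude
        rois[[ridx]] <- list(
          roi_id = sprintf("P%02d_R%02d", p, ridx),
          participant = p, hemisphere = hemi, region = reg,
          centroid = c(x = x, y = y, z = z),
          betas = betas, loc_betas = loc,
          planted_slope = slope, patch = patch, pref_lang = pref_lang)
        gt_rois[[length(gt_rois) + 1L]] <- data.frame(
          participant = p, roi_id = rois[[ridx]]$roi_id, region = reg,
          hemisphere = hemi, y = y, planted_slope = slope, patch = patch)
      }
    }
    n1 <- max(1, round(stats::rnorm(1, reading_mean, reading_sd)))
    n2 <- max(1, round(stats::rnorm(1, reading_mean, reading_sd)))
    participants[[p]] <- list(
      id = sprintf("P%02d", p),
      reading = c(L1 = n1, L2 = n2),
      dominance = dominance_score(n1, n2),
      rois = rois)
  }
  structure(list(
    participants = participants,
    labels = labels, loc_categories = loc_categories,
    ground_truth = list(
      gradient_coef = gradient_coef, baseline = baseline,
      noise_sd = noise_sd, predictor = pred, y_ranges = y_ranges,
      scenario = scenario, patch_fraction = patch_fraction,
      patch_effect = patch_effect, face_amplitude = face_amplitude,
      slope_jitter_sd = slope_jitter_sd, seed = as.integer(seed),
      rois = do.call(rbind, gt_rois))),
    class = "cohort_data")
}

#' @export
print.cohort_data <- function(x, ...) {
  nroi <- sum(vapply(x$participants, function(p) length(p$rois), 0L))
  cat("<cohort_data>", length(x$participants), "participants,", nroi,
      "ROIs,", length(x$labels), "main conditions\n")
  invisible(x)
}

#' Flatten a cohort into an ROI-level table of mean betas
#'
#' Averages each ROI's beta matrix across voxels.
#'
#' @param cohort a \code{cohort_data}.
#' @param data "main" (condition betas) or "localizer".
#' @return data.frame: participant, roi_id, hemisphere, region, x, y, z,
#'   then one column per condition/category.
#' @export
cohort_roi_table <- function(cohort, data = c("main", "localizer")) {
  stopifnot(inherits(cohort, "cohort_data"))
  data <- match.arg(data)
  rows <- lapply(cohort$participants, function(p)
    lapply(p$rois, function(r) {
      m <- colMeans(if (data == "main") r$betas else r$loc_betas)
      cbind(data.frame(participant = r$participant, roi_id = r$roi_id,
                       hemisphere = r$hemisphere, region = r$region,
                       x = r$centroid[["x"]], y = r$centroid[["y"]],
                       z = r$centroid[["z"]]),
            as.data.frame(as.list(m), check.names = FALSE))
    }))
  out <- do.call(rbind, unlist(rows, recursive = FALSE))
  rownames(out) <- NULL
  out
}

#' Deterministic dominance-effect cohort fixture
#'
#' Builds a minimal cohort in which the across-participant correlation
#' between the language dominance score and the region-mean WE - WF beta
#' difference equals \code{target_r} exactly, via
#' \code{\link{plant_correlation}}. Reading counts are chosen on a fixed
#' grid; the beta difference is injected symmetrically around a common
#' baseline, identically in all voxels, so region averaging is exact.
#'
#' @param n_participants participants (study: 21).
#' @param target_r exact sample correlation to plant.
#' @param region region label carrying the effect (default "fusiform").
#' @param labels main-run condition labels.
#' @param baseline common beta baseline.
#' @param diff_sd sd of the planted beta differences.
#' @param voxels_per_roi voxels per ROI (identical values).
#' @param seed integer seed (reading-count jitter only; the correlation is
#'   exact for every seed).
#' @return a \code{cohort_data} with one ROI per participant.
#' @export
make_dominance_cohort <- function(n_participants = 21L, target_r = -0.550,
                                  region = "fusiform",
                                  labels = condition_labels("enfr"),
                                  baseline = 0.5, diff_sd = 0.2,
                                  voxels_per_roi = 5L, seed = 1L) {
  rs <- local_seed(seed)
  on.exit(restore_seed(rs), add = TRUE)
  # dominance scores on a continuum, deterministic given seed
  n1 <- round(seq(80, 140, length.out = n_participants) +
                stats::rnorm(n_participants, 0, 3))
  n2 <- round(rev(seq(85, 135, length.out = n_participants)) +
                stats::rnorm(n_participants, 0, 3))
  dom <- dominance_score(n1, n2)
  if (stats::sd(dom) == 0) stop("degenerate dominance scores")
  diffs <- plant_correlation(dom, target_r,
                             helper = stats::rnorm(n_participants),
                             scale_sd = diff_sd)
  loc_categories <- c("words_en", "words_fr", "numbers", "false_fonts",
                      "faces", "bodies", "houses", "tools", "checkerboard")
  participants <- lapply(seq_len(n_participants), function(p) {
    b <- stats::setNames(rep(baseline, length(labels)), labels)
    b["WE"] <- baseline + diffs[p] / 2
    b["WF"] <- baseline - diffs[p] / 2
    betas <- matrix(b, voxels_per_roi, length(labels), byrow = TRUE,
                    dimnames = list(NULL, labels))
    loc <- matrix(baseline, voxels_per_roi, length(loc_categories),
                  dimnames = list(NULL, loc_categories))
    roi <- list(roi_id = sprintf("P%02d_R01", p), participant = p,
                hemisphere = "left", region = region,
                centroid = c(x = -40, y = -50, z = -15),
                betas = betas, loc_betas = loc,
                planted_slope = NA_real_, patch = FALSE,
                pref_lang = NA_character_)
    list(id = sprintf("P%02d", p), reading = c(L1 = n1[p], L2 = n2[p]),
         dominance = dom[p], rois = list(roi))
  })
  structure(list(
    participants = participants, labels = labels,
    loc_categories = loc_categories,
    ground_truth = list(target_r = target_r, diffs = diffs,
                        dominance = dom, region = region,
                        baseline = baseline, seed = as.integer(seed))),
    class = "cohort_data")
}

#' Forward-simulate an ROI time course from condition betas
#'
#' Builds the same HRF-convolved condition regressors as
#' \code{\link{roi_glm}}, combines them with the supplied betas (percent
#' signal change), centers the combined signal over the run, and emits a
#' raw time course around the baseline level with optional AR(1) Gaussian
#' noise: \code{x = baseline * (1 + (s - mean(s)) / 100) + noise}. Defining
#' the baseline as the temporal mean makes the percent transform in
#' \code{roi_glm} its exact inverse at zero noise.
#'
#' @param betas named numeric vector of condition betas.
#' @param schedule the run \code{schedule}.
#' @param noise_sd innovation sd of the AR(1) noise, in percent-signal
#'   units.
#' @param ar_coef AR(1) coefficient of the noise.
#' @param baseline raw signal level.
#' @param dt fine grid step.
#' @param hrf HRF function.
#' @param seed integer seed.
#' @return numeric vector, one value per volume.
#' @export
simulate_roi_timecourses <- function(betas, schedule, noise_sd = 0,
                                     ar_coef = 0, baseline = 100,
                                     dt = 0.05, hrf = hrf_two_gamma,
                                     seed = 1L) {
  X <- glm_design_matrix(schedule, dt = dt, hrf = hrf)
  if (is.null(names(betas)) || !all(colnames(X) %in% names(betas)))
    stop("betas must be named over the schedule's conditions")
  s <- drop(X %*% betas[colnames(X)])
  s <- s - mean(s)
  eps <- 0
  if (noise_sd > 0) {
    rs <- local_seed(seed)
    on.exit(restore_seed(rs), add = TRUE)
    innov <- stats::rnorm(length(s), 0, noise_sd)
    eps <- as.numeric(stats::filter(innov, ar_coef, method = "recursive"))
  }
  baseline * (1 + (s + eps) / 100)
}

#' Serialize a cohort to a directory of CSV matrices plus a JSON manifest
#'
#' One CSV per ROI and data type (main/localizer betas, voxels in rows),
#' and \code{manifest.json} holding ROI metadata, behavioral counts and the
#' ground-truth record.
#'
#' @param cohort a \code{cohort_data}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(labels = cohort$labels,
               loc_categories = cohort$loc_categories,
               ground_truth = cohort$ground_truth[
                 setdiff(names(cohort$ground_truth), "rois")],
               participants = lapply(cohort$participants, function(p)
                 list(id = p$id, reading = as.list(p$reading),
                      dominance = p$dominance,
                      rois = lapply(p$rois, function(r)
                        list(roi_id = r$roi_id,
                             hemisphere = r$hemisphere,
                             region = r$region,
                             centroid = as.list(r$centroid),
                             planted_slope = r$planted_slope,
                             patch = r$patch)))))
  jsonlite::write_json(meta, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (p in cohort$participants) for (r in p$rois) {
    utils::write.csv(r$betas,
                     file.path(dir, paste0(r$roi_id, "_main.csv")),
                     row.names = FALSE)
    utils::write.csv(r$loc_betas,
                     file.path(dir, paste0(r$roi_id, "_localizer.csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Load a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory path.
#' @return a \code{cohort_data} (without the per-ROI ground-truth table).
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "manifest.json"),
                              simplifyVector = TRUE, simplifyDataFrame = FALSE)
  participants <- lapply(meta$participants, function(p) {
    rois <- lapply(p$rois, function(r) {
      betas <- as.matrix(utils::read.csv(
        file.path(dir, paste0(r$roi_id, "_main.csv")), check.names = FALSE))
      loc <- as.matrix(utils::read.csv(
        file.path(dir, paste0(r$roi_id, "_localizer.csv")),
        check.names = FALSE))
      list(roi_id = r$roi_id, participant = NA_integer_,
           hemisphere = r$hemisphere, region = r$region,
           centroid = unlist(r$centroid), betas = betas, loc_betas = loc,
           planted_slope = r$planted_slope %||% NA_real_,
           patch = isTRUE(r$patch), pref_lang = NA_character_)
    })
    list(id = p$id, reading = unlist(p$reading), dominance = p$dominance,
         rois = rois)
  })
  for (i in seq_along(participants))
    for (j in seq_along(participants[[i]]$rois))
      participants[[i]]$rois[[j]]$participant <- i
  structure(list(participants = participants,
                 labels = unlist(meta$labels),
                 loc_categories = unlist(meta$loc_categories),
                 ground_truth = meta$ground_truth),
            class = "cohort_data")
}
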