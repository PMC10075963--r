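#' Define ROIs from a thresholded statistical map
#'
#' Connected components of voxels with p below \code{p_thresh}, keeping
#' clusters of size strictly greater than \code{min_cluster} (the study
#' convention "cluster size > 4" means at least 5 voxels). Connectivity is
#' 6 (faces) by default or 26 (faces, edges, corners).
#'
#' @param stat_map 3D array of voxel p-values.
#' @param p_thresh significance threshold (default 0.001).
#' @param min_cluster clusters must exceed this size (default 4).
#' @param connectivity 6 or 26.
#' @param affine optional 4 x 4 voxel-to-mm matrix applied to 1-based
#'   voxel indices; identity by default.
#' @return data.frame with one row per ROI: \code{roi}, \code{size},
#'   centroid \code{x}, \code{y}, \code{z} (mm), and a list-column
#'   \code{voxels} of linear voxel indices. Zero rows if nothing survives.
#' @export
define_rois <- function(stat_map, p_thresh = 0.001, min_cluster = 4L,
                        connectivity = 6L, affine = NULL) {
  stopifnot(length(dim(stat_map)) == 3L)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  dm <- dim(stat_map)
  mask <- which(stat_map < p_thresh)
  empty <- data.frame(roi = integer(0), size = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0))
  empty$voxels <- list()
  if (!length(mask)) return(empty)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  if (connectivity == 6L)
    offs <- offs[abs(offs$dx) + abs(offs$dy) + abs(offs$dz) == 1L, ]
  coords <- arrayInd(mask, dm)
  in_mask <- array(FALSE, dm)
  in_mask[mask] <- TRUE
  label <- array(0L, dm)
  clusters <- list()
  cl <- 0L
  for (v in mask) {
    if (label[v] != 0L) next
    cl <- cl + 1L
    queue <- v
    label[v] <- cl
    members <- v
    while (length(queue)) {
      cur <- queue[1L]
      queue <- queue[-1L]
      ci <- arrayInd(cur, dm)
      for (o in seq_len(nrow(offs))) {
        ni <- ci + c(offs$dx[o], offs$dy[o], offs$dz[o])
        if (any(ni < 1L) || any(ni > dm)) next
        nl <- ni[1L] + (ni[2L] - 1L) * dm[1L] +
          (ni[3L] - 1L) * dm[1L] * dm[2L]
        if (in_mask[nl] && label[nl] == 0L) {
          label[nl] <- cl
          queue <- c(queue, nl)
          members <- c(members, nl)
        }
      }
    }
    clusters[[cl]] <- members
  }
  keep <- which(lengths(clusters) > min_cluster)
  if (!length(keep)) return(empty)
  rows <- lapply(seq_along(keep), function(i) {
    vox <- clusters[[keep[i]]]
    ci <- arrayInd(vox, dm)
    cen <- colMeans(ci)
    if (!is.null(affine)) {
      cen <- drop(affine %*% c(cen, 1))[1:3]
    }
    data.frame(roi = i, size = length(vox),
               x = cen[1L], y = cen[2L], z = cen[3L])
  })
  out <- do.call(rbind, rows)
  out$voxels <- clusters[keep]
  out
}

#' Word-similarity regression slope of an ROI
#'
#' Ordinary least-squares fit of the ROI's condition betas on the
#' word-similarity predictor weights: \code{beta = intercept + slope *
#' weight}. The slope is the ROI's word-similarity effect; its two-tailed p
#' value comes from the t distribution with n - 2 degrees of freedom.
#'
#' @param betas numeric vector of condition betas (voxel-averaged).
#' @param predictor named or plain numeric vector of the same length with
#'   nonzero variance (e.g. \code{\link{predictor_enfr}}).
#' @return list: \code{slope}, \code{intercept}, \code{se}, \code{t},
#'   \code{df}, \code{p}.
#' @export
word_similarity_slope <- function(betas, predictor) {
  if (length(betas) != length(predictor))
    stop("betas and predictor lengths differ")
  if (length(betas) < 3L) stop("need at least 3 conditions")
  if (!is.null(names(betas)) && !is.null(names(predictor)))
    betas <- betas[names(predictor)]
  w <- as.numeric(predictor)
  if (stats::sd(w) == 0) stop("constant predictor")
  n <- length(w)
  wm <- mean(w); bm <- mean(betas)
  sxx <- sum((w - wm)^2)
  slope <- sum((w - wm) * (betas - bm)) / sxx
  intercept <- bm - slope * wm
  res <- betas - intercept - slope * w
  df <- n - 2L
  se <- sqrt(sum(res^2) / df / sxx)
  tval <- slope / se
  list(slope = slope, intercept = intercept, se = se, t = tval, df = df,
       p = 2 * stats::pt(-abs(tval), df))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up BH procedure: monotone adjusted q-values (via
#' \code{stats::p.adjust}) and the rejection mask at level \code{q}. The
#' mask and q-values agree by construction (\code{reject == (qvalue <= q)}).
#'
#' @param pvalues numeric vector of p values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list: \code{qvalues}, \code{reject} (logical).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must be in [0, 1]")
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(qvalues = qv, reject = qv <= q)
}

#' Word-similarity slopes for every ROI of a cohort
#'
#' Voxel-averages each ROI's betas, fits \code{\link{word_similarity_slope}}
#' and applies BH-FDR across all ROIs.
#'
#' @param cohort a \code{cohort_data}.
#' @param predictor predictor weights (default \code{\link{predictor_enfr}}
#'   restricted to the cohort's labels).
#' @param q FDR level.
#' @return data.frame: participant, roi_id, hemisphere, region, y (TAL),
#'   slope, p, qvalue, significant.
#' @export
cohort_slope_table <- function(cohort, predictor = NULL, q = 0.05) {
  stopifnot(inherits(cohort, "cohort_data"))
  if (is.null(predictor)) predictor <- predictor_enfr()[cohort$labels]
  tab <- cohort_roi_table(cohort, "main")
  fits <- lapply(seq_len(nrow(tab)), function(i)
    word_similarity_slope(unlist(tab[i, cohort$labels]), predictor))
  out <- tab[, c("participant", "roi_id", "hemisphere", "region", "y")]
  out$slope <- vapply(fits, `[[`, 0, "slope")
  out$p <- vapply(fits, `[[`, 0, "p")
  adj <- fdr_bh(out$p, q = q)
  out$qvalue <- adj$qvalues
  out$significant <- adj$reject
  out
}

#' Group test of a posterior-to-anterior gradient
#'
#' Within each participant, regresses an ROI-level functional value (by
#' default the word-similarity slope) on the ROIs' TAL Y coordinates,
#' giving one regression coefficient per participant (slope units per mm);
#' then tests the coefficients against zero with a two-tailed one-sample t
#' test. Participants with fewer than \code{min_rois} usable ROIs are
#' skipped with a warning.
#'
#' @param slopes data.frame with columns \code{participant}, \code{y},
#'   \code{hemisphere} and the value column.
#' @param value column name of the functional value (default "slope").
#' @param hemisphere "left", "right" or "both" (which ROIs enter the fit).
#' @param min_rois minimum ROIs per participant (default 2; the study used
#'   3 for right-hemisphere tests, see \code{min_rois}).
#' @return list of class \code{gradient_result}: \code{coefficients}
#'   (named per participant), \code{mean}, \code{t}, \code{df}, \code{p},
#'   \code{hemisphere}, \code{n_excluded}.
#' @export
gradient_test <- function(slopes, value = "slope",
                          hemisphere = c("left", "right", "both"),
                          min_rois = 2L) {
  hemisphere <- match.arg(hemisphere)
  d <- slopes
  if (hemisphere != "both") d <- d[d$hemisphere == hemisphere, ]
  sp <- split(d, d$participant)
  coefs <- c()
  excluded <- 0L
  for (pp in names(sp)) {
    di <- sp[[pp]]
    if (nrow(di) < min_rois || stats::sd(di$y) == 0) {
      warning("participant ", pp, " skipped (", nrow(di),
              " usable ROIs for hemisphere ", hemisphere, ")")
      excluded <- excluded + 1L
      next
    }
    cf <- stats::lm.fit(cbind(1, di$y), di[[value]])$coefficients[2L]
    coefs[pp] <- cf
  }
  if (length(coefs) < 2L)
    stop("fewer than 2 participants with enough ROIs")
  tt <- tryCatch(stats::t.test(coefs, mu = 0), error = function(e) NULL)
  if (is.null(tt)) {
    # noiseless cohorts: every participant has the identical coefficient
    warning("coefficients have zero variance; t statistic undefined")
    tt <- list(statistic = NaN, parameter = length(coefs) - 1L,
               p.value = NA_real_)
  }
  structure(list(coefficients = coefs, mean = mean(coefs),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, hemisphere = hemisphere,
                 n_excluded = excluded),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf(
    "<gradient_result> %s hemisphere: mean coefficient %.4f, t(%d) = %.3f, p = %.3g (%d participants)\n",
    x$hemisphere, x$mean, x$df, x$t, x$p, length(x$coefficients)))
  invisible(x)
}

#' Paired hemispheric comparison of gradient coefficients
#'
#' Computes per-participant gradient coefficients separately for the left
#' and right hemispheres and compares them with a paired two-tailed t test,
#' restricted to participants with at least \code{min_rois_rh}
#' right-hemisphere ROIs (study rule: 3).
#'
#' @inheritParams gradient_test
#' @param min_rois_rh inclusion threshold on right-hemisphere ROI count.
#' @return list: per-hemisphere coefficient vectors (aligned), \code{t},
#'   \code{df}, \code{p}, \code{n}.
#' @export
gradient_laterality <- function(slopes, value = "slope", min_rois_rh = 3L) {
  rh_counts <- table(slopes$participant[slopes$hemisphere == "right"])
  keep <- names(rh_counts)[rh_counts >= min_rois_rh]
  if (length(keep) < 2L)
    stop("fewer than 2 participants with >= ", min_rois_rh,
         " right-hemisphere ROIs")
  d <- slopes[slopes$participant %in% keep, ]
  gl <- suppressWarnings(gradient_test(d, value, "left",
                                       min_rois = 2L))
  gr <- suppressWarnings(gradient_test(d, value, "right",
                                       min_rois = 2L))
  common <- intersect(names(gl$coefficients), names(gr$coefficients))
  if (length(common) < 2L) stop("fewer than 2 participants in both hemispheres")
  tt <- stats::t.test(gl$coefficients[common], gr$coefficients[common],
                      paired = TRUE)
  list(left = gl$coefficients[common], right = gr$coefficients[common],
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n = length(common))
}

#' Frontal gradient along the first principal axis
#'
#' For lateral frontal ROIs, runs a principal components analysis of the
#' centered TAL (Y, Z) centroid coordinates, takes the first component
#' scores as the main anatomical axis, and correlates them with the ROIs'
#' word-similarity slopes (Pearson, two-tailed).
#'
#' @param rois data.frame with columns \code{y}, \code{z} and the slope
#'   column.
#' @param value slope column name (default "slope").
#' @return list: \code{scores} (PC1 coordinate per ROI), \code{loadings},
#'   \code{r}, \code{df}, \code{p}.
#' @export
frontal_axis_correlation <- function(rois, value = "slope") {
  if (nrow(rois) < 3L) stop("need at least 3 frontal ROIs")
  pc <- stats::prcomp(cbind(rois$y, rois$z), center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1L]
  sl <- rois[[value]]
  if (stats::sd(sl) == 0 || stats::sd(scores) == 0)
    stop("correlation undefined: zero variance in slopes or axis scores")
  ct <- stats::cor.test(scores, sl)
  list(scores = scores, loadings = pc$rotation[, 1L],
       r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Word selectivity index with negative-beta padding
#'
#' \code{(word - other) / (word + other)} on condition means, where both
#' means are computed after padding: if the smallest involved condition
#' beta is negative, its absolute value is added to every involved
#' condition so all are nonnegative. The index is then guaranteed to lie
#' in [-1, 1]. A zero padded denominator yields 0 with a warning.
#'
#' @param condition_betas named numeric vector of condition betas.
#' @param word_labels names of the word conditions.
#' @param other_labels names of the comparison conditions.
#' @return selectivity index in [-1, 1].
#' @export
selectivity_index <- function(condition_betas, word_labels, other_labels) {
  if (!length(word_labels) || !length(other_labels))
    stop("both label sets must be non-empty")
  if (length(intersect(word_labels, other_labels)))
    stop("label sets must be disjoint")
  involved <- c(word_labels, other_labels)
  if (!all(involved %in% names(condition_betas)))
    stop("missing conditions: ",
         paste(setdiff(involved, names(condition_betas)), collapse = ", "))
  b <- condition_betas[involved]
  mn <- min(b)
  if (mn < 0) b <- b + abs(mn)
  wa <- mean(b[word_labels])
  oa <- mean(b[other_labels])
  if (wa + oa == 0) {
    warning("padded denominator is zero; selectivity defined as 0")
    return(0)
  }
  (wa - oa) / (wa + oa)
}

#' Language dominance score from one-minute reading counts
#'
#' \code{(n1 - n2) / (n1 + n2)}: positive when the first language is
#' dominant. Vectorized.
#'
#' @param words_read_l1,words_read_l2 nonnegative reading counts.
#' @return score(s) in [-1, 1].
#' @export
dominance_score <- function(words_read_l1, words_read_l2) {
  if (any(words_read_l1 < 0) || any(words_read_l2 < 0))
    stop("counts must be nonnegative")
  tot <- words_read_l1 + words_read_l2
  if (any(tot == 0)) stop("both counts are zero")
  (words_read_l1 - words_read_l2) / tot
}

#' Correlate regional language differences with dominance scores
#'
#' For each region, averages each participant's betas over the region's
#' ROIs and voxels, computes per-pair activity differences (by default the
#' five study comparisons: main-run WE-WF, LE-LF, BE-BF, QE-QF and the
#' localizer word difference), correlates each difference with the
#' participants' language dominance scores (Pearson, two-tailed), and
#' applies BH-FDR over the family of pairs within each region.
#'
#' @param cohort a \code{cohort_data} with dominance scores.
#' @param pairs named list; each element \code{list(data, a, b)} with
#'   \code{data} "main" or "localizer" and condition/category names
#'   \code{a}, \code{b}.
#' @param regions regions to analyze (default: all present).
#' @param q FDR level within region.
#' @return data.frame: region, pair, n, r, df, p, qvalue, significant.
#'   Degenerate correlations (zero variance) yield NA with a warning.
#' @export
region_dominance_correlation <- function(cohort,
                                         pairs = list(
                                           WEmWF = list(data = "main",
                                                        a = "WE", b = "WF"),
                                           LEmLF = list(data = "main",
                                                        a = "LE", b = "LF"),
                                           BEmBF = list(data = "main",
                                                        a = "BE", b = "BF"),
                                           QEmQF = list(data = "main",
                                                        a = "QE", b = "QF"),
                                           loc_words = list(
                                             data = "localizer",
                                             a = "words_en",
                                             b = "words_fr")),
                                         regions = NULL, q = 0.05) {
  stopifnot(inherits(cohort, "cohort_data"))
  dom <- vapply(cohort$participants, `[[`, 0, "dominance")
  main_tab <- cohort_roi_table(cohort, "main")
  loc_tab <- cohort_roi_table(cohort, "localizer")
  if (is.null(regions)) regions <- sort(unique(main_tab$region))
  rows <- list()
  for (reg in regions) {
    sub_m <- main_tab[main_tab$region == reg, ]
    if (!nrow(sub_m)) stop("region ", reg, " absent in all participants")
    parts <- sort(unique(sub_m$participant))
    if (length(parts) < 3L)
      stop("region ", reg, " has fewer than 3 participants")
    pvals <- numeric(0)
    reg_rows <- list()
    for (nm in names(pairs)) {
      pr <- pairs[[nm]]
      tab <- if (pr$data == "main") main_tab else loc_tab
      sub <- tab[tab$region == reg, ]
      diffs <- vapply(parts, function(pp) {
        di <- sub[sub$participant == pp, ]
        mean(di[[pr$a]]) - mean(di[[pr$b]])
      }, 0)
      dd <- dom[parts]
      if (stats::sd(diffs) == 0 || stats::sd(dd) == 0) {
        warning("correlation undefined for ", reg, "/", nm,
                " (zero variance)")
        reg_rows[[nm]] <- data.frame(region = reg, pair = nm,
                                     n = length(parts), r = NA_real_,
                                     df = NA_integer_, p = NA_real_)
        next
      }
      ct <- stats::cor.test(dd, diffs)
      reg_rows[[nm]] <- data.frame(region = reg, pair = nm,
                                   n = length(parts),
                                   r = unname(ct$estimate),
                                   df = unname(ct$parameter),
                                   p = ct$p.value)
    }
    rr <- do.call(rbind, reg_rows)
    ok <- !is.na(rr$p)
    rr$qvalue <- NA_real_
    rr$significant <- NA
    if (any(ok)) {
      adj <- fdr_bh(rr$p[ok], q = q)
      rr$qvalue[ok] <- adj$qvalues
      rr$significant[ok] <- adj$reject
    }
    rows[[reg]] <- rr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent overlap of one voxel set in another
#'
#' \code{100 * |A intersect B| / |A|}.
#'
#' @param voxel_set_a,voxel_set_b vectors of comparable voxel identifiers.
#' @return percentage in [0, 100].
#' @export
voxel_overlap <- function(voxel_set_a, voxel_set_b) {
  a <- unique(voxel_set_a)
  if (!length(a)) stop("voxel set A is empty")
  100 * length(intersect(a, unique(voxel_set_b))) / length(a)
}
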