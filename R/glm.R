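#' Canonical two-gamma haemodynamic response function
#'
#' Difference of two gamma densities: a positive response peaking around
#' \code{peak} seconds and a delayed undershoot around \code{undershoot}
#' seconds scaled by \code{undershoot_ratio}; normalized to a maximum of 1.
#'
#' @param t time in seconds (vector).
#' @param peak shape of the response gamma (seconds to peak at rate 1).
#' @param undershoot shape of the undershoot gamma.
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric vector of HRF values.
#' @export
hrf_two_gamma <- function(t, peak = 6, undershoot = 16,
                          undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot, rate = 1)
  h / max(h)
}

#' Condition regressors for a run schedule
#'
#' Builds one regressor per condition: a boxcar spanning each stimulus
#' block, convolved with the two-gamma HRF on a fine time grid and sampled
#' at the TR. Used identically by the GLM and by the forward simulator, so
#' noiseless round trips are exact.
#'
#' @param schedule a \code{\link{build_main_run}}-style schedule.
#' @param dt fine grid step in seconds (must divide the schedule's 50 ms
#'   grid and the TR).
#' @param hrf function of time returning HRF values.
#' @return matrix (volumes x conditions), column names the condition
#'   labels, attribute \code{"tr"}.
#' @export
glm_design_matrix <- function(schedule, dt = 0.05, hrf = hrf_two_gamma) {
  stopifnot(inherits(schedule, "schedule"))
  tr <- schedule$timing$tr
  if (abs(tr / dt - round(tr / dt)) > 1e-9)
    stop("dt must divide the TR")
  ev <- schedule$events
  total <- sum(ev$duration)
  if (abs(total / dt - round(total / dt)) > 1e-6)
    stop("dt must divide the schedule grid")
  n_fine <- round(total / dt)
  n_vol <- as.integer(ceiling(total / tr))
  conds <- sort(unique(ev$condition[ev$kind == "stimulus"]))
  hrf_len <- round(32 / dt)
  h <- hrf(seq(0, by = dt, length.out = hrf_len))
  X <- matrix(0, n_vol, length(conds), dimnames = list(NULL, conds))
  vol_idx <- round(seq(0, by = tr, length.out = n_vol) / dt) + 1L
  for (j in seq_along(conds)) {
    box <- numeric(n_fine)
    rows <- which(ev$kind == "stimulus" & ev$condition == conds[j])
    for (r in rows) {
      i0 <- round(ev$onset[r] / dt) + 1L
      i1 <- round((ev$onset[r] + ev$duration[r]) / dt)
      box[i0:i1] <- 1
    }
    conv <- stats::convolve(box, rev(h), type = "open")[seq_len(n_fine)] * dt
    X[, j] <- conv[vol_idx]
  }
  attr(X, "tr") <- tr
  X
}

#' Percent-signal transform of a time course
#'
#' \code{100 * (x - mean(x)) / mean(x)}.
#'
#' @param x numeric time course.
#' @return transformed vector.
#' @export
percent_transform <- function(x) {
  m <- mean(x)
  if (!is.finite(m) || m == 0) stop("time-course mean must be finite and nonzero")
  100 * (x - m) / m
}

#' ROI general linear model with optional AR(2) correction
#'
#' Percent-transforms the ROI time course, regresses it on the HRF-convolved
#' condition regressors of the schedule plus optional confounds and an
#' intercept, by ordinary least squares; with \code{ar_order = 2}, serial
#' correlations are handled by two-pass prewhitening (Cochrane-Orcutt): AR(2)
#' coefficients are estimated from the OLS residuals by Yule-Walker, data
#' and design are filtered, and the model refit. Contrasts are evaluated
#' with \code{\link{glm_contrast}}.
#'
#' @param y raw ROI time course (one value per volume).
#' @param schedule the run \code{schedule}.
#' @param confounds optional numeric matrix of confound regressors
#'   (z-scored internally).
#' @param ar_order 0 (OLS) or 2 (AR(2)-prewhitened GLS).
#' @param dt fine grid step for the design matrix.
#' @param hrf HRF function.
#' @return object of class \code{roi_glm}: condition betas (percent signal
#'   change), covariance factors, residual variance, degrees of freedom, AR
#'   coefficients.
#' @export
roi_glm <- function(y, schedule, confounds = NULL, ar_order = 0L,
                    dt = 0.05, hrf = hrf_two_gamma) {
  if (!ar_order %in% c(0L, 2L)) stop("ar_order must be 0 or 2")
  X0 <- glm_design_matrix(schedule, dt = dt, hrf = hrf)
  if (length(y) != nrow(X0))
    stop("time course has ", length(y), " volumes; schedule implies ",
         nrow(X0))
  conds <- colnames(X0)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    confounds <- scale(confounds)
    colnames(confounds) <- colnames(confounds) %||%
      paste0("confound", seq_len(ncol(confounds)))
  }
  X <- cbind(X0, confounds, intercept = 1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(drop, collapse = ", "))
  }
  yp <- percent_transform(y)
  fit <- stats::lm.fit(X, yp)
  phi <- numeric(0)
  if (ar_order == 2L) {
    phi <- stats::ar.yw(fit$residuals, order.max = 2L, aic = FALSE,
                        demean = TRUE)$ar
    pw <- function(v) {
      n <- length(v)
      v[3:n] - phi[1L] * v[2:(n - 1L)] - phi[2L] * v[1:(n - 2L)]
    }
    Xw <- apply(X, 2L, pw)
    yw <- pw(yp)
    fit <- stats::lm.fit(Xw, yw)
    X <- Xw
  }
  df <- length(fit$residuals) - ncol(X)
  sigma2 <- sum(fit$residuals^2) / df
  XtXinv <- chol2inv(qr.R(qr(X)))
  dimnames(XtXinv) <- list(colnames(X), colnames(X))
  structure(list(coef = fit$coefficients, conditions = conds,
                 sigma2 = sigma2, XtXinv = XtXinv, df = df,
                 ar = phi, n = length(y)),
            class = "roi_glm")
}

#' @export
print.roi_glm <- function(x, ...) {
  cat("<roi_glm>", length(x$conditions), "conditions,", x$n, "volumes, df",
      x$df, if (length(x$ar)) sprintf(", AR(2) = %.3f, %.3f",
                                      x$ar[1], x$ar[2]) else "", "\n")
  print(round(x$coef[x$conditions], 4))
  invisible(x)
}

#' Evaluate a condition contrast on a fitted ROI GLM
#'
#' @param fit a \code{\link{roi_glm}}.
#' @param weights named numeric vector of contrast weights over (a subset
#'   of) the condition labels; unnamed conditions get weight 0.
#' @return list with \code{estimate}, \code{se}, \code{t}, \code{df},
#'   \code{p} (two-tailed).
#' @export
glm_contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "roi_glm"))
  if (is.null(names(weights)) || !all(names(weights) %in% fit$conditions))
    stop("contrast weights must be named over the condition labels")
  if (all(weights == 0)) stop("contrast weights are all zero")
  w <- stats::setNames(numeric(length(fit$coef)), names(fit$coef))
  w[names(weights)] <- weights
  est <- sum(w * fit$coef)
  se <- sqrt(fit$sigma2 * drop(t(w) %*% fit$XtXinv %*% w))
  tval <- est / se
  list(estimate = est, se = se, t = tval, df = fit$df,
       p = 2 * stats::pt(-abs(tval), fit$df))
}

#' Named contrast weight vectors for the main-run condition batteries
#'
#' For the alphabetic two-language design: lexicality (words vs matched
#' quadrigram nonwords), component-frequency effects per level, adjacent
#' level differences (including lexicality vs twice the quadrigram effect),
#' per-language high-frequency pairs, and 2 x 2 main effects and
#' interactions per level. For the alphabetic-logographic design:
#' frequency effects and lexicality on the alphabetic side, and adjacent
#' steps of the character hierarchy. Simple differences are coded as
#' differences of condition means (+1 side summing to 1), compound
#' contrasts as differences of such differences.
#'
#' @param design "enfr" or "encn".
#' @return named list of named weight vectors.
#' @export
contrast_definitions <- function(design = c("enfr", "encn")) {
  design <- match.arg(design)
  w <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }
  pair <- function(a, b) w(stats::setNames(c(1, -1), c(a, b)))
  if (design == "encn") {
    return(list(
      freq_letters = pair("L+", "L-"),
      freq_bigrams = pair("B+", "B-"),
      freq_quadrigrams = pair("Q+", "Q-"),
      lexicality_en = pair("WE", "Q+"),
      sg_vs_s = pair("SG", "S"),
      ri_vs_sg = pair("RI", "SG"),
      rp_vs_ri = pair("RP", "RI"),
      cp_vs_rp = pair("CP", "RP"),
      wl_vs_cp = pair("WL", "CP"),
      wh_vs_wl = pair("WH", "WL")))
  }
  add <- function(a, b) {
    out <- stats::setNames(numeric(length(union(names(a), names(b)))),
                           union(names(a), names(b)))
    out[names(a)] <- out[names(a)] + a
    out[names(b)] <- out[names(b)] + b
    out
  }
  lexicality <- w(`WE` = 0.5, `WF` = 0.5, `QE` = -0.5, `QF` = -0.5)
  freq <- list(letters = pair("L+", "L-"), bigrams = pair("B+", "B-"),
               quadrigrams = pair("Q+", "Q-"))
  out <- list(
    lexicality = lexicality,
    freq_letters = freq$letters,
    freq_bigrams = freq$bigrams,
    freq_quadrigrams = freq$quadrigrams,
    level_big_vs_let = add(freq$bigrams, -freq$letters),
    level_quad_vs_big = add(freq$quadrigrams, -freq$bigrams),
    level_lex_vs_quad = add(lexicality, -2 * freq$quadrigrams),
    lang_letters = pair("LF", "LE"),
    lang_bigrams = pair("BF", "BE"),
    lang_quadrigrams = pair("QF", "QE"))
  for (lv in c("L", "B", "Q")) {
    lo <- paste0(lv, "-"); hi <- paste0(lv, "+")
    e <- paste0(lv, "E"); f <- paste0(lv, "F")
    nm <- c(L = "letters", B = "bigrams", Q = "quadrigrams")[[lv]]
    out[[paste0("main_f_", nm)]] <-
      w(stats::setNames(c(0.5, 0.5, -0.5, -0.5), c(f, hi, e, lo)))
    out[[paste0("main_e_", nm)]] <-
      w(stats::setNames(c(0.5, 0.5, -0.5, -0.5), c(e, hi, f, lo)))
    out[[paste0("interaction_", nm)]] <-
      w(stats::setNames(c(1, -1, -1, 1), c(hi, f, e, lo)))
  }
  out
}

#' Evaluate the full contrast battery
#'
#' On a named beta vector, returns contrast estimates; on a fitted
#' \code{\link{roi_glm}}, additionally returns t statistics and two-tailed
#' p values.
#'
#' @param x named numeric vector of condition betas, or a \code{roi_glm}.
#' @param design "enfr" or "encn".
#' @return data.frame with columns \code{contrast}, \code{estimate} and,
#'   for GLM input, \code{t}, \code{df}, \code{p}.
#' @export
contrast_battery <- function(x, design = c("enfr", "encn")) {
  design <- match.arg(design)
  defs <- contrast_definitions(design)
  labels <- condition_labels(design)
  if (inherits(x, "roi_glm")) {
    if (!all(labels %in% x$conditions))
      stop("GLM conditions do not match the ", design, " design")
    rows <- lapply(names(defs), function(nm) {
      cr <- glm_contrast(x, defs[[nm]])
      data.frame(contrast = nm, estimate = cr$estimate, t = cr$t,
                 df = cr$df, p = cr$p)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(names(x)) || !all(labels %in% names(x)))
    stop("betas must be named with the ", design, " condition labels")
  est <- vapply(defs, function(wv) sum(wv * x[names(wv)]), 0)
  data.frame(contrast = names(defs), estimate = unname(est))
}
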