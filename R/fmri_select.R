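## Mass-univariate GLM T-contrast (music vs no-music) and the greedy
## minimum-distance voxel-cluster selection that yields the dipole
## locations for source analysis.

#' Per-voxel GLM T-map for the music contrast
#'
#' Fits an ordinary-least-squares GLM to every voxel time series. The design
#' holds one music regressor (boxcar of music trials convolved with the
#' double-gamma HRF) and one no-music regressor (reporting-only trials,
#' same convolution), plus an intercept and a linear drift per run. The
#' T statistic tests the linear contrast music minus no-music.
#'
#' @param bold a `bold_volume` (with `run` labels per volume, or supply via
#'   `run`)
#' @param schedule the `trial_schedule` the volume was acquired under
#' @param contrast named numeric contrast over the condition columns
#'   (default `c(music = 1, no_music = -1)`)
#' @param run optional run index per volume (overrides `bold$run`)
#' @param t_max cap on |T| for numerically exact fits (default 1e6)
#' @return a `tmap`: list with `coords` (voxels x 3 mm), `t`, `p`
#'   (two-sided), `df`, `contrast`
#' @export
glm_tmap <- function(bold, schedule, contrast = c(music = 1, no_music = -1),
                     run = NULL, t_max = 1e6) {
  run <- run %||% bold$run
  if (is.null(run)) stop("run labels per volume are required")
  nv <- ncol(bold$ts)
  if (length(run) != nv) stop("run labels do not match volume count")
  runs <- sort(unique(run))
  run_len <- attr(schedule, "run_length_s")

  music <- numeric(nv); nomusic <- numeric(nv)
  drift <- matrix(0, nv, length(runs)); icpt <- matrix(0, nv, length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    sel <- which(run == r)
    sr <- schedule[schedule$run == r, , drop = FALSE]
    dur <- if (!is.null(run_len)) run_len[ri] else
      max(sr$onset_s + sr$duration_s) + 0.5
    mt <- sr[sr$type %in% c("music_only", "music_reporting"), , drop = FALSE]
    nt <- sr[sr$type == "reporting_only", , drop = FALSE]
    music[sel] <- hrf_regressor(mt$onset_s, mt$duration_s, dur, bold$tr_s)[seq_along(sel)]
    if (nrow(nt))
      nomusic[sel] <- hrf_regressor(nt$onset_s, nt$duration_s, dur, bold$tr_s)[seq_along(sel)]
    icpt[sel, ri] <- 1
    drift[sel, ri] <- scale(seq_along(sel))
  }
  X <- cbind(music = music, no_music = nomusic, icpt, drift)
  colnames(X) <- c("music", "no_music", paste0("intercept_run", runs),
                   paste0("drift_run", runs))

  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  XtXinv <- chol2inv(chol(crossprod(X)))
  beta <- XtXinv %*% crossprod(X, t(bold$ts))        # p x voxels
  resid <- t(bold$ts) - X %*% beta
  df <- nv - ncol(X)
  sigma2 <- colSums(resid^2) / df
  cvec <- numeric(ncol(X)); names(cvec) <- colnames(X)
  cvec["music"] <- contrast[["music"]]
  cvec["no_music"] <- contrast[["no_music"]]
  cb <- as.numeric(crossprod(cvec, beta))
  se <- sqrt(pmax(sigma2 * as.numeric(t(cvec) %*% XtXinv %*% cvec), 0))
  tval <- ifelse(se > 0, cb / se, sign(cb) * t_max)
  tval <- pmin(pmax(tval, -t_max), t_max)
  p <- 2 * stats::pt(-abs(tval), df)
  p <- pmax(p, .Machine$double.xmin)
  structure(list(coords = bold$grid, t = tval, p = p, df = df,
                 contrast = contrast, design = X),
            class = "tmap")
}

#' @export
print.tmap <- function(x, ...) {
  cat("T-map:", length(x$t), "voxels, df =", x$df,
      "; max |T| =", round(max(abs(x$t)), 2), "\n")
  invisible(x)
}

#' Greedy minimum-distance dipole selection
#'
#' From the candidate voxels whose (corrected) p-value passes `alpha`,
#' repeatedly pop the candidate with the largest T value (ties broken by
#' lowest voxel index) and add it to the selected set if its smallest
#' Euclidean distance to every already-selected location is strictly
#' greater than `m_mm`; stop when `n_l` locations are selected or the
#' candidates are exhausted.
#'
#' @param tmap a `tmap`
#' @param alpha significance threshold (default 0.05)
#' @param correction multiple-comparison control over voxels:
#'   `"bonferroni"` (family-wise, default) or `"none"`
#' @param m_mm minimum pairwise distance in mm (default 30)
#' @param n_l number of locations to select (default 4)
#' @return a `dipole_set`: list with `locations` (k x 3 mm, k <= n_l),
#'   `t_values` (non-increasing), `voxel_index`, and `params`
#' @export
select_dipoles <- function(tmap, alpha = 0.05,
                           correction = c("bonferroni", "none"),
                           m_mm = 30, n_l = 4) {
  correction <- match.arg(correction)
  p <- if (correction == "bonferroni") pmin(tmap$p * length(tmap$p), 1) else tmap$p
  cand <- which(p < alpha)
  if (!length(cand)) {
    warning("no significant voxels at alpha = ", alpha,
            " (", correction, "); returning an empty dipole set")
    return(structure(list(locations = matrix(numeric(0), 0, 3),
                          t_values = numeric(0), voxel_index = integer(0),
                          params = list(alpha = alpha, correction = correction,
                                        m_mm = m_mm, n_l = n_l)),
                     class = "dipole_set"))
  }
  V <- integer(0)
  C <- cand[order(-tmap$t[cand], cand)]   # by T desc, index asc on ties
  while (length(V) < n_l && length(C)) {
    v <- C[1]; C <- C[-1]
    if (!length(V)) { V <- v; next }
    dmin <- min(sqrt(rowSums(sweep(tmap$coords[V, , drop = FALSE], 2,
                                   tmap$coords[v, ])^2)))
    if (dmin > m_mm) V <- c(V, v)
  }
  if (length(V) < n_l)
    message("candidates exhausted: selected ", length(V), " of ", n_l,
            " dipole locations")
  loc <- tmap$coords[V, , drop = FALSE]
  dimnames(loc) <- NULL
  structure(list(locations = loc,
                 t_values = tmap$t[V], voxel_index = V,
                 params = list(alpha = alpha, correction = correction,
                               m_mm = m_mm, n_l = n_l)),
            class = "dipole_set")
}

#' @export
print.dipole_set <- function(x, ...) {
  cat("Dipole set:", nrow(x$locations), "location(s), m =", x$params$m_mm,
      "mm, n_l =", x$params$n_l, "\n")
  if (nrow(x$locations))
    print(cbind(round(x$locations, 1), T = round(x$t_values, 2)))
  invisible(x)
}

#' Read / write a dipole set (JSON)
#' @param dipoles a `dipole_set`
#' @param path `.json` path
#' @return `read_dipoles` returns a `dipole_set`
#' @export
write_dipoles <- function(dipoles, path) {
  jsonlite::write_json(list(locations = dipoles$locations,
                            t_values = dipoles$t_values,
                            voxel_index = dipoles$voxel_index,
                            params = dipoles$params),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dipoles
#' @export
read_dipoles <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(locations = rbind(as.matrix(obj$locations)),
                 t_values = as.numeric(obj$t_values),
                 voxel_index = as.integer(obj$voxel_index),
                 params = obj$params),
            class = "dipole_set")
}
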