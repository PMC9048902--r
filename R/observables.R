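# Trajectory observables: z-density profiles and layer thicknesses, radial
# distribution functions and the potential of mean force, multi-origin mean
# square displacements and anomalous-diffusion exponent fits.

group_indices <- function(traj, group) {
  idx <- which(traj$config$group == group)
  if (length(idx) == 0) stop("no beads in group '", group, "'")
  idx
}

#' z-density profile
#'
#' Frame-averaged histogram of wrapped z coordinates for one bead group.
#'
#' @param traj a \code{cg_traj}
#' @param group "lipid", "peg" or "water"
#' @param bin_width bin width, A
#' @param frames frame subset (indices), default all
#' @return object of class \code{density_profile} with bin centers (A), raw
#'   summed counts, and the number of frames averaged
#' @export
density_profile <- function(traj, group, bin_width = 1, frames = NULL) {
  idx <- group_indices(traj, group)
  if (is.null(frames)) frames <- seq_along(traj$time)
  if (length(frames) < 1) stop("need at least one frame")
  lz <- max(traj$frame_lz[frames])
  breaks <- seq(0, lz + bin_width, by = bin_width)
  counts <- numeric(length(breaks) - 1)
  rows <- 3 * (idx - 1) + 3
  for (f in frames) {
    z <- traj$frames[rows, f] %% traj$frame_lz[f]
    h <- hist(z, breaks = breaks, plot = FALSE)
    counts <- counts + h$counts
  }
  out <- list(z = (breaks[-1] + breaks[-length(breaks)]) / 2,
              counts = counts, n_frames = length(frames),
              bin_width = bin_width, group = group, Lz = lz)
  class(out) <- "density_profile"
  out
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile (%s): %d bins of %.2f A, %d frames, %g counts\n",
              x$group, length(x$z), x$bin_width, x$n_frames, sum(x$counts)))
  invisible(x)
}

#' @export
plot.density_profile <- function(x, ...) {
  plot(x$z / 10, x$counts / x$n_frames, type = "l",
       xlab = "z (nm)", ylab = "beads per bin per frame",
       main = paste("z-density:", x$group), ...)
}

# interpolated crossing of `level` between bins i and i+1 walking in `dir`
.cross <- function(z, y, i, dir, level) {
  j <- i + dir
  if (y[j] == y[i]) return(z[j])
  z[i] + (z[j] - z[i]) * (level - y[i]) / (y[j] - y[i])
}

#' Membrane and polymer-layer thickness from a density profile
#'
#' For a single membrane, the thickness \code{h} is the full width at half
#' maximum of the lipid profile. For a double membrane the profile is
#' circularly rotated so the widest low-density region (the polymer-filled
#' inner gap) sits at the center; each lipid slab's FWHM gives \code{h}, the
#' distance between the two facing half-maximum edges gives the
#' inter-membrane distance \code{d}, and the polymer-layer thickness is
#' \code{L = d/2}.
#'
#' @param profile a lipid \code{density_profile}
#' @param geometry "single" or "double"
#' @return list of class \code{thickness_result} with \code{h}, \code{d},
#'   \code{L} in nm
#' @details The profile is treated as periodic. For the double geometry the
#' widest low-density region is taken as the polymer-filled inner gap and
#' rotated to the array center; the outer membrane surfaces may be in
#' contact across the boundary, so each slab's thickness is measured as half
#' the total width above half maximum rather than by walking to an outer
#' edge.
#' @export
extract_thickness <- function(profile, geometry = c("single", "double")) {
  geometry <- match.arg(geometry)
  y <- profile$counts
  n <- length(y)
  # light circular smoothing to stabilize the half-max crossings
  ys <- (y + c(y[-1], y[1]) + c(y[n], y[-n])) / 3
  if (max(ys) <= 0) stop("empty density profile")
  bw <- profile$bin_width
  if (geometry == "single") {
    # rotate the peak to the center so the slab cannot straddle the boundary
    shift <- round(n / 2) - which.max(ys)
    yr <- ys[((seq_len(n) - 1 - shift) %% n) + 1]
    pk <- which.max(yr)
    half <- yr[pk] / 2
    li <- pk; while (li > 1 && yr[li - 1] >= half) li <- li - 1
    ri <- pk; while (ri < n && yr[ri + 1] >= half) ri <- ri + 1
    if (li == 1 || ri == n)
      stop("slab not detected (spans the whole profile); counts: ",
           paste(round(ys), collapse = " "))
    zl <- .cross(profile$z, yr, li, -1L, half)
    zr <- .cross(profile$z, yr, ri, +1L, half)
    out <- list(h = (zr - zl) / 10, d = NA_real_, L = NA_real_)
  } else {
    # longest circular run below 25% of max = inner (polymer) gap
    low <- ys < 0.25 * max(ys)
    if (!any(low)) stop("no inter-membrane gap detected in profile")
    ext <- rep(low, 2)
    best_len <- 0; best_start <- NA
    i <- 1
    while (i <= n) {
      if (ext[i]) {
        j <- i
        while (j < 2 * n && ext[j + 1]) j <- j + 1
        if (j - i + 1 > best_len) { best_len <- j - i + 1; best_start <- i }
        i <- j + 1
      } else i <- i + 1
    }
    gap_center <- (best_start + best_len / 2 - 1) %% n + 1
    shift <- round(n / 2) - gap_center
    yr <- ys[((seq_len(n) - 1 - shift) %% n) + 1]
    mid <- round(n / 2)
    peakL <- max(yr[1:mid]); peakR <- max(yr[(mid + 1):n])
    # facing edges: walk outward from the gap center to each half-max crossing
    i <- mid; while (i > 1 && yr[i] < peakL / 2) i <- i - 1
    if (i == 1) stop("left slab not detected")
    eL <- .cross(profile$z, yr, i, +1L, peakL / 2)
    j <- mid; while (j < n && yr[j] < peakR / 2) j <- j + 1
    if (j == n) stop("right slab not detected")
    eR <- .cross(profile$z, yr, j, -1L, peakR / 2)
    d <- eR - eL
    # membrane thickness: half the total width above half maximum (the two
    # slabs may touch across the periodic boundary)
    half_ref <- (peakL + peakR) / 4
    h <- sum(ys >= half_ref) * bw / 2
    out <- list(h = h / 10, d = d / 10, L = d / 20)
  }
  class(out) <- "thickness_result"
  out
}

#' @export
print.thickness_result <- function(x, ...) {
  cat(sprintf("membrane thickness h = %.2f nm", x$h))
  if (!is.na(x$d))
    cat(sprintf("; inter-membrane d = %.2f nm; polymer layer L = d/2 = %.2f nm",
                x$d, x$L))
  cat("\n")
  invisible(x)
}

#' Radial distribution function
#'
#' Shell-normalized pair histogram over all frames using minimum-image
#' distances among the beads of one group, with the homogeneous 3-D ideal
#' gas as reference.
#'
#' @param traj a \code{cg_traj}
#' @param group bead group
#' @param r_max largest distance, A (at most half the smallest box edge)
#' @param n_bins number of bins
#' @param frames frame subset
#' @return object of class \code{rdf_result} with fields \code{r} (A),
#'   \code{g}, \code{rho} (beads/A^3)
#' @export
rdf <- function(traj, group, r_max = NULL, n_bins = 100, frames = NULL) {
  idx <- group_indices(traj, group)
  if (length(idx) < 2) stop("need at least two beads for an RDF")
  if (is.null(frames)) frames <- seq_along(traj$time)
  box <- c(traj$box[1], traj$box[2], min(traj$frame_lz[frames]))
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge")
  hist <- cpp_rdf_hist(traj$frames[, frames, drop = FALSE], box,
                       as.integer(idx), r_max, as.integer(n_bins))
  dr <- r_max / n_bins
  r <- (seq_len(n_bins) - 0.5) * dr
  V <- prod(box)
  m <- length(idx)
  rho <- m / V
  shell <- 4 * pi * r^2 * dr
  ideal <- length(frames) * m * (m - 1) / V * shell
  out <- list(r = r, g = hist / ideal, rho = rho, group = group,
              n_frames = length(frames))
  class(out) <- "rdf_result"
  out
}

#' Potential of mean force from an RDF
#'
#' \eqn{U_{eff}/k_BT = -\ln g(r)}; bins with \eqn{g = 0} are masked (NA)
#' rather than clipped to a finite barrier.
#'
#' @param rdf_result an [rdf()] result
#' @return the same object with a \code{U_eff} field (k_B T units)
#' @export
effective_potential <- function(rdf_result) {
  u <- ifelse(rdf_result$g > 0, -log(rdf_result$g), NA_real_)
  rdf_result$U_eff <- u
  rdf_result
}

#' @export
plot.rdf_result <- function(x, which = c("g", "U_eff"), ...) {
  which <- match.arg(which)
  if (which == "g")
    plot(x$r, x$g, type = "l", xlab = "r (A)", ylab = "g(r)", ...)
  else
    plot(x$r, x$U_eff, type = "l", xlab = "r (A)",
         ylab = expression(U[eff] / k[B] * T), ...)
}

#' Mean square displacement
#'
#' Multi-time-origin MSD from unwrapped coordinates. Lipid analyses
#' conventionally use molecule centers of mass and in-plane (x, y)
#' displacements (\code{d = 2}); polymer analyses use monomer positions in
#' three dimensions (\code{d = 3}).
#'
#' @param traj a \code{cg_traj} with unwrapped coordinates
#' @param group bead group
#' @param dims "xyz" or "xy"
#' @param reference "monomer" (raw beads) or "com" (per-molecule center of
#'   mass)
#' @param n_lags number of log-spaced lag times
#' @param origin_stride origin subsampling (1 = every frame)
#' @return object of class \code{msd_result}: data frame fields \code{t}
#'   (fs) and \code{msd} (A^2), plus the dimensionality \code{d}
#' @export
msd <- function(traj, group, dims = c("xyz", "xy"),
                reference = c("monomer", "com"), n_lags = 60,
                origin_stride = 1) {
  dims <- match.arg(dims)
  reference <- match.arg(reference)
  if (isTRUE(traj$wrapped))
    stop("trajectory has wrapped coordinates without image information; MSD needs unwrapped positions")
  idx <- group_indices(traj, group)
  F <- length(traj$time)
  if (F < 3) stop("need at least 3 frames")
  if (reference == "com") {
    # center of mass of the complete molecules containing the group
    idx <- which(traj$config$mol %in% unique(traj$config$mol[idx]))
    mols <- traj$config$mol[idx]
    mass <- traj$config$mass[idx]
    um <- sort(unique(mols))
    mtot <- rowsum(mass, mols)[, 1]
    com <- matrix(0, 3 * length(um), F)
    for (d in 1:3) {
      sub <- traj$frames[3 * (idx - 1) + d, , drop = FALSE]
      com[3 * (seq_along(um) - 1) + d, ] <-
        rowsum(sub * mass, mols) / mtot
    }
    mat <- com
    sel <- seq_along(um)
  } else {
    mat <- traj$frames
    sel <- idx
  }
  dim_idx <- if (dims == "xy") c(1L, 2L) else c(1L, 2L, 3L)
  lags <- unique(round(exp(seq(log(1), log(F - 1), length.out = n_lags))))
  vals <- cpp_msd(mat, as.integer(sel), as.integer(lags),
                  dim_idx, as.integer(origin_stride))
  dt_frame <- if (F > 1) traj$time[2] - traj$time[1] else NA
  out <- list(t = c(0, lags * dt_frame), msd = c(0, vals),
              d = length(dim_idx), group = group, reference = reference,
              dims = dims)
  class(out) <- "msd_result"
  out
}

#' @export
plot.msd_result <- function(x, ...) {
  ok <- x$t > 0 & x$msd > 0
  plot(x$t[ok], x$msd[ok], log = "xy", type = "b", pch = 16, cex = 0.5,
       xlab = "lag time (fs)", ylab = expression(MSD ~ (ring(A)^2)), ...)
}

#' Anomalous-diffusion fits on log-log windows
#'
#' Least-squares lines in log10-log10 space on each requested lag-time
#' window: the slope is the anomalous exponent \eqn{\alpha} and the
#' intercept gives the generalized diffusion coefficient via
#' \eqn{\mathrm{MSD} = 2 d D_\alpha t^\alpha}. \eqn{D_\alpha} is reported
#' both in \eqn{\mathrm{\AA^2/fs^\alpha}} and in
#' \eqn{\mathrm{cm^2/s^\alpha}}.
#'
#' @param msd_result an [msd()] result
#' @param windows list of \code{c(t_lo, t_hi)} windows, fs
#' @return object of class \code{regime_fit}; one row per window
#' @export
fit_anomalous <- function(msd_result, windows) {
  if (is.numeric(windows)) windows <- list(windows)
  rows <- lapply(windows, function(w) {
    sel <- msd_result$t >= w[1] & msd_result$t <= w[2] & msd_result$t > 0
    if (any(sel & !(msd_result$msd > 0)))
      stop("non-positive MSD values inside the fit window")
    if (sum(sel) < 5) stop("fewer than 5 MSD points in window [",
                           w[1], ", ", w[2], "]")
    x <- log10(msd_result$t[sel])
    y <- log10(msd_result$msd[sel])
    fit <- lm(y ~ x)
    alpha <- unname(coef(fit)[2])
    D_A2fs <- 10^unname(coef(fit)[1]) / (2 * msd_result$d)
    data.frame(t_lo = w[1], t_hi = w[2], alpha = alpha,
               D_alpha_A2fs = D_A2fs,
               D_alpha_cm2 = d_alpha_to_cm2(D_A2fs, alpha),
               n = sum(sel))
  })
  out <- list(fits = do.call(rbind, rows), d = msd_result$d,
              msd = msd_result)
  class(out) <- "regime_fit"
  out
}

#' @export
print.regime_fit <- function(x, ...) {
  cat(sprintf("anomalous-diffusion fits (d = %d):\n", x$d))
  f <- x$fits
  for (i in seq_len(nrow(f)))
    cat(sprintf("  [%.3g, %.3g] fs : alpha = %.3f, D_alpha = %.3g cm^2/s^alpha (%d pts)\n",
                f$t_lo[i], f$t_hi[i], f$alpha[i], f$D_alpha_cm2[i], f$n[i]))
  invisible(x)
}

#' @export
coef.regime_fit <- function(object, ...) object$fits

#' @export
plot.regime_fit <- function(x, ...) {
  plot(x$msd, ...)
  f <- x$fits
  for (i in seq_len(nrow(f))) {
    tt <- 10^seq(log10(f$t_lo[i]), log10(f$t_hi[i]), length.out = 20)
    lines(tt, 2 * x$d * f$D_alpha_A2fs[i] * tt^f$alpha[i], col = 2, lwd = 2)
  }
}

#' Automatic MSD regime segmentation
#'
#' Fits continuous piecewise-linear models with 1-3 segments in log-log
#' space and picks the segment count by BIC. Breakpoints are returned in fs;
#' they are invariant (up to the same factor) under uniform time rescaling.
#'
#' @param msd_result an [msd()] result spanning several decades of lag time
#' @param max_segments 1-3
#' @param min_pts minimum points per segment
#' @return list of class \code{msd_segments}: \code{breakpoints} (fs),
#'   \code{slopes}, \code{n_segments}, \code{bic}
#' @export
segment_msd <- function(msd_result, max_segments = 3, min_pts = 5) {
  ok <- msd_result$t > 0 & msd_result$msd > 0
  x <- log10(msd_result$t[ok])
  y <- log10(msd_result$msd[ok])
  n <- length(x)
  span <- diff(range(x))
  if (span < 2) stop("need at least two decades of lag time to segment")
  if (span < 3) warning("fewer than three decades of lag time; breakpoints may be poorly constrained")
  # residual floor (10^-6 per point in log10 units) keeps the BIC comparison
  # meaningful on noiseless synthetic curves
  bic_of <- function(rss, p) n * log(max(rss, n * 1e-12) / n) + p * log(n)
  fits <- list()
  r1 <- lm.fit(cbind(1, x), y)
  fits[[1]] <- list(k = 1, bp = numeric(0), rss = sum(r1$residuals^2),
                    coefs = r1$coefficients, bic = bic_of(sum(r1$residuals^2), 2))
  cand <- x[seq(min_pts, n - min_pts)]
  cand <- unique(cand)
  if (max_segments >= 2 && length(cand) > 0) {
    best <- NULL
    for (b in cand) {
      X <- cbind(1, x, pmax(x - b, 0))
      f <- lm.fit(X, y)
      rss <- sum(f$residuals^2)
      if (is.null(best) || rss < best$rss)
        best <- list(k = 2, bp = b, rss = rss, coefs = f$coefficients)
    }
    best$bic <- bic_of(best$rss, 4)
    fits[[2]] <- best
  }
  if (max_segments >= 3 && length(cand) > 1) {
    best <- NULL
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (cand[j] < cand[i] + 0.3) next
        X <- cbind(1, x, pmax(x - cand[i], 0), pmax(x - cand[j], 0))
        f <- lm.fit(X, y)
        rss <- sum(f$residuals^2)
        if (is.null(best) || rss < best$rss)
          best <- list(k = 3, bp = c(cand[i], cand[j]), rss = rss,
                       coefs = f$coefficients)
      }
    }
    if (!is.null(best)) {
      best$bic <- bic_of(best$rss, 6)
      fits[[3]] <- best
    }
  }
  fits <- Filter(Negate(is.null), fits)
  pick <- fits[[which.min(vapply(fits, `[[`, 0, "bic"))]]
  slopes <- cumsum(pick$coefs[-1])
  out <- list(breakpoints = 10^pick$bp, slopes = unname(slopes),
              n_segments = pick$k,
              bic = vapply(fits, `[[`, 0, "bic"))
  class(out) <- "msd_segments"
  out
}

#' @export
print.msd_segments <- function(x, ...) {
  cat(sprintf("MSD segmentation: %d segment(s)\n", x$n_segments))
  cat("  slopes     :", paste(sprintf("%.3f", x$slopes), collapse = ", "), "\n")
  if (length(x$breakpoints))
    cat("  breakpoints:", paste(sprintf("%.3g fs", x$breakpoints), collapse = ", "), "\n")
  invisible(x)
}
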