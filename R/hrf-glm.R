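#' 4-D BOLD container
#'
#' @param data 4-D array (x, y, z, time) in arbitrary BOLD units.
#' @param tr repetition time, seconds (must be positive).
#' @param affine 4x4 voxel-to-mm map (default 3 mm isotropic identity
#'   scaling).
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, tr, affine = diag(c(3, 3, 3, 1))) {
  if (length(dim(data)) != 4L) stop("BOLD data must be a 4-D array")
  if (is.null(tr) || !is.finite(tr) || tr <= 0) {
    stop("TR must be a positive number")
  }
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  structure(list(data = data, tr = tr, affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("BOLD series: %dx%dx%d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

# volumes x voxels matrix view
as_voxel_matrix <- function(bold) {
  d <- dim(bold$data)
  t(matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4]))
}

#' Canonical double-gamma haemodynamic response function
#'
#' `h(t) = g(t; peak) - g(t; undershoot) / ratio` where `g` is a gamma
#' density with shape `delay/dispersion` and scale `dispersion`, sampled
#' at `dt` over `kernel_length` seconds and normalised to peak amplitude
#' 1. Defaults are the widely used canonical values: 6 s peak, 16 s
#' undershoot, unit dispersions, undershoot ratio 6, 32 s support (the
#' kernel peaks near 5 s with a single late negative lobe).
#'
#' @param dt sampling interval, seconds.
#' @param peak_delay,undershoot_delay gamma delays, seconds.
#' @param peak_dispersion,undershoot_dispersion gamma dispersions, seconds.
#' @param undershoot_ratio positive scalar dividing the undershoot lobe.
#' @param kernel_length kernel support, seconds.
#' @return numeric kernel sampled at `0, dt, 2 dt, ...`.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                          peak_dispersion = 1, undershoot_dispersion = 1,
                          undershoot_ratio = 6, kernel_length = 32) {
  if (dt <= 0) stop("dt must be positive")
  if (peak_delay <= 0 || undershoot_delay <= 0 ||
      peak_dispersion <= 0 || undershoot_dispersion <= 0 ||
      undershoot_ratio <= 0) {
    stop("HRF shape parameters must be positive")
  }
  t <- seq(0, kernel_length, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     scale = peak_dispersion) -
    stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                  scale = undershoot_dispersion) / undershoot_ratio
  if (max(h) <= 0) stop("degenerate HRF: kernel has no positive lobe")
  h / max(h)
}

#' Causal convolution with a kernel, truncated to the input length
#'
#' @param x input series (finite).
#' @param kernel HRF (or other) kernel samples.
#' @return the convolved series, same length as `x`.
#' @export
convolve_regressor <- function(x, kernel) {
  if (length(x) == 0L) stop("empty input series")
  if (!all(is.finite(x))) stop("input series must be finite")
  full <- stats::convolve(c(x, numeric(length(kernel))),
                          rev(c(kernel, numeric(length(x)))),
                          type = "open")
  full[seq_along(x)]
}

#' Build a GLM design matrix
#'
#' Columns are HRF-convolved, standardised effects of interest, followed
#' by unconvolved confounds (e.g. the movement boxcar), a Legendre
#' polynomial drift basis, and the intercept.
#'
#' @param regressors named list of effect-of-interest series at the TR
#'   grid (convolved with `hrf` then standardised to zero mean, unit SD).
#' @param confounds named list of confound series (entered as supplied).
#' @param drift_order Legendre drift order (0 adds nothing beyond the
#'   intercept).
#' @param n_volumes number of volumes; every series must match.
#' @param tr repetition time, seconds (sets the HRF sampling grid).
#' @param hrf optional kernel; default [canonical_hrf()] at `dt = tr`.
#' @return object of class `bold_design`: `matrix`, `effect_cols`,
#'   `confound_cols`, `n_volumes`, `tr`.
#' @export
build_design <- function(regressors = list(), confounds = list(),
                         drift_order = 3L, n_volumes, tr,
                         hrf = NULL) {
  hrf <- hrf %||% canonical_hrf(dt = tr)
  cols <- list()
  for (nm in names(regressors)) {
    x <- regressors[[nm]]
    if (length(x) != n_volumes) {
      stop("regressor '", nm, "' length != n_volumes")
    }
    cols[[nm]] <- standardize(convolve_regressor(x, hrf), label = nm)
  }
  for (nm in names(confounds)) {
    x <- confounds[[nm]]
    if (length(x) != n_volumes) stop("confound '", nm, "' length != n_volumes")
    cols[[nm]] <- x
  }
  L <- legendre_basis(n_volumes, max(drift_order, 0L))
  drift_cols <- colnames(L)[-1]
  for (j in seq_along(drift_cols)) cols[[drift_cols[j]]] <- L[, j + 1L]
  cols[["intercept"]] <- rep(1, n_volumes)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (any(colSums(abs(X)) == 0)) {
    stop("all-zero design column: ",
         paste(colnames(X)[colSums(abs(X)) == 0], collapse = ", "))
  }
  if (ncol(X) >= n_volumes) stop("more design columns than volumes")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  structure(list(matrix = X, effect_cols = names(regressors),
                 confound_cols = names(confounds),
                 n_volumes = n_volumes, tr = tr),
            class = "bold_design")
}

#' @export
print.bold_design <- function(x, ...) {
  cat(sprintf("GLM design: %d volumes x %d columns\n",
              x$n_volumes, ncol(x$matrix)))
  cat("  effects:  ", paste(x$effect_cols, collapse = ", "), "\n")
  cat("  confounds:", paste(x$confound_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the mass-univariate GLM
#'
#' Ordinary least squares per voxel, computed once through the QR
#' decomposition of the shared design.
#'
#' @param bold a [bold_series()] or a volumes x voxels matrix.
#' @param design a [build_design()] object.
#' @return object of class `bold_glm`: `beta` (columns x voxels),
#'   `sigma2` (residual variance), `dof` (n - rank), `design`, `dims`,
#'   `affine`, plus the data matrix for permutation inference.
#' @export
fit_glm <- function(bold, design) {
  if (inherits(bold, "bold_series")) {
    Y <- as_voxel_matrix(bold)
    dims <- dim(bold$data)[1:3]
    affine <- bold$affine
  } else {
    Y <- as.matrix(bold)
    dims <- c(ncol(Y), 1L, 1L)
    affine <- diag(4)
  }
  X <- design$matrix
  if (nrow(Y) != nrow(X)) stop("BOLD volumes != design n_volumes")
  bad <- which(!apply(is.finite(Y), 2L, all))
  if (length(bad)) {
    stop("non-finite voxel series at voxel index ", bad[1])
  }
  qx <- qr(X)
  beta <- qr.coef(qx, Y)
  rownames(beta) <- colnames(X)
  res <- qr.resid(qx, Y)
  dof <- nrow(X) - qx$rank
  sigma2 <- colSums(res^2) / dof
  structure(list(beta = beta, sigma2 = sigma2, dof = dof,
                 design = design, dims = dims, affine = affine,
                 data = Y, qr = qx),
            class = "bold_glm")
}

#' @export
print.bold_glm <- function(x, ...) {
  cat(sprintf("Mass-univariate GLM fit: %d voxels, %d volumes, %d columns, dof = %d\n",
              ncol(x$beta), nrow(x$data), nrow(x$beta), x$dof))
  invisible(x)
}

#' @export
coef.bold_glm <- function(object, ...) object$beta

#' @export
residuals.bold_glm <- function(object, ...) {
  qr.resid(object$qr, object$data)
}

# resolve a contrast argument (column name(s) or numeric matrix) into a
# rows x p matrix aligned with the design columns
resolve_contrast <- function(design, contrast) {
  X <- design$matrix
  if (is.character(contrast)) {
    missing <- setdiff(contrast, colnames(X))
    if (length(missing)) {
      stop("contrast names not in design: ", paste(missing, collapse = ", "))
    }
    C <- matrix(0, nrow = length(contrast), ncol = ncol(X))
    C[cbind(seq_along(contrast), match(contrast, colnames(X)))] <- 1
    return(C)
  }
  C <- rbind(contrast)
  if (ncol(C) != ncol(X)) stop("contrast has wrong number of columns")
  C
}

#' F-contrast over the fitted GLM
#'
#' Standard extra-sum-of-squares F statistic
#' `F = (C b)' [C (X'X)^-1 C']^-1 (C b) / (r s^2)` with
#' `(rank(C), n - rank(X))` degrees of freedom, and its p-value from the
#' F distribution.
#'
#' @param fit a [fit_glm()] object.
#' @param contrast design column name(s) (tests those coefficients
#'   jointly zero) or a numeric contrast matrix with one row per
#'   constraint.
#' @return object of class `stat_map`: `f_values`, `p_values` (arrays on
#'   the voxel grid), `dof`, `dims`, `affine`, `contrast`.
#' @export
f_contrast <- function(fit, contrast) {
  C <- resolve_contrast(fit$design, contrast)
  if (qr(C)$rank < nrow(C)) stop("contrast matrix is rank deficient")
  X <- fit$design$matrix
  XtXi <- chol2inv(qr.R(fit$qr))  # (X'X)^-1 from the stored QR
  M <- C %*% XtXi %*% t(C)
  Cb <- C %*% fit$beta
  r <- nrow(C)
  quad <- colSums(Cb * solve(M, Cb))
  f <- quad / (r * fit$sigma2)
  # perfectly fitted voxels: residual variance at rounding level
  scale <- colMeans(fit$data^2) + .Machine$double.eps
  degenerate <- fit$sigma2 <= scale * 1e-20
  f[degenerate] <- ifelse(quad[degenerate] <= scale[degenerate] * 1e-20,
                          0, Inf)
  p <- stats::pf(f, r, fit$dof, lower.tail = FALSE)
  structure(list(f_values = array(f, dim = fit$dims),
                 p_values = array(p, dim = fit$dims),
                 dof = c(numerator = r, denominator = fit$dof),
                 dims = fit$dims, affine = fit$affine,
                 contrast = C),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("Stat map: F(%d, %d) over %s voxels; max F = %.2f, min p = %.3g\n",
              x$dof[1], x$dof[2], paste(x$dims, collapse = "x"),
              max(x$f_values), min(x$p_values)))
  invisible(x)
}

#' Family-wise error thresholding
#'
#' Bonferroni rejects voxels with `p < alpha / n_voxels`. The
#' permutation alternative builds the max-F null distribution under the
#' Freedman-Lane scheme: the data are reduced-model fitted values plus
#' permuted reduced-model residuals, the full model is refitted, and the
#' maximum F over voxels is recorded per permutation; rejection is at
#' the (1 - alpha) quantile of that null.
#'
#' @param statmap a [f_contrast()] result.
#' @param alpha family-wise level in (0, 1).
#' @param method `"bonferroni"` or `"permutation_maxT"`.
#' @param fit the [fit_glm()] object (required for permutation).
#' @param n_permutations permutation count (>= 100).
#' @param seed RNG seed for the permutations.
#' @return logical significance mask (array on the voxel grid) with
#'   attributes `alpha`, `method`, `threshold`.
#' @export
fwe_threshold <- function(statmap, alpha,
                          method = c("bonferroni", "permutation_maxT"),
                          fit = NULL, n_permutations = 200L, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)")
  }
  n_vox <- prod(statmap$dims)
  if (method == "bonferroni") {
    mask <- statmap$p_values < alpha / n_vox
    thr <- stats::qf(alpha / n_vox, statmap$dof[1], statmap$dof[2],
                     lower.tail = FALSE)
  } else {
    if (is.null(fit)) stop("permutation_maxT requires the fitted GLM")
    if (n_permutations < 100L) stop("use at least 100 permutations")
    if (!is.null(seed)) set.seed(seed)
    C <- statmap$contrast
    X <- fit$design$matrix
    # reduced model: columns not involved in the contrast
    keep <- colSums(abs(C)) == 0
    Z <- X[, keep, drop = FALSE]
    qz <- qr(Z)
    fitted_z <- qr.fitted(qz, fit$data)
    resid_z <- fit$data - fitted_z
    n <- nrow(X)
    maxF <- vapply(seq_len(n_permutations), function(b) {
      perm <- sample.int(n)
      Yb <- fitted_z + resid_z[perm, , drop = FALSE]
      fb <- fit_glm(Yb, fit$design)
      max(f_contrast(fb, C)$f_values)
    }, numeric(1))
    thr <- stats::quantile(maxF, 1 - alpha, names = FALSE, type = 1)
    mask <- statmap$f_values > thr
  }
  structure(mask, alpha = alpha, method = method, threshold = thr)
}

#' Exclusion contrast C = A \ B
#'
#' Voxels significant in mask A but not in mask B (affect-related voxels
#' minus reporting-related voxels), computed exactly as `A & !B`.
#'
#' @param mask_A,mask_B logical arrays on the same voxel grid.
#' @return logical array `C`.
#' @export
exclusion_contrast <- function(mask_A, mask_B) {
  if (!identical(dim(mask_A), dim(mask_B))) {
    stop("masks lie on different voxel grids")
  }
  out <- mask_A & !mask_B
  attributes(out) <- list(dim = dim(mask_A))
  out
}

# neighbour offsets for 6- or 26-connectivity
neighbour_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g
}

#' Local maxima / cluster table of a significance mask
#'
#' Connected components of the mask (26-neighbour by default), each
#' reported with its voxel count, peak-F location in mm (via the
#' affine), peak F and Bonferroni-corrected peak p. An empty mask yields
#' an empty table.
#'
#' @param statmap a [f_contrast()] result.
#' @param mask logical significance mask on the same grid.
#' @param connectivity 26 (default) or 6.
#' @return data.frame: `cluster`, `voxels`, `x_mm`, `y_mm`, `z_mm`,
#'   `peak_f`, `p_fwe`.
#' @export
local_maxima_table <- function(statmap, mask, connectivity = 26L) {
  if (!identical(dim(mask), statmap$dims) &&
      !identical(as.integer(dim(mask)), as.integer(statmap$dims))) {
    stop("mask grid does not match the stat map")
  }
  empty <- data.frame(cluster = integer(), voxels = integer(),
                      x_mm = numeric(), y_mm = numeric(), z_mm = numeric(),
                      peak_f = numeric(), p_fwe = numeric())
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  offs <- neighbour_offsets(connectivity)
  dims <- statmap$dims
  labels <- array(0L, dim = dims)
  cur <- 0L
  for (s in seq_len(nrow(idx))) {
    v <- idx[s, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    cur <- cur + 1L
    queue <- matrix(v, ncol = 3)
    labels[v[1], v[2], v[3]] <- cur
    while (nrow(queue)) {
      head <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      nb <- sweep(offs, 2L, head, `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      for (q in seq_len(nrow(nb))) {
        w <- nb[q, ]
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  n_vox <- prod(dims)
  rows <- lapply(seq_len(cur), function(cl) {
    vox <- which(labels == cl, arr.ind = TRUE)
    fv <- statmap$f_values[cbind(vox)]
    peak <- vox[which.max(fv), ]
    mm <- statmap$affine %*% c(peak - 1L, 1)
    p_peak <- statmap$p_values[peak[1], peak[2], peak[3]]
    data.frame(cluster = cl, voxels = nrow(vox),
               x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
               peak_f = max(fv), p_fwe = min(1, p_peak * n_vox))
  })
  out <- do.call(rbind, rows)
  out[order(-out$peak_f), ]
}

#' Amplitude giving a target theoretical per-voxel power
#'
#' For a single-column F test (equivalently a t test) at a
#' Bonferroni-corrected level, solves for the coupling amplitude such
#' that a voxel carrying `amplitude * truth_column` on top of Gaussian
#' noise is detected with the requested power. The analysis column is
#' residualised against the remaining design columns; the noncentrality
#' delivered by the truth column is projected onto it.
#'
#' @param design a [build_design()] object.
#' @param column name of the analysed effect column.
#' @param truth_column the generator's signal time course at the TR grid
#'   (already convolved; same length as the design).
#' @param noise_sd voxel noise SD.
#' @param power target power (default 0.95).
#' @param alpha FWE level; the per-voxel level is `alpha / n_comparisons`.
#' @param n_comparisons number of voxels compared.
#' @return the required amplitude (BOLD units per unit truth column).
#' @export
amplitude_for_power <- function(design, column, truth_column, noise_sd,
                                power = 0.95, alpha = 0.01,
                                n_comparisons = 1L) {
  X <- design$matrix
  j <- match(column, colnames(X))
  if (is.na(j)) stop("column '", column, "' not in design")
  x <- X[, j]
  Z <- X[, -j, drop = FALSE]
  x_res <- qr.resid(qr(Z), x)
  proj <- sum(x_res * truth_column) / sqrt(sum(x_res^2))
  if (abs(proj) < 1e-12) {
    stop("truth column is orthogonal to the analysed regressor")
  }
  a_crit <- alpha / n_comparisons
  dof <- design$n_volumes - ncol(X)
  fcrit <- stats::qf(a_crit, 1, dof, lower.tail = FALSE)
  pow_at <- function(ncp) {
    stats::pf(fcrit, 1, dof, ncp = ncp^2, lower.tail = FALSE) - power
  }
  ncp <- stats::uniroot(pow_at, c(1e-6, 100))$root
  ncp * noise_sd / abs(proj)
}
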