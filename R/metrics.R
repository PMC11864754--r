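#' Force-compensation slope
#'
#' Regresses a recorded (or model-predicted) lateral force series against
#' the perfect-compensation signal — the lateral force of the unscaled curl
#' field, `gain * speed`, which is positive in every movement direction.  A
#' slope of 1 means full compensation; the sign captures clockwise versus
#' counter-clockwise force production.
#'
#' The series is cropped to the movement window between the first and last
#' samples at which speed exceeds 5% of its maximum.  By default an
#' intercept is included in the regression (robust to baseline offsets such
#' as the tool-use condition exhibits); set `intercept = FALSE` for
#' regression through the origin.
#'
#' @param lateral Recorded signed lateral force series, N.
#' @param velocity n x 2 matrix of hand velocities, m/s.
#' @param gain Curl gain of the reference field, N s/m.
#' @param intercept Include an intercept in the regression.
#' @param crop Crop to the 5%-of-peak-speed window.
#' @return Dimensionless slope.
#' @export
force_compensation <- function(lateral, velocity, gain = 0.16,
                               intercept = TRUE, crop = TRUE) {
  speed <- sqrt(rowSums(velocity^2))
  if (length(lateral) != length(speed)) {
    stop("lateral force and velocity series must have the same length")
  }
  if (crop) {
    keep <- which(speed > 0.05 * max(speed))
    if (!length(keep)) {
      stop("perfect-compensation signal is constant; cannot regress")
    }
    idx <- seq(min(keep), max(keep))
    speed <- speed[idx]; lateral <- lateral[idx]
  }
  perfect <- gain * speed
  if (stats::var(perfect) == 0) {
    stop("perfect-compensation signal is constant; cannot regress")
  }
  if (intercept) {
    stats::cov(perfect, lateral) / stats::var(perfect)
  } else {
    sum(perfect * lateral) / sum(perfect^2)
  }
}

#' Force-compensation profile across movement directions
#'
#' Averages per-trial compensation slopes over repetitions for each of the
#' protocol's movement directions.
#'
#' @param direction Per-trial movement directions, degrees.
#' @param slope Per-trial compensation slopes.
#' @param workspace Workspace label.
#' @param directions The full direction grid every direction must cover.
#' @return A `compensation_profile`: data frame with `direction` and
#'   `compensation`.
#' @export
compensation_profile <- function(direction, slope, workspace = NA_character_,
                                 directions = standard_directions()) {
  missing_d <- setdiff(directions, unique(direction))
  if (length(missing_d)) {
    stop("no trials for direction(s): ", paste(missing_d, collapse = ", "))
  }
  mean_slope <- vapply(directions,
                       function(d) mean(slope[direction == d]), numeric(1))
  as_compensation_profile(mean_slope, directions, workspace)
}

#' Build a compensation profile from per-direction values
#' @param values Compensation values, one per direction.
#' @param directions Direction grid, degrees.
#' @param workspace Workspace label.
#' @return A `compensation_profile` data frame.
#' @export
as_compensation_profile <- function(values, directions = standard_directions(),
                                    workspace = NA_character_) {
  stopifnot(length(values) == length(directions))
  structure(data.frame(direction = directions, compensation = as.numeric(values)),
            class = c("compensation_profile", "data.frame"),
            workspace = workspace)
}

.profile_values <- function(x) {
  if (inherits(x, "compensation_profile")) x$compensation else as.numeric(x)
}

# Periodic (Fourier) upsampling of a circular profile to n_out samples.
.fourier_upsample <- function(x, n_out) {
  N <- length(x)
  if (n_out <= N) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  half <- N %/% 2
  Y[1] <- X[1]
  if (half > 1) {
    ks <- 1:(half - 1)
    Y[1 + ks] <- X[1 + ks]
    Y[n_out + 1 - ks] <- X[N + 1 - ks]
  }
  if (N %% 2 == 0) {                 # split the Nyquist bin symmetrically
    Y[1 + half] <- X[1 + half] / 2
    Y[n_out + 1 - half] <- X[1 + half] / 2
  } else {
    Y[1 + half] <- X[1 + half]
    Y[n_out + 1 - half] <- X[N + 1 - half]
  }
  Re(stats::fft(Y, inverse = TRUE)) / N
}

#' Circular phase shift between two compensation profiles
#'
#' Signed circular lag (degrees of movement direction) that maximizes the
#' circular cross-correlation between a profile and a reference, after
#' periodic Fourier upsampling of both 16-point curves to a fine grid of
#' `resolution` degrees (so sub-bin shifts are resolved).  Positive values
#' mean the profile is
#' shifted rightward (toward larger directions) relative to the reference;
#' leftward shifts are negative.  Range (-180, 180].
#'
#' Compensation curves are close to 180-degree periodic (the field is a
#' `cos(2 alpha)` pattern), so the circular cross-correlation has twin peaks
#' half a turn apart whose heights differ only through noise; when the
#' antipodal peak is within `tie_tol` (fraction of the correlation range) of
#' the maximum, the tie resolves toward the smallest absolute shift.
#'
#' @param profile,reference `compensation_profile`s (or plain numeric
#'   vectors) on the same direction grid.
#' @param resolution Output resolution in degrees (default 0.5, so bin and
#'   sub-bin shifts are resolved exactly).
#' @param tie_tol Relative near-tie tolerance for twin correlation peaks.
#' @return Signed shift, degrees.
#' @export
phase_shift <- function(profile, reference, resolution = 0.5, tie_tol = 0.01) {
  a <- .profile_values(profile); b <- .profile_values(reference)
  if (length(a) != length(b)) stop("profiles must share the direction grid")
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("cannot estimate a phase shift for a flat profile")
  }
  n_out <- round(360 / resolution)
  au <- .fourier_upsample(a - mean(a), n_out)
  bu <- .fourier_upsample(b - mean(b), n_out)
  cc <- Re(stats::fft(stats::fft(au) * Conj(stats::fft(bu)), inverse = TRUE))
  M <- length(cc)
  best <- which.max(cc)
  lag <- wrap180((best - 1) * resolution)
  # antipodal twin peak: best lag within a 10-degree window half a turn away
  win <- round(10 / resolution)
  anti <- ((best - 1 + M / 2 + seq(-win, win)) %% M) + 1
  twin <- anti[which.max(cc[anti])]
  twin_lag <- wrap180((twin - 1) * resolution)
  if (cc[best] - cc[twin] <= tie_tol * diff(range(cc)) &&
      abs(twin_lag) < abs(lag)) {
    lag <- twin_lag
  }
  lag
}

#' Amplitude decay factor between experimental and model profiles
#'
#' Peak-to-peak ratio `(max - min experimental) / (max - min model)`: the
#' amplitude scaling that matches a model compensation curve to the (decayed)
#' experimental one while preserving the relative frame contributions.
#'
#' @param experimental,model `compensation_profile`s or numeric vectors.
#' @return The decay factor, dimensionless.
#' @export
decay_factor <- function(experimental, model) {
  e <- .profile_values(experimental); m <- .profile_values(model)
  pp <- diff(range(m))
  if (pp == 0) stop("model profile is flat; decay factor undefined")
  diff(range(e)) / pp
}

#' Maximum perpendicular error of a trajectory
#'
#' Largest unsigned distance between trajectory samples and the straight
#' line joining start and target; the standard kinematic-error measure for
#' force-field adaptation.
#'
#' @param trajectory n x 2 matrix of positions, metres.
#' @param start,target Endpoints of the intended straight path, metres.
#' @return Length in metres.
#' @export
max_perpendicular_error <- function(trajectory, start, target) {
  d <- target - start
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("start and target coincide")
  max(abs((trajectory[, 1] - start[1]) * d[2] -
            (trajectory[, 2] - start[2]) * d[1]) / len)
}

#' Root-mean-square error between two profiles
#' @param a,b `compensation_profile`s or numeric vectors on the same grid.
#' @return RMSE, dimensionless.
#' @export
profile_rmse <- function(a, b) {
  av <- .profile_values(a); bv <- .profile_values(b)
  if (length(av) != length(bv)) stop("profiles must share the direction grid")
  sqrt(mean((av - bv)^2))
}

#' Bayesian information criterion for a residual vector
#'
#' `BIC = -2 log(L) + k log(n)` under i.i.d. Gaussian residuals with
#' maximum-likelihood variance (floored at 1e-12 to keep the criterion
#' finite for perfect fits).
#'
#' @param residuals Model residuals.
#' @param k Number of model degrees of freedom.
#' @param n Number of data points (defaults to `length(residuals)`).
#' @return BIC value.
#' @export
model_bic <- function(residuals, k, n = length(residuals)) {
  if (n <= 0) stop("n must be positive")
  if (k < 0) stop("k must be >= 0")
  sigma2 <- max(mean(residuals^2), 1e-12)
  logL <- -n / 2 * (log(2 * pi * sigma2) + 1)
  -2 * logL + k * log(n)
}

#' BIC improvement over the no-generalization null model
#'
#' `BIC(null) - BIC(model)` where the null predicts zero force in every
#' direction (its residuals are the observations themselves, `k = 0`).
#' Positive values favour the candidate model.
#'
#' @param residuals Candidate-model residuals.
#' @param k Candidate-model degrees of freedom.
#' @param observed Observed values (the null model's residuals).
#' @param n Number of data points.
#' @return BIC improvement.
#' @export
bic_improvement <- function(residuals, k, observed, n = length(residuals)) {
  model_bic(observed, 0L, n) - model_bic(residuals, k, n)
}
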