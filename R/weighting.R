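#' Planning-noise specification for the Monte-Carlo weight simulation
#'
#' Angular noise of SD `angular_sd` degrees is added inside the trigonometric
#' terms of the start/target coordinates for the joint and object frames; for
#' the Cartesian frame the equivalent linear noise is added to the
#' coordinates themselves, with SD given by the arc-length rule
#' `Arc = R * theta` ([arc_length_sd()]) at `arc_radius` (default 0.1 m,
#' the printed 10 cm calibration, so 1 degree is about 1.7 mm per
#' coordinate).  Passing `arc_radius = NULL` evaluates the rule at the
#' movement circle radius instead, which puts linear and angular noise on
#' an exactly equal footing; under the default calibration the Cartesian
#' frame carries a somewhat larger endpoint displacement.
#'
#' @param angular_sd Angular noise SD, degrees (> 0).
#' @param replicates Number of Monte-Carlo replicates (>= 1; 1000 matches the
#'   reference simulation scale).
#' @param seed Integer seed; every weight simulation under the same seed is
#'   exactly reproducible.
#' @param arc_radius Radius used in the arc-length equivalence, metres, or
#'   `NULL` to use the movement radius.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(angular_sd = 1, replicates = 1000, seed = 1L,
                       arc_radius = 0.1) {
  if (angular_sd <= 0) stop("angular_sd must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(angular_sd = as.numeric(angular_sd),
                 replicates = as.integer(replicates),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 arc_radius = if (is.null(arc_radius)) NULL else as.numeric(arc_radius)),
            class = "noise_spec")
}

#' Arc-length equivalent linear noise SD
#'
#' `Arc = R * theta`: the chord/arc displacement corresponding to an angular
#' SD at a given radius.
#'
#' @param radius Radius, metres.
#' @param angular_sd Angular SD, degrees.
#' @return Linear SD in metres.
#' @export
arc_length_sd <- function(radius, angular_sd = 1) radius * deg2rad(angular_sd)

#' Noise-perturbed movement endpoints
#'
#' Applies one draw of planning noise to the start and target of a movement
#' on the workspace circle.  For the Cartesian frame the four draws (in
#' degrees) are converted to their arc-length-equivalent linear offsets and
#' added to the coordinates; for the joint/object frames the draws are added
#' inside the cosine/sine arguments (i.e. they rotate each endpoint along
#' the circle).
#'
#' @param frame `"cartesian"`, `"joint"` or `"object"`.
#' @param center Workspace centre, metres.
#' @param radius Movement circle radius, metres.
#' @param direction Movement direction `alpha`, degrees.
#' @param eps Length-4 noise draws `(eps_xs, eps_ys, eps_xf, eps_yf)`,
#'   degrees.
#' @param arc_radius Arc-length equivalence radius, metres (default the
#'   printed 10 cm calibration).
#' @return List with `start` and `target` (metres).
#' @export
perturbed_endpoints <- function(frame = c("cartesian", "joint", "object"),
                                center, radius, direction, eps,
                                arc_radius = 0.1) {
  frame <- match.arg(frame)
  if (length(eps) != 4L) stop("eps must hold four draws")
  a <- deg2rad(direction)
  if (frame == "cartesian") {
    lin <- arc_length_sd(arc_radius, eps)
    list(start = center + radius * c(cos(a + pi), sin(a + pi)) + lin[1:2],
         target = center + radius * c(cos(a), sin(a)) + lin[3:4])
  } else {
    e <- deg2rad(eps)
    list(start = center + radius * c(cos(a + pi + e[1]), sin(a + pi + e[2])),
         target = center + radius * c(cos(a + e[3]), sin(a + e[4])))
  }
}

# Mean signed lateral force (projected on the nominal direction a0, radians)
# for a batch of movements given by endpoint arrays; vectorized over
# replicates.  `ctx` carries the shared movement/time/arm context.
.mc_mean_lateral <- function(frame, sx, sy, tx, ty, a0, ctx) {
  R <- length(sx); n <- length(ctx$spd)
  dx <- tx - sx; dy <- ty - sy
  d <- sqrt(dx^2 + dy^2)
  ux <- dx / d; uy <- dy / d
  velx <- outer(ctx$spd, ux); vely <- outer(ctx$spd, uy)
  if (frame == "cartesian" || (frame == "joint" && ctx$hand_in_train)) {
    f <- .cartesian_force_xy(ctx$field, velx, vely)
  } else if (frame == "joint") {
    posx <- outer(ctx$mjp, d * ux) + matrix(sx, n, R, byrow = TRUE)
    posy <- outer(ctx$mjp, d * uy) + matrix(sy, n, R, byrow = TRUE)
    # matched training path: the planned (possibly perturbed) path carried
    # over by the nominal workspace translation, so test==train collapses
    # the transformation exactly
    trx <- posx - ctx$center_diff[1]
    trry <- posy - ctx$center_diff[2]
    f <- .joint_force_xy(ctx$field, ctx$geom, ctx$test_geom,
                         trx, trry, posx, posy, velx, vely)
  } else {
    midx <- (sx + tx) / 2 - ctx$pole_offset[1]
    midy <- (sy + ty) / 2 - ctx$pole_offset[2]
    qh <- .ik_rad(ctx$hand_geom, midx, midy)
    seg <- .segment_orientation_rad(ctx$hand_geom, qh$ts, qh$te)
    theta <- ctx$rotation_rad + (seg - ctx$seg0)
    f <- .object_force_xy(ctx$field, matrix(theta, n, R, byrow = TRUE),
                          velx, vely)
  }
  colMeans(f$x * sin(a0) - f$y * cos(a0))
}

#' Re-Dyn inverse-variance frame weights
#'
#' The reliability-based weighting model.  For every movement direction and
#' each coordinate frame, planning noise is injected into the movement
#' endpoints ([perturbed_endpoints()]), the frame's generalized force
#' profile is recomputed, and the error in mean signed lateral force
#' relative to the noiseless prediction is collected over
#' `noise$replicates` draws.  The per-frame error variances are converted
#' to normalized inverse-variance weights.  Noise draws are shared across
#' frames (common random numbers), so frames with identical predictions get
#' exactly equal weights.
#'
#' Noise propagates into each frame the way its state variables enter the
#' prediction: for the joint frame the instantaneous Jacobians follow the
#' perturbed path; for the object frame the rotation angle is re-derived
#' from the hand posture at the perturbed movement midpoint.
#'
#' @inheritParams joint_prediction
#' @param noise A [noise_spec()].
#' @param directions Movement directions, degrees.
#' @param radius,peak_speed,dt Movement parameters (m, m/s, s).
#' @param hand_in_train Virtual-pole mode (experiment 3): the hand executes
#'   every movement in the training workspace.
#' @param rotation Object rotation override, degrees; derived from the
#'   workspace pair when `NULL`.
#' @return A `frame_weights` data frame: `direction`, `cartesian`, `joint`,
#'   `object` (rows sum to 1), with the per-frame error variances in
#'   `attr(, "sigma2")`.
#' @export
redyn_weights <- function(geom, train_ws, test_ws, field,
                          noise = noise_spec(),
                          directions = standard_directions(),
                          radius = 0.05, peak_speed = 0.5, dt = 0.002,
                          test_geom = geom, hand_in_train = FALSE,
                          rotation = NULL) {
  stopifnot(inherits(noise, "noise_spec"))
  if (is.null(rotation)) {
    rotation <- if (hand_in_train) pole_rotation(geom, train_ws, test_ws)
                else object_rotation(geom, train_ws, test_ws, test_geom)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  arc_radius <- noise$arc_radius %||% radius
  m0 <- min_jerk_movement(test_ws$center, 0, radius, peak_speed, dt)
  tau <- m0$t / max(m0$t)
  pole_offset <- if (hand_in_train) test_ws$center - train_ws$center else c(0, 0)
  hand_geom <- if (hand_in_train) geom else test_geom
  hand_mid0 <- test_ws$center - pole_offset
  q0 <- .ik_rad(hand_geom, hand_mid0[1], hand_mid0[2])
  ctx <- list(field = field, geom = geom, test_geom = test_geom,
              hand_geom = hand_geom, hand_in_train = hand_in_train,
              train_center = train_ws$center,
              center_diff = test_ws$center - train_ws$center,
              pole_offset = pole_offset,
              rotation_rad = deg2rad(rotation),
              seg0 = .segment_orientation_rad(hand_geom, q0$ts, q0$te),
              mjp = .mj_pos(tau), spd = (peak_speed / 1.875) * .mj_vel(tau))
  frames <- c("cartesian", "joint", "object")
  D <- length(directions)
  sigma2 <- matrix(NA_real_, D, 3L, dimnames = list(NULL, frames))
  cx <- test_ws$center[1]; cy <- test_ws$center[2]
  for (i in seq_len(D)) {
    a0 <- deg2rad(directions[i])
    E <- matrix(stats::rnorm(4L * noise$replicates, 0, noise$angular_sd),
                noise$replicates, 4L)
    for (k in seq_along(frames)) {
      if (frames[k] == "cartesian") {
        lin <- arc_length_sd(arc_radius, E)
        sx <- cx + radius * cos(a0 + pi) + lin[, 1]
        sy <- cy + radius * sin(a0 + pi) + lin[, 2]
        tx <- cx + radius * cos(a0) + lin[, 3]
        ty <- cy + radius * sin(a0) + lin[, 4]
      } else {
        e <- deg2rad(E)
        sx <- cx + radius * cos(a0 + pi + e[, 1])
        sy <- cy + radius * sin(a0 + pi + e[, 2])
        tx <- cx + radius * cos(a0 + e[, 3])
        ty <- cy + radius * sin(a0 + e[, 4])
      }
      nominal <- .mc_mean_lateral(frames[k],
                                  cx + radius * cos(a0 + pi),
                                  cy + radius * sin(a0 + pi),
                                  cx + radius * cos(a0),
                                  cy + radius * sin(a0), a0, ctx)
      noisy <- .mc_mean_lateral(frames[k], sx, sy, tx, ty, a0, ctx)
      sigma2[i, k] <- stats::var(noisy - nominal)
    }
  }
  w <- t(apply(sigma2, 1L, .inverse_normalize))
  out <- data.frame(direction = directions, cartesian = w[, 1],
                    joint = w[, 2], object = w[, 3])
  structure(out, class = c("frame_weights", "data.frame"),
            model = "redyn", sigma2 = sigma2,
            seed = noise$seed, replicates = noise$replicates)
}

# normalized inverse magnitudes with the degenerate limiting rule: any
# zero-magnitude entries take the full weight, split equally.
.inverse_normalize <- function(v, tol = 1e-24) {
  z <- abs(v) < tol
  if (any(z)) return(as.numeric(z) / sum(z))
  inv <- 1 / abs(v)
  inv / sum(inv)
}

#' Inverse-variance weights from given variances
#'
#' Direct arithmetic form of the inverse-variance rule; exposed so injected
#' variance triples can be converted without a simulation.
#'
#' @param sigma2 Numeric length-3 (or D x 3 matrix) of error variances.
#' @return Normalized weights, same shape.
#' @export
inverse_variance_weights <- function(sigma2) {
  if (is.matrix(sigma2)) t(apply(sigma2, 1L, .inverse_normalize))
  else .inverse_normalize(sigma2)
}

#' Minimum-energy frame weights
#'
#' Per direction, the energy demanded by a frame is proportional to the
#' magnitude of its time-mean lateral force; weights are the normalized
#' inverse magnitudes.  Frames with exactly zero mean force take the full
#' weight (split equally) in that direction.
#'
#' @param lateral Named list `cartesian`, `joint`, `object` of n x D
#'   signed-lateral force matrices (one column per direction), e.g. the
#'   `lateral` element of [frame_compensation()].
#' @param directions Movement directions, degrees.
#' @return A `frame_weights` data frame.
#' @export
energy_weights <- function(lateral, directions = standard_directions()) {
  stats_ <- vapply(lateral[c("cartesian", "joint", "object")],
                   function(m) colMeans(m), numeric(length(directions)))
  stats_ <- matrix(stats_, ncol = 3L)
  w <- t(apply(stats_, 1L, .inverse_normalize))
  structure(data.frame(direction = directions, cartesian = w[, 1],
                       joint = w[, 2], object = w[, 3]),
            class = c("frame_weights", "data.frame"),
            model = "energy", statistic = stats_)
}

#' Maximum-smoothness frame weights
#'
#' Per direction, smoothness is measured by the mean absolute third finite
#' difference of the lateral force profile (at least 4 samples); weights are
#' the normalized inverse magnitudes, so smoother profiles weigh more.
#'
#' @inheritParams energy_weights
#' @return A `frame_weights` data frame.
#' @export
smoothness_weights <- function(lateral, directions = standard_directions()) {
  third <- function(m) {
    if (nrow(m) < 4L) stop("smoothness needs at least 4 samples per profile")
    colMeans(abs(diff(m, differences = 3L)))
  }
  stats_ <- vapply(lateral[c("cartesian", "joint", "object")],
                   third, numeric(length(directions)))
  stats_ <- matrix(stats_, ncol = 3L)
  w <- t(apply(stats_, 1L, .inverse_normalize))
  structure(data.frame(direction = directions, cartesian = w[, 1],
                       joint = w[, 2], object = w[, 3]),
            class = c("frame_weights", "data.frame"),
            model = "smoothness", statistic = stats_)
}

#' Direction-independent optimal frame weights fitted to data
#'
#' Finds the single triple `(w_c, w_j, w_o)` minimizing the summed squared
#' error between the weighted frame compensation profiles and an observed
#' profile, subject to `w >= 0` and `sum(w) <= 1` (the inequality absorbs
#' the generalization decay).  The quadratic program is solved exactly by
#' enumerating the active sets of the four constraints; ties are broken
#' toward the minimum-norm solution, and rank-deficient (collinear) frame
#' profiles are reported through the `nonunique` flag.
#'
#' @param observed Numeric vector of observed compensation values (>= 3
#'   directions; concatenate workspaces for a global fit).
#' @param frames Matrix with columns `cartesian`, `joint`, `object` of model
#'   compensation values, same rows as `observed`.
#' @return List with `weights` (named length-3), `rss`, and `nonunique`.
#' @export
fit_optimal_weights <- function(observed, frames) {
  P <- as.matrix(frames); y <- as.numeric(observed)
  if (nrow(P) != length(y) || ncol(P) != 3L) {
    stop("'frames' must be a length(observed) x 3 matrix")
  }
  if (length(y) < 3L) stop("need at least 3 directions of data")
  G <- crossprod(P); b <- drop(crossprod(P, y))
  nonunique <- qr(P)$rank < 3L
  slack <- 1e-9
  best <- NULL
  for (mask in 0:7) {                      # which of w1..w3 are pinned to 0
    zero <- which(bitwAnd(mask, c(1L, 2L, 4L)) > 0)
    free <- setdiff(1:3, zero)
    for (sum_active in c(FALSE, TRUE)) {
      if (length(free) == 0L) {
        if (sum_active) next               # sum(w)=1 incompatible with w=0
        w <- numeric(3L)
      } else {
        Gf <- G[free, free, drop = FALSE]; bf <- b[free]
        if (!sum_active) {
          wf <- tryCatch(solve(Gf, bf),
                         error = function(e) drop(MASS::ginv(Gf) %*% bf))
        } else {
          K <- rbind(cbind(Gf, 1), c(rep(1, length(free)), 0))
          sol <- tryCatch(solve(K, c(bf, 1)),
                          error = function(e) drop(MASS::ginv(K) %*% c(bf, 1)))
          wf <- sol[seq_along(free)]
        }
        w <- numeric(3L); w[free] <- wf
      }
      if (any(w < -slack) || sum(w) > 1 + slack) next
      rss <- sum((P %*% w - y)^2)
      nrm <- sum(w^2)
      if (is.null(best) || rss < best$rss - 1e-12 ||
          (rss < best$rss + 1e-12 && nrm < best$nrm)) {
        best <- list(w = w, rss = rss, nrm = nrm)
      }
    }
  }
  w <- pmax(best$w, 0)
  names(w) <- c("cartesian", "joint", "object")
  list(weights = w, rss = best$rss, nonunique = nonunique)
}

#' @export
print.frame_weights <- function(x, ...) {
  cat(sprintf("Frame weights (%s model), %d directions\n",
              attr(x, "model"), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}
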