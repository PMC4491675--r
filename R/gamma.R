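# Gamma-index dose-distribution comparison: 2D, depth-searched "2.5D", 3D,
# plus the point-dose difference and the clinical QA decision cascade.

#' Gamma-index criteria
#'
#' @param dose_pct dose-difference criterion, % of the global normalization
#'   (the reference-plane maximum unless \code{normalization} is given).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param threshold_pct low-dose cutoff, % of the global normalization:
#'   reference points below it are excluded from the pass rate entirely.
#' @param normalization explicit global normalization dose; \code{NULL} means
#'   use the reference maximum.
#' @return object of class \code{gamma_criteria}.
#' @export
gamma_criteria <- function(dose_pct = 3, dta_mm = 3, threshold_pct = 10,
                           normalization = NULL) {
  if (dose_pct <= 0 || dta_mm <= 0 || threshold_pct <= 0)
    stop("gamma_criteria: criteria must be > 0")
  if (threshold_pct >= 100) stop("gamma_criteria: threshold_pct must be < 100")
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 threshold_pct = threshold_pct, normalization = normalization),
            class = "gamma_criteria")
}

# bilinear interpolation of a dose plane at arbitrary points; NA outside
.interp_plane <- function(plane, qx, qy) {
  v <- plane$values; sp <- plane$spacing
  fx <- (qx - plane$origin_x) / sp
  fy <- (qy - plane$origin_y) / sp
  nx <- ncol(v); ny <- nrow(v)
  out <- rep(NA_real_, length(qx))
  ok <- fx >= 0 & fx <= nx - 1 & fy >= 0 & fy <= ny - 1
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]
  i0 <- pmin(floor(fx), nx - 2); j0 <- pmin(floor(fy), ny - 2)
  tx <- fx - i0; ty <- fy - j0
  # rows index y, columns index x
  v00 <- v[cbind(j0 + 1, i0 + 1)]; v01 <- v[cbind(j0 + 1, i0 + 2)]
  v10 <- v[cbind(j0 + 2, i0 + 1)]; v11 <- v[cbind(j0 + 2, i0 + 2)]
  out[ok] <- (1 - ty) * ((1 - tx) * v00 + tx * v01) +
    ty * ((1 - tx) * v10 + tx * v11)
  out
}

.gamma_result <- function(gamma_map, pass_rate, n_evaluated, criteria,
                          meta = list()) {
  structure(list(gamma_map = gamma_map, pass_rate = pass_rate,
                 n_evaluated = n_evaluated, criteria = criteria, meta = meta),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("Gamma %g%%/%g mm (threshold %g%%): pass rate %.1f%% (%d points)\n",
              x$criteria$dose_pct, x$criteria$dta_mm, x$criteria$threshold_pct,
              x$pass_rate, x$n_evaluated))
  invisible(x)
}

# shared pass convention: gamma <= 1 passes; tiny slack absorbs the
# floating-point residue of exact-boundary cases (e.g. a uniform +3.0%
# offset at the 3% criterion)
.GAMMA_PASS_TOL <- 1e-9

.gamma_norm <- function(reference, criteria) {
  norm <- criteria$normalization
  if (is.null(norm)) norm <- max(reference$values)
  if (!is.finite(norm) || norm <= 0)
    stop("gamma: global normalization must be positive (empty reference?)")
  norm
}

.check_overlap <- function(reference, evaluated) {
  rx <- range(plane_x(reference)); ry <- range(plane_y(reference))
  ex <- range(plane_x(evaluated)); ey <- range(plane_y(evaluated))
  if (rx[1] > ex[2] || rx[2] < ex[1] || ry[1] > ey[2] || ry[2] < ey[1])
    stop("gamma: reference and evaluated grids do not overlap")
}

#' 2D gamma-index comparison
#'
#' For every reference grid point at or above the low-dose threshold,
#' \deqn{\gamma = \min_{\Delta r} \sqrt{ (\|\Delta r\|/DTA)^2 +
#'   ((D_{ref} - D_{eval}(r+\Delta r)) / (\delta D))^2 }}
#' where \eqn{\delta D} is \code{dose_pct}% of the global normalization.
#' The evaluated plane is interpolated bilinearly and the minimization runs
#' over a search lattice of pitch \code{dta_mm/10} within a radius of
#' \code{3 * dta_mm}.  A point passes when \eqn{\gamma \le 1}.
#'
#' @param reference,evaluated \code{\link{dose_plane}} objects on overlapping
#'   grids (the reference grid defines the comparison points).
#' @param criteria a \code{\link{gamma_criteria}}.
#' @return a \code{gamma_result}: \code{gamma_map} (matrix, NA where below
#'   threshold), \code{pass_rate} (%), \code{n_evaluated}, \code{criteria},
#'   \code{meta}.  If every point is below threshold, \code{n_evaluated} is 0,
#'   \code{pass_rate} is NA and \code{meta$all_below_threshold} is TRUE.
#' @export
gamma_2d <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"))
  .check_overlap(reference, evaluated)
  norm <- .gamma_norm(reference, criteria)
  dd <- criteria$dose_pct / 100 * norm
  dta <- criteria$dta_mm
  thr <- criteria$threshold_pct / 100 * norm

  xs <- plane_x(reference); ys <- plane_y(reference)
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  eval_mask <- reference$values >= thr
  # points whose own location falls outside the evaluated grid cannot be
  # compared; they are excluded like sub-threshold points
  inside <- !is.na(.interp_plane(evaluated, as.numeric(X), as.numeric(Y)))
  eval_mask <- eval_mask & matrix(inside, nrow = nrow(eval_mask))
  n_eval <- sum(eval_mask)
  gm <- matrix(NA_real_, nrow = nrow(reference$values), ncol = ncol(reference$values))
  if (n_eval == 0L) {
    warning("gamma_2d: no reference points at or above the dose threshold")
    return(.gamma_result(gm, NA_real_, 0L, criteria,
                         meta = list(all_below_threshold = TRUE)))
  }
  qx <- X[eval_mask]; qy <- Y[eval_mask]; dref <- reference$values[eval_mask]
  g <- sqrt(.gamma_min2(evaluated, qx, qy, dref, dta, dd, 3 * dta, dta / 10))
  gm[eval_mask] <- g
  pass <- 100 * mean(g <= 1 + .GAMMA_PASS_TOL)
  .gamma_result(gm, pass, n_eval, criteria,
                meta = list(reference_depth = reference$depth,
                            evaluated_depth = evaluated$depth,
                            normalization = norm))
}

# vectorized gamma^2 minimization for a set of reference points against one
# evaluated plane.  Three stages: (1) coarse lattice sweep keeping every
# candidate, (2) per point, select the best nodes of up to three basins more
# than 1.5 lattice pitches apart, (3) dense local scan (2 pitches around
# each center) plus a halving-step pattern search.  The dense scan exists
# because bilinear interpolation makes kinked micro-valleys at grid-cell
# boundaries that are narrower than the coarse pitch; any continuum minimum
# lies within half a pitch of some lattice node, and a node not covered by
# one center's dense disk is eligible to seed the next basin, so the three
# separated centers cover the minima that matter.
.gamma_min2 <- function(evaluated, qx, qy, dref, dta, dd, radius, step,
                        n_basins = 3L) {
  off <- .search_offsets(radius, step)
  n <- length(qx); m <- nrow(off)
  # chunk points to bound the n x m candidate matrix at ~4e7 doubles
  if (n * m > 4e7) {
    half <- seq_len(ceiling(n / 2))
    return(c(.gamma_min2(evaluated, qx[half], qy[half], dref[half],
                         dta, dd, radius, step, n_basins),
             .gamma_min2(evaluated, qx[-half], qy[-half], dref[-half],
                         dta, dd, radius, step, n_basins)))
  }
  C <- matrix(Inf, n, m)
  for (k in seq_len(m)) {
    de <- .interp_plane(evaluated, qx + off[k, 1], qy + off[k, 2])
    cand <- off[k, 3] / dta^2 + ((dref - de) / dd)^2
    cand[is.na(cand)] <- Inf
    C[, k] <- cand
  }
  sep2 <- (1.5 * step)^2
  cen_x <- matrix(NA_real_, n, n_basins)
  cen_y <- matrix(NA_real_, n, n_basins)
  cen_v <- matrix(Inf, n, n_basins)
  for (i in seq_len(n)) {
    ci <- C[i, ]
    for (b in seq_len(n_basins)) {
      k <- which.min(ci)
      if (!is.finite(ci[k])) break
      cen_x[i, b] <- off[k, 1]; cen_y[i, b] <- off[k, 2]; cen_v[i, b] <- ci[k]
      ci[(off[, 1] - off[k, 1])^2 + (off[, 2] - off[k, 2])^2 <= sep2] <- Inf
    }
  }
  dense <- .search_offsets(2 * step, step / 15)
  best <- rep(Inf, n)
  for (b in seq_len(n_basins)) {
    sel <- which(is.finite(cen_v[, b]))
    if (length(sel) == 0L) next
    b2 <- cen_v[sel, b]; cx0 <- cen_x[sel, b]; cy0 <- cen_y[sel, b]
    cx <- cx0; cy <- cy0
    for (k in seq_len(nrow(dense))) {
      tx <- cx0 + dense[k, 1]; ty <- cy0 + dense[k, 2]
      r2 <- tx^2 + ty^2
      de <- .interp_plane(evaluated, qx[sel] + tx, qy[sel] + ty)
      cand <- r2 / dta^2 + ((dref[sel] - de) / dd)^2
      cand[is.na(cand) | r2 > radius^2] <- Inf
      upd <- cand < b2
      b2[upd] <- cand[upd]; cx[upd] <- tx[upd]; cy[upd] <- ty[upd]
    }
    rb <- .gamma_refine(evaluated, qx[sel], qy[sel], dref[sel],
                        cx, cy, b2, dta, dd, step / 15, n_levels = 5L)
    best[sel] <- pmin(best[sel], rb)
  }
  best
}

# vectorized pattern search: halve the step repeatedly, each time sweeping
# the 8-neighborhood of every point's current best offset; offsets stay
# within the 3*dta disk
.gamma_refine <- function(evaluated, qx, qy, dref, bx, by, best2, dta, dd,
                          step0, n_levels = 7L, sweeps = 12L) {
  nb <- cbind(dx = c(-1, 0, 1, -1, 1, -1, 0, 1),
              dy = c(-1, -1, -1, 0, 0, 1, 1, 1))
  h <- step0
  rmax2 <- (3 * dta)^2
  for (lev in seq_len(n_levels)) {
    for (sw in seq_len(sweeps)) {
      improved <- FALSE
      for (k in seq_len(nrow(nb))) {
        tx <- bx + nb[k, 1] * h; ty <- by + nb[k, 2] * h
        r2 <- tx^2 + ty^2
        de <- .interp_plane(evaluated, qx + tx, qy + ty)
        cand <- r2 / dta^2 + ((dref - de) / dd)^2
        cand[is.na(cand) | r2 > rmax2] <- Inf
        upd <- cand < best2
        if (any(upd)) {
          improved <- TRUE
          best2[upd] <- cand[upd]; bx[upd] <- tx[upd]; by[upd] <- ty[upd]
        }
      }
      if (!improved) break
    }
    h <- h / 2
  }
  best2
}

# lattice of (dx, dy, dx^2+dy^2) within a disk
.search_offsets <- function(radius, step) {
  s <- seq(-radius, radius, by = step)
  off <- expand.grid(dx = s, dy = s)
  off$r2 <- off$dx^2 + off$dy^2
  off <- off[off$r2 <= radius^2 + 1e-12, ]
  as.matrix(off[order(off$r2), ])
}

#' Brute-force 2D gamma oracle
#'
#' Independent reference implementation: a per-point exhaustive minimization
#' over a fine sub-millimeter lattice (\code{dta_mm/20}) within a
#' \code{3 * dta_mm} radius.  Intended as the test oracle for
#' \code{\link{gamma_2d}}; refuses grids larger than 200 x 200.
#'
#' @inheritParams gamma_2d
#' @param step_mm search-lattice pitch, mm (default \code{dta_mm/20}).
#' @return a \code{gamma_result}.
#' @export
gamma_2d_bruteforce <- function(reference, evaluated,
                                criteria = gamma_criteria(), step_mm = NULL) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"))
  if (nrow(reference$values) > 200L || ncol(reference$values) > 200L)
    stop("gamma_2d_bruteforce: oracle restricted to grids <= 200 x 200")
  .check_overlap(reference, evaluated)
  norm <- .gamma_norm(reference, criteria)
  dd <- criteria$dose_pct / 100 * norm
  dta <- criteria$dta_mm
  thr <- criteria$threshold_pct / 100 * norm
  if (is.null(step_mm)) step_mm <- dta / 20
  off <- .search_offsets(3 * dta, step_mm)
  odx <- off[, 1]; ody <- off[, 2]; or2 <- off[, 3]
  xs <- plane_x(reference); ys <- plane_y(reference)
  gm <- matrix(NA_real_, nrow = nrow(reference$values), ncol = ncol(reference$values))
  rmax2 <- (3 * dta)^2
  for (j in seq_along(ys)) {
    for (i in seq_along(xs)) {
      dref <- reference$values[j, i]
      if (dref < thr) next
      de0 <- .interp_plane(evaluated, xs[i], ys[j])
      if (is.na(de0)) next
      de <- .interp_plane(evaluated, xs[i] + odx, ys[j] + ody)
      cand <- or2 / dta^2 + ((dref - de) / dd)^2
      g2 <- function(o) {
        r2 <- o[1]^2 + o[2]^2
        if (r2 > rmax2) return(Inf)
        dv <- .interp_plane(evaluated, xs[i] + o[1], ys[j] + o[2])
        if (is.na(dv)) return(Inf)
        r2 / dta^2 + ((dref - dv) / dd)^2
      }
      # derivative-free polish from the best lattice nodes of up to three
      # distinct basins (the continuum minimum sits between nodes, and
      # near-tied basins must all be polished)
      cc <- cand; cc[is.na(cc)] <- Inf
      best <- min(cc)
      for (b in 1:3) {
        k <- which.min(cc)
        # a basin whose lattice value cannot beat the current best even
        # after a generous polish gain is not worth restarting from
        if (!is.finite(cc[k]) || cc[k] > best + 0.5) break
        opt <- stats::optim(c(odx[k], ody[k]), g2, method = "Nelder-Mead",
                            control = list(maxit = 200, reltol = 1e-10))
        best <- min(best, opt$value)
        far <- (odx - odx[k])^2 + (ody - ody[k])^2 > (dta / 4)^2
        cc[!far] <- Inf
      }
      gm[j, i] <- sqrt(best)
    }
  }
  g <- gm[!is.na(gm)]
  n_eval <- length(g)
  pass <- if (n_eval) 100 * mean(g <= 1 + .GAMMA_PASS_TOL) else NA_real_
  if (n_eval == 0L) warning("gamma_2d_bruteforce: no points above threshold")
  .gamma_result(gm, pass, n_eval, criteria, meta = list(oracle = TRUE))
}

#' Depth-searched ("2.5D") gamma analysis
#'
#' Compares one measured plane against calculated planes at depths shifted by
#' up to \code{search_mm} around the nominal depth (1 mm of water = 0.1
#' g/cm^2), mirroring the clinical practice of disambiguating distal-gradient
#' failures by re-computing the calculation up to 3 mm deeper and shallower.
#'
#' @param measured a \code{\link{dose_plane}}.
#' @param calc_source either a function \code{function(depth_gcm2)} returning
#'   a calculated \code{dose_plane}, or a list of pre-computed planes whose
#'   \code{depth} fields cover the searched depths.
#' @param nominal_depth nominal comparison depth, g/cm^2.
#' @param criteria a \code{\link{gamma_criteria}}.
#' @param search_mm half-width of the depth search, mm (default 3).
#' @param step_mm depth step, mm (default 1).
#' @return list with \code{table} (offset_mm, depth, pass_rate),
#'   \code{results} (per-depth \code{gamma_result}), \code{best_offset_mm},
#'   \code{best_depth}, \code{best_pass_rate}.  Ties in pass rate break
#'   toward the nominal depth.
#' @export
gamma_2p5d <- function(measured, calc_source, nominal_depth,
                       criteria = gamma_criteria(), search_mm = 3, step_mm = 1) {
  if (step_mm <= 0) stop("gamma_2p5d: step_mm must be > 0")
  if (search_mm < 0) stop("gamma_2p5d: search_mm must be >= 0")
  offsets <- if (search_mm == 0) 0 else seq(-search_mm, search_mm, by = step_mm)
  if (!any(abs(offsets) < 1e-9)) offsets <- sort(c(offsets, 0))
  get_plane <- if (is.function(calc_source)) {
    calc_source
  } else {
    planes <- calc_source
    depths <- vapply(planes, `[[`, numeric(1), "depth")
    function(d) {
      i <- which(abs(depths - d) < 1e-6)
      if (length(i) == 0L)
        stop(sprintf("gamma_2p5d: no calculated plane at depth %.4f g/cm^2", d))
      planes[[i[1]]]
    }
  }
  res <- lapply(offsets, function(o) {
    d <- nominal_depth + o / 10          # mm of water -> g/cm^2
    if (d < 0) return(NULL)
    gamma_2d(measured, get_plane(d), criteria)
  })
  keep <- !vapply(res, is.null, logical(1))
  offsets <- offsets[keep]; res <- res[keep]
  rates <- vapply(res, `[[`, numeric(1), "pass_rate")
  tab <- data.frame(offset_mm = offsets, depth = nominal_depth + offsets / 10,
                    pass_rate = rates)
  # tie-break toward nominal: order candidates by (-rate, |offset|, offset)
  ord <- order(-rates, abs(offsets), offsets)
  best <- ord[1]
  list(table = tab, results = res,
       best_offset_mm = offsets[best],
       best_depth = nominal_depth + offsets[best] / 10,
       best_pass_rate = rates[best])
}

#' 3D gamma-index comparison of plane stacks
#'
#' Both stacks must share a common lateral lattice; depths may differ but are
#' compared in physical mm (1 mm water = 0.1 g/cm^2).  The minimization
#' searches laterally (continuous, bilinear) within each evaluated slice and
#' discretely across slices, with the full 3D distance in the DTA term.
#' With single-plane stacks it reduces to \code{\link{gamma_2d}}.
#'
#' @param reference,evaluated lists of \code{\link{dose_plane}} objects with
#'   ascending depths on a common lateral grid.
#' @param criteria a \code{\link{gamma_criteria}}.
#' @return a \code{gamma_result}; \code{gamma_map} is a list of per-slice
#'   matrices.
#' @export
gamma_3d <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(is.list(reference), is.list(evaluated),
            length(reference) >= 1L, length(evaluated) >= 1L)
  if (length(reference) == 1L && length(evaluated) == 1L) {
    message("gamma_3d: single-plane stacks; falling through to gamma_2d")
    res <- gamma_2d(reference[[1]], evaluated[[1]], criteria)
    res$gamma_map <- list(res$gamma_map)
    res$meta$note <- "single-plane stacks: 2D comparison"
    return(res)
  }
  rdep <- vapply(reference, `[[`, numeric(1), "depth")
  edep <- vapply(evaluated, `[[`, numeric(1), "depth")
  if (any(diff(rdep) <= 0) || any(diff(edep) <= 0))
    stop("gamma_3d: stack depths must be strictly increasing")
  norm <- criteria$normalization
  if (is.null(norm)) norm <- max(vapply(reference, function(p) max(p$values), numeric(1)))
  crit <- criteria; crit$normalization <- norm
  dd <- crit$dose_pct / 100 * norm
  dta <- crit$dta_mm
  thr <- crit$threshold_pct / 100 * norm
  maps <- vector("list", length(reference))
  all_g <- numeric(0)
  for (ri in seq_along(reference)) {
    ref <- reference[[ri]]
    xs <- plane_x(ref); ys <- plane_y(ref)
    X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
    Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
    mask <- ref$values >= thr
    gm <- matrix(NA_real_, nrow = nrow(ref$values), ncol = ncol(ref$values))
    if (any(mask)) {
      qx <- X[mask]; qy <- Y[mask]; dref <- ref$values[mask]
      best2 <- rep(Inf, length(qx))
      for (ei in seq_along(evaluated)) {
        dz <- 10 * (edep[ei] - rdep[ri])      # g/cm^2 -> mm of water
        if (abs(dz) > 3 * dta) next
        lat_r <- sqrt(max(0, (3 * dta)^2 - dz^2))
        # in-slice lateral minimization, then add the fixed depth penalty
        sl2 <- .gamma_min2(evaluated[[ei]], qx, qy, dref, dta, dd, lat_r, dta / 10)
        best2 <- pmin(best2, sl2 + (dz / dta)^2)
      }
      g <- sqrt(best2)
      g[!is.finite(g)] <- NA_real_      # points never comparable
      gm[mask] <- g
      all_g <- c(all_g, g[!is.na(g)])
    }
    maps[[ri]] <- gm
  }
  n_eval <- length(all_g)
  pass <- if (n_eval) 100 * mean(all_g <= 1 + .GAMMA_PASS_TOL) else NA_real_
  .gamma_result(maps, pass, n_eval, crit,
                meta = list(reference_depths = rdep, evaluated_depths = edep))
}

#' Signed point-dose difference
#'
#' @param measured,calculated point doses (same units).
#' @param normalization positive normalization dose.
#' @return \code{100 * (measured - calculated) / normalization}, %.
#' @export
point_dose_difference <- function(measured, calculated, normalization) {
  if (any(!is.finite(normalization)) || any(normalization <= 0))
    stop("point_dose_difference: normalization must be > 0")
  100 * (measured - calculated) / normalization
}

#' QA decision cascade
#'
#' Applies the clinical action-level cascade: pass outright when the 2%/2 mm
#' rate reaches the action level; otherwise review at 3%/3 mm; otherwise run
#' the depth-searched 2.5D analysis, passing when its best rate reaches the
#' action level and failing otherwise.  When the 2.5D rate is required but
#' missing, the disposition stays \code{"review"} with an action-needed flag.
#'
#' @param pass22 pass rate at 2%/2 mm, % in [0, 100].
#' @param pass33 pass rate at 3%/3 mm, %.
#' @param best25d best 2.5D pass rate at 3%/3 mm, % (optional).
#' @param action_level action level, % (default 90).
#' @return list with \code{status} ("pass" | "review" | "fail"),
#'   \code{route} (which gate decided), \code{evidence} (the input rates),
#'   \code{action_needed}.
#' @export
qa_disposition <- function(pass22, pass33, best25d = NULL, action_level = 90) {
  rates <- c(pass22, pass33, best25d)
  if (any(!is.finite(rates)) || any(rates < 0 | rates > 100))
    stop("qa_disposition: rates must lie in [0, 100]")
  if (action_level <= 0 || action_level > 100)
    stop("qa_disposition: action level must lie in (0, 100]")
  evidence <- list(pass22 = pass22, pass33 = pass33,
                   best25d = if (is.null(best25d)) NA_real_ else best25d,
                   action_level = action_level)
  if (pass22 >= action_level)
    return(list(status = "pass", route = "2%/2mm", evidence = evidence,
                action_needed = FALSE))
  if (pass33 >= action_level)
    return(list(status = "pass", route = "review: 3%/3mm", evidence = evidence,
                action_needed = FALSE))
  if (is.null(best25d))
    return(list(status = "review", route = "2.5D required", evidence = evidence,
                action_needed = TRUE))
  if (best25d >= action_level)
    return(list(status = "pass", route = "review: 2.5D", evidence = evidence,
                action_needed = FALSE))
  list(status = "fail", route = "2.5D", evidence = evidence, action_needed = FALSE)
}
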