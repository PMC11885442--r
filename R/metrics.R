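# Movement metrics on regularized tracks: per-step displacement, speed,
# bearing-from-migration-start, cumulative distance, and the time-varying
# move-persistence index gamma_t in (0,1).

#' Per-step movement metrics
#'
#' Metrics for each 2-h step of a regularized track. Speeds are defined only
#' between consecutive positions of the same segment (straight-line speeds
#' across transmission gaps would underestimate real travel speed).
#' Cumulative distance is accumulated over the whole track, with the
#' straight-line (great-circle) distance bridging segment joins — itself an
#' acknowledged underestimate of the true path. Bearings, when a migration
#' start position is supplied, are initial great-circle azimuths from that
#' start to each position.
#'
#' @param rt a `whale_rtrack`.
#' @param migration_start optional `c(lat, lon)` of the migration start.
#' @return tibble with `date`, `segment_id`, `displacement_km`, `speed_kmh`,
#'   `cumulative_distance_km`, and `bearing_deg` (NA when no start given).
#'   Row i describes the step arriving at position i; the first row has zero
#'   displacement.
#' @export
step_metrics <- function(rt, migration_start = NULL) {
  n <- nrow(rt)
  if (n < 2)
    return(tibble(date = rt$date[0], segment_id = integer(0),
                  displacement_km = numeric(0), speed_kmh = numeric(0),
                  cumulative_distance_km = numeric(0),
                  bearing_deg = numeric(0)))
  disp <- c(0, great_circle_km(rt$lat[-n], rt$lon[-n],
                               rt$lat[-1], rt$lon[-1]))
  dt_h <- c(NA, as.numeric(diff(rt$date), units = "secs") / 3600)
  same_seg <- c(FALSE, rt$segment_id[-1] == rt$segment_id[-n])
  speed <- ifelse(same_seg & dt_h > 0, disp / dt_h, NA_real_)
  bearing <- if (is.null(migration_start)) rep(NA_real_, n) else
    initial_bearing_deg(migration_start[1], migration_start[2],
                        rt$lat, rt$lon)
  tibble(date = rt$date, segment_id = rt$segment_id,
         displacement_km = disp, speed_kmh = speed,
         cumulative_distance_km = cumsum(disp), bearing_deg = bearing)
}

# ---- move persistence -------------------------------------------------------
# Model: with planar displacement vectors d_k between consecutive grid
# positions of a segment,
#     d_k = gamma_k d_{k-1} + e_k,   e_k ~ N(0, sigma_p^2 I_2),
#     logit(gamma_k) follows a Gaussian random walk with SD sigma_g per step.
# gamma near 1: directed, persistent transit; near 0: uncorrelated,
# area-restricted movement. Estimated by Laplace-approximated marginal
# likelihood over (sigma_p, sigma_g) with a Newton inner solve for the logit
# series (Gauss-Newton curvature; the penalized Hessian is tridiagonal per
# chain, so each inner iteration is O(n)).

# Build per-chain step summaries from one rtrack. A chain is a segment; only
# chains with >= min_steps displacement steps enter the fit.
mpm_chains <- function(rt, min_steps) {
  chains <- list()
  for (s in unique(rt$segment_id)) {
    seg <- rt[rt$segment_id == s, ]
    m <- nrow(seg) - 1
    if (m - 1 < min_steps) next
    dx <- diff(seg$x_km); dy <- diff(seg$y_km)
    k <- 2:m
    chains[[length(chains) + 1]] <- list(
      animal_id = attr(rt, "animal_id"), segment_id = s,
      date = seg$date[k + 1],
      a = dx[k] * dx[k - 1] + dy[k] * dy[k - 1],   # d_k . d_{k-1}
      b = dx[k - 1]^2 + dy[k - 1]^2,               # |d_{k-1}|^2
      c = dx[k]^2 + dy[k]^2)                       # |d_k|^2
  }
  chains
}

# tridiagonal solve (Thomas algorithm); diag d, sub/super e (length n-1)
tri_solve <- function(d, e, rhs) {
  n <- length(d)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- if (n > 1) e[1] / d[1] else 0
  dp[1] <- rhs[1] / d[1]
  if (n > 1) {
    for (i in 2:n) {
      m <- d[i] - e[i - 1] * cp[i - 1]
      cp[i] <- if (i < n) e[i] / m else 0
      dp[i] <- (rhs[i] - e[i - 1] * dp[i - 1]) / m
    }
  }
  x <- numeric(n)
  x[n] <- dp[n]
  if (n > 1) for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

tri_logdet <- function(d, e) {
  n <- length(d)
  ld <- log(d[1]); prev <- d[1]
  if (n > 1) {
    for (i in 2:n) {
      cur <- d[i] - e[i - 1]^2 / prev
      if (cur <= 0) return(NA_real_)
      ld <- ld + log(cur)
      prev <- cur
    }
  }
  ld
}

# Penalized fit of one chain's logit series given variances. Returns the
# mode, the joint negative log density at the mode, the Gauss-Newton
# logdet, and the number of latents.
mpm_fit_chain <- function(ch, sp2, sg2, g_init = NULL) {
  n <- length(ch$a)
  g <- if (is.null(g_init)) rep(stats::qlogis(0.7), n) else g_init
  for (iter in 1:60) {
    gam <- stats::plogis(g)
    dgam <- gam * (1 - gam)
    # data gradient / GN curvature
    grad_d <- (gam * ch$b - ch$a) * dgam / sp2
    h_d <- (dgam^2 * ch$b) / sp2 + 1e-10
    # RW penalty: tridiagonal second-difference
    pen_grad <- numeric(n)
    if (n > 1) {
      dg <- diff(g)
      pen_grad[1:(n - 1)] <- pen_grad[1:(n - 1)] - dg / sg2
      pen_grad[2:n] <- pen_grad[2:n] + dg / sg2
    }
    d_diag <- h_d + c(1, rep(2, max(0, n - 2)), 1)[seq_len(n)] / sg2
    if (n == 1) d_diag <- h_d + 0
    e_off <- rep(-1 / sg2, max(0, n - 1))
    grad <- grad_d + pen_grad
    step <- tri_solve(d_diag, e_off, grad)
    # backtracking on the penalized objective
    obj <- function(gv) {
      gm <- stats::plogis(gv)
      val <- sum((ch$c - 2 * gm * ch$a + gm^2 * ch$b) / (2 * sp2))
      if (n > 1) val <- val + sum(diff(gv)^2) / (2 * sg2)
      if (!is.finite(val)) Inf else val
    }
    f0 <- obj(g)
    alpha <- 1
    repeat {
      # clamp the logit series: beyond +-12 the likelihood is flat anyway
      g_new <- pmin(12, pmax(-12, g - alpha * step))
      if (obj(g_new) <= f0 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    delta <- max(abs(g_new - g))
    g <- g_new
    if (delta < 1e-8) break
  }
  gam <- stats::plogis(g)
  nld <- sum((ch$c - 2 * gam * ch$a + gam^2 * ch$b) / (2 * sp2)) +
    n * log(2 * pi * sp2) +
    (if (n > 1) sum(diff(g)^2) / (2 * sg2) +
       (n - 1) * 0.5 * log(2 * pi * sg2) else 0)
  # recompute curvature at the mode for the Laplace determinant
  dgam <- gam * (1 - gam)
  h_d <- (dgam^2 * ch$b) / sp2 + 1e-10
  d_diag <- h_d + c(1, rep(2, max(0, n - 2)), 1)[seq_len(n)] / sg2
  if (n == 1) d_diag <- h_d
  e_off <- rep(-1 / sg2, max(0, n - 1))
  list(g = g, gamma = gam, nld = nld,
       logdet = tri_logdet(d_diag, e_off), n = n)
}

#' Fit the move-persistence model
#'
#' Estimates the time-varying persistence index gamma_t on the 2-h segments
#' of one or several regularized tracks. When several tracks are supplied
#' they are fitted jointly with a single pooled pair of variance parameters
#' (process SD of the displacement noise and random-walk SD of the logit
#' persistence), which makes gamma comparable across animals.
#'
#' @param rt a `whale_rtrack` (fitted per individual) or a list of them
#'   (pooled fit).
#' @param min_steps minimum number of displacement steps a segment must have
#'   to enter the fit; shorter segments are skipped.
#' @return object of class `whale_mpm`: list with `series` (tibble
#'   `animal_id`, `segment_id`, `date`, `gamma`), `sigma_p_km`,
#'   `sigma_g`, `loglik`, `convergence`.
#' @export
fit_move_persistence <- function(rt, min_steps = 20) {
  rts <- if (inherits(rt, "whale_rtrack")) list(rt) else rt
  chains <- unlist(lapply(rts, mpm_chains, min_steps = min_steps),
                   recursive = FALSE)
  if (!length(chains))
    abort("no segment with enough steps for the move-persistence model",
          class = "whalemigrate_mpm_failure")
  # moment-based initial values from a global lag-1 regression
  a_all <- unlist(lapply(chains, `[[`, "a"))
  b_all <- unlist(lapply(chains, `[[`, "b"))
  c_all <- unlist(lapply(chains, `[[`, "c"))
  gam0 <- min(0.95, max(0.05, sum(a_all) / max(sum(b_all), 1e-12)))
  sp0 <- sqrt(max(mean(c_all - 2 * gam0 * a_all + gam0^2 * b_all) / 2,
                  1e-6))
  warm <- vector("list", length(chains))
  neg_marg <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > log(1e5))) return(1e10)
    sp2 <- exp(2 * theta[1]); sg2 <- exp(2 * theta[2])
    tot <- 0
    for (i in seq_along(chains)) {
      f <- mpm_fit_chain(chains[[i]], sp2, sg2, warm[[i]])
      warm[[i]] <<- f$g
      if (!is.finite(f$logdet)) return(1e10)
      tot <- tot + f$nld - f$n / 2 * log(2 * pi) + 0.5 * f$logdet
    }
    if (!is.finite(tot)) 1e10 else tot
  }
  opt <- optim(c(log(sp0), log(0.2)), neg_marg, method = "Nelder-Mead",
               control = list(maxit = 200, reltol = 1e-7))
  sp2 <- exp(2 * opt$par[1]); sg2 <- exp(2 * opt$par[2])
  series <- dplyr::bind_rows(lapply(seq_along(chains), function(i) {
    f <- mpm_fit_chain(chains[[i]], sp2, sg2, warm[[i]])
    tibble(animal_id = chains[[i]]$animal_id,
           segment_id = chains[[i]]$segment_id,
           date = chains[[i]]$date, gamma = f$gamma)
  }))
  structure(list(series = series,
                 sigma_p_km = sqrt(sp2), sigma_g = sqrt(sg2),
                 loglik = -opt$value, convergence = opt$convergence),
            class = "whale_mpm")
}

#' @export
print.whale_mpm <- function(x, ...) {
  cat(sprintf(
    "<whale_mpm> %d steps, %d animal(s); sigma_p = %.2f km, sigma_g = %.3f, mean gamma = %.2f\n",
    nrow(x$series), length(unique(x$series$animal_id)),
    x$sigma_p_km, x$sigma_g, mean(x$series$gamma)))
  invisible(x)
}
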