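## Whole-brain Hopf (Stuart-Landau) oscillator network.  Each region is a
## normal-form oscillator poised near its bifurcation, diffusively coupled
## through a connectivity matrix, integrated with Euler-Maruyama noise.

#' Hopf model parameters
#'
#' @param a per-region bifurcation parameter; negative values place nodes
#'   below the bifurcation (noise-driven damped oscillations), positive
#'   values give a stable limit cycle of radius `sqrt(a)`.  Default -0.01,
#'   just below the bifurcation point.
#' @param omega per-region angular frequency (rad per model time unit);
#'   default `2*pi*0.05` (a 0.05 Hz BOLD-band rhythm).
#' @param G global coupling scale (default 1).
#' @param epsilon additive Gaussian noise amplitude (default 0.02).
#' @param dt Euler-Maruyama integration step in model time units, mapped
#'   one-to-one to seconds (default 0.1).
#' @param duration number of output timepoints.
#' @param burn_in initial integration steps to discard; default 25% of
#'   `duration` (i.e. 20% of all integrated steps), letting the system
#'   settle into its stationary regime.
#' @param seed integer seed for the noise stream.
#' @param coupling_sign `"difference"` (default) couples through
#'   `G * sum_j C_ij (x_j - x_i)`, the diffusive form of the source model;
#'   `"reversed"` flips the difference for sensitivity checks.
#' @param rotation_sign `"standard"` (default) uses the Hopf normal form
#'   (`dx` gets `-omega*y`, `dy` gets `+omega*x`); `"flipped"` reverses
#'   the rotation.
#' @return A list of class `hopf_params`.
#' @export
hopf_params <- function(a = -0.01, omega = 2 * pi * 0.05, G = 1,
                        epsilon = 0.02, dt = 0.1, duration = 1200,
                        burn_in = NULL, seed = 1,
                        coupling_sign = c("difference", "reversed"),
                        rotation_sign = c("standard", "flipped")) {
  if (dt <= 0) stop("dt must be positive")
  if (duration < 3) stop("duration must be >= 3 timepoints")
  if (epsilon < 0) stop("epsilon must be nonnegative")
  if (is.null(burn_in)) burn_in <- ceiling(0.25 * duration)
  structure(list(a = a, omega = omega, G = G, epsilon = epsilon, dt = dt,
                 duration = as.integer(duration),
                 burn_in = as.integer(burn_in), seed = seed,
                 coupling_sign = match.arg(coupling_sign),
                 rotation_sign = match.arg(rotation_sign)),
            class = "hopf_params")
}

#' Estimate per-region peak frequencies
#'
#' Welch-averaged periodogram per region (Hann-windowed segments, 50%
#' overlap); the returned angular frequency is `2*pi` times the frequency
#' of the largest spectral peak within `band`.  Regions whose spectrum is
#' flat within the band (no dominant rhythm, e.g. white noise) fall back
#' to the band midpoint with a warning.
#'
#' @param ts a [region_ts()].
#' @param band numeric length-2, frequency band in Hz (default
#'   `c(0.01, 0.1)`, the conventional BOLD band).
#' @param n_segments number of Welch segments (default 8).
#' @return Named numeric vector of angular frequencies (rad/s).
#' @export
estimate_peak_frequencies <- function(ts, band = c(0.01, 0.1),
                                      n_segments = 8) {
  stopifnot(inherits(ts, "region_ts"))
  n <- ncol(ts$values)
  if (n * ts$dt < 2 / band[1]) {
    stop("series shorter than two cycles of the band's low edge")
  }
  seg_len <- floor(n / ((n_segments + 1) / 2))
  seg_len <- max(seg_len, 8L)
  step <- max(floor(seg_len / 2), 1L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  freqs <- (seq_len(seg_len) - 1) / (seg_len * ts$dt)
  inband <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(inband)) stop("band contains no resolvable frequency bin")
  omega <- numeric(nrow(ts$values))
  for (i in seq_len(nrow(ts$values))) {
    pxx <- rep(0, seg_len)
    for (s in starts) {
      seg <- ts$values[i, s:(s + seg_len - 1L)]
      seg <- (seg - mean(seg)) * win
      pxx <- pxx + Mod(stats::fft(seg))^2
    }
    pb <- pxx[inband]
    ## flat = no dominant rhythm: the band's peak fails to stand out from
    ## the band's mean level (a genuine tone exceeds it by orders of
    ## magnitude; Welch-averaged broadband noise stays below 3x)
    if (max(pb) <= 0 || max(pb) < 3 * mean(pb)) {
      warning("flat spectrum in band for region ", ts$region_ids[i],
              "; falling back to band midpoint")
      omega[i] <- 2 * pi * mean(band)
    } else {
      omega[i] <- 2 * pi * freqs[inband[which.max(pb)]]
    }
  }
  stats::setNames(omega, ts$region_ids)
}

#' Simulate the coupled Stuart-Landau (Hopf) network
#'
#' Integrates, per region i,
#' \deqn{\dot x_i = (a_i - x_i^2 - y_i^2)\,x_i - \omega_i y_i +
#'       G \sum_j C_{ij} (x_j - x_i) + \epsilon\,\eta_i(t)}
#' and the rotated counterpart for y, with the Euler-Maruyama scheme
#' (noise scaled by `sqrt(dt)`).  The coupling matrix follows the package
#' convention `C[i, j]` = influence of j on i; when simulating from an
#' estimated EC the signed matrix is used directly (standardize it first,
#' with `G` as the overall scale).  Burn-in steps are discarded and the x
#' component is returned as the signal.
#'
#' @param coupling a [weighted_digraph()].
#' @param p a [hopf_params()]; scalar `a`/`omega` are recycled per region.
#' @return A [region_ts()] of `p$duration` timepoints at interval `p$dt`.
#' @export
simulate_hopf <- function(coupling, p = hopf_params()) {
  stopifnot(inherits(coupling, "weighted_digraph"),
            inherits(p, "hopf_params"))
  C <- coupling$weights
  n <- nrow(C)
  a <- rep_len(p$a, n)
  omega <- rep_len(p$omega, n)
  if (p$rotation_sign == "flipped") omega <- -omega
  csign <- if (p$coupling_sign == "difference") 1 else -1
  rs <- rowSums(C)
  total <- p$burn_in + p$duration
  out <- matrix(0, n, p$duration)
  set.seed(p$seed)
  x <- stats::rnorm(n, 0, 0.1)
  y <- stats::rnorm(n, 0, 0.1)
  sdt <- sqrt(p$dt)
  for (t in seq_len(total)) {
    r2 <- x^2 + y^2
    cx <- csign * p$G * (as.vector(C %*% x) - rs * x)
    cy <- csign * p$G * (as.vector(C %*% y) - rs * y)
    dx <- (a - r2) * x - omega * y + cx
    dy <- (a - r2) * y + omega * x + cy
    x <- x + p$dt * dx + p$epsilon * sdt * stats::rnorm(n)
    y <- y + p$dt * dy + p$epsilon * sdt * stats::rnorm(n)
    if (max(abs(x)) > 1e6) {
      stop("numerical blow-up at step ", t,
           "; reduce dt or the coupling scale G")
    }
    if (t > p$burn_in) out[, t - p$burn_in] <- x
  }
  region_ts(out, coupling$region_ids, dt = p$dt)
}
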