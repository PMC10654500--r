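#' Reconstruct a periodic free-energy profile by WHAM
#'
#' Weighted histogram analysis of harmonically biased umbrella windows on
#' the dihedral circle. Bias energies use the minimal-image angular
#' distance, so the profile is genuinely periodic. The self-consistent
#' window free energies are iterated until the largest change falls below
#' `tolerance`.
#'
#' @param windows list of umbrella windows (fields `center`, `k_bias`,
#'   `samples`, `temperature`), e.g. from [generate_umbrella_samples()].
#' @param n_bins bins over the full circle (default 72, i.e. 5-degree bins).
#' @param tolerance convergence threshold on window free energies
#'   (kcal/mol).
#' @param max_iter iteration cap.
#' @param min_count bins with fewer total samples are treated as unsampled:
#'   a nearly empty bin at the edge of the sampled range otherwise produces
#'   a spurious deep minimum (its tiny denominator inflates its estimated
#'   probability) that would corrupt the profile anchor.
#' @param ci_window degree pair flagging the conical-intersection region
#'   where classical sampling is unreliable; values there are reported but
#'   flagged, no correction is attempted.
#' @return a `pmf_profile`: list with `bin_centers`, `free_energy`
#'   (kcal/mol, minimum 0, `NA` for unsampled bins), `counts`, `flagged_ci`,
#'   `temperature`, `n_bins`, `iterations`.
#' @export
wham <- function(windows, n_bins = 72, tolerance = 1e-4, max_iter = 1e5,
                 min_count = 10, ci_window = c(90, 100)) {
  if (length(windows) == 0) stop("no umbrella windows given")
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9)
    stop("all windows must share one temperature")
  kT <- .R_KCAL * temps[1]
  edges <- seq(-180, 180, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2

  H <- matrix(0, length(windows), n_bins)
  for (i in seq_along(windows)) {
    s <- wrap_angle(windows[[i]]$samples)
    b <- findInterval(s, edges, rightmost.closed = TRUE)
    b[b == 0] <- 1
    H[i, ] <- tabulate(b, n_bins)
  }
  total <- colSums(H)
  pop <- total >= min_count

  # populated bins must form one contiguous circular arc
  if (!any(pop)) stop("coverage error: no samples in any bin")
  if (any(!pop)) {
    runs <- rle(pop)
    gaps <- sum(!runs$values)
    if (!pop[1] && !pop[n_bins]) gaps <- gaps - 1   # wraparound gap merges
    if (gaps > 1) {
      first_interior <- which(!pop & c(FALSE, pop[-n_bins]))[1]
      stop(sprintf(
        "coverage error: unsampled gap between populated regions near %g deg",
        centers[first_interior]))
    }
  }

  n_i <- rowSums(H)
  # bias energy of every window at every bin center
  C <- matrix(0, length(windows), n_bins)
  for (i in seq_along(windows))
    C[i, ] <- 0.5 * windows[[i]]$k_bias *
      angle_diff(centers, windows[[i]]$center)^2
  expC <- exp(-C / kT)

  f <- numeric(length(windows))
  P <- numeric(n_bins)
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- colSums(n_i * exp(f / kT) * expC)
    P[pop] <- total[pop] / denom[pop]
    f_new <- -kT * log(as.vector(expC[, pop, drop = FALSE] %*% P[pop]))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tolerance) break
    if (iter >= max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                   max_iter, delta))
  }
  G <- rep(NA_real_, n_bins)
  G[pop] <- -kT * log(P[pop])
  G <- G - min(G, na.rm = TRUE)
  flagged <- centers >= ci_window[1] & centers <= ci_window[2]
  structure(list(bin_centers = centers, free_energy = G, counts = total,
                 flagged_ci = flagged, ci_window = ci_window,
                 temperature = temps[1], n_bins = n_bins,
                 iterations = iter, window_f = f),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf(
    "pmf_profile: %d bins, %d sampled, T = %g K, converged in %d iterations\n",
    x$n_bins, sum(!is.na(x$free_energy)), x$temperature, x$iterations))
  cat(sprintf("  max free energy %.2f kcal/mol (CI region %g-%g deg flagged)\n",
              max(x$free_energy, na.rm = TRUE), x$ci_window[1],
              x$ci_window[2]))
  invisible(x)
}

#' @export
plot.pmf_profile <- function(x, ...) {
  graphics::plot(x$bin_centers, x$free_energy, type = "l",
                 xlab = expression(phi[I] ~ "(deg)"),
                 ylab = "free energy (kcal/mol)", ...)
  graphics::abline(v = x$ci_window, lty = 3, col = "red")
  invisible(x)
}

in_circular_region <- function(x, region) {
  width <- (region[2] - region[1]) %% 360
  ((x - region[1]) %% 360) <= width
}

#' Isomerization barrier from a PMF
#'
#' Barrier between the cis-side and trans-side minima: the maximum of the
#' profile along the lower of the two circular paths connecting the two
#' minima, minus the cis minimum. Unsampled bins make a path unusable.
#'
#' @param pmf a `pmf_profile`.
#' @param cis_region,trans_region degree ranges (may wrap past 180) in which
#'   the respective minima are sought.
#' @return barrier height (kcal/mol) with the chosen path direction in
#'   attribute `"path"` (`"+"` increasing angle, `"-"` decreasing).
#' @export
barrier_height <- function(pmf, cis_region = c(-30, 30),
                           trans_region = c(150, 210)) {
  G <- pmf$free_energy
  ctr <- pmf$bin_centers
  pick_min <- function(region) {
    idx <- which(in_circular_region(ctr, region) & !is.na(G))
    if (!length(idx)) stop("region [", region[1], ", ", region[2],
                           "] contains no sampled bins")
    idx[which.min(G[idx])]
  }
  i_cis <- pick_min(cis_region)
  i_trans <- pick_min(trans_region)
  n <- length(G)
  path_max <- function(from, to, step) {
    idx <- from
    i <- from
    while (i != to) {
      i <- ((i - 1 + step) %% n) + 1
      idx <- c(idx, i)
    }
    if (anyNA(G[idx])) Inf else max(G[idx])
  }
  up <- path_max(i_cis, i_trans, 1L)
  down <- path_max(i_cis, i_trans, -1L)
  if (!is.finite(up) && !is.finite(down))
    stop("no fully sampled path between the two minima")
  barrier <- min(up, down) - G[i_cis]
  attr(barrier, "path") <- if (up <= down) "+" else "-"
  barrier
}

#' Barrier difference between two profiles
#'
#' @param pmf_a,pmf_b `pmf_profile` objects at the same temperature.
#' @param cis_region,trans_region passed to [barrier_height()].
#' @return `barrier(a) - barrier(b)` in kcal/mol.
#' @export
compare_pmf <- function(pmf_a, pmf_b, cis_region = c(-30, 30),
                        trans_region = c(150, 210)) {
  if (abs(pmf_a$temperature - pmf_b$temperature) > 1e-9)
    stop("profiles were sampled at different temperatures")
  as.numeric(barrier_height(pmf_a, cis_region, trans_region) -
               barrier_height(pmf_b, cis_region, trans_region))
}

#' RMSE of a reconstructed PMF against a reference potential
#'
#' Compares sampled bins (optionally restricted to a region and excluding
#' the flagged conical-intersection bins) against `V - min(V)` evaluated at
#' the bin centers.
#'
#' @param pmf a `pmf_profile`.
#' @param potential a [periodic_potential()] (or plain function of degrees).
#' @param region optional degree range restricting the comparison.
#' @param exclude_ci drop bins flagged as the conical-intersection window.
#' @return root-mean-square error (kcal/mol).
#' @export
pmf_rmse <- function(pmf, potential, region = NULL, exclude_ci = TRUE) {
  V <- if (inherits(potential, "periodic_potential")) potential$V
       else potential
  keep <- !is.na(pmf$free_energy)
  if (exclude_ci) keep <- keep & !pmf$flagged_ci
  if (!is.null(region))
    keep <- keep & in_circular_region(pmf$bin_centers, region)
  ref <- V(pmf$bin_centers[keep])
  ref <- ref - min(V(pmf$bin_centers[!is.na(pmf$free_energy)]))
  sqrt(mean((pmf$free_energy[keep] - ref)^2))
}
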