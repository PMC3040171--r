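# Binding-event detection from directional reads: candidate-region
# segmentation, MAP-EM fitting of a mixture of strand-shifted t
# distributions with mappability truncation, BIC model selection,
# control-relative enrichment scores and an exchange-based FDR.
#
# Model: forward 5' positions ~ sum_k w_k t_nu(mu_k - delta_k/2, sigma_fk),
# reverse 5' positions ~ sum_k w_k t_nu(mu_k + delta_k/2, sigma_rk), with a
# Normal(xi, delta_sd^2) prior on delta_k and inverse-gamma(a, b) priors on
# the squared spreads. EM uses the normal-scale-mixture representation of
# the t distribution (latent gamma weights).

#' Priors for binding-event fitting
#'
#' @param xi prior mean of the strand-mode separation delta, interpreted as
#'   the typical immunoprecipitated fragment length (bp).
#' @param delta_sd prior standard deviation of delta (bp).
#' @param sigma_shape,sigma_scale inverse-gamma hyperparameters (shape a,
#'   scale b) for the squared spreads; the default is weak and centered near
#'   read-scale spread.
#' @param nu t-distribution degrees of freedom (> 2); heavy-tailed but
#'   finite-variance.
#' @return A list of class `"peak_priors"`.
#' @export
peak_priors <- function(xi = 175, delta_sd = 50, sigma_shape = 2,
                        sigma_scale = 2 * 35^2, nu = 4) {
  if (xi <= 0 || delta_sd <= 0) stop("xi and delta_sd must be positive")
  if (sigma_shape <= 1) stop("sigma_shape must exceed 1")
  if (nu <= 2) stop("nu must exceed 2")
  structure(list(xi = xi, delta_sd = delta_sd, sigma_shape = sigma_shape,
                 sigma_scale = sigma_scale, nu = nu),
            class = "peak_priors")
}

#' Peak-calling configuration
#'
#' @param window,step sliding-window width and step (bp) for segmentation.
#' @param min_fwd,min_rev minimum forward/reverse 5' counts for a window to
#'   qualify.
#' @param Kmax maximum number of binding events fitted per region.
#' @param tol relative penalized log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap.
#' @return A list of class `"peak_config"`.
#' @export
peak_config <- function(window = 300L, step = 50L, min_fwd = 5L, min_rev = 5L,
                        Kmax = 3L, tol = 1e-6, max_iter = 500L) {
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_fwd = as.integer(min_fwd), min_rev = as.integer(min_rev),
                 Kmax = as.integer(Kmax), tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "peak_config")
}

#' Segment reads into candidate binding regions
#'
#' Sliding windows with at least `min_fwd` forward and `min_rev` reverse 5'
#' positions are kept; overlapping kept windows are merged, each merged
#' region is extended by the prior fragment length `xi` on both sides, and
#' reads are assigned to the region containing their 5' end.
#'
#' @param reads an [aligned_reads] table.
#' @param priors a [peak_priors] list (only `xi` is used here).
#' @param min_fwd,min_rev,window,step see [peak_config].
#' @return A list of candidate regions, each a list with `chrom`, `start`,
#'   `end`, and numeric 5'-position vectors `fwd` and `rev`.
#' @export
segment_regions <- function(reads, priors = peak_priors(), min_fwd = 5L,
                            min_rev = 5L, window = 300L, step = 50L) {
  regions <- list()
  ext <- as.integer(round(priors$xi))
  for (ch in unique(reads$chrom)) {
    x <- reads[reads$chrom == ch, , drop = FALSE]
    fwd <- sort(x$pos5[x$strand == "+"])
    rev <- sort(x$pos5[x$strand == "-"])
    if (length(fwd) < min_fwd || length(rev) < min_rev) next
    lo <- min(fwd[1L], rev[1L])
    hi <- max(fwd[length(fwd)], rev[length(rev)])
    starts <- seq.int(max(0L, lo - window + 1L), hi, by = step)
    nf <- findInterval(starts + window - 0.5, fwd) - findInterval(starts - 0.5, fwd)
    nr <- findInterval(starts + window - 0.5, rev) - findInterval(starts - 0.5, rev)
    keep <- which(nf >= min_fwd & nr >= min_rev)
    if (!length(keep)) next
    # merge overlapping kept windows
    ks <- starts[keep]
    ke <- ks + window
    ms <- ks[1L]; me <- ke[1L]
    merged <- list()
    for (i in seq_along(ks)[-1L]) {
      if (ks[i] <= me) me <- max(me, ke[i]) else {
        merged[[length(merged) + 1L]] <- c(ms, me); ms <- ks[i]; me <- ke[i]
      }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    for (m in merged) {
      s <- max(0L, m[1L] - ext)
      e <- m[2L] + ext
      rf <- fwd[fwd >= s & fwd < e]
      rr <- rev[rev >= s & rev < e]
      if (!length(rf) || !length(rr)) next
      regions[[length(regions) + 1L]] <- list(
        chrom = ch, start = as.integer(s), end = as.integer(e),
        fwd = as.numeric(rf), rev = as.numeric(rr)
      )
    }
  }
  regions
}

# log inverse-gamma density of sigma^2 (up to no constant dropped).
.lig <- function(s2, a, b) a * log(b) - lgamma(a) - (a + 1) * log(s2) - b / s2

# Penalized observed-data log-likelihood of the current parameters.
# Zf, Zr are per-component mappable fractions within the region (1 when no
# profile is given or nothing is masked).
.peak_loglik <- function(f, r, par, priors, Zf, Zr) {
  nu <- priors$nu
  dens <- function(x, m, s, Z) {
    d <- sapply(seq_len(nrow(par)), function(k) {
      par$w[k] * dt((x - m[k]) / s[k], nu) / s[k] / Z[k]
    })
    if (is.null(dim(d))) d <- matrix(d, nrow = length(x))
    rowSums(d)
  }
  ll <- sum(log(pmax(dens(f, par$mu - par$delta / 2, par$sigma_f, Zf), 1e-300))) +
    sum(log(pmax(dens(r, par$mu + par$delta / 2, par$sigma_r, Zr), 1e-300)))
  pen <- sum(stats::dnorm(par$delta, priors$xi, priors$delta_sd, log = TRUE)) +
    sum(.lig(par$sigma_f^2, priors$sigma_shape, priors$sigma_scale)) +
    sum(.lig(par$sigma_r^2, priors$sigma_shape, priors$sigma_scale))
  ll + pen
}

#' Fit a K-component strand-shifted t mixture to a candidate region
#'
#' MAP-EM estimation of binding positions (`mu`), strand-mode separations
#' (`delta`), per-strand spreads and component weights. When a mappability
#' profile is given, each component density is renormalized over the
#' mappable subset of the region (evaluated on a 1-bp grid) and the
#' expected sufficient statistics of the masked read mass are folded back
#' into the M-step, so that estimates are corrected for reads that could
#' not be mapped. The penalized log-likelihood trace is non-decreasing; if
#' a numerical step would decrease it, the previous parameters are kept and
#' the fit is declared converged.
#'
#' @param region a candidate region from [segment_regions].
#' @param K number of components (>= 1).
#' @param priors a [peak_priors] list.
#' @param map_profile optional mappability profile ([mappability_profile]);
#'   `NULL` means fully mappable.
#' @param tol relative penalized log-likelihood tolerance.
#' @param max_iter EM iteration cap.
#' @return A list of class `"mixture_fit"`: `K`, `components` (data frame
#'   with `mu`, `delta`, `sigma_f`, `sigma_r`, `w`, `se_mu`), `loglik`,
#'   `loglik_trace`, `converged`, `n_iter`, `pruned`, `n_reads`, `chrom`.
#' @export
fit_mixture <- function(region, K, priors = peak_priors(), map_profile = NULL,
                        tol = 1e-6, max_iter = 500L) {
  f <- as.numeric(region$fwd)
  r <- as.numeric(region$rev)
  if (K < 1L) stop("K must be >= 1")
  if (length(f) < 2L || length(r) < 2L) {
    stop("region needs at least 2 reads per strand")
  }
  nu <- priors$nu
  xi <- priors$xi
  a0 <- priors$sigma_shape
  b0 <- priors$sigma_scale
  sd2 <- priors$delta_sd^2

  # mappability grid over the region (NULL grid means nothing masked)
  grid <- NULL
  if (!is.null(map_profile)) {
    gx <- seq.int(region$start, region$end - 1L)
    gm <- is_mappable(map_profile, region$chrom, gx)
    if (!all(gm)) grid <- list(x = gx, mappable = gm)
  }

  # deterministic quantile initialization from implied binding centers
  centers <- c(f + xi / 2, r - xi / 2)
  mu0 <- as.numeric(quantile(centers, (seq_len(K) - 0.5) / K, names = FALSE))
  par <- data.frame(mu = mu0, delta = rep(xi, K),
                    sigma_f = rep(35, K), sigma_r = rep(35, K),
                    w = rep(1 / K, K))
  pruned <- FALSE
  trace <- numeric()
  converged <- FALSE
  iter <- 0L
  A_mu <- rep(NA_real_, K)

  repeat {
    iter <- iter + 1L
    K_cur <- nrow(par)
    m_f <- par$mu - par$delta / 2
    m_r <- par$mu + par$delta / 2

    # per-component mappable fractions (1-bp grid)
    Zf <- rep(1, K_cur); Zr <- rep(1, K_cur)
    ghosts_f <- ghosts_r <- vector("list", K_cur)
    if (!is.null(grid)) {
      for (k in seq_len(K_cur)) {
        df_all <- dt((grid$x - m_f[k]) / par$sigma_f[k], nu) / par$sigma_f[k]
        dr_all <- dt((grid$x - m_r[k]) / par$sigma_r[k], nu) / par$sigma_r[k]
        Zf[k] <- sum(df_all[grid$mappable]) / max(sum(df_all), 1e-300)
        Zr[k] <- sum(dr_all[grid$mappable]) / max(sum(dr_all), 1e-300)
        ghosts_f[[k]] <- list(x = grid$x[!grid$mappable],
                              d = df_all[!grid$mappable])
        ghosts_r[[k]] <- list(x = grid$x[!grid$mappable],
                              d = dr_all[!grid$mappable])
      }
    }

    ll <- .peak_loglik(f, r, par, priors, Zf, Zr)
    if (length(trace) && ll < trace[length(trace)] - 1e-10 * abs(trace[length(trace)])) {
      # numerical non-monotone step: keep previous parameters
      par <- prev_par
      converged <- TRUE
      break
    }
    trace <- c(trace, ll)
    if (length(trace) >= 2L) {
      rel <- abs(trace[length(trace)] - trace[length(trace) - 1L]) /
        max(abs(trace[length(trace) - 1L]), 1e-12)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter > max_iter) break
    prev_par <- par

    # E-step: responsibilities and t-latent weights
    resp <- function(x, m, s, Z) {
      d <- sapply(seq_len(K_cur), function(k) {
        par$w[k] * dt((x - m[k]) / s[k], nu) / s[k] / Z[k]
      })
      if (is.null(dim(d))) d <- matrix(d, nrow = length(x))
      sweep(d, 1L, pmax(rowSums(d), 1e-300), "/")
    }
    rho_f <- resp(f, m_f, par$sigma_f, Zf)
    rho_r <- resp(r, m_r, par$sigma_r, Zr)

    new_par <- par
    Nf_k <- Nr_k <- numeric(K_cur)
    for (k in seq_len(K_cur)) {
      df2 <- ((f - m_f[k]) / par$sigma_f[k])^2
      dr2 <- ((r - m_r[k]) / par$sigma_r[k])^2
      uf <- (nu + 1) / (nu + df2)
      ur <- (nu + 1) / (nu + dr2)
      wf <- rho_f[, k]
      wr <- rho_r[, k]
      xs <- f; ys <- r
      # ghost (masked-mass) pseudo-observations
      if (!is.null(grid)) {
        nobs_f <- sum(wf); nobs_r <- sum(wr)
        gf <- ghosts_f[[k]]; gr <- ghosts_r[[k]]
        # total ghost weight = n_obs * (1 - Z) / Z, distributed ~ density
        gw_f <- if (sum(gf$d) > 0) {
          nobs_f * (1 - Zf[k]) / max(Zf[k], 1e-12) * gf$d / sum(gf$d)
        } else rep(0, length(gf$x))
        gw_r <- if (sum(gr$d) > 0) {
          nobs_r * (1 - Zr[k]) / max(Zr[k], 1e-12) * gr$d / sum(gr$d)
        } else rep(0, length(gr$x))
        guf <- (nu + 1) / (nu + ((gf$x - m_f[k]) / par$sigma_f[k])^2)
        gur <- (nu + 1) / (nu + ((gr$x - m_r[k]) / par$sigma_r[k])^2)
        xs <- c(f, gf$x); wf <- c(wf, gw_f); uf <- c(uf, guf)
        ys <- c(r, gr$x); wr <- c(wr, gw_r); ur <- c(ur, gur)
      }
      Nf_k[k] <- sum(wf); Nr_k[k] <- sum(wr)

      # joint (mu, delta) update: weighted least squares with the Normal
      # prior on delta
      A <- sum(wf * uf) / par$sigma_f[k]^2
      B <- sum(wr * ur) / par$sigma_r[k]^2
      Sx <- sum(wf * uf * xs) / par$sigma_f[k]^2
      Sy <- sum(wr * ur * ys) / par$sigma_r[k]^2
      M <- matrix(c(A + B, (B - A) / 2,
                    (B - A) / 2, (A + B) / 4 + 1 / sd2), 2L, 2L)
      rhs <- c(Sx + Sy, (Sy - Sx) / 2 + xi / sd2)
      sol <- tryCatch(solve(M, rhs), error = function(e) c(par$mu[k], par$delta[k]))
      new_par$mu[k] <- sol[1L]
      new_par$delta[k] <- max(sol[2L], 1)
      A_mu[k] <- A + B

      nm_f <- new_par$mu[k] - new_par$delta[k] / 2
      nm_r <- new_par$mu[k] + new_par$delta[k] / 2
      new_par$sigma_f[k] <- sqrt(
        (b0 + 0.5 * sum(wf * uf * (xs - nm_f)^2)) / (a0 + 1 + 0.5 * sum(wf))
      )
      new_par$sigma_r[k] <- sqrt(
        (b0 + 0.5 * sum(wr * ur * (ys - nm_r)^2)) / (a0 + 1 + 0.5 * sum(wr))
      )
    }
    new_par$w <- (Nf_k + Nr_k) / sum(Nf_k + Nr_k)

    # prune degenerate components
    bad <- new_par$w < 1e-3 | new_par$sigma_f < 1 | new_par$sigma_r < 1
    if (any(bad) && sum(!bad) >= 1L) {
      new_par <- new_par[!bad, , drop = FALSE]
      new_par$w <- new_par$w / sum(new_par$w)
      A_mu <- A_mu[!bad]
      pruned <- TRUE
      rownames(new_par) <- NULL
    }
    par <- new_par
  }

  par$se_mu <- sqrt(1 / pmax(A_mu[seq_len(nrow(par))], 1e-12))
  o <- order(par$mu)
  par <- par[o, , drop = FALSE]
  rownames(par) <- NULL
  structure(
    list(K = nrow(par), components = par, loglik = trace[length(trace)],
         loglik_trace = trace, converged = converged, n_iter = iter,
         pruned = pruned, n_reads = length(f) + length(r),
         chrom = region$chrom),
    class = "mixture_fit"
  )
}

#' Select the number of binding events in a region by BIC
#'
#' Fits `K = 1..Kmax` components and returns the fit minimizing
#' `BIC = -2 loglik + p log(n)` with `p = 5K - 1` free parameters and `n`
#' the total read count. Components closer than a quarter of their mean
#' separation estimate are merged (weight-averaged) before return.
#'
#' @inheritParams fit_mixture
#' @param Kmax maximum component count tried.
#' @return A `"mixture_fit"` with extra fields `bic` (vector over K) and
#'   `K_selected`.
#' @export
select_K <- function(region, Kmax = 3L, priors = peak_priors(),
                     map_profile = NULL, tol = 1e-6, max_iter = 500L) {
  n <- length(region$fwd) + length(region$rev)
  fits <- vector("list", Kmax)
  bic <- rep(Inf, Kmax)
  for (K in seq_len(Kmax)) {
    fit <- tryCatch(
      fit_mixture(region, K, priors, map_profile, tol, max_iter),
      error = function(e) NULL
    )
    if (is.null(fit) || !is.finite(fit$loglik)) next
    fits[[K]] <- fit
    bic[K] <- -2 * fit$loglik + (5 * fit$K - 1) * log(n)
  }
  if (all(!is.finite(bic))) {
    # all fits degenerate: K = 1 fallback
    fit <- fit_mixture(region, 1L, priors, map_profile, tol, max_iter)
    fit$fallback <- TRUE
    fit$bic <- bic
    fit$K_selected <- 1L
    return(fit)
  }
  best <- fits[[which.min(bic)]]
  # post-hoc merge of components closer than delta_hat / 4
  par <- best$components
  repeat {
    if (nrow(par) < 2L) break
    d <- diff(par$mu)
    lim <- (par$delta[-nrow(par)] + par$delta[-1L]) / 2 / 4
    j <- which(d < lim)
    if (!length(j)) break
    j <- j[1L]
    wsum <- par$w[j] + par$w[j + 1L]
    for (col in c("mu", "delta", "sigma_f", "sigma_r", "se_mu")) {
      par[[col]][j] <- (par$w[j] * par[[col]][j] +
                          par$w[j + 1L] * par[[col]][j + 1L]) / wsum
    }
    par$w[j] <- wsum
    par <- par[-(j + 1L), , drop = FALSE]
  }
  rownames(par) <- NULL
  best$components <- par
  best$K <- nrow(par)
  best$bic <- bic
  best$K_selected <- best$K
  best
}

#' Enrichment scores and confidence intervals for fitted events
#'
#' Per component, the estimated fragment count is `w_k * n_reads / 2`.
#' With a control sample the score is that count divided by the
#' library-size-adjusted local control count within `mu +/- delta`; without
#' a control the score is the fragment count itself. The 95% interval for
#' `mu` comes from the observed-information approximation of the EM fit.
#'
#' @param fit a `"mixture_fit"`.
#' @param region the candidate region the fit came from.
#' @param control_reads optional [aligned_reads] control table.
#' @param lib_ratio treatment/control total read count ratio (used only with
#'   a control).
#' @return A `data.frame` of binding events: `chrom`, `mu`, `delta`,
#'   `sigma_f`, `sigma_r`, `score`, `ci_lo`, `ci_hi`, `n_frag_est`.
#' @export
enrichment_score <- function(fit, region, control_reads = NULL, lib_ratio = 1) {
  par <- fit$components
  n_frag_est <- par$w * fit$n_reads / 2
  score <- n_frag_est
  if (!is.null(control_reads)) {
    eps <- 0.5
    ctrl <- control_reads[control_reads$chrom == region$chrom, , drop = FALSE]
    c_local <- vapply(seq_len(nrow(par)), function(k) {
      sum(ctrl$pos5 >= par$mu[k] - par$delta[k] &
            ctrl$pos5 <= par$mu[k] + par$delta[k])
    }, 0)
    score <- n_frag_est / pmax(c_local / lib_ratio, eps)
  }
  data.frame(
    chrom = region$chrom, mu = par$mu, delta = par$delta,
    sigma_f = par$sigma_f, sigma_r = par$sigma_r, score = score,
    ci_lo = par$mu - 1.96 * par$se_mu, ci_hi = par$mu + 1.96 * par$se_mu,
    n_frag_est = n_frag_est, stringsAsFactors = FALSE
  )
}

#' Exchange-based false discovery rate as a function of the score
#'
#' `FDR(s) = #\{swapped >= s\} / max(#\{treatment >= s\}, 1)`, clipped to
#' `[0, 1]` and made monotone non-increasing in `s` by a running minimum
#' from the right. The swapped scores come from re-running the caller with
#' treatment and control exchanged.
#'
#' @param scores_treatment numeric event scores from the treatment run.
#' @param scores_swapped numeric event scores from the swapped run (may be
#'   empty).
#' @return A list of class `"fdr_estimate"`: `fdr(s)` step function and the
#'   evaluation `table`.
#' @export
estimate_fdr <- function(scores_treatment, scores_swapped) {
  if (!length(scores_treatment)) stop("no treatment scores")
  grid <- sort(unique(c(scores_treatment, scores_swapped)))
  raw <- vapply(grid, function(s) {
    min(max(sum(scores_swapped >= s), 0) /
          max(sum(scores_treatment >= s), 1), 1)
  }, 0)
  mono <- rev(cummin(rev(raw)))
  fn <- stats::approxfun(grid, mono, method = "constant", f = 1,
                         yleft = mono[1L], yright = 0, rule = 2)
  structure(
    list(fdr = function(s) fn(s),
         table = data.frame(score = grid, fdr = mono)),
    class = "fdr_estimate"
  )
}

#' Call binding events from directional reads
#'
#' Full composition of the peak-calling stage: segmentation, per-region
#' model selection, enrichment scoring, and ranking by score (ties broken
#' by chromosome then position, for determinism).
#'
#' @param treatment an [aligned_reads] table.
#' @param control optional [aligned_reads] control table; enables
#'   control-relative scores.
#' @param map_profile optional mappability profile.
#' @param priors a [peak_priors] list.
#' @param config a [peak_config] list.
#' @return A `data.frame` of ranked binding events (columns as in
#'   [enrichment_score], plus `event`, `region_id`, `K_region`).
#' @export
call_peaks <- function(treatment, control = NULL, map_profile = NULL,
                       priors = peak_priors(), config = peak_config()) {
  regions <- segment_regions(treatment, priors, config$min_fwd,
                             config$min_rev, config$window, config$step)
  if (!length(regions)) {
    return(data.frame(chrom = character(), mu = numeric(), delta = numeric(),
                      sigma_f = numeric(), sigma_r = numeric(),
                      score = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                      n_frag_est = numeric(), event = character(),
                      region_id = integer(), K_region = integer(),
                      stringsAsFactors = FALSE))
  }
  lib_ratio <- if (!is.null(control) && nrow(control)) {
    nrow(treatment) / nrow(control)
  } else 1
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    fit <- select_K(regions[[i]], config$Kmax, priors, map_profile,
                    config$tol, config$max_iter)
    ev <- enrichment_score(fit, regions[[i]], control, lib_ratio)
    ev$region_id <- i
    ev$K_region <- fit$K
    out[[i]] <- ev
  }
  out <- do.call(rbind, out)
  out <- out[order(-out$score, out$chrom, out$mu), , drop = FALSE]
  out$event <- sprintf("event%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}
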