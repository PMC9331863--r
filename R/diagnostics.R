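# Simulation-based model evaluation: goodness-of-fit regression, visual
# predictive check (VPC) and normalized prediction distribution errors (NPDE).

#' Goodness-of-fit regression of observed on predicted concentrations
#'
#' Ordinary least squares of observed versus predicted concentrations on the
#' untransformed scale.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3 pairs).
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
gof_regression <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 3) stop("need at least 3 pairs")
  if (var(predicted) == 0) stop("predictions have zero variance")
  f <- lm(observed ~ predicted)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r_squared = summary(f)$r.squared)
}

cohort_design <- function(cohort, drop_blq = TRUE) {
  lapply(cohort, function(s) {
    keep <- if (drop_blq) !s$obs$blq else rep(TRUE, nrow(s$obs))
    list(id = s$id, clcr = s$covariates$CLcr, regimen = s$regimen,
         times = s$obs$time[keep], obs = s$obs$conc[keep])
  })
}

#' Visual predictive check
#'
#' Simulates replicate datasets at the original design (same subjects,
#' regimens, covariates and sampling times, with IIV and residual error) and
#' compares observed concentration percentiles per time bin with the
#' simulation envelope of the same percentiles.
#'
#' @param m a [population_model()].
#' @param cohort a `"pk_cohort"` or NONMEM-style data frame.
#' @param n_replicates number of Monte Carlo replicates (default 1000).
#' @param bins number of quantile-based time bins (default 8); bins with
#'   fewer than 5 observations are merged with a neighbour.
#' @param percentiles observed percentiles to track (default 10/50/90).
#' @param envelope coverage of the simulation envelope (default 0.90).
#' @return An object of class `"vpc_result"`: a data frame with, per bin and
#'   percentile, the observed value and the envelope bounds, plus attributes
#'   `bin_edges` and `n_replicates`. Has a `plot` method.
#' @export
vpc <- function(m, cohort, n_replicates = 1000, bins = 8,
                percentiles = c(10, 50, 90), envelope = 0.90) {
  cohort <- as_pk_cohort(cohort)
  design <- cohort_design(cohort)
  times <- unlist(lapply(design, `[[`, "times"))
  obs <- unlist(lapply(design, `[[`, "obs"))
  if (length(obs) < 5) stop("too few observations for a VPC")
  edges <- unique(quantile(times, probs = seq(0, 1, length.out = bins + 1)))
  bin_of <- function(t) pmin(pmax(findInterval(t, edges,
                                               rightmost.closed = TRUE,
                                               all.inside = TRUE), 1L),
                             length(edges) - 1L)
  bin <- bin_of(times)
  # merge sparse bins leftward
  repeat {
    cnt <- tabulate(bin, nbins = length(edges) - 1L)
    small <- which(cnt > 0 & cnt < 5)
    if (!length(small) || length(unique(bin)) <= 1L) break
    j <- small[1]
    edges <- edges[-max(j, 2L)]
    bin <- bin_of(times)
  }
  nb <- length(edges) - 1L
  probs <- percentiles / 100
  obs_q <- t(vapply(seq_len(nb), function(b)
    quantile(obs[bin == b], probs = probs, names = FALSE),
    numeric(length(probs))))
  sim_q <- array(NA_real_, c(n_replicates, nb, length(probs)))
  for (r in seq_len(n_replicates)) {
    sc <- simulate_design(m, design)
    sv <- unlist(lapply(sc, function(s) s$obs$conc))
    for (b in seq_len(nb))
      sim_q[r, b, ] <- quantile(sv[bin == b], probs = probs, names = FALSE)
  }
  a <- (1 - envelope) / 2
  rows <- do.call(rbind, lapply(seq_len(nb), function(b)
    data.frame(bin = b,
               time_mid = median(times[bin == b]),
               percentile = percentiles,
               observed = obs_q[b, ],
               lower = apply(sim_q[, b, , drop = FALSE], 3, quantile,
                             probs = a),
               upper = apply(sim_q[, b, , drop = FALSE], 3, quantile,
                             probs = 1 - a),
               n_obs = sum(bin == b))))
  structure(rows, class = c("vpc_result", "data.frame"),
            bin_edges = edges, n_replicates = n_replicates)
}

#' @export
plot.vpc_result <- function(x, ...) {
  pcts <- unique(x$percentile)
  xlim <- range(x$time_mid)
  ylim <- range(c(x$observed, x$lower, x$upper))
  plot(NA, xlim = xlim, ylim = ylim, xlab = "Time (h)",
       ylab = "Concentration (mg/L)", main = "Visual predictive check", ...)
  cols <- grDevices::adjustcolor(c("steelblue", "firebrick", "steelblue"),
                                 alpha.f = 0.3)
  for (i in seq_along(pcts)) {
    d <- x[x$percentile == pcts[i], ]
    graphics::polygon(c(d$time_mid, rev(d$time_mid)),
                      c(d$lower, rev(d$upper)), border = NA,
                      col = cols[min(i, 3)])
    graphics::lines(d$time_mid, d$observed, type = "b", pch = 16)
  }
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' For each subject, simulates the observation vector `n_replicates` times
#' under the model (IIV + residual error), decorrelates both observed and
#' simulated vectors with the inverse Cholesky factor of the empirical
#' simulated covariance, and maps the rank of each decorrelated observation
#' among its simulated counterparts through the standard-normal quantile
#' using the (r - 0.5)/K rule. Under a correct model the NPDE are standard
#' normal; a symmetry-around-zero test (Wilcoxon signed-rank by default) and
#' the Shapiro-Wilk normality test are attached.
#'
#' @param m a [population_model()].
#' @param cohort a `"pk_cohort"` or NONMEM-style data frame.
#' @param n_replicates Monte Carlo replicates per subject (>= 200).
#' @param symmetry_test `"wilcoxon"` (default) or `"t"`.
#' @return An object of class `"npde_result"`: list with `npde` (data frame
#'   `id`, `time`, `npde`), `p_symmetry`, `p_shapiro`, `degenerate` (ids
#'   whose simulated covariance needed regularization).
#' @export
npde <- function(m, cohort, n_replicates = 1000,
                 symmetry_test = c("wilcoxon", "t")) {
  symmetry_test <- match.arg(symmetry_test)
  if (n_replicates < 200) stop("n_replicates must be >= 200")
  cohort <- as_pk_cohort(cohort)
  design <- cohort_design(cohort)
  K <- n_replicates
  degenerate <- integer(0)
  out <- lapply(design, function(d) {
    nt <- length(d$times)
    if (nt == 0L) return(NULL)
    sims <- matrix(NA_real_, K, nt)
    for (r in seq_len(K)) {
      p <- sample_individual(m, d$clcr)
      tc <- concentration(p, d$regimen, d$times)
      sims[r, ] <- as.numeric(apply_residual_error(tc, b = m$prop_error_b,
                                                   a = m$add_error_a))
    }
    mu <- colMeans(sims)
    S <- stats::cov(sims)
    U <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(U)) {
      degenerate <<- c(degenerate, d$id)
      warning(sprintf(
        "subject %s: singular simulated covariance, ridge-regularized",
        d$id))
      S <- S + diag(max(diag(S), 1e-8) * 1e-6 + 1e-10, nt)
      U <- chol(S)
    }
    dec <- function(v) backsolve(U, v, transpose = TRUE)
    y_star <- dec(d$obs - mu)
    sim_star <- t(apply(sims, 1, function(s) dec(s - mu)))
    if (nt == 1L) sim_star <- matrix(sim_star, K, 1)
    rank_r <- vapply(seq_len(nt), function(j)
      sum(sim_star[, j] < y_star[j]) + 1L, integer(1))
    u <- pmin(pmax((rank_r - 0.5) / K, 0.5 / K), 1 - 0.5 / K)
    data.frame(id = d$id, time = d$times, npde = qnorm(u))
  })
  tab <- do.call(rbind, out)
  p_sym <- if (symmetry_test == "wilcoxon")
    wilcox.test(tab$npde, mu = 0)$p.value
  else t.test(tab$npde, mu = 0)$p.value
  # Shapiro-Wilk is defined for 3..5000 values; subsample when larger
  p_sw <- if (nrow(tab) < 3) NA_real_
  else shapiro.test(if (nrow(tab) > 5000)
    sample(tab$npde, 5000) else tab$npde)$p.value
  structure(list(npde = tab, p_symmetry = p_sym, p_shapiro = p_sw,
                 degenerate = degenerate, n_replicates = K),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d replicates/subject)\n",
              nrow(x$npde), x$n_replicates))
  cat(sprintf("  mean %.3f, variance %.3f\n", mean(x$npde$npde),
              var(x$npde$npde)))
  cat(sprintf("  symmetry around 0: p = %.3f; Shapiro-Wilk: p = %.3f\n",
              x$p_symmetry, x$p_shapiro))
  if (length(x$degenerate))
    cat("  regularized subjects:", paste(x$degenerate, collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
plot.npde_result <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  stats::qqnorm(x$npde$npde, main = "NPDE Q-Q")
  stats::qqline(x$npde$npde)
  plot(x$npde$time, x$npde$npde, xlab = "Time (h)", ylab = "NPDE", ...)
  abline(h = 0, lty = 2)
  invisible(x)
}
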