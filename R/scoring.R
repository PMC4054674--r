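# Variant-enrichment scoring and mixture-based selection.
#
# Each positioned nucleosome gets two window-median scores over the 147-bp
# footprint around its center: an enrichment score (variant ChIP normalized
# to bulk-histone ChIP) and a background noise score (non-immune IgG
# normalized to bulk-histone). The genome-wide enrichment distribution is
# deconvolved into a background and a specific component with a
# two-component Gaussian mixture fitted by EM; a nucleosome is selected as
# variant-containing when (1) its posterior probability of belonging to the
# specific (higher-mean) component exceeds the threshold and (2) its
# enrichment exceeds `noise_factor` times its own noise score as a fold
# change.

#' Scoring parameters
#'
#' @param window bp centered on the nucleosome center over which the score
#'   medians are taken (default 147, one footprint).
#' @param posterior_threshold minimum posterior probability of the specific
#'   mixture component (default 0.75; strict inequality).
#' @param noise_factor fold-change multiplier on the noise score (default
#'   2; strict inequality).
#' @param ratio_scale `"log2"` (channels are log-scale, so per-probe ratios
#'   are differences; the noise criterion is still applied as a linear fold
#'   change) or `"linear"`.
#' @return a validated list of class `scoring_params`.
#' @export
scoring_params <- function(window = 147, posterior_threshold = 0.75,
                           noise_factor = 2,
                           ratio_scale = c("log2", "linear")) {
  ratio_scale <- match.arg(ratio_scale)
  if (window <= 0) stop("window must be positive")
  if (posterior_threshold <= 0 || posterior_threshold >= 1)
    stop("posterior_threshold must be in (0, 1)")
  if (noise_factor <= 0) stop("noise_factor must be positive")
  structure(list(window = window,
                 posterior_threshold = posterior_threshold,
                 noise_factor = noise_factor, ratio_scale = ratio_scale),
            class = "scoring_params")
}

#' Window-median ratio of two channels at one position
#'
#' Per-probe ratios (differences when `ratio_scale = "log2"`) are computed
#' at probe positions present in both channels inside
#' `[center - window/2, center + window/2)`, then the median is taken.
#'
#' @param num_pos,num_val numerator-channel probe positions and values
#'   (one chromosome, sorted).
#' @param den_pos,den_val denominator-channel probe positions and values.
#' @param center nucleosome center (bp).
#' @param window window width (bp).
#' @param ratio_scale `"log2"` or `"linear"`.
#' @return the median ratio, or `NA_real_` when no probe of both channels
#'   falls in the window (the nucleosome is then unscored).
#' @export
window_median_ratio <- function(num_pos, num_val, den_pos, den_val,
                                center, window, ratio_scale = "log2") {
  lo <- center - window / 2
  hi <- center + window / 2
  # binary-search the sorted positions: indices with lo <= pos < hi
  n1 <- findInterval(lo - 1e-9, num_pos) + 1L
  n2 <- findInterval(hi - 1e-9, num_pos)
  if (n2 < n1) return(NA_real_)
  d1 <- findInterval(lo - 1e-9, den_pos) + 1L
  d2 <- findInterval(hi - 1e-9, den_pos)
  if (d2 < d1) return(NA_real_)
  ni <- n1:n2
  m <- match(num_pos[ni], den_pos[d1:d2])
  keep <- !is.na(m)
  if (!any(keep)) return(NA_real_)
  nv <- num_val[ni[keep]]
  dv <- den_val[(d1:d2)[m[keep]]]
  if (ratio_scale == "log2") median(nv - dv) else median(nv / dv)
}

#' Score nucleosome calls for enrichment and noise
#'
#' @param calls call table from [merge_calls()] or [call_nucleosomes()].
#' @param variant,histone,igg [probe_track()]s of the three ChIP channels.
#' @param params a [scoring_params()].
#' @return the call table with `enrichment` and `noise` columns appended
#'   (NA where a window had no probes; such calls are flagged `scored =
#'   FALSE`).
#' @export
score_nucleosomes <- function(calls, variant, histone, igg,
                              params = scoring_params()) {
  stopifnot(inherits(params, "scoring_params"))
  out <- copy(as.data.table(calls))
  out[, `:=`(enrichment = NA_real_, noise = NA_real_)]
  # vectorized window-median scoring, same semantics as
  # window_median_ratio (tested for equality against it)
  score_chrom <- function(num, den, centers) {
    lo <- centers - params$window / 2
    hi <- centers + params$window / 2
    n1 <- findInterval(lo - 1e-9, num$pos) + 1L
    n2 <- findInterval(hi - 1e-9, num$pos)
    d1 <- findInterval(lo - 1e-9, den$pos) + 1L
    d2 <- findInterval(hi - 1e-9, den$pos)
    vapply(seq_along(centers), function(i) {
      if (n2[i] < n1[i] || d2[i] < d1[i]) return(NA_real_)
      ni <- n1[i]:n2[i]; di <- d1[i]:d2[i]
      m <- match(num$pos[ni], den$pos[di])
      keep <- !is.na(m)
      if (!any(keep)) return(NA_real_)
      nv <- num$value[ni[keep]]
      dv <- den$value[di[m[keep]]]
      if (params$ratio_scale == "log2") median(nv - dv)
      else median(nv / dv)
    }, 0)
  }
  for (cc in unique(out$chrom)) {
    v <- variant[chrom == cc]; h <- histone[chrom == cc]
    g <- igg[chrom == cc]
    idx <- which(out$chrom == cc)
    out$enrichment[idx] <- score_chrom(v, h, out$center[idx])
    out$noise[idx] <- score_chrom(g, h, out$center[idx])
  }
  out[, scored := !is.na(enrichment) & !is.na(noise)]
  if (any(!out$scored))
    warning(sum(!out$scored), " nucleosome(s) had no probes in the scoring",
            " window and were left unscored")
  out[]
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Unequal-variance two-component Gaussian mixture fitted by
#' expectation-maximization: means initialized at the 25th/75th percentiles
#' of the data, variances at the pooled variance, weights at 1/2;
#' convergence when the log-likelihood improves by less than `tol` or after
#' `max_iter` iterations. Deterministic given the data (the initialization
#' is quantile-based, so no RNG is consumed).
#'
#' @param scores finite numeric scores (>= 10).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 500).
#' @return list of class `mixture_model`: `weights`, `means`, `variances`,
#'   `specific_index` (component with the larger mean), `loglik`,
#'   `n_iter`, `converged`.
#' @export
fit_mixture <- function(scores, tol = 1e-8, max_iter = 500) {
  x <- scores[is.finite(scores)]
  if (length(x) < 10) stop("need at least 10 finite scores")
  if (max(x) - min(x) < .Machine$double.eps^0.5)
    stop("degenerate scores (all equal): fit a single component instead")
  mu <- as.numeric(quantile(x, c(0.25, 0.75)))
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * sd(x)
  v <- rep(var(x), 2)
  w <- c(0.5, 0.5)
  vfloor <- 1e-8 * var(x)
  ll_old <- -Inf
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    n_iter <- it
    d1 <- w[1] * dnorm(x, mu[1], sqrt(v[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(v[2]))
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll_old) && ll - ll_old < tol) { converged <- TRUE; break }
    ll_old <- ll
    n1 <- sum(r); n2 <- length(x) - n1
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    v <- pmax(c(sum(r * (x - mu[1])^2) / n1,
                sum((1 - r) * (x - mu[2])^2) / n2), vfloor)
  }
  structure(list(weights = w, means = mu, variances = v,
                 specific_index = which.max(mu), loglik = ll,
                 n_iter = n_iter, converged = converged),
            class = "mixture_model")
}

#' Posterior probability of the specific (higher-mean) component
#'
#' @param model a [fit_mixture()] result.
#' @param score numeric score(s).
#' @return posterior probabilities in [0, 1].
#' @export
posterior_specific <- function(model, score) {
  stopifnot(inherits(model, "mixture_model"))
  k <- model$specific_index
  o <- 3 - k
  ds <- model$weights[k] * dnorm(score, model$means[k],
                                 sqrt(model$variances[k]))
  db <- model$weights[o] * dnorm(score, model$means[o],
                                 sqrt(model$variances[o]))
  tot <- ds + db
  ifelse(tot == 0, as.numeric(score > mean(model$means)), ds / tot)
}

#' Apply the dual selection criteria for variant nucleosomes
#'
#' A scored nucleosome is selected iff (strict inequalities):
#' 1. its posterior probability of the specific mixture component exceeds
#'    `posterior_threshold`, and
#' 2. its enrichment exceeds `noise_factor` times its own noise score as a
#'    fold change (on the log2 scale: `enrichment > log2(noise_factor) +
#'    noise`).
#'
#' @param scored scored call table from [score_nucleosomes()].
#' @param model a [fit_mixture()] fitted on all enrichment scores; `NULL`
#'   fits it here.
#' @param params a [scoring_params()].
#' @return the table with `posterior` and `selected` columns appended;
#'   attribute `"mixture"` carries the model.
#' @export
select_variant_nucleosomes <- function(scored, model = NULL,
                                       params = scoring_params()) {
  out <- copy(as.data.table(scored))
  if (is.null(model)) model <- fit_mixture(out$enrichment)
  out[, posterior := posterior_specific(model, enrichment)]
  noise_cut <- if (params$ratio_scale == "log2")
    log2(params$noise_factor) + out$noise
  else params$noise_factor * out$noise
  out[, selected := !is.na(enrichment) & !is.na(noise) &
        posterior > params$posterior_threshold & enrichment > noise_cut]
  setattr(out, "mixture", model)
  out[]
}
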