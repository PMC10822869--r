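## Posterior sampling: adaptive HMC (dual-averaging step size, diagonal
## mass adaptation, jittered leapfrog count) with a random-walk fallback.

#' Sampler configuration
#'
#' Defaults reproduce the study budget: 4 chains, 1000 warmup iterations
#' and 2500 saved draws per chain (10,000 saved draws total).
#'
#' @param n_chains number of chains.
#' @param n_warmup warmup (adaptation) iterations per chain, discarded.
#' @param n_saved_per_chain post-warmup draws kept per chain.
#' @param seed integer seed; chain c runs on `seed + c`.
#' @param algorithm `"hmc"` (gradient-based, default) or `"rw"`
#'   (random-walk Metropolis fallback).
#' @param target_accept HMC dual-averaging target acceptance rate.
#' @param max_leapfrog upper bound of the jittered leapfrog count.
#' @return Named list.
#' @export
samplerConfig <- function(n_chains = 4L, n_warmup = 1000L,
                          n_saved_per_chain = 2500L, seed = 1L,
                          algorithm = c("hmc", "rw"),
                          target_accept = 0.8, max_leapfrog = 32L) {
  algorithm <- match.arg(algorithm)
  stopifnot(n_chains >= 1, n_warmup >= 50, n_saved_per_chain >= 1)
  list(n_chains = as.integer(n_chains), n_warmup = as.integer(n_warmup),
       n_saved_per_chain = as.integer(n_saved_per_chain),
       seed = as.integer(seed), algorithm = algorithm,
       target_accept = target_accept,
       max_leapfrog = as.integer(max_leapfrog))
}

## draw an initial point from the priors shrunk toward 0 (keeps the
## log transform of beta_rt finite)
.initTheta <- function(npar, n24, n18, includeSpq, priors) {
  v <- c(rnorm(n24, 0, priors$sd_alpha),
         abs(rnorm(n18, 0, priors$sd_beta_rt)),
         rnorm(n18, 0, priors$sd_beta_trial))
  if (includeSpq)
    v <- c(v, rnorm(3 * n18, 0, priors$sd_spq_direct),
           rnorm(6 * n18, 0, priors$sd_spq_mod))
  v <- v * 0.5
  v[seq.int(n24 + 1L, n24 + n18)] <-
    log(pmax(v[seq.int(n24 + 1L, n24 + n18)], 0.05))
  v
}

.hmcChain <- function(lpg, theta0, n_warmup, n_save, target_accept,
                      max_leapfrog) {
  npar <- length(theta0)
  theta <- theta0
  cur <- lpg(theta)
  invmass <- rep(1, npar)           # estimated posterior variances
  sqrt_m <- 1 / sqrt(invmass)
  # dual averaging state
  eps <- 0.1
  mu <- log(10 * eps); logeps_bar <- log(eps); hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  # welford accumulator for mass adaptation window
  w_lo <- max(10L, floor(0.15 * n_warmup))
  w_hi <- floor(0.75 * n_warmup)
  wn <- 0; wmean <- numeric(npar); wm2 <- numeric(npar)
  draws <- matrix(NA_real_, n_save, npar)
  accept_sum <- 0; n_acc <- 0L; divergences <- 0L
  total <- n_warmup + n_save
  for (it in seq_len(total)) {
    p <- rnorm(npar) * sqrt_m
    L <- sample.int(max_leapfrog, 1L)
    th <- theta; gr <- cur$grad
    K0 <- 0.5 * sum(p * p * invmass)
    H0 <- -cur$lp + K0
    p <- p + 0.5 * eps * gr
    diverged <- FALSE
    for (l in seq_len(L)) {
      th <- th + eps * invmass * p
      prop <- lpg(th)
      if (!is.finite(prop$lp)) { diverged <- TRUE; break }
      if (l < L) p <- p + eps * prop$grad
    }
    if (!diverged) {
      p <- p + 0.5 * eps * prop$grad
      H1 <- -prop$lp + 0.5 * sum(p * p * invmass)
      a <- min(1, exp(H0 - H1))
      if (!is.finite(a)) { a <- 0; diverged <- TRUE }
    } else a <- 0
    if (diverged) divergences <- divergences + 1L
    if (runif(1) < a) { theta <- th; cur <- prop }
    if (it <= n_warmup) {
      # dual averaging (Hoffman & Gelman 2014)
      m <- it
      hbar <- (1 - 1 / (m + t0)) * hbar + (target_accept - a) / (m + t0)
      logeps <- mu - sqrt(m) / gamma * hbar
      w <- m^(-kappa)
      logeps_bar <- w * logeps + (1 - w) * logeps_bar
      eps <- exp(logeps)
      if (it >= w_lo && it <= w_hi) {
        wn <- wn + 1
        d <- theta - wmean
        wmean <- wmean + d / wn
        wm2 <- wm2 + d * (theta - wmean)
      }
      if (it == w_hi && wn > 10) {
        invmass <- wm2 / (wn - 1) + 1e-6
        sqrt_m <- 1 / sqrt(invmass)
        # restart step-size adaptation around the current value
        mu <- log(10 * exp(logeps_bar)); hbar <- 0
      }
      if (it == n_warmup) eps <- exp(logeps_bar)
    } else {
      draws[it - n_warmup, ] <- theta
      accept_sum <- accept_sum + a; n_acc <- n_acc + 1L
    }
  }
  list(draws = draws, accept_rate = accept_sum / max(1L, n_acc),
       divergences = divergences, step_size = eps)
}

.rwChain <- function(lpg, theta0, n_warmup, n_save, target_accept) {
  npar <- length(theta0)
  theta <- theta0
  cur <- lpg(theta)$lp
  lsc <- log(2.38 / sqrt(npar))
  scales <- rep(1, npar)
  w_lo <- max(10L, floor(0.15 * n_warmup)); w_hi <- floor(0.75 * n_warmup)
  wn <- 0; wmean <- numeric(npar); wm2 <- numeric(npar)
  draws <- matrix(NA_real_, n_save, npar)
  accept_sum <- 0; n_acc <- 0L
  for (it in seq_len(n_warmup + n_save)) {
    th <- theta + exp(lsc) * scales * rnorm(npar)
    lp1 <- lpg(th)$lp
    a <- if (is.finite(lp1)) min(1, exp(lp1 - cur)) else 0
    if (runif(1) < a) { theta <- th; cur <- lp1 }
    if (it <= n_warmup) {
      lsc <- lsc + (a - 0.234) / sqrt(it)
      if (it >= w_lo && it <= w_hi) {
        wn <- wn + 1
        d <- theta - wmean
        wmean <- wmean + d / wn
        wm2 <- wm2 + d * (theta - wmean)
      }
      if (it == w_hi && wn > 10) scales <- sqrt(wm2 / (wn - 1) + 1e-6)
    } else {
      draws[it - n_warmup, ] <- theta
      accept_sum <- accept_sum + a; n_acc <- n_acc + 1L
    }
  }
  list(draws = draws, accept_rate = accept_sum / max(1L, n_acc),
       divergences = 0L, step_size = exp(lsc))
}

#' Sample the posterior of the accuracy model
#'
#' Runs MCMC over the full parameter set (intercepts, RT penalties on the
#' log scale with the exact Jacobian correction, learning slopes and --
#' when SPQ profiles are present -- the nine SPQ effect families).
#' Initialization draws from the priors shrunk toward zero and retries on a
#' non-finite log posterior. A split-chain Gelman-Rubin diagnostic is
#' attached to the result.
#'
#' @param dataset a [TrialDataset-class] (may hold zero trials, in which
#'   case the posterior equals the prior).
#' @param config a [samplerConfig()].
#' @param index a [ConditionIndex-class]; by default derived from the data.
#' @param includeSpq force inclusion/exclusion of the SPQ families;
#'   defaults to whether the dataset carries standardized profiles.
#' @param priors a [priorSpec()] list.
#' @return A [PosteriorDraws-class] with diagnostics.
#' @export
samplePosterior <- function(dataset, config = samplerConfig(),
                            index = NULL, includeSpq = NULL,
                            priors = priorSpec()) {
  if (is.null(index)) index <- conditionIndexFromData(dataset)
  spq <- spqProfiles(dataset)
  if (nrow(spq) && !all(c("z_cp", "z_in", "z_di") %in% names(spq))) {
    spq <- standardizeFactors(spq)
    dataset <- new("TrialDataset", trials = trials(dataset), spq = spq)
  }
  if (is.null(includeSpq)) includeSpq <- nrow(spq) > 0
  md <- .modelData(dataset, index)
  n <- countParameterSlots(index)
  n24 <- n[["cond24"]]; n18 <- n[["cond18"]]
  npar <- n24 + 2L * n18 + if (includeSpq) 9L * n18 else 0L
  lpg <- function(theta) .lpGrad(theta, md, index, includeSpq, priors)

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch)
    theta0 <- NULL
    for (try in 1:100) {
      cand <- .initTheta(npar, n24, n18, includeSpq, priors)
      if (is.finite(lpg(cand)$lp)) { theta0 <- cand; break }
    }
    if (is.null(theta0))
      stop("could not find a finite log-posterior initialization")
    chains[[ch]] <- if (config$algorithm == "hmc")
      .hmcChain(lpg, theta0, config$n_warmup, config$n_saved_per_chain,
                config$target_accept, config$max_leapfrog)
    else
      .rwChain(lpg, theta0, config$n_warmup, config$n_saved_per_chain,
               config$target_accept)
  }

  draws <- do.call(rbind, lapply(chains, `[[`, "draws"))
  # back-transform the RT penalties to their natural (non-negative) scale
  iu <- seq.int(n24 + 1L, n24 + n18)
  draws[, iu] <- exp(draws[, iu])
  colnames(draws) <- paramNames(index, includeSpq)
  chain <- rep(seq_len(config$n_chains), each = config$n_saved_per_chain)
  ps <- new("PosteriorDraws", draws = draws, chain = as.integer(chain),
            index = index, includeSpq = includeSpq, config = config,
            diagnostics = list(
              accept_rate = mean(vapply(chains, `[[`, numeric(1),
                                        "accept_rate")),
              divergences = sum(vapply(chains, `[[`, integer(1),
                                       "divergences")),
              step_size = vapply(chains, `[[`, numeric(1), "step_size")))
  if (config$n_chains >= 2 && config$n_saved_per_chain >= 4)
    ps@diagnostics$rhat <- gelmanRubin(ps)$rhat
  ps
}

#' Split-chain Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factor per parameter. By default each chain is
#' split in half (strictly more conservative than the plain statistic,
#' which is available with `split = FALSE`).
#'
#' @param samples a [PosteriorDraws-class] (or a list with elements
#'   `draws`, `chain`).
#' @param split split each chain in half before computing?
#' @return List with `rhat` (named numeric), `n_chains`, `n_draws`.
#' @export
gelmanRubin <- function(samples, split = TRUE) {
  draws <- samples@draws; chain <- samples@chain
  ids <- unique(chain)
  if (length(ids) < 2 && !split)
    stop("need >= 2 chains; consider split-chain mode")
  pieces <- list()
  for (id in ids) {
    d <- draws[chain == id, , drop = FALSE]
    if (split) {
      h <- floor(nrow(d) / 2)
      if (h < 2) stop("need >= 4 draws per chain for split R-hat")
      pieces <- c(pieces, list(d[seq_len(h), , drop = FALSE],
                               d[seq.int(h + 1, 2 * h), , drop = FALSE]))
    } else pieces <- c(pieces, list(d))
  }
  m <- length(pieces)
  nn <- nrow(pieces[[1]])
  means <- vapply(pieces, colMeans, numeric(ncol(draws)))
  vars <- vapply(pieces, function(p) apply(p, 2, var),
                 numeric(ncol(draws)))
  if (ncol(draws) == 1) { means <- rbind(means); vars <- rbind(vars) }
  B <- nn * apply(means, 1, var)
  W <- rowMeans(vars)
  rhat <- sqrt(((nn - 1) / nn * W + B / nn) / W)
  names(rhat) <- colnames(draws)
  list(rhat = rhat, n_chains = length(ids), n_draws = nrow(draws),
       split = split)
}

#' Extract draws of one parameter
#'
#' @param samples a [PosteriorDraws-class].
#' @param family parameter family, e.g. `"alpha"`, `"beta_rt"`,
#'   `"beta_cp_trial"`.
#' @param condition slot name, e.g. `"DOP.Feedback.Anger"` or
#'   `"FeedbackNOP.Fear"`.
#' @return Numeric vector of draws.
#' @export
drawsFor <- function(samples, family, condition) {
  col <- sprintf("%s[%s]", family, condition)
  if (!col %in% colnames(samples@draws))
    stop("no such parameter: ", col)
  samples@draws[, col]
}

#' @rdname drawsFor
#' @export
posteriorMatrix <- function(samples) samples@draws

#' Persist posterior draws as CSV + JSON sidecar
#'
#' The draws go to a columnar CSV (chain column first); configuration,
#' seed and the R-hat summary go to a JSON sidecar named
#' `<path>.meta.json`.
#'
#' @param samples a [PosteriorDraws-class].
#' @param path CSV output path.
#' @return Invisibly, the paths written.
#' @export
writeDraws <- function(samples, path) {
  df <- data.frame(chain = samples@chain, check.names = FALSE)
  df <- cbind(df, as.data.frame(samples@draws, check.names = FALSE))
  write.csv(.numToChar(df), path, row.names = FALSE, quote = FALSE)
  meta <- list(config = samples@config, includeSpq = samples@includeSpq,
               groups = samples@index@groups,
               feedbacks = samples@index@feedbacks,
               emotions = samples@index@emotions,
               rhat_max = if (!is.null(samples@diagnostics$rhat))
                 max(samples@diagnostics$rhat) else NULL,
               accept_rate = samples@diagnostics$accept_rate,
               divergences = samples@diagnostics$divergences)
  mp <- paste0(path, ".meta.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(path, mp))
}

#' Reload posterior draws written by [writeDraws()]
#'
#' @param path CSV path (the `.meta.json` sidecar must sit next to it).
#' @return A [PosteriorDraws-class].
#' @export
readDraws <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  chain <- as.integer(df$chain)
  draws <- as.matrix(df[, setdiff(names(df), "chain"), drop = FALSE])
  index <- conditionIndex(groups = meta$groups,
                          feedbacks = meta$feedbacks,
                          emotions = meta$emotions)
  ps <- new("PosteriorDraws", draws = draws, chain = chain, index = index,
            includeSpq = isTRUE(meta$includeSpq),
            config = as.list(meta$config), diagnostics = list())
  if (length(unique(chain)) >= 2)
    ps@diagnostics$rhat <- gelmanRubin(ps)$rhat
  ps
}
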