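#' Settings for stochastic-approximation estimation
#'
#' The estimator follows the standard three-phase schedule used by
#' PNet-style ERGM software: phase 1 estimates the scaling of each
#' statistic by simulation at the initial parameters; phase 2 runs
#' Robbins-Monro iterations with diagonal scaling and gains halved across
#' subphases; phase 3 draws a large sample at the final parameters for
#' convergence t-ratios and standard errors.
#'
#' @param phase1_n phase-1 sample size (default 500).
#' @param subphases number of phase-2 subphases (default 5).
#' @param iter_per_subphase Robbins-Monro iterations per subphase
#'   (default 100).
#' @param gain initial gain, halved at each subphase (default 0.1, in
#'   (0, 1]).
#' @param phase3_n phase-3 sample size (default 1000).
#' @param burnin_sweeps sweeps (expected toggles per tie variable) of
#'   burn-in before phases 1 and 3 (default 20).
#' @param steps_per_iter updates between phase-2 iterations; \code{NULL}
#'   (default) uses one sweep.
#' @param polish_max maximum damped Newton refinement rounds after phase
#'   2 (default 8; 0 disables). Each round draws a phase-3-sized sample
#'   and moves \eqn{\theta} by half a Newton step until the convergence
#'   t-ratios fall below \code{polish_tol}.
#' @param polish_tol target |t| for the refinement rounds (default 0.04).
#' @param seed optional integer seed.
#' @return A list of class \code{"estimation_settings"}.
#' @export
estimation_settings <- function(phase1_n = 500, subphases = 5,
                                iter_per_subphase = 100, gain = 0.1,
                                phase3_n = 1000, burnin_sweeps = 20,
                                steps_per_iter = NULL, polish_max = 8,
                                polish_tol = 0.04, seed = NULL) {
  stopifnot(phase1_n >= 2, subphases >= 1, iter_per_subphase >= 1,
            gain > 0, gain <= 1, phase3_n >= 2, burnin_sweeps >= 0,
            polish_max >= 0, polish_tol > 0)
  structure(list(phase1_n = phase1_n, subphases = subphases,
                 iter_per_subphase = iter_per_subphase, gain = gain,
                 phase3_n = phase3_n, burnin_sweeps = burnin_sweeps,
                 steps_per_iter = steps_per_iter, polish_max = polish_max,
                 polish_tol = polish_tol, seed = seed),
            class = "estimation_settings")
}

#' Significance rule for MERGM parameters
#'
#' A parameter is classified significant when the ratio of the estimate to
#' its estimated standard error exceeds 2.0 in absolute value.
#'
#' @param estimate parameter estimate.
#' @param stderr positive standard error.
#' @return \code{TRUE} if \code{|estimate / stderr| > 2}.
#' @examples
#' classify_significance(1.362, 0.481)   # TRUE
#' classify_significance(0.141, 0.213)   # FALSE
#' @export
classify_significance <- function(estimate, stderr) {
  if (any(!is.finite(stderr)) || any(stderr <= 0)) {
    stop("stderr must be positive and finite")
  }
  abs(estimate / stderr) > 2.0
}

#' Check convergence of a fit
#'
#' A fit is converged when every modelled effect has a convergence
#' t-ratio below the threshold in absolute value.
#'
#' @param fit a \code{mergm_fit} from [fit_mergm()].
#' @param threshold positive t-ratio threshold (default 0.1).
#' @return A list: \code{converged} (logical) and \code{report}
#'   (data.frame with per-effect t-ratios and pass flags).
#' @export
check_convergence <- function(fit, threshold = 0.1) {
  stopifnot(inherits(fit, "mergm_fit"), threshold > 0)
  rep <- data.frame(effect = fit$effects$effect,
                    tratio = fit$effects$tratio,
                    ok = abs(fit$effects$tratio) < threshold,
                    stringsAsFactors = FALSE)
  list(converged = all(rep$ok), report = rep)
}

theta_init <- function(mnet, specs, z_obs) {
  specs <- as_spec_list(specs)
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  theta <- numeric(length(specs))
  clamp <- function(p) min(max(p, 0.02), 0.98)
  for (k in seq_along(specs)) {
    if (specs[[k]]$name == "Density") {
      theta[k] <- stats::qlogis(clamp(sum(mnet$A) / (n_A * (n_A - 1))))
    } else if (specs[[k]]$name == "DensityX") {
      theta[k] <- stats::qlogis(clamp(sum(mnet$X) / (n_A * n_B)))
    }
  }
  theta
}

check_not_degenerate <- function(stat_matrix, mnet, specs) {
  nm <- colnames(stat_matrix)
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  bounds <- c(Density = n_A * (n_A - 1), DensityX = n_A * n_B)
  for (d in intersect(nm, names(bounds))) {
    v <- stat_matrix[, d]
    if (all(v == 0) || all(v == bounds[[d]])) {
      stop("near-degenerate model: simulated networks are all-",
           if (all(v == 0)) "empty" else "full", " in layer ",
           if (d == "Density") "A" else "X")
    }
  }
  invisible(TRUE)
}

#' Fit a multilevel ERGM by MCMC maximum likelihood
#'
#' Robbins-Monro stochastic approximation of the maximum-likelihood
#' parameters of the model \eqn{P_\theta(A, X | B, Y) \propto
#' \exp(\theta \cdot z)}. Density effects are initialized at the logit of
#' the observed layer densities and all other effects at zero (unless
#' \code{theta0} is given). Standard errors are the square roots of the
#' diagonal of the inverse of the phase-3 statistic covariance matrix
#' (the estimated Fisher information), and convergence t-ratios are
#' \eqn{(\bar z_{sim} - z_{obs}) / sd(z_{sim})}.
#'
#' @param mnet observed \code{mlnet}.
#' @param specs effect list ([config_spec()] list or character names);
#'   must include a density effect for each free layer.
#' @param settings an [estimation_settings()].
#' @param theta0 optional initial parameter vector.
#' @param refits number of automatic re-estimation rounds (phase 2 + 3
#'   restarted from the current estimate) while the convergence check
#'   fails (default 1).
#' @return An object of class \code{"mergm_fit"}: \code{effects} (a
#'   data.frame with estimate, se, tratio, significant), \code{covariance}
#'   (phase-3 statistic covariance), \code{z_obs}, \code{converged},
#'   \code{acceptance_rate}, \code{settings}.
#' @export
fit_mergm <- function(mnet, specs, settings = estimation_settings(),
                      theta0 = NULL, refits = 1) {
  stopifnot(inherits(mnet, "mlnet"))
  specs <- as_spec_list(specs)
  if (!is.null(settings$seed)) set.seed(settings$seed)
  nm <- vapply(specs, `[[`, character(1), "name")
  fl <- free_layers(specs)
  if (fl[["A"]] && !"Density" %in% nm) {
    stop("specs with A-level effects must include the Density effect")
  }
  if (fl[["X"]] && !"DensityX" %in% nm) {
    stop("specs with X-level effects must include the DensityX effect")
  }
  z_obs <- evaluate_statistics(mnet, specs)
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  n_free <- fl[["A"]] * n_A * (n_A - 1) + fl[["X"]] * n_A * n_B
  sweep <- max(n_free, 10L)
  steps <- if (is.null(settings$steps_per_iter)) sweep else settings$steps_per_iter
  mix <- default_mix(mnet, specs)

  theta <- if (is.null(theta0)) theta_init(mnet, specs, z_obs) else as.numeric(theta0)
  if (length(theta) != length(specs)) stop("theta0 has the wrong length")

  sim_batch <- function(theta, state, n, burn_sweeps) {
    model <- model_spec(specs, theta)
    enc <- spec_encoding(state, specs)
    z0 <- evaluate_statistics(state, specs)
    out <- cpp_mcmc(state$A, state$X, state$B, enc$ymat,
                    enc$codes, enc$lambdas, enc$aidx,
                    theta, unname(z0), mix,
                    burn_sweeps * sweep, sweep, as.integer(n))
    state$A[] <- out$A
    state$X[] <- out$X
    colnames(out$stats) <- names(z_obs)
    list(stats = out$stats, state = state, acc = out$acceptance_rate)
  }

  state <- mnet

  # Phase 1: diagonal scaling at theta0
  p1 <- sim_batch(theta, state, settings$phase1_n, settings$burnin_sweeps)
  state <- p1$state
  check_not_degenerate(p1$stats, mnet, specs)
  D <- stats::cov(p1$stats)
  dscale <- diag(D)
  if (any(dscale <= .Machine$double.eps)) {
    bad <- names(z_obs)[dscale <= .Machine$double.eps]
    stop("statistic(s) with zero simulated variance (inestimable): ",
         paste(bad, collapse = ", "))
  }

  run_phase23 <- function(theta, state) {
    model <- model_spec(specs, theta)
    # Phase 2: Robbins-Monro with halving gains; the last subphase's
    # iterate average is taken as the estimate.
    for (sub in seq_len(settings$subphases)) {
      a <- settings$gain / 2^(sub - 1)
      acc <- matrix(NA_real_, settings$iter_per_subphase, length(theta))
      for (it in seq_len(settings$iter_per_subphase)) {
        model$theta[] <- theta
        adv <- advance_chain(state, model, steps, mix)
        state <- adv$state
        theta <- theta - a * (adv$z - z_obs) / dscale
        acc[it, ] <- theta
      }
      if (sub == settings$subphases) theta <- colMeans(acc)
    }
    # Damped Newton refinement: polish theta until the simulated means
    # line up with the observed statistics.
    polish <- 0
    repeat {
      p3 <- sim_batch(theta, state, settings$phase3_n, settings$burnin_sweeps)
      state <- p3$state
      check_not_degenerate(p3$stats, mnet, specs)
      mu <- colMeans(p3$stats)
      sdv <- apply(p3$stats, 2, stats::sd)
      tt <- (mu - z_obs) / sdv
      if (polish >= settings$polish_max || all(abs(tt) < settings$polish_tol)) break
      covm <- stats::cov(p3$stats)
      step <- tryCatch(solve(covm, mu - z_obs), error = function(e) {
        (mu - z_obs) / pmax(diag(covm), .Machine$double.eps)
      })
      theta <- theta - 0.5 * step
      polish <- polish + 1
    }
    list(theta = theta, p3 = p3, state = state)
  }

  attempt <- run_phase23(theta, state)
  tries <- 0
  make_fit <- function(attempt) {
    p3 <- attempt$p3
    mu <- colMeans(p3$stats)
    sdv <- apply(p3$stats, 2, stats::sd)
    tratio <- (mu - z_obs) / sdv
    covm <- stats::cov(p3$stats)
    inv <- tryCatch(solve(covm), error = function(e) {
      ev <- eigen(covm, symmetric = TRUE)
      bad <- names(z_obs)[abs(ev$vectors[, length(z_obs)]) > 0.4]
      stop("singular statistic covariance; collinear statistics: ",
           paste(bad, collapse = ", "))
    })
    se <- sqrt(pmax(diag(inv), 0))
    effects <- data.frame(
      effect = names(z_obs),
      estimate = unname(attempt$theta),
      se = unname(se),
      tratio = unname(tratio),
      significant = unname(classify_significance(attempt$theta, se)),
      stringsAsFactors = FALSE
    )
    structure(list(effects = effects, covariance = covm, z_obs = z_obs,
                   sim_mean = mu, sim_sd = sdv,
                   converged = all(abs(tratio) < 0.1),
                   acceptance_rate = p3$acc,
                   specs = specs, settings = settings),
              class = "mergm_fit")
  }
  fit <- make_fit(attempt)
  while (!fit$converged && tries < refits) {
    tries <- tries + 1
    attempt <- run_phase23(attempt$theta, attempt$state)
    fit <- make_fit(attempt)
  }
  fit
}

#' @export
print.mergm_fit <- function(x, ...) {
  cat("Multilevel ERGM fit",
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  e <- x$effects
  cat(sprintf("%-20s %9s %9s %7s\n", "Effect", "Est.", "Std.Err.", "t"))
  for (k in seq_len(nrow(e))) {
    cat(sprintf("%-20s %9.3f %9.3f %7.3f%s\n", e$effect[k], e$estimate[k],
                e$se[k], e$tratio[k], if (e$significant[k]) " *" else ""))
  }
  invisible(x)
}

#' Export fit results as a TSV table
#'
#' One row per effect: name, estimate, standard error, and a significance
#' star per the |estimate/se| > 2 rule.
#'
#' @param fit a \code{mergm_fit}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_fit_table <- function(fit, path) {
  e <- fit$effects
  out <- data.frame(Effect = e$effect,
                    Est. = sprintf("%.3f", e$estimate),
                    Std.Err. = sprintf("%.3f", e$se),
                    Sig. = ifelse(e$significant, "*", ""),
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
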