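#' Organisation-type and education code lists
#'
#' The declared category code lists used by the attribute table.
#' @name code_lists
#' @export
org_type_levels <- function() {
  c("Local Government", "Education", "Health Service",
    "Primary Care Partnership", "Primary Health Network", "Other")
}

#' @rdname code_lists
#' @export
education_levels <- function() {
  c("Less than Year 12", "Year 12 or equivalent",
    "Diploma or Advanced Diploma", "Bachelor's Degree",
    "Graduate Certificate or Graduate Diploma", "Master's Degree")
}

#' Community profile for the synthetic generator
#'
#' A profile fixes the scale and composition of a synthetic community:
#' committee size and survey response, CLD size and shape, target mean
#' collaboration out-degree and actions per member, attribute category
#' probabilities, and the true parameter vector used to draw (A, X).
#' Two presets, [community1_profile()] and [community2_profile()],
#' reproduce the two study communities' reported scale (committees of 18
#' and 20 respondents of 27 invited, CLDs of 58 and 64 variables, mean
#' out-degrees 7.1 and 6.0, mean actions 5.4 and 10.7).
#'
#' @param invited invited committee members.
#' @param respondents survey respondents (<= invited, >= 2).
#' @param n_B number of CLD variables.
#' @param mean_outdegree target mean collaboration out-degree.
#' @param mean_actions target mean actions per member.
#' @param org_probs,edu_probs named probability vectors over
#'   [org_type_levels()] / [education_levels()] (must sum to 1).
#' @param female_prob probability of gender "Female".
#' @param effects character vector of effect names for the generating
#'   model (must include \code{Density} and \code{DensityX}).
#' @param theta named true parameter vector (one per effect); the
#'   \code{Density} and \code{DensityX} entries are starting values that
#'   [generate_community()] calibrates to the degree targets.
#' @param cld_density,cld_hub_bias arc density and preferential-attachment
#'   skew of the generated CLD.
#' @param seed optional integer seed.
#' @return A list of class \code{"community_profile"}.
#' @export
community_profile <- function(invited = 27, respondents = 18, n_B = 58,
                              mean_outdegree = 7.1, mean_actions = 5.4,
                              org_probs = NULL, edu_probs = NULL,
                              female_prob = 0.78,
                              effects = c("Density", "Reciprocity", "DensityX"),
                              theta = c(Density = 0, Reciprocity = 1,
                                        DensityX = 0),
                              cld_density = 0.03, cld_hub_bias = 1,
                              seed = NULL) {
  if (respondents > invited) stop("respondents must be <= invited")
  if (respondents < 2) stop("at least 2 respondents required")
  if (is.null(org_probs)) {
    org_probs <- stats::setNames(rep(1 / 6, 6), org_type_levels())
  }
  if (is.null(edu_probs)) {
    edu_probs <- stats::setNames(rep(1 / 6, 6), education_levels())
  }
  chk <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-8) stop(what, " probabilities must sum to 1")
    p
  }
  org_probs <- chk(org_probs, "organisation")
  edu_probs <- chk(edu_probs, "education")
  if (!all(c("Density", "DensityX") %in% effects)) {
    stop("the generating model must include Density and DensityX")
  }
  if (length(theta) != length(effects)) {
    stop("theta must have one entry per effect")
  }
  names(theta) <- effects
  structure(list(invited = invited, respondents = respondents, n_B = n_B,
                 mean_outdegree = mean_outdegree,
                 mean_actions = mean_actions,
                 org_probs = org_probs, edu_probs = edu_probs,
                 female_prob = female_prob,
                 effects = effects, theta = theta,
                 cld_density = cld_density, cld_hub_bias = cld_hub_bias,
                 seed = seed),
            class = "community_profile")
}

#' @rdname community_profile
#' @export
community1_profile <- function(seed = NULL) {
  community_profile(
    invited = 27, respondents = 18, n_B = 58,
    mean_outdegree = 7.1, mean_actions = 5.4,
    org_probs = stats::setNames(c(4, 3, 4, 5, 0, 2) / 18, org_type_levels()),
    edu_probs = stats::setNames(c(0, 1, 2, 9, 4, 2) / 18, education_levels()),
    female_prob = 14 / 18, seed = seed
  )
}

#' @rdname community_profile
#' @export
community2_profile <- function(seed = NULL) {
  community_profile(
    invited = 27, respondents = 20, n_B = 64,
    mean_outdegree = 6.0, mean_actions = 10.7,
    org_probs = stats::setNames(c(3, 3, 3, 1, 0, 10) / 20, org_type_levels()),
    edu_probs = stats::setNames(c(1, 0, 5, 7, 6, 1) / 20, education_levels()),
    female_prob = 18 / 20, seed = seed
  )
}

#' Generate a synthetic causal loop diagram
#'
#' Draws a directed graph on \code{n_B} variables with expected arc count
#' \code{arc_density * n_B * (n_B - 1)}. With \code{hub_bias > 0} arc
#' targets are chosen by preferential attachment (probability proportional
#' to \code{(in-degree + 1)^hub_bias}), so some variables become central
#' "hubs" as in real CLDs; \code{hub_bias = 0} reduces to uniform
#' (Erdos-Renyi) target choice.
#'
#' @param n_B number of variables (>= 2).
#' @param arc_density arc probability in [0, 1].
#' @param hub_bias non-negative preferential-attachment exponent.
#' @param seed optional integer seed.
#' @return An \code{n_B x n_B} binary matrix with zero diagonal.
#' @export
generate_cld <- function(n_B, arc_density = 0.03, hub_bias = 1, seed = NULL) {
  if (n_B < 2) stop("n_B must be >= 2")
  if (arc_density < 0 || arc_density > 1) stop("arc_density must be in [0, 1]")
  if (hub_bias < 0) stop("hub_bias must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  B <- matrix(0L, n_B, n_B)
  n_slots <- n_B * (n_B - 1)
  m <- stats::rbinom(1, n_slots, arc_density)
  placed <- 0
  attempts <- 0
  while (placed < m && attempts < 200 * (m + 1)) {
    attempts <- attempts + 1
    w <- (colSums(B) + 1)^hub_bias
    v <- sample.int(n_B, 1L, prob = w)
    i <- sample.int(n_B - 1L, 1L)
    if (i >= v) i <- i + 1L
    if (B[i, v] == 0L) {
      B[i, v] <- 1L
      placed <- placed + 1
    }
  }
  B
}

#' Generate a synthetic attribute table
#'
#' Independent categorical draws from the profile's category
#' probabilities for organisation type, education level and gender.
#'
#' @param n number of actors (>= 1).
#' @param profile a [community_profile()].
#' @param seed optional integer seed.
#' @return A data.frame with columns \code{actor}, \code{org_type},
#'   \code{education}, \code{gender}.
#' @export
generate_attributes <- function(n, profile, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  data.frame(
    actor = sprintf("m%02d", seq_len(n)),
    org_type = sample(names(profile$org_probs), n, replace = TRUE,
                      prob = profile$org_probs),
    education = sample(names(profile$edu_probs), n, replace = TRUE,
                       prob = profile$edu_probs),
    gender = sample(c("Female", "Male"), n, replace = TRUE,
                    prob = c(profile$female_prob, 1 - profile$female_prob)),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic community
#'
#' Builds the CLD (B) and attributes (Y), then draws (A, X) from the
#' profile's multilevel ERGM by MCMC. The \code{Density} and
#' \code{DensityX} parameters are calibrated by coordinate bisection so
#' that the realized mean collaboration out-degree and mean actions per
#' member match the profile targets within \code{tolerance} (default
#' 15\%); other parameters are held at their declared true values.
#'
#' @param profile a [community_profile()].
#' @param tolerance relative calibration tolerance (default 0.15).
#' @param max_iter bisection iterations before giving up (default 25).
#' @return An \code{mlnet} with attributes \code{"theta"} (the calibrated
#'   generating parameters) and \code{"profile"}.
#' @export
generate_community <- function(profile, tolerance = 0.15, max_iter = 25) {
  stopifnot(inherits(profile, "community_profile"))
  if (!is.null(profile$seed)) set.seed(profile$seed)
  n <- profile$respondents
  B <- generate_cld(profile$n_B, profile$cld_density, profile$cld_hub_bias)
  Y <- generate_attributes(n, profile)
  actors <- Y$actor
  variables <- sprintf("v%02d", seq_len(profile$n_B))
  state <- multilevel_network(matrix(0L, n, n), B,
                              matrix(0L, n, profile$n_B), Y,
                              actors, variables)

  specs <- spec_list(profile$effects)
  theta <- profile$theta
  target_A <- profile$mean_outdegree * n          # target arc count
  target_X <- profile$mean_actions * n            # target tie count
  pA <- min(max(target_A / (n * (n - 1)), 0.02), 0.98)
  pX <- min(max(target_X / (n * profile$n_B), 0.02), 0.98)
  theta["Density"] <- stats::qlogis(pA)
  theta["DensityX"] <- stats::qlogis(pX)
  loA <- theta["Density"] - 6; hiA <- theta["Density"] + 6
  loX <- theta["DensityX"] - 6; hiX <- theta["DensityX"] + 6
  mix <- default_mix(state, specs)
  sweep <- n * (n - 1) + n * profile$n_B

  measure <- function(theta, state) {
    model <- model_spec(specs, theta)
    enc <- spec_encoding(state, specs)
    z0 <- evaluate_statistics(state, specs)
    out <- cpp_mcmc(state$A, state$X, state$B, enc$ymat,
                    enc$codes, enc$lambdas, enc$aidx,
                    unname(theta), unname(z0), mix,
                    10 * sweep, sweep, 30L)
    state$A[] <- out$A
    state$X[] <- out$X
    colnames(out$stats) <- profile$effects
    list(mA = mean(out$stats[, "Density"]),
         mX = mean(out$stats[, "DensityX"]), state = state)
  }

  # Calibrate the chain mean to half the tolerance, leaving headroom for
  # the sampling noise of the single returned network.
  cal_tol <- tolerance / 2
  okA <- okX <- FALSE
  last <- NULL
  for (it in seq_len(max_iter)) {
    last <- measure(theta, state)
    state <- last$state
    okA <- abs(last$mA - target_A) <= cal_tol * target_A
    okX <- abs(last$mX - target_X) <= cal_tol * target_X
    if (okA && okX) break
    if (!okA) {
      if (last$mA < target_A) loA <- theta["Density"] else hiA <- theta["Density"]
      theta["Density"] <- (loA + hiA) / 2
    }
    if (!okX) {
      if (last$mX < target_X) loX <- theta["DensityX"] else hiX <- theta["DensityX"]
      theta["DensityX"] <- (loX + hiX) / 2
    }
  }
  if (!(okA && okX)) {
    stop(sprintf(paste0("density calibration failed after %d iterations ",
                        "(mean out-degree %.2f vs target %.2f; ",
                        "mean actions %.2f vs target %.2f)"),
                 max_iter, last$mA / n, target_A / n,
                 last$mX / n, target_X / n))
  }
  # Final draw at the calibrated parameters; redraw if the realized
  # network itself strays outside the tolerance band.
  model <- model_spec(specs, theta)
  mnet <- NULL
  for (draw in 1:10) {
    final <- advance_chain(state, model, 30 * sweep, mix)
    state <- final$state
    rA <- sum(state$A); rX <- sum(state$X)
    if (abs(rA - target_A) <= tolerance * target_A &&
        abs(rX - target_X) <= tolerance * target_X) {
      mnet <- state
      break
    }
  }
  if (is.null(mnet)) {
    stop(sprintf(paste0("calibrated draws kept missing the targets ",
                        "(last mean out-degree %.2f vs %.2f; ",
                        "mean actions %.2f vs %.2f)"),
                 sum(state$A) / n, target_A / n,
                 sum(state$X) / n, target_X / n))
  }
  attr(mnet, "theta") <- theta
  attr(mnet, "profile") <- profile
  mnet
}

#' Parameter-recovery experiment
#'
#' Repeatedly generates a community from a profile and refits the
#' generating model, reporting per-effect mean estimate, bias against the
#' per-replicate generating value, spread, and 2-standard-error coverage.
#'
#' @param profile a [community_profile()].
#' @param n_reps number of replicates (>= 2).
#' @param settings an [estimation_settings()] used for each fit.
#' @param refits re-estimation rounds per fit (see [fit_mergm()]).
#' @return A list: \code{report} (data.frame, one row per effect),
#'   \code{estimates} (replicate-by-effect matrix), \code{truth}
#'   (replicate-by-effect matrix of generating values).
#' @export
recovery_experiment <- function(profile, n_reps,
                                settings = estimation_settings(),
                                refits = 1) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  q <- length(profile$effects)
  est <- se <- truth <- matrix(NA_real_, n_reps, q,
                               dimnames = list(NULL, profile$effects))
  base_seed <- if (is.null(profile$seed)) 0L else profile$seed
  for (rep_i in seq_len(n_reps)) {
    p <- profile
    p$seed <- base_seed + rep_i
    mnet <- generate_community(p)
    truth[rep_i, ] <- attr(mnet, "theta")
    fit <- fit_mergm(mnet, spec_list(profile$effects), settings,
                     refits = refits)
    est[rep_i, ] <- fit$effects$estimate
    se[rep_i, ] <- fit$effects$se
  }
  covered <- abs(est - truth) < 2 * se
  report <- data.frame(
    effect = profile$effects,
    mean_estimate = colMeans(est),
    mean_truth = colMeans(truth),
    bias = colMeans(est - truth),
    sd_estimate = apply(est, 2, stats::sd),
    mc_se = apply(est, 2, stats::sd) / sqrt(n_reps),
    coverage_2se = colMeans(covered),
    stringsAsFactors = FALSE
  )
  rownames(report) <- NULL
  list(report = report, estimates = est, truth = truth, se = se)
}
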