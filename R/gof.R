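#' Structural auxiliary summaries of the collaboration layer
#'
#' In-degree and out-degree standard deviations and the (directed) global
#' clustering of A, used alongside the effect catalogue in goodness-of-fit
#' batteries.
#'
#' @param mnet an \code{mlnet}.
#' @return Named numeric vector.
#' @export
structural_summaries <- function(mnet) {
  A <- mnet$A
  twop <- A %*% A
  denom <- sum(twop) - sum(diag(twop))
  clust <- if (denom > 0) sum(A * twop) / denom else 0
  c(SD_indegree_A = stats::sd(colSums(A)),
    SD_outdegree_A = stats::sd(rowSums(A)),
    Clustering_A = clust)
}

default_auxiliary <- function(mnet, fitted_names) {
  cat_ <- effect_catalogue()
  nm <- setdiff(cat_$name, fitted_names)
  # match effects need their attribute to exist
  have <- if (is.null(mnet$Y)) character() else names(mnet$Y)
  drop <- cat_$name[cat_$code == 9L & !(cat_$attribute %in% have)]
  spec_list(setdiff(nm, drop))
}

#' Simulation-based goodness of fit
#'
#' Simulates networks from the fitted model (starting at the observed
#' network, spaced \code{total_updates / n_graphs} MCMC updates apart) and
#' compares observed statistics with the simulated distribution through
#' GOF t-ratios \eqn{(z_{obs} - \bar z_{sim}) / sd(z_{sim})}. Fitted
#' effects are adequate at |t| < 0.1; auxiliary statistics (by default the
#' remaining effect catalogue plus degree-spread and clustering summaries
#' of A) at |t| < 2. The defaults mirror the study-scale battery of 5000
#' graphs from 50 million updates.
#'
#' @param mnet observed \code{mlnet}.
#' @param fit a converged \code{mergm_fit}.
#' @param auxiliary list of [config_spec()] for statistics not in the
#'   model; \code{NULL} (default) uses the full catalogue minus fitted
#'   effects. \code{list()} disables auxiliary effects.
#' @param n_graphs number of simulated graphs (default 5000, >= 2).
#' @param total_updates total MCMC updates across the run (default 5e7).
#' @param include_structural add degree-SD / clustering summaries of A
#'   (default TRUE).
#' @param fitted_threshold,aux_threshold adequacy thresholds (defaults
#'   0.1 and 2).
#' @return A data.frame of class \code{"mergm_gof"}: statistic, role,
#'   observed, simulated mean/SD, t-ratio, adequacy flag.
#' @export
run_gof <- function(mnet, fit, auxiliary = NULL, n_graphs = 5000,
                    total_updates = 5e7, include_structural = TRUE,
                    fitted_threshold = 0.1, aux_threshold = 2) {
  stopifnot(inherits(mnet, "mlnet"), inherits(fit, "mergm_fit"))
  if (n_graphs < 2) stop("n_graphs must be >= 2")
  if (!fit$converged) {
    warning("fit did not pass the convergence check; GOF t-ratios may be misleading")
  }
  fitted_specs <- fit$specs
  fitted_names <- vapply(fitted_specs, `[[`, character(1), "name")
  aux_specs <- if (is.null(auxiliary)) default_auxiliary(mnet, fitted_names) else auxiliary
  aux_specs <- if (length(aux_specs)) as_spec_list(aux_specs) else list()
  all_specs <- c(fitted_specs, aux_specs)

  obs <- evaluate_statistics(mnet, all_specs)
  if (include_structural) obs <- c(obs, structural_summaries(mnet))

  model <- model_spec(fitted_specs, fit$effects$estimate)
  mix <- default_mix(mnet, fitted_specs)
  interval <- max(1, round(total_updates / n_graphs))

  sims <- matrix(NA_real_, n_graphs, length(obs),
                 dimnames = list(NULL, names(obs)))
  state <- mnet
  for (g in seq_len(n_graphs)) {
    adv <- advance_chain(state, model, interval, mix)
    state <- adv$state
    z <- evaluate_statistics(state, all_specs)
    if (include_structural) z <- c(z, structural_summaries(state))
    sims[g, ] <- z
  }

  mu <- colMeans(sims)
  sdv <- apply(sims, 2, stats::sd)
  tt <- ifelse(sdv > 0, (obs - mu) / sdv,
               ifelse(obs == mu, 0, Inf * sign(obs - mu)))
  role <- c(rep("fitted", length(fitted_specs)),
            rep("auxiliary", length(obs) - length(fitted_specs)))
  adequate <- ifelse(role == "fitted",
                     abs(tt) < fitted_threshold,
                     abs(tt) < aux_threshold)
  out <- data.frame(statistic = names(obs), role = role,
                    observed = unname(obs), sim_mean = unname(mu),
                    sim_sd = unname(sdv), tratio = unname(tt),
                    adequate = unname(adequate),
                    stringsAsFactors = FALSE)
  class(out) <- c("mergm_gof", "data.frame")
  out
}

#' @export
print.mergm_gof <- function(x, ...) {
  cat("Goodness of fit (", sum(x$role == "fitted"), " fitted, ",
      sum(x$role == "auxiliary"), " auxiliary)\n", sep = "")
  d <- as.data.frame(x)
  d$observed <- round(d$observed, 3)
  d$sim_mean <- round(d$sim_mean, 3)
  d$sim_sd <- round(d$sim_sd, 3)
  d$tratio <- round(d$tratio, 3)
  print(d, row.names = FALSE)
  invisible(x)
}

#' Export a GOF report as TSV
#'
#' @param gof a \code{mergm_gof} from [run_gof()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gof_table <- function(gof, path) {
  utils::write.table(as.data.frame(gof), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
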