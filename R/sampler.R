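#' Model specification: effects plus parameter vector
#'
#' @param specs list of [config_spec()] (or character vector of names);
#'   every level must be one of A, X, AX, BX, AXB (layer B is exogenous).
#' @param theta numeric parameter vector, one value per spec.
#' @return A list of class \code{"mergm_model"}.
#' @export
model_spec <- function(specs, theta) {
  specs <- as_spec_list(specs)
  theta <- as.numeric(theta)
  if (length(theta) != length(specs)) {
    stop("theta must have one value per configuration spec")
  }
  if (any(!is.finite(theta))) stop("theta must be finite")
  names(theta) <- vapply(specs, `[[`, character(1), "name")
  structure(list(specs = specs, theta = theta), class = "mergm_model")
}

#' MCMC settings for the tie-toggle sampler
#'
#' @param burnin number of updates discarded before the first sample
#'   (default 1e5).
#' @param interval number of updates between recorded samples
#'   (default 1e4; the study-scale default of 5000 graphs per 5e7 updates).
#' @param mix probability of proposing an A-layer toggle; \code{NULL}
#'   (default) uses the proportion of A tie variables among all free tie
#'   variables, so that every free tie variable is proposed uniformly.
#' @param seed optional integer seed applied via \code{set.seed()}.
#' @return A list of class \code{"mcmc_settings"}.
#' @export
mcmc_settings <- function(burnin = 1e5, interval = 1e4, mix = NULL,
                          seed = NULL) {
  if (burnin < 0) stop("burnin must be >= 0")
  if (interval < 1) stop("interval must be >= 1")
  if (!is.null(mix) && (mix < 0 || mix > 1)) stop("mix must be in [0, 1]")
  structure(list(burnin = burnin, interval = interval, mix = mix,
                 seed = seed), class = "mcmc_settings")
}

free_layers <- function(specs) {
  lv <- vapply(as_spec_list(specs), `[[`, character(1), "level")
  c(A = any(lv %in% c("A", "AX", "AXB")),
    X = any(lv %in% c("X", "AX", "BX", "AXB")))
}

default_mix <- function(mnet, specs = NULL) {
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  nties_A <- n_A * (n_A - 1)
  nties_X <- n_A * n_B
  if (!is.null(specs)) {
    fl <- free_layers(specs)
    if (!fl[["A"]]) return(0)
    if (!fl[["X"]]) return(1)
  }
  nties_A / (nties_A + nties_X)
}

#' Propose a single tie toggle
#'
#' With probability \code{mix} draws a uniformly random ordered actor pair
#' (an A tie variable), otherwise a uniformly random actor-variable pair
#' (an X tie variable). B ties are never proposed. This mirrors the
#' proposal used inside [mcmc_sample()].
#'
#' @param mnet an \code{mlnet} (defines the tie-variable space).
#' @param settings an [mcmc_settings()]; \code{mix = NULL} uses the
#'   uniform-over-tie-variables default.
#' @return A list with \code{layer} ("A" or "X"), \code{i}, \code{j}.
#' @export
propose_toggle <- function(mnet, settings = mcmc_settings()) {
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  mix <- if (is.null(settings$mix)) default_mix(mnet) else settings$mix
  if (stats::runif(1) < mix) {
    i <- sample.int(n_A, 1L)
    j <- sample.int(n_A - 1L, 1L)
    if (j >= i) j <- j + 1L
    list(layer = "A", i = i, j = j)
  } else {
    list(layer = "X", i = sample.int(n_A, 1L), j = sample.int(n_B, 1L))
  }
}

#' Simulate multilevel networks by Metropolis tie-toggle MCMC
#'
#' Runs a single Metropolis chain over the free tie variables of (A, X),
#' holding B and Y fixed. A proposed toggle is accepted with probability
#' \eqn{\min(1, \exp(\theta \cdot \Delta z))}. Statistics are tracked
#' incrementally via change statistics and recorded every
#' \code{interval} updates after \code{burnin}.
#'
#' @param start an \code{mlnet} giving the starting state (and B, Y).
#' @param model a [model_spec()].
#' @param settings an [mcmc_settings()].
#' @param n_samples number of recorded statistic vectors.
#' @param return_state if \code{TRUE}, also return the final network.
#' @return A list of class \code{"sample_batch"}: \code{stats} (matrix,
#'   \code{n_samples} rows, one column per effect), \code{acceptance_rate},
#'   and (optionally) \code{final} (an \code{mlnet}).
#' @export
mcmc_sample <- function(start, model, settings = mcmc_settings(),
                        n_samples, return_state = FALSE) {
  stopifnot(inherits(start, "mlnet"), inherits(model, "mergm_model"))
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (!is.null(settings$seed)) set.seed(settings$seed)
  mix <- if (is.null(settings$mix)) default_mix(start, model$specs) else settings$mix
  enc <- spec_encoding(start, model$specs)
  z0 <- evaluate_statistics(start, model$specs)
  out <- cpp_mcmc(start$A, start$X, start$B, enc$ymat,
                  enc$codes, enc$lambdas, enc$aidx,
                  unname(model$theta), unname(z0), mix,
                  settings$burnin, settings$interval, as.integer(n_samples))
  colnames(out$stats) <- names(z0)
  res <- list(stats = out$stats, acceptance_rate = out$acceptance_rate)
  if (return_state) {
    res$final <- multilevel_network(out$A, start$B, out$X, start$Y,
                                    start$actors, start$variables)
  }
  structure(res, class = "sample_batch")
}

#' @export
print.sample_batch <- function(x, ...) {
  cat(sprintf("MCMC sample batch: %d samples, %d statistics (acceptance %.3f)\n",
              nrow(x$stats), ncol(x$stats), x$acceptance_rate))
  print(round(colMeans(x$stats), 3))
  invisible(x)
}

#' Export a sample batch as TSV
#'
#' @param batch a \code{sample_batch} from [mcmc_sample()].
#' @param path output file path (one row per sample, one column per
#'   statistic).
#' @return Invisibly, \code{path}.
#' @export
write_sample_batch <- function(batch, path) {
  utils::write.table(batch$stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Internal: advance a chain by n_updates and return the new state plus the
# current statistics vector. Used by the estimator and GOF loops.
advance_chain <- function(state, model, n_updates, mix) {
  enc <- spec_encoding(state, model$specs)
  z0 <- evaluate_statistics(state, model$specs)
  out <- cpp_mcmc(state$A, state$X, state$B, enc$ymat,
                  enc$codes, enc$lambdas, enc$aidx,
                  unname(model$theta), unname(z0), mix,
                  n_updates, 1, 0L)
  state$A[] <- out$A
  state$X[] <- out$X
  list(state = state, z = stats::setNames(out$z, names(z0)))
}

#' Exact moments of a multilevel ERGM by full enumeration
#'
#' Computes the normalizing constant \eqn{\kappa} and the expected
#' statistics vector exactly by summing \eqn{\exp(\theta \cdot z(g))} over
#' every state of the free tie variables. Only feasible for tiny
#' networks; serves as the independent oracle for the MCMC sampler.
#'
#' @param model a [model_spec()].
#' @param n_A number of actors.
#' @param n_B number of CLD variables.
#' @param B the fixed CLD adjacency matrix (\code{n_B x n_B}).
#' @param Y optional attribute table (needed for match effects).
#' @param free character vector naming the free layers; defaults to the
#'   layers carrying at least one modelled effect. The total number of
#'   free tie variables must not exceed 20.
#' @return A list: \code{mean} (expected statistics), \code{kappa}, and
#'   \code{n_states}.
#' @export
exact_enumeration_moments <- function(model, n_A, n_B, B = matrix(0L, n_B, n_B),
                                      Y = NULL, free = NULL) {
  stopifnot(inherits(model, "mergm_model"))
  if (is.null(free)) {
    fl <- free_layers(model$specs)
    free <- c("A", "X")[fl]
  }
  m_A <- if ("A" %in% free) n_A * (n_A - 1) else 0L
  m_X <- if ("X" %in% free) n_A * n_B else 0L
  m <- m_A + m_X
  if (m > 20L) stop("too many free tie variables for exact enumeration (max 20)")
  actors <- sprintf("m%02d", seq_len(n_A))
  variables <- sprintf("v%02d", seq_len(n_B))
  Apairs <- which(diag(n_A) == 0, arr.ind = TRUE)  # off-diagonal cells
  Xpairs <- as.matrix(expand.grid(seq_len(n_A), seq_len(n_B)))

  A <- matrix(0L, n_A, n_A)
  X <- matrix(0L, n_A, n_B)
  theta <- unname(model$theta)
  q <- length(theta)
  kappa <- 0
  sumz <- numeric(q)
  n_states <- 2^m
  bits <- integer(m)
  for (s in 0:(n_states - 1)) {
    v <- s
    for (b in seq_len(m)) { bits[b] <- v %% 2L; v <- v %/% 2L }
    if (m_A > 0) A[Apairs] <- bits[seq_len(m_A)]
    if (m_X > 0) X[Xpairs] <- bits[m_A + seq_len(m_X)]
    mnet <- multilevel_network(A, B, X, Y, actors, variables)
    z <- evaluate_statistics(mnet, model$specs)
    w <- exp(sum(theta * z))
    kappa <- kappa + w
    sumz <- sumz + w * z
  }
  list(mean = stats::setNames(sumz / kappa, names(model$theta)),
       kappa = kappa, n_states = n_states)
}
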