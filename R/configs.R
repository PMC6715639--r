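#' Catalogue of configuration statistics
#'
#' The model statistics z_Q count (or geometrically smooth) small
#' configurations spanning the collaboration network A, the action network
#' X, and the exogenous CLD B. Levels: \code{A} (within collaboration),
#' \code{X} (bipartite actions), \code{AX}, \code{BX} and \code{AXB}
#' (cross-level interactions). Alternating statistics use a smoothing
#' constant lambda > 1 (default 2).
#'
#' @return A data.frame with columns \code{name}, \code{level},
#'   \code{code} (internal formula id), \code{uses_lambda} and
#'   \code{attribute} (default attribute for homophily effects, else NA).
#' @export
effect_catalogue <- function() {
  data.frame(
    name = c("Density", "Reciprocity", "In2Star", "AinS", "AoutS",
             "AinAoutS", "ATT", "ACT", "Edu_Match", "Org_Match",
             "DensityX", "ASA", "ASB", "ACA",
             "ATXAX",
             "In2StarBX", "Out2StarBX", "TXBX", "L3XBXreciprocity",
             "L3AXBin", "C4AXBentrainment", "C4AXBexchange",
             "C4AXBreciprocity"),
    level = c(rep("A", 10), rep("X", 4), "AX", rep("BX", 4), rep("AXB", 4)),
    code = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 9L,
             10L, 11L, 12L, 13L,
             14L,
             15L, 16L, 17L, 18L,
             19L, 20L, 21L, 22L),
    uses_lambda = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                    FALSE, FALSE,
                    FALSE, TRUE, TRUE, TRUE,
                    TRUE,
                    FALSE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE, FALSE),
    attribute = c(rep(NA, 8), "education", "org_type", rep(NA, 13)),
    stringsAsFactors = FALSE
  )
}

#' Create a configuration-statistic specification
#'
#' @param name effect name from [effect_catalogue()].
#' @param lambda smoothing constant for alternating statistics
#'   (must be > 1; ignored by non-alternating effects).
#' @param attribute attribute column name for homophily (match) effects;
#'   defaults to the catalogue's attribute for `Edu_Match`/`Org_Match`.
#' @return A list of class \code{"config_spec"} with fields \code{name},
#'   \code{level}, \code{code}, \code{lambda}, \code{attribute}.
#' @examples
#' config_spec("Reciprocity")
#' config_spec("AinS", lambda = 3)
#' @export
config_spec <- function(name, lambda = 2, attribute = NULL) {
  cat_ <- effect_catalogue()
  row <- cat_[cat_$name == name, ]
  if (nrow(row) != 1L) stop("unknown effect name: ", name)
  if (row$uses_lambda && (!is.numeric(lambda) || lambda <= 1)) {
    stop("lambda must be > 1 for alternating statistic ", name)
  }
  if (row$code == 9L && is.null(attribute)) attribute <- row$attribute
  if (row$code == 9L && (is.null(attribute) || is.na(attribute))) {
    stop("match effect ", name, " requires an attribute name")
  }
  structure(list(name = name, level = row$level, code = row$code,
                 lambda = as.numeric(lambda),
                 attribute = if (row$code == 9L) attribute else NA_character_),
            class = "config_spec")
}

#' @export
print.config_spec <- function(x, ...) {
  cat(sprintf("<config_spec> %s [level %s]%s%s\n", x$name, x$level,
              if (effect_uses_lambda(x)) sprintf(" lambda=%g", x$lambda) else "",
              if (!is.na(x$attribute)) sprintf(" attribute=%s", x$attribute) else ""))
  invisible(x)
}

effect_uses_lambda <- function(spec) {
  cat_ <- effect_catalogue()
  cat_$uses_lambda[match(spec$name, cat_$name)]
}

#' Build a list of configuration specs from effect names
#'
#' @param names character vector of catalogue effect names.
#' @param lambda smoothing constant applied to every alternating effect.
#' @return A list of [config_spec()] objects.
#' @export
spec_list <- function(names, lambda = 2) {
  lapply(names, config_spec, lambda = lambda)
}

as_spec_list <- function(specs) {
  if (inherits(specs, "config_spec")) return(list(specs))
  if (is.character(specs)) return(spec_list(specs))
  stopifnot(is.list(specs), length(specs) > 0L,
            all(vapply(specs, inherits, logical(1), "config_spec")))
  specs
}

#' Export the statistic catalogue or a spec list as JSON
#'
#' @param specs a list of [config_spec()] (default: the full catalogue).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_catalogue_json <- function(specs = spec_list(effect_catalogue()$name),
                                 path) {
  rows <- lapply(specs, function(s) {
    list(name = s$name, level = s$level, formula_id = s$code,
         lambda = if (effect_uses_lambda(s)) s$lambda else NULL,
         attribute = if (!is.na(s$attribute)) s$attribute else NULL)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# Integer-code an attribute column; NA -> -1 (never matches).
attr_codes <- function(mnet, attribute) {
  if (is.null(mnet$Y) || !attribute %in% names(mnet$Y)) {
    stop("attribute '", attribute, "' not found in the attribute table")
  }
  v <- mnet$Y[[attribute]]
  codes <- as.integer(factor(as.character(v)))
  codes[is.na(codes)] <- -1L
  codes
}

# ---- closed-form evaluation ------------------------------------------------

#' Evaluate one within-A configuration statistic
#'
#' Closed forms for the collaboration-network statistics: arc count
#' (Density), mutual dyads (Reciprocity), in-two-stars, alternating
#' in/out-star statistics AinS/AoutS, the in/out-degree product statistic
#' AinAoutS, alternating transitive and cyclic closure ATT/ACT, and
#' attribute homophily (match) counts.
#'
#' @param mnet an \code{mlnet}.
#' @param spec a [config_spec()] with level \code{A}.
#' @return A single finite numeric value.
#' @export
z_within_A <- function(mnet, spec) {
  spec <- as_spec_list(spec)[[1L]]
  if (spec$level != "A") stop("spec level must be A, got ", spec$level)
  A <- mnet$A
  lam <- spec$lambda
  r <- 1 - 1 / lam
  din <- colSums(A)
  dout <- rowSums(A)
  switch(as.character(spec$code),
    "1" = sum(A),
    "2" = sum(A * t(A)) / 2,
    "3" = sum(choose(din, 2)),
    "4" = lam^2 * sum(r^din - 1 + din / lam),
    "5" = lam^2 * sum(r^dout - 1 + dout / lam),
    "6" = lam^2 * sum((1 - r^din) * (1 - r^dout)),
    "7" = {
      P <- A %*% A
      lam * sum(A * (1 - r^P))
    },
    "8" = {
      C <- t(A %*% A)
      lam * sum(A * (1 - r^C))
    },
    "9" = {
      y <- attr_codes(mnet, spec$attribute)
      m <- outer(y, y, "==") & outer(y, y, function(a, b) a >= 0 & b >= 0)
      sum(A * m)
    },
    stop("not an A-level statistic: ", spec$name)
  )
}

#' Evaluate one bipartite action-network statistic
#'
#' Closed forms for the action-layer statistics: tie count (DensityX),
#' alternating actor-side and variable-side stars (ASA, ASB), and the
#' alternating shared-choice statistic ACA over actor pairs.
#'
#' @inheritParams z_within_A
#' @param spec a [config_spec()] with level \code{X}.
#' @return A single finite numeric value.
#' @export
z_bipartite_X <- function(mnet, spec) {
  spec <- as_spec_list(spec)[[1L]]
  if (spec$level != "X") stop("spec level must be X, got ", spec$level)
  X <- mnet$X
  lam <- spec$lambda
  r <- 1 - 1 / lam
  dact <- rowSums(X)
  dvar <- colSums(X)
  switch(as.character(spec$code),
    "10" = sum(X),
    "11" = lam^2 * sum(r^dact - 1 + dact / lam),
    "12" = lam^2 * sum(r^dvar - 1 + dvar / lam),
    "13" = {
      S <- X %*% t(X)
      v <- 1 - r^S
      lam * sum(v[upper.tri(v)])
    },
    stop("not an X-level statistic: ", spec$name)
  )
}

#' Evaluate one cross-level interaction statistic
#'
#' Closed forms for the interaction statistics joining A, X and the
#' exogenous CLD B: the activity product ATXAX, the star interactions
#' In2StarBX/Out2StarBX, the cross-level triangle TXBX, the three-path
#' L3XBXreciprocity, the three-path L3AXBin, and the cross-level
#' four-cycles C4AXBentrainment / C4AXBexchange / C4AXBreciprocity.
#' Ordered-tuple counting is used throughout; each directed B arc is
#' counted once (a reciprocated B dyad contributes twice).
#'
#' @inheritParams z_within_A
#' @param spec a [config_spec()] with level \code{AX}, \code{BX} or
#'   \code{AXB}.
#' @return A single finite numeric value.
#' @export
z_interaction <- function(mnet, spec) {
  spec <- as_spec_list(spec)[[1L]]
  if (!spec$level %in% c("AX", "BX", "AXB")) {
    stop("spec level must be AX, BX or AXB, got ", spec$level)
  }
  A <- mnet$A; B <- mnet$B; X <- mnet$X
  lam <- spec$lambda
  r <- 1 - 1 / lam
  switch(as.character(spec$code),
    "14" = {
      doutA <- rowSums(A); dX <- rowSums(X)
      lam^2 * sum((1 - r^doutA) * (1 - r^dX))
    },
    "15" = sum(colSums(B) * colSums(X)),
    "16" = sum(rowSums(B) * colSums(X)),
    "17" = sum(B * (t(X) %*% X)),
    "18" = {
      M <- B * t(B)
      dv <- colSums(X)
      sum(M * (outer(dv, dv) - t(X) %*% X))
    },
    "19" = as.numeric(colSums(A) %*% X %*% colSums(B)),
    "20" = sum(A * (X %*% B %*% t(X))),
    "21" = sum(A * (X %*% t(B) %*% t(X))),
    "22" = sum((A * t(A)) * (X %*% (B * t(B)) %*% t(X))),
    stop("not an interaction statistic: ", spec$name)
  )
}

#' Evaluate a vector of configuration statistics
#'
#' Dispatches each spec to [z_within_A()], [z_bipartite_X()] or
#' [z_interaction()]; order is preserved.
#'
#' @param mnet an \code{mlnet}.
#' @param specs a non-empty list of [config_spec()] (or a character vector
#'   of effect names).
#' @return A named numeric vector, one finite value per spec.
#' @export
evaluate_statistics <- function(mnet, specs) {
  specs <- as_spec_list(specs)
  vals <- vapply(specs, function(s) {
    switch(s$level,
      A = z_within_A(mnet, s),
      X = z_bipartite_X(mnet, s),
      z_interaction(mnet, s)
    )
  }, numeric(1))
  names(vals) <- vapply(specs, `[[`, character(1), "name")
  if (any(!is.finite(vals))) stop("non-finite statistic value")
  vals
}

# ---- change statistics -----------------------------------------------------

# Internal: encode specs for the C++ core.
spec_encoding <- function(mnet, specs) {
  specs <- as_spec_list(specs)
  codes <- vapply(specs, `[[`, integer(1) , "code")
  lambdas <- vapply(specs, `[[`, numeric(1), "lambda")
  attrs <- vapply(specs, `[[`, character(1), "attribute")
  need <- unique(attrs[!is.na(attrs)])
  if (length(need)) {
    ymat <- vapply(need, function(a) attr_codes(mnet, a),
                   integer(length(mnet$actors)))
    ymat <- matrix(as.integer(ymat), nrow = length(mnet$actors))
    aidx <- ifelse(is.na(attrs), 0L, match(attrs, need))
  } else {
    ymat <- matrix(0L, nrow = length(mnet$actors), ncol = 1L)
    aidx <- rep(0L, length(specs))
  }
  list(specs = specs, codes = codes, lambdas = lambdas,
       ymat = ymat, aidx = aidx)
}

#' Change statistics for a single tie toggle
#'
#' Returns the vector of differences \eqn{\Delta z = z(tie present) -
#' z(tie absent)} for every spec, computed by local formulas without full
#' re-evaluation. The current state of the toggled tie in \code{mnet} does
#' not matter: the difference is always oriented as present minus absent.
#' Layer B is exogenous and cannot be toggled.
#'
#' @param mnet an \code{mlnet}.
#' @param layer \code{"A"} or \code{"X"}.
#' @param i actor index (1-based) of the tie's sender.
#' @param j partner index: an actor for layer A, a CLD variable for
#'   layer X.
#' @param specs list of [config_spec()] or character vector of names.
#' @return A named numeric vector of changes, one per spec.
#' @export
change_statistics <- function(mnet, layer, i, j, specs) {
  stopifnot(inherits(mnet, "mlnet"))
  if (identical(layer, "B")) stop("layer B is exogenous; its ties cannot be toggled")
  if (!layer %in% c("A", "X")) stop("layer must be 'A' or 'X'")
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  i <- as.integer(i); j <- as.integer(j)
  if (i < 1L || i > n_A) stop("sender index out of range")
  if (layer == "A") {
    if (j < 1L || j > n_A) stop("target index out of range")
    if (i == j) stop("self-loops are not valid ties")
  } else if (j < 1L || j > n_B) stop("variable index out of range")
  enc <- spec_encoding(mnet, specs)
  d <- cpp_change_stats(mnet$A, mnet$X, mnet$B, enc$ymat,
                        enc$codes, enc$lambdas, enc$aidx,
                        if (layer == "A") 0L else 1L, i - 1L, j - 1L)
  names(d) <- vapply(enc$specs, `[[`, character(1), "name")
  d
}

# ---- brute-force oracle ----------------------------------------------------

#' Brute-force configuration counting oracle
#'
#' Evaluates a statistic by exhaustive enumeration over node tuples;
#' alternating statistics are computed as the alternating sum
#' \eqn{\sum_k (-1)^k S_k / \lambda^{k-2}} over raw k-configuration counts
#' obtained by enumerating node subsets. Independent of the closed-form
#' path and only intended for small networks.
#'
#' @param mnet an \code{mlnet} with at most 8 actors and 8 variables.
#' @param spec a single [config_spec()].
#' @return A single numeric value.
#' @export
brute_force_count <- function(mnet, spec) {
  spec <- as_spec_list(spec)[[1L]]
  n_A <- length(mnet$actors); n_B <- length(mnet$variables)
  if (n_A > 8L || n_B > 8L) stop("brute_force_count requires n_A <= 8 and n_B <= 8")
  A <- mnet$A; B <- mnet$B; X <- mnet$X
  lam <- spec$lambda

  n_subsets <- function(members, k) {
    # number of k-subsets, counted by explicit enumeration
    m <- length(members)
    if (m < k) return(0)
    ncol(utils::combn(m, k, simplify = TRUE))
  }
  alt_star <- function(degree_neighbours) {
    # sum over nodes of sum_{k>=2} (-1)^k C(d,k) / lam^(k-2)
    tot <- 0
    for (nb in degree_neighbours) {
      d <- length(nb)
      if (d < 2) next
      for (k in 2:d) tot <- tot + (-1)^k * n_subsets(nb, k) / lam^(k - 2)
    }
    tot
  }
  alt_closure <- function(base_pairs, paths_of_pair) {
    # sum over base ties/pairs of sum_{k>=1} (-1)^(k+1) C(p,k) lam^(1-k)
    tot <- 0
    for (idx in seq_len(nrow(base_pairs))) {
      mid <- paths_of_pair(base_pairs[idx, 1], base_pairs[idx, 2])
      p <- length(mid)
      if (p < 1) next
      for (k in 1:p) tot <- tot + (-1)^(k + 1) * n_subsets(mid, k) * lam^(1 - k)
    }
    tot
  }

  acts <- seq_len(n_A); vars <- seq_len(n_B)
  switch(as.character(spec$code),
    "1" = {
      tot <- 0
      for (i in acts) for (j in acts) if (i != j) tot <- tot + A[i, j]
      tot
    },
    "2" = {
      tot <- 0
      for (i in acts) for (j in acts) if (i < j) tot <- tot + A[i, j] * A[j, i]
      tot
    },
    "3" = {
      tot <- 0
      for (j in acts) tot <- tot + n_subsets(which(A[, j] == 1L), 2)
      tot
    },
    "4" = alt_star(lapply(acts, function(j) which(A[, j] == 1L))),
    "5" = alt_star(lapply(acts, function(i) which(A[i, ] == 1L))),
    "6" = {
      # lam^2 * sum_i sum_{p,q>=1} (-1)^(p+q) C(din,p) C(dout,q) lam^(-p-q)
      tot <- 0
      for (i in acts) {
        nin <- which(A[, i] == 1L); nout <- which(A[i, ] == 1L)
        if (!length(nin) || !length(nout)) next
        for (p in seq_along(nin)) for (q in seq_along(nout)) {
          tot <- tot + (-1)^(p + q) * n_subsets(nin, p) * n_subsets(nout, q) *
            lam^(2 - p - q)
        }
      }
      tot
    },
    "7" = {
      ties <- which(A == 1L, arr.ind = TRUE)
      if (nrow(ties) == 0L) return(0)
      alt_closure(ties, function(i, j) {
        which(A[i, ] == 1L & A[, j] == 1L)
      })
    },
    "8" = {
      ties <- which(A == 1L, arr.ind = TRUE)
      if (nrow(ties) == 0L) return(0)
      alt_closure(ties, function(i, j) {
        which(A[j, ] == 1L & A[, i] == 1L)
      })
    },
    "9" = {
      y <- attr_codes(mnet, spec$attribute)
      tot <- 0
      for (i in acts) for (j in acts) {
        if (i != j && y[i] >= 0L && y[j] >= 0L && y[i] == y[j]) {
          tot <- tot + A[i, j]
        }
      }
      tot
    },
    "10" = {
      tot <- 0
      for (i in acts) for (v in vars) tot <- tot + X[i, v]
      tot
    },
    "11" = alt_star(lapply(acts, function(i) which(X[i, ] == 1L))),
    "12" = alt_star(lapply(vars, function(v) which(X[, v] == 1L))),
    "13" = {
      pairs <- if (n_A >= 2) t(utils::combn(acts, 2)) else matrix(0, 0, 2)
      alt_closure(pairs, function(i, j) {
        which(X[i, ] == 1L & X[j, ] == 1L)
      })
    },
    "14" = {
      tot <- 0
      for (i in acts) {
        nout <- which(A[i, ] == 1L); nx <- which(X[i, ] == 1L)
        if (!length(nout) || !length(nx)) next
        for (p in seq_along(nout)) for (q in seq_along(nx)) {
          tot <- tot + (-1)^(p + q) * n_subsets(nout, p) * n_subsets(nx, q) *
            lam^(2 - p - q)
        }
      }
      tot
    },
    "15" = {
      tot <- 0
      for (v in vars) for (u in vars) for (i in acts) {
        if (u != v) tot <- tot + B[u, v] * X[i, v]
      }
      tot
    },
    "16" = {
      tot <- 0
      for (v in vars) for (u in vars) for (i in acts) {
        if (u != v) tot <- tot + B[v, u] * X[i, v]
      }
      tot
    },
    "17" = {
      tot <- 0
      for (i in acts) for (u in vars) for (v in vars) {
        if (u != v) tot <- tot + X[i, u] * X[i, v] * B[u, v]
      }
      tot
    },
    "18" = {
      tot <- 0
      for (i in acts) for (j in acts) for (u in vars) for (v in vars) {
        if (i != j && u != v) {
          tot <- tot + X[i, u] * X[j, v] * B[u, v] * B[v, u]
        }
      }
      tot
    },
    "19" = {
      tot <- 0
      for (i in acts) for (v in vars) {
        if (X[i, v] == 1L) {
          tot <- tot + sum(A[, i]) * sum(B[, v])
        }
      }
      tot
    },
    "20" = {
      tot <- 0
      for (i in acts) for (j in acts) for (u in vars) for (v in vars) {
        if (i != j && u != v) {
          tot <- tot + A[i, j] * X[i, u] * X[j, v] * B[u, v]
        }
      }
      tot
    },
    "21" = {
      tot <- 0
      for (i in acts) for (j in acts) for (u in vars) for (v in vars) {
        if (i != j && u != v) {
          tot <- tot + A[i, j] * X[i, u] * X[j, v] * B[v, u]
        }
      }
      tot
    },
    "22" = {
      tot <- 0
      for (i in acts) for (j in acts) for (u in vars) for (v in vars) {
        if (i != j && u != v) {
          tot <- tot + A[i, j] * A[j, i] * X[i, u] * X[j, v] *
            B[u, v] * B[v, u]
        }
      }
      tot
    },
    stop("unknown statistic: ", spec$name)
  )
}
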