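# Random multilevel networks and small fixtures used across the suite.

rand_mnet <- function(n_A, n_B, pA = 0.3, pB = 0.3, pX = 0.3,
                      with_attrs = TRUE) {
  A <- matrix(rbinom(n_A * n_A, 1, pA), n_A); diag(A) <- 0L
  B <- matrix(rbinom(n_B * n_B, 1, pB), n_B); diag(B) <- 0L
  X <- matrix(rbinom(n_A * n_B, 1, pX), n_A)
  Y <- if (with_attrs) {
    data.frame(actor = sprintf("m%02d", seq_len(n_A)),
               org_type = sample(c("gov", "edu", NA), n_A, replace = TRUE),
               education = sample(c("dip", "bach", "mast"), n_A,
                                  replace = TRUE),
               stringsAsFactors = FALSE)
  } else NULL
  multilevel_network(A, B, X, Y,
                     sprintf("m%02d", seq_len(n_A)),
                     sprintf("v%02d", seq_len(n_B)))
}

empty_mnet <- function(n_A, n_B, B = matrix(0L, n_B, n_B), Y = NULL) {
  multilevel_network(matrix(0L, n_A, n_A), B, matrix(0L, n_A, n_B), Y,
                     sprintf("m%02d", seq_len(n_A)),
                     sprintf("v%02d", seq_len(n_B)))
}

# A network whose A layer holds the given arcs (i, j), 1-based.
arcs_mnet <- function(n_A, arcs, n_B = 1) {
  A <- matrix(0L, n_A, n_A)
  for (a in arcs) A[a[1], a[2]] <- 1L
  multilevel_network(A, matrix(0L, n_B, n_B), matrix(0L, n_A, n_B), NULL,
                     sprintf("m%02d", seq_len(n_A)),
                     sprintf("v%02d", seq_len(n_B)))
}

all_effect_names <- function() effect_catalogue()$name
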