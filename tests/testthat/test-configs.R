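test_that("direct counts on a three-node collaboration network", {
  net <- arcs_mnet(3, list(c(1, 2), c(2, 1), c(2, 3)))
  expect_equal(z_within_A(net, config_spec("Density")), 3)
  expect_equal(z_within_A(net, config_spec("Reciprocity")), 1)
  expect_equal(z_within_A(net, config_spec("In2Star")), 0)
})

test_that("alternating in-star matches the alternating-sum oracle", {
  # one node receiving d nominations; oracle sum_{k>=2} (-1)^k C(d,k)/lam^(k-2)
  for (lam in c(2, 3)) {
    for (d in 0:7) {
      net <- arcs_mnet(8, lapply(setdiff(1:8, 8)[seq_len(d)],
                                 function(i) c(i, 8)))
      expected <- 0
      if (d >= 2) {
        for (k in 2:d) expected <- expected + (-1)^k * choose(d, k) / lam^(k - 2)
      }
      expect_equal(z_within_A(net, config_spec("AinS", lambda = lam)),
                   expected, tolerance = 1e-12)
    }
  }
  # in-degree 3 at lambda 2 contributes 3 - 1/2
  net3 <- arcs_mnet(4, list(c(1, 4), c(2, 4), c(3, 4)))
  expect_equal(z_within_A(net3, config_spec("AinS", lambda = 2)), 2.5)
})

test_that("alternating transitive closure counts the minimal triangle once", {
  # i->k, k->j, i->j: the tie i->j closes one two-path
  net <- arcs_mnet(3, list(c(1, 3), c(3, 2), c(1, 2)))
  expect_equal(z_within_A(net, config_spec("ATT", lambda = 2)), 1)
})

test_that("bipartite statistics match their closed forms on tiny cases", {
  # one actor with two action ties: ASA = lam^2 ((1-1/lam)^2 - 1 + 2/lam) = 1
  X <- matrix(0L, 2, 2); X[1, ] <- 1L
  net <- multilevel_network(matrix(0L, 2, 2), matrix(0L, 2, 2), X, NULL,
                           c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_bipartite_X(net, config_spec("ASA", lambda = 2)), 1)

  # two actors sharing the same 2 variables: ACA = 2 (1 - 1/4) = 1.5
  X2 <- matrix(1L, 2, 2)
  net2 <- multilevel_network(matrix(0L, 2, 2), matrix(0L, 2, 2), X2, NULL,
                             c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_bipartite_X(net2, config_spec("ACA", lambda = 2)), 1.5)

  empty <- empty_mnet(3, 3)
  for (nm in c("DensityX", "ASA", "ASB", "ACA")) {
    expect_equal(z_bipartite_X(empty, config_spec(nm)), 0)
  }
})

test_that("cross-level statistics count the pictured minimal configurations", {
  # one actor acting on both endpoints of one CLD arc -> TXBX = 1
  B <- matrix(0L, 2, 2); B[1, 2] <- 1L
  X <- matrix(0L, 2, 2); X[1, ] <- 1L
  net <- multilevel_network(matrix(0L, 2, 2), B, X, NULL,
                            c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_interaction(net, config_spec("TXBX")), 1)

  # nominated actor working on a variable with one incoming CLD arc
  A <- matrix(0L, 2, 2); A[2, 1] <- 1L
  X2 <- matrix(0L, 2, 2); X2[1, 2] <- 1L
  net2 <- multilevel_network(A, B, X2, NULL, c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_interaction(net2, config_spec("L3AXBin")), 1)

  # entrainment joins a collaboration arc with B-adjacent action targets
  A3 <- matrix(0L, 2, 2); A3[1, 2] <- 1L
  X3 <- matrix(0L, 2, 2); X3[1, 1] <- 1L; X3[2, 2] <- 1L
  net3 <- multilevel_network(A3, B, X3, NULL, c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_interaction(net3, config_spec("C4AXBentrainment")), 1)
  expect_equal(z_interaction(net3, config_spec("C4AXBexchange")), 0)

  empty <- empty_mnet(3, 3)
  for (nm in c("ATXAX", "In2StarBX", "Out2StarBX", "TXBX",
               "L3XBXreciprocity", "L3AXBin", "C4AXBentrainment",
               "C4AXBexchange", "C4AXBreciprocity")) {
    expect_equal(z_interaction(empty, config_spec(nm)), 0)
  }
})

test_that("reciprocated B dyads under one actor contribute twice to TXBX", {
  B <- matrix(0L, 2, 2); B[1, 2] <- 1L; B[2, 1] <- 1L
  X <- matrix(0L, 2, 2); X[1, ] <- 1L
  net <- multilevel_network(matrix(0L, 2, 2), B, X, NULL,
                            c("m1", "m2"), c("v1", "v2"))
  expect_equal(z_interaction(net, config_spec("TXBX")), 2)
})

test_that("evaluate_statistics preserves order and equals per-spec calls", {
  set.seed(31)
  net <- rand_mnet(5, 4)
  nms <- community1_effects()
  v <- evaluate_statistics(net, spec_list(nms))
  expect_length(v, 17)
  expect_identical(names(v), nms)
  for (k in seq_along(nms)) {
    s <- config_spec(nms[k])
    single <- switch(s$level, A = z_within_A(net, s),
                     X = z_bipartite_X(net, s), z_interaction(net, s))
    expect_equal(unname(v[k]), single)
  }
})

test_that("unknown names and missing attributes are rejected", {
  expect_error(config_spec("Banana"), "unknown effect")
  expect_error(config_spec("AinS", lambda = 1), "lambda")
  net <- rand_mnet(4, 3, with_attrs = FALSE)
  expect_error(evaluate_statistics(net, list(config_spec("Edu_Match"))),
               "attribute")
})

test_that("missing attribute values never match", {
  A <- matrix(0L, 3, 3); A[1, 2] <- 1L; A[1, 3] <- 1L
  Y <- data.frame(actor = c("m1", "m2", "m3"),
                  org_type = c("gov", NA, "gov"))
  net <- multilevel_network(A, matrix(0L, 1, 1), matrix(0L, 3, 1), Y,
                            c("m1", "m2", "m3"), "v1")
  expect_equal(z_within_A(net, config_spec("Org_Match")), 1)
})

test_that("every catalogued statistic equals the brute-force oracle", {
  set.seed(202)
  for (rep in 1:25) {
    net <- rand_mnet(sample(3:6, 1), sample(2:6, 1),
                     pA = runif(1, 0.1, 0.6), pB = runif(1, 0.1, 0.6),
                     pX = runif(1, 0.1, 0.6))
    for (nm in all_effect_names()) {
      s <- config_spec(nm, lambda = sample(c(2, 3), 1))
      expect_equal(unname(evaluate_statistics(net, list(s))),
                   brute_force_count(net, s), tolerance = 1e-9,
                   label = nm)
    }
  }
})

test_that("the brute-force oracle refuses large networks and empty ones are zero", {
  expect_error(brute_force_count(rand_mnet(9, 3), config_spec("Density")),
               "n_A <= 8")
  empty <- empty_mnet(4, 4)
  for (nm in setdiff(all_effect_names(), c("Edu_Match", "Org_Match"))) {
    expect_equal(brute_force_count(empty, config_spec(nm)), 0, label = nm)
  }
})

test_that("change statistics equal full-evaluation differences", {
  set.seed(77)
  specs <- spec_list(all_effect_names())
  for (rep in 1:15) {
    net <- rand_mnet(5, 5)
    n_A <- 5; n_B <- 5
    for (k in 1:8) {
      if (runif(1) < 0.5) {
        layer <- "A"; i <- sample(n_A, 1); j <- sample(setdiff(1:n_A, i), 1)
      } else {
        layer <- "X"; i <- sample(n_A, 1); j <- sample(n_B, 1)
      }
      d <- change_statistics(net, layer, i, j, specs)
      on <- net; off <- net
      if (layer == "A") { on$A[i, j] <- 1L; off$A[i, j] <- 0L }
      else { on$X[i, j] <- 1L; off$X[i, j] <- 0L }
      full <- evaluate_statistics(on, specs) - evaluate_statistics(off, specs)
      expect_equal(d, full, tolerance = 1e-9)
    }
  }
})

test_that("simple change statistics have their closed values", {
  net <- arcs_mnet(4, list(c(2, 1)))
  d <- change_statistics(net, "A", 1, 2, spec_list(c("Density", "Reciprocity")))
  expect_equal(unname(d), c(1, 1))
  net0 <- arcs_mnet(4, list())
  d0 <- change_statistics(net0, "A", 1, 2, spec_list(c("Density", "Reciprocity")))
  expect_equal(unname(d0), c(1, 0))
  expect_error(change_statistics(net, "B", 1, 2, spec_list("Density")),
               "exogenous")
})

test_that("pure counting statistics never decrease when a tie is added", {
  set.seed(404)
  mono <- c("Density", "DensityX", "In2StarBX", "Out2StarBX", "TXBX",
            "L3AXBin")
  specs <- spec_list(mono)
  for (rep in 1:10) {
    net <- rand_mnet(5, 4)
    for (k in 1:6) {
      if (runif(1) < 0.5) {
        d <- change_statistics(net, "A", 1, sample(2:5, 1), specs)
      } else {
        d <- change_statistics(net, "X", sample(5, 1), sample(4, 1), specs)
      }
      expect_true(all(d >= 0))
    }
  }
})

test_that("statistics are invariant under node relabelling", {
  set.seed(88)
  specs <- spec_list(setdiff(all_effect_names(), c("Edu_Match", "Org_Match")))
  for (rep in 1:5) {
    net <- rand_mnet(6, 5, with_attrs = FALSE)
    pa <- sample(6); pv <- sample(5)
    perm <- multilevel_network(net$A[pa, pa], net$B[pv, pv],
                               net$X[pa, pv], NULL,
                               net$actors, net$variables)
    expect_equal(evaluate_statistics(perm, specs),
                 evaluate_statistics(net, specs), tolerance = 1e-9)
  }
})

test_that("the catalogue exports to JSON", {
  p <- file.path(withr::local_tempdir(), "catalogue.json")
  write_catalogue_json(path = p)
  j <- jsonlite::read_json(p)
  expect_length(j, 23)
  expect_equal(j[[1]]$name, "Density")
})
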