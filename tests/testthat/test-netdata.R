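test_that("constructor enforces the layer invariants", {
  expect_error(multilevel_network(matrix(0, 2, 2), matrix(0, 1, 1),
                                  matrix(0, 2, 1), NULL,
                                  c("m1", "m1"), "v1"),
               "unique")
  A <- matrix(0L, 2, 2); A[1, 1] <- 1L
  expect_error(multilevel_network(A, matrix(0, 1, 1), matrix(0, 2, 1),
                                  NULL, c("m1", "m2"), "v1"),
               "diagonal")
  expect_error(multilevel_network(matrix(2, 2, 2) - diag(2, 2),
                                  matrix(0, 1, 1), matrix(0, 2, 1),
                                  NULL, c("m1", "m2"), "v1"),
               "binary")
  expect_error(multilevel_network(matrix(0, 1, 1), matrix(0, 1, 1),
                                  matrix(0, 1, 1), NULL, "m1", "v1"),
               "2 actors")
})

write_edge_fixture <- function(lines,
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  p <- file.path(dir, "edges.tsv")
  writeLines(c("layer\tfrom\tto", lines), p)
  p
}

test_that("edge lists route records to the correct layer", {
  p <- write_edge_fixture(c("A\tm1\tm2", "B\tv1\tv2", "X\tm1\tv1"))
  net <- read_multilevel(p, actors = c("m1", "m2"),
                         variables = c("v1", "v2"))
  expect_equal(sum(net$A), 1)
  expect_equal(sum(net$B), 1)
  expect_equal(sum(net$X), 1)
  expect_equal(net$A["m1", "m2"], 1L)
  expect_equal(net$B["v1", "v2"], 1L)
  expect_equal(net$X["m1", "v1"], 1L)
})

test_that("an empty edge file over a registry gives zero matrices", {
  p <- write_edge_fixture(character())
  net <- read_multilevel(p, actors = c("m1", "m2", "m3"), variables = "v1")
  expect_equal(net$A, matrix(0L, 3, 3,
               dimnames = list(c("m1","m2","m3"), c("m1","m2","m3"))))
})

test_that("invalid records are rejected with informative errors", {
  p <- write_edge_fixture("A\tm1\tm1")
  expect_error(read_multilevel(p, actors = c("m1", "m2"), variables = "v1"),
               "self-loop in layer A.*m1")
  p2 <- write_edge_fixture("X\tm1\tv9")
  expect_error(read_multilevel(p2, actors = c("m1", "m2"), variables = "v1"),
               "unknown identifiers.*v9")
  p3 <- write_edge_fixture(c("A\tm1\tm2", "A\tm1\tm2"))
  expect_warning(net <- read_multilevel(p3, actors = c("m1", "m2"),
                                        variables = "v1"),
                 "duplicate")
  expect_equal(sum(net$A), 1)
})

test_that("write followed by read reproduces the network exactly", {
  set.seed(101)
  net <- rand_mnet(6, 4)
  dir <- withr::local_tempdir()
  write_multilevel(net, dir)
  back <- read_multilevel(file.path(dir, "edges.tsv"),
                          attr_path = file.path(dir, "attributes.csv"),
                          actors = readLines(file.path(dir, "actors.txt")),
                          variables = readLines(file.path(dir, "variables.txt")))
  expect_identical(back$A, net$A)
  expect_identical(back$B, net$B)
  expect_identical(back$X, net$X)
  expect_equal(back$Y, net$Y)
})

test_that("restriction to respondents reshapes A and X and keeps B", {
  set.seed(7)
  net <- rand_mnet(27, 5)
  resp <- net$actors[1:18]
  r <- restrict_to_respondents(net, resp)
  expect_equal(dim(r$A), c(18, 18))
  expect_equal(dim(r$X), c(18, 5))
  expect_identical(r$B, net$B)
  expect_identical(r$A, net$A[resp, resp])
  # idempotent
  r2 <- restrict_to_respondents(r, resp)
  expect_identical(r2$A, r$A)
  # identity
  expect_identical(restrict_to_respondents(net, net$actors)$A, net$A)
  expect_error(restrict_to_respondents(net, c(resp, "ghost")), "ghost")
  expect_error(restrict_to_respondents(net, character()), "non-empty")
})

test_that("descriptive summary mirrors the reported table layout", {
  net <- arcs_mnet(3, list(c(1, 2), c(1, 3), c(2, 3)))
  s <- descriptive_summary(net, invited = 3)
  expect_equal(s$outdegree$mean, 1)
  expect_equal(s$outdegree$min, 0)
  expect_equal(s$outdegree$max, 2)

  # survey of 27 with 18 respondents -> 67%
  set.seed(1)
  net18 <- rand_mnet(18, 5)
  s18 <- descriptive_summary(net18, invited = 27)
  expect_equal(s18$response_rate_percent, 67)
  expect_equal(descriptive_summary(rand_mnet(20, 5), 27)$response_rate_percent, 74)

  # 14 of 18 female -> 78%
  Y <- data.frame(actor = sprintf("m%02d", 1:18),
                  gender = rep(c("Female", "Male"), c(14, 4)))
  netg <- multilevel_network(matrix(0L, 18, 18), matrix(0L, 1, 1),
                             matrix(0L, 18, 1), Y,
                             sprintf("m%02d", 1:18), "v1")
  sg <- descriptive_summary(netg, 27)
  expect_equal(sg$attributes$gender$percent[sg$attributes$gender$category == "Female"], 78)

  expect_error(descriptive_summary(net, 0), "positive")
  expect_error(descriptive_summary(net18, 17), ">=")
})

test_that("summary equals brute-force recomputation on simulated data", {
  set.seed(55)
  net <- rand_mnet(10, 6)
  s <- descriptive_summary(net, invited = 12)
  expect_equal(s$outdegree$mean, mean(rowSums(net$A)))
  expect_equal(s$actions$max, max(rowSums(net$X)))
  expect_equal(s$n_cld_variables, 6)
  tab <- table(net$Y$education)
  expect_equal(s$attributes$education$n[match(names(tab), s$attributes$education$category)],
               as.integer(tab))
})
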