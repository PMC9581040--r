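# Tied parameter vector, DE optimizer, objectives and replicate summaries.

test_that("expandTied applies the tying scheme and round-trips", {
  laws <- referenceLaws()
  expect_equal(lawFor(laws, "G1", 0)@location, 7.11)
  expect_equal(lawFor(laws, "G1", 0)@scale, 0.18)
  expect_equal(lawFor(laws, "G1", 2)@location, 14.76)
  expect_equal(lawFor(laws, "G1", 2)@scale, 2.33)
  for (r in 0:3) {
    expect_equal(lawFor(laws, "M", r)@location, 1.69)
    expect_equal(lawFor(laws, "M", r)@scale, 0.1)
    expect_equal(lawFor(laws, "G2", r)@location, 4.84)
  }
  expect_equal(lawFor(laws, "S", 1)@shape, 0.68)

  # no round-0/later distinction when the entries coincide
  v <- c(5, 5, 6, 6, 4, 2, 0.5, 0.5, 0.7, 0.7)
  same <- expandTied(v)
  expect_identical(lawFor(same, "G1", 0), lawFor(same, "G1", 3))

  # flatten is the inverse of expand
  expect_identical(unname(flattenLaws(expandTied(v))), v)
  expect_equal(expandTied(flattenLaws(laws)), laws)

  # negative support endpoints are rejected
  expect_error(expandTied(c(1, 5, 6, 6, 4, 2, 8, 0.5, 0.7, 0.7)), "support")
})

test_that("parameterCount reflects the three tying schemes", {
  expect_identical(parameterCount("full"), 32L)
  expect_identical(parameterCount("sigma_fixed"), 24L)
  expect_identical(parameterCount("tied"), 10L)
  expect_error(parameterCount("other"))
})

test_that("differentialEvolution minimizes a smooth function reproducibly", {
  sphere <- function(x) sum((x - c(1, -2, 3))^2)
  r1 <- differentialEvolution(sphere, lower = rep(-5, 3), upper = rep(5, 3),
                              control = deControl(maxGen = 60, tol = 0),
                              seed = 42)
  expect_lt(r1$value, 1e-4)
  expect_equal(r1$par, c(1, -2, 3), tolerance = 1e-2)
  r2 <- differentialEvolution(sphere, lower = rep(-5, 3), upper = rep(5, 3),
                              control = deControl(maxGen = 60, tol = 0),
                              seed = 42)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$trace) <= 0))
})

test_that("the untreated objective is zero at the generating parameters", {
  v <- flattenLaws(fastLaws())
  cpf0 <- mixedCpf0()
  sched <- schedule(dT = 0.36, tEnd = 18, observationTimes = c(9, 18))
  exp <- makeUntreatedExp(v, cpf0, sched, simSeed = 500, nCells = 400)
  expect_identical(
    objectiveUntreated(v, exp, cpf0, simSeed = 500, nCells = 400,
                       sched = sched),
    0)
  # a different simulation seed leaves only sampling noise
  noise <- objectiveUntreated(v, exp, cpf0, simSeed = 501, nCells = 400,
                              sched = sched)
  expect_gt(noise, 0)
  expect_lt(noise, 500)  # well below any real misfit at 400 cells
  # out-of-bounds vectors receive the finite penalty
  bad <- v
  bad[1] <- 1000
  expect_identical(
    objectiveUntreated(bad, exp, cpf0, simSeed = 500, nCells = 400,
                       sched = sched),
    1e9)
})

test_that("objective evaluation does not perturb the caller's RNG stream", {
  v <- flattenLaws(fastLaws())
  cpf0 <- mixedCpf0()
  sched <- schedule(dT = 0.36, tEnd = 9, observationTimes = 9)
  exp <- makeUntreatedExp(v, cpf0, sched, simSeed = 1, nCells = 100)
  set.seed(99)
  a <- runif(3)
  set.seed(99)
  invisible(objectiveUntreated(v, exp, cpf0, simSeed = 1, nCells = 100,
                               sched = sched))
  b <- runif(3)
  expect_identical(a, b)
})

test_that("the treated objective is zero at the generating blocking", {
  laws <- fastLaws()
  cpf0 <- mixedCpf0()
  bTruth <- c(0.1, 0.5, 0, 0.8)
  ds <- generateTreatedDataset(laws, bTruth, cpf0 = cpf0, drugTime = 6,
                               observationTime = 12, nCells = 400,
                               noisePct = 0, seed = 77)
  od <- cpfData(ds@observations)
  exp12 <- cpfTable(od$time_h[od$time_h == 12], od$phase[od$time_h == 12],
                    od$division_round[od$time_h == 12],
                    od$cpf_percent[od$time_h == 12])
  expect_identical(
    objectiveTreated(bTruth, exp12, cpf0, laws, simSeed = 77, drugTime = 6,
                     nCells = 400),
    0)
  expect_identical(
    objectiveTreated(c(0.5, 0.5, 0.5, 1.5), exp12, cpf0, laws, simSeed = 77,
                     drugTime = 6, nCells = 400),
    1e9)
})

test_that("summarizeReplicates computes means, standard errors, quantiles", {
  fit <- summarizeReplicates(matrix(c(1, 2, 3), ncol = 1,
                                    dimnames = list(NULL, "x")))
  expect_equal(unname(fit@estimate), 2)
  expect_equal(unname(fit@stderr), stats::sd(1:3) / sqrt(3))
  expect_equal(unname(fit@quantiles[, "x"]), c(1.5, 2, 2.5))

  single <- summarizeReplicates(matrix(5, dimnames = list(NULL, "x")))
  expect_equal(unname(single@estimate), 5)
  expect_identical(unname(single@stderr), 0)

  # permutation invariance
  m <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  f1 <- summarizeReplicates(m)
  f2 <- summarizeReplicates(m[c(3, 1, 4, 2), ])
  expect_equal(f1@estimate, f2@estimate)
  expect_equal(f1@stderr, f2@stderr)
  expect_equal(f1@quantiles, f2@quantiles)
})

test_that("fitting is deterministic given the master seed", {
  laws <- fastLaws()
  cpf0 <- mixedCpf0()
  sched <- schedule(dT = 0.36, tEnd = 9, observationTimes = 9)
  v <- flattenLaws(laws)
  exp <- makeUntreatedExp(v, cpf0, sched, simSeed = 3, nCells = 150)
  ctl <- deControl(popSize = 2, maxGen = 2)
  f1 <- fitUntreated(exp, cpf0, control = ctl, nReplicates = 2,
                     nCells = 150, sched = sched, seed = 5)
  f2 <- fitUntreated(exp, cpf0, control = ctl, nReplicates = 2,
                     nCells = 150, sched = sched, seed = 5)
  expect_identical(f1@replicates, f2@replicates)
  expect_identical(f1@objectives, f2@objectives)
})

test_that("raising the true b_S visibly shifts the treated observable", {
  # identifiability sanity: more S blocking leaves more round->=1 mass in S
  laws <- fastLaws()
  cpf0 <- mixedCpf0()
  sInMass <- sapply(c(0, 0.45, 0.9), function(b) {
    ds <- generateTreatedDataset(laws, c(0, b, 0, 0), cpf0 = cpf0,
                                 drugTime = 6, observationTime = 12,
                                 nCells = 2000, noisePct = 0, seed = 123)
    od <- cpfData(ds@observations)
    sum(od$cpf_percent[od$time_h == 12 & od$phase == "S"])
  })
  expect_true(all(diff(sInMass) > 0))
})
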