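test_that("node strength matches hand summation and conserves total weight", {
  w <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  expect_equal(unname(nodeStrength(connectivityMatrix(w))), c(3, 4, 5))
  expect_equal(unname(nodeStrength(connectivityMatrix(matrix(0, 3, 3)))),
               c(0, 0, 0))
  set.seed(42)
  for (i in 1:20) {
    w <- randomGraph(sample(3:8, 1))
    s <- nodeStrength(connectivityMatrix(w))
    expect_equal(unname(s), oracleStrength(w))
    expect_equal(sum(s), 2 * sum(w[upper.tri(w)]))
  }
})

test_that("asymmetric or negative matrices are rejected", {
  w <- matrix(c(0, 1, 2, 0), 2)
  expect_error(connectivityMatrix(w), "symmetric")
  w <- matrix(c(0, -1, -1, 0), 2)
  expect_error(connectivityMatrix(w), "non-negative")
})

test_that("eigenvector centrality returns the Perron eigenpair", {
  # single edge: closed form (1, 1)/sqrt(2), lambda = 1
  ec <- eigenvectorCentrality(connectivityMatrix(matrix(c(0, 1, 1, 0), 2)))
  expect_equal(unname(ec$vector), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(ec$lambda, 1, tolerance = 1e-9)
  # complete unweighted K3: (1,1,1)/sqrt(3), lambda = 2
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  ec <- eigenvectorCentrality(connectivityMatrix(k3))
  expect_equal(unname(ec$vector), rep(1 / sqrt(3), 3), tolerance = 1e-9)
  expect_equal(ec$lambda, 2, tolerance = 1e-9)
})

test_that("eigenvector centrality satisfies its defining residual and matches a dense eigensolver", {
  set.seed(7)
  for (i in 1:20) {
    w <- randomConnectedGraph(sample(3:8, 1))
    c <- connectivityMatrix(w)
    ec <- eigenvectorCentrality(c, tol = 1e-10)
    expect_lte(max(abs(w %*% ec$vector - ec$lambda * ec$vector)), 1e-9)
    expect_gte(min(ec$vector), 0)
    expect_equal(sum(ec$vector^2), 1, tolerance = 1e-10)
    oe <- oracleEig(w)
    expect_equal(unname(ec$vector), oe$vector, tolerance = 1e-7)
    expect_equal(ec$lambda, oe$lambda, tolerance = 1e-8)
  }
})

test_that("eigenvector centrality errors on empty graphs and warns on disconnected ones", {
  expect_error(eigenvectorCentrality(connectivityMatrix(matrix(0, 3, 3))),
               "undefined")
  w <- matrix(0, 4, 4); w[1, 2] <- w[2, 1] <- 5; w[3, 4] <- w[4, 3] <- 1
  expect_warning(eigenvectorCentrality(connectivityMatrix(w)), "disconnected")
})

test_that("local efficiency handles complete and degenerate neighbourhoods", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(localEfficiency(connectivityMatrix(tri))), c(1, 1, 1))
  # path a-b-c: b's neighbours are mutually disconnected, a and c have a
  # single neighbour
  path <- matrix(0, 3, 3); path[1, 2] <- path[2, 1] <- 1
  path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(localEfficiency(connectivityMatrix(path))), c(0, 0, 0))
})

test_that("local efficiency matches the exhaustive shortest-path oracle on random graphs", {
  set.seed(11)
  for (i in 1:40) {
    w <- randomGraph(sample(4:8, 1), density = runif(1, 0.3, 0.9))
    eff <- localEfficiency(connectivityMatrix(w))
    expect_equal(unname(eff), oracleLocalEfficiency(w), tolerance = 1e-10)
    expect_true(all(eff >= 0 & eff <= 1))
  }
})

test_that("metrics respect scaling and permutation symmetries", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    w <- randomConnectedGraph(n)
    c1 <- connectivityMatrix(w)
    c2 <- connectivityMatrix(w * 3.7)
    expect_equal(unname(nodeStrength(c2)), 3.7 * unname(nodeStrength(c1)))
    expect_equal(unname(eigenvectorCentrality(c2)$vector),
                 unname(eigenvectorCentrality(c1)$vector), tolerance = 1e-8)
    expect_equal(unname(localEfficiency(c2)), unname(localEfficiency(c1)),
                 tolerance = 1e-12)
    p <- sample(n)
    cp <- connectivityMatrix(w[p, p])
    expect_equal(unname(nodeStrength(cp)), unname(nodeStrength(c1))[p])
    expect_equal(unname(localEfficiency(cp)),
                 unname(localEfficiency(c1))[p], tolerance = 1e-12)
    expect_equal(unname(eigenvectorCentrality(cp)$vector),
                 unname(eigenvectorCentrality(c1)$vector)[p],
                 tolerance = 1e-7)
  }
})

test_that("raw-length convention uses weights as link distances", {
  # two neighbours joined by weight w: inverse convention gives w/wmax = 1
  # (single strongest link), raw gives 1/w
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 4; w[1, 3] <- w[3, 1] <- 4; w[2, 3] <- w[3, 2] <- 2
  inv <- localEfficiency(connectivityMatrix(w), lengths = "inverse")
  raw <- localEfficiency(connectivityMatrix(w), lengths = "raw")
  # node 1's neighbours {2,3} connect by weight 2: inverse length 4/2 = 2,
  # raw length 2
  expect_equal(unname(inv)[1], 1 / 2)
  expect_equal(unname(raw)[1], 1 / 2)
  # node 2's neighbours {1,3} connect by weight 4: inverse length 1, raw 4
  expect_equal(unname(inv)[2], 1)
  expect_equal(unname(raw)[2], 1 / 4)
})
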