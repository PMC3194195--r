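test_that("shell counts match the hand-built three-residue case", {
  st <- toy_structure(list(
    list(type = "GLY", atoms = c(3, 0, 0)),
    list(type = "ALA", atoms = c(0, 0, 0)),        # center
    list(type = "LYS", atoms = rbind(c(10, 0, 0), c(10, 1, 0)))
  ))
  counts <- shell_residue_counts(st, 2, radius = 6)
  expect_equal(unname(counts["GLY"]), 1L)
  expect_equal(sum(counts), 1L)

  single <- toy_structure(list(list(type = "TRP", atoms = c(0, 0, 0))))
  expect_equal(sum(shell_residue_counts(single, 1)), 0L)

  expect_equal(sum(shell_residue_counts(st, 2, radius = 0)), 0L)
})

test_that("shell counts equal a brute-force all-pairs scan on random structures", {
  for (s in 1:100) {
    st <- random_toy_structure(n = sample(4:12, 1), seed = s)
    center <- sample(st$residues$ordinal, 1)
    radius <- runif(1, 2, 10)
    expect_identical(shell_residue_counts(st, center, radius),
                     brute_shell_counts(st, center, radius))
  }
})

test_that("shell counts are non-decreasing in radius", {
  st <- random_toy_structure(10, seed = 123)
  prev <- shell_residue_counts(st, 3, radius = 1)
  for (r in c(3, 5, 8, 12)) {
    cur <- shell_residue_counts(st, 3, radius = r)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("contact partners use the same shell rule as the histogram", {
  st <- toy_structure(list(
    list(type = "GLY", atoms = c(3, 0, 0)),
    list(type = "ALA", atoms = c(0, 0, 0)),
    list(type = "LYS", atoms = c(10, 0, 0))
  ))
  cp <- contact_partners(st, 2)
  expect_equal(cp$center, "ALA")
  expect_equal(cp$partners, "GLY")

  single <- toy_structure(list(list(type = "TRP", atoms = c(0, 0, 0))))
  expect_length(contact_partners(single, 1)$partners, 0L)

  for (s in 1:20) {
    st <- random_toy_structure(8, seed = 500 + s)
    cp <- contact_partners(st, 1, radius = 7)
    cnt <- shell_residue_counts(st, 1, radius = 7)
    expect_equal(length(cp$partners), sum(cnt))
    expect_equal(as.integer(table(factor(cp$partners, aa_order()))),
                 unname(as.integer(cnt)))
  }
})

test_that("isolated-atom SASA matches the analytic sphere area within 1%", {
  st <- toy_structure(list(list(type = "GLY", atoms = c(0, 0, 0))))
  s <- compute_sasa(st, probe = 1.4, n_points = 960)
  analytic <- 4 * pi * (1.7 + 1.4)^2
  expect_lt(abs(s$residue_asa[["1"]] - analytic) / analytic, 0.01)
})

test_that("an atom caged by overlapping neighbours has zero accessible area", {
  # surround the centre atom with a shell of atoms dense enough that every
  # quadrature point on the expanded sphere is inside a neighbour
  dirs <- sap3d:::.sphere_points(42)
  cage <- lapply(seq_len(nrow(dirs)), function(i)
    list(type = "GLY", atoms = 2.0 * dirs[i, , drop = FALSE]))
  st <- toy_structure(c(list(list(type = "ALA", atoms = c(0, 0, 0))), cage))
  s <- compute_sasa(st, n_points = 960)
  expect_equal(unname(s$residue_asa["1"]), 0)
  # brute-force confirmation: every point on the centre's expanded sphere
  # is within a neighbour's expanded radius
  pts <- sap3d:::.sphere_points(960) * 3.1
  centers <- 2.0 * dirs
  covered <- vapply(seq_len(nrow(pts)), function(i) {
    d2 <- rowSums((centers - matrix(pts[i, ], nrow(centers), 3,
                                    byrow = TRUE))^2)
    any(d2 <= 3.1^2)
  }, logical(1))
  expect_true(all(covered))
})

test_that("occlusion only removes area: two-atom systems", {
  iso <- 4 * pi * (1.7 + 1.4)^2
  set.seed(99)
  for (i in 1:50) {
    d <- runif(1, 0.5, 8)
    st <- toy_structure(list(list(type = "GLY", atoms = c(0, 0, 0)),
                             list(type = "GLY", atoms = c(d, 0, 0))))
    s <- compute_sasa(st, n_points = 240)
    expect_lte(s$residue_asa[["1"]], iso * 1.005)
    expect_lte(s$residue_asa[["2"]], iso * 1.005)
    if (d > 2 * 3.1) expect_equal(unname(s$residue_asa["1"]), iso,
                                  tolerance = 0.01)
  }
})

test_that("SASA converges when the quadrature is refined", {
  # doubling the default point count moves exposed residues < 2% and
  # near-buried ones < 1 A^2 (a single grid point is ~0.13 A^2, so tiny
  # areas can only converge in absolute terms)
  for (s in c(5, 17)) {
    st <- make_structure(40, "globule", seed = s)
    a1 <- compute_sasa(st, n_points = 960)$residue_asa
    a2 <- compute_sasa(st, n_points = 1920)$residue_asa
    exposed <- a2 > 25
    rel <- abs(a1[exposed] - a2[exposed]) / a2[exposed]
    expect_lt(mean(rel), 0.01)
    expect_lt(max(rel), 0.03)
    expect_true(all(abs(a1[!exposed] - a2[!exposed]) < 1))
  }
})

test_that("relative accessibility normalises and clips correctly", {
  expect_equal(relative_sasa(0, "ALA"), 0)
  expect_equal(relative_sasa(max_asa_table()[["ALA"]], "ALA"), 100)
  expect_equal(relative_sasa(max_asa_table()[["GLY"]] / 2, "GLY"), 50)
  expect_equal(relative_sasa(1e6, "TRP"), 100)  # clipped
})

test_that("an extended residue is more exposed than one buried in a cluster", {
  tri <- toy_structure(list(
    list(type = "GLY", atoms = c(-3.8, 0, 0)),
    list(type = "ALA", atoms = c(0, 0, 0)),
    list(type = "GLY", atoms = c(3.8, 0, 0))
  ))
  rsa_ext <- rsa_profile(tri, n_points = 480)[["2"]]
  clu <- make_structure(60, "globule", seed = 31)
  rsa_core <- min(rsa_profile(clu, n_points = 480))
  expect_gt(rsa_ext, rsa_core)
})

test_that("structure_environment is 21 elements: counts then RSA", {
  st <- random_toy_structure(6, seed = 7)
  env <- structure_environment(st, 1, rsa = 42.5)
  expect_length(env, 21L)
  expect_equal(unname(env[21]), 42.5)
  expect_equal(names(env)[21], "RSA")
  expect_equal(unname(env[1:20]),
               unname(as.numeric(shell_residue_counts(st, 1))))
})
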