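test_that("mass schemes follow their defining formulas", {
  expect_equal(assign_masses(3, "mass_unit")$masses, c(1, 1, 1))
  expect_equal(assign_masses(3, "mass_TSS", tss_counts = c(0, 3, 0))$masses,
               c(1, 4, 1))
  expect_equal(assign_masses(2, "mass_or", tss_counts = c(1, 0),
                             h3k4me3_counts = c(0, 0),
                             polii_counts = c(0, 2))$masses, c(2, 2))
  expect_equal(assign_masses(2, "mass_and", tss_counts = c(1, 0),
                             h3k4me3_counts = c(0, 0),
                             polii_counts = c(0, 2))$masses, c(2, 3))
  expect_error(assign_masses(2, "mass_TSS"), "tss_counts")
  expect_error(assign_masses(2, "mass_or", tss_counts = c(1, 0)),
               "h3k4me3_counts")
  mv <- assign_masses(3, "mass_TSS", tss_counts = c(2, 0, 1))
  expect_equal(mv$total_mass, 6)
  expect_true(all(mv$masses >= 1))
})

test_that("center of mass is the weighted mean and satisfies its identity", {
  s <- structure3d(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(s), c(1, 0, 0))
  mv <- assign_masses(2, "mass_TSS", tss_counts = c(2, 0))  # masses 3, 1
  expect_equal(center_of_mass(s, mv), c(0.5, 0, 0))

  set.seed(5)
  sr <- structure3d(matrix(rnorm(36), 12, 3))
  mvr <- assign_masses(12, "mass_TSS", tss_counts = rpois(12, 2))
  rc <- center_of_mass(sr, mvr)
  residual <- colSums(mvr$masses * sweep(sr$coords, 2, rc))
  expect_lt(max(abs(residual)), 1e-9)
})

test_that("radius of gyration matches closed forms and the direct oracle", {
  two <- structure3d(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(radius_of_gyration(two), 3 / 2)

  s <- 2.5
  square <- structure3d(cbind(c(0, s, s, 0), c(0, 0, s, s), 0))
  expect_equal(radius_of_gyration(square), s / sqrt(2))

  set.seed(8)
  cloud <- structure3d(matrix(rnorm(60), 20, 3))
  oracle <- sqrt(mean(rowSums(
    sweep(cloud$coords, 2, colMeans(cloud$coords))^2)))
  expect_equal(radius_of_gyration(cloud), oracle, tolerance = 1e-12)

  # all-zero TSS counts reduce mass_TSS to mass_unit
  mv0 <- assign_masses(20, "mass_TSS", tss_counts = rep(0, 20))
  expect_equal(radius_of_gyration(cloud, mv0), radius_of_gyration(cloud),
               tolerance = 1e-12)

  # invariance under rigid motion, linearity under scaling
  th <- 0.8
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- structure3d(cloud$coords %*% rot + 5)
  expect_equal(radius_of_gyration(moved), radius_of_gyration(cloud),
               tolerance = 1e-9)
  expect_equal(radius_of_gyration(structure3d(3 * cloud$coords)),
               3 * radius_of_gyration(cloud), tolerance = 1e-9)

  # length-normalized variant divides total mass by n
  expect_equal(radius_of_gyration(cloud, length_normalized = TRUE),
               sqrt(20) * radius_of_gyration(cloud), tolerance = 1e-9)
})

test_that("iterated line graphs of a path shrink by one node per level", {
  g <- bead_chain_graph(5)
  l1 <- line_graph(g)
  expect_equal(nrow(l1$adjacency), 4)
  # L(P5) = P4: degree sequence 1,2,2,1 and connected in order
  expect_equal(sort(rowSums(l1$adjacency)), c(1, 1, 2, 2))
  l3 <- line_graph(line_graph(l1))
  expect_equal(nrow(l3$adjacency), 2)
  expect_equal(sum(l3$adjacency) / 2, 1)  # n - 4 = 1 edge

  # label tuples track the beads each node spans
  expect_equal(l1$node_labels[[1]], c(1, 2))
  expect_equal(l3$node_labels[[1]], 1:4)

  # P4 -> P1 after three applications: single node, no edges
  p1 <- line_graph(line_graph(line_graph(bead_chain_graph(4))))
  expect_equal(nrow(p1$adjacency), 1)
  expect_equal(sum(p1$adjacency), 0)
  expect_error(line_graph(p1), "3 times|no edges|no line graph")

  # triangle is a fixed point of the line-graph map
  tri <- structure(list(level = 0L,
                        adjacency = matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3),
                        node_labels = as.list(1:3)),
                   class = "line_graph_chain")
  lt <- line_graph(tri)
  expect_equal(nrow(lt$adjacency), 3)
  expect_equal(lt$adjacency, matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))

  # path property at larger n: L3(Pn) has n-3 nodes and n-4 edges
  for (n in c(6, 9, 12)) {
    l3n <- line_graph(line_graph(line_graph(bead_chain_graph(n))))
    expect_equal(nrow(l3n$adjacency), n - 3)
    expect_equal(sum(l3n$adjacency) / 2, n - 4)
  }
})

test_that("dihedral angles follow the unsigned plane-normal convention", {
  # right-angle staircase
  s <- structure3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(dihedral_angles(s), pi / 2)

  # planar zigzag chain: all angles pi (trans)
  zig <- structure3d(cbind(0:5, rep(c(0, 1), 3), 0))
  expect_equal(dihedral_angles(zig), rep(pi, 3), tolerance = 1e-9)

  # regular helix: all dihedrals equal
  hel <- make_structure(helix_spec(n_beads = 10))
  ang <- dihedral_angles(hel)
  expect_equal(max(ang) - min(ang), 0, tolerance = 1e-9)

  lin <- structure3d(cbind(0:3, 0, 0))
  expect_error(dihedral_angles(lin), "collinear")
})

test_that("folding degree matches closed forms and an eigen oracle", {
  # n = 4: single node, S = [phi], degree = exp(phi)
  s4 <- structure3d(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)))
  expect_equal(as.numeric(folding_degree(s4)), exp(pi / 2), tolerance = 1e-12)

  # n = 5: 2x2 closed form from the quadratic
  set.seed(3)
  s5 <- make_structure(random_walk_spec(5, seed = 13))
  phi <- dihedral_angles(s5)
  tr <- phi[1] + phi[2]
  disc <- sqrt((phi[1] - phi[2])^2 + 4)
  lam <- c((tr + disc) / 2, (tr - disc) / 2)
  expect_equal(as.numeric(folding_degree(s5)), mean(exp(lam)),
               tolerance = 1e-12)

  # characteristic-polynomial root oracle for n <= 12
  for (n in c(6, 8, 12)) {
    sr <- make_structure(random_walk_spec(n, seed = n))
    phis <- dihedral_angles(sr)
    m <- n - 3
    adj <- matrix(0, m, m)
    idx <- seq_len(m - 1)
    adj[cbind(idx, idx + 1)] <- adj[cbind(idx + 1, idx)] <- 1
    s_mat <- adj + diag(phis, m)
    # independent eigen oracle: roots of det(S - x I) located by sign
    # changes of the determinant over a fine grid + uniroot refinement
    detf <- function(x) det(s_mat - diag(x, m))
    grid <- seq(min(diag(s_mat)) - 3, max(diag(s_mat)) + 3, length.out = 4000)
    vals <- vapply(grid, detf, numeric(1))
    roots <- c()
    for (k in seq_len(length(grid) - 1)) {
      if (sign(vals[k]) != sign(vals[k + 1])) {
        roots <- c(roots, uniroot(detf, c(grid[k], grid[k + 1]),
                                  tol = 1e-12)$root)
      }
    }
    expect_length(roots, m)
    expect_equal(as.numeric(folding_degree(sr)), mean(exp(roots)),
                 tolerance = 1e-9)
    expect_equal(attr(folding_degree(sr), "estrada_sum"),
                 sum(exp(roots)), tolerance = 1e-9)
  }
})

test_that("contact-decay exponent recovers planted power laws", {
  expect_equal(exponent_parameter(make_power_law_matrix(20, 1, 1)), 1,
               tolerance = 1e-9)
  expect_equal(exponent_parameter(make_power_law_matrix(20, 1.2, 5)), 1.2,
               tolerance = 1e-9)
  # constant off-diagonal -> flat decay
  expect_equal(exponent_parameter(make_power_law_matrix(10, 0, 3)), 0,
               tolerance = 1e-12)
  # noise tolerance: 5% lognormal noise moves the estimate < 0.05
  pm <- make_power_law_matrix(40, 1.1, 2)
  set.seed(21)
  up <- upper.tri(pm$counts)
  noisy <- pm$counts
  noisy[up] <- noisy[up] * rlnorm(sum(up), 0, 0.05)
  noisy[lower.tri(noisy)] <- t(noisy)[lower.tri(noisy)]
  est <- exponent_parameter(contact_matrix(noisy))
  expect_lt(abs(est - 1.1), 0.05)

  tiny <- contact_matrix(matrix(0, 4, 4))
  expect_error(exponent_parameter(tiny), "insufficient decay range")
})

test_that("structure_metrics assembles a per-TAD table", {
  specs <- list(helix_spec(8), helix_spec(10, radius = 2))
  structs <- lapply(specs, make_structure)
  mats <- lapply(structs, structure_to_contacts)
  tab <- structure_metrics(structs, mats, ids = c("a", "b"))
  expect_equal(tab$tad_id, c("a", "b"))
  expect_equal(tab$n_beads, c(8, 10))
  expect_true(all(tab$rg > 0))
  expect_true(all(is.finite(tab$folding_degree)))
  expect_equal(tab$mass_scheme, rep("mass_unit", 2))
})
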