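make_two_bead_model <- function(c01 = 1) {
  m <- matrix(0, 2, 2)
  m[1, 2] <- m[2, 1] <- c01
  contacts_to_distances(contact_matrix(m))
}

test_that("objective values match hand computations", {
  # single C1 pair at distance 2 with delta 1: eq2 = (2-1)^2/1^2 = 1
  tm <- make_two_bead_model(1)
  coords <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(objective_value(coords, tm, mds_config("eq2")), 1)

  # perfect fit -> 0
  perfect <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_equal(objective_value(perfect, tm, mds_config("eq2")), 0)

  # 3 beads on a line, C1 = {(1,2),(2,3)} delta 1, C2 = {(1,3)}, R scalar 1:
  # eq4 = 0 + (2-1)^2/1^2 = 1
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1
  m[2, 3] <- m[3, 2] <- 1
  tm3 <- contacts_to_distances(contact_matrix(m))
  tm3$r_scalar <- 1
  line <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(objective_value(line, tm3, mds_config("eq4-max")), 1)

  # same configuration under eq3: 0 - gamma * 2^2
  expect_equal(objective_value(line, tm3, mds_config("eq3", gamma = 0.01)),
               -0.01 * 4)

  # eq3 divides C1 misfit by delta, not delta^2
  m2 <- matrix(0, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 8   # delta 0.5
  m2[2, 3] <- m2[3, 2] <- 8
  tmh <- contacts_to_distances(contact_matrix(m2))
  xs <- cbind(c(0, 1, 2), 0, 0)
  expect_equal(objective_value(xs, tmh, mds_config("eq3", gamma = 0)),
               2 * (1 - 0.5)^2 / 0.5 + 0)  # plus empty... C2={(1,3)} gamma 0
})

test_that("eq4 needs its R field and eq3 rejects contact-free beads", {
  tm <- make_two_bead_model()
  expect_error(objective_value(rbind(c(0, 0, 0), c(1, 0, 0)), tm,
                               mds_config("eq4-max")), "max_distance_r")
  expect_error(objective_value(rbind(c(0, 0, 0), c(1, 0, 0)), tm,
                               mds_config("eq4-shortest")), "shortest_path_r")
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 1  # bead 3 has no contacts
  tm3 <- contacts_to_distances(contact_matrix(m))
  x <- matrix(rnorm(9), 3, 3)
  expect_error(objective_value(x, tm3, mds_config("eq3")), "unbounded")
})

test_that("analytic gradients match finite differences for all objectives", {
  cm <- noisy_fixture(n = 5, seed = 3, dropout = 0.3)
  tm <- max_distance_r(shortest_path_r(contacts_to_distances(cm)))
  set.seed(11)
  for (obj in c("eq2", "eq3", "eq4-shortest", "eq4-max")) {
    cfg <- mds_config(obj, seed = 1)
    for (rep in 1:2) {
      x <- matrix(rnorm(15), 5, 3)
      g <- objective_gradient(x, tm, cfg)
      fd <- fd_gradient(x, tm, cfg)
      expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
    }
  }
})

test_that("gradient vanishes at a perfect fit and is translation invariant", {
  truth <- make_structure(helix_spec(n_beads = 8))
  cm <- structure_to_contacts(truth)
  tm <- contacts_to_distances(cm)
  cfg <- mds_config("eq2")
  g0 <- objective_gradient(truth$coords, tm, cfg)
  expect_lt(max(abs(g0)), 1e-9)

  x <- matrix(rnorm(24), 8, 3)
  shift <- matrix(rep(c(3, -1, 2), each = 8), 8, 3)
  expect_equal(objective_value(x, tm, cfg),
               objective_value(x + shift, tm, cfg))
  expect_equal(objective_gradient(x, tm, cfg),
               objective_gradient(x + shift, tm, cfg), tolerance = 1e-9)
})

test_that("objectives are rotation invariant but scale variant off-optimum", {
  cm <- noisy_fixture(n = 6, seed = 5, dropout = 0.2)
  tm <- max_distance_r(contacts_to_distances(cm))
  cfg <- mds_config("eq4-max")
  x <- matrix(rnorm(18), 6, 3)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(objective_value(x %*% rot, tm, cfg),
               objective_value(x, tm, cfg), tolerance = 1e-12)
  expect_gt(abs(objective_value(2 * x, tm, cfg) -
                  objective_value(x, tm, cfg)), 1e-6)
})

test_that("two-bead reconstruction hits the closed-form distance", {
  m <- matrix(0, 2, 2)
  m[1, 2] <- m[2, 1] <- 8
  fit <- reconstruct(contact_matrix(m), mds_config("eq2", seed = 3))
  d <- pairwise_distances(fit)[1, 2]
  expect_equal(d, 0.5, tolerance = 1e-6)
})

test_that("noiseless helix contacts are recovered and runs are deterministic", {
  truth <- make_structure(helix_spec(n_beads = 25))
  cm <- structure_to_contacts(truth)
  fit <- reconstruct(cm, mds_config("eq2", seed = 7))
  expect_lt(fit$provenance$value, 1e-6)
  tm <- contacts_to_distances(cm)
  ev <- evaluate_reconstruction(fit, tm, cm)
  expect_gt(ev$pearson_c1, 0.999)
  expect_lt(recovery_rmsd(fit, truth), 1e-2)

  fit2 <- reconstruct(cm, mds_config("eq2", seed = 7))
  expect_equal(fit$coords, fit2$coords, tolerance = 1e-12)

  expect_error(reconstruct(contact_matrix(matrix(0, 3, 3))), "no contacts")
})

test_that("evaluation report matches a hand-computed 4-bead instance", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 8    # delta 0.5
  m[2, 3] <- m[3, 2] <- 1    # delta 1
  m[3, 4] <- m[4, 3] <- 0.125  # delta 2
  cm <- contact_matrix(m)
  tm <- contacts_to_distances(cm)
  s <- structure3d(cbind(c(0, 1, 2, 3), 0, 0))  # consecutive distances all 1
  ev <- evaluate_reconstruction(s, tm, cm)
  d_c1 <- c(1, 1, 1)
  delta_c1 <- c(0.5, 1, 2)
  expect_equal(ev$rmse_c1, sqrt(mean((d_c1 - delta_c1)^2)))
  expect_true(is.na(ev$pearson_c1))  # zero variance in d -> cor undefined -> NA
  expect_equal(ev$n_c1, 3)
  expect_equal(ev$n_c2, 3)
  expect_equal(ev$c2_min, 2)   # distances 2, 2, 3 for pairs (1,3),(2,4),(1,4)
  expect_equal(ev$c2_median, 2)
  expect_equal(ev$c2_max, 3)

  # perfect-fit structure: pearson 1, rmse 0, and spearman(d, c) negative
  truth <- make_structure(helix_spec(n_beads = 10))
  cmt <- structure_to_contacts(truth)
  tmt <- contacts_to_distances(cmt)
  evt <- evaluate_reconstruction(truth, tmt, cmt)
  expect_equal(evt$pearson_c1, 1)
  expect_equal(evt$rmse_c1, 0, tolerance = 1e-12)
  expect_lt(evt$spearman_c1, 0)
})

test_that("eq4-max places zero-contact pairs farther than eq4-shortest", {
  truth <- make_structure(helix_spec(n_beads = 40))
  cm <- structure_to_contacts(truth, dropout_rate = 0.2, seed = 5)
  tm <- contacts_to_distances(cm)
  fmax <- reconstruct(cm, mds_config("eq4-max", seed = 11))
  fsp <- reconstruct(cm, mds_config("eq4-shortest", seed = 11))
  med_max <- evaluate_reconstruction(fmax, max_distance_r(tm), cm)$c2_median
  med_sp <- evaluate_reconstruction(fsp, shortest_path_r(tm), cm)$c2_median
  expect_gte(med_max, med_sp)
})

test_that("glance and tidy expose provenance and per-bead coordinates", {
  truth <- make_structure(helix_spec(n_beads = 6))
  cm <- structure_to_contacts(truth)
  fit <- reconstruct(cm, mds_config("eq2", seed = 2, n_restarts = 2))
  g <- glance(fit)
  expect_equal(g$objective, "eq2")
  expect_equal(g$n_beads, 6)
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_equal(td$end - td$start, rep(40000, 6))
})
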