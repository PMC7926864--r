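test_that("contacts are pairs strictly within the cutoff", {
  two <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(0, 5), y = 0, z = 0))
  net <- build_network(two, rc = 9)
  expect_equal(nrow(net$contacts), 1)
  expect_equal(net$contacts$d0, 5)
  far <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(0, 9.5), y = 0, z = 0))
  expect_equal(nrow(build_network(far, rc = 9)$contacts), 0)
  atcut <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                      x = c(0, 9), y = 0, z = 0))
  expect_equal(nrow(build_network(atcut, rc = 9)$contacts), 0)  # strict <
})

test_that("contact list matches a brute-force all-pairs distance check", {
  model <- make_chain(50, jitter = 0.5, seed = 31)
  net <- build_network(model, rc = 9)
  xyz <- coords(model)
  expected <- list()
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d < 9) expected[[length(expected) + 1]] <- c(i, j, d)
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(net$contacts), nrow(expected))
  expect_equal(as.matrix(net$contacts), expected, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("coincident nodes are rejected", {
  bad <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(1, 1), y = 2, z = 3))
  expect_error(build_network(bad), "coincident")
})

test_that("two-node Hessian has the closed-form block structure", {
  two <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(0, 5), y = 0, z = 0))
  H <- build_hessian(build_network(two, rc = 9, gamma = 1))
  xx <- H[c(1, 4), c(1, 4)]
  expect_equal(xx, matrix(c(1, -1, -1, 1), 2), ignore_attr = TRUE)
  H_no_xx <- H; H_no_xx[c(1, 4), c(1, 4)] <- 0
  expect_equal(max(abs(H_no_xx)), 0)
})

test_that("Hessian block rows sum to zero (translation invariance)", {
  f <- coil_fixture()
  n <- n_nodes(f$model)
  for (i in seq_len(n)) {
    rows <- (3 * i - 2):(3 * i)
    blocksum <- matrix(0, 3, 3)
    for (j in seq_len(n))
      blocksum <- blocksum + f$H[rows, (3 * j - 2):(3 * j)]
    expect_lt(max(abs(blocksum)), 1e-12)
  }
})

test_that("Hessian equals central finite differences of the network energy", {
  f <- coil_fixture()
  xyz0 <- coords(f$model)
  n3 <- 3 * n_nodes(f$model)
  h <- 1e-4
  bump <- function(k, amount) {
    x <- xyz0
    x[ceiling(k / 3), ((k - 1) %% 3) + 1] <- x[ceiling(k / 3), ((k - 1) %% 3) + 1] + amount
    x
  }
  fd <- matrix(0, n3, n3)
  for (k in seq_len(n3)) for (l in k:n3) {
    if (k == l) {
      val <- (enm_energy(f$net, bump(k, h)) - 2 * enm_energy(f$net, xyz0) +
                enm_energy(f$net, bump(k, -h))) / h^2
    } else {
      xpp <- bump(k, h); xpp[ceiling(l / 3), ((l - 1) %% 3) + 1] <-
        xpp[ceiling(l / 3), ((l - 1) %% 3) + 1] + h
      xpm <- bump(k, h); xpm[ceiling(l / 3), ((l - 1) %% 3) + 1] <-
        xpm[ceiling(l / 3), ((l - 1) %% 3) + 1] - h
      xmp <- bump(k, -h); xmp[ceiling(l / 3), ((l - 1) %% 3) + 1] <-
        xmp[ceiling(l / 3), ((l - 1) %% 3) + 1] + h
      xmm <- bump(k, -h); xmm[ceiling(l / 3), ((l - 1) %% 3) + 1] <-
        xmm[ceiling(l / 3), ((l - 1) %% 3) + 1] - h
      val <- (enm_energy(f$net, xpp) - enm_energy(f$net, xpm) -
                enm_energy(f$net, xmp) + enm_energy(f$net, xmm)) / (4 * h^2)
    }
    fd[k, l] <- val; fd[l, k] <- val
  }
  expect_lt(max(abs(fd - f$H)), 1e-5)
})

test_that("two connected nodes have a single nonzero eigenvalue equal to 2*gamma", {
  two <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(0, 5), y = 0, z = 0))
  for (g in c(1, 2.5)) {
    m <- suppressWarnings(compute_modes(build_hessian(build_network(two, 9, g))))
    nz <- m$values[m$values > 1e-8 * max(m$values)]
    expect_equal(length(nz), 1)
    expect_equal(nz, 2 * g, tolerance = 1e-12)
  }
})

test_that("a connected cluster has exactly six zero modes; disjoint clusters twelve", {
  tet <- structure_model(data.frame(
    chain = "A", resno = 1:4, resname = "ALA",
    x = c(0, 3.8, 1.9, 1.9), y = c(0, 0, 3.29, 1.1),
    z = c(0, 0, 0, 3.1)))
  m <- compute_modes(build_hessian(build_network(tet)))
  expect_equal(m$n_zero, 6)
  expect_length(m$warnings, 0)
  apart <- tet
  apart2 <- tet$nodes; apart2$x <- apart2$x + 50; apart2$chain <- "B"
  both <- structure_model(rbind(tet$nodes, apart2))
  expect_warning(m2 <- compute_modes(build_hessian(build_network(both))),
                 "disconnected")
  expect_equal(m2$n_zero, 12)
  expect_match(m2$warnings, "disconnected")
})

test_that("mode sets are orthonormal with eigenvalues reproduced by Rayleigh quotients", {
  f <- coil_fixture()
  gram <- crossprod(f$modes$vectors)
  expect_lt(max(abs(gram - diag(nrow(gram)))), 1e-8)
  expect_true(all(f$modes$values >= -1e-8 * max(f$modes$values)))
  rq <- colSums(f$modes$vectors * (f$H %*% f$modes$vectors))
  nz <- nonzero_modes(f$modes)
  expect_equal(rq[nz], f$modes$values[nz],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(compute_modes(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("reference energy is zero and zero-mode excursions cost nothing", {
  f <- coil_fixture()
  expect_lt(abs(enm_energy(f$net)), 1e-20)
  xyz0 <- coords(f$model)
  for (k in seq_len(f$modes$n_zero)) {
    q <- matrix(f$modes$vectors[, k], ncol = 3, byrow = TRUE)
    expect_lt(enm_energy(f$net, xyz0 + 1e-3 * q), 1e-12 * f$net$gamma)
  }
})

test_that("the spectrum is invariant under global rotation and scales with gamma", {
  f <- coil_fixture()
  rotated <- apply_transform(f$model, random_rotation(41), c(2, 3, 4))
  m_rot <- compute_modes(build_hessian(build_network(rotated, 9, 1)))
  expect_equal(m_rot$values, f$modes$values, tolerance = 1e-8)
  m2 <- compute_modes(build_hessian(build_network(f$model, 9, 2)))
  expect_equal(m2$values, 2 * f$modes$values, tolerance = 1e-8)
  nz <- nonzero_modes(f$modes)
  dots <- abs(colSums(m2$vectors[, nz] * f$modes$vectors[, nz]))
  expect_equal(dots, rep(1, length(nz)), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("mode B-factors match the Hessian pseudo-inverse per-node trace", {
  f <- coil_fixture()
  b <- calc_bfactors(f$modes)
  expect_equal(mean(b), 1)
  g <- MASS::ginv(f$H)
  tr <- vapply(seq_len(n_nodes(f$model)), function(i)
    sum(diag(g[(3 * i - 2):(3 * i), (3 * i - 2):(3 * i)])), numeric(1))
  expect_equal(b, tr / mean(tr), tolerance = 1e-6)
})

test_that("chain termini fluctuate more than the interior", {
  model <- helix_model(20, seed = 17)
  m <- compute_modes(build_hessian(build_network(model, 9, 1)))
  b <- calc_bfactors(m)
  expect_gt(b[1], max(b[8:13]))
  expect_gt(b[20], max(b[8:13]))
  two <- structure_model(data.frame(chain = "A", resno = 1:2, resname = "ALA",
                                    x = c(0, 5), y = 0, z = 0))
  b2 <- calc_bfactors(suppressWarnings(
    compute_modes(build_hessian(build_network(two)))))
  expect_equal(b2[1], b2[2])
})

test_that("cutoff calibration recovers the generating cutoff", {
  model <- blob_model(60, seed = 19)
  b9 <- calc_bfactors(compute_modes(build_hessian(build_network(model, 9, 1))))
  model$nodes$b <- b9
  tab <- calibrate_cutoff(model, rc_grid = c(7, 8, 9, 11, 13))
  expect_equal(tab$correlation[tab$rc == 9], 1, tolerance = 1e-10)
  model$nodes$b <- b9 + withr::with_seed(20, stats::rnorm(60, sd = 0.1 * stats::sd(b9)))
  tab2 <- calibrate_cutoff(model, rc_grid = c(7, 8, 9, 11, 13))
  expect_lt(max(tab2$correlation), 1)
  expect_equal(tab2$rc[which.max(tab2$correlation)], 9)
})

test_that("calibration flags disconnection and rejects unusable B-factors", {
  model <- blob_model(30, seed = 1)
  model$nodes$b <- seq_len(30) / 10
  tab <- calibrate_cutoff(model, rc_grid = c(2, 9))
  expect_true(tab$disconnected[tab$rc == 2])
  expect_true(is.na(tab$correlation[tab$rc == 2]))
  expect_false(tab$disconnected[tab$rc == 9])
  model$nodes$b <- rep(1, 30)
  expect_error(calibrate_cutoff(model, 9), "constant")
  few <- blob_model(30, seed = 1)
  few$nodes$b <- c(1:5, rep(NA, 25))
  expect_error(calibrate_cutoff(few, 9), "at least 10")
})

test_that("network and spectrum exports are readable 1-based tables", {
  f <- coil_fixture()
  tf <- tempfile(); vf <- tempfile(); ef <- tempfile()
  write_contacts(f$net, tf)
  ct <- utils::read.delim(tf)
  expect_equal(ct$i, f$net$contacts$i)
  expect_true(all(ct$i >= 1))
  write_modes(f$modes, values_file = ef, vectors_file = vf)
  ev <- utils::read.csv(ef)
  expect_equal(ev$mode[1], 1)
  expect_equal(ev$eigenvalue, f$modes$values, tolerance = 1e-12)
  vecs <- as.matrix(utils::read.table(vf))
  expect_equal(dim(vecs), dim(f$modes$vectors))
})
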