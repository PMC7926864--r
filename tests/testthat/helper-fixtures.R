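# Shared fixtures, computed once per test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# hinged two-domain toy with its network and full mode spectrum
hinge_fixture <- function() cached("hinge", {
  pair <- make_hinge_dimer(seed = 1)
  net <- build_network(pair$open, rc = 9, gamma = 1)
  modes <- compute_modes(build_hessian(net))
  list(pair = pair, net = net, modes = modes)
})

# helical coil: rigid at rc = 9 (multiple contact shells), generic spectrum.
# A straight bead chain is floppy in a distance-only network (bending
# mechanisms), so spectral fixtures use coiled geometry.
helix_model <- function(n, seed, jitter = 0.3) {
  xyz <- withr::with_seed(seed, {
    t <- (seq_len(n) - 1) * 100 * pi / 180
    cbind(2.3 * cos(t), 2.3 * sin(t), 1.5 * (seq_len(n) - 1)) +
      matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  })
  structure_model(data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# compact jittered blob (globular contact topology)
blob_model <- function(n, seed, jitter = 0.3) {
  xyz <- withr::with_seed(seed, enmspm:::make_cluster(n, jitter))
  structure_model(data.frame(chain = "A", resno = seq_len(n), resname = "ALA",
                             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}

# small irregular coil used for oracle comparisons (generic spectrum)
coil_fixture <- function() cached("coil", {
  model <- helix_model(10, seed = 7)
  net <- build_network(model, rc = 9, gamma = 1)
  H <- build_hessian(net)
  list(model = model, net = net, H = H, modes = compute_modes(H))
})

# 30-node compact toy for the perturbation-theory oracle
spm_toy_fixture <- function() cached("spm_toy", {
  model <- helix_model(30, seed = 11)
  net <- build_network(model, rc = 9, gamma = 1)
  H <- build_hessian(net)
  list(model = model, net = net, H = H, modes = compute_modes(H))
})

# dimer fixtures with 0/1/2 bound cochaperones, plus modes
dimer_fixture <- function(n_bound) cached(paste0("dimer", n_bound), {
  model <- make_symmetric_dimer_with_cochaperones(n_bound = n_bound, seed = 1)
  net <- build_network(model, rc = 9, gamma = 1)
  modes <- compute_modes(build_hessian(net))
  end <- displace_structure(model, attr(model, "closing_delta"))
  tv <- transition_vector(model, end, align = TRUE)
  list(model = model, net = net, modes = modes, tv = tv,
       profile = overlap(modes, tv))
})

# a valid fixed-column PDB ATOM line for one CA
pdb_ca_line <- function(serial, resname, chain, resno, x, y, z,
                        b = 0, altloc = " ", icode = " ") {
  sprintf("ATOM  %5d  CA %s%-3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          serial, altloc, resname, chain, resno, icode, x, y, z, 1.00, b)
}

# write a minimal CA-only PDB file, returning its path
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# random proper rotation matrix from a seed
random_rotation <- function(seed) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(9), 3, 3)
    q <- qr.Q(qr(m))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    q
  })
}
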