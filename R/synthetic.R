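# Synthetic structure generators with known ground-truth dynamics.
#
# Domains are jittered FCC-like compact clusters: only the contact topology
# matters for elastic-network behavior, so no attempt is made at realistic
# backbone geometry. Residues are labeled poly-alanine. All generators are
# deterministic given their seed. Jitter is uniform in [-jitter, +jitter]
# per coordinate (bounded, so generated distance guarantees are exact).

# checkerboard (FCC-like) lattice cluster of n sites, nearest-neighbor
# distance ~3.8 A, centered at the origin
make_cluster <- function(n, jitter = 0.3, nn_dist = 3.8) {
  a <- nn_dist / sqrt(2)
  m <- ceiling((n * 2)^(1/3)) + 2
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  g <- g[(g$i + g$j + g$k) %% 2 == 0, ]
  pts <- as.matrix(g) * a
  pts <- pts[order(rowSums(pts^2)), , drop = FALSE][seq_len(n), , drop = FALSE]
  pts <- pts + matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  sweep(pts, 2, colMeans(pts))
}

# cross Euclidean distance matrix between two point sets
cross_dist <- function(x, y)
  sqrt(pmax(outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y), 0))

rot_z <- function(theta_deg) {
  t <- theta_deg * pi / 180
  matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
}

nodes_df <- function(xyz, chain, resno = seq_len(nrow(xyz))) {
  data.frame(chain = chain, resno = resno, resname = "ALA",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b = NA_real_,
             stringsAsFactors = FALSE)
}

#' Generate a near-linear bead chain
#'
#' Beads along the x axis at the given spacing, with uniform jitter in
#' `[-jitter, +jitter]` applied per coordinate. Reproducible from the seed.
#'
#' @param n number of beads (>= 2).
#' @param spacing inter-bead spacing in Angstrom (default 3.8, the CA-CA
#'   virtual bond length).
#' @param jitter half-width of the uniform positional jitter (Angstrom).
#' @param seed integer RNG seed.
#' @return a `structure_model` (single chain "A", one segment `chain`).
#' @export
make_chain <- function(n, spacing = 3.8, jitter = 0, seed = 1) {
  stopifnot(n >= 2)
  xyz <- withr::with_seed(seed, {
    base <- cbind(x = (seq_len(n) - 1) * spacing, y = 0, z = 0)
    base + matrix(stats::runif(3 * n, -jitter, jitter), n, 3)
  })
  structure_model(nodes_df(xyz, "A"),
                  segments = list(chain = seq_len(n)),
                  label = sprintf("chain-n%d-seed%d", n, seed))
}

#' Generate an open/closed pair of a hinged two-domain structure
#'
#' Two internally rigid compact domains joined at a hinge; the closed
#' conformation equals the open one with the moving domain rotated rigidly
#' about the hinge (z) axis, so the ground-truth displacement field is known
#' exactly (and identically zero on the static side).
#'
#' The hinge is built as a revolute joint: each domain carries a short pillar
#' of nodes running parallel to the rotation axis at a small radius from it,
#' and the two pillars interdigitate across the axis. Contacts within this
#' tall, narrow column are barely strained by rotation about the axis (their
#' moment arm is the pillar radius) but strongly strained by out-of-plane
#' rocking or torsion (whose moment arm is the column height), so the
#' in-plane hinge rotation is the softest internal motion by construction
#' while the network keeps exactly six zero modes. The static domain carries
#' `static_mass_ratio` times as many nodes as the moving domain, so the soft
#' mode's counter-rotation (which splits inversely with domain inertia)
#' concentrates its amplitude on the moving domain.
#'
#' @param n_per_domain nodes in the moving domain body (default 30).
#' @param hinge_angle_open,hinge_angle_closed opening angle between the two
#'   domain arms in degrees (defaults 120 and 105; wide enough that the two
#'   domain bodies stay beyond contact range of each other).
#' @param jitter uniform jitter half-width (Angstrom).
#' @param static_mass_ratio node-count multiplier for the static domain
#'   (default 10).
#' @param seed integer RNG seed.
#' @return a `toy_pair`: `open` and `closed` `structure_model`s (segments
#'   `static`, `moving`, `hinge`; the hinge segment holds both pillars, the
#'   moving-side pillar rotating with the moving domain), the exact
#'   `true_delta` (N x 3), the seed and a description. `closed` equals
#'   `open + true_delta` exactly.
#' @export
make_hinge_dimer <- function(n_per_domain = 30, hinge_angle_open = 120,
                             hinge_angle_closed = 105, jitter = 0.3,
                             static_mass_ratio = 10, seed = 1) {
  n_static <- static_mass_ratio * n_per_domain
  parts <- withr::with_seed(seed, list(
    static = make_cluster(n_static, jitter),
    moving = make_cluster(n_per_domain, jitter)
  ))
  dir_of <- function(angle_deg)
    c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
  # slide each domain along its arm until its nearest node sits exactly at
  # the standoff distance from the hinge origin
  place <- function(cluster, dir, standoff = 6.5) {
    c0 <- sqrt(max(rowSums(cluster^2))) + standoff
    for (it in 1:3) {
      pts <- sweep(cluster, 2, c0 * dir, "+")
      c0 <- c0 + (standoff - min(sqrt(rowSums(pts^2))))
    }
    sweep(cluster, 2, c0 * dir, "+")
  }
  dir_a <- dir_of(+hinge_angle_open / 2)
  dir_b <- dir_of(-hinge_angle_open / 2)
  xa <- place(parts$static, dir_a)
  xb <- place(parts$moving, dir_b)
  # each pillar sits at a small radius along its own arm, so the tall
  # interdigitated column resists rocking and torsion (moment arm = column
  # height) while rotation about z strains it only through the pillar radius
  pillar <- function(dir, radius = 0.8, zs = seq(-7.6, 7.6, by = 3.8))
    cbind(radius * dir[1], radius * dir[2], zs)
  pa <- pillar(dir_a); pb <- pillar(dir_b)
  n_mov <- n_per_domain
  n_pil <- nrow(pa)
  nodes <- rbind(nodes_df(xa, "A"), nodes_df(xb, "B"),
                 nodes_df(rbind(pa, pb), "C"))
  segs <- list(static = seq_len(n_static),
               moving = n_static + seq_len(n_mov),
               hinge = n_static + n_mov + seq_len(2 * n_pil))
  open <- structure_model(nodes, segments = segs,
                          label = sprintf("hinge-open-seed%d", seed))
  # close by rotating the moving domain (body + its pillar) about the hinge
  # (z) axis toward the static domain
  delta_angle <- hinge_angle_open - hinge_angle_closed
  rot <- t(rot_z(delta_angle))
  n_tot <- n_nodes(open)
  true_delta <- matrix(0, n_tot, 3)
  true_delta[segs$moving, ] <- xb %*% rot - xb
  ipb <- segs$hinge[n_pil + seq_len(n_pil)]   # moving-side pillar
  true_delta[ipb, ] <- pb %*% rot - pb
  closed <- open
  cxyz <- coords(open) + true_delta
  closed$nodes$x <- cxyz[, 1]; closed$nodes$y <- cxyz[, 2]
  closed$nodes$z <- cxyz[, 3]
  closed$label <- sprintf("hinge-closed-seed%d", seed)
  structure(list(open = open, closed = closed, true_delta = true_delta,
                 description = sprintf(
                   "hinged two-domain toy, %g deg -> %g deg closure",
                   hinge_angle_open, hinge_angle_closed),
                 seed = seed),
            class = "toy_pair")
}

#' @export
print.toy_pair <- function(x, ...) {
  cat(sprintf("toy_pair: %s (%d nodes, seed %d)\n", x$description,
              n_nodes(x$open), x$seed))
  invisible(x)
}

#' Generate a symmetric homodimer with 0, 1 or 2 bound cochaperones
#'
#' Two exact two-fold-symmetric protomer copies (the second is the first
#' rotated 180 degrees about the z axis) joined across a revolute dimer
#' interface, emulating an Hsp90-like homodimer whose softest internal
#' motion is the open/close counter-rotation of the protomers; optionally
#' one cochaperone cluster bound to the first protomer (asymmetric complex)
#' or a second copy placed by [assemble_symmetric_complex()] (symmetric 1:1
#' complex, which by construction preserves the exact two-fold symmetry).
#'
#' Each protomer consists of a compact body plus a 5-node interface pillar
#' running along the y axis at a small offset from it; the interdigitated
#' pillar column acts as a revolute joint (as in [make_hinge_dimer()]), so
#' the counter-rotation of the protomers about y -- the recorded ground
#' truth `closing_delta` -- is the softest interface motion. The cochaperone
#' attaches broadly (tight contact gap) to the outer face of its protomer.
#'
#' @param n_protomer nodes per protomer (>= 10; includes the 5 pillar nodes).
#' @param n_cochaperone nodes per cochaperone (>= 4).
#' @param n_bound number of bound cochaperones: 0, 1 or 2.
#' @param jitter uniform jitter half-width (Angstrom).
#' @param seed integer RNG seed.
#' @return a `structure_model`. Segments are `protomerA`/`protomerB` for
#'   `n_bound = 0` and `protomer_bound`/`protomer_free`/`cochaperone`
#'   (/`cochaperone2`) otherwise. Attributes: `mirror` maps each node index
#'   to its two-fold symmetry mate; `closing_delta` is the ground-truth
#'   open-to-closed displacement field (12 degree counter-rotation of the
#'   protomers, zero on cochaperone nodes, which the dimer transition says
#'   nothing about).
#' @export
make_symmetric_dimer_with_cochaperones <- function(n_protomer = 60,
                                                   n_cochaperone = 40,
                                                   n_bound = 0,
                                                   jitter = 0.3, seed = 1) {
  n_pil <- 5
  stopifnot(n_protomer >= n_pil + 4, n_cochaperone >= 4, n_bound %in% 0:2)
  parts <- withr::with_seed(seed, list(
    prot = make_cluster(n_protomer - n_pil, jitter),
    coch = make_cluster(n_cochaperone, jitter)
  ))
  c2 <- diag(c(-1, -1, 1))                       # 180 deg about z
  min_cross <- function(x, y) min(cross_dist(x, y))
  # slide the protomer body out along -x until its closest approach to its
  # own two-fold image is beyond direct contact range: the bodies couple
  # only through the interface pillars, keeping the counter-rotation about
  # the pillar (y) axis the softest interface motion
  gap <- 9.5
  off <- sqrt(max(rowSums(parts$prot^2))) + gap / 2
  for (it in 1:6) {
    body_a <- sweep(parts$prot, 2, c(-off, 0, 0), "+")
    off <- off + (gap - min_cross(body_a, body_a %*% t(c2))) / 2
  }
  body_a <- sweep(parts$prot, 2, c(-off, 0, 0), "+")
  pil_a <- cbind(-0.8, seq(-7.6, 7.6, by = 3.8), 0)
  xa <- rbind(body_a, pil_a)
  xb <- xa %*% t(c2)
  # cochaperone docks laterally onto its protomer's flank (above the body,
  # +z), as a cochaperone binding a middle domain would: a tight gap gives a
  # broad, stiff attachment and a moderate lever arm about the closing axis
  kgap <- 4.5
  koff <- sqrt(max(rowSums(parts$prot^2))) +
    sqrt(max(rowSums(parts$coch^2))) + kgap
  for (it in 1:6) {
    xk <- sweep(parts$coch, 2, c(-off, 0, koff), "+")
    koff <- koff + (kgap - min_cross(xk, body_a))
  }
  xk <- sweep(parts$coch, 2, c(-off, 0, koff), "+")
  # ground-truth "closing" transition: each protomer rotates 12 degrees
  # about the y axis through the dimer interface, in opposite senses
  # (exactly two-fold symmetric). The reference transition is defined on
  # the dimer only -- cochaperone nodes carry zero displacement, as a
  # conformational change of the dimer says nothing about the cochaperone.
  closing <- function(xyz, side) {
    phi <- side * 12 * pi / 180
    ry <- matrix(c(cos(phi), 0, -sin(phi), 0, 1, 0, sin(phi), 0, cos(phi)),
                 3, 3)
    xyz %*% t(ry) - xyz
  }
  zero_delta <- function(xyz) matrix(0, nrow(xyz), 3)
  if (n_bound == 0) {
    nodes <- rbind(nodes_df(xa, "A"), nodes_df(xb, "B"))
    segs <- list(protomerA = seq_len(n_protomer),
                 protomerB = n_protomer + seq_len(n_protomer))
    model <- structure_model(nodes, segments = segs,
                             label = sprintf("dimer-0K-seed%d", seed))
    attr(model, "mirror") <- c(segs$protomerB, segs$protomerA)
    attr(model, "closing_delta") <- rbind(closing(xa, +1), closing(xb, -1))
    return(model)
  }
  nodes <- rbind(nodes_df(xa, "A"), nodes_df(xb, "B"), nodes_df(xk, "C"))
  segs <- list(protomer_bound = seq_len(n_protomer),
               protomer_free = n_protomer + seq_len(n_protomer),
               cochaperone = 2 * n_protomer + seq_len(n_cochaperone))
  model <- structure_model(nodes, segments = segs,
                           label = sprintf("dimer-1K-seed%d", seed))
  attr(model, "closing_delta") <- rbind(closing(xa, +1), closing(xb, -1),
                                        zero_delta(xk))
  if (n_bound == 1) return(model)
  model2 <- assemble_symmetric_complex(model)
  model2$label <- sprintf("dimer-2K-seed%d", seed)
  segs2 <- model2$segments
  attr(model2, "mirror") <- c(segs2$protomer_free, segs2$protomer_bound,
                              segs2$cochaperone2, segs2$cochaperone)
  xk2 <- coords(model2)[segs2$cochaperone2, , drop = FALSE]
  attr(model2, "closing_delta") <- rbind(closing(xa, +1), closing(xb, -1),
                                         zero_delta(xk), zero_delta(xk2))
  model2
}

#' Displace a structure by a per-node field
#'
#' Returns a copy of the model with `delta` added to every node position
#' (e.g. to materialize the end conformation of a known transition).
#'
#' @param model a `structure_model`.
#' @param delta N x 3 matrix of displacements (Angstrom).
#' @param label label for the displaced copy.
#' @return a `structure_model`.
#' @export
displace_structure <- function(model, delta,
                               label = paste0(model$label, "+delta")) {
  delta <- as.matrix(delta)
  if (nrow(delta) != n_nodes(model) || ncol(delta) != 3)
    stop("delta must be an N x 3 matrix")
  xyz <- coords(model) + delta
  model$nodes$x <- xyz[, 1]; model$nodes$y <- xyz[, 2]; model$nodes$z <- xyz[, 3]
  model$label <- label
  model
}

#' Write the standard fixture suite to a directory
#'
#' Emits the bead chain, the hinge open/closed pair and the 0/1/2-cochaperone
#' dimer models as PDB files, the hinge ground-truth displacement field as
#' JSON (kept out of the PDB to avoid its 3-decimal precision), and a JSON
#' manifest recording each file with its seed and node count. Re-running with
#' the same seed reproduces every file byte for byte.
#'
#' @param outdir writable output directory (created if missing).
#' @param seed integer RNG seed used for every generator.
#' @return the manifest as a data.frame, invisibly; files on disk.
#' @export
write_fixture_set <- function(outdir, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hinge <- make_hinge_dimer(seed = seed)
  models <- list(
    chain = make_chain(50, jitter = 0.3, seed = seed),
    hinge_open = hinge$open,
    hinge_closed = hinge$closed,
    dimer_0k = make_symmetric_dimer_with_cochaperones(n_bound = 0, seed = seed),
    dimer_1k = make_symmetric_dimer_with_cochaperones(n_bound = 1, seed = seed),
    dimer_2k = make_symmetric_dimer_with_cochaperones(n_bound = 2, seed = seed)
  )
  files <- character(0)
  for (nm in names(models)) {
    f <- file.path(outdir, paste0(nm, ".pdb"))
    write_structure(models[[nm]], f)
    files[nm] <- basename(f)
  }
  delta_file <- file.path(outdir, "hinge_true_delta.json")
  jsonlite::write_json(hinge$true_delta, delta_file, digits = NA)
  manifest <- data.frame(
    file = unname(files), seed = seed,
    n_nodes = vapply(models, n_nodes, integer(1)),
    ground_truth_ref = ifelse(names(models) %in% c("hinge_open", "hinge_closed"),
                              basename(delta_file), NA_character_),
    row.names = NULL)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE, na = "null",
                       digits = NA)
  invisible(manifest)
}
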