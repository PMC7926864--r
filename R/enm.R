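#' Build an anisotropic elastic network from a structure
#'
#' Nodes within a cutoff distance `rc` of each other are joined by harmonic
#' springs of a single global spring constant `gamma`; the reference spring
#' length is the observed CA-CA distance. Contacts use the strict inequality
#' `d < rc` ("within" the cutoff); boundary ties are measure-zero but
#' documented.
#'
#' @param model a `structure_model` with at least 2 nodes.
#' @param rc cutoff distance in Angstrom (default 9, the value selected by
#'   B-factor calibration for the chaperone models).
#' @param gamma spring constant in arbitrary energy/Angstrom^2 units; a single
#'   global scalar, never per-contact.
#' @return an `elastic_network` with a `contacts` data.frame (i, j, d0), i < j.
#' @export
build_network <- function(model, rc = 9, gamma = 1) {
  stopifnot(inherits(model, "structure_model"))
  n <- n_nodes(model)
  if (n < 2) stop("need at least 2 nodes")
  if (rc <= 0 || gamma <= 0) stop("rc and gamma must be positive")
  d <- as.matrix(stats::dist(coords(model)))
  if (any(d[upper.tri(d)] == 0)) stop("coincident nodes (zero distance)")
  sel <- which(upper.tri(d) & d < rc, arr.ind = TRUE)
  contacts <- data.frame(i = sel[, 1], j = sel[, 2],
                         d0 = d[sel])
  ord <- order(contacts$i, contacts$j)
  contacts <- contacts[ord, , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(model = model, rc = rc, gamma = gamma, contacts = contacts),
            class = "elastic_network")
}

#' @export
print.elastic_network <- function(x, ...) {
  cat(sprintf("elastic_network: %d nodes, %d contacts (rc = %g A, gamma = %g)\n",
              n_nodes(x$model), nrow(x$contacts), x$rc, x$gamma))
  invisible(x)
}

#' Elastic network energy at arbitrary coordinates
#'
#' The harmonic Hamiltonian: half the spring constant times the squared
#' deviation of each contact's length from its reference length, summed over
#' contacts. Exactly zero at the reference structure.
#'
#' @param network an `elastic_network`.
#' @param xyz N x 3 coordinate matrix (defaults to the reference structure).
#' @return scalar energy in `gamma` * Angstrom^2 units.
#' @export
enm_energy <- function(network, xyz = coords(network$model)) {
  ct <- network$contacts
  dv <- xyz[ct$j, , drop = FALSE] - xyz[ct$i, , drop = FALSE]
  d <- sqrt(rowSums(dv^2))
  0.5 * network$gamma * sum((d - ct$d0)^2)
}

#' Hessian of the elastic network at the reference structure
#'
#' For each contact (i, j) the off-diagonal 3 x 3 block is `-gamma e e^T`
#' with `e` the unit vector along the reference separation; diagonal blocks
#' accumulate minus the sum of a node's off-diagonal blocks, so every block
#' row sums to zero (translation invariance).
#'
#' @param network an `elastic_network`.
#' @return dense symmetric 3N x 3N matrix.
#' @export
build_hessian <- function(network) {
  n <- n_nodes(network$model)
  xyz <- coords(network$model)
  H <- matrix(0, 3 * n, 3 * n)
  ct <- network$contacts
  g <- network$gamma
  for (k in seq_len(nrow(ct))) {
    i <- ct$i[k]; j <- ct$j[k]
    e <- (xyz[j, ] - xyz[i, ]) / ct$d0[k]
    K <- g * tcrossprod(e)
    bi <- (3 * i - 2):(3 * i); bj <- (3 * j - 2):(3 * j)
    H[bi, bi] <- H[bi, bi] + K
    H[bj, bj] <- H[bj, bj] + K
    H[bi, bj] <- H[bi, bj] - K
    H[bj, bi] <- H[bj, bi] - K
  }
  H
}

#' Normal modes of an elastic network Hessian
#'
#' Full spectrum of the symmetric Hessian under unit masses, sorted
#' ascending. Mode numbering is 1-based over the full spectrum including the
#' zero (rigid-body) modes, so for a connected network the first internal
#' mode is mode 7. Eigenvector signs are fixed deterministically (largest
#' magnitude component positive) so covariance signs are reproducible.
#'
#' @param hessian symmetric 3N x 3N matrix from [build_hessian()].
#' @param tol_zero relative tolerance below which an eigenvalue counts as
#'   zero (default 1e-8 of the largest eigenvalue).
#' @return a `mode_set` with `values` (ascending), `vectors` (columns,
#'   orthonormal), `n_zero`, and any `warnings` (e.g. disconnection).
#' @export
compute_modes <- function(hessian, tol_zero = 1e-8) {
  if (!is.matrix(hessian) || nrow(hessian) != ncol(hessian))
    stop("hessian must be a square matrix")
  if (max(abs(hessian - t(hessian))) > 1e-8 * max(abs(hessian), 1))
    stop("hessian is not symmetric")
  e <- eigen(hessian, symmetric = TRUE)
  ord <- rev(seq_along(e$values))           # eigen() returns descending
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  vmax <- max(values)
  if (vmax <= 0) {
    values[] <- pmax(values, 0)
    n_zero <- length(values)
  } else {
    small <- abs(values) < tol_zero * vmax
    values[small] <- pmax(values[small], 0)
    n_zero <- sum(values < tol_zero * vmax)
  }
  # deterministic sign: largest-magnitude component positive
  for (k in seq_len(ncol(vectors))) {
    m <- which.max(abs(vectors[, k]))
    if (vectors[m, k] < 0) vectors[, k] <- -vectors[, k]
  }
  warn <- character(0)
  if (n_zero > 6) {
    warn <- sprintf(paste("network has %d zero modes: it is disconnected or",
                          "contains floppy mechanisms"), n_zero)
    warning(warn)
  }
  structure(list(values = values, vectors = vectors, n_zero = n_zero,
                 tol_zero = tol_zero, warnings = warn),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  nz <- nonzero_modes(x)
  cat(sprintf("mode_set: %d modes, %d zero; first nonzero eigenvalue %.4g (mode %d)\n",
              length(x$values), x$n_zero,
              if (length(nz)) x$values[nz[1]] else NA, if (length(nz)) nz[1] else NA))
  invisible(x)
}

#' Indices of the nonzero (internal) modes
#' @param modes a `mode_set`.
#' @return integer vector of mode indices (1-based over the full spectrum).
#' @export
nonzero_modes <- function(modes) {
  seq_along(modes$values)[-seq_len(modes$n_zero)]
}

#' Theoretical B-factors from the normal modes
#'
#' Per-node mean-square fluctuation summed over nonzero modes with thermal
#' weight 1/eigenvalue, i.e. the per-node trace of the Hessian pseudo-inverse.
#' Returned to an arbitrary positive scale, normalized to unit mean.
#'
#' @param modes a `mode_set` (zero modes are excluded automatically).
#' @return numeric vector of length N, mean 1.
#' @export
calc_bfactors <- function(modes) {
  nz <- nonzero_modes(modes)
  if (length(nz) == 0) stop("no nonzero modes: cannot compute B-factors")
  n <- length(modes$values) / 3
  w <- 1 / modes$values[nz]
  sq <- modes$vectors[, nz, drop = FALSE]^2
  per_coord <- sq %*% w
  b <- rowSums(matrix(per_coord, nrow = n, byrow = TRUE))
  b / mean(b)
}

#' Calibrate the contact cutoff against experimental B-factors
#'
#' For each candidate cutoff, builds the network, computes modes and
#' mode-based B-factors, and reports the Pearson correlation with the
#' experimental B-factors stored on the model. The cutoff maximizing the
#' correlation is the calibrated choice (9 Angstrom for the chaperone
#' structures).
#'
#' @param model a `structure_model` whose nodes carry experimental B-factors
#'   (at least 10 non-missing values required).
#' @param rc_grid numeric vector of candidate cutoffs in Angstrom.
#' @param gamma spring constant (the correlation is gamma-independent).
#' @return data.frame with one row per cutoff: `rc`, `correlation`, `n_zero`,
#'   `disconnected`.
#' @export
calibrate_cutoff <- function(model, rc_grid = c(7, 8, 9, 11, 13), gamma = 1) {
  b_exp <- model$nodes$b
  ok <- !is.na(b_exp)
  if (sum(ok) < 10) stop("need experimental B-factors for at least 10 nodes")
  if (stats::sd(b_exp[ok]) == 0)
    stop("experimental B-factors are constant: correlation undefined")
  rows <- lapply(rc_grid, function(rc) {
    res <- withCallingHandlers({
      net <- build_network(model, rc = rc, gamma = gamma)
      modes <- compute_modes(build_hessian(net))
      corr <- if (length(nonzero_modes(modes)) == 0) NA_real_ else
        stats::cor(calc_bfactors(modes)[ok], b_exp[ok])
      list(cor = corr, n_zero = modes$n_zero)
    }, warning = function(w) invokeRestart("muffleWarning"))
    data.frame(rc = rc, correlation = res$cor, n_zero = res$n_zero,
               disconnected = res$n_zero > 6)
  })
  do.call(rbind, rows)
}

#' Export a contact list as TSV (1-based indices)
#' @param network an `elastic_network`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_contacts <- function(network, file) {
  utils::write.table(network$contacts, file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Export eigenvalues (CSV) and eigenvectors (dense text matrix)
#' @param modes a `mode_set`.
#' @param values_file,vectors_file output paths (either may be NULL to skip).
#' @return invisibly, the file paths written.
#' @export
write_modes <- function(modes, values_file = NULL, vectors_file = NULL) {
  if (!is.null(values_file))
    utils::write.csv(data.frame(mode = seq_along(modes$values),
                                eigenvalue = modes$values),
                     values_file, row.names = FALSE)
  if (!is.null(vectors_file))
    utils::write.table(modes$vectors, vectors_file, sep = " ",
                       row.names = FALSE, col.names = FALSE)
  invisible(c(values_file, vectors_file))
}

#' Connected components of an elastic network (diagnostic)
#' @param network an `elastic_network`.
#' @return integer vector of component labels per node.
#' @export
network_components <- function(network) {
  n <- n_nodes(network$model)
  comp <- integer(n)
  adj <- split(c(network$contacts$j, network$contacts$i),
               c(network$contacts$i, network$contacts$j))
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[as.character(v)]]
      nb <- nb[comp[nb] == 0]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}
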