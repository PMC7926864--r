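#' Displacement field between two corresponded conformations
#'
#' Computes the per-node difference vector from the start conformation to the
#' end conformation. With `align = TRUE` (default) the end conformation is
#' first rigid-body superposed onto the start over all corresponded nodes, so
#' the field reflects internal deformation only; without alignment, rigid
#' offsets between the deposited structures leak into the field and inflate
#' apparent overlap with the rigid-body modes.
#'
#' @param start,end `structure_model`s of the two conformations.
#' @param correspondence a `node_correspondence`; defaults to positional
#'   (requires equal node counts).
#' @param align superpose `end` onto `start` before subtracting?
#' @return a `transition_vector`: `delta` (N x 3, Angstrom), `aligned` flag
#'   and conformation labels.
#' @export
transition_vector <- function(start, end, correspondence = NULL, align = TRUE) {
  if (is.null(correspondence)) correspondence <- positional_correspondence(start, end)
  ia <- correspondence$pairs[, "a"]; ib <- correspondence$pairs[, "b"]
  xs <- coords(start)[ia, , drop = FALSE]
  xe <- coords(end)[ib, , drop = FALSE]
  if (align) {
    fit <- superpose(xe, xs)
    xe <- sweep(tcrossprod(xe, fit$rotation), 2, fit$translation, "+")
  }
  structure(list(delta = xe - xs, aligned = align,
                 from = start$label, to = end$label),
            class = "transition_vector")
}

#' @export
print.transition_vector <- function(x, ...) {
  cat(sprintf("transition_vector: %d nodes, |delta| max %.3f A (%s -> %s, aligned = %s)\n",
              nrow(x$delta), sqrt(max(rowSums(x$delta^2))), x$from, x$to, x$aligned))
  invisible(x)
}

# flatten an N x 3 per-node field to the 3N-dimensional mode space
as_mode_space <- function(delta) as.vector(t(delta))

#' Overlap of each normal mode with a conformational transition
#'
#' For each mode M the overlap is the absolute normalized inner product of
#' the mode eigenvector with the transition displacement field,
#' `I_M = |q^M . delta| / (||q^M|| ||delta||)`, so `0 <= I_M <= 1` and the
#' squared overlaps sum to one over the complete 3N-mode basis. The sign of
#' an eigenvector is arbitrary, hence the absolute value; the signed
#' projection is retained in the `signed` column. Nonzero modes at or above
#' the threshold form the dominant set, reported in descending overlap.
#'
#' @param modes a `mode_set`.
#' @param tv a `transition_vector` (or N x 3 matrix) on the same node space.
#' @param threshold dominant-mode cutoff on `I_M` (default 0.35).
#' @return an `overlap_profile`: data.frame `profile` (mode, overlap, signed),
#'   integer vector `dominant`, and the threshold.
#' @export
overlap <- function(modes, tv, threshold = 0.35) {
  delta <- if (inherits(tv, "transition_vector")) tv$delta else as.matrix(tv)
  d <- as_mode_space(delta)
  if (length(d) != nrow(modes$vectors))
    stop("transition vector dimension (", length(d),
         ") does not match mode space (", nrow(modes$vectors), ")")
  nd <- sqrt(sum(d^2))
  if (nd < 1e-10)
    stop("zero-length transition: the two conformations are identical")
  signed <- as.vector(crossprod(modes$vectors, d)) / nd
  i_m <- abs(signed)
  nz <- nonzero_modes(modes)
  dom <- nz[i_m[nz] >= threshold]
  dom <- dom[order(i_m[dom], decreasing = TRUE)]
  structure(list(profile = data.frame(mode = seq_along(i_m), overlap = i_m,
                                      signed = signed),
                 dominant = dom, threshold = threshold),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat(sprintf("overlap_profile: %d modes, %d dominant (I >= %g)",
              nrow(x$profile), length(x$dominant), x$threshold))
  if (length(x$dominant) > 0) {
    top <- x$dominant[seq_len(min(3, length(x$dominant)))]
    cat(": ", paste(sprintf("mode %d (%.2f)", top, x$profile$overlap[top]),
                    collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Residue cross-correlation (covariance) map from normal modes
#'
#' The normalized covariance of per-node displacement directions over a mode
#' subset, each mode weighted by the reciprocal of its eigenvalue (thermal
#' convention; a `"frequency"` switch weights by the reciprocal square root
#' instead, and `"none"` drops the weight -- for a single mode all three
#' agree). Entries are +1 for fully concerted motion, -1 for opposed motion.
#' Nodes with no displacement in any requested mode give undefined (NA) rows.
#'
#' @param modes a `mode_set`, or a 3N x k matrix of displacement vectors
#'   (columns) to correlate directly (weighting `"none"`).
#' @param which_modes integer mode indices, or `"all-nonzero"` (default).
#'   Zero modes must be requested explicitly.
#' @param weighting `"eigenvalue"` (1/lambda, default), `"frequency"`
#'   (1/sqrt(lambda)) or `"none"`.
#' @return a `covariance_matrix`: N x N symmetric matrix with unit diagonal
#'   where defined, plus the mode subset and weighting used.
#' @export
covariance <- function(modes, which_modes = "all-nonzero",
                       weighting = c("eigenvalue", "frequency", "none")) {
  weighting <- match.arg(weighting)
  if (inherits(modes, "mode_set")) {
    if (identical(which_modes, "all-nonzero")) which_modes <- nonzero_modes(modes)
    which_modes <- as.integer(which_modes)
    if (length(which_modes) == 0) stop("empty mode subset")
    if (any(which_modes < 1 | which_modes > length(modes$values)))
      stop("mode index out of range")
    Q <- modes$vectors[, which_modes, drop = FALSE]
    lam <- modes$values[which_modes]
    w <- switch(weighting,
                eigenvalue = 1 / lam,
                frequency = 1 / sqrt(lam),
                none = rep(1, length(lam)))
    if (any(!is.finite(w)))
      stop("zero modes have infinite thermal weight; use weighting = 'none' ",
           "to include them")
  } else {
    Q <- as.matrix(modes)
    which_modes <- seq_len(ncol(Q))
    w <- rep(1, ncol(Q))
    weighting <- "none"
  }
  n <- nrow(Q) / 3
  num <- matrix(0, n, n)
  for (k in seq_len(ncol(Q))) {
    P <- matrix(Q[, k], nrow = n, byrow = TRUE)   # N x 3 for this mode
    num <- num + w[k] * tcrossprod(P)
  }
  dg <- diag(num)
  undef <- dg <= 0
  denom <- sqrt(outer(dg, dg))
  C <- num / denom
  C[undef, ] <- NA; C[, undef] <- NA
  C <- pmin(pmax(C, -1), 1)
  structure(list(matrix = C, modes = which_modes, weighting = weighting),
            class = "covariance_matrix")
}

#' @export
print.covariance_matrix <- function(x, ...) {
  cat(sprintf("covariance_matrix: %d x %d, modes {%s}, weighting %s\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(x$modes, collapse = ","), x$weighting))
  invisible(x)
}

#' Relative displacement profile of a mode (or sum over modes)
#'
#' For one normalized mode the per-node displacement magnitude
#' `sqrt(qx^2 + qy^2 + qz^2)`; its squares sum to 1. For a set of modes, the
#' arithmetic sum of the per-mode profiles (the "sum of the individual amino
#' acid fluctuations" convention used for mapping mobility onto structures).
#'
#' @param modes a `mode_set`, or a 3N numeric vector / 3N x k matrix of
#'   displacement vectors.
#' @param which_modes integer mode indices (ignored when `modes` is raw
#'   vectors). Requesting a zero mode warns but computes.
#' @return a `displacement_profile`: numeric vector of length N plus the mode
#'   set used.
#' @export
displacement <- function(modes, which_modes = NULL) {
  if (inherits(modes, "mode_set")) {
    if (is.null(which_modes)) stop("which_modes required for a mode_set")
    which_modes <- as.integer(which_modes)
    if (any(which_modes < 1 | which_modes > length(modes$values)))
      stop("requested mode does not exist")
    if (any(which_modes <= modes$n_zero))
      warning("zero (rigid-body) mode requested; profile reflects rigid motion")
    Q <- modes$vectors[, which_modes, drop = FALSE]
  } else {
    Q <- as.matrix(modes)
    which_modes <- seq_len(ncol(Q))
  }
  n <- nrow(Q) / 3
  prof <- rowSums(vapply(seq_len(ncol(Q)), function(k) {
    P <- matrix(Q[, k], nrow = n, byrow = TRUE)
    sqrt(rowSums(P^2))
  }, numeric(n)))
  structure(list(values = prof, modes = which_modes),
            class = "displacement_profile")
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf("displacement_profile: %d nodes, modes {%s}, max %.4f\n",
              length(x$values), paste(x$modes, collapse = ","), max(x$values)))
  invisible(x)
}

#' Segment-block summary of a covariance map or displacement profile
#'
#' Averages a covariance matrix over every segment-pair block, or a
#' displacement profile over every segment, supporting statements about
#' domain-level motion (e.g. whether two domains move together).
#'
#' @param x a `covariance_matrix`, `displacement_profile`, plain matrix or
#'   numeric vector.
#' @param segments named list of integer node-index vectors.
#' @return data.frame: (`segment_i`, `segment_j`, `mean`) for matrices,
#'   (`segment`, `mean`) for profiles.
#' @export
segment_summary <- function(x, segments) {
  if (length(segments) == 0 || is.null(names(segments)))
    stop("segments must be a named list")
  if (inherits(x, "covariance_matrix")) x <- x$matrix
  if (inherits(x, "displacement_profile")) x <- x$values
  if (is.matrix(x)) {
    n <- nrow(x)
    check_segments(segments, n)
    nm <- names(segments)
    out <- expand.grid(segment_i = nm, segment_j = nm,
                       stringsAsFactors = FALSE)
    out$mean <- mapply(function(a, b) mean(x[segments[[a]], segments[[b]]]),
                       out$segment_i, out$segment_j)
    out
  } else {
    check_segments(segments, length(x))
    data.frame(segment = names(segments),
               mean = vapply(segments, function(i) mean(x[i]), numeric(1)),
               row.names = NULL)
  }
}

check_segments <- function(segments, n) {
  idx <- unlist(segments, use.names = FALSE)
  if (any(idx < 1 | idx > n))
    stop("unknown segment indices: outside 1..", n)
  invisible(TRUE)
}

#' Export an overlap profile as a two-column CSV (mode, I_M)
#' @param profile an `overlap_profile`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_overlap <- function(profile, file) {
  utils::write.csv(profile$profile[, c("mode", "overlap")], file,
                   row.names = FALSE)
  invisible(file)
}

#' Export a covariance matrix as dense CSV with 1-based node headers
#' @param cov a `covariance_matrix`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_covariance <- function(cov, file) {
  m <- cov$matrix
  colnames(m) <- seq_len(ncol(m))
  utils::write.csv(m, file, row.names = FALSE)
  invisible(file)
}
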