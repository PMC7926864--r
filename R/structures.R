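#' Construct a coarse-grained structure model
#'
#' A `structure_model` holds one conformation of one assembly as an ordered
#' set of carbon-alpha nodes, each identified by `(chain, residue number)`,
#' together with a segment map naming index ranges (protomers, cochaperones,
#' domains). It is the container every downstream stage (network building,
#' superposition, mode analysis) operates on.
#'
#' @param nodes data.frame with columns `chain` (character), `resno`
#'   (integer), `resname` (3-letter code), `x`, `y`, `z` (Angstrom) and
#'   optionally `b` (experimental B-factor, `NA` when absent).
#' @param segments named list of integer index vectors over `1..N`. Segments
#'   must be disjoint.
#' @param label free-text identifier carried through reports.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(nodes, segments = list(), label = "") {
  stopifnot(is.data.frame(nodes))
  need <- c("chain", "resno", "resname", "x", "y", "z")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols) > 0)
    stop("nodes is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(nodes) < 1) stop("empty structure: need at least one node")
  if (!is.null(nodes$b) && !is.numeric(nodes$b)) stop("b must be numeric")
  if (is.null(nodes$b)) nodes$b <- NA_real_
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  n <- nrow(nodes)
  if (length(segments) > 0) {
    if (is.null(names(segments)) || any(names(segments) == ""))
      stop("segments must be named")
    idx <- unlist(segments, use.names = FALSE)
    if (length(idx) > 0) {
      if (any(idx < 1 | idx > n)) stop("segment indices out of range 1..", n)
      if (anyDuplicated(idx)) stop("segments must be disjoint")
    }
  }
  nodes$chain <- as.character(nodes$chain)
  nodes$resno <- as.integer(nodes$resno)
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, segments = segments, label = label),
            class = "structure_model")
}

#' Coordinates of a structure model
#'
#' @param model a `structure_model`.
#' @return N x 3 numeric matrix of node positions in Angstrom.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$nodes[, c("x", "y", "z")])
}

#' Number of nodes
#' @param model a `structure_model`.
#' @return integer node count.
#' @export
n_nodes <- function(model) nrow(model$nodes)

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d nodes, %d chain(s)",
              x$label, n_nodes(x), length(unique(x$nodes$chain))))
  if (length(x$segments) > 0)
    cat(sprintf(", segments: %s", paste(names(x$segments), collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Read a structure from a PDB file into a CA-only model
#'
#' One node per residue is taken from its CA atom. HETATM records, waters and
#' alternate locations beyond 'A' are ignored; insertion codes are rejected
#' (prepared chaperone models carry none and silent renumbering would corrupt
#' node correspondence). Experimental B-factors are retained per node for
#' cutoff calibration.
#'
#' @param pdb path to a PDB file, or a character vector of PDB-format lines.
#' @param chain_filter optional character vector of chain ids to keep.
#' @param label label for the returned model; defaults to the file name.
#' @return a `structure_model` with nodes ordered by (chain, residue number).
#' @export
read_structure <- function(pdb, chain_filter = NULL, label = NULL) {
  if (length(pdb) > 1 || grepl("\n", pdb) || grepl("^(ATOM|HETATM|HEADER|REMARK)", pdb[1])) {
    tmp <- tempfile(fileext = ".pdb")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(unlist(strsplit(pdb, "\n", fixed = TRUE)), tmp)
    file <- tmp
    if (is.null(label)) label <- "pdb-text"
  } else {
    file <- pdb
    if (is.null(label)) label <- basename(file)
  }
  p <- bio3d::read.pdb(file, verbose = FALSE)
  at <- p$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  ins <- at$insert
  if (any(!is.na(ins) & ins != ""))
    stop("insertion codes are not supported; renumber residues first")
  alt <- at$alt
  at <- at[is.na(alt) | alt %in% c("", "A"), , drop = FALSE]
  if (!is.null(chain_filter)) at <- at[at$chain %in% chain_filter, , drop = FALSE]
  if (nrow(at) == 0) stop("no CA atoms found (empty structure)")
  at <- at[order(at$chain, at$resno), , drop = FALSE]
  dup <- duplicated(paste(at$chain, at$resno))
  if (any(dup)) {
    warning("duplicate CA atoms for ", sum(dup), " residue(s); keeping first")
    at <- at[!dup, , drop = FALSE]
  }
  structure_model(
    data.frame(chain = at$chain, resno = at$resno, resname = at$resid,
               x = at$x, y = at$y, z = at$z, b = at$b,
               stringsAsFactors = FALSE),
    label = label)
}

#' Write a CA-only model to a PDB file
#'
#' Optionally writes a per-node scalar (a displacement or hot-spot profile)
#' into the B-factor column, min-max rescaled to `[0, 99.99]` so any profile
#' fits the fixed-width field; a constant profile is written as all zeros.
#' Coordinates round-trip through [read_structure()] at PDB precision
#' (3 decimals).
#'
#' @param model a `structure_model`.
#' @param file output path.
#' @param per_node_scalar optional numeric vector of length N to encode in
#'   the B-factor column.
#' @return `file`, invisibly.
#' @export
write_structure <- function(model, file, per_node_scalar = NULL) {
  stopifnot(inherits(model, "structure_model"))
  n <- n_nodes(model)
  if (is.null(per_node_scalar)) {
    b <- model$nodes$b
    b[is.na(b)] <- 0
  } else {
    if (length(per_node_scalar) != n)
      stop("per_node_scalar must have length ", n)
    rng <- range(per_node_scalar)
    b <- if (diff(rng) == 0) rep(0, n) else
      (per_node_scalar - rng[1]) / diff(rng) * 99.99
  }
  xyz <- as.vector(t(coords(model)))
  bio3d::write.pdb(file = file, xyz = xyz,
                   resno = model$nodes$resno, resid = model$nodes$resname,
                   chain = model$nodes$chain, elety = rep("CA", n),
                   o = rep(1, n), b = b)
  invisible(file)
}

#' Node correspondence between two structures
#'
#' @param idx_a,idx_b parallel integer index vectors into structure A and B.
#' @param complete whether the mapping is bijective over both structures.
#' @return a `node_correspondence` object.
#' @export
node_correspondence <- function(idx_a, idx_b, complete = FALSE) {
  idx_a <- as.integer(idx_a); idx_b <- as.integer(idx_b)
  if (length(idx_a) != length(idx_b)) stop("index vectors differ in length")
  if (anyDuplicated(idx_a) || anyDuplicated(idx_b))
    stop("correspondence indices must be unique within each side")
  structure(list(pairs = cbind(a = idx_a, b = idx_b), complete = complete),
            class = "node_correspondence")
}

#' Positional correspondence for equal-length structures
#'
#' Matched open/closed conformations prepared to the same node count are
#' corresponded positionally (node k of A to node k of B).
#'
#' @param a,b `structure_model`s of equal node count.
#' @return a complete `node_correspondence`.
#' @export
positional_correspondence <- function(a, b) {
  if (n_nodes(a) != n_nodes(b))
    stop("structures differ in node count (", n_nodes(a), " vs ", n_nodes(b),
         "); supply an explicit correspondence")
  node_correspondence(seq_len(n_nodes(a)), seq_len(n_nodes(b)), complete = TRUE)
}

#' Read a two-column TSV correspondence file (indexA, indexB, 1-based)
#' @param file path to TSV with two integer columns.
#' @return a `node_correspondence`.
#' @export
read_correspondence <- function(file) {
  tab <- utils::read.table(file, header = FALSE)
  node_correspondence(tab[[1]], tab[[2]])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing the RMSD of
#' `R x + t` over corresponded node pairs of `mobile` against `target`.
#' Reflections are corrected by flipping the smallest singular direction, so
#' `det(R) = +1` always.
#'
#' @param mobile,target `structure_model`s (or N x 3 coordinate matrices).
#' @param correspondence a `node_correspondence`; defaults to positional.
#' @return a `superposition` object with fields `rotation` (3 x 3),
#'   `translation` (length 3) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile, target, correspondence = NULL) {
  xm <- if (inherits(mobile, "structure_model")) coords(mobile) else as.matrix(mobile)
  xt <- if (inherits(target, "structure_model")) coords(target) else as.matrix(target)
  if (is.null(correspondence)) {
    if (nrow(xm) != nrow(xt))
      stop("structures differ in node count; supply an explicit correspondence")
    ia <- seq_len(nrow(xm)); ib <- ia
  } else {
    ia <- correspondence$pairs[, "a"]; ib <- correspondence$pairs[, "b"]
  }
  if (length(ia) < 3) stop("degenerate superposition: need at least 3 corresponded pairs")
  X <- xm[ia, , drop = FALSE]; Y <- xt[ib, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  # collinearity: a point set with rank < 2 leaves rotation about the line free
  sv_x <- svd(Xc, nu = 0, nv = 0)$d
  if (sv_x[2] <= 1e-8 * max(sv_x[1], 1e-300))
    stop("degenerate superposition: corresponded nodes are collinear")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- cy - as.vector(R %*% cx)
  fitted <- sweep(tcrossprod(X, R), 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to a structure model
#'
#' @param model a `structure_model`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return transformed `structure_model` (identity otherwise preserved).
#' @export
apply_transform <- function(model, rotation, translation) {
  xyz <- sweep(tcrossprod(coords(model), rotation), 2, translation, "+")
  model$nodes$x <- xyz[, 1]; model$nodes$y <- xyz[, 2]; model$nodes$z <- xyz[, 3]
  model
}

#' Assemble a symmetric 1:1 complex from an asymmetric one
#'
#' Given an assembly with segments naming a cochaperone-bound protomer, a free
#' protomer and the cochaperone, computes the rigid transform superposing the
#' bound protomer onto the free protomer and applies it to a copy of the
#' cochaperone, appending the copy after the existing nodes. This is the
#' least-RMSD overlay construction used to place a second Hsp70 molecule on
#' the opposite Hsp90 protomer. Input coordinates are preserved exactly; only
#' the appended nodes are new.
#'
#' @param asym `structure_model` with segments `protomer_bound`,
#'   `protomer_free` and `cochaperone` (names configurable).
#' @param bound,free,cochaperone segment names.
#' @return `structure_model` with `N + N_cochaperone` nodes; the copy gets the
#'   next unused chain id and a new segment `<cochaperone>2`. If the
#'   cochaperone segment is absent or empty the input is returned unchanged.
#' @export
assemble_symmetric_complex <- function(asym, bound = "protomer_bound",
                                       free = "protomer_free",
                                       cochaperone = "cochaperone") {
  stopifnot(inherits(asym, "structure_model"))
  segs <- asym$segments
  for (nm in c(bound, free)) {
    if (is.null(segs[[nm]]))
      stop("configuration error: missing segment '", nm, "'")
  }
  ck <- segs[[cochaperone]]
  if (is.null(ck) || length(ck) == 0) return(asym)
  ib <- segs[[bound]]; ifr <- segs[[free]]
  if (length(ib) != length(ifr))
    stop("bound and free protomers differ in node count (",
         length(ib), " vs ", length(ifr), ")")
  xyz <- coords(asym)
  fit <- superpose(xyz[ib, , drop = FALSE], xyz[ifr, , drop = FALSE])
  copy <- asym$nodes[ck, , drop = FALSE]
  new_xyz <- sweep(tcrossprod(as.matrix(copy[, c("x", "y", "z")]), fit$rotation),
                   2, fit$translation, "+")
  copy$x <- new_xyz[, 1]; copy$y <- new_xyz[, 2]; copy$z <- new_xyz[, 3]
  used <- unique(asym$nodes$chain)
  copy$chain <- setdiff(c(LETTERS, letters, 0:9), used)[1]
  n0 <- n_nodes(asym)
  out_nodes <- rbind(asym$nodes, copy)
  segs[[paste0(cochaperone, "2")]] <- n0 + seq_along(ck)
  structure_model(out_nodes, segments = segs,
                  label = paste0(asym$label, "+sym"))
}
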