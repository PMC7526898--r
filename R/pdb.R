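#' Write C-alpha coordinates as a PDB file
#'
#' One ATOM record per bead (atom name CA), one chain per subunit, 1-based
#' residue numbering within each chain.
#'
#' @param x a \code{fibril_fixture}, or an n x 3 coordinate matrix.
#' @param path output file.
#' @param chains integer chain id per bead (fixtures supply their own).
#' @param resno residue numbers per bead (default 1..n within each chain).
#' @return the path, invisibly.
#' @export
write_ca_pdb <- function(x, path, chains = NULL, resno = NULL) {
  if (inherits(x, "fibril_fixture")) {
    coords <- x$coords; chains <- x$chains; resno <- x$resno
  } else {
    coords <- as.matrix(x)
    if (is.null(chains)) chains <- rep(1L, nrow(coords))
    if (is.null(resno))
      resno <- stats::ave(seq_along(chains), chains, FUN = seq_along)
  }
  n <- nrow(coords)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(coords)),
                   resno = resno, chain = LETTERS[chains],
                   resid = rep("ALA", n), elety = rep("CA", n))
  invisible(path)
}

#' Read a C-alpha reference structure from a PDB file
#'
#' Extracts C-alpha ATOM records per chain (1-based residue numbering
#' preserved) and precomputes the reference contact map under the active
#' contact-map parameters.
#'
#' @param path PDB file.
#' @param params a [contact_map_params()].
#' @return a [reference_structure()] with attributes \code{chains} (integer
#'   subunit id per bead) and \code{resno}.
#' @export
read_reference_pdb <- function(path, params = contact_map_params()) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0) stop("no ATOM records in ", path)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0) stop("no C-alpha ATOM records in ", path)
  for (ch in unique(ca$chain)) {
    rn <- ca$resno[ca$chain == ch]
    if (anyDuplicated(rn))
      stop("duplicate residue number ", rn[duplicated(rn)][1],
           " in chain ", ch)
  }
  coords <- as.matrix(ca[, c("x", "y", "z")])
  rownames(coords) <- NULL
  ref <- reference_structure(coords, params)
  attr(ref, "chains") <- as.integer(factor(ca$chain, levels = unique(ca$chain)))
  attr(ref, "resno") <- ca$resno
  ref
}
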