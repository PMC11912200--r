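# Supercell frame container: an NVT ensemble of configurations with fixed
# box, per-atom roles (O / H1 / H2 / M) and molecule ids. Coordinates are an
# n_frames x n_atoms x 3 array in nm; atoms are molecule-major so molecule m
# occupies a contiguous block.

#' Water-type molecular topology
#'
#' Describes the per-molecule atom roles, masses (amu) and optional
#' virtual-site weights of a rigid-block water model. The virtual site M is
#' the force-field interaction site reconstructed as
#' `w_O * r_O + w_H * r_H1 + w_H * r_H2`; its weights are a force-field
#' property and are therefore supplied, not hard-coded.
#'
#' @param n_mol number of molecules in the supercell.
#' @param masses named numeric vector with elements `O` and `H` (amu).
#' @param vsite_weights length-3 numeric `(w_O, w_H, w_H)` summing to 1, or
#'   `NULL` when the model carries no virtual site.
#' @return an object of class `water_topology`.
#' @export
#' @examples
#' water_topology(16)
water_topology <- function(n_mol,
                           masses = c(O = 15.999, H = 1.008),
                           vsite_weights = NULL) {
  stopifnot(n_mol >= 1, all(c("O", "H") %in% names(masses)))
  if (!is.null(vsite_weights)) {
    if (length(vsite_weights) != 3 || abs(sum(vsite_weights) - 1) > 1e-10) {
      abort("virtual-site weights must be 3 scalars summing to 1 (tol 1e-10)")
    }
  }
  structure(
    list(n_mol = as.integer(n_mol), masses = masses,
         vsite_weights = vsite_weights,
         roles = rep(c("O", "H1", "H2"), n_mol),
         mol_index = rep(seq_len(n_mol), each = 3L)),
    class = "water_topology"
  )
}

#' Construct a supercell frame ensemble
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (nm).
#' @param topology a [water_topology()].
#' @param roles per-atom role tags; defaults to the topology's roles.
#' @param mol_index per-atom molecule id; defaults to the topology's.
#' @param box optional 3 x 3 matrix of box vectors (nm), fixed for the ensemble.
#' @param temperature temperature in kelvin.
#' @return object of class `supercell_frames`.
#' @export
supercell_frames <- function(coords, topology, roles = NULL, mol_index = NULL,
                             box = NULL, temperature = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    abort("coords must be an n_frames x n_atoms x 3 array")
  }
  if (!all(is.finite(coords))) abort("non-finite coordinates in frame ensemble")
  roles <- roles %||% topology$roles
  mol_index <- mol_index %||% topology$mol_index
  if (dim(coords)[2] != length(roles)) {
    abort("atom count does not match role vector")
  }
  for (m in unique(mol_index)) {
    r <- roles[mol_index == m & roles != "M"]
    if (!setequal(r, c("O", "H1", "H2")) || length(r) != 3) {
      abort(sprintf("molecule %d must have exactly one O, H1 and H2", m))
    }
  }
  structure(
    list(coords = coords, roles = roles, mol_index = mol_index,
         topology = topology, box = box, temperature = temperature),
    class = "supercell_frames"
  )
}

#' @export
print.supercell_frames <- function(x, ...) {
  cat(sprintf(
    "<supercell_frames> %d frames, %d atoms (%d molecules)%s\n",
    dim(x$coords)[1], dim(x$coords)[2], x$topology$n_mol,
    if (is.null(x$temperature)) "" else sprintf(", T = %.2f K", x$temperature)
  ))
  invisible(x)
}

n_frames <- function(frames) dim(frames$coords)[1]

atom_indices <- function(frames, role) which(frames$roles == role)

# frames coords flattened to n_frames x (3 * n_atoms), atom-major (x,y,z per atom)
flatten_coords <- function(coords) {
  d <- dim(coords)
  out <- matrix(0, d[1], d[2] * 3)
  out[, seq(1, d[2] * 3, by = 3)] <- coords[, , 1]
  out[, seq(2, d[2] * 3, by = 3)] <- coords[, , 2]
  out[, seq(3, d[2] * 3, by = 3)] <- coords[, , 3]
  out
}

unflatten_coords <- function(mat) {
  n_atoms <- ncol(mat) / 3
  arr <- array(0, c(nrow(mat), n_atoms, 3))
  arr[, , 1] <- mat[, seq(1, ncol(mat), by = 3)]
  arr[, , 2] <- mat[, seq(2, ncol(mat), by = 3)]
  arr[, , 3] <- mat[, seq(3, ncol(mat), by = 3)]
  arr
}
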