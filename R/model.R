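#' Coarse-grained atomic model
#'
#' A bead-level structural model: an N x 3 coordinate matrix plus per-bead
#' scattering length, chain and domain labels, and (for hinged surrogates)
#' the hinge pivot geometry that [sample_conformers()] rotates about.
#'
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @param f per-bead scattering lengths (arbitrary units); recycled.
#' @param chain per-bead chain identifiers; recycled.
#' @param domain per-bead domain labels (e.g. `"Fa"`, `"Fb"`, `"Fc"`).
#' @param element per-bead element symbols; recycled.
#' @param bead_radius nominal bead radius (Angstrom) used for clash tests,
#'   SASA and voxelization defaults.
#' @param hinges named list of hinge descriptors (`pivot`, `axis_bend`,
#'   `axis_arm`), one per mobile domain, or `NULL`.
#' @return An object of class `atomic_model`.
#' @export
atomic_model <- function(xyz, f = 1, chain = "A", domain = "A",
                         element = "C", bead_radius = 2, hinges = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3) stop("xyz must be an N x 3 matrix")
  if (nrow(xyz) < 1) stop("model must contain at least one scatterer")
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  n <- nrow(xyz)
  structure(list(
    xyz = unname(xyz),
    f = rep_len(as.numeric(f), n),
    chain = rep_len(as.character(chain), n),
    domain = rep_len(as.character(domain), n),
    element = rep_len(as.character(element), n),
    bead_radius = bead_radius,
    hinges = hinges
  ), class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("<atomic_model> %d beads, domains: %s, Rg = %.2f A\n",
              nrow(x$xyz), paste(unique(x$domain), collapse = "/"),
              model_rg(x)))
  invisible(x)
}

#' Radius of gyration of a model
#'
#' `Rg = sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with weights `w` equal to
#' the scattering lengths (mass proxies) or 1.
#'
#' @param model an [atomic_model()].
#' @param mass_weighted weight by `model$f` (default) or uniformly.
#' @return Rg in Angstrom.
#' @export
model_rg <- function(model, mass_weighted = TRUE) {
  w <- if (mass_weighted) model$f else rep(1, nrow(model$xyz))
  coords_rg(model$xyz, w)
}

#' Maximum intra-particle distance of a model
#'
#' @param model an [atomic_model()].
#' @return Dmax in Angstrom.
#' @export
model_dmax <- function(model) coords_dmax(model$xyz)

domain_split <- function(model) split(seq_len(nrow(model$xyz)), model$domain)

# Minimum distance between beads of different domains.
min_interdomain_distance <- function(model) {
  idx <- domain_split(model)
  if (length(idx) < 2) return(Inf)
  best <- Inf
  labs <- names(idx)
  for (a in seq_along(labs)) {
    for (b in seq_along(labs)) {
      if (b <= a) next
      A <- model$xyz[idx[[a]], , drop = FALSE]
      B <- model$xyz[idx[[b]], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      best <- min(best, sqrt(max(0, min(d2))))
    }
  }
  best
}

#' Write a model to a PDB file
#'
#' Beads are written as CA pseudo-atoms, one residue per bead, one chain per
#' domain (in the order the domains appear in the model).
#'
#' @param model an [atomic_model()].
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(model, path) {
  n <- nrow(model$xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(model$xyz)),
    resno = seq_len(n),
    resid = rep("ALA", n),
    chain = model$chain,
    elety = rep("CA", n),
    o = rep(1, n),
    b = rep(0, n)
  )
  invisible(path)
}

#' Read a bead model from a PDB file
#'
#' The inverse of [write_model_pdb()]: chains become domains.
#'
#' @param path PDB file path.
#' @param bead_radius nominal bead radius to attach (Angstrom).
#' @return An [atomic_model()].
#' @export
read_model_pdb <- function(path, bead_radius = 2) {
  pdb <- bio3d::read.pdb(path)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  atomic_model(xyz,
               chain = pdb$atom$chain,
               domain = pdb$atom$chain,
               element = substr(trimws(pdb$atom$elety), 1, 1),
               bead_radius = bead_radius)
}
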