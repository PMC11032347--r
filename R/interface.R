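#' Interface patch between two chains
#'
#' The interaction patch is defined by Euclidean distance: it contains
#' exactly the target atoms whose minimum distance to any partner atom is
#' at or below the threshold (6 A by default).  Heavy atoms only unless
#' `include_h` is set; structures are often protonated late and
#' inconsistently, so heavy-atom distances keep heterodimer and
#' protein-ligand treatment uniform.
#'
#' @param target Atom data frame of the target chain (see [chain_atoms()]).
#' @param partner Atom data frame of the partner chain.
#' @param threshold Distance threshold in Angstrom (default 6).
#' @param include_h Include hydrogens/deuteriums in the distance scan.
#' @return List of class `interface_patch` with `atoms` (subset of the
#'   target atoms), `residues` (unique `chain`/`resno`/`resid`),
#'   `threshold`.
#' @export
interface_patch <- function(target, partner, threshold = 6.0,
                            include_h = FALSE) {
  if (!include_h) {
    target <- target[!(toupper(target$elesy) %in% .hydrogen_elements), , drop = FALSE]
    partner <- partner[!(toupper(partner$elesy) %in% .hydrogen_elements), , drop = FALSE]
  }
  if (!nrow(target) || !nrow(partner)) stop("empty chain in interface_patch()")
  inpatch <- .min_dist2(.xyz(target), .xyz(partner)) <= threshold^2
  atoms <- target[inpatch, , drop = FALSE]
  out <- list(atoms = atoms,
              residues = unique(atoms[, c("chain", "resno", "resid")]),
              threshold = threshold)
  class(out) <- "interface_patch"
  out
}

#' Residues in contact with a ligand
#'
#' Protein residues with at least one heavy atom within the threshold of
#' any ligand heavy atom.
#'
#' @param protein Atom data frame of the protein chain.
#' @param lig A [ligand_record()].
#' @param threshold Distance threshold in Angstrom (default 6).
#' @return Data frame `chain`, `resno`, `resid` (possibly empty).
#' @export
ligand_interface_residues <- function(protein, lig, threshold = 6.0) {
  heavy_lig <- ligand_heavy_atoms(lig)
  if (!nrow(heavy_lig)) stop("ligand has no heavy atoms")
  protein <- protein[!(toupper(protein$elesy) %in% .hydrogen_elements), , drop = FALSE]
  if (!nrow(protein))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character()))
  hit <- .min_dist2(.xyz(protein), .xyz(heavy_lig)) <= threshold^2
  unique(protein[hit, c("chain", "resno", "resid")])
}

#' Write a ligand-contact residue list
#'
#' Plain-text `"<resid> <resno> <chain>"` lines, in the style of the
#' published `__interface-residues_6A.txt` files.
#'
#' @param residues Data frame from [ligand_interface_residues()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interface_residues <- function(residues, path) {
  writeLines(sprintf("%s %d %s", residues$resid, residues$resno,
                     residues$chain), path)
  invisible(path)
}

#' Is a cavity orthosteric?
#'
#' A pocket detected on the target is orthosteric when it resides at the
#' partner interface: at least `min_fraction` of its points lie within
#' `threshold` of a partner heavy atom (both comparisons inclusive).
#'
#' @param cav A [cavity()].
#' @param partner Atom data frame of the partner chain (or epitope).
#' @param threshold Distance threshold in Angstrom (default 6).
#' @param min_fraction Minimal qualifying point fraction (default 0.5).
#' @return Logical.
#' @export
is_orthosteric <- function(cav, partner, threshold = 6.0, min_fraction = 0.5) {
  stopifnot(inherits(cav, "cavity"))
  if (!nrow(cav$points)) stop("empty cavity")
  partner <- partner[!(toupper(partner$elesy) %in% .hydrogen_elements), , drop = FALSE]
  if (!nrow(partner)) return(FALSE)
  frac <- mean(.min_dist2(.xyz(cav$points), .xyz(partner)) <= threshold^2)
  frac >= min_fraction
}

#' Classify a liganded pocket (PLOC / PLONC / PLA)
#'
#' Orthosteric pockets are split by the closest approach between ligand
#' heavy atoms and partner-epitope heavy atoms (expressed in the same
#' frame, normally after [superpose_pl_on_hd()]): within `cutoff`
#' (default 1 A, inclusive) is orthosteric competitive (`PLOC`), farther
#' is orthosteric non-competitive (`PLONC`).  Non-orthosteric pockets are
#' allosteric (`PLA`) regardless of the distance.  The ligand must
#' occupy the cavity: at least one ligand heavy atom within
#' `occupancy_dist` of a cavity point.
#'
#' @param cav A [cavity()].
#' @param lig A [ligand_record()].
#' @param partner_epitope Atom data frame of the partner epitope.
#' @param ortho Logical from [is_orthosteric()].
#' @param cutoff Competitive-distance cutoff in Angstrom (default 1).
#' @param occupancy_dist Ligand-to-cavity occupancy distance (default 2 A).
#' @return One of `"PLOC"`, `"PLONC"`, `"PLA"`.
#' @export
classify_ligand_pocket <- function(cav, lig, partner_epitope, ortho,
                                   cutoff = 1.0, occupancy_dist = 2.0) {
  stopifnot(inherits(cav, "cavity"), inherits(lig, "ligand_record"),
            is.logical(ortho), length(ortho) == 1L)
  heavy <- ligand_heavy_atoms(lig)
  if (!nrow(heavy)) stop("ligand has no heavy atoms")
  if (min(.min_dist2(.xyz(heavy), .xyz(cav$points))) > occupancy_dist^2)
    stop("ligand/cavity mismatch: no ligand heavy atom within ",
         occupancy_dist, " A of a cavity point")
  if (!ortho) return("PLA")
  epi <- partner_epitope[!(toupper(partner_epitope$elesy) %in%
                             .hydrogen_elements), , drop = FALSE]
  if (!nrow(epi)) stop("empty partner epitope")
  dmin <- sqrt(min(.min_dist2(.xyz(heavy), .xyz(epi))))
  if (dmin <= cutoff) "PLOC" else "PLONC"
}

# Kabsch rigid-body superposition: rotation/translation mapping P onto Q
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  list(R = R, t = t_vec)
}

#' Superpose a protein-ligand monomer onto its heterodimer
#'
#' Rigid-body least-squares (Kabsch) superposition of the shared chain's
#' common C-alpha atoms (matched by residue number), applied to all atoms
#' of the PL entry.  After superposition the partner epitope of the
#' heterodimer and the PL ligand live in one frame, which is what the
#' PLOC/PLONC distance criterion needs.
#'
#' @param pl A [structure_entry()] with one protein chain.
#' @param hd A [structure_entry()] heterodimer.
#' @param shared_uniprot UniProt accession present in both entries.
#' @return List with `pl` (transformed entry), `rmsd` (C-alpha RMSD after
#'   fit), `rotation`, `translation`, `n_common` and the matched chain
#'   labels `pl_chain`, `hd_chain`.
#' @export
superpose_pl_on_hd <- function(pl, hd, shared_uniprot) {
  stopifnot(inherits(pl, "structure_entry"), inherits(hd, "structure_entry"))
  find_chain <- function(e) {
    ch <- protein_chains(e)
    hit <- ch[!is.na(e$uniprot[ch]) & e$uniprot[ch] == shared_uniprot]
    if (!length(hit)) stop("no chain mapped to ", shared_uniprot,
                           " in entry ", e$entry_id)
    hit[1L]
  }
  pc <- find_chain(pl); hc <- find_chain(hd)
  ca_of <- function(e, ch) {
    a <- chain_atoms(e, ch)
    a <- a[a$elety == "CA" & (a$alt == "" | a$alt == "A"), , drop = FALSE]
    a[!duplicated(a$resno), , drop = FALSE]
  }
  pa <- ca_of(pl, pc); ha <- ca_of(hd, hc)
  common <- intersect(pa$resno, ha$resno)
  if (length(common) < 3L)
    stop("need at least 3 common C-alpha residues, found ", length(common))
  P <- .xyz(pa[match(common, pa$resno), ])
  Q <- .xyz(ha[match(common, ha$resno), ])
  fit <- .kabsch(P, Q)
  Pf <- sweep(tcrossprod(P, fit$R), 2L, fit$t, "+")
  rmsd <- sqrt(mean(rowSums((Pf - Q)^2)))
  all_xyz <- .xyz(pl$atoms)
  moved <- sweep(tcrossprod(all_xyz, fit$R), 2L, fit$t, "+")
  pl$atoms$x <- moved[, 1L]; pl$atoms$y <- moved[, 2L]; pl$atoms$z <- moved[, 3L]
  list(pl = pl, rmsd = rmsd, rotation = fit$R, translation = fit$t,
       n_common = length(common), pl_chain = pc, hd_chain = hc)
}
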