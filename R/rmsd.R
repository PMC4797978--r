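#' In-place heavy-atom RMSD against a crystal reference
#'
#' Computes `sqrt(mean(||r_ref(i) - r_pose(map(i))||^2))` over the mapped
#' heavy atoms, in the shared coordinate frame. No superposition is
#' performed: the whole point of a cross-docking RMSD is that receptors are
#' pre-aligned, so a fitted RMSD would hide binding-mode errors.
#'
#' @param reference A [molecule]: the crystal pose. Hydrogens are dropped
#'   before mapping.
#' @param pose_coords Matrix of pose coordinates (one row per reference
#'   heavy atom, columns x/y/z, Angstrom).
#' @param mapping Integer vector mapping reference heavy-atom index `i` to
#'   pose row `mapping[i]`; must be a bijection. Default: identity.
#' @return An `rmsd_value`: list with `value` (Angstrom), `mapping`
#'   (the mapping used) and `symmetry_corrected` (here `FALSE`).
#' @seealso [symmetry_min_rmsd()] for the symmetry-corrected version.
#' @export
rmsd_in_place <- function(reference, pose_coords, mapping = NULL) {
  ref_xyz <- coords(reference, heavy_only = TRUE)
  pose_coords <- as.matrix(pose_coords)
  n <- nrow(ref_xyz)
  if (n == 0) {
    abort("reference has no heavy atoms", class = "crossdockr_mapping_error")
  }
  if (nrow(pose_coords) != n || ncol(pose_coords) != 3) {
    abort(sprintf(
      "pose has %d coordinate rows but the reference has %d heavy atoms",
      nrow(pose_coords), n), class = "crossdockr_correspondence_error")
  }
  if (is.null(mapping)) mapping <- seq_len(n)
  check_bijection(mapping, n)
  new_rmsd_value(rmsd_given_mapping(ref_xyz, pose_coords, mapping),
                 mapping, symmetry_corrected = FALSE)
}

check_bijection <- function(mapping, n) {
  if (length(mapping) != n || anyNA(mapping) ||
      !setequal(mapping, seq_len(n))) {
    abort("mapping is not a bijection on the heavy-atom set",
          class = "crossdockr_mapping_error")
  }
}

rmsd_given_mapping <- function(ref_xyz, pose_xyz, mapping) {
  d <- ref_xyz - pose_xyz[mapping, , drop = FALSE]
  sqrt(sum(d * d) / nrow(ref_xyz))
}

new_rmsd_value <- function(value, mapping, symmetry_corrected) {
  structure(list(value = value, mapping = mapping,
                 symmetry_corrected = symmetry_corrected),
            class = "rmsd_value")
}

#' @export
print.rmsd_value <- function(x, ...) {
  cat(sprintf("RMSD %.4f A (%s)\n", x$value,
              if (x$symmetry_corrected) "symmetry-corrected"
              else "identity mapping"))
  invisible(x)
}

#' @export
as.double.rmsd_value <- function(x, ...) x$value

#' Symmetry-corrected RMSD
#'
#' The minimum of [rmsd_in_place()] over every element- and bond-preserving
#' automorphism of the reference's heavy-atom graph. Topologically
#' equivalent atoms (the two oxygens of a carboxylate, ring atoms under a
#' rotation) are thereby never over-penalised by an arbitrary file-order
#' correspondence. Bonds are perceived by covalent-radius distance when the
#' reference carries none (PDB input).
#'
#' Automorphisms are enumerated by closing the generator set reported by
#' bliss (via igraph) under composition. If the automorphism group exceeds
#' `max_mappings`, the identity mapping is used instead, a warning is
#' emitted, and `symmetry_corrected` is `FALSE` in the result — a
#' pathological ligand must not hang a grid of thousands of cells.
#'
#' @inheritParams rmsd_in_place
#' @param max_mappings Enumeration cap on the automorphism group order.
#' @return An `rmsd_value`; `mapping` holds the argmin correspondence.
#' @export
#' @examples
#' # O=C=O with its two oxygens swapped in the pose: RMSD 0, not 2.33
#' co2 <- molecule(data.frame(name = c("O1", "C", "O2"),
#'                            element = c("O", "C", "O"),
#'                            x = c(-1.16, 0, 1.16), y = 0, z = 0))
#' swapped <- coords(co2)[c(3, 2, 1), ]
#' symmetry_min_rmsd(co2, swapped)$value
symmetry_min_rmsd <- function(reference, pose_coords, max_mappings = 10000) {
  ref_h <- heavy_atoms(reference)
  if (nrow(ref_h$bonds) == 0 && n_atoms(ref_h) > 1) {
    ref_h <- perceive_bonds(ref_h)
  }
  ref_xyz <- coords(ref_h)
  pose_coords <- as.matrix(pose_coords)
  n <- nrow(ref_xyz)
  if (n == 0) {
    abort("reference has no heavy atoms", class = "crossdockr_mapping_error")
  }
  if (nrow(pose_coords) != n || ncol(pose_coords) != 3) {
    abort(sprintf(
      "pose has %d coordinate rows but the reference has %d heavy atoms",
      nrow(pose_coords), n), class = "crossdockr_correspondence_error")
  }
  autos <- enumerate_automorphisms(ref_h, max_mappings)
  if (is.null(autos)) {
    warn(sprintf(
      "automorphism group of '%s' exceeds %d mappings; using identity",
      reference$name, max_mappings))
    return(new_rmsd_value(
      rmsd_given_mapping(ref_xyz, pose_coords, seq_len(n)),
      seq_len(n), symmetry_corrected = FALSE))
  }
  best_val <- Inf
  best_map <- seq_len(n)
  for (map in autos) {
    v <- rmsd_given_mapping(ref_xyz, pose_coords, map)
    if (v < best_val) {
      best_val <- v
      best_map <- map
    }
  }
  new_rmsd_value(best_val, best_map, symmetry_corrected = TRUE)
}

#' Enumerate element-preserving graph automorphisms of a molecule
#'
#' @param mol A [molecule] whose bond list defines the graph (heavy atoms
#'   expected; no subsetting is done here).
#' @param max_mappings Give up (return `NULL`) when the group order exceeds
#'   this.
#' @return A list of integer permutations (the identity first), or `NULL`
#'   when the group is larger than `max_mappings`.
#' @keywords internal
enumerate_automorphisms <- function(mol, max_mappings = 10000) {
  n <- n_atoms(mol)
  if (n == 1) return(list(1L))
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(mol$bonds) > 0) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
  }
  colors <- as.integer(factor(mol$atoms$element))
  info <- igraph::count_automorphisms(g, colors = colors)
  size <- suppressWarnings(as.numeric(info$group_size %||% info))
  if (!is.finite(size) || size > max_mappings) return(NULL)
  gens <- igraph::automorphism_group(g, colors = colors)
  gens <- lapply(gens, as.integer)
  close_permutation_group(gens, n, max_mappings)
}

# BFS closure of a permutation group from its generators.
close_permutation_group <- function(generators, n, cap) {
  identity_p <- seq_len(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  assign(key(identity_p), TRUE, envir = seen)
  out <- list(identity_p)
  frontier <- list(identity_p)
  while (length(frontier) > 0) {
    nxt <- list()
    for (p in frontier) {
      for (gen in generators) {
        q <- gen[p]  # apply p, then gen
        k <- key(q)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          out[[length(out) + 1L]] <- q
          nxt[[length(nxt) + 1L]] <- q
          if (length(out) > cap) return(NULL)
        }
      }
    }
    frontier <- nxt
  }
  out
}

#' Match pose atoms to reference atoms by name
#'
#' The default correspondence between a reference ligand and an engine pose
#' is positional (the pose is the engine's transform of the submitted
#' file, in the same atom order). For engines that reorder atoms, this
#' builds the mapping from atom names instead.
#'
#' @param reference,pose [molecule]s with matching heavy-atom name sets
#'   (names must be unique within each).
#' @return Integer mapping suitable for [rmsd_in_place()]: element `i`
#'   gives the pose heavy-atom row matching reference heavy atom `i`.
#' @export
map_atoms_by_name <- function(reference, pose) {
  rn <- heavy_atoms(reference)$atoms$name
  pn <- heavy_atoms(pose)$atoms$name
  if (anyDuplicated(rn) || anyDuplicated(pn)) {
    abort("atom names are not unique; name-based matching is ambiguous",
          class = "crossdockr_mapping_error")
  }
  m <- match(rn, pn)
  if (anyNA(m)) {
    abort(paste0("pose lacks atom(s) named: ",
                 paste(rn[is.na(m)], collapse = ", ")),
          class = "crossdockr_mapping_error")
  }
  m
}
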