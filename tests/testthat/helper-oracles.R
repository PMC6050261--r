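# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force single-linkage partition at threshold eps: iterative merge
# of any two groups containing a pair within eps.
brute_components <- function(dist_mat, eps) {
  n <- nrow(dist_mat)
  labels <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (dist_mat[i, j] <= eps && labels[i] != labels[j]) {
          labels[labels == labels[j]] <- labels[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(labels, unique(labels))
}

# Partition of pose ids induced by cluster_poses output, as a canonical
# sorted list of sorted member vectors.
canonical_partition <- function(groups) {
  out <- lapply(groups, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}

# Brute-force enumeration of embeddings of `core` into `glycan`: try every
# assignment of the core root onto each glycan residue and extend over
# edges requiring exact (name, anomer, child_pos, parent_pos) equality.
brute_embeddings <- function(glycan, core) {
  out <- list()
  try_root <- function(gid) {
    assign_rec <- function(cid, gid) {
      cr <- core$residues[core$residues$id == cid, ]
      gr <- glycan$residues[glycan$residues$id == gid, ]
      if (cr$name != gr$name || cr$anomer != gr$anomer) return(NULL)
      m <- stats::setNames(gid, cid)
      ce <- core$edges[core$edges$parent == cid, , drop = FALSE]
      for (k in seq_len(nrow(ce))) {
        ge <- glycan$edges[glycan$edges$parent == gid &
                             glycan$edges$parent_pos == ce$parent_pos[k] &
                             glycan$edges$child_pos == ce$child_pos[k], ,
                           drop = FALSE]
        if (nrow(ge) != 1) return(NULL)
        sub <- assign_rec(ce$child[k], ge$child[1])
        if (is.null(sub)) return(NULL)
        m <- c(m, sub)
      }
      m
    }
    assign_rec(core$root, gid)
  }
  for (gid in glycan$residues$id) {
    m <- try_root(gid)
    if (!is.null(m)) out[[length(out) + 1]] <- m
  }
  out
}

# A small ligand of two labelled protons at controlled positions, plus a
# receptor of one proton, for closed-form STD checks.
two_proton_system <- function(dA = 3, dB = 6) {
  ligand <- structure3d(data.frame(
    name = c("HA", "HB"), element = "H", resid = 1L, residue = "Lig",
    x = c(dA, -dB), y = 0, z = 0))
  receptor <- structure3d(data.frame(
    name = "HR", element = "H", resid = 1L, residue = "pocket",
    x = 0, y = 0, z = 0))
  list(ligand = ligand, receptor = receptor)
}

# Random rigid pose ensemble used by clustering property tests: poses of
# a 4-atom rigid body translated by random offsets.
random_pose_set <- function(n, seed, spread = 3) {
  set.seed(seed)
  base <- structure3d(data.frame(
    name = c("C1", "C2", "C3", "O1"), element = c("C", "C", "C", "O"),
    resid = 1L, residue = "Lig",
    x = c(0, 1.5, 3.0, 4.2), y = c(0, 0.8, 0, 0.5), z = 0))
  lapply(seq_len(n), function(i) {
    st <- transform_structure(base, t = stats::rnorm(3, sd = spread))
    pose_record(sprintf("p%03d", i), st, model = "M", protocol = "rigid",
                rotamer = 1L, snapshot = i,
                score = round(stats::runif(1, -9, -4), 3))
  })
}
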