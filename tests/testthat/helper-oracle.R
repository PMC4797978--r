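# Brute-force mapping oracle: the minimum in-place RMSD over ALL
# element-preserving bijections of the heavy atoms that preserve adjacency.
# Independent of the package's automorphism route (igraph + group closure):
# this enumerates raw permutations and filters.

all_perms <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- if (n == 1) list(1L) else {
      sub <- all_perms(n - 1)
      out <- vector("list", n * length(sub))
      k <- 0L
      for (s in sub) {
        for (pos in seq_len(n)) {
          k <- k + 1L
          out[[k]] <- as.integer(append(s, n, after = pos - 1))
        }
      }
      out
    }
    cache[[key]] <<- p
    p
  }
})

brute_force_min_rmsd <- function(mol, pose_xyz) {
  h <- crossdockr::heavy_atoms(mol)
  n <- crossdockr::n_atoms(h)
  el <- h$atoms$element
  adj <- matrix(FALSE, n, n)
  if (nrow(h$bonds) > 0) {
    adj[cbind(h$bonds$i, h$bonds$j)] <- TRUE
    adj[cbind(h$bonds$j, h$bonds$i)] <- TRUE
  }
  ref <- crossdockr::coords(h)
  best <- Inf
  for (p in all_perms(n)) {
    if (any(el[p] != el)) next
    if (!identical(adj[p, p, drop = FALSE], adj)) next
    d <- ref - pose_xyz[p, , drop = FALSE]
    v <- sqrt(sum(d * d) / n)
    if (v < best) best <- v
  }
  best
}

# A pose for a reference molecule: atoms shuffled within element classes
# (sometimes by a true automorphism), jittered and translated.
random_pose <- function(mol, seed, jitter = 0.3) {
  withr::with_seed(seed, {
    xyz <- crossdockr::coords(mol, heavy_only = TRUE)
    n <- nrow(xyz)
    el <- crossdockr::heavy_atoms(mol)$atoms$element
    perm <- seq_len(n)
    for (e in unique(el)) {
      idx <- which(el == e)
      if (length(idx) > 1) perm[idx] <- sample(idx)
    }
    xyz[perm, , drop = FALSE] +
      matrix(stats::rnorm(3 * n, sd = jitter), n, 3) +
      matrix(stats::runif(3, -2, 2), n, 3, byrow = TRUE)
  })
}

# Oracle-vs-implementation comparison over a mixed bag of random and
# deliberately symmetric molecules; returns max absolute disagreement.
oracle_disagreement <- function(n_trials, seed_base = 100) {
  worst <- 0
  for (t in seq_len(n_trials)) {
    mol <- switch((t %% 4) + 1,
      crossdockr::random_molecule(3 + (t %% 5), seed = seed_base + t),
      crossdockr::random_molecule(4 + (t %% 4), seed = seed_base + t,
                                  elements = c("C", "C", "N")),
      swap_pair_molecule(),
      ring_molecule(5 + (t %% 3))
    )
    pose <- random_pose(mol, seed = seed_base + 1000 + t)
    got <- crossdockr::symmetry_min_rmsd(mol, pose)$value
    want <- brute_force_min_rmsd(mol, pose)
    worst <- max(worst, abs(got - want))
  }
  worst
}

swap_pair_molecule <- function() {
  crossdockr::molecule(
    data.frame(name = c("O1", "C1", "O2", "C2"),
               element = c("O", "C", "O", "C"),
               x = c(-1.2, 0, 1.2, 0), y = c(0, 0, 0, 1.5), z = 0),
    bonds = data.frame(i = c(1, 2, 2), j = c(2, 3, 4)))
}

ring_molecule <- function(n) {
  r <- 1.4 / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  crossdockr::molecule(
    data.frame(name = paste0("C", seq_len(n)), element = "C",
               x = r * cos(ang), y = r * sin(ang), z = 0),
    bonds = data.frame(i = seq_len(n), j = c(seq_len(n)[-1], 1)))
}
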