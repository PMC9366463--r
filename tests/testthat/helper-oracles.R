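# Independent oracles and fixture builders used across the test files.

# Brute-force JC likelihood by enumerating all internal-node states.
# tree: timetree; states: integer matrix (tips x sites, 1..4); rate converts
# durations to substitutions.
enumerate_jc_loglik <- function(tree, states, rate) {
  phy <- tree$phy
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  E <- phy$edge
  en <- rate * (tree$ages[E[, 1]] - tree$ages[E[, 2]])
  ptrans <- lapply(en, function(n) {
    ps <- 0.25 + 0.75 * exp(-4 / 3 * n)
    pd <- (1 - ps) / 3
    m <- matrix(pd, 4, 4); diag(m) <- ps; m
  })
  internal <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  tipmap <- match(phy$tip.label, rownames(states))
  total <- 0
  for (site in seq_len(ncol(states))) {
    sl <- 0
    for (g in seq_len(nrow(grid))) {
      assign_state <- integer(nn)
      assign_state[seq_len(ntip)] <- states[tipmap, site]
      assign_state[internal] <- grid[g, ]
      p <- 0.25
      for (e in seq_len(nrow(E))) {
        p <- p * ptrans[[e]][assign_state[E[e, 1]], assign_state[E[e, 2]]]
      }
      sl <- sl + p
    }
    total <- total + log(sl)
  }
  total
}

# Random ultrametric timetree on n tips with unique labels.
random_timetree <- function(n, labels = paste0("t", seq_len(n))) {
  as_timetree(ape::rcoal(n, tip.label = labels))
}

# JC expected mismatch proportion at total path length d (substitutions).
jc_mismatch <- function(d) 0.75 * (1 - exp(-4 / 3 * d))

# MRCA ages of every tip pair of a timetree, as a named matrix.
pair_mrca_ages <- function(tree) {
  phy <- tree$phy
  mr <- ape::mrca(phy)
  ages <- matrix(tree$ages[mr], nrow(mr), ncol(mr),
                 dimnames = dimnames(mr))
  ages
}
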