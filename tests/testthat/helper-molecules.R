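## Shared fixtures: the reference library is read once per test run.
ref_lib <- referenceLibrary(graphs = TRUE)
ref_by_name <- function(nm) ref_lib[[which(vapply(ref_lib, `[[`, "", "name") == nm)]]

all_tables <- lapply(c("dHvap", "dHsub", "dHsolv", "dSfus", "tpcE"), loadTable)
names(all_tables) <- c("dHvap", "dHsub", "dHsolv", "dSfus", "tpcE")

## order-independent comparison of named count vectors
expect_same_counts <- function(got, want) {
  got <- got[order(names(got))]
  want <- want[order(names(want))]
  expect_identical(names(got), names(want))
  expect_equal(unname(as.integer(got)), unname(as.integer(want)))
}

## permute the atoms of a MolecularGraph (for order-invariance properties)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  a <- atomTable(g)[perm, , drop = FALSE]
  rownames(a) <- NULL
  b <- bondTable(g)
  b$a1 <- inv[b$a1]
  b$a2 <- inv[b$a2]
  new("MolecularGraph", atoms = a, bonds = b, name = molName(g),
      properties = molProperties(g))
}

## canonical invariants used as a graph-isomorphism proxy
graph_signature <- function(g) {
  a <- atomTable(g)
  atom_sig <- sort(paste(a$element, a$charge, a$implicit_h,
                         a$hybridization, a$ring_min))
  b <- bondTable(g)
  ends <- function(k) sort(c(a$element[b$a1[k]], a$element[b$a2[k]]))
  bond_sig <- sort(vapply(seq_len(nrow(b)), function(k)
    paste(paste(ends(k), collapse = "-"), b$order[k]), character(1)))
  list(atoms = atom_sig, bonds = bond_sig)
}

## a small abstract synthetic problem used across fitter/validation tests
make_synth <- function(n = 200, noise = 2, seed = 11, p = 6) {
  vocab <- paste0("G", seq_len(p))
  coefs <- stats::setNames(seq(3, 3 * p, length.out = p), vocab)
  generateSyntheticTraining(
    syntheticSpec(vocab, coefs, constant = 5, n = n,
                  noise_sigma = noise, seed = seed))
}
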