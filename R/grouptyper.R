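#' @include AllClasses.R chemgraph.R
NULL

## Canonical orderings of the descriptor grammar.
.ELEMENT_ORDER <- c("B", "C", "N", "O", "S", "P", "Si", "F", "Cl", "Br", "J")
.MARKER_ORDER <- c("", "=", "#", ":")
.BOND_MARKER <- c(single = "", double = "=", triple = "#", aromatic = ":")

## Is atom i a typed center? Halogens and terminal multiply-bonded atoms
## (carbonyl O, nitrile N, thiocarbonyl S, the oxygens of a nitro group,
## ...) have no center rows in the vocabulary: they are absorbed into the
## neighbour descriptors of the atoms they decorate.
.isCenter <- function(atoms, degree, i) {
  if (atoms$element[i] %in% .HALOGENS) return(FALSE)
  atoms$implicit_h[i] >= 1L || degree[i] >= 2L
}

## neighbour bond indices per atom
.heavyDegree <- function(g) {
  n <- atomCount(g)
  d <- integer(n)
  for (k in seq_len(nrow(g@bonds))) {
    d[g@bonds$a1[k]] <- d[g@bonds$a1[k]] + 1L
    d[g@bonds$a2[k]] <- d[g@bonds$a2[k]] + 1L
  }
  d
}

## central-atom type label, e.g. "C sp3", "N(+) sp2", "O", "P4", "S2"
.atomTypeLabel <- function(g, i, bondsum) {
  a <- g@atoms
  el <- a$element[i]; hyb <- a$hybridization[i]; q <- a$charge[i]
  qs <- if (q > 0L) "(+)" else if (q < 0L) "(-)" else ""
  switch(el,
    C = paste0("C", qs, " ", hyb),
    N = paste0("N", qs, " ", hyb),
    O = paste0("O", qs),
    S = paste0("S", qs, if (bondsum[i] > 2) "4" else "2"),
    P = paste0("P", qs, if (bondsum[i] > 3) "4" else "3"),
    Si = paste0("Si", qs),
    B = paste0("B", qs),
    paste0(el, qs))
}

## heavy-atom bond-order sum (aromatic = 1.5, floored), used for S2/S4 and
## P3/P4 discrimination
.bondOrderSums <- function(g) {
  n <- atomCount(g)
  s <- numeric(n)
  val <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  for (k in seq_len(nrow(g@bonds))) {
    v <- val[[g@bonds$order[k]]]
    s[g@bonds$a1[k]] <- s[g@bonds$a1[k]] + v
    s[g@bonds$a2[k]] <- s[g@bonds$a2[k]] + v
  }
  floor(s) + g@atoms$implicit_h
}

#' Assign the atom-group key of one heavy atom
#'
#' Encodes the central atom (element, hybridization, formal charge) and its
#' immediate neighbourhood as the canonical descriptor string of the group
#' vocabulary, e.g. \code{"C sp3|H2CO"} for the methylene carbon of ethanol
#' or \code{"N(+) sp2|CO=O(-)"} for a nitro nitrogen. Neighbour tokens are
#' ordered by element (B, C, N, O, S, P, Si, F, Cl, Br, J) and, within one
#' element, by bond marker (single, \code{=}, \code{#}, \code{:}); iodine is
#' spelled \code{J}; neighbour formal charges are appended to the element
#' run; sp3 nitrogen, ether-type oxygen and divalent sulfur centers carry a
#' \code{(pi)}/\code{(2pi)}/\code{(3pi)} suffix counting C and N neighbours
#' engaged in a pi system (aromatic, sp2 or sp).
#'
#' @param g a perceived \code{MolecularGraph}.
#' @param i heavy-atom index.
#' @return the group key string, or \code{NA_character_} if the atom is not
#'   a typed center (hydrogen-, halogen- or terminal multiply-bonded
#'   decoration atoms) or no grammar production matches.
#' @export
typeAtom <- function(g, i) {
  degree <- .heavyDegree(g)
  bondsum <- .bondOrderSums(g)
  .typeAtomFast(g, i, degree, bondsum)
}

.typeAtomFast <- function(g, i, degree, bondsum) {
  a <- g@atoms; b <- g@bonds
  if (!.isCenter(a, degree, i)) return(NA_character_)
  if (!a$element[i] %in% .ALLOWED_ELEMENTS) return(NA_character_)

  ks <- which(b$a1 == i | b$a2 == i)
  nb_idx <- ifelse(b$a1[ks] == i, b$a2[ks], b$a1[ks])
  nb_el <- a$element[nb_idx]
  nb_el[nb_el == "I"] <- "J"
  nb_marker <- unname(.BOND_MARKER[b$order[ks]])
  nb_charge <- a$charge[nb_idx]
  if (any(!a$element[nb_idx] %in% .ALLOWED_ELEMENTS)) return(NA_character_)

  ## aggregate per (element, marker), charges collected per element run
  parts <- character()
  h <- a$implicit_h[i]
  if (h > 0L) parts <- c(parts, paste0("H", if (h > 1L) h else ""))
  for (el in .ELEMENT_ORDER) {
    sel_el <- nb_el == el
    if (!any(sel_el)) next
    run <- character()
    for (mk in .MARKER_ORDER) {
      cnt <- sum(sel_el & nb_marker == mk)
      if (cnt > 0L)
        run <- c(run, paste0(mk, el, if (cnt > 1L) cnt else ""))
    }
    npos <- sum(nb_charge[sel_el] > 0L)
    nneg <- sum(nb_charge[sel_el] < 0L)
    run <- paste0(paste0(run, collapse = ""),
                  strrep("(+)", npos), strrep("(-)", nneg))
    parts <- c(parts, run)
  }
  desc <- paste0(parts, collapse = "")

  ## pi annotation for sp3 N, divalent S and ether-type O centers
  atype <- .atomTypeLabel(g, i, bondsum)
  base <- sub("\\(.\\)", "", atype)  # strip center charge for the test
  pi_typed <- (a$element[i] == "N" && a$hybridization[i] == "sp3") ||
    (a$element[i] == "O" && degree[i] >= 1L && !a$aromatic[i]) ||
    (a$element[i] == "S" && bondsum[i] <= 2)
  if (pi_typed) {
    ## only C and N neighbours carry the annotation: an sp2-typed
    ## phosphorus or sulfur (phosphate, sulfone) leaves the plain spelling
    ## (the vocabulary writes "O|CP" for trialkyl phosphates but
    ## "O|CN(+)(pi)" for nitrate esters)
    k_pi <- sum(a$element[nb_idx] %in% c("C", "N") &
                  (a$aromatic[nb_idx] |
                     a$hybridization[nb_idx] %in% c("sp2", "sp", "aromatic")))
    if (k_pi >= 1L)
      desc <- paste0(desc, "(", if (k_pi > 1L) k_pi else "", "pi)")
  }
  paste0(atype, "|", desc)
}

#' Count endocyclic single bonds
#'
#' The number of ring bonds of single order; aromatic, double and triple
#' ring bonds are never counted. This is the "Endocyclic bonds" special
#' group of the entropy models, accounting for the reduced conformational
#' freedom of single bonds locked in rings.
#'
#' @param g a perceived \code{MolecularGraph}.
#' @return integer count.
#' @export
countEndocyclicSingleBonds <- function(g) {
  sum(g@bonds$in_ring & g@bonds$order == "single")
}

#' Count small-ring angle-strain groups
#'
#' Angle60 counts ring atoms whose smallest ring is three-membered, Angle90
#' four-membered and Angle102 five-membered: one count per ring atom. These
#' groups counterbalance the endocyclic-bond correction in small rings.
#'
#' @param g a perceived \code{MolecularGraph}.
#' @return named integer vector \code{c(Angle60=, Angle90=, Angle102=)}.
#' @export
countAngleGroups <- function(g) {
  rm <- g@atoms$ring_min
  c(Angle60 = sum(rm == 3L), Angle90 = sum(rm == 4L),
    Angle102 = sum(rm == 5L))
}

#' Pure-hydrocarbon per-carbon correction
#'
#' Molecules containing only carbon and hydrogen receive a correction for
#' each carbon atom: "Alkane/No. of C atoms" when fully saturated,
#' "Unsaturated HC/No. of C atoms" when any multiple bond or aromatic ring
#' is present. Other molecules receive none.
#'
#' @param g a perceived \code{MolecularGraph}.
#' @return list with \code{key} (special-group name or NA) and \code{count}.
#' @export
countHydrocarbonCorrection <- function(g) {
  el <- g@atoms$element
  if (length(el) == 0L || !all(el == "C"))
    return(list(key = NA_character_, count = 0L))
  unsat <- any(g@bonds$order != "single")
  key <- if (unsat) "Unsaturated HC/No. of C atoms" else "Alkane/No. of C atoms"
  list(key = key, count = length(el))
}

#' Count intramolecular hydrogen-bond motifs
#'
#' A topological surrogate for intramolecular acid-base interactions: one
#' count per unordered donor-acceptor pair where the donor is an N, O or S
#' atom carrying at least one hydrogen, the acceptor is an N or O atom with
#' a lone pair (formal charge <= 0) and the two heteroatoms are separated
#' by exactly 3 or 4 bonds, closing a 5- or 6-membered hydrogen-bonded
#' ring. Salicylaldehyde counts 1 (phenol OH to the ortho carbonyl oxygen),
#' ethylene glycol counts 1 (one reciprocal OH/OH pair), phenol counts 0.
#'
#' @param g a perceived \code{MolecularGraph}.
#' @return integer count (the "H/H Acceptor" special group).
#' @export
countHAcceptor <- function(g) {
  a <- g@atoms
  donors <- which(a$element %in% c("N", "O", "S") & a$implicit_h >= 1L)
  acceptors <- which(a$element %in% c("N", "O") & a$charge <= 0L)
  if (!length(donors) || !length(acceptors)) return(0L)
  dist <- .bondDistances(g)
  count <- 0L
  seen <- matrix(FALSE, atomCount(g), atomCount(g))
  for (d in donors) for (acc in acceptors) {
    if (d == acc || seen[d, acc]) next
    if (dist[d, acc] %in% c(3L, 4L)) {
      count <- count + 1L
      seen[d, acc] <- TRUE; seen[acc, d] <- TRUE
    }
  }
  count
}

## all-pairs topological distances (BFS per atom)
.bondDistances <- function(g) {
  n <- atomCount(g)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g@bonds))) {
    adj[[g@bonds$a1[k]]] <- c(adj[[g@bonds$a1[k]]], g@bonds$a2[k])
    adj[[g@bonds$a2[k]]] <- c(adj[[g@bonds$a2[k]]], g@bonds$a1[k])
  }
  d <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) if (is.na(d[s, w])) {
        d[s, w] <- d[s, v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  d
}

#' Decompose a molecule into its feature vector
#'
#' Fragments a perceived molecule into atom-centered groups (every typed
#' heavy atom contributes exactly one group count) and evaluates the seven
#' whole-molecule special groups. The result is independent of atom order.
#'
#' @param g a perceived \code{MolecularGraph}.
#' @return a [FeatureVector].
#' @examples
#' if (requireNamespace("ChemmineOB", quietly = TRUE)) {
#'   fragmentMolecule(readSMILES("CCO", "ethanol"))
#' }
#' @export
fragmentMolecule <- function(g) {
  n <- atomCount(g)
  specials <- stats::setNames(integer(length(.SPECIAL_GROUPS)), .SPECIAL_GROUPS)
  if (!all(g@atoms$element %in% .ALLOWED_ELEMENTS)) {
    return(new("FeatureVector", groups = integer(), specials = specials,
               untypable = integer(), decorations = integer(),
               n_heavy = n, out_of_scope = TRUE))
  }
  degree <- .heavyDegree(g)
  bondsum <- .bondOrderSums(g)
  keys <- vapply(seq_len(n), function(i)
    .typeAtomFast(g, i, degree, bondsum), character(1))
  centers <- vapply(seq_len(n), function(i)
    .isCenter(g@atoms, degree, i), logical(1))
  untypable <- which(centers & is.na(keys))
  decorations <- which(!centers)
  tab <- table(keys[!is.na(keys)])
  groups <- stats::setNames(as.integer(tab), names(tab))
  groups <- groups[order(names(groups))]

  hc <- countHydrocarbonCorrection(g)
  if (!is.na(hc$key)) specials[hc$key] <- hc$count
  specials["H/H Acceptor"] <- countHAcceptor(g)
  specials["Endocyclic bonds"] <- countEndocyclicSingleBonds(g)
  ang <- countAngleGroups(g)
  specials[names(ang)] <- ang

  new("FeatureVector", groups = groups, specials = specials,
      untypable = as.integer(untypable),
      decorations = as.integer(decorations),
      n_heavy = n, out_of_scope = FALSE)
}
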