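#' @include AllClasses.R
NULL

## ---- internal: V2000 helpers -------------------------------------------

## old-style atom-block charge codes (column 37-39 of a V2000 atom line)
.chargeFromCode <- function(code) {
  c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
    `5` = -1L, `6` = -2L, `7` = -3L)[as.character(code)]
}

## Formal charges of one V2000 record, taken from the atom-block charge
## column and overridden by M CHG lines (which ChemmineR ignores).
.chargesFromLines <- function(lines, natoms) {
  charges <- integer(natoms)
  atom_lines <- lines[5:(4 + natoms)]
  code <- suppressWarnings(as.integer(substr(atom_lines, 37L, 39L)))
  code[is.na(code)] <- 0L
  charges <- unname(.chargeFromCode(code))
  chg <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg)) {
    charges[] <- 0L  # presence of M CHG supersedes the atom-block column
    for (l in chg) {
      v <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7L)),
                                                "[[:space:]]+")[[1]]))
      n <- v[1L]
      for (i in seq_len(n)) {
        at <- v[2L * i]; val <- v[2L * i + 1L]
        if (!is.na(at) && at >= 1L && at <= natoms) charges[at] <- val
      }
    }
  }
  charges
}

## Default valence model used to derive implicit hydrogen counts.
.implicitH <- function(element, charge, bondsum) {
  val <- switch(element,
    B = 3L, C = 4L, N = 3L, O = 2L, Si = 4L,
    P = if (bondsum > 3) 5L else 3L,
    S = if (bondsum > 4) 6L else if (bondsum > 2) 4L else 2L,
    F = 1L, Cl = 1L, Br = 1L, I = 1L, H = 1L,
    0L)
  if (element %in% c("N", "O")) val <- val + charge
  else if (element == "C" && charge != 0L) val <- val - abs(charge)
  else if (element == "S" && charge > 0L) val <- val + charge
  max(0L, as.integer(val - bondsum))
}

## atom/bond counts of a V2000 record
.recordCounts <- function(lines) {
  c(natoms = suppressWarnings(as.integer(substr(lines[4L], 1L, 3L))),
    nbonds = suppressWarnings(as.integer(substr(lines[4L], 4L, 6L))))
}

## Build a perceived MolecularGraph from one SDF record given as an
## ChemmineR SDF object plus its raw text lines (for charge recovery).
## ChemmineR refuses records without bonds (single heavy atoms), so for
## those the atom block is taken from the raw lines directly (sdf = NULL).
.graphFromRecord <- function(sdf, lines, name = NULL) {
  if (!is.null(sdf)) {
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    natoms <- nrow(ab)
    element <- sub("_.*$", "", rownames(ab))
  } else {
    cnt <- .recordCounts(lines)
    natoms <- cnt[["natoms"]]
    if (is.na(natoms)) stop("malformed counts line")
    element <- trimws(substr(lines[4L + seq_len(natoms)], 32L, 34L))
    bb <- NULL
  }
  charge <- if (natoms) .chargesFromLines(lines, natoms) else integer()

  if (is.null(dim(bb)) && length(bb)) bb <- matrix(bb, nrow = 1L)
  nb <- if (is.null(bb)) 0L else nrow(bb)
  a1 <- a2 <- integer(nb); ord <- character(nb)
  if (nb) {
    a1 <- as.integer(bb[, 1L]); a2 <- as.integer(bb[, 2L])
    ord <- c("single", "double", "triple", "aromatic")[
      pmin(as.integer(bb[, 3L]), 4L)]
  }

  ## fold explicit hydrogens into implicit_h of their heavy partner
  is_h <- element == "H"
  extra_h <- integer(natoms)
  if (any(is_h)) {
    for (k in seq_len(nb)) {
      if (is_h[a1[k]] && !is_h[a2[k]]) extra_h[a2[k]] <- extra_h[a2[k]] + 1L
      if (is_h[a2[k]] && !is_h[a1[k]]) extra_h[a1[k]] <- extra_h[a1[k]] + 1L
    }
    keep <- which(!is_h)
    remap <- integer(natoms); remap[keep] <- seq_along(keep)
    kb <- !(is_h[a1] | is_h[a2])
    a1 <- remap[a1[kb]]; a2 <- remap[a2[kb]]; ord <- ord[kb]
    element <- element[keep]; charge <- charge[keep]
    extra_h <- extra_h[keep]
    natoms <- length(keep); nb <- length(a1)
  }

  ## bond-order sum per heavy atom (aromatic order counts 1.5, floored)
  bsum <- numeric(natoms)
  ordval <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)[ord]
  for (k in seq_len(nb)) {
    bsum[a1[k]] <- bsum[a1[k]] + ordval[k]
    bsum[a2[k]] <- bsum[a2[k]] + ordval[k]
  }
  bsum <- floor(bsum) + extra_h

  implicit_h <- vapply(seq_len(natoms), function(i)
    .implicitH(element[i], charge[i], bsum[i]), integer(1)) + extra_h

  atoms <- data.frame(element = element, charge = charge,
                      implicit_h = implicit_h,
                      hybridization = "other", aromatic = FALSE,
                      ring_min = 0L, stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = a1, a2 = a2, order = ord,
                      in_ring = rep(FALSE, nb), stringsAsFactors = FALSE)

  db <- if (!is.null(sdf)) {
    tryCatch(ChemmineR::datablock(sdf), error = function(e) character())
  } else {
    tag_idx <- grep("^>\\s*<", lines)
    stats::setNames(trimws(lines[tag_idx + 1L]),
                    sub("^>\\s*<([^>]+)>.*$", "\\1", lines[tag_idx]))
  }
  props <- if (length(db)) as.list(db) else list()
  num <- suppressWarnings(lapply(props, function(v) {
    x <- as.numeric(v); if (!is.na(x)) x else v
  }))

  if (is.null(name)) name <- trimws(lines[1L])
  g <- new("MolecularGraph", atoms = atoms, bonds = bonds,
           name = name, properties = num)
  perceiveGraph(g)
}

## ---- readers ------------------------------------------------------------

#' Read molecules from an MDL SDF (V2000) file
#'
#' Each record becomes a perceived [MolecularGraph]. Explicit hydrogens are
#' folded into implicit hydrogen counts; formal charges are taken from the
#' atom-block charge column or \code{M  CHG} lines; SDF data fields are kept
#' in \code{molProperties()}. A malformed record is reported as a warning
#' carrying its record index and the remaining records are still returned.
#'
#' @param path path to an SDF file (multi-record allowed).
#' @return list of \code{MolecularGraph} objects.
#' @examples
#' sdf <- system.file("extdata", "reference_molecules.sdf",
#'                    package = "thermgroups")
#' mols <- readSDF(sdf)
#' mols[[1]]
#' @export
readSDF <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(raw)))) return(list())
  str <- ChemmineR::read.SDFstr(path)
  blocks <- as(str, "list")
  out <- vector("list", length(blocks))
  ok <- logical(length(blocks))
  for (i in seq_along(blocks)) {
    out[[i]] <- tryCatch({
      cnt <- .recordCounts(blocks[[i]])
      if (is.na(cnt[["natoms"]])) stop("malformed counts line")
      sdf <- if (!is.na(cnt[["nbonds"]]) && cnt[["nbonds"]] > 0L) {
        one <- methods::new("SDFstr", a = blocks[i])
        suppressWarnings(ChemmineR::read.SDFset(one))[[1L]]
      } else NULL
      g <- .graphFromRecord(sdf, blocks[[i]])
      ok[i] <- TRUE
      g
    }, error = function(e) {
      warning("SDF record ", i, " could not be parsed: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
  }
  out[ok]
}

#' Read a molecule from a SMILES string
#'
#' The SMILES is converted to a V2000 record through OpenBabel (ChemmineOB)
#' and then follows the same perception path as [readSDF()], so the result
#' is identical (up to atom order) to reading an SDF of the same structure.
#'
#' @param smiles a single SMILES string.
#' @param name molecule name to store.
#' @return a perceived [MolecularGraph].
#' @examples
#' if (requireNamespace("ChemmineOB", quietly = TRUE)) {
#'   readSMILES("CCO", "ethanol")
#' }
#' @export
readSMILES <- function(smiles, name = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("readSMILES requires the ChemmineOB package")
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                     error = function(e)
                       stop("SMILES parse failure for ", sQuote(smiles), ": ",
                            conditionMessage(e), call. = FALSE))
  lines <- ChemmineR::sdfstr2list(methods::as(sdfset, "SDFstr"))[[1L]]
  cnt <- .recordCounts(lines)
  if (is.na(cnt[["natoms"]]) || cnt[["natoms"]] == 0L)
    stop("SMILES parse failure for ", sQuote(smiles))
  sdf <- if (cnt[["nbonds"]] > 0L) sdfset[[1L]] else NULL
  .graphFromRecord(sdf, lines, name = name)
}

## ---- perception ---------------------------------------------------------

.adjacency <- function(g) {
  n <- atomCount(g)
  adj <- vector("list", n)
  b <- g@bonds
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  adj
}

## BFS shortest path from `from` to `to`, not using bond `skip`.
## Returns atom index path or NULL.
.shortestPath <- function(g, adj, from, to, skip) {
  n <- atomCount(g)
  prev <- rep(NA_integer_, n)
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  b <- g@bonds
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (k in adj[[v]]) {
      if (k == skip) next
      w <- if (b$a1[k] == v) b$a2[k] else b$a1[k]
      if (!seen[w]) {
        seen[w] <- TRUE; prev[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

#' Perceive ring membership, aromaticity and hybridization
#'
#' Deterministically annotates a [MolecularGraph]: smallest-ring sizes from
#' shortest cycles through each bond, aromaticity, and hybridization
#' (\code{sp3}/\code{sp2}/\code{sp}/\code{aromatic}). Formal charges are
#' taken from the input and never invented. Aromatic perception operates on
#' the kekulized bond orders of the input and marks six-membered rings in
#' which every atom carries an endocyclic double bond (directly or, for
#' fused systems, a double or aromatic bond into an already-aromatic ring);
#' five-membered heteroaromatic rings (furan, thiophene, pyrrole) are left
#' kekulized, matching the group vocabulary, which describes their atoms as
#' sp2 carbons and pi-decorated sp3-type heteroatom centers. The operation
#' is idempotent.
#'
#' @param g a \code{MolecularGraph}.
#' @return the annotated \code{MolecularGraph}.
#' @export
perceiveGraph <- function(g) {
  n <- atomCount(g); b <- g@bonds
  if (n == 0L) return(g)
  adj <- .adjacency(g)

  ## smallest cycle through each bond
  cyc <- rep(NA_integer_, nrow(b))
  rings6 <- list()
  for (k in seq_len(nrow(b))) {
    p <- .shortestPath(g, adj, b$a1[k], b$a2[k], skip = k)
    if (!is.null(p)) {
      cyc[k] <- length(p)
      if (length(p) == 6L) rings6[[length(rings6) + 1L]] <- p
    }
  }
  rings6 <- unique(lapply(rings6, sort))
  b$in_ring <- !is.na(cyc)
  ring_min <- rep(0L, n)
  for (k in which(b$in_ring)) {
    for (v in c(b$a1[k], b$a2[k]))
      ring_min[v] <- if (ring_min[v] == 0L) cyc[k] else min(ring_min[v], cyc[k])
  }

  ## aromaticity: iterate over candidate 6-rings until no change
  aromatic <- rep(FALSE, n)
  arom_rings <- rep(FALSE, length(rings6))
  repeat {
    changed <- FALSE
    for (ri in seq_along(rings6)) {
      if (arom_rings[ri]) next
      atoms_r <- rings6[[ri]]
      ok <- vapply(atoms_r, function(v) {
        any(vapply(adj[[v]], function(k) {
          w <- if (b$a1[k] == v) b$a2[k] else b$a1[k]
          inring <- w %in% atoms_r
          (b$order[k] == "double" && (inring || aromatic[w])) ||
            (b$order[k] == "aromatic")
        }, logical(1)))
      }, logical(1))
      if (all(ok)) {
        arom_rings[ri] <- TRUE
        aromatic[atoms_r] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  ## relabel endocyclic bonds of aromatic rings
  for (ri in which(arom_rings)) {
    atoms_r <- rings6[[ri]]
    sel <- b$in_ring & b$a1 %in% atoms_r & b$a2 %in% atoms_r &
      b$order %in% c("single", "double", "aromatic")
    b$order[sel] <- "aromatic"
  }

  ## hybridization from (possibly relabelled) bond orders
  hyb <- character(n)
  ndouble <- ntriple <- integer(n)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] == "double") {
      ndouble[b$a1[k]] <- ndouble[b$a1[k]] + 1L
      ndouble[b$a2[k]] <- ndouble[b$a2[k]] + 1L
    } else if (b$order[k] == "triple") {
      ntriple[b$a1[k]] <- ntriple[b$a1[k]] + 1L
      ntriple[b$a2[k]] <- ntriple[b$a2[k]] + 1L
    }
  }
  for (i in seq_len(n)) {
    hyb[i] <- if (aromatic[i]) "aromatic"
      else if (ntriple[i] >= 1L || ndouble[i] >= 2L) "sp"
      else if (ndouble[i] == 1L) "sp2"
      else "sp3"
  }

  g@atoms$hybridization <- hyb
  g@atoms$aromatic <- aromatic
  g@atoms$ring_min <- ring_min
  g@bonds <- b
  methods::validObject(g)
  g
}

## ---- fixture SDF writer -------------------------------------------------

#' Write molecular graphs to an SDF (V2000) file
#'
#' Minimal V2000 writer used for fixture round trips and data export.
#' Coordinates are written as zeros (the models are purely topological);
#' aromatic bonds use order 4; formal charges are emitted as \code{M  CHG}
#' lines; numeric properties become SDF data fields (dialect:
#' \code{EXP_VALUE}, \code{DESCRIPTOR}, \code{UNITS}, or any other tag
#' present in \code{molProperties}).
#'
#' @param graphs list of \code{MolecularGraph} objects (or a single one).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSDF <- function(graphs, path) {
  if (methods::is(graphs, "MolecularGraph")) graphs <- list(graphs)
  con <- file(path, "w"); on.exit(close(con))
  for (g in graphs) {
    a <- g@atoms; b <- g@bonds
    writeLines(c(molName(g), "  thermgroups", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    for (i in seq_len(nrow(a)))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, a$element[i]), con)
    ordnum <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)
    for (k in seq_len(nrow(b)))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$a1[k], b$a2[k],
                         ordnum[[b$order[k]]]), con)
    chg <- which(a$charge != 0L)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, a$charge[chg]),
                               collapse = "")), con)
    writeLines("M  END", con)
    props <- molProperties(g)
    for (tag in names(props))
      writeLines(c(paste0(">  <", tag, ">"),
                   as.character(props[[tag]]), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}
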