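#' @include AllGenerics.R
NULL

#' Construct a StructureSet from an atom table
#'
#' @param atoms data.frame with columns \code{chain, resno, resid, elety,
#'   element, x, y, z, b} (file order).
#' @param source optional label for the origin of the records.
#' @return a \linkS4class{StructureSet}.
#' @export
StructureSet <- function(atoms, source = NA_character_) {
  atoms <- as.data.frame(atoms)
  if (nrow(atoms)) {
    atoms$chain <- as.character(atoms$chain)
    atoms$elety <- as.character(atoms$elety)
    atoms$element <- as.character(atoms$element)
    rownames(atoms) <- NULL
  }
  new("StructureSet", atoms = atoms, source = as.character(source)[1])
}

#' @describeIn chainIds chain ids in order of first appearance
#' @export
setMethod("chainIds", "StructureSet", function(x) unique(x@atoms$chain))

#' @describeIn chainAtoms atoms of the requested chain, file order
#' @export
setMethod("chainAtoms", "StructureSet", function(x, id) {
  out <- x@atoms[x@atoms$chain == id, , drop = FALSE]
  rownames(out) <- NULL
  out
})

#' @describeIn nAtoms total number of atoms
#' @export
setMethod("nAtoms", "StructureSet", function(x) nrow(x@atoms))

setMethod("show", "StructureSet", function(object) {
  cat("StructureSet with", nAtoms(object), "atoms in",
      length(chainIds(object)), "chain(s)\n")
  if (!is.na(object@source)) cat("source:", object@source, "\n")
  for (id in chainIds(object)) {
    a <- chainAtoms(object, id)
    cat(sprintf("  chain %s: %d atoms, %d residues\n",
                id, nrow(a), length(unique(a$resno))))
  }
  invisible(NULL)
})

# element symbol from the atom-name column when the element column is absent
# or blank; quotes/asterisks/digits are decoration, the leading letter is the
# element for the organic set handled here
.element_from_name <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", elety)
  first <- toupper(substr(nm, 1L, 1L))
  ifelse(first %in% c(HEAVY_ELEMENTS, "H"), first,
         ifelse(first == "", "other", "other"))
}

.normalize_element <- function(elesy, elety) {
  elesy <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  known <- elesy %in% c(HEAVY_ELEMENTS, "H")
  blank <- elesy == ""
  out <- character(length(elesy))
  out[known] <- elesy[known]
  out[!known & !blank] <- "other"   # a filled element column is trusted
  out[blank] <- .element_from_name(elety)[blank]
  out
}

#' Read an atomic structure from a PDB file
#'
#' Parses fixed-column ATOM (and optionally HETATM) records into a
#' \linkS4class{StructureSet}. Alternate locations keep the first-listed
#' conformer per atom; hydrogens are retained (filter them later with
#' \code{\link{selectHeavyAtoms}}); for multi-model files only the first
#' model is used. The element is taken from the element column (77-78) when
#' present, otherwise derived from the atom name.
#'
#' @param path PDB file path.
#' @param includeHetatm keep HETATM records (default FALSE: RNA chains only).
#' @return a \linkS4class{StructureSet}.
#' @export
readStructure <- function(path, includeHetatm = FALSE) {
  if (!file.exists(path)) stop("cannot read structure: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("no atoms parsed from ", path, call. = FALSE))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0L) stop("no atoms parsed from ", path)
  if (!includeHetatm) a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms parsed from ", path)
  bad <- !is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)
  if (any(bad)) {
    warning(sum(bad), " record(s) with unparseable coordinates skipped")
    a <- a[!bad, , drop = FALSE]
  }
  if (nrow(a) == 0L) stop("no atoms parsed from ", path)
  # first-listed altloc per atom site
  key <- paste(a$chain, a$resno, a$insert, trimws(a$elety), sep = "\r")
  a <- a[!duplicated(key), , drop = FALSE]
  chain <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  b <- suppressWarnings(as.numeric(a$b))
  b[!is.finite(b)] <- 0
  atoms <- data.frame(
    chain = chain,
    resno = as.integer(a$resno),
    resid = as.character(a$resid),
    elety = trimws(as.character(a$elety)),
    element = .normalize_element(a$elesy, trimws(as.character(a$elety))),
    x = a$x, y = a$y, z = a$z, b = b,
    stringsAsFactors = FALSE)
  StructureSet(atoms, source = path)
}

#' Write a StructureSet to a PDB file
#'
#' Emits fixed-column ATOM records (coordinates to 3 decimals, B-factors to
#' 2); \code{readStructure(writeStructure(x))} reproduces every atom field to
#' that format precision.
#'
#' @param x a \linkS4class{StructureSet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeStructure <- function(x, path) {
  a <- x@atoms
  if (nrow(a) == 0L) stop("refusing to write an empty StructureSet")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z) &
           is.finite(a$b)))
    stop("non-finite coordinates or B-factors; not writing ", path)
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = rep("ATOM", nrow(a)),
    resno = a$resno, resid = a$resid,
    eleno = seq_len(nrow(a)), elety = a$elety,
    chain = a$chain, o = rep(1, nrow(a)), b = a$b,
    elesy = ifelse(a$element %in% c(HEAVY_ELEMENTS, "H"), a$element, ""))
  invisible(path)
}

#' Filter a chain (or structure) to heavy atoms
#'
#' Keeps atoms whose element lies in the given set, preserving order.
#' Hydrogens are excluded by the default set; the operation is idempotent.
#'
#' @param atoms data.frame of atoms (one chain) or a
#'   \linkS4class{StructureSet}.
#' @param elements element set to keep (default C, N, O, P).
#' @return object of the same kind as \code{atoms}, filtered.
#' @export
selectHeavyAtoms <- function(atoms, elements = HEAVY_ELEMENTS) {
  if (is(atoms, "StructureSet")) {
    keep <- atoms@atoms$element %in% elements
    return(StructureSet(atoms@atoms[keep, , drop = FALSE], atoms@source))
  }
  out <- atoms[atoms$element %in% elements, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate the per-nucleotide sample atoms of a chain
#'
#' The flexibility of each nucleotide is represented by its ribose C1' atom.
#' Atom names are matched after whitespace-stripping with priority
#' \code{C1'}, then the legacy \code{C1*}, then bare \code{C1}; the first
#' naming convention with any match is used for the whole chain.
#'
#' @param atoms data.frame of one chain's atoms.
#' @return data.frame of sample atoms in residue order (possibly empty).
#' @export
findSampleAtoms <- function(atoms) {
  nm <- trimws(atoms$elety)
  for (alias in c("C1'", "C1*", "C1")) {
    hit <- nm == alias
    if (any(hit)) {
      out <- atoms[hit, , drop = FALSE]
      out <- out[order(out$resno), , drop = FALSE]
      rownames(out) <- NULL
      return(out)
    }
  }
  atoms[integer(0), , drop = FALSE]
}
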